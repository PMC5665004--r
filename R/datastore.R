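## Relational store: table schemas, users/roles, audit, barcode registry,
## workflow status, persistence as a directory of UTF-8 CSVs.

.WORKFLOW_STATUSES <- c("imaged", "transcribed", "normalized", "georeferenced", "exported")
.USER_ROLES <- c("transcriber", "georeferencer", "scrutineer", "data_manager")

# column prototypes per table; also drives CSV round-trip typing
.storeSchemas <- function() list(
  barcodes = data.frame(code = character(), state = character(),
                        stringsAsFactors = FALSE),
  users = data.frame(name = character(), roles = character(), stringsAsFactors = FALSE),
  specimens = data.frame(
    id = integer(), barcode = character(), drawer = character(),
    taxon_variant_id = integer(), site_variant_id = integer(),
    collector_ids = character(), date_verbatim = character(),
    date_start = character(), date_end = character(),
    registration = character(), type_status = character(),
    breeding_info = character(), status = character(),
    assigned_to = character(), flags = character(),
    cms_irn = integer(), pre_databased = logical(), stringsAsFactors = FALSE),
  images = data.frame(
    id = integer(), path = character(), role = character(),
    width = integer(), height = integer(), specimen_id = integer(),
    cms_irn = integer(), stringsAsFactors = FALSE),
  processed = data.frame(hash = character(), path = character(), stringsAsFactors = FALSE),
  site_variants = data.frame(id = integer(), name = character(),
                             master_id = integer(), stringsAsFactors = FALSE),
  site_masters = data.frame(
    id = integer(), name = character(), lat = numeric(), lon = numeric(),
    extent_m = numeric(), method = character(), georef_by = character(),
    ungeoreferenceable = logical(), note = character(), cms_irn = integer(),
    stringsAsFactors = FALSE),
  taxon_variants = data.frame(id = integer(), name = character(),
                              master_id = integer(), stringsAsFactors = FALSE),
  taxon_masters = data.frame(id = integer(), name = character(),
                             cms_irn = integer(), stringsAsFactors = FALSE),
  collectors = data.frame(id = integer(), name = character(), cms_irn = integer(),
                          stringsAsFactors = FALSE),
  collection_events = data.frame(id = integer(), specimen_id = integer(),
                                 cms_irn = integer(), stringsAsFactors = FALSE),
  locations = data.frame(id = integer(), name = character(), cms_irn = integer(),
                         stringsAsFactors = FALSE),
  audit = data.frame(seq = integer(), who = character(), time = character(),
                     action = character(), detail = character(), stringsAsFactors = FALSE)
)

#' Create an empty digitisation store
#'
#' @param project Project name, recorded in the store config.
#' @param barcodePrefix Prefix of issued barcodes; the payload is the prefix
#'   followed by a zero-padded counter.
#' @param barcodeDigits Width of the zero-padded numeric part.
#' @param barcodeStart Numeric value of the first barcode to issue.
#' @return A \code{\linkS4class{DigiStore}}.
#' @examples
#' store <- createStore("demo")
#' store
#' @export
createStore <- function(project = "digitisation", barcodePrefix = "NHMUK",
                        barcodeDigits = 9L, barcodeStart = 10000001L) {
  env <- new.env(parent = emptyenv())
  for (nm in names(.storeSchemas())) env[[nm]] <- .storeSchemas()[[nm]]
  env$.counters <- list(specimens = 0L, images = 0L, site_variants = 0L,
                        site_masters = 0L, taxon_variants = 0L, taxon_masters = 0L,
                        collectors = 0L, collection_events = 0L, locations = 0L,
                        audit = 0L, barcode = as.integer(barcodeStart) - 1L)
  env$.readonly <- FALSE
  new("DigiStore", tables = env,
      config = list(project = project, barcodePrefix = barcodePrefix,
                    barcodeDigits = as.integer(barcodeDigits)))
}

.requireWritable <- function(store) {
  if (isTRUE(store@tables$.readonly)) stop("store is archived and read-only")
}

.nextId <- function(store, counter) {
  v <- store@tables$.counters[[counter]] + 1L
  store@tables$.counters[[counter]] <- v
  v
}

.audit <- function(store, who, action, detail = "") {
  .requireWritable(store)
  t <- store@tables
  t$audit <- rbind(t$audit, data.frame(
    seq = .nextId(store, "audit"), who = who,
    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    action = action, detail = detail, stringsAsFactors = FALSE))
  invisible(NULL)
}

#' Add a user account with one or more roles
#'
#' @param store A \code{\linkS4class{DigiStore}}.
#' @param name User name (unique).
#' @param roles Character vector drawn from transcriber, georeferencer,
#'   scrutineer, data_manager.
#' @return The store, invisibly.
#' @export
addUser <- function(store, name, roles) {
  .requireWritable(store)
  roles <- match.arg(roles, .USER_ROLES, several.ok = TRUE)
  t <- store@tables
  if (name %in% t$users$name) stop("user already exists: ", name)
  t$users <- rbind(t$users, data.frame(name = name, roles = .joinMulti(roles),
                                       stringsAsFactors = FALSE))
  .audit(store, "system", "add_user", paste(name, .joinMulti(roles)))
  invisible(store)
}

#' User roles
#' @param store A \code{\linkS4class{DigiStore}}.
#' @param name User name.
#' @return Character vector of roles.
#' @export
userRoles <- function(store, name) {
  u <- store@tables$users
  i <- match(name, u$name)
  if (is.na(i)) stop("unknown user: ", name)
  .splitMulti(u$roles[i])
}

.requireRole <- function(store, user, role) {
  if (!role %in% userRoles(store, user))
    stop(sprintf("user '%s' lacks required role '%s'", user, role))
}

## ---- barcode registry ----

.formatBarcode <- function(store, n) {
  sprintf(paste0("%s%0", store@config$barcodeDigits, "d"), store@config$barcodePrefix, n)
}

#' Allocate fresh unique barcodes
#'
#' Issues \code{n} new codes with strictly increasing numeric parts. The
#' counter never rewinds, so a code, once issued, is never issued again --
#' discarded codes in particular are never re-used.
#'
#' @param store A \code{\linkS4class{DigiStore}}.
#' @param user Caller; requires the data_manager role.
#' @param n Number of codes, >= 1.
#' @return Character vector of \code{n} codes in state "allocated".
#' @export
allocateBarcodes <- function(store, user, n) {
  .requireWritable(store)
  .requireRole(store, user, "data_manager")
  if (!.isCount(n)) stop("n must be a positive integer")
  t <- store@tables
  base <- store@tables$.counters$barcode
  codes <- .formatBarcode(store, base + seq_len(n))
  store@tables$.counters$barcode <- base + as.integer(n)
  t$barcodes <- rbind(t$barcodes, data.frame(code = codes, state = "allocated",
                                             stringsAsFactors = FALSE))
  .audit(store, user, "allocate_barcodes", sprintf("%d codes from %s", n, codes[1L]))
  codes
}

#' Discard allocated barcodes
#'
#' Used when printed labels are misplaced: the codes become unusable and are
#' never re-issued. Codes already attached to a specimen cannot be discarded.
#'
#' @inheritParams allocateBarcodes
#' @param codes Codes in state "allocated".
#' @return Number of codes discarded.
#' @export
discardBarcodes <- function(store, user, codes) {
  .requireWritable(store)
  .requireRole(store, user, "data_manager")
  if (length(codes) == 0L) return(0L)
  t <- store@tables
  i <- match(codes, t$barcodes$code)
  if (anyNA(i)) stop("unknown barcode(s): ", paste(codes[is.na(i)], collapse = ", "))
  st <- t$barcodes$state[i]
  if (any(st == "attached"))
    stop("conflict: cannot discard attached barcode(s): ",
         paste(codes[st == "attached"], collapse = ", "))
  t$barcodes$state[i] <- "discarded"
  .audit(store, user, "discard_barcodes", paste(codes, collapse = ","))
  length(codes)
}

# register a code as attached to a physical specimen; codes may have been
# printed by another instance, so unknown codes are registered on the fly
.attachBarcode <- function(store, code) {
  t <- store@tables
  i <- match(code, t$barcodes$code)
  if (is.na(i)) {
    t$barcodes <- rbind(t$barcodes, data.frame(code = code, state = "attached",
                                               stringsAsFactors = FALSE))
    return(TRUE)
  }
  if (t$barcodes$state[i] == "discarded") stop("barcode was discarded: ", code)
  if (t$barcodes$state[i] == "attached") return(FALSE)  # collision
  t$barcodes$state[i] <- "attached"
  TRUE
}

.barcodeState <- function(store, code) {
  t <- store@tables
  i <- match(code, t$barcodes$code)
  if (is.na(i)) NA_character_ else t$barcodes$state[i]
}

## ---- workflow status ----

#' Advance a specimen along the workflow
#'
#' The workflow order is imaged < transcribed < normalized < georeferenced <
#' exported. Transitions are monotone: moving backwards is refused, repeats
#' are no-ops, and skipped stages are noted in the audit trail.
#'
#' @param store A \code{\linkS4class{DigiStore}}.
#' @param specimenId Specimen id.
#' @param newStatus Target status.
#' @param user Actor recorded in the audit log.
#' @return The updated specimen row, invisibly.
#' @export
setSpecimenStatus <- function(store, specimenId, newStatus, user = "system") {
  .requireWritable(store)
  newStatus <- match.arg(newStatus, .WORKFLOW_STATUSES)
  t <- store@tables
  i <- match(specimenId, t$specimens$id)
  if (is.na(i)) stop("unknown specimen: ", specimenId)
  cur <- match(t$specimens$status[i], .WORKFLOW_STATUSES)
  new <- match(newStatus, .WORKFLOW_STATUSES)
  if (new < cur)
    stop(sprintf("backward status transition refused: %s -> %s",
                 t$specimens$status[i], newStatus))
  if (new > cur) {
    skipped <- if (new - cur > 1L) .WORKFLOW_STATUSES[(cur + 1L):(new - 1L)] else character(0L)
    t$specimens$status[i] <- newStatus
    .audit(store, user, "set_status",
           sprintf("specimen %d: %s -> %s%s", specimenId,
                   .WORKFLOW_STATUSES[cur], newStatus,
                   if (length(skipped)) paste0(" (skipped: ", paste(skipped, collapse = ","), ")") else ""))
  }
  invisible(t$specimens[i, ])
}

.addFlag <- function(store, specimenId, flag) {
  t <- store@tables
  i <- match(specimenId, t$specimens$id)
  cur <- .splitMulti(t$specimens$flags[i])
  t$specimens$flags[i] <- .joinMulti(union(cur, flag)) %||% flag
  invisible(NULL)
}

.hasFlag <- function(store, specimenId, flag) {
  i <- match(specimenId, store@tables$specimens$id)
  flag %in% .splitMulti(store@tables$specimens$flags[i])
}

## ---- get-or-create lookups ----

# exact, case-sensitive matching: verbatim strings are deliberately not
# normalised at capture time
.getOrCreate <- function(store, table, name, counter = table) {
  t <- store@tables
  i <- match(name, t[[table]]$name)
  if (!is.na(i)) return(list(id = t[[table]]$id[i], created = FALSE))
  id <- .nextId(store, counter)
  row <- .storeSchemas()[[table]][0, ]
  row[1L, "id"] <- id
  row[1L, "name"] <- name
  if ("ungeoreferenceable" %in% names(row)) row[1L, "ungeoreferenceable"] <- FALSE
  t[[table]] <- rbind(t[[table]], row)
  list(id = id, created = TRUE)
}

## ---- referential integrity ----

# which (table, column) pairs reference which target table
.refMap <- list(
  specimens = list(c("images", "specimen_id"), c("collection_events", "specimen_id")),
  site_variants = list(c("specimens", "site_variant_id")),
  site_masters = list(c("site_variants", "master_id")),
  taxon_variants = list(c("specimens", "taxon_variant_id")),
  taxon_masters = list(c("taxon_variants", "master_id"))
)

#' Delete a row, refusing when it is referenced elsewhere
#'
#' @param store A \code{\linkS4class{DigiStore}}.
#' @param table Table name.
#' @param id Row id.
#' @return TRUE invisibly on success.
#' @export
deleteRow <- function(store, table, id) {
  .requireWritable(store)
  t <- store@tables
  if (is.null(t[[table]])) stop("unknown table: ", table)
  refs <- .refMap[[table]] %||% list()
  for (r in refs) {
    col <- t[[r[1L]]][[r[2L]]]
    if (id %in% col[!is.na(col)])
      stop(sprintf("cannot delete %s %s: referenced by %s.%s", table, id, r[1L], r[2L]))
  }
  # collectors are referenced via the multi-valued specimens.collector_ids
  if (table == "collectors") {
    used <- unlist(lapply(t$specimens$collector_ids, .splitMulti))
    if (as.character(id) %in% used)
      stop(sprintf("cannot delete collectors %s: referenced by specimens.collector_ids", id))
  }
  i <- match(id, t[[table]]$id)
  if (is.na(i)) stop("no such row")
  t[[table]] <- t[[table]][-i, , drop = FALSE]
  invisible(TRUE)
}

## ---- persistence ----

#' Save a store as a directory of CSV files
#'
#' Every table is written as a UTF-8, header-rowed, comma-separated file;
#' counters and config go to \code{meta.yaml}. The layout is the store's
#' interchange format as well as its persistence format.
#'
#' @param store A \code{\linkS4class{DigiStore}}.
#' @param dir Target directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
saveStore <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  t <- store@tables
  for (nm in names(.storeSchemas())) {
    utils::write.csv(t[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, fileEncoding = "UTF-8", na = "")
  }
  yaml::write_yaml(list(config = store@config, counters = t$.counters,
                        readonly = isTRUE(t$.readonly)),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Load a store saved with \code{\link{saveStore}}
#'
#' @param dir Directory written by \code{\link{saveStore}}.
#' @return A \code{\linkS4class{DigiStore}}.
#' @export
loadStore <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  store <- createStore(project = meta$config$project,
                       barcodePrefix = meta$config$barcodePrefix,
                       barcodeDigits = meta$config$barcodeDigits)
  t <- store@tables
  schemas <- .storeSchemas()
  for (nm in names(schemas)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    proto <- schemas[[nm]]
    df <- utils::read.csv(f, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                          colClasses = vapply(proto, function(x) class(x)[1L], ""))
    # NA was written as ""; restore it, except where "" is a real value
    for (cc in names(proto)) {
      if (is.character(proto[[cc]]) && !cc %in% c("flags", "detail"))
        df[[cc]][!is.na(df[[cc]]) & df[[cc]] == ""] <- NA_character_
    }
    t[[nm]] <- df
  }
  t$.counters <- lapply(meta$counters, as.integer)
  t$.readonly <- isTRUE(meta$readonly)
  store
}

#' Export any table as CSV
#'
#' @param store A \code{\linkS4class{DigiStore}}.
#' @param table Table name.
#' @param file Target file.
#' @return \code{file}, invisibly.
#' @export
exportTable <- function(store, table, file) {
  if (is.null(store@tables[[table]])) stop("unknown table: ", table)
  utils::write.csv(store@tables[[table]], file, row.names = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(file)
}
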