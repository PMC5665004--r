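## CMS ingest round-trip: dependency-ordered export of new entities as CSV
## reports, IRN import-back, match-or-create policies per entity type,
## embargo filtering and Darwin Core occurrence publication, and project
## archiving. The CMS itself is emulated by MockCms, which assigns
## sequential IRNs and applies the same per-entity matching policies the
## production ingest used.

.ENTITY_TYPES <- c("multimedia", "parties", "taxonomy", "sites",
                   "collection_events", "locations", "catalogue")

# reference graph: a type can be exported only after the types it references
.ENTITY_DEPS <- list(
  multimedia = character(0L),
  parties = character(0L),
  taxonomy = character(0L),
  sites = character(0L),
  locations = character(0L),
  collection_events = c("sites", "parties"),
  catalogue = c("taxonomy", "sites", "collection_events", "parties",
                "multimedia", "locations")
)

.ENTITY_POLICY <- c(multimedia = "create_new", parties = "match_or_create",
                    taxonomy = "match_or_create", sites = "create_new",
                    collection_events = "create_new", locations = "match_existing",
                    catalogue = "create_new")

#' Is an export order consistent with the entity reference graph?
#'
#' @param order Character vector of entity types in proposed export order.
#' @return TRUE iff every type appears after all types it references.
#' @export
exportOrderOk <- function(order) {
  for (i in seq_along(order)) {
    deps <- .ENTITY_DEPS[[order[i]]]
    if (!all(deps %in% order[seq_len(i - 1L)])) return(FALSE)
  }
  all(.ENTITY_TYPES %in% order)
}

# the store-side table and key columns behind each entity type
.entityTable <- function(type) {
  switch(type,
         multimedia = "images", parties = "collectors", taxonomy = "taxon_masters",
         sites = "site_masters", collection_events = "collection_events",
         locations = "locations", catalogue = "specimens")
}

.irnComplete <- function(store, type) {
  tab <- store@tables[[.entityTable(type)]]
  # derived tables that have not been materialised yet are incomplete
  if (type %in% c("collection_events", "locations") && nrow(tab) == 0L &&
      nrow(store@tables$specimens) > 0L) return(FALSE)
  all(!is.na(tab$cms_irn))
}

# lazily materialise collection events (one per specimen) and drawer
# location rows before their first export
.materialiseDerived <- function(store, type) {
  t <- store@tables
  if (type == "collection_events" && nrow(t$collection_events) == 0L) {
    for (sid in t$specimens$id) {
      t$collection_events <- rbind(t$collection_events, data.frame(
        id = .nextId(store, "collection_events"), specimen_id = sid,
        cms_irn = NA_integer_, stringsAsFactors = FALSE))
    }
  }
  if (type == "locations" && nrow(t$locations) == 0L) {
    for (d in sort(unique(t$specimens$drawer))) {
      t$locations <- rbind(t$locations, data.frame(
        id = .nextId(store, "locations"), name = d, cms_irn = NA_integer_,
        stringsAsFactors = FALSE))
    }
  }
}

#' Export new records of one entity type as a CSV report
#'
#' Emits the rows of the given type that do not yet carry a CMS IRN, with a
#' stable \code{local_id} column for round-trip matching. Export is refused
#' (naming the blocking types) until every type the entity references has a
#' complete IRN map -- records must exist in the CMS before being
#' referenced. Exporting the catalogue marks its specimens "exported".
#'
#' @param store A \code{\linkS4class{DigiStore}}.
#' @param type One of multimedia, parties, taxonomy, sites,
#'   collection_events, locations, catalogue.
#' @param file Optional CSV path to write.
#' @return data.frame of records lacking an IRN.
#' @export
exportNewEntities <- function(store, type, file = NULL) {
  type <- match.arg(type, .ENTITY_TYPES)
  t <- store@tables
  blockers <- Filter(function(d) !.irnComplete(store, d), .ENTITY_DEPS[[type]])
  if (length(blockers))
    stop("cannot export ", type, ": missing IRNs for ", paste(blockers, collapse = ", "))
  .materialiseDerived(store, type)
  tab <- t[[.entityTable(type)]]
  new <- tab[is.na(tab$cms_irn), , drop = FALSE]

  out <- switch(type,
    multimedia = data.frame(local_id = new$id, path = new$path, role = new$role,
                            stringsAsFactors = FALSE),
    parties = data.frame(local_id = new$id, name = new$name, stringsAsFactors = FALSE),
    taxonomy = data.frame(local_id = new$id, name = new$name, stringsAsFactors = FALSE),
    sites = {
      data.frame(local_id = new$id, name = new$name, lat = new$lat, lon = new$lon,
                 extent_m = new$extent_m, stringsAsFactors = FALSE)
    },
    locations = data.frame(local_id = new$id, name = new$name, stringsAsFactors = FALSE),
    collection_events = {
      s <- t$specimens[match(new$specimen_id, t$specimens$id), ]
      sv <- t$site_variants[match(s$site_variant_id, t$site_variants$id), ]
      siteIrn <- t$site_masters$cms_irn[match(sv$master_id, t$site_masters$id)]
      data.frame(local_id = new$id, site_irn = siteIrn,
                 date_start = s$date_start, date_end = s$date_end,
                 stringsAsFactors = FALSE)
    },
    catalogue = {
      s <- new
      tv <- t$taxon_variants[match(s$taxon_variant_id, t$taxon_variants$id), ]
      taxIrn <- t$taxon_masters$cms_irn[match(tv$master_id, t$taxon_masters$id)]
      sv <- t$site_variants[match(s$site_variant_id, t$site_variants$id), ]
      siteIrn <- t$site_masters$cms_irn[match(sv$master_id, t$site_masters$id)]
      evIrn <- t$collection_events$cms_irn[match(s$id, t$collection_events$specimen_id)]
      locIrn <- t$locations$cms_irn[match(s$drawer, t$locations$name)]
      data.frame(local_id = s$id, barcode = s$barcode, registration = s$registration,
                 taxonomy_irn = taxIrn, site_irn = siteIrn,
                 collection_event_irn = evIrn, location_irn = locIrn,
                 stringsAsFactors = FALSE)
    })
  if (type == "catalogue") {
    for (sid in new$id) setSpecimenStatus(store, sid, "exported", "system")
  }
  .audit(store, "system", "export_new_entities", sprintf("%s: %d rows", type, nrow(out)))
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE,
                                       fileEncoding = "UTF-8", na = "")
  out
}

#' Import IRNs returned by the CMS
#'
#' Links returned (local_id, irn) pairs back onto the store's records.
#' Rows with unknown local ids are rejected and logged; duplicate IRNs
#' within a type are rejected; re-importing the same file links nothing
#' new.
#'
#' @param store A \code{\linkS4class{DigiStore}}.
#' @param type Entity type.
#' @param irns data.frame with columns local_id, irn, or a CSV path.
#' @return Number of records newly linked.
#' @export
importIrns <- function(store, type, irns) {
  type <- match.arg(type, .ENTITY_TYPES)
  .requireWritable(store)
  if (is.character(irns)) irns <- utils::read.csv(irns, stringsAsFactors = FALSE)
  t <- store@tables
  tabName <- .entityTable(type)
  tab <- t[[tabName]]
  linked <- 0L
  for (k in seq_len(nrow(irns))) {
    lid <- irns$local_id[k]
    irn <- as.integer(irns$irn[k])
    i <- match(lid, tab$id)
    if (is.na(i)) {
      .audit(store, "system", "import_irns_rejected", sprintf("%s local_id %s unknown", type, lid))
      next
    }
    if (is.na(irn)) next
    if (!is.na(tab$cms_irn[i])) next                      # already linked: idempotent
    if (irn %in% tab$cms_irn[!is.na(tab$cms_irn)]) {
      .audit(store, "system", "import_irns_rejected", sprintf("%s duplicate irn %d", type, irn))
      next
    }
    tab$cms_irn[i] <- irn
    linked <- linked + 1L
  }
  t[[tabName]] <- tab
  .audit(store, "system", "import_irns", sprintf("%s: %d linked of %d rows", type, linked, nrow(irns)))
  linked
}

## ---- mock CMS ----

#' Create an empty mock CMS
#'
#' @return A \code{\linkS4class{MockCms}}.
#' @export
createMockCms <- function() {
  env <- new.env(parent = emptyenv())
  for (tp in .ENTITY_TYPES) env[[tp]] <- data.frame(irn = integer(), key = character(),
                                                    stringsAsFactors = FALSE)
  env$.irn <- 0L
  new("MockCms", tables = env)
}

#' Pre-seed CMS records of a type
#'
#' Used to emulate pre-existing institutional records: drawer locations to
#' match against, already-known taxa and parties, and legacy catalogue
#' records keyed by registration number.
#'
#' @param cms A \code{\linkS4class{MockCms}}.
#' @param type Entity type.
#' @param keys Character keys (names, drawer codes or registrations).
#' @return Integer IRNs assigned, invisibly.
#' @export
cmsSeed <- function(cms, type, keys) {
  type <- match.arg(type, .ENTITY_TYPES)
  t <- cms@tables
  irns <- t$.irn + seq_along(keys)
  t$.irn <- t$.irn + length(keys)
  t[[type]] <- rbind(t[[type]], data.frame(irn = irns, key = as.character(keys),
                                           stringsAsFactors = FALSE))
  invisible(irns)
}

#' Ingest an export report into the mock CMS
#'
#' Applies the per-entity policy of the production ingest: catalogue,
#' collection events, sites and multimedia are always created new; taxonomy
#' and parties are matched by exact key, created when unmatched; locations
#' are matched to existing records only -- an unmatched location row gets no
#' IRN and is reported.
#'
#' @param cms A \code{\linkS4class{MockCms}}.
#' @param type Entity type.
#' @param report data.frame from \code{\link{exportNewEntities}}.
#' @return data.frame with columns local_id, irn (NA where match_existing
#'   found nothing).
#' @export
cmsIngest <- function(cms, type, report) {
  type <- match.arg(type, .ENTITY_TYPES)
  t <- cms@tables
  policy <- .ENTITY_POLICY[[type]]
  keyCol <- if ("name" %in% names(report)) "name" else "local_id"
  irns <- integer(nrow(report))
  for (k in seq_len(nrow(report))) {
    key <- as.character(report[[keyCol]][k])
    existing <- t[[type]]$irn[match(key, t[[type]]$key)]
    if (policy == "match_existing") {
      irns[k] <- if (is.na(existing)) NA_integer_ else existing
    } else if (policy == "match_or_create" && !is.na(existing)) {
      irns[k] <- existing
    } else {
      t$.irn <- t$.irn + 1L
      t[[type]] <- rbind(t[[type]], data.frame(irn = t$.irn, key = key,
                                               stringsAsFactors = FALSE))
      irns[k] <- t$.irn
    }
  }
  data.frame(local_id = report$local_id, irn = irns, stringsAsFactors = FALSE)
}

#' Delete and replace pre-existing CMS specimen records
#'
#' Legacy specimen records (matched by registration number) are removed
#' from the CMS catalogue before the new catalogue export, so the fresh
#' records replace rather than duplicate them. The action is audited.
#'
#' @param cms A \code{\linkS4class{MockCms}}.
#' @param store A \code{\linkS4class{DigiStore}} (for role check and audit).
#' @param user Caller; requires the data_manager role.
#' @param registrations Character registration numbers.
#' @return Number of CMS records deleted.
#' @export
replaceExistingSpecimens <- function(cms, store, user, registrations) {
  .requireRole(store, user, "data_manager")
  t <- cms@tables
  hit <- t$catalogue$key %in% registrations
  ndel <- sum(hit)
  if (ndel == 0L && length(registrations) > 0L)
    warning("no pre-existing specimen records matched")
  t$catalogue <- t$catalogue[!hit, , drop = FALSE]
  .audit(store, user, "replace_existing_specimens",
         sprintf("%d CMS records deleted of %d registrations", ndel, length(registrations)))
  ndel
}

## ---- publication ----

#' Embargo rule constructors
#'
#' An embargo rule is a predicate over a specimen row: TRUE means withhold
#' from publication (the record stays in the store). \code{embargoYearFrom}
#' withholds specimens collected in or after a cutoff year;
#' \code{embargoTaxa} withholds named taxa (matched on the taxon master).
#'
#' @param cutoffYear First withheld collection year.
#' @return A predicate function(data.frame row) -> logical.
#' @export
embargoYearFrom <- function(cutoffYear) {
  function(rec) {
    y <- suppressWarnings(as.integer(substr(rec$date_start, 1L, 4L)))
    !is.na(y) & y >= cutoffYear
  }
}

#' @rdname embargoYearFrom
#' @param taxa Character vector of withheld taxon master names.
#' @export
embargoTaxa <- function(taxa) {
  function(rec) !is.na(rec$scientificName) & rec$scientificName %in% taxa
}

#' Publish occurrence records as a Darwin Core table
#'
#' One row per exported, non-embargoed specimen, with Darwin Core column
#' names: occurrenceID (the barcode), scientificName (taxon master),
#' verbatimLocality (the untouched verbatim site string), locality (site
#' master), decimalLatitude/Longitude, coordinateUncertaintyInMeters (the
#' extent radius), eventDate (ISO interval), verbatimEventDate and
#' recordedBy. Withheld records appear in no output but remain in the
#' store.
#'
#' @param store A \code{\linkS4class{DigiStore}}.
#' @param embargoRules List of predicate functions (see
#'   \code{\link{embargoYearFrom}}).
#' @param file Optional CSV path to write (UTF-8, RFC 4180 quoting).
#' @return data.frame of occurrence rows.
#' @export
publishOccurrences <- function(store, embargoRules = list(), file = NULL) {
  t <- store@tables
  s <- t$specimens[t$specimens$status == "exported", , drop = FALSE]
  if (nrow(s) == 0L) stop("no exported specimens to publish")
  tv <- t$taxon_variants[match(s$taxon_variant_id, t$taxon_variants$id), ]
  tm <- t$taxon_masters$name[match(tv$master_id, t$taxon_masters$id)]
  sv <- t$site_variants[match(s$site_variant_id, t$site_variants$id), ]
  sm <- t$site_masters[match(sv$master_id, t$site_masters$id), ]
  recBy <- vapply(s$collector_ids, function(ids) {
    ids <- .splitMulti(ids)
    if (!length(ids)) return(NA_character_)
    paste(t$collectors$name[match(as.integer(ids), t$collectors$id)], collapse = " | ")
  }, "", USE.NAMES = FALSE)
  eventDate <- ifelse(is.na(s$date_start), NA_character_,
                      ifelse(s$date_start == s$date_end, s$date_start,
                             paste0(s$date_start, "/", s$date_end)))
  occ <- data.frame(
    occurrenceID = s$barcode,
    scientificName = ifelse(is.na(tm), tv$name, tm),
    verbatimLocality = sv$name,
    locality = sm$name,
    decimalLatitude = sm$lat,
    decimalLongitude = sm$lon,
    coordinateUncertaintyInMeters = sm$extent_m,
    eventDate = eventDate,
    verbatimEventDate = s$date_verbatim,
    recordedBy = recBy,
    date_start = s$date_start,
    stringsAsFactors = FALSE)
  withheld <- rep(FALSE, nrow(occ))
  for (rule in embargoRules) withheld <- withheld | as.logical(rule(occ))
  withheld[is.na(withheld)] <- FALSE
  out <- occ[!withheld, setdiff(names(occ), "date_start"), drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE,
                                       fileEncoding = "UTF-8", na = "")
  out
}

#' Archive a completed project
#'
#' Once every specimen has been exported to the CMS the working store has
#' no further utility: its tables, the image file listing and any manifests
#' are bundled into an archive directory and the store is marked
#' read-only. Archiving is refused (with the count) while unexported
#' specimens remain.
#'
#' @param store A \code{\linkS4class{DigiStore}}.
#' @param outDir Archive directory.
#' @param copyImages Copy the image files themselves into the bundle.
#' @return \code{outDir}, invisibly.
#' @export
archiveProject <- function(store, outDir, copyImages = TRUE) {
  t <- store@tables
  nUnexported <- sum(t$specimens$status != "exported")
  if (nUnexported > 0L)
    stop(sprintf("%d specimen(s) not yet exported; archive refused", nUnexported))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  .audit(store, "system", "archive_project", outDir)
  saveStore(store, file.path(outDir, "store"))
  if (copyImages && nrow(t$images)) {
    imgDir <- file.path(outDir, "images")
    dir.create(imgDir, showWarnings = FALSE)
    ok <- file.exists(t$images$path)
    file.copy(t$images$path[ok], imgDir)
  }
  t$.readonly <- TRUE
  # persist the read-only mark in the bundle
  meta <- yaml::read_yaml(file.path(outDir, "store", "meta.yaml"))
  meta$readonly <- TRUE
  yaml::write_yaml(meta, file.path(outDir, "store", "meta.yaml"))
  invisible(outDir)
}
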