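## Transcription: allocation of specimen records to transcribers, verbatim
## capture of label fields (no interpretation), escalation flags, verbatim
## date parsing into calendar ranges, and the completeness census.

#' Build a transcription input
#'
#' All fields are stored exactly as supplied -- transcription captures
#' verbatim data without interpretation; normalisation happens later. At
#' least one field must be non-empty unless the record is being escalated.
#'
#' @param siteVerbatim,dateVerbatim,registration,typeStatus,breedingInfo
#'   Character or NA.
#' @param collectors Character vector of collector strings.
#' @param uncertainFields Character vector of field names the transcriber is
#'   unsure about.
#' @param escalate "none", "for_scrutiny" (curator) or "refer_to_admin".
#' @return A list of class-free transcription input.
#' @export
transcriptionInput <- function(siteVerbatim = NA_character_,
                               dateVerbatim = NA_character_,
                               collectors = character(0L),
                               registration = NA_character_,
                               typeStatus = NA_character_,
                               breedingInfo = NA_character_,
                               uncertainFields = character(0L),
                               escalate = c("none", "for_scrutiny", "refer_to_admin")) {
  escalate <- match.arg(escalate)
  inp <- list(siteVerbatim = siteVerbatim, dateVerbatim = dateVerbatim,
              collectors = collectors, registration = registration,
              typeStatus = typeStatus, breedingInfo = breedingInfo,
              uncertainFields = uncertainFields, escalate = escalate)
  filled <- c(!is.na(siteVerbatim), !is.na(dateVerbatim), length(collectors) > 0L,
              !is.na(registration), !is.na(typeStatus), !is.na(breedingInfo))
  if (!any(filled) && escalate == "none")
    stop("empty transcription input: supply at least one field or an escalation")
  inp
}

#' Allocate specimen records to a transcriber
#'
#' Allocated records are visible only to that transcriber; reallocating a
#' record replaces the previous allocation (latest wins) and both moves are
#' audited.
#'
#' @param store A \code{\linkS4class{DigiStore}}.
#' @param manager Caller; requires the data_manager role.
#' @param transcriber Target user; requires the transcriber role.
#' @param specimenIds Specimen ids.
#' @return Number of records allocated.
#' @export
allocateRecords <- function(store, manager, transcriber, specimenIds) {
  .requireWritable(store)
  .requireRole(store, manager, "data_manager")
  .requireRole(store, transcriber, "transcriber")
  t <- store@tables
  i <- match(specimenIds, t$specimens$id)
  if (anyNA(i)) stop("unknown specimen id(s): ", paste(specimenIds[is.na(i)], collapse = ","))
  prev <- t$specimens$assigned_to[i]
  t$specimens$assigned_to[i] <- transcriber
  for (k in seq_along(i)) {
    .audit(store, manager, "allocate_record",
           sprintf("specimen %d -> %s%s", specimenIds[k], transcriber,
                   if (!is.na(prev[k])) paste0(" (was ", prev[k], ")") else ""))
  }
  length(i)
}

#' Specimen records visible to a transcriber
#'
#' @param store A \code{\linkS4class{DigiStore}}.
#' @param user User name.
#' @return Integer vector of specimen ids allocated to the user.
#' @export
recordsFor <- function(store, user) {
  t <- store@tables
  t$specimens$id[!is.na(t$specimens$assigned_to) & t$specimens$assigned_to == user]
}

.workedOnBefore <- function(store, user, specimenId) {
  a <- store@tables$audit
  any(a$who == user & a$action == "transcribe" &
        startsWith(a$detail, sprintf("specimen %d ", specimenId)))
}

#' Parse a verbatim label date into a calendar range
#'
#' Grammar of common pinned-insect label conventions:
#' \code{day.month.year} with roman (i-xii) or arabic months
#' ("14.vi.1921"), \code{month.year} ("vi.1921"), bare \code{year}, and
#' dash ranges where the left side may be a prefix completed from the right
#' ("12-14.vi.1921", "vi.1921-vii.1921"). Two-digit years are refused --
#' the century would be a guess -- and flagged uncertain by the caller.
#'
#' @param s Verbatim date string.
#' @return list(ok, start, end, reason); start/end are \code{Date}s.
#' @export
parseVerbatimDate <- function(s) {
  bad <- function(reason) list(ok = FALSE, start = NA, end = NA, reason = reason)
  if (is.na(s) || !nzchar(trimws(s))) return(bad("empty"))
  s <- trimws(s)

  parseMonth <- function(tok) {
    tok <- tolower(trimws(tok))
    m <- match(tok, .romanMonths)
    if (!is.na(m)) return(m)
    if (grepl("^[0-9]{1,2}$", tok)) {
      v <- as.integer(tok)
      if (v >= 1L && v <= 12L) return(v)
    }
    NA_integer_
  }
  parseYear <- function(tok) {
    tok <- trimws(tok)
    if (grepl("^[0-9]{4}$", tok)) as.integer(tok) else NA_integer_
  }
  # parse one token list (split on ".") into (d, m, y) with NA for absent
  parseSingle <- function(x) {
    toks <- strsplit(trimws(x), "[./]")[[1L]]
    toks <- toks[nzchar(toks)]
    n <- length(toks)
    if (n == 0L || n > 3L) return(NULL)
    if (n == 3L) {
      d <- suppressWarnings(as.integer(toks[1L]))
      m <- parseMonth(toks[2L]); y <- parseYear(toks[3L])
      if (is.na(d) || is.na(m) || is.na(y)) return(NULL)
      return(c(d = d, m = m, y = y))
    }
    if (n == 2L) {
      m <- parseMonth(toks[1L]); y <- parseYear(toks[2L])
      if (is.na(m) || is.na(y)) return(NULL)
      return(c(d = NA_integer_, m = m, y = y))
    }
    y <- parseYear(toks[1L])
    if (is.na(y)) return(NULL)
    c(d = NA_integer_, m = NA_integer_, y = y)
  }
  rangeOf <- function(p) {
    y <- p[["y"]]; m <- p[["m"]]; d <- p[["d"]]
    if (!is.na(d)) {
      dt <- tryCatch(as.Date(sprintf("%04d-%02d-%02d", y, m, d)), error = function(e) NA)
      if (is.na(dt)) return(NULL)
      return(c(dt, dt))
    }
    if (!is.na(m)) {
      return(c(as.Date(sprintf("%04d-%02d-01", y, m)),
               as.Date(sprintf("%04d-%02d-%02d", y, m, .daysInMonth(y, m)))))
    }
    c(as.Date(sprintf("%04d-01-01", y)), as.Date(sprintf("%04d-12-31", y)))
  }

  if (grepl("^[0-9]{1,2}$", s) || grepl("\\b[0-9]{2}$", s) && !grepl("[0-9]{4}", s))
    return(bad("two-digit year refused"))

  if (grepl("-", s, fixed = TRUE)) {
    halves <- strsplit(s, "-", fixed = TRUE)[[1L]]
    if (length(halves) != 2L) return(bad("unparseable range"))
    right <- parseSingle(halves[2L])
    if (is.null(right)) return(bad("unparseable range end"))
    left <- parseSingle(halves[1L])
    if (is.null(left)) {
      # left may be a bare day or day.month completed from the right
      toks <- strsplit(trimws(halves[1L]), "[./]")[[1L]]
      if (length(toks) == 1L && grepl("^[0-9]{1,2}$", toks)) {
        left <- c(d = as.integer(toks), m = right[["m"]], y = right[["y"]])
      } else if (length(toks) == 2L) {
        d <- suppressWarnings(as.integer(toks[1L])); m <- parseMonth(toks[2L])
        if (is.na(d) || is.na(m)) return(bad("unparseable range start"))
        left <- c(d = d, m = m, y = right[["y"]])
      } else return(bad("unparseable range start"))
    }
    if (is.na(left[["y"]])) left[["y"]] <- right[["y"]]
    rl <- rangeOf(left); rr <- rangeOf(right)
    if (is.null(rl) || is.null(rr)) return(bad("invalid calendar date"))
    if (rl[1L] > rr[2L]) return(bad("range start after end"))
    return(list(ok = TRUE, start = rl[1L], end = rr[2L], reason = ""))
  }

  p <- parseSingle(s)
  if (is.null(p)) return(bad("unparseable date"))
  r <- rangeOf(p)
  if (is.null(r)) return(bad("invalid calendar date"))
  list(ok = TRUE, start = r[1L], end = r[2L], reason = "")
}

#' Transcribe a specimen record
#'
#' Stores the verbatim fields, matching the site string case-sensitively
#' against existing site variants (a new variant is created on a miss and
#' is immediately visible to all transcribers); collector strings are
#' handled likewise. The verbatim date is parsed into a calendar range when
#' unambiguous, otherwise the date field is flagged uncertain. The specimen
#' advances to status "transcribed"; an escalation-only input just sets the
#' flag and leaves the status unchanged.
#'
#' @param store A \code{\linkS4class{DigiStore}}.
#' @param user Caller; requires the transcriber role and must be allocated
#'   to the specimen (or have worked on it before).
#' @param specimenId Specimen id.
#' @param input A \code{\link{transcriptionInput}}.
#' @return The updated specimen row, invisibly.
#' @export
transcribe <- function(store, user, specimenId, input) {
  .requireWritable(store)
  .requireRole(store, user, "transcriber")
  t <- store@tables
  i <- match(specimenId, t$specimens$id)
  if (is.na(i)) stop("unknown specimen: ", specimenId)
  allocated <- identical(t$specimens$assigned_to[i], user)
  if (!allocated && !.workedOnBefore(store, user, specimenId))
    stop(sprintf("specimen %d is not allocated to user '%s'", specimenId, user))

  filled <- c(!is.na(input$siteVerbatim), !is.na(input$dateVerbatim),
              length(input$collectors) > 0L, !is.na(input$registration),
              !is.na(input$typeStatus), !is.na(input$breedingInfo))
  if (!any(filled)) {
    if (input$escalate == "none") stop("empty transcription input")
    .addFlag(store, specimenId, input$escalate)
    .audit(store, user, "transcribe", sprintf("specimen %d escalated: %s",
                                              specimenId, input$escalate))
    return(invisible(t$specimens[i, ]))
  }

  if (!is.na(input$siteVerbatim)) {
    sv <- .getOrCreate(store, "site_variants", input$siteVerbatim)
    t$specimens$site_variant_id[i] <- sv$id
  }
  if (length(input$collectors)) {
    ids <- vapply(input$collectors, function(nm) .getOrCreate(store, "collectors", nm)$id, 1L)
    t$specimens$collector_ids[i] <- .joinMulti(as.character(ids))
  }
  if (!is.na(input$dateVerbatim)) {
    t$specimens$date_verbatim[i] <- input$dateVerbatim
    pd <- parseVerbatimDate(input$dateVerbatim)
    if (pd$ok) {
      t$specimens$date_start[i] <- format(pd$start)
      t$specimens$date_end[i] <- format(pd$end)
    } else {
      .addFlag(store, specimenId, "uncertain:date")
    }
  }
  for (f in c("registration", "typeStatus", "breedingInfo")) {
    col <- c(registration = "registration", typeStatus = "type_status",
             breedingInfo = "breeding_info")[[f]]
    if (!is.na(input[[f]])) t$specimens[[col]][i] <- input[[f]]
  }
  for (uf in input$uncertainFields) .addFlag(store, specimenId, paste0("uncertain:", uf))
  if (input$escalate != "none") .addFlag(store, specimenId, input$escalate)

  .audit(store, user, "transcribe", sprintf("specimen %d transcribed", specimenId))
  setSpecimenStatus(store, specimenId, "transcribed", user)
  invisible(store@tables$specimens[match(specimenId, store@tables$specimens$id), ])
}

#' Transcribe a batch of records from a CSV table
#'
#' Non-interactive transcription for testing and scripted runs: rows are
#' keyed by barcode and columns mirror \code{\link{transcriptionInput}}
#' (site_verbatim, date_verbatim, collectors with ";" separators,
#' registration, type_status, breeding_info).
#'
#' @param store A \code{\linkS4class{DigiStore}}.
#' @param user Transcriber; the usual allocation rules apply per record.
#' @param rows data.frame or path to a CSV file.
#' @return Number of records transcribed.
#' @export
transcribeBatch <- function(store, user, rows) {
  if (is.character(rows)) rows <- utils::read.csv(rows, stringsAsFactors = FALSE,
                                                  fileEncoding = "UTF-8")
  t <- store@tables
  n <- 0L
  for (k in seq_len(nrow(rows))) {
    sid <- t$specimens$id[match(rows$barcode[k], t$specimens$barcode)]
    if (is.na(sid)) next
    getcol <- function(nm) {
      v <- if (nm %in% names(rows)) rows[[nm]][k] else NA
      if (is.null(v) || is.na(v) || !nzchar(as.character(v))) NA_character_ else as.character(v)
    }
    coll <- getcol("collectors")
    inp <- transcriptionInput(
      siteVerbatim = getcol("site_verbatim"), dateVerbatim = getcol("date_verbatim"),
      collectors = if (is.na(coll)) character(0L) else .splitMulti(coll),
      registration = getcol("registration"), typeStatus = getcol("type_status"),
      breedingInfo = getcol("breeding_info"))
    transcribe(store, user, sid, inp)
    n <- n + 1L
  }
  n
}

.COMPLETENESS_LEVELS <- c("Site + Date + Collector", "Site + Date only",
                          "Site + Collector only", "Site only", "Collector only",
                          "Date only", "Date + Collector only", "None")

.completenessFromFlags <- function(site, date, coll) {
  cat8 <- ifelse(site & date & coll, 1L,
          ifelse(site & date, 2L,
          ifelse(site & coll, 3L,
          ifelse(site, 4L,
          ifelse(coll & !date, 5L,
          ifelse(date & !coll, 6L,
          ifelse(date & coll, 7L, 8L)))))))
  tabulate(cat8, nbins = 8L)
}

#' Completeness census over site/date/collector presence
#'
#' Partitions records into the eight presence/absence categories of the
#' \{site, date, collector\} fields and reports counts and half-up rounded
#' integer percentages. Dispatches on a \code{\linkS4class{DigiStore}} (the
#' census is computed from the specimen table) or on a numeric vector of
#' eight pre-computed category counts.
#'
#' @param records A store or a numeric vector of 8 counts in category order
#'   (S+D+C, S+D, S+C, S, C, D, D+C, none).
#' @return data.frame with columns category, count, percent.
#' @examples
#' completenessCategories(c(100798, 39869, 16942, 8966, 3968, 771, 688, 9543))
#' @export
setGeneric("completenessCategories", function(records) standardGeneric("completenessCategories"))

#' @rdname completenessCategories
#' @export
setMethod("completenessCategories", "DigiStore", function(records) {
  s <- records@tables$specimens
  counts <- .completenessFromFlags(!is.na(s$site_variant_id),
                                   !is.na(s$date_start),
                                   !is.na(s$collector_ids))
  completenessCategories(counts)
})

#' @rdname completenessCategories
#' @export
setMethod("completenessCategories", "numeric", function(records) {
  if (length(records) != 8L) stop("expected 8 category counts")
  total <- sum(records)
  pct <- if (total > 0) roundHalfUp(100 * records / total, 0L) else rep(0, 8L)
  data.frame(category = .COMPLETENESS_LEVELS, count = records, percent = pct,
             stringsAsFactors = FALSE)
})
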