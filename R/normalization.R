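## Normalisation: expert assignment of verbatim site/taxon variants to
## standardised master records, deduplication statistics, and seeding of the
## taxon master list from a checklist of accepted names.

.variantTables <- function(type) {
  switch(type,
         site = list(variants = "site_variants", masters = "site_masters",
                     role = "georeferencer", counter = "site_masters"),
         taxon = list(variants = "taxon_variants", masters = "taxon_masters",
                      role = "scrutineer", counter = "taxon_masters"),
         stop("type must be 'site' or 'taxon'"))
}

#' Assign a variant to a master record
#'
#' Links one verbatim variant to a standardised master concept, creating
#' the master if it does not exist. A variant has at most one master:
#' reassignment replaces the previous link. All specimens carrying the
#' variant resolve transitively to the master and advance to status
#' "normalized". Site assignment requires the georeferencer role, taxon
#' assignment the scrutineer role.
#'
#' @param store A \code{\linkS4class{DigiStore}}.
#' @param expert Caller.
#' @param type "site" or "taxon".
#' @param variantName Verbatim variant string (must exist as a variant of
#'   that type; a site variant cannot be pointed at a taxon master).
#' @param masterName Master record name (created if new).
#' @return list(variant_id, master_id), invisibly.
#' @export
assignVariant <- function(store, expert, type = c("site", "taxon"),
                          variantName, masterName) {
  .requireWritable(store)
  type <- match.arg(type)
  tb <- .variantTables(type)
  .requireRole(store, expert, tb$role)
  t <- store@tables
  vi <- match(variantName, t[[tb$variants]]$name)
  if (is.na(vi)) stop(sprintf("no %s variant named '%s'", type, variantName))
  m <- .getOrCreate(store, tb$masters, masterName, counter = tb$counter)
  t[[tb$variants]]$master_id[vi] <- m$id
  vid <- t[[tb$variants]]$id[vi]
  .audit(store, expert, "assign_variant",
         sprintf("%s variant %d '%s' -> master %d '%s'", type, vid, variantName,
                 m$id, masterName))
  # specimens carrying the variant are now normalised
  col <- if (type == "site") "site_variant_id" else "taxon_variant_id"
  sids <- t$specimens$id[!is.na(t$specimens[[col]]) & t$specimens[[col]] == vid]
  for (sid in sids) {
    cur <- match(t$specimens$status[match(sid, t$specimens$id)], .WORKFLOW_STATUSES)
    if (cur == 2L) setSpecimenStatus(store, sid, "normalized", expert)
  }
  invisible(list(variant_id = vid, master_id = m$id))
}

# specimen counts per master for one variant type
.specimensPerMaster <- function(store, type) {
  tb <- .variantTables(type)
  t <- store@tables
  col <- if (type == "site") "site_variant_id" else "taxon_variant_id"
  v <- t[[tb$variants]]
  sv <- t$specimens[[col]]
  masters <- v$master_id[match(sv, v$id)]
  masters[!is.na(masters)]
}

#' Deduplication report
#'
#' Measures what normalisation achieved: how many verbatim variants map to
#' how many masters, the percent reduction (half-up rounded to integer, so
#' the quantity a project report would print), the distribution of
#' specimens per master, and the coverage of the most heavily used masters.
#' Dispatches on a \code{\linkS4class{DigiStore}} or directly on printed
#' variant/master counts.
#'
#' @param x A store, or the number of variants.
#' @param type "site" or "taxon" (store method).
#' @param partial Allow unassigned variants (normalisation still running);
#'   they are counted in \code{nVariants} but not in \code{nMasters}.
#' @param nMasters Number of masters (numeric method).
#' @return A \code{\linkS4class{DedupReport}}.
#' @examples
#' dedupReport(9591, nMasters = 4835)   # 50% reduction
#' @export
setGeneric("dedupReport", function(x, type = "site", partial = FALSE, nMasters = NULL)
  standardGeneric("dedupReport"))

.pctReduction <- function(nVariants, nMasters) {
  if (nVariants == 0L) return(0)
  roundHalfUp(100 * (nVariants - nMasters) / nVariants, 0L)
}

#' @rdname dedupReport
#' @export
setMethod("dedupReport", "DigiStore", function(x, type = "site", partial = FALSE,
                                               nMasters = NULL) {
  type <- match.arg(type, c("site", "taxon"))
  tb <- .variantTables(type)
  v <- x@tables[[tb$variants]]
  unassigned <- sum(is.na(v$master_id))
  if (unassigned > 0L && !partial)
    stop(sprintf("%d %s variant(s) unassigned; normalisation incomplete (use partial=TRUE)",
                 unassigned, type))
  nv <- nrow(v)
  nm <- length(unique(v$master_id[!is.na(v$master_id)]))
  perMaster <- .specimensPerMaster(x, type)
  spm <- if (length(perMaster)) {
    tab <- sort(table(perMaster), decreasing = TRUE)
    c(median = unname(stats::median(as.numeric(tab))), mean = unname(mean(tab)))
  } else c(median = NA_real_, mean = NA_real_)
  topK <- if (length(perMaster)) {
    tab <- sort(table(perMaster), decreasing = TRUE)
    ks <- unique(pmin(c(1L, 10L, 100L), length(tab)))
    data.frame(k = ks,
               specimens = vapply(ks, function(k) as.integer(sum(tab[seq_len(k)])), 1L),
               stringsAsFactors = FALSE)
  } else data.frame(k = integer(), specimens = numeric())
  new("DedupReport", type = type, nVariants = nv, nAssigned = nv - unassigned,
      nMasters = nm, pctReduction = .pctReduction(nv - unassigned, nm),
      specimensPerMaster = spm, topKCoverage = topK)
})

#' @rdname dedupReport
#' @export
setMethod("dedupReport", "numeric", function(x, type = "site", partial = FALSE,
                                             nMasters = NULL) {
  if (is.null(nMasters)) stop("supply nMasters")
  new("DedupReport", type = type, nVariants = as.integer(x),
      nAssigned = as.integer(x), nMasters = as.integer(nMasters),
      pctReduction = .pctReduction(x, nMasters),
      specimensPerMaster = numeric(0L),
      topKCoverage = data.frame(k = integer(), specimens = numeric()))
})

#' Seed taxon masters from a checklist of accepted names
#'
#' Pre-populating the taxon master list from an authoritative checklist
#' before transcription begins saves expert time later. Duplicate and
#' already-present names are skipped with a warning; malformed rows are
#' skipped and logged.
#'
#' @param store A \code{\linkS4class{DigiStore}}.
#' @param checklist data.frame with a \code{name} column (optionally
#'   \code{irn} carrying a pre-matched CMS identifier) or a CSV path.
#' @return Number of masters created.
#' @export
seedTaxonMasters <- function(store, checklist) {
  .requireWritable(store)
  if (is.character(checklist)) checklist <- utils::read.csv(checklist,
                                                            stringsAsFactors = FALSE,
                                                            fileEncoding = "UTF-8")
  if (!"name" %in% names(checklist)) stop("checklist needs a 'name' column")
  t <- store@tables
  created <- 0L
  skipped <- 0L
  for (k in seq_len(nrow(checklist))) {
    nm <- checklist$name[k]
    if (is.na(nm) || !nzchar(trimws(nm))) { skipped <- skipped + 1L; next }
    nm <- trimws(nm)
    if (nm %in% t$taxon_masters$name) { skipped <- skipped + 1L; next }
    m <- .getOrCreate(store, "taxon_masters", nm)
    if ("irn" %in% names(checklist) && !is.na(checklist$irn[k])) {
      t$taxon_masters$cms_irn[match(m$id, t$taxon_masters$id)] <- as.integer(checklist$irn[k])
    }
    created <- created + 1L
  }
  if (skipped > 0L) warning(skipped, " checklist row(s) skipped (blank or duplicate)")
  .audit(store, "system", "seed_taxon_masters", sprintf("%d created, %d skipped", created, skipped))
  created
}
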