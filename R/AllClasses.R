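#' @import methods
NULL

#' DigiStore: the digitisation project database
#'
#' A handle on the relational store backing a digitisation project: specimen
#' records, image records, barcode registry, site/taxon variants and masters,
#' collectors, users, georeferences, CMS identifier maps and an append-only
#' audit log. Tables live in an environment slot, so the handle has reference
#' semantics and every operation mutates the store in place, as a database
#' connection would. \code{\link{saveStore}} / \code{\link{loadStore}}
#' persist the tables as a directory of UTF-8 CSV files.
#'
#' @slot tables environment holding one data.frame per table plus counters.
#' @slot config list of store-level settings (barcode prefix and width,
#'   project name).
#' @export
setClass("DigiStore", representation(tables = "environment", config = "list"))

#' Configuration for the synthetic collection generator
#'
#' Defines the statistical structure of a generated specimen collection:
#' drawers and taxa, the site variant pool (verbatim spellings mapping to
#' ground-truth master sites, with sampling weights), collectors, the
#' collecting-date window, corruption rates for barcode misreads and missing
#' barcodes, the fraction of double-sided labels, image geometry and the
#' random seed. Build with \code{\link{collectionConfig}}.
#'
#' @slot nDrawers integer, number of drawers.
#' @slot taxa character, taxon names cycled over drawers.
#' @slot specimensPerDrawer integer.
#' @slot sitePool data.frame with columns master, variant, weight.
#' @slot collectorPool character.
#' @slot dateRange integer length 2, first and last collecting year.
#' @slot misreadRate,missingBarcodeRate,doubleSidedFraction numeric in [0,1].
#' @slot seed integer.
#' @slot imageWidth,imageHeight integer pixel dimensions of generated photos.
#' @slot barcodePrefix character scalar.
#' @slot barcodeStart integer, numeric part of the first barcode.
#' @export
setClass("GenerationConfig", representation(
  nDrawers = "integer", taxa = "character", specimensPerDrawer = "integer",
  sitePool = "data.frame", collectorPool = "character",
  dateRange = "integer", misreadRate = "numeric",
  missingBarcodeRate = "numeric", doubleSidedFraction = "numeric",
  seed = "integer", imageWidth = "integer", imageHeight = "integer",
  barcodePrefix = "character", barcodeStart = "integer"
))

setValidity("GenerationConfig", function(object) {
  msgs <- character(0L)
  for (nm in c("misreadRate", "missingBarcodeRate", "doubleSidedFraction")) {
    v <- slot(object, nm)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1) msgs <- c(msgs, paste(nm, "must be in [0,1]"))
  }
  sp <- object@sitePool
  if (!all(c("master", "variant", "weight") %in% names(sp)))
    msgs <- c(msgs, "sitePool needs columns master, variant, weight")
  else if (any(sp$weight <= 0)) msgs <- c(msgs, "sitePool weights must be positive")
  if (anyDuplicated(sp$variant)) msgs <- c(msgs, "sitePool variants must be unique")
  if (object@nDrawers < 1L || object@specimensPerDrawer < 1L) msgs <- c(msgs, "need at least one drawer and specimen")
  if (length(object@dateRange) != 2L || object@dateRange[1L] > object@dateRange[2L])
    msgs <- c(msgs, "dateRange must be (first year, last year)")
  if (length(msgs)) msgs else TRUE
})

#' Report from one image-processing batch run
#'
#' @slot nImagesSeen,nSpecimensCreated,nLabelCrops,nBarcodeFailures,nSkippedExisting integer counts.
#' @slot failures data.frame with columns path, reason.
#' @export
setClass("BatchReport", representation(
  nImagesSeen = "integer", nSpecimensCreated = "integer",
  nLabelCrops = "integer", nBarcodeFailures = "integer",
  nSkippedExisting = "integer", failures = "data.frame"
))

setValidity("BatchReport", function(object) {
  cnt <- c(object@nImagesSeen, object@nSpecimensCreated, object@nLabelCrops,
           object@nBarcodeFailures, object@nSkippedExisting)
  if (any(cnt < 0L)) return("counts must be non-negative")
  if (object@nSpecimensCreated > object@nImagesSeen)
    return("cannot create more specimens than images seen")
  TRUE
})

#' Variant-to-master deduplication report
#'
#' @slot type "site" or "taxon".
#' @slot nVariants,nAssigned,nMasters integer.
#' @slot pctReduction integer percent, half-up rounded.
#' @slot specimensPerMaster named numeric (median, mean) or empty.
#' @slot topKCoverage data.frame with columns k, specimens.
#' @export
setClass("DedupReport", representation(
  type = "character", nVariants = "integer", nAssigned = "integer",
  nMasters = "integer", pctReduction = "numeric",
  specimensPerMaster = "numeric", topKCoverage = "data.frame"
))

setValidity("DedupReport", function(object) {
  if (object@nMasters > object@nVariants) return("masters cannot exceed variants")
  TRUE
})

#' Georeferencing triage queue
#'
#' @slot threshold integer, minimum specimen count for the high-frequency pass.
#' @slot entries data.frame with columns master_id, name, n_specimens, stage,
#'   partition.
#' @slot coverageHighFreq numeric, fraction of sited specimens covered by the
#'   high-frequency stage.
#' @export
setClass("TriageQueue", representation(
  threshold = "integer", entries = "data.frame", coverageHighFreq = "numeric"
))

#' Project cost summary
#'
#' @slot items named numeric, expense line items in currency units.
#' @slot nSpecimens integer.
#' @slot total numeric.
#' @slot perSpecimen named numeric: total, digitisers_only, georeferencing.
#' @export
setClass("CostSummary", representation(
  items = "numeric", nSpecimens = "numeric", total = "numeric",
  perSpecimen = "numeric"
))

#' Mock collection management system
#'
#' Emulates the institutional CMS end of the ingest round-trip: it holds its
#' own record tables keyed by IRN (internal record number), assigns
#' sequential IRNs to ingested rows, and applies the per-entity policy
#' (always-create, match-or-create by key, or match-existing-only) that the
#' real ingest used. Data travel in and out as plain data.frames mirroring
#' the CSV reports of the production process.
#'
#' @slot tables environment with one data.frame per entity type.
#' @export
setClass("MockCms", representation(tables = "environment"))

setMethod("show", "DigiStore", function(object) {
  t <- object@tables
  cat("DigiStore:", object@config$project, "\n")
  cat(sprintf("  specimens: %d  images: %d  barcodes issued: %d\n",
              nrow(t$specimens), nrow(t$images), nrow(t$barcodes)))
  cat(sprintf("  site variants/masters: %d/%d  taxon variants/masters: %d/%d\n",
              nrow(t$site_variants), nrow(t$site_masters),
              nrow(t$taxon_variants), nrow(t$taxon_masters)))
  cat(sprintf("  users: %d  audit entries: %d%s\n", nrow(t$users), nrow(t$audit),
              if (isTRUE(t$.readonly)) "  [archived, read-only]" else ""))
})

setMethod("show", "BatchReport", function(object) {
  cat("BatchReport:\n")
  cat(sprintf("  images seen: %d  specimens created: %d  label crops: %d\n",
              object@nImagesSeen, object@nSpecimensCreated, object@nLabelCrops))
  cat(sprintf("  barcode failures: %d  skipped (already processed): %d\n",
              object@nBarcodeFailures, object@nSkippedExisting))
  if (nrow(object@failures)) {
    cat("  failures:\n")
    for (i in seq_len(min(nrow(object@failures), 10L)))
      cat("   ", object@failures$path[i], "--", object@failures$reason[i], "\n")
  }
})

setMethod("show", "DedupReport", function(object) {
  cat(sprintf("DedupReport (%s): %d variants -> %d masters (%d assigned), %g%% reduction\n",
              object@type, object@nVariants, object@nMasters, object@nAssigned,
              object@pctReduction))
  if (length(object@specimensPerMaster))
    cat(sprintf("  specimens per master: median %g, mean %.1f\n",
                object@specimensPerMaster[["median"]], object@specimensPerMaster[["mean"]]))
  if (nrow(object@topKCoverage))
    cat("  top-k coverage:", paste(sprintf("k=%d: %d", object@topKCoverage$k,
                                           object@topKCoverage$specimens), collapse = ", "), "\n")
})

setMethod("show", "TriageQueue", function(object) {
  e <- object@entries
  cat(sprintf("TriageQueue (threshold %d): %d masters, %d high-frequency (%.0f%% of sited specimens)\n",
              object@threshold, nrow(e), sum(e$stage == "high_frequency"),
              100 * object@coverageHighFreq))
  cat(sprintf("  split pass: A-M %d, N-Z %d\n",
              sum(e$partition == "A-M"), sum(e$partition == "N-Z")))
})

setMethod("show", "CostSummary", function(object) {
  cat("CostSummary:\n")
  for (nm in names(object@items)) cat(sprintf("  %-28s %12.2f\n", nm, object@items[[nm]]))
  cat(sprintf("  %-28s %12.2f\n", "Total", object@total))
  cat(sprintf("  per specimen (n=%d): total %.2f, digitisers only %.2f, georeferencing %.2f\n",
              object@nSpecimens, object@perSpecimen[["total"]],
              object@perSpecimen[["digitisers_only"]], object@perSpecimen[["georeferencing"]]))
})

setMethod("show", "MockCms", function(object) {
  t <- object@tables
  nm <- setdiff(ls(t), ".irn")
  cat("MockCms:", paste(sprintf("%s=%d", nm, vapply(nm, function(x) nrow(t[[x]]), 1L)),
                        collapse = " "), "\n")
})
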