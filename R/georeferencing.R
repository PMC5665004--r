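## Georeferencing: frequency-ranked triage queue, point-plus-extent capture
## against site masters, un-georeferenceable marking, and the double-blind
## QA comparison of two independent georeferencers.

#' Build the georeferencing triage queue
#'
#' The first pass georeferences only sites with at least \code{threshold}
#' collected specimens -- a small number of heavily collected sites covers
#' a large share of the collection. Those masters form the high_frequency
#' stage, ordered by specimen count (descending, ties by name); every other
#' master goes to the split pass, partitioned alphabetically A-M / N-Z so
#' two georeferencers can divide the work. Masters already flagged
#' un-georeferenceable are excluded.
#'
#' @param store A \code{\linkS4class{DigiStore}}.
#' @param threshold Minimum specimen count for the high-frequency stage.
#' @return A \code{\linkS4class{TriageQueue}}.
#' @export
buildTriageQueue <- function(store, threshold = 5L) {
  t <- store@tables
  m <- t$site_masters
  m <- m[!m$ungeoreferenceable, , drop = FALSE]
  counts <- .specimensPerMaster(store, "site")
  nSited <- length(counts)
  tab <- table(counts)
  n <- as.integer(tab[match(as.character(m$id), names(tab))])
  n[is.na(n)] <- 0L
  hi <- n >= threshold
  ordHi <- order(-n[hi], m$name[hi])
  ordLo <- order(-n[!hi], m$name[!hi])
  first <- toupper(substr(m$name[!hi], 1L, 1L))
  part <- ifelse(first >= "A" & first <= "M", "A-M", "N-Z")
  entries <- rbind(
    data.frame(master_id = m$id[hi][ordHi], name = m$name[hi][ordHi],
               n_specimens = n[hi][ordHi],
               stage = rep("high_frequency", sum(hi)),
               partition = rep("none", sum(hi)), stringsAsFactors = FALSE),
    data.frame(master_id = m$id[!hi][ordLo], name = m$name[!hi][ordLo],
               n_specimens = n[!hi][ordLo],
               stage = rep("split_pass", sum(!hi)),
               partition = part[ordLo], stringsAsFactors = FALSE))
  cov <- if (nSited > 0L) sum(n[hi]) / nSited else 0
  new("TriageQueue", threshold = as.integer(threshold), entries = entries,
      coverageHighFreq = cov)
}

#' Record a point-and-extent georeference on a site master
#'
#' Stores WGS84 decimal-degree coordinates and an extent radius expressing
#' locality uncertainty. All specimens of all variants of the master become
#' georeferenced. Re-georeferencing keeps the previous value in the audit
#' history.
#'
#' @param store A \code{\linkS4class{DigiStore}}.
#' @param user Caller; requires the georeferencer role.
#' @param masterName Site master name.
#' @param lat,lon WGS84 decimal degrees.
#' @param extentM Extent radius in metres, > 0.
#' @param method Free-text method note.
#' @return The updated master row, invisibly.
#' @export
setGeoreference <- function(store, user, masterName, lat, lon, extentM,
                            method = "point-radius") {
  .requireWritable(store)
  .requireRole(store, user, "georeferencer")
  if (is.na(lat) || lat < -90 || lat > 90) stop("latitude out of range [-90, 90]")
  if (is.na(lon) || lon < -180 || lon > 180) stop("longitude out of range [-180, 180]")
  if (is.na(extentM) || extentM <= 0) stop("extent must be positive metres")
  t <- store@tables
  i <- match(masterName, t$site_masters$name)
  if (is.na(i)) stop("no site master named '", masterName, "'")
  if (t$site_masters$ungeoreferenceable[i])
    stop("master is flagged un-georeferenceable: ", masterName)
  if (!is.na(t$site_masters$lat[i]))
    .audit(store, user, "georeference_superseded",
           sprintf("master %d previous (%.6f, %.6f, %sm)", t$site_masters$id[i],
                   t$site_masters$lat[i], t$site_masters$lon[i],
                   format(t$site_masters$extent_m[i])))
  t$site_masters$lat[i] <- lat
  t$site_masters$lon[i] <- lon
  t$site_masters$extent_m[i] <- extentM
  t$site_masters$method[i] <- method
  t$site_masters$georef_by[i] <- user
  .audit(store, user, "set_georeference",
         sprintf("master %d '%s' (%.6f, %.6f, %sm)", t$site_masters$id[i],
                 masterName, lat, lon, format(extentM)))
  # specimens of all variants of this master advance
  vids <- t$site_variants$id[!is.na(t$site_variants$master_id) &
                               t$site_variants$master_id == t$site_masters$id[i]]
  sids <- t$specimens$id[!is.na(t$specimens$site_variant_id) &
                           t$specimens$site_variant_id %in% vids]
  for (sid in sids) {
    cur <- match(t$specimens$status[match(sid, t$specimens$id)], .WORKFLOW_STATUSES)
    if (cur < 4L) setSpecimenStatus(store, sid, "georeferenced", user)
  }
  invisible(t$site_masters[i, ])
}

#' Mark a site master as un-georeferenceable
#'
#' Sites that defeat the whole triage sequence are noted as
#' un-georeferenceable and drop out of subsequent queue builds. A master
#' that already carries a georeference cannot be flagged. Clearing the flag
#' requires a scrutineer (\code{\link{unmarkUngeoreferenceable}}).
#'
#' @param store A \code{\linkS4class{DigiStore}}.
#' @param user Caller; requires the georeferencer role.
#' @param masterName Site master name.
#' @param note Why the site cannot be georeferenced.
#' @return The updated master row, invisibly.
#' @export
markUngeoreferenceable <- function(store, user, masterName, note = "") {
  .requireWritable(store)
  .requireRole(store, user, "georeferencer")
  t <- store@tables
  i <- match(masterName, t$site_masters$name)
  if (is.na(i)) stop("no site master named '", masterName, "'")
  if (!is.na(t$site_masters$lat[i]))
    stop("master is already georeferenced: ", masterName)
  t$site_masters$ungeoreferenceable[i] <- TRUE
  t$site_masters$note[i] <- note
  .audit(store, user, "mark_ungeoreferenceable", sprintf("master %d '%s': %s",
                                                         t$site_masters$id[i], masterName, note))
  invisible(t$site_masters[i, ])
}

#' @rdname markUngeoreferenceable
#' @export
unmarkUngeoreferenceable <- function(store, user, masterName) {
  .requireWritable(store)
  .requireRole(store, user, "scrutineer")
  t <- store@tables
  i <- match(masterName, t$site_masters$name)
  if (is.na(i)) stop("no site master named '", masterName, "'")
  t$site_masters$ungeoreferenceable[i] <- FALSE
  .audit(store, user, "unmark_ungeoreferenceable", masterName)
  invisible(t$site_masters[i, ])
}

#' Agreement rate between two independent georeferencers
#'
#' Quality assurance for a georeferencing campaign: a seeded random sample
#' of sites georeferenced by both workers is compared. Two results agree
#' when their points lie within a great-circle distance threshold of each
#' other and their extent circles overlap. The default threshold for each
#' site is the larger of the two extents. The measure is symmetric in the
#' two result sets.
#'
#' @param resultsA,resultsB data.frames with columns master, lat, lon,
#'   extent_m.
#' @param sampleN Number of sites to sample.
#' @param seed Sampling seed.
#' @param thresholdM Fixed distance threshold in metres, or NULL for
#'   per-site max(extent).
#' @return list(rate, n, sample) -- the agreement rate in [0,1], the sample
#'   size used, and the per-site comparison table.
#' @export
qaAgreement <- function(resultsA, resultsB, sampleN = 100L, seed = 1L,
                        thresholdM = NULL) {
  common <- intersect(resultsA$master, resultsB$master)
  if (length(common) == 0L) stop("no sites in common between the two result sets")
  if (sampleN > length(common)) {
    warning(sprintf("sample_n=%d exceeds %d available sites; using all", sampleN, length(common)))
    sampleN <- length(common)
  }
  sampled <- .withSeed(seed, sample(common, sampleN))
  ia <- match(sampled, resultsA$master)
  ib <- match(sampled, resultsB$master)
  d <- geosphere::distHaversine(cbind(resultsA$lon[ia], resultsA$lat[ia]),
                                cbind(resultsB$lon[ib], resultsB$lat[ib]),
                                r = 6371000)
  ea <- resultsA$extent_m[ia]
  eb <- resultsB$extent_m[ib]
  thr <- if (is.null(thresholdM)) pmax(ea, eb) else rep(thresholdM, length(d))
  agree <- d <= thr & d <= ea + eb
  list(rate = mean(agree), n = sampleN,
       sample = data.frame(master = sampled, distance_m = d, threshold_m = thr,
                           agree = agree, stringsAsFactors = FALSE))
}
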