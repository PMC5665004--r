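## Project analytics: three-point (PERT) performance estimation from timing
## logs, per-stage shares, and cost-per-specimen reporting.
##
## The three-point estimate summarises task-time observations with
##   E  = (a + 4m + b) / 6      SD = (b - a) / 6
## where a is the best-case (minimum) time, m the median, and b the
## worst-case taken as the 90th percentile of observed times. Reported
## values are rounded half-up to 2 decimals, matching how digitisation
## project reports print minutes-per-specimen figures.

.DIGI_STAGES <- c("preparation", "imaging", "transcription")

.pertE <- function(a, m, b) (a + 4 * m + b) / 6

#' Three-point (PERT) base estimate
#'
#' @param a Best-case minutes per specimen (minimum observed).
#' @param m Most-likely minutes per specimen (median).
#' @param b Worst-case minutes per specimen (90th percentile).
#' @param digits Decimals for half-up rounding; NULL returns the raw value.
#' @return E = (a + 4m + b)/6, between a and b for any valid triple.
#' @examples
#' pertEstimate(0.13, 0.85, 1.50)   # 0.84
#' @export
pertEstimate <- function(a, m, b, digits = 2L) {
  if (any(is.na(c(a, m, b))) || a <= 0 || a > m || m > b)
    stop("invalid three-point triple: need 0 < a <= m <= b")
  e <- .pertE(a, m, b)
  if (is.null(digits)) e else roundHalfUp(e, digits)
}

#' Three-point standard deviation
#'
#' @inheritParams pertEstimate
#' @return SD = (b - a)/6, non-negative.
#' @examples
#' pertSd(0.13, 1.50)   # 0.23
#' @export
pertSd <- function(a, b, digits = 2L) {
  if (any(is.na(c(a, b))) || a > b) stop("invalid bounds: need a <= b")
  sd <- (b - a) / 6
  if (is.null(digits)) sd else roundHalfUp(sd, digits)
}

#' Whole-workflow performance estimate from per-stage triples
#'
#' Combines preparation, imaging and transcription three-point triples into
#' per-stage base estimates, a total minutes-per-specimen figure (the sum
#' of the unrounded per-stage estimates, then rounded) and integer percent
#' stage shares. All three stages must be present.
#'
#' @param timings Named list with elements preparation, imaging,
#'   transcription, each \code{c(a, m, b)} in minutes per specimen; or the
#'   data.frame from \code{\link{timingsFromLog}}.
#' @return list(stages, totalE, shares): per-stage rounded estimates, the
#'   total, and percent shares.
#' @examples
#' projectEstimate(list(preparation = c(0.13, 0.85, 1.50),
#'                      imaging = c(0.47, 0.93, 1.88),
#'                      transcription = c(0.05, 0.53, 1.14)))
#' @export
projectEstimate <- function(timings) {
  if (is.data.frame(timings)) {
    timings <- stats::setNames(lapply(seq_len(nrow(timings)), function(i)
      c(timings$a[i], timings$m[i], timings$b[i])), timings$stage)
  }
  missing <- setdiff(.DIGI_STAGES, names(timings))
  if (length(missing))
    stop("missing stage(s): ", paste(missing, collapse = ", "))
  eRaw <- vapply(.DIGI_STAGES, function(st) {
    tr <- timings[[st]]
    pertEstimate(tr[1L], tr[2L], tr[3L], digits = NULL)
  }, 1)
  total <- sum(eRaw)
  list(stages = roundHalfUp(eRaw, 2L),
       totalE = roundHalfUp(total, 2L),
       shares = roundHalfUp(100 * eRaw / total, 0L))
}

#' Derive three-point triples from a task timing log
#'
#' Reduces raw per-specimen task timings to the (a, m, b) triple per stage:
#' a is the minimum, m the median and b the 90th percentile (linear
#' interpolation between order statistics), converted from seconds to
#' minutes. Stages with fewer than \code{minObs} observations are refused,
#' naming the stage.
#'
#' @param log data.frame with columns specimen, stage, seconds.
#' @param minObs Minimum observations required per stage.
#' @return data.frame with columns stage, a, m, b, n (minutes per specimen).
#' @export
timingsFromLog <- function(log, minObs = 10L) {
  if (!all(c("stage", "seconds") %in% names(log)))
    stop("log needs columns stage and seconds")
  stages <- intersect(.DIGI_STAGES, unique(log$stage))
  out <- lapply(.DIGI_STAGES, function(st) {
    x <- log$seconds[log$stage == st] / 60
    if (length(x) < minObs)
      stop(sprintf("stage '%s' has %d observation(s); need at least %d",
                   st, length(x), minObs))
    data.frame(stage = st, a = min(x), m = unname(stats::median(x)),
               b = unname(stats::quantile(x, 0.9, type = 7)), n = length(x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Project cost summary
#'
#' Totals the expense line items and derives cost-per-specimen figures:
#' the all-in total per specimen, the digitiser-salaries-only variant, and
#' georeferencing cost per specimen.
#'
#' @param items Named numeric expense lines; names containing "digitiser"
#'   feed the digitisers-only figure and names containing "georef" the
#'   georeferencing figure.
#' @param nSpecimens Number of specimens digitised, > 0.
#' @return A \code{\linkS4class{CostSummary}}.
#' @examples
#' costReport(c("Digitiser salaries" = 171465.40,
#'              "Georeferencing" = 19907.72,
#'              "Project staff salaries" = 158198.58,
#'              "Office preparation" = 6181.80,
#'              "Equipment" = 14718.38), 181545)
#' @export
costReport <- function(items, nSpecimens) {
  if (is.null(names(items)) || any(!nzchar(names(items))))
    stop("items must be a named numeric vector")
  if (any(items < 0)) stop("expense amounts must be non-negative")
  if (!.isCount(nSpecimens)) stop("nSpecimens must be a positive integer")
  total <- sum(items)
  digi <- sum(items[grepl("digitiser", names(items), ignore.case = TRUE)])
  geo <- sum(items[grepl("georef", names(items), ignore.case = TRUE)])
  new("CostSummary", items = items, nSpecimens = as.integer(nSpecimens),
      total = total,
      perSpecimen = c(total = total / nSpecimens,
                      digitisers_only = digi / nSpecimens,
                      georeferencing = geo / nSpecimens))
}
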