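#' Align single-cell traces on a per-cell event frame
#'
#' Shifts each cell's per-frame metric trace so that its event frame (e.g.
#' anaphase onset, defined as spindle length exceeding 3 um, or the frame at
#' which the daughter spindle pole body enters the bud) maps to relative
#' time 0, padding the unequal overhangs with `NA`. This is the alignment
#' step behind every averaged single-cell time course in the pipeline.
#'
#' @param traces List of numeric vectors, one metric trace per cell (values
#'   per movie frame; `NA` allowed).
#' @param event_frames Integer vector, one event frame (1-based) per cell.
#'   Cells with `NA` event frames are dropped with a warning.
#' @param frame_interval Minutes between frames (default 1), used to label
#'   the relative time axis.
#' @return An `aligned_ensemble`: list with `matrix` (cells x relative
#'   frames), `rel_frames` (integer offsets, 0 = event), `rel_time_min` and
#'   `cell_ids`.
#' @export
align_traces <- function(traces, event_frames, frame_interval = 1) {
  stopifnot(is.list(traces), length(traces) == length(event_frames))
  ids <- names(traces) %||% as.character(seq_along(traces))
  keep <- !is.na(event_frames)
  if (!any(keep)) stop("no cells with the alignment event")
  if (!all(keep)) {
    warning(sprintf("%d cell(s) without the event dropped", sum(!keep)))
    traces <- traces[keep]; event_frames <- event_frames[keep]
    ids <- ids[keep]
  }
  event_frames <- as.integer(event_frames)
  lens <- lengths(traces)
  if (any(event_frames < 1L | event_frames > lens)) {
    stop("event frames must lie within each trace")
  }
  lo <- min(1L - event_frames)           # most negative relative frame
  hi <- max(lens - event_frames)         # most positive relative frame
  rel <- seq.int(lo, hi)
  mat <- matrix(NA_real_, nrow = length(traces), ncol = length(rel),
                dimnames = list(ids, rel))
  for (i in seq_along(traces)) {
    offs <- seq_len(lens[i]) - event_frames[i]
    mat[i, match(offs, rel)] <- as.numeric(traces[[i]])
  }
  structure(
    list(matrix = mat, rel_frames = rel,
         rel_time_min = rel * frame_interval, cell_ids = ids),
    class = "aligned_ensemble"
  )
}

#' @export
print.aligned_ensemble <- function(x, ...) {
  cat(sprintf("Aligned ensemble: %d cells, relative frames %d..%d\n",
              nrow(x$matrix), min(x$rel_frames), max(x$rel_frames)))
  invisible(x)
}

#' 95% confidence half-width
#'
#' Half-width of the 95% normal confidence band, `1.96 * sigma / sqrt(n)`
#' (the standard-error form). `se_mode = "sd_over_n"` instead computes
#' `1.96 * sigma / n`, reproducing a legacy band definition.
#'
#' @param sigma Standard deviation(s).
#' @param n Number(s) of observations.
#' @param se_mode `"sd_over_sqrt_n"` (default) or `"sd_over_n"`.
#' @return Half-width(s), same length as the inputs after recycling.
#' @export
ci_halfwidth <- function(sigma, n, se_mode = c("sd_over_sqrt_n", "sd_over_n")) {
  se_mode <- match.arg(se_mode)
  denom <- if (se_mode == "sd_over_sqrt_n") sqrt(n) else n
  1.96 * sigma / denom
}

#' Pointwise mean and 95% confidence band of an aligned ensemble
#'
#' At each relative time, averages the non-missing values across cells and
#' attaches the 95% band `mean +/- 1.96 * sd / sqrt(n)`; `sd` is the sample
#' (n - 1) standard deviation and `n` the per-time non-missing count, so the
#' band is `NA` where a single cell contributes.
#'
#' @param ensemble An [align_traces()] result.
#' @inheritParams ci_halfwidth
#' @return Data frame with `rel_frame`, `time_min`, `mean`, `sd`, `n`,
#'   `ci_lo`, `ci_hi`.
#' @export
mean_ci <- function(ensemble, se_mode = c("sd_over_sqrt_n", "sd_over_n")) {
  stopifnot(inherits(ensemble, "aligned_ensemble"))
  se_mode <- match.arg(se_mode)
  m <- ensemble$matrix
  n <- colSums(!is.na(m))
  mu <- colMeans(m, na.rm = TRUE)
  mu[n == 0] <- NA_real_
  sdv <- apply(m, 2, stats::sd, na.rm = TRUE)
  hw <- ci_halfwidth(sdv, n, se_mode)
  data.frame(
    rel_frame = ensemble$rel_frames,
    time_min = ensemble$rel_time_min,
    mean = mu, sd = sdv, n = n,
    ci_lo = mu - hw, ci_hi = mu + hw,
    row.names = NULL
  )
}

#' Maximum of a per-cell metric trace over a window
#'
#' Per-cell summary used for "maximum enrichment in anaphase" style
#' comparisons: the maximum of the metric between two frames (e.g. anaphase
#' onset to mitotic exit), ignoring missing values.
#'
#' @param trace Numeric per-frame metric values for one cell.
#' @param window Integer vector of frame indices, or `c(from, to)` when
#'   `as_range = TRUE`.
#' @param as_range Interpret `window` as an inclusive frame range.
#' @return Scalar maximum over the window.
#' @export
max_enrichment <- function(trace, window, as_range = length(window) == 2L) {
  idx <- if (as_range) seq.int(window[1], window[2]) else as.integer(window)
  if (length(idx) == 0L) stop("empty window")
  if (min(idx) < 1L || max(idx) > length(trace)) {
    stop("window outside the trace")
  }
  vals <- trace[idx]
  if (all(is.na(vals))) return(NA_real_)
  max(vals, na.rm = TRUE)
}

#' Two-sided Wilcoxon rank sum test
#'
#' Compares two groups of per-cell summaries with the two-sided Wilcoxon
#' (Mann-Whitney) rank sum test. For combined sample sizes up to
#' `exact_limit` the null distribution of the rank sum is enumerated over
#' all assignments of the pooled midranks (ties handled naturally); larger
#' samples use the normal approximation with tie-corrected variance and
#' continuity correction.
#'
#' @param a,b Numeric vectors of group values (each non-empty).
#' @param method `"auto"` (default: exact when `length(a) + length(b) <=
#'   exact_limit`), `"exact"` or `"normal"`.
#' @param exact_limit Combined size up to which the exact enumeration is
#'   used (default 10).
#' @return List with `p` (two-sided), `statistic` (rank sum of `a`) and
#'   `method`.
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4))$p  # exact: 1/3
#' @export
rank_sum_test <- function(a, b, method = c("auto", "exact", "normal"),
                          exact_limit = 10L) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)                      # midranks for ties
  w_obs <- sum(r[seq_len(na)])

  if (length(unique(pooled)) == 1L) {
    return(list(p = 1, statistic = w_obs, method = "degenerate"))
  }
  if (method == "auto") method <- if (n <= exact_limit) "exact" else "normal"

  if (method == "exact") {
    sets <- utils::combn(n, na)
    w_all <- colSums(matrix(r[sets], nrow = na))
    eps <- 1e-9
    p_lo <- mean(w_all <= w_obs + eps)
    p_hi <- mean(w_all >= w_obs - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    mu <- na * (n + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v <- na * nb / 12 * ((n + 1) - tie_term)
    if (v <= 0) return(list(p = 1, statistic = w_obs, method = "degenerate"))
    z <- (w_obs - mu - sign(w_obs - mu) * 0.5) / sqrt(v)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(p = p, statistic = w_obs, method = method)
}
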