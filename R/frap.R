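#' Construct a FRAP trace
#'
#' Bundles the raw measurements of a fluorescence-recovery-after-
#' photobleaching experiment: background-subtracted intensities at the
#' bleached spindle pole body (SPB) and in the cytosol of the same cell,
#' sampled at the acquisition times, together with the indices of the last
#' pre-bleach frame and the first post-bleach frame.
#'
#' @param time_s Numeric vector of acquisition times in seconds, strictly
#'   increasing.
#' @param i_spb Intensity at the bleached SPB (arbitrary units), same length
#'   as `time_s`.
#' @param i_cytosol Cytosolic reference intensity (arbitrary units), strictly
#'   positive; used to correct for acquisition photobleaching.
#' @param pre Index (1-based) of the pre-bleach reference frame, typically
#'   the frame immediately before the bleach pulse.
#' @param bleach Index (1-based) of the first post-bleach frame; its time is
#'   taken as t = 0 for the recovery.
#' @return An object of class `frap_trace`.
#' @seealso [double_normalize()], [fit_recovery()], [generate_frap_trace()]
#' @export
frap_trace <- function(time_s, i_spb, i_cytosol, pre, bleach) {
  n <- length(time_s)
  stopifnot(length(i_spb) == n, length(i_cytosol) == n)
  if (any(diff(time_s) <= 0)) {
    stop("`time_s` must be strictly increasing")
  }
  if (any(!is.finite(i_cytosol)) || any(i_cytosol <= 0)) {
    stop("`i_cytosol` must be finite and > 0 at every frame")
  }
  pre <- as.integer(pre)
  bleach <- as.integer(bleach)
  if (pre < 1L || bleach > n || pre >= bleach) {
    stop("need 1 <= pre < bleach <= length(trace)")
  }
  structure(
    list(time_s = as.numeric(time_s), i_spb = as.numeric(i_spb),
         i_cytosol = as.numeric(i_cytosol), pre = pre, bleach = bleach),
    class = "frap_trace"
  )
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf(
    "FRAP trace: %d frames, pre-bleach frame %d, bleach frame %d (t = 0 at %.3g s)\n",
    length(x$time_s), x$pre, x$bleach, x$time_s[x$bleach]
  ))
  invisible(x)
}

#' Double normalization of a FRAP trace
#'
#' Corrects the bleached-region signal for acquisition photobleaching by
#' dividing by the cytosolic reference, then rescales between the first
#' post-bleach level (0) and the pre-bleach level (1):
#' \deqn{I_{norm}(t) = I_{SPB}(t) / I_{cytosol}(t)}
#' \deqn{I_{FRAP}(t) = \frac{I_{norm}(t) - I_{norm}(0)}{I_{norm}(pre) - I_{norm}(0)}}
#' where frame `pre` is the pre-bleach reference and t = 0 is the first
#' post-bleach frame. By construction the output is 0 at the bleach frame and
#' 1 at the pre-bleach frame; it is invariant to any positive per-frame gain
#' applied to both channels.
#'
#' @param trace A [frap_trace()].
#' @param average_pre If `TRUE`, the pre-bleach reference level is the mean of
#'   the normalized values of all frames up to and including `pre` (useful
#'   when several pre-bleach images were acquired). Default uses the single
#'   `pre` frame.
#' @return Numeric vector of double-normalized intensities, one per frame.
#' @export
double_normalize <- function(trace, average_pre = FALSE) {
  stopifnot(inherits(trace, "frap_trace"))
  i_norm <- trace$i_spb / trace$i_cytosol
  ref_pre <- if (average_pre) mean(i_norm[seq_len(trace$pre)]) else i_norm[trace$pre]
  ref_0 <- i_norm[trace$bleach]
  depth <- ref_pre - ref_0
  if (!is.finite(depth) || abs(depth) < .Machine$double.eps * max(1, abs(ref_pre))) {
    stop("degenerate normalization: no bleach depth (pre and post-bleach levels equal)")
  }
  (i_norm - ref_0) / depth
}

#' Single-exponential recovery model
#'
#' Recovery fraction at time `t` for the model
#' \eqn{y = y_{max}\,(1 - e^{-\ln 2\, t / t_{1/2}})}: `ymax` is the mobile
#' fraction recovered at the plateau and `t_half` the half-recovery time, so
#' the value at `t = t_half` is exactly `ymax / 2`.
#'
#' @param t Time since the bleach, seconds (vector).
#' @param ymax Plateau recovery fraction (unitless).
#' @param t_half Half-recovery time, seconds, > 0.
#' @return Model values, same length as `t`.
#' @export
recovery_model <- function(t, ymax, t_half) {
  stopifnot(t_half > 0)
  ymax * (1 - exp(-log(2) * t / t_half))
}

#' Fit a single-exponential recovery to a double-normalized FRAP series
#'
#' Least-squares fit of [recovery_model()] to the post-bleach portion of a
#' double-normalized FRAP series. Only frames at or after the bleach frame
#' enter the fit; time is measured from the bleach frame. Starting values are
#' `ymax` = last observed value and `t_half` = the first time the series
#' crosses half of that, with Levenberg-Marquardt refinement.
#'
#' @param normalized Double-normalized intensity series (see
#'   [double_normalize()]), or a [frap_trace()] (normalized internally).
#' @param time_s Acquisition times in seconds (ignored when `normalized` is a
#'   `frap_trace`).
#' @param bleach Index of the first post-bleach frame (ignored for a
#'   `frap_trace`).
#' @return A `recovery_fit` object: a list with `ymax`, `t_half` (s), `rss`,
#'   `converged` and `n_points`.
#' @examples
#' tt <- seq(0, 30, by = 1)
#' y <- recovery_model(tt, ymax = 0.9, t_half = 5)
#' fit <- fit_recovery(y, tt, bleach = 1)
#' fit$t_half  # 5, to numerical precision
#' @export
fit_recovery <- function(normalized, time_s = NULL, bleach = 1L) {
  if (inherits(normalized, "frap_trace")) {
    time_s <- normalized$time_s
    bleach <- normalized$bleach
    normalized <- double_normalize(normalized)
  }
  stopifnot(length(normalized) == length(time_s))
  post <- seq.int(bleach, length(normalized))
  if (length(post) < 4L) {
    stop("need at least 4 post-bleach points to fit the recovery")
  }
  t <- time_s[post] - time_s[bleach]
  y <- normalized[post]

  ymax0 <- y[length(y)]
  if (!is.finite(ymax0) || ymax0 <= 0) ymax0 <- max(y, 0.1)
  cross <- which(y >= ymax0 / 2 & t > 0)
  t_half0 <- if (length(cross)) t[cross[1]] else max(t) / 2
  if (t_half0 <= 0) t_half0 <- max(t) / 4

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ ymax * (1 - exp(-log(2) * t / t_half)),
      data = list(y = y, t = t),
      start = list(ymax = ymax0, t_half = t_half0),
      lower = c(ymax = 1e-8, t_half = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12)
    ),
    error = function(e) NULL
  )

  if (is.null(fit)) {
    warning("recovery fit did not converge; returning starting values")
    est <- c(ymax = ymax0, t_half = t_half0)
    rss <- sum((y - recovery_model(t, est[1], est[2]))^2)
    converged <- FALSE
  } else {
    est <- stats::coef(fit)
    rss <- sum(stats::resid(fit)^2)
    converged <- fit$convInfo$isConv %||% TRUE
  }
  structure(
    list(ymax = unname(est["ymax"]), t_half = unname(est["t_half"]),
         rss = rss, converged = converged, n_points = length(y)),
    class = "recovery_fit"
  )
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf(
    "Recovery fit: ymax = %.4g, t1/2 = %.4g s (rss %.3g, %d points%s)\n",
    x$ymax, x$t_half, x$rss, x$n_points,
    if (x$converged) "" else ", NOT converged"
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
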