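#' Simulate a FRAP trace with known recovery parameters
#'
#' Generates a raw SPB/cytosol intensity pair whose noiseless
#' double-normalized values follow the single-exponential recovery model
#' exactly (see [recovery_model()]). The cytosolic reference decays
#' exponentially frame to frame, emulating acquisition photobleaching, and
#' the SPB signal is embedded back on the raw scale so that
#' [double_normalize()] has to undo the bleaching non-trivially.
#'
#' Noise is added on the normalized (recovery-fraction) scale, so `noise_sd`
#' is directly the standard deviation of the double-normalized values around
#' the model. The pre-bleach reference frame and the bleach frame are left
#' noise-free: they anchor the normalization, and perturbing them would
#' change the scale of the whole trace rather than scatter points about it.
#'
#' @param t_half True half-recovery time, seconds, > 0.
#' @param plateau True recovery plateau `ymax`, in (0, 1].
#' @param noise_sd Gaussian noise standard deviation on the normalized scale
#'   (0 for a noiseless trace).
#' @param frame_interval Seconds between post-bleach frames (default 1 s).
#' @param duration Post-bleach acquisition length, seconds (default 30 s); at
#'   least several `t_half` is recommended for a well-conditioned fit.
#' @param pre_frames Number of pre-bleach frames (default 2).
#' @param bleach_depth Fraction of the pre-bleach normalized level removed by
#'   the bleach pulse (default 0.75).
#' @param cytosol0 Cytosolic intensity at the first frame, arbitrary units.
#' @param acq_bleach_rate Per-frame exponential photobleaching rate of the
#'   cytosolic reference during acquisition (default 0.01/frame).
#' @param seed Optional integer seed; the trace is fully determined by it.
#' @return A [frap_trace()] with attribute `truth`, a list holding the
#'   generating `t_half`, `plateau` and the noiseless normalized series.
#' @export
generate_frap_trace <- function(t_half, plateau, noise_sd = 0,
                                frame_interval = 1, duration = 30,
                                pre_frames = 2L, bleach_depth = 0.75,
                                cytosol0 = 1000, acq_bleach_rate = 0.01,
                                seed = NULL) {
  if (!is.numeric(t_half) || t_half <= 0) stop("`t_half` must be > 0")
  stopifnot(plateau > 0, plateau <= 1, noise_sd >= 0,
            frame_interval > 0, duration > 0, pre_frames >= 1,
            bleach_depth > 0, bleach_depth <= 1, cytosol0 > 0)
  if (!is.null(seed)) set.seed(as.integer(seed))

  n_post <- floor(duration / frame_interval) + 1L
  t_post <- (seq_len(n_post) - 1L) * frame_interval
  t_pre <- -rev(seq_len(pre_frames)) * frame_interval
  time_s <- c(t_pre, t_post)
  n <- length(time_s)
  pre <- pre_frames
  bleach <- pre_frames + 1L

  # normalized-scale scaffold: pre level n_pre, bleach floor n_0
  n_pre <- 0.5
  n_0 <- n_pre * (1 - bleach_depth)
  model <- c(rep(1, pre_frames), recovery_model(t_post, plateau, t_half))
  noisy <- model
  if (noise_sd > 0) {
    free <- setdiff(seq_len(n), c(pre, bleach))
    noisy[free] <- noisy[free] + stats::rnorm(length(free), 0, noise_sd)
  }
  i_norm <- n_0 + noisy * (n_pre - n_0)

  frame_idx <- seq_len(n) - 1L
  i_cytosol <- cytosol0 * exp(-acq_bleach_rate * frame_idx)
  tr <- frap_trace(time_s, i_spb = i_norm * i_cytosol,
                   i_cytosol = i_cytosol, pre = pre, bleach = bleach)
  attr(tr, "truth") <- list(t_half = t_half, plateau = plateau,
                            normalized = model)
  tr
}
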