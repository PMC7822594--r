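#' Configuration for a synthetic dividing-yeast movie
#'
#' Describes the scene rendered by [generate_movie()]: dividing cells with
#' two spindle pole body (SPB) puncta, a nucleolar region, a growing bud,
#' diffuse cytosolic probe signal, cell-cycle-staged enrichment dynamics,
#' optional Cdc14-like and reporter channels, acquisition photobleaching,
#' stage drift and multiplicative noise. Defaults approximate the study
#' conditions: 0.2 um pixels, one frame every 3 min, probe enrichment
#' appearing at anaphase onset.
#'
#' @param ny,nx Image size in pixels.
#' @param n_frames Number of frames.
#' @param n_cells Number of cells (1-3 with the built-in layout).
#' @param pixel_size_um Pixel size, um/pixel.
#' @param frame_interval_min Frame interval, minutes.
#' @param channels Channels to render, a subset of `c("spb", "nucleolus",
#'   "probe", "cdc14", "reporter")`.
#' @param schedule Optional data frame with one row per cell: `bud_frame`,
#'   `onset_frame`, `exit_frame` (must satisfy bud <= onset <= exit). The
#'   default staggers the built-in schedule across cells.
#' @param baseline Named list of channel intensity levels (arbitrary
#'   units): `probe` cytosolic baseline, `spb` marker spot amplitude,
#'   `nucleolus` marker level, `cdc14` nucleolar level, `reporter_nuc` /
#'   `reporter_cyt` reporter levels.
#' @param background Per-channel additive background (scalar, same for all
#'   channels).
#' @param noise_sd Multiplicative Gaussian noise sd as a fraction of signal
#'   (0 disables noise).
#' @param bleach_rate Per-frame exponential photobleaching rate applied to
#'   all signal (not the camera background).
#' @param drift_px_per_frame `c(dy, dx)` stage drift per frame, pixels.
#' @param spb_enrichment_ana Planted relative probe enrichment at SPBs
#'   during anaphase (onset to exit).
#' @param nuc_enrichment_ana Planted relative probe enrichment in the
#'   nucleolus during late anaphase (onset + 2 to exit).
#' @param release_depth Planted fractional drop of the Cdc14-like channel
#'   in the nucleolus at its minimum (relative release ground truth).
#' @param seed Integer seed; fully determines the rendered movie.
#' @return A `movie_config` list.
#' @export
movie_config <- function(ny = 120L, nx = 120L, n_frames = 40L, n_cells = 1L,
                         pixel_size_um = 0.2, frame_interval_min = 3,
                         channels = c("spb", "nucleolus", "probe"),
                         schedule = NULL,
                         baseline = list(probe = 100, spb = 500,
                                         nucleolus = 300, cdc14 = 200,
                                         reporter_nuc = 300,
                                         reporter_cyt = 100),
                         background = 10, noise_sd = 0.05,
                         bleach_rate = 0.002,
                         drift_px_per_frame = c(0, 0),
                         spb_enrichment_ana = 4, nuc_enrichment_ana = 2,
                         release_depth = 0.8, seed = 1L) {
  stopifnot(ny > 0, nx > 0, n_frames >= 1, n_cells >= 1, n_cells <= 3,
            pixel_size_um > 0, frame_interval_min > 0,
            all(unlist(baseline) > 0), background >= 0, noise_sd >= 0,
            bleach_rate >= 0)
  known <- c("spb", "nucleolus", "probe", "cdc14", "reporter")
  if (!all(channels %in% known)) {
    stop("unknown channel(s): ", paste(setdiff(channels, known), collapse = ", "))
  }
  if (is.null(schedule)) {
    schedule <- data.frame(
      bud_frame = pmin(4L + 2L * (seq_len(n_cells) - 1L), n_frames),
      onset_frame = pmin(15L + 2L * (seq_len(n_cells) - 1L), n_frames),
      exit_frame = pmin(32L + 2L * (seq_len(n_cells) - 1L), n_frames)
    )
  }
  stopifnot(nrow(schedule) == n_cells)
  bad <- schedule$bud_frame > schedule$onset_frame |
    schedule$onset_frame > schedule$exit_frame
  if (any(bad)) {
    stop("invalid cell-cycle schedule: need bud_frame <= onset_frame <= exit_frame")
  }
  structure(
    list(ny = as.integer(ny), nx = as.integer(nx),
         n_frames = as.integer(n_frames), n_cells = as.integer(n_cells),
         pixel_size_um = pixel_size_um,
         frame_interval_min = frame_interval_min, channels = channels,
         schedule = schedule, baseline = baseline, background = background,
         noise_sd = noise_sd, bleach_rate = bleach_rate,
         drift_px_per_frame = drift_px_per_frame,
         spb_enrichment_ana = spb_enrichment_ana,
         nuc_enrichment_ana = nuc_enrichment_ana,
         release_depth = release_depth, seed = as.integer(seed)),
    class = "movie_config"
  )
}

disk_mask <- function(ny, nx, center, radius) {
  row <- matrix(seq_len(ny), ny, nx)
  col <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  (row - center[1])^2 + (col - center[2])^2 <= radius^2
}

gaussian_spot <- function(ny, nx, center, amplitude, sigma = 1, extent = 5) {
  img <- matrix(0, ny, nx)
  px <- disk_pixels(center, extent, c(ny, nx))
  d2 <- (px[, 1] - center[1])^2 + (px[, 2] - center[2])^2
  img[px] <- amplitude * exp(-d2 / (2 * sigma^2))
  img
}

#' Render a synthetic dividing-yeast movie with ground truth
#'
#' Renders the scene described by a [movie_config()]. Each cell is a disk
#' of diffuse probe signal with a nucleolar region offset from the spindle
#' axis; a bud appears at its scheduled frame and grows; the two SPBs sit
#' on a spindle that elongates through anaphase onset (crossing the 3 um
#' threshold at the scheduled onset frame) and drives the daughter SPB into
#' the bud. SPBs are rendered as 2D Gaussians (sigma = 1 px,
#' diffraction-limited). Probe enrichment at the SPBs and in the nucleolus
#' follows the planted cell-cycle profiles. Drift, per-channel
#' photobleaching, additive background and multiplicative noise are applied
#' in that order, and the recorded ground truth (masks, SPB coordinates,
#' event frames, enrichment values) refers to the rendered, drifted pixels.
#'
#' @param config A [movie_config()].
#' @return List with `movie` (a [movie()]) and `truth`, a list of
#'   \describe{
#'     \item{cell_masks}{per-frame integer label matrices; mother cells are
#'       labeled 1..n_cells, the bud of cell i is labeled n_cells + i}
#'     \item{nucleolus_masks}{per-frame label matrices (label = cell id)}
#'     \item{spb}{data frame: `frame`, `cell`, `role` ("d"/"m"), `row`,
#'       `col` (rendered integer coordinates)}
#'     \item{events}{per cell: `cell`, `bud_id`, `bud_frame`,
#'       `onset_frame`, `entry_frame`, `exit_frame`}
#'     \item{enrichment}{per frame per cell: planted `e_spb`, `e_nuc`}
#'     \item{cdc14_profile}{per frame per cell: planted nucleolar Cdc14
#'       level relative to baseline (when the channel is rendered)}
#'     \item{shifts}{per-frame cumulative drift offsets applied}
#'   }
#' @export
generate_movie <- function(config) {
  stopifnot(inherits(config, "movie_config"))
  set.seed(config$seed)
  ny <- config$ny; nx <- config$nx; nt <- config$n_frames
  nc <- config$n_cells
  chans <- config$channels
  bl <- config$baseline

  centers <- list(c(38, 38), c(38, 84), c(86, 62))[seq_len(nc)]
  angles <- c(0, pi / 2, 5 * pi / 4)[seq_len(nc)]
  r_mother <- 12

  drift <- config$drift_px_per_frame
  shifts <- cbind(round(drift[1] * (seq_len(nt) - 1L)),
                  round(drift[2] * (seq_len(nt) - 1L)))

  data <- array(0, dim = c(nt, length(chans), ny, nx))
  cell_masks <- vector("list", nt)
  nucl_masks <- vector("list", nt)
  spb_rows <- list()
  enr_rows <- list()
  c14_rows <- list()
  events <- data.frame(cell = seq_len(nc), bud_id = nc + seq_len(nc),
                       bud_frame = config$schedule$bud_frame,
                       onset_frame = config$schedule$onset_frame,
                       entry_frame = NA_integer_,
                       exit_frame = config$schedule$exit_frame)

  px_3um <- 3 / config$pixel_size_um
  for (t in seq_len(nt)) {
    off <- shifts[t, ]
    labs <- matrix(0L, ny, nx)
    nlabs <- matrix(0L, ny, nx)
    sig <- lapply(chans, function(ch) matrix(0, ny, nx))
    names(sig) <- chans

    for (i in seq_len(nc)) {
      m <- centers[[i]] + off
      u <- c(sin(angles[i]), cos(angles[i]))   # (row, col) unit vector
      sched <- config$schedule[i, ]
      t0 <- sched$onset_frame

      # bud geometry
      bud_mask <- NULL
      if (t >= sched$bud_frame) {
        r_bud <- min(3 + 0.5 * (t - sched$bud_frame), 8)
        bud_center <- m + (r_mother + 1 + r_bud) * u
        bud_mask <- disk_mask(ny, nx, bud_center, r_bud)
      }
      mother_mask <- disk_mask(ny, nx, m, r_mother)
      labs[mother_mask] <- i
      if (!is.null(bud_mask)) labs[bud_mask & labs == 0L] <- nc + i

      # spindle: elongation starts 5 frames before onset and crosses
      # 3 um (15 px at 0.2 um/px) at the scheduled onset frame
      te <- t0 - 5L
      len <- if (t < te) 4 else min(4 + 2.5 * (t - te), 32)
      d_spb <- round(m + 0.65 * len * u)
      m_spb <- round(m - 0.35 * len * u)
      in_bud <- !is.null(bud_mask) &&
        d_spb[1] >= 1 && d_spb[2] >= 1 && d_spb[1] <= ny && d_spb[2] <= nx &&
        bud_mask[d_spb[1], d_spb[2]]
      if (in_bud && is.na(events$entry_frame[i])) events$entry_frame[i] <- t
      spb_rows[[length(spb_rows) + 1L]] <- data.frame(
        frame = t, cell = i, role = c("d", "m"),
        row = c(d_spb[1], m_spb[1]), col = c(d_spb[2], m_spb[2]))

      # nucleolus offset perpendicular to the spindle axis, in the mother
      v <- c(u[2], -u[1])
      nuc_mask <- disk_mask(ny, nx, m + 7 * v, 3.5)
      nlabs[nuc_mask] <- i

      # planted enrichment profiles
      e_spb <- if (t >= t0 && t <= sched$exit_frame) config$spb_enrichment_ana else 0
      e_nuc <- if (t >= t0 + 2L && t <= sched$exit_frame) config$nuc_enrichment_ana else 0
      enr_rows[[length(enr_rows) + 1L]] <- data.frame(
        frame = t, cell = i, e_spb = e_spb, e_nuc = e_nuc)

      cell_mask <- if (is.null(bud_mask)) mother_mask else mother_mask | bud_mask

      if ("spb" %in% chans) {
        sig$spb <- sig$spb + gaussian_spot(ny, nx, d_spb, bl$spb) +
          gaussian_spot(ny, nx, m_spb, bl$spb)
      }
      if ("nucleolus" %in% chans) {
        sig$nucleolus[nuc_mask] <- bl$nucleolus
      }
      if ("probe" %in% chans) {
        base <- matrix(0, ny, nx)
        base[cell_mask] <- bl$probe
        base[nuc_mask] <- bl$probe * (1 + e_nuc)
        spots <- gaussian_spot(ny, nx, d_spb, bl$probe * e_spb) +
          gaussian_spot(ny, nx, m_spb, bl$probe * e_spb)
        sig$probe <- sig$probe + base + spots
      }
      if ("cdc14" %in% chans) {
        # nucleolar Cdc14 dips to (1 - release_depth) three frames after
        # bud entry (entry occurs ~2 frames after onset by the spindle
        # geometry), then partially recovers by mitotic exit
        tmin_f <- t0 + 5L
        c14 <- if (t < t0 + 2L) {
          1
        } else if (t <= tmin_f) {
          1 - config$release_depth * (t - (t0 + 2L)) / (tmin_f - (t0 + 2L))
        } else if (t <= sched$exit_frame) {
          (1 - config$release_depth) +
            (0.9 - (1 - config$release_depth)) *
              (t - tmin_f) / (sched$exit_frame - tmin_f)
        } else {
          0.9
        }
        sig$cdc14[cell_mask] <- 0.2 * bl$cdc14
        sig$cdc14[nuc_mask] <- bl$cdc14 * c14
        c14_rows[[length(c14_rows) + 1L]] <- data.frame(
          frame = t, cell = i, c14 = c14)
      }
      if ("reporter" %in% chans) {
        nuc_disk <- disk_mask(ny, nx, m, 5)
        rep_img <- matrix(0, ny, nx)
        if (t <= sched$exit_frame) {
          rep_img[cell_mask] <- bl$reporter_cyt
          rep_img[nuc_disk & cell_mask] <- bl$reporter_nuc
        } else {
          area <- sum(cell_mask)
          mean_lvl <- (bl$reporter_nuc * sum(nuc_disk & cell_mask) +
                         bl$reporter_cyt * (area - sum(nuc_disk & cell_mask))) / area
          rep_img[cell_mask] <- mean_lvl
        }
        sig$reporter <- sig$reporter + rep_img
      }
    }

    bleach <- exp(-config$bleach_rate * (t - 1L))
    for (k in seq_along(chans)) {
      img <- sig[[chans[k]]] * bleach + config$background
      if (config$noise_sd > 0) {
        img <- img * (1 + stats::rnorm(length(img), 0, config$noise_sd))
        img[img < 0] <- 0
      }
      data[t, k, , ] <- img
    }
    cell_masks[[t]] <- labs
    nucl_masks[[t]] <- nlabs
  }

  mv <- movie(data, chans, config$pixel_size_um, config$frame_interval_min)
  truth <- list(
    cell_masks = cell_masks,
    nucleolus_masks = nucl_masks,
    spb = do.call(rbind, c(spb_rows, list(make.row.names = FALSE))),
    events = events,
    enrichment = do.call(rbind, c(enr_rows, list(make.row.names = FALSE))),
    cdc14_profile = if (length(c14_rows)) {
      do.call(rbind, c(c14_rows, list(make.row.names = FALSE)))
    } else NULL,
    shifts = shifts,
    config = config
  )
  list(movie = mv, truth = truth)
}
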