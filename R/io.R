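#' Write a movie as multi-page TIFF with a YAML sidecar
#'
#' Pages are ordered frame-major, channel-minor (page `(t-1) * C + c`), and
#' intensities are stored as 32-bit floats scaled into \[0, 1\] by a scale
#' factor recorded in the sidecar. The sidecar documents the axis order
#' (`TCYX`), channel names, pixel size and frame interval, so
#' [read_movie()] can reconstruct the movie exactly (to 32-bit float
#' precision).
#'
#' @param x A [movie()].
#' @param path Output TIFF path.
#' @param sidecar Output YAML path (default: `path` with `.yaml`).
#' @return Invisibly, the sidecar metadata list.
#' @export
write_movie <- function(x, path, sidecar = paste0(path, ".yaml")) {
  stopifnot(inherits(x, "movie"))
  d <- dim(x$data)
  scale <- max(x$data, 1e-12)
  pages <- vector("list", d[1] * d[2])
  for (t in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      pages[[(t - 1L) * d[2] + ch]] <- x$data[t, ch, , ] / scale
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(axes = "TCYX", n_frames = d[1], channels = as.list(x$channels),
               ny = d[3], nx = d[4], pixel_size_um = x$pixel_size_um,
               frame_interval_min = x$frame_interval_min,
               intensity_scale = scale)
  yaml::write_yaml(meta, sidecar)
  invisible(meta)
}

#' Read a movie from TIFF plus YAML sidecar
#'
#' @param path TIFF path written by [write_movie()].
#' @param sidecar Sidecar YAML path.
#' @param channels Optional channel names that must be present; a missing
#'   channel raises an error naming it.
#' @return A [movie()].
#' @export
read_movie <- function(path, sidecar = paste0(path, ".yaml"),
                       channels = NULL) {
  meta <- yaml::read_yaml(sidecar)
  need <- c("axes", "n_frames", "channels", "pixel_size_um",
            "frame_interval_min", "intensity_scale")
  missing_meta <- setdiff(need, names(meta))
  if (length(missing_meta)) {
    stop("sidecar missing fields: ", paste(missing_meta, collapse = ", "))
  }
  if (!identical(meta$axes, "TCYX")) {
    stop(sprintf("unsupported axis order '%s' (expected TCYX)", meta$axes))
  }
  chs <- unlist(meta$channels)
  if (!is.null(channels)) {
    absent <- setdiff(channels, chs)
    if (length(absent)) {
      stop("channel(s) not in sidecar: ", paste(absent, collapse = ", "))
    }
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nt <- meta$n_frames; nc <- length(chs)
  if (length(pages) != nt * nc) {
    stop(sprintf("TIFF has %d pages, sidecar declares %d frames x %d channels",
                 length(pages), nt, nc))
  }
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  data <- array(0, c(nt, nc, ny, nx))
  for (t in seq_len(nt)) {
    for (ch in seq_len(nc)) {
      data[t, ch, , ] <- pages[[(t - 1L) * nc + ch]] * meta$intensity_scale
    }
  }
  movie(data, chs, meta$pixel_size_um, meta$frame_interval_min)
}

#' Write / read a FRAP trace as CSV
#'
#' Columns: `time_s`, `i_spb`, `i_cytosol`, `role` with role `"pre"` for
#' pre-bleach frames, `"bleach"` for the first post-bleach frame and
#' `"post"` for the rest. The pre-bleach reference is the last `"pre"` row.
#'
#' @param trace A [frap_trace()].
#' @param path CSV path.
#' @return `write_frap_trace` returns the path invisibly;
#'   `read_frap_trace` returns a [frap_trace()].
#' @export
write_frap_trace <- function(trace, path) {
  stopifnot(inherits(trace, "frap_trace"))
  role <- rep("post", length(trace$time_s))
  role[seq_len(trace$pre)] <- "pre"
  role[trace$bleach] <- "bleach"
  utils::write.csv(
    data.frame(time_s = trace$time_s, i_spb = trace$i_spb,
               i_cytosol = trace$i_cytosol, role = role),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frap_trace
#' @export
read_frap_trace <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time_s", "i_spb", "i_cytosol", "role") %in% names(d)))
  pre <- max(which(d$role == "pre"))
  bleach <- which(d$role == "bleach")
  if (length(bleach) != 1L) stop("trace must mark exactly one 'bleach' frame")
  frap_trace(d$time_s, d$i_spb, d$i_cytosol, pre = pre, bleach = bleach)
}
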