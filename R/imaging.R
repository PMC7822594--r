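#' Translate an image by an integer pixel shift
#'
#' @param img Numeric or logical matrix.
#' @param shift `c(dy, dx)` integer shift: content moves down/right for
#'   positive values; vacated pixels take `fill`.
#' @param fill Fill value (default 0).
#' @return Shifted matrix of the same dimensions.
#' @keywords internal
translate_image <- function(img, shift, fill = 0) {
  dy <- as.integer(round(shift[1])); dx <- as.integer(round(shift[2]))
  out <- matrix(fill, nrow(img), ncol(img))
  src_r <- seq_len(nrow(img)) - dy
  src_c <- seq_len(ncol(img)) - dx
  ok_r <- src_r >= 1L & src_r <= nrow(img)
  ok_c <- src_c >= 1L & src_c <= ncol(img)
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

#' Estimate the integer shift between a reference and an image
#'
#' Maximizes the circular cross-correlation (computed by FFT) between the
#' reference and the image over shifts within `max_shift` pixels, and
#' returns the translation that aligns the image to the reference.
#'
#' @param ref,img Numeric matrices of equal dimensions.
#' @param max_shift Search window half-width in pixels (default 10).
#' @return `c(dy, dx)`: apply [translate_image()] with this shift to align
#'   `img` onto `ref`. Featureless inputs give `c(0, 0)` with a warning.
#' @export
estimate_shift <- function(ref, img, max_shift = 10L) {
  stopifnot(identical(dim(ref), dim(img)))
  if (stats::sd(ref) == 0 || stats::sd(img) == 0) {
    warning("featureless frame; assuming zero shift")
    return(c(0L, 0L))
  }
  cc <- Re(stats::fft(Conj(stats::fft(ref)) * stats::fft(img),
                      inverse = TRUE)) / length(ref)
  ny <- nrow(ref); nx <- ncol(ref)
  # wrap frequencies to signed shifts and restrict to the window
  sy <- ifelse(seq_len(ny) - 1L > ny %/% 2, seq_len(ny) - 1L - ny,
               seq_len(ny) - 1L)
  sx <- ifelse(seq_len(nx) - 1L > nx %/% 2, seq_len(nx) - 1L - nx,
               seq_len(nx) - 1L)
  ok <- outer(abs(sy) <= max_shift, abs(sx) <= max_shift, `&`)
  cc[!ok] <- -Inf
  peak <- arrayInd(which.max(cc), dim(cc))
  offset <- c(sy[peak[1]], sx[peak[2]])  # img is ref moved by +offset
  -offset
}

#' Drift correction of a time-lapse movie
#'
#' Aligns every frame to the reference frame (by default the last frame,
#' which also anchors cell tracking) by maximizing image cross-correlation
#' on the chosen channel, then resamples all channels by the same
#' integer-pixel shift.
#'
#' @param movie A [movie()] object.
#' @param reference_channel Channel name used for the alignment.
#' @param reference_frame Frame all others are aligned to (default: last).
#' @param max_shift Search window half-width, pixels.
#' @return List with `movie` (drift-corrected) and `shifts` (T x 2 matrix
#'   of applied `(dy, dx)` shifts).
#' @export
correct_drift <- function(movie, reference_channel,
                          reference_frame = n_frames(movie),
                          max_shift = 10L) {
  stopifnot(inherits(movie, "movie"), n_frames(movie) >= 2L)
  ci <- channel_index(movie, reference_channel)
  ref <- movie$data[reference_frame, ci, , ]
  shifts <- matrix(0L, n_frames(movie), 2,
                   dimnames = list(NULL, c("dy", "dx")))
  out <- movie$data
  for (t in seq_len(n_frames(movie))) {
    if (t == reference_frame) next
    s <- estimate_shift(ref, movie$data[t, ci, , ], max_shift)
    shifts[t, ] <- s
    if (any(s != 0L)) {
      for (ch in seq_len(dim(out)[2])) {
        out[t, ch, , ] <- translate_image(movie$data[t, ch, , ], s)
      }
    }
  }
  movie$data <- out
  list(movie = movie, shifts = shifts)
}

#' Segment a fluorescent marker image
#'
#' Thresholds a background-subtracted single-channel image with Otsu's
#' method and labels connected components, discarding objects below a
#' minimum area. A blank image yields an empty labeling, not an error.
#'
#' @param frame Single-channel image (matrix).
#' @param background Scalar background estimate subtracted before
#'   thresholding (default 0: already subtracted).
#' @param min_area Minimum object area in pixels (default 4).
#' @return Integer label matrix (0 = background).
#' @export
segment_marker <- function(frame, background = 0, min_area = 4L) {
  stopifnot(is.matrix(frame))
  x <- frame - background
  x[x < 0] <- 0
  rng <- range(x)
  if (diff(rng) == 0) {
    return(matrix(0L, nrow(frame), ncol(frame)))
  }
  xs <- (x - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(xs), range = c(0, 1))
  lab <- EBImage::bwlabel(xs > thr)
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(frame), ncol(frame))
  counts <- tabulate(lab)
  small <- which(counts < min_area)
  if (length(small)) lab[lab %in% small] <- 0L
  # relabel consecutively
  keep <- sort(unique(lab[lab > 0L]))
  if (length(keep)) lab <- matrix(match(lab, keep, nomatch = 0L) * (lab > 0L),
                                  nrow(frame), ncol(frame)) + 0L
  storage.mode(lab) <- "integer"
  lab
}

#' Centroids of a label matrix
#'
#' @param labels Integer label matrix.
#' @return Data frame with `label`, `row`, `col` (centroid, 1-based) and
#'   `area`.
#' @export
label_centroids <- function(labels) {
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids)) {
    return(data.frame(label = integer(), row = numeric(), col = numeric(),
                      area = integer()))
  }
  idx <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[labels > 0L]
  data.frame(
    label = ids,
    row = as.numeric(tapply(idx[, 1], lab, mean)[as.character(ids)]),
    col = as.numeric(tapply(idx[, 2], lab, mean)[as.character(ids)]),
    area = as.integer(table(lab)[as.character(ids)]),
    row.names = NULL
  )
}

#' Detect spindle pole bodies inside a cell mask
#'
#' Finds up to two local intensity maxima of the SPB-marker channel inside
#' the cell mask, sorted by decreasing intensity. A peak qualifies only when
#' it stands clearly above the in-mask intensity distribution (above the
#' median by both three median absolute deviations and 25% of the median),
#' so a uniform cell yields no detections. The second peak must lie at least
#' `min_separation` pixels from the first.
#'
#' @param spb_frame SPB-marker channel image (background-subtracted).
#' @param cell_mask Logical matrix for the cell.
#' @param max_points Maximum detections (default 2).
#' @param min_separation Minimum peak separation, pixels (default 3).
#' @return Numeric matrix with columns `row`, `col`, `intensity` (0 rows
#'   when no spot is present).
#' @export
detect_spbs <- function(spb_frame, cell_mask, max_points = 2L,
                        min_separation = 3) {
  stopifnot(identical(dim(spb_frame), dim(cell_mask)))
  if (!any(cell_mask)) stop("empty cell mask")
  vals <- spb_frame[cell_mask]
  med <- stats::median(vals)
  thr <- med + max(3 * stats::mad(vals), 0.25 * abs(med), 1e-12)
  work <- spb_frame
  work[!cell_mask] <- -Inf
  pts <- matrix(numeric(), 0, 3, dimnames = list(NULL, c("row", "col",
                                                         "intensity")))
  for (k in seq_len(max_points)) {
    i <- which.max(work)
    v <- work[i]
    if (!is.finite(v) || v <= thr) break
    rc <- arrayInd(i, dim(work))
    pts <- rbind(pts, c(rc[1], rc[2], v))
    px <- disk_pixels(c(rc[1], rc[2]), min_separation, dim(work))
    work[px] <- -Inf
  }
  pts
}

#' Track cells backward from the last frame by mask overlap
#'
#' Propagates cell identities from the last frame backwards: each labeled
#' object in frame t is matched to the identity in frame t + 1 with which
#' it shares the largest pixel overlap (ties broken by larger overlap area,
#' then lower cell id). Objects without any overlapping successor receive a
#' fresh id, so a cell that disappears mid-movie keeps a track that ends at
#' its last visible frame.
#'
#' @param masks List of integer label matrices, one per (drift-corrected)
#'   frame.
#' @return List with `labels` (relabeled matrices with consistent ids
#'   across frames) and `table` (data frame: `frame`, `cell_id`, `row`,
#'   `col`, `area`).
#' @export
track_cells <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 1L)
  n <- length(masks)
  out <- vector("list", n)
  out[[n]] <- masks[[n]]
  next_id <- max(0L, masks[[n]])
  for (t in rev(seq_len(n - 1L))) {
    cur <- masks[[t]]
    nxt <- out[[t + 1L]]
    relab <- matrix(0L, nrow(cur), ncol(cur))
    objs <- sort(unique(cur[cur > 0L]))
    if (length(objs)) {
      both <- cur > 0L & nxt > 0L
      cand <- if (any(both)) {
        ov <- table(cur[both], nxt[both])
        data.frame(obj = as.integer(rep(rownames(ov), ncol(ov))),
                   id = as.integer(rep(colnames(ov), each = nrow(ov))),
                   overlap = as.integer(ov))
      } else {
        data.frame(obj = integer(), id = integer(), overlap = integer())
      }
      cand <- cand[cand$overlap > 0L, , drop = FALSE]
      cand <- cand[order(-cand$overlap, cand$id), , drop = FALSE]
      assigned_obj <- integer(); assigned_id <- integer()
      for (i in seq_len(nrow(cand))) {
        if (cand$obj[i] %in% assigned_obj || cand$id[i] %in% assigned_id) next
        relab[cur == cand$obj[i]] <- cand$id[i]
        assigned_obj <- c(assigned_obj, cand$obj[i])
        assigned_id <- c(assigned_id, cand$id[i])
      }
      for (o in setdiff(objs, assigned_obj)) {
        next_id <- next_id + 1L
        relab[cur == o] <- next_id
      }
    }
    out[[t]] <- relab
  }
  tabs <- lapply(seq_len(n), function(t) {
    cen <- label_centroids(out[[t]])
    if (!nrow(cen)) return(NULL)
    data.frame(frame = t, cell_id = cen$label, row = cen$row, col = cen$col,
               area = cen$area)
  })
  list(labels = out,
       table = do.call(rbind, c(tabs, list(make.row.names = FALSE))))
}

#' Assign buds to mother cells via migrating cell-cycle markers
#'
#' A tracked cell in which the cell-cycle marker (e.g. the SPB marker)
#' first appears after the first frame is a bud; its mother is the cell
#' that hosted the same marker object in the preceding frame. Marker
#' objects are themselves tracked by backward overlap, so "the same marker
#' object" means the marker track whose centroid lies in the bud at its
#' first-appearance frame. Two marker tracks arriving from different
#' mothers leave the bud unassigned with a warning; a marker with no
#' earlier history (appearing de novo in the bud) yields no link.
#'
#' @param cell_labels List of tracked cell label matrices (from
#'   [track_cells()]).
#' @param marker_masks List of labeled marker-object matrices per frame
#'   (from [segment_marker()]).
#' @return Data frame with `bud_id`, `mother_id` (`NA` when unassigned) and
#'   `marker_frame` (first frame the marker appeared in the bud).
#' @export
assign_buds <- function(cell_labels, marker_masks) {
  stopifnot(length(cell_labels) == length(marker_masks))
  n <- length(cell_labels)
  mtrack <- track_cells(marker_masks)

  cell_at <- function(t, p) {
    r <- round(p[1]); c <- round(p[2])
    lab <- cell_labels[[t]]
    if (r < 1 || c < 1 || r > nrow(lab) || c > ncol(lab)) return(0L)
    lab[r, c]
  }
  # per frame: which cell hosts each marker track (by centroid)
  host <- lapply(seq_len(n), function(t) {
    cen <- label_centroids(mtrack$labels[[t]])
    if (!nrow(cen)) return(integer())
    stats::setNames(vapply(seq_len(nrow(cen)), function(i) {
      cell_at(t, c(cen$row[i], cen$col[i]))
    }, integer(1)), cen$label)
  })

  # first frame each cell contains any marker
  cells <- sort(unique(unlist(lapply(cell_labels,
                                     function(m) m[m > 0L]))))
  first_marker <- stats::setNames(rep(NA_integer_, length(cells)),
                                  cells)
  for (t in seq_len(n)) {
    hosted <- unique(host[[t]][host[[t]] > 0L])
    for (cid in hosted) {
      k <- as.character(cid)
      if (is.na(first_marker[k])) first_marker[k] <- t
    }
  }

  links <- list()
  for (k in names(first_marker)) {
    f <- first_marker[[k]]
    if (is.na(f) || f <= 1L) next  # marker from the start (or never): not a bud
    bud <- as.integer(k)
    # marker tracks inside the bud at frame f
    mk <- as.integer(names(host[[f]])[host[[f]] == bud])
    mothers <- integer()
    for (m in mk) {
      prev <- host[[f - 1L]]
      if (as.character(m) %in% names(prev)) {
        mom <- prev[[as.character(m)]]
        if (mom > 0L && mom != bud) mothers <- c(mothers, mom)
      }
    }
    mothers <- unique(mothers)
    mother <- if (length(mothers) == 1L) {
      mothers
    } else if (length(mothers) > 1L) {
      warning(sprintf("bud %d: ambiguous mother (candidates %s); unassigned",
                      bud, paste(mothers, collapse = ", ")))
      NA_integer_
    } else {
      NA_integer_
    }
    if (length(mothers) >= 1L || length(mk)) {
      links[[length(links) + 1L]] <- data.frame(
        bud_id = bud, mother_id = mother, marker_frame = f
      )
    }
  }
  if (!length(links)) {
    return(data.frame(bud_id = integer(), mother_id = integer(),
                      marker_frame = integer()))
  }
  do.call(rbind, c(links, list(make.row.names = FALSE)))
}

#' Estimate image background outside all cells
#'
#' Median intensity of the pixels outside the union of cell masks.
#'
#' @param frame Single-channel image (matrix).
#' @param cell_union Logical matrix: `TRUE` inside any cell.
#' @return Scalar background estimate.
#' @export
estimate_background <- function(frame, cell_union) {
  stopifnot(identical(dim(frame), dim(cell_union)))
  outside <- !cell_union
  if (!any(outside)) {
    stop("no pixels outside the cell masks; supply a background estimate")
  }
  stats::median(frame[outside])
}
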