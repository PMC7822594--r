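# Shared fixtures built in code: tiny images and peptide tables.

# uniform disk cell with optional SPB spot and nucleolar patch
make_cell_image <- function(ny = 60, nx = 60, center = c(30, 30), radius = 15,
                            baseline = 100, spot = NULL, spot_peak = NULL,
                            nucleolus_center = NULL, nucleolus_radius = 4,
                            nucleolus_level = NULL) {
  row <- matrix(seq_len(ny), ny, nx)
  col <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  cell <- (row - center[1])^2 + (col - center[2])^2 <= radius^2
  img <- matrix(0, ny, nx)
  img[cell] <- baseline
  nuc <- matrix(FALSE, ny, nx)
  if (!is.null(nucleolus_center)) {
    nuc <- (row - nucleolus_center[1])^2 + (col - nucleolus_center[2])^2 <=
      nucleolus_radius^2
    img[nuc] <- nucleolus_level
  }
  if (!is.null(spot)) {
    d2 <- (row - spot[1])^2 + (col - spot[2])^2
    g <- exp(-d2 / 2)
    g[d2 > 25] <- 0
    img <- img + (spot_peak - baseline) * g
  }
  list(img = img, cell = cell, nucleolus = nuc)
}

# minimal long-format peptide table from a wide spec:
# rows list(peptide_id, sites, n_phospho, wt = c(...), as1 = c(...)) with NA
# for non-detections
make_peptide_table <- function(rows, protein = "P1") {
  do.call(rbind, lapply(rows, function(r) {
    rbind(
      data.frame(protein = protein, peptide_id = r$peptide_id,
                 sites = r$sites, n_phospho = r$n_phospho,
                 condition = "WT", replicate = seq_along(r$wt),
                 intensity = r$wt, stringsAsFactors = FALSE),
      data.frame(protein = protein, peptide_id = r$peptide_id,
                 sites = r$sites, n_phospho = r$n_phospho,
                 condition = "as1", replicate = seq_along(r$as1),
                 intensity = r$as1, stringsAsFactors = FALSE)
    )
  }))
}

# textbook BH step-up by direct sorting (independent of stats::p.adjust)
bh_textbook <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# brute-force reimplementation of the three differential-calling rules,
# operating on one peptide's replicate vectors
brute_force_hit <- function(wt, as1, p_adj, wt_min, ratio_threshold = 2) {
  wt_d <- wt[!is.na(wt)]; as1_d <- as1[!is.na(as1)]
  if (length(wt_d) >= 2 && length(as1_d) >= 2) {
    return(mean(wt_d) / mean(as1_d) > ratio_threshold &&
             !is.na(p_adj) && p_adj < 0.05)
  }
  if (length(as1_d) == 0 && length(wt_d) >= wt_min) return(TRUE)
  if (length(as1_d) == 1 && length(wt_d) >= wt_min &&
      mean(wt_d) / as1_d > ratio_threshold) return(TRUE)
  FALSE
}
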