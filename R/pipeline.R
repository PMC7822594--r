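#' Quantify probe localization across a movie
#'
#' Runs the per-frame measurement stage on a (drift-corrected) movie given
#' per-frame cell label masks: estimates the background outside all cells,
#' segments the nucleolar marker inside each cell, detects up to two SPBs
#' from the SPB-marker channel, and computes the relative probe enrichment
#' at the brightest SPB and in the nucleolus against the cytosol (cell
#' area minus nucleolus and dilated SPB disks).
#'
#' @param mv A [movie()] containing at least the `probe`, `spb` and
#'   `nucleolus` channels.
#' @param cell_masks Per-frame integer label matrices (one label per cell;
#'   mother and bud merged if they should be quantified as one cell).
#' @param probe_channel,spb_channel,nucleolus_channel Channel names.
#' @param dilation_radius SPB dilation radius in pixels (default 2).
#' @return Long data frame: `frame`, `cell_id`, `metric`
#'   (`"spb_enrichment"` / `"nucleolar_enrichment"`), `value` (`NA` when
#'   the compartment was not found in that frame).
#' @export
quantify_movie <- function(mv, cell_masks, probe_channel = "probe",
                           spb_channel = "spb",
                           nucleolus_channel = "nucleolus",
                           dilation_radius = 2) {
  stopifnot(inherits(mv, "movie"), length(cell_masks) == n_frames(mv))
  rows <- list()
  for (t in seq_len(n_frames(mv))) {
    labs <- cell_masks[[t]]
    union_mask <- labs > 0L
    probe <- get_frame(mv, t, probe_channel)
    spb <- get_frame(mv, t, spb_channel)
    nucl <- get_frame(mv, t, nucleolus_channel)
    bg_probe <- estimate_background(probe, union_mask)
    bg_spb <- estimate_background(spb, union_mask)
    bg_nucl <- estimate_background(nucl, union_mask)
    probe_bs <- probe - bg_probe
    spb_bs <- spb - bg_spb
    nucl_seg <- segment_marker(nucl, background = bg_nucl)

    for (cid in sort(unique(labs[labs > 0L]))) {
      cmask <- labs == cid
      pts <- detect_spbs(spb_bs, cmask)
      nmask <- nucl_seg > 0L & cmask
      spb_disks <- matrix(FALSE, nrow(cmask), ncol(cmask))
      if (nrow(pts)) {
        for (j in seq_len(nrow(pts))) {
          spb_disks[disk_pixels(pts[j, 1:2], dilation_radius, dim(cmask))] <- TRUE
        }
      }
      cyt <- cmask & !nmask & !spb_disks
      e_spb <- if (nrow(pts) && any(cyt)) {
        spb_enrichment(probe_bs, pts[1, 1:2], cyt, dilation_radius)
      } else NA_real_
      e_nuc <- if (any(nmask) && any(cyt)) {
        nucleolar_enrichment(probe_bs, nmask, cyt)
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        frame = t, cell_id = cid,
        metric = c("spb_enrichment", "nucleolar_enrichment"),
        value = c(e_spb, e_nuc))
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Merge mother and bud labels into per-division-event masks
#'
#' @param cell_masks Per-frame label matrices from [generate_movie()]
#'   truth (mothers 1..n, bud of cell i labeled n + i).
#' @param events The truth `events` table (columns `cell`, `bud_id`).
#' @return Per-frame label matrices with each bud relabeled to its mother.
#' @export
merge_mother_bud <- function(cell_masks, events) {
  lapply(cell_masks, function(labs) {
    for (i in seq_len(nrow(events))) {
      labs[labs == events$bud_id[i]] <- events$cell[i]
    }
    labs
  })
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the configured stages end to end and writes all stage outputs
#' plus a machine-readable run log (parameters, seed, package version) to
#' the output directory. With `modes = "imaging"` a synthetic movie is
#' generated, drift-corrected, quantified per cell and frame, anaphase
#' onset is detected from the SPB tracks, and the nucleolar-enrichment
#' traces are aligned on onset and averaged with 95% confidence bands.
#' With `modes = "omics"` synthetic phosphoproteomics tables are generated
#' for the CDC5 and CDC15 contrasts and run through differential calling,
#' site calling, kinase-dependence subtraction and zone assignment, plus a
#' TurboID table through ratio thresholding. Outputs are deterministic
#' given the configuration and seed.
#'
#' @param config A named list, or path to a YAML file with the same
#'   structure: fields `modes` (character subset of `c("imaging",
#'   "omics")`), `seed`, `out_dir`, and optional parameter overrides
#'   `movie` (arguments to [movie_config()]), `omics` (fields
#'   `n_background`, `cdc5_residues`, `cdc15_residues`, `n_replicates`,
#'   `fold_change`, `cv`) and `turboid` (`n_proteins`, `planted_protein`,
#'   `enrichment`).
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  modes <- config$modes %||% c("imaging", "omics")
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()

  if ("imaging" %in% modes) {
    margs <- config$movie %||% list()
    margs$seed <- seed
    cfg <- do.call(movie_config, margs)
    sim <- generate_movie(cfg)
    write_movie(sim$movie, file.path(out_dir, "movie.tif"))
    dc <- correct_drift(sim$movie, "nucleolus")
    masks <- merge_mother_bud(sim$truth$cell_masks, sim$truth$events)
    metrics <- quantify_movie(dc$movie, masks)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)

    onsets <- vapply(seq_len(cfg$n_cells), function(i) {
      s <- sim$truth$spb[sim$truth$spb$cell == i, ]
      d <- s[s$role == "d", c("row", "col")]
      m <- s[s$role == "m", c("row", "col")]
      detect_anaphase_onset(as.matrix(d), as.matrix(m), cfg$pixel_size_um)
    }, integer(1))
    events <- data.frame(cell_id = seq_len(cfg$n_cells),
                         onset_frame = onsets)
    utils::write.csv(events, file.path(out_dir, "events.csv"),
                     row.names = FALSE)

    nuc <- metrics[metrics$metric == "nucleolar_enrichment", ]
    traces <- lapply(seq_len(cfg$n_cells), function(i) {
      v <- rep(NA_real_, cfg$n_frames)
      sub <- nuc[nuc$cell_id == i, ]
      v[sub$frame] <- sub$value
      v
    })
    ens <- align_traces(traces, onsets,
                        frame_interval = cfg$frame_interval_min)
    band <- mean_ci(ens)
    utils::write.csv(band, file.path(out_dir, "ensemble.csv"),
                     row.names = FALSE)
    results$imaging <- list(config = cfg, metrics = metrics,
                            events = events, band = band,
                            shifts = dc$shifts)
  }

  if ("omics" %in% modes) {
    oargs <- config$omics %||% list()
    design <- phospho_design(
      n_background = oargs$n_background %||% 30L,
      cdc5_residues = unlist(oargs$cdc5_residues %||% c(201:212)),
      cdc15_residues = unlist(oargs$cdc15_residues %||% c(301:305))
    )
    site_calls <- list()
    for (ctr in c("CDC5", "CDC15")) {
      gen <- generate_peptide_table(
        design, contrast = ctr,
        n_replicates = oargs$n_replicates %||% 7L,
        fold_change = oargs$fold_change %||% 8,
        cv = oargs$cv %||% 0.15,
        seed = seed + match(ctr, c("CDC5", "CDC15")))
      utils::write.csv(gen$table,
                       file.path(out_dir, sprintf("peptides_%s.csv", ctr)),
                       row.names = FALSE)
      calls <- differential_peptides(gen$table, contrast = ctr)
      utils::write.csv(calls,
                       file.path(out_dir, sprintf("peptide_calls_%s.csv", ctr)),
                       row.names = FALSE)
      site_calls[[ctr]] <- call_sites(calls)
      utils::write.csv(site_calls[[ctr]],
                       file.path(out_dir, sprintf("site_calls_%s.csv", ctr)),
                       row.names = FALSE)
    }
    dep <- kinase_dependence(
      site_calls$CDC15[site_calls$CDC15$hit, c("protein", "residue")],
      site_calls$CDC5[site_calls$CDC5$hit, c("protein", "residue")])
    dep$zone <- assign_zones(dep$residue)
    utils::write.csv(dep, file.path(out_dir, "kinase_dependence.csv"),
                     row.names = FALSE)

    targs <- config$turboid %||% list()
    planted <- data.frame(protein = targs$planted_protein %||% "CFI1",
                          enrichment = targs$enrichment %||% 50)
    tb <- generate_turboid_counts(n_proteins = targs$n_proteins %||% 300L,
                                  planted = planted, seed = seed)
    hits <- turboid_hits(turboid_ratios(tb$table))
    utils::write.csv(hits, file.path(out_dir, "turboid_hits.csv"),
                     row.names = FALSE)
    results$omics <- list(dependence = dep, site_calls = site_calls,
                          turboid = hits)
  }

  log <- list(
    package = "menquant",
    version = as.character(utils::packageVersion("menquant")),
    seed = seed, modes = modes,
    parameters = config[setdiff(names(config), c("out_dir"))]
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}
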