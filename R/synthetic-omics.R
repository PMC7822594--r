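#' Design table for a synthetic phosphoproteomics experiment
#'
#' One row per phospho-site; each site gets a singly phosphorylated peptide
#' in the generated table (plus optional multi-phospho peptides). Sites
#' marked dependent on a kinase lose intensity by `fold_change` in the
#' inhibited (`as1`) condition of that kinase's contrast.
#'
#' @param n_background Number of unaffected sites.
#' @param cdc5_residues,cdc15_residues Residue positions (1-based) of sites
#'   dependent on CDC5 / CDC15 (overlap allowed: sites dependent on both).
#' @param background_residues Optional explicit positions for the background
#'   sites; defaults to positions following the planted ones.
#' @param protein Protein identifier (single protein by default).
#' @return Data frame with `protein`, `residue`, `cdc5_dependent`,
#'   `cdc15_dependent`.
#' @export
phospho_design <- function(n_background = 30L,
                           cdc5_residues = integer(),
                           cdc15_residues = integer(),
                           background_residues = NULL,
                           protein = "CFI1") {
  planted <- sort(unique(c(cdc5_residues, cdc15_residues)))
  if (is.null(background_residues)) {
    pool <- setdiff(seq_len(length(planted) * 10L + n_background * 10L + 10L),
                    planted)
    background_residues <- pool[seq_len(n_background)]
  }
  residues <- c(planted, background_residues)
  data.frame(
    protein = protein,
    residue = as.integer(residues),
    cdc5_dependent = residues %in% cdc5_residues,
    cdc15_dependent = residues %in% cdc15_residues,
    stringsAsFactors = FALSE
  )
}

#' Simulate a replicate-structured phosphopeptide intensity table
#'
#' Generates a long-format peptide intensity table for one kinase contrast
#' (`WT` vs `as1`), with log-normal intensities, a planted fold drop for
#' kinase-dependent sites in the inhibited condition, and missingness from a
#' detection floor: intensities falling below `detection_floor` are recorded
#' as `NA` (not detected), the way an MS detection limit silently drops low
#' signals. One singly phosphorylated peptide is generated per site; sites
#' listed in `multi_groups` additionally contribute shared multi-phospho
#' peptides.
#'
#' @param design A [phospho_design()] data frame.
#' @param contrast `"CDC5"` or `"CDC15"`: which dependence column drives the
#'   planted drop.
#' @param n_replicates Replicates per condition (default 7).
#' @param fold_change Planted fold drop in `as1` for dependent sites
#'   (default 8; must be > 0).
#' @param cv Replicate-to-replicate coefficient of variation (default 0.15).
#' @param base_intensity Median peptide intensity, arbitrary units.
#' @param base_sdlog Log-sd of the per-peptide baseline spread.
#' @param detection_floor Intensity below which a measurement is recorded as
#'   missing (default 0: no missingness).
#' @param multi_groups Optional list of integer vectors of residues; each
#'   vector yields one multi-phospho peptide covering those sites.
#' @param seed Integer seed; the table is fully determined by it.
#' @return List with `table` (long format: `protein`, `peptide_id`, `sites`,
#'   `n_phospho`, `condition`, `replicate`, `intensity`) and `truth` (the
#'   design with an added `affected` column for this contrast).
#' @export
generate_peptide_table <- function(design, contrast = c("CDC5", "CDC15"),
                                   n_replicates = 7L, fold_change = 8,
                                   cv = 0.15, base_intensity = 1e6,
                                   base_sdlog = 0.5, detection_floor = 0,
                                   multi_groups = NULL, seed = 1L) {
  contrast <- match.arg(contrast)
  if (!is.numeric(fold_change) || fold_change <= 0) {
    stop("`fold_change` must be > 0")
  }
  stopifnot(n_replicates >= 2L, cv > 0)
  set.seed(as.integer(seed))
  dep_col <- if (contrast == "CDC5") "cdc5_dependent" else "cdc15_dependent"
  affected <- design[[dep_col]]

  peptides <- data.frame(
    protein = design$protein,
    peptide_id = sprintf("%s_p%04d", design$protein, design$residue),
    sites = as.character(design$residue),
    n_phospho = 1L,
    affected = affected,
    stringsAsFactors = FALSE
  )
  if (!is.null(multi_groups)) {
    for (g in multi_groups) {
      idx <- match(g, design$residue)
      if (any(is.na(idx))) stop("multi_groups residues must be in the design")
      peptides <- rbind(peptides, data.frame(
        protein = design$protein[idx[1]],
        peptide_id = sprintf("%s_m%s", design$protein[idx[1]],
                             paste(g, collapse = "_")),
        sites = paste(g, collapse = ";"),
        n_phospho = length(g),
        # a multi-phospho peptide is lost when any of its sites is dephosphorylated
        affected = any(affected[idx]),
        stringsAsFactors = FALSE
      ))
    }
  }

  sdlog <- sqrt(log(1 + cv^2))
  conds <- c("WT", "as1")
  rows <- vector("list", nrow(peptides))
  for (i in seq_len(nrow(peptides))) {
    base_i <- base_intensity * stats::rlnorm(1, 0, base_sdlog)
    for (cond in conds) {
      mu <- base_i
      if (cond == "as1" && peptides$affected[i]) mu <- mu / fold_change
      vals <- mu * stats::rlnorm(n_replicates, -sdlog^2 / 2, sdlog)
      if (detection_floor > 0) vals[vals < detection_floor] <- NA_real_
      rows[[i]] <- rbind(rows[[i]], data.frame(
        protein = peptides$protein[i], peptide_id = peptides$peptide_id[i],
        sites = peptides$sites[i], n_phospho = peptides$n_phospho[i],
        condition = cond, replicate = seq_len(n_replicates),
        intensity = vals, stringsAsFactors = FALSE
      ))
    }
  }
  table <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  truth <- design
  truth$affected <- affected
  list(table = table, truth = truth)
}

#' Simulate a TurboID peptide-count table
#'
#' Per-protein total peptide counts for a TurboID-tagged sample and an
#' untagged control. Background proteins (endogenously biotinylated or
#' nonspecific) have tagged/control ratios scattered around 1; planted
#' interactors are enriched in the tagged sample by their `enrichment`
#' factor.
#'
#' @param n_proteins Number of background proteins (>= 10).
#' @param planted Optional data frame with `protein` and `enrichment`
#'   columns for the true interactors.
#' @param base_count Mean control peptide count per background protein.
#' @param background_ratio_sd Log-scale spread of background tagged/control
#'   ratios (default 0.15).
#' @param seed Integer seed.
#' @return List with `table` (`protein`, `tagged_peptides`,
#'   `control_peptides`) and `truth` (`protein`, `interactor` flag).
#' @export
generate_turboid_counts <- function(n_proteins = 100L, planted = NULL,
                                    base_count = 20, background_ratio_sd = 0.15,
                                    seed = 1L) {
  if (n_proteins < 10L) stop("`n_proteins` must be >= 10")
  set.seed(as.integer(seed))
  prot <- sprintf("bg%03d", seq_len(n_proteins))
  lam <- stats::rlnorm(n_proteins, log(base_count), 0.4)
  control <- stats::rpois(n_proteins, lam)
  tagged <- stats::rpois(n_proteins, lam * exp(stats::rnorm(n_proteins, 0,
                                                            background_ratio_sd)))
  table <- data.frame(protein = prot, tagged_peptides = tagged,
                      control_peptides = control, stringsAsFactors = FALSE)
  truth <- data.frame(protein = prot, interactor = FALSE,
                      stringsAsFactors = FALSE)
  if (!is.null(planted) && nrow(planted) > 0) {
    stopifnot(all(c("protein", "enrichment") %in% names(planted)))
    ctl <- stats::rpois(nrow(planted), 1)
    tag <- stats::rpois(nrow(planted), pmax(1, (ctl + 1) * planted$enrichment))
    table <- rbind(table, data.frame(protein = planted$protein,
                                     tagged_peptides = tag,
                                     control_peptides = ctl,
                                     stringsAsFactors = FALSE))
    truth <- rbind(truth, data.frame(protein = planted$protein,
                                     interactor = TRUE,
                                     stringsAsFactors = FALSE))
  }
  list(table = table, truth = truth)
}
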