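#' TurboID enrichment ratios
#'
#' Per-protein enrichment of total peptide counts in the TurboID-tagged
#' sample over the untagged control, with a pseudocount added to both
#' numerator and denominator so proteins absent from the control remain
#' defined: `(tagged + pc) / (control + pc)`.
#'
#' @param table Data frame with columns `protein`, `tagged_peptides`,
#'   `control_peptides` (non-negative counts).
#' @param pseudocount Count added to both samples (default 1).
#' @return The input with an added `ratio` column.
#' @export
turboid_ratios <- function(table, pseudocount = 1) {
  stopifnot(is.data.frame(table), nrow(table) >= 1,
            all(c("protein", "tagged_peptides", "control_peptides") %in%
                  names(table)))
  if (any(table$tagged_peptides < 0) || any(table$control_peptides < 0)) {
    stop("peptide counts must be non-negative")
  }
  table$ratio <- (table$tagged_peptides + pseudocount) /
    (table$control_peptides + pseudocount)
  table
}

#' TurboID hit calling at 10 standard deviations
#'
#' Flags proteins whose enrichment ratio exceeds the mean ratio of all
#' proteins in the sample by more than `n_sd` standard deviations — a
#' deliberately stringent threshold that separates genuine proximity
#' interactors from the broad background of endogenously biotinylated
#' proteins.
#'
#' @param table Output of [turboid_ratios()] (must contain `ratio`).
#' @param n_sd Number of standard deviations above the mean (default 10).
#' @return The input with logical `hit` column and attributes `threshold`,
#'   `mean_ratio`, `sd_ratio`.
#' @export
turboid_hits <- function(table, n_sd = 10) {
  stopifnot("ratio" %in% names(table), nrow(table) >= 3)
  mu <- mean(table$ratio)
  s <- stats::sd(table$ratio)
  if (s == 0) {
    warning("all enrichment ratios identical; no hits can be called")
    table$hit <- FALSE
    thr <- Inf
  } else {
    thr <- mu + n_sd * s
    table$hit <- table$ratio > thr
  }
  attr(table, "threshold") <- thr
  attr(table, "mean_ratio") <- mu
  attr(table, "sd_ratio") <- s
  table
}

#' Benjamini-Hochberg adjustment
#'
#' Linear step-up false-discovery-rate adjustment of a p-value vector
#' (monotone in rank, capped at 1), delegating to [stats::p.adjust()].
#'
#' @param p P-values in \[0, 1\] (`NA` allowed and preserved).
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential phosphopeptide calling between WT and kinase-inhibited cells
#'
#' For each phosphopeptide, compares replicate intensities between the
#' wild-type (`WT`) and analog-sensitive inhibited (`as1`) condition of one
#' kinase contrast and calls hits — peptides whose phosphorylation depends
#' on the kinase — by three rules:
#'
#' 1. **Threshold**: for peptides detected in at least 2 replicates of each
#'    condition, the ratio `R = mean(WT) / mean(as1)` (detected intensities
#'    only) and a two-sided pooled-variance Student's t-test on
#'    log-intensities, BH-adjusted across all such peptides; hit when
#'    `R > 2` and `p_adj < 0.05`.
#' 2. **Absent-in-as1 rescue**: peptides never detected in `as1` but
#'    detected in at least `ceiling((5/7) * n_WT)` WT replicates are hits
#'    regardless of p (with 7 WT replicates this is 5 of 7; with 6, 4 of 6
#'    after rounding to the same fraction).
#' 3. **Single-as1-replicate rescue**: peptides detected in exactly one
#'    `as1` replicate and at least the rule-2 WT minimum, with
#'    `mean(WT) / (the single as1 value) > 2`, are hits.
#'
#' Missing intensities (`NA`) are non-detections; they are excluded from
#' means, never zero-imputed — the rescue rules are what handles
#' missingness.
#'
#' @param table Long-format data frame with columns `protein`, `peptide_id`,
#'   `sites` (";"-separated 1-based residue positions), `n_phospho`,
#'   `condition` (`"WT"`/`"as1"`), `replicate`, `intensity` (`NA` =
#'   not detected).
#' @param contrast Label for the kinase contrast (e.g. `"CDC5"`), recorded
#'   in the output.
#' @param ratio_threshold Fold-change threshold on R (default 2).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param rescue_frac WT detection fraction required by the rescue rules
#'   (default 5/7).
#' @param var_equal Pooled-variance t-test (default `TRUE`); `FALSE` for
#'   Welch.
#' @param log_transform Run the t-test on log intensities (default `TRUE`).
#' @return Data frame of peptide calls: `protein`, `peptide_id`, `sites`,
#'   `n_phospho`, `n_wt`, `n_as1` (detection counts), `ratio`, `p`, `p_adj`,
#'   `rescue` (`"none"`, `"absent-in-as1"`, `"single-as1-replicate"`) and
#'   logical `hit`; attribute `contrast`.
#' @export
differential_peptides <- function(table, contrast = "contrast",
                                  ratio_threshold = 2, alpha = 0.05,
                                  rescue_frac = 5 / 7, var_equal = TRUE,
                                  log_transform = TRUE) {
  req <- c("protein", "peptide_id", "sites", "n_phospho", "condition",
           "replicate", "intensity")
  stopifnot(is.data.frame(table), all(req %in% names(table)))
  conds <- unique(table$condition)
  if (!all(c("WT", "as1") %in% conds)) {
    stop("`condition` must contain both 'WT' and 'as1' labels; got: ",
         paste(conds, collapse = ", "))
  }
  n_wt_design <- length(unique(table$replicate[table$condition == "WT"]))
  wt_min <- ceiling(rescue_frac * n_wt_design)

  split_key <- paste(table$protein, table$peptide_id, sep = "\r")
  groups <- split(table, split_key)

  rows <- lapply(groups, function(g) {
    wt <- g$intensity[g$condition == "WT"]
    as1 <- g$intensity[g$condition == "as1"]
    wt_d <- wt[!is.na(wt)]; as1_d <- as1[!is.na(as1)]
    n_wt <- length(wt_d); n_as1 <- length(as1_d)
    ratio <- p <- NA_real_
    rescue <- "none"
    if (n_wt >= 2L && n_as1 >= 2L) {
      ratio <- mean(wt_d) / mean(as1_d)
      x <- if (log_transform) log(wt_d) else wt_d
      y <- if (log_transform) log(as1_d) else as1_d
      p <- tryCatch(
        stats::t.test(x, y, var.equal = var_equal,
                      alternative = "two.sided")$p.value,
        error = function(e) NA_real_
      )
    } else if (n_as1 == 0L && n_wt >= wt_min) {
      rescue <- "absent-in-as1"
      ratio <- Inf
    } else if (n_as1 == 1L && n_wt >= wt_min) {
      ratio <- mean(wt_d) / as1_d
      if (is.finite(ratio) && ratio > ratio_threshold) {
        rescue <- "single-as1-replicate"
      }
    }
    data.frame(protein = g$protein[1], peptide_id = g$peptide_id[1],
               sites = g$sites[1], n_phospho = g$n_phospho[1],
               n_wt = n_wt, n_as1 = n_as1, ratio = ratio, p = p,
               rescue = rescue, stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  calls$p_adj <- NA_real_
  tested <- !is.na(calls$p)
  calls$p_adj[tested] <- bh_adjust(calls$p[tested])

  threshold_hit <- tested & !is.na(calls$ratio) &
    calls$ratio > ratio_threshold & calls$p_adj < alpha
  calls$hit <- threshold_hit | calls$rescue != "none"
  attr(calls, "contrast") <- contrast
  calls
}

#' Site-level calls from peptide calls
#'
#' Maps peptide-level hits onto individual phosphorylation sites with
#' priority for singly phosphorylated peptides:
#' * a site covered by one or more single-phospho peptides is a **strong**
#'   hit only when *all* of those peptides are hits (any non-hit
#'   single-phospho peptide vetoes the site);
#' * a site detected only in multi-phospho peptides is a **weak** hit when
#'   at least one covering peptide is a hit (a multi-phospho peptide cannot
#'   attribute the loss to one of its sites, hence the weaker label);
#' * otherwise the site is not a hit.
#'
#' @param peptide_calls Output of [differential_peptides()].
#' @return Data frame with `protein`, `residue` (1-based), `strength`
#'   (`"strong"`, `"weak"`, `"none"`), logical `hit`, `n_single`, `n_multi`
#'   and `peptides` (";"-joined supporting peptide ids); one row per
#'   (protein, residue) covered by at least one peptide. Attribute
#'   `contrast` is carried over.
#' @export
call_sites <- function(peptide_calls) {
  stopifnot(all(c("protein", "sites", "n_phospho", "hit") %in%
                  names(peptide_calls)))
  site_list <- strsplit(as.character(peptide_calls$sites), ";", fixed = TRUE)
  n_sites <- lengths(site_list)
  long <- data.frame(
    protein = rep(peptide_calls$protein, n_sites),
    residue = as.integer(unlist(site_list)),
    peptide_id = rep(peptide_calls$peptide_id, n_sites),
    n_phospho = rep(peptide_calls$n_phospho, n_sites),
    hit = rep(peptide_calls$hit, n_sites),
    stringsAsFactors = FALSE
  )
  if (any(is.na(long$residue) | long$residue < 1L)) {
    stop("site annotations must be 1-based residue positions")
  }
  key <- paste(long$protein, long$residue, sep = "\r")
  rows <- lapply(split(long, key), function(g) {
    single <- g$n_phospho == 1L
    if (any(single)) {
      strength <- if (all(g$hit[single])) "strong" else "none"
    } else {
      strength <- if (any(g$hit)) "weak" else "none"
    }
    data.frame(protein = g$protein[1], residue = g$residue[1],
               strength = strength, hit = strength != "none",
               n_single = sum(single), n_multi = sum(!single),
               peptides = paste(unique(g$peptide_id), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$protein, out$residue), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "contrast") <- attr(peptide_calls, "contrast")
  out
}

#' Kinase-dependence labels and the CDC5-only set
#'
#' Given the sites called dependent on CDC15 (MEN activity) and on CDC5,
#' labels each site and forms the CDC5-only set — sites lost upon Cdc5
#' inhibition but not upon Cdc15 inhibition, i.e. attributable to direct
#' Cdc5 phosphorylation rather than to loss of MEN activity:
#' `CDC5-only = CDC5-dependent \ CDC15-dependent`.
#'
#' @param cdc15_sites,cdc5_sites Data frames with `protein` and `residue`
#'   columns (e.g. hit rows of [call_sites()] output).
#' @return Data frame with `protein`, `residue`, logical `cdc15_dependent`,
#'   `cdc5_dependent`, `cdc5_only`; one row per site in either set.
#' @export
kinase_dependence <- function(cdc15_sites, cdc5_sites) {
  key <- function(d) paste(d$protein, d$residue, sep = "\r")
  s15 <- unique(key(cdc15_sites))
  s5 <- unique(key(cdc5_sites))
  all_keys <- union(s15, s5)
  parts <- strsplit(all_keys, "\r", fixed = TRUE)
  out <- data.frame(
    protein = vapply(parts, `[`, "", 1L),
    residue = as.integer(vapply(parts, `[`, "", 2L)),
    cdc15_dependent = all_keys %in% s15,
    cdc5_dependent = all_keys %in% s5,
    stringsAsFactors = FALSE
  )
  out$cdc5_only <- out$cdc5_dependent & !out$cdc15_dependent
  out <- out[order(out$protein, out$residue), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Zone map of Cfi1/Net1
#'
#' Named residue intervals grouping the phosphorylation sites of Cfi1/Net1
#' by its disorder-associated regions: z1 = 31-69, z2 = 160-615,
#' z3 = 676-840, z4 = 1017-1166 (bounds inclusive).
#'
#' @param starts,ends Integer vectors of interval bounds (1-based,
#'   inclusive); must be disjoint and sorted.
#' @param names_ Zone labels.
#' @return A `zone_map` data frame with `zone`, `start`, `end`.
#' @export
zone_map <- function(starts = c(31L, 160L, 676L, 1017L),
                     ends = c(69L, 615L, 840L, 1166L),
                     names_ = paste0("z", seq_along(starts))) {
  stopifnot(length(starts) == length(ends), length(starts) == length(names_),
            all(starts <= ends))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]; names_ <- names_[o]
  if (length(starts) > 1L && any(starts[-1] <= ends[-length(ends)])) {
    stop("zone intervals must be disjoint")
  }
  structure(
    data.frame(zone = names_, start = as.integer(starts),
               end = as.integer(ends), stringsAsFactors = FALSE),
    class = c("zone_map", "data.frame")
  )
}

#' Assign residues to zones
#'
#' Labels each site with the zone whose inclusive interval contains its
#' residue, or `"none"` when it falls between zones.
#'
#' @param residues Integer residue positions (1-based).
#' @param zones A [zone_map()] (default: the Cfi1/Net1 zones).
#' @return Character vector of zone labels.
#' @export
assign_zones <- function(residues, zones = zone_map()) {
  stopifnot(inherits(zones, "zone_map"))
  vapply(as.integer(residues), function(r) {
    i <- which(zones$start <= r & r <= zones$end)
    if (length(i)) zones$zone[i] else "none"
  }, character(1))
}

#' Merge phosphorylation-site catalogs
#'
#' Union of site catalogs — e.g. previously known in-vivo sites, sites
#' identified by phosphoproteomics and sites added by IP-MS — counting each
#' distinct (protein, residue) pair once.
#'
#' @param ... Data frames with `protein` and `residue` columns (empty
#'   frames allowed).
#' @return Data frame of distinct sites, sorted, with attribute `n_sites`.
#' @export
merge_catalogs <- function(...) {
  cats <- list(...)
  pieces <- lapply(cats, function(d) {
    if (is.null(d) || nrow(d) == 0) {
      return(data.frame(protein = character(), residue = integer(),
                        stringsAsFactors = FALSE))
    }
    stopifnot(all(c("protein", "residue") %in% names(d)))
    data.frame(protein = as.character(d$protein),
               residue = as.integer(d$residue), stringsAsFactors = FALSE)
  })
  all_sites <- do.call(rbind, pieces)
  out <- unique(all_sites)
  out <- out[order(out$protein, out$residue), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_sites") <- nrow(out)
  out
}
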