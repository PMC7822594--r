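test_that("TurboID ratios: pseudocount arithmetic and positivity", {
  tb <- data.frame(protein = c("a", "b", "c"),
                   tagged_peptides = c(10, 21, 0),
                   control_peptides = c(10, 1, 0))
  r <- turboid_ratios(tb)
  expect_equal(r$ratio, c(1, 11, 1))
  expect_true(all(r$ratio > 0))
  expect_error(turboid_ratios(data.frame(protein = "a", tagged_peptides = -1,
                                         control_peptides = 0)),
               "non-negative")
})

test_that("TurboID 10-SD hit calling: planted interactor, degenerate table, brute force", {
  # with n proteins the z-score of a single outlier is bounded by
  # n / sqrt(n + 1), so exceeding 10 SD needs the realistic table size of
  # an MS run (hundreds of quantified proteins), not a toy one
  gen <- generate_turboid_counts(n_proteins = 300,
                                 planted = data.frame(protein = "CFI1",
                                                      enrichment = 50),
                                 seed = 7)
  hits <- turboid_hits(turboid_ratios(gen$table))
  expect_identical(hits$protein[hits$hit], "CFI1")
  # brute-force filter on the same table
  thr <- mean(hits$ratio) + 10 * sd(hits$ratio)
  expect_identical(hits$hit, hits$ratio > thr)

  flat <- data.frame(protein = letters[1:5], tagged_peptides = rep(4, 5),
                     control_peptides = rep(4, 5))
  expect_warning(h0 <- turboid_hits(turboid_ratios(flat)), "identical")
  expect_false(any(h0$hit))
})

test_that("no hits are called on unplanted TurboID tables across seeds", {
  n_hit <- vapply(1:20, function(s) {
    gen <- generate_turboid_counts(n_proteins = 100, planted = NULL, seed = s)
    sum(turboid_hits(turboid_ratios(gen$table))$hit)
  }, numeric(1))
  expect_gte(mean(n_hit == 0), 0.95)
})

test_that("BH adjustment equals the textbook step-up and is permutation-stable", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(6)
  for (k in 1:5) {
    p <- runif(50)
    expect_equal(bh_adjust(p), bh_textbook(p))
    perm <- sample(50)
    expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("differential calling applies the threshold and both rescue rules", {
  wt7 <- c(100, 110, 95, 105, 98, 102, 107) * 1e3
  tab <- make_peptide_table(list(
    list(peptide_id = "same", sites = "10", n_phospho = 1,
         wt = wt7, as1 = wt7),
    list(peptide_id = "drop8", sites = "20", n_phospho = 1,
         wt = wt7, as1 = wt7 / 8),
    list(peptide_id = "absent", sites = "30", n_phospho = 1,
         wt = c(wt7[1:6], NA), as1 = rep(NA_real_, 7)),
    list(peptide_id = "single", sites = "40", n_phospho = 1,
         wt = wt7, as1 = c(20e3, rep(NA_real_, 6))),
    list(peptide_id = "single_lowratio", sites = "50", n_phospho = 1,
         wt = wt7, as1 = c(90e3, rep(NA_real_, 6)))
  ))
  calls <- differential_peptides(tab, contrast = "CDC5")
  get <- function(id) calls[calls$peptide_id == id, ]
  expect_false(get("same")$hit)
  d8 <- get("drop8")
  expect_true(d8$hit)
  expect_gt(d8$ratio, 2)
  expect_lt(d8$p_adj, 0.05)
  ab <- get("absent")  # 6/7 WT, 0/7 as1: hit regardless of p
  expect_true(ab$hit)
  expect_identical(ab$rescue, "absent-in-as1")
  sg <- get("single")
  expect_true(sg$hit)
  expect_identical(sg$rescue, "single-as1-replicate")
  expect_false(get("single_lowratio")$hit)
  # invariant: hit implies threshold pass or a rescue tag
  thr_ok <- !is.na(calls$p_adj) & !is.na(calls$ratio) &
    calls$ratio > 2 & calls$p_adj < 0.05
  expect_true(all(!calls$hit | thr_ok | calls$rescue != "none"))
})

test_that("hit flags equal a brute-force reimplementation of the three rules", {
  for (s in 1:5) {
    design <- phospho_design(n_background = 20,
                             cdc5_residues = c(101:106),
                             cdc15_residues = c(104:108))
    gen <- generate_peptide_table(design, "CDC5", fold_change = 6,
                                  detection_floor = 3e5, seed = s)
    calls <- differential_peptides(gen$table, "CDC5")
    n_wt <- length(unique(gen$table$replicate))
    wt_min <- ceiling(5 / 7 * n_wt)
    for (i in seq_len(nrow(calls))) {
      sub <- gen$table[gen$table$peptide_id == calls$peptide_id[i], ]
      wt <- sub$intensity[sub$condition == "WT"]
      as1 <- sub$intensity[sub$condition == "as1"]
      expect_identical(calls$hit[i],
                       brute_force_hit(wt, as1, calls$p_adj[i], wt_min),
                       label = sprintf("seed %d peptide %s", s,
                                       calls$peptide_id[i]))
    }
  }
})

test_that("null tables produce no hits and respect the nominal FDR", {
  hit_frac <- vapply(1:20, function(s) {
    design <- phospho_design(n_background = 40)
    gen <- generate_peptide_table(design, "CDC5", fold_change = 1, seed = s)
    calls <- differential_peptides(gen$table, "CDC5")
    mean(calls$hit)
  }, numeric(1))
  expect_lte(mean(hit_frac), 0.05)
  expect_gte(mean(hit_frac == 0), 0.95)
})

test_that("site calls follow single-phosphopeptide priority", {
  wt7 <- rep(100e3, 7) * c(1, 1.1, 0.95, 1.05, 0.98, 1.02, 1.07)
  tab <- make_peptide_table(list(
    # two single-phospho peptides for site 10, both dropping: strong
    list(peptide_id = "s10a", sites = "10", n_phospho = 1,
         wt = wt7, as1 = wt7 / 8),
    list(peptide_id = "s10b", sites = "10", n_phospho = 1,
         wt = wt7, as1 = wt7 / 10),
    # site 20: single-phospho non-hit vetoes the multi-phospho hit
    list(peptide_id = "s20", sites = "20", n_phospho = 1,
         wt = wt7, as1 = wt7),
    list(peptide_id = "m2030", sites = "20;30", n_phospho = 2,
         wt = wt7, as1 = wt7 / 8),
    # site 40 only in a multi-phospho hit: weak
    list(peptide_id = "m4050", sites = "40;50", n_phospho = 2,
         wt = wt7, as1 = wt7 / 8)
  ))
  sites <- call_sites(differential_peptides(tab, "CDC5"))
  g <- function(res) sites[sites$residue == res, ]
  expect_identical(g(10)$strength, "strong")
  expect_identical(g(20)$strength, "none")
  # site 30 is covered only by the multi-phospho hit: weak
  expect_identical(g(30)$strength, "weak")
  expect_identical(g(40)$strength, "weak")
  expect_true(g(40)$hit)
})

test_that("kinase dependence subtraction reproduces the planted set sizes", {
  # 22 CDC5-dependent sites, 10 shared with an 11-site CDC15 set -> 12 only
  cdc5 <- data.frame(protein = "CFI1", residue = c(101:110, 201:212))
  cdc15 <- data.frame(protein = "CFI1", residue = c(101:110, 301))
  dep <- kinase_dependence(cdc15, cdc5)
  expect_equal(sum(dep$cdc5_only), 12)
  expect_equal(sum(dep$cdc5_dependent) - sum(dep$cdc5_dependent &
                                               dep$cdc15_dependent),
               sum(dep$cdc5_only))
  # empty CDC15 set: everything CDC5-only; identical sets: none
  d2 <- kinase_dependence(cdc5[0, ], cdc5)
  expect_equal(sum(d2$cdc5_only), 22)
  d3 <- kinase_dependence(cdc5, cdc5)
  expect_equal(sum(d3$cdc5_only), 0)
})

test_that("set identity |CDC5-only| = |CDC5| - |intersection| holds on random sets", {
  set.seed(10)
  for (k in 1:10) {
    a <- data.frame(protein = "P", residue = sample(1:80, sample(5:25, 1)))
    b <- data.frame(protein = "P", residue = sample(1:80, sample(5:25, 1)))
    dep <- kinase_dependence(a, b)
    expect_equal(sum(dep$cdc5_only),
                 length(unique(b$residue)) -
                   length(intersect(unique(a$residue), unique(b$residue))))
  }
})

test_that("zone assignment uses inclusive bounds and partitions the sites", {
  expect_identical(assign_zones(50), "z1")
  expect_identical(assign_zones(100), "none")
  expect_identical(assign_zones(c(160, 615)), c("z2", "z2"))
  expect_identical(assign_zones(c(31, 69, 676, 840, 1017, 1166)),
                   c("z1", "z1", "z3", "z3", "z4", "z4"))
  set.seed(11)
  res <- sample(1:1200, 200)
  z <- assign_zones(res)
  expect_equal(sum(table(z)), length(res))   # every site gets one label
  zm <- zone_map()
  in_any <- vapply(res, function(r) any(zm$start <= r & r <= zm$end),
                   logical(1))
  expect_identical(z != "none", in_any)
  expect_error(zone_map(starts = c(10, 20), ends = c(25, 40)), "disjoint")
})

test_that("catalog merging counts distinct sites and is idempotent", {
  known <- data.frame(protein = "CFI1", residue = 1:64 * 10)
  ms <- data.frame(protein = "CFI1",
                   residue = c(1:44 * 10, 1000 + 1:18))  # 44 known + 18 new
  ipms <- data.frame(protein = "CFI1", residue = 2000 + 1:9)
  merged <- merge_catalogs(known, ms, ipms)
  expect_equal(attr(merged, "n_sites"), 91)
  expect_equal(attr(merge_catalogs(merged, merged), "n_sites"), 91)
  expect_equal(attr(merge_catalogs(known[0, ], ms[0, ]), "n_sites"), 0)
})
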