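test_that("fisherEnrichment reproduces the known 2x2 example", {
  tab <- matrix(c(30, 10, 70, 90), nrow = 2, byrow = TRUE)
  # rows feature yes/no, columns pg4/non: OR = (30*90)/(70*10)
  r <- fisherEnrichment(t(tab))
  expect_equal(oddsRatio(r), 30 * 90 / (70 * 10), tolerance = 1e-12)
  expect_equal(pValue(r),
               oracle_fisher_two_sided(t(tab)), tolerance = 1e-9)
  ci <- confint95(r)
  expect_true(ci[1] < oddsRatio(r) && oddsRatio(r) < ci[2])
  # swapping both rows and both columns leaves the OR unchanged
  sw <- fisherEnrichment(t(tab)[2:1, 2:1])
  expect_equal(oddsRatio(sw), oddsRatio(r))
  expect_equal(pValue(sw), pValue(r))
})

test_that("eqtlEnrichment builds the right table per subset", {
  status <- c(rep("lead", 5), rep("nominal", 15),
              rep("tested_nonsignificant", 80),
              rep("causal_candidate", 3))
  in_pg4 <- c(rep(TRUE, 3), rep(FALSE, 2),       # leads
              rep(TRUE, 5), rep(FALSE, 10),      # nominal
              rep(TRUE, 20), rep(FALSE, 60),     # tested non-sig
              rep(TRUE, 1), rep(FALSE, 2))       # causal
  r_lead <- eqtlEnrichment(status, in_pg4, "lead")
  expect_equal(unname(r_lead@table[1, ]), c(3L, 2L))
  r_nom <- eqtlEnrichment(status, in_pg4, "nominal")
  expect_equal(unname(r_nom@table[1, ]), c(8L, 12L))
  r_c <- eqtlEnrichment(status, in_pg4, "causal")
  expect_equal(unname(r_c@table[1, ]), c(1L, 2L))
  # collapsing nominal pG4 eQTLs sharing a feature
  feat <- rep(NA_character_, length(status))
  feat[6:10] <- "m1"   # the 5 nominal pG4 eQTLs share one motif
  r_col <- eqtlEnrichment(status, in_pg4, "nominal", collapse_by = feat)
  expect_equal(unname(r_col@table[1, 1]), 4L)   # 3 leads + 1 collapsed
})

test_that("direction bias recovers a planted tract effect", {
  set.seed(61)
  ors <- replicate(60, {
    in_tract <- rep(c(TRUE, FALSE), c(1500, 1500))
    up <- ifelse(in_tract, rbinom(3000, 1, 0.64), rbinom(3000, 1, 0.5))
    r <- eqtlDirectionBias(ifelse(up == 1, "+", "-"), in_tract)
    oddsRatio(r)
  })
  truth <- (0.64 / 0.36) / 1
  expect_lt(abs(median(ors) - truth) / truth, 0.1)
  # null: no bias
  set.seed(62)
  null_or <- oddsRatio(eqtlDirectionBias(
    sample(c("+", "-"), 5000, TRUE), sample(c(TRUE, FALSE), 5000, TRUE)))
  expect_lt(abs(log(null_or)), 0.2)
})

test_that("clipDensity computes per-kb densities and fold enrichment", {
  pg4 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
  utr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2000))
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = c(10, 210, 410, 610, 810, 910, 1500), width = 20))
  d <- clipDensity(peaks, pg4, utr)
  expect_equal(d$density_pg4, 6)
  expect_equal(d$density_non_pg4, 1)
  expect_equal(d$fold, 6)
  expect_equal(d$result@method, "chisq")
  # overlapping peaks collapse to unique sites before counting
  dup <- c(peaks, GenomicRanges::GRanges("chr1",
                                         IRanges::IRanges(15, 30)))
  expect_equal(clipDensity(dup, pg4, utr)$density_pg4, 6)
  expect_error(clipDensity(peaks, pg4, pg4), "zero-length")
  # the stated 2 d.f. default gives a larger p than the conventional 1
  d1 <- clipDensity(peaks, pg4, utr, df = 1)
  expect_lt(d1$result@p_value, d$result@p_value)
})

test_that("per-RBP hypergeometric p matches direct tail summation", {
  rbp <- c(rep("A", 50), rep("B", 950))
  in_pg4 <- c(rep(TRUE, 20), rep(FALSE, 30),      # RBP A: 20/50
              rep(TRUE, 80), rep(FALSE, 870))     # rest: 80/950
  res <- rbpPG4Enrichment(rbp, in_pg4)
  pa <- res$p_value[res$rbp == "A"]
  expect_equal(pa, oracle_hyper_upper(20, 100, 1000, 50),
               tolerance = 1e-12)
  # a random subset RBP is not enriched
  set.seed(71)
  rbp2 <- sample(c("X", "Y"), 1000, TRUE)
  res2 <- rbpPG4Enrichment(rbp2, in_pg4[sample(1000)])
  expect_true(all(!res2$significant | res2$p_value < 0.001 / 2))
})

test_that("pairwise target overlap behaves at the extremes", {
  universe <- sprintf("g%03d", 1:200)
  idA <- universe[1:20]; idB <- universe[101:120]
  m <- rbpTargetOverlap(list(A = idA, B = idB, C = idA), universe)
  # disjoint sets: p near 1 so -log10 p near 0
  expect_lt(m["A", "B"], 0.5)
  # identical sets: p equals the minimal achievable tail
  expect_equal(10^(-m["A", "C"]),
               oracle_hyper_upper(20, 20, 200, 20), tolerance = 1e-9)
  expect_equal(m["A", "C"], m["C", "A"])
  # module membership by shared interactions
  genes <- sharedModuleGenes(list(A = idA, B = idB, C = idA,
                                  D = idA[1:5]), min_interactions = 3)
  expect_setequal(genes, idA[1:5])
})

test_that("knockdown DE odds ratios and BH selection are correct", {
  de <- simulateKnockdownDE(n_rbp = 3, n_genes = 1500,
                            odds_multiplier = 3, seed = 81)
  res <- knockdownDEOdds(de)
  expect_true(all(res$odds_ratio > 1))
  expect_true(all(res$direction == -1))   # planted negative shift
  # BH column equals the step-up procedure applied by hand
  for (cl in unique(res$cell_line)) {
    p <- res$p_value[res$cell_line == cl]
    expect_equal(res$p_bh[res$cell_line == cl],
                 p.adjust(p, "BH"))
  }
  # independent DE and label: OR near 1
  de0 <- simulateKnockdownDE(n_rbp = 2, n_genes = 4000,
                             odds_multiplier = 1, seed = 82)
  res0 <- knockdownDEOdds(de0)
  expect_lt(max(abs(log(res0$odds_ratio))), 0.5)
  expect_true(all(!res0$significant))
})

test_that("clinvarDensity filters and recovers a null OR", {
  # hand fixture: the >40 nt and benign records must drop out
  v <- data.frame(
    gene = c("DG001", "DG001", "DG001", "XX", "DG002"),
    span = c(1, 50, 1, 1, 2),
    clnsig = c("Pathogenic", "Pathogenic", "Benign",
               "Uncertain_significance", "Likely_pathogenic"),
    in_pg4 = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  r <- clinvarDensity(v, c("DG001", "DG002"), pg4_bases = 1000,
                      non_pg4_bases = 1000)
  expect_equal(unname(r@table[1, ]), c(1L, 1L))
  set.seed(91)
  sim <- simulateClinvar(multiplier = 1, seed = 91)
  r0 <- clinvarDensity(sim$variants, sim$disease_genes, 20000, 200000)
  expect_lt(abs(log(oddsRatio(r0))), 0.35)
})
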