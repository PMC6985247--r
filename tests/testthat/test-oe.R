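test_that("heptamer table validates and symmetrizes", {
  df <- data.frame(heptamer = c("AAAAAAA", "TTTTTTT"),
                   alt = c("C", "G"), probability = c(0.02, 0.04))
  # AAAAAAA>C and its reverse complement TTTTTTT>G average to 0.03
  tb <- heptamerTable(df, symmetrize = TRUE)
  expect_equal(unname(tb@prob["AAAAAAA>C"]), 0.03)
  expect_equal(unname(tb@prob["TTTTTTT>G"]), 0.03)
  tb2 <- heptamerTable(df, symmetrize = FALSE)
  expect_equal(unname(tb2@prob["AAAAAAA>C"]), 0.02)
  expect_error(heptamerTable(transform(df, alt = c("A", "T"))), "center")
  expect_error(heptamerTable(transform(df, probability = c(2, 0.1))),
               "\\[0, 1\\]")
})

test_that("expectedSubstitutions sums cumulative probabilities", {
  df <- expand.grid(alt = c("C", "G", "T"), heptamer = "AAAAAAA",
                    stringsAsFactors = FALSE)
  df$probability <- 0.01 / 3
  tb <- heptamerTable(df, symmetrize = FALSE)
  ctx <- rep("AAAAAAA", 10)
  expect_equal(expectedSubstitutions(ctx, tb), 0.1)
  # all CpG-masked positions contribute nothing
  expect_equal(expectedSubstitutions(ctx, tb, cpg_mask = rep(TRUE, 10)), 0)
  # N-containing contexts are dropped
  expect_message(
    e <- expectedSubstitutions(c(ctx, "AAANAAA"), tb), "dropped")
  expect_equal(e, 0.1)
})

test_that("expected counts match a position-by-position oracle and are additive", {
  tb <- makeHeptamerTable(seed = 31)
  reg <- simulateNeutralRegion(500, tb, seed = 32)
  manual <- 0
  for (i in seq_along(reg$contexts)) {
    if (!reg$cpg_mask[i])
      manual <- manual + sum(tb@prob[paste0(
        reg$contexts[i], ">",
        setdiff(c("A", "C", "G", "T"), substr(reg$contexts[i], 4, 4)))])
  }
  expect_equal(expectedSubstitutions(reg$contexts, tb, reg$cpg_mask),
               manual, tolerance = 1e-12)
  # additive over a disjoint split
  half <- seq_len(250)
  expect_equal(
    expectedSubstitutions(reg$contexts[half], tb, reg$cpg_mask[half]) +
      expectedSubstitutions(reg$contexts[-half], tb, reg$cpg_mask[-half]),
    expectedSubstitutions(reg$contexts, tb, reg$cpg_mask))
})

test_that("observedSubstitutions counts intersecting non-CpG positions once", {
  pos <- 101:110
  expect_equal(observedSubstitutions(pos, c(1, 2, 3)), 0L)
  expect_equal(observedSubstitutions(pos, pos), 10L)
  # a site polymorphic for several alts still counts once
  expect_equal(observedSubstitutions(pos, c(105, 105, 200)), 1L)
  mask <- rep(c(TRUE, FALSE), 5)
  expect_equal(observedSubstitutions(pos, pos, mask), 5L)
  set.seed(9)
  p2 <- sample.int(1e4, 300)
  s2 <- sample.int(1e4, 500)
  expect_equal(observedSubstitutions(p2, s2), sum(p2 %in% s2))
})

test_that("cpgMask marks both bases of every CG dinucleotide", {
  expect_equal(cpgMask("ACGT"), c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(cpgMask("CGCG"), rep(TRUE, 4))
  expect_equal(cpgMask("GGCC"), rep(FALSE, 4))
})

test_that("neutral simulation yields O/E near 1 with a covering CI", {
  tb <- makeHeptamerTable(seed = 41)
  reg <- simulateNeutralRegion(10000, tb, seed = 42)
  r <- oeBootstrap(reg$contexts, reg$is_polymorphic, tb, reg$cpg_mask,
                   n_iter = 1000, seed = 43)
  expect_gt(oeRatio(r), 0.9)
  expect_lt(oeRatio(r), 1.1)
  ci <- confint90(r)
  expect_true(ci[1] <= 1 && 1 <= ci[2])
  # zero observed sites: ratio 0 with a degenerate interval
  r0 <- oeBootstrap(reg$contexts, rep(FALSE, length(reg$contexts)), tb,
                    reg$cpg_mask, n_iter = 200, seed = 44)
  expect_equal(oeRatio(r0), 0)
  expect_equal(confint90(r0), c(0, 0))
})

test_that("empirical null is calibrated for a background subset and detects thinning", {
  tb <- makeHeptamerTable(seed = 51)
  bg <- simulateNeutralRegion(6000, tb, seed = 52)
  # target = random subset of the background pool: p should be moderate
  set.seed(53)
  idx <- sample.int(6000, 800)
  r <- oeEmpiricalNull(bg$contexts[idx], bg$is_polymorphic[idx],
                       bg$contexts, bg$is_polymorphic, tb,
                       bg$cpg_mask[idx], bg$cpg_mask,
                       n_windows = 300, n_iter = 500, seed = 54)
  expect_gt(pValue(r), 0.01)
  expect_lt(pValue(r), 0.99)
  # a region with sites thinned to 50% of neutral is clearly depleted
  thin <- simulateNeutralRegion(5000, tb, seed = 55, thin = 0.5)
  r2 <- oeEmpiricalNull(thin$contexts, thin$is_polymorphic,
                        bg$contexts, bg$is_polymorphic, tb,
                        thin$cpg_mask, bg$cpg_mask,
                        n_windows = 300, n_iter = 500, seed = 56)
  expect_lt(pValue(r2), 0.01)
  expect_lt(oeRatio(r2), 0.65)
})
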