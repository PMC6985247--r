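test_that("scanPG4 handles the canonical worked examples", {
  m <- scanPG4("GGGAGGGAGGGAGGG")
  df <- as.data.frame(m)
  expect_equal(nrow(df), 1L)
  expect_equal(df$start, 0L)
  expect_equal(df$end, 15L)
  expect_equal(df$n_tracts, 4L)
  pt <- partitionTracts(m)[[1L]]
  expect_equal(pt$tracts$length, rep(3L, 4L))
  expect_equal(pt$gaps$length, rep(1L, 3L))

  expect_length(scanPG4("GGAGGAGGAGG"), 0L)
  # only possible 4-tract arrangement has an 8-nt first loop
  expect_length(scanPG4("GGGAAAAAAAAGGGAGGGAGGG"), 0L)
  expect_length(scanPG4(""), 0L)
  expect_error(scanPG4("GGGAXGGG"), "non-nucleotide")
  # N breaks G-runs and counts as a loop character
  expect_length(scanPG4("GGNGAGGGAGGGAGGG"), 0L)
  expect_equal(as.data.frame(scanPG4("GGGNGGGAGGGAGGG"))$n_tracts, 4L)
})

test_that("central guanine labels sit at the expected offsets", {
  g <- tractGuanines(scanPG4("GGGAGGGAGGGAGGG"))
  expect_equal(g$offset[g$label == "central"], c(1L, 5L, 9L, 13L))
  # a length-4 tract carries no positional labels
  g2 <- tractGuanines(scanPG4("GGGGAGGGAGGGAGGG"))
  expect_false(1L %in% g2$tract)
  expect_equal(sort(unique(g2$tract)), 2:4)
})

test_that("scanPG4 matches the brute-force run-enumeration oracle", {
  set.seed(101)
  for (i in 1:300) {
    len <- sample(50:400, 1L)
    gc <- runif(1, 0.15, 0.45)
    s <- random_dna(len, c((1 - 2 * gc) / 2, gc, gc, (1 - 2 * gc) / 2))
    got <- as.data.frame(scanPG4(s))[, c("start", "end")]
    want <- oracle_scan(s)
    expect_equal(got, want, info = paste("seq", i))
  }
})

test_that("tract/gap tiling reconstructs every motif sequence", {
  set.seed(7)
  checked <- 0L
  while (checked < 50L) {
    s <- random_dna(300, c(0.2, 0.3, 0.3, 0.2))
    m <- scanPG4(s)
    if (!length(m)) next
    parts <- partitionTracts(m)
    df <- as.data.frame(m)
    for (k in seq_along(parts)) {
      pieces <- rbind(parts[[k]]$tracts[, c("start", "end")],
                      parts[[k]]$gaps[, c("start", "end")])
      pieces <- pieces[order(pieces$start), ]
      rebuilt <- paste(substring(s, pieces$start + 1L, pieces$end),
                       collapse = "")
      expect_equal(rebuilt, df$sequence[k])
      checked <- checked + 1L
    }
  }
})

test_that("projectToGenome maps plus, minus and spliced UTRs", {
  utr_p <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1100), "+")
  bp <- projectToGenome(10, 25, utr_p)[[1L]]
  expect_equal(GenomicRanges::start(bp) - 1L, 1010L)
  expect_equal(GenomicRanges::end(bp), 1025L)

  utr_m <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1100), "-")
  bm <- projectToGenome(10, 25, utr_m)[[1L]]
  expect_equal(GenomicRanges::start(bm) - 1L, 1075L)
  expect_equal(GenomicRanges::end(bm), 1090L)

  # two-exon UTR: blocks [1001,1040) + [1200,1260) (0-based), + strand;
  # motif at transcript offsets [30, 50) straddles the junction
  utr2 <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(1002, 1201), end = c(1040, 1260)), "+")
  b2 <- projectToGenome(30, 50, utr2)[[1L]]
  expect_equal(length(b2), 2L)
  expect_equal(sum(GenomicRanges::width(b2)), 20L)
  expect_equal(GenomicRanges::start(b2) - 1L, c(1031L, 1200L))
  expect_equal(GenomicRanges::end(b2), c(1040L, 1211L))

  # same junction on the minus strand: offset 0 = highest coordinate
  utr2m <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(1002, 1201), end = c(1040, 1260)), "-")
  b2m <- projectToGenome(58, 62, utr2m)[[1L]]
  expect_equal(sum(GenomicRanges::width(b2m)), 4L)
  expect_error(projectToGenome(10, 200, utr_p), "outside")
})

test_that("minus-strand motifs appear as C-runs on the plus strand", {
  set.seed(42)
  n_checked <- 0L
  for (i in 1:20) {
    # plant one canonical motif in a G-poor background
    loops <- vapply(sample(1:7, 3, replace = TRUE), function(l)
      random_dna(l, c(0.4, 0.3, 0, 0.3)), character(1))
    motif <- paste0("GGG", loops[1], "GGG", loops[2], "GGG", loops[3],
                    "GGG")
    sense <- paste0(random_dna(80, c(0.4, 0.3, 0, 0.3)), motif,
                    random_dna(80, c(0.4, 0.3, 0, 0.3)))
    len <- nchar(sense)
    plus <- revcomp_chr(sense)     # genomic plus strand of a minus gene
    m <- scanPG4(sense)
    expect_equal(length(m), 1L)
    utr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(501, 500 + len),
                                  "-")
    df <- as.data.frame(scanPG4(sense))
    for (k in seq_len(nrow(df))) {
      blk <- projectToGenome(df$start[k], df$end[k], utr)[[1L]]
      # the projected plus-strand bases must be the motif's complement
      sub <- substr(plus, GenomicRanges::start(blk) - 500L,
                    GenomicRanges::end(blk) - 500L)
      expect_equal(sub, revcomp_chr(df$sequence[k]))
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 5L)
})

test_that("flagCDSOverlap marks motifs intersecting any CDS block", {
  blocks <- GenomicRanges::GRangesList(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 120)),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(500, 520)))
  cds <- GenomicRanges::GRanges("chr1", IRanges::IRanges(110, 400))
  expect_equal(flagCDSOverlap(blocks, cds), c(TRUE, FALSE))
})

test_that("classifyIsoforms applies the constitutive/alternative rule", {
  # 3 isoforms, all with the same motif
  r <- classifyIsoforms(rep("g1", 3), paste0("t", 1:3),
                        rep("chr1:10-40", 3))
  expect_equal(r$status, "constitutive")
  expect_true(r$identical_pg4)
  # 2 isoforms, one without
  r2 <- classifyIsoforms(rep("g1", 2), c("t1", "t2"), c("chr1:10-40", ""))
  expect_equal(r2$status, "alternative")
  expect_equal(r2$n_pg4_isoforms, 1L)
  # nonidentical motifs in a constitutive gene
  r3 <- classifyIsoforms(rep("g1", 2), c("t1", "t2"),
                         c("chr1:10-40", "chr1:90-120"))
  expect_equal(r3$status, "constitutive")
  expect_false(r3$identical_pg4)
  # invariant to isoform input order
  r4 <- classifyIsoforms(rep("g1", 2), c("t2", "t1"), c("", "chr1:10-40"))
  expect_equal(r4$status, r2$status)
  expect_equal(r4$n_pg4_isoforms, r2$n_pg4_isoforms)
})

test_that("permuteIsoformLabels handles degenerate and excluded genes", {
  # all single-isoform genes: everything constitutive in every permutation
  r <- permuteIsoformLabels(rep(1L, 5L), rep(1L, 5L), n_iter = 50,
                            seed = 1)
  expect_equal(r$p_value, 1)
  expect_equal(r$observed_ratio, 0)
  expect_warning(
    permuteIsoformLabels(c(2L, 2L), c(1L, 0L), n_iter = 10, seed = 1),
    "zero pG4")
})

test_that("classifyExpression applies the strict 1-TPM rule per side", {
  tpm <- matrix(c(5, 3, 0.9, 1.2, 0.5, 0.4), nrow = 2,
                dimnames = list(c("pg4", "non"), c("t1", "t2", "t3")))
  lab <- classifyExpression(tpm, c(TRUE, FALSE))
  expect_equal(unname(lab),
               c("both_expressed", "non_pg4_only", "neither"))
  # exactly 1 TPM is not expressed
  tpm2 <- matrix(c(1, 1), nrow = 2, dimnames = list(NULL, "t1"))
  expect_equal(unname(classifyExpression(tpm2, c(TRUE, FALSE))), "neither")
  expect_error(classifyExpression(tpm, c(TRUE, FALSE), tissues = "nope"),
               "not found")
})
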