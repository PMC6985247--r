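test_that("the generator is deterministic given config and seed", {
  cfg <- simulationConfig(n_genes = 6)
  a <- simulateTranscriptome(cfg, seed = 5)
  b <- simulateTranscriptome(cfg, seed = 5)
  expect_identical(a$transcripts$utr5_seq, b$transcripts$utr5_seq)
  expect_identical(a$truth_motifs, b$truth_motifs)
  expect_identical(a$truth_genes, b$truth_genes)
  c <- simulateTranscriptome(cfg, seed = 6)
  expect_false(identical(a$transcripts$utr5_seq, c$transcripts$utr5_seq))

  v1 <- simulateVariantClass(500, makeRateTable(1), 0.02, seed = 3)
  v2 <- simulateVariantClass(500, makeRateTable(1), 0.02, seed = 3)
  expect_identical(v1, v2)
})

test_that("a zero planting rate yields a motif-free transcriptome", {
  cfg <- simulationConfig(n_genes = 5, pg4_rate = 0,
                          utr_len = c(100L, 400L))
  sim <- simulateTranscriptome(cfg, seed = 8)
  expect_equal(nrow(sim$truth_motifs), 0L)
  for (i in seq_len(nrow(sim$transcripts))) {
    expect_length(scanPG4(sim$transcripts$utr5_seq[i]), 0L)
    expect_length(scanPG4(sim$transcripts$utr3_seq[i]), 0L)
  }
  expect_true(all(sim$truth_genes$status == "non_pg4"))
})

test_that("the scanner recovers every planted motif exactly", {
  sim <- simulateTranscriptome(simulationConfig(n_genes = 15), seed = 12)
  expect_gt(nrow(sim$truth_motifs), 0L)
  for (i in seq_len(nrow(sim$transcripts))) {
    tx <- sim$transcripts[i, ]
    for (side in c("5p", "3p")) {
      s <- if (side == "5p") tx$utr5_seq else tx$utr3_seq
      found <- as.data.frame(scanPG4(s))[, c("start", "end")]
      truth <- sim$truth_motifs[
        sim$truth_motifs$transcript_id == tx$transcript_id &
          sim$truth_motifs$side == side, c("start", "end")]
      expect_equal(found[order(found$start), ],
                   truth[order(truth$start), ],
                   ignore_attr = TRUE)
    }
  }
})

test_that("isoform classification matches the generator's truth", {
  sim <- simulateTranscriptome(simulationConfig(n_genes = 30), seed = 19)
  for (side in c("5p", "3p")) {
    keys <- vapply(seq_len(nrow(sim$transcripts)), function(i) {
      tx <- sim$transcripts[i, ]
      tm <- sim$truth_motifs[
        sim$truth_motifs$transcript_id == tx$transcript_id &
          sim$truth_motifs$side == side, , drop = FALSE]
      if (!nrow(tm)) return("")
      blocks <- if (side == "5p") tx$utr5_blocks[[1]] else
        tx$utr3_blocks[[1]]
      paste(sort(vapply(seq_len(nrow(tm)), function(k)
        motifKey(projectToGenome(tm$start[k], tm$end[k], blocks)[[1]]),
        character(1))), collapse = ";")
    }, character(1))
    got <- classifyIsoforms(sim$transcripts$gene_id,
                            sim$transcripts$transcript_id, keys)
    truth <- sim$truth_genes[sim$truth_genes$side == side, ]
    truth <- truth[match(got$gene_id, truth$gene_id), ]
    expect_equal(got$status, truth$status)
    expect_equal(got$n_pg4_isoforms, truth$n_pg4_isoforms)
    expect_equal(got$n_total_isoforms, truth$n_total_isoforms)
    expect_equal(got$identical_pg4, truth$identical_pg4)
  }
})

test_that("every planted motif appears in exactly one truth record", {
  sim <- simulateTranscriptome(simulationConfig(n_genes = 12), seed = 33)
  key <- with(sim$truth_motifs,
              paste(transcript_id, side, start, end))
  expect_false(anyDuplicated(key) > 0)
  # genes in truth_genes with pG4 status have matching motif records
  for (side in c("5p", "3p")) {
    tg <- sim$truth_genes[sim$truth_genes$side == side, ]
    with_motifs <- unique(sim$truth_motifs$gene_id[
      sim$truth_motifs$side == side])
    expect_setequal(tg$gene_id[tg$status != "non_pg4"], with_motifs)
  }
})

test_that("rate table covers every context the class generator can emit", {
  rt <- makeRateTable(seed = 44)
  # 64 contexts x 3 alts for not_cpg
  expect_equal(sum(rt$methylation_bin == "not_cpg"), 192L)
  # CpG-containing contexts additionally carry 3 methylation bins
  cpg_ctx <- unique(rt$context[grepl("CG", rt$context)])
  for (b in c("none_low", "intermediate", "high"))
    expect_setequal(unique(rt$context[rt$methylation_bin == b]), cpg_ctx)
  expect_true(all(rt$rate > 0))
})

test_that("neutral functional layers carry no planted signal", {
  set.seed(55)
  e <- simulateEQTLs(odds_multiplier = 1, seed = 56)
  r <- eqtlEnrichment(e$status, e$in_pg4, "nominal")
  expect_lt(abs(log(oddsRatio(r))), 0.35)
  a <- simulateASECounts(84, 50, 0.5, 0.05, seed = 57)
  expect_gt(pValue(lrtNoBias(a$ref, a$alt)), 0.01)
})
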