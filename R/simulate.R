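#' @importFrom stats runif rbinom rpois rbeta var setNames
NULL

#' Configuration for the synthetic-data generator
#'
#' Bundles the generator's study conditions. Defaults give a desk-scale
#' transcriptome (200 genes, up to 5 isoforms, UTRs of 100-2000 nt) that
#' exercises the full pipeline in minutes while preserving the statistical
#' structure each analysis assumes.
#'
#' @param n_genes number of genes.
#' @param max_isoforms isoform count per gene is uniform on
#'   `1:max_isoforms`.
#' @param utr_len numeric(2) range of UTR lengths (nt).
#' @param pg4_rate probability that a gene carries a planted pG4 on a
#'   given UTR side.
#' @param carry_rate probability that each additional isoform of a pG4
#'   gene carries the gene's motif (one isoform always does).
#' @param nonidentical_rate probability that a pG4-carrying isoform gets
#'   its own, distinct motif-bearing UTR instead of the shared one.
#' @param base_probs background base composition (A, C, G, T); guanine is
#'   kept modest so motif-free background sampling converges.
#' @param cds_len CDS length per transcript (nt).
#' @param two_exon_rate probability that a UTR is split into two genomic
#'   blocks.
#' @param max_tries rejection-sampling cap per sequence.
#' @return A list of class `g4utr_sim_config`.
#' @export
simulationConfig <- function(n_genes = 200L, max_isoforms = 5L,
                             utr_len = c(100L, 2000L), pg4_rate = 0.6,
                             carry_rate = 0.6, nonidentical_rate = 0.1,
                             base_probs = c(A = 0.28, C = 0.26,
                                            G = 0.20, T = 0.26),
                             cds_len = 300L, two_exon_rate = 0.2,
                             max_tries = 50L) {
  stopifnot(n_genes >= 1L, max_isoforms >= 1L, utr_len[1L] >= 30L,
            utr_len[2L] >= utr_len[1L], pg4_rate >= 0, pg4_rate <= 1,
            abs(sum(base_probs) - 1) < 1e-8)
  structure(list(n_genes = n_genes, max_isoforms = max_isoforms,
                 utr_len = utr_len, pg4_rate = pg4_rate,
                 carry_rate = carry_rate,
                 nonidentical_rate = nonidentical_rate,
                 base_probs = base_probs, cds_len = cds_len,
                 two_exon_rate = two_exon_rate, max_tries = max_tries),
            class = "g4utr_sim_config")
}

random_seq <- function(len, probs) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = probs),
        collapse = "")
}

# background sequence guaranteed to contain no canonical motif
motif_free_seq <- function(len, probs, max_tries) {
  for (i in seq_len(max_tries)) {
    s <- random_seq(len, probs)
    if (length(scanPG4(s)) == 0L) return(s)
  }
  stop("could not sample a motif-free background sequence in ", max_tries,
       " tries; lower the G content")
}

# one canonical motif string: 4 tracts (length 3, occasionally 4),
# loops of 1-7 nt drawn from {A,C,T} so tracts never extend
random_motif <- function() {
  tracts <- strrep("G", sample(3:4, 4L, replace = TRUE, prob = c(0.8, 0.2)))
  loops <- vapply(sample(1:7, 3L, replace = TRUE), function(l)
    paste(sample(c("A", "C", "T"), l, replace = TRUE), collapse = ""),
    character(1))
  paste0(tracts[1L], loops[1L], tracts[2L], loops[2L], tracts[3L],
         loops[3L], tracts[4L])
}

# plant one motif into a motif-free background; returns seq + 0-based span
plant_motif <- function(len, probs, max_tries) {
  for (i in seq_len(max_tries)) {
    motif <- random_motif()
    mlen <- nchar(motif)
    bg <- motif_free_seq(len, probs, max_tries)
    pos <- sample.int(len - mlen - 2L, 1L) + 1L   # 1-based, leave flanks
    left <- substr(bg, 1L, pos - 1L)
    right <- substr(bg, pos + mlen, len)
    # guanine flanks would extend the outer tracts
    if (substr(left, nchar(left), nchar(left)) == "G")
      left <- paste0(substr(left, 1L, nchar(left) - 1L), "A")
    if (substr(right, 1L, 1L) == "G")
      right <- paste0("A", substr(right, 2L, nchar(right)))
    seq <- paste0(left, motif, right)
    found <- scanPG4(seq)
    df <- as.data.frame(found)
    if (nrow(df) == 1L && df$start == pos - 1L &&
        df$end == pos - 1L + mlen)
      return(list(seq = seq, start = pos - 1L, end = pos - 1L + mlen,
                  motif = motif))
  }
  stop("motif planting failed after ", max_tries, " tries")
}

#' Simulate a transcriptome with planted pG4 motifs and known truth
#'
#' Generates genes with 1 to `max_isoforms` protein-coding isoforms, UTR
#' sequences whose background is rejection-sampled to contain no canonical
#' motif, and pG4 motifs planted at known offsets. Isoforms of a pG4 gene
#' that carry the motif share one motif-bearing UTR (and hence genomic
#' coordinates) unless the nonidentical branch fires, mirroring shared
#' versus isoform-specific UTRs in real annotation. Each transcript is
#' laid out on a synthetic chromosome (5' UTR, CDS, 3' UTR; some UTRs
#' split across two exons) with strand drawn per gene.
#'
#' @param cfg a [simulationConfig()].
#' @param seed integer RNG seed; identical `cfg` and `seed` give
#'   byte-identical output.
#' @return list with `transcripts` (data.frame: `gene_id`,
#'   `transcript_id`, `strand`, `utr5_seq`, `utr3_seq`, plus list-columns
#'   `utr5_blocks`, `cds_blocks`, `utr3_blocks` of GRanges),
#'   `truth_motifs` (per planted motif: ids, `side`, 0-based `start`,
#'   `end` within the UTR, `sequence`), and `truth_genes` (per gene and
#'   side: `status`, `n_pg4_isoforms`, `n_total_isoforms`,
#'   `identical_pg4`).
#' @export
simulateTranscriptome <- function(cfg = simulationConfig(), seed = 2020L) {
  stopifnot(inherits(cfg, "g4utr_sim_config"))
  set.seed(as.integer(seed))
  offset <- 1000L   # running genomic cursor on the synthetic chromosome

  tx_rows <- list(); motif_rows <- list(); gene_rows <- list()
  utr5_blocks <- list(); utr3_blocks <- list(); cds_blocks <- list()

  place_blocks <- function(len, strand) {
    # lay 'len' nt at the cursor, optionally split in two exons
    two <- runif(1) < cfg$two_exon_rate && len >= 60L
    if (two) {
      l1 <- sample(20:(len - 20L), 1L)
      intron <- sample(50:500, 1L)
      gr <- GRanges("chrS", IRanges(
        start = c(offset, offset + l1 + intron),
        width = c(l1, len - l1)), strand)
      offset <<- offset + len + intron + sample(100:300, 1L)
    } else {
      gr <- GRanges("chrS", IRanges(start = offset, width = len), strand)
      offset <<- offset + len + sample(100:300, 1L)
    }
    gr
  }

  for (g in seq_len(cfg$n_genes)) {
    gene_id <- sprintf("G%04d", g)
    n_iso <- sample.int(cfg$max_isoforms, 1L)
    strand <- sample(c("+", "-"), 1L)

    for (side in c("5p", "3p")) {
      has_gene_pg4 <- runif(1) < cfg$pg4_rate
      carriers <- logical(n_iso)
      if (has_gene_pg4) {
        carriers[sample.int(n_iso, 1L)] <- TRUE
        extra <- runif(n_iso) < cfg$carry_rate
        carriers <- carriers | extra
      }
      len <- sample(cfg$utr_len[1L]:cfg$utr_len[2L], 1L)
      shared_plant <- if (has_gene_pg4)
        plant_motif(len, cfg$base_probs, cfg$max_tries) else NULL
      shared_blocks <- place_blocks(len, strand)
      alt_seq <- motif_free_seq(
        sample(cfg$utr_len[1L]:cfg$utr_len[2L], 1L),
        cfg$base_probs, cfg$max_tries)
      alt_blocks <- place_blocks(nchar(alt_seq), strand)

      iso_info <- vector("list", n_iso)
      n_distinct_keys <- 0L
      keys <- character(0)
      for (i in seq_len(n_iso)) {
        if (carriers[i]) {
          if (runif(1) < cfg$nonidentical_rate) {
            own_len <- sample(cfg$utr_len[1L]:cfg$utr_len[2L], 1L)
            pl <- plant_motif(own_len, cfg$base_probs, cfg$max_tries)
            bl <- place_blocks(own_len, strand)
          } else {
            pl <- shared_plant
            bl <- shared_blocks
          }
          iso_info[[i]] <- list(seq = pl$seq, blocks = bl, plant = pl)
          keys <- c(keys, motifKey(bl))
        } else {
          iso_info[[i]] <- list(seq = alt_seq, blocks = alt_blocks,
                                plant = NULL)
        }
      }
      status <- if (!any(carriers)) "non_pg4"
        else if (all(carriers)) "constitutive" else "alternative"
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = gene_id, side = side, status = status,
        n_pg4_isoforms = sum(carriers), n_total_isoforms = n_iso,
        identical_pg4 = any(carriers) && length(unique(keys)) == 1L,
        stringsAsFactors = FALSE)

      for (i in seq_len(n_iso)) {
        tid <- sprintf("%s.T%d", gene_id, i)
        key <- paste(gene_id, i)
        if (side == "5p") {
          tx_rows[[key]] <- data.frame(
            gene_id = gene_id, transcript_id = tid, strand = strand,
            utr5_seq = iso_info[[i]]$seq, utr3_seq = NA_character_,
            stringsAsFactors = FALSE)
          utr5_blocks[[key]] <- iso_info[[i]]$blocks
          cds_blocks[[key]] <- place_blocks(cfg$cds_len, strand)
        } else {
          tx_rows[[key]]$utr3_seq <- iso_info[[i]]$seq
          utr3_blocks[[key]] <- iso_info[[i]]$blocks
        }
        if (carriers[i]) {
          pl <- iso_info[[i]]$plant
          motif_rows[[length(motif_rows) + 1L]] <- data.frame(
            gene_id = gene_id, transcript_id = tid, side = side,
            start = pl$start, end = pl$end, sequence = pl$motif,
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  transcripts <- do.call(rbind, tx_rows)
  rownames(transcripts) <- NULL
  transcripts$utr5_blocks <- unname(utr5_blocks[names(tx_rows)])
  transcripts$utr3_blocks <- unname(utr3_blocks[names(tx_rows)])
  transcripts$cds_blocks <- unname(cds_blocks[names(tx_rows)])
  list(transcripts = transcripts,
       truth_motifs = if (length(motif_rows)) do.call(rbind, motif_rows)
         else data.frame(),
       truth_genes = do.call(rbind, gene_rows))
}

#' Synthetic trinucleotide mutation-rate table
#'
#' All 64 ACGT trinucleotide contexts x 3 alternate alleles with positive
#' rates; CpG-containing contexts additionally carry three
#' methylation-binned entries with rates increasing with methylation, the
#' structure the MAPS model expects.
#'
#' @param seed integer RNG seed.
#' @return data.frame with columns `context`, `alt`, `methylation_bin`,
#'   `rate`.
#' @export
makeRateTable <- function(seed = 2020L) {
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  ctx <- apply(expand.grid(bases, bases, bases), 1L, paste, collapse = "")
  rows <- list()
  for (c3 in ctx) {
    center <- substr(c3, 2L, 2L)
    alts <- setdiff(bases, center)
    base_rate <- runif(3L, 0.5, 2)
    rows[[length(rows) + 1L]] <- data.frame(
      context = c3, alt = alts, methylation_bin = "not_cpg",
      rate = base_rate, stringsAsFactors = FALSE)
    if (grepl("CG", c3)) {
      for (k in seq_along(c("none_low", "intermediate", "high"))) {
        bin <- c("none_low", "intermediate", "high")[k]
        rows[[length(rows) + 1L]] <- data.frame(
          context = c3, alt = alts, methylation_bin = bin,
          rate = base_rate * (1 + 1.5 * (k - 1)),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a variant class with a controlled singleton excess
#'
#' Draws variant contexts with probability proportional to their mutation
#' rate, then assigns singleton status with probability
#' `p_base(rate) + delta`, clipped to \[0,1\] (clipping is reported).
#' `p_base` is linear in the rate, so the MAPS calibration regression is
#' correctly specified and a class with `delta = 0` has expected MAPS of
#' zero; `delta > 0` encodes purifying selection of known strength.
#'
#' @param n number of variants.
#' @param rates rate table from [makeRateTable()].
#' @param delta singleton-proportion excess (>= 0).
#' @param seed integer RNG seed.
#' @param p_intercept,p_slope coefficients of the base singleton
#'   proportion as a function of rate.
#' @param an allele number assigned to every record.
#' @return data.frame with `tri_context`, `alt`, `methylation_bin`,
#'   `is_singleton`, `ac`, `an`.
#' @export
simulateVariantClass <- function(n, rates, delta = 0, seed = 2020L,
                                 p_intercept = 0.25, p_slope = 0.05,
                                 an = 30000L) {
  stopifnot(n >= 1L, delta >= 0)
  set.seed(as.integer(seed))
  idx <- sample.int(nrow(rates), n, replace = TRUE, prob = rates$rate)
  p <- p_intercept + p_slope * rates$rate[idx] + delta
  if (any(p > 1)) {
    message(sum(p > 1), " singleton probability(ies) clipped to 1")
    p <- pmin(p, 1)
  }
  s <- rbinom(n, 1L, p) == 1L
  ac <- ifelse(s, 1L, 1L + rpois(n, 5L) + 1L)   # non-singletons: ac >= 2
  data.frame(tri_context = rates$context[idx], alt = rates$alt[idx],
             methylation_bin = rates$methylation_bin[idx],
             is_singleton = s, ac = ac, an = an,
             stringsAsFactors = FALSE)
}

#' Simulate a gnomAD-style raw variant table
#'
#' Random records with quality fields spanning the filter boundaries, for
#' exercising [filterVariants()] against an independent re-implementation.
#'
#' @param n number of records.
#' @param seed integer RNG seed.
#' @param max_an dataset maximum allele number.
#' @return data.frame with the [filterVariants()] input columns.
#' @export
simulateVariantTable <- function(n, seed = 2020L, max_an = 30000L) {
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L),
                character(1), USE.NAMES = FALSE)
  indel <- runif(n) < 0.05
  alt[indel] <- paste0(alt[indel], "A")
  an <- as.integer(round(runif(n, 0.6, 1) * max_an))
  data.frame(
    chrom = sample(c("chr1", "chr2", "chrX"), n, replace = TRUE),
    pos = sample.int(1e6L, n), ref = ref, alt = alt,
    ac = pmin(1L + rpois(n, 2L), an), an = an,
    rf_prob = runif(n),
    segdup = runif(n) < 0.05, lcr = runif(n) < 0.05,
    decoy = runif(n) < 0.02, stringsAsFactors = FALSE)
}

#' Synthetic heptamer substitution table
#'
#' Random per-alternate substitution probabilities for all 4^7 heptamers,
#' with cumulative probability per heptamer centered on `mean_cumulative`.
#'
#' @param seed integer RNG seed.
#' @param mean_cumulative target mean cumulative substitution probability
#'   (default 0.05).
#' @param symmetrize passed to [heptamerTable()].
#' @return A [HeptamerTable].
#' @export
makeHeptamerTable <- function(seed = 2020L, mean_cumulative = 0.05,
                              symmetrize = TRUE) {
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  hep <- apply(do.call(expand.grid, rep(list(bases), 7L)), 1L, paste,
               collapse = "")
  center <- substr(hep, 4L, 4L)
  rows <- data.frame(
    heptamer = rep(hep, each = 3L),
    alt = as.vector(vapply(center, function(c) setdiff(bases, c),
                           character(3))),
    stringsAsFactors = FALSE)
  rows$probability <- runif(nrow(rows), 0.2, 1.8) * mean_cumulative / 3
  heptamerTable(rows, symmetrize = symmetrize)
}

#' Neutral region fixture for the observed/expected model
#'
#' Generates a random reference sequence, takes its interior positions'
#' heptamer contexts and CpG mask, and draws polymorphism per position as
#' Bernoulli with the table's cumulative probability — the neutral model
#' under which the O/E ratio is 1 in expectation.
#'
#' @param n_positions number of interior positions.
#' @param table a [HeptamerTable].
#' @param seed integer RNG seed.
#' @param thin keep each neutral polymorphic site with this probability
#'   (thinning below 1 plants depletion of known strength).
#' @return list with `contexts`, `is_polymorphic`, `cpg_mask`.
#' @export
simulateNeutralRegion <- function(n_positions, table, seed = 2020L,
                                  thin = 1) {
  set.seed(as.integer(seed))
  len <- n_positions + 6L
  seq <- random_seq(len, c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  pos <- 4:(len - 3L)
  contexts <- substring(seq, pos - 3L, pos + 3L)
  mask <- cpgMask(seq)[pos]
  pr <- cumulativeProb(table, contexts)
  poly <- rbinom(length(pos), 1L, pr * thin) == 1L
  list(contexts = contexts, is_polymorphic = poly, cpg_mask = mask)
}

#' Simulate tested SNPs with planted eQTL enrichment
#'
#' Tested SNPs are assigned to pG4 or non-pG4 UTR regions; the odds of a
#' SNP being a (nominally significant) eQTL are `odds_multiplier` times
#' higher in pG4 regions, so [eqtlEnrichment()] should recover an OR close
#' to the multiplier.
#'
#' @param n_pg4,n_non tested SNPs per region class.
#' @param base_rate eQTL probability in non-pG4 regions.
#' @param odds_multiplier planted odds ratio.
#' @param seed integer RNG seed.
#' @return data.frame with `status` and `in_pg4`.
#' @export
simulateEQTLs <- function(n_pg4 = 2000L, n_non = 8000L, base_rate = 0.15,
                          odds_multiplier = 2, seed = 2020L) {
  set.seed(as.integer(seed))
  odds <- base_rate / (1 - base_rate) * odds_multiplier
  p_pg4 <- odds / (1 + odds)
  sig <- c(rbinom(n_pg4, 1L, p_pg4), rbinom(n_non, 1L, base_rate)) == 1L
  data.frame(
    status = ifelse(sig, "nominal", "tested_nonsignificant"),
    in_pg4 = rep(c(TRUE, FALSE), c(n_pg4, n_non)),
    stringsAsFactors = FALSE)
}

#' Simulate CLIP binding sites with planted density enrichment
#'
#' Places Poisson numbers of non-overlapping binding sites in a pG4 block
#' and a non-pG4 UTR block, with per-kb density `fold` times higher in
#' pG4 sequence.
#'
#' @param pg4_kb,non_kb region sizes in kilobases.
#' @param density_non sites per kb in non-pG4 UTR.
#' @param fold planted density ratio.
#' @param seed integer RNG seed.
#' @return list with `peaks`, `pg4_regions`, `utr_regions` (GRanges).
#' @export
simulateClipPeaks <- function(pg4_kb = 10, non_kb = 100, density_non = 1,
                              fold = 6, seed = 2020L) {
  set.seed(as.integer(seed))
  len_pg4 <- as.integer(pg4_kb * 1000)
  len_non <- as.integer(non_kb * 1000)
  pg4 <- GRanges("chrS", IRanges(1L, len_pg4))
  utr <- GRanges("chrS", IRanges(1L, len_pg4 + len_non))
  n1 <- rpois(1L, density_non * fold * pg4_kb)
  n2 <- rpois(1L, density_non * non_kb)
  w <- 20L
  s1 <- if (n1 > 0) sort(sample.int(len_pg4 - w, n1)) else integer(0)
  s2 <- if (n2 > 0) len_pg4 + sort(sample.int(len_non - w, n2))
        else integer(0)
  peaks <- GRanges("chrS", IRanges(start = c(s1, s2), width = w))
  list(peaks = peaks, pg4_regions = pg4, utr_regions = utr)
}

#' Simulate knockdown differential-expression tables
#'
#' @param n_rbp number of knockdown experiments per cell line.
#' @param n_genes genes per experiment.
#' @param frac_pg4 fraction of pG4 genes.
#' @param de_rate_non DE probability for non-pG4 genes.
#' @param odds_multiplier planted DE odds ratio for pG4 genes.
#' @param lfc_shift_pg4 mean log2FC shift of pG4 genes (sets direction).
#' @param seed integer RNG seed.
#' @return data.frame in [knockdownDEOdds()] input format.
#' @export
simulateKnockdownDE <- function(n_rbp = 4L, n_genes = 2000L,
                                frac_pg4 = 0.3, de_rate_non = 0.1,
                                odds_multiplier = 2,
                                lfc_shift_pg4 = -0.5, seed = 2020L) {
  set.seed(as.integer(seed))
  out <- list()
  for (cl in c("K562", "HepG2")) for (r in seq_len(n_rbp)) {
    is_pg4 <- runif(n_genes) < frac_pg4
    odds <- de_rate_non / (1 - de_rate_non) * odds_multiplier
    p <- ifelse(is_pg4, odds / (1 + odds), de_rate_non)
    is_de <- rbinom(n_genes, 1L, p) == 1L
    padj <- ifelse(is_de, runif(n_genes, 0, 0.049),
                   runif(n_genes, 0.06, 1))
    lfc <- stats::rnorm(n_genes, ifelse(is_pg4, lfc_shift_pg4, 0), 1)
    out[[length(out) + 1L]] <- data.frame(
      rbp = sprintf("RBP%02d", r), cell_line = cl,
      gene = sprintf("G%05d", seq_len(n_genes)), log2fc = lfc,
      padj = padj, is_pg4 = is_pg4, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate a ClinVar-style variant table with planted density enrichment
#'
#' @param pg4_bases,non_pg4_bases region sizes (nt).
#' @param rate_non variants per base in non-pG4 UTR.
#' @param multiplier planted density multiplier for pG4 regions.
#' @param seed integer RNG seed.
#' @return list with `variants` (data.frame for [clinvarDensity()]) and
#'   `disease_genes`.
#' @export
simulateClinvar <- function(pg4_bases = 20000L, non_pg4_bases = 200000L,
                            rate_non = 0.01, multiplier = 1.5,
                            seed = 2020L) {
  set.seed(as.integer(seed))
  n_pg4 <- rpois(1L, pg4_bases * rate_non * multiplier)
  n_non <- rpois(1L, non_pg4_bases * rate_non)
  n <- n_pg4 + n_non
  genes <- sprintf("DG%03d", sample.int(50L, n, replace = TRUE))
  sig <- sample(c("Pathogenic", "Likely_pathogenic",
                  "Uncertain_significance", "Benign"), n,
                replace = TRUE, prob = c(0.1, 0.1, 0.6, 0.2))
  span <- ifelse(runif(n) < 0.9, 1L, sample(2:60, n, replace = TRUE))
  variants <- data.frame(
    gene = genes, span = span, clnsig = sig,
    in_pg4 = rep(c(TRUE, FALSE), c(n_pg4, n_non)),
    stringsAsFactors = FALSE)
  list(variants = variants, disease_genes = sprintf("DG%03d", 1:50))
}

#' Simulate beta-binomial allele-specific read counts
#'
#' Per-sample depths are Poisson; reference counts are drawn
#' beta-binomially at the configured mean and overdispersion. Defaults
#' mirror a GTEx-style single-variant analysis (84 heterozygous samples,
#' ~50x coverage).
#'
#' @param n_samples number of heterozygous samples.
#' @param depth_mean mean total reads per sample.
#' @param rho true reference-allele proportion.
#' @param phi true overdispersion.
#' @param seed integer RNG seed.
#' @return data.frame with `ref` and `alt` counts.
#' @export
simulateASECounts <- function(n_samples = 84L, depth_mean = 50,
                              rho = 0.5, phi = 0.05, seed = 2020L) {
  set.seed(as.integer(seed))
  n <- pmax(rpois(n_samples, depth_mean), 1L)
  p <- if (phi < 1e-8) rep(rho, n_samples) else
    rbeta(n_samples, rho * (1 - phi) / phi, (1 - rho) * (1 - phi) / phi)
  ref <- rbinom(n_samples, n, p)
  data.frame(ref = ref, alt = n - ref)
}
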