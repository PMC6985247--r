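#' @importFrom stats fisher.test chisq.test pchisq phyper p.adjust median
#' @importFrom GenomicRanges setdiff union intersect
NULL

# Woolf (log-OR normal) CI with Haldane-Anscombe correction on zero cells
woolf_ci <- function(tab, level = 0.95) {
  zero <- any(tab == 0)
  tc <- if (zero) tab + 0.5 else tab
  or <- (tc[1, 1] * tc[2, 2]) / (tc[1, 2] * tc[2, 1])
  se <- sqrt(sum(1 / tc))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(or = or, ci = exp(log(or) + c(-z, z) * se), corrected = zero)
}

#' Two-sided Fisher enrichment on a 2x2 table
#'
#' Shared engine for the interval-annotation enrichment tests: sample odds
#' ratio (Haldane-Anscombe corrected when a cell is zero, flagged in
#' `note`), Woolf 95% confidence interval, and a two-sided Fisher exact p
#' computed on the raw table.
#'
#' @param tab 2x2 integer matrix; rows = feature of interest (yes/no),
#'   columns = region class.
#' @param test_label label stored in the result.
#' @return An [EnrichmentResult] with `method = "fisher"`.
#' @export
fisherEnrichment <- function(tab, test_label = "enrichment") {
  stopifnot(is.matrix(tab), all(dim(tab) == 2L), all(tab >= 0))
  w <- woolf_ci(tab)
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  new("EnrichmentResult", test_label = test_label,
      table = tab, odds_ratio = w$or, ci95 = w$ci, p_value = p,
      method = "fisher",
      note = if (w$corrected) "continuity" else "")
}

#' cis-eQTL enrichment in pG4 versus non-pG4 UTR regions
#'
#' Compares the number of significant cis-eQTL variants to the number of
#' tested non-significant SNPs between pG4 motifs and the remaining UTR.
#' The significant set is chosen by `subset`: `"lead"` (lowest-p variant
#' per gene and tissue), `"nominal"` (all nominally significant variants,
#' which includes leads), or `"causal"` (externally fine-mapped causal
#' candidates). With `collapse_by` set, at most one significant variant is
#' counted per pG4 feature (the sensitivity analysis guarding against
#' stacked linked eQTLs in long non-pG4 stretches).
#'
#' @param status character vector per tested variant: `lead`, `nominal`,
#'   `causal_candidate` or `tested_nonsignificant`.
#' @param in_pg4 logical vector: variant falls in a pG4 motif.
#' @param subset one of `"lead"`, `"nominal"`, `"causal"`.
#' @param collapse_by optional feature identifier per variant (e.g. motif
#'   id for pG4 variants, NA elsewhere); significant pG4 variants sharing
#'   a feature collapse to one.
#' @return An [EnrichmentResult]. Odds ratios above 1 indicate eQTL
#'   enrichment in pG4 regions.
#' @export
eqtlEnrichment <- function(status, in_pg4,
                           subset = c("nominal", "lead", "causal"),
                           collapse_by = NULL) {
  subset <- match.arg(subset)
  stopifnot(length(status) == length(in_pg4))
  sig <- switch(subset,
    lead = status == "lead",
    nominal = status %in% c("lead", "nominal"),
    causal = status == "causal_candidate")
  nonsig <- status == "tested_nonsignificant"
  if (!is.null(collapse_by)) {
    stopifnot(length(collapse_by) == length(status))
    keep <- rep(TRUE, length(status))
    idx <- which(sig & in_pg4 & !is.na(collapse_by))
    if (length(idx)) keep[idx[duplicated(collapse_by[idx])]] <- FALSE
    sig <- sig & keep
  }
  tab <- matrix(c(sum(sig & in_pg4), sum(sig & !in_pg4),
                  sum(nonsig & in_pg4), sum(nonsig & !in_pg4)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("eqtl", "tested_nonsig"),
                                c("pg4", "non_pg4")))
  fisherEnrichment(tab, paste0("eqtl_", subset))
}

#' Direction bias of pG4 eQTL effects: G-tract versus loop variants
#'
#' Within pG4 motifs, tests whether eQTLs hitting G-tract bases are biased
#' toward increasing expression relative to eQTLs in loop (gap) bases.
#' Every variant-tissue effect is counted separately; effects with a
#' missing sign are dropped with a message.
#'
#' @param nes_sign character/numeric vector of normalized-effect-size
#'   signs (`"+"`/`"-"` or +1/-1), one per variant-tissue effect.
#' @param in_tract logical: effect's variant falls in a G-tract (FALSE =
#'   loop).
#' @return An [EnrichmentResult]; OR > 1 means tract effects are more
#'   often positive.
#' @export
eqtlDirectionBias <- function(nes_sign, in_tract) {
  stopifnot(length(nes_sign) == length(in_tract))
  sgn <- ifelse(nes_sign %in% c("+", "1", "+1") | (is.numeric(nes_sign) &
                  suppressWarnings(as.numeric(nes_sign)) > 0), "+",
         ifelse(nes_sign %in% c("-", "-1") | (is.numeric(nes_sign) &
                  suppressWarnings(as.numeric(nes_sign)) < 0), "-",
                NA_character_))
  drop <- is.na(sgn)
  if (any(drop)) {
    message(sum(drop), " effect(s) without an effect-size sign dropped")
    sgn <- sgn[!drop]; in_tract <- in_tract[!drop]
  }
  tab <- matrix(c(sum(sgn == "+" & in_tract), sum(sgn == "+" & !in_tract),
                  sum(sgn == "-" & in_tract), sum(sgn == "-" & !in_tract)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("up", "down"), c("tract", "gap")))
  fisherEnrichment(tab, "eqtl_direction_bias")
}

#' CLIP-seq binding-site density over pG4 versus non-pG4 UTR
#'
#' Overlapping peaks (across RBPs) are collapsed into unique binding
#' sites, then counted against pG4 motifs and the remaining UTR; density
#' is sites per kilobase of each region class. Significance uses the
#' Pearson chi-square statistic on the 2x2 table of site counts versus
#' non-site base counts. The reference degrees of freedom are
#' configurable and default to 2 (kept as the published test's stated
#' d.f.; a 2x2 table conventionally has 1, selectable via `df = 1`).
#'
#' @param peaks [GenomicRanges::GRanges] of IDR-passing peaks (any RBP).
#' @param pg4_regions,utr_regions [GenomicRanges::GRanges]; `utr_regions`
#'   is the full UTR space containing `pg4_regions`.
#' @param df chi-square degrees of freedom (default 2).
#' @return list with `density_pg4`, `density_non_pg4` (sites/kb), `fold`
#'   (ratio), and `result` (an [EnrichmentResult] with method `"chisq"`).
#' @export
clipDensity <- function(peaks, pg4_regions, utr_regions, df = 2) {
  stopifnot(is(peaks, "GRanges"), is(pg4_regions, "GRanges"),
            is(utr_regions, "GRanges"))
  pg4 <- reduce(pg4_regions, ignore.strand = TRUE)
  utr <- reduce(utr_regions, ignore.strand = TRUE)
  non <- GenomicRanges::setdiff(utr, pg4, ignore.strand = TRUE)
  len_pg4 <- sum(width(pg4)); len_non <- sum(width(non))
  if (len_pg4 == 0L || len_non == 0L)
    stop("zero-length region class")
  sites <- reduce(peaks, ignore.strand = TRUE)
  n_pg4 <- sum(overlapsAny(sites, pg4, ignore.strand = TRUE))
  n_non <- sum(overlapsAny(sites, non, ignore.strand = TRUE) &
               !overlapsAny(sites, pg4, ignore.strand = TRUE))
  d_pg4 <- n_pg4 / (len_pg4 / 1000)
  d_non <- n_non / (len_non / 1000)
  tab <- matrix(c(n_pg4, n_non, len_pg4 - n_pg4, len_non - n_non),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("sites", "other_bases"),
                                c("pg4", "non_pg4")))
  stat <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
  w <- woolf_ci(tab)
  res <- new("EnrichmentResult", test_label = "clip_density",
             table = tab, odds_ratio = w$or, ci95 = w$ci,
             p_value = pchisq(unname(stat), df = df, lower.tail = FALSE),
             method = "chisq",
             note = sprintf("df=%d", df))
  list(density_pg4 = d_pg4, density_non_pg4 = d_non,
       fold = d_pg4 / d_non, result = res)
}

#' Per-RBP hypergeometric enrichment for pG4-overlapping binding sites
#'
#' For each RNA-binding protein, tests whether its UTR binding sites
#' overlap pG4 motifs more often than the background rate across all UTR
#' binding sites (upper-tail hypergeometric: population = all UTR peaks,
#' successes = pG4-overlapping peaks, draws = the RBP's peaks).
#' Significance is Bonferroni-corrected across the RBPs tested; module
#' membership additionally requires `min_pg4_sites` unique pG4 sites.
#'
#' @param rbp character vector, one entry per UTR peak.
#' @param peak_in_pg4 logical vector parallel to `rbp`.
#' @param alpha family-wise significance level (default 0.001).
#' @param min_pg4_sites minimum unique pG4-overlapping sites for module
#'   membership (default 20).
#' @return data.frame per RBP: counts, `p_value`, `significant`
#'   (Bonferroni), `module_member`.
#' @export
rbpPG4Enrichment <- function(rbp, peak_in_pg4, alpha = 0.001,
                             min_pg4_sites = 20L) {
  stopifnot(length(rbp) == length(peak_in_pg4))
  keep <- !is.na(rbp)
  rbp <- rbp[keep]; peak_in_pg4 <- peak_in_pg4[keep]
  N <- length(rbp)
  K <- sum(peak_in_pg4)
  rbps <- sort(unique(rbp))
  n_tests <- length(rbps)
  out <- lapply(rbps, function(r) {
    sel <- rbp == r
    n <- sum(sel)
    if (n == 0L) return(NULL)
    k <- sum(peak_in_pg4[sel])
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(rbp = r, n_peaks = n, n_pg4_peaks = k, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$significant <- res$p_value < alpha / n_tests
  res$module_member <- res$significant & res$n_pg4_peaks >= min_pg4_sites
  rownames(res) <- NULL
  res
}

#' Pairwise overlap of pG4 gene targets across RBPs
#'
#' Upper-tail hypergeometric test of the overlap between every pair of
#' RBPs' pG4 target-gene sets, against the shared universe of pG4 genes
#' with at least one binding site.
#'
#' @param target_sets named list of character vectors (pG4 gene targets
#'   per RBP).
#' @param universe character vector of all candidate pG4 target genes.
#' @return symmetric matrix of -log10 p-values (diagonal NA).
#' @export
rbpTargetOverlap <- function(target_sets, universe) {
  stopifnot(is.list(target_sets), length(names(target_sets)) ==
              length(target_sets))
  sets <- lapply(target_sets, function(s) intersect(unique(s), universe))
  U <- length(unique(universe))
  n <- length(sets)
  m <- matrix(NA_real_, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- length(sets[[i]]); b <- length(sets[[j]])
    k <- length(intersect(sets[[i]], sets[[j]]))
    p <- phyper(k - 1L, a, U - a, b, lower.tail = FALSE)
    m[i, j] <- -log10(max(p, .Machine$double.xmin))
  }
  m
}

#' Genes sharing binding interactions across a module of RBPs
#'
#' @param target_sets named list of pG4 target-gene sets per RBP.
#' @param min_interactions minimum number of RBPs that must target a gene
#'   (default 3).
#' @return character vector of genes targeted by at least
#'   `min_interactions` of the RBPs.
#' @export
sharedModuleGenes <- function(target_sets, min_interactions = 3L) {
  counts <- table(unlist(lapply(target_sets, unique)))
  names(counts)[counts >= min_interactions]
}

#' Knockdown differential-expression odds ratios for pG4 genes
#'
#' For every RBP knockdown experiment, tests whether pG4-containing genes
#' are more likely to be differentially expressed (FDR < `de_fdr`) than
#' non-pG4 genes, via a two-sided Fisher test. P-values are
#' Benjamini-Hochberg adjusted across RBPs within each cell line and
#' called significant at `bh_alpha`. The direction of the knockdown's
#' effect on pG4 genes is the sign of the median log2 fold-change over
#' all pG4 genes in the experiment.
#'
#' @param de data.frame of per-gene results with columns `rbp`,
#'   `cell_line`, `gene`, `log2fc`, `padj`, `is_pg4`.
#' @param de_fdr per-gene DE threshold (default 0.05).
#' @param bh_alpha BH-adjusted significance level across RBPs (default
#'   0.001).
#' @return data.frame per (rbp, cell_line): `odds_ratio`, `p_value`,
#'   `p_bh`, `significant`, `direction` (+1/-1/0), `median_log2fc_pg4`.
#' @export
knockdownDEOdds <- function(de, de_fdr = 0.05, bh_alpha = 0.001) {
  req <- c("rbp", "cell_line", "gene", "log2fc", "padj", "is_pg4")
  stopifnot(all(req %in% names(de)))
  de$is_de <- de$padj < de_fdr
  groups <- unique(de[, c("rbp", "cell_line")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    sub <- de[de$rbp == groups$rbp[i] & de$cell_line == groups$cell_line[i], ]
    tab <- matrix(c(sum(sub$is_de & sub$is_pg4),
                    sum(sub$is_de & !sub$is_pg4),
                    sum(!sub$is_de & sub$is_pg4),
                    sum(!sub$is_de & !sub$is_pg4)), nrow = 2L, byrow = TRUE)
    enr <- fisherEnrichment(tab, paste0("kd_", groups$rbp[i]))
    med <- median(sub$log2fc[sub$is_pg4])
    data.frame(rbp = groups$rbp[i], cell_line = groups$cell_line[i],
               odds_ratio = enr@odds_ratio, p_value = enr@p_value,
               median_log2fc_pg4 = med, direction = sign(med),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$p_bh <- NA_real_
  for (cl in unique(res$cell_line)) {
    sel <- res$cell_line == cl
    res$p_bh[sel] <- p.adjust(res$p_value[sel], method = "BH")
  }
  res$significant <- res$p_bh < bh_alpha
  rownames(res) <- NULL
  res
}

#' ClinVar variant density in pG4 versus non-pG4 UTR of disease genes
#'
#' Restricts ClinVar records to variants spanning at most 40 nt, drops
#' Benign / Likely_benign annotations, and keeps only genes with at least
#' one Pathogenic or Likely_pathogenic variant (the disease-gene set).
#' Variant counts are then compared to the base counts of each region
#' class with a two-sided Fisher test.
#'
#' @param variants data.frame with columns `gene`, `span` (nt affected),
#'   `clnsig` (clinical significance string) and `in_pg4` (logical).
#' @param disease_genes character vector of disease-associated genes.
#' @param pg4_bases,non_pg4_bases total nucleotides of each region class.
#' @param max_span maximum variant span (default 40 nt).
#' @return An [EnrichmentResult]; OR > 1 means variant density is higher
#'   in pG4 sequence.
#' @export
clinvarDensity <- function(variants, disease_genes, pg4_bases,
                           non_pg4_bases, max_span = 40L) {
  req <- c("gene", "span", "clnsig", "in_pg4")
  stopifnot(all(req %in% names(variants)), pg4_bases > 0, non_pg4_bases > 0)
  keep <- variants$span <= max_span &
    !tolower(variants$clnsig) %in% c("benign", "likely_benign") &
    variants$gene %in% disease_genes
  v <- variants[keep, , drop = FALSE]
  n_pg4 <- sum(v$in_pg4); n_non <- sum(!v$in_pg4)
  tab <- matrix(c(n_pg4, n_non, pg4_bases - n_pg4, non_pg4_bases - n_non),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("variants", "other_bases"),
                                c("pg4", "non_pg4")))
  fisherEnrichment(tab, "clinvar_density")
}
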