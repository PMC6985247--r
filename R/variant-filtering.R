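#' @importFrom stats fisher.test
NULL

#' Apply gnomAD-style quality filters to a variant table
#'
#' Keeps high-confidence single-nucleotide variants: random-forest true
#' positive probability strictly above 0.40, observed allele number at
#' least 80% of the dataset maximum, and no segmental-duplication,
#' low-complexity or decoy flag. Multi-allelic sites should be decomposed
#' to biallelic records upstream; each ALT is judged independently.
#'
#' @param variants data.frame with columns `chrom`, `pos` (0-based), `ref`,
#'   `alt`, `ac`, `an`, `rf_prob` and logical columns `segdup`, `lcr`,
#'   `decoy` (missing flag columns are treated as all-FALSE).
#' @param max_an maximum number of sequenced alleles for the dataset. When
#'   `NULL` (default) it is computed from the input per chromosome type
#'   (chrX/chrY vs autosome), since sex chromosomes have a lower ceiling.
#' @param rf_threshold random-forest probability cutoff (strict `>`;
#'   default 0.40).
#' @param an_fraction minimum fraction of `max_an` (default 0.8, `>=`).
#' @return The passing subset of `variants`, with an added logical column
#'   `is_singleton` (`ac == 1`). Filtering is idempotent.
#' @export
filterVariants <- function(variants, max_an = NULL, rf_threshold = 0.40,
                           an_fraction = 0.8) {
  req <- c("chrom", "pos", "ref", "alt", "ac", "an", "rf_prob")
  miss <- setdiff(req, names(variants))
  if (length(miss))
    stop("missing variant column(s): ", paste(miss, collapse = ", "))
  for (fl in c("segdup", "lcr", "decoy"))
    if (is.null(variants[[fl]])) variants[[fl]] <- FALSE
  if (any(variants$ac > variants$an))
    stop("allele count exceeds allele number for some record")

  sex <- grepl("^(chr)?[XY]$", variants$chrom)
  if (is.null(max_an)) {
    max_an_vec <- numeric(nrow(variants))
    if (any(!sex)) max_an_vec[!sex] <- max(variants$an[!sex])
    if (any(sex)) max_an_vec[sex] <- max(variants$an[sex])
  } else {
    stopifnot(max_an > 0)
    if (any(variants$an > max_an))
      stop("observed allele number exceeds 'max_an' for some record")
    max_an_vec <- rep(max_an, nrow(variants))
  }

  keep <- variants$rf_prob > rf_threshold &
    variants$an >= an_fraction * max_an_vec &
    !variants$segdup & !variants$lcr & !variants$decoy &
    nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
    variants$ref %in% c("A", "C", "G", "T") &
    variants$alt %in% c("A", "C", "G", "T")
  out <- variants[keep, , drop = FALSE]
  out$is_singleton <- out$ac == 1L
  rownames(out) <- NULL
  out
}

#' Select constraint-matched comparator transcripts by LOEUF
#'
#' Samples, without replacement, one comparator transcript per target from
#' the candidate pool's transcripts falling in the same LOEUF bin (bin
#' width `bin_width`, default 0.1). When a target's bin holds no remaining
#' candidate, the nearest non-empty bin is used with a warning.
#'
#' @param target_loeuf numeric LOEUF values of the target (pG4) transcripts.
#' @param pool data.frame with columns `transcript_id`, `loeuf` for the
#'   candidate (non-pG4) transcripts.
#' @param bin_width LOEUF bin width (default 0.1).
#' @param seed integer RNG seed.
#' @return list with `matched` (data.frame `transcript_id`, `loeuf`,
#'   `target_bin`) and `qc` (per-bin data.frame of target/matched counts
#'   and mean LOEUF).
#' @export
matchTranscriptsByLOEUF <- function(target_loeuf, pool, bin_width = 0.1,
                                    seed = 2020L) {
  stopifnot(is.numeric(target_loeuf), length(target_loeuf) >= 1L,
            all(c("transcript_id", "loeuf") %in% names(pool)),
            nrow(pool) >= length(target_loeuf), bin_width > 0)
  binof <- function(x) as.integer(floor(x / bin_width))
  tbin <- binof(target_loeuf)
  pbin <- binof(pool$loeuf)
  set.seed(as.integer(seed))
  avail <- rep(TRUE, nrow(pool))
  pick <- integer(length(target_loeuf))
  widened <- 0L
  for (i in order(tbin)) {
    cand <- which(avail & pbin == tbin[i])
    if (!length(cand)) {
      widened <- widened + 1L
      open <- which(avail)
      if (!length(open)) stop("candidate pool exhausted")
      cand <- open[abs(pbin[open] - tbin[i]) ==
                     min(abs(pbin[open] - tbin[i]))]
    }
    pick[i] <- if (length(cand) == 1L) cand else
      cand[sample.int(length(cand), 1L)]
    avail[pick[i]] <- FALSE
  }
  if (widened > 0L)
    warning(widened, " target(s) matched from a widened LOEUF bin")
  matched <- data.frame(transcript_id = pool$transcript_id[pick],
                        loeuf = pool$loeuf[pick],
                        target_bin = tbin, stringsAsFactors = FALSE)
  bins <- sort(unique(tbin))
  qc <- data.frame(
    bin = bins,
    n_targets = vapply(bins, function(b) sum(tbin == b), integer(1)),
    mean_target_loeuf = vapply(bins, function(b)
      mean(target_loeuf[tbin == b]), numeric(1)),
    mean_matched_loeuf = vapply(bins, function(b)
      mean(matched$loeuf[tbin == b]), numeric(1)))
  list(matched = matched, qc = qc)
}

#' Compare aggregate allele frequencies between two variant groups
#'
#' Sums allele counts (AC) and allele numbers (AN) within each group and
#' tests the 2x2 table `[[AC_a, AN_a - AC_a], [AC_b, AN_b - AC_b]]` with a
#' two-sided Fisher exact test. A depleted group A yields an odds ratio
#' below 1.
#'
#' @param variants_a,variants_b data.frames with `ac` and `an` columns
#'   (e.g. from [filterVariants()]); both must be non-empty.
#' @param labels character(2) group labels.
#' @return A [FrequencyComparison].
#' @export
compareAlleleFrequencies <- function(variants_a, variants_b,
                                     labels = c("A", "B")) {
  stopifnot(nrow(variants_a) >= 1L, nrow(variants_b) >= 1L)
  ac_a <- sum(variants_a$ac); an_a <- sum(variants_a$an)
  ac_b <- sum(variants_b$ac); an_b <- sum(variants_b$an)
  tab <- matrix(c(ac_a, an_a - ac_a, ac_b, an_b - ac_b),
                nrow = 2L, byrow = TRUE)
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  continuity <- any(tab == 0)
  or <- if (continuity) {
    tc <- tab + 0.5
    (tc[1, 1] / tc[1, 2]) / (tc[2, 1] / tc[2, 2])
  } else {
    (ac_a / (an_a - ac_a)) / (ac_b / (an_b - ac_b))
  }
  new("FrequencyComparison",
      group_a = labels[1L], group_b = labels[2L],
      ac_a = ac_a, an_a = an_a, ac_b = ac_b, an_b = an_b,
      odds_ratio = or, p_value = p, continuity = continuity)
}
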