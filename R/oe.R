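#' Heptamer-context substitution probability table
#'
#' Holds posterior substitution probabilities keyed by the 7-mer sequence
#' context centered on a position and the alternate allele of the center
#' base, plus the per-heptamer cumulative probability (sum over the three
#' possible substitutions), which is the expected contribution of one
#' position to the polymorphic-site count under neutrality.
#'
#' @slot prob named numeric vector, names `"HEPTAMER>ALT"`.
#' @slot cumulative named numeric vector keyed by heptamer.
#' @slot symmetrized TRUE when entries were averaged with their reverse
#'   complement on load.
#' @export
setClass("HeptamerTable",
  representation(prob = "numeric", cumulative = "numeric",
                 symmetrized = "logical"))

setMethod("show", "HeptamerTable", function(object) {
  cat(sprintf(
    "HeptamerTable: %d entries, %d heptamers%s; cumulative range [%.4g, %.4g]\n",
    length(object@prob), length(object@cumulative),
    if (object@symmetrized) " (strand-symmetrized)" else "",
    min(object@cumulative), max(object@cumulative)))
})

revcomp <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

#' Build a heptamer substitution table
#'
#' Constructs a [HeptamerTable] from a long-format table of per-heptamer,
#' per-alternate substitution probabilities. Because published
#' context-substitution models are strand-collapsed, entries are by
#' default symmetrized on load: each probability is averaged with the
#' probability of the reverse-complement heptamer mutating to the
#' complementary alternate.
#'
#' @param df data.frame with columns `heptamer` (7-mer over ACGT), `alt`
#'   (single base differing from the heptamer center) and `probability`
#'   in \[0,1\].
#' @param symmetrize average each entry with its reverse complement
#'   (default TRUE).
#' @return A [HeptamerTable].
#' @export
heptamerTable <- function(df, symmetrize = TRUE) {
  stopifnot(all(c("heptamer", "alt", "probability") %in% names(df)))
  hep <- toupper(df$heptamer); alt <- toupper(df$alt)
  if (any(nchar(hep) != 7L) || any(grepl("[^ACGT]", hep)))
    stop("heptamers must be 7-mers over ACGT")
  if (any(substr(hep, 4L, 4L) == alt))
    stop("alt must differ from the heptamer center base")
  if (any(df$probability < 0 | df$probability > 1))
    stop("probabilities must lie in [0, 1]")
  key <- paste0(hep, ">", alt)
  if (anyDuplicated(key)) stop("duplicate (heptamer, alt) entries")
  prob <- stats::setNames(df$probability, key)
  if (symmetrize) {
    rc_key <- paste0(revcomp(hep), ">", chartr("ACGT", "TGCA", alt))
    rc_prob <- prob[rc_key]
    rc_prob[is.na(rc_prob)] <- prob[is.na(rc_prob)]
    prob <- (prob + unname(rc_prob)) / 2
  }
  cum <- rowsum(unname(prob), group = hep)
  cumulative <- stats::setNames(as.numeric(cum), rownames(cum))
  if (any(cumulative > 1 + 1e-12))
    stop("cumulative substitution probability exceeds 1 for some heptamer")
  new("HeptamerTable", prob = prob, cumulative = cumulative,
      symmetrized = symmetrize)
}

#' Cumulative substitution probability per position
#'
#' @param table a [HeptamerTable].
#' @param contexts character vector of 7-mer contexts (reference strand);
#'   `NA` or contexts containing `N` yield `NA`.
#' @return numeric vector of per-position cumulative probabilities.
#' @export
cumulativeProb <- function(table, contexts) {
  stopifnot(is(table, "HeptamerTable"))
  out <- rep(NA_real_, length(contexts))
  ok <- !is.na(contexts) & !grepl("N", contexts, fixed = TRUE)
  out[ok] <- unname(table@cumulative[contexts[ok]])
  out
}

#' CpG dinucleotide mask for a reference sequence
#'
#' Marks every position that is the C or the G of a CG dinucleotide in the
#' reference (a CG on the reverse strand occupies the same two positions,
#' so scanning the forward strand covers both).
#'
#' @param seq single reference sequence string.
#' @return logical vector, one entry per position.
#' @export
cpgMask <- function(seq) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  mask <- logical(n)
  if (n < 2L) return(mask)
  m <- gregexpr("CG", seq)[[1L]]
  if (m[1L] != -1L) {
    mask[as.integer(m)] <- TRUE
    mask[as.integer(m) + 1L] <- TRUE
  }
  mask
}

# shared preprocessing: drop incomplete/N contexts and CpG positions
oe_usable <- function(contexts, cpg_mask) {
  if (is.null(cpg_mask)) cpg_mask <- logical(length(contexts))
  stopifnot(length(cpg_mask) == length(contexts))
  bad <- is.na(contexts) | grepl("N", contexts, fixed = TRUE)
  if (any(bad))
    message(sum(bad), " position(s) without a full ACGT heptamer dropped")
  !bad & !cpg_mask
}

#' Expected number of polymorphic sites under the heptamer model
#'
#' Sums the cumulative substitution probability over all usable positions:
#' positions lacking a full ACGT 7-mer context are dropped (and logged),
#' and CpG positions are excluded because the context model is not
#' methylation-adjusted.
#'
#' @param contexts per-position 7-mer contexts.
#' @param table a [HeptamerTable].
#' @param cpg_mask optional logical vector marking CpG positions.
#' @return expected count (numeric scalar).
#' @export
expectedSubstitutions <- function(contexts, table, cpg_mask = NULL) {
  use <- oe_usable(contexts, cpg_mask)
  sum(cumulativeProb(table, contexts[use]))
}

#' Observed number of polymorphic sites in a region
#'
#' Counts the usable (non-CpG) region positions that intersect at least
#' one polymorphic site; a position polymorphic for several alternates
#' counts once.
#'
#' @param positions vector of region position identifiers (e.g. genomic
#'   coordinates).
#' @param sites vector of polymorphic-site identifiers on the same scale.
#' @param cpg_mask optional logical vector parallel to `positions`.
#' @return integer count.
#' @export
observedSubstitutions <- function(positions, sites, cpg_mask = NULL) {
  if (is.null(cpg_mask)) cpg_mask <- logical(length(positions))
  stopifnot(length(cpg_mask) == length(positions))
  sum(positions[!cpg_mask] %in% sites)
}

# chunked bootstrap of sum(obs)/sum(exp) over resampled positions
bootRatio <- function(obs, exp, size, n_iter, chunk = 2e6) {
  n <- length(obs)
  out <- numeric(n_iter)
  done <- 0L
  per_chunk <- max(1L, as.integer(chunk %/% size))
  while (done < n_iter) {
    k <- min(per_chunk, n_iter - done)
    idx <- matrix(sample.int(n, size * k, replace = TRUE), nrow = size)
    num <- colSums(matrix(obs[idx], nrow = size))
    den <- colSums(matrix(exp[idx], nrow = size))
    out[done + seq_len(k)] <- num / den
    done <- done + k
  }
  out
}

#' Observed/expected substitution ratio with bootstrap confidence interval
#'
#' Computes the ratio of observed polymorphic positions to the
#' heptamer-model expectation for a region class, with a 90% interval from
#' resampling positions with replacement (resamples match the region's
#' size). Ratios below 1 indicate depletion of variation. Iterations whose
#' resampled expectation is zero are discarded and logged.
#'
#' @param contexts per-position 7-mer contexts of the region class
#'   (positions pooled across motifs within the class).
#' @param is_polymorphic logical vector parallel to `contexts`.
#' @param table a [HeptamerTable].
#' @param cpg_mask optional logical CpG mask parallel to `contexts`.
#' @param n_iter bootstrap iterations (default 10000).
#' @param seed integer RNG seed.
#' @param region_label label stored in the result.
#' @return A [RegionOEResult]; its metadata-free bootstrap draws are
#'   available via `attr(, "boot")` for downstream null comparisons.
#' @export
oeBootstrap <- function(contexts, is_polymorphic, table, cpg_mask = NULL,
                        n_iter = 10000L, seed = 2020L,
                        region_label = "region") {
  stopifnot(length(contexts) == length(is_polymorphic), n_iter >= 1L)
  use <- oe_usable(contexts, cpg_mask)
  if (!any(use)) stop("no usable positions in region")
  exp_i <- cumulativeProb(table, contexts[use])
  obs_i <- as.numeric(is_polymorphic[use])
  n <- length(obs_i)
  observed <- as.integer(sum(obs_i))
  expected <- sum(exp_i)
  ratio <- observed / expected

  set.seed(as.integer(seed))
  boot <- bootRatio(obs_i, exp_i, n, n_iter)
  bad <- !is.finite(boot)
  if (any(bad)) {
    message(sum(bad), " bootstrap iteration(s) with zero expectation discarded")
    boot <- boot[!bad]
  }
  ci <- if (length(boot)) unname(quantile(boot, c(0.05, 0.95)))
        else c(NA_real_, NA_real_)
  res <- new("RegionOEResult",
             region_label = region_label, n_positions = n,
             observed = observed, expected = expected, ratio = ratio,
             ci90 = ci)
  attr(res, "boot") <- boot
  res
}

#' Empirical-null depletion test against constraint-matched UTR windows
#'
#' Builds a null for the observed/expected ratio by sampling `n_windows`
#' contiguous windows of `window_len` positions from the UTRs of
#' constraint-matched transcripts, then pairs `n_iter` bootstrap draws of
#' the target region's ratio with draws of the background's ratio (each
#' resample matches its own region's size). The one-sided depletion p is
#' the proportion of pairs in which the target's ratio is at least the
#' background's, so a strongly depleted target yields a small p.
#'
#' @param target_contexts,target_polymorphic target region positions, as
#'   in [oeBootstrap()].
#' @param bg_contexts,bg_polymorphic position pool of constraint-matched
#'   UTRs, in sequence order (windows are contiguous slices of this pool).
#' @param table a [HeptamerTable].
#' @param target_cpg_mask,bg_cpg_mask optional CpG masks.
#' @param window_len window length in nt (default 25).
#' @param n_windows number of windows sampled (default 5000).
#' @param n_iter paired bootstrap iterations (default 10000).
#' @param seed integer RNG seed.
#' @param region_label label for the target region.
#' @return The target's [RegionOEResult] with `permutation_p` filled in;
#'   `attr(, "null_ratios")` carries the background bootstrap draws.
#' @export
oeEmpiricalNull <- function(target_contexts, target_polymorphic,
                            bg_contexts, bg_polymorphic, table,
                            target_cpg_mask = NULL, bg_cpg_mask = NULL,
                            window_len = 25L, n_windows = 5000L,
                            n_iter = 10000L, seed = 2020L,
                            region_label = "region") {
  stopifnot(length(bg_contexts) == length(bg_polymorphic),
            length(bg_contexts) >= window_len)
  set.seed(as.integer(seed))

  # contiguous windows from the background pool
  starts <- sample.int(length(bg_contexts) - window_len + 1L, n_windows,
                       replace = TRUE)
  widx <- as.vector(outer(0:(window_len - 1L), starts, `+`))
  bgc <- bg_contexts[widx]
  bgp <- bg_polymorphic[widx]
  bgm <- if (is.null(bg_cpg_mask)) NULL else bg_cpg_mask[widx]

  use_t <- oe_usable(target_contexts, target_cpg_mask)
  exp_t <- cumulativeProb(table, target_contexts[use_t])
  obs_t <- as.numeric(target_polymorphic[use_t])
  use_b <- oe_usable(bgc, bgm)
  exp_b <- cumulativeProb(table, bgc[use_b])
  obs_b <- as.numeric(bgp[use_b])

  boot_t <- bootRatio(obs_t, exp_t, length(obs_t), n_iter)
  boot_b <- bootRatio(obs_b, exp_b, length(obs_b), n_iter)
  ok <- is.finite(boot_t) & is.finite(boot_b)
  p <- mean(boot_t[ok] >= boot_b[ok])

  res <- new("RegionOEResult",
             region_label = region_label,
             n_positions = length(obs_t),
             observed = as.integer(sum(obs_t)),
             expected = sum(exp_t),
             ratio = sum(obs_t) / sum(exp_t),
             ci90 = unname(quantile(boot_t[is.finite(boot_t)],
                                    c(0.05, 0.95))),
             permutation_p = p)
  attr(res, "null_ratios") <- boot_b
  res
}
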