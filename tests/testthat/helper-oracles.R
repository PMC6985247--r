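# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: run enumeration via rle() instead of regex,
# Fisher/hypergeometric p via direct dhyper tail summation, and a
# record-by-record filter re-implementation.

# Brute-force pG4 scan: enumerate maximal G-runs >= 3 from an rle() of the
# character vector, then greedily take the leftmost 4 consecutive runs
# whose three inter-run gaps are each 1-7 nt; reported motifs never share
# a run. Returns 0-based half-open spans.
oracle_scan <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1L]]
  if (!length(chars))
    return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(chars == "G")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  g <- which(r$values & r$lengths >= 3L)
  rs <- starts[g]; re <- ends[g]
  n <- length(rs)
  out_s <- integer(0); out_e <- integer(0)
  i <- 1L
  while (i + 3L <= n) {
    gaps <- rs[(i + 1L):(i + 3L)] - re[i:(i + 2L)] - 1L
    if (all(gaps >= 1L & gaps <= 7L)) {
      out_s <- c(out_s, rs[i] - 1L)
      out_e <- c(out_e, re[i + 3L])
      i <- i + 4L
    } else i <- i + 1L
  }
  data.frame(start = out_s, end = out_e)
}

# Two-sided Fisher p by exhaustive enumeration of all 2x2 tables with the
# observed margins: sum hypergeometric probabilities not exceeding the
# observed table's probability (with the conventional relative tolerance).
oracle_fisher_two_sided <- function(tab) {
  m <- sum(tab[1L, ]); n2 <- sum(tab[2L, ]); k <- sum(tab[, 1L])
  supp <- max(0L, k - n2):min(k, m)
  probs <- dhyper(supp, m, n2, k)
  pobs <- dhyper(tab[1L, 1L], m, n2, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Upper-tail hypergeometric p by direct tail summation.
oracle_hyper_upper <- function(k, K, N, n) {
  supp <- k:min(n, K)
  sum(dhyper(supp, K, N - K, n))
}

# Record-by-record re-implementation of the variant quality filter.
oracle_filter <- function(v, max_an, rf = 0.40, frac = 0.8) {
  keep <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    r <- v[i, ]
    keep[i] <- r$rf_prob > rf &&
      r$an >= frac * max_an &&
      !r$segdup && !r$lcr && !r$decoy &&
      nchar(r$ref) == 1L && nchar(r$alt) == 1L &&
      r$ref %in% c("A", "C", "G", "T") && r$alt %in% c("A", "C", "G", "T")
  }
  v[keep, , drop = FALSE]
}

# Exhaustive enumeration of pG4 label assignments: all ways to place
# n_pg4_total labels on transcripts with every gene keeping >= 1, with the
# alternative:constitutive ratio of each assignment.
oracle_isoform_ratios <- function(n_isoforms, n_pg4_total) {
  G <- length(n_isoforms)
  N <- sum(n_isoforms)
  gidx <- rep.int(seq_len(G), n_isoforms)
  sel <- utils::combn(N, n_pg4_total)
  ratios <- numeric(0)
  for (j in seq_len(ncol(sel))) {
    cnt <- tabulate(gidx[sel[, j]], nbins = G)
    if (all(cnt >= 1L)) {
      n_alt <- sum(cnt < n_isoforms); n_con <- sum(cnt == n_isoforms)
      ratios <- c(ratios, if (n_con == 0L) Inf else n_alt / n_con)
    }
  }
  ratios
}

random_dna <- function(len, probs = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = probs),
        collapse = "")
}

revcomp_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1L]]), collapse = "")
}
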