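#' @importFrom GenomicRanges GRanges GRangesList seqnames strand reduce
#'   findOverlaps countOverlaps start end width
#' @importFrom IRanges overlapsAny
NULL

#' Project UTR motif offsets onto genomic coordinates
#'
#' Maps 0-based half-open offsets within a UTR sequence (sense orientation)
#' through the UTR's genomic exon blocks. On the minus strand, transcript
#' offset 0 maps to the highest genomic coordinate of the UTR. A motif
#' spanning a splice junction yields multiple genomic blocks whose widths
#' sum to the motif length.
#'
#' @param start0,end0 integer vectors of 0-based half-open intervals within
#'   the UTR sequence (e.g. motif spans from [scanPG4()]).
#' @param blocks a [GenomicRanges::GRanges] of the UTR's genomic exon
#'   blocks, all on one chromosome and one strand. Order is irrelevant;
#'   blocks are sorted genomically, and transcript order is derived from
#'   the strand.
#' @return A [GenomicRanges::GRangesList] with one element per input
#'   interval; each element contains the genomic blocks (1-based GRanges
#'   convention) covering exactly that interval's transcript positions.
#' @examples
#' utr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1100), "+")
#' projectToGenome(10, 25, utr)   # one block, genomic [1010,1025) 0-based
#' @export
projectToGenome <- function(start0, end0, blocks) {
  stopifnot(is(blocks, "GRanges"), length(blocks) >= 1L)
  if (length(unique(as.character(seqnames(blocks)))) != 1L)
    stop("UTR blocks must be on a single chromosome")
  std <- unique(as.character(strand(blocks)))
  if (length(std) != 1L || !std %in% c("+", "-"))
    stop("UTR blocks must share a single '+' or '-' strand")
  o <- order(start(blocks))
  if (any(start(blocks)[o][-1L] <= end(blocks)[o][-length(o)]))
    stop("UTR blocks overlap")
  blocks <- blocks[o]
  total <- sum(width(blocks))
  if (any(start0 < 0L) || any(end0 > total) || any(end0 < start0))
    stop("interval outside the UTR sequence (length ", total, ")")

  # per-block transcript offsets, walking 5'->3'
  if (std == "-") bidx <- rev(seq_along(blocks)) else bidx <- seq_along(blocks)
  w <- width(blocks)[bidx]
  cum_end <- cumsum(w)          # transcript offset one past each block
  cum_start <- cum_end - w

  res <- vector("list", length(start0))
  chr <- as.character(seqnames(blocks))[1L]
  for (k in seq_along(start0)) {
    s <- start0[k]; e <- end0[k]
    hit <- which(cum_start < e & cum_end > s)
    gs <- ge <- integer(length(hit))
    for (j in seq_along(hit)) {
      b <- hit[j]
      lo <- max(s, cum_start[b]); hi <- min(e, cum_end[b])  # transcript coords
      g <- bidx[b]
      if (std == "+") {
        g0 <- (start(blocks)[g] - 1L) + (lo - cum_start[b])
        gs[j] <- g0 + 1L
        ge[j] <- g0 + (hi - lo)
      } else {
        # transcript offset cum_start[b] sits at genomic end(block g) - 1 (0-based)
        g0hi <- (end(blocks)[g] - 1L) - (lo - cum_start[b])  # 0-based, inclusive
        g0lo <- g0hi - (hi - lo) + 1L
        gs[j] <- g0lo + 1L
        ge[j] <- g0hi + 1L
      }
    }
    gr <- GRanges(chr, IRanges(start = gs, end = ge), strand = std)
    res[[k]] <- sort(gr)
  }
  GRangesList(res)
}

#' Flag genomic motif blocks that overlap annotated coding sequence
#'
#' A motif overlapping any annotated CDS block (of any transcript in the
#' annotation set, not only the motif's own gene) is excluded from all
#' downstream gene- and variant-level analyses, so that intervals annotated
#' as UTR in one isoform but coding in another are never scored as UTR.
#'
#' @param genomicBlocks a [GenomicRanges::GRangesList], e.g. from
#'   [projectToGenome()].
#' @param cds a [GenomicRanges::GRanges] of CDS blocks (strand ignored).
#' @return logical vector, TRUE where any block intersects the CDS set.
#' @export
flagCDSOverlap <- function(genomicBlocks, cds) {
  stopifnot(is(genomicBlocks, "GRangesList"), is(cds, "GRanges"))
  as.logical(vapply(genomicBlocks, function(gr)
    any(overlapsAny(gr, cds, ignore.strand = TRUE)), logical(1)))
}

#' Canonical string key for a set of genomic motif blocks
#'
#' Used to compare motifs across isoforms: two motifs are "identical" when
#' their genomic block sets are identical.
#'
#' @param gr a [GenomicRanges::GRanges] of one motif's blocks.
#' @return character scalar key.
#' @export
motifKey <- function(gr) {
  gr <- sort(gr)
  paste(sprintf("%s:%d-%d", as.character(seqnames(gr)),
                start(gr) - 1L, end(gr)), collapse = ",")
}

#' Classify genes as constitutive or alternative pG4 producers
#'
#' A gene is a constitutive pG4 gene on a UTR side when every annotated
#' protein-coding isoform carries at least one (non-CDS-overlapping) pG4 on
#' that side, and an alternative pG4 gene when at least one isoform carries
#' a pG4 and at least one lacks one. Genes with no pG4 isoform are
#' `non_pg4`. `identical_pg4` is TRUE when all pG4-bearing isoforms carry
#' the same set of genomic motifs.
#'
#' @param gene_id,transcript_id character vectors, one entry per
#'   protein-coding isoform.
#' @param pg4_keys character vector parallel to `transcript_id`: the
#'   ";"-collapsed sorted [motifKey()] strings of the motifs carried by the
#'   isoform (on one UTR side), or `""` when the isoform carries none.
#' @return data.frame with one row per gene: `gene_id`, `status`
#'   (`constitutive` / `alternative` / `non_pg4`), `n_pg4_isoforms`,
#'   `n_total_isoforms`, `identical_pg4`. Row order follows the first
#'   appearance of each gene, so results are invariant to isoform input
#'   order up to that deterministic gene order.
#' @export
classifyIsoforms <- function(gene_id, transcript_id, pg4_keys) {
  stopifnot(length(gene_id) == length(transcript_id),
            length(gene_id) == length(pg4_keys))
  if (!length(gene_id))
    return(data.frame(gene_id = character(0), status = character(0),
                      n_pg4_isoforms = integer(0),
                      n_total_isoforms = integer(0),
                      identical_pg4 = logical(0)))
  o <- order(match(gene_id, unique(gene_id)), transcript_id)
  gene_id <- gene_id[o]; pg4_keys <- pg4_keys[o]
  sp <- split(pg4_keys, factor(gene_id, levels = unique(gene_id)))
  out <- lapply(names(sp), function(g) {
    keys <- sp[[g]]
    has <- keys != ""
    n_pg4 <- sum(has)
    status <- if (n_pg4 == 0L) "non_pg4"
      else if (n_pg4 == length(keys)) "constitutive" else "alternative"
    identical_pg4 <- n_pg4 > 0L && length(unique(keys[has])) == 1L
    data.frame(gene_id = g, status = status,
               n_pg4_isoforms = n_pg4, n_total_isoforms = length(keys),
               identical_pg4 = identical_pg4, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Permutation test for the alternative:constitutive pG4 gene ratio
#'
#' Tests whether the observed ratio of alternative to constitutive pG4
#' genes exceeds what random pG4-isoform assignment produces. Each
#' permutation redistributes the total number of pG4-bearing transcripts
#' uniformly across all transcripts, keeping every gene's isoform count
#' fixed and requiring every gene to retain at least one pG4 transcript.
#' Genes
#' entering with zero pG4 transcripts are excluded with a warning.
#'
#' Drawing an assignment uniformly over all valid ones is done exactly:
#' the number of assignments with per-gene label counts
#' \eqn{(c_1, ..., c_G)} is \eqn{\prod_g \binom{n_g}{c_g}}, so per-gene
#' counts are sampled sequentially from a dynamic-programming table of
#' suffix counts (in log space); which particular isoforms carry a label
#' is irrelevant to the alternative/constitutive status.
#'
#' @param n_isoforms,n_pg4 integer vectors per gene: total protein-coding
#'   isoforms and pG4-bearing isoforms.
#' @param n_iter number of permutations (>= 1).
#' @param seed integer RNG seed.
#' @return list with `p_value` = (1 + #\{permuted ratio >= observed\}) /
#'   (n_iter + 1), `observed_ratio`, `n_alternative`, `n_constitutive`, and
#'   the vector `null_ratios`.
#' @export
permuteIsoformLabels <- function(n_isoforms, n_pg4, n_iter = 10000L,
                                 seed = 2020L) {
  stopifnot(length(n_isoforms) == length(n_pg4), n_iter >= 1L)
  drop <- n_pg4 == 0L
  if (any(drop)) {
    warning(sum(drop), " gene(s) with zero pG4 transcripts excluded")
    n_isoforms <- n_isoforms[!drop]; n_pg4 <- n_pg4[!drop]
  }
  if (!length(n_isoforms)) stop("no genes with a pG4 transcript")
  if (any(n_pg4 > n_isoforms))
    stop("n_pg4 exceeds n_isoforms for some gene")

  ratio_of <- function(np, ni) {
    n_alt <- sum(np < ni)
    n_con <- sum(np == ni)
    if (n_con == 0L) Inf else n_alt / n_con
  }
  obs <- ratio_of(n_pg4, n_isoforms)

  G <- length(n_isoforms)
  T_total <- sum(n_pg4)
  logsumexp <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(-Inf)
    m + log(sum(exp(x - m)))
  }

  # lf[j, t + 1] = log #assignments of t labels to genes j..G, each >= 1
  lf <- matrix(-Inf, nrow = G + 1L, ncol = T_total + 1L)
  lf[G + 1L, 1L] <- 0
  lch <- lapply(seq_len(G), function(j)
    lchoose(n_isoforms[j], seq_len(n_isoforms[j])))
  min_suffix <- rev(cumsum(rev(rep(1L, G))))   # >= 1 label per gene
  max_suffix <- rev(cumsum(rev(n_isoforms)))
  for (j in G:1) {
    for (t in min_suffix[j]:min(T_total, max_suffix[j])) {
      cs <- seq_len(min(n_isoforms[j], t))
      vals <- lch[[j]][cs] + lf[j + 1L, t - cs + 1L]
      lf[j, t + 1L] <- logsumexp(vals)
    }
  }
  if (!is.finite(lf[1L, T_total + 1L]))
    stop("no valid assignment with every gene keeping a pG4 transcript")

  set.seed(as.integer(seed))
  null_ratios <- numeric(n_iter)
  counts <- integer(G)
  for (it in seq_len(n_iter)) {
    t <- T_total
    for (j in seq_len(G)) {
      cs <- seq_len(min(n_isoforms[j], t))
      lp <- lch[[j]][cs] + lf[j + 1L, t - cs + 1L]
      p <- exp(lp - max(lp))
      c_j <- if (length(cs) == 1L) cs else
        cs[sample.int(length(cs), 1L, prob = p)]
      counts[j] <- c_j
      t <- t - c_j
    }
    null_ratios[it] <- ratio_of(counts, n_isoforms)
  }
  ge <- if (is.infinite(obs)) sum(is.infinite(null_ratios))
        else sum(null_ratios >= obs)
  list(p_value = (1 + ge) / (n_iter + 1),
       observed_ratio = obs,
       n_alternative = sum(n_pg4 < n_isoforms),
       n_constitutive = sum(n_pg4 == n_isoforms),
       null_ratios = null_ratios)
}

#' Per-tissue expression label for a pG4 gene's isoforms
#'
#' For each tissue, the highest-expressed pG4 isoform and the
#' highest-expressed non-pG4 isoform are taken; each side counts as
#' expressed when its median TPM strictly exceeds 1. The gene is then
#' labeled `both_expressed`, `pg4_only`, `non_pg4_only` or `neither`.
#'
#' @param tpm numeric matrix of median TPM, isoforms x tissues.
#' @param is_pg4 logical vector per isoform (row) of `tpm`.
#' @param tissues optional character vector of tissue columns to use;
#'   requesting a missing column is an error.
#' @param threshold expression threshold (default 1 TPM, strict `>`).
#' @return named character vector of labels, one per tissue.
#' @export
classifyExpression <- function(tpm, is_pg4, tissues = colnames(tpm),
                               threshold = 1) {
  stopifnot(is.matrix(tpm), nrow(tpm) == length(is_pg4))
  if (is.null(colnames(tpm))) stop("'tpm' must have tissue column names")
  missing <- setdiff(tissues, colnames(tpm))
  if (length(missing))
    stop("tissue column(s) not found: ", paste(missing, collapse = ", "))
  tpm <- tpm[, tissues, drop = FALSE]
  top <- function(rows) {
    if (!any(rows)) rep(-Inf, ncol(tpm))
    else apply(tpm[rows, , drop = FALSE], 2L, max)
  }
  pg4_on <- top(is_pg4) > threshold
  non_on <- top(!is_pg4) > threshold
  lab <- ifelse(pg4_on & non_on, "both_expressed",
         ifelse(pg4_on, "pg4_only",
         ifelse(non_on, "non_pg4_only", "neither")))
  names(lab) <- tissues
  lab
}
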