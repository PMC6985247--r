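#' Scan a UTR sequence for canonical G-quadruplex motifs
#'
#' Finds putative G-quadruplex (pG4) motifs matching the canonical pattern
#' of four guanine tracts of length >= 3 separated by loops of 1-7
#' nucleotides, i.e. \code{G{3,}([ACGTN]{1,7}G{3,}){3}} on the sense strand.
#'
#' Because G-runs longer than three and adjacent motifs make the canonical
#' pattern ambiguous, matching follows a fixed disambiguation policy:
#' maximal G-runs of length >= 3 are enumerated left to right, and motifs
#' are built greedily from the leftmost four consecutive runs whose three
#' intervening loops each span 1-7 nt; every tract extends to its full
#' maximal run, and reported motifs never share a G-run (the scan resumes
#' after the last tract of a reported motif). `N` never counts as guanine:
#' it breaks G-runs and is an ordinary loop character.
#'
#' @param seq a single character string (or [Biostrings::DNAString]) over
#'   the alphabet ACGTN, in transcript (sense) orientation. Lowercase is
#'   accepted and upper-cased.
#' @return A [G4MotifSet] with coordinates 0-based half-open relative to
#'   `seq`. An empty string yields an empty set.
#' @examples
#' scanPG4("GGGAGGGAGGGAGGG")      # the minimal canonical motif
#' scanPG4("GGAGGAGGAGG")          # no run of 3 Gs: empty
#' @export
scanPG4 <- function(seq) {
  seq <- toupper(as.character(seq))
  if (length(seq) != 1L) stop("'seq' must be a single sequence")
  if (is.na(seq)) stop("'seq' must not be NA")
  if (nchar(seq) == 0L) return(emptyG4MotifSet())
  if (grepl("[^ACGTN]", seq))
    stop("'seq' contains non-nucleotide characters (allowed: ACGTN)")

  m <- gregexpr("G{3,}", seq)[[1L]]
  if (m[1L] == -1L) return(emptyG4MotifSet())
  run_start <- as.integer(m)                       # 1-based
  run_len <- attr(m, "match.length")
  run_end <- run_start + run_len - 1L
  n_runs <- length(run_start)

  motif_tracts <- list()
  i <- 1L
  while (i + 3L <= n_runs) {
    gaps <- run_start[(i + 1L):(i + 3L)] - run_end[i:(i + 2L)] - 1L
    if (all(gaps >= 1L & gaps <= 7L)) {
      motif_tracts[[length(motif_tracts) + 1L]] <- i:(i + 3L)
      i <- i + 4L
    } else {
      i <- i + 1L
    }
  }
  if (!length(motif_tracts)) return(emptyG4MotifSet())

  buildG4MotifSet(seq, run_start, run_end, motif_tracts)
}

emptyG4MotifSet <- function() {
  new("G4MotifSet",
      ranges = IRanges(), tracts = IRangesList(), gaps = IRangesList(),
      seqs = character(0))
}

buildG4MotifSet <- function(seq, run_start, run_end, motif_tracts) {
  spans <- tracts <- gaps <- seqs <- vector("list", length(motif_tracts))
  for (k in seq_along(motif_tracts)) {
    idx <- motif_tracts[[k]]
    s <- run_start[idx[1L]]
    e <- run_end[idx[length(idx)]]
    tr <- IRanges(start = run_start[idx], end = run_end[idx])
    gp <- IRanges(start = run_end[idx[-length(idx)]] + 1L,
                  end = run_start[idx[-1L]] - 1L)
    spans[[k]] <- IRanges(start = s, end = e)
    tracts[[k]] <- tr
    gaps[[k]] <- gp
    seqs[[k]] <- substr(seq, s, e)
  }
  new("G4MotifSet",
      ranges = do.call(c, spans),
      tracts = IRangesList(tracts),
      gaps = IRangesList(gaps),
      seqs = unlist(seqs))
}

#' @describeIn scanPG4 coerce a motif set to a data.frame with 0-based
#'   half-open `start`/`end`, `n_tracts` and `sequence` columns.
#' @param x a [G4MotifSet].
#' @param row.names,optional,... ignored, present for S3 compatibility.
#' @export
as.data.frame.G4MotifSet <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  data.frame(
    start = start(x@ranges) - 1L,
    end = end(x@ranges),
    n_tracts = lengths(x@tracts),
    sequence = x@seqs,
    stringsAsFactors = FALSE
  )
}

#' Partition motifs into G-tracts and loop (gap) intervals
#'
#' Returns, for every motif in the set, its maximal G-runs and the
#' complementary loop intervals. Tracts and gaps tile the motif span
#' exactly, so pasting the corresponding substrings in order reconstructs
#' the motif sequence.
#'
#' @param x a [G4MotifSet].
#' @return A list with one element per motif; each element is a list of two
#'   data.frames, `tracts` (columns `start`, `end`, `length`; 0-based
#'   half-open) and `gaps` (columns `start`, `end`, `length`).
#' @export
partitionTracts <- function(x) {
  stopifnot(is(x, "G4MotifSet"))
  lapply(seq_len(length(x)), function(i) {
    tr <- x@tracts[[i]]
    gp <- x@gaps[[i]]
    list(
      tracts = data.frame(start = start(tr) - 1L, end = end(tr),
                          length = width(tr)),
      gaps = data.frame(start = start(gp) - 1L, end = end(gp),
                        length = width(gp))
    )
  })
}

#' Positional guanine labels for trinucleotide G-tracts
#'
#' For every length-3 tract the three guanines are labeled `5pG`, `central`
#' and `3pG` (the central guanine of the tetrad stack is the position whose
#' substitution is most destabilizing to G4 structure). Tracts longer than
#' three guanines carry no positional labels, because which three of their
#' guanines stack is ambiguous.
#'
#' @param x a [G4MotifSet].
#' @return data.frame with columns `motif`, `tract`, `label`, `offset`
#'   (0-based position within the scanned sequence). Only length-3 tracts
#'   contribute rows.
#' @export
tractGuanines <- function(x) {
  stopifnot(is(x, "G4MotifSet"))
  out <- list()
  for (i in seq_len(length(x))) {
    tr <- x@tracts[[i]]
    keep <- which(width(tr) == 3L)
    for (j in keep) {
      s0 <- start(tr)[j] - 1L
      out[[length(out) + 1L]] <- data.frame(
        motif = i, tract = j,
        label = c("5pG", "central", "3pG"),
        offset = s0 + 0:2,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(motif = integer(0), tract = integer(0),
                      label = character(0), offset = integer(0)))
  do.call(rbind, out)
}
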