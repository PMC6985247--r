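#' @import methods
#' @importFrom S4Vectors isTRUEorFALSE
#' @importFrom IRanges IRanges IRangesList width start end
#' @importFrom stats quantile
NULL

#' Set of putative G-quadruplex motifs found in one sequence
#'
#' Container returned by [scanPG4()]. Each motif is a span of the scanned
#' (sense-strand) UTR sequence built from four consecutive maximal G-runs of
#' length >= 3 separated by loops of 1-7 nt. Coordinates are 0-based
#' half-open offsets into the scanned sequence.
#'
#' @slot ranges [IRanges::IRanges] of motif spans (stored 1-based internally,
#'   exposed 0-based half-open through accessors and `as.data.frame`).
#' @slot tracts [IRanges::IRangesList], per-motif maximal G-runs.
#' @slot gaps [IRanges::IRangesList], per-motif loop intervals between tracts.
#' @slot seqs character vector of motif sequences.
#'
#' @seealso [scanPG4()], [partitionTracts()], [tractGuanines()]
#' @export
setClass("G4MotifSet",
  representation(
    ranges = "IRanges",
    tracts = "IRangesList",
    gaps = "IRangesList",
    seqs = "character"
  )
)

setValidity("G4MotifSet", function(object) {
  n <- length(object@ranges)
  if (length(object@tracts) != n || length(object@gaps) != n ||
      length(object@seqs) != n)
    return("ranges, tracts, gaps and seqs must have equal length")
  for (i in seq_len(n)) {
    tr <- object@tracts[[i]]
    gp <- object@gaps[[i]]
    if (length(tr) < 4L)
      return(sprintf("motif %d has fewer than 4 G-tracts", i))
    if (any(width(tr) < 3L))
      return(sprintf("motif %d has a G-tract shorter than 3", i))
    if (length(gp) != length(tr) - 1L)
      return(sprintf("motif %d: gaps must interleave tracts", i))
    if (length(gp) && (any(width(gp) < 1L) || any(width(gp) > 7L)))
      return(sprintf("motif %d has a loop outside [1,7] nt", i))
    # tracts and gaps must tile the motif span exactly
    pieces <- sort(c(start(tr), start(gp)))
    ends <- sort(c(end(tr), end(gp)))
    if (pieces[1L] != start(object@ranges)[i] ||
        ends[length(ends)] != end(object@ranges)[i] ||
        any(pieces[-1L] != ends[-length(ends)] + 1L))
      return(sprintf("motif %d: tracts and gaps do not tile the span", i))
    seq_i <- object@seqs[i]
    off <- start(object@ranges)[i] - 1L
    for (j in seq_along(tr)) {
      sub <- substr(seq_i, start(tr)[j] - off, end(tr)[j] - off)
      if (gsub("G", "", sub) != "")
        return(sprintf("motif %d tract %d is not all G", i, j))
    }
  }
  TRUE
})

#' Mutation rate regression used by the MAPS metric
#'
#' Fit of per-context singleton proportion (synonymous calibration variants)
#' on context-specific mutation rate, produced by [calibrateMutability()].
#'
#' @slot intercept,slope numeric coefficients of the weighted least-squares
#'   fit; predictions are clamped to \[0,1\].
#' @slot r_squared weighted R-squared of the fit.
#' @slot diagnostics per-context data.frame (context key, rate, n variants,
#'   observed singleton proportion, fitted value).
#' @slot weighted logical; TRUE when the regression was weighted by
#'   per-context variant count.
#' @export
setClass("MutabilityCalibration",
  representation(
    intercept = "numeric",
    slope = "numeric",
    r_squared = "numeric",
    diagnostics = "data.frame",
    weighted = "logical"
  )
)

#' Mutability-adjusted proportion of singletons for a variant class
#'
#' @slot class_label character label of the variant class.
#' @slot n_variants integer number of variants scored.
#' @slot observed,expected observed and mutability-predicted singleton
#'   proportions; `maps = observed - expected`.
#' @slot maps the MAPS statistic.
#' @slot boot_q numeric(2) 5%/95% bootstrap quantiles (NA before
#'   [permuteMAPS()] is run).
#' @slot permutation_p bootstrap-permutation p versus the comparator class.
#' @slot comparator label of the comparator class ("" when none).
#' @export
setClass("MAPSResult",
  representation(
    class_label = "character",
    n_variants = "integer",
    observed = "numeric",
    expected = "numeric",
    maps = "numeric",
    boot_q = "numeric",
    permutation_p = "numeric",
    comparator = "character"
  ),
  prototype(boot_q = c(NA_real_, NA_real_), permutation_p = NA_real_,
            comparator = "")
)

setValidity("MAPSResult", function(object) {
  if (!is.na(object@maps) && abs(object@maps) > 1 + 1e-9)
    return("maps must lie in [-1, 1]")
  TRUE
})

#' Observed/expected polymorphic-site ratio for a region class
#'
#' @slot region_label character.
#' @slot n_positions number of (non-CpG, full-context) positions evaluated.
#' @slot observed integer count of polymorphic positions.
#' @slot expected heptamer-model expected count.
#' @slot ratio observed/expected.
#' @slot ci90 numeric(2) bootstrap 5%/95% interval for the ratio.
#' @slot permutation_p one-sided depletion p against an empirical null
#'   (NA until [oeEmpiricalNull()] is run).
#' @export
setClass("RegionOEResult",
  representation(
    region_label = "character",
    n_positions = "integer",
    observed = "integer",
    expected = "numeric",
    ratio = "numeric",
    ci90 = "numeric",
    permutation_p = "numeric"
  ),
  prototype(ci90 = c(NA_real_, NA_real_), permutation_p = NA_real_)
)

#' Aggregate allele-frequency comparison between two variant groups
#'
#' @slot group_a,group_b group labels.
#' @slot ac_a,an_a,ac_b,an_b summed allele counts / numbers.
#' @slot odds_ratio `(ac_a/(an_a-ac_a)) / (ac_b/(an_b-ac_b))`.
#' @slot p_value two-sided Fisher exact p on the 2x2 AC / (AN-AC) table.
#' @slot continuity TRUE when a zero marginal forced a continuity-corrected OR.
#' @export
setClass("FrequencyComparison",
  representation(
    group_a = "character", group_b = "character",
    ac_a = "numeric", an_a = "numeric",
    ac_b = "numeric", an_b = "numeric",
    odds_ratio = "numeric", p_value = "numeric",
    continuity = "logical"
  ),
  prototype(continuity = FALSE)
)

#' Generic 2x2 enrichment test result
#'
#' @slot test_label character.
#' @slot table 2x2 integer matrix (rows: feature of interest yes/no;
#'   columns: region class).
#' @slot odds_ratio sample odds ratio (Haldane-Anscombe corrected when a
#'   cell is zero).
#' @slot ci95 numeric(2) Woolf (log-OR normal) 95% confidence interval.
#' @slot p_value test p-value.
#' @slot method one of "fisher", "chisq", "hypergeom".
#' @slot note character; flags such as "continuity" for zero cells.
#' @export
setClass("EnrichmentResult",
  representation(
    test_label = "character",
    table = "matrix",
    odds_ratio = "numeric",
    ci95 = "numeric",
    p_value = "numeric",
    method = "character",
    note = "character"
  ),
  prototype(note = "")
)

#' Beta-binomial allelic-imbalance fit
#'
#' @slot variant_id character.
#' @slot n_samples number of heterozygous samples used.
#' @slot rho_hat ML estimate of the reference-allele proportion.
#' @slot dispersion_hat ML overdispersion (phi; 0 recovers the binomial).
#' @slot loglik_alt,loglik_null log-likelihoods of the free model and the
#'   rho = 0.5 null (dispersion re-estimated under the null by default).
#' @slot lrt_stat 2 * (loglik_alt - loglik_null), floored at 0.
#' @slot p_value chi-squared (1 d.f.) p for the LRT (NA before the test).
#' @slot boundary TRUE when the dispersion MLE lies at the boundary.
#' @slot converged optimizer convergence flag.
#' @export
setClass("ASEFit",
  representation(
    variant_id = "character",
    n_samples = "integer",
    rho_hat = "numeric",
    dispersion_hat = "numeric",
    loglik_alt = "numeric",
    loglik_null = "numeric",
    lrt_stat = "numeric",
    p_value = "numeric",
    boundary = "logical",
    converged = "logical"
  ),
  prototype(loglik_null = NA_real_, lrt_stat = NA_real_, p_value = NA_real_,
            boundary = FALSE, converged = TRUE)
)

# ---- show methods -----------------------------------------------------------

setMethod("show", "G4MotifSet", function(object) {
  cat(sprintf("G4MotifSet with %d motif(s)\n", length(object@ranges)))
  if (length(object@ranges)) {
    df <- as.data.frame(object)
    print(utils::head(df[, c("start", "end", "n_tracts", "sequence")], 6L))
    if (nrow(df) > 6L) cat("  ...\n")
  }
})

setMethod("length", "G4MotifSet", function(x) length(x@ranges))

setMethod("show", "MutabilityCalibration", function(object) {
  cat(sprintf(
    "MutabilityCalibration: intercept %.4g, slope %.4g (R^2 = %.3f, %d contexts%s)\n",
    object@intercept, object@slope, object@r_squared,
    nrow(object@diagnostics),
    if (object@weighted) ", count-weighted" else ""))
})

setMethod("show", "MAPSResult", function(object) {
  cat(sprintf("MAPSResult '%s': MAPS = %.4f (obs %.4f - exp %.4f), n = %d\n",
              object@class_label, object@maps, object@observed,
              object@expected, object@n_variants))
  if (!is.na(object@boot_q[1L]))
    cat(sprintf("  bootstrap 5%%/95%%: [%.4f, %.4f]\n",
                object@boot_q[1L], object@boot_q[2L]))
  if (!is.na(object@permutation_p))
    cat(sprintf("  permutation p vs '%s': %.4g\n",
                object@comparator, object@permutation_p))
})

setMethod("show", "RegionOEResult", function(object) {
  cat(sprintf(
    "RegionOEResult '%s': O/E = %d/%.2f = %.3f over %d positions\n",
    object@region_label, object@observed, object@expected, object@ratio,
    object@n_positions))
  if (!is.na(object@ci90[1L]))
    cat(sprintf("  90%% bootstrap CI: [%.3f, %.3f]\n",
                object@ci90[1L], object@ci90[2L]))
  if (!is.na(object@permutation_p))
    cat(sprintf("  empirical-null depletion p: %.4g\n", object@permutation_p))
})

setMethod("show", "FrequencyComparison", function(object) {
  cat(sprintf(
    "FrequencyComparison %s (AC/AN %d/%d) vs %s (%d/%d): OR = %.4f, p = %.4g%s\n",
    object@group_a, round(object@ac_a), round(object@an_a),
    object@group_b, round(object@ac_b), round(object@an_b),
    object@odds_ratio, object@p_value,
    if (object@continuity) " [continuity]" else ""))
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf("EnrichmentResult '%s' (%s): OR = %.4f [%.4f, %.4f], p = %.4g\n",
              object@test_label, object@method, object@odds_ratio,
              object@ci95[1L], object@ci95[2L], object@p_value))
})

setMethod("show", "ASEFit", function(object) {
  cat(sprintf(
    "ASEFit '%s': rho = %.4f, dispersion = %.4g (%d samples)\n",
    object@variant_id, object@rho_hat, object@dispersion_hat,
    object@n_samples))
  if (!is.na(object@lrt_stat))
    cat(sprintf("  LRT vs rho = 0.5: stat = %.3f, p = %.4g%s\n",
                object@lrt_stat, object@p_value,
                if (object@boundary) " [boundary]" else ""))
})

# ---- accessors --------------------------------------------------------------

#' Accessors for g4utr result objects
#'
#' Small read-only accessors for the S4 result classes; these avoid direct
#' slot access in user code.
#'
#' @param x a g4utr S4 object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
oddsRatio <- function(x) {
  if (is(x, "EnrichmentResult") || is(x, "FrequencyComparison"))
    return(x@odds_ratio)
  stop("no odds ratio for objects of class ", class(x))
}

#' @rdname accessors
#' @export
pValue <- function(x) {
  if (is(x, "EnrichmentResult") || is(x, "FrequencyComparison") ||
      is(x, "ASEFit"))
    return(x@p_value)
  if (is(x, "MAPSResult")) return(x@permutation_p)
  if (is(x, "RegionOEResult")) return(x@permutation_p)
  stop("no p-value for objects of class ", class(x))
}

#' @rdname accessors
#' @export
mapsScore <- function(x) {
  stopifnot(is(x, "MAPSResult"))
  x@maps
}

#' @rdname accessors
#' @export
oeRatio <- function(x) {
  stopifnot(is(x, "RegionOEResult"))
  x@ratio
}

#' @rdname accessors
#' @export
confint90 <- function(x) {
  stopifnot(is(x, "RegionOEResult"))
  x@ci90
}

#' @rdname accessors
#' @export
confint95 <- function(x) {
  stopifnot(is(x, "EnrichmentResult"))
  x@ci95
}

#' @rdname accessors
#' @export
rhoHat <- function(x) {
  stopifnot(is(x, "ASEFit"))
  x@rho_hat
}

#' @rdname accessors
#' @export
dispersionHat <- function(x) {
  stopifnot(is(x, "ASEFit"))
  x@dispersion_hat
}

#' @rdname accessors
#' @export
lrtStat <- function(x) {
  stopifnot(is(x, "ASEFit"))
  x@lrt_stat
}
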