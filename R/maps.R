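#' @importFrom stats lm coef quantile
NULL

#' Assign a CpG methylation bin
#'
#' Median methylation levels at CpG sites are binned into none/low
#' (< 0.2), intermediate (0.2-0.6) and high (> 0.6); both interval
#' endpoints belong to `intermediate`. Missing levels (and non-CpG sites)
#' map to `not_cpg`, for which unadjusted context rates apply.
#'
#' @param level numeric vector of methylation levels in \[0,1\], NA for
#'   non-CpG or unknown.
#' @return character vector of bins: `none_low`, `intermediate`, `high`,
#'   `not_cpg`.
#' @export
assignMethylationBin <- function(level) {
  if (any(!is.na(level) & (level < 0 | level > 1)))
    stop("methylation level outside [0, 1]")
  ifelse(is.na(level), "not_cpg",
  ifelse(level < 0.2, "none_low",
  ifelse(level <= 0.6, "intermediate", "high")))
}

rate_key <- function(context, alt, bin) paste(context, alt, bin, sep = "|")

lookupRates <- function(variants, rates) {
  req <- c("tri_context", "alt", "methylation_bin")
  miss <- setdiff(req, names(variants))
  if (length(miss))
    stop("missing variant column(s): ", paste(miss, collapse = ", "))
  key <- rate_key(variants$tri_context, variants$alt,
                  variants$methylation_bin)
  tab_key <- rate_key(rates$context, rates$alt, rates$methylation_bin)
  idx <- match(key, tab_key)
  if (anyNA(idx)) {
    bad <- unique(key[is.na(idx)])
    stop("context(s) not covered by the rate table: ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "")
  }
  rates$rate[idx]
}

#' Calibrate the singleton-proportion mutation-rate regression
#'
#' Trains the MAPS mutability model: the observed proportion of singleton
#' variants among (putatively neutral) synonymous calibration variants is
#' regressed on the context-specific mutation rate, one point per
#' (trinucleotide context, alternate allele, methylation bin) combination,
#' weighted by the per-context variant count. The fitted line predicts the
#' singleton proportion expected from mutability alone.
#'
#' @param variants data.frame of calibration variants with columns
#'   `tri_context`, `alt`, `methylation_bin`, `is_singleton`.
#' @param rates data.frame rate table with columns `context`, `alt`,
#'   `methylation_bin`, `rate` (all rates positive).
#' @param weighted weight the regression by per-context count (default
#'   TRUE; the unweighted fit is available for sensitivity analysis).
#' @return A [MutabilityCalibration].
#' @export
calibrateMutability <- function(variants, rates, weighted = TRUE) {
  rate <- lookupRates(variants, rates)
  key <- rate_key(variants$tri_context, variants$alt,
                  variants$methylation_bin)
  f <- factor(key)
  n <- as.vector(table(f))
  prop <- tapply(as.numeric(variants$is_singleton), f, mean)
  r <- tapply(rate, f, function(x) x[1L])
  if (length(unique(r)) < 2L)
    stop("degenerate design: need >= 2 distinct context rates")
  w <- if (weighted) n else rep(1, length(n))
  fit <- lm(prop ~ r, weights = w)
  fitted <- pmin(pmax(stats::fitted(fit), 0), 1)
  sse <- sum(w * (prop - stats::fitted(fit))^2)
  sst <- sum(w * (prop - sum(w * prop) / sum(w))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  diag <- data.frame(context_key = levels(f), rate = as.numeric(r),
                     n = n, observed_prop = as.numeric(prop),
                     fitted_prop = as.numeric(fitted),
                     stringsAsFactors = FALSE)
  new("MutabilityCalibration",
      intercept = unname(coef(fit)[1L]), slope = unname(coef(fit)[2L]),
      r_squared = r2, diagnostics = diag, weighted = weighted)
}

predictSingletonProp <- function(calibration, rate) {
  p <- calibration@intercept + calibration@slope * rate
  n_clamped <- sum(p < 0 | p > 1)
  if (n_clamped > 0L)
    message(n_clamped, " prediction(s) clamped to [0, 1]")
  pmin(pmax(p, 0), 1)
}

#' Mutability-adjusted proportion of singletons (MAPS)
#'
#' MAPS for a variant class is the observed singleton proportion minus the
#' proportion predicted from each variant's context mutation rate by the
#' calibration regression. Positive MAPS indicates an excess of rare
#' variation, i.e. purifying selection beyond mutability expectations.
#'
#' @param variants data.frame of class variants (`tri_context`, `alt`,
#'   `methylation_bin`, `is_singleton`); must be non-empty and fully
#'   covered by the rate table.
#' @param calibration a [MutabilityCalibration].
#' @param rates rate table as in [calibrateMutability()].
#' @param class_label label stored in the result.
#' @return A [MAPSResult] (bootstrap/permutation fields unset; see
#'   [permuteMAPS()]).
#' @export
computeMAPS <- function(variants, calibration, rates,
                        class_label = "class") {
  stopifnot(nrow(variants) >= 1L)
  rate <- lookupRates(variants, rates)
  pred <- predictSingletonProp(calibration, rate)
  s <- as.numeric(variants$is_singleton)
  n <- length(s)
  new("MAPSResult",
      class_label = class_label, n_variants = n,
      observed = mean(s), expected = mean(pred),
      maps = (sum(s) - sum(pred)) / n)
}

# bootstrap MAPS values: resample 'size' rows with replacement per
# iteration from per-variant singleton indicators s and predictions pred
bootMAPS <- function(s, pred, size, n_iter, chunk = 2e6) {
  n <- length(s)
  out <- numeric(n_iter)
  done <- 0L
  per_chunk <- max(1L, as.integer(chunk %/% size))
  while (done < n_iter) {
    k <- min(per_chunk, n_iter - done)
    idx <- matrix(sample.int(n, size * k, replace = TRUE), nrow = size)
    out[done + seq_len(k)] <-
      (colSums(matrix(s[idx], nrow = size)) -
       colSums(matrix(pred[idx], nrow = size))) / size
    done <- done + k
  }
  out
}

#' Bootstrap-permutation significance for a MAPS comparison
#'
#' Resamples the class and a comparator class with replacement `n_boot`
#' times (the comparator resample is sized to the class) and recomputes
#' MAPS for each draw. The permutation p is the proportion of draws in
#' which the class MAPS does not exceed the comparator MAPS, so small p
#' supports stronger constraint on the class. The 5%/95% bootstrap
#' quantiles of the class MAPS are attached to the result.
#'
#' @param class_variants,comparator_variants non-empty data.frames as in
#'   [computeMAPS()].
#' @param calibration a [MutabilityCalibration].
#' @param rates rate table.
#' @param n_boot bootstrap iterations (default 10000; fewer than 100
#'   triggers a warning because the p estimate is unstable).
#' @param seed integer RNG seed.
#' @param class_label,comparator_label labels stored in the result.
#' @return A [MAPSResult] for the class with `boot_q` and `permutation_p`
#'   filled in.
#' @export
permuteMAPS <- function(class_variants, comparator_variants, calibration,
                        rates, n_boot = 10000L, seed = 2020L,
                        class_label = "class",
                        comparator_label = "comparator") {
  stopifnot(nrow(class_variants) >= 1L, nrow(comparator_variants) >= 1L)
  if (n_boot < 100L)
    warning("n_boot < 100: permutation p will be unstable")
  base <- computeMAPS(class_variants, calibration, rates, class_label)

  s_c <- as.numeric(class_variants$is_singleton)
  p_c <- predictSingletonProp(calibration,
                              lookupRates(class_variants, rates))
  s_k <- as.numeric(comparator_variants$is_singleton)
  p_k <- predictSingletonProp(calibration,
                              lookupRates(comparator_variants, rates))

  set.seed(as.integer(seed))
  n_c <- length(s_c)
  boot_class <- bootMAPS(s_c, p_c, n_c, n_boot)
  boot_comp <- bootMAPS(s_k, p_k, n_c, n_boot)

  new("MAPSResult",
      class_label = class_label, n_variants = base@n_variants,
      observed = base@observed, expected = base@expected,
      maps = base@maps,
      boot_q = unname(quantile(boot_class, c(0.05, 0.95))),
      permutation_p = mean(boot_class <= boot_comp),
      comparator = comparator_label)
}
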