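# qPCR validation path: standard-curve calibration for the three amplicon
# assays (non-cleaved, loxP junction, lox2272 junction), copy-number
# quantification, rate reconstruction, and concordance with sequencing.

#' Fit a qPCR standard curve
#'
#' Least-squares fit of Cq on log10(copies) over a dilution series (the
#' screen used 7 points in 10-fold steps, 1e7 down to 1 copy/uL, one curve
#' per assay). Amplification efficiency is 10^(-1/slope) - 1 (1.0 = perfect
#' doubling each cycle).
#'
#' @param copies Template copy numbers (> 0), at least 3 distinct levels.
#' @param cq Measured quantification cycles, same length.
#' @return A list of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `range` (copy range of the series), `n`.
#' @export
fit_standard_curve <- function(copies, cq) {
  if (length(copies) != length(cq)) {
    stop("`copies` and `cq` must have equal length", call. = FALSE)
  }
  if (any(copies <= 0) || anyNA(copies) || anyNA(cq)) {
    stop("calibration requires positive copy numbers and non-missing Cq",
         call. = FALSE)
  }
  if (length(unique(copies)) < 3) {
    stop("calibration requires at least 3 distinct copy levels", call. = FALSE)
  }
  fit <- stats::lm(cq ~ log10(copies))
  slope <- unname(stats::coef(fit)[2])
  if (is.na(slope) || slope >= 0) {
    stop("calibration slope must be negative (Cq decreases with template)",
         call. = FALSE)
  }
  # computed directly: summary.lm warns on noiseless (perfect-fit) series
  r_squared <- 1 - sum(stats::residuals(fit)^2) / sum((cq - mean(cq))^2)
  structure(
    list(slope = slope,
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r_squared,
         efficiency = 10^(-1 / slope) - 1,
         range = range(copies),
         n = length(copies)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "qPCR standard curve: Cq = %.4f %+.4f log10(copies)\n  efficiency %.1f%%, R^2 = %.4f, %d points over %.3g..%.3g copies\n",
    x$intercept, x$slope, 100 * x$efficiency, x$r_squared, x$n,
    x$range[1], x$range[2]))
  invisible(x)
}

#' Copy number from a Cq value
#'
#' Inverts the calibration line: copies = 10^((cq - intercept)/slope).
#' Extrapolation beyond the dilution range is allowed but flagged in the
#' `"extrapolated"` attribute.
#'
#' @param curve A [fit_standard_curve()] result.
#' @param cq Cq values (vector).
#' @return Copy numbers, with a logical attribute `extrapolated`.
#' @export
quantify <- function(curve, cq) {
  stopifnot(inherits(curve, "standard_curve"))
  copies <- 10^((cq - curve$intercept) / curve$slope)
  attr(copies, "extrapolated") <-  # small relative slack at the boundaries
    copies < curve$range[1] * (1 - 1e-8) | copies > curve$range[2] * (1 + 1e-8)
  copies
}

#' Simulate Cq values from a known curve
#'
#' Cq = intercept + slope * log10(copies) + Gaussian noise. Used for testing
#' the calibration round trip and building synthetic validation data.
#'
#' @param copies Template copy numbers.
#' @param intercept,slope Curve parameters (default: perfect doubling
#'   chemistry, slope -log2(10) cycles per decade).
#' @param sd Cycle-scale noise standard deviation (default 0.15 cycles).
#' @param seed Integer seed.
#' @return Numeric Cq vector.
#' @export
simulate_cq <- function(copies, intercept = 38, slope = -log2(10), sd = 0.15,
                        seed = NULL) {
  stopifnot(all(copies > 0))
  with_seed(seed, {
    intercept + slope * log10(copies) + stats::rnorm(length(copies), 0, sd)
  })
}

#' Reconstruct cleavage rates from the three assay copy numbers
#'
#' Same algebra as the sequencing path, on copies instead of read counts:
#' loxP cleavage rate = 100 * P / (P + L2272); non-cleavage rate =
#' 100 * NC / (NC + P + L2272). Invariant to rescaling all three copy
#' numbers by a common positive factor, so template input amounts cancel.
#'
#' @param noncleaved,loxP,lox2272 Copy numbers of the non-cleaved, loxP-
#'   junction and lox2272-junction amplicons (vectors allowed).
#' @return A data.frame with `non_cleavage_pct` and `loxP_cleavage_pct`.
#' @export
rates_from_copies <- function(noncleaved, loxP, lox2272) {
  if (any(noncleaved < 0 | loxP < 0 | lox2272 < 0, na.rm = TRUE)) {
    stop("copy numbers must be non-negative", call. = FALSE)
  }
  if (any(noncleaved + loxP + lox2272 == 0, na.rm = TRUE)) {
    stop("at least one assay must be positive per measurement", call. = FALSE)
  }
  data.frame(
    non_cleavage_pct = non_cleavage_rate(noncleaved, loxP, lox2272),
    loxP_cleavage_pct = cleavage_rate(loxP, lox2272)
  )
}

#' Concordance between sequencing and qPCR rate estimates
#'
#' Squared Pearson correlation of paired per-variant rates, with the paired
#' data returned for plotting.
#'
#' @param ngs_rates,qpcr_rates Equal-length numeric vectors (n >= 3).
#' @return A list of class `concordance`: `r_squared`, `n`, `data`
#'   (data.frame with `ngs`, `qpcr`, `delta`).
#' @export
concordance <- function(ngs_rates, qpcr_rates) {
  if (length(ngs_rates) != length(qpcr_rates) || length(ngs_rates) < 3) {
    stop("need equal-length vectors with n >= 3", call. = FALSE)
  }
  if (stats::sd(ngs_rates) == 0 || stats::sd(qpcr_rates) == 0) {
    stop("correlation undefined for a constant rate vector", call. = FALSE)
  }
  r <- stats::cor(ngs_rates, qpcr_rates)
  structure(
    list(r_squared = r^2, n = length(ngs_rates),
         data = data.frame(ngs = ngs_rates, qpcr = qpcr_rates,
                           delta = qpcr_rates - ngs_rates)),
    class = "concordance"
  )
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("NGS vs qPCR concordance: R^2 = %.4f over %d variants\n",
              x$r_squared, x$n))
  invisible(x)
}

#' Simulate a full qPCR measurement of a truth table
#'
#' For each variant, converts the true outcome probabilities to expected
#' molecule counts, simulates Cq values for the three assays through a known
#' standard curve (with cycle-scale noise), re-quantifies them through a
#' curve fitted to a simulated dilution series, and reconstructs rates.
#' Replicates are averaged on the copy scale before the rate algebra, since
#' rates are ratios of copies.
#'
#' @param truth Truth data.frame (see [truth_record()]).
#' @param n_template Total template copies per reaction.
#' @param replicates Technical replicates per assay.
#' @param sd Cq noise standard deviation (cycles).
#' @param seed Integer seed.
#' @return A data.frame per variant: reconstructed `non_cleavage_pct`,
#'   `loxP_cleavage_pct`, plus the fitted per-assay curves in attribute
#'   `"curves"`.
#' @export
simulate_qpcr <- function(truth, n_template = 1e5, replicates = 2, sd = 0.15,
                          seed = 1L) {
  stopifnot(is.data.frame(truth), nrow(truth) >= 1)
  with_seed(seed, {
    dil <- 10^(0:6)  # 7-point, 10-fold dilution series
    assays <- c("NC", "loxP", "lox2272")
    curves <- lapply(assays, function(a) {
      fit_standard_curve(dil, simulate_cq(dil, sd = sd))
    })
    names(curves) <- assays
    true_copies <- cbind(
      NC = truth$p_noncleavage,
      loxP = (1 - truth$p_noncleavage) * truth$p_loxP_given_cleaved,
      lox2272 = (1 - truth$p_noncleavage) * (1 - truth$p_loxP_given_cleaved)
    ) * n_template
    mean_copies <- sapply(assays, function(a) {
      reps <- replicate(replicates, {
        cq <- simulate_cq(pmax(true_copies[, a], 1e-3), sd = sd)
        as.numeric(quantify(curves[[a]], cq))
      })
      rowMeans(matrix(reps, nrow = nrow(truth)))
    })
    mean_copies <- matrix(mean_copies, nrow = nrow(truth),
                          dimnames = list(NULL, assays))
    rates <- rates_from_copies(mean_copies[, "NC"], mean_copies[, "loxP"],
                               mean_copies[, "lox2272"])
    out <- cbind(data.frame(variant = truth$variant,
                            stringsAsFactors = FALSE), rates)
    attr(out, "curves") <- curves
    out
  })
}

#' Two-sample comparison of non-cleavage rates (induction on vs off)
#'
#' Welch two-tailed t-test utility mirroring the Cre-dependence control:
#' without induction the non-cleavage rate should sit near 100%, far above
#' the induced series.
#'
#' @param rates_off,rates_on Numeric vectors of non-cleavage percentages.
#' @return An `htest` object from [stats::t.test()].
#' @export
compare_induction <- function(rates_off, rates_on) {
  stats::t.test(rates_off, rates_on, alternative = "two.sided",
                var.equal = FALSE)
}
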