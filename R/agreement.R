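# Method-agreement statistics: Lin's concordance correlation coefficient,
# its asymptotic confidence interval, agreement classification, comparison
# of dependent CCCs sharing a common variable, and mean-difference t tests.

check_paired <- function(x, y, min_n = 2L) {
  if (!is.numeric(x) || !is.numeric(y)) {
    stop("'x' and 'y' must be numeric vectors", call. = FALSE)
  }
  if (length(x) != length(y)) {
    stop("'x' and 'y' must have equal length (", length(x), " vs ",
         length(y), ")", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("missing values are not allowed; filter complete cases first",
         call. = FALSE)
  }
  if (length(x) < min_n) {
    stop("need at least ", min_n, " paired observations, got ", length(x),
         call. = FALSE)
  }
  invisible(length(x))
}

#' Pearson product-moment correlation for paired measurements
#'
#' Thin wrapper around [stats::cor()] that fails loudly on the degenerate
#' zero-variance case instead of returning `NA`.
#'
#' @param x,y Numeric vectors of equal length, no missing values.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  check_paired(x, y, min_n = 2L)
  if (stats::var(x) == 0) stop("'x' has zero variance; correlation undefined", call. = FALSE)
  if (stats::var(y) == 0) stop("'y' has zero variance; correlation undefined", call. = FALSE)
  stats::cor(x, y)
}

#' Lin's concordance correlation coefficient
#'
#' \deqn{\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}}
#' with n-denominator (maximum-likelihood) moments, Lin's original estimator.
#' Unlike Pearson's correlation it penalizes both location and scale shifts,
#' so it measures agreement, not just linear association.
#'
#' @param x,y Numeric vectors of equal length, no missing values.
#' @return The CCC, in `[-1, 1]`.
#' @examples
#' lin_ccc(c(1, 2, 3, 4), c(2, 3, 4, 5))  # 0.714286: perfect correlation, shifted
#' @export
lin_ccc <- function(x, y) {
  n <- check_paired(x, y, min_n = 2L)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) {
    stop("both variances are zero and means coincide; CCC undefined (0/0)",
         call. = FALSE)
  }
  2 * sxy / denom
}

#' Lin's CCC with an asymptotic confidence interval
#'
#' The interval is built on the inverse-hyperbolic-tangent (Fisher z) scale
#' using Lin's (1989) asymptotic variance, which involves the standardized
#' location shift `u = (mean(x) - mean(y)) / sqrt(sx * sy)`, then
#' back-transformed, so the bounds always lie in (-1, 1).
#'
#' @param x,y Numeric vectors, length >= 3, both with positive variance.
#' @param level Coverage of the interval (default 0.95).
#' @return An object of class `ivc_agreement`: list with `ccc`, `ci_low`,
#'   `ci_high`, `pearson`, `n`, `level`, and `agreement_class` (see
#'   [classify_agreement()]).
#' @references Lin, L. I-K. (1989) A concordance correlation coefficient to
#'   evaluate reproducibility. Biometrics 45, 255-268.
#' @export
ccc_confidence_interval <- function(x, y, level = 0.95) {
  n <- check_paired(x, y, min_n = 3L)
  stopifnot(is.numeric(level), length(level) == 1L, level > 0, level < 1)
  r <- pearson_r(x, y)
  ccc <- lin_ccc(x, y)
  if (abs(ccc) >= 1 - 1e-15) {
    stop("|CCC| = 1: degenerate interval; report the point value instead",
         call. = FALSE)
  }
  sx <- sqrt(mean((x - mean(x))^2))
  sy <- sqrt(mean((y - mean(y))^2))
  u <- (mean(x) - mean(y)) / sqrt(sx * sy)
  # Lin (1989) asymptotic variance of atanh(ccc)
  se_z <- sqrt(((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
                4 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
                2 * ccc^4 * u^4 / (r^2 * (1 - ccc^2)^2)) / (n - 2))
  z <- atanh(ccc)
  q <- stats::qnorm(1 - (1 - level) / 2)
  out <- list(
    ccc = ccc,
    ci_low = tanh(z - q * se_z),
    ci_high = tanh(z + q * se_z),
    pearson = r,
    n = n,
    level = level,
    agreement_class = classify_agreement(ccc)
  )
  class(out) <- "ivc_agreement"
  out
}

#' @export
print.ivc_agreement <- function(x, digits = 3, ...) {
  cat(sprintf("Lin's CCC = %.*f, %d%% CI: %.*f-%.*f (Pearson rho = %.*f, n = %d)\n",
              digits, x$ccc, round(100 * x$level), digits, x$ci_low,
              digits, x$ci_high, digits, x$pearson, x$n))
  cat("Agreement:", x$agreement_class, "\n")
  invisible(x)
}

#' Classify a CCC into the conventional agreement taxonomy
#'
#' `poor` for CCC <= 0.40, `fair to good` for 0.40 < CCC <= 0.75,
#' `excellent` for CCC > 0.75. Boundary values belong to the lower class.
#'
#' @param ccc Numeric vector of CCC values in `[-1, 1]`.
#' @return Character vector of class labels.
#' @export
classify_agreement <- function(ccc) {
  if (!is.numeric(ccc) || anyNA(ccc) || any(ccc < -1 | ccc > 1)) {
    stop("'ccc' must be numeric in [-1, 1]", call. = FALSE)
  }
  ifelse(ccc <= 0.40, "poor",
         ifelse(ccc <= 0.75, "fair to good", "excellent"))
}

#' Compare two dependent CCCs that share a common variable
#'
#' Tests whether `candidate_a` agrees better with `common` than
#' `candidate_b` does: `delta = CCC(candidate_a, common) -
#' CCC(candidate_b, common)`. The principal inference is a percentile
#' bootstrap over subject resamples; a Steiger-style Fisher-z test that
#' accounts for the shared variable via the candidate-candidate correlation
#' is also reported (labelled approximate).
#'
#' @param common Numeric vector, the shared measurement (e.g. a
#'   post-placement diameter).
#' @param candidate_a,candidate_b Numeric vectors of the same length as
#'   `common`, the two competing predictors.
#' @param n_boot Bootstrap resamples (default 2000, minimum 200).
#' @param seed Integer seed; required, so reports are reproducible.
#' @param level Coverage of the percentile interval.
#' @return An object of class `ivc_ccc_comparison`: `ccc_a`, `ccc_b`,
#'   `delta`, `ci_low`, `ci_high`, `p_value` (bootstrap sign-crossing,
#'   add-one corrected), `fisher_z` (list: `statistic`, `p_value`, labelled
#'   approximate), `n`, `n_boot`, `seed`.
#' @export
compare_dependent_ccc <- function(common, candidate_a, candidate_b,
                                  n_boot = 2000, seed, level = 0.95) {
  n <- check_paired(common, candidate_a, min_n = 5L)
  check_paired(common, candidate_b, min_n = 5L)
  if (missing(seed)) stop("'seed' is required for a reproducible bootstrap", call. = FALSE)
  stopifnot(n_boot >= 200)
  ccc_a <- lin_ccc(candidate_a, common)
  ccc_b <- lin_ccc(candidate_b, common)
  delta <- ccc_a - ccc_b

  boot <- with_seed(seed, {
    out <- numeric(n_boot)
    max_tries <- 100L * n_boot
    tries <- 0L
    b <- 1L
    while (b <= n_boot) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("bootstrap redraw cap exceeded: resamples are persistently ",
             "degenerate (zero variance)", call. = FALSE)
      }
      idx <- sample.int(n, n, replace = TRUE)
      cm <- common[idx]
      if (stats::var(cm) == 0 ||
          (stats::var(candidate_a[idx]) == 0 && stats::var(candidate_b[idx]) == 0)) {
        next  # degenerate resample: redraw
      }
      out[b] <- lin_ccc(candidate_a[idx], cm) - lin_ccc(candidate_b[idx], cm)
      b <- b + 1L
    }
    out
  })
  alpha <- 1 - level
  ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), type = 7))
  p_boot <- min(1, 2 * (1 + min(sum(boot <= 0), sum(boot >= 0))) / (n_boot + 1))

  out <- list(
    ccc_a = ccc_a, ccc_b = ccc_b, delta = delta,
    ci_low = ci[1L], ci_high = ci[2L], p_value = p_boot,
    fisher_z = fisher_z_dependent(ccc_a, ccc_b,
                                  r_ab = stats::cor(candidate_a, candidate_b),
                                  n = n),
    n = n, n_boot = n_boot, seed = seed, level = level,
    method = "percentile bootstrap of CCC difference (shared variable)"
  )
  class(out) <- "ivc_ccc_comparison"
  out
}

# Steiger-style z test on atanh-transformed CCCs sharing one variable.
# Approximate: treats the CCCs as correlations on the Fisher-z scale.
fisher_z_dependent <- function(ccc_a, ccc_b, r_ab, n) {
  rbar2 <- ((ccc_a + ccc_b) / 2)^2
  s <- (r_ab * (1 - 2 * rbar2) - 0.5 * rbar2 * (1 - 2 * rbar2 - r_ab^2)) /
    (1 - rbar2)^2
  z <- (atanh(ccc_a) - atanh(ccc_b)) * sqrt((n - 3) / (2 - 2 * s))
  list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)),
       method = "Fisher z (Steiger-type, approximate)")
}

#' @export
print.ivc_ccc_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("CCC difference (shared variable): delta = %.*f\n", digits, x$delta))
  cat(sprintf("  CCC(a, common) = %.*f, CCC(b, common) = %.*f, n = %d\n",
              digits, x$ccc_a, digits, x$ccc_b, x$n))
  cat(sprintf("  bootstrap %d%% CI: %.*f-%.*f, p = %.4g (%d resamples, seed %d)\n",
              round(100 * x$level), digits, x$ci_low, digits, x$ci_high,
              x$p_value, x$n_boot, x$seed))
  cat(sprintf("  Fisher z (approximate): z = %.3f, p = %.4g\n",
              x$fisher_z$statistic, x$fisher_z$p_value))
  invisible(x)
}

#' Student's t test for mean differences
#'
#' Paired t test for within-subject contrasts (pre vs post, predicted vs
#' observed) or a two-sample pooled-variance Student's t test for
#' independent groups (e.g. two filter sizes).
#'
#' @param x,y Numeric vectors; equal length required when `paired = TRUE`.
#' @param paired Within-subject (`TRUE`, default) or independent groups.
#' @return An object of class `ivc_meandiff`: `mean_x`, `mean_y`, `sd_x`,
#'   `sd_y` (n-1 denominator), `t_statistic`, `df`, `p_value`, `paired`.
#' @export
mean_diff_test <- function(x, y, paired = TRUE) {
  if (paired) {
    check_paired(x, y, min_n = 2L)
    if (stats::var(x - y) == 0) {
      if (all(x == y)) {
        stop("zero variance of paired differences; t statistic undefined",
             call. = FALSE)
      }
      # constant non-zero difference: the mean contrast is exact but the
      # t statistic is undefined; report it as such instead of failing
      warning("paired differences are constant; t statistic undefined",
              call. = FALSE)
      out <- list(mean_x = mean(x), mean_y = mean(y),
                  sd_x = stats::sd(x), sd_y = stats::sd(y),
                  t_statistic = NA_real_, df = length(x) - 1,
                  p_value = NA_real_, paired = TRUE,
                  note = "zero variance of paired differences")
      class(out) <- "ivc_meandiff"
      return(out)
    }
    ht <- stats::t.test(x, y, paired = TRUE)
  } else {
    if (length(x) < 2L || length(y) < 2L) {
      stop("each group needs at least 2 observations", call. = FALSE)
    }
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      stop("both groups have zero variance; t statistic undefined", call. = FALSE)
    }
    ht <- stats::t.test(x, y, var.equal = TRUE)
  }
  out <- list(
    mean_x = mean(x), mean_y = mean(y),
    sd_x = stats::sd(x), sd_y = stats::sd(y),
    t_statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value, paired = paired
  )
  class(out) <- "ivc_meandiff"
  out
}

#' @export
print.ivc_meandiff <- function(x, digits = 2, ...) {
  cat(sprintf("%s Student's t test\n", if (x$paired) "Paired" else "Two-sample"))
  cat(sprintf("  x: %.*f +/- %.*f   y: %.*f +/- %.*f\n",
              digits, x$mean_x, digits, x$sd_x, digits, x$mean_y, digits, x$sd_y))
  cat(sprintf("  t = %.3f, df = %g, p = %.4g\n", x$t_statistic, x$df, x$p_value))
  invisible(x)
}

# Run code with a temporary RNG state seeded by `seed`; the caller's RNG
# stream is untouched.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}
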