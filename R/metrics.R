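#' Confidence interval for a binomial proportion
#'
#' The default is the continuity-corrected Wald interval
#' \deqn{p \pm \left(z\sqrt{p(1-p)/n} + 1/(2n)\right)}
#' truncated to \[0, 1\], with z the standard-normal quantile at
#' (1 + level)/2. This is the interval that reproduces the published
#' operating-characteristic tables of the original validation study to the
#' printed decimal. Alternatives: plain Wald, Wilson (score), and
#' Clopper-Pearson (exact, via [stats::binom.test()]).
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level, default 0.95.
#' @param method One of "wald-cc" (default), "wald", "wilson",
#'   "clopper-pearson".
#' @return Object of class `proportion_ci`: list with `estimate`, `lower`,
#'   `upper`, `level`, `numerator`, `denominator`, `method`.
#' @export
#' @examples
#' wald_cc_ci(50, 65) # (0.659, 0.879)
wald_cc_ci <- function(successes, n, level = 0.95,
                       method = c("wald-cc", "wald", "wilson", "clopper-pearson")) {
  method <- match.arg(method)
  if (length(successes) != 1 || length(n) != 1 ||
      !is.finite(successes) || !is.finite(n) ||
      n < 1 || successes < 0 || successes > n ||
      successes != round(successes) || n != round(n)) {
    stop("require integers 0 <= successes <= n, n >= 1", call. = FALSE)
  }
  if (length(level) != 1 || !is.finite(level) || level <= 0 || level >= 1) {
    stop("level must be in (0, 1)", call. = FALSE)
  }
  p <- successes / n
  z <- stats::qnorm((1 + level) / 2)
  bounds <- switch(method,
    "wald-cc" = {
      half <- z * sqrt(p * (1 - p) / n) + 1 / (2 * n)
      c(p - half, p + half)
    },
    "wald" = {
      half <- z * sqrt(p * (1 - p) / n)
      c(p - half, p + half)
    },
    "wilson" = {
      centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
      half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
      c(centre - half, centre + half)
    },
    "clopper-pearson" = {
      as.numeric(stats::binom.test(successes, n, conf.level = level)$conf.int)
    })
  structure(list(estimate = p,
                 # truncate to [0,1]; the min/max against p guards floating-
                 # point bounds landing a hair inside the point estimate
                 lower = max(0, min(bounds[1], p)),
                 upper = min(1, max(bounds[2], p)),
                 level = level, numerator = as.integer(successes),
                 denominator = as.integer(n), method = method),
            class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (%.0f%% CI %.1f-%.1f, %s)\n",
              x$numerator, x$denominator, 100 * x$estimate, 100 * x$level,
              100 * x$lower, 100 * x$upper, x$method))
  invisible(x)
}

# one-vs-rest cell counts for a category
ovr_counts <- function(cm, cat) {
  i <- match(match.arg(cat, broad_categories()), broad_categories())
  n <- sum(cm)
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  list(tp = tp, fn = fn, fp = fp, tn = n - tp - fn - fp, n = n)
}

#' One-vs-rest sensitivity of the algorithm for one category
#'
#' The proportion of patients given category `cat` by the physicians that
#' the algorithm also assigned to `cat` (true positives over the physician
#' row total).
#'
#' @param cm A `confusion4`.
#' @param cat Broad-category label.
#' @param level Confidence level.
#' @param method CI method, see [wald_cc_ci()].
#' @return A `proportion_ci`.
#' @export
sensitivity <- function(cm, cat, level = 0.95, method = "wald-cc") {
  k <- ovr_counts(cm, cat)
  if (k$tp + k$fn == 0) {
    stop(sprintf("undefined sensitivity: no physician-diagnosed %s patients", cat),
         call. = FALSE)
  }
  wald_cc_ci(k$tp, k$tp + k$fn, level = level, method = method)
}

#' One-vs-rest specificity of the algorithm for one category
#'
#' True negatives are the patients whose physician category is one of the
#' three other categories; specificity is the proportion of those that the
#' algorithm did not assign to `cat`.
#'
#' @inheritParams sensitivity
#' @return A `proportion_ci`.
#' @export
specificity <- function(cm, cat, level = 0.95, method = "wald-cc") {
  k <- ovr_counts(cm, cat)
  if (k$tn + k$fp == 0) {
    stop(sprintf("undefined specificity: every patient is physician-diagnosed %s", cat),
         call. = FALSE)
  }
  wald_cc_ci(k$tn, k$tn + k$fp, level = level, method = method)
}

#' Youden index for one category
#'
#' sensitivity + specificity - 1, computed on the unrounded estimates.
#' 1 marks perfect discrimination of the category, 0 chance-level.
#'
#' @inheritParams sensitivity
#' @return A number in \[-1, 1\].
#' @export
youden <- function(cm, cat) {
  sensitivity(cm, cat)$estimate + specificity(cm, cat)$estimate - 1
}

#' Cohen's kappa for the 4x4 agreement table
#'
#' Chance-corrected agreement between physicians and the algorithm:
#' kappa = (po - pe) / (1 - pe) with po the observed agreement (trace / n)
#' and pe the expected agreement from the row/column margins. The standard
#' error uses the common asymptotic form
#' `sqrt(po (1 - po) / (n (1 - pe)^2))`; see the methods vignette for why
#' the resulting interval is approximate.
#'
#' @param cm A `confusion4`.
#' @param level Confidence level for the interval.
#' @return Object of class `kappa_result`: list with `kappa`, `po`, `pe`,
#'   `se`, `lower`, `upper`, `level`, `n`.
#' @export
#' @examples
#' cohen_kappa(reference_confusion())$kappa # about 0.59
cohen_kappa <- function(cm, level = 0.95) {
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe >= 1) stop("degenerate margins: chance agreement is 1", call. = FALSE)
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  z <- stats::qnorm((1 + level) / 2)
  structure(list(kappa = kappa, po = po, pe = pe, se = se,
                 lower = max(-1, kappa - z * se),
                 upper = min(1, kappa + z * se),
                 level = level, n = as.integer(n)),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa %.2f (%.0f%% CI %.2f-%.2f), po = %.3f, pe = %.3f, n = %d\n",
              x$kappa, 100 * x$level, x$lower, x$upper, x$po, x$pe, x$n))
  invisible(x)
}

# round half away from zero, the convention used for display
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Full diagnostic evaluation of a confusion matrix
#'
#' Per-category one-vs-rest sensitivity and specificity with confidence
#' intervals, Youden index, and Cohen's kappa.
#'
#' @param cm A `confusion4`.
#' @param level Confidence level.
#' @param method CI method for proportions, see [wald_cc_ci()].
#' @return Object of class `diagnostic_report`: list with `metrics` (data
#'   frame: category, tp, fn, fp, tn, sensitivity, sens_lo, sens_hi,
#'   specificity, spec_lo, spec_hi, youden), `kappa` (a `kappa_result`),
#'   `cm`, `method`.
#' @export
evaluate_all <- function(cm, level = 0.95, method = "wald-cc") {
  rows <- lapply(broad_categories(), function(cat) {
    k <- ovr_counts(cm, cat)
    se_ <- sensitivity(cm, cat, level = level, method = method)
    sp <- specificity(cm, cat, level = level, method = method)
    data.frame(category = cat, tp = k$tp, fn = k$fn, fp = k$fp, tn = k$tn,
               sensitivity = se_$estimate, sens_lo = se_$lower,
               sens_hi = se_$upper, specificity = sp$estimate,
               spec_lo = sp$lower, spec_hi = sp$upper,
               youden = se_$estimate + sp$estimate - 1,
               stringsAsFactors = FALSE)
  })
  structure(list(metrics = do.call(rbind, rows), kappa = cohen_kappa(cm, level),
                 cm = cm, method = method),
            class = "diagnostic_report")
}

# rendering helpers: percentages to one decimal, indices to two (half-up)
fmt_pct <- function(x) sprintf("%.1f", round_half_up(100 * x, 1))
fmt_idx <- function(x) sprintf("%.2f", round_half_up(x, 2))

#' @export
print.diagnostic_report <- function(x, ...) {
  m <- x$metrics
  w <- 14
  pad <- function(v) formatC(v, width = w)
  cat("Operating characteristics by broad category\n")
  cat(formatC("", width = 18), paste(pad(m$category), collapse = ""), "\n", sep = "")
  cat(formatC("Sensitivity n-%", width = 18, flag = "-"),
      paste(pad(sprintf("%d/%d-%s%%", m$tp, m$tp + m$fn, fmt_pct(m$sensitivity))),
            collapse = ""), "\n", sep = "")
  cat(formatC("  (95% CI)", width = 18, flag = "-"),
      paste(pad(sprintf("(%s-%s)", fmt_pct(m$sens_lo), fmt_pct(m$sens_hi))),
            collapse = ""), "\n", sep = "")
  cat(formatC("Specificity n-%", width = 18, flag = "-"),
      paste(pad(sprintf("%d/%d-%s%%", m$tn, m$tn + m$fp, fmt_pct(m$specificity))),
            collapse = ""), "\n", sep = "")
  cat(formatC("  (95% CI)", width = 18, flag = "-"),
      paste(pad(sprintf("(%s-%s)", fmt_pct(m$spec_lo), fmt_pct(m$spec_hi))),
            collapse = ""), "\n", sep = "")
  cat(formatC("Youden index", width = 18, flag = "-"),
      paste(pad(fmt_idx(m$youden)), collapse = ""), "\n", sep = "")
  cat("\n")
  print(x$kappa)
  invisible(x)
}

#' Write a diagnostic report as CSV
#'
#' One row per category with the raw one-vs-rest counts and unrounded
#' estimates, plus a final `kappa` row reusing the sensitivity columns for
#' the kappa point estimate and interval (count columns left empty).
#'
#' @param report A `diagnostic_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(report, path) {
  m <- report$metrics
  k <- report$kappa
  kappa_row <- data.frame(category = "kappa", tp = NA, fn = NA, fp = NA, tn = NA,
                          sensitivity = k$kappa, sens_lo = k$lower,
                          sens_hi = k$upper, specificity = k$po,
                          spec_lo = k$pe, spec_hi = k$se, youden = NA)
  utils::write.csv(rbind(m, kappa_row), path, row.names = FALSE)
  invisible(path)
}
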