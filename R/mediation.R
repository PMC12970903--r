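# Three-variable mediation (X -> M -> Y) on standardized variables with
# nonparametric bootstrap bias-corrected confidence intervals for the
# indirect effect a * b.

# standardized OLS paths from the three pairwise correlations; closed form
# keeps the bootstrap loop cheap and makes c = c' + a*b exact
paths_from_cor <- function(rxm, rxy, rmy, tol = 1e-10) {
  det <- 1 - rxm^2
  if (det < tol) {
    stopf("mediator is (numerically) collinear with the predictor: |r| = %g",
          abs(rxm))
  }
  b <- (rmy - rxy * rxm) / det
  c_prime <- (rxy - rmy * rxm) / det
  list(a = rxm, b = b, c = rxy, c_prime = c_prime)
}

check_mediation_input <- function(x, m, y) {
  n <- length(x)
  if (length(m) != n || length(y) != n) stopf("x, m, y must have equal length")
  if (n < 10) stopf("mediation needs n >= 10, got %d", n)
  if (stats::sd(x) == 0 || stats::sd(m) == 0 || stats::sd(y) == 0) {
    stopf("constant variable in mediation input")
  }
  invisible(n)
}

#' Standardized mediation path coefficients
#'
#' All three variables are z-scored; `a` is the OLS slope of M on X, `c`
#' the slope of Y on X, and `(c_prime, b)` the slopes of Y on X and M
#' jointly. On standardized variables the product-of-coefficients
#' decomposition `c = c_prime + a * b` holds as an algebraic identity.
#'
#' @param x Predictor (e.g. training duration in years).
#' @param m Mediator (e.g. a network AUC metric).
#' @param y Outcome (e.g. strokes per 18 holes).
#' @return List with `a`, `b`, `c`, `c_prime`, and `indirect = a * b`.
#' @export
fit_paths <- function(x, m, y) {
  check_mediation_input(x, m, y)
  p <- paths_from_cor(stats::cor(x, m), stats::cor(x, y), stats::cor(m, y))
  p$indirect <- p$a * p$b
  p
}

#' Bootstrap mediation with bias-corrected confidence interval
#'
#' Resamples subjects with replacement, recomputes the standardized indirect
#' effect `a * b` in each replicate, and forms the bias-corrected (BC)
#' percentile interval: `z0 = qnorm(P(boot < estimate))`, bounds at the
#' `pnorm(2 z0 +/- z_{1 - alpha/2})` percentiles of the bootstrap
#' distribution. A confidence interval excluding zero indicates a
#' significant indirect effect. Replicates in which a resampled variable is
#' constant are redrawn (at most 10 attempts each).
#'
#' @param x,m,y As in [fit_paths()].
#' @param n_boot Number of bootstrap samples (>= 100; default 5000).
#' @param seed Integer seed; the full bootstrap is deterministic given it.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `mediation_result`: list with the point-estimate
#'   paths `a`, `b`, `c`, `c_prime`, `indirect`, the interval `ci_low`,
#'   `ci_high`, `n_boot`, `conf_level`, `significant`, `seed`, and `n`.
#' @export
bootstrap_indirect <- function(x, m, y, n_boot = 5000, seed = 1L,
                               conf_level = 0.95) {
  n <- check_mediation_input(x, m, y)
  if (n_boot < 100) stopf("n_boot must be >= 100")
  est <- fit_paths(x, m, y)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      for (attempt in 1:10) {
        idx <- sample.int(n, n, replace = TRUE)
        xb <- x[idx]; mb <- m[idx]; yb <- y[idx]
        if (stats::sd(xb) > 0 && stats::sd(mb) > 0 && stats::sd(yb) > 0) {
          rxm <- stats::cor(xb, mb)
          if (abs(rxm) < 1 - 1e-10) {
            p <- paths_from_cor(rxm, stats::cor(xb, yb), stats::cor(mb, yb))
            return(p$a * p$b)
          }
        }
      }
      stopf("degenerate bootstrap resample persisted after 10 redraws")
    }, numeric(1))
  })
  prop_below <- mean(boots < est$indirect)
  # guard the probit against all-below / none-below edge cases
  prop_below <- min(max(prop_below, 0.5 / n_boot), 1 - 0.5 / n_boot)
  z0 <- stats::qnorm(prop_below)
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  probs <- stats::pnorm(c(2 * z0 - zc, 2 * z0 + zc))
  ci <- unname(stats::quantile(boots, probs, type = 6))
  structure(list(a = est$a, b = est$b, c = est$c, c_prime = est$c_prime,
                 indirect = est$indirect,
                 ci_low = ci[1], ci_high = ci[2],
                 n_boot = as.integer(n_boot), conf_level = conf_level,
                 significant = ci[1] > 0 || ci[2] < 0,
                 seed = as.integer(seed), n = n),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation (standardized, n = %d):\n", x$n))
  cat(sprintf("  a = %.4f, b = %.4f, c = %.4f, c' = %.4f\n",
              x$a, x$b, x$c, x$c_prime))
  cat(sprintf("  indirect a*b = %.4f, %d%% BC bootstrap CI [%.4f, %.4f] (%s)\n",
              x$indirect, round(100 * x$conf_level), x$ci_low, x$ci_high,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Select candidate mediators
#'
#' A metric qualifies as a candidate mediator when it shows a significant
#' group difference and significant correlations with both the predictor
#' and the outcome.
#'
#' @param comparison A `comparison_result` (see [compare_cohorts()]).
#' @param correlations Row-bound `correlation_result`s in which
#'   `variable_x` names the metric and `variable_y` the behavioral variable.
#' @param predictor,outcome The behavioral variable names the metric must
#'   correlate with (defaults `"training_duration"` and `"strokes"`).
#' @param alpha Significance threshold on `p_fdr` and correlation `p`.
#' @return Character vector of metric names (possibly empty), ordered by
#'   comparison `p_fdr`.
#' @export
select_mediators <- function(comparison, correlations,
                             predictor = "training_duration",
                             outcome = "strokes", alpha = 0.05) {
  if (nrow(comparison) == 0 || is.null(correlations) ||
      nrow(correlations) == 0) {
    return(character(0))
  }
  sig <- comparison[!is.na(comparison$p_fdr) & comparison$p_fdr < alpha, ,
                    drop = FALSE]
  if (nrow(sig) == 0) return(character(0))
  sig <- sig[order(sig$p_fdr), , drop = FALSE]
  metric_id <- ifelse(is.na(sig$node), sig$metric,
                      paste(sig$metric, sig$node, sep = ":"))
  keep <- vapply(metric_id, function(mid) {
    with_pred <- correlations$variable_x == mid &
      correlations$variable_y == predictor & correlations$p < alpha
    with_out <- correlations$variable_x == mid &
      correlations$variable_y == outcome & correlations$p < alpha
    any(with_pred) && any(with_out)
  }, logical(1))
  unname(metric_id[keep])
}

#' Serialize a mediation result
#'
#' Writes the result both as JSON and as a one-row CSV.
#'
#' @param result A `mediation_result`.
#' @param json_path,csv_path Output paths (`NULL` to skip either).
#' @return `result`, invisibly.
#' @export
write_mediation_result <- function(result, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(result, "mediation_result"))
  row <- data.frame(a = result$a, b = result$b, c = result$c,
                    c_prime = result$c_prime, indirect = result$indirect,
                    ci_low = result$ci_low, ci_high = result$ci_high,
                    n_boot = result$n_boot, seed = result$seed,
                    significant = result$significant)
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(result), json_path, auto_unbox = TRUE,
                         digits = NA)
  }
  if (!is.null(csv_path)) utils::write.csv(row, csv_path, row.names = FALSE)
  invisible(result)
}
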