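# Permutation-based group comparison with FDR control, effect sizes, and
# normality-gated correlation.

#' Two-sample label-permutation test on the mean difference
#'
#' The observed statistic is `mean(a) - mean(b)`. The null distribution is
#' built by re-splitting the pooled values into groups of the original sizes.
#' When the number of distinct splits is at most `n_perm`, all splits are
#' enumerated and the p-value is the exact two-sided proportion; otherwise
#' `n_perm` random splits are drawn and the two-sided p-value uses the
#' add-one correction `(count + 1) / (n_perm + 1)`, which cannot be zero.
#'
#' @param values_a,values_b Numeric samples (each of size >= 2... size >= 1
#'   is rejected only when empty; degenerate sizes are the caller's risk).
#' @param n_perm Number of permutations (default 5000).
#' @param seed Integer seed (random mode only).
#' @return List with `observed_diff`, `p`, `exhaustive` (logical), and
#'   `n_perm_used`.
#' @export
permutation_test <- function(values_a, values_b, n_perm = 5000, seed = 1L) {
  if (length(values_a) == 0 || length(values_b) == 0) {
    stopf("both samples must be non-empty")
  }
  if (n_perm < 1) stopf("n_perm must be >= 1")
  pooled <- c(values_a, values_b)
  na <- length(values_a)
  n <- length(pooled)
  obs <- mean(values_a) - mean(values_b)
  n_splits <- choose(n, na)
  if (n_splits <= n_perm) {
    idx <- utils::combn(n, na)
    diffs <- apply(idx, 2, function(i) mean(pooled[i]) - mean(pooled[-i]))
    p <- mean(abs(diffs) >= abs(obs) - 1e-12)
    return(list(observed_diff = obs, p = p, exhaustive = TRUE,
                n_perm_used = ncol(idx)))
  }
  count <- with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      take <- sample.int(n, na)
      d <- mean(pooled[take]) - mean(pooled[-take])
      if (abs(d) >= abs(obs) - 1e-12) hits <- hits + 1L
    }
    hits
  })
  list(observed_diff = obs, p = (count + 1) / (n_perm + 1),
       exhaustive = FALSE, n_perm_used = n_perm)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, capped at 1,
#' mapped back to the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
fdr_bh <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stopf("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(p, method = "BH")
}

#' Cohen's d with pooled standard deviation
#'
#' `d = (mean_a - mean_b) / s_pooled`,
#' `s_pooled^2 = ((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2)`.
#'
#' @param values_a,values_b Numeric samples of size >= 2 each.
#' @return The effect size `d`.
#' @export
cohens_d <- function(values_a, values_b) {
  na <- length(values_a); nb <- length(values_b)
  if (na < 2 || nb < 2) stopf("each sample needs >= 2 values")
  sp2 <- ((na - 1) * stats::var(values_a) + (nb - 1) * stats::var(values_b)) /
    (na + nb - 2)
  if (sp2 == 0) stopf("pooled standard deviation is zero")
  (mean(values_a) - mean(values_b)) / sqrt(sp2)
}

#' Normality-gated correlation
#'
#' Applies the Shapiro-Wilk test to each variable; if both have normality
#' p > 0.05 the association is measured with Pearson's correlation,
#' otherwise with Spearman's rank correlation.
#'
#' @param x,y Paired numeric samples, n >= 4, neither constant.
#' @param label_x,label_y Variable names carried on the result.
#' @return Data frame of class `correlation_result` with columns
#'   `variable_x`, `variable_y`, `method`, `r`, `p`, `normality_p_x`,
#'   `normality_p_y`.
#' @export
gated_correlation <- function(x, y, label_x = "x", label_y = "y") {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stopf("need >= 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("constant variable: correlation undefined")
  }
  px <- stats::shapiro.test(x)$p.value
  py <- stats::shapiro.test(y)$p.value
  method <- if (px > 0.05 && py > 0.05) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  out <- data.frame(variable_x = label_x, variable_y = label_y,
                    method = method, r = unname(ct$estimate),
                    p = ct$p.value, normality_p_x = px, normality_p_y = py,
                    stringsAsFactors = FALSE)
  class(out) <- c("correlation_result", "data.frame")
  out
}

#' Permutation comparison of AUC tables between two groups
#'
#' Runs [permutation_test()] per global metric and per metric x node,
#' applies Benjamini-Hochberg correction within each metric family (the
#' global metrics form one family; each nodal metric forms a family across
#' its nodes — switch to a single pooled family with
#' `fdr_family = "pooled"`), and attaches [cohens_d()].
#'
#' @param auc_a,auc_b AUC tables ([auc_table()]) for the two groups
#'   (e.g. experts and novices).
#' @param n_perm Permutations per test.
#' @param seed Integer root seed; each test gets a distinct substream.
#' @param fdr_family `"within"` (default) or `"pooled"`.
#' @return Data frame: `metric`, `node`, `mean_a`, `mean_b`, `sd_a`, `sd_b`,
#'   `observed_diff`, `p_perm`, `p_fdr`, `cohen_d`.
#' @export
compare_cohorts <- function(auc_a, auc_b, n_perm = 5000, seed = 1L,
                            fdr_family = c("within", "pooled")) {
  fdr_family <- match.arg(fdr_family)
  if (nrow(auc_a) == 0 || nrow(auc_b) == 0) stopf("both groups must be non-empty")
  key <- function(tb) {
    paste(tb$metric, ifelse(is.na(tb$node), "<global>", tb$node), sep = "\r")
  }
  cells <- sort(unique(key(auc_a)))
  stopifnot(setequal(cells, unique(key(auc_b))))
  ka <- key(auc_a); kb <- key(auc_b)
  rows <- lapply(seq_along(cells), function(i) {
    va <- auc_a$auc[ka == cells[i]]
    vb <- auc_b$auc[kb == cells[i]]
    pt <- permutation_test(va, vb, n_perm = n_perm,
                           seed = (as.integer(seed) + i * 7919L) %% 2147483629L)
    parts <- strsplit(cells[i], "\r", fixed = TRUE)[[1]]
    data.frame(metric = parts[1],
               node = if (parts[2] == "<global>") NA_character_ else parts[2],
               mean_a = mean(va), mean_b = mean(vb),
               sd_a = stats::sd(va), sd_b = stats::sd(vb),
               observed_diff = pt$observed_diff, p_perm = pt$p,
               cohen_d = cohens_d(va, vb), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  family <- if (fdr_family == "pooled") {
    rep("all", nrow(out))
  } else {
    ifelse(is.na(out$node), "global", out$metric)
  }
  out$p_fdr <- NA_real_
  for (f in unique(family)) {
    sel <- family == f
    out$p_fdr[sel] <- fdr_bh(out$p_perm[sel])
  }
  out <- out[, c("metric", "node", "mean_a", "mean_b", "sd_a", "sd_b",
                 "observed_diff", "p_perm", "p_fdr", "cohen_d")]
  rownames(out) <- NULL
  class(out) <- c("comparison_result", "data.frame")
  out
}
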