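# Individualized SCN construction: residualization against the control
# fit, group correlation network, ESD weighting, and individualization.

toy_cohort <- function(vol, group, covs = NULL) {
  n <- length(group)
  df <- data.frame(subject_id = sprintf("s%02d", seq_len(n)), group = group,
                   age = if (is.null(covs)) rnorm(n) else covs,
                   sex = rep_len(0:1, n), tiv = rnorm(n, 100, 5),
                   training_duration = rnorm(n, 5),
                   strokes = rnorm(n, 80), stringsAsFactors = FALSE)
  vol <- as.matrix(vol)
  colnames(vol) <- sprintf("R%03d", seq_len(ncol(vol)))
  df <- cbind(df, as.data.frame(vol))
  class(df) <- c("cohort_table", "data.frame")
  attr(df, "region_labels") <- colnames(vol)
  df
}

test_that("intercept-only residuals are deviations from the control mean", {
  set.seed(1)
  co <- toy_cohort(matrix(rnorm(10 * 3, 100), 10),
                   group = rep(c("control", "expert"), each = 5))
  r <- residualize(co, covariates = character(0))
  ctrl_means <- colMeans(as.matrix(co[co$group == "control",
                                      attr(co, "region_labels")]))
  expect_equal(unname(r$residuals),
               unname(as.matrix(co[, attr(co, "region_labels")]) -
                        matrix(ctrl_means, 10, 3, byrow = TRUE)),
               tolerance = 1e-12)
})

test_that("a perfect linear relation residualizes to zero", {
  co <- toy_cohort(matrix(c(10, 12, 14, 16, 18, 20), 6),
                   group = rep("control", 6), covs = 1:6)
  r <- residualize(co, covariates = "age")
  expect_equal(max(abs(r$residuals)), 0, tolerance = 1e-10)
})

test_that("control-fit residuals match an explicit normal-equations solve", {
  set.seed(42)
  n <- 20
  covs <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("age", "sex", "tiv")))
  vol <- matrix(rnorm(n * 5, 100), n)
  co <- toy_cohort(vol, group = rep("control", n))
  co$age <- covs[, 1]; co$sex <- covs[, 2]; co$tiv <- covs[, 3]
  r <- residualize(co)
  x <- cbind(1, covs)
  oracle <- bf_ols_residuals(x, vol)
  expect_lt(max(abs(r$residuals - oracle)), 1e-8)
  # control residuals are exactly orthogonal to every covariate
  for (j in 1:3) {
    expect_lt(max(abs(cor(r$residuals, covs[, j]))), 1e-10)
  }
})

test_that("rank-deficient covariate designs are rejected by name", {
  set.seed(2)
  co <- toy_cohort(matrix(rnorm(30, 100), 10), rep("control", 10))
  co$tiv <- 2 * co$age # collinear with age given the intercept? no: with age
  co$sex <- co$age * 2
  expect_error(residualize(co, covariates = c("age", "sex")), "sex")
})

test_that("group SCN matches hand-computed Pearson correlations", {
  m <- matrix(c(1, 2, 3, 3, 2, 1, 2, 4, 8), 3,
              dimnames = list(NULL, c("A", "B", "C")))
  m <- rbind(m, c(2, 0, 1))
  scn <- build_group_scn(m)
  expect_true(isSymmetric(scn$matrix))
  expect_equal(unname(diag(scn$matrix)), rep(1, 3))
  hand <- function(u, v) {
    sum((u - mean(u)) * (v - mean(v))) /
      sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  }
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(scn$matrix[i, j], hand(m[, i], m[, j]), tolerance = 1e-12)
  }
  # perfect correlation and anticorrelation at the extremes
  dup <- cbind(A = c(1, 2, 3), B = c(1, 2, 3) * 2 + 1, C = c(3, 2, 1))
  scn2 <- build_group_scn(dup)
  expect_equal(scn2$matrix["A", "B"], 1)
  expect_equal(scn2$matrix["A", "C"], -1)
})

test_that("degenerate control inputs error with the offending region", {
  m <- cbind(A = c(1, 2, 3), B = c(2, 2, 2))
  expect_error(build_group_scn(m), "B")
  expect_error(control_reference(m), "B")
  expect_error(build_group_scn(m[1:2, ]), "control")
})

test_that("control reference gives two-pass mean and n-1 SD", {
  expect_ref <- control_reference(cbind(R1 = c(-1, 0, 1)))
  expect_equal(unname(expect_ref$mean), 0)
  expect_equal(unname(expect_ref$sd), 1)
  set.seed(3)
  m <- matrix(rnorm(60), 20, dimnames = list(NULL, c("A", "B", "C")))
  ref <- control_reference(m)
  for (j in 1:3) {
    mu <- sum(m[, j]) / 20
    expect_equal(unname(ref$mean[j]), mu, tolerance = 1e-12)
    expect_equal(unname(ref$sd[j]), sqrt(sum((m[, j] - mu)^2) / 19),
                 tolerance = 1e-12)
  }
})

test_that("ESD weights are symmetric, unit-diagonal, bounded, and exact", {
  ref <- control_reference(cbind(A = c(-1, 0, 1), B = c(9, 10, 11),
                                 C = c(4, 5, 6)))
  # z = (2, 0, 0): the A-B weight is exp(-2)
  w <- individual_weight_matrix(c(2, 10, 5), ref)
  expect_equal(w["A", "B"], exp(-2), tolerance = 1e-12)
  expect_equal(w["B", "C"], 1)
  expect_identical(w, t(w))
  expect_true(all(w > 0 & w <= 1))
  expect_equal(unname(diag(w)), rep(1, 3))
  # a subject at the control mean has an all-ones weight matrix
  w0 <- individual_weight_matrix(ref$mean, ref)
  expect_equal(unname(w0), matrix(1, 3, 3))
  # alternative transform is pluggable
  wi <- individual_weight_matrix(c(2, 10, 5), ref, transform = "inverse")
  expect_equal(wi["A", "B"], 1 / 3, tolerance = 1e-12)
})

test_that("individualization is the element-wise product with the group SCN", {
  set.seed(4)
  m <- matrix(rnorm(100), 20, 5, dimnames = list(NULL, paste0("R", 1:5)))
  scn <- build_group_scn(m)
  ref <- control_reference(m)
  w <- individual_weight_matrix(m[1, ] + rnorm(5), ref)
  ind <- individualize(w, scn, "s1")
  for (i in 1:5) for (j in 1:5) {
    expect_equal(ind$matrix[i, j], w[i, j] * scn$matrix[i, j],
                 tolerance = 1e-15)
  }
  expect_error(individualize(w[1:4, 1:4], scn), "4x4")
})

test_that("a pseudo-subject at the control mean reproduces the group SCN", {
  gen <- make_small_cohort(seed = 21)
  parts <- build_individual_scns(gen$cohort)
  w <- individual_weight_matrix(parts$reference$mean, parts$reference)
  ind <- individualize(w, parts$group_scn, "pseudo")
  expect_identical(unname(ind$matrix), unname(parts$group_scn$matrix))
})

test_that("individualized edges never exceed group edges in magnitude", {
  gen <- make_small_cohort(seed = 22)
  parts <- build_individual_scns(gen$cohort)
  g <- abs(parts$group_scn$matrix)
  for (scn in parts$scns) {
    expect_true(all(abs(scn$matrix) <= g + 1e-15))
    expect_true(isSymmetric(scn$weight_matrix))
  }
})

test_that("larger inter-regional deviation never strengthens an edge", {
  ref <- control_reference(cbind(A = c(-1, 0, 1), B = c(9, 10, 11),
                                 C = c(4, 5, 6)))
  scn <- build_group_scn(cbind(A = c(-1, 0, 1.5), B = c(9, 10.2, 11),
                               C = c(4.4, 5, 6)))
  dz <- seq(0, 4, by = 0.25)
  mags <- vapply(dz, function(delta) {
    w <- individual_weight_matrix(ref$mean + c(delta, 0, 0), ref)
    abs(individualize(w, scn)$matrix["A", "B"])
  }, numeric(1))
  expect_true(all(diff(mags) <= 1e-12))
})
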