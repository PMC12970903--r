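# Individualized structural covariance network construction.
#
# The control group defines the normative model: covariate regressions are
# fit on controls only, the group SCN is the Pearson correlation matrix of
# control residuals, and each subject's network is the group SCN modulated
# element-wise by a weight matrix derived from the subject's inter-regional
# effect-size differences relative to the control reference.

#' Covariate-adjust regional volumes against the control group
#'
#' Fits, per region, an ordinary-least-squares regression of volume on the
#' requested covariates (with intercept) using the control subjects only,
#' then computes residuals (observed minus predicted) for every subject in
#' every group from the control-fit coefficients.
#'
#' @param cohort A `cohort_table` (see [generate_cohort()] /
#'   [load_cohort_csv()]).
#' @param covariates Character vector of covariate column names (default
#'   `c("age", "sex", "tiv")`). May be empty for an intercept-only fit.
#' @return List with `residuals` (subjects x regions matrix, rownames =
#'   subject ids), `fit_coefficients` ((1 + covariates) x regions matrix),
#'   `covariates`, and `groups` (per-row group labels).
#' @export
residualize <- function(cohort, covariates = c("age", "sex", "tiv")) {
  stopifnot(is.data.frame(cohort))
  missing_cov <- setdiff(covariates, names(cohort))
  if (length(missing_cov) > 0) {
    stopf("covariates not found in cohort: %s",
          paste(missing_cov, collapse = ", "))
  }
  labels <- region_labels(cohort)
  vol <- as.matrix(cohort[, labels, drop = FALSE])
  storage.mode(vol) <- "double"
  ctrl <- cohort$group == "control"
  if (sum(ctrl) < length(covariates) + 2) {
    stopf("need at least %d control subjects to fit %d covariates",
          length(covariates) + 2, length(covariates))
  }
  xall <- cbind(`(Intercept)` = 1,
                as.matrix(cohort[, covariates, drop = FALSE]))
  storage.mode(xall) <- "double"
  xc <- xall[ctrl, , drop = FALSE]
  qx <- qr(xc)
  if (qx$rank < ncol(xc)) {
    bad <- colnames(xc)[qx$pivot[(qx$rank + 1):ncol(xc)]]
    stopf("covariate design is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, vol[ctrl, , drop = FALSE])
  res <- vol - xall %*% beta
  rownames(res) <- cohort$subject_id
  colnames(res) <- labels
  list(residuals = res, fit_coefficients = beta,
       covariates = covariates, groups = cohort$group)
}

# region columns of a cohort table = everything after the reserved prefix
region_labels <- function(cohort) {
  lab <- attr(cohort, "region_labels")
  if (!is.null(lab)) return(lab)
  setdiff(names(cohort), cohort_reserved_columns())
}

control_rows <- function(resid) {
  resid$residuals[resid$groups == "control", , drop = FALSE]
}

#' Group structural covariance network from control residuals
#'
#' Pearson correlation, across control subjects, of every pair of regional
#' residuals; diagonal fixed at 1.
#'
#' @param controls Matrix of control residuals (subjects x regions), or the
#'   list returned by [residualize()] (its control rows are used).
#' @return Object of class `group_scn`: list with `matrix` (symmetric,
#'   unit-diagonal correlation matrix) and `region_labels`.
#' @export
build_group_scn <- function(controls) {
  m <- if (is.list(controls) && !is.data.frame(controls)) {
    control_rows(controls)
  } else {
    as.matrix(controls)
  }
  if (nrow(m) < 3) stopf("need >= 3 control subjects, got %d", nrow(m))
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stopf("zero-variance region(s): %s",
          paste(colnames(m)[sds == 0], collapse = ", "))
  }
  cm <- stats::cor(m)
  diag(cm) <- 1
  structure(list(matrix = cm, region_labels = colnames(m)),
            class = "group_scn")
}

#' Control reference statistics (normative mean and SD per region)
#'
#' @param controls As in [build_group_scn()].
#' @param fit_coefficients Optional covariate-fit coefficients to carry along
#'   (from [residualize()]).
#' @return Object of class `control_reference`: list with per-region `mean`,
#'   `sd` (denominator n - 1), `region_labels`, and `fit_coefficients`.
#' @export
control_reference <- function(controls, fit_coefficients = NULL) {
  m <- if (is.list(controls) && !is.data.frame(controls)) {
    if (is.null(fit_coefficients)) fit_coefficients <- controls$fit_coefficients
    control_rows(controls)
  } else {
    as.matrix(controls)
  }
  if (nrow(m) < 2) stopf("need >= 2 control subjects, got %d", nrow(m))
  mu <- colMeans(m)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stopf("zero residual SD in region(s): %s",
          paste(colnames(m)[sds == 0], collapse = ", "))
  }
  structure(list(mean = mu, sd = sds, region_labels = colnames(m),
                 fit_coefficients = fit_coefficients),
            class = "control_reference")
}

#' Effect-size-difference weight transforms
#'
#' The weight for a region pair (j, k) is a decreasing function of the
#' subject's inter-regional effect-size difference `|z_j - z_k|`, where `z`
#' is the subject's residual standardized by the control reference. The
#' default transform is `exp(-|dz|)`: bounded in (0, 1], equal to 1 exactly
#' when the subject deviates identically at both regions, smoothly decaying
#' as the pair decouples. `esd_weight_inverse` (`1 / (1 + |dz|)`) is an
#' alternative with a heavier tail.
#'
#' @param dz Matrix (or vector) of absolute z-score differences.
#' @return Weights in (0, 1], same shape as `dz`.
#' @export
esd_weight_exp <- function(dz) exp(-abs(dz))

#' @rdname esd_weight_exp
#' @export
esd_weight_inverse <- function(dz) 1 / (1 + abs(dz))

resolve_esd_transform <- function(transform) {
  if (is.function(transform)) return(transform)
  switch(transform,
         exp = esd_weight_exp,
         inverse = esd_weight_inverse,
         stopf("unknown ESD transform '%s'", transform))
}

#' Individual ESD weight matrix
#'
#' Standardizes a subject's residual vector against the control reference
#' (`z = (residual - mean) / sd`), forms the inter-regional effect-size
#' difference `|z_j - z_k|` for every region pair, and maps it through a
#' decreasing transform to a symmetric, unit-diagonal weight matrix with
#' entries in (0, 1].
#'
#' @param residuals Numeric vector of one subject's covariate-adjusted
#'   regional volumes (same region order as the reference).
#' @param ref A [control_reference()].
#' @param transform `"exp"` (default), `"inverse"`, or a function of the
#'   absolute z-difference matrix.
#' @return Weight matrix (regions x regions).
#' @export
individual_weight_matrix <- function(residuals, ref, transform = "exp") {
  stopifnot(inherits(ref, "control_reference"))
  residuals <- as.numeric(residuals)
  p <- length(ref$mean)
  if (length(residuals) != p) {
    stopf("subject has %d regions but reference has %d",
          length(residuals), p)
  }
  z <- (residuals - ref$mean) / ref$sd
  dz <- abs(outer(z, z, "-"))
  w <- resolve_esd_transform(transform)(dz)
  diag(w) <- 1
  dimnames(w) <- list(ref$region_labels, ref$region_labels)
  w
}

#' Individualize the group SCN for one subject
#'
#' Element-wise product of the subject's ESD weight matrix with the group
#' SCN. Weights lie in (0, 1], so every individualized edge keeps the sign
#' of the group edge and never exceeds it in magnitude.
#'
#' @param w Weight matrix from [individual_weight_matrix()].
#' @param group_scn A [build_group_scn()] result.
#' @param subject_id Identifier carried on the result.
#' @return Object of class `individual_scn`: list with `subject_id`,
#'   `weight_matrix`, `matrix`, and `region_labels`.
#' @export
individualize <- function(w, group_scn, subject_id = NA_character_) {
  stopifnot(inherits(group_scn, "group_scn"))
  g <- group_scn$matrix
  if (!all(dim(w) == dim(g))) {
    stopf("weight matrix is %dx%d but group SCN is %dx%d",
          nrow(w), ncol(w), nrow(g), ncol(g))
  }
  structure(list(subject_id = subject_id, weight_matrix = w,
                 matrix = w * g, region_labels = group_scn$region_labels),
            class = "individual_scn")
}

#' Build individualized SCNs for a whole cohort
#'
#' Convenience wrapper running the full construction: residualize against
#' controls, build the group SCN and control reference, then one
#' individualized network per requested subject.
#'
#' @param cohort A `cohort_table`.
#' @param covariates Covariate column names for [residualize()].
#' @param subjects Which subjects to individualize: `"golfers"` (default;
#'   expert and novice groups), `"all"`, or a character vector of ids.
#' @param transform ESD weight transform (see [individual_weight_matrix()]).
#' @return List with `group_scn`, `reference`, `residuals` (the
#'   [residualize()] result), and `scns` (named list of `individual_scn`).
#' @export
build_individual_scns <- function(cohort, covariates = c("age", "sex", "tiv"),
                                  subjects = "golfers", transform = "exp") {
  resid <- residualize(cohort, covariates)
  gscn <- build_group_scn(resid)
  ref <- control_reference(resid)
  ids <- if (identical(subjects, "golfers")) {
    cohort$subject_id[cohort$group %in% c("expert", "novice")]
  } else if (identical(subjects, "all")) {
    cohort$subject_id
  } else {
    subjects
  }
  scns <- lapply(ids, function(id) {
    w <- individual_weight_matrix(resid$residuals[id, ], ref, transform)
    individualize(w, gscn, id)
  })
  names(scns) <- ids
  list(group_scn = gscn, reference = ref, residuals = resid, scns = scns)
}

#' Write a square matrix as labelled CSV
#' @param m Matrix (e.g. `group_scn$matrix` or an `individual_scn$matrix`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
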