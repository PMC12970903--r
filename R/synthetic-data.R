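#' Configuration for the synthetic cohort generator
#'
#' Describes a three-group (expert / novice / control) cohort of regional
#' gray-matter volumes with a block (modular) region-region correlation
#' structure, covariate confounds (age, sex, total intracranial volume),
#' optional planted group effects on named regions, and an optional embedded
#' mediation chain in which training duration tightens the within-module
#' covariance of a subject's deviation pattern and stroke performance
#' regresses on that latent tightness.
#'
#' @param n_per_group Subjects per group (default 20, the study design this
#'   generator emulates).
#' @param n_regions Number of brain regions (default 116, the AAL atlas;
#'   configurable down to 8 for fast tests).
#' @param n_modules Number of covariance blocks ("modules") among regions.
#' @param rho_within Correlation between regions in the same module, in
#'   `[0, 1)`. Zero (with `rho_between = 0`) gives an identity covariance.
#' @param rho_between Correlation between regions in different modules,
#'   in `[0, rho_within]`.
#' @param covariate_effects Named list with elements `age`, `sex`, `tiv`:
#'   linear coefficients on the log-volume scale (scalar, or one value per
#'   region). `age` is per year about the cohort mean, `sex` is the 0/1
#'   contrast, `tiv` is per SD of total intracranial volume.
#' @param group_effects `NULL`, or a data frame with columns `region`
#'   (index or label), `group`, and `shift` (volume shift in SD units of the
#'   subject-level deviation scale) planting regional group effects.
#' @param mediation `NULL` to disable, or a list with standardized path
#'   coefficients `a` (training duration -> latent tightness), `b`
#'   (tightness -> strokes, adjusting for duration), and `c_prime` (direct
#'   duration -> strokes).
#' @param group_tightness Named numeric: additive shift (SD units) of the
#'   latent within-module tightness per group, on top of the mediation chain.
#' @param tightness_gain Fractional change of `rho_within` per SD of the
#'   latent tightness variable (applies whenever tightness varies, whether
#'   from the mediation chain or from `group_tightness`).
#' @param behavior Group means/SDs for training duration (years) and strokes
#'   per 18 holes; defaults follow the demographic table of the emulated
#'   study design. Controls have no stroke score (`NA`).
#' @param age_params Group means/SDs for age in years.
#' @param volume_cv Coefficient of variation of regional volumes on the log
#'   scale (SD of the subject deviation term).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_per_group = 20,
                          n_regions = 116,
                          n_modules = 4,
                          rho_within = 0.5,
                          rho_between = 0.10,
                          covariate_effects = list(age = -0.003, sex = 0.02,
                                                   tiv = 0.06),
                          group_effects = NULL,
                          mediation = list(a = 0.5, b = -0.5, c_prime = 0),
                          group_tightness = c(expert = 0, novice = 0,
                                              control = 0),
                          tightness_gain = 0.5,
                          behavior = list(
                            training = list(expert = c(mean = 12.4, sd = 1.2),
                                            novice = c(mean = 1.8, sd = 1.1),
                                            control = c(mean = 0, sd = 0)),
                            strokes = list(expert = c(mean = 72.05, sd = 4.3),
                                           novice = c(mean = 86.15, sd = 5.63))
                          ),
                          age_params = list(expert = c(mean = 27.4, sd = 3.1),
                                            novice = c(mean = 27.1, sd = 2.8),
                                            control = c(mean = 27.6, sd = 2.2)),
                          volume_cv = 0.08,
                          seed = 1L) {
  if (n_per_group < 4) stopf("n_per_group must be >= 4 (got %d)", n_per_group)
  if (n_regions < 8) stopf("n_regions must be >= 8 (got %d)", n_regions)
  if (n_modules < 1 || n_modules > n_regions) {
    stopf("n_modules must be in [1, n_regions]")
  }
  if (rho_within < 0 || rho_within >= 1) {
    stopf("rho_within must be in [0, 1)")
  }
  if (rho_between < 0 || rho_between > rho_within) {
    stopf("rho_between must be in [0, rho_within]")
  }
  if (volume_cv <= 0) stopf("volume_cv must be > 0")
  for (p in c("training", "strokes")) {
    for (g in names(behavior[[p]])) {
      if (behavior[[p]][[g]][["sd"]] < 0) stopf("behavior SDs must be >= 0")
    }
  }
  if (!is.null(mediation)) {
    stopifnot(all(c("a", "b", "c_prime") %in% names(mediation)))
  }
  cfg <- list(
    n_per_group = as.integer(n_per_group),
    n_regions = as.integer(n_regions),
    n_modules = as.integer(n_modules),
    rho_within = rho_within,
    rho_between = rho_between,
    covariate_effects = covariate_effects,
    group_effects = group_effects,
    mediation = mediation,
    group_tightness = group_tightness,
    tightness_gain = tightness_gain,
    behavior = behavior,
    age_params = age_params,
    volume_cv = volume_cv,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  cfg
}

#' Region labels for a given atlas size
#'
#' For 116 regions, returns the AAL-116 label list shipped with the package;
#' for any other positive count, synthetic labels `R001`, `R002`, ...
#'
#' @param n_regions Number of regions (>= 1).
#' @return Character vector of length `n_regions`.
#' @export
#' @examples
#' make_region_names(3)
#' head(make_region_names(116))
make_region_names <- function(n_regions) {
  if (length(n_regions) != 1 || is.na(n_regions) || n_regions < 1) {
    stopf("n_regions must be a single integer >= 1")
  }
  n_regions <- as.integer(n_regions)
  if (n_regions == 116L) {
    path <- system.file("extdata", "aal116_labels.txt", package = "iscn",
                        mustWork = TRUE)
    labels <- readLines(path)
    stopifnot(length(labels) == 116L)
    return(labels)
  }
  sprintf("R%03d", seq_len(n_regions))
}

# Block ("modular") region-region correlation matrix.
block_correlation <- function(n_regions, n_modules, rho_within, rho_between) {
  sizes <- rep(n_regions %/% n_modules, n_modules)
  rem <- n_regions %% n_modules
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  module <- rep(seq_len(n_modules), times = sizes)
  sigma <- matrix(rho_between, n_regions, n_regions)
  same <- outer(module, module, "==")
  sigma[same] <- rho_within
  diag(sigma) <- 1
  attr(sigma, "module") <- module
  sigma
}

# Cholesky with a clear diagnostic for invalid covariance specifications.
chol_or_stop <- function(sigma, what = "covariance_spec") {
  tryCatch(chol(sigma),
           error = function(e) {
             stopf("%s is not positive definite: %s", what, conditionMessage(e))
           })
}

#' Generate a synthetic three-group cohort with ground truth
#'
#' Draws subject-level covariates, behavior, and regional gray-matter volumes
#' under the structure described by a [cohort_config()]. Volumes are
#' multivariate normal on the log scale and exponentiated, so they are
#' strictly positive. When the mediation chain is active, a latent
#' within-module "tightness" variable depends on (standardized) training
#' duration with slope `a`, each subject's deviation pattern is drawn with
#' within-module correlation `rho_within * (1 + gain * tightness)`, and the
#' stroke score regresses on tightness (slope `b`) and duration (slope
#' `c_prime`), centered on the pooled expert/novice stroke location.
#'
#' @param config A [cohort_config()].
#' @return A list with elements
#'   \describe{
#'     \item{cohort}{Data frame of class `cohort_table`: one row per subject
#'       with columns `subject_id`, `group`, `age`, `sex`, `tiv`,
#'       `training_duration`, `strokes`, then one column per region.}
#'     \item{truth}{Ground truth: `true_covariance` (the baseline region
#'       correlation matrix), `planted_effects`, `true_indirect`
#'       (`a * b`, `NA` when the chain is off), per-subject latent
#'       `tightness`, standardized duration `zx`, and `region_labels`.}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  labels <- make_region_names(config$n_regions)
  sigma <- block_correlation(config$n_regions, config$n_modules,
                             config$rho_within, config$rho_between)
  module <- attr(sigma, "module")
  chol_or_stop(sigma) # validate the baseline structure up front

  groups <- c("expert", "novice", "control")
  n <- config$n_per_group
  group <- rep(groups, each = n)
  n_tot <- 3L * n

  with_seed(config$seed, {
    age <- unlist(lapply(groups, function(g) {
      p <- config$age_params[[g]]
      rnorm(n, p[["mean"]], p[["sd"]])
    }))
    sex <- unlist(lapply(groups, function(g) rep_len(c(0L, 1L), n)))
    tiv <- rnorm(n_tot, 1.45e6, 1.2e5)
    training <- unlist(lapply(groups, function(g) {
      p <- config$behavior$training[[g]]
      pmax(rnorm(n, p[["mean"]], p[["sd"]]), 0)
    }))

    zx <- as.numeric(scale(training))
    med <- config$mediation
    gt <- config$group_tightness
    gt_vec <- ifelse(is.na(gt[group]), 0, gt[group])
    if (!is.null(med)) {
      a <- med$a
      tightness <- gt_vec + a * zx +
        sqrt(max(0, 1 - a^2)) * rnorm(n_tot)
    } else {
      tightness <- gt_vec + rnorm(n_tot)
    }

    # strokes: chain-generated when the mediation spec is active, otherwise
    # drawn independently per group; controls carry no stroke score
    strokes <- rep(NA_real_, n_tot)
    golfer <- group %in% c("expert", "novice")
    if (!is.null(med)) {
      b <- med$b; cp <- med$c_prime; a <- med$a
      resid_var <- max(0, 1 - (b^2 + cp^2 + 2 * a * b * cp))
      ystd <- cp * zx + b * tightness + sqrt(resid_var) * rnorm(n_tot)
      m_pool <- mean(c(config$behavior$strokes$expert[["mean"]],
                       config$behavior$strokes$novice[["mean"]]))
      s_pool <- mean(c(config$behavior$strokes$expert[["sd"]],
                       config$behavior$strokes$novice[["sd"]]))
      strokes[golfer] <- m_pool + s_pool * ystd[golfer]
    } else {
      for (g in c("expert", "novice")) {
        p <- config$behavior$strokes[[g]]
        strokes[group == g] <- rnorm(n, p[["mean"]], p[["sd"]])
      }
    }

    # per-subject deviation draws; tightness rescales within-module correlation
    gain <- config$tightness_gain
    dev <- matrix(NA_real_, n_tot, config$n_regions)
    z_raw <- matrix(rnorm(n_tot * config$n_regions), n_tot)
    same <- outer(module, module, "==")
    for (i in seq_len(n_tot)) {
      rho_i <- config$rho_within * (1 + gain * tightness[i])
      rho_i <- min(max(rho_i, config$rho_between), 0.95)
      sig_i <- sigma
      sig_i[same] <- rho_i
      diag(sig_i) <- 1
      dev[i, ] <- drop(z_raw[i, ] %*% chol_or_stop(sig_i, "subject covariance"))
    }

    # planted regional group effects, in SD units of the deviation scale
    shift <- matrix(0, n_tot, config$n_regions)
    ge <- config$group_effects
    if (!is.null(ge) && nrow(ge) > 0) {
      for (k in seq_len(nrow(ge))) {
        r <- ge$region[k]
        j <- if (is.character(r)) match(r, labels) else as.integer(r)
        if (is.na(j) || j < 1 || j > config$n_regions) {
          stopf("group_effects row %d: unknown region '%s'", k, as.character(r))
        }
        shift[group == ge$group[k], j] <-
          shift[group == ge$group[k], j] + ge$shift[k]
      }
    }

    mu <- runif(config$n_regions, log(2000), log(15000))
    ce <- config$covariate_effects
    b_age <- rep_len(ce$age %||% 0, config$n_regions)
    b_sex <- rep_len(ce$sex %||% 0, config$n_regions)
    b_tiv <- rep_len(ce$tiv %||% 0, config$n_regions)
    logv <- matrix(mu, n_tot, config$n_regions, byrow = TRUE) +
      outer(age - mean(age), b_age) +
      outer(as.numeric(sex), b_sex) +
      outer((tiv - 1.45e6) / 1.2e5, b_tiv) +
      config$volume_cv * (dev + shift)
    volumes <- exp(logv)
  })

  colnames(volumes) <- labels
  cohort <- data.frame(
    subject_id = sprintf("%s_%02d", group, unlist(lapply(groups, function(g)
      seq_len(n)))),
    group = group,
    age = age,
    sex = sex,
    tiv = tiv,
    training_duration = training,
    strokes = strokes,
    stringsAsFactors = FALSE
  )
  cohort <- cbind(cohort, as.data.frame(volumes))
  class(cohort) <- c("cohort_table", "data.frame")
  attr(cohort, "region_labels") <- labels

  truth <- list(
    true_covariance = sigma,
    module = module,
    planted_effects = config$group_effects,
    true_indirect = if (is.null(config$mediation)) NA_real_ else
      config$mediation$a * config$mediation$b,
    tightness = tightness,
    zx = zx,
    region_labels = labels
  )
  list(cohort = cohort, truth = truth)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Simulate a bare three-variable mediation data set
#'
#' Generates standardized-scale triples from the linear chain
#' `M = a X + e1`, `Y = c_prime X + b M + e2` with `X ~ N(0, 1)` and error
#' variances chosen so each variable has unit population variance.
#' Used for calibration and coverage studies of [bootstrap_indirect()].
#'
#' @param n Sample size.
#' @param a,b,c_prime Standardized path coefficients.
#' @param seed Integer seed.
#' @return Data frame with columns `x`, `m`, `y`.
#' @export
simulate_mediation_data <- function(n, a, b, c_prime, seed = 1L) {
  with_seed(seed, {
    x <- rnorm(n)
    m <- a * x + sqrt(max(0, 1 - a^2)) * rnorm(n)
    resid_var <- max(0, 1 - (b^2 + c_prime^2 + 2 * a * b * c_prime))
    y <- c_prime * x + b * m + sqrt(resid_var) * rnorm(n)
    data.frame(x = x, m = m, y = y)
  })
}

#' Columns reserved for subject metadata in cohort CSV files
#' @return Character vector of the fixed demographic/behavioral prefix.
#' @export
cohort_reserved_columns <- function() {
  c("subject_id", "group", "age", "sex", "tiv", "training_duration", "strokes")
}

#' Write a cohort table to CSV
#'
#' One row per subject: the reserved metadata columns
#' ([cohort_reserved_columns()]) followed by one column per region.
#'
#' @param cohort A `cohort_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Write generator ground truth to JSON
#' @param truth The `truth` element returned by [generate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  out <- truth
  out$true_covariance <- unclass(out$true_covariance)
  attr(out$true_covariance, "module") <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", matrix = "rowmajor")
  invisible(path)
}
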