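# End-to-end orchestration: cohort -> individualized SCNs -> sparsity-grid
# metric AUCs -> permutation group comparison -> gated correlations ->
# bootstrap mediation, with reproducible on-disk outputs and a manifest.

#' Pipeline configuration
#'
#' @param input Either a [cohort_config()] (synthetic cohort) or a path to a
#'   cohort CSV (see [load_cohort_csv()]).
#' @param covariates Covariates regressed out of regional volumes.
#' @param grid A [sparsity_grid()].
#' @param transform ESD weight transform (see [individual_weight_matrix()]).
#' @param binarize_mode `"absolute"` or `"positive"` edge ranking.
#' @param metrics Metric curves to compute (default: the four global
#'   metrics plus nodal clustering/efficiency/degree/betweenness).
#' @param n_perm Permutations per group test.
#' @param n_boot Bootstrap samples for mediation.
#' @param fdr_family FDR family mode, see [compare_cohorts()].
#' @param validate_grid Whether to emit the per-K connectivity /
#'   small-world report (the sigma screen is the slow part; it uses
#'   `sigma_surrogates` rewired nulls per network).
#' @param sigma_surrogates Surrogates per small-world evaluation.
#' @param mediation_groups Subjects entering correlation and mediation
#'   stages (default experts + novices; controls have no stroke score).
#' @param seed Root seed; every stage draws a deterministic substream.
#' @param out_dir Output directory (`NULL` for in-memory only).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = cohort_config(),
                            covariates = c("age", "sex", "tiv"),
                            grid = sparsity_grid(),
                            transform = "exp",
                            binarize_mode = "absolute",
                            metrics = c("Cp", "Lp", "Eg", "Eloc",
                                        "nodal_Cp", "nodal_Eloc",
                                        "nodal_Eg", "nodal_Lp",
                                        "degree", "betweenness"),
                            n_perm = 5000,
                            n_boot = 5000,
                            fdr_family = "within",
                            validate_grid = FALSE,
                            sigma_surrogates = 10,
                            mediation_groups = c("expert", "novice"),
                            seed = 1L,
                            out_dir = NULL) {
  stopifnot(inherits(grid, "sparsity_grid"))
  if (n_perm < 1 || n_boot < 100) {
    stopf("n_perm must be >= 1 and n_boot >= 100")
  }
  structure(list(input = input, covariates = covariates, grid = grid,
                 transform = transform, binarize_mode = binarize_mode,
                 metrics = metrics, n_perm = n_perm, n_boot = n_boot,
                 fdr_family = fdr_family, validate_grid = validate_grid,
                 sigma_surrogates = sigma_surrogates,
                 mediation_groups = mediation_groups,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Load and validate a cohort CSV
#'
#' Expects the reserved metadata columns ([cohort_reserved_columns()])
#' followed by one numeric column per region. Group labels must be among
#' `expert`, `novice`, `control`. Volumes must be strictly positive with no
#' missing cells; `strokes` may be missing for controls only.
#'
#' @param path CSV file path.
#' @return A validated `cohort_table`.
#' @export
load_cohort_csv <- function(path) {
  if (!file.exists(path)) stopf("cohort file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  reserved <- cohort_reserved_columns()
  missing_cols <- setdiff(reserved, names(df))
  if (length(missing_cols) > 0) {
    stopf("cohort CSV is missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  regions <- setdiff(names(df), reserved)
  if (length(regions) < 2) stopf("cohort CSV has fewer than 2 region columns")
  bad_group <- setdiff(unique(df$group), c("expert", "novice", "control"))
  if (length(bad_group) > 0) {
    stopf("unknown group label(s) %s; accepted labels: expert, novice, control",
          paste(sprintf("'%s'", bad_group), collapse = ", "))
  }
  for (rc in regions) {
    v <- suppressWarnings(as.numeric(df[[rc]]))
    bad <- which(is.na(v) | v <= 0)
    if (length(bad) > 0) {
      stopf("non-numeric, missing, or non-positive volume at row %d, column '%s'",
            bad[1], rc)
    }
    df[[rc]] <- v
  }
  for (cc in c("age", "sex", "tiv", "training_duration")) {
    bad <- which(is.na(suppressWarnings(as.numeric(df[[cc]]))))
    if (length(bad) > 0) {
      stopf("missing or non-numeric covariate at row %d, column '%s'",
            bad[1], cc)
    }
  }
  bad_strokes <- which(is.na(df$strokes) & df$group != "control")
  if (length(bad_strokes) > 0) {
    stopf("missing strokes at row %d (only controls may lack a stroke score)",
          bad_strokes[1])
  }
  if (anyDuplicated(df$subject_id)) stopf("duplicate subject_id values")
  class(df) <- c("cohort_table", "data.frame")
  attr(df, "region_labels") <- regions
  df
}

pipeline_log <- function(fmt, ...) {
  message(sprintf("[iscn %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

# writes via `writer(path)` and returns the manifest-relative name
write_if <- function(dir, name, writer) {
  if (is.null(dir)) return(NULL)
  writer(file.path(dir, name))
  name
}

#' Run the full analysis pipeline
#'
#' Sequences cohort acquisition, individualized SCN construction, sparsity
#' grid metrics and AUC summarization, expert-vs-novice permutation
#' comparison with FDR and Cohen's d, normality-gated correlations of
#' metric AUCs with training duration and stroke performance, mediator
#' selection, and bootstrap mediation. All stage outputs are returned; when
#' `out_dir` is set they are also written to disk and inventoried (with
#' checksums) in a run manifest. Identical config + seed gives
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` with elements `cohort`, `truth`
#'   (synthetic input only), `scn` (group SCN, reference, individual SCNs),
#'   `curves`, `auc`, `grid_report` (optional), `comparison`,
#'   `correlations`, `mediators`, `mediation`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir <- config$out_dir
  if (!is.null(dir) && !dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  files <- character(0)

  # stage 1: cohort
  pipeline_log("stage cohort: acquiring input")
  truth <- NULL
  if (inherits(config$input, "cohort_config")) {
    cfg <- config$input
    cfg$seed <- stage_seed(config$seed, "cohort")
    gen <- generate_cohort(cfg)
    cohort <- gen$cohort
    truth <- gen$truth
    files <- c(files,
               write_if(dir, "cohort.csv",
                        function(p) write_cohort_csv(cohort, p)),
               write_if(dir, "ground_truth.json",
                        function(p) write_ground_truth_json(truth, p)))
  } else {
    cohort <- load_cohort_csv(config$input)
  }
  n_ctrl <- sum(cohort$group == "control")
  if (n_ctrl < length(config$covariates) + 2) {
    stopf("stage cohort: need >= %d control subjects, found %d",
          length(config$covariates) + 2, n_ctrl)
  }
  for (g in config$mediation_groups) {
    if (!any(cohort$group == g)) {
      stopf("stage cohort: comparison group '%s' is empty", g)
    }
  }

  # stage 2: individualized SCNs
  pipeline_log("stage scn: residualizing and individualizing (%d subjects)",
               nrow(cohort))
  scn <- build_individual_scns(cohort, covariates = config$covariates,
                               subjects = "golfers",
                               transform = config$transform)
  files <- c(files,
             write_if(dir, "group_scn.csv",
                      function(p) write_matrix_csv(scn$group_scn$matrix, p)))
  if (!is.null(dir)) {
    scn_dir <- file.path(dir, "individual_scn")
    dir.create(scn_dir, showWarnings = FALSE)
    for (id in names(scn$scns)) {
      files <- c(files, write_if(dir, file.path("individual_scn",
                                                paste0(id, ".csv")),
                                 function(p)
                                   write_matrix_csv(scn$scns[[id]]$matrix, p)))
    }
  }

  # stage 3: metric curves and AUC
  pipeline_log("stage metrics: %d networks x %d sparsity levels",
               length(scn$scns), length(config$grid$values))
  curves <- do.call(rbind, lapply(names(scn$scns), function(id) {
    metric_curves(scn$scns[[id]], config$grid, metrics = config$metrics,
                  mode = config$binarize_mode, subject_id = id)
  }))
  group_of <- stats::setNames(cohort$group, cohort$subject_id)
  curves$group <- unname(group_of[curves$subject_id])
  auc <- auc_table(curves, config$grid)
  auc$group <- unname(group_of[auc$subject_id])
  files <- c(files,
             write_if(dir, "metric_curves.csv", function(p)
               utils::write.csv(curves, p, row.names = FALSE)),
             write_if(dir, "metric_auc.csv", function(p)
               utils::write.csv(auc, p, row.names = FALSE)))

  grid_report <- NULL
  if (isTRUE(config$validate_grid)) {
    pipeline_log("stage metrics: validating sparsity grid")
    grid_report <- validate_sparsity_grid(
      lapply(scn$scns, `[[`, "matrix"), config$grid,
      n_random = config$sigma_surrogates,
      seed = stage_seed(config$seed, "smallworld"),
      mode = config$binarize_mode)
    files <- c(files, write_if(dir, "grid_report.csv", function(p)
      utils::write.csv(grid_report, p, row.names = FALSE)))
  }

  # stage 4: group comparison
  ga <- config$mediation_groups[1]
  gb <- config$mediation_groups[2]
  pipeline_log("stage compare: %s vs %s, %d permutations", ga, gb,
               config$n_perm)
  comparison <- compare_cohorts(auc[auc$group == ga, ],
                                auc[auc$group == gb, ],
                                n_perm = config$n_perm,
                                seed = stage_seed(config$seed, "compare"),
                                fdr_family = config$fdr_family)
  files <- c(files, write_if(dir, "comparison.csv", function(p)
    utils::write.csv(comparison, p, row.names = FALSE)))

  # stage 5: correlations of candidate metric AUCs with behavior
  pipeline_log("stage correlate: metric AUC vs training duration / strokes")
  golfers <- cohort[cohort$group %in% config$mediation_groups, ]
  auc_golf <- auc[auc$group %in% config$mediation_groups, ]
  candidates <- unique(data.frame(
    metric = comparison$metric,
    node = comparison$node,
    keep = is.na(comparison$node) | comparison$p_fdr < 0.05,
    stringsAsFactors = FALSE))
  candidates <- candidates[candidates$keep, c("metric", "node")]
  correlations <- NULL
  metric_auc_vectors <- list()
  for (i in seq_len(nrow(candidates))) {
    m <- candidates$metric[i]; nd <- candidates$node[i]
    sel <- auc_golf$metric == m &
      (if (is.na(nd)) is.na(auc_golf$node) else !is.na(auc_golf$node) &
         auc_golf$node == nd)
    sub <- auc_golf[sel, ]
    v <- stats::setNames(sub$auc, sub$subject_id)[golfers$subject_id]
    mid <- if (is.na(nd)) m else paste(m, nd, sep = ":")
    metric_auc_vectors[[mid]] <- v
    for (bv in c("training_duration", "strokes")) {
      correlations <- rbind(correlations,
                            gated_correlation(v, golfers[[bv]],
                                              label_x = mid, label_y = bv))
    }
  }
  files <- c(files, write_if(dir, "correlations.csv", function(p)
    utils::write.csv(correlations, p, row.names = FALSE)))

  # stage 6: mediation
  mediators <- select_mediators(comparison, correlations)
  mediator <- if (length(mediators) > 0) mediators[1] else "Cp"
  pipeline_log("stage mediate: mediator = %s (%d candidate(s))",
               mediator, length(mediators))
  med_m <- metric_auc_vectors[[mediator]]
  mediation <- NULL
  if (!is.null(med_m)) {
    mediation <- bootstrap_indirect(golfers$training_duration, med_m,
                                    golfers$strokes,
                                    n_boot = config$n_boot,
                                    seed = stage_seed(config$seed, "mediate"))
    files <- c(files,
               write_if(dir, "mediation.json", function(p)
                 write_mediation_result(mediation, json_path = p)),
               write_if(dir, "mediation.csv", function(p)
                 write_mediation_result(mediation, csv_path = p)))
  }

  # manifest
  manifest <- list(
    package_version = as.character(utils::packageVersion("iscn")),
    seed = config$seed,
    config = list(
      input = if (inherits(config$input, "cohort_config"))
        unclass(config$input) else config$input,
      covariates = config$covariates,
      grid = unclass(config$grid),
      transform = if (is.function(config$transform)) "custom"
      else config$transform,
      binarize_mode = config$binarize_mode,
      metrics = config$metrics, n_perm = config$n_perm,
      n_boot = config$n_boot, fdr_family = config$fdr_family,
      mediation_groups = config$mediation_groups
    ),
    n_subjects = nrow(cohort),
    n_regions = length(region_labels(cohort)),
    n_networks = length(scn$scns),
    n_curve_rows = nrow(curves),
    n_auc_rows = nrow(auc),
    n_comparisons = nrow(comparison),
    flagged_sparsity = if (is.null(grid_report)) numeric(0) else
      grid_report$k[grid_report$flagged],
    mediator = mediator,
    outputs = if (is.null(dir)) list() else {
      lapply(files, function(f) list(
        file = f, md5 = unname(tools::md5sum(file.path(dir, f)))))
    }
  )
  if (!is.null(dir)) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  structure(list(cohort = cohort, truth = truth, scn = scn, curves = curves,
                 auc = auc, grid_report = grid_report,
                 comparison = comparison, correlations = correlations,
                 mediators = mediators, mediation = mediation,
                 manifest = manifest),
            class = "pipeline_result")
}
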