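# End-to-end orchestration: simulate or load inputs, infer fluxomes,
# aggregate and filter subsystem activities, run PCA / z-scores /
# correlation analyses, estimate benchmark doses, and write a
# reproducible artifact bundle.

#' Assemble a pipeline configuration
#'
#' @param output_dir Directory for the artifact bundle (created).
#' @param model A [metabolic_network()] or path to an SBML file. `NULL`
#'   together with `simulate` generates a toy network.
#' @param expression An [expression_set()], or path to an expression table
#'   (then `metadata` must be a path/data frame). `NULL` with `simulate`
#'   generates expression data.
#' @param metadata Metadata table or path (when `expression` is a path).
#' @param simulate Optional list of simulation settings: `n_subsystems`,
#'   `reactions_per_subsystem`, `effects` (list of [effect_spec()]),
#'   `dose_grids`, `sexes`, `noise_cv`, and any [simulate_expression()]
#'   argument.
#' @param seed Integer seed for all randomness in the run.
#' @param flux A [flux_control()].
#' @param bmd A [bmd_options()].
#' @param k_top Subsystems kept per (chemical, sex) PCA (default 10).
#' @param k_top_controls Subsystems reported from the control-only PCA
#'   (default 15).
#' @param standardize_pca Standardize features before PCA (default TRUE).
#' @param exclude Subsystem exclusion list for [filter_subsystems()].
#' @param alpha Mann-Whitney significance threshold.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir, model = NULL, expression = NULL,
                            metadata = NULL, simulate = NULL, seed = 1,
                            flux = flux_control(), bmd = bmd_options(),
                            k_top = 10, k_top_controls = 15,
                            standardize_pca = TRUE,
                            exclude = nonmetabolic_subsystems,
                            alpha = 0.05) {
  if (is.character(model) && !file.exists(model)) {
    rlang::abort(paste0("model path does not exist: ", model))
  }
  if (is.character(expression) && !file.exists(expression)) {
    rlang::abort(paste0("expression path does not exist: ", expression))
  }
  structure(
    list(output_dir = output_dir, model = model, expression = expression,
         metadata = metadata, simulate = simulate, seed = seed,
         flux = flux, bmd = bmd, k_top = k_top,
         k_top_controls = k_top_controls,
         standardize_pca = standardize_pca, exclude = exclude,
         alpha = alpha),
    class = "pipeline_config"
  )
}

write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(paste0("pipeline stage '", name, "' failed: ",
                        conditionMessage(e)))
  })
}

#' Run the full flux-to-benchmark-dose pipeline
#'
#' Executes: input loading or simulation, per-sample maximum-entropy flux
#' inference, subsystem activity aggregation and filtering, per
#' (chemical, sex) PCA with top-feature extraction and set algebra,
#' z-scores and Mann-Whitney flags against pooled controls, dose-group
#' correlation maps, and the BMD screen with extrapolation filtering and a
#' summary matrix. All tables are written under the configured output
#' directory together with a machine-readable run log.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage result (`network`,
#'   `expression`, `cohort`, `activity`, `zscores`, `mw_flags`, `pca`,
#'   `altered_sets`, `correlations`, `bmd`, `bmd_summary`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(seed = config$seed,
              package_version = as.character(utils::packageVersion("fluxbmd")),
              settings = list(
                bmr_mult = config$bmd$bmr_mult,
                confidence = config$bmd$confidence,
                min_doses = config$bmd$min_doses,
                standardize_pca = config$standardize_pca,
                k_top = config$k_top, alpha = config$alpha,
                exclude = config$exclude))

  # --- inputs --------------------------------------------------------------
  sim <- config$simulate
  net <- run_stage("network", {
    if (inherits(config$model, "metabolic_network")) config$model
    else if (is.character(config$model)) load_network(config$model)
    else make_toy_network(
      n_subsystems = sim$n_subsystems %||% 4,
      reactions_per_subsystem = sim$reactions_per_subsystem %||% 5,
      seed = config$seed)
  })
  es <- run_stage("expression", {
    if (inherits(config$expression, "expression_set")) config$expression
    else if (is.character(config$expression)) {
      read_expression(config$expression, config$metadata)
    } else {
      design <- make_design(
        dose_grids = sim$dose_grids %||% default_dose_grids(),
        sexes = sim$sexes %||% c("male", "female"),
        n_control = sim$n_control %||% 10,
        n_per_dose = sim$n_per_dose %||% 5)
      simulate_expression(
        design, net, effects = sim$effects %||% list(),
        seed = config$seed, noise_cv = sim$noise_cv %||% 0.1,
        baseline_median = sim$baseline_median %||% 100,
        baseline_cv = sim$baseline_cv %||% 1)
    }
  })
  meta <- es$metadata

  # --- flux inference ------------------------------------------------------
  cohort <- run_stage("flux_inference",
                      infer_cohort(net, es, control = config$flux))
  write_tsv_file(cohort$manifest, file.path(out_dir, "flux_manifest.tsv"))
  flux_tbl <- tibble::as_tibble(cohort$fluxes, rownames = "reaction")
  write_tsv_file(flux_tbl, file.path(out_dir, "fluxomes.tsv"))

  # --- subsystem activities ------------------------------------------------
  activity <- run_stage("subsystem_activity", {
    a <- subsystem_activity(cohort)
    filter_subsystems(a, net, exclude = config$exclude)
  })
  write_tsv_file(activity, file.path(out_dir, "subsystem_activity.tsv"))
  jsonlite::write_json(attr(activity, "audit"),
                       file.path(out_dir, "filtered_subsystems.json"))
  log$filtered_subsystems <- attr(activity, "audit")$subsystem

  # --- group statistics ----------------------------------------------------
  summary_tbl <- run_stage("group_means", group_means(activity, meta))
  ztbl <- run_stage("z_scores", z_scores(summary_tbl))
  mw <- run_stage("mann_whitney",
                  mann_whitney_flags(activity, meta, alpha = config$alpha))
  write_tsv_file(summary_tbl, file.path(out_dir, "group_means.tsv"))
  write_tsv_file(ztbl, file.path(out_dir, "z_scores.tsv"))
  write_tsv_file(mw, file.path(out_dir, "mann_whitney.tsv"))

  # --- multivariate --------------------------------------------------------
  groups <- dplyr::distinct(meta, .data$chemical, .data$sex)
  pca_runs <- run_stage("pca", {
    purrr::pmap(groups, function(chemical, sex) {
      ids <- meta$sample_id[meta$chemical == chemical & meta$sex == sex]
      sub <- dplyr::filter(activity, .data$sample_id %in% ids)
      pca <- run_pca(sub, n_components = 2,
                     standardize = config$standardize_pca)
      list(chemical = chemical, sex = sex, pca = pca,
           top = top_features(pca, 1, config$k_top))
    })
  })
  top_lists <- list()
  for (run in pca_runs) {
    top_lists[[run$chemical]][[run$sex]] <- run$top$feature
  }
  sets <- run_stage("altered_sets", combine_sets(top_lists))
  jsonlite::write_json(
    list(per_chemical = sets$per_chemical, union = sets$union,
         intersections = sets$intersections),
    file.path(out_dir, "altered_sets.json"))
  for (run in pca_runs) {
    tag <- gsub("[^A-Za-z0-9]", "", paste0(run$chemical, "_", run$sex))
    write_tsv_file(run$pca$scores,
                   file.path(out_dir, paste0("pca_scores_", tag, ".tsv")))
    write_tsv_file(run$pca$loadings,
                   file.path(out_dir, paste0("pca_loadings_", tag, ".tsv")))
  }

  cors <- run_stage("correlation_map", correlation_map(summary_tbl))
  utils::write.csv(unclass(cors), file.path(out_dir, "correlation_map.csv"))

  # --- benchmark doses -----------------------------------------------------
  bmd_results <- run_stage("bmd",
                           bmd_screen(activity, meta, options = config$bmd))
  bmd_kept <- filter_extrapolated(bmd_results)
  summary_matrix <- report_table2_layout(bmd_kept)
  write_tsv_file(dplyr::select(bmd_results, -"doses_retained"),
                 file.path(out_dir, "bmd_full_results.tsv"))
  write_tsv_file(summary_matrix, file.path(out_dir, "bmd_summary.tsv"))

  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(network = net, expression = es, cohort = cohort,
                 activity = activity, summary = summary_tbl,
                 zscores = ztbl, mw_flags = mw, pca = pca_runs,
                 altered_sets = sets, correlations = cors,
                 bmd = bmd_results, bmd_kept = bmd_kept,
                 bmd_summary = summary_matrix, paths = out_dir))
}

#' Summary matrix of benchmark doses by subsystem, chemical and sex
#'
#' One row per subsystem, one column per (chemical, sex); cells hold the
#' BMD (mg/kg) of the selected viable model and are blank where no viable
#' model was found. Subsystems with a viable model in every chemical/sex
#' combination are marked in the `common` column.
#'
#' @param results Tibble from [bmd_screen()] (optionally after
#'   [filter_extrapolated()]).
#' @param digits Rounding for display (default 1).
#' @return Tibble in wide layout; empty input gives a tibble with headers
#'   only.
#' @export
report_table2_layout <- function(results, digits = 1) {
  if (!nrow(results)) {
    return(tibble::tibble(subsystem = character(0), common = character(0)))
  }
  cells <- results %>%
    dplyr::mutate(
      column = paste(.data$chemical, .data$sex, sep = " / "),
      cell = dplyr::if_else(.data$status == "viable" & !is.na(.data$bmd),
                            formatC(round(.data$bmd, digits),
                                    format = "fg"),
                            "")
    )
  n_cols <- dplyr::n_distinct(cells$column)
  wide <- cells %>%
    dplyr::select("subsystem", "column", "cell") %>%
    tidyr::pivot_wider(names_from = "column", values_from = "cell",
                       values_fill = "")
  common <- cells %>%
    dplyr::filter(.data$cell != "") %>%
    dplyr::count(.data$subsystem) %>%
    dplyr::filter(.data$n == n_cols) %>%
    dplyr::pull(.data$subsystem)
  wide$common <- ifelse(wide$subsystem %in% common, "*", "")
  dplyr::arrange(wide, .data$subsystem)
}
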