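# Subsystem-level flux statistics: per-sample activities, subsystem
# filtering, dose-group means, z-scores against controls, and
# Mann-Whitney significance flags.

#' Per-sample subsystem activities from a flux cohort
#'
#' For each subsystem the mean absolute net flux over its `r` reactions is
#' computed and then divided by the sample's total absolute flux, giving a
#' dimensionless activity that is invariant to uniform rescaling of the
#' fluxome.
#'
#' @param cohort A `flux_cohort` from [infer_cohort()], or a reactions x
#'   samples flux matrix (then `network` is required).
#' @param network Optional [metabolic_network()] when `cohort` is a matrix.
#' @param normalize Divide by the sample's total absolute flux (default
#'   `TRUE`; set `FALSE` for raw mean absolute fluxes).
#' @return Tibble with columns `subsystem`, `sample_id`, `activity`.
#' @export
subsystem_activity <- function(cohort, network = NULL, normalize = TRUE) {
  if (inherits(cohort, "flux_cohort")) {
    fluxes <- cohort$fluxes
    network <- cohort$network
  } else {
    fluxes <- as.matrix(cohort)
    stopifnot(!is.null(network))
  }
  if (is.null(dim(fluxes))) fluxes <- matrix(fluxes, ncol = 1)
  ss <- network$reactions$subsystem[match(rownames(fluxes),
                                          network$reactions$id)]
  absflux <- abs(fluxes)
  totals <- colSums(absflux)
  if (any(totals == 0)) {
    rlang::abort(paste0("degenerate (all-zero) fluxome in sample(s): ",
                        paste(colnames(fluxes)[totals == 0], collapse = ", ")))
  }
  sums <- rowsum(absflux, group = ss)
  counts <- table(ss)
  means <- sums / as.vector(counts[rownames(sums)])
  if (normalize) means <- sweep(means, 2, totals, "/")
  tibble::as_tibble(as.data.frame.table(means, stringsAsFactors = FALSE),
                    .name_repair = "minimal") %>%
    stats::setNames(c("subsystem", "sample_id", "activity")) %>%
    tibble::as_tibble()
}

#' Pivot a long activity table to a subsystem x sample matrix
#'
#' @param activity Tibble from [subsystem_activity()].
#' @return Numeric matrix, subsystems in rows, samples in columns.
#' @export
activity_matrix <- function(activity) {
  wide <- tidyr::pivot_wider(activity, names_from = "sample_id",
                             values_from = "activity")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$subsystem
  m
}

#' Default non-metabolic subsystem exclusion list
#'
#' Subsystem labels that hold bookkeeping rather than metabolic chemistry;
#' they are dropped by [filter_subsystems()] when their reactions are
#' associated with fewer than two genes.
#' @export
nonmetabolic_subsystems <- c("miscellaneous", "artificial reactions",
                             "pool reactions", "biomass", "exchange",
                             "isolated", "transport")

#' Filter uninformative subsystems from an activity table
#'
#' Drops (a) subsystems on the non-metabolic exclusion list whose reactions
#' are associated with fewer than two distinct genes (union over the
#' subsystem's GPR rules), and (b) subsystems whose activity does not vary
#' across samples (SD = 0). Matching against the exclusion list is
#' case-insensitive. The removals are recorded in the `"audit"` attribute.
#'
#' @param activity Tibble from [subsystem_activity()].
#' @param network The [metabolic_network()] supplying GPR rules.
#' @param exclude Exclusion list (default [nonmetabolic_subsystems]).
#' @param sd_tol Treat SD below this as zero.
#' @return Filtered activity tibble; attribute `audit` is a tibble
#'   (`subsystem`, `reason`) of removals.
#' @export
filter_subsystems <- function(activity, network,
                              exclude = nonmetabolic_subsystems,
                              sd_tol = 0) {
  genes_per_ss <- network$reactions %>%
    dplyr::group_by(.data$subsystem) %>%
    dplyr::summarise(
      n_genes = length(unique(unlist(lapply(.data$gpr, gpr_genes)))),
      .groups = "drop")

  stats_tbl <- activity %>%
    dplyr::group_by(.data$subsystem) %>%
    dplyr::summarise(sd = stats::sd(.data$activity), .groups = "drop") %>%
    dplyr::left_join(genes_per_ss, by = "subsystem") %>%
    dplyr::mutate(n_genes = dplyr::coalesce(.data$n_genes, 0L))

  listed <- tolower(stats_tbl$subsystem) %in% tolower(exclude)
  gene_poor <- stats_tbl$n_genes < 2
  constant <- !is.na(stats_tbl$sd) & stats_tbl$sd <= sd_tol

  drop_listed <- listed & gene_poor
  drop_const <- constant & !drop_listed
  audit <- dplyr::bind_rows(
    tibble::tibble(subsystem = stats_tbl$subsystem[drop_listed],
                   reason = "non-metabolic with < 2 associated genes"),
    tibble::tibble(subsystem = stats_tbl$subsystem[drop_const],
                   reason = "constant across samples (SD = 0)")
  )
  keep <- stats_tbl$subsystem[!(drop_listed | drop_const)]
  out <- dplyr::filter(activity, .data$subsystem %in% keep)
  attr(out, "audit") <- audit
  out
}

#' Dose-group means of subsystem activities
#'
#' @param activity Tibble from [subsystem_activity()].
#' @param metadata Sample metadata (`sample_id`, `sex`, `chemical`, `dose`).
#'   Controls (dose 0) are pooled per (chemical, sex).
#' @return Tibble with one row per (subsystem, chemical, sex, dose):
#'   `mean`, `sd` (`NA` for single-animal groups), `n`.
#' @export
group_means <- function(activity, metadata) {
  metadata <- tibble::as_tibble(metadata)
  if ("dose_mg_per_kg" %in% names(metadata) && !"dose" %in% names(metadata)) {
    metadata <- dplyr::rename(metadata, dose = "dose_mg_per_kg")
  }
  joined <- dplyr::inner_join(activity, metadata, by = "sample_id")
  joined %>%
    dplyr::group_by(.data$subsystem, .data$chemical, .data$sex, .data$dose) %>%
    dplyr::summarise(mean = mean(.data$activity),
                     sd = stats::sd(.data$activity),
                     n = dplyr::n(), .groups = "drop") %>%
    dplyr::arrange(.data$subsystem, .data$chemical, .data$sex, .data$dose)
}

#' Z-scores of dose-group activities against pooled controls
#'
#' For each (subsystem, chemical, sex), every nonzero dose group is scored
#' as `z = (mean_dose - mean_control) / sd_control`. Positive z means
#' higher activity than control. Groups whose control SD is zero are
#' flagged `NA` rather than dropped.
#'
#' @param summary Tibble from [group_means()].
#' @return Tibble with columns `subsystem`, `chemical`, `sex`, `dose`,
#'   `z`, `control_mean`, `control_sd`, `n`.
#' @export
z_scores <- function(summary) {
  controls <- summary %>%
    dplyr::filter(.data$dose == 0) %>%
    dplyr::select("subsystem", "chemical", "sex",
                  control_mean = "mean", control_sd = "sd")
  summary %>%
    dplyr::filter(.data$dose > 0) %>%
    dplyr::inner_join(controls, by = c("subsystem", "chemical", "sex")) %>%
    dplyr::mutate(
      z = dplyr::if_else(
        !is.na(.data$control_sd) & .data$control_sd > 0,
        (.data$mean - .data$control_mean) / .data$control_sd,
        NA_real_)
    ) %>%
    dplyr::select("subsystem", "chemical", "sex", "dose", "z",
                  "control_mean", "control_sd", "n")
}

#' Mann-Whitney comparison of dose groups against controls
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney U) test of each nonzero dose
#' group against the pooled controls of the same (subsystem, chemical,
#' sex). The exact null distribution is used for small groups (total n <=
#' 20, no ties), the normal approximation otherwise; all-tied degenerate
#' comparisons give p = 1.
#'
#' @param activity Tibble from [subsystem_activity()] (filtered or not).
#' @param metadata Sample metadata (`sample_id`, `sex`, `chemical`, `dose`).
#' @param alpha Significance threshold for the flag (default 0.05; no
#'   multiplicity correction, see `adjust`).
#' @param adjust Optional p-adjustment method passed to
#'   [stats::p.adjust()] (default `"none"`).
#' @return Tibble with `subsystem`, `chemical`, `sex`, `dose`, `p_value`,
#'   `significant`.
#' @export
mann_whitney_flags <- function(activity, metadata, alpha = 0.05,
                               adjust = "none") {
  metadata <- tibble::as_tibble(metadata)
  if ("dose_mg_per_kg" %in% names(metadata) && !"dose" %in% names(metadata)) {
    metadata <- dplyr::rename(metadata, dose = "dose_mg_per_kg")
  }
  joined <- dplyr::inner_join(activity, metadata, by = "sample_id")
  res <- joined %>%
    dplyr::filter(.data$dose > 0) %>%
    dplyr::group_by(.data$subsystem, .data$chemical, .data$sex, .data$dose) %>%
    dplyr::summarise(values = list(.data$activity), .groups = "drop")

  ctrl <- joined %>%
    dplyr::filter(.data$dose == 0) %>%
    dplyr::group_by(.data$subsystem, .data$chemical, .data$sex) %>%
    dplyr::summarise(ctrl_values = list(.data$activity), .groups = "drop")

  res <- dplyr::inner_join(res, ctrl, by = c("subsystem", "chemical", "sex"))
  res$p_value <- purrr::map2_dbl(res$values, res$ctrl_values, function(x, y) {
    if (length(unique(c(x, y))) == 1L) return(1)
    exact <- (length(x) + length(y)) <= 20
    suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided",
                         exact = exact, correct = !exact)$p.value)
  })
  res$p_value <- stats::p.adjust(res$p_value, method = adjust)
  res %>%
    dplyr::mutate(significant = .data$p_value < alpha) %>%
    dplyr::select("subsystem", "chemical", "sex", "dose", "p_value",
                  "significant") %>%
    dplyr::arrange(.data$subsystem, .data$chemical, .data$sex, .data$dose)
}
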