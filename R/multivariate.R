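# PCA over subsystem activities, top-loading extraction, set algebra
# across chemicals, and correlation maps between dose-group mean fluxomes.

#' Principal component analysis of subsystem activities
#'
#' Samples are rows, subsystems (features) are columns. Features are
#' centered and, by default, standardized to unit variance before the
#' decomposition. Component signs are fixed deterministically: each
#' loading vector's largest-magnitude entry is made positive.
#'
#' @param x Samples x features numeric matrix, data frame, or a long
#'   activity tibble from [subsystem_activity()] (pivoted internally).
#' @param n_components Number of components to retain (default 2).
#' @param standardize Scale features to unit variance (default `TRUE`).
#' @return A `flux_pca`: list with `scores` (tibble: `sample_id`, `PC1`,
#'   ...), `loadings` (tibble: `feature`, `PC1`, ...), and
#'   `explained_variance` (fraction per retained component).
#' @export
run_pca <- function(x, n_components = 2, standardize = TRUE) {
  if (is.data.frame(x) &&
      all(c("subsystem", "sample_id", "activity") %in% names(x))) {
    x <- t(activity_matrix(x))
  }
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) {
    rlang::abort("PCA needs at least 2 samples and 2 features")
  }
  sds <- apply(x, 2, stats::sd)
  if (standardize && any(sds == 0)) {
    rlang::abort(paste0("constant feature(s) cannot be standardized: ",
                        paste(colnames(x)[sds == 0], collapse = ", ")))
  }
  n_components <- min(n_components, ncol(x), nrow(x) - 1)
  fit <- stats::prcomp(x, center = TRUE, scale. = standardize)
  k <- seq_len(n_components)
  rot <- fit$rotation[, k, drop = FALSE]
  scores <- fit$x[, k, drop = FALSE]
  # deterministic sign: largest-|loading| entry positive per component
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  structure(
    list(
      scores = dplyr::bind_cols(
        tibble::tibble(sample_id = rownames(x) %||%
                         as.character(seq_len(nrow(x)))),
        tibble::as_tibble(scores)),
      loadings = dplyr::bind_cols(
        tibble::tibble(feature = colnames(x)),
        tibble::as_tibble(rot)),
      explained_variance = ev[k],
      center = fit$center, scale = if (standardize) fit$scale else NULL
    ),
    class = "flux_pca"
  )
}

#' @export
print.flux_pca <- function(x, ...) {
  cat("<flux_pca> ", nrow(x$scores), " samples, ",
      nrow(x$loadings), " features; variance explained: ",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.flux_pca <- function(x, ...) {
  tidyr::pivot_longer(x$loadings, -"feature", names_to = "component",
                      values_to = "loading")
}

#' @export
glance.flux_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_features = nrow(x$loadings),
    n_components = length(x$explained_variance),
    variance_pc1 = x$explained_variance[1],
    variance_total = sum(x$explained_variance)
  )
}

#' @export
autoplot.flux_pca <- function(object, metadata = NULL, colour = "dose",
                              shape = "sex", ...) {
  df <- object$scores
  if (!is.null(metadata)) {
    df <- dplyr::left_join(df, tibble::as_tibble(metadata), by = "sample_id")
  }
  aes <- ggplot2::aes(x = .data$PC1, y = .data$PC2)
  p <- ggplot2::ggplot(df, aes)
  args <- list()
  if (!is.null(metadata) && colour %in% names(df)) {
    args$colour <- rlang::sym(colour)
  }
  if (!is.null(metadata) && shape %in% names(df)) {
    args$shape <- rlang::sym(shape)
  }
  p <- p + ggplot2::geom_point(
    mapping = ggplot2::aes(!!!args), size = 2)
  p + ggplot2::labs(
    x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance[1]),
    y = sprintf("PC2 (%.1f%%)", 100 * object$explained_variance[2])
  )
}

#' Top-loading features of a principal component
#'
#' Features ranked by decreasing absolute loading on the chosen component;
#' ties are broken lexicographically by feature label for determinism.
#'
#' @param pca A `flux_pca` from [run_pca()].
#' @param component Component index (default 1).
#' @param k Number of features to return.
#' @return Tibble with `rank`, `feature`, `loading`.
#' @export
top_features <- function(pca, component = 1, k = 10) {
  stopifnot(inherits(pca, "flux_pca"))
  col <- paste0("PC", component)
  if (!col %in% names(pca$loadings)) {
    rlang::abort(paste0("component ", component, " not retained"))
  }
  n <- nrow(pca$loadings)
  if (k > n) {
    rlang::warn(sprintf("k = %d exceeds feature count %d; returning all",
                        k, n))
    k <- n
  }
  tbl <- tibble::tibble(feature = pca$loadings$feature,
                        loading = pca$loadings[[col]])
  tbl <- tbl[order(-abs(tbl$loading), tbl$feature), ]
  out <- utils::head(tbl, k)
  out$rank <- seq_len(nrow(out))
  dplyr::select(out, "rank", "feature", "loading")
}

#' Combine per-(chemical, sex) top subsystem lists into altered-set algebra
#'
#' Builds, for each chemical, the union of its male and female most-altered
#' subsystem lists; then the global union across chemicals and all
#' pairwise/triple (or higher) intersections.
#'
#' @param top_lists Named list: `top_lists[[chemical]][[sex]]` is a
#'   character vector of subsystem labels (any nesting whose first level is
#'   the chemical works; deeper levels are flattened).
#' @return An `altered_sets`: list with `per_chemical` (named list of
#'   character sets), `union` (character), `intersections` (named list per
#'   chemical pair and the all-chemicals intersection), and `counts`
#'   (tibble).
#' @export
combine_sets <- function(top_lists) {
  per_chem <- lapply(top_lists, function(x) {
    sort(unique(unlist(x, use.names = FALSE)))
  })
  chems <- names(per_chem)
  global_union <- sort(unique(unlist(per_chem)))
  inters <- list()
  if (length(chems) >= 2) {
    pairs <- utils::combn(chems, 2, simplify = FALSE)
    for (pr in pairs) {
      inters[[paste(pr, collapse = " & ")]] <-
        intersect(per_chem[[pr[1]]], per_chem[[pr[2]]])
    }
  }
  if (length(chems) >= 3) {
    inters[["all"]] <- Reduce(intersect, per_chem)
  } else if (length(chems) == 2) {
    inters[["all"]] <- inters[[1]]
  } else {
    inters[["all"]] <- per_chem[[1]]
  }
  counts <- tibble::tibble(
    set = c(chems, "union", names(inters)),
    size = c(vapply(per_chem, length, integer(1)), length(global_union),
             vapply(inters, length, integer(1)))
  )
  structure(list(per_chemical = per_chem, union = global_union,
                 intersections = inters, counts = counts),
            class = "altered_sets")
}

#' @export
print.altered_sets <- function(x, ...) {
  cat("<altered_sets> union of", length(x$union), "subsystems across",
      length(x$per_chemical), "chemicals;",
      length(x$intersections$all), "common to all\n")
  invisible(x)
}

#' Correlation map between dose-group mean activity vectors
#'
#' Pearson (or Spearman) correlation over the subsystem dimension between
#' every pair of (chemical, sex, dose) group mean vectors.
#'
#' @param summary Tibble from [group_means()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Symmetric correlation matrix with group labels
#'   (`chemical/sex/dose`) as dimnames; zero-variance groups give `NA`
#'   rows/columns and are listed in the `"degenerate"` attribute.
#' @export
correlation_map <- function(summary, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  wide <- summary %>%
    dplyr::mutate(group = paste(.data$chemical, .data$sex, .data$dose,
                                sep = "/")) %>%
    dplyr::select("subsystem", "group", "mean") %>%
    tidyr::pivot_wider(names_from = "group", values_from = "mean")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$subsystem
  if (ncol(m) < 2) rlang::abort("need at least 2 groups")
  if (nrow(m) < 3) rlang::abort("need at least 3 subsystems")
  sds <- apply(m, 2, stats::sd)
  degenerate <- colnames(m)[sds == 0]
  suppressWarnings(cmat <- stats::cor(m, method = method))
  diag(cmat) <- 1
  attr(cmat, "degenerate") <- degenerate
  cmat
}

#' Heatmap of a correlation map
#'
#' @param cmat Matrix from [correlation_map()].
#' @return A ggplot object.
#' @export
plot_correlation_map <- function(cmat) {
  df <- as.data.frame.table(unclass(cmat), stringsAsFactors = FALSE)
  names(df) <- c("group1", "group2", "correlation")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group1, y = .data$group2,
                                   fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Heatmap of subsystem z-scores by dose group
#'
#' @param zscores Tibble from [z_scores()].
#' @return A ggplot object (doses on the x axis, subsystems on the y axis,
#'   faceted by chemical and sex).
#' @export
plot_zscore_heatmap <- function(zscores) {
  ggplot2::ggplot(zscores,
                  ggplot2::aes(x = factor(.data$dose), y = .data$subsystem,
                               fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "white",
                                  high = "red") +
    ggplot2::facet_grid(~ .data$chemical + .data$sex) +
    ggplot2::labs(x = "dose (mg/kg)", y = NULL, fill = "z")
}
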