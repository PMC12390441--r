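#' Construct an expression set (gene x sample matrix plus sample metadata)
#'
#' @param values Numeric matrix, genes in rows (ENTREZ-style ids as
#'   rownames), samples in columns.
#' @param metadata Data frame with one row per sample: `sample_id`, `sex`
#'   (`"male"`/`"female"`), `chemical`, `dose` (mg/kg; 0 for controls). A
#'   `dose_mg_per_kg` column is accepted and renamed.
#' @param scale Either `"log2"` or `"linear"` — the scale of `values`.
#' @return An object of class `expression_set`.
#' @export
expression_set <- function(values, metadata, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values))) rlang::abort("values must have gene rownames")
  if (anyDuplicated(rownames(values))) {
    rlang::abort(paste0("duplicated gene ids: ",
                        paste(unique(rownames(values)[duplicated(rownames(values))]),
                              collapse = ", ")))
  }
  if (!is.numeric(values)) rlang::abort("expression values must be numeric")
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    rlang::abort(sprintf("non-finite expression value at gene %s, sample %s",
                         rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  if (scale == "linear" && any(values < 0)) {
    rlang::abort("linear-scale expression must be nonnegative")
  }
  metadata <- tibble::as_tibble(metadata)
  if ("dose_mg_per_kg" %in% names(metadata) && !"dose" %in% names(metadata)) {
    metadata <- dplyr::rename(metadata, dose = "dose_mg_per_kg")
  }
  need <- c("sample_id", "sex", "chemical", "dose")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) {
    rlang::abort(paste0("metadata lacks columns: ", paste(miss, collapse = ", ")))
  }
  absent <- setdiff(colnames(values), metadata$sample_id)
  if (length(absent)) {
    rlang::abort(paste0("samples missing from metadata: ",
                        paste(absent, collapse = ", ")))
  }
  if (anyNA(metadata[need])) rlang::abort("metadata has missing entries")
  metadata <- metadata[match(colnames(values), metadata$sample_id), ]
  metadata$is_control <- metadata$dose == 0
  structure(list(values = values, metadata = metadata, scale = scale),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat("<expression_set> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", x$scale, " scale)\n", sep = "")
  invisible(x)
}

#' Read a gene x sample expression table with sample metadata
#'
#' @param path Delimited text file (tab or comma): first column gene ids,
#'   header row sample ids.
#' @param metadata Data frame or path to a delimited table with columns
#'   `sample_id`, `sex`, `chemical`, `dose` (or `dose_mg_per_kg`).
#' @param scale Scale of the stored values (`"log2"`, the TempO-Seq-style
#'   default, or `"linear"`).
#' @return An [expression_set()].
#' @export
read_expression <- function(path, metadata, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.delim(path, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
  genes <- as.character(tab[[1]])
  mat <- tab[, -1, drop = FALSE]
  for (j in seq_along(mat)) {
    col <- mat[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      if (anyNA(num)) {
        i <- which(is.na(num))[1]
        rlang::abort(sprintf(
          "non-numeric expression value '%s' at gene %s, sample %s",
          col[i], genes[i], names(mat)[j]))
      }
      mat[[j]] <- num
    }
  }
  values <- as.matrix(mat)
  rownames(values) <- genes
  if (is.character(metadata)) {
    msep <- if (grepl("\\.csv$", metadata, ignore.case = TRUE)) "," else "\t"
    metadata <- utils::read.delim(metadata, sep = msep,
                                  stringsAsFactors = FALSE)
  }
  expression_set(values, metadata, scale = scale)
}

#' Invert a log2 transform
#'
#' @param x Numeric vector/matrix on the log2 scale.
#' @return `2^x` (elementwise).
#' @export
delog2 <- function(x) 2^x

#' Expression values on the linear (count) scale
#'
#' @param es An [expression_set()].
#' @return Numeric matrix with all values on the linear scale.
#' @export
linear_values <- function(es) {
  stopifnot(inherits(es, "expression_set"))
  if (es$scale == "log2") delog2(es$values) else es$values
}

#' Map gene expression onto reactions through GPR rules
#'
#' Evaluates each reaction's GPR against one sample's linear-scale gene
#' expression (AND = min over complex members, OR = sum over isozymes).
#' Both halves of a split reversible reaction receive the same value.
#' Reactions with no GPR, or whose genes are all unmeasured, receive the
#' sample mean of the measured genes so that the reference distribution of
#' the flux objective stays strictly positive; the affected reactions are
#' recorded in the `"filled"` attribute.
#'
#' @param irr An `irreversible_network` from [split_reversible()].
#' @param gene_values Named numeric vector of linear-scale expression.
#' @return Named nonnegative numeric vector over `irr$reactions$id`, with
#'   attribute `filled` (base reaction ids that received the mean).
#' @export
reaction_expression <- function(irr, gene_values) {
  stopifnot(inherits(irr, "irreversible_network"))
  if (any(gene_values < 0, na.rm = TRUE)) {
    rlang::abort("gene expression must be on the linear (nonnegative) scale")
  }
  base_rx <- irr$base$reactions
  fill_value <- mean(gene_values, na.rm = TRUE)
  g_base <- vapply(seq_len(nrow(base_rx)), function(i) {
    eval_gpr(base_rx$gpr[i], gene_values, context = base_rx$id[i])
  }, numeric(1))
  filled <- base_rx$id[is.na(g_base)]
  g_base[is.na(g_base)] <- fill_value
  g <- g_base[irr$reactions$base_index]
  names(g) <- irr$reactions$id
  attr(g, "filled") <- filled
  g
}
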