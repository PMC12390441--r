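#' Construct a metabolic network object
#'
#' A `metabolic_network` bundles the stoichiometric matrix of a genome-scale
#' metabolic model (GEM) with per-reaction bounds, gene-protein-reaction
#' (GPR) rules and pathway annotations. It is the common input of flux
#' inference and subsystem aggregation.
#'
#' @param reactions A data frame with one row per reaction and columns
#'   `id`, `lower_bound`, `upper_bound` (mmol/gDW/h), `gpr` (boolean gene
#'   expression string, `""` if none), `subsystem`, `major_pathway`, and
#'   `is_exchange`. Missing annotation columns are filled with defaults
#'   (`subsystem = "miscellaneous"`, `major_pathway = NA`).
#' @param metabolites A data frame with columns `id` and optionally
#'   `compartment`.
#' @param stoichiometry A numeric matrix or `Matrix::sparseMatrix` of shape
#'   metabolites x reactions; dimnames must match the `id` columns.
#' @param genes Optional character vector of gene identifiers; defaults to
#'   the union of genes referenced by the GPR rules.
#'
#' @return An object of class `metabolic_network`: a list with elements
#'   `reactions` (tibble), `metabolites` (tibble), `stoichiometry`
#'   (`dgCMatrix`), and `genes` (character).
#' @export
metabolic_network <- function(reactions, metabolites, stoichiometry,
                              genes = NULL) {
  reactions <- tibble::as_tibble(reactions)
  metabolites <- tibble::as_tibble(metabolites)
  if (!"gpr" %in% names(reactions)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (!"subsystem" %in% names(reactions)) reactions$subsystem <- NA_character_
  missing_ss <- is.na(reactions$subsystem) | reactions$subsystem == ""
  if (any(missing_ss)) {
    rlang::warn(paste0(
      sum(missing_ss), " reaction(s) lack a subsystem annotation; ",
      "labelled 'miscellaneous'"
    ))
    reactions$subsystem[missing_ss] <- "miscellaneous"
  }
  if (!"major_pathway" %in% names(reactions)) {
    reactions$major_pathway <- NA_character_
  }
  if (!"is_exchange" %in% names(reactions)) {
    reactions$is_exchange <- detect_exchanges(stoichiometry)
  }
  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  S <- methods::as(methods::as(Matrix::Matrix(stoichiometry, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  dimnames(S) <- list(metabolites$id, reactions$id)
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(reactions$gpr, gpr_genes))))
  }
  net <- structure(
    list(reactions = reactions, metabolites = metabolites,
         stoichiometry = S, genes = genes),
    class = "metabolic_network"
  )
  validate_network(net)
  net
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", nrow(x$reactions), " reactions, ",
      nrow(x$metabolites), " metabolites, ", length(x$genes), " genes\n",
      sep = "")
  cat("  subsystems: ", length(unique(x$reactions$subsystem)), "\n", sep = "")
  invisible(x)
}

validate_network <- function(net) {
  S <- net$stoichiometry
  rx <- net$reactions
  if (nrow(rx) == 0L) rlang::abort("network has no reactions")
  if (nrow(S) != nrow(net$metabolites) || ncol(S) != nrow(rx)) {
    rlang::abort("stoichiometry shape does not match metabolite/reaction lists")
  }
  if (anyDuplicated(rx$id)) rlang::abort("duplicate reaction ids")
  if (anyDuplicated(net$metabolites$id)) rlang::abort("duplicate metabolite ids")
  bad <- which(is.na(rx$lower_bound) | is.na(rx$upper_bound))
  if (length(bad)) {
    rlang::abort(paste0("reactions with missing bounds: ",
                        paste(rx$id[bad], collapse = ", ")))
  }
  bad <- which(rx$lower_bound > rx$upper_bound)
  if (length(bad)) {
    rlang::abort(paste0("lower bound exceeds upper bound for: ",
                        paste(rx$id[bad], collapse = ", ")))
  }
  gpr_gene_set <- unique(unlist(lapply(rx$gpr, gpr_genes)))
  missing_genes <- setdiff(gpr_gene_set, net$genes)
  if (length(missing_genes)) {
    rlang::abort(paste0("GPR rules reference genes absent from gene set: ",
                        paste(utils::head(missing_genes, 5), collapse = ", ")))
  }
  invisible(net)
}

#' Detect exchange (boundary) reactions from the stoichiometric matrix
#'
#' A reaction is an exchange when its metabolites appear on only one side of
#' the equation, i.e. all nonzero stoichiometric coefficients share a sign.
#' Such reactions move a metabolite between the model and its environment.
#'
#' @param S Stoichiometric matrix (metabolites x reactions).
#' @return Logical vector, one entry per reaction column.
#' @keywords internal
detect_exchanges <- function(S) {
  S <- Matrix::Matrix(S, sparse = TRUE)
  apply_cols <- function(j) {
    x <- S[, j]
    x <- x[x != 0]
    length(x) > 0 && (all(x > 0) || all(x < 0))
  }
  vapply(seq_len(ncol(S)), apply_cols, logical(1))
}

#' Summarize a metabolic network
#'
#' Counts reactions, metabolites, genes, and the distinct subsystem and
#' major-pathway labels of a loaded network.
#'
#' @param net A [metabolic_network()].
#' @return A one-row tibble with columns `n_reactions`, `n_metabolites`,
#'   `n_genes`, `n_subsystems`, `n_major_pathways`.
#' @export
summarize_network <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  if (nrow(net$reactions) == 0L) rlang::abort("empty network")
  mp <- net$reactions$major_pathway
  mp <- mp[!is.na(mp) & mp != ""]
  tibble::tibble(
    n_reactions = nrow(net$reactions),
    n_metabolites = nrow(net$metabolites),
    n_genes = length(net$genes),
    n_subsystems = length(unique(net$reactions$subsystem)),
    n_major_pathways = length(unique(mp))
  )
}

#' Reset exchange-reaction bounds to the default open state
#'
#' Sets the bounds of every exchange reaction to \[-1000, 1000\]
#' mmol/gDW/h, the conventional unconstrained default for boundary
#' reactions, leaving internal reaction bounds untouched.
#'
#' @param net A [metabolic_network()].
#' @param bound Magnitude of the default bound (1000 mmol/gDW/h).
#' @return The network with updated exchange bounds.
#' @export
apply_exchange_defaults <- function(net, bound = 1000) {
  stopifnot(inherits(net, "metabolic_network"))
  ex <- net$reactions$is_exchange
  net$reactions$lower_bound[ex] <- -bound
  net$reactions$upper_bound[ex] <- bound
  net
}

#' Attach major-pathway labels from a sidecar mapping table
#'
#' Model files often carry subsystem labels but not the coarser
#' major-pathway grouping (e.g. "amino acid metabolism"). This joins a
#' two-column mapping (subsystem, major_pathway) onto the reaction table.
#'
#' @param net A [metabolic_network()].
#' @param mapping Data frame with columns `subsystem` and `major_pathway`,
#'   or a path to a tab-delimited file with those columns.
#' @return The network with `major_pathway` filled where the mapping matches.
#' @export
apply_pathway_map <- function(net, mapping) {
  if (is.character(mapping)) {
    mapping <- utils::read.delim(mapping, stringsAsFactors = FALSE)
  }
  mapping <- tibble::as_tibble(mapping)
  stopifnot(all(c("subsystem", "major_pathway") %in% names(mapping)))
  idx <- match(net$reactions$subsystem, mapping$subsystem)
  hit <- !is.na(idx)
  net$reactions$major_pathway[hit] <- mapping$major_pathway[idx[hit]]
  net
}

#' Split reversible reactions into irreversible forward/backward pairs
#'
#' The maximum-entropy flux objective treats fluxes as an (unnormalized)
#' probability distribution, which requires all fluxes to be nonnegative.
#' Every reversible reaction (lower bound < 0) is split into a forward
#' reaction with bounds \[0, max(UB, 0)\] and a backward reaction (negated
#' stoichiometric column) with bounds \[0, max(-LB, 0)\]; irreversible
#' reactions are kept as-is.
#'
#' @param net A [metabolic_network()].
#' @return An `irreversible_network`: list with `reactions` (tibble with
#'   `id`, `base_id`, `direction`, `lower_bound`, `upper_bound`,
#'   `subsystem`), `stoichiometry`, and `base` (the input network).
#' @export
split_reversible <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  rx <- net$reactions
  S <- net$stoichiometry
  rev_idx <- which(rx$lower_bound < 0)
  n <- nrow(rx)

  fwd <- tibble::tibble(
    id = rx$id,
    base_id = rx$id,
    direction = "forward",
    lower_bound = pmax(rx$lower_bound, 0),
    upper_bound = pmax(rx$upper_bound, 0),
    gpr = rx$gpr,
    subsystem = rx$subsystem,
    is_exchange = rx$is_exchange,
    base_index = seq_len(n)
  )
  cols <- list(S)
  if (length(rev_idx)) {
    bwd <- tibble::tibble(
      id = paste0(rx$id[rev_idx], "__rev"),
      base_id = rx$id[rev_idx],
      direction = "backward",
      lower_bound = 0,
      upper_bound = pmax(-rx$lower_bound[rev_idx], 0),
      gpr = rx$gpr[rev_idx],
      subsystem = rx$subsystem[rev_idx],
      is_exchange = rx$is_exchange[rev_idx],
      base_index = rev_idx
    )
    cols <- list(S, -S[, rev_idx, drop = FALSE])
    reactions <- dplyr::bind_rows(fwd, bwd)
  } else {
    reactions <- fwd
  }
  S_irr <- do.call(cbind, cols)
  colnames(S_irr) <- reactions$id
  structure(
    list(reactions = reactions, stoichiometry = S_irr, base = net),
    class = "irreversible_network"
  )
}

#' @export
print.irreversible_network <- function(x, ...) {
  cat("<irreversible_network> ", nrow(x$reactions),
      " nonnegative reactions (from ", nrow(x$base$reactions),
      " base reactions)\n", sep = "")
  invisible(x)
}

#' Recombine irreversible fluxes into net base-network fluxes
#'
#' @param irr An `irreversible_network` from [split_reversible()].
#' @param v Nonnegative flux vector on the irreversible network (ordered as
#'   `irr$reactions`).
#' @return Named numeric vector of net fluxes (forward - backward) on the
#'   base network, in base reaction order.
#' @export
recombine_fluxes <- function(irr, v) {
  stopifnot(inherits(irr, "irreversible_network"),
            length(v) == nrow(irr$reactions))
  base_ids <- irr$base$reactions$id
  out <- numeric(length(base_ids))
  names(out) <- base_ids
  sgn <- ifelse(irr$reactions$direction == "forward", 1, -1)
  contrib <- tapply(v * sgn, irr$reactions$base_index, sum)
  out[as.integer(names(contrib))] <- as.numeric(contrib)
  out
}
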