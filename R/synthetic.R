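# Synthetic study generator: toy genome-scale networks with subsystems and
# GPR rules, multi-chemical dose-response study designs, dose-responsive
# log2 expression tables with known gene-level effects, and a ground-truth
# benchmark-dose oracle computed on noiseless expression curves.

with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

#' Default dose grids of the three-chemical study design
#'
#' Dose levels (mg/kg) for the fluorotelomer alcohols 6:1 FTOH and
#' 10:2 FTOH and the sulfonamide PFHxSAm.
#' @return Named list of numeric dose vectors (each includes 0).
#' @export
default_dose_grids <- function() {
  list(
    "6:1 FTOH" = c(0, 0.15, 0.50, 1.40, 4, 12, 37, 111, 333, 1000),
    "10:2 FTOH" = c(0, 0.07, 0.20, 0.70, 2, 6, 18, 55, 160, 475),
    "PFHxSAm" = c(0, 0.15, 0.50, 1.40, 4, 12, 37, 111, 333, 1000)
  )
}

#' Enumerate the samples of a dose-response study design
#'
#' Per chemical and sex: `n_control` control animals at dose 0 and
#' `n_per_dose` animals at every nonzero dose of the chemical's grid.
#'
#' @param dose_grids Named list of dose vectors (default the
#'   three-chemical grids of [default_dose_grids()]).
#' @param sexes Character vector of sexes (default male and female).
#' @param n_control Control-group size per chemical and sex (default 10).
#' @param n_per_dose Group size at each nonzero dose (default 5).
#' @return Tibble with `sample_id`, `sex`, `chemical`, `dose`, `animal`.
#' @export
make_design <- function(dose_grids = default_dose_grids(),
                        sexes = c("male", "female"),
                        n_control = 10, n_per_dose = 5) {
  stopifnot(n_control >= 1, n_per_dose >= 1, length(dose_grids) >= 1)
  if (is.null(names(dose_grids))) {
    names(dose_grids) <- paste0("chemical_", seq_along(dose_grids))
  }
  rows <- purrr::imap(dose_grids, function(grid, chem) {
    if (anyDuplicated(grid)) {
      rlang::abort(paste0("duplicate dose levels for ", chem))
    }
    if (!0 %in% grid) rlang::abort(paste0("dose grid for ", chem,
                                          " lacks a 0 (control) level"))
    grid <- sort(grid)
    purrr::map(sexes, function(sx) {
      tibble::tibble(
        sex = sx, chemical = chem,
        dose = rep(grid, times = c(n_control,
                                   rep(n_per_dose, length(grid) - 1L))),
      ) %>%
        dplyr::group_by(.data$dose) %>%
        dplyr::mutate(animal = dplyr::row_number()) %>%
        dplyr::ungroup()
    }) %>% dplyr::bind_rows()
  })
  design <- dplyr::bind_rows(rows)
  chem_code <- gsub("[^A-Za-z0-9]", "", design$chemical)
  design$sample_id <- sprintf("%s_%s_d%s_a%02d", chem_code,
                              substr(design$sex, 1, 1),
                              formatC(design$dose, format = "fg", width = 1),
                              design$animal)
  design$sample_id <- gsub("[^A-Za-z0-9_.]", "_", design$sample_id)
  if (anyDuplicated(design$sample_id)) {
    rlang::abort("internal error: non-unique sample ids")
  }
  dplyr::select(design, "sample_id", "sex", "chemical", "dose", "animal")
}

#' Generate a toy genome-scale metabolic network
#'
#' Builds a connected network with one shared uptake route (an exchange
#' plus a transport reaction feeding a hub metabolite) and one linear
#' pathway per subsystem branching off the hub. Each subsystem contains a
#' branch point (two parallel routes between its first two chain
#' metabolites) and ends in a secretion exchange. Every internal reaction
#' carries a GPR rule over 1-3 subsystem-specific genes; exchange
#' reactions carry none. Output is deterministic per seed and can be
#' serialized with [write_sbml()].
#'
#' @param n_subsystems Number of metabolic subsystems (>= 2).
#' @param reactions_per_subsystem Internal reactions per subsystem (>= 3).
#' @param seed Integer seed controlling GPR structure.
#' @return A [metabolic_network()].
#' @export
make_toy_network <- function(n_subsystems = 4, reactions_per_subsystem = 5,
                             seed = 1) {
  if (n_subsystems < 2) rlang::abort("need at least 2 subsystems")
  k <- reactions_per_subsystem
  if (k < 3) rlang::abort("need at least 3 reactions per subsystem")
  with_seed(seed, {
    mets <- tibble::tibble(id = c("X_e", "X_c"),
                           compartment = c("e", "c"))
    rx <- list()
    trip <- list()
    gene_counter <- 0L
    new_genes <- function(n) {
      ids <- as.character(10000L + gene_counter + seq_len(n))
      gene_counter <<- gene_counter + n
      ids
    }
    random_gpr <- function() {
      n_g <- sample(1:3, 1)
      g <- new_genes(n_g)
      if (n_g == 1) return(g)
      if (n_g == 2) {
        return(paste(g[1], sample(c("and", "or"), 1), g[2]))
      }
      if (stats::runif(1) < 0.5) {
        sprintf("(%s and %s) or %s", g[1], g[2], g[3])
      } else {
        sprintf("%s or %s or %s", g[1], g[2], g[3])
      }
    }
    add_rxn <- function(id, from, to, lb, ub, gpr, subsystem, major) {
      rx[[length(rx) + 1L]] <<- tibble::tibble(
        id = id, lower_bound = lb, upper_bound = ub, gpr = gpr,
        subsystem = subsystem, major_pathway = major)
      for (m in from) trip[[length(trip) + 1L]] <<- c(m, id, -1)
      for (m in to) trip[[length(trip) + 1L]] <<- c(m, id, +1)
    }

    add_rxn("EX_substrate", character(0), "X_e", -1000, 1000, "",
            "exchange", "boundary")
    add_rxn("T_uptake", "X_e", "X_c", 0, 1000, new_genes(1),
            "transport", "boundary")

    ss_names <- sprintf("subsystem_%s", LETTERS[seq_len(n_subsystems)])
    for (i in seq_len(n_subsystems)) {
      ss <- ss_names[i]
      major <- sprintf("major_pathway_%02d", ceiling(i / 2))
      chain <- sprintf("A_%s_%d", LETTERS[i], seq_len(k - 1))
      mets <- dplyr::bind_rows(
        mets, tibble::tibble(id = chain, compartment = "c"))
      add_rxn(sprintf("R_%s_1", LETTERS[i]), "X_c", chain[1],
              0, 1000, random_gpr(), ss, major)
      # branch point: two parallel routes between the first two chain mets
      add_rxn(sprintf("R_%s_2", LETTERS[i]), chain[1], chain[2],
              0, 1000, random_gpr(), ss, major)
      add_rxn(sprintf("R_%s_3", LETTERS[i]), chain[1], chain[2],
              -1000, 1000, random_gpr(), ss, major)
      for (j in seq_len(k - 3)) {
        add_rxn(sprintf("R_%s_%d", LETTERS[i], j + 3),
                chain[j + 1], chain[j + 2],
                0, 1000, random_gpr(), ss, major)
      }
      add_rxn(sprintf("EX_%s", LETTERS[i]), chain[k - 1], character(0),
              -1000, 1000, "", "exchange", "boundary")
    }

    reactions <- dplyr::bind_rows(rx)
    tm <- do.call(rbind, trip)
    S <- Matrix::sparseMatrix(
      i = match(tm[, 1], mets$id),
      j = match(tm[, 2], reactions$id),
      x = as.numeric(tm[, 3]),
      dims = c(nrow(mets), nrow(reactions)))
    metabolic_network(reactions, mets, S)
  })
}

#' Specify a dose-dependent gene-expression effect
#'
#' Affected genes are scaled by a saturating multiplier
#' `m(d) = 1 + (e_max - 1) d^h / (d50^h + d^h)` (reciprocal for
#' down-effects), so expression moves smoothly from baseline at dose 0 to
#' `e_max`-fold at saturation.
#'
#' @param subsystem Target subsystem label (its genes are affected when
#'   `genes` is `NULL`).
#' @param genes Optional explicit gene-id set.
#' @param direction `+1` (up) or `-1` (down).
#' @param e_max Maximal fold change (> 1 for a non-null effect; 1 = null).
#' @param d50 Dose of half-maximal effect (mg/kg).
#' @param h Shape (steepness) exponent.
#' @return List of class `effect_spec`.
#' @export
effect_spec <- function(subsystem, genes = NULL, direction = 1,
                        e_max = 3, d50 = 50, h = 1.5) {
  stopifnot(e_max >= 1, d50 > 0, h > 0, direction %in% c(-1, 1))
  structure(list(subsystem = subsystem, genes = genes,
                 direction = direction, e_max = e_max, d50 = d50, h = h),
            class = "effect_spec")
}

effect_multiplier <- function(effect, dose) {
  m <- 1 + (effect$e_max - 1) * dose^effect$h /
    (effect$d50^effect$h + dose^effect$h)
  if (effect$direction < 0) 1 / m else m
}

subsystem_genes <- function(net, subsystem) {
  sel <- net$reactions$subsystem == subsystem
  sort(unique(unlist(lapply(net$reactions$gpr[sel], gpr_genes))))
}

#' Draw per-gene baseline expression levels
#'
#' Log-normal across genes: `median = baseline_median`, coefficient of
#' variation `baseline_cv`.
#'
#' @param net A [metabolic_network()] (baselines drawn for its genes).
#' @param seed Integer seed.
#' @param baseline_median Median linear-scale expression (counts).
#' @param baseline_cv Between-gene coefficient of variation.
#' @return Named numeric vector of linear-scale baselines.
#' @export
draw_baselines <- function(net, seed, baseline_median = 100,
                           baseline_cv = 1) {
  sdlog <- sqrt(log(1 + baseline_cv^2))
  with_seed(seed, {
    stats::setNames(
      stats::rlnorm(length(net$genes), meanlog = log(baseline_median),
                    sdlog = sdlog),
      net$genes)
  })
}

# Noiseless expected linear-scale expression at one dose.
expected_expression <- function(net, baselines, effects, dose) {
  vals <- baselines
  for (eff in effects) {
    genes <- eff$genes %||% subsystem_genes(net, eff$subsystem)
    genes <- intersect(genes, names(vals))
    vals[genes] <- vals[genes] * effect_multiplier(eff, dose)
  }
  vals
}

#' Simulate a dose-responsive log2 expression table
#'
#' Per animal, each gene's value is `baseline * m(dose) * noise` where the
#' multiplier `m` follows the [effect_spec()] saturating form (1 for
#' controls and unaffected genes) and the animal noise is log-normal with
#' mean 1 and coefficient of variation `noise_cv`. Values are emitted on
#' the log2 scale; output is bit-reproducible per seed.
#'
#' @param design Study design tibble from [make_design()].
#' @param net The [metabolic_network()] whose genes are measured.
#' @param effects List of [effect_spec()]s (possibly empty for a null
#'   study). Effects may be restricted to one chemical by adding a
#'   `chemical` element to the effect specification.
#' @param seed Integer seed.
#' @param noise_cv Animal-to-animal coefficient of variation (default 0.1).
#' @param baseline_median,baseline_cv Passed to [draw_baselines()].
#' @param baselines Optional precomputed baselines (overrides the draw).
#' @return An [expression_set()] on the log2 scale.
#' @export
simulate_expression <- function(design, net, effects = list(), seed = 1,
                                noise_cv = 0.1, baseline_median = 100,
                                baseline_cv = 1, baselines = NULL) {
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  if (is.null(baselines)) {
    baselines <- draw_baselines(net, seed, baseline_median, baseline_cv)
  }
  sdlog <- sqrt(log(1 + noise_cv^2))
  genes <- names(baselines)
  with_seed(seed + 1L, {
    mat <- vapply(seq_len(nrow(design)), function(i) {
      eff_here <- Filter(function(e) {
        is.null(e$chemical) || e$chemical == design$chemical[i]
      }, effects)
      mu <- expected_expression(net, baselines, eff_here, design$dose[i])
      noise <- stats::rlnorm(length(mu), meanlog = -sdlog^2 / 2,
                             sdlog = sdlog)
      mu * noise
    }, numeric(length(genes)))
  })
  rownames(mat) <- genes
  colnames(mat) <- design$sample_id
  expression_set(log2(mat), design, scale = "log2")
}

#' Ground-truth benchmark doses from noiseless expression curves
#'
#' Runs flux inference and subsystem aggregation on the noiseless expected
#' expression over a fine dose grid, estimates the control-level activity
#' SD from Monte-Carlo noise replicates at dose 0, and reports per
#' subsystem the smallest dose at which the noiseless activity departs
#' from its control value by one control SD (linear interpolation between
#' grid points). This defines the recovery target for the BMD engine
#' through the same one-SD criterion it estimates, but free of sampling
#' noise.
#'
#' @param net A [metabolic_network()].
#' @param effects List of [effect_spec()]s.
#' @param dose_grid Numeric vector of study doses (the span sets the
#'   oracle grid).
#' @param seed Integer seed (baselines and Monte-Carlo noise).
#' @param noise_cv Animal noise CV used for the control-SD replicates.
#' @param n_grid Number of log-spaced grid points across the dose span.
#' @param n_mc Number of Monte-Carlo control replicates.
#' @param baselines,baseline_median,baseline_cv Baseline control; see
#'   [simulate_expression()].
#' @param control A [flux_control()].
#' @return Tibble with `subsystem`, `true_bmd` (`NA` when the effect never
#'   reaches one control SD within the grid), `control_sd`,
#'   `control_activity`.
#' @export
true_bmd_oracle <- function(net, effects, dose_grid, seed = 1,
                            noise_cv = 0.1, n_grid = 40, n_mc = 100,
                            baselines = NULL, baseline_median = 100,
                            baseline_cv = 1, control = flux_control()) {
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  if (is.null(baselines)) {
    baselines <- draw_baselines(net, seed, baseline_median, baseline_cv)
  }
  net <- apply_exchange_defaults(net)
  irr <- split_reversible(net)
  polytope <- build_polytope(irr)
  nz <- sort(dose_grid[dose_grid > 0])
  grid <- c(0, exp(seq(log(min(nz)), log(max(nz)), length.out = n_grid)))

  activity_at <- function(values) {
    g <- reaction_expression(irr, values)
    f <- infer_fluxome(polytope, g, control)
    act <- subsystem_activity(matrix(f$v, ncol = 1,
                                     dimnames = list(names(f$v), "s")),
                              network = net)
    stats::setNames(act$activity, act$subsystem)
  }

  curves <- vapply(grid, function(d) {
    activity_at(expected_expression(net, baselines, effects, d))
  }, activity_at(baselines))

  sdlog <- sqrt(log(1 + noise_cv^2))
  mc <- with_seed(seed + 2L, {
    vapply(seq_len(n_mc), function(i) {
      noise <- stats::rlnorm(length(baselines), meanlog = -sdlog^2 / 2,
                             sdlog = sdlog)
      activity_at(baselines * noise)
    }, curves[, 1])
  })
  control_sd <- apply(mc, 1, stats::sd)

  out <- purrr::map_dfr(rownames(curves), function(ss) {
    a <- curves[ss, ]
    dev <- abs(a - a[1])
    sd_s <- control_sd[[ss]]
    hit <- which(dev >= sd_s)
    hit <- hit[hit > 1]
    true_bmd <- NA_real_
    if (length(hit)) {
      i <- hit[1]
      d0 <- grid[i - 1]; d1 <- grid[i]
      y0 <- dev[i - 1]; y1 <- dev[i]
      true_bmd <- if (y1 > y0) {
        d0 + (sd_s - y0) / (y1 - y0) * (d1 - d0)
      } else {
        d1
      }
    }
    tibble::tibble(subsystem = ss, true_bmd = true_bmd,
                   control_sd = sd_s, control_activity = a[1])
  })
  attr(out, "curves") <- curves
  attr(out, "grid") <- grid
  out
}
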