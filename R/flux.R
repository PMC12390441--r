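# Maximum-entropy fluxome inference.
#
# The fluxome is estimated by minimizing the Kullback-Leibler divergence
# between the flux proportion vector P (P_i = v_i / sum(v)) and the
# reaction-expression proportion vector Q (Q_i = g_i / sum(g)) over the
# steady-state flux polytope {v : Sv = 0, LB <= v <= UB} of the
# irreversible network. Because the objective depends on v only through
# proportions, the problem is solved on the unit-total-flux simplex: the
# stationarity conditions give P_i proportional to Q_i * exp(-(S'lambda)_i),
# where the metabolite multipliers lambda minimize the smooth convex dual
#   g(lambda) = log sum_i Q_i exp(-(S'lambda)_i),
# whose gradient is -S P. A damped Newton iteration on the dual drives the
# steady-state residual ||S P|| to numerical zero. Box constraints beyond
# nonnegativity (forced lower bounds, finite upper bounds on the unit
# scale) are handled by a log-barrier refinement over null-space
# coordinates when the dual solution violates them.

#' Solver settings for maximum-entropy flux inference
#'
#' @param tol_residual Convergence tolerance on the steady-state residual
#'   `max|Sv|` of the unit-scale flux vector.
#' @param max_iter Maximum Newton iterations on the dual.
#' @param epsilon Floor added inside logarithms to keep the objective
#'   defined at zero flux.
#' @param ridge Levenberg-style ridge added to the dual Hessian.
#' @return A list of class `flux_control`.
#' @export
flux_control <- function(tol_residual = 1e-9, max_iter = 300,
                         epsilon = 1e-9, ridge = 1e-12) {
  structure(list(tol_residual = tol_residual, max_iter = max_iter,
                 epsilon = epsilon, ridge = ridge),
            class = "flux_control")
}

#' Build the steady-state flux polytope of an irreversible network
#'
#' @param irr An `irreversible_network` from [split_reversible()].
#' @return A `flux_polytope`: list with the stoichiometric matrix `S`,
#'   bound vectors `lb` and `ub` (all `lb >= 0`), and the network.
#' @export
build_polytope <- function(irr) {
  stopifnot(inherits(irr, "irreversible_network"))
  lb <- irr$reactions$lower_bound
  ub <- irr$reactions$upper_bound
  if (any(lb < 0)) rlang::abort("irreversible network has negative lower bounds")
  if (any(lb > ub)) {
    rlang::abort(paste0("infeasible bounds (LB > UB) for: ",
                        paste(irr$reactions$id[lb > ub], collapse = ", ")))
  }
  structure(list(S = irr$stoichiometry, lb = lb, ub = ub, network = irr),
            class = "flux_polytope")
}

#' Kullback-Leibler flux objective
#'
#' `D_KL(P || Q)` with `P = v / sum(v)` and `Q = q / sum(q)`, in nats.
#'
#' @param v Nonnegative flux vector.
#' @param q Nonnegative reference (reaction-expression) vector.
#' @param epsilon Floor inside logarithms.
#' @return Scalar divergence (>= 0 up to the epsilon floor).
#' @export
kl_divergence <- function(v, q, epsilon = 1e-9) {
  p <- v / sum(v)
  qn <- q / sum(q)
  keep <- p > 0
  sum(p[keep] * (log(p[keep] + epsilon) - log(qn[keep] + epsilon)))
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Newton iteration on the dual of the simplex-constrained problem.
# Returns list(p, lambda, residual, converged, iterations).
solve_dual_maxent <- function(S, q, control) {
  # dense arithmetic is faster below a few thousand reactions; keep the
  # sparse path for genome-scale models
  dense <- (as.numeric(nrow(S)) * ncol(S)) <= 4e6
  S <- if (dense) as.matrix(S) else methods::as(S, "CsparseMatrix")
  St <- if (dense) t(S) else NULL
  cvec <- log(q / sum(q) + control$epsilon)
  m <- nrow(S)
  lambda <- numeric(m)
  softmax_p <- function(lambda) {
    theta <- if (dense) cvec - drop(St %*% lambda) else
      as.numeric(cvec - Matrix::crossprod(S, lambda))
    exp(theta - logsumexp(theta))
  }
  obj <- function(lambda) {
    theta <- if (dense) cvec - drop(St %*% lambda) else
      as.numeric(cvec - Matrix::crossprod(S, lambda))
    logsumexp(theta)
  }
  grad <- function(lambda) -as.numeric(S %*% softmax_p(lambda))

  # warm up with quasi-Newton when the problem is large or Newton stalls
  bfgs <- function(lambda) {
    fit <- stats::optim(lambda, fn = obj, gr = grad, method = "L-BFGS-B",
                        control = list(maxit = 500, factr = 1e4))
    fit$par
  }

  converged <- FALSE
  iter <- 0L
  stalls <- 0L
  while (iter < control$max_iter) {
    iter <- iter + 1L
    p <- softmax_p(lambda)
    g <- as.numeric(S %*% p)
    if (max(abs(g)) <= control$tol_residual) {
      converged <- TRUE
      break
    }
    H <- if (dense) {
      S %*% (p * St) - tcrossprod(g)
    } else {
      as.matrix(Matrix::tcrossprod(S %*% Matrix::Diagonal(x = p), S)) -
        tcrossprod(g)
    }
    ridge <- control$ridge * max(1, max(abs(diag(H))))
    # gradient of the dual is -S p = -g, so the Newton step solves H d = g
    step <- tryCatch(
      solve(H + diag(ridge, m), g),
      error = function(e) g  # fall back to steepest descent
    )
    # backtracking line search: accept an objective decrease, or (for the
    # full Newton step) a residual decrease — near the optimum the
    # objective change drops below machine precision first
    f0 <- obj(lambda)
    res0 <- max(abs(g))
    alpha <- 1
    improved <- FALSE
    for (ls in 1:40) {
      cand <- lambda + alpha * step
      accept <- obj(cand) < f0 - 1e-14 ||
        max(abs(S %*% softmax_p(cand))) < 0.9 * res0
      if (accept) {
        lambda <- cand
        improved <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!improved) {
      stalls <- stalls + 1L
      if (stalls > 2L) break
      lambda <- bfgs(lambda)
    }
  }
  p <- softmax_p(lambda)
  list(p = p, lambda = lambda,
       residual = max(abs(as.numeric(S %*% p))),
       converged = converged, iterations = iter)
}

# Orthonormal null-space basis of a (possibly sparse) matrix.
null_basis <- function(S) {
  S <- as.matrix(S)
  sv <- svd(S, nu = 0, nv = ncol(S))
  tol <- max(dim(S)) * max(sv$d, 0) * .Machine$double.eps
  keep <- sv$d > tol
  rank <- sum(keep)
  if (rank == ncol(S)) {
    matrix(0, nrow = ncol(S), ncol = 0)
  } else {
    sv$v[, (rank + 1):ncol(S), drop = FALSE]
  }
}

# Log-barrier refinement when box constraints bind: optimize the KL
# objective over null-space coordinates with constrOptim.
solve_box_constrained <- function(S, lb, ub, q, p_start, control) {
  N <- null_basis(S)
  if (ncol(N) == 0L) {
    rlang::abort("flux polytope has no degrees of freedom under Sv = 0")
  }
  qn <- q / sum(q)
  eps <- control$epsilon
  fn <- function(t) {
    v <- as.numeric(N %*% t)
    V <- sum(v)
    if (V <= eps) return(1e6)
    p <- v / V
    sum(p * (log(pmax(p, 0) + eps) - log(qn + eps)))
  }
  gr <- function(t) {
    v <- as.numeric(N %*% t)
    V <- sum(v)
    p <- v / V
    f <- sum(p * (log(pmax(p, 0) + eps) - log(qn + eps)))
    gv <- (log(pmax(p, 0) + eps) - log(qn + eps) - f) / V
    as.numeric(crossprod(N, gv))
  }
  # strictly interior start: scale the dual solution into the box, then
  # push off the faces with a penalty minimization if needed
  pos <- p_start > 1e-12
  tau_lo <- if (any(lb > 0)) max(lb[pos] / p_start[pos] * (lb[pos] > 0)) else 0
  tau_hi <- min(ub[pos] / p_start[pos])
  tau <- if (tau_lo > 0) sqrt(max(tau_lo, 1e-12) * tau_hi) else min(1, tau_hi / 2)
  v0 <- tau * p_start
  t0 <- as.numeric(crossprod(N, v0))
  margin <- 1e-8 * max(ub)
  interior <- function(t) {
    v <- as.numeric(N %*% t)
    all(v > lb + margin) && all(v < ub - margin)
  }
  if (!interior(t0)) {
    pen <- function(t) {
      v <- as.numeric(N %*% t)
      sum(pmax(lb + 2 * margin - v, 0)^2 + pmax(v - ub + 2 * margin, 0)^2)
    }
    fit0 <- stats::optim(t0, pen, method = "BFGS",
                         control = list(maxit = 500, reltol = 1e-14))
    t0 <- fit0$par
    if (!interior(t0)) {
      return(list(v = as.numeric(N %*% t0), converged = FALSE))
    }
  }
  ui <- rbind(N, -N)
  ci <- c(lb, -ub)
  fit <- tryCatch(
    stats::constrOptim(t0, f = fn, grad = gr, ui = ui, ci = ci,
                       outer.iterations = 50,
                       control = list(maxit = 1000, reltol = 1e-14)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(list(v = as.numeric(N %*% t0), converged = FALSE))
  list(v = as.numeric(N %*% fit$par), converged = fit$convergence == 0)
}

#' Infer a fluxome by maximum-entropy KL minimization
#'
#' Minimizes `D_KL(P || Q)` over the steady-state flux polytope, where `P`
#' is the flux proportion vector and `Q` the reaction-expression
#' proportion vector. The solution is reported on the unit-total-flux
#' scale (`sum(v) = 1` on the irreversible network) — the objective and
#' every downstream subsystem statistic are invariant to the overall flux
#' scale.
#'
#' @param polytope A [build_polytope()] result.
#' @param g Reaction expression from [reaction_expression()] (strictly
#'   positive, ordered as the irreversible reactions).
#' @param control A [flux_control()].
#' @return A `fluxome`: list with `v` (named net fluxes on the base
#'   network), `v_irr` (nonnegative irreversible fluxes), `d_kl` (nats),
#'   `residual` (`max|Sv|` on the base network), `status`
#'   (`"optimal"`/`"failed"`), and solver diagnostics.
#' @export
infer_fluxome <- function(polytope, g, control = flux_control()) {
  stopifnot(inherits(polytope, "flux_polytope"))
  irr <- polytope$network
  n <- nrow(irr$reactions)
  if (length(g) != n) rlang::abort("g must have one value per irreversible reaction")
  if (any(!is.finite(g)) || any(g < 0)) {
    rlang::abort("reaction expression must be finite and nonnegative")
  }

  active <- which(polytope$ub > 0)
  if (!length(active)) rlang::abort("all reactions are blocked (UB <= 0)")
  S_act <- polytope$S[, active, drop = FALSE]
  live_rows <- which(Matrix::rowSums(abs(S_act)) > 0)
  S_red <- S_act[live_rows, , drop = FALSE]
  q <- pmax(g[active], control$epsilon)

  dual <- solve_dual_maxent(S_red, q, control)
  p_full <- numeric(n)
  p_full[active] <- dual$p

  status <- if (dual$converged) "optimal" else "failed"
  v <- p_full
  boxed <- FALSE
  lb <- polytope$lb
  ub <- polytope$ub
  # bounds on the unit-total-flux scale: does some rescaling tau place
  # tau * p inside [lb, ub]?
  pos <- p_full > 0
  tau_lo <- if (any(lb > 0)) {
    need <- lb > 0
    if (any(need & !pos)) Inf else max(lb[need] / p_full[need])
  } else 0
  tau_hi <- min(ub[pos] / p_full[pos])
  if (tau_lo <= tau_hi) {
    tau <- min(max(1, tau_lo), tau_hi)
    v <- tau * p_full
  } else {
    boxed <- TRUE
    box <- solve_box_constrained(polytope$S, lb, ub, pmax(g, control$epsilon),
                                 p_full, control)
    v <- pmax(box$v, 0)
    status <- if (box$converged) "optimal" else "failed"
  }

  v_net <- recombine_fluxes(irr, v)
  base_S <- irr$base$stoichiometry
  residual <- max(abs(as.numeric(base_S %*% v_net)))
  bound_violation <- max(c(polytope$lb - v, v - polytope$ub, 0))
  d_kl <- kl_divergence(pmax(v, 0), pmax(g, control$epsilon),
                        epsilon = control$epsilon)
  if (status == "optimal" && residual > 1e-6) status <- "failed"

  structure(
    list(v = v_net, v_irr = stats::setNames(v, irr$reactions$id),
         d_kl = d_kl, residual = residual,
         bound_violation = bound_violation, status = status,
         box_constrained = boxed, iterations = dual$iterations,
         filled = attr(g, "filled")),
    class = "fluxome"
  )
}

#' @export
print.fluxome <- function(x, ...) {
  cat("<fluxome> ", length(x$v), " reactions, D_KL = ",
      format(x$d_kl, digits = 4), " nats, residual = ",
      format(x$residual, digits = 3), " [", x$status, "]\n", sep = "")
  invisible(x)
}

#' Tidy a fluxome into a reaction-level tibble
#'
#' @param x A `fluxome`.
#' @param network Optional `metabolic_network` supplying subsystem labels.
#' @param ... Unused.
#' @return Tibble with columns `reaction`, `flux`, and (when a network is
#'   given) `subsystem`.
#' @export
tidy.fluxome <- function(x, network = NULL, ...) {
  out <- tibble::tibble(reaction = names(x$v), flux = unname(x$v))
  if (!is.null(network)) {
    out$subsystem <- network$reactions$subsystem[
      match(out$reaction, network$reactions$id)]
  }
  out
}

#' Check the steady-state condition of a fluxome
#'
#' @param fluxome A `fluxome` (or named flux vector with a `network`).
#' @param tol Residual tolerance on `max|Sv|`.
#' @param network Required when `fluxome` is a bare vector.
#' @return Logical scalar with attribute `residual`.
#' @export
check_steady_state <- function(fluxome, tol = 1e-6, network = NULL) {
  if (inherits(fluxome, "fluxome")) {
    res <- fluxome$residual
  } else {
    stopifnot(!is.null(network))
    v <- fluxome[network$reactions$id]
    res <- max(abs(as.numeric(network$stoichiometry %*% v)))
  }
  structure(res <= tol, residual = res)
}

#' Infer fluxomes for every sample of an expression set
#'
#' Runs [infer_fluxome()] once per sample on a shared network. Failed
#' samples are excluded from the flux matrix and reported in the manifest;
#' the run aborts when the failure fraction exceeds `max_failure_frac`.
#'
#' @param net A [metabolic_network()] (exchange defaults are applied).
#' @param es An [expression_set()].
#' @param control A [flux_control()].
#' @param max_failure_frac Abort threshold for the per-sample failure rate.
#' @return A `flux_cohort`: list with `fluxes` (base reactions x
#'   successful samples matrix of net fluxes), `manifest` (tibble:
#'   `sample_id`, `status`, `d_kl`, `residual`, `n_filled`), and the
#'   networks used.
#' @export
infer_cohort <- function(net, es, control = flux_control(),
                         max_failure_frac = 0.2) {
  stopifnot(inherits(net, "metabolic_network"), inherits(es, "expression_set"))
  net <- apply_exchange_defaults(net)
  irr <- split_reversible(net)
  polytope <- build_polytope(irr)
  vals <- linear_values(es)
  samples <- colnames(vals)

  results <- purrr::map(samples, function(s) {
    g <- reaction_expression(irr, vals[, s])
    tryCatch(infer_fluxome(polytope, g, control),
             error = function(e) structure(list(status = "failed",
                                                message = conditionMessage(e)),
                                           class = "fluxome_failure"))
  })
  names(results) <- samples
  ok <- vapply(results, function(r) identical(r$status, "optimal"), logical(1))
  manifest <- tibble::tibble(
    sample_id = samples,
    status = vapply(results, function(r) r$status %||% "failed",
                    character(1), USE.NAMES = FALSE),
    d_kl = vapply(results, function(r) r$d_kl %||% NA_real_,
                  numeric(1), USE.NAMES = FALSE),
    residual = vapply(results, function(r) r$residual %||% NA_real_,
                      numeric(1), USE.NAMES = FALSE),
    n_filled = vapply(results, function(r) length(r$filled %||% character(0)),
                      integer(1), USE.NAMES = FALSE)
  )
  if (mean(!ok) > max_failure_frac) {
    rlang::abort(sprintf(
      "flux inference failed for %d of %d samples (threshold %.0f%%)",
      sum(!ok), length(ok), 100 * max_failure_frac))
  }
  fluxes <- vapply(results[ok], function(r) r$v,
                   numeric(nrow(net$reactions)))
  rownames(fluxes) <- net$reactions$id
  structure(list(fluxes = fluxes, manifest = manifest, network = net,
                 irreversible = irr),
            class = "flux_cohort")
}

#' @export
print.flux_cohort <- function(x, ...) {
  ok <- sum(x$manifest$status == "optimal")
  cat("<flux_cohort> ", ok, "/", nrow(x$manifest),
      " samples solved on ", nrow(x$fluxes), " reactions\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
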