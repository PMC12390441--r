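# Continuous benchmark-dose (BMD) modeling of subsystem activities.
#
# Five dose-response model families (linear, polynomial, power, hill,
# exponential) are fitted by maximum likelihood under normal errors with
# constant variance. The BMD is the dose at which the fitted mean departs
# from the control mean by one (fitted residual) standard deviation; BMDL
# and BMDU are two one-sided 95% profile-likelihood limits. Each fit is
# classified viable / questionable / unusable, the best viable fit is
# selected by AIC, and a highest-dose-dropping loop refits until a viable
# model is found or only three dose levels remain.

#' BMD analysis settings
#'
#' @param bmr_mult Benchmark response as a multiple of the residual SD
#'   (default 1).
#' @param confidence One-sided confidence level for BMDL/BMDU (default
#'   0.95; the profile uses the chi-square 1-df cutoff
#'   `qchisq(2 * confidence - 1, 1)`).
#' @param min_doses Floor of the dose-dropping loop (default 3 dose
#'   levels).
#' @param gof_alpha Goodness-of-fit threshold below which a fit is
#'   questionable (default 0.10).
#' @param bmd_bmdl_ratio_max Largest acceptable BMD/BMDL ratio (default 20).
#' @param bmdl_floor_frac BMDL below `lowest nonzero dose * this` makes a
#'   fit questionable (default 1/10).
#' @param sigma_source `"control"` (control-group SD, default — the
#'   benchmark response is defined relative to the controls) or `"model"`
#'   (fitted residual SD, which pools dose-group variances and is biased
#'   when the response variance changes with dose).
#' @param poly_degree Polynomial family degree (default 2; capped at the
#'   number of dose groups minus 2).
#' @return List of class `bmd_options`.
#' @export
bmd_options <- function(bmr_mult = 1, confidence = 0.95, min_doses = 3,
                        gof_alpha = 0.10, bmd_bmdl_ratio_max = 20,
                        bmdl_floor_frac = 0.1,
                        sigma_source = c("control", "model"),
                        poly_degree = 2) {
  structure(list(bmr_mult = bmr_mult, confidence = confidence,
                 min_doses = min_doses, gof_alpha = gof_alpha,
                 bmd_bmdl_ratio_max = bmd_bmdl_ratio_max,
                 bmdl_floor_frac = bmdl_floor_frac,
                 sigma_source = match.arg(sigma_source),
                 poly_degree = poly_degree),
            class = "bmd_options")
}

#' Model families available for BMD fitting
#' @export
bmd_families <- c("linear", "polynomial", "power", "hill", "exponential")

check_dose_response <- function(data) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("dose", "response") %in% names(data)))
  doses <- sort(unique(data$dose))
  if (length(doses) < 3) rlang::abort("need at least 3 distinct dose levels")
  if (!0 %in% doses) rlang::abort("dose 0 (control) must be present")
  data
}

# --- mean functions --------------------------------------------------------

bmd_mean_fn <- function(family, variant = NA_character_) {
  switch(family,
    linear = function(d, p) p[["a"]] + p[["b"]] * d,
    polynomial = function(d, p) {
      betas <- p[grepl("^b[0-9]+$", names(p))]
      out <- rep(p[["a"]], length(d))
      for (j in seq_along(betas)) out <- out + betas[[j]] * d^j
      out
    },
    power = function(d, p) p[["a"]] + p[["b"]] * d^p[["g"]],
    hill = function(d, p) {
      num <- d^p[["g"]]
      p[["a"]] + p[["b"]] * num / (p[["c"]]^p[["g"]] + num)
    },
    exponential = switch(variant,
      M2 = function(d, p) p[["a"]] * exp(p[["s"]] * p[["b"]] * d),
      M3 = function(d, p) p[["a"]] * exp(p[["s"]] * (p[["b"]] * d)^p[["g"]]),
      M4 = function(d, p) {
        p[["a"]] * (p[["c"]] - (p[["c"]] - 1) * exp(-p[["b"]] * d))
      },
      M5 = function(d, p) {
        p[["a"]] * (p[["c"]] - (p[["c"]] - 1) *
                      exp(-(p[["b"]] * d)^p[["g"]]))
      }),
    rlang::abort(paste0("unknown family: ", family))
  )
}

loglik_normal <- function(rss, n, sigma2 = rss / n) {
  -n / 2 * (log(2 * pi * sigma2)) - rss / (2 * sigma2)
}

# Saturated (group-means) log-likelihood for the goodness-of-fit test.
loglik_saturated <- function(data) {
  mu <- stats::ave(data$response, data$dose)
  rss <- sum((data$response - mu)^2)
  list(loglik = loglik_normal(rss, nrow(data)),
       k = length(unique(data$dose)) + 1)
}

finish_fit <- function(family, variant, par, data, converged = TRUE) {
  fn <- bmd_mean_fn(family, variant)
  pred <- fn(data$dose, par)
  rss <- sum((data$response - pred)^2)
  n <- nrow(data)
  sigma <- sqrt(rss / n)
  n_mean_par <- sum(!names(par) %in% "s")
  k <- n_mean_par + 1
  ll <- loglik_normal(rss, n)
  sat <- loglik_saturated(data)
  df_gof <- sat$k - k
  gof_p <- if (df_gof <= 0) 1 else {
    stat <- max(0, 2 * (sat$loglik - ll))
    stats::pchisq(stat, df_gof, lower.tail = FALSE)
  }
  direction <- sign(fn(max(data$dose), par) - fn(0, par))
  if (direction == 0) direction <- 1
  structure(
    list(family = family, variant = variant, coefficients = par,
         sigma = sigma, rss = rss, n = n, k = k, loglik = ll,
         aic = 2 * k - 2 * ll, gof_p = gof_p, direction = direction,
         converged = converged, data = data),
    class = "bmd_fit"
  )
}

#' @export
print.bmd_fit <- function(x, ...) {
  cat("<bmd_fit> ", x$family,
      if (!is.na(x$variant)) paste0(" (", x$variant, ")"), ": ",
      paste(sprintf("%s=%.4g", names(x$coefficients), x$coefficients),
            collapse = ", "),
      "; AIC = ", format(x$aic, digits = 5),
      ", gof p = ", format(x$gof_p, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.bmd_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(unlist(x$coefficients)))
}

#' @export
glance.bmd_fit <- function(x, ...) {
  tibble::tibble(family = x$family, variant = x$variant, sigma = x$sigma,
                 logLik = x$loglik, AIC = x$aic, gof_p = x$gof_p,
                 n = x$n, converged = x$converged)
}

#' @export
predict.bmd_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data$dose
       else if (is.list(newdata)) newdata$dose else newdata
  bmd_mean_fn(object$family, object$variant)(d, object$coefficients)
}

# Profile RSS over (a, b) by least squares given a design column x.
lm_ab <- function(x, y) {
  X <- cbind(1, x)
  fit <- stats::lm.fit(X, y)
  list(a = fit$coefficients[1], b = fit$coefficients[2],
       rss = sum(fit$residuals^2))
}

fit_linear <- function(data, ...) {
  f <- lm_ab(data$dose, data$response)
  finish_fit("linear", NA, list(a = unname(f$a), b = unname(f$b)), data)
}

fit_polynomial <- function(data, options) {
  degree <- min(options$poly_degree, length(unique(data$dose)) - 2)
  degree <- max(degree, 1)
  X <- outer(data$dose, seq_len(degree), `^`)
  # coefficients are restricted to the adverse direction (all terms share
  # one sign), the standard default for continuous polynomial models —
  # an unrestricted quadratic would chase non-monotone noise
  fit_dir <- function(s) {
    obj <- function(theta) {
      pred <- theta[1] + X %*% (s * theta[-1])
      sum((data$response - pred)^2)
    }
    start <- c(mean(data$response[data$dose == 0]), rep(1e-8, degree))
    opt <- stats::optim(start, obj, method = "L-BFGS-B",
                        lower = c(-Inf, rep(0, degree)),
                        control = list(maxit = 500, factr = 1e4))
    list(par = c(opt$par[1], s * opt$par[-1]), rss = opt$value,
         converged = opt$convergence == 0)
  }
  up <- fit_dir(1)
  down <- fit_dir(-1)
  best <- if (up$rss <= down$rss) up else down
  par <- as.list(stats::setNames(best$par,
                                 c("a", paste0("b", seq_len(degree)))))
  finish_fit("polynomial", NA, par, data, converged = best$converged)
}

fit_power <- function(data, ...) {
  prof <- function(g) lm_ab(data$dose^g, data$response)$rss
  grid <- c(1, 1.25, 1.5, 2, 3, 4, 6, 8, 12, 18)
  g0 <- grid[which.min(vapply(grid, prof, numeric(1)))]
  opt <- stats::optimize(prof, lower = max(1, g0 / 2), upper = min(18, g0 * 2))
  g <- if (prof(1) <= opt$objective) 1 else opt$minimum
  f <- lm_ab(data$dose^g, data$response)
  finish_fit("power", NA,
             list(a = unname(f$a), b = unname(f$b), g = g), data)
}

fit_hill <- function(data, ...) {
  nz <- sort(unique(data$dose[data$dose > 0]))
  xfun <- function(c0, g) data$dose^g / (c0^g + data$dose^g)
  prof <- function(c0, g) lm_ab(xfun(c0, g), data$response)$rss
  grid <- expand.grid(c0 = nz, g = c(1, 2, 4, 8))
  rss <- mapply(prof, grid$c0, grid$g)
  best <- grid[which.min(rss), ]
  opt <- stats::optim(
    c(log(best$c0), log(best$g)),
    function(t) prof(exp(t[1]), min(max(exp(t[2]), 1), 18)),
    method = "Nelder-Mead", control = list(maxit = 300, reltol = 1e-10))
  c0 <- exp(opt$par[1]); g <- min(max(exp(opt$par[2]), 1), 18)
  f <- lm_ab(xfun(c0, g), data$response)
  finish_fit("hill", NA,
             list(a = unname(f$a), b = unname(f$b), c = c0, g = g), data,
             converged = opt$convergence == 0)
}

fit_exponential <- function(data, ...) {
  d <- data$dose; y <- data$response
  ybar0 <- mean(y[d == 0])
  ytop <- mean(y[d == max(d)])
  s <- if (ytop >= ybar0) 1 else -1
  b0 <- 1 / stats::median(d[d > 0])
  rss_fn <- function(variant) {
    fn <- bmd_mean_fn("exponential", variant)
    function(t, par_names) {
      p <- as.list(stats::setNames(exp(t), par_names))
      p$s <- s
      if (!is.null(p$g)) p$g <- 1 + p$g  # g = 1 + exp(t_g) >= 1
      pred <- fn(d, p)
      if (any(!is.finite(pred))) return(1e12)
      sum((y - pred)^2)
    }
  }
  fit_variant <- function(variant, par_names, start) {
    f <- rss_fn(variant)
    opt <- stats::optim(log(start), f, par_names = par_names,
                        method = "Nelder-Mead",
                        control = list(maxit = 800, reltol = 1e-10))
    p <- as.list(stats::setNames(exp(opt$par), par_names))
    p$s <- s
    if (!is.null(p$g)) p$g <- 1 + p$g
    finish_fit("exponential", variant, p, data,
               converged = opt$convergence == 0)
  }
  a0 <- max(ybar0, 1e-9)
  c0 <- max(ytop, 1e-9) / a0
  c0 <- if (s > 0) max(c0, 1.05) else min(max(c0, 1e-3), 0.95)
  fits <- list(
    fit_variant("M2", c("a", "b"), c(a = a0, b = b0)),
    fit_variant("M3", c("a", "b", "g"), c(a = a0, b = b0, g = 0.5)),
    fit_variant("M4", c("a", "b", "c"), c(a = a0, b = b0, c = c0)),
    fit_variant("M5", c("a", "b", "c", "g"), c(a = a0, b = b0, c = c0, g = 0.5))
  )
  fits[[which.min(vapply(fits, function(f) f$aic, numeric(1)))]]
}

#' Fit a dose-response model family by maximum likelihood
#'
#' Normal errors with constant variance; the exponential family fits its
#' four nested variants and keeps the best by AIC. Optimization uses
#' deterministic profile grids and refinement, so repeated fits are
#' identical.
#'
#' @param data Tibble with columns `dose` (mg/kg, including 0) and
#'   `response` (per-animal subsystem activity).
#' @param family One of [bmd_families].
#' @param options A [bmd_options()].
#' @return A `bmd_fit` with coefficients, `sigma` (MLE residual SD),
#'   log-likelihood, AIC and goodness-of-fit p-value (likelihood ratio
#'   against the saturated group-means model).
#' @export
fit_model <- function(data, family = bmd_families, options = bmd_options()) {
  family <- match.arg(family)
  data <- check_dose_response(data)
  fitter <- switch(family, linear = fit_linear, polynomial = fit_polynomial,
                   power = fit_power, hill = fit_hill,
                   exponential = fit_exponential)
  tryCatch(fitter(data, options = options), error = function(e) {
    structure(list(family = family, variant = NA_character_,
                   converged = FALSE, error = conditionMessage(e),
                   data = data),
              class = "bmd_fit")
  })
}

bmr_sigma <- function(fit, options) {
  if (options$sigma_source == "control") {
    stats::sd(fit$data$response[fit$data$dose == 0])
  } else {
    fit$sigma
  }
}

#' Benchmark dose of a fitted dose-response model
#'
#' The BMD solves `|m(d) - m(0)| = bmr_mult * sigma` on the tested dose
#' range, in closed form for the linear and power families and by
#' bracketed root finding otherwise.
#'
#' @param fit A converged `bmd_fit`.
#' @param options A [bmd_options()].
#' @return The BMD (mg/kg), or `NA` when the benchmark response is not
#'   reached within the tested dose range.
#' @export
compute_bmd <- function(fit, options = bmd_options()) {
  if (!isTRUE(fit$converged)) return(NA_real_)
  sigma <- bmr_sigma(fit, options)
  bmr <- options$bmr_mult * sigma
  if (!is.finite(bmr) || bmr <= 0) return(NA_real_)
  p <- fit$coefficients
  dmax <- max(fit$data$dose)
  if (fit$family == "linear") {
    if (abs(p$b) < 1e-300) return(NA_real_)
    bmd <- bmr / abs(p$b)
    return(if (bmd <= dmax) bmd else NA_real_)
  }
  if (fit$family == "power") {
    if (abs(p$b) < 1e-300) return(NA_real_)
    bmd <- (bmr / abs(p$b))^(1 / p$g)
    return(if (bmd <= dmax) bmd else NA_real_)
  }
  fn <- bmd_mean_fn(fit$family, fit$variant)
  delta <- function(d) abs(fn(d, p) - fn(0, p)) - bmr
  grid <- seq(0, dmax, length.out = 512)
  vals <- delta(grid)
  cross <- which(vals[-1] >= 0 & vals[-length(vals)] < 0)
  if (!length(cross)) return(NA_real_)
  stats::uniroot(delta, lower = grid[cross[1]], upper = grid[cross[1] + 1],
                 tol = 1e-12 * max(dmax, 1))$root
}

# --- profile likelihood bounds --------------------------------------------

# Given a family, a target BMD value and the free parameters (with the
# scale parameter eliminated through the BMR equation), return predicted
# means; NULL signals an infeasible parameter combination.
constrained_mean <- function(fit, options, bmd0, free, d, bmr_fixed = NULL) {
  s <- fit$bmr_direction %||% fit$direction
  bmr <- bmr_fixed %||% (options$bmr_mult * free[["sigma"]])
  fam <- fit$family
  if (fam == "linear") {
    p <- list(a = free[["a"]], b = s * bmr / bmd0)
  } else if (fam == "polynomial") {
    b2 <- free[["b2"]] %||% 0
    p <- list(a = free[["a"]], b1 = (s * bmr - b2 * bmd0^2) / bmd0, b2 = b2)
    if (!"b2" %in% names(fit$coefficients)) p$b2 <- NULL
  } else if (fam == "power") {
    g <- min(max(free[["g"]], 1), 18)
    p <- list(a = free[["a"]], b = s * bmr / bmd0^g, g = g)
  } else if (fam == "hill") {
    g <- min(max(free[["g"]], 1), 18)
    c0 <- free[["c"]]
    if (c0 <= 0) return(NULL)
    p <- list(a = free[["a"]], b = s * bmr * (c0^g + bmd0^g) / bmd0^g,
              c = c0, g = g)
  } else { # exponential
    a <- free[["a"]]
    if (a <= 0) return(NULL)
    v <- fit$variant
    if (v %in% c("M2", "M3")) {
      g <- if (v == "M3") min(max(free[["g"]], 1), 18) else 1
      arg <- if (s > 0) log1p(bmr / a) else {
        if (bmr >= a) return(NULL) else -log1p(-bmr / a)
      }
      b <- arg^(1 / g) / bmd0
      p <- list(a = a, b = b, s = s)
      if (v == "M3") p$g <- g
    } else {
      g <- if (v == "M5") min(max(free[["g"]], 1), 18) else 1
      c0 <- free[["c"]]
      if (c0 <= 0) return(NULL)
      amp <- a * abs(c0 - 1)
      if (bmr >= amp) return(NULL)
      arg <- -log1p(-bmr / amp)
      b <- arg^(1 / g) / bmd0
      p <- list(a = a, b = b, c = c0)
      if (v == "M5") p$g <- g
    }
  }
  fn <- bmd_mean_fn(fam, fit$variant)
  pred <- fn(d, p)
  if (any(!is.finite(pred))) return(NULL)
  pred
}

profile_loglik <- function(fit, options, bmd0, bmr_fixed = NULL) {
  d <- fit$data$dose
  y <- fit$data$response
  n <- length(y)
  co <- fit$coefficients
  free0 <- c(a = co$a %||% mean(y[d == 0]), sigma = fit$sigma)
  if (fit$family == "polynomial" && "b2" %in% names(co)) {
    free0 <- c(free0, b2 = co$b2)
  }
  if (fit$family %in% c("power", "hill") ||
      (identical(fit$family, "exponential") &&
       fit$variant %in% c("M3", "M5"))) {
    free0 <- c(free0, g = co$g %||% 1)
  }
  if (fit$family == "hill" ||
      (identical(fit$family, "exponential") &&
       fit$variant %in% c("M4", "M5"))) {
    free0 <- c(free0, c = co$c)
  }
  nll <- function(theta) {
    free <- stats::setNames(as.list(theta), names(free0))
    sigma <- free$sigma
    if (!is.finite(sigma) || sigma <= 1e-12) return(1e12)
    pred <- constrained_mean(fit, options, bmd0, free, d, bmr_fixed)
    if (is.null(pred)) return(1e12)
    rss <- sum((y - pred)^2)
    n / 2 * log(2 * pi * sigma^2) + rss / (2 * sigma^2)
  }
  opt <- stats::optim(unlist(free0), nll, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  opt2 <- tryCatch(
    stats::optim(opt$par, nll, method = "BFGS",
                 control = list(maxit = 100, reltol = 1e-10)),
    error = function(e) opt)
  -min(opt$value, opt2$value)
}

#' Profile-likelihood confidence bounds for the BMD
#'
#' Two one-sided limits at the configured confidence level: the BMD is
#' treated as a model parameter by eliminating the scale parameter through
#' the benchmark-response equation, and the profile log-likelihood is
#' compared against the chi-square (1 df) cutoff.
#'
#' @param fit A converged `bmd_fit`.
#' @param bmd The BMD from [compute_bmd()].
#' @param options A [bmd_options()].
#' @return Named numeric `c(bmdl, bmdu)`; a side that never crosses the
#'   cutoff within the search range is `NA` (not found).
#' @export
profile_bounds <- function(fit, bmd, options = bmd_options()) {
  if (is.na(bmd) || !isTRUE(fit$converged)) {
    return(c(bmdl = NA_real_, bmdu = NA_real_))
  }
  # direction of the benchmark crossing at the BMD itself (a non-monotone
  # mean curve can cross in the opposite direction of its endpoint change)
  delta_at_bmd <- stats::predict(fit, newdata = bmd) -
    stats::predict(fit, newdata = 0)
  fit$bmr_direction <- if (delta_at_bmd >= 0) 1 else -1
  cutoff <- stats::qchisq(2 * options$confidence - 1, df = 1)
  ll_hat <- fit$loglik
  # with a control-referenced benchmark response the BMR is a fixed
  # quantity, not a function of the profiled residual SD
  bmr_fixed <- if (options$sigma_source == "control") {
    options$bmr_mult * bmr_sigma(fit, options)
  } else NULL
  h <- function(b0) {
    2 * (ll_hat - profile_loglik(fit, options, b0, bmr_fixed)) - cutoff
  }
  h_bmd <- h(bmd)

  search_side <- function(direction) {
    b0 <- bmd
    factor <- if (direction < 0) 0.5 else 2
    limit <- if (direction < 0) bmd * 1e-6 else max(fit$data$dose) * 100
    prev <- bmd
    for (i in 1:30) {
      b0 <- b0 * factor
      if ((direction < 0 && b0 < limit) || (direction > 0 && b0 > limit)) {
        return(NA_real_)
      }
      val <- h(b0)
      if (is.finite(val) && val > 0) {
        lo <- min(prev, b0); hi <- max(prev, b0)
        root <- tryCatch(
          stats::uniroot(h, lower = lo, upper = hi,
                         tol = 1e-9 * max(bmd, 1))$root,
          error = function(e) NA_real_)
        return(root)
      }
      prev <- b0
    }
    NA_real_
  }
  if (!is.finite(h_bmd) || h_bmd > 0.01) {
    # the constrained profile cannot reproduce the unconstrained maximum:
    # the bounds are unreliable and reported as not found
    return(c(bmdl = NA_real_, bmdu = NA_real_))
  }
  c(bmdl = search_side(-1), bmdu = search_side(1))
}

#' Classify a BMD model fit as viable, questionable or unusable
#'
#' Unusable: the fit did not converge or no BMD was found. Questionable:
#' goodness-of-fit p <= `gof_alpha`, BMD/BMDL ratio above
#' `bmd_bmdl_ratio_max`, BMDL below `bmdl_floor_frac` times the lowest
#' nonzero dose, or BMDL not found. Viable otherwise.
#'
#' @param fit A `bmd_fit`.
#' @param bmd,bmdl BMD and lower confidence limit.
#' @param options A [bmd_options()].
#' @return Character scalar with attribute `reasons`.
#' @export
classify_viability <- function(fit, bmd, bmdl, options = bmd_options()) {
  if (!isTRUE(fit$converged) || is.na(bmd)) {
    return(structure("unusable",
                     reasons = if (!isTRUE(fit$converged)) "non-convergence"
                               else "no BMD in tested range"))
  }
  reasons <- character(0)
  if (fit$gof_p <= options$gof_alpha) {
    reasons <- c(reasons, sprintf("goodness-of-fit p = %.3g <= %.2f",
                                  fit$gof_p, options$gof_alpha))
  }
  lowest_nz <- min(fit$data$dose[fit$data$dose > 0])
  if (is.na(bmdl)) {
    # bounds are skipped when the fit already failed goodness-of-fit; only
    # report a missing BMDL when it was actually searched for
    if (fit$gof_p > options$gof_alpha) {
      reasons <- c(reasons, "BMDL not found")
    }
  } else {
    if (bmd / bmdl > options$bmd_bmdl_ratio_max) {
      reasons <- c(reasons, sprintf("BMD/BMDL = %.1f > %d", bmd / bmdl,
                                    options$bmd_bmdl_ratio_max))
    }
    if (bmdl < lowest_nz * options$bmdl_floor_frac) {
      reasons <- c(reasons, "BMDL below lowest nonzero dose / 10")
    }
  }
  if (length(reasons)) structure("questionable", reasons = reasons)
  else structure("viable", reasons = character(0))
}

evaluate_family <- function(data, family, options) {
  fit <- fit_model(data, family, options)
  bmd <- compute_bmd(fit, options)
  # a failed goodness-of-fit already makes the fit questionable, so the
  # (expensive) profile bounds are only computed for candidate fits
  needs_bounds <- isTRUE(fit$converged) && !is.na(bmd) &&
    fit$gof_p > options$gof_alpha
  bounds <- if (needs_bounds) profile_bounds(fit, bmd, options) else
    c(bmdl = NA_real_, bmdu = NA_real_)
  viability <- classify_viability(fit, bmd, bounds[["bmdl"]], options)
  list(fit = fit, bmd = bmd, bmdl = bounds[["bmdl"]],
       bmdu = bounds[["bmdu"]], viability = as.character(viability),
       reasons = attr(viability, "reasons"))
}

#' Fit all families with the highest-dose-dropping loop
#'
#' Fits every model family to the dose-response data, classifies each fit,
#' and selects the viable fit with the lowest AIC. When no fit is viable,
#' the highest dose is dropped and the loop repeats; once dropping has
#' reduced the data to `min_doses` dose levels the series is reported as
#' `"no viable model"` (results obtained at the floor are not accepted).
#' Data supplied with exactly `min_doses` levels are still fitted once.
#'
#' @param data Tibble with `dose` and `response`.
#' @param options A [bmd_options()].
#' @param families Model families to try (default all five).
#' @return A one-row tibble: `family`, `variant`, `bmd`, `bmdl`, `bmdu`,
#'   `viability`, `status` (`"viable"` or `"no viable model"`), `aic`,
#'   `gof_p`, `n_dropped`, and `doses_retained` (list column). The
#'   selected `bmd_fit` is kept in the `"fit"` attribute.
#' @export
dose_drop_fit <- function(data, options = bmd_options(),
                          families = bmd_families) {
  data <- check_dose_response(data)
  full_doses <- sort(unique(data$dose))
  current <- data
  n_dropped <- 0L
  repeat {
    doses <- sort(unique(current$dose))
    # reaching the dose floor is reported as "no viable model": results
    # from the minimum number of dose groups are never accepted
    if (length(doses) <= options$min_doses && n_dropped > 0L) {
      return(tibble::tibble(
        family = NA_character_, variant = NA_character_,
        bmd = NA_real_, bmdl = NA_real_, bmdu = NA_real_,
        viability = NA_character_, status = "no viable model",
        aic = NA_real_, gof_p = NA_real_,
        n_dropped = n_dropped, doses_retained = list(doses)
      ))
    }
    evals <- lapply(families, function(f) evaluate_family(current, f, options))
    viable <- Filter(function(e) e$viability == "viable", evals)
    if (length(viable)) {
      aics <- vapply(viable, function(e) e$fit$aic, numeric(1))
      best <- viable[[which.min(aics)]]
      out <- tibble::tibble(
        family = best$fit$family, variant = best$fit$variant,
        bmd = best$bmd, bmdl = best$bmdl, bmdu = best$bmdu,
        viability = "viable", status = "viable",
        aic = best$fit$aic, gof_p = best$fit$gof_p,
        n_dropped = n_dropped, doses_retained = list(doses)
      )
      attr(out, "fit") <- best$fit
      return(out)
    }
    if (length(doses) <= options$min_doses) {
      return(tibble::tibble(
        family = NA_character_, variant = NA_character_,
        bmd = NA_real_, bmdl = NA_real_, bmdu = NA_real_,
        viability = NA_character_, status = "no viable model",
        aic = NA_real_, gof_p = NA_real_,
        n_dropped = n_dropped, doses_retained = list(doses)
      ))
    }
    current <- dplyr::filter(current, .data$dose < max(doses))
    n_dropped <- n_dropped + 1L
  }
}

#' BMD screen over every (subsystem, chemical, sex) dose-response series
#'
#' Maps [dose_drop_fit()] over the per-animal subsystem activities of a
#' study.
#'
#' @param activity Long activity tibble from [subsystem_activity()]
#'   (typically after [filter_subsystems()]).
#' @param metadata Sample metadata (`sample_id`, `sex`, `chemical`, `dose`).
#' @param options A [bmd_options()].
#' @return Tibble with one row per (subsystem, chemical, sex) and the
#'   columns of [dose_drop_fit()].
#' @export
bmd_screen <- function(activity, metadata, options = bmd_options()) {
  metadata <- tibble::as_tibble(metadata)
  if ("dose_mg_per_kg" %in% names(metadata) && !"dose" %in% names(metadata)) {
    metadata <- dplyr::rename(metadata, dose = "dose_mg_per_kg")
  }
  joined <- dplyr::inner_join(activity, metadata, by = "sample_id")
  joined %>%
    dplyr::group_by(.data$subsystem, .data$chemical, .data$sex) %>%
    dplyr::group_modify(function(df, key) {
      dose_drop_fit(tibble::tibble(dose = df$dose, response = df$activity),
                    options = options)
    }) %>%
    dplyr::ungroup()
}

#' Remove BMD results that extrapolate beyond the tested doses
#'
#' Drops results whose BMD or BMDU lies above the highest retained dose or
#' below zero — such values describe the fitted curve rather than the
#' exposure range. Removals are recorded in the `"audit"` attribute.
#'
#' @param results Tibble from [bmd_screen()] or [dose_drop_fit()] rows.
#' @return Filtered tibble with attribute `audit`.
#' @export
filter_extrapolated <- function(results) {
  if (!nrow(results)) {
    attr(results, "audit") <- results
    return(results)
  }
  max_dose <- vapply(results$doses_retained, function(d) max(unlist(d)),
                     numeric(1))
  out_of_range <- results$status == "viable" &
    ((!is.na(results$bmd) & (results$bmd > max_dose | results$bmd < 0)) |
       (!is.na(results$bmdu) & results$bmdu > max_dose))
  audit <- results[out_of_range, ]
  out <- results[!out_of_range, ]
  attr(out, "audit") <- audit
  out
}
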