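table1_doses <- c(0, 0.15, 0.5, 1.4, 4, 12, 37, 111, 333, 1000)

test_that("noiseless linear data are recovered exactly", {
  d <- rep(table1_doses, each = 3)
  data <- tibble::tibble(dose = d, response = 2.5 + 0.013 * d)
  fit <- fit_model(data, "linear")
  expect_equal(fit$coefficients$a, 2.5, tolerance = 1e-6)
  expect_equal(fit$coefficients$b, 0.013, tolerance = 1e-6)
})

test_that("constant response yields no benchmark dose", {
  data <- tibble::tibble(dose = rep(table1_doses, each = 3), response = 1)
  fit <- fit_model(data, "linear")
  expect_lt(abs(fit$coefficients$b), 1e-10)
  expect_true(is.na(compute_bmd(fit)))
  v <- classify_viability(fit, NA_real_, NA_real_)
  expect_equal(as.character(v), "unusable")
})

test_that("hill parameters are recovered from simulated data", {
  data <- simulate_hill_data(a = 1, b = 0.5, c = 50, g = 2, sigma = 0.02,
                             seed = 21)
  fit <- fit_model(data, "hill")
  expect_equal(fit$coefficients$a, 1, tolerance = 0.25)
  expect_equal(fit$coefficients$b, 0.5, tolerance = 0.25)
  expect_equal(fit$coefficients$c, 50, tolerance = 0.25 * 50 / 50)
  expect_equal(fit$coefficients$g, 2, tolerance = 0.5)
})

test_that("linear-family BMD equals the closed form on every fit", {
  for (seed in 1:10) {
    data <- withr::with_seed(seed, tibble::tibble(
      dose = rep(table1_doses, each = 5),
      response = 1 + 0.002 * rep(table1_doses, each = 5) +
        stats::rnorm(50, 0, 0.3)))
    fit <- fit_model(data, "linear")
    opts <- bmd_options()
    bmd <- compute_bmd(fit, opts)
    sigma <- fluxbmd:::bmr_sigma(fit, opts)
    expected <- sigma / abs(fit$coefficients$b)
    if (expected <= max(data$dose)) {
      expect_equal(bmd, expected, tolerance = 1e-6)
    } else {
      expect_true(is.na(bmd))
    }
  }
})

test_that("power with g = 1 reduces to the linear closed form", {
  data <- withr::with_seed(3, tibble::tibble(
    dose = rep(table1_doses, each = 5),
    response = 1 + 0.004 * rep(table1_doses, each = 5) +
      stats::rnorm(50, 0, 0.4)))
  fit <- fit_model(data, "power")
  opts <- bmd_options()
  expect_equal(fit$coefficients$g, 1, tolerance = 1e-6)
  expect_equal(compute_bmd(fit, opts),
               fluxbmd:::bmr_sigma(fit, opts) / abs(fit$coefficients$b),
               tolerance = 1e-4)
})

test_that("root-found BMD matches a dense grid evaluation", {
  data <- simulate_hill_data(seed = 22)
  fit <- fit_model(data, "hill")
  opts <- bmd_options()
  bmd <- compute_bmd(fit, opts)
  bmr <- opts$bmr_mult * fluxbmd:::bmr_sigma(fit, opts)
  fn <- fluxbmd:::bmd_mean_fn("hill", NA)
  grid <- seq(0, max(data$dose), length.out = 200001)
  dev <- abs(fn(grid, fit$coefficients) - fn(0, fit$coefficients))
  grid_bmd <- grid[which(dev >= bmr)[1]]
  expect_equal(bmd, grid_bmd, tolerance = 1e-3)
})

test_that("profile bounds bracket the BMD tightly under strong signal", {
  data <- simulate_hill_data(sigma = 0.004, seed = 23)
  res <- dose_drop_fit(data)
  expect_equal(res$status, "viable")
  expect_true(res$bmdl <= res$bmd && res$bmd <= res$bmdu)
  expect_lt((res$bmdu - res$bmdl) / res$bmd, 0.35)

  # near-noiseless: the interval collapses onto the BMD
  data0 <- simulate_hill_data(sigma = 1e-4, seed = 24)
  fit0 <- fit_model(data0, "hill")
  bmd0 <- compute_bmd(fit0)
  b0 <- profile_bounds(fit0, bmd0)
  expect_lt((b0[["bmdu"]] - b0[["bmdl"]]) / bmd0, 0.1)
})

test_that("weak signal widens or loses the upper bound", {
  data <- withr::with_seed(25, tibble::tibble(
    dose = rep(table1_doses, each = 5),
    response = 1 + 1e-5 * log1p(rep(table1_doses, each = 5)) +
      stats::rnorm(50, 0, 0.05)))
  fit <- fit_model(data, "power")
  bmd <- compute_bmd(fit)
  if (!is.na(bmd)) {
    b <- profile_bounds(fit, bmd)
    wide <- is.na(b[["bmdu"]]) ||
      (b[["bmdu"]] - b[["bmdl"]]) > 0.5 * max(data$dose)
    expect_true(wide || b[["bmdl"]] < min(table1_doses[table1_doses > 0]))
  } else {
    succeed("benchmark response not reached, as expected for weak signal")
  }
})

test_that("interval ordering holds across seeded simulations", {
  ok <- 0; n <- 0
  for (seed in 1:25) {
    data <- simulate_hill_data(sigma = 0.03, seed = 300 + seed)
    fit <- fit_model(data, "exponential")
    bmd <- compute_bmd(fit)
    if (is.na(bmd)) next
    b <- profile_bounds(fit, bmd)
    if (is.na(b[["bmdl"]])) next
    n <- n + 1
    upper_ok <- is.na(b[["bmdu"]]) || bmd <= b[["bmdu"]] + 1e-9
    if (b[["bmdl"]] <= bmd + 1e-9 && upper_ok) ok <- ok + 1
  }
  expect_gte(n, 15)
  expect_equal(ok, n)
})

test_that("viability classification applies the recommended-logic rules", {
  # clean strong signal: viable
  data <- simulate_hill_data(sigma = 0.01, seed = 40)
  ev <- fluxbmd:::evaluate_family(data, "hill", bmd_options())
  expect_equal(ev$viability, "viable")

  # failed goodness of fit: questionable
  fit <- fit_model(data, "hill")
  fit$gof_p <- 0.01
  v <- classify_viability(fit, 10, 5)
  expect_equal(as.character(v), "questionable")
  expect_match(attr(v, "reasons"), "goodness-of-fit", all = FALSE)

  # BMD/BMDL ratio beyond 20: questionable
  fit$gof_p <- 0.5
  v2 <- classify_viability(fit, 10, 0.4)
  expect_equal(as.character(v2), "questionable")

  # BMDL below lowest nonzero dose / 10: questionable
  v3 <- classify_viability(fit, 0.1, 0.01)
  expect_equal(as.character(v3), "questionable")

  # non-convergence: unusable
  bad <- structure(list(family = "hill", converged = FALSE, data = data),
                   class = "bmd_fit")
  expect_equal(as.character(classify_viability(bad, NA, NA)), "unusable")
})

test_that("dose dropping reproduces zero-drop, one-drop and exhaustion", {
  # strong clean signal: viable with no drops
  clean <- simulate_hill_data(sigma = 0.01, seed = 27)
  res <- dose_drop_fit(clean)
  expect_equal(res$status, "viable")
  expect_equal(res$n_dropped, 0L)

  # response reversal confined to the top dose breaks the fit until the
  # top dose is dropped
  onedrop <- simulate_hill_data(a = 1, b = 0.5, c = 10, g = 3,
                                sigma = 0.005, seed = 28)
  onedrop$response[onedrop$dose == 1000] <- 1.0
  res1 <- dose_drop_fit(onedrop)
  expect_equal(res1$status, "viable")
  expect_equal(res1$n_dropped, 1L)
  expect_equal(max(unlist(res1$doses_retained)), 333)

  # a null draw that no family fits acceptably at any drop level: the
  # loop exhausts to the three-dose floor
  noise <- withr::with_seed(33, tibble::tibble(
    dose = rep(table1_doses, each = 5),
    response = stats::rnorm(50)))
  res2 <- dose_drop_fit(noise)
  expect_equal(res2$status, "no viable model")
  expect_equal(length(unlist(res2$doses_retained)), 3)
  expect_gte(length(unlist(res2$doses_retained)), 3)
})

test_that("extrapolation filtering removes out-of-range results", {
  results <- tibble::tibble(
    subsystem = c("a", "b", "c", "d"),
    family = "linear", variant = NA_character_,
    bmd = c(1.4, 500, 900, NA),
    bmdl = c(1, 400, 800, NA),
    bmdu = c(2, 1200, 950, NA),
    viability = c("viable", "viable", "viable", NA),
    status = c("viable", "viable", "viable", "no viable model"),
    aic = 0, gof_p = 0.5, n_dropped = 0L,
    doses_retained = list(table1_doses, table1_doses, table1_doses,
                          table1_doses))
  kept <- filter_extrapolated(results)
  expect_setequal(kept$subsystem, c("a", "c", "d"))
  expect_equal(attr(kept, "audit")$subsystem, "b")
  empty <- filter_extrapolated(results[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("stronger effects give smaller benchmark doses on matched seeds", {
  smaller <- 0
  for (seed in 1:20) {
    weak <- simulate_hill_data(b = 0.2, sigma = 0.03, seed = 500 + seed)
    strong <- simulate_hill_data(b = 0.8, sigma = 0.03, seed = 500 + seed)
    bw <- dose_drop_fit(weak)
    bs <- dose_drop_fit(strong)
    if (bw$status == "viable" && bs$status == "viable" &&
        bs$bmd < bw$bmd) {
      smaller <- smaller + 1
    }
  }
  expect_gte(smaller, 16) # strictly smaller BMD in nearly all pairs
})

test_that("fit metadata follows the AIC definition", {
  data <- simulate_hill_data(seed = 30)
  fit <- fit_model(data, "linear")
  expect_equal(fit$aic, 2 * fit$k - 2 * fit$loglik)
  expect_equal(fit$k, 3) # intercept, slope, variance
  gl <- glance(fit)
  expect_equal(gl$AIC, fit$aic)
  td <- tidy(fit)
  expect_setequal(td$term, c("a", "b"))
})
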