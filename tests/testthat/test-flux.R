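test_that("the chain polytope has one degree of freedom", {
  net <- chain_network()
  irr <- split_reversible(net)
  pol <- build_polytope(irr)
  S <- as.matrix(pol$S)
  expect_equal(ncol(S) - qr(S)$rank, 1)
  # zero vector feasible when all LB = 0
  expect_true(all(pol$lb == 0))
})

test_that("infeasible bounds are rejected at polytope construction", {
  net <- chain_network()
  net$reactions$lower_bound[2] <- 20
  net$reactions$upper_bound[2] <- 10
  expect_error(metabolic_network(net$reactions, net$metabolites,
                                 net$stoichiometry),
               "lower bound exceeds")
})

test_that("uniform expression on an irreversible chain gives D_KL = 0", {
  net <- chain_network()
  irr <- split_reversible(net)
  pol <- build_polytope(irr)
  g <- stats::setNames(rep(2, 4), irr$reactions$id)
  f <- infer_fluxome(pol, g)
  expect_equal(f$status, "optimal")
  # stoichiometry forces uniform fluxes; Q is uniform, so P = Q
  expect_lt(f$d_kl, 1e-6)
  expect_lt(diff(range(f$v_irr)), 1e-8)
})

test_that("branch expression splits flux in proportion when P = Q is feasible", {
  net <- branch_network()
  irr <- split_reversible(net)
  pol <- build_polytope(irr)
  g <- c(EX_in = 2, R1 = 1.5, R2 = 0.5, EX_out = 2)
  f <- infer_fluxome(pol, g[irr$reactions$id])
  expect_equal(f$status, "optimal")
  expect_lt(f$d_kl, 1e-8)
  expect_equal(unname(f$v["R1"] / f$v["R2"]), 3, tolerance = 1e-4)
  # independent 1-D verification
  oracle <- grid_search_kl(net, g[irr$reactions$id], n_per_dim = 400)
  expect_lt(abs(f$d_kl - oracle$objective), 1e-4)
})

test_that("solver matches the brute-force oracle on small polytopes", {
  nets <- list(chain_network(), branch_network(), two_chain_network(),
               double_branch_network(), stoich_chain_network())
  withr::with_seed(42, {
    for (net in nets) {
      irr <- split_reversible(net)
      pol <- build_polytope(irr)
      for (rep in 1:2) {
        g <- stats::setNames(stats::rlnorm(nrow(irr$reactions), log(10), 0.7),
                             irr$reactions$id)
        f <- infer_fluxome(pol, g)
        expect_equal(f$status, "optimal")
        oracle <- grid_search_kl(net, g, n_per_dim = 40)
        # solver must not exceed the grid minimum by more than grid error
        expect_lt(f$d_kl, oracle$objective + 1e-4)
        expect_lt(abs(f$d_kl - oracle$objective), 5e-3)
      }
    }
  })
})

test_that("the objective is invariant to expression scale", {
  net <- two_chain_network()
  irr <- split_reversible(net)
  pol <- build_polytope(irr)
  g <- stats::setNames(seq(1, 7), irr$reactions$id)
  f1 <- infer_fluxome(pol, g)
  f2 <- infer_fluxome(pol, g * 1000)
  expect_equal(f1$v, f2$v, tolerance = 1e-9)
  expect_equal(f1$d_kl, f2$d_kl, tolerance = 1e-9)
})

test_that("steady-state checks accept solved and reject broken fluxomes", {
  net <- chain_network()
  irr <- split_reversible(net)
  f <- infer_fluxome(build_polytope(irr),
                     stats::setNames(1:4, irr$reactions$id))
  expect_true(check_steady_state(f, tol = 1e-6))
  v_bad <- stats::setNames(c(1, 5, 1, 1), net$reactions$id)
  expect_false(check_steady_state(v_bad, tol = 1e-6, network = net))
  v_zero <- stats::setNames(rep(0, 4), net$reactions$id)
  ok <- check_steady_state(v_zero, tol = 1e-6, network = net)
  expect_true(ok)
  expect_equal(attr(ok, "residual"), 0)
})

test_that("forced lower bounds route through the box-constrained solver", {
  net <- two_chain_network()
  # cap total uptake and force the pb pathway to carry a minimum flux:
  # rescaling alone cannot satisfy both, so the flux proportions must move
  net$reactions$lower_bound[net$reactions$id == "R2a"] <- 0.4
  net$reactions$upper_bound[net$reactions$id == "EX_in"] <- 1
  irr <- split_reversible(net)
  pol <- build_polytope(irr)
  # expression strongly favouring the pa pathway
  g <- c(EX_in = 10, R1a = 20, R1b = 20, R2a = 0.5, R2b = 0.5,
         EX_a = 10, EX_b = 10)
  f <- infer_fluxome(pol, g[irr$reactions$id])
  expect_equal(f$status, "optimal")
  expect_true(f$box_constrained)
  expect_gte(f$v[["R2a"]], 0.4 - 1e-6)
  expect_lte(f$v[["EX_in"]], 1 + 1e-6)
  expect_lt(f$residual, 1e-6)
  # the unconstrained proportions put far less than 40% on R2a
  net0 <- two_chain_network()
  f0 <- infer_fluxome(build_polytope(split_reversible(net0)),
                      g[irr$reactions$id])
  expect_lt(f0$v[["R2a"]] / sum(abs(f0$v[1])), 0.4)
  expect_lte(f0$d_kl, f$d_kl + 1e-9)
})

test_that("cohort inference is per-sample, deterministic and order-free", {
  net <- make_toy_network(2, 4, seed = 6)
  design <- make_design(list(chem = c(0, 1, 10)), sexes = "male",
                        n_control = 2, n_per_dose = 2)
  es <- simulate_expression(design, net, list(), seed = 5)
  cohort <- infer_cohort(net, es)
  expect_equal(ncol(cohort$fluxes), 6)
  expect_equal(cohort$manifest$status, rep("optimal", 6))

  # identical expression -> identical fluxome
  vals <- es$values
  vals[, 2] <- vals[, 1]
  es2 <- expression_set(vals, es$metadata, scale = "log2")
  c2 <- infer_cohort(net, es2)
  expect_equal(c2$fluxes[, 1], c2$fluxes[, 2], tolerance = 1e-10)

  # permuting sample order permutes, not changes, results
  perm <- c(4, 2, 6, 1, 3, 5)
  es3 <- expression_set(es$values[, perm], es$metadata[perm, ],
                        scale = "log2")
  c3 <- infer_cohort(net, es3)
  expect_equal(c3$fluxes[, colnames(cohort$fluxes)], cohort$fluxes,
               tolerance = 1e-10)
})

test_that("fluxome tidy method returns a reaction table", {
  study <- fixture_study()
  irr <- study$cohort$irreversible
  g <- reaction_expression(irr, linear_values(study$es)[, 1])
  f <- infer_fluxome(build_polytope(irr), g)
  tbl <- tidy(f, network = study$net)
  expect_named(tbl, c("reaction", "flux", "subsystem"))
  expect_equal(nrow(tbl), nrow(study$net$reactions))
})
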