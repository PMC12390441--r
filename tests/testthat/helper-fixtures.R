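# Shared fixtures and independent oracles for the test suite.

# --- small hand-built networks --------------------------------------------

# Irreversible linear chain: uptake -> A -> B -> secretion (1 free dim).
chain_network <- function() {
  rx <- tibble::tibble(
    id = c("EX_in", "R1", "R2", "EX_out"),
    lower_bound = 0, upper_bound = 1000,
    gpr = "", subsystem = "chain", major_pathway = NA_character_,
    is_exchange = c(TRUE, FALSE, FALSE, TRUE)
  )
  mets <- tibble::tibble(id = c("A", "B", "C"))
  S <- matrix(c(1, 0, 0,
                -1, 1, 0,
                0, -1, 1,
                0, 0, -1), nrow = 3)
  suppressWarnings(metabolic_network(rx, mets, S))
}

# Branch: uptake -> A, two parallel A -> B routes, secretion of B.
branch_network <- function() {
  rx <- tibble::tibble(
    id = c("EX_in", "R1", "R2", "EX_out"),
    lower_bound = 0, upper_bound = 1000,
    gpr = "", subsystem = "branch", major_pathway = NA_character_,
    is_exchange = c(TRUE, FALSE, FALSE, TRUE)
  )
  mets <- tibble::tibble(id = c("A", "B"))
  S <- matrix(c(1, 0,
                -1, 1,
                -1, 1,
                0, -1), nrow = 2)
  suppressWarnings(metabolic_network(rx, mets, S))
}

# Two chains from a shared hub (2 free dims).
two_chain_network <- function() {
  rx <- tibble::tibble(
    id = c("EX_in", "R1a", "R1b", "R2a", "R2b", "EX_a", "EX_b"),
    lower_bound = 0, upper_bound = 1000,
    gpr = "", subsystem = c("boundary", "pa", "pa", "pb", "pb",
                            "boundary", "boundary"),
    major_pathway = NA_character_,
    is_exchange = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  )
  mets <- tibble::tibble(id = c("H", "A1", "A2", "B1", "B2"))
  S <- matrix(0, nrow = 5, ncol = 7,
              dimnames = list(mets$id, rx$id))
  S["H", "EX_in"] <- 1
  S["H", "R1a"] <- -1; S["A1", "R1a"] <- 1
  S["A1", "R1b"] <- -1; S["A2", "R1b"] <- 1
  S["H", "R2a"] <- -1; S["B1", "R2a"] <- 1
  S["B1", "R2b"] <- -1; S["B2", "R2b"] <- 1
  S["A2", "EX_a"] <- -1
  S["B2", "EX_b"] <- -1
  suppressWarnings(metabolic_network(rx, mets, S))
}

# Double branch, 3 free dims: hub -> {A|B}, A -> {C|D}, all secreted.
double_branch_network <- function() {
  rx <- tibble::tibble(
    id = c("EX_in", "RA", "RB", "RC", "RD", "EX_b", "EX_c", "EX_d"),
    lower_bound = 0, upper_bound = 1000,
    gpr = "", subsystem = "net", major_pathway = NA_character_,
    is_exchange = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  )
  mets <- tibble::tibble(id = c("H", "A", "B", "C", "D"))
  S <- matrix(0, nrow = 5, ncol = 8, dimnames = list(mets$id, rx$id))
  S["H", "EX_in"] <- 1
  S["H", "RA"] <- -1; S["A", "RA"] <- 1
  S["H", "RB"] <- -1; S["B", "RB"] <- 1
  S["A", "RC"] <- -1; S["C", "RC"] <- 1
  S["A", "RD"] <- -1; S["D", "RD"] <- 1
  S["B", "EX_b"] <- -1
  S["C", "EX_c"] <- -1
  S["D", "EX_d"] <- -1
  suppressWarnings(metabolic_network(rx, mets, S))
}

# Chain with non-unit stoichiometry: A -> 2 B (1 free dim).
stoich_chain_network <- function() {
  rx <- tibble::tibble(
    id = c("EX_in", "R1", "EX_out"),
    lower_bound = 0, upper_bound = 1000,
    gpr = "", subsystem = "chain", major_pathway = NA_character_,
    is_exchange = c(TRUE, FALSE, TRUE)
  )
  mets <- tibble::tibble(id = c("A", "B"))
  S <- matrix(c(1, 0,
                -1, 2,
                0, -1), nrow = 2)
  suppressWarnings(metabolic_network(rx, mets, S))
}

# --- independent brute-force KL oracle ------------------------------------
# Grid search over null-space coordinates of the irreversible network;
# written from first principles (svd null space, direct KL evaluation)
# and independent of the solver implementation.
grid_search_kl <- function(net, g, n_per_dim = 60, zoom = 0) {
  irr <- split_reversible(net)
  S <- as.matrix(irr$stoichiometry)
  lb <- irr$reactions$lower_bound
  ub <- irr$reactions$upper_bound
  sv <- svd(S, nu = 0, nv = ncol(S))
  rank <- sum(sv$d > max(dim(S)) * max(sv$d) * .Machine$double.eps)
  stopifnot(rank < ncol(S))
  N <- sv$v[, (rank + 1):ncol(S), drop = FALSE]
  k <- ncol(N)
  stopifnot(k <= 3)
  qn <- g / sum(g)
  logq <- log(qn + 1e-9)

  eval_box <- function(centers, half) {
    axes <- lapply(seq_len(k), function(j) {
      seq(centers[j] - half, centers[j] + half, length.out = n_per_dim)
    })
    pts <- as.matrix(expand.grid(axes))
    V <- pts %*% t(N)
    ok <- rowSums(V < lb - 1e-12) == 0 & rowSums(V > ub + 1e-12) == 0 &
      rowSums(V) > 1e-8
    V <- V[ok, , drop = FALSE]
    pts <- pts[ok, , drop = FALSE]
    P <- V / rowSums(V)
    terms <- P * (log(P + 1e-9) - matrix(logq, nrow(P), ncol(P),
                                         byrow = TRUE))
    terms[P <= 0] <- 0
    kl <- rowSums(terms)
    i <- which.min(kl)
    list(objective = kl[i], t = pts[i, ], v = V[i, ] / sum(V[i, ]))
  }

  # coordinate box covering the unit-total-flux region, then local zooms
  best <- eval_box(rep(0, k), 2)
  half <- 2 * 2 / (n_per_dim - 1)
  for (z in seq_len(zoom)) {
    cand <- eval_box(best$t, half)
    if (cand$objective < best$objective) best <- cand
    half <- half * 2 / (n_per_dim - 1)
  }
  list(objective = best$objective, v = best$v)
}

# --- cached study fixture --------------------------------------------------
.fixture_cache <- new.env(parent = emptyenv())

fixture_study <- function() {
  if (is.null(.fixture_cache$study)) {
    net <- make_toy_network(4, 5, seed = 1)
    design <- make_design(default_dose_grids()["6:1 FTOH"], sexes = "male")
    es <- simulate_expression(design, net,
                              list(effect_spec("subsystem_A")), seed = 3)
    cohort <- infer_cohort(net, es)
    activity <- filter_subsystems(subsystem_activity(cohort), net)
    .fixture_cache$study <- list(net = net, design = design, es = es,
                                 cohort = cohort, activity = activity)
  }
  .fixture_cache$study
}

# Hill-shaped dose-response simulator for BMD-level tests (independent of
# the flux machinery).
simulate_hill_data <- function(a = 1, b = 0.5, c = 50, g = 2, sigma = 0.02,
                               doses = c(0, 0.15, 0.5, 1.4, 4, 12, 37, 111,
                                         333, 1000),
                               n_control = 10, n_per_dose = 5, seed = 1) {
  withr::with_seed(seed, {
    d <- rep(doses, times = c(n_control,
                              rep(n_per_dose, length(doses) - 1)))
    mu <- a + b * d^g / (c^g + d^g)
    tibble::tibble(dose = d, response = mu + stats::rnorm(length(d), 0, sigma))
  })
}
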