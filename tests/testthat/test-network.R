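test_that("toy network has the constructed counts and annotations", {
  net <- make_toy_network(4, 5, seed = 1)
  s <- summarize_network(net)
  # 4 subsystems x 5 internal + 4 secretions + shared uptake + transport
  expect_equal(s$n_reactions, 26)
  # 2 shared metabolites + 4 chains of 4
  expect_equal(s$n_metabolites, 18)
  expect_equal(s$n_subsystems, 6) # 4 metabolic + exchange + transport
  expect_true(all(c("exchange", "transport") %in% net$reactions$subsystem))
  expect_true(all(net$reactions$gpr[!net$reactions$is_exchange] != ""))
})

test_that("reactions without a subsystem are labelled miscellaneous", {
  rx <- tibble::tibble(id = c("R1", "R2"), lower_bound = 0, upper_bound = 10,
                       subsystem = c("glycolysis", NA))
  S <- matrix(c(1, -1), nrow = 1, dimnames = list("A", NULL))
  expect_warning(
    net <- metabolic_network(rx, tibble::tibble(id = "A"), S),
    "miscellaneous")
  expect_equal(net$reactions$subsystem, c("glycolysis", "miscellaneous"))
})

test_that("network validation rejects inconsistent inputs", {
  mets <- tibble::tibble(id = "A")
  S <- matrix(1, nrow = 1)
  expect_error(
    metabolic_network(tibble::tibble(id = "R1", lower_bound = 5,
                                     upper_bound = 1, subsystem = "s"),
                      mets, S),
    "lower bound exceeds")
  expect_error(
    metabolic_network(tibble::tibble(id = "R1", lower_bound = NA_real_,
                                     upper_bound = 1, subsystem = "s"),
                      mets, S),
    "missing bounds")
})

test_that("exchange defaults open boundary reactions to [-1000, 1000]", {
  net <- chain_network()
  net$reactions$lower_bound[1] <- -5
  net$reactions$upper_bound[1] <- 5
  out <- apply_exchange_defaults(net)
  expect_equal(out$reactions$lower_bound[1], -1000)
  expect_equal(out$reactions$upper_bound[1], 1000)
  # internal bounds untouched
  expect_equal(out$reactions$lower_bound[2], 0)
  expect_equal(out$reactions$upper_bound[2], 1000)
  # no exchanges -> identity
  net2 <- chain_network()
  net2$reactions$is_exchange <- FALSE
  expect_equal(apply_exchange_defaults(net2)$reactions, net2$reactions)
})

test_that("reversible splitting maps bounds and negates columns", {
  net <- chain_network()
  net$reactions$lower_bound[1] <- -1000 # make uptake reversible
  irr <- split_reversible(net)
  expect_equal(nrow(irr$reactions), 5) # 4 + 1 backward
  bwd <- irr$reactions[irr$reactions$direction == "backward", ]
  expect_equal(bwd$base_id, "EX_in")
  expect_equal(bwd$lower_bound, 0)
  expect_equal(bwd$upper_bound, 1000)
  expect_equal(as.numeric(irr$stoichiometry[, bwd$id]),
               -as.numeric(irr$stoichiometry[, "EX_in"]))
  # irreversible reactions unchanged
  expect_equal(irr$reactions$upper_bound[irr$reactions$id == "R1"], 1000)
})

test_that("recombined irreversible fluxes satisfy the base steady state", {
  net <- apply_exchange_defaults(make_toy_network(3, 4, seed = 2))
  irr <- split_reversible(net)
  N <- nrow(irr$reactions)
  S_irr <- as.matrix(irr$stoichiometry)
  sv <- svd(S_irr, nu = 0, nv = N)
  rank <- sum(sv$d > 1e-10)
  basis <- sv$v[, (rank + 1):N, drop = FALSE]
  withr::with_seed(7, {
    for (i in 1:20) {
      v <- as.numeric(basis %*% rnorm(ncol(basis)))
      v_net <- recombine_fluxes(irr, v)
      resid <- max(abs(as.numeric(net$stoichiometry %*% v_net)))
      expect_lt(resid, 1e-9)
    }
  })
})

test_that("network summary is invariant to reaction order", {
  net <- make_toy_network(3, 4, seed = 5)
  perm <- withr::with_seed(1, sample(nrow(net$reactions)))
  net2 <- metabolic_network(net$reactions[perm, ], net$metabolites,
                            net$stoichiometry[, perm], genes = net$genes)
  expect_equal(summarize_network(net2), summarize_network(net))
})

test_that("SBML round trip preserves the network", {
  net <- make_toy_network(4, 5, seed = 11)
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(net, path)
  net2 <- load_network(path)
  idx <- match(net$reactions$id, net2$reactions$id)
  expect_false(anyNA(idx))
  expect_equal(net2$reactions$lower_bound[idx], net$reactions$lower_bound)
  expect_equal(net2$reactions$upper_bound[idx], net$reactions$upper_bound)
  expect_equal(net2$reactions$subsystem[idx], net$reactions$subsystem)
  expect_equal(net2$reactions$major_pathway[idx], net$reactions$major_pathway)
  expect_equal(net2$reactions$gpr[idx], net$reactions$gpr)
  expect_setequal(net2$genes, net$genes)
  expect_equal(as.matrix(net2$stoichiometry[, idx]),
               as.matrix(net$stoichiometry),
               ignore_attr = TRUE)
})

test_that("SBML writing is byte-deterministic per seed", {
  p1 <- withr::local_tempfile(fileext = ".xml")
  p2 <- withr::local_tempfile(fileext = ".xml")
  write_sbml(make_toy_network(3, 4, seed = 9), p1)
  write_sbml(make_toy_network(3, 4, seed = 9), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("malformed SBML and missing bounds give informative errors", {
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model><unclosed></model></sbml>", bad)
  expect_error(load_network(bad), "malformed SBML")

  nobounds <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="m"><listOfSpecies>',
    '<species id="M_a" compartment="c"/></listOfSpecies>',
    '<listOfReactions><reaction id="R_r1" reversible="false">',
    '<listOfProducts><speciesReference species="M_a" stoichiometry="1"/></listOfProducts>',
    '</reaction></listOfReactions></model></sbml>'), nobounds)
  expect_error(load_network(nobounds), "without flux bounds.*r1")

  expect_error(load_network("/nonexistent/file.xml"), "no such file")
})

test_that("sidecar pathway mapping fills major pathways", {
  net <- chain_network()
  mapped <- apply_pathway_map(
    net, tibble::tibble(subsystem = "chain",
                        major_pathway = "central carbon"))
  expect_equal(unique(mapped$reactions$major_pathway), "central carbon")
})

test_that("generated SBML is readable by an independent parser", {
  # cobrapy as an external oracle for the SBML dialect
  py <- Sys.which("python")
  skip_if(py == "", "python not available")
  net <- make_toy_network(4, 5, seed = 1)
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(net, path)
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys, cobra",
    sprintf("m = cobra.io.read_sbml_model('%s')", path),
    "print(len(m.reactions), len(m.metabolites), len(m.genes), len(m.groups))"
  ), script)
  out <- tryCatch(system2(py, script, stdout = TRUE, stderr = TRUE),
                  warning = function(w) NULL)
  skip_if(is.null(out) || !length(out), "cobra unavailable")
  nums <- suppressWarnings(as.integer(strsplit(utils::tail(out, 1), " ")[[1]]))
  skip_if(anyNA(nums), "cobra output not parseable")
  expect_equal(nums[1], nrow(net$reactions))
  expect_equal(nums[2], nrow(net$metabolites))
  expect_equal(nums[3], length(net$genes))
  expect_equal(nums[4], length(unique(net$reactions$subsystem)))
})
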