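make_activity_network <- function(subsystems, genes_per = 2) {
  # one reaction per subsystem, n genes each, minimal 1-met stoichiometry
  n <- length(subsystems)
  gid <- 0
  gprs <- vapply(seq_len(n), function(i) {
    if (genes_per == 0) return("")
    g <- paste0("g", gid + seq_len(genes_per))
    gid <<- gid + genes_per
    paste(g, collapse = " or ")
  }, character(1))
  rx <- tibble::tibble(id = paste0("R", seq_len(n)), lower_bound = 0,
                       upper_bound = 1000, gpr = gprs,
                       subsystem = subsystems, major_pathway = NA,
                       is_exchange = FALSE)
  S <- matrix(0, nrow = 1, ncol = n, dimnames = list("A", rx$id))
  suppressWarnings(metabolic_network(rx, tibble::tibble(id = "A"), S))
}

test_that("subsystem activity is the normalized mean absolute flux", {
  net <- make_activity_network(c("X", "X", "Y", "Y", "Y"))
  fluxes <- matrix(c(2, -4, 1, 1, 0), ncol = 1,
                   dimnames = list(net$reactions$id, "s1"))
  act <- subsystem_activity(fluxes, network = net, normalize = FALSE)
  expect_equal(act$activity[act$subsystem == "X"], 3)  # mean(|2|, |-4|)
  expect_equal(act$activity[act$subsystem == "Y"], 2 / 3)
  norm <- subsystem_activity(fluxes, network = net)
  expect_equal(norm$activity[norm$subsystem == "X"], 3 / 8)
  # scale invariance
  norm10 <- subsystem_activity(fluxes * 10, network = net)
  expect_equal(norm10$activity, norm$activity)
  # all-zero subsystem has activity 0
  fluxes2 <- matrix(c(2, -4, 0, 0, 0), ncol = 1,
                    dimnames = list(net$reactions$id, "s1"))
  a2 <- subsystem_activity(fluxes2, network = net)
  expect_equal(a2$activity[a2$subsystem == "Y"], 0)
  # degenerate all-zero fluxome errors
  expect_error(subsystem_activity(fluxes * 0, network = net), "degenerate")
})

test_that("subsystem filtering drops listed gene-poor and constant rows", {
  # 58 subsystems: 7 named non-metabolic with < 2 genes, 6 constant,
  # 45 informative -- mirrors the documented filtering outcome
  listed <- c("miscellaneous", "artificial reactions", "pool reactions",
              "biomass", "exchange", "isolated", "transport")
  informative <- sprintf("pathway_%02d", 1:45)
  constant <- sprintf("constant_%02d", 1:6)
  all_ss <- c(listed, constant, informative)
  net <- make_activity_network(all_ss, genes_per = 2)
  # listed subsystems get a single gene
  net$reactions$gpr[match(listed, net$reactions$subsystem)] <- "gsolo"
  net$genes <- unique(c(net$genes, "gsolo"))

  withr::with_seed(8, {
    activity <- tidyr::expand_grid(subsystem = all_ss,
                                   sample_id = paste0("s", 1:6)) %>%
      dplyr::mutate(activity = stats::runif(dplyr::n()))
  })
  activity$activity[activity$subsystem %in% constant] <- 0.25

  kept <- filter_subsystems(activity, net)
  expect_equal(dplyr::n_distinct(kept$subsystem), 45)
  expect_setequal(unique(kept$subsystem), informative)
  audit <- attr(kept, "audit")
  expect_equal(nrow(audit), 13)

  # idempotence
  again <- filter_subsystems(kept, net)
  expect_equal(dplyr::n_distinct(again$subsystem), 45)
  expect_equal(nrow(attr(again, "audit")), 0)

  # case-insensitive list matching
  net2 <- make_activity_network(c("Exchange", "real"), genes_per = 2)
  net2$reactions$gpr[1] <- "gsolo"
  net2$genes <- unique(c(net2$genes, "gsolo"))
  act2 <- tibble::tibble(
    subsystem = rep(c("Exchange", "real"), each = 3),
    sample_id = rep(paste0("s", 1:3), 2),
    activity = c(1, 2, 3, 4, 5, 6))
  kept2 <- filter_subsystems(act2, net2)
  expect_equal(unique(kept2$subsystem), "real")

  # nothing to drop -> identity
  act3 <- dplyr::filter(activity, .data$subsystem %in% informative)
  expect_equal(nrow(filter_subsystems(act3, net)), nrow(act3))
})

test_that("group means pool controls per chemical and sex", {
  activity <- tibble::tibble(
    subsystem = "ss",
    sample_id = paste0("s", 1:5),
    activity = c(1, 2, 3, 10, 20))
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:5),
    sex = "male", chemical = "chemA",
    dose = c(0, 0, 0, 5, 5))
  gm <- group_means(activity, meta)
  expect_equal(gm$mean[gm$dose == 0], 2)
  expect_equal(gm$n[gm$dose == 0], 3L)
  expect_equal(gm$mean[gm$dose == 5], 15)

  # single-animal group: SD is NA, mean is the value
  meta1 <- meta
  meta1$dose[5] <- 7
  gm1 <- group_means(activity, meta1)
  expect_equal(gm1$mean[gm1$dose == 7], 20)
  expect_true(is.na(gm1$sd[gm1$dose == 7]))

  # two chemicals with disjoint samples summarize independently
  meta2 <- meta
  meta2$chemical <- c("A", "A", "B", "A", "B")
  gm2 <- group_means(activity, meta2)
  expect_equal(gm2$mean[gm2$chemical == "B" & gm2$dose == 0], 3)
  expect_equal(gm2$mean[gm2$chemical == "A" & gm2$dose == 0], 1.5)
})

test_that("z-scores are control-referenced in SD units", {
  base <- tibble::tibble(
    subsystem = "ss", chemical = "c", sex = "male",
    dose = c(0, 1, 2, 3),
    mean = c(10, 10, 14, 8), sd = c(2, 1, 1, 1), n = 5L)
  z <- z_scores(base)
  expect_equal(z$z[z$dose == 1], 0)
  expect_equal(z$z[z$dose == 2], 2)
  expect_equal(z$z[z$dose == 3], -1)
  # zero control SD flags NA
  base0 <- dplyr::mutate(base, sd = dplyr::if_else(dose == 0, 0, sd))
  z0 <- z_scores(base0)
  expect_true(all(is.na(z0$z)))
  expect_equal(nrow(z0), 3)
})

test_that("Mann-Whitney flags use the exact small-sample distribution", {
  act <- tibble::tibble(
    subsystem = "ss",
    sample_id = paste0("s", 1:15),
    activity = c(1:10, 11:15)) # complete separation
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:15), sex = "male", chemical = "c",
    dose = c(rep(0, 10), rep(5, 5)))
  mw <- mann_whitney_flags(act, meta)
  expect_equal(mw$p_value, 2 / 3003, tolerance = 1e-12)
  expect_true(mw$significant)

  # identical samples: not significant
  act2 <- act
  act2$activity <- rep(c(1, 2, 3), 5)
  mw2 <- mann_whitney_flags(act2, meta)
  expect_false(mw2$significant)

  # all-tied degenerate data give p = 1
  act3 <- act
  act3$activity <- 1
  expect_equal(mann_whitney_flags(act3, meta)$p_value, 1)

  # alpha = 0 flags nothing
  expect_false(any(mann_whitney_flags(act, meta, alpha = 0)$significant))
})

test_that("group statistics are invariant to sample order", {
  study <- fixture_study()
  act <- study$activity
  meta <- study$es$metadata
  perm <- withr::with_seed(2, sample(nrow(act)))
  gm1 <- group_means(act, meta)
  gm2 <- group_means(act[perm, ], meta[rev(seq_len(nrow(meta))), ])
  expect_equal(gm2, gm1)
  expect_equal(z_scores(gm2), z_scores(gm1))
})
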