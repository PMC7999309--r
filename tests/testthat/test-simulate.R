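test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_case = 1), "n_case")
  expect_error(simulation_config(missing_rate = 1), "missing_rate")
  expect_error(simulation_config(frac_diff = 1.2), "frac_diff")
  expect_error(simulation_config(noise_sd = 0), "noise_sd")
  cfg <- simulation_config(n_proteins = 100, seed = 3)
  expect_s3_class(cfg, "simulation_config")
})

test_that("planted differential counts are exact and frac_diff = 0 plants nothing", {
  sim0 <- simulate_abundance(simulation_config(n_proteins = 100, frac_diff = 0,
                                               seed = 1))
  expect_equal(nrow(sim0$truth$differential), 0)

  cfg <- simulation_config(n_proteins = 1000, n_case = 5, n_control = 7,
                           frac_diff = 0.05, seed = 1)
  sim <- simulate_abundance(cfg)
  expect_equal(dim(sim$abundance), c(1000, 12))
  expect_equal(nrow(sim$truth$differential), 50)
  expect_true(all(sim$truth$differential$protein_id %in% rownames(sim$abundance)))
  # half up, half down; odd counts favor up
  expect_equal(sum(sim$truth$differential$effect_log2fc > 0), 25)
  sim_odd <- simulate_abundance(simulation_config(n_proteins = 100,
                                                  frac_diff = 0.05, seed = 1))
  expect_equal(sum(sim_odd$truth$differential$effect_log2fc > 0), 3)
})

test_that("identical seeds reproduce the simulation exactly", {
  cfg <- simulation_config(n_proteins = 120, seed = 11)
  expect_identical(simulate_abundance(cfg), simulate_abundance(cfg))
  net_args <- list(proteins = sprintf("P%02d", 1:20),
                   case_proteins = sprintf("P%02d", 1:5),
                   cytokine_panel = c("IL6", "TNF"),
                   planted_cytokines = "IL6", seed = 4)
  expect_identical(do.call(simulate_network, net_args),
                   do.call(simulate_network, net_args))
})

test_that("planted effects are recovered at their nominal log2 size", {
  cfg <- simulation_config(n_proteins = 500, n_case = 20, n_control = 20,
                           frac_diff = 0.1, effect_log2fc = 2, noise_sd = 0.5,
                           missing_rate = 0, seed = 5)
  sim <- simulate_abundance(cfg)
  up <- sim$truth$differential$protein_id[sim$truth$differential$effect_log2fc > 0]
  grp <- sim$metadata$group[match(colnames(sim$abundance), sim$metadata$sample_id)]
  l2 <- log2(sim$abundance)
  diffs <- rowMeans(l2[up, grp == "V-AKI"]) - rowMeans(l2[up, grp == "control"])
  se <- cfg$noise_sd * sqrt(1 / 20 + 1 / 20) / sqrt(length(up))
  expect_lt(abs(mean(diffs) - 2), 4 * se)
  # per-protein log2 sample mean tracks base + baseline effect
  mono <- setdiff(rownames(sim$abundance), sim$truth$differential$protein_id)
  resid <- rowMeans(l2[mono, ]) - cfg$base_log2_mean
  expect_lt(abs(mean(resid)), 4 * cfg$protein_sd / sqrt(length(mono)))
})

test_that("missingness matches its Binomial target in random mode", {
  cfg <- simulation_config(n_proteins = 400, missing_rate = 0.15, seed = 9)
  sim <- simulate_abundance(cfg)
  n_cells <- length(sim$abundance)
  n_missing <- sum(is.na(sim$abundance))
  sd_bin <- sqrt(n_cells * 0.15 * 0.85)
  expect_lt(abs(n_missing - n_cells * 0.15), 4 * sd_bin)
})

test_that("intensity-dependent missingness hits the marginal rate and favors low intensity", {
  cfg <- simulation_config(n_proteins = 600, missing_rate = 0.2,
                           missing_mode = "intensity_dependent", seed = 13)
  sim <- simulate_abundance(cfg)
  rate <- mean(is.na(sim$abundance))
  expect_lt(abs(rate - 0.2), 4 * sqrt(0.2 * 0.8 / length(sim$abundance)))
  # low-abundance proteins lose more cells than high-abundance ones
  prot_mean <- rowMeans(sim$abundance, na.rm = TRUE)
  prot_miss <- rowMeans(is.na(sim$abundance))
  prot_mean[is.nan(prot_mean)] <- 0  # fully-missing proteins are low-abundance
  cut <- stats::median(prot_mean)
  lo <- prot_miss[prot_mean <= cut]
  hi <- prot_miss[prot_mean > cut]
  expect_gt(mean(lo), mean(hi))
})

test_that("network generator honors degenerate probabilities exactly", {
  prot <- sprintf("P%02d", 1:10)
  net <- simulate_network(prot, case_proteins = prot[1:4],
                          cytokine_panel = c("IL6", "TNF"),
                          planted_cytokines = "IL6",
                          p_base = 0, p_planted = 1,
                          score_range = c(0.4, 1), seed = 2)
  il6 <- sort(c(net$node2[net$node1 == "IL6"], net$node1[net$node2 == "IL6"]))
  expect_equal(il6, sort(prot[1:4]))
  expect_equal(nrow(net), 4)  # nothing else connected
  expect_true(all(net$combined_score >= 0.4 & net$combined_score <= 1))
})

test_that("realized edge counts follow the Binomial expectation", {
  prot <- sprintf("P%03d", 1:50)
  n_edges <- vapply(1:40, function(s) {
    nrow(simulate_network(prot, prot[1:10], c("IL6", "TNF", "IL10"), "IL6",
                          p_base = 0.1, p_planted = 0.6, seed = s))
  }, numeric(1))
  # pairs: 3 cytokines x 50 proteins; 10 planted-case pairs at 0.6
  mu <- 10 * 0.6 + (150 - 10) * 0.1
  sdev <- sqrt(10 * 0.6 * 0.4 + 140 * 0.1 * 0.9)
  expect_lt(abs(mean(n_edges) - mu), 4 * sdev / sqrt(length(n_edges)))
})

test_that("unplanted cytokines show no enrichment when p_planted equals p_base", {
  prot <- sprintf("P%03d", 1:60)
  sig <- data.frame(protein_id = prot,
                    class_label = rep(c("case_associated", "control_associated"),
                                      each = 30))
  folds <- vapply(1:100, function(s) {
    net <- simulate_network(prot, prot[1:30], c("CK1", "CK2"), "CK1",
                            p_base = 0.4, p_planted = 0.4,
                            score_range = c(0.5, 1), seed = s)
    enr <- enrichment_scores(filter_edges(net), sig, cytokines = c("CK1", "CK2"))
    enr$fold_connection[enr$cytokine == "CK1"]
  }, numeric(1))
  folds <- folds[is.finite(folds)]
  expect_lt(abs(mean(folds) - 1), 4 * stats::sd(folds) / sqrt(length(folds)))
})

test_that("unknown identifiers in planted sets are rejected", {
  expect_error(simulate_network(c("P1", "P2"), "P9", "IL6", "IL6"),
               "case_proteins")
  expect_error(simulate_network(c("P1", "P2"), "P1", "IL6", "TNF"),
               "planted_cytokines")
})

test_that("simulation bundles round-trip through the text formats", {
  sim <- simulate_abundance(simulation_config(n_proteins = 40,
                                              missing_rate = 0.2, seed = 21))
  dir <- withr::local_tempdir()
  paths <- write_simulation_bundle(sim, dir)
  back <- read_abundance(paths[["abundance"]])
  expect_equal(back, sim$abundance)
  expect_equal(read_metadata(paths[["metadata"]]), sim$metadata)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$differential$protein_id, sim$truth$differential$protein_id)
})
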