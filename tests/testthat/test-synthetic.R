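test_that("rho = 1 makes the child copy its parent exactly", {
  spec <- synthetic_spec(3, 40, 40, edges_sens = list(c(1, 2)),
                         edges_res = list(c(1, 2)), rho = 1, seed = 71)
  sim <- simulate_cluster_data(spec)
  expect_identical(sim$data$levels["G02", ], sim$data$levels["G01", ])
})

test_that("simulation is a pure function of its seed", {
  spec <- synthetic_spec(5, 30, 30, edges_sens = list(c(1, 2), c(2, 4)),
                         rho = 0.6, continuous = TRUE, seed = 72)
  a <- simulate_cluster_data(spec)
  b <- simulate_cluster_data(spec)
  expect_identical(a$data$values, b$data$values)
  spec2 <- spec; spec2$seed <- 73L
  c <- simulate_cluster_data(spec2)
  expect_false(identical(a$data$values, c$data$values))
})

test_that("rho = 0 pairs are independent: G-test rejects at about alpha", {
  rej <- 0L
  for (i in 1:200) {
    spec <- synthetic_spec(2, 50, 6, edges_sens = list(c(1, 2)),
                           edges_res = list(c(1, 2)), rho = 0, seed = 700 + i)
    sim <- simulate_cluster_data(spec)
    lv <- sim$data$levels[, sim$partition$sensitive_ids]
    rej <- rej + (g_test_pair(lv[1, ], lv[2, ])$p < 0.05)
  }
  # Binomial(200, 0.05): central 99% band roughly [2, 19]
  expect_gte(rej, 2L)
  expect_lte(rej, 19L)
})

test_that("root marginals are uniform over the three levels", {
  spec <- synthetic_spec(1, 3000, 6, rho = 0.5, seed = 74)
  sim <- simulate_cluster_data(spec)
  counts <- tabulate(sim$data$levels[1, sim$partition$sensitive_ids] + 1L, 3L)
  gof <- chisq.test(counts, p = rep(1 / 3, 3))
  expect_gt(gof$p.value, 0.001)
})

test_that("the empirical copy rate approaches rho", {
  for (rho in c(0.3, 0.8)) {
    spec <- synthetic_spec(2, 1000, 6, edges_sens = list(c(1, 2)),
                           edges_res = list(c(1, 2)), rho = rho, seed = 75)
    sim <- simulate_cluster_data(spec)
    lv <- sim$data$levels[, sim$partition$sensitive_ids]
    match_rate <- mean(lv[1, ] == lv[2, ])
    expected <- rho + (1 - rho) / 3
    se <- sqrt(expected * (1 - expected) / 1000)
    expect_lt(abs(match_rate - expected), 3 * se)
  }
})

test_that("continuous mode is approximately inverted by discretize", {
  spec <- synthetic_spec(3, 120, 6, edges_sens = list(c(1, 2)), rho = 0.9,
                         continuous = TRUE, noise_sd = 0.4, seed = 76)
  sim <- simulate_cluster_data(spec)
  d <- discretize(sim$data)
  # recovered levels agree with the generating ones for most samples
  spec_d <- synthetic_spec(3, 120, 6, edges_sens = list(c(1, 2)), rho = 0.9,
                           continuous = FALSE, noise_sd = 0.4, seed = 76)
  truth <- simulate_cluster_data(spec_d)$data$levels
  agreement <- mean(d$levels[, colnames(truth)] == truth)
  expect_gt(agreement, 0.8)
})

test_that("ground truth derives rewired pairs and hub mediators", {
  spec <- synthetic_spec(6, 30, 30,
                         edges_sens = list(c(1, 2), c(1, 3), c(4, 5)),
                         edges_res = list(c(4, 5)), rho = 0.8, seed = 77)
  gt <- ground_truth(spec)
  expect_setequal(vapply(gt$rewired_pairs, paste, character(1), collapse = "-"),
                  c("1-2", "1-3"))
  expect_identical(gt$planted_mediators, 1L)
})

test_that("the null simulator requires equal edge sets and yields no rewiring", {
  spec <- synthetic_spec(4, 30, 30, edges_sens = list(c(1, 2)),
                         edges_res = list(c(1, 2)), rho = 0.5, seed = 78)
  sim <- simulate_null(spec)
  expect_identical(length(sim$truth$rewired_pairs), 0L)
  bad <- synthetic_spec(4, 30, 30, edges_sens = list(c(1, 2)),
                        edges_res = list(c(3, 4)), rho = 0.5, seed = 78)
  expect_error(simulate_null(bad), class = "ddn_validation_error")
})

test_that("label swap leaves the null divergence distribution centered", {
  # under the null the two condition labels are exchangeable; check that
  # permutation p-values are not systematically small (median well above 0.2)
  ps <- sapply(1:15, function(i) {
    spec <- synthetic_spec(4, 30, 30, edges_sens = list(c(1, 2)),
                           edges_res = list(c(1, 2)), rho = 0.6, seed = 790 + i)
    sim <- simulate_null(spec)
    cfg <- eddy_config(n_resamples = 25, n_permutations = 39,
                       min_group_size = 15, seed = i)
    cl <- list(cluster_id = "c", members = sim$data$gene_ids, prior_edges = NULL)
    permutation_test(sim$data, sim$partition, cl, cfg)$p_value
  })
  expect_gt(median(ps), 0.2)
})

test_that("landscape fixture files round-trip through the readers", {
  dir <- tempfile()
  fx <- simulate_landscape_fixture(3, 2, data.frame(drug = 1, cluster = 1),
                                   seed = 80, dir = dir)
  x <- read_expression(fx$paths$expression)
  expect_identical(x$gene_ids, fx$expression$gene_ids)
  expect_identical(x$sample_ids, fx$expression$sample_ids)
  expect_equal(x$values, fx$expression$values)
  tab <- read_response(fx$paths$response)
  expect_identical(nrow(tab), nrow(fx$response))
  cat2 <- read_clusters(fx$paths$gmt, fx$paths$sif)
  expect_identical(cat2$clusters, fx$catalog$clusters)
  expect_identical(nrow(cat2$prior_edges), nrow(fx$catalog$prior_edges))
})

test_that("fixture AUC values recover the intended tertile groups exactly", {
  fx <- simulate_landscape_fixture(3, 2, data.frame(drug = 2, cluster = 2),
                                   seed = 81)
  for (drug in unique(fx$response$compound_id)) {
    p <- partition_by_response(fx$response, drug, min_group_size = 15)
    expect_false(p$underpowered)
    expect_identical(length(p$sensitive_ids), 60L)
    expect_identical(length(p$resistant_ids), 60L)
    # the sensitive set is the lowest-AUC third
    rows <- fx$response[fx$response$compound_id == drug, ]
    expect_setequal(p$sensitive_ids, rows$sample_id[order(rows$auc)][1:60])
  }
})

test_that("zero planted cells give an all-null expected mask", {
  fx <- simulate_landscape_fixture(2, 2, data.frame(drug = integer(0),
                                                    cluster = integer(0)),
                                   seed = 82)
  expect_false(any(fx$expected_mask))
})
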