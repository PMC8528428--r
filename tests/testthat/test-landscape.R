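two_by_two <- function() {
  results <- list(
    make_result("d1", "c1", p = 0.01, q = 0.02, significant = TRUE, statistic = 2),
    make_result("d1", "c2", p = 0.01, q = 0.02, significant = TRUE, statistic = 1),
    make_result("d2", "c1", p = 0.5, q = 0.6, statistic = 0.2),
    make_result("d2", "c2", p = 0.7, q = 0.7, statistic = 0.1)
  )
  ddns <- list("d1||c1" = make_ddn_stub(3), "d1||c2" = make_ddn_stub(2))
  build_landscape(results, ddns)
}

test_that("scores sum mediator counts over significant cells", {
  m <- two_by_two()
  expect_equal(unname(m$drug_score["d1"]), 5)
  expect_equal(unname(m$drug_freq["d1"]), 2L)
  expect_equal(unname(m$drug_score["d2"]), 0)
  expect_equal(unname(m$cluster_score["c1"]), 3)
  expect_equal(unname(m$cluster_freq["c1"]), 1L)
})

test_that("a landscape with no significant cells is all zero", {
  results <- list(make_result("d1", "c1", p = 0.5, q = 0.5),
                  make_result("d2", "c1", p = 0.6, q = 0.6))
  m <- build_landscape(results)
  expect_true(all(m$drug_score == 0))
  expect_true(all(m$cluster_freq == 0L))
  expect_false(any(m$cells$significant))
})

test_that("cluster frequency counts converging drugs", {
  # one cluster significant for 8 of 20 drugs
  results <- do.call(c, lapply(1:20, function(i) {
    list(make_result(sprintf("d%02d", i), "c1",
                     p = 0.01, q = 0.01, significant = i <= 8))
  }))
  m <- build_landscape(results)
  expect_equal(unname(m$cluster_freq["c1"]), 8L)
})

test_that("sorting is descending by score with lexicographic tie-break", {
  m <- two_by_two()
  m$drug_score <- c(A = 5, B = 5, C = 2)
  m$drugs <- c("C", "A", "B")
  ord <- sort_landscape(m)
  expect_identical(ord$drugs, c("A", "B", "C"))
  # all-zero scores -> pure lexicographic
  m$drug_score <- c(A = 0, B = 0, C = 0)
  expect_identical(sort_landscape(m)$drugs, c("A", "B", "C"))
  # idempotence
  m2 <- two_by_two()
  ord1 <- sort_landscape(m2)
  m2$drugs <- ord1$drugs
  m2$clusters <- ord1$clusters
  expect_identical(sort_landscape(m2), ord1)
})

test_that("hotspot selection takes the top 15 x 5 by default", {
  results <- do.call(c, lapply(1:20, function(i) lapply(1:10, function(j) {
    make_result(sprintf("d%02d", i), sprintf("c%02d", j),
                p = 0.01, q = 0.01, significant = (i + j) %% 3 == 0)
  })))
  keys <- vapply(results, function(r) paste(r$drug_id, r$cluster_id, sep = "||"),
                 character(1))
  ddns <- stats::setNames(
    lapply(results, function(r) make_ddn_stub(if (isTRUE(r$significant)) 2L else 0L)),
    keys)
  m <- build_landscape(results, ddns)
  hs <- select_hotspot(m)
  expect_identical(length(hs$drugs), 15L)
  expect_identical(length(hs$clusters), 5L)
  expect_identical(dim(hs$mediator_counts), c(5L, 15L))
  expect_true(all(hs$cluster_hit_fraction$fraction >= 0 &
                    hs$cluster_hit_fraction$fraction <= 1))
})

test_that("hotspot edge cases: empty selection and truncation", {
  m <- two_by_two()
  empty <- select_hotspot(m, top_drugs = 0, top_clusters = 0)
  expect_identical(length(empty$drugs), 0L)
  ws <- capture_warnings(big <- select_hotspot(m, top_drugs = 50,
                                               top_clusters = 50))
  expect_length(ws, 2L)
  expect_match(ws, "truncating", all = TRUE)
  expect_identical(length(big$drugs), 2L)
})

test_that("hotspot reports the convergence fraction per cluster", {
  # one cluster significant for exactly 7 of the top 15 drugs
  results <- do.call(c, lapply(1:15, function(i) {
    list(make_result(sprintf("d%02d", i), "hot",
                     p = 0.01, q = 0.01, significant = i <= 7),
         make_result(sprintf("d%02d", i), "cold", p = 0.5, q = 0.5))
  }))
  ddns <- stats::setNames(lapply(1:7, function(i) make_ddn_stub(1L)),
                          sprintf("d%02d||hot", 1:7))
  m <- build_landscape(results, ddns)
  hs <- select_hotspot(m, top_drugs = 15, top_clusters = 1)
  expect_identical(hs$clusters, "hot")
  expect_equal(hs$cluster_hit_fraction$hits, 7L)
  expect_equal(hs$cluster_hit_fraction$fraction, 7 / 15)
})

test_that("shared class clusters intersect member significant sets", {
  sets <- list(bet1 = c("3", "15", "27", "35", "40"),
               bet2 = c("3", "15", "27", "35"),
               bet3 = c("2", "3", "15", "27", "35"))
  expect_setequal(shared_class_clusters(sets, names(sets)),
                  c("3", "15", "27", "35"))
  expect_identical(shared_class_clusters(list(a = "1", b = "2"), c("a", "b")),
                   character(0))
  expect_setequal(shared_class_clusters(list(a = c("1", "2"), b = c("1", "2")),
                                        c("a", "b")),
                  c("1", "2"))
  expect_error(shared_class_clusters(sets, "bet1"),
               class = "ddn_validation_error")
})

test_that("shared set is anti-monotone in class membership", {
  set.seed(61)
  universe <- sprintf("c%02d", 1:12)
  sets <- lapply(1:5, function(i) sample(universe, sample(3:9, 1)))
  names(sets) <- sprintf("d%d", 1:5)
  for (k in 2:4) {
    small <- shared_class_clusters(sets, names(sets)[1:k])
    large <- shared_class_clusters(sets, names(sets)[1:(k + 1)])
    expect_true(all(large %in% small))
    for (i in 1:k) expect_true(all(small %in% sets[[i]]))
  }
})

test_that("class pooling averages frequencies and is order-invariant", {
  cfg <- eddy_config()
  pairs <- data.frame(gene_a = "a", gene_b = "b", known = FALSE)
  e1s <- make_ensemble(1, pairs); e1r <- make_ensemble(0, pairs, condition = "resistant")
  e2s <- make_ensemble(0, pairs); e2r <- make_ensemble(0, pairs, condition = "resistant")
  comb <- combine_class_ddn(list(e1s, e2s), list(e1r, e2r), cfg)
  expect_equal(comb$edges$p_sens, 0.5)
  swapped <- combine_class_ddn(list(e2s, e1s), list(e2r, e1r), cfg)
  expect_equal(comb$edges, swapped$edges)
  # identical per-drug profiles -> combined equals the single-drug DDN
  same <- combine_class_ddn(list(e1s, e1s), list(e1r, e1r), cfg)
  single <- build_ddn(e1s, e1r, cfg)
  expect_equal(same$edges, single$edges)
  expect_equal(same$nodes, single$nodes)
})

test_that("landscape export is deterministic and recomputable", {
  m <- two_by_two()
  stem1 <- tempfile(); stem2 <- tempfile()
  export_landscape(m, stem1)
  export_landscape(m, stem2)
  for (suffix in c("_heatmap.tsv", "_drug_marginals.tsv", "_cluster_marginals.tsv")) {
    expect_identical(readLines(paste0(stem1, suffix)),
                     readLines(paste0(stem2, suffix)))
  }
  # marginals recomputed from the cell-level score table match in-memory values
  spath <- tempfile()
  write_scores(m, spath)
  back <- read_scores(spath)
  sig <- back$cells[back$cells$significant, ]
  for (d in m$drugs) {
    expect_equal(sum(sig$mediator_count[sig$drug_id == d]),
                 unname(m$drug_score[d]))
  }
  dm <- back$drug_marginals
  expect_equal(dm$score[match(m$drugs, dm$drug_id)], unname(m$drug_score[m$drugs]))
})
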