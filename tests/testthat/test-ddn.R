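test_that("edge classification follows the presence/specificity rule", {
  cfg <- eddy_config()  # theta = 0.5, tau = 0.3
  expect_identical(classify_edge(1.0, 0.0, cfg), "sensitive")
  expect_identical(classify_edge(0.7, 0.65, cfg), "both")
  expect_identical(classify_edge(0.1, 0.15, cfg), "absent")
  expect_identical(classify_edge(0.0, 0.9, cfg), "resistant")
  expect_identical(classify_edge(0.7, 0.45, cfg), "both")
})

test_that("classification is antisymmetric under ensemble swap", {
  cfg <- eddy_config()
  set.seed(51)
  p <- runif(200)
  q <- runif(200)
  fwd <- classify_edge(p, q, cfg)
  rev <- classify_edge(q, p, cfg)
  flip <- c(sensitive = "resistant", resistant = "sensitive",
            both = "both", absent = "absent")
  expect_identical(unname(flip[fwd]), rev)
})

test_that("betweenness matches hand-computed small graphs", {
  # path a-b-c: b carries the single pair
  bc <- ddn_betweenness(c("a", "b", "c"),
                        data.frame(gene_a = c("a", "b"), gene_b = c("b", "c")))
  expect_equal(unname(bc), c(0, 1, 0))
  # 4-cycle: each node mediates half of one tied pair -> 1/6
  cyc <- data.frame(gene_a = c("a", "b", "c", "d"),
                    gene_b = c("b", "c", "d", "a"))
  expect_equal(unname(ddn_betweenness(letters[1:4], cyc)), rep(1 / 6, 4))
  # star: center mediates all leaf pairs
  star <- data.frame(gene_a = "hub", gene_b = c("x", "y", "z"))
  bc <- ddn_betweenness(c("hub", "x", "y", "z"), star)
  expect_equal(unname(bc[c("hub", "x")]), c(1, 0))
  # < 3 nodes: all zero
  expect_equal(unname(ddn_betweenness(c("a", "b"),
                                      data.frame(gene_a = "a", gene_b = "b"))),
               c(0, 0))
})

test_that("betweenness agrees with exhaustive path enumeration", {
  set.seed(52)
  for (i in 1:40) {
    n <- sample(4:6, 1)
    edges <- random_connected_graph(n, extra = sample(0:3, 1))
    nodes <- sprintf("v%d", 1:n)
    df <- data.frame(gene_a = nodes[vapply(edges, `[`, 1L, 1)],
                     gene_b = nodes[vapply(edges, `[`, 1L, 2)])
    got <- ddn_betweenness(nodes, df)
    want <- oracle_betweenness(n, edges)
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
})

test_that("build_ddn assembles edges, nodes and background fraction", {
  cfg <- eddy_config()
  pairs <- data.frame(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
                      known = c(TRUE, FALSE, FALSE))
  es <- make_ensemble(c(1, 0.9, 0.2), pairs)
  er <- make_ensemble(c(0, 0.9, 0.1), pairs, condition = "resistant")
  ddn <- build_ddn(es, er, cfg, drug_id = "d", cluster_id = "c")
  expect_identical(nrow(ddn$edges), 2L)
  expect_identical(ddn$edges$condition_class, c("sensitive", "both"))
  expect_identical(ddn$edges$known, c(TRUE, FALSE))
  expect_identical(nrow(ddn$nodes), 3L)
  expect_equal(ddn$background_specific_fraction, 0.5)
  a <- ddn$nodes[ddn$nodes$gene_id == "a", ]
  expect_identical(a$specific_edge_count, 1L)
  expect_identical(a$total_edge_count, 2L)
})

test_that("all-both networks have zero background and no specificity mediators", {
  cfg <- eddy_config()
  pairs <- data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"), known = FALSE)
  ddn <- build_ddn(make_ensemble(c(0.9, 0.9), pairs),
                   make_ensemble(c(0.9, 0.9), pairs, condition = "resistant"),
                   cfg)
  expect_equal(ddn$background_specific_fraction, 0)
  expect_false(any(ddn$nodes$specificity_mediator))
})

test_that("specificity mediator tail matches the closed-form binomial", {
  cfg <- eddy_config()  # mediator_alpha = 0.05
  # hub with 5/5 specific edges against background 0.3
  hub_pairs <- data.frame(gene_a = "hub", gene_b = sprintf("l%d", 1:5),
                          known = FALSE)
  # background fraction is a property of the whole DDN; build it directly
  ddn <- build_ddn(make_ensemble(rep(1, 5), hub_pairs),
                   make_ensemble(rep(0, 5), hub_pairs, condition = "resistant"),
                   cfg)
  ddn$background_specific_fraction <- 0.3
  ddn <- find_specificity_mediators(ddn, cfg)
  hub <- ddn$nodes[ddn$nodes$gene_id == "hub", ]
  expect_equal(hub$specificity_p, 0.3^5, tolerance = 1e-12)
  expect_true(hub$specificity_mediator)
  # 0.3^5 = 0.00243
  expect_equal(0.3^5, 0.00243, tolerance = 1e-12)
})

test_that("mediator limit cases behave as documented", {
  cfg <- eddy_config()
  pairs <- data.frame(gene_a = "a", gene_b = "b", known = FALSE)
  # background 1: every edge specific -> tail 1, never a mediator
  ddn1 <- build_ddn(make_ensemble(1, pairs),
                    make_ensemble(0, pairs, condition = "resistant"), cfg)
  expect_equal(ddn1$background_specific_fraction, 1)
  expect_false(any(ddn1$nodes$specificity_mediator))
  expect_true(all(ddn1$nodes$specificity_p == 1))
  # background 0 with a specific edge: limit flag
  ddn2 <- ddn1
  ddn2$background_specific_fraction <- 0
  ddn2 <- find_specificity_mediators(ddn2, cfg)
  expect_true(all(ddn2$nodes$specificity_mediator))
  # node with 0 specific edges: tail 1
  ddn3 <- build_ddn(make_ensemble(0.9, pairs),
                    make_ensemble(0.9, pairs, condition = "resistant"), cfg)
  expect_true(all(ddn3$nodes$specificity_p == 1))
})

test_that("essentiality mediators follow the centrality-difference cutoff", {
  cfg <- eddy_config()  # cutoff 0.3
  ddn <- make_ddn_stub(0)
  ddn$nodes <- data.frame(
    gene_id = c("x", "y", "z"),
    bc_sens = c(1.0, 0.5, 0.40), bc_res = c(0.0, 0.5, 0.15),
    specific_edge_count = 0L, total_edge_count = 0L,
    specificity_p = NA_real_, specificity_mediator = FALSE,
    essentiality_mediator = FALSE, stringsAsFactors = FALSE
  )
  ddn <- find_essentiality_mediators(ddn, cfg)
  expect_identical(ddn$nodes$essentiality_mediator, c(TRUE, FALSE, FALSE))
})

test_that("mediator flags are invariant to pair input order", {
  cfg <- eddy_config()
  set.seed(53)
  pairs <- candidate_pairs(sprintf("g%d", 1:6))
  p <- runif(nrow(pairs))
  q <- runif(nrow(pairs))
  ddn1 <- build_ddn(make_ensemble(p, pairs),
                    make_ensemble(q, pairs, condition = "resistant"), cfg)
  perm <- sample.int(nrow(pairs))
  ddn2 <- build_ddn(make_ensemble(p[perm], pairs[perm, ]),
                    make_ensemble(q[perm], pairs[perm, ], condition = "resistant"),
                    cfg)
  n1 <- ddn1$nodes[order(ddn1$nodes$gene_id), ]
  n2 <- ddn2$nodes[order(ddn2$nodes$gene_id), ]
  rownames(n1) <- rownames(n2) <- NULL
  expect_equal(n1, n2)
})
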