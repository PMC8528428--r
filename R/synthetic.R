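#' Specification for a synthetic two-condition cluster dataset
#'
#' Describes a gene cluster with condition-specific planted pairwise
#' dependencies. Edges are unordered gene-index pairs (1-based, indices
#' `<= n_genes`); generation orients each edge by index (lower index = parent),
#' which is always acyclic. Dependence strength `rho` is the probability a
#' child copies its (lowest-index) parent's level; `rho = 0` gives full
#' independence, `rho = 1` deterministic copying.
#'
#' @param n_genes Number of genes.
#' @param n_sens,n_res Samples per condition.
#' @param edges_sens,edges_res Lists of length-2 integer vectors (or a 2-column
#'   matrix) of planted dependencies per condition.
#' @param rho Dependence strength in \[0,1\].
#' @param continuous If TRUE, emit a continuous `expression_matrix` whose
#'   levels are recoverable by [discretize()]; otherwise emit levels directly.
#' @param noise_sd Gaussian noise s.d. of the continuous 3-component location
#'   mixture (default 0.4).
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes, n_sens, n_res,
                           edges_sens = list(), edges_res = list(),
                           rho = 0.8, continuous = FALSE, noise_sd = 0.4,
                           seed = 1L) {
  norm_edges <- function(e) {
    if (is.matrix(e)) e <- lapply(seq_len(nrow(e)), function(i) e[i, ])
    lapply(e, function(p) {
      p <- sort(as.integer(p))
      if (length(p) != 2L || p[1] == p[2] || p[1] < 1L || p[2] > n_genes) {
        stop(ddn_validation_error("edge must join two distinct genes within 1..n_genes"))
      }
      p
    })
  }
  stopifnot(rho >= 0, rho <= 1, noise_sd > 0, n_genes >= 1L)
  structure(
    list(n_genes = as.integer(n_genes), n_sens = as.integer(n_sens),
         n_res = as.integer(n_res),
         edges_sens = norm_edges(edges_sens), edges_res = norm_edges(edges_res),
         rho = rho, continuous = continuous, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

edge_key <- function(edges) {
  vapply(edges, function(p) paste(p, collapse = "-"), character(1))
}

#' Ground truth implied by a synthetic spec
#'
#' `rewired_pairs` is the symmetric difference of the two planted edge sets;
#' `planted_mediators` are the genes incident to at least two rewired pairs
#' (hub genes whose connectivity changes with condition).
#'
#' @param spec A `synthetic_spec`.
#' @return List with `rewired_pairs` (list of index pairs) and
#'   `planted_mediators` (integer gene indices).
#' @export
ground_truth <- function(spec) {
  ks <- edge_key(spec$edges_sens)
  kr <- edge_key(spec$edges_res)
  rewired <- c(spec$edges_sens[!ks %in% kr], spec$edges_res[!kr %in% ks])
  inc <- table(unlist(rewired))
  list(rewired_pairs = rewired,
       planted_mediators = as.integer(names(inc)[inc >= 2L]))
}

simulate_levels <- function(n_genes, n_samples, edges, rho) {
  # lowest-index parent per gene, or 0 for roots
  parent <- integer(n_genes)
  for (e in edges) {
    if (parent[e[2]] == 0L || e[1] < parent[e[2]]) parent[e[2]] <- e[1]
  }
  lev <- matrix(0L, n_genes, n_samples)
  for (g in seq_len(n_genes)) {
    if (parent[g] == 0L) {
      lev[g, ] <- sample(0:2, n_samples, replace = TRUE)
    } else {
      copy <- stats::runif(n_samples) < rho
      lev[g, ] <- ifelse(copy, lev[parent[g], ],
                         sample(0:2, n_samples, replace = TRUE))
    }
  }
  lev
}

#' Simulate a two-condition cluster dataset
#'
#' Per condition and sample: root genes draw a level uniformly from {0,1,2};
#' each child copies its lowest-index parent's level with probability `rho`,
#' otherwise draws uniformly. In continuous mode level `l` maps to a draw from
#' `Normal(l - 1, noise_sd)`, a 3-component location mixture that
#' [discretize()] approximately inverts. Fully seeded: identical spec and seed
#' give identical output.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `data` (an `expression_matrix` or `discretized_matrix`
#'   over samples named `sens_*`/`res_*`), `partition` (a
#'   `condition_partition` with the true groups), and `truth` (see
#'   [ground_truth()]).
#' @export
simulate_cluster_data <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  genes <- sprintf("G%02d", seq_len(spec$n_genes))
  sens_ids <- sprintf("sens_%03d", seq_len(spec$n_sens))
  res_ids <- sprintf("res_%03d", seq_len(spec$n_res))
  lev <- with_seed(spec$seed, {
    ls <- simulate_levels(spec$n_genes, spec$n_sens, spec$edges_sens, spec$rho)
    lr <- simulate_levels(spec$n_genes, spec$n_res, spec$edges_res, spec$rho)
    cbind(ls, lr)
  })
  dimnames(lev) <- list(genes, c(sens_ids, res_ids))
  data <- if (spec$continuous) {
    vals <- with_seed(derive_seed(spec$seed, "noise"),
                      lev - 1 + stats::rnorm(length(lev), sd = spec$noise_sd))
    dimnames(vals) <- dimnames(lev)
    new_expression_matrix(genes, colnames(vals), vals,
                          matrix(FALSE, nrow(vals), ncol(vals),
                                 dimnames = dimnames(vals)))
  } else {
    new_discretized_matrix(lev)
  }
  list(
    data = data,
    partition = new_condition_partition("synthetic", sens_ids, res_ids),
    truth = ground_truth(spec)
  )
}

#' Simulate under the rewiring null
#'
#' Both conditions are drawn from one common dependency structure
#' (`edges_sens` must equal `edges_res`), so the true rewired set is empty and
#' permutation p-values are uniform.
#'
#' @param spec A [synthetic_spec()] with identical edge sets.
#' @return As [simulate_cluster_data()].
#' @export
simulate_null <- function(spec) {
  if (!identical(edge_key(spec$edges_sens), edge_key(spec$edges_res))) {
    stop(ddn_validation_error("simulate_null requires edges_sens == edges_res"))
  }
  out <- simulate_cluster_data(spec)
  stopifnot(length(out$truth$rewired_pairs) == 0L)
  out
}

#' Simulate a full drug-by-cluster pipeline fixture
#'
#' Emits every input the end-to-end pipeline consumes — a continuous
#' expression matrix, a per-drug AUC response table whose tertile partition
#' recovers the intended groups exactly (AUC values are distinct and
#' separated), a GMT cluster catalog with SIF prior edges, and the expected
#' significance mask. Each planted (drug, cluster) cell receives
#' condition-specific dependencies: the cluster's planted edges hold (at
#' strength `rho`) only in that drug's sensitive group; all other genes and
#' samples are independent, so non-planted cells are null.
#'
#' @param n_drugs,n_clusters Grid dimensions.
#' @param planted_cells data.frame with integer columns `drug` and `cluster`
#'   (1-based indices); at most one planted drug per cluster.
#' @param seed Integer seed.
#' @param n_samples Total samples (default 180, giving tertile groups
#'   of 60 — the same per-condition size the package's power analyses use).
#' @param genes_per_cluster Cluster size (default 6).
#' @param rho Planted dependence strength (default 0.9).
#' @param noise_sd Continuous noise s.d. (default 0.4).
#' @param dir If non-NULL, write `expression.tsv`, `response.tsv`,
#'   `clusters.gmt`, `prior.sif` there.
#' @return List with `expression`, `response`, `catalog`, `expected_mask`
#'   (drugs x clusters logical), `planted_edges` (per cluster, gene-id pairs),
#'   and `paths` (when written).
#' @export
simulate_landscape_fixture <- function(n_drugs, n_clusters, planted_cells,
                                       seed = 1L, n_samples = 180L,
                                       genes_per_cluster = 6L, rho = 0.9,
                                       noise_sd = 0.4, dir = NULL) {
  stopifnot(n_samples %% 3L == 0L, genes_per_cluster >= 4L)
  planted_cells <- as.data.frame(planted_cells)
  if (nrow(planted_cells) > 0L) {
    stopifnot(all(planted_cells$drug %in% seq_len(n_drugs)),
              all(planted_cells$cluster %in% seq_len(n_clusters)))
    if (anyDuplicated(planted_cells$cluster)) {
      stop(ddn_validation_error("at most one planted drug per cluster"))
    }
  }
  drugs <- sprintf("drug%02d", seq_len(n_drugs))
  cluster_ids <- sprintf("C%02d", seq_len(n_clusters))
  samples <- sprintf("cell_%03d", seq_len(n_samples))
  third <- n_samples %/% 3L

  # per-drug sample ordering: first third sensitive, last third resistant
  perms <- lapply(seq_len(n_drugs), function(j) {
    with_seed(derive_seed(seed, "drugperm", j), sample(samples))
  })
  response <- do.call(rbind, lapply(seq_len(n_drugs), function(j) {
    # distinct, strictly increasing AUC along the permutation so the tertile
    # split recovers the intended groups exactly
    data.frame(compound_id = drugs[j], sample_id = perms[[j]],
               auc = seq_len(n_samples) / (n_samples + 1),
               stringsAsFactors = FALSE)
  }))
  class(response) <- c("drug_response", "data.frame")

  # planted edges within a cluster: disjoint consecutive pairs (no indirect
  # dependence between planted pairs)
  local_edges <- lapply(seq(1L, genes_per_cluster - 1L, by = 2L),
                        function(i) c(i, i + 1L))
  gene_ids <- unlist(lapply(seq_len(n_clusters), function(c) {
    sprintf("C%02dg%02d", c, seq_len(genes_per_cluster))
  }))
  n_genes <- length(gene_ids)

  planted_by_cluster <- stats::setNames(rep(NA_integer_, n_clusters), cluster_ids)
  if (nrow(planted_cells) > 0L) {
    planted_by_cluster[planted_cells$cluster] <- planted_cells$drug
  }

  lev <- matrix(0L, n_genes, n_samples, dimnames = list(gene_ids, samples))
  for (c in seq_len(n_clusters)) {
    rows <- (c - 1L) * genes_per_cluster + seq_len(genes_per_cluster)
    base <- with_seed(derive_seed(seed, "cluster", c),
                      matrix(sample(0:2, genes_per_cluster * n_samples,
                                    replace = TRUE),
                             genes_per_cluster, n_samples))
    j <- planted_by_cluster[c]
    if (!is.na(j)) {
      sens_cols <- match(perms[[j]][seq_len(third)], samples)
      copy <- with_seed(derive_seed(seed, "copy", c),
                        matrix(stats::runif(length(local_edges) * length(sens_cols)) < rho,
                               length(local_edges), length(sens_cols)))
      for (ei in seq_along(local_edges)) {
        e <- local_edges[[ei]]
        base[e[2], sens_cols] <- ifelse(copy[ei, ], base[e[1], sens_cols],
                                        base[e[2], sens_cols])
      }
    }
    lev[rows, ] <- base
  }
  vals <- with_seed(derive_seed(seed, "noise"),
                    lev - 1 + stats::rnorm(length(lev), sd = noise_sd))
  dimnames(vals) <- dimnames(lev)
  expression <- new_expression_matrix(gene_ids, samples, vals,
                                      matrix(FALSE, n_genes, n_samples,
                                             dimnames = dimnames(vals)))

  clusters <- stats::setNames(lapply(seq_len(n_clusters), function(c) {
    gene_ids[(c - 1L) * genes_per_cluster + seq_len(genes_per_cluster)]
  }), cluster_ids)
  planted_edge_ids <- stats::setNames(lapply(seq_len(n_clusters), function(c) {
    g <- clusters[[c]]
    lapply(local_edges, function(e) c(g[e[1]], g[e[2]]))
  }), cluster_ids)
  prior <- do.call(rbind, lapply(cluster_ids, function(cl) {
    do.call(rbind, lapply(planted_edge_ids[[cl]], function(e) {
      data.frame(cluster_id = cl, gene_a = min(e), gene_b = max(e),
                 stringsAsFactors = FALSE)
    }))
  }))
  catalog <- structure(
    list(clusters = clusters,
         descriptions = stats::setNames(
           sprintf("synthetic cluster %d", seq_len(n_clusters)), cluster_ids),
         prior_edges = prior),
    class = "cluster_catalog"
  )

  expected <- matrix(FALSE, n_drugs, n_clusters,
                     dimnames = list(drugs, cluster_ids))
  if (nrow(planted_cells) > 0L) {
    expected[cbind(planted_cells$drug, planted_cells$cluster)] <- TRUE
  }

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      expression = file.path(dir, "expression.tsv"),
      response = file.path(dir, "response.tsv"),
      gmt = file.path(dir, "clusters.gmt"),
      sif = file.path(dir, "prior.sif")
    )
    writeLines(c(
      paste(c("gene_id", samples), collapse = "\t"),
      vapply(seq_len(n_genes), function(i) {
        paste(c(gene_ids[i], num_fmt(vals[i, ])), collapse = "\t")
      }, character(1))
    ), paths$expression)
    writeLines(c("compound_id\tsample_id\tauc",
                 sprintf("%s\t%s\t%s", response$compound_id,
                         response$sample_id, num_fmt(response$auc))),
               paths$response)
    writeLines(vapply(cluster_ids, function(cl) {
      paste(c(cl, catalog$descriptions[[cl]], clusters[[cl]]), collapse = "\t")
    }, character(1)), paths$gmt)
    writeLines(sprintf("%s\t%s\t%s", prior$gene_a, prior$cluster_id,
                       prior$gene_b), paths$sif)
  }

  list(expression = expression, response = response, catalog = catalog,
       expected_mask = expected, planted_edges = planted_edge_ids,
       paths = paths)
}
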