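# Independent oracles used to cross-check the implementation.

# Direct likelihood-ratio computation on a 3x3 contingency table, written
# against the textbook formula (margins via outer product), independent of the
# package's C++ path.
oracle_gtest_table <- function(tab) {
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    return(list(G = 0, df = 0L, p = 1, informative = FALSE))
  }
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  obs <- tab[tab > 0]
  G <- 2 * sum(obs * log(obs / expected[tab > 0]))
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(G = G, df = df, p = stats::pchisq(G, df, lower.tail = FALSE),
       informative = TRUE)
}

# Expand a 3x3 count table into a pair of level vectors (row-major order).
table_to_levels <- function(tab) {
  a <- integer(0); b <- integer(0)
  for (i in 1:3) for (j in 1:3) {
    k <- tab[i, j]
    a <- c(a, rep(i - 1L, k)); b <- c(b, rep(j - 1L, k))
  }
  list(a = a, b = b)
}

# Brute-force betweenness by exhaustive simple-path enumeration: for every
# unordered node pair, list all simple paths, keep the shortest, and credit
# each intermediate node with (paths through it) / (number of shortest paths).
# Normalized by (n-1)(n-2)/2. Only feasible for tiny graphs.
oracle_betweenness <- function(n, edges) {
  adj <- vector("list", n)
  for (e in edges) {
    adj[[e[1]]] <- c(adj[[e[1]]], e[2])
    adj[[e[2]]] <- c(adj[[e[2]]], e[1])
  }
  all_paths <- function(s, t) {
    out <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        out[[length(out) + 1L]] <<- path
        return(invisible())
      }
      for (w in adj[[v]]) if (!w %in% path) walk(c(path, w))
    }
    walk(s)
    out
  }
  bc <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    paths <- all_paths(s, t)
    if (length(paths) == 0L) next
    lens <- vapply(paths, length, integer(1))
    shortest <- paths[lens == min(lens)]
    for (p in shortest) {
      inner <- setdiff(p, c(s, t))
      bc[inner] <- bc[inner] + 1 / length(shortest)
    }
  }
  bc / ((n - 1) * (n - 2) / 2)
}

# Random connected undirected simple graph on n nodes (spanning tree plus
# random extra edges).
random_connected_graph <- function(n, extra = 2L) {
  edges <- lapply(2:n, function(v) sort(c(sample.int(v - 1L, 1L), v)))
  all_pairs <- utils::combn(n, 2, simplify = FALSE)
  have <- vapply(edges, paste, character(1), collapse = "-")
  avail <- all_pairs[!vapply(all_pairs, paste, character(1), collapse = "-") %in% have]
  if (length(avail) > 0L && extra > 0L) {
    pick <- sample(seq_along(avail), min(extra, length(avail)))
    edges <- c(edges, avail[pick])
  }
  edges
}

# Minimal condition_ensemble over named pairs with given frequencies.
make_ensemble <- function(freq, pairs = NULL, condition = "sensitive",
                          known = FALSE) {
  if (is.null(pairs)) {
    pairs <- data.frame(gene_a = sprintf("a%02d", seq_along(freq)),
                        gene_b = sprintf("b%02d", seq_along(freq)),
                        known = known, stringsAsFactors = FALSE)
  }
  structure(
    list(condition = condition, pairs = pairs, edge_freq = as.numeric(freq),
         n_samples = 60L, n_resamples = 100L),
    class = "condition_ensemble"
  )
}

# Skeleton rewiring_result for landscape-level tests.
make_result <- function(drug, cluster, p = NA_real_, q = NA_real_,
                        significant = FALSE, statistic = NA_real_,
                        skipped = NA_character_) {
  structure(
    list(drug_id = drug, cluster_id = cluster, statistic = statistic,
         p_value = p, q_value = q, significant = significant,
         skipped_reason = skipped, ens_sens = NULL, ens_res = NULL,
         perm_stats = NULL),
    class = "rewiring_result"
  )
}

# DDN stub with a fixed mediator count, for landscape bookkeeping tests.
make_ddn_stub <- function(n_mediators, drug = "d", cluster = "c") {
  nodes <- data.frame(
    gene_id = sprintf("g%02d", seq_len(max(n_mediators, 1L))),
    bc_sens = 0, bc_res = 0, specific_edge_count = 0L, total_edge_count = 0L,
    specificity_p = NA_real_,
    specificity_mediator = seq_len(max(n_mediators, 1L)) <= n_mediators,
    essentiality_mediator = FALSE, stringsAsFactors = FALSE
  )
  structure(
    list(drug_id = drug, cluster_id = cluster,
         edges = data.frame(gene_a = character(0), gene_b = character(0),
                            p_sens = numeric(0), p_res = numeric(0),
                            condition_class = character(0), known = logical(0),
                            stringsAsFactors = FALSE),
         nodes = nodes, background_specific_fraction = 0),
    class = "ddn"
  )
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
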