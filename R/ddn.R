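#' Classify one edge by condition
#'
#' An edge is present when its inclusion frequency reaches `presence_theta` in
#' at least one condition; a present edge is condition-specific when the
#' frequency difference exceeds `specific_tau`, otherwise it is shared
#' (`"both"`). Swapping the two arguments maps sensitive to resistant and
#' fixes both/absent.
#'
#' @param p_sens,p_res Edge-inclusion frequencies in \[0,1\] (vectorized).
#' @param cfg An [eddy_config()].
#' @return Character vector: `"sensitive"`, `"resistant"`, `"both"`, or
#'   `"absent"`.
#' @examples
#' classify_edge(1, 0, eddy_config())      # "sensitive"
#' classify_edge(0.7, 0.65, eddy_config()) # "both"
#' @export
classify_edge <- function(p_sens, p_res, cfg) {
  stopifnot(all(p_sens >= 0 & p_sens <= 1), all(p_res >= 0 & p_res <= 1))
  out <- rep("absent", length(p_sens))
  present <- pmax(p_sens, p_res) >= cfg$presence_theta
  out[present & (p_sens - p_res > cfg$specific_tau)] <- "sensitive"
  out[present & (p_res - p_sens > cfg$specific_tau)] <- "resistant"
  out[present & abs(p_sens - p_res) <= cfg$specific_tau] <- "both"
  out
}

#' Normalized betweenness centrality on a condition subgraph
#'
#' Shortest-path betweenness with fractional credit for tied shortest paths,
#' normalized by `(n-1)(n-2)/2` where `n` is the node count (so values lie in
#' \[0,1\]); computed by `igraph::betweenness`. Graphs with fewer than 3 nodes
#' carry no intermediate vertices and return all zeros.
#'
#' @param nodes Character vector of node ids (isolated nodes allowed).
#' @param edges data.frame with `gene_a`, `gene_b`.
#' @return Named numeric vector over `nodes`.
#' @export
ddn_betweenness <- function(nodes, edges) {
  bc <- stats::setNames(numeric(length(nodes)), nodes)
  n <- length(nodes)
  if (n < 3L || nrow(edges) == 0L) return(bc)
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  raw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  bc[names(raw)] <- raw / ((n - 1) * (n - 2) / 2)
  bc
}

#' Build the annotated differential dependency network
#'
#' Classifies every candidate pair from the two observed ensembles, keeps the
#' non-absent edges (with the known/novel flag), and annotates nodes with:
#' betweenness centrality on the sensitive subgraph (edges classed sensitive
#' or both) and on the resistant subgraph (resistant or both); counts of
#' condition-specific vs total incident edges; and the two mediator flags from
#' [find_specificity_mediators()] and [find_essentiality_mediators()].
#' Cluster members with no retained edges appear as nodes with zero metrics so
#' mediator counting has a stable denominator.
#'
#' @param ens_s,ens_r Sensitive/resistant `condition_ensemble`s over identical
#'   candidate pairs.
#' @param cfg An [eddy_config()].
#' @param members Optional full member list (defaults to the genes spanned by
#'   the candidate pairs).
#' @param drug_id,cluster_id Identifiers stored on the network.
#' @return A `ddn`: list with `drug_id`, `cluster_id`, `edges`, `nodes`,
#'   `background_specific_fraction`.
#' @export
build_ddn <- function(ens_s, ens_r, cfg, members = NULL,
                      drug_id = NA_character_, cluster_id = NA_character_) {
  if (!identical(pair_key(ens_s$pairs), pair_key(ens_r$pairs))) {
    stop(ddn_validation_error("ensembles have mismatched candidate pair sets"))
  }
  pairs <- ens_s$pairs
  cls <- classify_edge(ens_s$edge_freq, ens_r$edge_freq, cfg)
  keep <- cls != "absent"
  edges <- data.frame(
    gene_a = pairs$gene_a[keep], gene_b = pairs$gene_b[keep],
    p_sens = ens_s$edge_freq[keep], p_res = ens_r$edge_freq[keep],
    condition_class = cls[keep], known = pairs$known[keep],
    stringsAsFactors = FALSE
  )
  if (is.null(members)) members <- unique(c(pairs$gene_a, pairs$gene_b))
  members <- sort(unique(members), method = "radix")

  specific <- edges$condition_class %in% c("sensitive", "resistant")
  background <- if (nrow(edges) > 0L) mean(specific) else 0

  bc_s <- ddn_betweenness(members,
                          edges[edges$condition_class %in% c("sensitive", "both"), ])
  bc_r <- ddn_betweenness(members,
                          edges[edges$condition_class %in% c("resistant", "both"), ])

  inc <- function(gene, rows) sum(rows$gene_a == gene | rows$gene_b == gene)
  total_cnt <- vapply(members, inc, integer(1), rows = edges)
  spec_cnt <- vapply(members, inc, integer(1), rows = edges[specific, , drop = FALSE])

  nodes <- data.frame(
    gene_id = members,
    bc_sens = unname(bc_s), bc_res = unname(bc_r),
    specific_edge_count = as.integer(spec_cnt),
    total_edge_count = as.integer(total_cnt),
    specificity_p = NA_real_,
    specificity_mediator = FALSE,
    essentiality_mediator = FALSE,
    stringsAsFactors = FALSE
  )
  ddn <- structure(
    list(drug_id = drug_id, cluster_id = cluster_id, edges = edges,
         nodes = nodes, background_specific_fraction = background),
    class = "ddn"
  )
  ddn <- find_specificity_mediators(ddn, cfg)
  find_essentiality_mediators(ddn, cfg)
}

#' @export
print.ddn <- function(x, ...) {
  tab <- table(factor(x$edges$condition_class,
                      levels = c("sensitive", "resistant", "both")))
  cat(sprintf(
    "<ddn> %s x %s: %d nodes, %d edges (%d sensitive / %d resistant / %d both), %d mediator(s)\n",
    x$drug_id, x$cluster_id, nrow(x$nodes), nrow(x$edges),
    tab[["sensitive"]], tab[["resistant"]], tab[["both"]],
    sum(x$nodes$specificity_mediator | x$nodes$essentiality_mediator)))
  invisible(x)
}

#' Flag specificity mediators
#'
#' A node with at least one incident edge is a specificity mediator when its
#' proportion of condition-specific incident edges is significantly above the
#' network-wide specific-edge fraction: one-sided binomial tail
#' `P(X >= k | n, p0)` with `k` specific incident edges of `n` total and `p0`
#' the background fraction, flagged when the tail falls below
#' `cfg$mediator_alpha`. With background 0, any specific edge flags the node
#' (the tail is 0).
#'
#' @param ddn A `ddn`.
#' @param cfg An [eddy_config()].
#' @return The `ddn` with `specificity_p` and `specificity_mediator` set.
#' @export
find_specificity_mediators <- function(ddn, cfg) {
  nd <- ddn$nodes
  p0 <- ddn$background_specific_fraction
  has <- nd$total_edge_count >= 1L
  tail <- rep(NA_real_, nrow(nd))
  tail[has] <- stats::pbinom(nd$specific_edge_count[has] - 1L,
                             nd$total_edge_count[has], p0,
                             lower.tail = FALSE)
  nd$specificity_p <- tail
  nd$specificity_mediator <- !is.na(tail) & tail < cfg$mediator_alpha
  ddn$nodes <- nd
  ddn
}

#' Flag essentiality mediators
#'
#' A node is an essentiality mediator when the absolute difference between its
#' normalized betweenness centralities on the sensitive and resistant
#' subgraphs reaches `cfg$bc_delta_cutoff` — the node's importance to network
#' information flow changes materially with the condition.
#'
#' @inheritParams find_specificity_mediators
#' @return The `ddn` with `essentiality_mediator` set.
#' @export
find_essentiality_mediators <- function(ddn, cfg) {
  nd <- ddn$nodes
  nd$essentiality_mediator <- abs(nd$bc_sens - nd$bc_res) >= cfg$bc_delta_cutoff
  ddn$nodes <- nd
  ddn
}

#' Count mediators of a DDN
#'
#' Union of the specificity and essentiality mediator sets.
#' @param ddn A `ddn`.
#' @return Integer count.
#' @export
mediator_count <- function(ddn) {
  sum(ddn$nodes$specificity_mediator | ddn$nodes$essentiality_mediator)
}

#' Write the per-node mediator table
#'
#' @param ddn A `ddn`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_mediators <- function(ddn, path) {
  nd <- ddn$nodes[order(ddn$nodes$gene_id, method = "radix"), , drop = FALSE]
  hdr <- paste(c("gene_id", "bc_sens", "bc_res", "specific_edge_count",
                 "total_edge_count", "specificity_p", "specificity_mediator",
                 "essentiality_mediator"), collapse = "\t")
  rows <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s",
                  nd$gene_id, num_fmt(nd$bc_sens), num_fmt(nd$bc_res),
                  nd$specific_edge_count, nd$total_edge_count,
                  num_fmt(nd$specificity_p),
                  tolower(nd$specificity_mediator),
                  tolower(nd$essentiality_mediator))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
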