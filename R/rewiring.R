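#' Candidate edge space for a cluster
#'
#' The edge space tested per cluster is every unordered pair of non-degenerate
#' members (novel pairs) united with the cluster's prior-knowledge edges
#' (known pairs). Known pairs are tested at the laxer `alpha_known`; novel
#' pairs at `alpha_novel`.
#'
#' @param members Character vector of cluster member gene ids.
#' @param prior_edges data.frame with `gene_a`, `gene_b` (unordered prior
#'   pairs for this cluster); may have zero rows.
#' @param degenerate Genes to exclude from all pairs (near-constant).
#' @return data.frame `gene_a`, `gene_b`, `known` with `gene_a < gene_b`,
#'   sorted for determinism.
#' @export
candidate_pairs <- function(members, prior_edges = NULL, degenerate = character(0)) {
  usable <- sort(setdiff(members, degenerate), method = "radix")
  if (length(usable) < 2L) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      known = logical(0), stringsAsFactors = FALSE))
  }
  idx <- utils::combn(usable, 2)
  pairs <- data.frame(gene_a = idx[1, ], gene_b = idx[2, ], known = FALSE,
                      stringsAsFactors = FALSE)
  if (!is.null(prior_edges) && nrow(prior_edges) > 0L) {
    a <- pmin(prior_edges$gene_a, prior_edges$gene_b)
    b <- pmax(prior_edges$gene_a, prior_edges$gene_b)
    keep <- a %in% usable & b %in% usable
    known_key <- paste(a[keep], b[keep], sep = "\r")
    pairs$known <- paste(pairs$gene_a, pairs$gene_b, sep = "\r") %in% known_key
  }
  pairs
}

pair_key <- function(pairs) paste(pairs$gene_a, pairs$gene_b, sep = "\r")

#' One resampled dependency structure
#'
#' Draws a bootstrap resample (with replacement, size preserved) of the given
#' samples and G-tests every candidate pair on the resampled levels; a pair
#' enters the structure when its p-value falls below its threshold
#' (`alpha_known` for prior edges, `alpha_novel` for novel pairs).
#'
#' @param d A `discretized_matrix`.
#' @param sample_ids Samples of one condition.
#' @param pairs Candidate pairs from [candidate_pairs()].
#' @param cfg An [eddy_config()].
#' @param draw_seed Integer seed for this single draw.
#' @return Logical vector over `pairs` rows: pair included in this structure.
#' @export
sample_structure <- function(d, sample_ids, pairs, cfg, draw_seed) {
  if (nrow(pairs) == 0L) return(logical(0))
  cols <- match(sample_ids, d$sample_ids)
  stopifnot(!anyNA(cols))
  n <- length(cols)
  boot <- with_seed(draw_seed, matrix(cols[sample.int(n, n, replace = TRUE)], n, 1))
  freq <- .boot_edge_freq_cpp(
    d$levels, pair_index_matrix(pairs, d$gene_ids), boot - 1L,
    ifelse(pairs$known, cfg$alpha_known, cfg$alpha_novel)
  )
  freq > 0
}

pair_index_matrix <- function(pairs, gene_ids) {
  m <- cbind(match(pairs$gene_a, gene_ids), match(pairs$gene_b, gene_ids))
  if (anyNA(m)) stop(ddn_validation_error("candidate pair gene absent from matrix"))
  storage.mode(m) <- "integer"
  m - 1L
}

#' Per-condition edge-frequency ensemble
#'
#' Runs `cfg$n_resamples` seeded bootstrap structure draws over one condition's
#' samples and records, per candidate pair, the fraction of draws in which the
#' pair tested dependent. This edge-inclusion frequency profile is the
#' condition's network estimate that the rewiring statistic compares.
#'
#' @inheritParams sample_structure
#' @param condition Condition tag, `"sensitive"` or `"resistant"`.
#' @param base_seed Integer seed for the block of resamples; defaults to a
#'   value derived from `cfg$seed` and the condition tag.
#' @return A `condition_ensemble`: list with `condition`, `pairs`,
#'   `edge_freq` (numeric in \[0,1\] per pair), `n_samples`, `n_resamples`.
#' @export
build_ensemble <- function(d, sample_ids, condition, pairs, cfg,
                           base_seed = NULL) {
  if (length(sample_ids) < cfg$min_group_size) {
    stop(ddn_validation_error(sprintf(
      "underpowered: %d samples < min_group_size %d",
      length(sample_ids), cfg$min_group_size
    )))
  }
  if (is.null(base_seed)) base_seed <- derive_seed(cfg$seed, "ensemble", condition)
  cols <- match(sample_ids, d$sample_ids)
  stopifnot(!anyNA(cols))
  n <- length(cols)
  R <- cfg$n_resamples
  boot <- with_seed(base_seed,
                    matrix(cols[sample.int(n, n * R, replace = TRUE)], n, R))
  freq <- if (nrow(pairs) > 0L) {
    .boot_edge_freq_cpp(d$levels, pair_index_matrix(pairs, d$gene_ids),
                        boot - 1L,
                        ifelse(pairs$known, cfg$alpha_known, cfg$alpha_novel))
  } else numeric(0)
  structure(
    list(condition = condition, pairs = pairs, edge_freq = as.numeric(freq),
         n_samples = n, n_resamples = R),
    class = "condition_ensemble"
  )
}

#' @export
print.condition_ensemble <- function(x, ...) {
  cat(sprintf("<condition_ensemble> %s: %d pairs, %d samples, R=%d\n",
              x$condition, nrow(x$pairs), x$n_samples, x$n_resamples))
  invisible(x)
}

binary_entropy <- function(p) {
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  q <- p[ok]
  h[ok] <- -q * log2(q) - (1 - q) * log2(1 - q)
  h
}

#' Rewiring divergence between two condition ensembles
#'
#' Treats each candidate pair's edge-inclusion frequency as a Bernoulli
#' presence probability and sums, over pairs, the Jensen-Shannon divergence
#' (in bits) between the two conditions:
#' `JSD(P, Q) = H((P + Q) / 2) - (H(P) + H(Q)) / 2` with `H` the binary
#' entropy. The statistic is symmetric, non-negative, zero iff the two
#' frequency profiles coincide, and at most 1 bit per candidate pair.
#'
#' @param ens_s,ens_r `condition_ensemble` objects over identical candidate
#'   pairs.
#' @return The divergence in bits.
#' @examples
#' # one pair, deterministic presence in one condition only -> 1 bit
#' @export
divergence_stat <- function(ens_s, ens_r) {
  if (!identical(pair_key(ens_s$pairs), pair_key(ens_r$pairs))) {
    stop(ddn_validation_error("ensembles have mismatched candidate pair sets"))
  }
  ps <- ens_s$edge_freq
  pr <- ens_r$edge_freq
  jsd <- binary_entropy((ps + pr) / 2) - (binary_entropy(ps) + binary_entropy(pr)) / 2
  sum(pmax(jsd, 0))
}

#' Permutation test of dependency-network rewiring
#'
#' Computes the observed divergence between the sensitive and resistant
#' ensembles, then re-estimates both ensembles under `cfg$n_permutations`
#' random relabelings of the pooled samples (group sizes preserved) and
#' reports the plus-one permutation p-value
#' `p = (1 + #(D_perm >= D_obs)) / (N + 1)`; ties count against rejection.
#' All resample and permutation seeds derive deterministically from
#' `cfg$seed`, the drug id, the cluster id, and the permutation index, so
#' results are reproducible and unaffected by other grid cells.
#'
#' Skipping rather than failing: underpowered partitions, clusters larger than
#' `cfg$max_cluster_size`, and clusters with fewer than two non-degenerate
#' members yield a result with `skipped_reason` set and no p-value.
#'
#' @param d A `discretized_matrix` covering both groups' samples.
#' @param partition A `condition_partition`.
#' @param cluster List with `cluster_id`, `members`, and optionally
#'   `prior_edges` (data.frame `gene_a`, `gene_b`).
#' @param cfg An [eddy_config()].
#' @return A `rewiring_result`: list with `drug_id`, `cluster_id`,
#'   `statistic`, `p_value`, `q_value` (NA until [fdr_adjust()]),
#'   `significant`, `skipped_reason`, the observed `ens_sens`/`ens_res`,
#'   and `perm_stats`.
#' @export
permutation_test <- function(d, partition, cluster, cfg) {
  res <- structure(
    list(drug_id = partition$compound_id, cluster_id = cluster$cluster_id,
         statistic = NA_real_, p_value = NA_real_, q_value = NA_real_,
         significant = NA, skipped_reason = NA_character_,
         ens_sens = NULL, ens_res = NULL, perm_stats = NULL),
    class = "rewiring_result"
  )
  if (isTRUE(partition$underpowered)) {
    res$skipped_reason <- partition$reason
    return(res)
  }
  if (length(cluster$members) > cfg$max_cluster_size) {
    res$skipped_reason <- sprintf("oversized cluster (%d > %d members)",
                                  length(cluster$members), cfg$max_cluster_size)
    return(res)
  }
  members_in <- intersect(cluster$members, d$gene_ids)
  pairs <- candidate_pairs(members_in, cluster$prior_edges, d$degenerate_genes)
  if (nrow(pairs) == 0L) {
    res$skipped_reason <- "fewer than two informative member genes"
    return(res)
  }
  sens <- intersect(partition$sensitive_ids, d$sample_ids)
  rest <- intersect(partition$resistant_ids, d$sample_ids)
  if (length(sens) < cfg$min_group_size || length(rest) < cfg$min_group_size) {
    res$skipped_reason <- sprintf(
      "underpowered pair after expression overlap (groups %d/%d)",
      length(sens), length(rest))
    return(res)
  }
  base <- derive_seed(cfg$seed, partition$compound_id, cluster$cluster_id)
  pool <- c(sens, rest)
  n_s <- length(sens)
  N <- cfg$n_permutations

  run_pair <- function(s_ids, r_ids, k) {
    es <- build_ensemble(d, s_ids, "sensitive", pairs, cfg,
                         base_seed = derive_seed(base, "sens", k))
    er <- build_ensemble(d, r_ids, "resistant", pairs, cfg,
                         base_seed = derive_seed(base, "res", k))
    list(es = es, er = er, D = divergence_stat(es, er))
  }

  obs <- run_pair(sens, rest, 0L)
  perm_stats <- vapply(seq_len(N), function(k) {
    perm <- with_seed(derive_seed(base, "perm", k), sample(pool))
    run_pair(perm[seq_len(n_s)], perm[-seq_len(n_s)], k)$D
  }, numeric(1))

  res$statistic <- obs$D
  res$p_value <- (1 + sum(perm_stats >= obs$D)) / (N + 1)
  res$ens_sens <- obs$es
  res$ens_res <- obs$er
  res$perm_stats <- perm_stats
  res
}

#' @export
print.rewiring_result <- function(x, ...) {
  if (!is.na(x$skipped_reason)) {
    cat(sprintf("<rewiring_result> %s x %s: skipped (%s)\n",
                x$drug_id, x$cluster_id, x$skipped_reason))
  } else {
    cat(sprintf("<rewiring_result> %s x %s: D=%.4f bits, p=%.4g%s\n",
                x$drug_id, x$cluster_id, x$statistic, x$p_value,
                if (!is.na(x$q_value))
                  sprintf(", q=%.4g%s", x$q_value,
                          if (isTRUE(x$significant)) " *" else "")
                else ""))
  }
  invisible(x)
}

#' Benjamini-Hochberg adjustment across the drug-by-cluster grid
#'
#' Computes q-values over all non-skipped results (skipped pairs produce no
#' p-value and are excluded from the multiplicity denominator) and sets the
#' significance flag `q <= fdr_alpha`.
#'
#' @param results List of `rewiring_result` objects.
#' @param fdr_alpha q-value threshold.
#' @return The list with `q_value` and `significant` filled in.
#' @export
fdr_adjust <- function(results, fdr_alpha = 0.05) {
  tested <- which(vapply(results, function(r) is.na(r$skipped_reason), logical(1)))
  if (length(tested) > 0L) {
    p <- vapply(results[tested], `[[`, numeric(1), "p_value")
    q <- stats::p.adjust(p, method = "BH")
    for (j in seq_along(tested)) {
      results[[tested[j]]]$q_value <- q[j]
      results[[tested[j]]]$significant <- q[j] <= fdr_alpha
    }
  }
  results
}
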