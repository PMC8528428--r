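#' Assemble the drug-by-cluster rewiring landscape
#'
#' Collects FDR-adjusted rewiring results for every attempted (drug, cluster)
#' pair into a grid, attaches per-cell mediator counts (non-significant cells
#' get no network, hence zero mediators), and computes marginal scores and
#' frequencies: a drug's score is the summed mediator count over its
#' significant cells, its frequency the number of significant clusters;
#' cluster marginals are symmetric.
#'
#' @param results List of `rewiring_result` objects (after [fdr_adjust()]),
#'   one per attempted pair (skips included).
#' @param ddns Named list of `ddn` objects for significant cells, keyed
#'   `"<drug>||<cluster>"`.
#' @return A `landscape`: list with `drugs`, `clusters`, `cells` (data.frame),
#'   `drug_score`, `cluster_score`, `drug_freq`, `cluster_freq`.
#' @export
build_landscape <- function(results, ddns = list()) {
  cells <- do.call(rbind, lapply(results, function(r) {
    key <- paste(r$drug_id, r$cluster_id, sep = "||")
    sig <- isTRUE(r$significant)
    mc <- if (sig && !is.null(ddns[[key]])) mediator_count(ddns[[key]]) else 0L
    data.frame(drug_id = r$drug_id, cluster_id = r$cluster_id,
               statistic = r$statistic, p_value = r$p_value,
               q_value = r$q_value, significant = sig,
               mediator_count = as.integer(mc),
               skipped_reason = r$skipped_reason,
               stringsAsFactors = FALSE)
  }))
  drugs <- sort(unique(cells$drug_id), method = "radix")
  clusters <- sort(unique(cells$cluster_id), method = "radix")
  sig_cells <- cells[cells$significant, , drop = FALSE]
  marg <- function(ids, field) {
    score <- stats::setNames(numeric(length(ids)), ids)
    freq <- stats::setNames(integer(length(ids)), ids)
    if (nrow(sig_cells) > 0L) {
      s <- tapply(sig_cells$mediator_count, sig_cells[[field]], sum)
      f <- tapply(rep(1L, nrow(sig_cells)), sig_cells[[field]], sum)
      score[names(s)] <- s
      freq[names(f)] <- f
    }
    list(score = score, freq = freq)
  }
  dm <- marg(drugs, "drug_id")
  cm <- marg(clusters, "cluster_id")
  structure(
    list(drugs = drugs, clusters = clusters, cells = cells,
         drug_score = dm$score, cluster_score = cm$score,
         drug_freq = dm$freq, cluster_freq = cm$freq),
    class = "landscape"
  )
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %d drugs x %d clusters, %d significant cell(s)\n",
              length(x$drugs), length(x$clusters), sum(x$cells$significant)))
  invisible(x)
}

#' Order drugs and clusters by rewiring score
#'
#' Descending by score; ties broken ascending-lexicographically by id, so the
#' ordering is stable and deterministic.
#'
#' @param m A `landscape`.
#' @return List with `drugs` and `clusters` in display order.
#' @export
sort_landscape <- function(m) {
  ord <- function(ids, score) ids[order(-score[ids], ids, method = "radix")]
  list(drugs = ord(m$drugs, m$drug_score),
       clusters = ord(m$clusters, m$cluster_score))
}

#' Select the high-activity hotspot sub-matrix
#'
#' Takes the `top_drugs` drugs and `top_clusters` clusters by rewiring score
#' (after [sort_landscape()] ordering) and reports, per selected cluster, the
#' fraction of selected drugs for which that cluster is significantly rewired
#' — the "how many of the top drugs converge on this cluster" statistic.
#'
#' @param m A `landscape`.
#' @param top_drugs,top_clusters Selection sizes (defaults 15 and 5).
#' @return List with `drugs`, `clusters`, `mediator_counts` (selected
#'   sub-matrix, clusters x drugs), and `cluster_hit_fraction` (data.frame
#'   with `cluster_id`, `hits`, `n_drugs`, `fraction`).
#' @export
select_hotspot <- function(m, top_drugs = 15L, top_clusters = 5L) {
  ord <- sort_landscape(m)
  if (top_drugs > length(ord$drugs)) {
    warning(sprintf("top_drugs = %d exceeds available %d; truncating",
                    top_drugs, length(ord$drugs)))
    top_drugs <- length(ord$drugs)
  }
  if (top_clusters > length(ord$clusters)) {
    warning(sprintf("top_clusters = %d exceeds available %d; truncating",
                    top_clusters, length(ord$clusters)))
    top_clusters <- length(ord$clusters)
  }
  drugs <- ord$drugs[seq_len(top_drugs)]
  clusters <- ord$clusters[seq_len(top_clusters)]
  sub <- matrix(0L, length(clusters), length(drugs),
                dimnames = list(clusters, drugs))
  sig <- matrix(FALSE, length(clusters), length(drugs),
                dimnames = list(clusters, drugs))
  cells <- m$cells
  for (i in seq_len(nrow(cells))) {
    d <- cells$drug_id[i]; cl <- cells$cluster_id[i]
    if (d %in% drugs && cl %in% clusters) {
      sub[cl, d] <- cells$mediator_count[i]
      sig[cl, d] <- cells$significant[i]
    }
  }
  hits <- rowSums(sig)
  hit_frac <- data.frame(
    cluster_id = clusters, hits = as.integer(hits),
    n_drugs = rep(length(drugs), length(clusters)),
    fraction = if (length(drugs) > 0L) hits / length(drugs)
               else numeric(length(clusters)),
    stringsAsFactors = FALSE
  )
  list(drugs = drugs, clusters = clusters, mediator_counts = sub,
       cluster_hit_fraction = hit_frac)
}

#' Clusters shared across a drug class
#'
#' Intersection of the per-drug significant-cluster sets over the class
#' members: the clusters rewired by every drug sharing the target.
#'
#' @param sig_sets Named list: per drug, the character vector of its
#'   significant cluster ids.
#' @param member_drug_ids At least two drugs forming the class.
#' @return Character vector of shared cluster ids (sorted).
#' @export
shared_class_clusters <- function(sig_sets, member_drug_ids) {
  if (length(member_drug_ids) < 2L) {
    stop(ddn_validation_error("a drug class needs at least 2 member drugs"))
  }
  missing <- setdiff(member_drug_ids, names(sig_sets))
  if (length(missing) > 0L) {
    stop(ddn_validation_error(sprintf("member drug(s) not analyzed: %s",
                                      paste(missing, collapse = ", "))))
  }
  sort(Reduce(intersect, sig_sets[member_drug_ids]), method = "radix")
}

#' Combined DDN for a drug class on one shared cluster
#'
#' Pools the member drugs' per-condition edge-inclusion frequencies by
#' arithmetic mean (order-invariant), then builds one joint network with
#' mediator detection on the pooled profiles — the class's collective
#' rewiring of the cluster.
#'
#' @param ens_s_list,ens_r_list Per-drug sensitive/resistant
#'   `condition_ensemble`s over identical candidate pairs.
#' @param cfg An [eddy_config()].
#' @param members Optional full member list for the node set.
#' @param drug_id Label for the combined network (e.g. the class id).
#' @param cluster_id Cluster id.
#' @return A `ddn` built on the pooled frequencies.
#' @export
combine_class_ddn <- function(ens_s_list, ens_r_list, cfg, members = NULL,
                              drug_id = "class", cluster_id = NA_character_) {
  stopifnot(length(ens_s_list) == length(ens_r_list), length(ens_s_list) >= 1L)
  ref <- pair_key(ens_s_list[[1]]$pairs)
  for (e in c(ens_s_list, ens_r_list)) {
    if (!identical(pair_key(e$pairs), ref)) {
      stop(ddn_validation_error("mismatched candidate pair sets across class members"))
    }
  }
  pool <- function(lst) {
    out <- lst[[1]]
    out$edge_freq <- rowMeans(do.call(cbind, lapply(lst, `[[`, "edge_freq")))
    out
  }
  build_ddn(pool(ens_s_list), pool(ens_r_list), cfg, members = members,
            drug_id = drug_id, cluster_id = cluster_id)
}

#' Export the landscape as heatmap matrix plus marginal tables
#'
#' Writes `<stem>_heatmap.tsv` (clusters x drugs mediator counts in sorted
#' display order), `<stem>_drug_marginals.tsv` and
#' `<stem>_cluster_marginals.tsv` (score and significant-cell frequency per
#' id, in the same order). Output bytes are deterministic.
#'
#' @param m A `landscape`.
#' @param stem Output path stem.
#' @return Invisibly, the files written.
#' @export
export_landscape <- function(m, stem) {
  ord <- sort_landscape(m)
  heat <- matrix(0L, length(ord$clusters), length(ord$drugs),
                 dimnames = list(ord$clusters, ord$drugs))
  for (i in seq_len(nrow(m$cells))) {
    heat[m$cells$cluster_id[i], m$cells$drug_id[i]] <- m$cells$mediator_count[i]
  }
  hpath <- paste0(stem, "_heatmap.tsv")
  writeLines(c(
    paste(c("cluster_id", ord$drugs), collapse = "\t"),
    vapply(ord$clusters, function(cl) {
      paste(c(cl, heat[cl, ]), collapse = "\t")
    }, character(1))
  ), hpath)
  marg_file <- function(ids, score, freq, idcol, path) {
    writeLines(c(
      paste(c(idcol, "score", "freq"), collapse = "\t"),
      sprintf("%s\t%s\t%d", ids, num_fmt(score[ids]), freq[ids])
    ), path)
    path
  }
  dpath <- marg_file(ord$drugs, m$drug_score, m$drug_freq, "drug_id",
                     paste0(stem, "_drug_marginals.tsv"))
  cpath <- marg_file(ord$clusters, m$cluster_score, m$cluster_freq, "cluster_id",
                     paste0(stem, "_cluster_marginals.tsv"))
  invisible(c(hpath, dpath, cpath))
}
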