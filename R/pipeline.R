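#' Run the full drug-by-cluster rewiring pipeline
#'
#' Orchestrates, for every (compound, cluster) pair: response dichotomization,
#' discretization, per-condition bootstrap ensembles, the permutation rewiring
#' test, Benjamini-Hochberg correction across the whole grid, differential
#' dependency networks with mediator detection for significant cells, and the
#' landscape with its exports. Skipped pairs (underpowered partition,
#' oversized cluster, too few informative genes) are recorded with their
#' reason and excluded from the FDR denominator. The entire run is a pure
#' function of the inputs and `config$seed`; per-pair seeds derive from the
#' drug and cluster ids, so adding a drug never perturbs other pairs.
#'
#' @param expression_path Path to the expression matrix (TSV/CSV).
#' @param response_path Path to the three-column response table.
#' @param gmt_path,sif_path Paths to the cluster catalog (GMT) and prior-edge
#'   file (SIF; may be empty).
#' @param out_dir Output directory (created if needed). Artifacts:
#'   `scores.tsv`, `landscape_*.tsv`, `partitions/`, `ddn/` (per significant
#'   cell: `.sif`, `.graphml`, `.json`, `_mediators.tsv`), `manifest.json`.
#' @param config An [eddy_config()].
#' @param compounds Optional subset of compound ids to analyze.
#' @return Invisibly, a `pipeline_result`: list with `manifest`, `results`
#'   (per-pair `rewiring_result`s incl. observed ensembles), `ddns`,
#'   `landscape`, `catalog`, and `out_dir`.
#' @export
run_pipeline <- function(expression_path, response_path, gmt_path, sif_path,
                         out_dir, config = eddy_config(), compounds = NULL) {
  t0 <- Sys.time()
  expr <- read_expression(expression_path)
  response <- read_response(response_path)
  catalog <- read_clusters(gmt_path, sif_path)

  shared <- intersect(expr$sample_ids, unique(response$sample_id))
  if (length(shared) == 0L) {
    stop(ddn_validation_error(
      "no shared sample ids between expression matrix and response table"))
  }
  if (is.null(compounds)) compounds <- sort(unique(response$compound_id),
                                            method = "radix")
  d <- discretize(expr)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "ddn"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "partitions"), showWarnings = FALSE)

  results <- list()
  status <- list()
  for (drug in compounds) {
    part <- partition_by_response(response, drug,
                                  lower_q = config$lower_q,
                                  upper_q = config$upper_q,
                                  min_group_size = config$min_group_size)
    write_partition(part, file.path(out_dir, "partitions",
                                    paste0(sanitize_id(drug), ".tsv")))
    for (cl in names(catalog$clusters)) {
      prior <- catalog$prior_edges[catalog$prior_edges$cluster_id == cl, ,
                                   drop = FALSE]
      cluster <- list(cluster_id = cl, members = catalog$clusters[[cl]],
                      prior_edges = prior)
      r <- permutation_test(d, part, cluster, config)
      key <- paste(drug, cl, sep = "||")
      results[[key]] <- r
      status[[key]] <- list(
        drug_id = drug, cluster_id = cl,
        status = if (is.na(r$skipped_reason)) "done" else "skipped",
        reason = if (is.na(r$skipped_reason)) NULL else r$skipped_reason
      )
    }
  }
  results <- fdr_adjust(results, config$fdr_alpha)

  ddns <- list()
  for (key in names(results)) {
    r <- results[[key]]
    if (isTRUE(r$significant)) {
      members <- catalog$clusters[[r$cluster_id]]
      ddn <- build_ddn(r$ens_sens, r$ens_res, config,
                       members = intersect(members, d$gene_ids),
                       drug_id = r$drug_id, cluster_id = r$cluster_id)
      ddns[[key]] <- ddn
      stem <- file.path(out_dir, "ddn",
                        paste(sanitize_id(r$drug_id), sanitize_id(r$cluster_id),
                              sep = "__"))
      write_ddn(ddn, stem)
      write_mediators(ddn, paste0(stem, "_mediators.tsv"))
    }
  }

  landscape <- build_landscape(unname(results), ddns)
  write_scores(landscape, file.path(out_dir, "scores.tsv"))
  export_landscape(landscape, file.path(out_dir, "landscape"))

  manifest <- list(
    tool = "ddnrewire",
    version = as.character(utils::packageVersion("ddnrewire")),
    seed = config$seed,
    config = unclass(config),
    inputs = list(
      expression = unname(tools::md5sum(expression_path)),
      response = unname(tools::md5sum(response_path)),
      gmt = unname(tools::md5sum(gmt_path)),
      sif = unname(tools::md5sum(sif_path))
    ),
    pairs = unname(status),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(structure(
    list(manifest = manifest, results = results, ddns = ddns,
         landscape = landscape, catalog = catalog, out_dir = out_dir),
    class = "pipeline_result"
  ))
}

sanitize_id <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

#' @export
print.pipeline_result <- function(x, ...) {
  n_done <- sum(vapply(x$manifest$pairs, function(p) p$status == "done", logical(1)))
  cat(sprintf("<pipeline_result> %d pair(s) attempted (%d tested), %d significant; outputs in %s\n",
              length(x$manifest$pairs), n_done,
              sum(x$landscape$cells$significant), x$out_dir))
  invisible(x)
}

#' Drug-class shared clusters and combined networks
#'
#' For a set of drugs sharing a target, intersects the members' significant
#' cluster sets and, for each shared cluster, pools the member drugs'
#' edge-inclusion frequencies into one combined class network with mediator
#' detection (see [combine_class_ddn()]).
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @param class_id Label for the drug class.
#' @param member_drug_ids At least two analyzed drugs.
#' @param out_dir Optional directory for the class report
#'   (`class_<id>.json` + combined DDN files).
#' @return List with `class_id`, `member_drug_ids`, `shared_cluster_ids`,
#'   `combined_ddns` (named by cluster).
#' @export
run_class <- function(result, class_id, member_drug_ids, out_dir = NULL) {
  stopifnot(inherits(result, "pipeline_result"))
  if (length(member_drug_ids) < 2L) {
    stop(ddn_validation_error("a drug class needs at least 2 member drugs"))
  }
  analyzed <- unique(vapply(result$results, `[[`, character(1), "drug_id"))
  missing <- setdiff(member_drug_ids, analyzed)
  if (length(missing) > 0L) {
    stop(ddn_validation_error(sprintf(
      "member drug(s) absent from the run: %s", paste(missing, collapse = ", "))))
  }
  cfg <- do.call(eddy_config, result$manifest$config)
  sig_sets <- lapply(stats::setNames(nm = analyzed), function(drug) {
    hits <- Filter(function(r) r$drug_id == drug && isTRUE(r$significant),
                   result$results)
    vapply(hits, `[[`, character(1), "cluster_id")
  })
  shared <- shared_class_clusters(sig_sets, member_drug_ids)

  combined <- list()
  for (cl in shared) {
    keys <- paste(member_drug_ids, cl, sep = "||")
    ens_s <- lapply(result$results[keys], `[[`, "ens_sens")
    ens_r <- lapply(result$results[keys], `[[`, "ens_res")
    pairs1 <- ens_s[[1]]$pairs
    combined[[cl]] <- combine_class_ddn(ens_s, ens_r, cfg,
                                        members = unique(c(pairs1$gene_a,
                                                           pairs1$gene_b)),
                                        drug_id = class_id, cluster_id = cl)
  }

  report <- list(class_id = class_id, member_drug_ids = member_drug_ids,
                 shared_cluster_ids = shared)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report,
                         file.path(out_dir, sprintf("class_%s.json",
                                                    sanitize_id(class_id))),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (cl in shared) {
      write_ddn(combined[[cl]],
                file.path(out_dir, sprintf("class_%s__%s", sanitize_id(class_id),
                                           sanitize_id(cl))))
    }
  }
  c(report, list(combined_ddns = combined))
}
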