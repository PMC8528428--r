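#' Dichotomize samples by drug response
#'
#' For one compound, splits the samples carrying a response record into
#' drug-sensitive (lowest AUC tail: a small area under the dose-response curve
#' means the drug killed effectively), drug-resistant (highest AUC tail) and
#' excluded (middle). Thresholds are empirical type-7 quantiles at the
#' `lower_q` fraction from the bottom and `upper_q` fraction from the top;
#' samples tied exactly at a boundary all join the extreme group, so the
#' partition is deterministic and invariant to record order.
#'
#' If either retained group ends up smaller than `min_group_size`, or the two
#' tails overlap (e.g. all AUC values equal), the partition is flagged
#' underpowered rather than raising an error, so a drug-by-cluster grid run
#' can skip the pair and continue.
#'
#' @param table A `drug_response` data.frame (see [read_response()]).
#' @param compound_id Compound to partition on.
#' @param lower_q Bottom-tail fraction assigned sensitive (default 1/3).
#' @param upper_q Top-tail fraction assigned resistant (default 1/3).
#' @param min_group_size Minimum retained group size (default 15).
#' @return A `condition_partition`: list with `compound_id`, `sensitive_ids`,
#'   `resistant_ids`, `excluded_ids`, `quantile_bounds`, `underpowered`,
#'   `reason`.
#' @examples
#' tab <- data.frame(compound_id = "drugA", sample_id = paste0("s", 1:9),
#'                   auc = 1:9)
#' class(tab) <- c("drug_response", "data.frame")
#' p <- partition_by_response(tab, "drugA", min_group_size = 3)
#' p$sensitive_ids  # s1 s2 s3
#' @export
partition_by_response <- function(table, compound_id,
                                  lower_q = 1 / 3, upper_q = 1 / 3,
                                  min_group_size = 15L) {
  stopifnot(lower_q > 0, lower_q < 1, upper_q > 0, upper_q < 1)
  if (lower_q + upper_q > 1) {
    stop(ddn_validation_error("lower_q + upper_q must not exceed 1"))
  }
  rows <- table[table$compound_id == compound_id, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop(ddn_validation_error(sprintf("compound %s not present in response table",
                                      compound_id)))
  }
  # sort by sample id for order invariance
  rows <- rows[order(rows$sample_id, method = "radix"), , drop = FALSE]
  lo <- unname(stats::quantile(rows$auc, lower_q, type = 7))
  hi <- unname(stats::quantile(rows$auc, 1 - upper_q, type = 7))
  sens <- rows$sample_id[rows$auc <= lo]
  res <- rows$sample_id[rows$auc >= hi]
  overlap <- intersect(sens, res)
  underpowered <- FALSE
  reason <- NA_character_
  if (length(overlap) > 0L) {
    underpowered <- TRUE
    reason <- "degenerate response distribution (tails overlap)"
    sens <- setdiff(sens, overlap)
    res <- setdiff(res, overlap)
  } else if (length(sens) < min_group_size || length(res) < min_group_size) {
    underpowered <- TRUE
    reason <- sprintf("underpowered pair (groups %d/%d < min_group_size %d)",
                      length(sens), length(res), min_group_size)
  }
  excluded <- setdiff(rows$sample_id, c(sens, res))
  new_condition_partition(compound_id, sens, res, excluded,
                          quantile_bounds = c(lower_q, upper_q),
                          underpowered = underpowered, reason = reason)
}

#' Construct a condition partition directly
#'
#' Programmatic constructor used when group labels come from a source other
#' than an AUC table (simulations, externally curated cohorts).
#'
#' @param compound_id Compound identifier.
#' @param sensitive_ids,resistant_ids,excluded_ids Disjoint sample-id vectors.
#' @param quantile_bounds Length-2 numeric, recorded verbatim.
#' @param underpowered Logical skip flag.
#' @param reason Skip reason when underpowered.
#' @return A `condition_partition` object.
#' @export
new_condition_partition <- function(compound_id, sensitive_ids, resistant_ids,
                                    excluded_ids = character(0),
                                    quantile_bounds = c(1 / 3, 1 / 3),
                                    underpowered = FALSE,
                                    reason = NA_character_) {
  if (length(intersect(sensitive_ids, resistant_ids)) > 0L) {
    stop(ddn_validation_error("sensitive and resistant sets must be disjoint"))
  }
  structure(
    list(compound_id = compound_id,
         sensitive_ids = as.character(sensitive_ids),
         resistant_ids = as.character(resistant_ids),
         excluded_ids = as.character(excluded_ids),
         quantile_bounds = quantile_bounds,
         underpowered = underpowered,
         reason = reason),
    class = "condition_partition"
  )
}

#' @export
print.condition_partition <- function(x, ...) {
  cat(sprintf("<condition_partition> %s: %d sensitive / %d resistant / %d excluded%s\n",
              x$compound_id, length(x$sensitive_ids), length(x$resistant_ids),
              length(x$excluded_ids),
              if (x$underpowered) sprintf(" [skipped: %s]", x$reason) else ""))
  invisible(x)
}

#' Export a partition as a two-column TSV
#'
#' @param partition A `condition_partition`.
#' @param path Output path; columns `sample_id`, `label`.
#' @return Invisibly, `path`.
#' @export
write_partition <- function(partition, path) {
  lab <- c(stats::setNames(rep("sensitive", length(partition$sensitive_ids)),
                           partition$sensitive_ids),
           stats::setNames(rep("resistant", length(partition$resistant_ids)),
                           partition$resistant_ids),
           stats::setNames(rep("excluded", length(partition$excluded_ids)),
                           partition$excluded_ids))
  lab <- lab[order(names(lab), method = "radix")]
  writeLines(c("sample_id\tlabel", sprintf("%s\t%s", names(lab), lab)), path)
  invisible(path)
}
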