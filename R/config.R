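#' Analysis configuration
#'
#' Bundles every tuning parameter of the rewiring engine. Defaults follow the
#' package's standard operating point; all are overridable here or through a
#' YAML/JSON config file (see [read_config()]).
#'
#' @param n_bins Number of discretization levels. Fixed at 3 (equal-frequency
#'   tertiles); present for config-file completeness.
#' @param alpha_known Per-resample G-test significance level for prior-knowledge
#'   ("known") edges. Known edges are admitted at a laxer threshold than novel
#'   pairs, which is how prior knowledge assists edge discovery.
#' @param alpha_novel Significance level for novel (non-prior) gene pairs.
#'   Must not exceed `alpha_known`.
#' @param n_resamples Number of bootstrap resamples per condition used to
#'   estimate edge-inclusion frequencies.
#' @param n_permutations Number of label permutations for the rewiring null.
#' @param presence_theta Minimum edge-inclusion frequency (in either condition)
#'   for an edge to appear in the differential dependency network.
#' @param specific_tau Minimum frequency difference for an edge to be called
#'   condition-specific rather than shared ("both").
#' @param bc_delta_cutoff Absolute normalized betweenness-centrality difference
#'   at or above which a gene is an essentiality mediator.
#' @param mediator_alpha Significance level of the one-sided binomial test for
#'   specificity mediators.
#' @param fdr_alpha Benjamini-Hochberg q-value threshold across the
#'   drug-by-cluster grid.
#' @param min_group_size Minimum size of each of the sensitive and resistant
#'   groups; smaller partitions are skipped as underpowered.
#' @param max_cluster_size Clusters with more members are skipped to bound the
#'   quadratic candidate-pair space.
#' @param lower_q,upper_q Lower/upper tail fractions for the response
#'   dichotomization (see [partition_by_response()]).
#' @param seed Master integer seed; every random draw in the engine derives
#'   deterministically from it.
#'
#' @return An object of class `eddy_config` (a validated named list).
#' @examples
#' cfg <- eddy_config(n_resamples = 50, n_permutations = 99, seed = 11)
#' cfg$alpha_novel
#' @export
eddy_config <- function(n_bins = 3L,
                        alpha_known = 0.05,
                        alpha_novel = 0.01,
                        n_resamples = 100L,
                        n_permutations = 999L,
                        presence_theta = 0.5,
                        specific_tau = 0.3,
                        bc_delta_cutoff = 0.3,
                        mediator_alpha = 0.05,
                        fdr_alpha = 0.05,
                        min_group_size = 15L,
                        max_cluster_size = 60L,
                        lower_q = 1 / 3,
                        upper_q = 1 / 3,
                        seed = 7L) {
  cfg <- list(
    n_bins = as.integer(n_bins),
    alpha_known = alpha_known,
    alpha_novel = alpha_novel,
    n_resamples = as.integer(n_resamples),
    n_permutations = as.integer(n_permutations),
    presence_theta = presence_theta,
    specific_tau = specific_tau,
    bc_delta_cutoff = bc_delta_cutoff,
    mediator_alpha = mediator_alpha,
    fdr_alpha = fdr_alpha,
    min_group_size = as.integer(min_group_size),
    max_cluster_size = as.integer(max_cluster_size),
    lower_q = lower_q,
    upper_q = upper_q,
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "eddy_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_bins == 3L)
  if (cfg$alpha_novel > cfg$alpha_known) {
    stop("alpha_novel must not exceed alpha_known", call. = FALSE)
  }
  if (cfg$n_resamples < 20L) stop("n_resamples must be >= 20", call. = FALSE)
  if (cfg$n_permutations < 19L) stop("n_permutations must be >= 19", call. = FALSE)
  for (f in c("alpha_known", "alpha_novel", "presence_theta", "specific_tau",
              "mediator_alpha", "fdr_alpha", "lower_q", "upper_q")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1) {
      stop(sprintf("%s must be a single value in (0,1)", f), call. = FALSE)
    }
  }
  if (cfg$bc_delta_cutoff <= 0 || cfg$bc_delta_cutoff > 1) {
    stop("bc_delta_cutoff must be in (0,1]", call. = FALSE)
  }
  if (cfg$lower_q + cfg$upper_q > 1) {
    stop("lower_q + upper_q must not exceed 1", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a configuration file
#'
#' Accepts a YAML or JSON file whose keys mirror [eddy_config()] arguments
#' field-for-field. Unknown keys are a validation error rather than being
#' silently ignored.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return An `eddy_config` object.
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(eddy_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L) {
    stop(ddn_validation_error(sprintf(
      "unknown config key(s): %s", paste(bad, collapse = ", ")
    )))
  }
  do.call(eddy_config, vals)
}

#' @export
print.eddy_config <- function(x, ...) {
  cat("<eddy_config>\n")
  for (f in names(x)) cat(sprintf("  %-16s %s\n", f, format(x[[f]])))
  invisible(x)
}

# Deterministic 31-bit seed from arbitrary tokens; polynomial string hash.
# Keeps the whole engine a pure function of (inputs, cfg$seed).
derive_seed <- function(...) {
  s <- paste(vapply(list(...), function(v) paste(as.character(v), collapse = ","),
                    character(1)), collapse = "\r")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483629
  as.integer(h + 1)
}

# Run code under a given seed without clobbering the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

ddn_validation_error <- function(msg) {
  structure(
    class = c("ddn_validation_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
}

ddn_format_error <- function(msg) {
  structure(
    class = c("ddn_format_error", "ddn_validation_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
}
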