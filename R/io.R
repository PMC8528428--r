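#' Read a delimited expression matrix
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; the delimiter is auto-detected from the header (tab preferred,
#' comma fallback). Values are continuous log-scale expression, assumed already
#' normalized. Genes with more than `max_missing_frac` missing entries are
#' dropped with a message.
#'
#' @param path Path to a TSV/CSV file.
#' @param missing_token Text token marking a missing value (default `"NA"`).
#' @param max_missing_frac Per-gene missing fraction above which the gene is
#'   excluded (default 0.2).
#' @return An `expression_matrix`: list with `gene_ids`, `sample_ids`, `values`
#'   (genes x samples numeric matrix) and `missing_mask` (logical matrix).
#' @export
read_expression <- function(path, missing_token = "NA", max_missing_frac = 0.2) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop(ddn_format_error("expression file has no data rows"))
  delim <- detect_delim(lines[[1]])
  header <- strsplit(lines[[1]], delim, fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids)) {
    stop(ddn_format_error(sprintf(
      "duplicate sample identifier: %s",
      sample_ids[duplicated(sample_ids)][1]
    )))
  }
  body <- strsplit(lines[-1], delim, fixed = TRUE)
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(gene_ids)) {
    stop(ddn_format_error(sprintf(
      "duplicate gene identifier: %s", gene_ids[duplicated(gene_ids)][1]
    )))
  }
  n <- length(sample_ids)
  values <- matrix(NA_real_, length(gene_ids), n,
                   dimnames = list(gene_ids, sample_ids))
  mask <- matrix(FALSE, length(gene_ids), n,
                 dimnames = list(gene_ids, sample_ids))
  for (i in seq_along(body)) {
    cells <- body[[i]][-1]
    if (length(cells) != n) {
      stop(ddn_format_error(sprintf(
        "row %d (%s): expected %d values, found %d",
        i + 1L, gene_ids[i], n, length(cells)
      )))
    }
    miss <- cells == missing_token
    num <- suppressWarnings(as.numeric(cells))
    bad <- which(!miss & !is.finite(num))
    if (length(bad) > 0L) {
      stop(ddn_format_error(sprintf(
        "non-numeric value '%s' at row %d, column %d (gene %s, sample %s)",
        cells[bad[1]], i + 1L, bad[1] + 1L, gene_ids[i], sample_ids[bad[1]]
      )))
    }
    values[i, ] <- num
    mask[i, ] <- miss
  }
  too_missing <- rowMeans(mask) > max_missing_frac
  if (any(too_missing)) {
    message(sprintf(
      "read_expression: dropping %d gene(s) with > %d%% missing entries: %s",
      sum(too_missing), round(100 * max_missing_frac),
      paste(gene_ids[too_missing], collapse = ", ")
    ))
    values <- values[!too_missing, , drop = FALSE]
    mask <- mask[!too_missing, , drop = FALSE]
    gene_ids <- gene_ids[!too_missing]
  }
  new_expression_matrix(gene_ids, sample_ids, values, mask)
}

new_expression_matrix <- function(gene_ids, sample_ids, values, missing_mask) {
  stopifnot(!anyDuplicated(gene_ids), !anyDuplicated(sample_ids))
  if (any(!is.finite(values[!missing_mask]))) {
    stop(ddn_format_error("non-finite expression value outside missing mask"))
  }
  structure(
    list(gene_ids = gene_ids, sample_ids = sample_ids,
         values = values, missing_mask = missing_mask),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (%d missing cells)\n",
              length(x$gene_ids), length(x$sample_ids), sum(x$missing_mask)))
  invisible(x)
}

detect_delim <- function(header) {
  if (grepl("\t", header, fixed = TRUE)) "\t"
  else if (grepl(",", header, fixed = TRUE)) ","
  else stop(ddn_format_error("could not detect delimiter (no tab or comma in header)"))
}

#' Read a drug-response table
#'
#' Three delimited columns: compound identifier, sample identifier, and area
#' under the dose-response curve (AUC; lower = more sensitive). A header row is
#' detected by a non-numeric third field on line 1.
#'
#' @param path Path to a delimited file.
#' @return A `drug_response` data.frame with columns `compound_id`,
#'   `sample_id`, `auc`.
#' @export
read_response <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop(ddn_format_error("empty response file"))
  delim <- detect_delim(lines[[1]])
  rows <- strsplit(lines, delim, fixed = TRUE)
  start <- 1L
  first <- rows[[1]]
  if (length(first) >= 3L && is.na(suppressWarnings(as.numeric(first[[3]])))) {
    start <- 2L  # header row
  }
  if (start > length(rows)) stop(ddn_format_error("response file has no data rows"))
  recs <- lapply(start:length(rows), function(i) {
    r <- rows[[i]]
    if (length(r) != 3L) {
      stop(ddn_format_error(sprintf("line %d: expected 3 fields, found %d", i, length(r))))
    }
    auc <- suppressWarnings(as.numeric(r[[3]]))
    if (!is.finite(auc)) {
      stop(ddn_format_error(sprintf("line %d: non-numeric auc '%s'", i, r[[3]])))
    }
    data.frame(compound_id = r[[1]], sample_id = r[[2]], auc = auc,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, recs)
  key <- paste(tab$compound_id, tab$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- tab[duplicated(key), ][1, ]
    stop(ddn_format_error(sprintf(
      "duplicate (compound, sample) pair: (%s, %s)", d$compound_id, d$sample_id
    )))
  }
  class(tab) <- c("drug_response", "data.frame")
  tab
}

#' Read a gene-cluster catalog (GMT + SIF)
#'
#' Cluster membership comes from a GMT file (`cluster_id<TAB>description<TAB>`
#' `gene...`); prior-knowledge interaction edges come from a SIF file whose
#' relation token names the source cluster (`geneA<TAB>cluster_id<TAB>geneB`).
#' Every prior edge must join two members of its tagged cluster.
#'
#' @param gmt_path Path to the GMT gene-set file.
#' @param sif_path Path to the SIF prior-edge file; may be an empty file, in
#'   which case all candidate pairs downstream are novel.
#' @return A `cluster_catalog`: list with `clusters` (named list of member
#'   character vectors), `descriptions`, and `prior_edges` (data.frame
#'   `cluster_id`, `gene_a`, `gene_b`).
#' @export
read_clusters <- function(gmt_path, sif_path) {
  lines <- readLines(gmt_path)
  clusters <- list()
  descriptions <- character(0)
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[[i]]))) {
      stop(ddn_format_error(sprintf("empty GMT line at %d", i)))
    }
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop(ddn_format_error(sprintf("GMT line %d: fewer than 3 fields", i)))
    }
    id <- f[[1]]
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0L) {
      stop(ddn_format_error(sprintf("GMT line %d (%s): no members", i, id)))
    }
    if (anyDuplicated(members)) {
      stop(ddn_format_error(sprintf(
        "GMT cluster %s: duplicate member %s", id, members[duplicated(members)][1]
      )))
    }
    if (id %in% names(clusters)) {
      stop(ddn_format_error(sprintf("duplicate cluster id %s", id)))
    }
    clusters[[id]] <- members
    descriptions[[id]] <- f[[2]]
  }

  sif_lines <- readLines(sif_path)
  sif_lines <- sif_lines[nzchar(trimws(sif_lines))]
  if (length(sif_lines) > 0L) {
    parts <- strsplit(sif_lines, "[\t ]+")
    prior <- do.call(rbind, lapply(seq_along(parts), function(i) {
      f <- parts[[i]]
      if (length(f) != 3L) {
        stop(ddn_format_error(sprintf("SIF line %d: expected 3 fields", i)))
      }
      data.frame(cluster_id = f[[2]], gene_a = f[[1]], gene_b = f[[3]],
                 stringsAsFactors = FALSE)
    }))
    for (i in seq_len(nrow(prior))) {
      cl <- prior$cluster_id[i]
      if (!cl %in% names(clusters)) {
        stop(ddn_validation_error(sprintf(
          "SIF edge (%s, %s) tagged with unknown cluster %s",
          prior$gene_a[i], prior$gene_b[i], cl
        )))
      }
      out <- setdiff(c(prior$gene_a[i], prior$gene_b[i]), clusters[[cl]])
      if (length(out) > 0L) {
        stop(ddn_validation_error(sprintf(
          "SIF edge (%s, %s) of cluster %s has non-member endpoint %s",
          prior$gene_a[i], prior$gene_b[i], cl, out[1]
        )))
      }
    }
    # canonical unordered representation
    swap <- prior$gene_a > prior$gene_b
    tmp <- prior$gene_a[swap]
    prior$gene_a[swap] <- prior$gene_b[swap]
    prior$gene_b[swap] <- tmp
  } else {
    prior <- data.frame(cluster_id = character(0), gene_a = character(0),
                        gene_b = character(0), stringsAsFactors = FALSE)
  }
  structure(
    list(clusters = clusters, descriptions = descriptions, prior_edges = prior),
    class = "cluster_catalog"
  )
}

#' @export
print.cluster_catalog <- function(x, ...) {
  cat(sprintf("<cluster_catalog> %d clusters, %d prior edges\n",
              length(x$clusters), nrow(x$prior_edges)))
  invisible(x)
}

num_fmt <- function(x) {
  # full binary precision so read-back reproduces values exactly;
  # %.17g round-trips IEEE doubles
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write a differential dependency network
#'
#' Emits three sibling files from one path stem: `<stem>.sif` with relation
#' tokens `sensitive`/`resistant`/`both`, `<stem>.graphml` with full edge and
#' node attributes, and `<stem>.json` mirroring both. Output bytes are a pure
#' function of the DDN, so repeated calls are byte-identical.
#'
#' @param ddn A `ddn` object from [build_ddn()].
#' @param stem Output path stem (no extension).
#' @return Invisibly, the character vector of files written.
#' @export
write_ddn <- function(ddn, stem) {
  stopifnot(inherits(ddn, "ddn"))
  e <- ddn$edges
  nd <- ddn$nodes
  if (nrow(e) > 0L) e <- e[order(e$gene_a, e$gene_b, method = "radix"), , drop = FALSE]
  if (nrow(nd) > 0L) nd <- nd[order(nd$gene_id, method = "radix"), , drop = FALSE]

  sif_path <- paste0(stem, ".sif")
  sif <- if (nrow(e) > 0L) {
    sprintf("%s\t%s\t%s", e$gene_a, e$condition_class, e$gene_b)
  } else character(0)
  writeLines(sif, sif_path)

  gml_path <- paste0(stem, ".graphml")
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="condition_class" for="edge" attr.name="condition_class" attr.type="string"/>',
    '  <key id="known" for="edge" attr.name="known" attr.type="boolean"/>',
    '  <key id="p_sens" for="edge" attr.name="p_sens" attr.type="double"/>',
    '  <key id="p_res" for="edge" attr.name="p_res" attr.type="double"/>',
    '  <key id="bc_sens" for="node" attr.name="bc_sens" attr.type="double"/>',
    '  <key id="bc_res" for="node" attr.name="bc_res" attr.type="double"/>',
    '  <key id="specificity_mediator" for="node" attr.name="specificity_mediator" attr.type="boolean"/>',
    '  <key id="essentiality_mediator" for="node" attr.name="essentiality_mediator" attr.type="boolean"/>',
    '  <graph edgedefault="undirected">'
  )
  if (nrow(nd) > 0L) {
    out <- c(out, sprintf(
      paste0('    <node id="%s"><data key="bc_sens">%s</data>',
             '<data key="bc_res">%s</data>',
             '<data key="specificity_mediator">%s</data>',
             '<data key="essentiality_mediator">%s</data></node>'),
      xml_escape(nd$gene_id), num_fmt(nd$bc_sens), num_fmt(nd$bc_res),
      tolower(nd$specificity_mediator), tolower(nd$essentiality_mediator)
    ))
  }
  if (nrow(e) > 0L) {
    out <- c(out, sprintf(
      paste0('    <edge source="%s" target="%s">',
             '<data key="condition_class">%s</data>',
             '<data key="known">%s</data>',
             '<data key="p_sens">%s</data>',
             '<data key="p_res">%s</data></edge>'),
      xml_escape(e$gene_a), xml_escape(e$gene_b), e$condition_class,
      tolower(e$known), num_fmt(e$p_sens), num_fmt(e$p_res)
    ))
  }
  out <- c(out, "  </graph>", "</graphml>")
  writeLines(out, gml_path)

  json_path <- paste0(stem, ".json")
  obj <- list(
    drug_id = ddn$drug_id,
    cluster_id = ddn$cluster_id,
    background_specific_fraction = ddn$background_specific_fraction,
    nodes = nd,
    edges = e
  )
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(c(sif_path, gml_path, json_path))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

#' Write the landscape score table
#'
#' One row per (drug, cluster) cell (`row_type = "cell"`) with the rewiring
#' statistic, p, q, significance flag and mediator count, followed by marginal
#' score/frequency rows per drug and per cluster. Numeric fields are printed at
#' full precision so a read-back reproduces them exactly.
#'
#' @param landscape A `landscape` object from [build_landscape()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @seealso [read_scores()]
#' @export
write_scores <- function(landscape, path) {
  stopifnot(inherits(landscape, "landscape"))
  cells <- landscape$cells
  hdr <- paste(c("row_type", "drug_id", "cluster_id", "statistic", "p_value",
                 "q_value", "significant", "mediator_count", "score",
                 "freq", "skipped_reason"), collapse = "\t")
  cell_rows <- vapply(seq_len(nrow(cells)), function(i) {
    r <- cells[i, ]
    paste(c("cell", r$drug_id, r$cluster_id, num_fmt(r$statistic),
            num_fmt(r$p_value), num_fmt(r$q_value), tolower(r$significant),
            r$mediator_count, "NA", "NA",
            if (is.na(r$skipped_reason)) "" else r$skipped_reason),
          collapse = "\t")
  }, character(1))
  drug_rows <- vapply(landscape$drugs, function(d) {
    paste(c("drug_marginal", d, "NA", "NA", "NA", "NA", "NA", "NA",
            num_fmt(landscape$drug_score[[d]]), landscape$drug_freq[[d]], ""),
          collapse = "\t")
  }, character(1))
  cl_rows <- vapply(landscape$clusters, function(cl) {
    paste(c("cluster_marginal", "NA", cl, "NA", "NA", "NA", "NA", "NA",
            num_fmt(landscape$cluster_score[[cl]]), landscape$cluster_freq[[cl]], ""),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, cell_rows, drug_rows, cl_rows), path)
  invisible(path)
}

#' Read back a landscape score table
#'
#' @param path A TSV written by [write_scores()].
#' @return A list with data.frames `cells`, `drug_marginals`,
#'   `cluster_marginals`.
#' @export
read_scores <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(
                             row_type = "character", drug_id = "character",
                             cluster_id = "character", statistic = "numeric",
                             p_value = "numeric", q_value = "numeric",
                             significant = "character",
                             mediator_count = "numeric", score = "numeric",
                             freq = "numeric", skipped_reason = "character"
                           ))
  tab$significant <- tab$significant == "true"
  list(
    cells = tab[tab$row_type == "cell", , drop = FALSE],
    drug_marginals = tab[tab$row_type == "drug_marginal", , drop = FALSE],
    cluster_marginals = tab[tab$row_type == "cluster_marginal", , drop = FALSE]
  )
}
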