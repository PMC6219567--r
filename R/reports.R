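#' Per-biotype nuclear-localization summary
#'
#' For each lncRNA biotype, the number of predicted transcripts and the
#' percentage predicted nuclear — the table behind a "percent nuclear by
#' biotype" bar chart with its 50% reference line.
#'
#' @param predictions Data frame with `transcript_id` and either a
#'   `label` column (nuclear/cytosolic) or a `P_nuclear` column (labelled
#'   at `cutoff`).
#' @param annotation Annotation data frame from [read_annotation()].
#' @param cutoff Cutoff used when only probabilities are supplied.
#' @return Data frame `biotype`, `n`, `percent_nuclear`, plus a
#'   `reference_line` attribute at 50. Biotypes with no predicted
#'   transcripts are omitted with a warning.
#' @export
report_biotype_localization <- function(predictions, annotation,
                                        cutoff = 0.5) {
  stopifnot("transcript_id" %in% names(predictions))
  if (!"label" %in% names(predictions)) {
    if (!"P_nuclear" %in% names(predictions)) {
      stop("predictions need a 'label' or 'P_nuclear' column")
    }
    predictions$label <- classify(predictions$P_nuclear, cutoff)
  }
  idx <- match(predictions$transcript_id, annotation$transcript_id)
  keep <- !is.na(idx)
  if (!any(keep)) stop("no overlap between predictions and annotation")
  df <- data.frame(biotype = as.character(annotation$biotype[idx[keep]]),
                   nuclear = predictions$label[keep] == "nuclear")
  out <- do.call(rbind, lapply(split(df, df$biotype), function(g) {
    data.frame(biotype = g$biotype[1L], n = nrow(g),
               percent_nuclear = 100 * mean(g$nuclear))
  }))
  rownames(out) <- NULL
  empty <- setdiff(unique(as.character(annotation$biotype)), out$biotype)
  if (length(empty) > 0L) {
    warning("biotype group(s) with no predictions omitted: ",
            paste(empty, collapse = ", "))
  }
  attr(out, "reference_line") <- 50
  out
}

#' Cross-cell-type localization matrix for heatmap plotting
#'
#' Collects per-cell-type log2 fold-changes into a transcript-by-cell-type
#' matrix with `NA` as the not-detected sentinel, orders cell types by
#' complete-linkage clustering on pairwise correlation distance
#' (`1 - cor`, pairwise-complete), and also returns the plotting-ready
#' long-format table. Transcripts detected in no cell type are dropped
#' with a warning.
#'
#' @param tables List of `fc_table` objects.
#' @return List with `matrix` (transcripts x cell types, columns in
#'   clustered order), `long` (data frame `transcript_id`, `cell_type`,
#'   `l2fc`, `detected`) and `celltype_order`.
#' @export
report_localization_heatmap_table <- function(tables) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "fc_table")))
  ids <- unique(unlist(lapply(tables, function(t) names(t$l2fc))))
  cts <- vapply(tables, function(t) t$cell_type, character(1))
  if (anyDuplicated(cts)) {
    cts <- make.unique(cts, sep = "_dup")
  }
  m <- matrix(NA_real_, nrow = length(ids), ncol = length(cts),
              dimnames = list(ids, cts))
  for (j in seq_along(tables)) {
    m[names(tables[[j]]$l2fc), j] <- tables[[j]]$l2fc
  }
  all_missing <- rowSums(!is.na(m)) == 0L
  if (any(all_missing)) {
    warning(sprintf("dropped %d transcript(s) detected in no cell type",
                    sum(all_missing)))
    m <- m[!all_missing, , drop = FALSE]
  }
  ord <- seq_len(ncol(m))
  if (ncol(m) > 1L) {
    cors <- suppressWarnings(
      stats::cor(m, use = "pairwise.complete.obs"))
    cors[!is.finite(cors)] <- 0
    d <- stats::as.dist(1 - cors)
    ord <- stats::hclust(d, method = "complete")$order
  }
  m <- m[, ord, drop = FALSE]
  long <- data.frame(
    transcript_id = rep(rownames(m), times = ncol(m)),
    cell_type = rep(colnames(m), each = nrow(m)),
    l2fc = as.vector(m))
  long$detected <- !is.na(long$l2fc)
  list(matrix = m, long = long, celltype_order = colnames(m))
}

#' Write a run manifest next to an output artifact
#'
#' Records what produced an artifact: command name, configuration hash,
#' input checksums, seeds, timestamp and package version, so any run can
#' be reproduced from its manifest alone.
#'
#' @param path Manifest output path (JSON).
#' @param command Command or function name.
#' @param config List of configuration values (hashed and embedded).
#' @param inputs Character vector of input file paths (checksummed with
#'   [tools::md5sum()] where they exist).
#' @param seed Integer seed(s) used.
#' @param warnings Character vector of warnings raised during the run.
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(path, command, config = list(),
                               inputs = character(0), seed = NA_integer_,
                               warnings = character(0)) {
  checks <- if (length(inputs) > 0L) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else list()
  manifest <- list(
    command = command,
    config = config,
    config_hash = fnv1a_hash(vapply(config, function(v)
      paste(format(v), collapse = ","), character(1))),
    input_checksums = checks,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("lncloc")),
    warnings = warnings)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
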