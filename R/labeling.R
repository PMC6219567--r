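#' Aggregate log2 fold-changes across cell types
#'
#' For each transcript, a weighted average of its nuclear:cytosolic log2
#' fold-changes over the cell types in which it was detected, weighted by
#' each cell type's sample count. Transcripts absent from every table are
#' omitted; absence from a cell type excludes that cell type from the
#' average (it is never imputed as zero).
#'
#' @param tables List of `fc_table` objects (see [fc_table()]).
#' @return `data.frame` with columns `transcript_id`, `aggregated_l2fc`,
#'   `n_celltypes_detected`, ordered by first appearance.
#' @examples
#' t1 <- fc_table("A", c(tx1 = 1), n_samples = 4)
#' t2 <- fc_table("B", c(tx1 = 4), n_samples = 2)
#' aggregate_l2fc(list(t1, t2))  # weighted mean (4*1 + 2*4)/6 = 2
#' @export
aggregate_l2fc <- function(tables) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "fc_table")))
  ids <- unique(unlist(lapply(tables, function(t) names(t$l2fc))))
  if (length(ids) == 0L) stop("all fold-change tables are empty")
  wsum <- num <- det <- stats::setNames(numeric(length(ids)), ids)
  for (t in tables) {
    j <- names(t$l2fc)
    num[j] <- num[j] + t$n_samples * t$l2fc
    wsum[j] <- wsum[j] + t$n_samples
    det[j] <- det[j] + 1
  }
  data.frame(transcript_id = ids,
             aggregated_l2fc = unname(num / wsum),
             n_celltypes_detected = as.integer(unname(det)),
             stringsAsFactors = FALSE)
}

#' Quartile localization thresholds
#'
#' First and third quartiles of the aggregated fold-change distribution
#' (linear-interpolation quantile definition, `stats::quantile` type 7),
#' used as the cytosolic/nuclear labeling cutoffs when no fixed override is
#' given. A nuclear-skewed fractionation experiment typically yields
#' thresholds near (0, 2.8).
#'
#' @param l2fc Numeric vector of aggregated log2 fold-changes, length >= 4.
#' @return Named numeric vector `c(cytosolic = Q1, nuclear = Q3)`.
#' @export
derive_thresholds <- function(l2fc) {
  l2fc <- l2fc[is.finite(l2fc)]
  if (length(l2fc) < 4L) stop("need at least 4 finite l2fc values")
  q <- stats::quantile(l2fc, c(0.25, 0.75), names = FALSE, type = 7)
  if (q[1] == q[2]) {
    warning("degenerate distribution: Q1 == Q3")
  }
  c(cytosolic = q[1], nuclear = q[2])
}

#' Assign nuclear/cytosolic labels from aggregated fold-changes
#'
#' Strict-inequality thresholding: `nuclear` when the aggregated l2fc is
#' greater than the nuclear threshold, `cytosolic` when less than the
#' cytosolic threshold, otherwise `unlabeled` (boundary values included).
#'
#' @param aggregated Output of [aggregate_l2fc()].
#' @param thresholds Length-2 numeric `(cytosolic, nuclear)` with
#'   `cytosolic <= nuclear`; e.g. `c(0, 2.8)` or [derive_thresholds()].
#' @return The input `data.frame` with a `label` factor column
#'   (levels nuclear, cytosolic, unlabeled); per-label counts are attached
#'   as `attr(, "counts")`.
#' @examples
#' agg <- data.frame(transcript_id = c("a", "b", "c"),
#'                   aggregated_l2fc = c(3, 1.5, -1),
#'                   n_celltypes_detected = 1L)
#' table(assign_labels(agg, c(0, 2.8))$label)
#' @export
assign_labels <- function(aggregated, thresholds) {
  stopifnot(is.numeric(thresholds), length(thresholds) == 2L)
  lo <- unname(thresholds[1]); hi <- unname(thresholds[2])
  if (lo > hi) stop("inverted thresholds: cytosolic > nuclear")
  x <- aggregated$aggregated_l2fc
  label <- factor(ifelse(x > hi, "nuclear",
                         ifelse(x < lo, "cytosolic", "unlabeled")),
                  levels = c("nuclear", "cytosolic", "unlabeled"))
  out <- aggregated
  out$label <- label
  attr(out, "thresholds") <- c(cytosolic = lo, nuclear = hi)
  attr(out, "counts") <- table(label)
  class(out) <- c("localization_table", "data.frame")
  out
}

#' @export
print.localization_table <- function(x, ...) {
  thr <- attr(x, "thresholds")
  cnt <- attr(x, "counts")
  cat(sprintf(
    "Localization table: %d transcripts (thresholds: cytosolic < %g, nuclear > %g)\n",
    nrow(x), thr[1], thr[2]))
  cat(sprintf("  nuclear %d | cytosolic %d | unlabeled %d\n",
              cnt[["nuclear"]], cnt[["cytosolic"]], cnt[["unlabeled"]]))
  NextMethod()
}

#' Split labeled transcripts into train/validation/test sets
#'
#' Randomized partition at the given fractions (default 70/15/15),
#' deterministic for a fixed seed. Sizes are `round(f_train * n)` and
#' `round(f_val * n)`, with the test set taking the remainder; the split is
#' optionally stratified by label.
#'
#' @param ids Character vector of labeled transcript IDs (length >= 3).
#' @param fractions Numeric length-3 `(train, val, test)` summing to 1.
#' @param seed Integer seed fixing the permutation.
#' @param stratify_by Optional factor aligned with `ids`; when given, each
#'   level is split at the same fractions before pooling.
#' @return Named list of character vectors `train`, `val`, `test`
#'   (disjoint, exhaustive).
#' @export
split_dataset <- function(ids, fractions = c(0.70, 0.15, 0.15), seed = 1L,
                          stratify_by = NULL) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-9,
            all(fractions >= 0))
  if (length(ids) < 3L) stop("need at least 3 labeled transcripts to split")
  if (!is.null(stratify_by)) {
    stopifnot(length(stratify_by) == length(ids))
    parts <- lapply(split(ids, stratify_by), split_dataset,
                    fractions = fractions, seed = seed)
    return(list(train = unname(unlist(lapply(parts, `[[`, "train"))),
                val = unname(unlist(lapply(parts, `[[`, "val"))),
                test = unname(unlist(lapply(parts, `[[`, "test")))))
  }
  n <- length(ids)
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  n_test <- n - n_train - n_val
  if (n_test < 0L) {  # rounding pushed train+val past n; give back from val
    n_val <- n_val + n_test
    n_test <- 0L
  }
  perm <- with_local_seed(seed, sample(ids))
  list(train = perm[seq_len(n_train)],
       val = perm[seq_len(n_val) + n_train],
       test = perm[seq_len(n_test) + n_train + n_val])
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

#' Write a localization table as TSV
#'
#' @param x `localization_table` from [assign_labels()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_localization_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a localization table written by [write_localization_table()]
#'
#' @param path TSV path.
#' @return `data.frame` with a `label` factor column.
#' @export
read_localization_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "aggregated_l2fc", "label")
  if (!all(need %in% names(df))) {
    stop("localization table is missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  df$label <- factor(df$label, levels = c("nuclear", "cytosolic", "unlabeled"))
  df
}
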