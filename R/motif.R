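#' Construct a position weight matrix object
#'
#' @param motif_id Motif identifier (unique within a collection).
#' @param probs Numeric matrix, one row per motif position, columns A,C,G,T,
#'   each row summing to 1 within 1e-3 (renormalized exactly internally).
#' @param pseudocount Small positive pseudocount mixed with the background
#'   when forming log-odds (default 1e-3); guarantees finite scores.
#' @param background Base composition of the null model, A/C/G/T, summing
#'   to 1 (default uniform 0.25).
#' @return Object of class `lnc_pwm`.
#' @export
new_pwm <- function(motif_id, probs, pseudocount = 1e-3,
                    background = rep(0.25, 4)) {
  probs <- as.matrix(probs)
  stopifnot(ncol(probs) == 4L, nrow(probs) >= 1L, all(probs >= 0),
            pseudocount > 0, length(background) == 4L,
            abs(sum(background) - 1) < 1e-6)
  if (any(abs(rowSums(probs) - 1) > 1e-3)) {
    stop("PWM rows must sum to 1 within 1e-3")
  }
  probs <- probs / rowSums(probs)
  colnames(probs) <- c("A", "C", "G", "T")
  structure(list(motif_id = as.character(motif_id), probs = probs,
                 pseudocount = pseudocount, background = background),
            class = "lnc_pwm")
}

#' @export
print.lnc_pwm <- function(x, ...) {
  cat(sprintf("PWM '%s' (width %d, pseudocount %g)\n", x$motif_id,
              nrow(x$probs), x$pseudocount))
  cat("consensus:", paste(colnames(x$probs)[max.col(x$probs)], collapse = ""),
      "\n")
  invisible(x)
}

#' Log-odds scoring matrix of a PWM
#'
#' Per-position, per-base log2 likelihood ratio of the motif model against
#' the background, with the pseudocount mixed in:
#' `log2((p(i,b) + c * bg(b)) / ((1 + c) * bg(b)))` where `c` is the
#' pseudocount. All entries are finite.
#'
#' @param pwm An `lnc_pwm`.
#' @return Numeric matrix (width x 4), columns A,C,G,T, in bits.
#' @export
log_odds_matrix <- function(pwm) {
  stopifnot(inherits(pwm, "lnc_pwm"))
  bg <- matrix(pwm$background, nrow = nrow(pwm$probs), ncol = 4L, byrow = TRUE)
  lo <- log2((pwm$probs + pwm$pseudocount * bg) / ((1 + pwm$pseudocount) * bg))
  dimnames(lo) <- dimnames(pwm$probs)
  lo
}

#' Maximal attainable PWM score
#'
#' Sum over positions of the best per-position log-odds entry; the score of
#' the consensus sequence.
#'
#' @param log_odds Log-odds matrix from [log_odds_matrix()].
#' @return Numeric scalar (bits).
#' @export
max_score <- function(log_odds) {
  sum(apply(log_odds, 1L, max))
}

#' Score one window against a log-odds matrix
#'
#' @param log_odds Log-odds matrix.
#' @param subsequence String of length `nrow(log_odds)` over \{A,C,G,T,N\}.
#' @return Summed log-odds score, or `NA` (no-score) if the window contains N.
#' @export
score_window <- function(log_odds, subsequence) {
  w <- nrow(log_odds)
  if (nchar(subsequence) != w) {
    stop("window length ", nchar(subsequence), " != PWM width ", w)
  }
  codes <- match(strsplit(subsequence, "")[[1L]], c("A", "C", "G", "T"))
  if (anyNA(codes)) return(NA_real_)
  sum(log_odds[cbind(seq_len(w), codes)])
}

#' Count motif matches in a sequence
#'
#' Slides the PWM along the sequence one base at a time and counts windows
#' whose log-odds score strictly exceeds `alpha` times the maximal PWM score
#' (default 80%). Windows containing N are excluded. Overlapping matches all
#' count. With `threshold_mode = "relative_range"` the threshold is instead
#' `min_score + alpha * (max_score - min_score)`, which is robust when
#' log-odds scores can be negative.
#'
#' @param pwm An `lnc_pwm`.
#' @param sequence Canonical sequence string.
#' @param alpha Fraction of the maximal score, in (0, 1] (default 0.8).
#' @param threshold_mode `"relative_max"` (default; threshold =
#'   `alpha * max_score`) or `"relative_range"`.
#' @return List of class `motif_match` with `motif_id`, `match_count`,
#'   `threshold_score`, `max_score`.
#' @examples
#' pwm <- new_pwm("ACG", diag(4)[c(1, 2, 3), ])
#' count_matches(pwm, "TACGT")$match_count  # 1
#' @export
count_matches <- function(pwm, sequence, alpha = 0.8,
                          threshold_mode = c("relative_max",
                                             "relative_range")) {
  stopifnot(inherits(pwm, "lnc_pwm"), alpha > 0, alpha <= 1)
  threshold_mode <- match.arg(threshold_mode)
  lo <- log_odds_matrix(pwm)
  mx <- max_score(lo)
  thr <- if (threshold_mode == "relative_max") {
    alpha * mx
  } else {
    mn <- sum(apply(lo, 1L, min))
    mn + alpha * (mx - mn)
  }
  scores <- window_scores(lo, sequence)
  n_match <- sum(scores > thr, na.rm = TRUE)
  structure(list(motif_id = pwm$motif_id, match_count = as.integer(n_match),
                 threshold_score = thr, max_score = mx),
            class = "motif_match")
}

# All sliding-window scores for one sequence; NA for windows containing N.
window_scores <- function(log_odds, sequence) {
  w <- nrow(log_odds)
  n <- nchar(sequence)
  if (n < w) return(numeric(0))
  codes <- match(strsplit(sequence, "")[[1L]], c("A", "C", "G", "T"))
  n_win <- n - w + 1L
  scores <- numeric(n_win)
  for (i in seq_len(w)) {
    scores <- scores + log_odds[i, codes[i:(i + n_win - 1L)]]
  }
  scores
}

#' Motif-count feature vector for one sequence
#'
#' One match count per motif, aligned to the sorted motif IDs of the
#' collection; columns are named `rbp_<motif_id>`.
#'
#' @param pwm_collection Named list of `lnc_pwm` (e.g. from
#'   [read_pwm_collection()]).
#' @param sequence Canonical sequence string.
#' @param alpha,threshold_mode Passed to [count_matches()].
#' @return Named integer vector, one entry per motif.
#' @export
motif_feature_vector <- function(pwm_collection, sequence, alpha = 0.8,
                                 threshold_mode = "relative_max") {
  stopifnot(length(pwm_collection) > 0L)
  ids <- vapply(pwm_collection, function(p) p$motif_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate motif_id in collection: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  ord <- order(ids)
  counts <- vapply(pwm_collection[ord], function(p) {
    count_matches(p, sequence, alpha, threshold_mode)$match_count
  }, integer(1))
  stats::setNames(counts, paste0("rbp_", ids[ord]))
}

#' Motif-count feature matrix for many sequences
#'
#' @param pwm_collection Named list of `lnc_pwm`.
#' @param sequences Character vector of canonical sequences (names become
#'   row names).
#' @param alpha,threshold_mode Passed to [count_matches()].
#' @return Integer matrix, rows = sequences, columns `rbp_<motif_id>` in
#'   sorted-ID order.
#' @export
motif_feature_matrix <- function(pwm_collection, sequences, alpha = 0.8,
                                 threshold_mode = "relative_max") {
  ids <- sort(vapply(pwm_collection, function(p) p$motif_id, character(1)))
  m <- t(vapply(sequences, function(s) {
    as.numeric(motif_feature_vector(pwm_collection, s, alpha, threshold_mode))
  }, numeric(length(pwm_collection))))
  dimnames(m) <- list(names(sequences), paste0("rbp_", ids))
  m
}
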