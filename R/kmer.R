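#' Enumerate the k-mer feature registry
#'
#' Deterministic ordering of all DNA k-mers for k in `[k_min, k_max]`:
#' k ascending, lexicographic within each k. The default range 2..5 yields
#' the 1360-feature k-mer spectrum (4^2 + 4^3 + 4^4 + 4^5).
#'
#' @param k_min,k_max Integer k range, `1 <= k_min <= k_max`.
#' @return Character vector of k-mers, length `sum(4^(k_min:k_max))`.
#' @examples
#' length(enumerate_kmers())      # 1360
#' enumerate_kmers(1, 1)          # "A" "C" "G" "T"
#' @export
enumerate_kmers <- function(k_min = 2L, k_max = 5L) {
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (is.na(k_min) || k_min < 1L) stop("k_min must be >= 1")
  if (k_max < k_min) stop("k_max must be >= k_min")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(k_min:k_max, function(k) {
    grid <- do.call(expand.grid,
                    c(rep(list(bases), k), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE))
    # expand.grid varies the first column fastest; reverse for lexicographic
    sort(do.call(paste0, grid[rev(seq_len(k))]))
  }), use.names = FALSE)
}

#' Count k-mers in a canonical sequence
#'
#' Counts every length-k window whose characters are all in \{A,C,G,T\};
#' windows containing N are skipped (they contribute to neither numerator nor
#' denominator of the frequency features).
#'
#' @param sequence Canonical sequence string (see [normalize_sequence()]).
#' @param k Window length, `k >= 1`.
#' @return Named integer vector over all 4^k k-mers (lexicographic order).
#'   All zeros when `k > nchar(sequence)`.
#' @examples
#' count_kmers("AAAA", 2)["AA"]   # 3
#' count_kmers("ANAA", 2)["AA"]   # 1
#' @export
count_kmers <- function(sequence, k) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1")
  kmers <- enumerate_kmers(k, k)
  if (k > nchar(sequence)) {
    return(stats::setNames(integer(4^k), kmers))
  }
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(sequence), width = k)
  stats::setNames(as.integer(counts[kmers]), kmers)
}

#' k-mer frequency vector for one sequence
#'
#' Within each k, counts are normalized by the number of valid (N-free)
#' windows of that k, so each k-block sums to 1 for any sequence with at
#' least one valid window. A k-block with zero valid windows is all zeros
#' (with a warning). With `mode = "count"` the raw counts are returned
#' instead.
#'
#' @param sequence Canonical sequence string.
#' @param registry k-mer registry from [enumerate_kmers()].
#' @param mode `"frequency"` (default, per-k relative frequency) or
#'   `"count"` (raw window counts).
#' @return Numeric vector aligned to `registry`, names `kmer_<seq>`.
#' @export
kmer_frequency_vector <- function(sequence, registry = enumerate_kmers(),
                                  mode = c("frequency", "count")) {
  mode <- match.arg(mode)
  ks <- sort(unique(nchar(registry)))
  out <- numeric(length(registry))
  for (k in ks) {
    in_block <- nchar(registry) == k
    counts <- count_kmers(sequence, k)
    block <- counts[registry[in_block]]
    if (mode == "frequency") {
      total <- sum(counts)
      if (total == 0L) {
        warning(sprintf("no valid windows at k=%d; block left all-zero", k))
        block <- as.numeric(block)
      } else {
        block <- block / total
      }
    }
    out[in_block] <- block
  }
  stats::setNames(out, paste0("kmer_", registry))
}

#' k-mer frequency matrix for many sequences
#'
#' Vectorized equivalent of applying [kmer_frequency_vector()] per row.
#'
#' @param sequences Character vector of canonical sequences (names become
#'   row names).
#' @param registry k-mer registry from [enumerate_kmers()].
#' @param mode `"frequency"` or `"count"`, as in [kmer_frequency_vector()].
#' @return Numeric matrix, rows = sequences, columns `kmer_<seq>` in
#'   registry order.
#' @export
kmer_feature_matrix <- function(sequences, registry = enumerate_kmers(),
                                mode = c("frequency", "count")) {
  mode <- match.arg(mode)
  ks <- sort(unique(nchar(registry)))
  set <- Biostrings::DNAStringSet(sequences)
  blocks <- lapply(ks, function(k) {
    cnt <- Biostrings::oligonucleotideFrequency(set, width = k)
    short <- Biostrings::width(set) < k
    if (any(short)) cnt[short, ] <- 0L
    cnt <- cnt[, registry[nchar(registry) == k], drop = FALSE]
    if (mode == "frequency") {
      tot <- rowSums(cnt)
      if (any(tot == 0)) {
        warning(sprintf("%d sequence(s) with no valid windows at k=%d",
                        sum(tot == 0), k))
      }
      cnt / pmax(tot, 1L)
    } else {
      cnt
    }
  })
  m <- do.call(cbind, blocks)
  colnames(m) <- paste0("kmer_", registry)
  rownames(m) <- names(sequences)
  m
}
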