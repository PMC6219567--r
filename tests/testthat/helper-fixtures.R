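# Shared fixture builders. Everything is generated in code at test time;
# nothing is read from disk except files the tests themselves write.

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Naive substring-scan k-mer counter: the independent oracle for the
# Biostrings-backed implementation. Windows containing N are skipped.
naive_count_kmers <- function(sequence, k) {
  kmers <- enumerate_kmers(k, k)
  counts <- stats::setNames(integer(length(kmers)), kmers)
  n <- nchar(sequence)
  if (k <= n) {
    for (i in seq_len(n - k + 1L)) {
      w <- substr(sequence, i, i + k - 1L)
      if (!grepl("N", w, fixed = TRUE)) counts[w] <- counts[w] + 1L
    }
  }
  counts
}

# Random valid PWM (rows on the simplex), for round-trip and oracle tests.
random_pwm <- function(id, width) {
  m <- matrix(stats::rexp(width * 4), width, 4)
  new_pwm(id, m / rowSums(m))
}

# Brute-force motif match counter: enumerate every window, score by direct
# per-entry lookup, apply the strict threshold rule.
brute_force_matches <- function(pwm, sequence, alpha = 0.8) {
  lo <- log_odds_matrix(pwm)
  thr <- alpha * max_score(lo)
  w <- nrow(lo)
  n <- nchar(sequence)
  if (n < w) return(0L)
  hits <- 0L
  for (i in seq_len(n - w + 1L)) {
    s <- score_window(lo, substr(sequence, i, i + w - 1L))
    if (!is.na(s) && s > thr) hits <- hits + 1L
  }
  hits
}

# Small annotated transcript set reused across featurization tests.
tiny_records <- function(n = 10L, len = 120L, seed = 42L) {
  set.seed(seed)
  ids <- sprintf("tx%03d", seq_len(n))
  ann <- data.frame(
    transcript_id = ids,
    biotype = factor(sample(biotype_categories(), n, replace = TRUE),
                     levels = biotype_categories()),
    chromosome = factor(sample(chromosome_categories(), n, replace = TRUE),
                        levels = chromosome_categories()),
    stringsAsFactors = FALSE)
  seqs <- stats::setNames(vapply(seq_len(n), function(i) random_dna(len),
                                 character(1)), ids)
  transcript_records(seqs, ann)
}
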