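#' Canonical lncRNA biotype categories
#'
#' The major lncRNA genomic-context classes (intergenic/lincRNA, antisense,
#' sense intronic, sense overlapping) plus an `"other"` fallback for any
#' annotation outside the set.
#'
#' @return Character vector of category names, fixed order.
#' @export
biotype_categories <- function() {
  c("lincRNA", "antisense", "sense_intronic", "sense_overlapping", "other")
}

#' Canonical chromosome categories
#'
#' @return Character vector: autosomes 1..22, X, Y, MT, and `"other"`.
#' @export
chromosome_categories <- function() {
  c(as.character(1:22), "X", "Y", "MT", "other")
}

#' One-hot encode a lncRNA biotype
#'
#' Produces the biotype indicator block plus the derived
#' `sense_proximal` flag, set for transcripts lying sense to a proximal
#' protein-coding gene (sense intronic or sense overlapping biotypes).
#'
#' @param biotype Character or factor vector of biotypes (unknowns map to
#'   `"other"`).
#' @return Numeric matrix with columns `bio_<category>` and
#'   `sense_proximal`; each biotype row sums to 1 over the `bio_` block.
#' @examples
#' encode_biotype("sense_intronic")
#' @export
encode_biotype <- function(biotype) {
  cats <- biotype_categories()
  b <- canonical_biotype(as.character(biotype))
  m <- outer(b, cats, "==") * 1
  colnames(m) <- paste0("bio_", cats)
  flag <- as.numeric(b %in% c("sense_intronic", "sense_overlapping"))
  cbind(m, sense_proximal = flag)
}

#' One-hot encode a chromosome
#'
#' @param chrom Character or factor vector over [chromosome_categories()]
#'   (anything else maps to `"other"`).
#' @return Numeric matrix with columns `chr_<category>`, one indicator set
#'   per row.
#' @export
encode_chromosome <- function(chrom) {
  cats <- chromosome_categories()
  ch <- as.character(chrom)
  ch[!ch %in% cats] <- "other"
  m <- outer(ch, cats, "==") * 1
  colnames(m) <- paste0("chr_", cats)
  m
}

#' Assemble the full feature matrix
#'
#' Column order is k-mer block, motif block, biotype block (with the
#' `sense_proximal` flag), chromosome block; rows follow the input record
#' order. The column-name registry and the featurization configuration are
#' attached as attributes and persisted alongside the matrix by
#' [write_feature_matrix()], so a trained model can refuse matrices built
#' under a different registry.
#'
#' @param records Transcript table from [transcript_records()] (columns
#'   `transcript_id`, `sequence`, `biotype`, `chromosome`).
#' @param registry k-mer registry (default [enumerate_kmers()]).
#' @param pwms Named list of `lnc_pwm`, or `NULL` to skip the motif block.
#' @param alpha,threshold_mode Motif-scan settings (see [count_matches()]).
#' @param kmer_mode `"frequency"` or `"count"` (see
#'   [kmer_frequency_vector()]).
#' @return Numeric matrix of class `lnc_features`; row names are transcript
#'   IDs, `attr(, "registry")` holds the column registry and
#'   `attr(, "config")` the featurization settings.
#' @export
assemble_feature_matrix <- function(records, registry = enumerate_kmers(),
                                    pwms = NULL, alpha = 0.8,
                                    threshold_mode = "relative_max",
                                    kmer_mode = "frequency") {
  need <- c("transcript_id", "sequence", "biotype", "chromosome")
  stopifnot(all(need %in% names(records)))
  bad <- is.na(records$biotype) | is.na(records$chromosome)
  if (any(bad)) {
    stop("transcript(s) missing annotation: ",
         paste(records$transcript_id[bad], collapse = ", "))
  }
  seqs <- stats::setNames(records$sequence, records$transcript_id)
  km <- kmer_feature_matrix(seqs, registry, mode = kmer_mode)
  blocks <- list(km)
  if (!is.null(pwms) && length(pwms) > 0L) {
    blocks <- c(blocks, list(motif_feature_matrix(pwms, seqs, alpha,
                                                  threshold_mode)))
  }
  blocks <- c(blocks, list(encode_biotype(records$biotype),
                           encode_chromosome(records$chromosome)))
  m <- do.call(cbind, blocks)
  rownames(m) <- records$transcript_id
  structure(m,
            registry = colnames(m),
            config = list(k_range = range(nchar(registry)),
                          kmer_mode = kmer_mode,
                          n_motifs = length(pwms), alpha = alpha,
                          threshold_mode = threshold_mode,
                          biotype_categories = biotype_categories(),
                          chromosome_categories = chromosome_categories()),
            class = c("lnc_features", "matrix", "array"))
}

#' Persist a feature matrix as TSV plus JSON manifest
#'
#' Writes `<path>` (TSV, `transcript_id` first column) and
#' `<path>.manifest.json` holding the column registry, the featurization
#' config and a registry hash.
#'
#' @param x `lnc_features` matrix from [assemble_feature_matrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(x, path) {
  stopifnot(inherits(x, "lnc_features"))
  df <- data.frame(transcript_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(registry = attr(x, "registry"),
                   registry_hash = fnv1a_hash(attr(x, "registry")),
                   config = attr(x, "config"),
                   n_transcripts = nrow(x))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path TSV path; the sidecar `<path>.manifest.json` must exist and
#'   its registry must match the TSV columns exactly.
#' @return `lnc_features` matrix.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  manifest_path <- paste0(path, ".manifest.json")
  if (!file.exists(manifest_path)) {
    stop("feature-matrix manifest not found: ", manifest_path)
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$transcript_id
  if (!identical(colnames(m), as.character(manifest$registry))) {
    stop("feature-matrix columns do not match their manifest registry")
  }
  structure(m, registry = colnames(m), config = manifest$config,
            class = c("lnc_features", "matrix", "array"))
}

# FNV-1a 32-bit hash of a character vector, as 8 hex digits. Used only for
# manifest fingerprints; model/registry compatibility is checked by exact
# column-name equality, never by hash alone.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte (b < 256), keeping h a double-safe 32-bit value
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b %% 256)
    # 32-bit modular multiply by 16777619, split to stay within 2^53
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
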