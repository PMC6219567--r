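#' Read a FASTA file of transcript sequences
#'
#' Reads a (possibly multi-line) FASTA file into a named character vector of
#' raw sequences, one element per record, in file order. Sequences are returned
#' as-is; use [normalize_sequence()] to coerce them to the canonical
#' \{A,C,G,T,N\} DNA alphabet.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector: names are record IDs (first whitespace-
#'   delimited token of each header), values are the concatenated sequence
#'   lines.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">tx1", "ACGT", "ACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(stats::setNames(character(0), character(0)))
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[1L]) {
    stop("FASTA parse error: sequence line before any '>' header")
  }
  rec <- cumsum(is_header)
  ids <- vapply(lines[is_header], function(h) {
    strsplit(sub("^>", "", h), "[ \t]")[[1L]][1L]
  }, character(1), USE.NAMES = FALSE)
  dup <- duplicated(ids)
  if (any(dup)) {
    offsets <- which(is_header)
    bad <- ids[dup][1L]
    stop(sprintf("duplicate FASTA ID '%s' (header lines %s)", bad,
                 paste(offsets[ids == bad], collapse = ", ")))
  }
  seqs <- vapply(seq_along(ids), function(i) {
    paste(lines[rec == i & !is_header], collapse = "")
  }, character(1))
  if (any(!nzchar(seqs))) {
    stop("empty FASTA record(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' Inverse of [read_fasta()] on valid inputs.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(length(names(seqs)) == length(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Normalize a raw sequence to the canonical DNA alphabet
#'
#' Uppercases, maps U to T (cDNA convention), and collapses any residual IUPAC
#' ambiguity code other than N to N. The result is over \{A,C,G,T,N\} and the
#' operation is idempotent.
#'
#' @param raw Non-empty character scalar.
#' @return Canonical sequence string. If the result is entirely N, an
#'   `all_n` attribute is set to `TRUE` and a warning raised; the caller
#'   decides whether to keep the record.
#' @examples
#' normalize_sequence("acgu")   # "ACGT"
#' normalize_sequence("ACGRN")  # "ACGNN"
#' @export
normalize_sequence <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (!nzchar(raw)) stop("cannot normalize an empty sequence")
  s <- chartr("u", "T", toupper(raw))
  s <- chartr("U", "T", s)
  s <- gsub("[^ACGT]", "N", s)
  if (!grepl("[ACGT]", s)) {
    warning("sequence is all-N after normalization")
    attr(s, "all_n") <- TRUE
  }
  s
}

#' Read a transcript annotation table
#'
#' Parses a tab-separated annotation file with header columns
#' `transcript_id`, `biotype` and `chromosome` (the three fields the
#' featurizer needs; producing this TSV from a GTF is a one-liner, e.g.
#' `gffread`/`awk` on the attributes column). Unknown biotypes are mapped to
#' `"other"` with a warning; chromosome names are normalized by stripping any
#' `"chr"` prefix, and names outside 1..22/X/Y/MT become `"other"`.
#'
#' @param path Path to the TSV.
#' @return `data.frame` with columns `transcript_id`, `biotype`
#'   (factor over [biotype_categories()]), `chromosome` (factor over
#'   [chromosome_categories()]), one row per transcript.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("transcript_id", "biotype", "chromosome")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("annotation is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[, need]
  if (anyDuplicated(df$transcript_id)) {
    dups <- unique(df$transcript_id[duplicated(df$transcript_id)])
    conflict <- vapply(dups, function(id) {
      sub <- unique(df[df$transcript_id == id, c("biotype", "chromosome")])
      nrow(sub) > 1L
    }, logical(1))
    if (any(conflict)) {
      stop("duplicate transcript_id with conflicting annotation: ",
           paste(dups[conflict], collapse = ", "))
    }
    df <- df[!duplicated(df$transcript_id), ]
  }
  biotype <- canonical_biotype(df$biotype)
  unknown <- setdiff(unique(df$biotype[biotype == "other"]), "other")
  if (length(unknown) > 0L) {
    warning("unknown biotype(s) mapped to 'other': ",
            paste(unknown, collapse = ", "))
  }
  chrom <- sub("^chr", "", df$chromosome, ignore.case = TRUE)
  chrom <- toupper(chrom)
  chrom[chrom == "M"] <- "MT"
  chrom[!chrom %in% chromosome_categories()] <- "other"
  data.frame(
    transcript_id = df$transcript_id,
    biotype = factor(biotype, levels = biotype_categories()),
    chromosome = factor(chrom, levels = chromosome_categories()),
    stringsAsFactors = FALSE
  )
}

# Map raw Ensembl/GENCODE biotype strings onto the canonical category set.
canonical_biotype <- function(x) {
  x <- tolower(x)
  x[x %in% c("lincrna", "intergenic")] <- "lincRNA"
  x[x == "antisense"] <- "antisense"
  x[x == "sense_intronic"] <- "sense_intronic"
  x[x == "sense_overlapping"] <- "sense_overlapping"
  x[!x %in% biotype_categories()] <- "other"
  x
}

#' Read a collection of RNA-binding-protein PWMs
#'
#' Reads every motif file in a directory (or a single file) in the CISBP-RNA
#' text layout: a header row `Pos A C G U` followed by one row of four
#' probabilities per motif position. The U column is stored under T so that
#' scanning DNA-alphabet cDNA needs no per-call conversion. Rows that do not
#' sum to 1 within 1e-3 are renormalized with a warning. The motif ID is the
#' file name without extension.
#'
#' @param path Directory of motif files, or one motif file.
#' @param pseudocount Pseudocount attached to each PWM (default 1e-3).
#' @param background Background base probabilities, A/C/G/T (default uniform).
#' @return Named list of `lnc_pwm` objects (see [new_pwm()]), sorted by
#'   motif ID.
#' @export
read_pwm_collection <- function(path, pseudocount = 1e-3,
                                background = rep(0.25, 4)) {
  files <- if (dir.exists(path)) {
    list.files(path, full.names = TRUE)
  } else if (file.exists(path)) {
    path
  } else {
    stop("PWM path not found: ", path)
  }
  if (length(files) == 0L) stop("no PWM files found under ", path)
  pwms <- lapply(files, read_pwm_file, pseudocount = pseudocount,
                 background = background)
  ids <- vapply(pwms, function(p) p$motif_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate motif_id in PWM collection: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  pwms <- pwms[order(ids)]
  stats::setNames(pwms, sort(ids))
}

read_pwm_file <- function(file, pseudocount = 1e-3, background = rep(0.25, 4)) {
  motif_id <- tools::file_path_sans_ext(basename(file))
  df <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  cols <- toupper(names(df))
  if (!all(c("A", "C", "G") %in% cols) || !any(c("U", "T") %in% cols)) {
    stop("PWM file ", file, ": expected columns Pos A C G U")
  }
  u_col <- names(df)[match(TRUE, cols %in% c("U", "T"))]
  m <- as.matrix(df[, c(names(df)[match(c("A", "C", "G"), cols)], u_col)])
  if (ncol(m) != 4L) stop("PWM file ", file, ": wrong column count")
  if (nrow(m) == 0L) stop("PWM file ", file, ": empty matrix")
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("PWM file ", file, ": negative or non-finite probability entry")
  }
  colnames(m) <- c("A", "C", "G", "T")
  rs <- rowSums(m)
  if (any(rs == 0)) stop("PWM file ", file, ": all-zero probability row")
  off <- abs(rs - 1) > 1e-3
  if (any(off)) {
    warning(sprintf("PWM '%s': %d row(s) renormalized to sum to 1",
                    motif_id, sum(off)))
  }
  m <- m / rs
  new_pwm(motif_id, m, pseudocount = pseudocount, background = background)
}

#' Write one PWM in CISBP-RNA text layout
#'
#' Inverse of the PWM reader on valid matrices; the stored T column is emitted
#' under the U header.
#'
#' @param pwm An `lnc_pwm` object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_pwm <- function(pwm, file) {
  stopifnot(inherits(pwm, "lnc_pwm"))
  df <- data.frame(Pos = seq_len(nrow(pwm$probs)), pwm$probs,
                   check.names = FALSE)
  names(df) <- c("Pos", "A", "C", "G", "U")
  utils::write.table(format(df, digits = 17), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a per-cell-type nuclear:cytosolic fold-change table
#'
#' Parses a TSV with columns `transcript_id` and `l2fc` (nuclear:cytosolic
#' log2 fold-change). Rows with a non-finite fold change are dropped with a
#' warning.
#'
#' @param path Path to the TSV.
#' @param cell_type Cell-type name for this table.
#' @param n_samples Number of RNA-seq samples behind this cell type's
#'   differential test; must be at least 2 (each fraction needs replicates).
#' @return An object of class `fc_table`: list with `cell_type`, `n_samples`
#'   and `l2fc` (named numeric vector keyed by transcript ID).
#' @export
read_foldchange_table <- function(path, cell_type, n_samples) {
  if (!file.exists(path)) stop("fold-change table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "l2fc")
  if (!all(need %in% names(df))) {
    stop("fold-change table is missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  bad <- !is.finite(df$l2fc)
  if (any(bad)) {
    warning(sprintf("dropped %d row(s) with non-finite l2fc (%d retained)",
                    sum(bad), sum(!bad)))
    df <- df[!bad, ]
  }
  fc_table(cell_type, stats::setNames(df$l2fc, df$transcript_id), n_samples)
}

#' Construct a fold-change table object
#'
#' @param cell_type Cell-type name.
#' @param l2fc Named numeric vector of nuclear:cytosolic log2 fold-changes,
#'   keyed by transcript ID; must be finite.
#' @param n_samples Positive integer, at least 2.
#' @return `fc_table` object.
#' @export
fc_table <- function(cell_type, l2fc, n_samples) {
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 2L) {
    stop("n_samples must be an integer >= 2 (both fractions need replicates)")
  }
  stopifnot(is.numeric(l2fc), length(names(l2fc)) == length(l2fc))
  if (any(!is.finite(l2fc))) stop("l2fc values must be finite")
  structure(list(cell_type = as.character(cell_type),
                 n_samples = n_samples, l2fc = l2fc),
            class = "fc_table")
}

#' Write a fold-change table as TSV
#'
#' @param tab An `fc_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_foldchange_table <- function(tab, path) {
  stopifnot(inherits(tab, "fc_table"))
  utils::write.table(
    data.frame(transcript_id = names(tab$l2fc), l2fc = tab$l2fc),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble validated transcript records
#'
#' Joins normalized sequences with their annotation into the canonical
#' transcript table used by the featurizer.
#'
#' @param seqs Named character vector of raw sequences (e.g. from
#'   [read_fasta()]); normalized internally.
#' @param annotation Annotation `data.frame` from [read_annotation()].
#' @return `data.frame` with columns `transcript_id`, `sequence`, `biotype`,
#'   `chromosome`; rows in `seqs` order.
#' @export
transcript_records <- function(seqs, annotation) {
  if (length(seqs) == 0L) stop("no sequences supplied")
  if (anyDuplicated(names(seqs))) stop("duplicate transcript IDs in sequences")
  miss <- setdiff(names(seqs), annotation$transcript_id)
  if (length(miss) > 0L) {
    stop("transcript(s) missing annotation: ",
         paste(utils::head(miss, 10L), collapse = ", "),
         if (length(miss) > 10L) sprintf(" (and %d more)", length(miss) - 10L))
  }
  norm <- vapply(seqs, function(s) as.character(normalize_sequence(s)),
                 character(1))
  idx <- match(names(seqs), annotation$transcript_id)
  data.frame(
    transcript_id = names(seqs),
    sequence = unname(norm),
    biotype = annotation$biotype[idx],
    chromosome = annotation$chromosome[idx],
    stringsAsFactors = FALSE
  )
}
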