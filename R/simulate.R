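#' Specification of a synthetic planted-motif dataset
#'
#' Describes the generative model for synthetic benchmark data: i.i.d.
#' background bases (optionally GC-biased per class), Poisson-distributed
#' insertions of a planted nuclear-retention motif at class-specific rates,
#' and biotype/chromosome annotations drawn from categorical distributions.
#' The default planted motif is the AGCCC pentamer, a known
#' nuclear-retention signal in human lncRNAs.
#'
#' @param n_per_class Transcripts per class.
#' @param length_range Integer `(min, max)`; lengths are uniform on this
#'   range (default 200..1000 nt, typical lncRNA lengths).
#' @param planted_motif Motif string inserted into nuclear transcripts
#'   (default `"AGCCC"`).
#' @param nuclear_motif_rate,cytosolic_motif_rate Expected insertions per
#'   transcript in each class (Poisson means; defaults 3 and 0).
#' @param gc_bias Additive shift in GC content of the nuclear class
#'   relative to the 0.5/0.5 background (default 0, no compositional bias).
#' @param seed Integer seed fixing the whole dataset.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = 2000L, length_range = c(200L, 1000L),
                           planted_motif = "AGCCC",
                           nuclear_motif_rate = 3, cytosolic_motif_rate = 0,
                           gc_bias = 0, seed = 1L) {
  stopifnot(n_per_class >= 0, length(length_range) == 2L,
            length_range[1] <= length_range[2],
            nuclear_motif_rate >= 0, cytosolic_motif_rate >= 0,
            abs(gc_bias) < 0.5)
  if (length_range[1] < nchar(planted_motif)) {
    stop("minimum transcript length is shorter than the planted motif")
  }
  structure(list(n_per_class = as.integer(n_per_class),
                 length_range = as.integer(length_range),
                 planted_motif = toupper(planted_motif),
                 nuclear_motif_rate = nuclear_motif_rate,
                 cytosolic_motif_rate = cytosolic_motif_rate,
                 gc_bias = gc_bias, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate synthetic transcripts with planted motif structure
#'
#' Draws `n_per_class` transcripts per class. Background bases are i.i.d.
#' with class-specific GC content; each nuclear (resp. cytosolic)
#' transcript then receives a Poisson-distributed number of
#' non-overlapping insertions of the planted motif at uniform positions
#' (overlapping placements are retried up to 50 times, then skipped with a
#' warning). Biotypes and chromosomes are drawn independently of class from
#' realistic categorical distributions. Deterministic for a fixed seed.
#'
#' @param spec `synthetic_spec` object.
#' @return List with `sequences` (named character vector), `annotation`
#'   (data frame `transcript_id`, `biotype`, `chromosome`) and `truth`
#'   (data frame `transcript_id`, `class` in nuclear/cytosolic,
#'   `n_inserted`).
#' @export
generate_transcripts <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n_per_class
    if (n == 0L) {
      return(list(sequences = stats::setNames(character(0), character(0)),
                  annotation = data.frame(transcript_id = character(0),
                                          biotype = character(0),
                                          chromosome = character(0)),
                  truth = data.frame(transcript_id = character(0),
                                     class = character(0),
                                     n_inserted = integer(0))))
    }
    classes <- rep(c("nuclear", "cytosolic"), each = n)
    ids <- sprintf("synthTX%05d", seq_along(classes))
    rates <- ifelse(classes == "nuclear", spec$nuclear_motif_rate,
                    spec$cytosolic_motif_rate)
    gc <- ifelse(classes == "nuclear", 0.5 + spec$gc_bias, 0.5)
    lens <- sample(spec$length_range[1]:spec$length_range[2],
                   length(ids), replace = TRUE)
    motif <- strsplit(spec$planted_motif, "")[[1L]]
    w <- length(motif)
    n_inserted <- integer(length(ids))
    seqs <- character(length(ids))
    for (i in seq_along(ids)) {
      p <- c((1 - gc[i]) / 2, gc[i] / 2, gc[i] / 2, (1 - gc[i]) / 2)
      chars <- sample(c("A", "C", "G", "T"), lens[i], replace = TRUE,
                      prob = p)
      k <- stats::rpois(1L, rates[i])
      placed <- integer(0)
      for (j in seq_len(k)) {
        pos <- NA_integer_
        for (try in seq_len(50L)) {
          cand <- sample.int(lens[i] - w + 1L, 1L)
          if (!any(abs(cand - placed) < w)) { pos <- cand; break }
        }
        if (is.na(pos)) {
          warning(sprintf("could not place motif copy %d in %s; skipped",
                          j, ids[i]))
          next
        }
        chars[pos:(pos + w - 1L)] <- motif
        placed <- c(placed, pos)
      }
      n_inserted[i] <- length(placed)
      seqs[i] <- paste(chars, collapse = "")
    }
    annotation <- data.frame(
      transcript_id = ids,
      biotype = sample(biotype_categories(), length(ids), replace = TRUE,
                       prob = c(0.45, 0.30, 0.08, 0.05, 0.12)),
      chromosome = sample(chromosome_categories()[1:24], length(ids),
                          replace = TRUE),
      stringsAsFactors = FALSE)
    list(sequences = stats::setNames(seqs, ids),
         annotation = annotation,
         truth = data.frame(transcript_id = ids, class = classes,
                            n_inserted = n_inserted,
                            stringsAsFactors = FALSE))
  })
}

#' Generate synthetic per-cell-type fold-change tables
#'
#' Emulates the tabular output of nuclear/cytosolic fractionation RNA-seq:
#' each transcript carries a true localization log2 ratio drawn from a
#' two-component mixture (nuclear mean above cytosolic mean, optional
#' within-class spread); every cell type observes truth plus Gaussian
#' noise, and each (transcript, cell type) entry is dropped at the
#' detection-dropout rate. Sample counts per cell type are drawn from
#' 4..8 to exercise the weighted aggregation.
#'
#' @param classes Character vector over \{nuclear, cytosolic\}, one per
#'   transcript; names (or `ids`) give transcript IDs.
#' @param ids Transcript IDs (default `names(classes)`).
#' @param n_celltypes Number of cell-type tables (default 5).
#' @param class_means Length-2 numeric `(nuclear, cytosolic)` true-ratio
#'   means (default `c(3, -1)`).
#' @param class_sd Within-class spread of the true ratio (default 0: the
#'   class effect is a common true localization ratio and all variation is
#'   per-cell-type noise).
#' @param noise_sd Per-cell-type observation noise sd (default 0.3).
#' @param dropout_rate Probability an entry is not detected in a given cell
#'   type (default 0.1).
#' @param seed Integer seed.
#' @return List with `tables` (list of [fc_table()]) and `truth`
#'   (data frame `transcript_id`, `class`, `true_l2fc`). All tables empty
#'   (with a warning) when `dropout_rate = 1`.
#' @export
generate_foldchange_tables <- function(classes, ids = names(classes),
                                       n_celltypes = 5L,
                                       class_means = c(nuclear = 3,
                                                       cytosolic = -1),
                                       class_sd = 0, noise_sd = 0.3,
                                       dropout_rate = 0.1, seed = 1L) {
  stopifnot(n_celltypes >= 1L, noise_sd >= 0, class_sd >= 0,
            dropout_rate >= 0, dropout_rate <= 1,
            all(classes %in% c("nuclear", "cytosolic")))
  if (is.null(ids)) stop("transcript ids required (names(classes) or ids=)")
  with_local_seed(seed, {
    mu <- ifelse(classes == "nuclear", class_means[[1]], class_means[[2]])
    true_l2fc <- stats::rnorm(length(ids), mu, class_sd)
    tables <- lapply(seq_len(n_celltypes), function(ct) {
      obs <- true_l2fc + stats::rnorm(length(ids), 0, noise_sd)
      keep <- stats::runif(length(ids)) >= dropout_rate
      fc_table(sprintf("celltype%02d", ct),
               stats::setNames(obs[keep], ids[keep]),
               n_samples = sample(4:8, 1L))
    })
    if (all(vapply(tables, function(t) length(t$l2fc), integer(1)) == 0L)) {
      warning("all synthetic fold-change tables are empty (dropout too high)")
    }
    list(tables = tables,
         truth = data.frame(transcript_id = ids, class = unname(classes),
                            true_l2fc = true_l2fc,
                            stringsAsFactors = FALSE))
  })
}

#' Consensus-based fixture PWMs
#'
#' Builds one PWM per consensus string with probability `1 - softness` on
#' the consensus base at each position and the remainder spread over the
#' other three bases. With `softness = 0` the PWM is a deterministic
#' consensus matcher (under the default 80%-of-max rule it matches exactly
#' the consensus windows).
#'
#' @param motifs Character vector of consensus strings over \{A,C,G,T\};
#'   names override the default motif IDs (the consensus itself).
#' @param softness Probability mass off the consensus base, in `[0, 0.5)`.
#' @param pseudocount,background Passed to [new_pwm()].
#' @return Named list of `lnc_pwm`, sorted by motif ID.
#' @export
generate_fixture_pwms <- function(motifs, softness = 0,
                                  pseudocount = 1e-3,
                                  background = rep(0.25, 4)) {
  stopifnot(length(motifs) > 0L, softness >= 0, softness < 0.5)
  ids <- if (is.null(names(motifs))) toupper(motifs) else names(motifs)
  pwms <- lapply(seq_along(motifs), function(i) {
    chars <- strsplit(toupper(motifs[[i]]), "")[[1L]]
    codes <- match(chars, c("A", "C", "G", "T"))
    if (anyNA(codes)) stop("consensus must be over {A,C,G,T}: ", motifs[[i]])
    m <- matrix(softness / 3, nrow = length(codes), ncol = 4L)
    m[cbind(seq_along(codes), codes)] <- 1 - softness
    new_pwm(ids[i], m, pseudocount = pseudocount, background = background)
  })
  names(pwms) <- ids
  pwms[order(ids)]
}

#' Emit a full synthetic fixture bundle to disk
#'
#' Writes FASTA, annotation TSV, a PWM directory, per-cell-type fold-change
#' TSVs (with a `tables.tsv` index of cell_type/path/n_samples) and the
#' truth TSV under one directory — everything needed to run the entire
#' pipeline from files.
#'
#' @param dir Output directory (created if needed).
#' @param spec `synthetic_spec`.
#' @param pwm_motifs Consensus strings for the fixture PWM set (default the
#'   planted motif plus four unrelated hexamers).
#' @param ... Passed to [generate_foldchange_tables()].
#' @return Invisible list of the generated in-memory objects.
#' @export
write_fixture_bundle <- function(dir, spec = synthetic_spec(),
                                 pwm_motifs = NULL, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tx <- generate_transcripts(spec)
  write_fasta(tx$sequences, file.path(dir, "transcripts.fa"))
  utils::write.table(tx$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tx$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (is.null(pwm_motifs)) {
    pwm_motifs <- c(spec$planted_motif, "GAATTC", "TTAGGG", "CACGTG",
                    "ATCGAT")
  }
  pwms <- generate_fixture_pwms(pwm_motifs)
  pwm_dir <- file.path(dir, "pwms")
  dir.create(pwm_dir, showWarnings = FALSE)
  for (p in pwms) write_pwm(p, file.path(pwm_dir, paste0(p$motif_id, ".txt")))
  fc <- generate_foldchange_tables(
    stats::setNames(tx$truth$class, tx$truth$transcript_id),
    seed = spec$seed, ...)
  index <- data.frame(cell_type = character(0), path = character(0),
                      n_samples = integer(0))
  for (t in fc$tables) {
    path <- file.path(dir, paste0("l2fc_", t$cell_type, ".tsv"))
    write_foldchange_table(t, path)
    index <- rbind(index, data.frame(cell_type = t$cell_type, path = path,
                                     n_samples = t$n_samples))
  }
  utils::write.table(index, file.path(dir, "tables.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(transcripts = tx, pwms = pwms, foldchanges = fc))
}
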