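# Full simulate -> featurize -> split -> train -> evaluate pipeline on the
# planted-motif benchmark, optionally with permuted (null) labels.
run_planted_pipeline <- function(n_per_class = 2000, seed = 11,
                                 permute_labels = FALSE) {
  spec <- synthetic_spec(n_per_class = n_per_class, seed = seed)
  tx <- generate_transcripts(spec)
  pwms <- generate_fixture_pwms(c(spec$planted_motif, "GAATTC", "TTAGGG",
                                  "CACGTG", "ATCGAT"))
  ann <- data.frame(
    transcript_id = tx$annotation$transcript_id,
    biotype = factor(tx$annotation$biotype, levels = biotype_categories()),
    chromosome = factor(tx$annotation$chromosome,
                        levels = chromosome_categories()))
  rec <- transcript_records(tx$sequences, ann)
  fm <- assemble_feature_matrix(rec, pwms = pwms)
  y <- stats::setNames(tx$truth$class, tx$truth$transcript_id)
  if (permute_labels) {
    y <- stats::setNames(with_seed_sample(seed + 90L, unname(y)), names(y))
  }
  sp <- split_dataset(rownames(fm), seed = seed,
                      stratify_by = y[rownames(fm)])
  fit <- dnn_localizer(fm[sp$train, ], y[sp$train], fm[sp$val, ], y[sp$val],
                       config = dnn_config(seed = seed))
  ev <- evaluate_predictions(predict(fit, fm[sp$test, ]), y[sp$test])
  list(fit = fit, metrics = ev, n_test = length(sp$test))
}

with_seed_sample <- function(seed, x) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  sample(x)
}
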