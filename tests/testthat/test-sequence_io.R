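test_that("FASTA reader concatenates multi-line records in order", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">tx1", "ACGT", "ACGT", ">tx2 description here", "GGGA"), fa)
  out <- read_fasta(fa)
  expect_identical(out, c(tx1 = "ACGTACGT", tx2 = "GGGA"))
})

test_that("FASTA reader handles empty files and rejects malformed input", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), fa)
  expect_length(read_fasta(fa), 0)

  writeLines(c("ACGT", ">tx1", "ACGT"), fa)
  expect_error(read_fasta(fa), "before any")

  writeLines(c(">tx1", "ACGT", ">tx1", "GGGA"), fa)
  expect_error(read_fasta(fa), "duplicate")

  writeLines(c(">tx1", ">tx2", "ACGT"), fa)
  expect_error(read_fasta(fa), "empty")

  expect_error(read_fasta(file.path(tempdir(), "nope.fa")), "not found")
})

test_that("FASTA writer and reader are exact inverses on random records", {
  set.seed(7)
  seqs <- stats::setNames(
    vapply(1:100, function(i) random_dna(sample(10:300, 1)), character(1)),
    paste0("rand", 1:100))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, fa)
  expect_identical(read_fasta(fa), seqs)
})

test_that("sequence normalization maps case/U/ambiguity codes and is idempotent", {
  expect_equal(as.character(normalize_sequence("acgu")), "ACGT")
  expect_equal(as.character(normalize_sequence("ACGRN")), "ACGNN")
  expect_error(normalize_sequence(""), "empty")
  expect_warning(out <- normalize_sequence("NNRN"), "all-N")
  expect_true(attr(out, "all_n"))

  set.seed(11)
  for (i in 1:25) {
    raw <- random_dna(50, alphabet = c("A", "c", "g", "T", "u", "N", "R", "Y"))
    once <- as.character(normalize_sequence(raw))
    expect_identical(as.character(normalize_sequence(once)), once)
    expect_true(grepl("^[ACGTN]+$", once))
  }
})

test_that("annotation reader parses, normalizes chromosomes and maps unknown biotypes", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tbiotype\tchromosome",
               "tx1\tantisense\tchr7",
               "tx2\tTEC\tchrX"), tsv)
  expect_warning(ann <- read_annotation(tsv), "TEC")
  expect_equal(as.character(ann$biotype), c("antisense", "other"))
  expect_equal(as.character(ann$chromosome), c("7", "X"))
})

test_that("annotation reader matches a hand-built map on a 50-row fixture", {
  set.seed(3)
  bios <- sample(c("lincRNA", "antisense", "sense_intronic",
                   "sense_overlapping"), 50, replace = TRUE)
  chroms <- sample(c(1:22, "X", "Y", "MT"), 50, replace = TRUE)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(transcript_id = sprintf("t%02d", 1:50), biotype = bios,
               chromosome = paste0("chr", chroms)),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- read_annotation(tsv)
  expect_identical(as.character(ann$biotype), bios)
  expect_identical(as.character(ann$chromosome), as.character(chroms))
})

test_that("annotation reader rejects missing columns and conflicting duplicates", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tbiotype", "tx1\tantisense"), tsv)
  expect_error(read_annotation(tsv), "chromosome")

  writeLines(c("transcript_id\tbiotype\tchromosome",
               "tx1\tantisense\tchr7",
               "tx1\tlincRNA\tchr7"), tsv)
  expect_error(read_annotation(tsv), "conflicting")
})

test_that("PWM reader parses CISBP-style text, stores U under T, renormalizes", {
  dir <- withr::local_tempdir()
  writeLines(c("Pos\tA\tC\tG\tU", "1\t1\t0\t0\t0", "2\t0\t1\t0\t0",
               "3\t0\t0\t1\t0"), file.path(dir, "M1.txt"))
  pwms <- read_pwm_collection(dir)
  expect_named(pwms, "M1")
  expect_equal(nrow(pwms$M1$probs), 3)
  expect_equal(colnames(pwms$M1$probs), c("A", "C", "G", "T"))
  expect_equal(unname(pwms$M1$probs[1, ]), c(1, 0, 0, 0))

  writeLines(c("Pos\tA\tC\tG\tU", "1\t0.3\t0.3\t0.3\t0.3"),
             file.path(dir, "M2.txt"))
  expect_warning(pwms <- read_pwm_collection(dir), "renormalized")
  expect_equal(unname(pwms$M2$probs[1, ]), rep(0.25, 4))
})

test_that("PWM reader rejects malformed matrices", {
  dir <- withr::local_tempdir()
  writeLines(c("Pos\tA\tC\tG\tU", "1\t-0.5\t0.5\t0.5\t0.5"),
             file.path(dir, "bad.txt"))
  expect_error(read_pwm_collection(file.path(dir, "bad.txt")), "negative")
  writeLines("Pos\tA\tC\tG\tU", file.path(dir, "empty.txt"))
  expect_error(read_pwm_collection(file.path(dir, "empty.txt")), "empty")
})

test_that("PWM write-then-read round-trips within 1e-9", {
  set.seed(5)
  dir <- withr::local_tempdir()
  originals <- lapply(1:5, function(i) random_pwm(sprintf("R%d", i),
                                                  width = sample(3:9, 1)))
  for (p in originals) {
    write_pwm(p, file.path(dir, paste0(p$motif_id, ".txt")))
  }
  back <- read_pwm_collection(dir)
  for (p in originals) {
    expect_lt(max(abs(p$probs - back[[p$motif_id]]$probs)), 1e-9)
  }
})

test_that("fold-change table reader drops non-finite rows and validates inputs", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tl2fc", "tx1\t2.3", "tx2\tNA", "tx3\t-1.1"), tsv)
  expect_warning(tab <- read_foldchange_table(tsv, "HepG2", 4), "non-finite")
  expect_s3_class(tab, "fc_table")
  expect_equal(tab$l2fc, c(tx1 = 2.3, tx3 = -1.1))
  expect_error(suppressWarnings(read_foldchange_table(tsv, "HepG2", 1)),
               "n_samples")

  writeLines(c("transcript_id\tvalue", "tx1\t2.3"), tsv)
  expect_error(suppressWarnings(read_foldchange_table(tsv, "HepG2", 4)),
               "l2fc")
})

test_that("fold-change tables round-trip through write and read", {
  set.seed(9)
  tab <- fc_table("K562", stats::setNames(round(rnorm(40), 6),
                                          sprintf("t%02d", 1:40)), 6)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_foldchange_table(tab, tsv)
  back <- read_foldchange_table(tsv, "K562", 6)
  expect_equal(back$l2fc, tab$l2fc)
})

test_that("transcript_records joins sequences with annotation and validates", {
  rec <- tiny_records(5)
  expect_named(rec, c("transcript_id", "sequence", "biotype", "chromosome"))
  expect_true(all(grepl("^[ACGTN]+$", rec$sequence)))
  ann <- data.frame(transcript_id = "other", biotype = factor("lincRNA"),
                    chromosome = factor("1"))
  expect_error(transcript_records(c(tx1 = "ACGT"), ann), "missing annotation")
})
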