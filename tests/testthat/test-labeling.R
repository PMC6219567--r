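test_that("aggregation is a sample-size weighted mean over detected cell types", {
  one <- fc_table("A", c(tx1 = 2.3), 4)
  agg <- aggregate_l2fc(list(one))
  expect_equal(agg$aggregated_l2fc, 2.3)

  two <- list(fc_table("A", c(tx1 = 1), 4), fc_table("B", c(tx1 = 4), 2))
  expect_equal(aggregate_l2fc(two)$aggregated_l2fc, 2.0)

  # absence from a cell type excludes it from the average
  tabs <- list(fc_table("A", c(tx1 = 1, tx2 = 5), 4),
               fc_table("B", c(tx1 = 4), 2))
  agg <- aggregate_l2fc(tabs)
  expect_equal(agg$aggregated_l2fc[agg$transcript_id == "tx2"], 5)
  expect_equal(agg$n_celltypes_detected[agg$transcript_id == "tx2"], 1L)
})

test_that("aggregation matches a direct per-transcript weighted-mean oracle", {
  set.seed(17)
  ids <- sprintf("t%02d", 1:30)
  tabs <- lapply(1:5, function(ct) {
    keep <- sample(ids, sample(15:30, 1))
    fc_table(sprintf("ct%d", ct),
             stats::setNames(rnorm(length(keep)), keep),
             n_samples = sample(2:8, 1))
  })
  agg <- aggregate_l2fc(tabs)
  for (id in agg$transcript_id) {
    vals <- c(); ws <- c()
    for (t in tabs) {
      if (id %in% names(t$l2fc)) {
        vals <- c(vals, t$l2fc[[id]]); ws <- c(ws, t$n_samples)
      }
    }
    expect_equal(agg$aggregated_l2fc[agg$transcript_id == id],
                 sum(ws * vals) / sum(ws))
    expect_equal(agg$n_celltypes_detected[agg$transcript_id == id],
                 length(vals))
  }
})

test_that("quartile thresholds use linear interpolation with degenerate warning", {
  expect_equal(unname(derive_thresholds(c(0, 1, 2, 3))), c(0.75, 2.25))
  expect_warning(thr <- derive_thresholds(rep(2, 10)), "degenerate")
  expect_equal(unname(thr), c(2, 2))
  expect_error(derive_thresholds(c(1, 2, 3)), "at least 4")
})

test_that("label assignment uses strict inequalities at the fixed thresholds", {
  agg <- data.frame(transcript_id = c("a", "b", "c", "d", "e"),
                    aggregated_l2fc = c(3.0, 1.5, 0, 2.8, -0.1),
                    n_celltypes_detected = 1L)
  lab <- assign_labels(agg, c(0, 2.8))
  expect_identical(as.character(lab$label),
                   c("nuclear", "unlabeled", "unlabeled", "unlabeled",
                     "cytosolic"))
  cnt <- attr(lab, "counts")
  expect_equal(sum(cnt), nrow(agg))
  expect_error(assign_labels(agg, c(2.8, 0)), "inverted")
})

test_that("label counts are conserved and monotone in the nuclear threshold", {
  set.seed(23)
  agg <- data.frame(transcript_id = sprintf("t%03d", 1:500),
                    aggregated_l2fc = rnorm(500, 1.5, 2),
                    n_celltypes_detected = 1L)
  thresholds <- seq(3, -1, by = -0.5)
  n_nuclear <- vapply(thresholds, function(hi) {
    lab <- assign_labels(agg, c(-1.5, hi))
    sum(lab$label == "nuclear")
  }, numeric(1))
  expect_true(all(diff(n_nuclear) >= 0))
  lab <- assign_labels(agg, c(0, 2.8))
  expect_equal(sum(attr(lab, "counts")), 500)
})

test_that("splitting is deterministic, disjoint, exhaustive with rounded sizes", {
  ids <- as.character(1:100)
  sp <- split_dataset(ids, seed = 5)
  expect_equal(lengths(sp), c(train = 70, val = 15, test = 15))
  expect_identical(split_dataset(ids, seed = 5), sp)
  expect_false(identical(split_dataset(ids, seed = 6), sp))
  expect_setequal(unlist(sp), ids)
  expect_equal(anyDuplicated(unlist(sp)), 0)

  big <- split_dataset(as.character(1:8678), seed = 1)
  expect_equal(lengths(big), c(train = 6075, val = 1302, test = 1301))

  expect_error(split_dataset(c("a", "b"), seed = 1), "at least 3")
})

test_that("stratified splitting preserves per-class fractions", {
  ids <- sprintf("t%04d", 1:1000)
  strat <- factor(rep(c("nuclear", "cytosolic"), c(600, 400)))
  sp <- split_dataset(ids, seed = 9, stratify_by = strat)
  expect_setequal(unlist(sp), ids)
  cls <- stats::setNames(as.character(strat), ids)
  expect_equal(sum(cls[sp$train] == "nuclear"), 420)
  expect_equal(sum(cls[sp$val] == "nuclear"), 90)
})

test_that("planted label proportions are recovered within binomial error", {
  # two-point mixture with low noise: labels at (0, 2.8) should recover the
  # planted 60/40 composition of clearly localized transcripts
  set.seed(77)
  n <- 2000
  classes <- sample(c("nuclear", "cytosolic"), n, replace = TRUE,
                    prob = c(0.6, 0.4))
  names(classes) <- sprintf("t%04d", 1:n)
  fc <- generate_foldchange_tables(classes, n_celltypes = 5, seed = 77)
  agg <- aggregate_l2fc(fc$tables)
  lab <- assign_labels(agg, c(0, 2.8))
  p_nuc <- mean(lab$label[lab$label != "unlabeled"] == "nuclear")
  # binomial 3-sigma band around the planted proportion
  expect_lt(abs(p_nuc - 0.6), 3 * sqrt(0.6 * 0.4 / n) + 0.02)
})

test_that("localization tables round-trip through TSV", {
  agg <- data.frame(transcript_id = c("a", "b"),
                    aggregated_l2fc = c(3.2, -0.5),
                    n_celltypes_detected = c(2L, 1L))
  lab <- assign_labels(agg, c(0, 2.8))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_localization_table(lab, tsv)
  back <- read_localization_table(tsv)
  expect_identical(as.character(back$label), as.character(lab$label))
  expect_equal(back$aggregated_l2fc, lab$aggregated_l2fc)
})
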