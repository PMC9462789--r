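toy_motifs <- list(motif_iupac("X", "TTAATT"), motif_iupac("Y", "GGCCGG"))

planted_seq <- function(len = 500) {
  s <- random_dna(len)
  a <- sample(50:(len - 150), 1)
  substr(s, a, a + 5) <- "TTAATT"
  substr(s, a + 40, a + 45) <- "GGCCGG"
  s
}

toy_training <- function(n_pos = 15, n_neg = 30, len = 500) {
  dplyr::bind_rows(
    tibble::tibble(name = paste0("p", seq_len(n_pos)),
                   seq = replicate(n_pos, planted_seq(len)),
                   class = "positive"),
    tibble::tibble(name = paste0("n", seq_len(n_neg)),
                   seq = replicate(n_neg, random_dna(len)),
                   class = "background"))
}

test_that("log-odds weights follow the closed form", {
  x_pos <- matrix(c(1, 1, 3, 3), 2, 2, dimnames = list(NULL, c("f1", "f2")))
  x_neg <- matrix(c(1, 1, 0, 0), 2, 2, dimnames = list(NULL, c("f1", "f2")))
  b <- fit_base(base_log_odds(alpha = 1), rbind(x_pos, x_neg),
                c("p", "p", "n", "n"), "p")
  expect_equal(unname(b$weights["f1"]), 0)               # equal means -> 0
  expect_equal(unname(b$weights["f2"]), log(4 / 1))
  expect_equal(score_base(b, x_pos)[1], 3 * log(4))
  # single feature engineered so mean_pos + a = e * (mean_neg + a)
  xp <- matrix(exp(1) * 2 - 1, 1, 1, dimnames = list(NULL, "f"))
  xn <- matrix(1, 1, 1, dimnames = list(NULL, "f"))
  b2 <- fit_base(base_log_odds(alpha = 1), rbind(xp, xn), c("p", "n"), "p")
  expect_equal(unname(b2$weights), 1)
})

test_that("identical class means give all-zero weights and scores", {
  x <- matrix(runif(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  b <- fit_base(base_log_odds(), rbind(x, x),
                rep(c("p", "n"), each = 10), "p")
  expect_equal(unname(b$weights), c(0, 0))
  expect_equal(score_base(b, x), rep(0, 10))
})

test_that("a planted motif pair earns the top log-odds weight", {
  set.seed(71)
  train <- toy_training()
  model <- pypredictor(toy_motifs, max_distance = 219)
  model <- fit_sequence_model(model, train)
  w <- tidy(model)
  expect_equal(w$term[1], "X:Y")
  expect_gt(w$estimate[1], 0)
})

test_that("dimension mismatches and untrained scoring raise errors", {
  x <- matrix(1, 2, 2, dimnames = list(NULL, c("a", "b")))
  b <- fit_base(base_log_odds(), x, c("p", "n"), "p")
  expect_error(score_base(b, matrix(1, 1, 3)), "mismatch")
  expect_error(score_base(base_log_odds(), x), "fitted")
  m <- pypredictor(toy_motifs)
  expect_error(score_sequences(m, dna_tbl("a", "ACGT")), "trained")
})

test_that("window scoring aggregates as configured", {
  set.seed(72)
  # unweighted sum over all-ones features: score = dimensionality per window
  ones <- ft_motif_freq(list(motif_iupac("N1", "N")), normalization = "raw",
                        strands = "forward")
  model <- sequence_model(ones, base_unweighted_sum(), window = 100, step = 50,
                          aggregation = "sum")
  model$trained <- TRUE
  s <- random_dna(300)
  # 5 windows of 100bp, each scoring 100 N-matches
  expect_equal(score_sequences(model, dna_tbl("a", s))$score, 5 * 100)
  model$aggregation <- "max"
  expect_equal(score_sequences(model, dna_tbl("a", s))$score, 100)
  model$aggregation <- "mean"
  expect_equal(score_sequences(model, dna_tbl("a", s))$score, 100)
  # shorter than the window: scored as one whole-sequence window
  expect_equal(score_sequences(model, dna_tbl("a", "ACGTT"))$score, 5)
})

test_that("a 3 kb sequence at 500/250 aggregates over 11 windows", {
  counter <- ft_motif_freq(list(motif_iupac("N1", "N")), normalization = "raw",
                           strands = "forward")
  model <- sequence_model(counter, base_unweighted_sum(), window = 500,
                          step = 250, aggregation = "sum")
  model$trained <- TRUE
  s <- random_dna(3000, seed = 73)
  expect_equal(score_sequences(model, dna_tbl("a", s))$score, 11 * 500)
})

test_that("external classifier backends plug into the same scoring path", {
  skip_if_not_installed("e1071")
  skip_if_not_installed("randomForest")
  set.seed(74)
  train <- toy_training(20, 20)
  for (engine in c("svm", "rf")) {
    model <- sequence_model(
      ft_concat(ft_motif_freq(toy_motifs), ft_motif_pairs(toy_motifs)),
      base_classifier(engine), window = 500, step = 250)
    model <- fit_sequence_model(model, train)
    sc <- score_sequences(model, train)
    expect_true(all(sc$score >= 0 & sc$score <= 1))
    auc_pos <- mean(sc$score[train$class == "positive"])
    auc_neg <- mean(sc$score[train$class == "background"])
    expect_gt(auc_pos, auc_neg)
  }
})

test_that("retraining on identical data reproduces identical weights", {
  set.seed(75)
  train <- toy_training()
  m1 <- fit_sequence_model(pypredictor(toy_motifs), train)
  m2 <- fit_sequence_model(m1, train)
  expect_identical(m1$base$weights, m2$base$weights)
})

test_that("threshold calibration meets its target on separable scores", {
  set.seed(76)
  train <- toy_training(24, 48)
  model <- fit_sequence_model(pypredictor(toy_motifs), train)
  held_out <- dplyr::filter(toy_training(12, 1), class == "positive")
  bg_model <- train_markov(dna_tbl("bg", random_dna(20000)), order = 2)
  thr <- calibrate_threshold(model, held_out, bg_model,
                             target_precision = 0.8, genome_length = 1e5,
                             seed = 5)
  expect_false(attr(thr, "unreachable"))
  expect_gte(attr(thr, "precision"), 0.8)
  # monotone: a stricter target never lowers the threshold
  thr95 <- calibrate_threshold(model, held_out, bg_model,
                               target_precision = 0.95, genome_length = 1e5,
                               seed = 5)
  expect_gte(as.numeric(thr95), as.numeric(thr))
})

test_that("indistinguishable score distributions flag the target unreachable", {
  ones <- ft_motif_freq(list(motif_iupac("N1", "N")), normalization = "raw",
                        strands = "forward")
  model <- sequence_model(ones, base_unweighted_sum(), window = 100, step = 100)
  model$trained <- TRUE
  pos <- dna_tbl(paste0("p", 1:10), replicate(10, random_dna(100)))
  bg_model <- train_iid(dna_tbl("b", random_dna(1000, seed = 77)))
  expect_warning(
    thr <- calibrate_threshold(model, pos, bg_model, target_precision = 0.8,
                               genome_length = 1e4,
                               expected_positive_fraction = 0.5, seed = 6),
    "degenerate|unreachable")
  expect_true(attr(thr, "unreachable"))
})

test_that("genome-wide prediction recovers a planted locus and streams invariantly", {
  set.seed(78)
  train <- toy_training(20, 40)
  model <- fit_sequence_model(pypredictor(toy_motifs), train)
  chrom <- random_dna(20000)
  for (k in 0:3) {   # a strong planted locus: several pairs
    a <- 9000 + k * 120
    substr(chrom, a, a + 5) <- "TTAATT"
    substr(chrom, a + 50, a + 55) <- "GGCCGG"
  }
  genome <- dna_tbl("chrT", chrom)
  sc <- score_sequences(model, dna_tbl("w", substr(chrom, 8751, 9250)))$score
  pred <- predict_genome_wide(model, genome, threshold = sc / 2)
  expect_equal(nrow(pred$regions), 1)
  expect_true(pred$regions$start < 9000 & pred$regions$end > 9300)
  # chunking invariance
  pred2 <- predict_genome_wide(model, genome, threshold = sc / 2,
                               chunk_windows = 7)
  expect_equal(pred2$regions, pred$regions)
  expect_equal(pred2$curve, pred$curve)
  # threshold above the global max: no regions, curve still emitted
  pred3 <- predict_genome_wide(model, genome,
                               threshold = max(pred$curve$value) + 1)
  expect_equal(nrow(pred3$regions), 0)
  expect_gt(nrow(pred3$curve), 0)
})

test_that("N-rich windows are skipped during prediction", {
  ones <- ft_motif_freq(list(motif_iupac("A1", "A")), normalization = "raw")
  model <- sequence_model(ones, base_unweighted_sum(), window = 100, step = 100)
  model$trained <- TRUE
  genome <- dna_tbl("c", paste0(strrep("A", 100), strrep("N", 100),
                                strrep("A", 100)))
  pred <- predict_genome_wide(model, genome, threshold = 1)
  expect_equal(pred$curve$start, c(0L, 200L))
})

test_that("log-odds model bundles survive a save/load round-trip", {
  set.seed(79)
  train <- toy_training()
  model <- fit_sequence_model(pypredictor(toy_motifs), train)
  model$threshold <- 1.25
  f <- withr::local_tempfile(fileext = ".json")
  save_model(model, f)
  back <- load_model(f)
  expect_equal(back$base$weights, model$base$weights)
  expect_equal(back$threshold, 1.25)
  probe <- dna_tbl("probe", planted_seq())
  expect_equal(score_sequences(back, probe), score_sequences(model, probe))
})
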