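labelled_pool <- function(sizes, seed = 1) {
  set.seed(seed)
  dplyr::bind_rows(purrr::imap(sizes, function(n, cls) {
    tibble::tibble(name = paste0(cls, "_", seq_len(n)),
                   seq = replicate(n, random_dna(60)), class = cls)
  }))
}

test_that("balanced training sets use min(class size - held out) per class", {
  pool <- labelled_pool(c(pos = 10, neg = 50))
  cv <- make_cv_sets(pool, "pos", repeats = 5, min_test_per_class = 2,
                     test_neg_ratio = 2, seed = 3)
  expect_equal(cv$train_per_class, 8)
  for (sp in cv$splits) {
    expect_equal(unname(table(sp$train$class)), c(8, 8), ignore_attr = TRUE)
    # train/test disjoint within the repeat
    expect_length(intersect(sp$train$name, sp$test$name), 0)
    # sampling without replacement
    expect_false(any(duplicated(sp$train$name)))
    expect_false(any(duplicated(sp$test$name)))
  }
})

test_that("test sets honour the negative ratio from pooled negative classes", {
  pool <- labelled_pool(c(pos = 12, negA = 40, negB = 40))
  cv <- make_cv_sets(pool, "pos", repeats = 4, min_test_per_class = 4,
                     test_neg_ratio = 3, seed = 5)
  for (sp in cv$splits) {
    n_pos <- sum(sp$test$positive)
    expect_equal(n_pos, 4)   # 12 - train_n (8) held out
    expect_equal(sum(!sp$test$positive), 12)
    expect_true(all(sp$test$class[!sp$test$positive] %in% c("negA", "negB")))
  }
})

test_that("splits are deterministic under the seed and error on tiny classes", {
  pool <- labelled_pool(c(pos = 10, neg = 20))
  a <- make_cv_sets(pool, "pos", repeats = 3, seed = 7)
  b <- make_cv_sets(pool, "pos", repeats = 3, seed = 7)
  expect_identical(a$splits, b$splits)
  expect_false(identical(a$splits,
                         make_cv_sets(pool, "pos", repeats = 3, seed = 8)$splits))
  expect_error(make_cv_sets(labelled_pool(c(pos = 2, neg = 20)), "pos",
                            min_test_per_class = 2),
               "pos")
})

test_that("perfect separation gives unit AUCs with zero-width intervals", {
  scores <- tidyr::crossing(rep = 1:5, i = 1:10) |>
    dplyr::mutate(positive = i <= 3,
                  score = ifelse(positive, 10 + i, i))
  cur <- roc_pr_curves(scores)
  expect_equal(cur$roc$auc, rep(1, 5))
  expect_equal(cur$pr$auc, rep(1, 5))
  expect_equal(cur$roc$auc_ci$half_width, 0)
  expect_equal(cur$pr$auc_ci$half_width, 0)
  expect_true(all(tidy(cur)$mean >= 0 & tidy(cur)$mean <= 1))
})

test_that("ROC AUC equals the pairwise-comparison (Mann-Whitney) oracle", {
  set.seed(81)
  for (i in 1:10) {
    n_pos <- sample(5:40, 1); n_neg <- sample(5:60, 1)
    pos <- round(rnorm(n_pos, 1), 1)   # rounding forces ties
    neg <- round(rnorm(n_neg, 0), 1)
    scores <- tibble::tibble(rep = 1,
                             positive = rep(c(TRUE, FALSE), c(n_pos, n_neg)),
                             score = c(pos, neg))
    # oracle: P(pos > neg) + 0.5 P(tie) over all pairs
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    got <- roc_pr_curves(dplyr::bind_rows(scores,
                                          dplyr::mutate(scores, rep = 2)))
    expect_equal(got$roc$auc[1], mean(cmp), tolerance = 1e-12)
  }
})

test_that("ROC AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(82)
  pos <- rnorm(30, 0.8); neg <- rnorm(60)
  scores <- tibble::tibble(rep = 1, positive = rep(c(TRUE, FALSE), c(30, 60)),
                           score = c(pos, neg))
  got <- roc_pr_curves(dplyr::bind_rows(scores,
                                        dplyr::mutate(scores, rep = 2)))
  want <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 30), rep(0, 60)), predictor = c(pos, neg),
    quiet = TRUE, direction = "<")))
  expect_equal(got$roc$auc[1], want, tolerance = 1e-12)
})

test_that("random scores at 1:100 imbalance give PR AUC near prevalence", {
  set.seed(83)
  scores <- dplyr::bind_rows(purrr::map(1:20, function(r) {
    tibble::tibble(rep = r,
                   positive = rep(c(TRUE, FALSE), c(20, 2000)),
                   score = rnorm(2020))
  }))
  cur <- roc_pr_curves(scores)
  prevalence <- 20 / 2020
  sem <- sd(cur$pr$auc) / sqrt(20)
  expect_lt(abs(cur$pr$auc_ci$mean - prevalence), 3 * sem + 0.002)
  expect_lt(abs(cur$roc$auc_ci$mean - 0.5), 0.05)
})

test_that("confidence intervals use the t quantile with n - 1 df", {
  ci <- aggregate_ci(rep(2.5, 6))
  expect_equal(ci$half_width, 0)
  vals <- as.numeric(1:20)
  ci <- aggregate_ci(vals, level = 0.95)
  expect_equal(ci$df, 19)
  expect_equal(ci$mean, mean(vals))
  expect_equal(ci$half_width, qt(0.975, 19) * sd(vals) / sqrt(20),
               tolerance = 1e-12)
  expect_error(aggregate_ci(1), "at least 2")
})

test_that("model evaluation over splits is reproducible and incremental", {
  set.seed(84)
  motifs <- list(motif_iupac("X", "TTAATT"), motif_iupac("Y", "GGCCGG"))
  mk_pos <- function(n) replicate(n, {
    s <- random_dna(300)
    substr(s, 50, 55) <- "TTAATT"; substr(s, 120, 125) <- "GGCCGG"
    s
  })
  pool <- dplyr::bind_rows(
    tibble::tibble(name = paste0("p", 1:12), seq = mk_pos(12), class = "positive"),
    tibble::tibble(name = paste0("n", 1:24),
                   seq = replicate(24, random_dna(300)), class = "dummy"))
  cv <- make_cv_sets(pool, "positive", repeats = 4, min_test_per_class = 3,
                     test_neg_ratio = 3, seed = 11)
  model <- pypredictor(motifs, window = 300)
  res1 <- cv_evaluate(cv, model)
  res2 <- cv_evaluate(cv, model)   # adding a model never changes the splits
  expect_identical(res1$scores, res2$scores)
  cur <- roc_pr_curves(res1$scores)
  expect_gt(cur$pr$auc_ci$mean, 0.5)
  p <- autoplot(cur)
  expect_s3_class(p, "ggplot")
})

test_that("cross-validated genome prediction reports support fractions", {
  set.seed(85)
  counter <- ft_motif_freq(list(motif_iupac("X", "TTAATT")),
                           normalization = "raw")
  mk_model <- function() {
    m <- sequence_model(counter, base_unweighted_sum(), window = 100,
                        step = 50)
    m$trained <- TRUE
    m
  }
  chrom <- random_dna(3000)
  substr(chrom, 1000, 1005) <- "TTAATT"
  genome <- dna_tbl("c", chrom)
  models <- list(mk_model(), mk_model(), mk_model(), mk_model())
  # two permissive and two impossible thresholds
  pred <- cv_genome_prediction(models, genome, c(0.5, 0.5, 99, 99))
  expect_true(all(pred$regions$support > 0 & pred$regions$support <= 1))
  hit <- dplyr::filter(pred$regions, .data$start < 1005, .data$end > 999)
  expect_equal(hit$support, 0.5)
  # identical models and thresholds: support 1 everywhere
  pred1 <- cv_genome_prediction(models[1:2], genome, c(0.5, 0.5))
  expect_true(all(pred1$regions$support == 1))
  expect_s3_class(autoplot(pred), "ggplot")
})
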