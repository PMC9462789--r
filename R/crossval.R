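# Cross-validation workbench for imbalanced multi-class sequence data:
# repeated balanced training sets (equal per-class counts, sampled without
# replacement) paired with imbalanced binary test sets (positives vs pooled
# controls at a configured ratio), ROC/PR curves with t-based confidence
# intervals, and cross-validated genome-wide prediction with per-locus
# support.

#' Construct repeated balanced-train / imbalanced-test splits
#'
#' Per repeat, an equal number of sequences is drawn without replacement
#' from every class — the minimum over classes of (class size minus
#' `min_test_per_class`) — giving a balanced multi-class training set. The
#' binary test set takes all held-out positives and
#' `test_neg_ratio` times as many negatives, sampled from the held-out
#' members of all other classes pooled. Train and test are disjoint within a
#' repeat; repeats are independent draws. Deterministic under `seed`.
#'
#' @param seqs Sequence tibble with a `class` column.
#' @param positive_label The positive class.
#' @param repeats Number of repeats (the reference workbench uses 20).
#' @param min_test_per_class Minimum sequences per class held out of
#'   training.
#' @param test_neg_ratio Negatives per test positive (e.g. 100 for 1:100
#'   imbalance).
#' @param seed Integer seed.
#' @return A `crescan_cv_sets`: list of splits, each with `train` and `test`
#'   tibbles (`test` has a logical `positive` column).
#' @export
make_cv_sets <- function(seqs, positive_label, repeats = 20,
                         min_test_per_class = 1, test_neg_ratio = 1, seed = 1) {
  validate_seq_tbl(seqs)
  if (!"class" %in% names(seqs)) abort("`seqs` needs a `class` column")
  stopifnot(repeats >= 2, min_test_per_class >= 1, test_neg_ratio > 0)
  if (!positive_label %in% seqs$class) {
    abort(sprintf("positive label '%s' absent from classes", positive_label))
  }
  sizes <- table(seqs$class)
  short <- names(sizes)[sizes < min_test_per_class + 1]
  if (length(short)) {
    abort(sprintf("class '%s' too small: %d sequences, need at least %d",
                  short[1], sizes[short[1]], min_test_per_class + 1))
  }
  train_n <- min(sizes - min_test_per_class)
  by_class <- split(seq_len(nrow(seqs)), seqs$class)
  splits <- withr::with_seed(seed, {
    purrr::map(seq_len(repeats), function(r) {
      train_idx <- unlist(purrr::map(by_class, ~ sample(.x, train_n)))
      held <- setdiff(seq_len(nrow(seqs)), train_idx)
      held_pos <- held[seqs$class[held] == positive_label]
      held_neg <- held[seqs$class[held] != positive_label]
      n_neg <- round(test_neg_ratio * length(held_pos))
      if (n_neg > length(held_neg)) {
        warn(sprintf("repeat %d: only %d held-out negatives for a target of %d",
                     r, length(held_neg), n_neg))
        n_neg <- length(held_neg)
      }
      test_idx <- c(held_pos, sample(held_neg, n_neg))
      list(repeat_index = r,
           train = seqs[sort(train_idx), , drop = FALSE],
           test = dplyr::mutate(seqs[test_idx, , drop = FALSE],
                                positive = .data$class == positive_label))
    })
  })
  structure(list(splits = splits, positive_label = positive_label,
                 train_per_class = train_n, repeats = repeats, seed = seed),
            class = "crescan_cv_sets")
}

#' @export
print.crescan_cv_sets <- function(x, ...) {
  cat(sprintf("<cv sets: %d repeats, %d training sequences per class>\n",
              x$repeats, x$train_per_class))
  invisible(x)
}

#' Cross-validate a sequence model over prepared splits
#'
#' Retrains the model on each repeat's balanced training set and scores that
#' repeat's test set. Splits are immutable, so further models can be
#' evaluated incrementally on the same splits without affecting earlier
#' results.
#'
#' @param cv A `crescan_cv_sets`.
#' @param model An untrained `crescan_sequence_model`.
#' @return List with `scores` (tibble `rep`, `name`, `positive`, `score`)
#'   and `models` (the per-repeat trained models).
#' @export
cv_evaluate <- function(cv, model) {
  stopifnot(inherits(cv, "crescan_cv_sets"),
            inherits(model, "crescan_sequence_model"))
  fitted <- purrr::map(cv$splits, function(sp) {
    fit_sequence_model(model, sp$train)
  })
  scores <- purrr::map2(cv$splits, fitted, function(sp, m) {
    sc <- score_sequences(m, sp$test)
    tibble(rep = sp$repeat_index, name = sp$test$name,
           positive = sp$test$positive, score = sc$score)
  })
  list(scores = dplyr::bind_rows(scores), models = fitted)
}

roc_pr_one <- function(positive, score) {
  # exhaustive-threshold curves; thresholds between distinct scores, ties
  # grouped; returns step-curve points and trapezoidal AUCs
  o <- order(score, decreasing = TRUE)
  pos <- positive[o]
  sc <- score[o]
  grp_last <- c(sc[-1] != sc[-length(sc)], TRUE)   # last index of each tie group
  tp <- cumsum(pos)[grp_last]
  fp <- cumsum(!pos)[grp_last]
  P <- sum(positive); N <- sum(!positive)
  tpr <- tp / P
  fpr <- fp / N
  prec <- tp / (tp + fp)
  rec <- tpr
  prev_tpr <- c(0, head(tpr, -1))
  roc_auc <- sum(diff(c(0, fpr)) * (prev_tpr + tpr) / 2)
  prev_prec <- c(prec[1], head(prec, -1))
  pr_auc <- sum(diff(c(0, rec)) * (prev_prec + prec) / 2)
  list(roc = tibble(fpr = c(0, fpr), tpr = c(0, tpr)),
       pr = tibble(recall = rec, precision = prec),
       roc_auc = roc_auc, pr_auc = pr_auc)
}

#' ROC and PR curves with confidence intervals across repeats
#'
#' Computes exhaustive-threshold ROC and precision/recall curves and
#' trapezoidal AUCs per repeat, then a mean curve with pointwise t-based
#' confidence intervals on a fixed 101-point grid (repeats have different
#' thresholds, so curves are aligned on FPR / recall). ROC uses step
#' interpolation; PR uses stepwise interpolated precision (the maximum
#' precision at any recall at least the grid value), avoiding the bias of
#' linear PR interpolation. PR curves are the informative view under class
#' imbalance.
#'
#' @param scores Tibble with columns `rep`, `positive` (logical), `score`.
#' @param level Confidence level (default 0.95).
#' @param grid_points Grid size (default 101).
#' @return A `crescan_cv_curves` object; see [tidy.crescan_cv_curves()] and
#'   [glance.crescan_cv_curves()].
#' @export
roc_pr_curves <- function(scores, level = 0.95, grid_points = 101) {
  stopifnot(all(c("rep", "positive", "score") %in% names(scores)))
  reps <- split(scores, scores$rep)
  if (any(purrr::map_lgl(reps, ~ !any(.x$positive) || all(.x$positive)))) {
    abort("every repeat needs at least one positive and one negative score")
  }
  per <- purrr::map(reps, ~ roc_pr_one(.x$positive, .x$score))
  grid <- seq(0, 1, length.out = grid_points)
  roc_mat <- purrr::map(per, function(p) {
    stats::approx(p$roc$fpr, p$roc$tpr, xout = grid, method = "constant",
                  f = 0, rule = 2, ties = max)$y
  })
  pr_mat <- purrr::map(per, function(p) {
    # interpolated precision: max precision among points with recall >= r
    o <- order(p$pr$recall)
    rec <- p$pr$recall[o]
    prec <- rev(cummax(rev(p$pr$precision[o])))
    idx <- findInterval(grid, rec, left.open = TRUE) + 1L
    ifelse(idx > length(prec), prec[length(prec)], prec[idx])
  })
  summarise_grid <- function(mat, xname) {
    m <- do.call(cbind, mat)
    ci <- apply(m, 1, function(v) unlist(aggregate_ci(v, level)))
    tibble(!!xname := grid, mean = ci["mean", ],
           half_width = ci["half_width", ],
           lo = pmax(0, ci["mean", ] - ci["half_width", ]),
           hi = pmin(1, ci["mean", ] + ci["half_width", ]))
  }
  roc_auc <- purrr::map_dbl(per, "roc_auc")
  pr_auc <- purrr::map_dbl(per, "pr_auc")
  structure(list(
    roc = list(grid = summarise_grid(roc_mat, "fpr"),
               auc = unname(roc_auc), auc_ci = aggregate_ci(roc_auc, level)),
    pr = list(grid = summarise_grid(pr_mat, "recall"),
              auc = unname(pr_auc), auc_ci = aggregate_ci(pr_auc, level)),
    level = level, repeats = length(per)),
    class = "crescan_cv_curves")
}

#' @export
print.crescan_cv_curves <- function(x, ...) {
  cat(sprintf(
    "<cv curves over %d repeats: ROC AUC %.3f +/- %.3f, PR AUC %.3f +/- %.3f>\n",
    x$repeats, x$roc$auc_ci$mean, x$roc$auc_ci$half_width,
    x$pr$auc_ci$mean, x$pr$auc_ci$half_width))
  invisible(x)
}

#' @describeIn roc_pr_curves Long tibble of both mean curves with CI bounds
#'   (`curve`, `x`, `mean`, `lo`, `hi`, `half_width`).
#' @param x A `crescan_cv_curves`.
#' @param ... Unused.
#' @export
tidy.crescan_cv_curves <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::rename(dplyr::mutate(x$roc$grid, curve = "roc"), x = "fpr"),
    dplyr::rename(dplyr::mutate(x$pr$grid, curve = "pr"), x = "recall")) |>
    dplyr::relocate("curve")
}

#' @describeIn roc_pr_curves One row per curve with mean AUC and CI
#'   half-width.
#' @export
glance.crescan_cv_curves <- function(x, ...) {
  tibble(curve = c("roc", "pr"),
         auc = c(x$roc$auc_ci$mean, x$pr$auc_ci$mean),
         auc_half_width = c(x$roc$auc_ci$half_width, x$pr$auc_ci$half_width),
         level = x$level, repeats = x$repeats)
}

#' Mean and t-based confidence half-width of repeated measurements
#'
#' `half_width = t((1 + level)/2, n - 1) * sd / sqrt(n)`; with the
#' workbench's 20 repeats the quantile uses 19 degrees of freedom.
#'
#' @param values Numeric vector (per-repeat measurements), length >= 2.
#' @param level Confidence level (default 0.95).
#' @return One-row tibble with columns `mean`, `half_width`, `df`, `level`.
#' @export
aggregate_ci <- function(values, level = 0.95) {
  if (length(values) < 2) abort("aggregate_ci() needs at least 2 values")
  n <- length(values)
  tibble(mean = mean(values),
         half_width = stats::qt((1 + level) / 2, df = n - 1) *
           stats::sd(values) / sqrt(n),
         df = n - 1, level = level)
}

#' Cross-validated genome-wide prediction with per-locus support
#'
#' Applies each repeat's trained model genome-wide at its own calibrated
#' threshold, merges all repeats' predicted regions into loci and annotates
#' every locus with its support: the fraction of repeats with at least one
#' overlapping prediction. Loci therefore always have support in (0, 1].
#'
#' @param models List of trained `crescan_sequence_model`s, one per repeat.
#' @param genome Sequence tibble of chromosomes.
#' @param thresholds Numeric vector of per-repeat thresholds.
#' @return A `crescan_prediction` whose `regions` carry a `support` column;
#'   `curve` holds the mean score track across repeats.
#' @export
cv_genome_prediction <- function(models, genome, thresholds) {
  stopifnot(length(models) == length(thresholds), length(models) >= 1)
  preds <- purrr::map2(models, thresholds,
                       ~ predict_genome_wide(.x, genome, .y))
  all_regions <- dplyr::bind_rows(purrr::map(preds, ~ .x$regions))
  loci <- if (nrow(all_regions) == 0) empty_regions() else regions_merge(all_regions)
  if (nrow(loci) > 0) {
    gl <- as_granges(loci)
    support <- rowSums(do.call(cbind, purrr::map(preds, function(p) {
      v <- integer(nrow(loci))
      if (nrow(p$regions) > 0) {
        hit <- unique(S4Vectors::queryHits(
          GenomicRanges::findOverlaps(gl, as_granges(p$regions))))
        v[hit] <- 1L
      }
      v
    }))) / length(preds)
    loci$support <- support
  } else {
    loci$support <- numeric(0)
  }
  curve <- dplyr::bind_rows(purrr::map(preds, "curve")) |>
    dplyr::group_by(.data$seqname, .data$start, .data$span) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  structure(list(curve = curve, regions = loci, threshold = NULL,
                 per_repeat = preds),
            class = "crescan_prediction")
}
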