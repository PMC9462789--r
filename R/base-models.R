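# Base classifiers over numeric feature vectors. Three kinds: an unweighted
# sum (useful as a null scorer and for arithmetic checks), a log-odds model
# over class feature means (the scorer behind the classic motif-pair CRE
# predictor), and a wrapper for external classifiers (SVMs, random forests)
# so that any backend can stand behind the same scoring/calibration/
# prediction code paths.

#' Base classifiers for feature vectors
#'
#' `base_unweighted_sum()` scores a vector by the plain sum of its features.
#' `base_log_odds(alpha)` learns one weight per feature,
#' `w_f = ln((mean_pos_f + alpha) / (mean_neg_f + alpha))`, and scores by the
#' weighted feature sum; `alpha > 0` is an additive pseudocount that
#' stabilises rare features. `base_classifier(engine)` wraps an external
#' classifier (`"svm"` via e1071 or `"rf"` via randomForest) scoring by the
#' predicted positive-class probability.
#'
#' @param alpha Log-odds pseudocount (default 1).
#' @param engine `"svm"` or `"rf"`.
#' @param ... Extra arguments passed to the engine's fitting function.
#' @return A `crescan_base` specification, to be fitted with [fit_base()].
#' @export
base_log_odds <- function(alpha = 1) {
  stopifnot(alpha > 0)
  structure(list(kind = "log_odds", alpha = alpha), class = "crescan_base")
}

#' @rdname base_log_odds
#' @export
base_unweighted_sum <- function() {
  structure(list(kind = "unweighted_sum"), class = "crescan_base")
}

#' @rdname base_log_odds
#' @export
base_classifier <- function(engine = c("svm", "rf"), ...) {
  engine <- match.arg(engine)
  pkg <- c(svm = "e1071", rf = "randomForest")[[engine]]
  if (!requireNamespace(pkg, quietly = TRUE)) {
    abort(sprintf("base_classifier('%s') requires the %s package", engine, pkg))
  }
  structure(list(kind = "external_classifier", engine = engine,
                 args = list(...)),
            class = "crescan_base")
}

#' Fit a base classifier
#'
#' Binary base models handle multi-class data by scoring the designated
#' positive class against all other classes pooled.
#'
#' @param base A `crescan_base` specification.
#' @param x Numeric feature matrix (rows = examples, named columns).
#' @param y Class labels, one per row of `x`.
#' @param positive_label The label treated as the positive class.
#' @return A fitted `crescan_base` (carries the training dimensionality).
#' @export
fit_base <- function(base, x, y, positive_label) {
  stopifnot(inherits(base, "crescan_base"), is.matrix(x), nrow(x) == length(y))
  if (!positive_label %in% y) {
    abort(sprintf("positive label '%s' absent from training labels", positive_label))
  }
  base$features <- colnames(x)
  base$positive_label <- positive_label
  pos <- y == positive_label
  if (base$kind == "log_odds") {
    mp <- colMeans(x[pos, , drop = FALSE])
    mn <- colMeans(x[!pos, , drop = FALSE])
    base$weights <- log((mp + base$alpha) / (mn + base$alpha))
  } else if (base$kind == "external_classifier") {
    yf <- factor(ifelse(pos, "pos", "neg"), levels = c("neg", "pos"))
    base$model <- if (base$engine == "svm") {
      do.call(e1071::svm, c(list(x = x, y = yf, probability = TRUE), base$args))
    } else {
      do.call(randomForest::randomForest, c(list(x = x, y = yf), base$args))
    }
  }
  base$trained <- TRUE
  base
}

#' Score feature vectors with a fitted base classifier
#'
#' @param base A fitted `crescan_base`.
#' @param x Feature matrix with the training dimensionality.
#' @return Numeric score per row (log-odds sum, plain sum, or positive-class
#'   probability depending on the base kind).
#' @export
score_base <- function(base, x) {
  stopifnot(inherits(base, "crescan_base"), is.matrix(x))
  if (base$kind == "unweighted_sum") return(unname(rowSums(x)))
  if (is.null(base$trained)) abort("base model must be fitted before scoring")
  if (ncol(x) != length(base$features)) {
    abort(sprintf("feature dimension mismatch: got %d, trained on %d",
                  ncol(x), length(base$features)))
  }
  if (base$kind == "log_odds") {
    unname(drop(x %*% base$weights))
  } else if (base$engine == "svm") {
    p <- stats::predict(base$model, x, probability = TRUE)
    unname(attr(p, "probabilities")[, "pos"])
  } else {
    unname(stats::predict(base$model, x, type = "prob")[, "pos"])
  }
}

#' @export
tidy.crescan_base <- function(x, ...) {
  if (x$kind != "log_odds" || is.null(x$weights)) {
    abort("tidy() is defined for fitted log-odds base models")
  }
  tibble(term = names(x$weights), estimate = unname(x$weights)) |>
    dplyr::arrange(dplyr::desc(.data$estimate))
}
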