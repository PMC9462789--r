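# Sequence models: a feature node (or a trained network) plus a base
# classifier, a sliding-window policy and an optional calibrated threshold.
# The same object supports whole-sequence scoring, precision-targeted
# threshold calibration and streamed genome-wide prediction.

#' Specify a sequence model
#'
#' Combines a feature node and a base classifier with a sliding-window
#' scoring policy. A sequence is scored by sliding windows of
#' `window`/`step` bp over it, scoring each window's feature vector with the
#' base model and aggregating window scores (`max` by default — the presence
#' of a regulatory element is a local property of its best window; `mean`
#' and `sum` are available). Sequences shorter than `window` are scored as a
#' single whole-sequence window.
#'
#' @param features A `crescan_feature` node.
#' @param base A `crescan_base` classifier specification.
#' @param window,step Window length and step in bp (defaults 500/250, the
#'   usual scanning resolution for short CREs).
#' @param aggregation `"max"`, `"mean"` or `"sum"`.
#' @param positive_label Label of the positive class (default `"positive"`).
#' @return A `crescan_sequence_model` (untrained; see [fit_sequence_model()]).
#' @export
sequence_model <- function(features, base, window = 500, step = 250,
                           aggregation = c("max", "mean", "sum"),
                           positive_label = "positive") {
  stopifnot(inherits(features, "crescan_feature"), inherits(base, "crescan_base"),
            window >= 1, step >= 1)
  structure(list(features = features, base = base, network = NULL,
                 window = as.integer(window), step = as.integer(step),
                 aggregation = match.arg(aggregation),
                 positive_label = positive_label, threshold = NULL,
                 trained = FALSE),
            class = "crescan_sequence_model")
}

#' The classic motif-pair CRE predictor
#'
#' Convenience constructor for the log-odds motif-pair model: singular motif
#' occurrence frequencies plus pair occurrence frequencies within a cut-off
#' distance, scored by per-feature log-odds between positives and negatives.
#'
#' @param motifs List of `crescan_motif` objects.
#' @param max_distance Pairing cut-off in bp (default 219).
#' @param alpha Log-odds pseudocount.
#' @inheritParams sequence_model
#' @return A `crescan_sequence_model`.
#' @export
pypredictor <- function(motifs, max_distance = 219, alpha = 1,
                        window = 500, step = 250) {
  sequence_model(
    features = ft_concat(ft_motif_freq(motifs),
                         ft_motif_pairs(motifs, max_distance = max_distance)),
    base = base_log_odds(alpha = alpha),
    window = window, step = step, aggregation = "max")
}

#' Train a sequence model on labelled sequences
#'
#' Trains the feature node recursively on all training sequences, computes
#' the feature table and fits the base classifier. Retraining an identical
#' model on identical data reproduces identical weights.
#'
#' @param model A `crescan_sequence_model`.
#' @param seqs Sequence tibble with a `class` column.
#' @return The trained model.
#' @export
fit_sequence_model <- function(model, seqs) {
  stopifnot(inherits(model, "crescan_sequence_model"))
  validate_seq_tbl(seqs)
  if (!"class" %in% names(seqs)) abort("training sequences need a `class` column")
  model$features <- ft_train(model$features, seqs)
  x <- ft_matrix(model$features, seqs)
  model$base <- fit_base(model$base, x, seqs$class, model$positive_label)
  model$trained <- TRUE
  model
}

# Internal: score fixed-length windows (character vector) directly.
score_windows_chr <- function(model, wins) {
  if (!is.null(model$network)) {
    return(nn_score(model$network, wins))
  }
  x <- ft_matrix(model$features, tibble(name = as.character(seq_along(wins)),
                                        seq = wins))
  score_base(model$base, x)
}

#' Score whole sequences with a sliding window
#'
#' @param model A trained `crescan_sequence_model`.
#' @param seqs Sequence tibble.
#' @return Tibble with columns `name` and `score` (one aggregated score per
#'   sequence).
#' @export
score_sequences <- function(model, seqs) {
  stopifnot(inherits(model, "crescan_sequence_model"))
  if (!isTRUE(model$trained)) abort("model must be trained before scoring")
  validate_seq_tbl(seqs)
  agg <- switch(model$aggregation, max = max, mean = mean, sum = sum)
  scores <- purrr::map_dbl(seqs$seq, function(s) {
    wins <- if (nchar(s) < model$window) s else {
      starts <- seq(0L, nchar(s) - model$window, by = model$step)
      stringr::str_sub(s, starts + 1L, starts + model$window)
    }
    agg(score_windows_chr(model, wins))
  })
  tibble(name = seqs$name, score = scores)
}

#' Calibrate a prediction threshold for a target genome-wide precision
#'
#' Estimates, for every candidate threshold, the precision a genome-wide scan
#' would achieve, and returns the smallest threshold whose estimate reaches
#' `target_precision`. Background windows are generated from `background_model`
#' (e.g. a high-order Markov chain trained genome-wide) totalling at least
#' `genome_length / 10` bases, and the precision estimate combines the
#' true-positive rate on `positives` with the background false-positive rate
#' under the expected positive prevalence `pi`:
#' `precision(t) = pi TPR(t) / (pi TPR(t) + (1 - pi) FPR(t))`.
#' `pi` defaults to `nrow(positives) * window / genome_length`, i.e. the
#' fraction of the genome expected to be covered by true elements. If the
#' target is unreachable the maximum positive score is returned with a
#' warning and attribute `unreachable = TRUE`.
#'
#' @param model A trained `crescan_sequence_model`.
#' @param positives Sequence tibble of held-out positive examples.
#' @param background_model A `crescan_iid` or `crescan_markov` model.
#' @param target_precision Desired genome-wide precision in (0, 1)
#'   (default 0.8).
#' @param genome_length Genome size in bp.
#' @param expected_positive_fraction Prevalence `pi`; computed from the
#'   positives when `NULL`.
#' @param seed Integer seed for background generation.
#' @return The calibrated threshold (numeric scalar), with attribute
#'   `precision` (the estimate at the returned threshold).
#' @export
calibrate_threshold <- function(model, positives, background_model,
                                target_precision = 0.8, genome_length,
                                expected_positive_fraction = NULL, seed = 1) {
  stopifnot(inherits(model, "crescan_sequence_model"),
            target_precision > 0, target_precision < 1)
  validate_seq_tbl(positives, "positives")
  if (nrow(positives) == 0) abort("calibration requires positive examples")
  n_bg <- ceiling(genome_length / 10 / model$window)
  bg <- generate_sequences(background_model, model$window, n_bg, seed = seed,
                           prefix = "bg")
  pos_scores <- score_sequences(model, positives)$score
  bg_scores <- score_sequences(model, bg)$score
  pi0 <- expected_positive_fraction %||%
    (nrow(positives) * model$window / genome_length)
  cand <- sort(unique(c(pos_scores, bg_scores)))
  if (length(cand) == 1) {
    warn("calibration degenerate: all scores identical")
    return(structure(cand, precision = NA_real_, unreachable = TRUE))
  }
  # thresholds sit between consecutive distinct scores (strict > downstream)
  thr <- c(cand[-length(cand)], cand[length(cand)])
  prec <- purrr::map_dbl(thr, function(t) {
    tpr <- mean(pos_scores > t)
    fpr <- mean(bg_scores > t)
    denom <- pi0 * tpr + (1 - pi0) * fpr
    if (denom == 0) return(NA_real_)
    pi0 * tpr / denom
  })
  ok <- which(!is.na(prec) & prec >= target_precision)
  if (length(ok) == 0) {
    warn(sprintf("target precision %.2f unreachable; returning max positive score",
                 target_precision))
    return(structure(max(pos_scores), precision = max(prec, na.rm = TRUE),
                     unreachable = TRUE))
  }
  structure(thr[min(ok)], precision = prec[min(ok)], unreachable = FALSE)
}

#' Genome-wide prediction by sliding-window scanning
#'
#' Streams fixed windows over every chromosome in bounded-size chunks, scores
#' each window, and returns (i) a score curve sampled at the window step and
#' (ii) the merged regions formed by windows scoring strictly above the
#' threshold. Windows with more than `max_n_fraction` unknown bases (assembly
#' gaps) are skipped. Results are independent of the chunk size.
#'
#' @param model A trained `crescan_sequence_model`.
#' @param genome Sequence tibble of chromosomes.
#' @param threshold Score threshold (e.g. from [calibrate_threshold()]).
#' @param chunk_windows Number of windows scored per chunk (memory knob).
#' @param max_n_fraction Skip windows with a higher fraction of `N`.
#' @return A `crescan_prediction`: list with `curve` (score track tibble)
#'   and `regions` (merged predicted regions).
#' @export
predict_genome_wide <- function(model, genome, threshold,
                                chunk_windows = 2000, max_n_fraction = 0.5) {
  stopifnot(inherits(model, "crescan_sequence_model"))
  if (!isTRUE(model$trained)) abort("model must be trained before prediction")
  validate_seq_tbl(genome, "genome")
  curves <- list()
  hits <- list()
  for (i in seq_len(nrow(genome))) {
    L <- nchar(genome$seq[i])
    if (L < model$window) next
    starts <- seq(0L, L - model$window, by = model$step)
    for (ck in split(starts, ceiling(seq_along(starts) / chunk_windows))) {
      wins <- stringr::str_sub(genome$seq[i], ck + 1L, ck + model$window)
      n_frac <- stringr::str_count(wins, "N") / model$window
      keep <- n_frac <= max_n_fraction
      if (!any(keep)) next
      sc <- score_windows_chr(model, wins[keep])
      curves[[length(curves) + 1L]] <- tibble(
        seqname = genome$name[i], start = ck[keep],
        span = model$step, value = sc)
      above <- sc > threshold
      if (any(above)) {
        hits[[length(hits) + 1L]] <- tibble(
          seqname = genome$name[i], start = ck[keep][above],
          end = ck[keep][above] + model$window)
      }
    }
  }
  curve <- if (length(curves)) dplyr::bind_rows(curves) else curve_tbl()
  regs <- if (length(hits)) {
    h <- dplyr::bind_rows(hits)
    regions_merge(regions(h$seqname, h$start, h$end))
  } else empty_regions()
  structure(list(curve = curve, regions = regs, threshold = threshold),
            class = "crescan_prediction")
}

#' @export
print.crescan_prediction <- function(x, ...) {
  cat(sprintf("<genome-wide prediction: %d regions, %d score samples>\n",
              nrow(x$regions), nrow(x$curve)))
  invisible(x)
}

#' @export
tidy.crescan_prediction <- function(x, ...) x$regions

#' @export
glance.crescan_prediction <- function(x, ...) {
  tibble(n_regions = nrow(x$regions),
         predicted_bases = sum(x$regions$end - x$regions$start),
         threshold = x$threshold %||% NA_real_)
}

#' @export
tidy.crescan_sequence_model <- function(x, ...) tidy(x$base, ...)

#' @export
glance.crescan_sequence_model <- function(x, ...) {
  tibble(kind = if (!is.null(x$network)) "network" else x$base$kind,
         n_features = if (!is.null(x$network)) NA_integer_
                      else length(feature_names(x$features)),
         window = x$window, step = x$step, aggregation = x$aggregation,
         trained = isTRUE(x$trained),
         threshold = x$threshold %||% NA_real_)
}

#' Save or load a log-odds sequence model bundle
#'
#' Serialises a trained motif-based log-odds model (motifs, pairing
#' distance, weights, window policy, threshold) to a documented JSON layout.
#' External-classifier and network models carry fitted state that is not
#' portable as JSON and are rejected.
#'
#' @param model A trained `crescan_sequence_model` with a log-odds base.
#' @param path JSON file path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "crescan_sequence_model"))
  if (!is.null(model$network) || model$base$kind != "log_odds") {
    abort("save_model() supports log-odds models only")
  }
  spec <- serialize_feature_node(model$features)
  obj <- list(type = "log_odds_sequence_model", features = spec,
              weights = as.list(model$base$weights), alpha = model$base$alpha,
              window = model$window, step = model$step,
              aggregation = model$aggregation,
              positive_label = model$positive_label,
              threshold = model$threshold)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path)
  m <- sequence_model(
    features = deserialize_feature_node(obj$features),
    base = base_log_odds(alpha = obj$alpha),
    window = obj$window, step = obj$step, aggregation = obj$aggregation,
    positive_label = obj$positive_label)
  w <- purrr::map_dbl(obj$weights, identity)
  m$base$weights <- setNames(w, names(obj$weights))
  m$base$features <- names(obj$weights)
  m$base$positive_label <- obj$positive_label
  m$base$trained <- TRUE
  m$trained <- TRUE
  m$threshold <- obj$threshold
  m
}

serialize_feature_node <- function(node) {
  out <- list(kind = node$kind)
  if (node$kind %in% c("motif_freq", "motif_pairs")) {
    out$motifs <- purrr::map(node$params$motifs, function(m) {
      if (m$kind != "iupac") abort("only IUPAC motifs serialise to JSON")
      list(name = m$name, pattern = m$pattern)
    })
    out$normalization <- node$params$normalization
    out$strands <- node$params$strands
    if (node$kind == "motif_pairs") out$max_distance <- node$params$max_distance
  } else if (node$kind == "kspectrum") {
    out$k <- node$params$k; out$m <- node$params$m
    out$strands <- node$params$strands
  } else if (node$kind == "concat") {
    out$children <- purrr::map(node$children, serialize_feature_node)
  } else {
    abort(sprintf("feature node kind '%s' does not serialise to JSON", node$kind))
  }
  out
}

deserialize_feature_node <- function(obj) {
  kind <- obj$kind
  if (kind == "motif_freq") {
    ft_motif_freq(purrr::map(obj$motifs, ~ motif_iupac(.x$name, .x$pattern)),
                  normalization = obj$normalization, strands = obj$strands)
  } else if (kind == "motif_pairs") {
    ft_motif_pairs(purrr::map(obj$motifs, ~ motif_iupac(.x$name, .x$pattern)),
                   max_distance = obj$max_distance,
                   normalization = obj$normalization, strands = obj$strands)
  } else if (kind == "kspectrum") {
    if (obj$m > 0) ft_kspectrum_mismatch(obj$k, obj$m, strands = obj$strands)
    else ft_kspectrum(obj$k, strands = obj$strands)
  } else if (kind == "concat") {
    do.call(ft_concat, purrr::map(obj$children, deserialize_feature_node))
  } else {
    abort(sprintf("unknown serialised feature kind '%s'", kind))
  }
}
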