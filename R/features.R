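# Composable, trainable feature sets over DNA sequences, organised as a
# directed acyclic graph of nodes. Base nodes map sequences to non-negative
# counts/frequencies (motif occurrences, motif pairs, k-spectra); transform
# nodes combine, filter, pair or standardise their children's outputs.
# ft_train() is recursive and idempotent; ft_transform() returns a tidy
# feature table (one row per sequence).

new_feature_node <- function(kind, params = list(), children = list(),
                             state = NULL) {
  structure(list(kind = kind, params = params, children = children,
                 state = state),
            class = "crescan_feature")
}

#' @export
print.crescan_feature <- function(x, ...) {
  cat(sprintf("<feature node: %s, %d features%s>\n", x$kind,
              length(feature_names(x)),
              if (length(x$children)) sprintf(", %d children", length(x$children))
              else ""))
  invisible(x)
}

#' Motif occurrence frequency features
#'
#' One feature per motif: its occurrence count in the sequence (both strands
#' by default), optionally normalised to occurrences per kilobase.
#'
#' @param motifs List of `crescan_motif` objects.
#' @param normalization `"per_kb"` (default, matching motif-frequency
#'   convention) or `"raw"` counts.
#' @param strands `"both"` (default) or `"forward"`.
#' @return A `crescan_feature` node.
#' @export
ft_motif_freq <- function(motifs, normalization = c("per_kb", "raw"),
                          strands = c("both", "forward")) {
  stopifnot(length(motifs) >= 1)
  new_feature_node("motif_freq",
                   params = list(motifs = motifs,
                                 normalization = match.arg(normalization),
                                 strands = match.arg(strands)))
}

#' Motif pair occurrence frequency features
#'
#' One feature per unordered motif pair, self-pairs included (`m` motifs give
#' `m (m + 1) / 2` features). The value is the number of occurrence pairs —
#' one occurrence from each motif of the pair, distinct occurrences — whose
#' start positions lie within `max_distance` of each other. For self-pairs
#' each unordered occurrence pair is counted once, and two occurrences of the
#' same motif at the same offset (opposite strands) do not pair. Motif
#' pairing within a cut-off distance is the classic signal for Polycomb
#' response element prediction.
#'
#' @inheritParams ft_motif_freq
#' @param max_distance Maximum separation between occurrence starts in bp
#'   (default 219, the classic pairing cut-off).
#' @return A `crescan_feature` node.
#' @export
ft_motif_pairs <- function(motifs, max_distance = 219,
                           normalization = c("per_kb", "raw"),
                           strands = c("both", "forward")) {
  stopifnot(length(motifs) >= 1, max_distance >= 0)
  new_feature_node("motif_pairs",
                   params = list(motifs = motifs, max_distance = max_distance,
                                 normalization = match.arg(normalization),
                                 strands = match.arg(strands)))
}

#' k-spectrum features
#'
#' One feature per k-mer (dimensionality `4^k`, lexicographic order): the
#' number of offsets whose k-mer equals the feature's k-mer. Windows
#' containing `N` are skipped. Forward-strand counting by default, following
#' spectrum-kernel convention; `"both"` adds the counts of the reverse
#' complement of the sequence.
#'
#' @param k Word length (1-12).
#' @param strands `"forward"` (default) or `"both"`.
#' @return A `crescan_feature` node.
#' @export
ft_kspectrum <- function(k, strands = c("forward", "both")) {
  stopifnot(k >= 1, k <= 12)
  new_feature_node("kspectrum",
                   params = list(k = as.integer(k), m = 0L,
                                 strands = match.arg(strands)))
}

#' k-spectrum mismatch features
#'
#' Like [ft_kspectrum()], but an offset's k-mer counts toward every feature
#' k-mer within Hamming distance `m` of it. `m = 0` reduces exactly to the
#' plain spectrum. For an N-free sequence the feature sum is
#' `(L - k + 1) * sum_{i <= m} choose(k, i) * 3^i`.
#'
#' @inheritParams ft_kspectrum
#' @param m Maximum number of mismatches (`0 <= m < k`).
#' @return A `crescan_feature` node.
#' @export
ft_kspectrum_mismatch <- function(k, m, strands = c("forward", "both")) {
  stopifnot(k >= 1, k <= 12, m >= 0, m < k)
  new_feature_node("kspectrum",
                   params = list(k = as.integer(k), m = as.integer(m),
                                 strands = match.arg(strands)))
}

#' Combine, filter, pair or standardise feature nodes
#'
#' * `ft_concat()` concatenates the outputs of two or more nodes.
#' * `ft_filter()` keeps the features whose names satisfy a predicate (or
#'   match a regular expression), preserving order.
#' * `ft_product_pair()` emits all unordered pairwise products of one node's
#'   features, squares included (`d` features give `d (d + 1) / 2`) — a
#'   quadratic feature map.
#' * `ft_scale()` standardises each feature to zero mean and unit variance
#'   using statistics learned by [ft_train()]; a zero-variance feature is
#'   emitted as 0.
#'
#' @param ... Feature nodes (for `ft_concat()`).
#' @param node A feature node.
#' @param predicate Function from feature name to logical, or a regex string.
#' @return A `crescan_feature` node.
#' @export
ft_concat <- function(...) {
  children <- list(...)
  stopifnot(length(children) >= 2)
  new_feature_node("concat", children = children)
}

#' @rdname ft_concat
#' @export
ft_filter <- function(node, predicate) {
  if (is.character(predicate)) {
    rx <- predicate
    predicate <- function(nm) stringr::str_detect(nm, rx)
  }
  new_feature_node("filter", params = list(predicate = predicate),
                   children = list(node))
}

#' @rdname ft_concat
#' @export
ft_product_pair <- function(node) {
  new_feature_node("product_pair", children = list(node))
}

#' @rdname ft_concat
#' @export
ft_scale <- function(node) {
  new_feature_node("scale", children = list(node))
}

#' Feature names of a node
#'
#' Stable order; length equals the node's output dimensionality.
#'
#' @param node A `crescan_feature`.
#' @return Character vector of feature names.
#' @export
feature_names <- function(node) {
  stopifnot(inherits(node, "crescan_feature"))
  switch(node$kind,
    motif_freq = purrr::map_chr(node$params$motifs, "name"),
    motif_pairs = {
      nms <- purrr::map_chr(node$params$motifs, "name")
      n <- length(nms)
      idx <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
      sprintf("%s:%s", nms[idx[, "row"]], nms[idx[, "col"]])
    },
    kspectrum = all_kmers(node$params$k),
    concat = unlist(purrr::map(node$children, feature_names)),
    filter = {
      nm <- feature_names(node$children[[1]])
      nm[purrr::map_lgl(nm, node$params$predicate)]
    },
    product_pair = {
      nm <- feature_names(node$children[[1]])
      d <- length(nm)
      idx <- which(upper.tri(diag(d), diag = TRUE), arr.ind = TRUE)
      o <- order(idx[, "row"], idx[, "col"])
      sprintf("%s*%s", nm[idx[o, "row"]], nm[idx[o, "col"]])
    },
    scale = paste0("z_", feature_names(node$children[[1]])),
    abort(sprintf("unknown feature node kind '%s'", node$kind)))
}

#' Train a feature node recursively
#'
#' Walks the node graph depth-first, training children before parents.
#' Stateless nodes (motif and spectrum counters, concat, filter, product)
#' pass through unchanged; `ft_scale()` learns per-feature mean and standard
#' deviation over the training sequences. Training is idempotent on fixed
#' data.
#'
#' @param node A `crescan_feature`.
#' @param seqs Training sequence tibble.
#' @return The trained node.
#' @export
ft_train <- function(node, seqs) {
  stopifnot(inherits(node, "crescan_feature"))
  validate_seq_tbl(seqs)
  node$children <- purrr::map(node$children, ft_train, seqs = seqs)
  if (node$kind == "scale") {
    x <- ft_matrix(node$children[[1]], seqs)
    node$state <- list(mean = colMeans(x), sd = apply(x, 2, stats::sd))
  }
  node
}

# Internal: numeric feature matrix (rows = sequences, columns = features).
ft_matrix <- function(node, seqs) {
  validate_seq_tbl(seqs)
  n <- nrow(seqs)
  out <- switch(node$kind,
    motif_freq = {
      p <- node$params
      vals <- purrr::map(seqs$seq, function(s) {
        codes <- encode_bases(s)
        purrr::map_dbl(p$motifs, function(m) {
          length(scan_motif_one(codes, m, p$strands)$pos)
        })
      })
      m <- do.call(rbind, vals)
      if (p$normalization == "per_kb") {
        len <- nchar(seqs$seq)
        m <- m * ifelse(len > 0, 1000 / len, 0)
      }
      m
    },
    motif_pairs = {
      p <- node$params
      vals <- purrr::map(seqs$seq, function(s) {
        codes <- encode_bases(s)
        occ <- purrr::map(p$motifs, function(m) {
          sort(scan_motif_one(codes, m, p$strands)$pos)
        })
        count_motif_pairs(occ, p$max_distance)
      })
      m <- do.call(rbind, vals)
      if (p$normalization == "per_kb") {
        len <- nchar(seqs$seq)
        m <- m * ifelse(len > 0, 1000 / len, 0)
      }
      m
    },
    kspectrum = {
      p <- node$params
      set <- Biostrings::DNAStringSet(seqs$seq)
      m <- Biostrings::oligonucleotideFrequency(set, width = p$k)
      if (is.null(dim(m))) m <- matrix(m, nrow = 1)
      if (p$strands == "both") {
        rc <- Biostrings::oligonucleotideFrequency(
          Biostrings::reverseComplement(set), width = p$k)
        if (is.null(dim(rc))) rc <- matrix(rc, nrow = 1)
        m <- m + rc
      }
      if (p$m > 0) m <- m %*% hamming_ball_matrix(p$k, p$m)
      m
    },
    concat = do.call(cbind, purrr::map(node$children, ft_matrix, seqs = seqs)),
    filter = {
      nm <- feature_names(node$children[[1]])
      keep <- purrr::map_lgl(nm, node$params$predicate)
      ft_matrix(node$children[[1]], seqs)[, keep, drop = FALSE]
    },
    product_pair = {
      x <- ft_matrix(node$children[[1]], seqs)
      d <- ncol(x)
      idx <- which(upper.tri(diag(d), diag = TRUE), arr.ind = TRUE)
      o <- order(idx[, "row"], idx[, "col"])
      x[, idx[o, "row"], drop = FALSE] * x[, idx[o, "col"], drop = FALSE]
    },
    scale = {
      if (is.null(node$state)) {
        abort("scale node must be trained with ft_train() before transform")
      }
      x <- ft_matrix(node$children[[1]], seqs)
      sdv <- node$state$sd
      z <- sweep(x, 2, node$state$mean)
      z <- sweep(z, 2, ifelse(sdv > 0, sdv, 1), "/")
      z[, sdv == 0] <- 0
      z
    },
    abort(sprintf("unknown feature node kind '%s'", node$kind)))
  dimnames(out) <- list(seqs$name, feature_names(node))
  out
}

# Count occurrence pairs within max_distance for every unordered motif pair
# (self-pairs included). occ: list of sorted 0-based occurrence positions.
count_motif_pairs <- function(occ, max_distance) {
  n <- length(occ)
  idx <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  o <- order(idx[, "row"], idx[, "col"])
  purrr::map_dbl(o, function(oi) {
    i <- idx[oi, "row"]; j <- idx[oi, "col"]
    pi <- occ[[i]]; pj <- occ[[j]]
    if (length(pi) == 0 || length(pj) == 0) return(0)
    if (i == j) {
      # unordered pairs of distinct occurrences; identical offsets never pair
      within <- sum(findInterval(pi + max_distance + 0.5, pi) -
                      findInterval(pi - max_distance - 0.5, pi)) - length(pi)
      dup <- table(pi)
      same_offset <- sum(dup * (dup - 1))
      (within - same_offset) / 2
    } else {
      sum(findInterval(pj + max_distance + 0.5, pi) -
            findInterval(pj - max_distance - 0.5, pi))
    }
  })
}

hamming_ball_cache <- new.env(parent = emptyenv())

# Indicator matrix B with B[g, f] = 1 iff Hamming distance(g, f) <= m over
# all 4^k k-mers (lexicographic order). Cached; k <= 8 is precomputable in
# memory, larger k falls back to a per-position accumulation as well (same
# code path) but is not cached.
hamming_ball_matrix <- function(k, m) {
  key <- sprintf("k%d_m%d", k, m)
  if (!is.null(hamming_ball_cache[[key]])) return(hamming_ball_cache[[key]])
  n <- 4^k
  digits <- matrix(0L, nrow = n, ncol = k)
  v <- 0:(n - 1)
  for (j in k:1) {
    digits[, j] <- v %% 4L
    v <- v %/% 4L
  }
  dist <- matrix(0L, n, n)
  for (j in seq_len(k)) {
    dist <- dist + outer(digits[, j], digits[, j], "!=")
  }
  b <- (dist <= m) * 1
  if (k <= 8) hamming_ball_cache[[key]] <- b
  b
}

#' Build a tidy feature value table
#'
#' Applies a trained feature node to labelled sequences and returns one row
#' per sequence with a `name` column, an optional `class` column (taken from
#' `seqs$class` or the `classes` argument) and one column per feature.
#'
#' @param node A trained `crescan_feature`.
#' @param seqs Sequence tibble, optionally with a `class` column.
#' @param classes Optional character vector of class labels (overrides
#'   `seqs$class`).
#' @return Tibble of feature values.
#' @export
feature_table <- function(node, seqs, classes = NULL) {
  validate_seq_tbl(seqs)
  cls <- classes %||% seqs[["class"]]
  x <- ft_matrix(node, seqs)
  tb <- dplyr::bind_cols(tibble(name = seqs$name), as_tibble(x, .name_repair = "minimal"))
  if (!is.null(cls)) tb <- dplyr::mutate(tb, class = cls, .after = "name")
  tb
}

#' Per-class summary statistics of a feature table
#'
#' @param table Feature table from [feature_table()] with a `class` column.
#' @return Tibble with columns `class`, `feature`, `mean`, `sd`.
#' @export
summary_stats <- function(table) {
  if (!"class" %in% names(table)) abort("feature table has no `class` column")
  table |>
    tidyr::pivot_longer(-c("name", "class"), names_to = "feature",
                        values_to = "value") |>
    dplyr::group_by(.data$class, .data$feature) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
}

#' Differential summary statistics between two classes
#'
#' Ranks features by the difference of class means (positive minus negative),
#' the simplest readout of which features discriminate the classes.
#'
#' @param table Feature table with a `class` column.
#' @param positive,negative Class labels to contrast.
#' @return Tibble with columns `feature`, `mean_diff`, `rank` (1 = largest
#'   positive difference).
#' @export
differential_stats <- function(table, positive, negative) {
  st <- summary_stats(table)
  if (!all(c(positive, negative) %in% st$class)) {
    abort(sprintf("unknown class label: %s",
                  setdiff(c(positive, negative), st$class)[1]))
  }
  wide <- st |>
    dplyr::select("class", "feature", "mean") |>
    tidyr::pivot_wider(names_from = "class", values_from = "mean")
  wide |>
    dplyr::mutate(mean_diff = .data[[positive]] - .data[[negative]]) |>
    dplyr::select("feature", "mean_diff") |>
    dplyr::mutate(rank = rank(-.data$mean_diff, ties.method = "first")) |>
    dplyr::arrange(.data$rank)
}
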