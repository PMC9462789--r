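# A small pure-R trainer for the package's convolutional architectures:
# im2col convolutions with 'same' zero padding and ReLU, average pooling,
# the fixed sliding-average convolution, global max pooling and a dense
# softmax head, trained by per-example SGD with momentum on the
# cross-entropy loss. The backend is pluggable: train_neural() accepts any
# object providing the same train() contract, so an external deep-learning
# engine can stand in without changes elsewhere.

# ---- forward/backward ops --------------------------------------------------

pad_same <- function(w) c(floor((w - 1) / 2), ceiling((w - 1) / 2))

im2col <- function(x, w) {
  # x: L x C, returns L x (w*C) with 'same' zero padding
  L <- nrow(x); C <- ncol(x)
  p <- pad_same(w)
  xp <- rbind(matrix(0, p[1], C), x, matrix(0, p[2], C))
  out <- matrix(0, L, w * C)
  for (j in seq_len(w)) {
    out[, ((j - 1) * C + 1):(j * C)] <- xp[j:(j + L - 1), , drop = FALSE]
  }
  out
}

col2im_grad <- function(dxc, w, L, C) {
  p <- pad_same(w)
  dxp <- matrix(0, L + w - 1, C)
  for (j in seq_len(w)) {
    dxp[j:(j + L - 1), ] <- dxp[j:(j + L - 1), ] +
      dxc[, ((j - 1) * C + 1):(j * C), drop = FALSE]
  }
  dxp[(p[1] + 1):(p[1] + L), , drop = FALSE]
}

sliding_avg <- function(x, w, flip = FALSE) {
  # depthwise sliding mean with 'same' zero padding, weight 1/w
  L <- nrow(x)
  p <- pad_same(w)
  if (flip) p <- rev(p)
  cs <- apply(rbind(0, x), 2, cumsum)   # (L+1) x C
  lo <- pmax(0L, seq_len(L) - 1L - p[1])
  hi <- pmin(L, seq_len(L) + p[2])
  (cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]) / w
}

nn_forward <- function(net, x, keep_cache = FALSE) {
  cache <- list()
  cur <- x
  branch_out <- NULL
  for (i in seq_along(net$ops)) {
    op <- net$ops[[i]]
    if (op$type == "conv") {
      inp <- if (isTRUE(op$branch)) x else cur
      xc <- im2col(inp, op$w)
      pre <- sweep(xc %*% net$weights[[op$id]]$W, 2, net$weights[[op$id]]$b, "+")
      out <- pre * (pre > 0)
      if (keep_cache) cache[[i]] <- list(xc = xc, pre = pre, L = nrow(inp),
                                         C = ncol(inp))
      if (isTRUE(op$branch)) {
        branch_out <- c(branch_out, list(out))
      } else cur <- out
    } else if (op$type == "concat") {
      cur <- do.call(cbind, branch_out)
      if (keep_cache) cache[[i]] <- purrr::map_int(branch_out, ncol)
      branch_out <- NULL
    } else if (op$type == "avg_pool") {
      L2 <- floor(nrow(cur) / op$p)
      idx <- rep(seq_len(L2), each = op$p)
      if (keep_cache) cache[[i]] <- list(L = nrow(cur))
      cur <- rowsum(cur[seq_along(idx), , drop = FALSE], idx) / op$p
    } else if (op$type == "fixed_avg_conv") {
      cur <- sliding_avg(cur, op$w)
    } else if (op$type == "global_max_pool") {
      amax <- max.col(t(cur), ties.method = "first")
      if (keep_cache) cache[[i]] <- list(amax = amax, L = nrow(cur))
      cur <- cur[cbind(amax, seq_len(ncol(cur)))]
    } else if (op$type == "dense_softmax") {
      z <- drop(cur %*% net$weights[[op$id]]$W) + net$weights[[op$id]]$b
      z <- z - max(z)
      p <- exp(z) / sum(exp(z))
      if (keep_cache) cache[[i]] <- list(v = cur)
      cur <- p
    }
  }
  list(prob = cur, cache = cache)
}

nn_backward <- function(net, fw, y_index) {
  # returns gradients per trainable op id; y_index: true class (1-based)
  grads <- list()
  n_ops <- length(net$ops)
  p <- fw$prob
  dz <- p
  dz[y_index] <- dz[y_index] - 1
  dcur <- NULL
  for (i in rev(seq_len(n_ops))) {
    op <- net$ops[[i]]
    if (op$type == "dense_softmax") {
      v <- fw$cache[[i]]$v
      grads[[op$id]] <- list(W = outer(v, dz), b = dz)
      dcur <- drop(net$weights[[op$id]]$W %*% dz)
    } else if (op$type == "global_max_pool") {
      cc <- fw$cache[[i]]
      d <- matrix(0, cc$L, length(cc$amax))
      d[cbind(cc$amax, seq_along(cc$amax))] <- dcur
      dcur <- d
    } else if (op$type == "fixed_avg_conv") {
      dcur <- sliding_avg(dcur, op$w, flip = TRUE)
    } else if (op$type == "avg_pool") {
      L <- fw$cache[[i]]$L
      L2 <- nrow(dcur)
      d <- matrix(0, L, ncol(dcur))
      d[seq_len(L2 * op$p), ] <- dcur[rep(seq_len(L2), each = op$p), ] / op$p
      dcur <- d
    } else if (op$type == "concat") {
      widths <- fw$cache[[i]]
      splits <- split(seq_len(sum(widths)), rep(seq_along(widths), widths))
      dcur <- purrr::map(splits, ~ dcur[, .x, drop = FALSE])  # list per branch
    } else if (op$type == "conv") {
      d <- if (isTRUE(op$branch)) dcur[[op$branch_index]] else dcur
      cc <- fw$cache[[i]]
      dpre <- d * (cc$pre > 0)
      grads[[op$id]] <- list(W = t(cc$xc) %*% dpre, b = colSums(dpre))
      if (!isTRUE(op$branch)) {
        dcur <- col2im_grad(dpre %*% t(net$weights[[op$id]]$W), op$w, cc$L, cc$C)
      }
      # branch convs sit on the input; no input gradient needed
    }
  }
  grads
}

arch_to_ops <- function(arch) {
  has_concat <- any(arch$kind == "concat")
  concat_at <- if (has_concat) which(arch$kind == "concat") else Inf
  ops <- list()
  id <- 0
  bi <- 0
  for (i in seq_len(nrow(arch))) {
    k <- arch$kind[i]
    if (k == "conv") {
      id <- id + 1
      branch <- has_concat && i < concat_at
      if (branch) bi <- bi + 1
      ops[[length(ops) + 1]] <- list(
        type = "conv", id = id, w = arch$width[i],
        c_in = arch$in_channels[i], c_out = arch$filters[i],
        branch = branch, branch_index = if (branch) bi else NA)
    } else if (k == "concat") {
      ops[[length(ops) + 1]] <- list(type = "concat")
    } else if (k == "avg_pool") {
      ops[[length(ops) + 1]] <- list(type = "avg_pool", p = arch$pool[i])
    } else if (k == "fixed_avg_conv") {
      ops[[length(ops) + 1]] <- list(type = "fixed_avg_conv", w = arch$width[i])
    } else if (k == "global_max_pool") {
      ops[[length(ops) + 1]] <- list(type = "global_max_pool")
    } else if (k == "dense_softmax") {
      id <- id + 1
      ops[[length(ops) + 1]] <- list(type = "dense_softmax", id = id,
                                     c_in = arch$in_channels[i],
                                     c_out = arch$out_channels[i])
    }
  }
  ops
}

nn_init <- function(arch, seed) {
  ops <- arch_to_ops(arch)
  weights <- list()
  withr::with_seed(seed, {
    for (op in ops) {
      if (op$type == "conv") {
        fan_in <- op$w * op$c_in
        weights[[op$id]] <- list(
          W = matrix(stats::rnorm(fan_in * op$c_out, sd = sqrt(2 / fan_in)),
                     fan_in, op$c_out),
          b = rep(0, op$c_out))
      } else if (op$type == "dense_softmax") {
        weights[[op$id]] <- list(
          W = matrix(stats::rnorm(op$c_in * op$c_out, sd = sqrt(1 / op$c_in)),
                     op$c_in, op$c_out),
          b = rep(0, op$c_out))
      }
    }
  })
  list(arch = arch, ops = ops, weights = weights)
}

nn_n_parameters <- function(net) {
  sum(purrr::map_dbl(net$weights, ~ length(.x$W) + length(.x$b)))
}

# ---- backend + training ----------------------------------------------------

#' Built-in gradient-descent neural backend
#'
#' Minibatch gradient descent with momentum on the cross-entropy loss
#' (default: full batch, which is stable for the small, heavily averaged
#' architectures this package builds — per-example updates tend to kill the
#' ReLU units behind the global max pool). Any object with the same
#' `train(arch, x_list, y, epochs, seed)` contract can replace it in
#' [train_neural()].
#'
#' @param learning_rate Step size per (averaged) minibatch gradient.
#' @param momentum Momentum coefficient.
#' @param batch_size Examples per update; `Inf` (default) means full batch.
#' @return A backend object for [train_neural()].
#' @export
nn_backend_sgd <- function(learning_rate = 0.3, momentum = 0.9,
                           batch_size = Inf) {
  train_fn <- function(arch, x_list, y_index, epochs, seed) {
    net <- nn_init(arch, seed)
    vel <- purrr::map(net$weights, ~ list(W = .x$W * 0, b = .x$b * 0))
    n <- length(x_list)
    bs <- min(batch_size, n)
    withr::with_seed(seed + 1, {
      for (ep in seq_len(epochs)) {
        ord <- if (bs < n) sample(n) else seq_len(n)
        for (batch in split(ord, ceiling(seq_along(ord) / bs))) {
          acc <- NULL
          for (i in batch) {
            fw <- nn_forward(net, x_list[[i]], keep_cache = TRUE)
            gr <- nn_backward(net, fw, y_index[i])
            if (is.null(acc)) acc <- gr
            else for (id in seq_along(gr)) {
              if (is.null(gr[[id]])) next
              acc[[id]]$W <- acc[[id]]$W + gr[[id]]$W
              acc[[id]]$b <- acc[[id]]$b + gr[[id]]$b
            }
          }
          for (id in seq_along(net$weights)) {
            if (is.null(acc[[id]])) next
            vel[[id]]$W <- momentum * vel[[id]]$W -
              learning_rate * acc[[id]]$W / length(batch)
            vel[[id]]$b <- momentum * vel[[id]]$b -
              learning_rate * acc[[id]]$b / length(batch)
            net$weights[[id]]$W <- net$weights[[id]]$W + vel[[id]]$W
            net$weights[[id]]$b <- net$weights[[id]]$b + vel[[id]]$b
          }
        }
      }
    })
    net
  }
  structure(list(train = train_fn, name = "gd_momentum"),
            class = "crescan_nn_backend")
}

#' Train a convolutional sequence model
#'
#' Extracts fixed windows from the labelled training sequences, one-hot
#' encodes them, and trains the architecture with the given backend. The
#' fitted model plugs into the same scoring, calibration and genome-wide
#' prediction machinery as feature-based models; its sequence score is the
#' softmax probability of the positive class.
#'
#' @param arch A `crescan_architecture`.
#' @param seqs Sequence tibble with a `class` column.
#' @param positive_label Class whose probability is the model score.
#' @param epochs Training epochs (the reference setting for this
#'   architecture family is 350).
#' @param seed Integer seed (weight initialisation and example order).
#' @param step Window step when cutting training sequences (default: the
#'   architecture window, i.e. non-overlapping).
#' @param backend A backend from [nn_backend_sgd()] or a drop-in
#'   replacement; an explicit `NULL` raises a capability error.
#' @return A trained `crescan_sequence_model` carrying the network.
#' @export
train_neural <- function(arch, seqs, positive_label, epochs = 350, seed = 1,
                         step = NULL, backend = nn_backend_sgd()) {
  stopifnot(inherits(arch, "crescan_architecture"))
  if (is.null(backend)) {
    abort("no neural backend available: supply nn_backend_sgd() or a drop-in")
  }
  validate_seq_tbl(seqs)
  if (!"class" %in% names(seqs)) abort("training sequences need a `class` column")
  classes <- sort(unique(seqs$class))
  if (length(classes) < 2) abort("neural training needs at least 2 classes")
  if (length(classes) != attr(arch, "classes")) {
    abort(sprintf("architecture has %d output classes but data has %d: rebuild with classes = %d",
                  attr(arch, "classes"), length(classes), length(classes)))
  }
  if (!positive_label %in% classes) {
    abort(sprintf("positive label '%s' absent from training labels", positive_label))
  }
  window <- attr(arch, "window")
  step <- step %||% window
  wins <- slide_windows(seqs, window, step) |>
    dplyr::left_join(dplyr::select(seqs, "name", "class"), by = "name")
  if (nrow(wins) == 0) abort("no training windows: sequences shorter than the window")
  x_list <- purrr::map(wins$seq, one_hot)
  y_index <- match(wins$class, classes)
  net <- backend$train(arch, x_list, y_index, epochs, seed)
  net$classes <- classes
  net$positive_label <- positive_label
  model <- structure(list(features = NULL, base = NULL, network = net,
                          window = window, step = 250L, aggregation = "max",
                          positive_label = positive_label, threshold = NULL,
                          trained = TRUE),
                     class = "crescan_sequence_model")
  model
}

# Score fixed-length windows with a trained network (positive-class prob).
nn_score <- function(net, wins) {
  k <- match(net$positive_label, net$classes)
  purrr::map_dbl(wins, function(s) {
    x <- one_hot(s)
    w <- attr(net$arch, "window")
    if (nrow(x) < w) x <- rbind(x, matrix(0, w - nrow(x), 4))
    nn_forward(net, x)$prob[k]
  })
}

#' Class probabilities from a trained network model
#'
#' @param model A network `crescan_sequence_model` from [train_neural()].
#' @param seqs Sequence tibble (each scored as a single window).
#' @return Tibble with `name` and one probability column per class (rows sum
#'   to 1).
#' @export
predict_proba <- function(model, seqs) {
  stopifnot(inherits(model, "crescan_sequence_model"), !is.null(model$network))
  validate_seq_tbl(seqs)
  net <- model$network
  probs <- purrr::map(seqs$seq, function(s) {
    x <- one_hot(s)
    w <- attr(net$arch, "window")
    if (nrow(x) < w) x <- rbind(x, matrix(0, w - nrow(x), 4))
    nn_forward(net, x)$prob
  })
  m <- do.call(rbind, probs)
  colnames(m) <- net$classes
  dplyr::bind_cols(tibble(name = seqs$name), as_tibble(m))
}
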