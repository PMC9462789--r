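# Generative background models: i.i.d. nucleotide model and nth-order Markov
# chains. Used to produce "dummy" negative training sequences (e.g. dummy
# CREs preserving low-order k-mer composition) and calibration backgrounds.
# k-mer counting is delegated to Biostrings::oligonucleotideFrequency, which
# skips windows containing N.

DNA_BASES <- c("A", "C", "G", "T")

all_kmers <- function(k) {
  if (k == 0) return("")
  do.call(paste0, rev(purrr::map(seq_len(k), function(i) {
    rep(DNA_BASES, each = 4^(i - 1), times = 4^(k - i))
  })))
}

count_kmers <- function(seqs, k) {
  set <- Biostrings::DNAStringSet(seqs$seq)
  m <- Biostrings::oligonucleotideFrequency(set, width = k)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(m)))
  colSums(m)
}

#' Train an i.i.d. nucleotide model
#'
#' Estimates per-base probabilities from the pooled base counts of the
#' training sequences, with an additive pseudocount per base; `N` positions
#' are skipped.
#'
#' @param seqs Sequence tibble.
#' @param pseudocount Additive count per base (default 1).
#' @return An object of class `crescan_iid` with element `p`, a named
#'   probability vector over `A, C, G, T`.
#' @export
train_iid <- function(seqs, pseudocount = 1) {
  validate_seq_tbl(seqs)
  stopifnot(pseudocount >= 0)
  counts <- count_kmers(seqs, 1)
  total <- sum(counts) + 4 * pseudocount
  if (total == 0) abort("cannot train i.i.d. model: no bases and pseudocount 0")
  structure(list(kind = "iid", p = (counts + pseudocount) / total,
                 pseudocount = pseudocount),
            class = c("crescan_iid", "crescan_seq_model"))
}

#' Train an nth-order Markov chain on DNA sequences
#'
#' Transition probabilities are estimated from all (context, next-base) pairs
#' not containing `N`, with an additive pseudocount per transition cell; the
#' initial distribution is the empirical n-mer frequency (plus pseudocount).
#' With `add_reverse_complement = TRUE` the reverse complement of every
#' training sequence is counted as well, enforcing strand symmetry.
#'
#' @param seqs Sequence tibble.
#' @param order Markov order `n >= 1` (each base depends on the preceding
#'   `n` bases). Orders 4-7 are typical for genomic background models.
#' @param pseudocount Additive count per transition cell (default 1; avoids
#'   zero-probability dead ends on small training sets).
#' @param add_reverse_complement Also count reverse-complemented training
#'   sequences (default `FALSE`).
#' @return An object of class `crescan_markov` with elements `order`,
#'   `transition` (a `4^order x 4` row-stochastic matrix, rownames the
#'   contexts) and `initial` (probability vector over n-mers).
#' @export
train_markov <- function(seqs, order, pseudocount = 1,
                         add_reverse_complement = FALSE) {
  validate_seq_tbl(seqs)
  stopifnot(order >= 1, pseudocount >= 0)
  if (add_reverse_complement) {
    seqs <- tibble(name = c(seqs$name, paste0(seqs$name, "_rc")),
                   seq = c(seqs$seq, revcomp(seqs$seq)))
  }
  counts <- count_kmers(seqs, order + 1)
  if (sum(counts) == 0 && pseudocount == 0) {
    abort("cannot train Markov model: no valid (context, next) pairs and pseudocount 0")
  }
  tm <- matrix(counts, ncol = 4, byrow = TRUE,
               dimnames = list(all_kmers(order), DNA_BASES))
  tm <- tm + pseudocount
  rs <- rowSums(tm)
  unseen <- rs == 0
  tm[!unseen, ] <- tm[!unseen, , drop = FALSE] / rs[!unseen]
  tm[unseen, ] <- NA_real_   # resolved to uniform (with a message) at generation
  init <- count_kmers(seqs, order) + pseudocount
  if (sum(init) == 0) init <- init + 1
  structure(list(kind = "markov", order = as.integer(order),
                 transition = tm, initial = init / sum(init),
                 pseudocount = pseudocount),
            class = c("crescan_markov", "crescan_seq_model"))
}

#' Generate sequences from a trained background model
#'
#' Draws `count` sequences of exactly `length` bases over `A,C,G,T` from an
#' i.i.d. or Markov model. For a Markov model the first `order` bases are
#' sampled from the initial n-mer distribution and the remainder from the
#' transition distributions. Identical seeds give identical output.
#'
#' @param model A `crescan_iid` or `crescan_markov` model.
#' @param length Sequence length in bp.
#' @param count Number of sequences.
#' @param seed Integer seed.
#' @param prefix Name prefix for the generated records.
#' @return Sequence tibble of `count` records.
#' @export
generate_sequences <- function(model, length, count, seed, prefix = "gen") {
  stopifnot(inherits(model, "crescan_seq_model"), length >= 1, count >= 0)
  withr::with_seed(seed, {
    if (inherits(model, "crescan_iid")) {
      seqs <- purrr::map_chr(seq_len(count), function(i) {
        paste(sample(DNA_BASES, length, replace = TRUE, prob = model$p),
              collapse = "")
      })
    } else {
      stopifnot(length >= model$order)
      tm <- model$transition
      if (anyNA(tm)) {
        inform("Markov model has unseen contexts; drawing uniformly when reached")
        tm[is.na(tm)] <- 0.25
      }
      cum <- tm %*% upper.tri(diag(4), diag = TRUE)   # row-wise cumulative
      c1 <- cum[, 1]; c2 <- cum[, 2]; c3 <- cum[, 3]
      n_ctx <- nrow(tm)
      ctx_of <- function(kmer) {
        # lexicographic index (0-based) of an n-mer
        sum((match(stringr::str_split_1(kmer, ""), DNA_BASES) - 1L) *
              4^((model$order - 1):0))
      }
      kmers <- rownames(tm)
      seqs <- purrr::map_chr(seq_len(count), function(i) {
        first <- sample(kmers, 1, prob = model$initial)
        n_rest <- length - model$order
        if (n_rest == 0) return(first)
        u <- runif(n_rest)
        out <- integer(n_rest)
        ctx <- ctx_of(first)
        for (j in seq_len(n_rest)) {
          b <- 1L + (u[j] > c1[ctx + 1L]) + (u[j] > c2[ctx + 1L]) +
            (u[j] > c3[ctx + 1L])
          out[j] <- b
          ctx <- (ctx * 4L + (b - 1L)) %% n_ctx
        }
        paste0(first, paste(DNA_BASES[out], collapse = ""))
      })
    }
    tibble(name = paste0(prefix, "_", seq_len(count)), seq = seqs)
  })
}

#' Save or load a background model as JSON
#'
#' Models are serialised to a small documented JSON layout (`kind`, `order`,
#' `pseudocount`, probability tables) so they can be versioned alongside
#' analyses.
#'
#' @param model A `crescan_iid` or `crescan_markov` model.
#' @param path JSON file path.
#' @return `save_seq_model()` returns `path` invisibly; `load_seq_model()`
#'   returns the model.
#' @export
save_seq_model <- function(model, path) {
  stopifnot(inherits(model, "crescan_seq_model"))
  obj <- list(kind = model$kind, pseudocount = model$pseudocount)
  if (model$kind == "iid") {
    obj$p <- as.list(model$p)
  } else {
    obj$order <- model$order
    obj$initial <- as.list(model$initial)
    obj$transition <- purrr::map(setNames(seq_len(nrow(model$transition)),
                                          rownames(model$transition)),
                                 ~ unname(model$transition[.x, ]))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_seq_model
#' @export
load_seq_model <- function(path) {
  obj <- jsonlite::read_json(path)
  if (obj$kind == "iid") {
    structure(list(kind = "iid",
                   p = setNames(purrr::map_dbl(obj$p, identity), names(obj$p)),
                   pseudocount = obj$pseudocount),
              class = c("crescan_iid", "crescan_seq_model"))
  } else {
    tm <- do.call(rbind, purrr::map(obj$transition, ~ purrr::map_dbl(.x, identity)))
    dimnames(tm) <- list(names(obj$transition), DNA_BASES)
    structure(list(kind = "markov", order = as.integer(obj$order),
                   transition = tm,
                   initial = setNames(purrr::map_dbl(obj$initial, identity),
                                      names(obj$initial)),
                   pseudocount = obj$pseudocount),
              class = c("crescan_markov", "crescan_seq_model"))
  }
}
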