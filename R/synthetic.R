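# Synthetic genomes with planted CREs. The generator emulates the study
# design the rest of the package is built for: a Markov-chain genomic
# background, a set of fixed-length elements carrying co-occurring motif
# pairs within a pairing cut-off distance, and noisy "biomarker" peak tracks
# surrounding the true elements. Ground truth is recorded exactly, so
# recovery can be measured end to end without any external data.

#' Example CRE-associated motif set
#'
#' A small built-in IUPAC motif set in the style of the classic Polycomb
#' response element motifs (GA-repeat, PHO-like, GT-repeat cores), read from
#' the package's `extdata/motifs_example.tsv`. Used as the default motif set
#' by the synthetic-genome generator and the command-line tools.
#'
#' @return List of `crescan_motif` objects.
#' @export
default_pre_motifs <- function() {
  read_motifs_tsv(system.file("extdata", "motifs_example.tsv",
                              package = "crescan", mustWork = TRUE))
}

#' Specify a synthetic genome with planted CREs
#'
#' Defaults describe a compact but realistic testbed: a 2 Mb genome over two
#' chromosomes with a 4th-order Markov background at fly-like GC content,
#' 40 planted elements of 1 kb, each seeded with 8 motif pairs (one
#' occurrence of each of two distinct motifs, their starts within the 219 bp
#' pairing cut-off — the motif-cluster density characteristic of real
#' regulatory elements of this kind), and four noisy marker tracks covering
#' each element with probability 0.9.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param background_order Order of the Markov background model.
#' @param gc Background GC content (default 0.42).
#' @param n_cres Number of planted elements.
#' @param cre_length Element length in bp.
#' @param motifs List of exactly two `crescan_motif` IUPAC motifs planted as
#'   pairs (defaults to the GA-repeat and PHO-like motifs of
#'   [default_pre_motifs()]).
#' @param pairs_per_cre Motif pairs planted per element.
#' @param pairing_distance Maximum planted pair separation in bp.
#' @param min_gap Minimum spacing between planted elements in bp.
#' @param n_markers Number of synthetic biomarker tracks.
#' @param marker_prob Probability that a marker covers an element.
#' @param marker_jitter Maximum extension of marker peaks beyond the element
#'   boundaries in bp.
#' @return A `crescan_synthetic_spec` list.
#' @export
synthetic_genome_spec <- function(chrom_lengths = c(chrL = 1e6, chrR = 1e6),
                                  background_order = 4, gc = 0.42,
                                  n_cres = 40, cre_length = 1000,
                                  motifs = NULL, pairs_per_cre = 8,
                                  pairing_distance = 219, min_gap = 5000,
                                  n_markers = 4, marker_prob = 0.9,
                                  marker_jitter = 500) {
  motifs <- motifs %||% {
    all <- default_pre_motifs()
    nm <- purrr::map_chr(all, "name")
    list(all[[match("GA_repeat", nm)]], all[[match("PHO_extended", nm)]])
  }
  stopifnot(length(motifs) == 2, n_cres >= 1, cre_length >= 100,
            pairs_per_cre >= 1, pairing_distance >= 10)
  if (n_cres * (cre_length + min_gap) >= sum(chrom_lengths)) {
    abort("infeasible packing: planted elements plus gaps exceed genome length")
  }
  structure(list(chrom_lengths = chrom_lengths,
                 background_order = background_order, gc = gc,
                 n_cres = n_cres, cre_length = cre_length, motifs = motifs,
                 pairs_per_cre = pairs_per_cre,
                 pairing_distance = pairing_distance, min_gap = min_gap,
                 n_markers = n_markers, marker_prob = marker_prob,
                 marker_jitter = marker_jitter),
            class = "crescan_synthetic_spec")
}

sample_iupac_instance <- function(pattern) {
  chars <- stringr::str_split_1(pattern, "")
  paste(purrr::map_chr(chars, function(ch) {
    opts <- IUPAC_SETS[[ch]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }), collapse = "")
}

#' Generate a synthetic genome with planted CREs
#'
#' Produces, fully reproducibly under `seed`: the genome (background drawn
#' from a Markov chain trained on an i.i.d. seed sequence at the requested
#' GC content), the exact truth regions of the planted elements (each
#' carrying `pairs_per_cre` co-occurring motif pairs within the pairing
#' distance), and `n_markers` noisy peak tracks around the truth regions.
#'
#' @param spec A `crescan_synthetic_spec`.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with elements `genome` (sequence tibble), `truth` (region
#'   tibble, one labelled record per element), `markers` (list of region
#'   tibbles) and `background` (the trained `crescan_markov` model).
#' @export
generate_synthetic_genome <- function(spec, seed) {
  stopifnot(inherits(spec, "crescan_synthetic_spec"))
  p <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2, G = spec$gc / 2,
         T = (1 - spec$gc) / 2)
  iid <- structure(list(kind = "iid", p = p, pseudocount = 0),
                   class = c("crescan_iid", "crescan_seq_model"))
  seed_seqs <- generate_sequences(iid, 2e5, 1, seed = seed, prefix = "seed")
  background <- train_markov(seed_seqs, spec$background_order, pseudocount = 1)
  chroms <- purrr::imap(spec$chrom_lengths, function(L, nm) {
    generate_sequences(background, L, 1,
                       seed = seed + 1 + match(nm, names(spec$chrom_lengths)),
                       prefix = nm)$seq
  })
  # allocate elements to chromosomes proportionally, place one per slot
  n_per <- round(spec$n_cres * spec$chrom_lengths / sum(spec$chrom_lengths))
  while (sum(n_per) < spec$n_cres) n_per[which.max(spec$chrom_lengths)] <-
    n_per[which.max(spec$chrom_lengths)] + 1
  while (sum(n_per) > spec$n_cres) n_per[which.max(n_per)] <-
    n_per[which.max(n_per)] - 1
  truth <- list()
  withr::with_seed(seed + 100, {
    for (ci in seq_along(chroms)) {
      n <- n_per[ci]
      if (n == 0) next
      L <- spec$chrom_lengths[ci]
      slot <- floor(L / n)
      if (slot < spec$cre_length + spec$min_gap) {
        abort("infeasible packing on a chromosome: reduce n_cres or min_gap")
      }
      for (k in seq_len(n)) {
        lo <- (k - 1) * slot
        start <- lo + sample.int(slot - spec$cre_length - spec$min_gap, 1)
        cre <- plant_motif_pairs(
          stringr::str_sub(chroms[[ci]], start + 1, start + spec$cre_length),
          spec)
        stringr::str_sub(chroms[[ci]], start + 1,
                         start + spec$cre_length) <- cre
        truth[[length(truth) + 1]] <- tibble(
          seqname = names(spec$chrom_lengths)[ci],
          start = as.integer(start), end = as.integer(start + spec$cre_length))
      }
    }
  })
  truth <- dplyr::bind_rows(truth)
  truth <- regions(truth$seqname, truth$start, truth$end,
                   label = paste0("CRE_", seq_len(nrow(truth))))
  markers <- withr::with_seed(seed + 200, {
    purrr::map(seq_len(spec$n_markers), function(mi) {
      cover <- runif(nrow(truth)) < spec$marker_prob
      if (!any(cover)) return(empty_regions())
      tt <- truth[cover, , drop = FALSE]
      ext_l <- floor(runif(nrow(tt)) * spec$marker_jitter)
      ext_r <- floor(runif(nrow(tt)) * spec$marker_jitter)
      regions_merge(regions(tt$seqname, pmax(0, tt$start - ext_l),
                            tt$end + ext_r))
    })
  })
  list(genome = dna_tbl(names(spec$chrom_lengths), unlist(chroms)),
       truth = truth, markers = markers, background = background)
}

plant_motif_pairs <- function(cre_seq, spec) {
  len <- nchar(cre_seq)
  block <- floor(len / spec$pairs_per_cre)
  w1 <- spec$motifs[[1]]$width
  w2 <- spec$motifs[[2]]$width
  for (b in seq_len(spec$pairs_per_cre)) {
    lo <- (b - 1) * block
    max_delta <- min(spec$pairing_distance, block - w1 - w2 - 2)
    a <- lo + sample.int(max(1, block - w1 - max_delta - w2), 1) - 1
    delta <- w1 + 1 + sample.int(max(1, max_delta - w1 - 1), 1)
    inst1 <- sample_iupac_instance(spec$motifs[[1]]$pattern)
    inst2 <- sample_iupac_instance(spec$motifs[[2]]$pattern)
    stringr::str_sub(cre_seq, a + 1, a + w1) <- inst1
    stringr::str_sub(cre_seq, a + delta + 1, a + delta + w2) <- inst2
  }
  cre_seq
}
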