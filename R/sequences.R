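# DNA sequences are plain tibbles with columns `name` and `seq`. Sequences are
# stored uppercase over the alphabet {A,C,G,T,N}; all functions in the package
# that accept sequences take such a tibble as their first argument.

SEQ_ALPHABET <- c("A", "C", "G", "T", "N")

#' Construct a tibble of DNA sequences
#'
#' The canonical sequence container used throughout the package: one row per
#' sequence, columns `name` and `seq`. Input sequences are uppercased and
#' validated against the alphabet `A, C, G, T, N`.
#'
#' @param name Character vector of sequence labels.
#' @param seq Character vector of DNA sequences (case-insensitive).
#' @return A tibble with columns `name` and `seq`.
#' @examples
#' dna_tbl(c("a", "b"), c("acgt", "NNN"))
#' @export
dna_tbl <- function(name, seq) {
  seq <- toupper(seq)
  bad <- stringr::str_detect(seq, "[^ACGTN]")
  if (any(bad)) {
    offending <- stringr::str_extract(seq[bad][1], "[^ACGTN]")
    abort(sprintf("sequence '%s' contains non-IUPAC character '%s'",
                  name[bad][1], offending))
  }
  tibble(name = unname(as.character(name)), seq = unname(seq))
}

validate_seq_tbl <- function(seqs, arg = "seqs") {
  if (!is.data.frame(seqs) || !all(c("name", "seq") %in% names(seqs))) {
    abort(sprintf("`%s` must be a data frame with columns `name` and `seq`", arg))
  }
  invisible(seqs)
}

#' Read sequences from a FASTA file
#'
#' Loads a (optionally gzip-compressed) FASTA file into a sequence tibble.
#' Whitespace inside sequence lines is stripped and bases are uppercased.
#'
#' @param path Path to a FASTA file (`.gz` handled transparently).
#' @return A tibble with columns `name` and `seq`.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) abort(sprintf("malformed FASTA '%s': %s", path,
                                      conditionMessage(e)))
  )
  nm <- stringr::str_trim(names(set))
  seqs <- toupper(as.character(set))
  bad <- stringr::str_detect(seqs, "[^ACGTN]")
  if (any(bad)) {
    # locate the first offending line for the error message
    lines <- readr::read_lines(path)
    idx <- which(stringr::str_detect(toupper(lines), "[^ACGTN>\\s]") &
                   !stringr::str_starts(lines, ">"))
    abort(sprintf("non-IUPAC characters in FASTA '%s' (line %s)", path,
                  if (length(idx)) idx[1] else "?"))
  }
  dna_tbl(nm, seqs)
}

#' Write sequences to a FASTA file
#'
#' Sequences are wrapped at 80 columns; `read_fasta(write_fasta(x))` restores
#' `x` exactly (modulo line wrapping of the source file).
#'
#' @param seqs Sequence tibble (columns `name`, `seq`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  validate_seq_tbl(seqs)
  set <- Biostrings::DNAStringSet(seqs$seq)
  names(set) <- seqs$name
  Biostrings::writeXStringSet(set, path, width = 80)
  invisible(path)
}

#' Reverse-complement DNA strings
#'
#' @param x Character vector of sequences over `A,C,G,T,N`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract sliding windows from sequences
#'
#' Slides a fixed-length window along every sequence. Windows never span two
#' source sequences; a sequence shorter than `window` yields no windows. For a
#' sequence of length `L >= window` the number of windows is
#' `floor((L - window) / step) + 1`.
#'
#' @param seqs Sequence tibble.
#' @param window Window length in bp.
#' @param step Step between window starts in bp.
#' @return Tibble with columns `name`, `start` (0-based window offset) and
#'   `seq` (the window sequence, exactly `window` bp).
#' @export
slide_windows <- function(seqs, window, step) {
  validate_seq_tbl(seqs)
  stopifnot(window >= 1, step >= 1)
  res <- purrr::map2(seqs$name, seqs$seq, function(nm, s) {
    L <- nchar(s)
    if (L < window) return(NULL)
    starts <- seq(0L, L - window, by = step)
    tibble(name = nm, start = starts,
           seq = stringr::str_sub(s, starts + 1L, starts + window))
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) out <- tibble(name = character(), start = integer(),
                                    seq = character())
  out
}

#' Stream sliding windows in bounded-memory chunks
#'
#' Equivalent to [slide_windows()] but the caller supplies a function that is
#' invoked once per chunk of windows, so no more than roughly
#' `chunk_size + window` bases of any one sequence are materialised as windows
#' at a time. Useful for genome-wide scans.
#'
#' @inheritParams slide_windows
#' @param callback Function called with a tibble of windows (as from
#'   [slide_windows()]) once per chunk; its return values are collected in a
#'   list.
#' @param chunk_size Buffering granularity in bp (default 1e6).
#' @return Invisibly, the list of callback return values.
#' @export
stream_windows <- function(seqs, window, step, callback, chunk_size = 1e6) {
  validate_seq_tbl(seqs)
  stopifnot(window >= 1, step >= 1, chunk_size >= window)
  results <- list()
  for (i in seq_len(nrow(seqs))) {
    nm <- seqs$name[i]
    L <- nchar(seqs$seq[i])
    if (L < window) next
    starts <- seq(0L, L - window, by = step)
    n_per_chunk <- max(1L, floor((chunk_size - window) / step) + 1L)
    chunk_idx <- split(starts, ceiling(seq_along(starts) / n_per_chunk))
    for (ck in chunk_idx) {
      wins <- tibble(
        name = nm, start = as.integer(ck),
        seq = stringr::str_sub(seqs$seq[i], ck + 1L, ck + window)
      )
      results[[length(results) + 1L]] <- callback(wins)
    }
  }
  invisible(results)
}

#' Concatenate sequences and split into fixed-length fragments
#'
#' All input sequences are concatenated in order and the concatenation is cut
#' into consecutive non-overlapping fragments of exactly `length` bp; a
#' trailing remainder shorter than `length` is dropped. This mirrors the
#' standard preparation of coding-sequence training fragments.
#'
#' @param seqs Sequence tibble.
#' @param length Fragment length in bp.
#' @param prefix Name prefix for output fragments.
#' @return Sequence tibble of fragments named `<prefix>_1 ...`.
#' @export
fragment_sequences <- function(seqs, length, prefix = "frag") {
  validate_seq_tbl(seqs)
  stopifnot(length >= 1)
  cat_seq <- paste(seqs$seq, collapse = "")
  n <- floor(nchar(cat_seq) / length)
  if (n == 0) return(tibble(name = character(), seq = character()))
  starts <- (seq_len(n) - 1L) * length + 1L
  tibble(name = paste0(prefix, "_", seq_len(n)),
         seq = stringr::str_sub(cat_seq, starts, starts + length - 1L))
}

#' One-hot encode a DNA sequence
#'
#' Encodes a sequence as an `L x 4` indicator matrix with column order
#' `A, C, G, T`. `N` positions encode as all-zero rows so that unknown bases
#' contribute no signal to downstream convolutions.
#'
#' @param seq A single sequence string over `A,C,G,T,N`.
#' @return Numeric matrix of dimension `nchar(seq) x 4`, columns named
#'   `A, C, G, T`.
#' @export
one_hot <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  chars <- stringr::str_split_1(toupper(seq), "")
  idx <- match(chars, c("A", "C", "G", "T"))
  if (any(is.na(idx) & chars != "N")) {
    abort(sprintf("cannot one-hot encode character '%s'",
                  chars[is.na(idx) & chars != "N"][1]))
  }
  m <- matrix(0, nrow = length(chars), ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  ok <- which(!is.na(idx))
  m[cbind(ok, idx[ok])] <- 1
  m
}
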