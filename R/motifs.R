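# Motif models and occurrence search. IUPAC motifs are scanned with a
# vectorized shifted-comparison matcher (cost O(width x L) per sequence);
# PWMs score one-hot columns and report offsets at or above their threshold.
# An `N` in the scanned sequence matches nothing: unknown bases never create
# motif occurrences.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N")

#' Define sequence motifs
#'
#' `motif_iupac()` defines a motif as a degenerate-code string over the
#' 15-letter IUPAC nucleotide alphabet. `motif_pwm()` defines a position
#' weight matrix motif: a `4 x w` matrix of log-odds weights (rows
#' `A, C, G, T`) with an occurrence threshold on the summed weight. PWM score
#' scaling is caller-defined, so the threshold is a mandatory argument.
#'
#' @param name Motif name.
#' @param pattern IUPAC string (e.g. `"GAGAG"`).
#' @param matrix `4 x w` numeric matrix of per-position weights, rows in
#'   `A, C, G, T` order.
#' @param threshold Minimum summed weight for an occurrence.
#' @return A `crescan_motif` object.
#' @examples
#' motif_iupac("GAF", "GAGAG")
#' @export
motif_iupac <- function(name, pattern) {
  pattern <- toupper(pattern)
  chars <- stringr::str_split_1(pattern, "")
  if (!all(chars %in% names(IUPAC_SETS))) {
    abort(sprintf("invalid IUPAC character '%s' in motif '%s'",
                  chars[!chars %in% names(IUPAC_SETS)][1], name))
  }
  structure(list(name = name, kind = "iupac", pattern = pattern,
                 width = nchar(pattern)),
            class = "crescan_motif")
}

#' @rdname motif_iupac
#' @export
motif_pwm <- function(name, matrix, threshold) {
  stopifnot(is.matrix(matrix), nrow(matrix) == 4, ncol(matrix) >= 1,
            is.numeric(threshold))
  rownames(matrix) <- DNA_BASES
  structure(list(name = name, kind = "pwm", matrix = matrix,
                 threshold = threshold, width = ncol(matrix)),
            class = "crescan_motif")
}

#' Read an IUPAC motif set from a tab-separated file
#'
#' Expects two columns, `name` and IUPAC `pattern`, no header; lines starting
#' with `#` are skipped.
#'
#' @param path File path.
#' @return List of `crescan_motif` objects.
#' @export
read_motifs_tsv <- function(path) {
  tb <- readr::read_tsv(path, col_names = c("name", "pattern"),
                        comment = "#", col_types = "cc")
  purrr::map2(tb$name, tb$pattern, motif_iupac)
}

encode_bases <- function(seq) {
  # integer codes 1..4 for ACGT, 5 for N
  x <- match(stringr::str_split_1(seq, ""), c(DNA_BASES, "N"))
  if (anyNA(x)) abort("sequence contains characters outside {A,C,G,T,N}")
  x
}

revcomp_iupac <- function(pattern) {
  chars <- rev(stringr::str_split_1(pattern, ""))
  paste(IUPAC_COMPLEMENT[chars], collapse = "")
}

scan_iupac_codes <- function(codes, pattern) {
  w <- nchar(pattern)
  L <- length(codes)
  if (L < w) return(integer(0))
  chars <- stringr::str_split_1(pattern, "")
  acc <- rep(TRUE, L - w + 1L)
  for (j in seq_len(w)) {
    ok <- c(DNA_BASES %in% IUPAC_SETS[[chars[j]]], FALSE)   # N matches nothing
    acc <- acc & ok[codes[j:(j + L - w)]]
  }
  which(acc) - 1L   # 0-based offsets
}

scan_pwm_codes <- function(codes, matrix, threshold) {
  w <- ncol(matrix)
  L <- length(codes)
  if (L < w) return(integer(0))
  score <- numeric(L - w + 1L)
  wt <- rbind(matrix, -Inf)   # row 5: N contributes -Inf
  for (j in seq_len(w)) {
    score <- score + wt[cbind(codes[j:(j + L - w)], j)]
  }
  which(score >= threshold) - 1L
}

revcomp_pwm <- function(m) m[4:1, ncol(m):1, drop = FALSE]

scan_motif_one <- function(codes, motif, strands) {
  fwd <- if (motif$kind == "iupac") scan_iupac_codes(codes, motif$pattern)
         else scan_pwm_codes(codes, motif$matrix, motif$threshold)
  pos <- fwd
  strand <- rep("+", length(fwd))
  if (strands == "both") {
    rev_hits <- if (motif$kind == "iupac") {
      scan_iupac_codes(codes, revcomp_iupac(motif$pattern))
    } else {
      scan_pwm_codes(codes, revcomp_pwm(motif$matrix), motif$threshold)
    }
    pos <- c(pos, rev_hits)
    strand <- c(strand, rep("-", length(rev_hits)))
  }
  o <- order(pos, strand)
  list(pos = pos[o], strand = strand[o])
}

#' Scan sequences for motif occurrences
#'
#' Reports every offset at which the motif occurs, including overlapping
#' occurrences (tandem repeats are real occurrences here). In `"both"` mode
#' the reverse strand is scanned as well and minus-strand occurrences are
#' reported at their forward (leftmost) coordinate.
#'
#' @param seqs Sequence tibble.
#' @param motif A `crescan_motif`.
#' @param strands `"both"` (default) or `"forward"`.
#' @return Tibble with columns `name`, `pos` (0-based occurrence offset) and
#'   `strand`.
#' @export
scan_motif <- function(seqs, motif, strands = c("both", "forward")) {
  validate_seq_tbl(seqs)
  strands <- match.arg(strands)
  stopifnot(inherits(motif, "crescan_motif"))
  res <- purrr::map2(seqs$name, seqs$seq, function(nm, s) {
    hits <- scan_motif_one(encode_bases(s), motif, strands)
    tibble(name = nm, pos = as.integer(hits$pos), strand = hits$strand)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) out <- tibble(name = character(), pos = integer(),
                                    strand = character())
  out
}
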