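# 2bit container: 2 bits per base (T=0, C=1, A=2, G=3, most significant bits
# first), N runs and soft-mask runs stored as block lists. Both byte orders
# are accepted; masks are discarded (sequences returned uppercase).

TWOBIT_MAGIC <- 0x1A412743
TWOBIT_BASES <- c("T", "C", "A", "G")

read_u32 <- function(raw, off, endian) {
  # off is 0-based byte offset; returns double (values can exceed .Machine int)
  if (off + 4 > length(raw)) abort("truncated 2bit file")
  b <- as.integer(raw[(off + 1):(off + 4)])
  if (endian == "little") {
    b[1] + b[2] * 256 + b[3] * 65536 + b[4] * 16777216
  } else {
    b[4] + b[3] * 256 + b[2] * 65536 + b[1] * 16777216
  }
}

#' Read a 2bit genome file
#'
#' Decodes a UCSC 2bit container into a sequence tibble. Both byte orders are
#' supported; N-blocks are restored as `N` characters; mask blocks are ignored
#' and sequences are returned uppercase.
#'
#' @param path Path to a 2bit file.
#' @return A tibble with columns `name` and `seq`.
#' @export
read_2bit <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 16) abort("truncated 2bit file: missing header")
  endian <- if (read_u32(raw, 0, "little") == TWOBIT_MAGIC) "little"
            else if (read_u32(raw, 0, "big") == TWOBIT_MAGIC) "big"
            else abort("not a 2bit file: bad magic number")
  n_seq <- read_u32(raw, 8, endian)
  # index: nameSize (1 byte), name, offset (4 bytes) per sequence
  off <- 16
  names <- character(n_seq)
  offsets <- numeric(n_seq)
  for (i in seq_len(n_seq)) {
    if (off + 1 > length(raw)) abort("truncated 2bit file: index")
    nmsize <- as.integer(raw[off + 1])
    names[i] <- rawToChar(raw[(off + 2):(off + 1 + nmsize)])
    offsets[i] <- read_u32(raw, off + 1 + nmsize, endian)
    off <- off + 1 + nmsize + 4
  }
  seqs <- purrr::map_chr(offsets, function(o) decode_2bit_record(raw, o, endian))
  dna_tbl(names, seqs)
}

decode_2bit_record <- function(raw, off, endian) {
  dna_size <- read_u32(raw, off, endian)
  n_blocks <- read_u32(raw, off + 4, endian)
  pos <- off + 8
  n_starts <- purrr::map_dbl(seq_len(n_blocks) - 1, ~ read_u32(raw, pos + 4 * .x, endian))
  pos <- pos + 4 * n_blocks
  n_sizes <- purrr::map_dbl(seq_len(n_blocks) - 1, ~ read_u32(raw, pos + 4 * .x, endian))
  pos <- pos + 4 * n_blocks
  m_blocks <- read_u32(raw, pos, endian)
  pos <- pos + 4 + 8 * m_blocks   # skip mask starts + sizes
  pos <- pos + 4                  # reserved word
  n_bytes <- ceiling(dna_size / 4)
  if (pos + n_bytes > length(raw)) abort("truncated 2bit file: packed data")
  if (dna_size == 0) return("")
  bytes <- as.integer(raw[(pos + 1):(pos + n_bytes)])
  codes <- rbind(bytes %/% 64L, (bytes %/% 16L) %% 4L,
                 (bytes %/% 4L) %% 4L, bytes %% 4L)
  chars <- TWOBIT_BASES[as.vector(codes) + 1L][seq_len(dna_size)]
  for (i in seq_len(n_blocks)) {
    chars[(n_starts[i] + 1):(n_starts[i] + n_sizes[i])] <- "N"
  }
  paste(chars, collapse = "")
}

#' Write sequences to a 2bit file
#'
#' Encodes a sequence tibble as a UCSC 2bit container. `N` runs are recorded
#' as N-blocks (with arbitrary packed bits underneath, here `T`); no mask
#' blocks are written. Primarily useful for preparing compact genome files and
#' round-trip checks of [read_2bit()].
#'
#' @param seqs Sequence tibble.
#' @param path Output path.
#' @param endian Byte order, `"little"` (default) or `"big"`.
#' @return `path`, invisibly.
#' @export
write_2bit <- function(seqs, path, endian = c("little", "big")) {
  validate_seq_tbl(seqs)
  endian <- match.arg(endian)
  u32 <- function(x) {
    b <- c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256)
    if (endian == "big") b <- rev(b)
    as.raw(b)
  }
  records <- purrr::map(seqs$seq, function(s) {
    chars <- stringr::str_split_1(s, "")
    is_n <- chars == "N"
    runs <- rle(is_n)
    run_end <- cumsum(runs$lengths)
    run_start <- run_end - runs$lengths   # 0-based
    n_starts <- run_start[runs$values]
    n_sizes <- runs$lengths[runs$values]
    codes <- match(chars, TWOBIT_BASES) - 1L
    codes[is.na(codes)] <- 0L             # N packed as T under the block
    pad <- (-length(codes)) %% 4
    codes <- c(codes, rep(0L, pad))
    m <- matrix(codes, nrow = 4)
    bytes <- as.raw(m[1, ] * 64L + m[2, ] * 16L + m[3, ] * 4L + m[4, ])
    c(u32(length(chars)), u32(length(n_starts)),
      do.call(c, c(list(raw(0)), purrr::map(n_starts, u32))),
      do.call(c, c(list(raw(0)), purrr::map(n_sizes, u32))),
      u32(0),   # no mask blocks
      u32(0),   # reserved
      bytes)
  })
  index_size <- sum(1 + nchar(seqs$name) + 4)
  header <- c(u32(TWOBIT_MAGIC), u32(0), u32(nrow(seqs)), u32(0))
  offsets <- 16 + index_size + cumsum(c(0, head(purrr::map_int(records, length), -1)))
  index <- do.call(c, c(list(raw(0)), purrr::map(seq_len(nrow(seqs)), function(i) {
    c(as.raw(nchar(seqs$name[i])), charToRaw(seqs$name[i]), u32(offsets[i]))
  })))
  writeBin(c(header, index, do.call(c, c(list(raw(0)), records))), path)
  invisible(path)
}
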