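# Independent brute-force oracles used across the suite. These deliberately
# share no code with the implementation: region algebra is checked against
# per-base bitmaps, spectra against substring dictionaries, motif pairs
# against exhaustive occurrence-pair enumeration.

random_dna <- function(len, seed = NULL, alphabet = c("A", "C", "G", "T")) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# --- per-base bitmap region oracle -----------------------------------------

bitmap_from_regions <- function(r, chrom_len) {
  b <- rep(FALSE, chrom_len)
  for (i in seq_len(nrow(r))) {
    b[(r$start[i] + 1):r$end[i]] <- TRUE
  }
  b
}

regions_from_bitmap <- function(b, seqname = "chr") {
  if (!any(b)) return(crescan::regions())
  runs <- rle(b)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths
  crescan::regions(seqname, starts[runs$values], ends[runs$values])
}

random_region_tbl <- function(n, chrom_len, seqname = "chr", max_width = 200) {
  start <- sample.int(chrom_len - max_width, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  crescan::regions(seqname, start, pmin(start + width, chrom_len))
}

# --- dictionary spectrum oracle --------------------------------------------

oracle_kspectrum <- function(seq, k) {
  kmers <- crescan:::all_kmers(k)
  counts <- setNames(numeric(length(kmers)), kmers)
  L <- nchar(seq)
  if (L >= k) {
    for (i in 1:(L - k + 1)) {
      w <- substr(seq, i, i + k - 1)
      if (!grepl("N", w, fixed = TRUE)) counts[w] <- counts[w] + 1
    }
  }
  counts
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

oracle_mismatch_spectrum <- function(seq, k, m) {
  plain <- oracle_kspectrum(seq, k)
  kmers <- names(plain)
  sapply(kmers, function(f) {
    sum(sapply(kmers, function(g) if (hamming(f, g) <= m) plain[g] else 0))
  })
}

# --- exhaustive motif-pair oracle ------------------------------------------

oracle_iupac_hits <- function(seq, pattern) {
  # via Biostrings degenerate matching (independent of the package scanner)
  hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(seq),
                                   fixed = FALSE)
  BiocGenerics::start(hits) - 1L
}

oracle_motif_occurrences <- function(seq, pattern) {
  fwd <- oracle_iupac_hits(seq, pattern)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
  rev <- oracle_iupac_hits(seq, rc)
  sort(c(fwd, rev))
}

oracle_pair_count <- function(occ_i, occ_j, max_distance, self = FALSE) {
  cnt <- 0
  if (self) {
    n <- length(occ_i)
    if (n < 2) return(0)
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      if (occ_i[a] != occ_i[b] && abs(occ_i[a] - occ_i[b]) <= max_distance) {
        cnt <- cnt + 1
      }
    }
  } else {
    for (a in seq_along(occ_i)) for (b in seq_along(occ_j)) {
      if (abs(occ_i[a] - occ_j[b]) <= max_distance) cnt <- cnt + 1
    }
  }
  cnt
}
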