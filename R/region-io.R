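# Region I/O. Dialects: BED (0-based half-open, native), GFF/GTF (1-based
# inclusive, converted on the fly), and plain coordinate lists
# ("seqname:start..end", 1-based inclusive). Gzipped input is read
# transparently; writers compress when the path ends in .gz.

#' Read genomic regions from a file
#'
#' Parses BED (3-6 columns), GFF/GTF (9 columns; 1-based inclusive
#' coordinates converted to the package's 0-based half-open convention) or a
#' plain coordinate list (`seqname:start..end`, 1-based inclusive). Gzipped
#' files are read transparently. For GFF/GTF the feature column becomes the
#' region `label`; `feature_filter` restricts rows to one feature type (e.g.
#' `"CDS"` when loading coding regions from a gene annotation).
#'
#' @param path Input path (`.gz` allowed).
#' @param dialect One of `"bed"`, `"gff"`, `"gtf"`, `"coords"`.
#' @param feature_filter Optional feature name to keep (GFF/GTF only).
#' @return Region tibble.
#' @seealso [write_regions()]
#' @export
read_regions <- function(path, dialect = c("bed", "gff", "gtf", "coords"),
                         feature_filter = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path)
  keep <- !stringr::str_starts(lines, "#") & stringr::str_trim(lines) != ""
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(empty_regions())
  parse_fail <- function(i, msg) {
    abort(sprintf("%s (%s line %d)", msg, basename(path), lineno[i]))
  }
  if (dialect == "coords") {
    m <- stringr::str_match(lines, "^(\\S+?):(\\d+)\\.\\.(\\d+)$")
    bad <- which(is.na(m[, 1]))
    if (length(bad)) parse_fail(bad[1], "malformed coordinate entry")
    start <- as.integer(m[, 3]) - 1L
    end <- as.integer(m[, 4])
    bad <- which(start >= end | start < 0)
    if (length(bad)) parse_fail(bad[1], "start > end after conversion")
    return(regions(m[, 2], start, end))
  }
  fields <- stringr::str_split(lines, "\t")
  nf <- lengths(fields)
  if (dialect == "bed") {
    bad <- which(nf < 3)
    if (length(bad)) parse_fail(bad[1], "BED line has fewer than 3 columns")
    get <- function(i) purrr::map_chr(fields, ~ if (length(.x) >= i) .x[i] else NA)
    start <- suppressWarnings(as.integer(get(2)))
    end <- suppressWarnings(as.integer(get(3)))
    bad <- which(is.na(start) | is.na(end))
    if (length(bad)) parse_fail(bad[1], "non-numeric BED coordinate")
    bad <- which(start >= end | start < 0)
    if (length(bad)) parse_fail(bad[1], "invalid BED interval")
    score <- suppressWarnings(as.numeric(get(5)))
    strand <- get(6)
    strand[!strand %in% c("+", "-")] <- "*"
    return(regions(get(1), start, end, strand = strand,
                   label = get(4), score = score))
  }
  # GFF / GTF
  bad <- which(nf < 9)
  if (length(bad)) parse_fail(bad[1], sprintf("%s line has fewer than 9 columns",
                                              toupper(dialect)))
  get <- function(i) purrr::map_chr(fields, i)
  start1 <- suppressWarnings(as.integer(get(4)))
  end1 <- suppressWarnings(as.integer(get(5)))
  bad <- which(is.na(start1) | is.na(end1))
  if (length(bad)) parse_fail(bad[1], "non-numeric coordinate")
  start <- start1 - 1L
  bad <- which(start >= end1 | start < 0)
  if (length(bad)) parse_fail(bad[1], "start > end after conversion")
  score <- suppressWarnings(as.numeric(get(6)))
  strand <- get(7)
  strand[!strand %in% c("+", "-")] <- "*"
  r <- regions(get(1), start, end1, strand = strand, label = get(3),
               score = score)
  if (!is.null(feature_filter)) r <- dplyr::filter(r, .data$label == feature_filter)
  r
}

#' Write genomic regions to a file
#'
#' Inverse of [read_regions()]: emits BED (scores/labels/strand when
#' present), GFF (coordinates converted back to 1-based inclusive; the region
#' label is written as the feature column) or a coordinate list. A path
#' ending in `.gz` is gzip-compressed.
#'
#' @param r Region tibble.
#' @param path Output path.
#' @param dialect One of `"bed"`, `"gff"`, `"coords"`.
#' @return `path`, invisibly.
#' @export
write_regions <- function(r, path, dialect = c("bed", "gff", "coords")) {
  dialect <- match.arg(dialect)
  validate_region_tbl(r)
  strand <- if ("strand" %in% names(r)) r$strand else rep("*", nrow(r))
  label <- if ("label" %in% names(r)) r$label else rep(NA_character_, nrow(r))
  score <- if ("score" %in% names(r)) r$score else rep(NA_real_, nrow(r))
  dot <- function(x) ifelse(is.na(x), ".", as.character(x))
  lines <- switch(dialect,
    bed = sprintf("%s\t%d\t%d\t%s\t%s\t%s", r$seqname, r$start, r$end,
                  dot(label), dot(score),
                  ifelse(strand %in% c("+", "-"), strand, ".")),
    gff = sprintf("%s\tcrescan\t%s\t%d\t%d\t%s\t%s\t.\t.",
                  r$seqname, ifelse(is.na(label), "region", label),
                  r$start + 1L, r$end, dot(score),
                  ifelse(strand %in% c("+", "-"), strand, ".")),
    coords = sprintf("%s:%d..%d", r$seqname, r$start + 1L, r$end))
  readr::write_lines(lines, path)
  invisible(path)
}
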