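# Genomic regions are tibbles with columns seqname, start, end, strand,
# label, score. Coordinates are 0-based half-open internally (BED-native);
# GFF/GTF and coordinate-list I/O converts on the way in and out. Interval
# algebra is delegated to GenomicRanges/IRanges behind these tidy wrappers;
# set algebra is strand-blind, sequence extraction honours strand.

#' Construct a region tibble
#'
#' @param seqname Character vector of chromosome/scaffold names.
#' @param start,end Integer coordinates, 0-based half-open (`start < end`).
#' @param strand `"+"`, `"-"` or `"*"` (unstranded, default).
#' @param label Optional character labels.
#' @param score Optional numeric scores.
#' @return A tibble sorted by (seqname, start, end) with columns `seqname`,
#'   `start`, `end`, `strand`, `label`, `score`.
#' @examples
#' regions("chr1", c(0, 50), c(10, 80))
#' @export
regions <- function(seqname = character(), start = integer(), end = integer(),
                    strand = "*", label = NA_character_, score = NA_real_) {
  r <- tibble(seqname = as.character(seqname),
              start = as.integer(start), end = as.integer(end),
              strand = strand, label = as.character(label),
              score = as.numeric(score))
  if (any(r$start < 0 | r$start >= r$end)) {
    i <- which(r$start < 0 | r$start >= r$end)[1]
    abort(sprintf("invalid region %s:%d-%d (need 0 <= start < end)",
                  r$seqname[i], r$start[i], r$end[i]))
  }
  sort_regions(r)
}

sort_regions <- function(r) dplyr::arrange(r, .data$seqname, .data$start, .data$end)

empty_regions <- function() {
  tibble(seqname = character(), start = integer(), end = integer(),
         strand = character(), label = character(), score = numeric())
}

validate_region_tbl <- function(r, arg = "regions") {
  need <- c("seqname", "start", "end")
  if (!is.data.frame(r) || !all(need %in% names(r))) {
    abort(sprintf("`%s` must be a data frame with columns seqname, start, end", arg))
  }
  invisible(r)
}

as_granges <- function(r, stranded = FALSE) {
  validate_region_tbl(r)
  GenomicRanges::GRanges(
    seqnames = r$seqname,
    ranges = IRanges::IRanges(start = r$start + 1L, end = r$end),
    strand = if (stranded && "strand" %in% names(r)) r$strand
             else rep("*", nrow(r))
  )
}

from_granges <- function(gr) {
  if (length(gr) == 0) return(empty_regions())
  regions(seqname = as.character(GenomicRanges::seqnames(gr)),
          start = GenomicRanges::start(gr) - 1L,
          end = GenomicRanges::end(gr),
          strand = as.character(GenomicRanges::strand(gr)))
}

#' Merge overlapping regions
#'
#' Coalesces overlapping — and by default also bookended (touching) —
#' regions on each seqname into maximal intervals. The set of covered bases
#' is preserved.
#'
#' @param r Region tibble.
#' @param bookended Also merge regions that touch without overlapping
#'   (default `TRUE`).
#' @return Merged region tibble (strand-blind; labels and scores dropped).
#' @export
regions_merge <- function(r, bookended = TRUE) {
  validate_region_tbl(r)
  if (nrow(r) == 0) return(empty_regions())
  gr <- GenomicRanges::reduce(as_granges(r),
                              min.gapwidth = if (bookended) 1L else 0L)
  from_granges(gr)
}

#' Set algebra on two region sets
#'
#' Base-level and region-level set operations:
#' * `intersect` — intervals of bases covered by both `a` and `b`;
#' * `exclude` — bases of `a` not covered by `b`;
#' * `overlapping` — regions of `a`, kept whole, that share at least one base
#'   with some region of `b`;
#' * `non_overlapping` — the remaining regions of `a`.
#'
#' All modes are strand-blind.
#'
#' @param a,b Region tibbles.
#' @param mode One of `"intersect"`, `"exclude"`, `"overlapping"`,
#'   `"non_overlapping"`.
#' @return Region tibble.
#' @export
region_set_op <- function(a, b, mode = c("intersect", "exclude",
                                         "overlapping", "non_overlapping")) {
  mode <- match.arg(mode)
  validate_region_tbl(a, "a"); validate_region_tbl(b, "b")
  if (nrow(a) == 0) return(empty_regions())
  ga <- as_granges(a); gb <- as_granges(b)
  switch(mode,
    intersect = from_granges(GenomicRanges::intersect(ga, gb)),
    exclude = from_granges(GenomicRanges::setdiff(ga, gb)),
    overlapping = {
      hit <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(ga, gb)))
      sort_regions(a[sort(hit), , drop = FALSE])
    },
    non_overlapping = {
      hit <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(ga, gb)))
      sort_regions(a[setdiff(seq_len(nrow(a)), hit), , drop = FALSE])
    })
}

#' @rdname region_set_op
#' @export
regions_intersect <- function(a, b) region_set_op(a, b, "intersect")

#' @rdname region_set_op
#' @export
regions_exclude <- function(a, b) region_set_op(a, b, "exclude")

#' @rdname region_set_op
#' @export
regions_overlapping <- function(a, b) region_set_op(a, b, "overlapping")

#' @rdname region_set_op
#' @export
regions_non_overlapping <- function(a, b) region_set_op(a, b, "non_overlapping")

#' Resize regions about their centres
#'
#' Each region is replaced by a region of exactly `length` bp centred on the
#' midpoint of the input region (midpoint rounded down). Regions that would
#' start before the chromosome origin are shifted right to start at 0 so the
#' requested length is preserved.
#'
#' @param r Region tibble.
#' @param length Target length in bp.
#' @return Region tibble with all widths equal to `length`.
#' @export
regions_resize <- function(r, length) {
  validate_region_tbl(r)
  stopifnot(length >= 1)
  if (nrow(r) == 0) return(empty_regions())
  centre <- (r$start + r$end) %/% 2L
  start <- pmax(0L, centre - length %/% 2L)
  r$start <- as.integer(start)
  r$end <- as.integer(start + length)
  sort_regions(r)
}

#' Randomly recentre regions
#'
#' Draws a new centre uniformly within each region (seeded, reproducible) and
#' resizes to `length` about it, clipping at the origin as in
#' [regions_resize()].
#'
#' @param r Region tibble.
#' @param length Target length in bp.
#' @param seed Integer seed for the uniform draws.
#' @return Region tibble with all widths equal to `length`.
#' @export
regions_recentre_random <- function(r, length, seed) {
  validate_region_tbl(r)
  stopifnot(length >= 1)
  if (nrow(r) == 0) return(empty_regions())
  centre <- withr::with_seed(seed, {
    r$start + floor(runif(nrow(r)) * (r$end - r$start))
  })
  start <- pmax(0L, as.integer(centre) - length %/% 2L)
  r$start <- as.integer(start)
  r$end <- as.integer(start + length)
  sort_regions(r)
}

#' Extract the sequences under a set of regions
#'
#' Looks up each region's substring in `genome`; minus-strand regions are
#' reverse-complemented. Output records are named after the region label when
#' present, else `seqname:start..end` (1-based inclusive display).
#'
#' @param r Region tibble.
#' @param genome Sequence tibble (e.g. from [read_fasta()]).
#' @return Sequence tibble with one record per region.
#' @export
extract_sequences <- function(r, genome) {
  validate_region_tbl(r); validate_seq_tbl(genome, "genome")
  if (nrow(r) == 0) return(tibble(name = character(), seq = character()))
  idx <- match(r$seqname, genome$name)
  if (anyNA(idx)) {
    abort(sprintf("seqname '%s' not found in genome", r$seqname[is.na(idx)][1]))
  }
  too_long <- r$end > nchar(genome$seq[idx])
  if (any(too_long)) {
    i <- which(too_long)[1]
    abort(sprintf("region %s:%d-%d extends past end of sequence (%d bp)",
                  r$seqname[i], r$start[i], r$end[i], nchar(genome$seq[idx[i]])))
  }
  s <- stringr::str_sub(genome$seq[idx], r$start + 1L, r$end)
  strand <- if ("strand" %in% names(r)) r$strand else "*"
  minus <- strand == "-"
  if (any(minus)) s[minus] <- revcomp(s[minus])
  nm <- if ("label" %in% names(r)) r$label else NA_character_
  auto <- sprintf("%s:%d..%d", r$seqname, r$start + 1L, r$end)
  tibble(name = ifelse(is.na(nm), auto, nm), seq = s)
}

#' Biomarker-enrichment windows
#'
#' Slides fixed-length windows over each chromosome and counts, per window,
#' how many of the supplied marker region sets overlap it by at least one
#' base. `mode = "HBME"` (highly biomarker-enriched) keeps windows whose
#' count is at least `min_markers`; `mode = "LBME"` keeps windows whose count
#' is below `min_markers` (so `LBME` with `min_markers = 1` selects windows
#' not enriched in any marker). Kept windows are merged before return.
#' Windows that would extend past a chromosome end are skipped.
#'
#' @param markers List of region tibbles, one per biomarker (e.g. ChIP peak
#'   sets).
#' @param genome_lengths Named numeric vector of chromosome lengths in bp.
#' @param window,step Window length and step in bp.
#' @param mode `"HBME"` or `"LBME"`.
#' @param min_markers Enrichment cut-off (number of distinct markers).
#' @return Merged region tibble of the selected windows.
#' @export
marker_enrichment <- function(markers, genome_lengths, window, step,
                              mode = c("HBME", "LBME"), min_markers = 1) {
  mode <- match.arg(mode)
  stopifnot(window >= 1, step >= 1, min_markers >= 1)
  if (length(markers) > 0) stopifnot(min_markers <= length(markers))
  wins <- purrr::imap(genome_lengths, function(L, nm) {
    if (L < window) return(NULL)
    starts <- seq(0L, L - window, by = step)
    tibble(seqname = nm, start = as.integer(starts),
           end = as.integer(starts + window))
  })
  wins <- dplyr::bind_rows(wins)
  if (nrow(wins) == 0) return(empty_regions())
  gw <- as_granges(wins)
  count <- rep(0L, nrow(wins))
  for (mk in markers) {
    if (nrow(mk) == 0) next
    hit <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(gw, as_granges(mk))))
    count[hit] <- count[hit] + 1L
  }
  keep <- if (mode == "HBME") count >= min_markers else count < min_markers
  if (!any(keep)) return(empty_regions())
  regions_merge(wins[keep, , drop = FALSE])
}

#' Overlap statistics between predictions and a reference
#'
#' Two complementary accuracy measures for genome-wide predictions:
#' * overlap sensitivity — the fraction of reference regions overlapped by at
#'   least one prediction;
#' * nucleotide precision — the fraction of predicted bases (after merging)
#'   that fall inside the reference.
#'
#' @param pred,ref Region tibbles of predictions and reference elements.
#' @return A one-row tibble with columns `overlap_sensitivity` and
#'   `nucleotide_precision`, both in `[0, 1]`.
#' @export
overlap_stats <- function(pred, ref) {
  validate_region_tbl(pred, "pred"); validate_region_tbl(ref, "ref")
  if (nrow(ref) == 0) abort("overlap sensitivity undefined: empty reference set")
  if (nrow(pred) == 0) abort("nucleotide precision undefined: empty prediction set")
  hit <- nrow(region_set_op(ref, pred, "overlapping"))
  sens <- hit / nrow(ref)
  pm <- regions_merge(pred)
  inside <- regions_intersect(pm, regions_merge(ref))
  prec <- sum(inside$end - inside$start) / sum(pm$end - pm$start)
  tibble(overlap_sensitivity = sens, nucleotide_precision = prec)
}
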