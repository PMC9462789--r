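# Genome-wide signal curves (e.g. ChIP signal, model score tracks) as
# tibbles with columns seqname, start (0-based), span, value. Wiggle files
# are 1-based; conversion happens at the I/O boundary.

curve_tbl <- function(seqname = character(), start = integer(),
                      span = integer(), value = numeric()) {
  tibble(seqname = as.character(seqname), start = as.integer(start),
         span = as.integer(span), value = as.numeric(value)) |>
    dplyr::arrange(.data$seqname, .data$start)
}

#' Read a Wiggle signal track
#'
#' Parses `fixedStep` and `variableStep` Wiggle files (gzipped transparently)
#' into a curve tibble. Wiggle's 1-based starts are converted to the
#' package's 0-based convention; each sample covers `span` bases.
#'
#' @param path Path to a `.wig` or `.wig.gz` file.
#' @return Curve tibble with columns `seqname`, `start`, `span`, `value`.
#' @seealso [write_wig()], [threshold_curve()]
#' @export
read_wig <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path)
  out <- list()
  state <- NULL   # list(mode, chrom, next_start (0-based), step, span)
  for (i in seq_along(lines)) {
    ln <- stringr::str_trim(lines[i])
    if (ln == "" || stringr::str_starts(ln, "#") ||
        stringr::str_starts(ln, "track")) next
    fail <- function(msg) abort(sprintf("%s (%s line %d)", msg, basename(path), i))
    if (stringr::str_starts(ln, "fixedStep") ||
        stringr::str_starts(ln, "variableStep")) {
      kv <- stringr::str_match_all(ln, "(\\w+)=(\\S+)")[[1]]
      keys <- setNames(kv[, 3], kv[, 2])
      if (!"chrom" %in% names(keys)) fail("declaration line missing chrom key")
      mode <- if (stringr::str_starts(ln, "fixedStep")) "fixed" else "variable"
      if (mode == "fixed" && !"start" %in% names(keys)) {
        fail("fixedStep declaration missing start key")
      }
      key_or <- function(k, default) {
        if (k %in% names(keys)) unname(keys[k]) else default
      }
      state <- list(mode = mode, chrom = unname(keys["chrom"]),
                    next_start = as.integer(key_or("start", NA)) - 1L,
                    step = as.integer(key_or("step", "1")),
                    span = as.integer(key_or("span", "1")))
      next
    }
    if (is.null(state)) fail("data line before any declaration line")
    parts <- stringr::str_split_1(ln, "\\s+")
    if (state$mode == "fixed") {
      v <- suppressWarnings(as.numeric(parts[1]))
      if (is.na(v)) fail("non-numeric value")
      out[[length(out) + 1L]] <- list(state$chrom, state$next_start, state$span, v)
      state$next_start <- state$next_start + state$step
    } else {
      if (length(parts) < 2) fail("variableStep data line needs position and value")
      pos <- suppressWarnings(as.integer(parts[1]))
      v <- suppressWarnings(as.numeric(parts[2]))
      if (is.na(pos) || is.na(v)) fail("non-numeric value")
      out[[length(out) + 1L]] <- list(state$chrom, pos - 1L, state$span, v)
    }
  }
  if (length(out) == 0) return(curve_tbl())
  m <- purrr::transpose(out)
  curve_tbl(unlist(m[[1]]), unlist(m[[2]]), unlist(m[[3]]), unlist(m[[4]]))
}

#' Write a curve tibble as Wiggle
#'
#' Emits `fixedStep` blocks where sample spacing and span are uniform within
#' a seqname, `variableStep` blocks otherwise. `read_wig(write_wig(x))`
#' reproduces `x`'s coordinates and values exactly.
#'
#' @param curve Curve tibble (`seqname`, `start`, `span`, `value`).
#' @param path Output path (`.gz` compresses).
#' @return `path`, invisibly.
#' @export
write_wig <- function(curve, path) {
  stopifnot(all(c("seqname", "start", "span", "value") %in% names(curve)))
  blocks <- curve |>
    dplyr::arrange(.data$seqname, .data$start) |>
    dplyr::group_split(.data$seqname)
  lines <- purrr::map(blocks, function(b) {
    spacing <- diff(b$start)
    uniform <- length(unique(b$span)) == 1 &&
      (nrow(b) == 1 || length(unique(spacing)) == 1)
    if (uniform) {
      step <- if (nrow(b) > 1) spacing[1] else b$span[1]
      c(sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                b$seqname[1], b$start[1] + 1L, step, b$span[1]),
        format(b$value, trim = TRUE, scientific = FALSE))
    } else {
      unlist(purrr::map(dplyr::group_split(b, .data$span), function(g) {
        c(sprintf("variableStep chrom=%s span=%d", g$seqname[1], g$span[1]),
          sprintf("%d %s", g$start + 1L,
                  format(g$value, trim = TRUE, scientific = FALSE)))
      }))
    }
  })
  readr::write_lines(unlist(lines), path)
  invisible(path)
}

#' Threshold a curve into regions
#'
#' Maximal runs of samples with `value > t` (strict, so `t = 0` excludes
#' zero-signal background) become regions; runs whose samples touch are
#' merged, but unsampled gaps are never covered.
#'
#' @param curve Curve tibble.
#' @param t Threshold; bases with sample value strictly above `t` are kept.
#' @return Region tibble.
#' @export
threshold_curve <- function(curve, t) {
  stopifnot(all(c("seqname", "start", "span", "value") %in% names(curve)))
  keep <- curve$value > t
  if (!any(keep)) return(empty_regions())
  k <- curve[keep, , drop = FALSE]
  regions_merge(regions(k$seqname, k$start, k$start + k$span))
}
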