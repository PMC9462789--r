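# Region algebra is validated against a per-base bitmap oracle and the
# format converters against coordinate conventions and round-trips.

test_that("merge coalesces overlapping and bookended regions", {
  r <- regions("chr", c(0, 3), c(5, 8))
  expect_equal(regions_merge(r)[, c("start", "end")],
               tibble::tibble(start = 0L, end = 8L))
  r <- regions("chr", c(0, 5), c(5, 8))
  expect_equal(regions_merge(r)$end, 8L)
  expect_equal(nrow(regions_merge(r, bookended = FALSE)), 2)
})

test_that("merge preserves covered bases against the bitmap oracle", {
  set.seed(10)
  for (i in 1:5) {
    r <- random_region_tbl(100, 10000)
    m <- regions_merge(r)
    expect_equal(bitmap_from_regions(m, 10000), bitmap_from_regions(r, 10000))
    # no two output regions overlap or touch
    if (nrow(m) > 1) expect_true(all(m$start[-1] > m$end[-nrow(m)]))
    expect_equal(regions_merge(m), m)   # idempotent
  }
})

test_that("set operations equal per-base / per-region brute force", {
  set.seed(11)
  for (i in 1:4) {
    a <- random_region_tbl(100, 10000)
    b <- random_region_tbl(100, 10000)
    ba <- bitmap_from_regions(a, 10000); bb <- bitmap_from_regions(b, 10000)
    expect_equal(region_set_op(a, b, "intersect"),
                 regions_from_bitmap(ba & bb))
    expect_equal(region_set_op(a, b, "exclude"),
                 regions_from_bitmap(ba & !bb))
    overlap_brute <- sapply(seq_len(nrow(a)), function(k) {
      any(bb[(a$start[k] + 1):a$end[k]])
    })
    expect_equal(nrow(region_set_op(a, b, "overlapping")), sum(overlap_brute))
    expect_equal(nrow(region_set_op(a, b, "non_overlapping")),
                 sum(!overlap_brute))
  }
})

test_that("set-operation identities hold at the covered-base level", {
  set.seed(12)
  a <- random_region_tbl(50, 5000)
  expect_equal(bitmap_from_regions(region_set_op(a, regions(), "exclude"), 5000),
               bitmap_from_regions(a, 5000))
  expect_equal(bitmap_from_regions(region_set_op(a, a, "intersect"), 5000),
               bitmap_from_regions(regions_merge(a), 5000))
})

test_that("resizing centres regions and clips at the origin", {
  expect_equal(regions_resize(regions("c", 10000, 10010), 3000)[, c("start", "end")],
               tibble::tibble(start = 8505L, end = 11505L))
  out <- regions_resize(regions("c", 100, 110), 3000)
  expect_equal(c(out$start, out$end), c(0L, 3000L))
  r <- random_region_tbl(20, 5000)
  out <- regions_resize(r, 700)
  expect_true(all(out$end - out$start == 700))
})

test_that("random recentring is reproducible and stays near the source", {
  r <- regions("c", c(1000, 4000), c(2000, 4500))
  a <- regions_recentre_random(r, 300, seed = 9)
  b <- regions_recentre_random(r, 300, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, regions_recentre_random(r, 300, seed = 10)))
  centres <- a$start + 150
  expect_true(all(centres >= r$start & centres < r$end))
})

test_that("sequence extraction honours strand", {
  genome <- dna_tbl("chr", "AACGTT")
  expect_equal(extract_sequences(regions("chr", 0, 4), genome)$seq, "AACG")
  r <- regions("chr", 1, 5, strand = "-")
  expect_equal(extract_sequences(r, genome)$seq, revcomp("ACGT"))
  set.seed(13)
  genome <- dna_tbl("chr", random_dna(2000))
  r <- random_region_tbl(50, 2000, max_width = 60)
  r$strand <- sample(c("+", "-"), 50, replace = TRUE)
  got <- extract_sequences(r, genome)$seq
  want <- sapply(seq_len(nrow(r)), function(i) {
    s <- substr(genome$seq, r$start[i] + 1, r$end[i])
    if (r$strand[i] == "-") {
      paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
    } else s
  })
  expect_equal(got, unname(want))
  expect_error(extract_sequences(regions("nope", 0, 5), genome), "not found")
  expect_error(extract_sequences(regions("chr", 0, 99999), genome), "past end")
})

test_that("overlap statistics match their definitions", {
  r <- regions("c", c(0, 100), c(10, 150))
  expect_equal(unlist(overlap_stats(r, r)),
               c(overlap_sensitivity = 1, nucleotide_precision = 1))
  st <- overlap_stats(regions("c", 0, 10), regions("c", 5, 6))
  expect_equal(st$overlap_sensitivity, 1)
  expect_equal(st$nucleotide_precision, 0.1)
  st <- overlap_stats(regions("c", 0, 10), regions("c", 50, 60))
  expect_equal(unlist(st),
               c(overlap_sensitivity = 0, nucleotide_precision = 0))
  expect_error(overlap_stats(regions("c", 0, 1), regions()), "empty reference")
})

test_that("overlap statistics equal the bitmap computation on random sets", {
  set.seed(14)
  for (i in 1:3) {
    pred <- random_region_tbl(40, 8000)
    ref <- random_region_tbl(30, 8000)
    st <- overlap_stats(pred, ref)
    bp <- bitmap_from_regions(pred, 8000); br <- bitmap_from_regions(ref, 8000)
    sens <- mean(sapply(seq_len(nrow(ref)), function(k) {
      any(bp[(ref$start[k] + 1):ref$end[k]])
    }))
    expect_equal(st$overlap_sensitivity, sens)
    expect_equal(st$nucleotide_precision, sum(bp & br) / sum(bp))
  }
})

test_that("marker-enrichment windows partition and match enumeration", {
  markers <- list(regions("c", 0, 100))
  lens <- c(c = 200)
  hb <- marker_enrichment(markers, lens, window = 50, step = 50, mode = "HBME")
  lb <- marker_enrichment(markers, lens, window = 50, step = 50, mode = "LBME")
  expect_equal(hb[, c("start", "end")], tibble::tibble(start = 0L, end = 100L))
  expect_equal(lb[, c("start", "end")], tibble::tibble(start = 100L, end = 200L))
  expect_equal(nrow(marker_enrichment(list(), lens, 50, 50, "HBME")), 0)

  set.seed(15)
  markers <- purrr::map(1:4, ~ random_region_tbl(20, 5000))
  lens <- c(chr = 5000)
  for (minm in c(1, 2, 4)) {
    hb <- marker_enrichment(markers, lens, 300, 250, "HBME", minm)
    lb <- marker_enrichment(markers, lens, 300, 250, "LBME", minm)
    # window-level enumeration oracle
    starts <- seq(0, 5000 - 300, by = 250)
    counts <- sapply(starts, function(s) {
      sum(sapply(markers, function(mk) {
        any(mk$start < s + 300 & mk$end > s)
      }))
    })
    want_hb <- regions_merge(regions("chr", starts[counts >= minm],
                                     starts[counts >= minm] + 300))
    if (any(counts >= minm)) expect_equal(hb, want_hb)
    want_lb <- regions_merge(regions("chr", starts[counts < minm],
                                     starts[counts < minm] + 300))
    if (any(counts < minm)) expect_equal(lb, want_lb)
  }
})
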