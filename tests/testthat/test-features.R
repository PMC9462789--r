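two_motifs <- list(motif_iupac("X", "AAAA"), motif_iupac("Y", "CCCC"))

test_that("motif frequency features count both strands and normalise per kb", {
  gaf <- list(motif_iupac("GAF", "GAGAG"))
  raw <- ft_motif_freq(gaf, normalization = "raw")
  expect_equal(unname(crescan:::ft_matrix(raw, dna_tbl("a", "GAGAGAG"))[1, 1]), 2)
  perkb <- ft_motif_freq(gaf, normalization = "per_kb")
  s500 <- paste0(strrep("T", 200), "GAGAG", strrep("T", 295))
  expect_equal(unname(crescan:::ft_matrix(perkb, dna_tbl("a", s500))[1, 1]), 2)
  expect_equal(unname(crescan:::ft_matrix(raw, dna_tbl("a", "TTTTTTTT"))[1, 1]), 0)
})

test_that("motif pair features enumerate unordered pairs within the cut-off", {
  node <- ft_motif_pairs(two_motifs, max_distance = 219, normalization = "raw")
  expect_equal(feature_names(node), c("X:X", "X:Y", "Y:Y"))
  v <- crescan:::ft_matrix(node, dna_tbl("a", "AAAACCCC"))[1, ]
  expect_gte(v[["X:Y"]], 1)
  # center-to-center distance 0 with disjoint motifs: no cross pairs
  node0 <- ft_motif_pairs(two_motifs, max_distance = 0, normalization = "raw")
  v0 <- crescan:::ft_matrix(node0, dna_tbl("a", "AAAATTCCCC"))[1, ]
  expect_equal(unname(v0[c("X:Y")]), 0)
})

test_that("pair counts match the exhaustive occurrence-pair oracle", {
  set.seed(61)
  node <- ft_motif_pairs(two_motifs, max_distance = 20, normalization = "raw")
  for (i in 1:30) {
    s <- random_dna(60)
    v <- crescan:::ft_matrix(node, dna_tbl("a", s))[1, ]
    occ_x <- oracle_motif_occurrences(s, "AAAA")
    occ_y <- oracle_motif_occurrences(s, "CCCC")
    expect_equal(unname(v[["X:X"]]), oracle_pair_count(occ_x, NULL, 20, self = TRUE))
    expect_equal(unname(v[["Y:Y"]]), oracle_pair_count(occ_y, NULL, 20, self = TRUE))
    expect_equal(unname(v[["X:Y"]]), oracle_pair_count(occ_x, occ_y, 20))
  }
})

test_that("duplicating a motif's occurrences scales its self-pair count as expected", {
  node <- ft_motif_pairs(list(motif_iupac("X", "TTAATT")), max_distance = 50,
                         normalization = "raw")
  one <- paste0("TTAATT", strrep("G", 10), "TTAATT")
  two <- paste0(one, strrep("G", 10), one)
  v1 <- crescan:::ft_matrix(node, dna_tbl("a", one))[1, 1]
  v2 <- crescan:::ft_matrix(node, dna_tbl("a", two))[1, 1]
  occ <- oracle_motif_occurrences(two, "TTAATT")
  expect_equal(unname(v2), oracle_pair_count(occ, NULL, 50, self = TRUE))
  expect_equal(unname(v1), oracle_pair_count(
    oracle_motif_occurrences(one, "TTAATT"), NULL, 50, self = TRUE))
  expect_gt(v2, 3.5 * v1)   # ~quadruples with doubled occurrences
})

test_that("k-spectrum features count words in lexicographic order", {
  node <- ft_kspectrum(2)
  v <- crescan:::ft_matrix(node, dna_tbl("a", "AAAA"))[1, ]
  expect_equal(unname(v[["AA"]]), 3)
  expect_equal(sum(v), 3)
  set.seed(62)
  for (i in 1:5) {
    s <- random_dna(40)
    expect_equal(sum(crescan:::ft_matrix(node, dna_tbl("a", s))[1, ]),
                 40 - 2 + 1)
  }
})

test_that("k-spectrum matches the dictionary oracle on random sequences", {
  set.seed(63)
  for (k in c(1, 2, 3)) {
    node <- ft_kspectrum(k)
    for (i in 1:30) {
      s <- random_dna(50, alphabet = c("A", "C", "G", "T", "N"))
      got <- crescan:::ft_matrix(node, dna_tbl("a", s))[1, ]
      expect_equal(unname(got), unname(oracle_kspectrum(s, k)),
                   info = sprintf("k=%d seq=%s", k, s))
    }
  }
})

test_that("mismatch spectrum reduces to plain at m = 0 and obeys the count identity", {
  set.seed(64)
  for (i in 1:10) {
    s <- random_dna(50)
    m0 <- crescan:::ft_matrix(ft_kspectrum_mismatch(3, 0), dna_tbl("a", s))[1, ]
    plain <- crescan:::ft_matrix(ft_kspectrum(3), dna_tbl("a", s))[1, ]
    expect_equal(unname(m0), unname(plain))
    for (m in 1:2) {
      vm <- crescan:::ft_matrix(ft_kspectrum_mismatch(3, m), dna_tbl("a", s))[1, ]
      ball <- sum(choose(3, 0:m) * 3^(0:m))
      expect_equal(sum(vm), (50 - 3 + 1) * ball)
      expect_true(all(vm >= plain))   # mismatch dominates plain feature-wise
    }
  }
})

test_that("mismatch spectrum equals Hamming-ball enumeration", {
  v <- crescan:::ft_matrix(ft_kspectrum_mismatch(2, 1), dna_tbl("a", "AA"))[1, ]
  expect_equal(unname(v[c("AA", "AC", "AG", "AT", "CA", "GA", "TA", "CC")]),
               c(1, 1, 1, 1, 1, 1, 1, 0))
  set.seed(65)
  for (i in 1:5) {
    s <- random_dna(30)
    got <- crescan:::ft_matrix(ft_kspectrum_mismatch(2, 1), dna_tbl("a", s))[1, ]
    expect_equal(unname(got), unname(oracle_mismatch_spectrum(s, 2, 1)))
  }
})

test_that("concat, filter and product transformations compose dimensions", {
  a <- ft_kspectrum(1)           # 4 features
  b <- ft_motif_freq(two_motifs) # 2 features
  cc <- ft_concat(a, b)
  expect_equal(length(feature_names(cc)), 6)
  expect_equal(feature_names(cc), c("A", "C", "G", "T", "X", "Y"))
  fl <- ft_filter(cc, function(nm) nm %in% c("C", "Y"))
  expect_equal(feature_names(fl), c("C", "Y"))
  pp <- ft_product_pair(b)
  expect_equal(feature_names(pp), c("X*X", "X*Y", "Y*Y"))
  x <- crescan:::ft_matrix(ft_product_pair(ft_kspectrum(1)), dna_tbl("a", "AACG"))
  # counts A=2,C=1,G=1: squares and cross products
  expect_equal(unname(x[1, c("A*A", "A*C", "C*G")]), c(4, 2, 1))
})

test_that("scaling standardises training features and requires training", {
  set.seed(66)
  seqs <- dna_tbl(paste0("s", 1:20), replicate(20, random_dna(60)))
  node <- ft_scale(ft_kspectrum(1))
  expect_error(crescan:::ft_matrix(node, seqs), "trained")
  node <- ft_train(node, seqs)
  z <- crescan:::ft_matrix(node, seqs)
  expect_lt(max(abs(colMeans(z))), 1e-12)
  nondeg <- apply(z, 2, sd) > 0
  expect_equal(unname(apply(z, 2, sd)[nondeg]), rep(1, sum(nondeg)),
               tolerance = 1e-9)
  # idempotent retraining
  expect_equal(crescan:::ft_matrix(ft_train(node, seqs), seqs), z)
})

test_that("feature tables carry labels; summary and differential stats behave", {
  seqs <- dna_tbl(c("a", "b", "c", "d"), c("AAAA", "AAAC", "CCCC", "CCCA"))
  seqs$class <- c("pos", "pos", "neg", "neg")
  tb <- feature_table(ft_kspectrum(1), seqs)
  expect_equal(rowSums(as.matrix(tb[, -(1:2)])), nchar(seqs$seq),
               ignore_attr = TRUE)
  st <- summary_stats(tb)
  cst <- st[st$feature == "G", ]
  expect_true(all(cst$mean == 0 & cst$sd == 0))
  d1 <- differential_stats(tb, "pos", "neg")
  d2 <- differential_stats(tb, "neg", "pos")
  expect_equal(d1$mean_diff[order(d1$feature)],
               -d2$mean_diff[order(d2$feature)])
  expect_equal(d1$feature[d1$rank == 1], "A")
  expect_error(differential_stats(tb, "pos", "nope"), "unknown class")
})
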