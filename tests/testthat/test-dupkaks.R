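test_that("pairwise alignment reports identity and coverage per definition", {
  pa <- align_pair("MKWVDD", "MKWVDD")
  expect_equal(pa$identity, 1)
  expect_equal(pa$coverage, 1)

  long <- "MKWVDDERAGHILMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKL"
  pref <- substr(long, 1, round(nchar(long) * 0.7))
  pa2 <- align_pair(pref, long)
  expect_equal(pa2$coverage, nchar(pref) / nchar(long), tolerance = 1e-9)
  expect_equal(pa2$identity, 1)
  expect_error(align_pair("", "MK"), "empty")
})

test_that("duplicate detection applies strict coverage/identity thresholds", {
  ann <- generate_annotation(small_config(seed = 71L))
  prot <- ann$proteins[ann$truth$members$protein_id]
  dup <- find_duplicates(prot)
  truth_pairs <- ann$truth$pairs
  key <- function(a, b) paste(sort(c(a, b)), collapse = "|")
  found <- unname(mapply(key, sub("\\.\\d+$", "", dup$idA),
                         sub("\\.\\d+$", "", dup$idB)))
  planted <- unname(mapply(key, truth_pairs$idA, truth_pairs$idB))
  expect_setequal(found, planted)
  expect_true(all(dup$identity > 0.70 & dup$coverage > 0.70))

  # a pair below either threshold is excluded even at the boundary
  fake <- c(a = "MKWVDDERAG", b = "MKWVDD")   # coverage 0.6
  expect_equal(nrow(find_duplicates(fake)), 0)
})

test_that("tandem classification follows gap and intervening-gene rules", {
  mk <- function(id, chrom, start, end) {
    gene_model(id, chrom, "+", start, end, matrix(c(start, end), 1),
               matrix(c(start, end), 1))
  }
  genes <- list(
    A = mk("A", "chr1", 1000, 2000),
    x1 = mk("x1", "chr1", 3000, 3500),
    x2 = mk("x2", "chr1", 4000, 4500),
    B = mk("B", "chr1", 9000, 10000),
    C = mk("C", "chr2", 1000, 2000),
    far = mk("far", "chr1", 300000, 301000))
  names(genes) <- vapply(genes, `[[`, character(1), "gene_id")

  t1 <- classify_duplication("A", "B", genes)
  expect_identical(t1$dup_class, "tandem")
  expect_equal(t1$gap_bp, 9000 - 2000 - 1)
  expect_equal(t1$n_intervening, 2)

  # cross-chromosome is dispersed
  expect_identical(classify_duplication("A", "C", genes)$dup_class,
                   "dispersed")
  # same chromosome but > 100 kb apart is dispersed
  expect_identical(classify_duplication("A", "far", genes)$dup_class,
                   "dispersed")
  # more than five intervening genes forces dispersed
  many <- genes
  for (k in 1:6) {
    id <- paste0("y", k)
    many[[id]] <- mk(id, "chr1", 2100 + 200 * k, 2150 + 200 * k)
  }
  expect_identical(classify_duplication("A", "B", many)$dup_class,
                   "dispersed")
  expect_error(classify_duplication("A", "nope", genes),
               "missing from annotation")
})

test_that("NG counts match hand enumeration on canonical codons", {
  r <- ng_counts("TTT", "TTC")
  expect_equal(r$S, 1 / 3, tolerance = 1e-12)
  expect_equal(r$N, 8 / 3, tolerance = 1e-12)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)

  same <- ng_counts("ATGAAA", "ATGAAA")
  expect_equal(same$Sd + same$Nd, 0)
  expect_equal(same$S + same$N, 6, tolerance = 1e-12)

  # codons with gaps or ambiguity are skipped
  skip2 <- ng_counts("ATG---AAA", "ATGTTTAAA")
  expect_equal(skip2$n_codons, 2)
  expect_error(ng_counts("TAA", "TAA"), "stop")
  expect_error(ng_counts("---", "ATG"), "no comparable")
})

test_that("NG counts are symmetric and conserve total sites", {
  set.seed(13)
  sense <- sense_codon_list()
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    a <- paste(sample(sense, n, replace = TRUE), collapse = "")
    b <- paste(sample(sense, n, replace = TRUE), collapse = "")
    ab <- ng_counts(a, b); ba <- ng_counts(b, a)
    expect_equal(ab[c("S", "N", "Sd", "Nd")], ba[c("S", "N", "Sd", "Nd")])
    expect_equal(ab$S + ab$N, 3 * n, tolerance = 1e-9)
  }
})

test_that("NG counts equal the exhaustive-pathway oracle", {
  sense <- sense_codon_list()
  # every single-codon pair
  for (a in sense) {
    for (b in sense) {
      mine <- ng_counts(a, b)
      orc <- oracle_ng(a, b)
      expect_equal(mine$S, orc$S, tolerance = 1e-10)
      expect_equal(mine$Sd, orc$Sd, tolerance = 1e-10)
      expect_equal(mine$Nd, orc$Nd, tolerance = 1e-10)
    }
  }
  # random multi-codon pairs
  set.seed(29)
  for (rep in 1:40) {
    n <- sample(2:3, 1)
    a <- paste(sample(sense, n, replace = TRUE), collapse = "")
    b <- paste(sample(sense, n, replace = TRUE), collapse = "")
    mine <- ng_counts(a, b); orc <- oracle_ng(a, b)
    expect_equal(mine$Sd, orc$Sd, tolerance = 1e-10)
    expect_equal(mine$Nd, orc$Nd, tolerance = 1e-10)
    expect_equal(mine$S, orc$S, tolerance = 1e-10)
  }
})

test_that("Jukes-Cantor correction matches the closed form and saturates", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.1), -0.75 * log(1 - 0.4 / 3),
               tolerance = 1e-12)
  expect_equal(jukes_cantor(0.1), 0.107326, tolerance = 1e-5)
  expect_error(jukes_cantor(0.75), "saturated")
  expect_error(jukes_cantor(-0.1), "non-negative")
})

test_that("Ka/Ks behaves on identical and synonymous-only pairs", {
  cds <- "ATGAAACCCGGGTTTTAA"
  kk <- kaks_pair(cds, cds)
  expect_equal(kk$ka, 0)
  expect_equal(kk$ks, 0)
  expect_true(is.na(kk$omega))

  # plant synonymous-only divergence: proteins identical, ka = 0, ks > 0
  dp <- generate_duplicate_pair(0.2, 0, 100, seed = 5)
  expect_identical(translate_cds(dp$cdsA), translate_cds(dp$cdsB))
  kk2 <- kaks_pair(dp$cdsA, dp$cdsB)
  expect_equal(kk2$ka, 0)
  expect_gt(kk2$ks, 0)

  expect_error(kaks_pair("ATGAAA", "ATGAAA",
                         align_pair("MKW", "MK", idA = "gX", idB = "gY")),
               "mismatch.*gX")
})

test_that("simulated pairs recover the planted ks within tolerance", {
  rel_err <- function(ks_true, seed) {
    dp <- generate_duplicate_pair(ks_true, 0.05, 500, seed = seed)
    abs(kaks_pair(dp$cdsA, dp$cdsB)$ks - ks_true) / ks_true
  }
  for (ks_true in c(0.1, 0.3, 0.5)) {
    errs <- vapply(1:8, function(s) rel_err(ks_true, s), numeric(1))
    expect_lte(median(errs), 0.10)
  }
})

test_that("divergence time applies T = Ks / 2r in million years", {
  expect_equal(divergence_time(0), 0)
  expect_equal(divergence_time(0.3), 10)          # r = 1.5e-8
  expect_equal(divergence_time(0.3, r = 3e-8), 5)
  expect_equal(divergence_time(1.1583), 38.61)
})
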