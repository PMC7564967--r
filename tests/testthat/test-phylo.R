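test_that("Poisson distance implements pairwise deletion and the log correction", {
  expect_equal(poisson_distance("ACDEF", "ACDEF"), 0)
  # p = 0.5 over compared columns
  expect_equal(poisson_distance("AAAA", "AAGG"), -log(0.5),
               tolerance = 1e-12)
  # gap column dropped: compared 4, one mismatch
  expect_equal(poisson_distance("AR-ND", "AK-ND"), -log(1 - 0.25),
               tolerance = 1e-12)
  # symmetry
  expect_equal(poisson_distance("ARWND", "AKWNE"),
               poisson_distance("AKWNE", "ARWND"))
  expect_error(poisson_distance("A-", "-A"), "no comparable")
  expect_error(poisson_distance("AA", "CC"), "saturated")
})

test_that("NJ solves the three-taxon case by the three-point formulas", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[["A"]], 0.5)
  expect_equal(len[["B"]], 1.5)
  expect_equal(len[["C"]], 2.5)
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
})

test_that("NJ reconstructs additive matrices exactly and matches ape", {
  set.seed(17)
  for (rep in 1:5) {
    n <- sample(5:9, 1)
    tr0 <- ape::rtree(n)
    tr0$edge.length <- runif(nrow(tr0$edge), 0.05, 1)
    D <- stats::cophenetic(tr0)
    tr <- nj_tree(D)
    # path lengths reproduce the generating additive metric
    expect_equal(max(abs(stats::cophenetic(tr)[rownames(D), colnames(D)]
                         - D)), 0, tolerance = 1e-9)
    # topology identical to the generating tree and to ape's NJ
    expect_equal(ape::dist.topo(ape::unroot(tr0), tr), 0,
                 ignore_attr = TRUE)
    expect_equal(ape::dist.topo(ape::nj(D), tr), 0, ignore_attr = TRUE)
  }
})

test_that("NJ topology is invariant to taxon input order", {
  set.seed(23)
  tr0 <- ape::rtree(7)
  tr0$edge.length <- runif(nrow(tr0$edge), 0.05, 1)
  D <- stats::cophenetic(tr0)
  perm <- sample(rownames(D))
  trA <- nj_tree(D)
  trB <- nj_tree(D[perm, perm])
  expect_equal(ape::dist.topo(trA, trB), 0, ignore_attr = TRUE)
})

test_that("negative NJ branches are clamped with the deficit transferred", {
  # a non-additive matrix known to produce a negative branch estimate
  D <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 1, 9, 10, 1, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports are deterministic, bounded and catch clean splits", {
  # two well-separated clades of near-duplicate sequences sharing a
  # conserved core (distances must stay below saturation)
  core <- strrep("GALVIKRHE", 4)
  aln <- c(a1 = paste0(core, "WWWWWWWWWW"), a2 = paste0(core, "WWWWWWWWWV"),
           a3 = paste0(core, "CWWWWWWWWW"),
           b1 = paste0(core, "DDDDDDDDDD"), b2 = paste0(core, "DDDDDDDDDK"),
           b3 = paste0(core, "EDDDDDDDDD"))
  tr1 <- bootstrap_supports(aln, n_reps = 100, seed = 7)
  tr2 <- bootstrap_supports(aln, n_reps = 100, seed = 7)
  expect_identical(write_newick(tr1), write_newick(tr2))
  sup <- suppressWarnings(as.integer(tr1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  # the a|b bipartition is in every replicate
  expect_true(100 %in% sup)
  # n_reps = 0 returns the plain tree
  tr0 <- bootstrap_supports(aln, n_reps = 0)
  expect_null(tr0$node.label)
})

test_that("progressive alignment preserves sequences and aligns relatives", {
  set.seed(5)
  base <- paste(sample(c("A", "C", "D", "E", "F", "G", "H", "K"), 60,
                       replace = TRUE), collapse = "")
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(length(ch), k)
    ch[idx] <- sample(c("L", "M", "N", "P"), k, replace = TRUE)
    paste(ch, collapse = "")
  }
  seqs <- c(s1 = base, s2 = mut(base, 5), s3 = mut(base, 8),
            s4 = paste0(substr(base, 1, 50)))
  aln <- align_proteins(seqs)
  expect_length(unique(nchar(aln)), 1)
  expect_identical(gsub("-", "", aln), seqs, ignore_attr = TRUE)
  # closely related rows should be nearly gap-free relative to each other
  expect_lt(poisson_distance(aln[["s1"]], aln[["s2"]]), 0.15)
})
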