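test_that("duplicate-pair generator honors targets and edge cases", {
  z <- generate_duplicate_pair(0, 0, 50, seed = 1)
  expect_identical(z$cdsA, z$cdsB)

  dp <- generate_duplicate_pair(0.3, 0.05, 200, seed = 2)
  expect_equal(nchar(dp$cdsA), nchar(dp$cdsB))
  expect_equal(nchar(dp$cdsA) %% 3, 0)
  # no stops introduced anywhere
  expect_silent(translate_cds(dp$cdsA))
  expect_silent(translate_cds(dp$cdsB))
  # planted difference counts are reflected in the NG counts exactly
  cnt <- ng_counts(substr(dp$cdsA, 1, nchar(dp$cdsA) - 3),
                   substr(dp$cdsB, 1, nchar(dp$cdsB) - 3))
  expect_equal(cnt$Sd, dp$truth$n_syn_changes)
  expect_equal(cnt$Nd, dp$truth$n_non_changes)

  expect_error(generate_duplicate_pair(0.8, 0, 100), "0.75|saturation")
  expect_error(generate_duplicate_pair(0.1, 0, 10), "n_codons")
})

test_that("generators are pure functions of config and seed", {
  cfg <- small_config(seed = 121L)
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1$genome, a2$genome)
  expect_identical(a1$hits, a2$hits)
  expect_identical(a1$truth, a2$truth)
  e1 <- generate_expression(cfg); e2 <- generate_expression(cfg)
  expect_identical(e1$mat, e2$mat)
  q1 <- generate_qpcr(cfg, rownames(e1$mat)[1:5])
  q2 <- generate_qpcr(cfg, rownames(e2$mat)[1:5])
  expect_identical(q1$records, q2$records)

  # written bundles are byte-identical across runs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synth_bundle(cfg, d1)
  write_synth_bundle(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE),
                     label = paste("file", f))
  }
  # a different seed changes the data
  a3 <- generate_annotation(small_config(seed = 122L))
  expect_false(identical(a1$genome, a3$genome))
})

test_that("annotation truth is consistent with the emitted files", {
  cfg <- small_config(seed = 131L)
  d <- withr::local_tempdir()
  b <- write_synth_bundle(cfg, d)
  ann <- b$annotation

  # genome round-trips and gene models read back with exact coordinates
  genome <- read_fasta(b$paths[["genome"]], "dna")
  expect_identical(unname(nchar(genome)), unname(nchar(ann$genome)))
  models <- read_gff3(b$paths[["gff3"]])
  for (gid in ann$truth$members$gene_id[1:4]) {
    expect_identical(models[[gid]]$exons, ann$models[[gid]]$exons)
    expect_identical(models[[gid]]$strand, ann$models[[gid]]$strand)
  }

  # CDS concatenated from genome equals the planted CDS (strand-aware)
  for (gid in ann$truth$members$gene_id[1:4]) {
    m <- ann$models[[gid]]
    segs <- vapply(seq_len(nrow(m$cds)), function(i)
      substr(ann$genome[[m$chrom]], m$cds[i, 1], m$cds[i, 2]), character(1))
    cds_gen <- paste(segs, collapse = "")
    if (m$strand == "-") cds_gen <- reverse_complement(cds_gen)
    expect_identical(cds_gen, unname(ann$cds[[gid]]))
  }

  # proteins are the translations of the planted CDS
  pid <- ann$truth$members$protein_id[1]
  gid <- ann$truth$members$gene_id[1]
  expect_identical(unname(ann$proteins[[pid]]),
                   translate_cds(ann$cds[[gid]]))

  # decoys never pass the identification filter; members always do
  kept <- filter_candidates(ann$hits)
  expect_length(intersect(kept, ann$truth$decoys$protein_id), 0)
  expect_setequal(kept, ann$truth$members$protein_id)

  # planted tandem/dispersed classes are rule-forced
  for (i in seq_len(nrow(ann$truth$pairs))) {
    pr <- ann$truth$pairs[i, ]
    cls <- classify_duplication(pr$idA, pr$idB, models)
    expect_identical(cls$dup_class, pr$expected_class)
  }
})
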