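mini_genome <- function() {
  set.seed(3)
  c(chr1 = paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                 collapse = ""))
}

test_that("promoter extraction is strand-aware and anchored at the CDS start", {
  genome <- mini_genome()
  plus <- gene_model("gp", "chr1", "+", 2001, 2600,
                     matrix(c(2001, 2600), 1), matrix(c(2001, 2600), 1))
  prom <- extract_upstream(plus, genome, length = 1500)
  expect_equal(nchar(prom), 1500)
  expect_identical(as.character(prom), substr(genome[["chr1"]], 501, 2000))

  minus <- gene_model("gm", "chr1", "-", 1001, 1600,
                      matrix(c(1001, 1600), 1), matrix(c(1001, 1600), 1))
  promm <- extract_upstream(minus, genome, length = 1500)
  expect_identical(as.character(promm),
                   reverse_complement(substr(genome[["chr1"]], 1601, 3100)))

  # truncation at the chromosome start produces a warning and a short promoter
  near <- gene_model("gn", "chr1", "+", 800, 1100,
                     matrix(c(800, 1100), 1), matrix(c(800, 1100), 1))
  expect_warning(pr <- extract_upstream(near, genome, 1500), "truncated")
  expect_equal(nchar(pr), 799)
  expect_error(extract_upstream(plus, genome["chr1"][0], 10), "chromosome")
})

test_that("IUPAC scanning finds planted motifs on both strands", {
  catalog <- data.frame(
    name = c("m1", "m2", "TATA-box"),
    iupac = c("ACGTG", "WCGTG", "TATAWA"),
    category = c("hormone", "stress", "other"), stringsAsFactors = FALSE)
  prom <- paste0(strrep("C", 9), "ACGTG", strrep("C", 10),
                 reverse_complement("TCGTG"), strrep("C", 10))
  attr(prom, "gene_id") <- "g"
  hits <- scan_motifs(prom, catalog)
  # exact plant at offset 10 on the plus strand
  expect_true(any(hits$motif == "m1" & hits$position == 10 &
                  hits$strand == "+"))
  # degenerate W matches both the planted A and the reverse-strand T variant
  expect_true(any(hits$motif == "m2" & hits$position == 10 &
                  hits$strand == "+"))
  expect_true(any(hits$motif == "m2" & hits$position == 25 &
                  hits$strand == "-"))
  # excluded ubiquitous elements never appear
  expect_false("TATA-box" %in% hits$motif)

  bad <- data.frame(name = "x", iupac = "AC?G", category = "other")
  expect_error(scan_motifs(prom, bad), "malformed|illegal")
})

test_that("scanning the reverse complement flips strands but keeps the hit set", {
  set.seed(8)
  prom <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                collapse = "")
  catalog <- data.frame(
    name = c("a", "b"), iupac = c("CACGTG", "CAANNNNATC"),
    category = c("light", "other"), stringsAsFactors = FALSE)
  h_fwd <- scan_motifs(prom, catalog, exclude = character(0))
  h_rev <- scan_motifs(reverse_complement(prom), catalog,
                       exclude = character(0))
  # map reverse-scan coordinates back onto the forward promoter
  w <- setNames(nchar(catalog$iupac), catalog$name)
  L <- nchar(prom)
  mapped <- data.frame(
    motif = h_rev$motif,
    position = L - (h_rev$position + w[h_rev$motif] - 1) + 1,
    strand = ifelse(h_rev$strand == "+", "-", "+"))
  key <- function(d) sort(paste(d$motif, d$position, d$strand))
  expect_identical(key(mapped), key(h_fwd))
})

test_that("category summaries count element types and instances per gene", {
  catalog <- data.frame(
    name = c("h1", "h2", "l1"), iupac = c("AAAA", "CCCC", "GGGG"),
    category = c("hormone", "hormone", "light"), stringsAsFactors = FALSE)
  hits <- data.frame(
    gene_id = c("g1", "g1", "g1", "g2"),
    motif = c("h1", "h1", "h2", "l1"),
    position = c(1, 10, 20, 5), strand = "+",
    category = c("hormone", "hormone", "hormone", "light"),
    stringsAsFactors = FALSE)
  cats <- categorize_elements(hits, catalog)
  expect_equal(cats$per_gene_types["g1", "hormone"], 2)
  expect_equal(cats$per_gene_instances["g1", "hormone"], 3)
  expect_equal(cats$per_gene_types["g2", "light"], 1)
  expect_equal(cats$per_gene_types["g2", "hormone"], 0)
  expect_equal(unname(cats$family_types[["hormone"]]), 2)
  expect_error(categorize_elements(
    transform(hits, motif = "zz"), catalog), "unknown motif")
  # excluding a name never increases counts
  h2 <- hits[hits$motif != "h1", ]
  cats2 <- categorize_elements(h2, catalog)
  expect_true(all(cats2$per_gene_instances <= cats$per_gene_instances))
})

test_that("planted promoter elements are recovered exactly from the genome", {
  ann <- generate_annotation(small_config(seed = 81L))
  truth <- ann$truth$motifs
  gids <- unique(truth$gene_id)[1:3]
  for (gid in gids) {
    prom <- extract_upstream(ann$models[[gid]], ann$genome)
    hits <- scan_motifs(prom, ann$catalog)
    tr <- truth[truth$gene_id == gid, ]
    for (r in seq_len(nrow(tr))) {
      expect_true(any(hits$motif == tr$motif[r] &
                      hits$position == tr$position[r] &
                      hits$strand == tr$strand[r]),
                  label = paste("planted", tr$motif[r], "at",
                                tr$position[r], tr$strand[r], "in", gid))
    }
  }
})
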