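# Shared fixtures: a scaled-down synthetic configuration for fast tests,
# small on-disk FASTA/GFF3 builders, and an independent Nei-Gojobori
# oracle used to cross-check the production counter.

small_config <- function(seed = 11L, ...) {
  synth_config(
    seed = seed,
    n_chromosomes = 3L,
    n_members = c(G = 5L, L = 4L, C = 1L),
    n_decoys = 4L,
    cds_len_range_bp = c(903L, 1203L),
    tandem_pairs = 1L,
    tandem_intervening = 2L,
    dispersed_pairs = 1L,
    pair_ks = c(0.30, 0.22),
    group_sizes = c(2L, 3L, 5L),
    tissue_specific = c(root = 1L),
    qpcr_plants = data.frame(
      slot = c(1L, 2L, 3L),
      condition = c("ABA", "ABA", "IAA"),
      fold = c(88, 1 / 17, 1 / 5),
      stringsAsFactors = FALSE),
    ...)
}

write_fasta_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fa",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# minimal GFF3: one gene with one mRNA; exons/cds are (start, end) matrices
gff3_gene_lines <- function(gid, chrom, strand, start, end, exons, cds,
                            tid = paste0(gid, ".1")) {
  out <- c(sprintf("%s\t.\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   chrom, start, end, strand, gid),
           sprintf("%s\t.\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                   chrom, start, end, strand, tid, gid))
  for (i in seq_len(nrow(exons))) {
    out <- c(out, sprintf("%s\t.\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                          chrom, exons[i, 1], exons[i, 2], strand, tid))
  }
  for (i in seq_len(nrow(cds))) {
    out <- c(out, sprintf("%s\t.\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                          chrom, cds[i, 1], cds[i, 2], strand, tid))
  }
  out
}

# ---- independent Nei-Gojobori oracle (exhaustive enumeration) ----------
.oracle_code <- local({
  code <- NULL
  function() {
    if (is.null(code)) {
      nts <- c("T", "C", "A", "G")
      aas <- strsplit(paste0(
        "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRR",
        "IIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"), "")[[1]]
      cods <- as.vector(t(outer(
        as.vector(t(outer(nts, nts, paste0))), nts, paste0)))
      code <<- stats::setNames(aas, cods)
    }
    code
  }
})

oracle_syn_sites <- function(codon) {
  code <- .oracle_code()
  ch <- strsplit(codon, "")[[1]]
  total <- 0
  for (pos in 1:3) {
    syn <- 0; valid <- 0
    for (nt in c("A", "C", "G", "T")) {
      if (nt == ch[pos]) next
      alt <- ch; alt[pos] <- nt
      alt <- paste(alt, collapse = "")
      if (code[[alt]] == "*") next
      valid <- valid + 1
      if (code[[alt]] == code[[codon]]) syn <- syn + 1
    }
    if (valid > 0) total <- total + syn / valid
  }
  total
}

oracle_pathways <- function(c1, c2) {
  code <- .oracle_code()
  ch1 <- strsplit(c1, "")[[1]]; ch2 <- strsplit(c2, "")[[1]]
  dpos <- which(ch1 != ch2)
  if (!length(dpos)) return(c(sd = 0, nd = 0))
  results <- list()
  recurse <- function(cur, remaining, sd, nd, stopped) {
    if (!length(remaining)) {
      results[[length(results) + 1]] <<- c(sd, nd, stopped)
      return(invisible())
    }
    for (k in seq_along(remaining)) {
      pos <- remaining[k]
      nxt <- cur; nxt[pos] <- ch2[pos]
      a1 <- code[[paste(cur, collapse = "")]]
      a2 <- code[[paste(nxt, collapse = "")]]
      recurse(nxt, remaining[-k],
              sd + (a1 == a2), nd + (a1 != a2),
              stopped || a2 == "*")
    }
  }
  recurse(ch1, dpos, 0, 0, FALSE)
  m <- do.call(rbind, results)
  ok <- m[, 3] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(m))
  c(sd = mean(m[ok, 1]), nd = mean(m[ok, 2]))
}

oracle_ng <- function(cdsA, cdsB) {
  n <- nchar(cdsA) / 3
  st <- 3 * seq_len(n) - 2
  ca <- substring(cdsA, st, st + 2); cb <- substring(cdsB, st, st + 2)
  S <- 0; Sd <- 0; Nd <- 0
  for (k in seq_len(n)) {
    S <- S + (oracle_syn_sites(ca[k]) + oracle_syn_sites(cb[k])) / 2
    d <- oracle_pathways(ca[k], cb[k])
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  list(S = S, N = 3 * n - S, Sd = Sd, Nd = Nd)
}

sense_codon_list <- function() {
  code <- .oracle_code()
  names(code)[code != "*"]
}
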