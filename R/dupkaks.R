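# Duplication-event detection (coverage/identity criteria plus tandem
# clustering on gene order), Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor
# correction, and divergence dating T = Ks / (2 r).

.codon_env <- new.env(parent = emptyenv())

.genetic_code <- function() {
  if (is.null(.codon_env$code)) {
    .codon_env$code <- Biostrings::GENETIC_CODE
  }
  .codon_env$code
}

.translate_codon <- function(codon) {
  aa <- .genetic_code()[codon]
  if (is.na(aa)) stop("not a valid codon: ", codon)
  unname(aa)
}

# Synonymous site count of one sense codon: each position contributes the
# fraction of its possible changes (changes to stop codons are disregarded)
# that preserve the amino acid; positions where every change hits a stop
# contribute 0. Site totals per codon always sum to 3.
.syn_sites_codon <- function(codon) {
  if (is.null(.codon_env$syn_sites)) {
    code <- .genetic_code()
    sense <- names(code)[code != "*"]
    nts <- c("A", "C", "G", "T")
    syn <- stats::setNames(numeric(length(sense)), sense)
    for (cd in sense) {
      ch <- strsplit(cd, "", fixed = TRUE)[[1L]]
      s <- 0
      for (pos in 1:3) {
        alts <- vapply(setdiff(nts, ch[pos]), function(nt) {
          x <- ch; x[pos] <- nt; paste(x, collapse = "")
        }, character(1))
        viable <- alts[code[alts] != "*"]
        if (length(viable)) {
          s <- s + mean(code[viable] == code[cd])
        }
      }
      syn[cd] <- s
    }
    .codon_env$syn_sites <- syn
  }
  v <- .codon_env$syn_sites[codon]
  if (is.na(v)) stop("stop or invalid codon in CDS: ", codon)
  unname(v)
}

.perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in .perms(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

# Average synonymous/nonsynonymous step counts over all minimal mutational
# pathways between two sense codons; pathways passing through a stop codon
# are excluded (all pathways used if none survive).
.pathway_diffs <- function(c1, c2) {
  ch1 <- strsplit(c1, "", fixed = TRUE)[[1L]]
  ch2 <- strsplit(c2, "", fixed = TRUE)[[1L]]
  diff_pos <- which(ch1 != ch2)
  if (length(diff_pos) == 0L) return(c(sd = 0, nd = 0))
  code <- .genetic_code()
  paths <- list()
  for (ord in .perms(diff_pos)) {
    cur <- ch1
    sd <- 0; nd <- 0; via_stop <- FALSE
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- ch2[pos]
      aa_cur <- code[paste(cur, collapse = "")]
      aa_nxt <- code[paste(nxt, collapse = "")]
      if (aa_nxt == "*") via_stop <- TRUE
      if (aa_cur == aa_nxt) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    paths[[length(paths) + 1L]] <- c(sd = sd, nd = nd, stop = via_stop)
  }
  pm <- do.call(rbind, paths)
  ok <- pm[, "stop"] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(pm))
  c(sd = mean(pm[ok, "sd"]), nd = mean(pm[ok, "nd"]))
}

#' Nei-Gojobori site and difference counts for an aligned codon pair
#'
#' Synonymous site counts are computed per codon (fractions of viable
#' single-nucleotide changes that are synonymous; changes to stop codons
#' are disregarded), summed along each sequence and averaged between the
#' two. Differences are averaged over all minimal mutational pathways
#' between each codon pair, excluding pathways through stop codons.
#' Codons containing gaps or ambiguity characters in either sequence are
#' skipped.
#'
#' @param cdsA,cdsB Aligned CDS strings of equal length divisible by 3;
#'   internal stop codons are an error.
#' @return List: S, N (site counts), Sd, Nd (differences), pS, pN
#'   (proportions), n_codons (codons compared).
#' @export
ng_counts <- function(cdsA, cdsB) {
  cdsA <- toupper(cdsA); cdsB <- toupper(cdsB)
  if (nchar(cdsA) != nchar(cdsB)) stop("aligned CDS differ in length")
  if (nchar(cdsA) %% 3 != 0) stop("aligned CDS length not divisible by 3")
  nc <- nchar(cdsA) / 3
  starts <- 3 * seq_len(nc) - 2
  codA <- substring(cdsA, starts, starts + 2)
  codB <- substring(cdsB, starts, starts + 2)
  code <- .genetic_code()
  S <- 0; N <- 0; Sd <- 0; Nd <- 0; used <- 0L
  for (k in seq_len(nc)) {
    a <- codA[k]; b <- codB[k]
    if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b)) next
    if (code[a] == "*" || code[b] == "*") {
      stop("internal stop codon at codon ", k)
    }
    sa <- .syn_sites_codon(a); sb <- .syn_sites_codon(b)
    S <- S + (sa + sb) / 2
    N <- N + (3 - (sa + sb) / 2)
    d <- .pathway_diffs(a, b)
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
    used <- used + 1L
  }
  if (used == 0L) stop("no comparable codons (all gapped or ambiguous)")
  list(S = S, N = N, Sd = Sd, Nd = Nd,
       pS = Sd / S, pN = Nd / N, n_codons = used)
}

#' Jukes-Cantor distance correction
#'
#' @param p Observed proportion of differences per site, `0 <= p < 0.75`.
#' @return `d = -(3/4) ln(1 - 4p/3)`.
#' @export
jukes_cantor <- function(p) {
  if (is.na(p) || p < 0) stop("proportion must be non-negative")
  if (p >= 0.75) stop("saturated: p >= 0.75, Jukes-Cantor distance undefined")
  -0.75 * log(1 - 4 * p / 3)
}

#' Global pairwise protein alignment with identity and coverage
#'
#' Needleman-Wunsch (BLOSUM62, gap open 10, gap extend 0.5) via
#' `Biostrings::pairwiseAlignment`. Identity is matches over aligned
#' residue pairs (columns gapped in either row excluded); coverage is the
#' aligned-pair count over the length of the longer sequence.
#'
#' @param protA,protB Ungapped protein sequences (trailing `*` tolerated).
#' @param idA,idB Optional sequence ids carried into the result.
#' @return Object of class `pair_alignment`: idA, idB, alnA, alnB,
#'   identity, coverage, n_aligned.
#' @export
align_pair <- function(protA, protB, idA = "A", idB = "B") {
  protA <- sub("\\*$", "", toupper(protA))
  protB <- sub("\\*$", "", toupper(protB))
  if (!nzchar(protA) || !nzchar(protB)) stop("empty protein sequence")
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  B62 <- get("BLOSUM62", envir = data_env)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protA), Biostrings::AAString(protB),
    substitutionMatrix = B62, gapOpening = 10, gapExtension = 0.5,
    type = "global")
  a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  both <- a != "-" & b != "-"
  n_aligned <- sum(both)
  identity <- if (n_aligned) sum(a[both] == b[both]) / n_aligned else 0
  coverage <- n_aligned / max(nchar(protA), nchar(protB))
  structure(list(idA = idA, idB = idB,
                 alnA = paste(a, collapse = ""),
                 alnB = paste(b, collapse = ""),
                 identity = identity, coverage = coverage,
                 n_aligned = n_aligned),
            class = "pair_alignment")
}

#' @export
print.pair_alignment <- function(x, ...) {
  cat(sprintf("<pair_alignment> %s vs %s: identity %.3f, coverage %.3f\n",
              x$idA, x$idB, x$identity, x$coverage))
  invisible(x)
}

#' Find duplicate gene pairs by coverage and identity
#'
#' All unordered protein pairs are aligned with [align_pair()]; a pair is a
#' duplicate candidate iff coverage and identity both strictly exceed their
#' thresholds (the `> 70 %` criteria).
#'
#' @param proteins Named character vector of member protein sequences.
#' @param cov_min,id_min Strict lower bounds.
#' @return `data.frame`: idA, idB, identity, coverage; the alignments are
#'   attached as attribute `alignments` (keyed `idA|idB`).
#' @export
find_duplicates <- function(proteins, cov_min = 0.70, id_min = 0.70) {
  ids <- names(proteins)
  if (length(ids) < 2L) {
    out <- data.frame(idA = character(0), idB = character(0),
                      identity = numeric(0), coverage = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "alignments") <- list()
    return(out)
  }
  rows <- list(); alns <- list()
  for (i in seq_len(length(ids) - 1L)) {
    for (j in (i + 1L):length(ids)) {
      pa <- align_pair(proteins[[i]], proteins[[j]], ids[i], ids[j])
      if (pa$coverage > cov_min && pa$identity > id_min) {
        rows[[length(rows) + 1L]] <- data.frame(
          idA = ids[i], idB = ids[j], identity = pa$identity,
          coverage = pa$coverage, stringsAsFactors = FALSE)
        alns[[paste(ids[i], ids[j], sep = "|")]] <- pa
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(idA = character(0), idB = character(0),
               identity = numeric(0), coverage = numeric(0),
               stringsAsFactors = FALSE)
  attr(out, "alignments") <- alns
  out
}

#' Classify a duplicate pair as tandem or dispersed
#'
#' Tandem iff both genes sit on the same chromosome, the gap between their
#' nearest boundaries is below `max_gap_bp` (strict), and at most
#' `max_intervening` annotated genes (any strand, any family) lie strictly
#' between them; otherwise dispersed.
#'
#' @param idA,idB Gene ids of the pair.
#' @param genes Named list of [gene_model]s covering the whole annotation.
#' @param max_gap_bp Tandem gap bound in bp (default 100 kb).
#' @param max_intervening Maximum intervening gene count (default 5).
#' @return One-row `data.frame`: idA, idB, dup_class, gap_bp, n_intervening
#'   (the latter two `NA` for cross-chromosome pairs).
#' @export
classify_duplication <- function(idA, idB, genes, max_gap_bp = 100000L,
                                 max_intervening = 5L) {
  for (id in c(idA, idB)) {
    if (!id %in% names(genes)) stop("gene missing from annotation: ", id)
  }
  ga <- genes[[idA]]; gb <- genes[[idB]]
  if (!identical(ga$chrom, gb$chrom)) {
    return(data.frame(idA = idA, idB = idB, dup_class = "dispersed",
                      gap_bp = NA_integer_, n_intervening = NA_integer_,
                      stringsAsFactors = FALSE))
  }
  left <- if (ga$start <= gb$start) ga else gb
  right <- if (ga$start <= gb$start) gb else ga
  gap <- max(0L, right$start - left$end - 1L)
  inter <- 0L
  for (g in genes) {
    if (g$gene_id %in% c(idA, idB)) next
    if (!identical(g$chrom, ga$chrom)) next
    if (g$start > left$end && g$end < right$start) inter <- inter + 1L
  }
  cls <- if (gap < max_gap_bp && inter <= max_intervening) "tandem"
         else "dispersed"
  data.frame(idA = idA, idB = idB, dup_class = cls, gap_bp = gap,
             n_intervening = inter, stringsAsFactors = FALSE)
}

# Project a protein pair alignment onto the two CDS: returns the aligned
# codon strings (gap codons where the protein alignment has gaps).
.project_codon_alignment <- function(cdsA, cdsB, protAln) {
  a <- strsplit(protAln$alnA, "", fixed = TRUE)[[1L]]
  b <- strsplit(protAln$alnB, "", fixed = TRUE)[[1L]]
  la <- sum(a != "-"); lb <- sum(b != "-")
  if (nchar(cdsA) != 3 * la) {
    stop("CDS/protein length mismatch for ", protAln$idA,
         ": ", nchar(cdsA), " nt vs ", la, " aa")
  }
  if (nchar(cdsB) != 3 * lb) {
    stop("CDS/protein length mismatch for ", protAln$idB,
         ": ", nchar(cdsB), " nt vs ", lb, " aa")
  }
  ca <- character(length(a)); cb <- character(length(b))
  ia <- 0L; ib <- 0L
  for (col in seq_along(a)) {
    if (a[col] == "-") {
      ca[col] <- "---"
    } else {
      ca[col] <- substr(cdsA, 3 * ia + 1, 3 * ia + 3); ia <- ia + 1L
    }
    if (b[col] == "-") {
      cb[col] <- "---"
    } else {
      cb[col] <- substr(cdsB, 3 * ib + 1, 3 * ib + 3); ib <- ib + 1L
    }
  }
  list(A = paste(ca, collapse = ""), B = paste(cb, collapse = ""))
}

#' Ka and Ks for a coding pair (Nei-Gojobori with Jukes-Cantor correction)
#'
#' The codon alignment is projected from the protein alignment (terminal
#' stop codons are trimmed from the CDS first), [ng_counts()] supplies the
#' proportions, and `ka = JC(pN)`, `ks = JC(pS)`. `omega = ka/ks` is `NA`
#' when `ks` is zero.
#'
#' @param cdsA,cdsB Ungapped CDS whose lengths equal 3 x the ungapped
#'   protein lengths after stop trimming.
#' @param protAln Optional [align_pair()] result; computed from the
#'   translated CDS when omitted.
#' @return List: ka, ks, omega, counts (the [ng_counts()] list).
#' @export
kaks_pair <- function(cdsA, cdsB, protAln = NULL) {
  cdsA <- .trim_stop(toupper(cdsA)); cdsB <- .trim_stop(toupper(cdsB))
  if (is.null(protAln)) {
    protAln <- align_pair(translate_cds(cdsA), translate_cds(cdsB))
  }
  proj <- .project_codon_alignment(cdsA, cdsB, protAln)
  cnt <- ng_counts(proj$A, proj$B)
  ks <- jukes_cantor(cnt$pS)
  ka <- jukes_cantor(cnt$pN)
  omega <- if (ks > 0) ka / ks else NA_real_
  list(ka = ka, ks = ks, omega = omega, counts = cnt)
}

.trim_stop <- function(cds) {
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3")
  last <- substr(cds, nchar(cds) - 2, nchar(cds))
  if (!grepl("[^ACGT]", last) && .genetic_code()[last] == "*") {
    cds <- substr(cds, 1, nchar(cds) - 3)
  }
  cds
}

#' Translate a CDS with the standard genetic code
#'
#' @param cds Ungapped CDS string, length divisible by 3; an internal stop
#'   codon is an error (a terminal stop is trimmed).
#' @return Protein sequence string.
#' @export
translate_cds <- function(cds) {
  cds <- .trim_stop(toupper(cds))
  nc <- nchar(cds) / 3
  starts <- 3 * seq_len(nc) - 2
  aa <- .genetic_code()[substring(cds, starts, starts + 2)]
  if (anyNA(aa)) stop("ambiguous codon in CDS")
  if (any(aa == "*")) stop("internal stop codon in CDS")
  paste(aa, collapse = "")
}

#' Divergence time from a synonymous distance
#'
#' `T = Ks / (2 r)`, reported in million years. The default rate is the
#' dicot nuclear clock of 1.5e-8 synonymous substitutions per site per
#' year.
#'
#' @param ks Synonymous substitutions per synonymous site.
#' @param r Substitution rate per site per year.
#' @return Divergence time in MYA.
#' @export
divergence_time <- function(ks, r = 1.5e-8) {
  stopifnot(ks >= 0, r > 0)
  ks / (2 * r) / 1e6
}
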