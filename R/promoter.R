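# Promoter extraction (1500 bp upstream of the translation start) and
# cis-element scanning against a user-supplied IUPAC motif catalog, with
# ubiquitous-element filtering and per-category summaries.

.IUPAC_CLASS <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")

.MOTIF_CATEGORIES <- c("light", "hormone", "stress", "development", "other")

#' Default ubiquitous elements excluded from scans
#' @export
DEFAULT_EXCLUDED_ELEMENTS <- c("CAAT-box", "TATA-box", "TATC-box")

.iupac_regex <- function(pattern) {
  ch <- strsplit(toupper(pattern), "", fixed = TRUE)[[1L]]
  cls <- .IUPAC_CLASS[ch]
  if (anyNA(cls)) {
    stop("malformed IUPAC pattern '", pattern, "': illegal code '",
         ch[is.na(cls)][1L], "'")
  }
  paste(cls, collapse = "")
}

#' Reverse complement of a DNA string (IUPAC-aware)
#'
#' @param x DNA string, ambiguity codes allowed.
#' @return Reverse-complemented string.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Read a cis-element catalog
#'
#' TSV with header columns `name`, `iupac`, `category`
#' (light/hormone/stress/development/other).
#'
#' @param path Path to the catalog TSV.
#' @return `data.frame` with validated patterns.
#' @export
read_motif_catalog <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "iupac", "category")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("catalog missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$name)) {
    stop("duplicate motif name: ", tab$name[duplicated(tab$name)][1L])
  }
  for (p in tab$iupac) .iupac_regex(p)  # validates
  bad <- setdiff(tab$category, .MOTIF_CATEGORIES)
  if (length(bad)) stop("unknown motif category: ", bad[[1L]])
  tab
}

#' Extract the upstream promoter of a gene
#'
#' Returns the `length` bp 5' of the translation start (the first CDS base),
#' strand-aware: minus-strand promoters are reverse-complemented so the
#' returned string reads 5' to 3' toward the gene. Promoters running off
#' the chromosome end are truncated with a warning.
#'
#' @param model A [gene_model].
#' @param genome Named character vector of chromosome sequences.
#' @param length Promoter length in bp (default 1500).
#' @return Promoter string with attributes `gene_id` and `truncated`.
#' @export
extract_upstream <- function(model, genome, length = 1500L) {
  if (!model$chrom %in% names(genome)) {
    stop("chromosome not in genome: ", model$chrom)
  }
  chrom <- genome[[model$chrom]]
  clen <- nchar(chrom)
  truncated <- FALSE
  if (model$strand == "+") {
    tss <- min(model$cds[, 1L])
    from <- tss - length
    if (from < 1L) { from <- 1L; truncated <- TRUE }
    to <- tss - 1L
    seq <- if (to >= from) substr(chrom, from, to) else ""
  } else {
    tss <- max(model$cds[, 2L])
    to <- tss + length
    if (to > clen) { to <- clen; truncated <- TRUE }
    from <- tss + 1L
    seq <- if (to >= from) reverse_complement(substr(chrom, from, to)) else ""
  }
  if (truncated) {
    warning("promoter of ", model$gene_id, " truncated to ",
            nchar(seq), " bp at chromosome end")
  }
  attr(seq, "gene_id") <- model$gene_id
  attr(seq, "truncated") <- truncated
  seq
}

#' Scan a promoter against a motif catalog
#'
#' Exact IUPAC matching on both strands at every offset (overlapping
#' occurrences included). Positions are 1-based offsets of the match on the
#' promoter string as given; minus-strand hits are occurrences of a
#' pattern's reverse complement. Elements named in `exclude` are dropped.
#'
#' @param promoter Promoter string (attribute `gene_id` is propagated).
#' @param catalog Catalog `data.frame` from [read_motif_catalog()].
#' @param exclude Names of ubiquitous elements to drop
#'   (default CAAT-box/TATA-box/TATC-box).
#' @return `data.frame`: gene_id, motif, position, strand, category.
#' @export
scan_motifs <- function(promoter, catalog,
                        exclude = DEFAULT_EXCLUDED_ELEMENTS) {
  stopifnot(nrow(catalog) >= 1L)
  gene_id <- attr(promoter, "gene_id")
  if (is.null(gene_id)) gene_id <- NA_character_
  prom <- toupper(as.character(promoter))
  cat_use <- catalog[!(catalog$name %in% exclude), , drop = FALSE]
  rows <- list()
  find_all <- function(rx) {
    if (!nzchar(prom)) return(integer(0))
    m <- gregexpr(paste0("(?=", rx, ")"), prom, perl = TRUE)[[1L]]
    if (m[1L] == -1L) integer(0) else as.integer(m)
  }
  for (i in seq_len(nrow(cat_use))) {
    pat <- cat_use$iupac[[i]]
    fw <- find_all(.iupac_regex(pat))
    rv <- find_all(.iupac_regex(reverse_complement(pat)))
    for (p in fw) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene_id, motif = cat_use$name[[i]], position = p,
        strand = "+", category = cat_use$category[[i]],
        stringsAsFactors = FALSE)
    }
    for (p in rv) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene_id, motif = cat_use$name[[i]], position = p,
        strand = "-", category = cat_use$category[[i]],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(gene_id = character(0), motif = character(0),
                      position = integer(0), strand = character(0),
                      category = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$position, out$motif, out$strand), , drop = FALSE]
}

#' Category summaries of cis-element hits
#'
#' Reports, per gene and family-wide, both the number of distinct element
#' names per category (element types) and the raw occurrence counts
#' (element instances).
#'
#' @param hits Hit `data.frame` from [scan_motifs()] (possibly several
#'   genes row-bound together).
#' @param catalog Catalog used for the scan; a hit naming an unknown motif
#'   is an error.
#' @return List: per_gene_types, per_gene_instances (gene x category
#'   matrices) and family_types (distinct element names per category across
#'   all genes).
#' @export
categorize_elements <- function(hits, catalog) {
  unknown <- setdiff(hits$motif, catalog$name)
  if (length(unknown)) stop("hit references unknown motif: ", unknown[[1L]])
  genes <- unique(hits$gene_id)
  cats <- .MOTIF_CATEGORIES
  types <- matrix(0L, length(genes), length(cats),
                  dimnames = list(genes, cats))
  inst <- matrix(0L, length(genes), length(cats),
                 dimnames = list(genes, cats))
  for (g in genes) {
    h <- hits[hits$gene_id == g, , drop = FALSE]
    for (cc in cats) {
      hc <- h[h$category == cc, , drop = FALSE]
      types[g, cc] <- length(unique(hc$motif))
      inst[g, cc] <- nrow(hc)
    }
  }
  family <- vapply(cats, function(cc)
    length(unique(hits$motif[hits$category == cc])), integer(1))
  list(per_gene_types = types, per_gene_instances = inst,
       family_types = family)
}
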