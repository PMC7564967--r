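# Readers/writers for FASTA, GFF3, domain-hit tables and Newick, plus the
# shared record types (sequence sets, gene models, domain hits) every other
# stage consumes. Coordinates are 1-based inclusive throughout.

.ALPHABET_CHARS <- list(
  dna     = c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N", "-"),
  protein = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V", "B", "Z", "J", "U",
              "O", "X", "*", "-")
)

#' Read a FASTA file into a named character vector
#'
#' Sequences are returned uppercase with all whitespace stripped, in file
#' order, named by the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file. An empty file yields an empty set.
#' @param alphabet `"dna"` or `"protein"`; characters outside the declared
#'   alphabet (IUPAC ambiguity codes and `-` are allowed) raise an error
#'   naming the sequence and offending position.
#' @return Named character vector with attribute `alphabet`.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  if (!any(grepl("^>", raw))) {
    if (all(!nzchar(trimws(raw)))) {
      out <- character(0)
      attr(out, "alphabet") <- alphabet
      return(out)
    }
    stop("not a FASTA file (no '>' header): ", path)
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(gsub("[[:space:]]", "", as.character(set)))
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id: ", dup[[1L]])
  ok <- .ALPHABET_CHARS[[alphabet]]
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[[i]])) stop("empty sequence for id ", ids[[i]])
    ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1L]]
    bad <- which(!(ch %in% ok))
    if (length(bad)) {
      stop(sprintf("illegal %s character '%s' at position %d in sequence %s",
                   alphabet, ch[bad[1L]], bad[1L], ids[[i]]))
    }
  }
  names(seqs) <- ids
  attr(seqs, "alphabet") <- alphabet
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[[i]]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome / scaffold name.
#' @param strand `"+"` or `"-"`.
#' @param start,end 1-based inclusive gene span.
#' @param exons Two-column matrix of exon (start, end), sorted, non-overlapping.
#' @param cds Two-column matrix of CDS segments, each contained in an exon.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, start, end, exons, cds) {
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  cds <- matrix(as.integer(cds), ncol = 2L,
                dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  cds <- cds[order(cds[, 1L]), , drop = FALSE]
  if (start > end) stop("gene ", gene_id, ": start > end")
  if (!strand %in% c("+", "-")) stop("gene ", gene_id, ": bad strand")
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] <= exons[-nrow(exons), 2L])) {
    stop("gene ", gene_id, ": overlapping exons")
  }
  for (i in seq_len(nrow(cds))) {
    inside <- any(cds[i, 1L] >= exons[, 1L] & cds[i, 2L] <= exons[, 2L])
    if (!inside) stop("gene ", gene_id, ": CDS segment outside any exon")
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 start = as.integer(start), end = as.integer(end),
                 exons = exons, cds = cds),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s) exons=%d cds_bp=%d\n",
              x$gene_id, x$chrom, x$start, x$end, x$strand,
              nrow(x$exons), sum(x$cds[, 2L] - x$cds[, 1L] + 1L)))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS features. When a gene carries several mRNAs the
#' transcript with the longest total CDS is kept (ties broken by transcript
#' id); the retained transcript id is stored in the model's
#' `transcript_id` element. Exon/CDS features whose `Parent` cannot be
#' resolved, and CDS segments falling outside every exon, are errors.
#'
#' @param path Path to a GFF3 file.
#' @return Named list of [gene_model] objects in gene file order.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  g <- as.data.frame(rtracklayer::readGFF(
    path, columns = c("seqid", "type", "start", "end", "strand"),
    tags = c("ID", "Parent")))
  g$Parent <- vapply(g$Parent, function(p)
    if (length(p)) as.character(p[[1L]]) else NA_character_, character(1))
  g$type <- as.character(g$type)
  g$seqid <- as.character(g$seqid)
  g$strand <- as.character(g$strand)

  genes <- g[g$type == "gene", , drop = FALSE]
  mrnas <- g[g$type %in% c("mRNA", "transcript"), , drop = FALSE]
  parts <- g[g$type %in% c("exon", "CDS"), , drop = FALSE]
  if (nrow(mrnas)) {
    unknown <- setdiff(mrnas$Parent, genes$ID)
    if (length(unknown)) stop("mRNA with unknown Parent: ", unknown[[1L]])
  }
  known_parents <- c(mrnas$ID, genes$ID)
  bad <- setdiff(parts$Parent, known_parents)
  if (length(bad)) stop("feature with unknown Parent: ", bad[[1L]])

  out <- vector("list", nrow(genes))
  names(out) <- genes$ID
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[[i]]
    tx <- mrnas[!is.na(mrnas$Parent) & mrnas$Parent == gid, , drop = FALSE]
    if (nrow(tx) == 0L) {
      # exon/CDS attached directly to the gene
      tx_ids <- gid
    } else {
      cds_len <- vapply(tx$ID, function(tid) {
        seg <- parts[parts$type == "CDS" & parts$Parent == tid, , drop = FALSE]
        sum(seg$end - seg$start + 1L)
      }, numeric(1))
      tx_ids <- tx$ID[order(-cds_len, tx$ID)][1L]
    }
    ex <- parts[parts$type == "exon" & parts$Parent == tx_ids, , drop = FALSE]
    cd <- parts[parts$type == "CDS" & parts$Parent == tx_ids, , drop = FALSE]
    if (nrow(ex) == 0L && nrow(cd) > 0L) ex <- cd
    m <- gene_model(gid, genes$seqid[[i]], genes$strand[[i]],
                    genes$start[[i]], genes$end[[i]],
                    cbind(ex$start, ex$end), cbind(cd$start, cd$end))
    m$transcript_id <- if (identical(tx_ids, gid)) NA_character_ else tx_ids
    out[[i]] <- m
  }
  out
}

#' Summarize a gene-model collection as a table
#'
#' @param models List of [gene_model] objects.
#' @return `data.frame` with one row per gene (id, chrom, strand, span,
#'   exon count, CDS bp).
#' @export
gene_table <- function(models) {
  do.call(rbind, lapply(models, function(m) {
    data.frame(gene_id = m$gene_id, chrom = m$chrom, strand = m$strand,
               start = m$start, end = m$end, n_exons = nrow(m$exons),
               cds_len_bp = sum(m$cds[, 2L] - m$cds[, 1L] + 1L),
               stringsAsFactors = FALSE)
  }))
}

# Pfam accession / alias -> controlled domain vocabulary
.DOMAIN_ALIASES <- c(
  "PF00139" = "Lectin_legB", "Lectin_legB" = "Lectin_legB",
  "PF01453" = "B_lectin",    "B_lectin"    = "B_lectin",
  "PF00059" = "Lectin_C",    "Lectin_C"    = "Lectin_C",
  "PF00069" = "kinase", "Pkinase" = "kinase",
  "PF07714" = "kinase", "Pkinase_Tyr" = "kinase", "kinase" = "kinase",
  "TM" = "TM", "transmembrane" = "TM", "TMhelix" = "TM",
  "signal_peptide" = "signal_peptide", "SignalP" = "signal_peptide",
  "PF00008" = "EGF", "EGF" = "EGF",
  "PF00024" = "PAN", "PAN" = "PAN", "PAN_2" = "PAN", "PAN_AP" = "PAN",
  "PF05382" = "S_locus", "S_locus" = "S_locus",
  "S_locus_glycop" = "S_locus", "PF00954" = "S_locus"
)

.normalize_domain <- function(name, accession = NA_character_) {
  acc <- sub("\\.\\d+$", "", accession)
  if (!is.na(acc) && acc %in% names(.DOMAIN_ALIASES)) {
    return(unname(.DOMAIN_ALIASES[[acc]]))
  }
  if (name %in% names(.DOMAIN_ALIASES)) return(unname(.DOMAIN_ALIASES[[name]]))
  name
}

#' Read a domain-hit table
#'
#' Two dialects are supported: HMMER3 `domtblout` (as written by
#' `hmmscan --domtblout`, where the query is the protein and the target the
#' model; the per-domain independent E-value is used) and a generic TSV with
#' header columns `protein_id`, `domain`, `evalue`, `start`, `end` and
#' optionally `source`. Pfam accessions for the lectin (PF00139, PF01453,
#' PF00059), kinase (PF00069, PF07714) and accessory (EGF, PAN, S-locus)
#' models are normalized to the controlled vocabulary.
#'
#' @param path Path to the table.
#' @param dialect `"tsv"` or `"domtblout"`.
#' @return `data.frame` of hits: protein_id, domain, evalue, start, end,
#'   source.
#' @export
read_domain_table <- function(path, dialect = c("tsv", "domtblout")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("domain table not found: ", path)
  if (dialect == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("protein_id", "domain", "evalue", "start", "end")
    miss <- setdiff(need, names(tab))
    if (length(miss)) stop("domain TSV missing columns: ",
                           paste(miss, collapse = ", "))
    if (is.null(tab$source)) tab$source <- "tsv"
    hits <- data.frame(
      protein_id = as.character(tab$protein_id),
      domain = vapply(as.character(tab$domain), .normalize_domain,
                      character(1), USE.NAMES = FALSE),
      evalue = as.numeric(tab$evalue),
      start = as.integer(tab$start), end = as.integer(tab$end),
      source = as.character(tab$source), stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
    rows <- lapply(keep, function(i) {
      f <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1L]]
      if (length(f) < 22L) stop("unparseable domtblout row at line ", i)
      list(line = i, target = f[[1L]], acc = f[[2L]], query = f[[4L]],
           ievalue = suppressWarnings(as.numeric(f[[13L]])),
           from = suppressWarnings(as.integer(f[[18L]])),
           to = suppressWarnings(as.integer(f[[19L]])))
    })
    if (length(rows) == 0L) {
      return(data.frame(protein_id = character(0), domain = character(0),
                        evalue = numeric(0), start = integer(0),
                        end = integer(0), source = character(0),
                        stringsAsFactors = FALSE))
    }
    for (r in rows) {
      if (is.na(r$ievalue) || is.na(r$from) || is.na(r$to)) {
        stop("unparseable domtblout row at line ", r$line)
      }
    }
    hits <- data.frame(
      protein_id = vapply(rows, `[[`, character(1), "query"),
      domain = vapply(rows, function(r) .normalize_domain(r$target, r$acc),
                      character(1)),
      evalue = vapply(rows, `[[`, numeric(1), "ievalue"),
      start = vapply(rows, `[[`, integer(1), "from"),
      end = vapply(rows, `[[`, integer(1), "to"),
      source = "domtblout", stringsAsFactors = FALSE)
  }
  bad <- which(hits$end < hits$start)
  if (length(bad)) stop("domain hit with end < start at row ", bad[[1L]])
  if (any(hits$evalue < 0)) stop("negative e-value in domain table")
  hits
}

.newick_quote <- function(label) {
  if (grepl("[][():;,'\" \t]", label)) {
    paste0("'", gsub("'", "''", label), "'")
  } else {
    label
  }
}

#' Serialize a phylogeny to Newick
#'
#' Branch lengths are written with six decimals; internal-node labels
#' (integer bootstrap supports, when present) are written after the closing
#' parenthesis. Leaf names containing Newick metacharacters are quoted. The
#' output round-trips through standard Newick parsers.
#'
#' @param tree An object of class `phylo` (at least 2 leaves).
#' @return A single Newick string, terminated by `;`.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("tree must have at least 2 leaves")
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  has_len <- !is.null(tree$edge.length)
  node_lab <- tree$node.label
  fmt <- function(node, edge_idx) {
    if (node <= ntip) {
      s <- .newick_quote(tree$tip.label[[node]])
    } else {
      ch <- kids[[as.character(node)]]
      inner <- vapply(ch, function(e) fmt(tree$edge[e, 2L], e), character(1))
      lab <- ""
      if (!is.null(node_lab)) {
        l <- node_lab[[node - ntip]]
        if (!is.na(l) && nzchar(l)) lab <- as.character(l)
      }
      s <- paste0("(", paste(inner, collapse = ","), ")", lab)
    }
    if (!is.null(edge_idx) && has_len) {
      s <- paste0(s, sprintf(":%.6f", tree$edge.length[[edge_idx]]))
    }
    s
  }
  paste0(fmt(ntip + 1L, NULL), ";")
}

#' Write a table as TSV (tab-separated, header row)
#'
#' @param x A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
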