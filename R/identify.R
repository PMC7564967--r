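# Candidate identification by domain architecture and subfamily
# classification. A protein is a family member iff it carries a significant
# lectin-class domain plus at least one kinase and one transmembrane
# segment; the lectin class with the best e-value fixes the subfamily.

.LECTIN_DOMAINS <- c(Lectin_legB = "L", B_lectin = "G", Lectin_C = "C")

#' Apply the identification filter to a domain-hit table
#'
#' A protein is retained iff it has at least one lectin-class hit
#' (Lectin_legB, B_lectin or Lectin_C) with e-value strictly below
#' `evalue_cutoff`, at least one kinase hit and at least one transmembrane
#' hit. The e-value cutoff applies to the lectin hit only; kinase and TM
#' evidence need only be present.
#'
#' @param hits Domain-hit `data.frame` as returned by [read_domain_table()].
#' @param evalue_cutoff Strict upper bound on the lectin-hit e-value.
#' @return Character vector of retained protein ids, in order of first
#'   appearance. An empty hit table yields an empty set.
#' @export
filter_candidates <- function(hits, evalue_cutoff = 0.001) {
  if (nrow(hits) == 0L) return(character(0))
  ids <- unique(hits$protein_id)
  keep <- vapply(ids, function(p) {
    h <- hits[hits$protein_id == p, , drop = FALSE]
    lectin_ok <- any(h$domain %in% names(.LECTIN_DOMAINS) &
                     h$evalue < evalue_cutoff)
    lectin_ok && any(h$domain == "kinase") && any(h$domain == "TM")
  }, logical(1))
  ids[keep]
}

#' Classify one retained protein into a subfamily
#'
#' The subfamily follows the lectin class of the best (lowest e-value)
#' significant lectin hit: Lectin_legB -> L, B_lectin -> G, Lectin_C -> C.
#' An exact e-value tie between two different lectin classes is an error
#' requiring manual resolution. Signal-peptide, TM-count and EGF/PAN/S-locus
#' flags are set from the remaining hits.
#'
#' @param hits Domain hits for a single protein that passed
#'   [filter_candidates()].
#' @param evalue_cutoff Same cutoff used for filtering.
#' @param gene_id Optional gene id; defaults to the protein id with a
#'   trailing `.N` isoform suffix removed.
#' @return One-row `data.frame`: gene_id, protein_id, subfamily, has_signal,
#'   n_tm, has_EGF, has_PAN, has_S_locus, lectin_evalue.
#' @export
classify_subfamily <- function(hits, evalue_cutoff = 0.001, gene_id = NULL) {
  pid <- unique(hits$protein_id)
  if (length(pid) != 1L) stop("hits must belong to a single protein")
  lec <- hits[hits$domain %in% names(.LECTIN_DOMAINS) &
              hits$evalue < evalue_cutoff, , drop = FALSE]
  if (nrow(lec) == 0L) stop("protein ", pid, " has no significant lectin hit")
  best_e <- min(lec$evalue)
  best <- unique(lec$domain[lec$evalue == best_e])
  if (length(best) > 1L) {
    stop("protein ", pid, ": lectin classes ",
         paste(best, collapse = " and "),
         " tie at e-value ", best_e, "; resolve manually")
  }
  if (is.null(gene_id)) gene_id <- sub("\\.\\d+$", "", pid)
  data.frame(
    gene_id = gene_id, protein_id = pid,
    subfamily = unname(.LECTIN_DOMAINS[[best]]),
    has_signal = any(hits$domain == "signal_peptide"),
    n_tm = sum(hits$domain == "TM"),
    has_EGF = any(hits$domain == "EGF"),
    has_PAN = any(hits$domain == "PAN"),
    has_S_locus = any(hits$domain == "S_locus"),
    lectin_evalue = best_e, stringsAsFactors = FALSE)
}

#' Identify and classify all family members in a hit table
#'
#' Convenience wrapper: [filter_candidates()] followed by
#' [classify_subfamily()] per retained protein.
#'
#' @inheritParams filter_candidates
#' @return `data.frame` of family members (one row per retained protein).
#' @export
classify_members <- function(hits, evalue_cutoff = 0.001) {
  kept <- filter_candidates(hits, evalue_cutoff)
  if (length(kept) == 0L) {
    return(data.frame(gene_id = character(0), protein_id = character(0),
                      subfamily = character(0), has_signal = logical(0),
                      n_tm = integer(0), has_EGF = logical(0),
                      has_PAN = logical(0), has_S_locus = logical(0),
                      lectin_evalue = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(kept, function(p) {
    classify_subfamily(hits[hits$protein_id == p, , drop = FALSE],
                       evalue_cutoff)
  }))
}

#' Tabulate domain architectures across subfamilies
#'
#' Counts members per subfamily and per accessory-domain combination
#' (EGF and PAN, EGF only, PAN only, neither), plus signal-peptide and
#' multi-TM tallies. All three subfamilies appear in the output even when
#' empty.
#'
#' @param members Member table from [classify_members()].
#' @return `data.frame` with one row per subfamily: n, egf_and_pan,
#'   egf_only, pan_only, neither, with_signal, without_signal, multi_tm.
#' @export
architecture_summary <- function(members) {
  out <- lapply(c("L", "G", "C"), function(sf) {
    m <- members[members$subfamily == sf, , drop = FALSE]
    data.frame(
      subfamily = sf, n = nrow(m),
      egf_and_pan = sum(m$has_EGF & m$has_PAN),
      egf_only = sum(m$has_EGF & !m$has_PAN),
      pan_only = sum(!m$has_EGF & m$has_PAN),
      neither = sum(!m$has_EGF & !m$has_PAN),
      with_signal = sum(m$has_signal),
      without_signal = sum(!m$has_signal),
      multi_tm = sum(m$n_tm > 1L), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
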