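# Physicochemical protein statistics (average-mass MW, Bjellqvist pI) and
# exon/intron structure summaries.

# average (isotope-weighted) residue masses, Da
.RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.WATER_MASS <- 18.0153

# Bjellqvist pKa set (ExPASy convention)
.PKA <- list(
  positive = c(Nterm = 7.50, K = 10.00, R = 12.00, H = 5.98),
  negative = c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.00, Y = 10.00))

#' Protein molecular weight (average masses)
#'
#' Sum of average residue masses plus one water (18.0153 Da). A trailing
#' stop (`*`) is tolerated and ignored; gaps are not.
#'
#' @param seq Protein sequence string.
#' @param allow_x When `TRUE`, `X` contributes a 110.0 Da placeholder;
#'   otherwise unknown residues are an error.
#' @return Molecular weight in kilodaltons.
#' @export
molecular_weight <- function(seq, allow_x = FALSE) {
  seq <- sub("\\*$", "", toupper(seq))
  if (!nzchar(seq)) stop("empty protein sequence")
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (any(ch == "-")) stop("gapped sequence: remove '-' before computing MW")
  mass <- .RESIDUE_MASS[ch]
  if (anyNA(mass)) {
    bad <- ch[is.na(mass)]
    if (allow_x && all(bad == "X")) {
      mass[is.na(mass)] <- 110.0
    } else {
      stop("unknown residue code: ", bad[[1L]])
    }
  }
  (sum(mass) + .WATER_MASS) / 1000
}

.protein_charge <- function(counts, pH, pka = .PKA) {
  pos <- sum(counts[names(pka$positive)] /
             (1 + 10^(pH - pka$positive)), na.rm = TRUE)
  neg <- sum(counts[names(pka$negative)] /
             (1 + 10^(pka$negative - pH)), na.rm = TRUE)
  pos - neg
}

#' Protein isoelectric point
#'
#' pH at which the Henderson-Hasselbalch net charge of the ionizable groups
#' (termini plus D, E, C, Y, H, K, R side chains) vanishes, located by
#' bisection on `[0, 14]` until `|charge| < 1e-4`. The default pKa table is
#' the Bjellqvist set as used by ExPASy; supply `pka` to override.
#'
#' @param seq Protein sequence string (a trailing `*` is ignored).
#' @param pka List with numeric vectors `positive` (Nterm, K, R, H) and
#'   `negative` (Cterm, D, E, C, Y) of pKa values.
#' @return The pI in pH units.
#' @export
isoelectric_point <- function(seq, pka = .PKA) {
  seq <- sub("\\*$", "", toupper(seq))
  if (!nzchar(seq)) stop("empty protein sequence")
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  counts <- table(factor(ch, levels = names(.RESIDUE_MASS)))
  counts <- c(as.numeric(counts), Nterm = 1, Cterm = 1)
  names(counts) <- c(names(.RESIDUE_MASS), "Nterm", "Cterm")
  lo <- 0; hi <- 14
  if (.protein_charge(counts, lo, pka) < 0 ||
      .protein_charge(counts, hi, pka) > 0) {
    stop("net charge does not bracket zero on [0, 14]")
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- .protein_charge(counts, mid, pka)
    if (abs(q) < 1e-4) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Per-protein property table
#'
#' @param seqs Named character vector of protein sequences.
#' @param allow_x Passed to [molecular_weight()].
#' @return `data.frame`: protein_id, length_aa, mw_kda, pi.
#' @export
protein_props <- function(seqs, allow_x = FALSE) {
  ids <- names(seqs)
  data.frame(
    protein_id = ids,
    length_aa = nchar(sub("\\*$", "", seqs)),
    mw_kda = vapply(seqs, molecular_weight, numeric(1), allow_x = allow_x,
                    USE.NAMES = FALSE),
    pi = vapply(seqs, isoelectric_point, numeric(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}

#' Exon/intron structure statistics for one gene
#'
#' @param model A [gene_model].
#' @return One-row `data.frame`: gene_id, n_exons, n_introns, cds_len_bp,
#'   gene_len_bp.
#' @export
gene_structure <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  n_ex <- nrow(model$exons)
  data.frame(
    gene_id = model$gene_id, n_exons = n_ex, n_introns = n_ex - 1L,
    cds_len_bp = sum(model$cds[, 2L] - model$cds[, 1L] + 1L),
    gene_len_bp = model$end - model$start + 1L, stringsAsFactors = FALSE)
}

#' Family-wide structure summary
#'
#' Ranges of CDS length and molecular weight (with the carrier ids) and the
#' mean intron count, reported to two decimals.
#'
#' @param stats `data.frame` of per-gene rows from [gene_structure()].
#' @param props Optional [protein_props()] table for the MW range.
#' @return List: cds_len (min/max + ids), mean_introns, and when `props`
#'   is given, mw_kda (min/max + ids).
#' @export
family_structure_report <- function(stats, props = NULL) {
  stopifnot(nrow(stats) >= 1L)
  rep <- list(
    cds_len = list(
      min = min(stats$cds_len_bp),
      min_id = stats$gene_id[which.min(stats$cds_len_bp)],
      max = max(stats$cds_len_bp),
      max_id = stats$gene_id[which.max(stats$cds_len_bp)]),
    mean_introns = round(mean(stats$n_introns), 2))
  if (!is.null(props)) {
    rep$mw_kda <- list(
      min = round(min(props$mw_kda), 1),
      min_id = props$protein_id[which.min(props$mw_kda)],
      max = round(max(props$mw_kda), 1),
      max_id = props$protein_id[which.max(props$mw_kda)])
  }
  rep
}
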