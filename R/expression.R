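# FPKM tissue-expression profiling (constitutive/expressed flags, 3-group
# partition, Venn membership) and 2^-ddCt qPCR fold-change calling.

#' Read a gene x tissue FPKM matrix
#'
#' TSV with gene ids in the first column and tissue labels in the header.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix (genes x tissues).
#' @export
read_expression_matrix <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(mat) <- tab[[1L]]
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop("missing cells in expression matrix")
  if (any(mat < 0)) stop("negative FPKM in expression matrix")
  mat
}

#' Constitutive flags and per-tissue expressed sets
#'
#' A gene is constitutive iff its FPKM is at least `constitutive_min` in
#' every tissue; the per-tissue expressed sets collect genes with FPKM at
#' least `expressed_min` (both thresholds inclusive).
#'
#' @param mat FPKM matrix (genes x tissues).
#' @param constitutive_min Inclusive constitutive threshold (default 1).
#' @param expressed_min Inclusive membership threshold for the per-tissue
#'   sets used in Venn analyses (default 2).
#' @return List: `constitutive` (named logical vector) and
#'   `expressed_sets` (list of gene-id vectors per tissue).
#' @export
expression_flags <- function(mat, constitutive_min = 1.0,
                             expressed_min = 2.0) {
  stopifnot(nrow(mat) >= 1L)
  constitutive <- apply(mat >= constitutive_min, 1L, all)
  expressed_sets <- lapply(seq_len(ncol(mat)), function(j)
    rownames(mat)[mat[, j] >= expressed_min])
  names(expressed_sets) <- colnames(mat)
  list(constitutive = constitutive, expressed_sets = expressed_sets)
}

#' Partition genes into expression-level groups
#'
#' Seeded k-means (100 restarts) on the per-gene mean of `log2(FPKM + 1)`;
#' groups are relabeled 1..k by descending mean FPKM so group 1 is the
#' highest-expressed. Deterministic given `seed`. When all genes share one
#' expression value the clustering is degenerate: a single group is
#' returned with a warning.
#'
#' @param mat FPKM matrix (genes x tissues).
#' @param k Number of groups (default 3).
#' @param seed Integer seed.
#' @return `data.frame` rows per group: group, n, mean_fpkm, plus a
#'   `membership` attribute (named integer vector gene -> group).
#' @export
group_expression <- function(mat, k = 3L, seed = 1L) {
  if (nrow(mat) < k) stop("fewer genes than groups: ", nrow(mat), " < ", k)
  x <- rowMeans(log2(mat + 1))
  if (length(unique(x)) == 1L) {
    warning("all genes have identical mean expression; single group")
    member <- stats::setNames(rep(1L, length(x)), names(x))
    out <- data.frame(group = 1L, n = length(x),
                      mean_fpkm = round(mean(rowMeans(mat)), 2))
    attr(out, "membership") <- member
    return(out)
  }
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  k_use <- min(k, length(unique(x)))
  km <- if (length(unique(x)) <= k_use) {
    # as many distinct expression levels as groups: clustering is trivial
    list(cluster = match(x, sort(unique(x), decreasing = TRUE)))
  } else {
    stats::kmeans(x, centers = k_use, nstart = 100)
  }
  raw_mean <- vapply(seq_len(k_use), function(g)
    mean(rowMeans(mat[km$cluster == g, , drop = FALSE])), numeric(1))
  relabel <- order(order(-raw_mean))  # old cluster id -> rank label
  member <- stats::setNames(relabel[km$cluster], rownames(mat))
  out <- do.call(rbind, lapply(seq_len(k_use), function(g) {
    sel <- member == g
    data.frame(group = g, n = sum(sel),
               mean_fpkm = round(mean(rowMeans(mat[sel, , drop = FALSE])), 2))
  }))
  attr(out, "membership") <- member
  out
}

#' Venn region counts for 2-5 named sets
#'
#' Counts every non-empty region of the Venn diagram by exact set algebra:
#' a region is the set of elements in all named sets of the region and in
#' none of the others.
#'
#' @param sets Named list of 2-5 character vectors.
#' @return `data.frame`: region (member set names joined by `&`), count.
#' @export
venn_membership <- function(sets) {
  n <- length(sets)
  if (n < 2L || n > 5L) stop("venn_membership supports 2-5 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be named")
  }
  sets <- lapply(sets, unique)
  nm <- names(sets)
  rows <- list()
  for (mask in seq_len(2^n - 1L)) {
    inside <- nm[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0]
    outside <- setdiff(nm, inside)
    members <- Reduce(intersect, sets[inside])
    for (o in outside) members <- setdiff(members, sets[[o]])
    rows[[length(rows) + 1L]] <- data.frame(
      region = paste(inside, collapse = "&"),
      count = length(members), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Read a qPCR Ct table
#'
#' CSV with columns `gene_id`, `condition`, `replicate`, `ct_target`,
#' `ct_reference`; Ct values must lie in (0, 45).
#'
#' @param path Path to the CSV.
#' @return Validated `data.frame`.
#' @export
read_qpcr <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "condition", "replicate", "ct_target", "ct_reference")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("qPCR table missing columns: ",
                         paste(miss, collapse = ", "))
  ct <- c(tab$ct_target, tab$ct_reference)
  if (any(ct <= 0 | ct >= 45)) stop("Ct values must lie in (0, 45)")
  tab
}

#' 2^-ddCt fold change with a Welch t-test call
#'
#' Per replicate `dCt = ct_target - ct_reference`; `ddCt` is the mean dCt
#' of the treatment minus the mean dCt of the control, the fold change is
#' `2^-ddCt`, and the p-value comes from a two-sided Welch t-test on the
#' replicate dCt values. Call: `up` iff fold change > 1 and p <= p_cutoff,
#' `down` iff fold change < 1 and p <= p_cutoff, else `ns`. When both
#' replicate groups are exactly constant (noise-free data) the t-test is
#' degenerate and p is 0 when the means differ, 1 otherwise.
#'
#' @param records qPCR `data.frame` as from [read_qpcr()].
#' @param gene Gene id.
#' @param condition Treatment label (not the control).
#' @param control Control label (default `"control"`).
#' @param p_cutoff Significance threshold (default 0.05).
#' @return One-row `data.frame`: gene_id, condition, fold_change, p_value,
#'   call.
#' @export
ddct_fold_change <- function(records, gene, condition, control = "control",
                             p_cutoff = 0.05) {
  g <- records[records$gene_id == gene, , drop = FALSE]
  trt <- g[g$condition == condition, , drop = FALSE]
  ctl <- g[g$condition == control, , drop = FALSE]
  if (nrow(ctl) < 2L) stop("missing or underreplicated control for ", gene)
  if (nrow(trt) < 2L) {
    stop("fewer than 2 replicates for ", gene, " under ", condition)
  }
  dct_t <- trt$ct_target - trt$ct_reference
  dct_c <- ctl$ct_target - ctl$ct_reference
  ddct <- mean(dct_t) - mean(dct_c)
  fc <- 2^(-ddct)
  p <- if (stats::sd(dct_t) == 0 && stats::sd(dct_c) == 0) {
    if (isTRUE(all.equal(mean(dct_t), mean(dct_c)))) 1 else 0
  } else {
    stats::t.test(dct_t, dct_c, var.equal = FALSE)$p.value
  }
  call <- if (p <= p_cutoff && fc > 1) "up"
          else if (p <= p_cutoff && fc < 1) "down"
          else "ns"
  data.frame(gene_id = gene, condition = condition, fold_change = fc,
             p_value = p, call = call, stringsAsFactors = FALSE)
}

#' Fold-change calls for every gene x treatment in a qPCR table
#'
#' @inheritParams ddct_fold_change
#' @return `data.frame` with one row per gene x non-control condition.
#' @export
ddct_all <- function(records, control = "control", p_cutoff = 0.05) {
  conds <- setdiff(unique(records$condition), control)
  genes <- unique(records$gene_id)
  rows <- list()
  for (g in genes) {
    for (cc in conds) {
      rows[[length(rows) + 1L]] <-
        ddct_fold_change(records, g, cc, control, p_cutoff)
    }
  }
  do.call(rbind, rows)
}
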