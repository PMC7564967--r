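# Poisson-corrected protein distances with pairwise deletion, Saitou-Nei
# neighbor joining, and column-bootstrap supports. The NJ implementation is
# the package's own; ape is used only for the tree container and Newick
# round-trips.

#' Poisson-corrected distance between two aligned rows
#'
#' Columns gapped in either row are dropped (pairwise deletion); with
#' mismatch proportion `p` over the compared columns the distance is
#' `-ln(1 - p)`.
#'
#' @param rowA,rowB Equal-length gapped residue strings.
#' @return Non-negative distance.
#' @export
poisson_distance <- function(rowA, rowB) {
  a <- strsplit(rowA, "", fixed = TRUE)[[1L]]
  b <- strsplit(rowB, "", fixed = TRUE)[[1L]]
  if (length(a) != length(b)) stop("rows differ in length")
  keep <- a != "-" & b != "-"
  n <- sum(keep)
  if (n == 0L) stop("no comparable columns (all pairwise-deleted)")
  p <- sum(a[keep] != b[keep]) / n
  if (p >= 1) stop("saturated distance: p >= 1")
  -log(1 - p)
}

#' Poisson distance matrix for a multiple alignment
#'
#' @param aln Named character vector of equal-length gapped rows.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
poisson_dist_matrix <- function(aln) {
  ids <- names(aln)
  if (length(unique(nchar(aln))) != 1L) stop("alignment rows differ in length")
  m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      keep <- m[i, ] != "-" & m[j, ] != "-"
      nc <- sum(keep)
      if (nc == 0L) stop("no comparable columns between ", ids[i],
                         " and ", ids[j])
      p <- sum(m[i, keep] != m[j, keep]) / nc
      if (p >= 1) stop("saturated distance between ", ids[i], " and ", ids[j])
      D[i, j] <- D[j, i] <- -log(1 - p)
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion. Negative branch
#' lengths are clamped to zero with the deficit transferred to the sister
#' branch. The result is unrooted (a basal trifurcation), returned as an
#' `ape::phylo` object.
#'
#' @param D Symmetric distance matrix with ids as dimnames (or a `dist`).
#' @return Object of class `phylo`.
#' @export
nj_tree <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  ids <- rownames(D)
  n <- length(ids)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  # node bookkeeping: leaves 1..n, new internal nodes n+1, n+2, ...
  active <- seq_len(n)
  next_node <- n + 1L
  d <- D
  rownames(d) <- colnames(d) <- as.character(active)
  edges <- list()
  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }
  while (length(active) > 3L) {
    m <- length(active)
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, `+`)
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)[1L, ]  # first min: deterministic
    i <- min(ij); j <- max(ij)
    dij <- d[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    ll <- clamp_pair(li, lj)
    u <- next_node; next_node <- next_node + 1L
    ni <- as.integer(rownames(d)[i]); nj_ <- as.integer(rownames(d)[j])
    edges[[length(edges) + 1L]] <- c(u, ni, ll[1])
    edges[[length(edges) + 1L]] <- c(u, nj_, ll[2])
    du <- (d[i, ] + d[j, ] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    rn <- c(rownames(d)[keep], as.character(u))
    rownames(d2) <- colnames(d2) <- rn
    d <- d2
    active <- as.integer(rn)
  }
  # join the final three nodes at one internal node (three-point formulas)
  u <- next_node
  abc <- as.integer(rownames(d))
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  for (k in 1:3) {
    edges[[length(edges) + 1L]] <- c(u, abc[k], max(c(la, lb, lc)[k], 0))
  }
  em <- do.call(rbind, edges)
  .build_phylo(em[, 1:2, drop = FALSE], em[, 3], ids, root = u)
}

# Renumber an edge list (parent, child) into ape's phylo convention:
# tips 1..n keep their numbers, root becomes n+1, internal nodes numbered
# in preorder; edges emitted cladewise.
.build_phylo <- function(edge, lengths, tip_labels, root) {
  n <- length(tip_labels)
  kids <- split(seq_len(nrow(edge)), edge[, 1L])
  new_id <- integer(max(edge))
  new_id[seq_len(n)] <- seq_len(n)
  counter <- n
  out_edge <- matrix(0L, nrow(edge), 2L)
  out_len <- numeric(nrow(edge))
  pos <- 0L
  assign_node <- function(node) {
    counter <<- counter + 1L
    new_id[node] <<- counter
  }
  walk <- function(node) {
    for (e in kids[[as.character(node)]]) {
      child <- edge[e, 2L]
      if (child > n) assign_node(child)
      pos <<- pos + 1L
      out_edge[pos, ] <<- c(new_id[node], new_id[child])
      out_len[pos] <<- lengths[e]
      if (child > n) walk(child)
    }
  }
  assign_node(root)
  walk(root)
  tr <- list(edge = out_edge, edge.length = out_len,
             tip.label = tip_labels, Nnode = counter - n)
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr
}

# Non-trivial bipartitions of an unrooted tree, keyed canonically by the
# sorted tip set on the side NOT containing the alphabetically first label.
.bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  all_tips <- sort(tree$tip.label)
  first <- all_tips[[1L]]
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  below <- vector("list", n + tree$Nnode)
  fill <- function(node) {
    if (node <= n) {
      below[[node]] <<- tree$tip.label[[node]]
    } else {
      for (ch in kids[[as.character(node)]]) fill(ch)
      below[[node]] <<- unlist(below[kids[[as.character(node)]]])
    }
  }
  fill(n + 1L)
  keys <- character(0)
  nodes <- integer(0)
  if (tree$Nnode < 2L) return(list(keys = keys, nodes = nodes))
  for (node in (n + 2L):(n + tree$Nnode)) {
    side <- below[[node]]
    if (length(side) < 2L || length(side) > n - 2L) next
    if (first %in% side) side <- setdiff(all_tips, side)
    keys <- c(keys, paste(sort(side), collapse = "\r"))
    nodes <- c(nodes, node)
  }
  list(keys = keys, nodes = nodes)
}

#' Bootstrap supports on the neighbor-joining tree of an alignment
#'
#' Builds the full-data tree (Poisson distance + NJ), then resamples
#' alignment columns with replacement `n_reps` times and scores each
#' internal bipartition of the full tree by the percentage of replicate
#' trees containing it. Supports are attached as integer `node.label`s
#' (the root label is empty). With `n_reps = 0` the tree is returned
#' without supports. Deterministic given `seed`.
#'
#' @param aln Named character vector of equal-length gapped rows (>= 4).
#' @param n_reps Number of bootstrap replicates.
#' @param seed Optional integer seed.
#' @return `phylo` tree with `node.label` supports (when `n_reps > 0`).
#' @export
bootstrap_supports <- function(aln, n_reps = 1000L, seed = NULL) {
  if (length(aln) < 4L && n_reps > 0L) {
    stop("bootstrap needs an alignment with at least 4 rows")
  }
  full <- nj_tree(poisson_dist_matrix(aln))
  if (n_reps == 0L) return(full)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  ncol_aln <- ncol(m)
  bp <- .bipartitions(full)
  counts <- stats::setNames(numeric(length(bp$keys)), bp$keys)
  for (rep in seq_len(n_reps)) {
    cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
    rows <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
    names(rows) <- names(aln)
    tr <- tryCatch(nj_tree(poisson_dist_matrix(rows)),
                   error = function(e) NULL)
    if (is.null(tr)) next
    rk <- .bipartitions(tr)$keys
    hit <- bp$keys %in% rk
    counts[hit] <- counts[hit] + 1
  }
  support <- round(100 * counts / n_reps)
  n <- length(full$tip.label)
  labs <- rep("", full$Nnode)
  labs[bp$nodes - n] <- as.character(as.integer(support))
  full$node.label <- labs
  full
}

#' Progressive (center-star) global protein alignment
#'
#' Multiple alignment built from Needleman-Wunsch pairwise alignments
#' (BLOSUM62, gap open 10, gap extend 0.5): the center sequence maximizing
#' the summed pairwise alignment score is aligned to every other sequence
#' and the pairwise gaps are merged ("once a gap, always a gap"). Intended
#' for within-family protein sets; externally produced alignments can be
#' supplied anywhere an alignment is accepted.
#'
#' @param seqs Named character vector of >= 2 ungapped protein sequences.
#' @return Named character vector of equal-length gapped rows (input order).
#' @export
align_proteins <- function(seqs) {
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences")
  if (n == 2L) {
    pa <- align_pair(seqs[[1L]], seqs[[2L]],
                     idA = names(seqs)[1L], idB = names(seqs)[2L])
    out <- c(pa$alnA, pa$alnB)
    names(out) <- names(seqs)
    return(out)
  }
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  B62 <- get("BLOSUM62", envir = data_env)
  sets <- Biostrings::AAStringSet(seqs)
  score_sum <- numeric(n)
  pas <- vector("list", n)
  for (i in seq_len(n)) pas[[i]] <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- Biostrings::pairwiseAlignment(
        sets[[i]], sets[[j]], substitutionMatrix = B62,
        gapOpening = 10, gapExtension = 0.5, type = "global",
        scoreOnly = TRUE)
      score_sum[i] <- score_sum[i] + s
      score_sum[j] <- score_sum[j] + s
    }
  }
  center <- which.max(score_sum)
  others <- setdiff(seq_len(n), center)
  L <- nchar(seqs[[center]])
  # ins[[k]][p]: gap columns inserted before center residue p (p = L+1: after)
  ins <- list(); rows <- list()
  for (k in others) {
    pa <- Biostrings::pairwiseAlignment(
      sets[[center]], sets[[k]], substitutionMatrix = B62,
      gapOpening = 10, gapExtension = 0.5, type = "global")
    cg <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
    sg <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
    ib <- integer(L + 1L)
    blocks <- vector("list", L + 1L)
    resid_chars <- character(L)
    p <- 1L; pend <- 0L
    for (col in seq_along(cg)) {
      if (cg[col] == "-") {
        ib[p] <- ib[p] + 1L
        blocks[[p]] <- c(blocks[[p]], sg[col])
      } else {
        resid_chars[p] <- sg[col]
        p <- p + 1L
      }
    }
    ins[[as.character(k)]] <- ib
    rows[[as.character(k)]] <- list(blocks = blocks, resid = resid_chars)
  }
  master_ins <- Reduce(pmax, ins, accumulate = FALSE)
  center_chars <- strsplit(seqs[[center]], "", fixed = TRUE)[[1L]]
  build_row <- function(ib, blocks, resid) {
    out <- character(0)
    for (p in seq_len(L)) {
      pad <- master_ins[p] - ib[p]
      out <- c(out, rep("-", pad), blocks[[p]], resid[p])
    }
    pad <- master_ins[L + 1L] - ib[L + 1L]
    c(out, rep("-", pad), blocks[[L + 1L]])
  }
  aligned <- vector("list", n)
  aligned[[center]] <- build_row(integer(L + 1L),
                                 rep(list(character(0)), L + 1L),
                                 center_chars)
  for (k in others) {
    r <- rows[[as.character(k)]]
    aligned[[k]] <- build_row(ins[[as.character(k)]], r$blocks, r$resid)
  }
  out <- vapply(aligned, paste, character(1), collapse = "")
  names(out) <- names(seqs)
  out
}
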