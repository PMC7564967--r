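# End-to-end orchestration: identify -> seqprops -> phylo -> dupkaks ->
# promoter -> expression, with stage skipping on missing inputs, per-stage
# TSV outputs and a plain-text summary report. Deterministic given the
# configured seed; outputs carry no timestamps.

#' Default pipeline configuration
#'
#' Input paths default to `NA` (the corresponding stage is skipped);
#' thresholds default to the pipeline's standard values.
#'
#' @param ... Named overrides (paths: proteins_fa, cds_fa, gff3,
#'   domains_tsv, genome_fa, motif_catalog_tsv, fpkm_tsv, qpcr_csv;
#'   thresholds: evalue_cutoff, cov_min, id_min, tandem_gap_bp,
#'   max_intervening, promoter_len, constitutive_min, expressed_min,
#'   rate_r, p_cutoff; plus domains_dialect, boot_reps, seed, out_dir).
#' @return List of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    proteins_fa = NA, cds_fa = NA, gff3 = NA, domains_tsv = NA,
    domains_dialect = "tsv", genome_fa = NA, motif_catalog_tsv = NA,
    fpkm_tsv = NA, qpcr_csv = NA,
    evalue_cutoff = 0.001, cov_min = 0.70, id_min = 0.70,
    tandem_gap_bp = 100000, max_intervening = 5,
    promoter_len = 1500, constitutive_min = 1.0, expressed_min = 2.0,
    rate_r = 1.5e-8, p_cutoff = 0.05,
    boot_reps = 1000, seed = 1L, out_dir = "famscan_out")
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field: ", unknown[[1L]])
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  num <- c("evalue_cutoff", "cov_min", "id_min", "tandem_gap_bp",
           "max_intervening", "promoter_len", "constitutive_min",
           "expressed_min", "rate_r", "p_cutoff")
  for (nm in num) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop("config threshold must be positive: ", nm)
    }
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a flat key: value file
#'
#' One `key: value` pair per line (`#` comments allowed); keys are the
#' [run_config()] fields.
#'
#' @param path Path to the config file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_]+)\\s*:\\s*(.*?)\\s*$",
                                  lines))
  args <- list()
  for (m in kv) {
    if (length(m) != 3L) next
    val <- m[[3L]]
    num <- suppressWarnings(as.numeric(val))
    args[[m[[2L]]]] <- if (!is.na(num)) num else val
  }
  do.call(run_config, args)
}

.stage_log <- function(log, stage, status, detail = "") {
  c(log, sprintf("[%s] %s%s", stage, status,
                 if (nzchar(detail)) paste0(": ", detail) else ""))
}

.has_input <- function(path) {
  length(path) == 1L && !is.na(path) && is.character(path) &&
    file.exists(path)
}

#' Run the full characterization pipeline
#'
#' Executes identification, sequence/gene-structure statistics, phylogeny,
#' duplication + Ka/Ks, promoter scanning and expression/qPCR analysis in
#' order, skipping (and logging) stages whose inputs are absent. Writes
#' per-stage TSVs, a Newick tree and `summary.txt` under
#' `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with every stage result plus the log.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cfg$out_dir, f)
  log <- character(0)
  res <- list()
  summary_lines <- c("famscan pipeline summary", "========================")
  thr <- sprintf(
    "thresholds: evalue<%g cov>%g id>%g tandem_gap<%g bp intervening<=%g promoter=%g bp fpkm>=%g/%g r=%g p<=%g seed=%d",
    cfg$evalue_cutoff, cfg$cov_min, cfg$id_min, cfg$tandem_gap_bp,
    cfg$max_intervening, cfg$promoter_len, cfg$constitutive_min,
    cfg$expressed_min, cfg$rate_r, cfg$p_cutoff, as.integer(cfg$seed))
  log <- .stage_log(log, "config", "ok", thr)

  # ---- identify
  members <- NULL
  if (.has_input(cfg$domains_tsv)) {
    hits <- read_domain_table(cfg$domains_tsv, cfg$domains_dialect)
    members <- classify_members(hits, cfg$evalue_cutoff)
    write_tsv(members, p("members.tsv"))
    arch <- architecture_summary(members)
    write_tsv(arch, p("architecture.tsv"))
    res$members <- members; res$architecture <- arch
    counts <- table(factor(members$subfamily, levels = c("L", "G", "C")))
    summary_lines <- c(summary_lines, sprintf(
      "members: %d (L=%d G=%d C=%d)", nrow(members),
      counts[["L"]], counts[["G"]], counts[["C"]]))
    log <- .stage_log(log, "identify", "ok",
                      sprintf("%d members", nrow(members)))
  } else {
    log <- .stage_log(log, "identify", "skipped", "no domain table")
  }

  # ---- seqprops
  proteins <- if (.has_input(cfg$proteins_fa)) {
    read_fasta(cfg$proteins_fa, "protein")
  }
  models <- if (.has_input(cfg$gff3)) read_gff3(cfg$gff3)
  member_prot <- NULL
  if (!is.null(proteins) && !is.null(members)) {
    member_prot <- proteins[intersect(members$protein_id, names(proteins))]
    props <- protein_props(member_prot)
    write_tsv(props, p("protein_props.tsv"))
    res$props <- props
    stats_tab <- NULL
    if (!is.null(models)) {
      member_models <- models[intersect(members$gene_id, names(models))]
      stats_tab <- do.call(rbind, lapply(member_models, gene_structure))
      write_tsv(stats_tab, p("gene_structure.tsv"))
      res$structure <- stats_tab
      rep <- family_structure_report(stats_tab, props)
      summary_lines <- c(summary_lines, sprintf(
        "CDS length: %d (%s) - %d (%s) bp; mean introns %.2f",
        rep$cds_len$min, rep$cds_len$min_id, rep$cds_len$max,
        rep$cds_len$max_id, rep$mean_introns), sprintf(
        "MW: %.1f (%s) - %.1f (%s) kDa",
        rep$mw_kda$min, rep$mw_kda$min_id, rep$mw_kda$max,
        rep$mw_kda$max_id))
      res$structure_report <- rep
    }
    log <- .stage_log(log, "seqprops", "ok")
  } else {
    log <- .stage_log(log, "seqprops", "skipped",
                      "needs proteins and members")
  }

  # ---- phylo
  if (!is.null(member_prot) && length(member_prot) >= 4L) {
    aln <- align_proteins(member_prot)
    tree <- bootstrap_supports(aln, n_reps = cfg$boot_reps,
                               seed = as.integer(cfg$seed))
    writeLines(write_newick(tree), p("tree.nwk"))
    res$tree <- tree
    log <- .stage_log(log, "phylo", "ok",
                      sprintf("%d taxa, %d bootstrap replicates",
                              length(member_prot), cfg$boot_reps))
  } else {
    log <- .stage_log(log, "phylo", "skipped", "needs >=4 member proteins")
  }

  # ---- dupkaks
  if (!is.null(member_prot) && !is.null(models) && .has_input(cfg$cds_fa)) {
    cds <- read_fasta(cfg$cds_fa, "dna")
    dup <- find_duplicates(member_prot, cfg$cov_min, cfg$id_min)
    alns <- attr(dup, "alignments")
    rows <- list()
    for (i in seq_len(nrow(dup))) {
      pa <- alns[[paste(dup$idA[i], dup$idB[i], sep = "|")]]
      gidA <- sub("\\.\\d+$", "", dup$idA[i])
      gidB <- sub("\\.\\d+$", "", dup$idB[i])
      cls <- classify_duplication(gidA, gidB, models, cfg$tandem_gap_bp,
                                  cfg$max_intervening)
      kk <- kaks_pair(cds[[gidA]], cds[[gidB]], pa)
      rows[[i]] <- data.frame(
        idA = gidA, idB = gidB, dup_class = cls$dup_class,
        gap_bp = cls$gap_bp, n_intervening = cls$n_intervening,
        identity = round(dup$identity[i], 4),
        coverage = round(dup$coverage[i], 4),
        ka = round(kk$ka, 4), ks = round(kk$ks, 4),
        ka_ks = round(kk$omega, 4),
        t_mya = round(divergence_time(kk$ks, cfg$rate_r), 2),
        stringsAsFactors = FALSE)
    }
    dup_tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(idA = character(0), idB = character(0),
                 dup_class = character(0), gap_bp = integer(0),
                 n_intervening = integer(0), identity = numeric(0),
                 coverage = numeric(0), ka = numeric(0), ks = numeric(0),
                 ka_ks = numeric(0), t_mya = numeric(0),
                 stringsAsFactors = FALSE)
    write_tsv(dup_tab, p("duplications.tsv"))
    res$duplications <- dup_tab
    summary_lines <- c(summary_lines, sprintf(
      "duplication events: %d (%d tandem); T = %s MYA",
      nrow(dup_tab), sum(dup_tab$dup_class == "tandem"),
      paste(dup_tab$t_mya, collapse = ", ")))
    log <- .stage_log(log, "dupkaks", "ok",
                      sprintf("%d events", nrow(dup_tab)))
  } else {
    log <- .stage_log(log, "dupkaks", "skipped",
                      "needs proteins, CDS and annotation")
  }

  # ---- promoter
  if (!is.null(models) && .has_input(cfg$genome_fa) &&
      .has_input(cfg$motif_catalog_tsv) && !is.null(members)) {
    genome <- read_fasta(cfg$genome_fa, "dna")
    catalog <- read_motif_catalog(cfg$motif_catalog_tsv)
    hit_list <- list()
    for (gid in intersect(members$gene_id, names(models))) {
      prom <- extract_upstream(models[[gid]], genome, cfg$promoter_len)
      hit_list[[gid]] <- scan_motifs(prom, catalog)
    }
    hits <- do.call(rbind, hit_list)
    write_tsv(hits, p("promoter_hits.tsv"))
    cats <- categorize_elements(hits, catalog)
    fam <- data.frame(category = names(cats$family_types),
                      distinct_elements = as.integer(cats$family_types),
                      stringsAsFactors = FALSE)
    write_tsv(fam, p("promoter_categories.tsv"))
    res$promoter_hits <- hits; res$promoter_categories <- cats
    summary_lines <- c(summary_lines, sprintf(
      "cis-elements: %s",
      paste(sprintf("%s=%d", fam$category, fam$distinct_elements),
            collapse = " ")))
    log <- .stage_log(log, "promoter", "ok",
                      sprintf("%d hits", nrow(hits)))
  } else {
    log <- .stage_log(log, "promoter", "skipped",
                      "needs genome, catalog, annotation and members")
  }

  # ---- expression
  if (.has_input(cfg$fpkm_tsv)) {
    mat <- read_expression_matrix(cfg$fpkm_tsv)
    flags <- expression_flags(mat, cfg$constitutive_min, cfg$expressed_min)
    flag_tab <- data.frame(gene_id = rownames(mat),
                           constitutive = unname(flags$constitutive),
                           stringsAsFactors = FALSE)
    write_tsv(flag_tab, p("expression_flags.tsv"))
    groups <- group_expression(mat, k = 3L, seed = as.integer(cfg$seed))
    member_of <- attr(groups, "membership")
    write_tsv(data.frame(gene_id = names(member_of),
                         group = unname(member_of),
                         stringsAsFactors = FALSE),
              p("expression_groups.tsv"))
    venn_sets <- flags$expressed_sets[
      intersect(.VENN_TISSUES, names(flags$expressed_sets))]
    venn <- if (length(venn_sets) >= 2L) venn_membership(venn_sets)
    if (!is.null(venn)) write_tsv(venn, p("venn.tsv"))
    res$expression <- list(flags = flags, groups = groups, venn = venn)
    summary_lines <- c(summary_lines, sprintf(
      "expression: %d constitutive; group means %s FPKM",
      sum(flags$constitutive),
      paste(groups$mean_fpkm, collapse = "/")))
    log <- .stage_log(log, "expression", "ok")
  } else {
    log <- .stage_log(log, "expression", "skipped", "no FPKM matrix")
  }

  # ---- qPCR
  if (.has_input(cfg$qpcr_csv)) {
    records <- read_qpcr(cfg$qpcr_csv)
    fc <- ddct_all(records, p_cutoff = cfg$p_cutoff)
    fc$fold_change <- round(fc$fold_change, 4)
    fc$p_value <- signif(fc$p_value, 4)
    write_tsv(fc, p("fold_changes.tsv"))
    res$fold_changes <- fc
    summary_lines <- c(summary_lines, sprintf(
      "qPCR: %d up events, %d down events",
      sum(fc$call == "up"), sum(fc$call == "down")))
    log <- .stage_log(log, "qpcr", "ok", sprintf("%d calls", nrow(fc)))
  } else {
    log <- .stage_log(log, "qpcr", "skipped", "no Ct table")
  }

  writeLines(c(summary_lines, "", log), p("summary.txt"))
  res$log <- log
  invisible(res)
}
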