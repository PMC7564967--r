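# Synthetic-data generators: a toy annotated genome with a planted
# receptor-kinase family (subfamily labels, decoy architectures, tandem and
# dispersed duplicate pairs at controlled Ka/Ks), planted promoter
# elements, a three-level FPKM matrix and qPCR Ct tables with planted fold
# changes. Every generator is a pure function of (config, seed): reruns are
# byte-identical. The defaults reproduce the study conditions of the
# motivating family: 46 members (23 G / 22 L / 1 C), one tandem and two
# cross-chromosome duplicate pairs, 7/12/27 expression groups with means
# 18.01 / 6.48 / 1.29 FPKM over ten tissues, and hormone/cold qPCR with
# three replicates.

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

.sense_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}

.TISSUES <- c("root", "hypocotyl", "cotyledon", "true_leaf", "stem",
              "tendril", "female_flower", "male_flower", "ovary", "peel")
.VENN_TISSUES <- c("root", "hypocotyl", "cotyledon", "true_leaf", "tendril")
.CONDITIONS <- c("GA", "ABA", "NAA", "IAA", "cold")

#' Default synthetic-run configuration
#'
#' Bundles every knob of the generators with defaults matching the study
#' conditions the package emulates. Override fields by name.
#'
#' @param seed Master seed; all sub-generators derive from it.
#' @param ... Named overrides of any default field.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(seed = 42L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = 7L,
    n_members = c(G = 23L, L = 22L, C = 1L),
    n_decoys = 6L,
    cds_len_range_bp = c(1803L, 2502L),  # including the stop codon
    exon_count_probs = c(0.40, 0.25, 0.12, 0.08, 0.05, 0.04, 0.03,
                         0.02, 0.01),    # exons 1..9
    intron_len_range = c(100L, 400L),
    gene_spacing_bp = 1800L,             # leaves the 1500-bp promoter clear
    n_without_signal = 25L,
    n_multi_tm = 8L,
    g_architectures = c(both = 9L, pan_only = 5L, egf_only = 8L,
                        neither = 1L),
    # duplicate pairs: one tandem, two cross-chromosome (dispersed)
    tandem_pairs = 1L,
    tandem_intervening = 2L,
    dispersed_pairs = 2L,
    pair_ks = c(0.58, 0.46, 0.49),
    pair_omega = 0.15,                   # ka = omega * ks (purifying)
    motifs_per_promoter = c(2L, 5L),
    promoter_len = 1500L,
    group_sizes = c(7L, 12L, 27L),
    group_means_fpkm = c(18.01, 6.48, 1.29),
    fpkm_sdlog = 0.35,
    tissue_specific = c(root = 2L, tendril = 1L, cotyledon = 2L),
    specific_on_fpkm = 5.0,
    specific_off_fpkm = 0.2,
    qpcr_replicates = 3L,
    ct_sd = 0.1,
    qpcr_plants = data.frame(
      slot = c(1L, 2L, 3L, 4L, 5L, 6L),
      condition = c("ABA", "ABA", "IAA", "GA", "NAA", "cold"),
      fold = c(88, 1 / 17, 1 / 5, 2.5, 1 / 3, 1 / 2.2),
      stringsAsFactors = FALSE))
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  stopifnot(all(cfg$pair_ks < 0.75), cfg$n_decoys >= 0,
            all(cfg$n_members > 0))
  class(cfg) <- "synth_config"
  cfg
}

.random_cds <- function(n_sense_codons) {
  paste0(paste(sample(.sense_codons(), n_sense_codons, replace = TRUE),
               collapse = ""), "TAA")
}

# single-nucleotide change candidates of a codon, split syn/nonsyn,
# excluding changes to stop codons
.change_candidates <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  ch <- strsplit(codon, "", fixed = TRUE)[[1L]]
  syn <- list(); non <- list()
  for (pos in 1:3) {
    for (nt in setdiff(c("A", "C", "G", "T"), ch[pos])) {
      x <- ch; x[pos] <- nt
      alt <- paste(x, collapse = "")
      if (code[alt] == "*") next
      if (code[alt] == code[codon]) syn[[length(syn) + 1L]] <- alt
      else non[[length(non) + 1L]] <- alt
    }
  }
  list(syn = unlist(syn), non = unlist(non))
}

#' Generate a duplicate coding pair at controlled Ka and Ks
#'
#' An ancestral CDS of random sense codons is copied and mutated: the
#' expected proportion `pS = invJC(ks_target)` of synonymous sites receives
#' a synonymous substitution and likewise `pN = invJC(ka_target)` of
#' nonsynonymous sites, at most one substitution per codon and never
#' through a stop codon, so the planted difference counts are exact.
#' Deterministic given `seed`.
#'
#' @param ks_target,ka_target Target synonymous/nonsynonymous distances
#'   (`ks_target < 0.75`).
#' @param n_codons Number of sense codons (>= 30).
#' @param seed Integer seed.
#' @return List: cdsA, cdsB (with terminal stops), truth (targets, planted
#'   difference counts, site counts of the ancestor).
#' @export
generate_duplicate_pair <- function(ks_target, ka_target, n_codons,
                                    seed = 1L) {
  stopifnot(ks_target >= 0, ks_target < 0.75, ka_target >= 0,
            ka_target < 0.75, n_codons >= 30L)
  .with_seed(seed, {
    anc_codons <- sample(.sense_codons(), n_codons, replace = TRUE)
    S <- sum(vapply(anc_codons, .syn_sites_codon, numeric(1)))
    N <- 3 * n_codons - S
    inv_jc <- function(d) 0.75 * (1 - exp(-4 * d / 3))
    n_syn <- round(inv_jc(ks_target) * S)
    n_non <- round(inv_jc(ka_target) * N)
    cand <- lapply(anc_codons, .change_candidates)
    syn_ok <- which(vapply(cand, function(x) length(x$syn) > 0, logical(1)))
    if (length(syn_ok) < n_syn) {
      stop("infeasible targets: only ", length(syn_ok),
           " codons admit a synonymous change, need ", n_syn)
    }
    des_codons <- anc_codons
    syn_idx <- if (n_syn > 0) sample(syn_ok, n_syn) else integer(0)
    for (i in syn_idx) {
      des_codons[i] <- sample(cand[[i]]$syn, 1L)
    }
    non_ok <- setdiff(
      which(vapply(cand, function(x) length(x$non) > 0, logical(1))),
      syn_idx)
    if (length(non_ok) < n_non) {
      stop("infeasible targets: only ", length(non_ok),
           " untouched codons admit a nonsynonymous change, need ", n_non)
    }
    non_idx <- if (n_non > 0) sample(non_ok, n_non) else integer(0)
    for (i in non_idx) {
      des_codons[i] <- sample(cand[[i]]$non, 1L)
    }
    list(cdsA = paste0(paste(anc_codons, collapse = ""), "TAA"),
         cdsB = paste0(paste(des_codons, collapse = ""), "TAA"),
         truth = list(ks_target = ks_target, ka_target = ka_target,
                      n_syn_changes = n_syn, n_non_changes = n_non,
                      S_anc = S, N_anc = N))
  })
}

#' Built-in cis-element catalog for synthetic runs
#'
#' A small catalog of named IUPAC patterns across the light / hormone /
#' stress / development categories plus the ubiquitous CAAT- and TATA-box
#' entries that scans exclude by default.
#'
#' @return Catalog `data.frame`: name, iupac, category.
#' @export
default_motif_catalog <- function() {
  data.frame(
    name = c("G-box", "Box-4", "GT1-motif",
             "ABRE", "TGA-element", "GARE-motif", "P-box",
             "LTR", "MBS", "TC-rich",
             "O2-site", "CAT-box",
             "circadian",
             "CAAT-box", "TATA-box"),
    iupac = c("CACGTG", "ATTAAT", "GGTTAA",
              "ACGTGGC", "AACGAC", "TCTGTTG", "CCTTTTG",
              "CCGAAA", "CAACTG", "GTTTTCTTAC",
              "GATGAYRTGR", "GCCACT",
              "CAANNNNATC",
              "CCAAT", "TATAWAW"),
    category = c("light", "light", "light",
                 "hormone", "hormone", "hormone", "hormone",
                 "stress", "stress", "stress",
                 "development", "development",
                 "other",
                 "other", "other"),
    stringsAsFactors = FALSE)
}

# split a CDS into exon chunks and intron lengths; returns transcript-
# oriented exon lengths and intron lengths
.split_exons <- function(cds_len, n_exons, intron_range) {
  if (n_exons == 1L) return(list(exon_len = cds_len, intron_len = integer(0)))
  cuts <- sort(sample(seq_len(cds_len - 1L), n_exons - 1L))
  exon_len <- diff(c(0L, cuts, cds_len))
  intron_len <- sample(seq(intron_range[1L], intron_range[2L]),
                       n_exons - 1L, replace = TRUE)
  list(exon_len = as.integer(exon_len), intron_len = as.integer(intron_len))
}

.random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate an annotated toy genome with a planted gene family
#'
#' Builds chromosomes carrying planted family members (lectin + kinase +
#' TM domain architectures below the e-value cutoff), decoys with
#' incomplete architectures, background genes, duplicate pairs at
#' controlled Ka/Ks (one tandem block with a configured number of
#' intervening genes; the remaining pairs split across chromosomes),
#' planted promoter elements, and both strands. Deterministic given
#' `config$seed`.
#'
#' @param config A [synth_config()].
#' @return List: genome (named chromosome sequences), models (named list
#'   of [gene_model]), hits (domain-hit `data.frame`), proteins, cds
#'   (named vectors over member+decoy proteins), catalog (motif catalog),
#'   truth (planted membership, pairs, motif positions, decoys).
#' @export
generate_annotation <- function(config = synth_config()) {
  cfg <- config
  .with_seed(cfg$seed, {
    code <- Biostrings::GENETIC_CODE
    n_mem <- sum(cfg$n_members)
    subfam <- rep(names(cfg$n_members), cfg$n_members)
    # ---- CDS for members, with duplicate pairs planted first
    n_pairs <- cfg$tandem_pairs + cfg$dispersed_pairs
    stopifnot(length(cfg$pair_ks) >= n_pairs)
    cds_len <- sample(seq(cfg$cds_len_range_bp[1L], cfg$cds_len_range_bp[2L],
                          by = 3L), n_mem, replace = TRUE)
    member_cds <- character(n_mem)
    pair_rows <- list()
    used <- integer(0)
    # pair members are drawn from the G subfamily (largest) and L subfamily
    pool <- which(subfam %in% c("G", "L"))
    for (p in seq_len(n_pairs)) {
      ks <- cfg$pair_ks[[p]]
      ka <- cfg$pair_omega * ks
      cand <- setdiff(pool, used)
      ab <- cand[1:2]
      used <- c(used, ab)
      n_cod <- (max(cds_len[ab]) - 3L) / 3L
      dup <- generate_duplicate_pair(ks, ka, n_cod,
                                     seed = cfg$seed + 1000L + p)
      member_cds[ab[1L]] <- dup$cdsA
      member_cds[ab[2L]] <- dup$cdsB
      cds_len[ab] <- nchar(dup$cdsA)
      pair_rows[[p]] <- data.frame(
        slotA = ab[1L], slotB = ab[2L], ks_target = ks, ka_target = ka,
        expected_class = if (p <= cfg$tandem_pairs) "tandem" else "dispersed",
        stringsAsFactors = FALSE)
    }
    for (i in setdiff(seq_len(n_mem), used)) {
      member_cds[i] <- .random_cds((cds_len[i] - 3L) / 3L)
    }
    pairs <- do.call(rbind, pair_rows)
    # ---- decoys and background genes
    n_dec <- cfg$n_decoys
    decoy_cds <- vapply(seq_len(n_dec), function(i) .random_cds(300L),
                        character(1))
    # ---- chromosome layout
    # tandem pairs form a block: A, k intervening background genes, B.
    # dispersed pairs are pinned to different chromosomes.
    n_chr <- cfg$n_chromosomes
    placements <- list()  # per chromosome: list of units
    for (ch in seq_len(n_chr)) placements[[ch]] <- list()
    unit <- function(kind, slot = NA_integer_) list(kind = kind, slot = slot)
    # start from a balanced shuffle of non-pair members
    free <- setdiff(seq_len(n_mem), unlist(pairs[, c("slotA", "slotB")]))
    free <- sample(free)
    chr_of_free <- rep(seq_len(n_chr), length.out = length(free))
    for (k in seq_along(free)) {
      ch <- chr_of_free[[k]]
      placements[[ch]][[length(placements[[ch]]) + 1L]] <-
        unit("member", free[[k]])
    }
    for (p in seq_len(nrow(pairs))) {
      if (pairs$expected_class[[p]] == "tandem") {
        ch <- 1L
        placements[[ch]][[length(placements[[ch]]) + 1L]] <-
          unit("tandem_block", p)
      } else {
        chA <- 1L + (2L * p) %% n_chr
        chB <- 1L + (2L * p + 3L) %% n_chr
        if (chB == chA) chB <- 1L + chA %% n_chr
        placements[[chA]][[length(placements[[chA]]) + 1L]] <-
          unit("pairA", p)
        placements[[chB]][[length(placements[[chB]]) + 1L]] <-
          unit("pairB", p)
      }
    }
    for (d in seq_len(n_dec)) {
      ch <- 1L + (d + 1L) %% n_chr
      placements[[ch]][[length(placements[[ch]]) + 1L]] <- unit("decoy", d)
    }
    # shuffle unit order per chromosome (tandem blocks stay intact)
    for (ch in seq_len(n_chr)) {
      placements[[ch]] <- placements[[ch]][sample(length(placements[[ch]]))]
    }
    # ---- assemble chromosomes
    catalog <- default_motif_catalog()
    plantable <- catalog[!(catalog$name %in% DEFAULT_EXCLUDED_ELEMENTS), ]
    genome <- character(n_chr)
    names(genome) <- paste0("chr", seq_len(n_chr))
    models <- list()
    motif_truth <- list()
    member_gene_id <- character(n_mem)
    decoy_gene_id <- character(n_dec)
    bg_counter <- 0L
    plant_promoter <- function(gene_id, want_motifs) {
      prom <- .random_dna(cfg$promoter_len)
      if (!want_motifs) return(prom)
      n_plant <- sample(seq(cfg$motifs_per_promoter[1L],
                            cfg$motifs_per_promoter[2L]), 1L)
      rows <- plantable[sample(nrow(plantable), n_plant, replace = TRUE), ,
                        drop = FALSE]
      cursor <- 1L
      for (r in seq_len(n_plant)) {
        pat <- rows$iupac[[r]]
        # realize ambiguity codes into concrete bases
        realize <- vapply(strsplit(pat, "")[[1L]], function(cc) {
          opts <- strsplit(gsub("\\[|\\]", "", .IUPAC_CLASS[[cc]]), "")[[1L]]
          sample(opts, 1L)
        }, character(1))
        site <- paste(realize, collapse = "")
        strand <- sample(c("+", "-"), 1L)
        w <- nchar(site)
        pos <- cursor + sample.int(60L, 1L)
        if (pos + w - 1L > cfg$promoter_len) break
        ins <- if (strand == "+") site else reverse_complement(site)
        substr(prom, pos, pos + w - 1L) <- ins
        motif_truth[[length(motif_truth) + 1L]] <<- data.frame(
          gene_id = gene_id, motif = rows$name[[r]], position = pos,
          strand = strand, category = rows$category[[r]],
          stringsAsFactors = FALSE)
        cursor <- pos + w + 10L
      }
      prom
    }
    emit_gene <- function(chrom_name, cursor, gene_id, cds, strand,
                          plant = FALSE) {
      # returns list(segment, model, new_cursor)
      cds_nt <- cds
      n_ex <- sample(seq_along(cfg$exon_count_probs), 1L,
                     prob = cfg$exon_count_probs)
      sp <- .split_exons(nchar(cds_nt), n_ex, cfg$intron_len_range)
      tx_parts <- character(0)
      exon_rel <- matrix(0L, n_ex, 2L)
      at <- 1L; off <- 0L
      for (e in seq_len(n_ex)) {
        el <- sp$exon_len[[e]]
        tx_parts <- c(tx_parts, substr(cds_nt, at, at + el - 1L))
        exon_rel[e, ] <- c(off + 1L, off + el)
        off <- off + el
        at <- at + el
        if (e < n_ex) {
          il <- sp$intron_len[[e]]
          tx_parts <- c(tx_parts, .random_dna(il))
          off <- off + il
        }
      }
      body_tx <- paste(tx_parts, collapse = "")
      body_len <- nchar(body_tx)
      prom <- plant_promoter(gene_id, plant)
      if (strand == "+") {
        seg <- paste0(prom, body_tx)
        gstart <- cursor + cfg$promoter_len
        ex <- cbind(gstart + exon_rel[, 1L] - 1L, gstart + exon_rel[, 2L] - 1L)
      } else {
        seg <- paste0(reverse_complement(body_tx), reverse_complement(prom))
        gstart <- cursor
        ex <- cbind(gstart + body_len - exon_rel[, 2L],
                    gstart + body_len - exon_rel[, 1L])
      }
      gend <- gstart + body_len - 1L
      model <- gene_model(gene_id, chrom_name, strand, gstart, gend, ex, ex)
      list(segment = seg, model = model,
           new_cursor = cursor + nchar(seg))
    }
    spacer <- cfg$gene_spacing_bp - cfg$promoter_len  # pad before promoter
    for (ch in seq_len(n_chr)) {
      chrom_name <- names(genome)[[ch]]
      segs <- list()
      cursor <- 1L
      gene_no <- 0L
      add_unit <- function(gene_id, cds, strand, plant) {
        segs[[length(segs) + 1L]] <<- .random_dna(spacer)
        cursor <<- cursor + spacer
        g <- emit_gene(chrom_name, cursor, gene_id, cds, strand, plant)
        segs[[length(segs) + 1L]] <<- g$segment
        cursor <<- g$new_cursor
        models[[gene_id]] <<- g$model
      }
      for (u in placements[[ch]]) {
        if (u$kind %in% c("member", "pairA", "pairB")) {
          slot <- if (u$kind == "member") u$slot
                  else if (u$kind == "pairA") pairs$slotA[[u$slot]]
                  else pairs$slotB[[u$slot]]
          gene_no <- gene_no + 1L
          gid <- sprintf("SYN%dG%04d0", ch, gene_no)
          member_gene_id[slot] <- gid
          add_unit(gid, member_cds[[slot]], sample(c("+", "-"), 1L),
                   plant = TRUE)
        } else if (u$kind == "tandem_block") {
          p <- u$slot
          for (side in c("A", "B")) {
            gene_no <- gene_no + 1L
            gid <- sprintf("SYN%dG%04d0", ch, gene_no)
            slot <- if (side == "A") pairs$slotA[[p]] else pairs$slotB[[p]]
            member_gene_id[slot] <- gid
            add_unit(gid, member_cds[[slot]], "+", plant = TRUE)
            if (side == "A") {
              for (k in seq_len(cfg$tandem_intervening)) {
                bg_counter <- bg_counter + 1L
                bgid <- sprintf("SYNBG%04d", bg_counter)
                add_unit(bgid, .random_cds(120L), sample(c("+", "-"), 1L),
                         plant = FALSE)
              }
            }
          }
        } else if (u$kind == "decoy") {
          gene_no <- gene_no + 1L
          gid <- sprintf("SYN%dD%04d0", ch, gene_no)
          decoy_gene_id[u$slot] <- gid
          add_unit(gid, decoy_cds[[u$slot]], sample(c("+", "-"), 1L),
                   plant = FALSE)
        }
      }
      segs[[length(segs) + 1L]] <- .random_dna(500L)
      genome[[ch]] <- paste(unlist(segs), collapse = "")
    }
    # ---- member/decoy tables, proteins, domain hits
    prot_id <- function(gid) paste0(gid, ".1")
    lectin_of <- c(L = "Lectin_legB", G = "B_lectin", C = "Lectin_C")
    no_signal <- sample(seq_len(n_mem), min(cfg$n_without_signal, n_mem))
    multi_tm <- sample(seq_len(n_mem), min(cfg$n_multi_tm, n_mem))
    g_slots <- which(subfam == "G")
    arch <- rep("neither", n_mem)
    ga <- cfg$g_architectures
    arch_lab <- c(rep("both", ga[["both"]]), rep("pan_only", ga[["pan_only"]]),
                  rep("egf_only", ga[["egf_only"]]),
                  rep("neither", ga[["neither"]]))
    arch_lab <- rep(arch_lab, length.out = length(g_slots))
    arch[g_slots] <- sample(arch_lab)
    s_locus <- rep(FALSE, n_mem)
    s_locus[sample(g_slots, max(1L, length(g_slots) %/% 2L))] <- TRUE
    hit_rows <- list()
    add_hit <- function(pid, domain, evalue, start, end) {
      hit_rows[[length(hit_rows) + 1L]] <<- data.frame(
        protein_id = pid, domain = domain, evalue = evalue,
        start = start, end = end, source = "synthetic",
        stringsAsFactors = FALSE)
    }
    proteins <- character(0); cds_out <- character(0)
    members_truth <- list()
    for (i in seq_len(n_mem)) {
      gid <- member_gene_id[[i]]
      pid <- prot_id(gid)
      prot <- translate_cds(member_cds[[i]])
      proteins[[pid]] <- prot
      cds_out[[gid]] <- member_cds[[i]]
      plen <- nchar(prot)
      lec_e <- 10^(-stats::runif(1, 5, 40))
      add_hit(pid, lectin_of[[subfam[i]]], lec_e, 30L,
              min(plen, 170L))
      add_hit(pid, "kinase", 10^(-stats::runif(1, 10, 60)),
              max(1L, plen - 280L), plen - 10L)
      n_tm <- if (i %in% multi_tm) 3L else 1L
      for (t in seq_len(n_tm)) {
        add_hit(pid, "TM", 0.5, 180L + 25L * t, 200L + 25L * t)
      }
      if (!(i %in% no_signal)) add_hit(pid, "signal_peptide", 0.01, 1L, 22L)
      if (subfam[i] == "G") {
        if (arch[i] %in% c("both", "egf_only")) {
          add_hit(pid, "EGF", 1e-4, 300L, 340L)
        }
        if (arch[i] %in% c("both", "pan_only")) {
          add_hit(pid, "PAN", 1e-4, 350L, 420L)
        }
        if (s_locus[i]) add_hit(pid, "S_locus", 1e-6, 40L, 160L)
      }
      members_truth[[i]] <- data.frame(
        gene_id = gid, protein_id = pid, subfamily = subfam[i],
        has_signal = !(i %in% no_signal), n_tm = n_tm,
        has_EGF = arch[i] %in% c("both", "egf_only"),
        has_PAN = arch[i] %in% c("both", "pan_only"),
        has_S_locus = s_locus[i], stringsAsFactors = FALSE)
    }
    # decoys: each misses at least one requirement
    decoy_kinds <- rep(c("no_tm", "no_kinase", "no_lectin",
                         "weak_lectin", "lectin_only", "kinase_only"),
                       length.out = n_dec)
    for (d in seq_len(n_dec)) {
      gid <- decoy_gene_id[[d]]
      pid <- prot_id(gid)
      prot <- translate_cds(decoy_cds[[d]])
      proteins[[pid]] <- prot
      cds_out[[gid]] <- decoy_cds[[d]]
      kind <- decoy_kinds[[d]]
      if (kind %in% c("no_tm", "lectin_only", "no_kinase", "weak_lectin")) {
        ev <- if (kind == "weak_lectin") 0.01 else 1e-8
        add_hit(pid, "Lectin_legB", ev, 10L, 150L)
      }
      if (kind %in% c("no_tm", "no_lectin", "kinase_only", "weak_lectin")) {
        add_hit(pid, "kinase", 1e-20, 160L, 290L)
      }
      if (kind %in% c("no_kinase", "no_lectin", "weak_lectin")) {
        add_hit(pid, "TM", 0.5, 152L, 158L)
      }
    }
    members_df <- do.call(rbind, members_truth)
    pairs_df <- data.frame(
      idA = member_gene_id[pairs$slotA], idB = member_gene_id[pairs$slotB],
      ks_target = pairs$ks_target, ka_target = pairs$ka_target,
      expected_class = pairs$expected_class, stringsAsFactors = FALSE)
    truth <- list(
      members = members_df,
      decoys = data.frame(gene_id = decoy_gene_id,
                          protein_id = prot_id(decoy_gene_id),
                          kind = decoy_kinds, stringsAsFactors = FALSE),
      pairs = pairs_df,
      motifs = if (length(motif_truth)) do.call(rbind, motif_truth)
               else data.frame())
    list(genome = genome, models = models,
         hits = do.call(rbind, hit_rows),
         proteins = proteins, cds = cds_out,
         catalog = catalog, truth = truth)
  })
}

#' Generate a three-level FPKM matrix with planted groups
#'
#' FPKM values are drawn log-normally around the planted group means in
#' every tissue; a configurable handful of genes is made tissue-specific
#' (high in exactly one of the five typical tissues, near zero elsewhere).
#' Deterministic given `config$seed`.
#'
#' @param config A [synth_config()].
#' @param gene_ids Member gene ids (defaults to placeholder names sized by
#'   `group_sizes`).
#' @return List: mat (FPKM matrix), truth (planted group membership and
#'   tissue-specific plants).
#' @export
generate_expression <- function(config = synth_config(), gene_ids = NULL) {
  cfg <- config
  sizes <- cfg$group_sizes
  n <- sum(sizes)
  if (is.null(gene_ids)) gene_ids <- sprintf("SYNG%04d0", seq_len(n))
  stopifnot(length(gene_ids) == n)
  .with_seed(cfg$seed + 7L, {
    order_ids <- sample(gene_ids)
    group <- rep(seq_along(sizes), sizes)
    names(group) <- order_ids
    mat <- matrix(0, n, length(.TISSUES),
                  dimnames = list(order_ids, .TISSUES))
    for (g in seq_along(sizes)) {
      sel <- names(group)[group == g]
      mu <- log(cfg$group_means_fpkm[[g]])
      mat[sel, ] <- exp(mu + stats::rnorm(length(sel) * ncol(mat),
                                          sd = cfg$fpkm_sdlog))
    }
    # tissue-specific plants come from the low group
    low <- names(group)[group == length(sizes)]
    spec_rows <- list()
    ti <- 0L
    for (tissue in names(cfg$tissue_specific)) {
      for (r in seq_len(cfg$tissue_specific[[tissue]])) {
        ti <- ti + 1L
        gid <- low[[ti]]
        mat[gid, ] <- cfg$specific_off_fpkm *
          exp(stats::rnorm(ncol(mat), sd = cfg$fpkm_sdlog))
        mat[gid, tissue] <- cfg$specific_on_fpkm *
          exp(stats::rnorm(1, sd = cfg$fpkm_sdlog))
        spec_rows[[ti]] <- data.frame(gene_id = gid, tissue = tissue,
                                      stringsAsFactors = FALSE)
      }
    }
    mat <- mat[gene_ids, , drop = FALSE]
    list(mat = mat,
         truth = list(groups = group[gene_ids],
                      tissue_specific = do.call(rbind, spec_rows)))
  })
}

#' Generate a qPCR Ct table with planted fold changes
#'
#' The reference gene is stable; the treatment target Ct is shifted by
#' `-log2(fold)` relative to control, with Gaussian noise of sd
#' `config$ct_sd` on every Ct. Plants are assigned to member genes by slot
#' index. Deterministic given `config$seed`.
#'
#' @param config A [synth_config()].
#' @param gene_ids Member gene ids.
#' @return List: records (`data.frame` in the qPCR CSV layout), truth
#'   (planted fold change per gene x condition, 1 = no change).
#' @export
generate_qpcr <- function(config = synth_config(), gene_ids = NULL) {
  cfg <- config
  if (is.null(gene_ids)) gene_ids <- sprintf("SYNG%04d0", seq_len(12L))
  .with_seed(cfg$seed + 13L, {
    plants <- cfg$qpcr_plants
    stopifnot(max(plants$slot) <= length(gene_ids))
    fold <- matrix(1, length(gene_ids), length(.CONDITIONS),
                   dimnames = list(gene_ids, .CONDITIONS))
    for (r in seq_len(nrow(plants))) {
      fold[gene_ids[[plants$slot[[r]]]], plants$condition[[r]]] <-
        plants$fold[[r]]
    }
    rows <- list()
    base_ct <- stats::setNames(stats::runif(length(gene_ids), 23, 27),
                               gene_ids)
    for (g in gene_ids) {
      for (cond in c("control", .CONDITIONS)) {
        shift <- if (cond == "control") 0 else -log2(fold[g, cond])
        for (rep in seq_len(cfg$qpcr_replicates)) {
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = g, condition = cond, replicate = rep,
            ct_target = base_ct[[g]] + shift +
              stats::rnorm(1, sd = cfg$ct_sd),
            ct_reference = 19 + stats::rnorm(1, sd = cfg$ct_sd),
            stringsAsFactors = FALSE)
        }
      }
    }
    list(records = do.call(rbind, rows), truth = list(fold = fold))
  })
}

.write_gff3 <- function(models, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (m in models) {
    tid <- paste0(m$gene_id, ".1")
    writeLines(sprintf("%s\tfamscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       m$chrom, m$start, m$end, m$strand, m$gene_id), con)
    writeLines(sprintf("%s\tfamscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       m$chrom, m$start, m$end, m$strand, tid, m$gene_id),
               con)
    for (e in seq_len(nrow(m$exons))) {
      writeLines(sprintf("%s\tfamscan\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                         m$chrom, m$exons[e, 1L], m$exons[e, 2L], m$strand,
                         tid), con)
    }
    for (e in seq_len(nrow(m$cds))) {
      writeLines(sprintf("%s\tfamscan\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                         m$chrom, m$cds[e, 1L], m$cds[e, 2L], m$strand,
                         tid), con)
    }
  }
  invisible(path)
}

#' Write a complete synthetic input bundle to a directory
#'
#' Emits genome.fa, annotation.gff3, domains.tsv, proteins.fa, cds.fa,
#' motif_catalog.tsv, fpkm.tsv, qpcr.csv and truth.json. Byte-identical
#' across runs with the same config.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the list of generated objects (annotation,
#'   expression, qpcr) with file paths attached as `paths`.
#' @export
write_synth_bundle <- function(config = synth_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ann <- generate_annotation(config)
  member_ids <- ann$truth$members$gene_id
  expr <- generate_expression(config, member_ids)
  qp <- generate_qpcr(config, member_ids)
  p <- function(f) file.path(out_dir, f)
  write_fasta(ann$genome, p("genome.fa"))
  .write_gff3(ann$models, p("annotation.gff3"))
  write_tsv(ann$hits, p("domains.tsv"))
  write_fasta(ann$proteins, p("proteins.fa"))
  write_fasta(ann$cds, p("cds.fa"))
  write_tsv(ann$catalog, p("motif_catalog.tsv"))
  fp <- data.frame(gene_id = rownames(expr$mat), expr$mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(fp, p("fpkm.tsv"))
  utils::write.csv(qp$records, p("qpcr.csv"), row.names = FALSE,
                   quote = FALSE)
  truth <- list(members = ann$truth$members, decoys = ann$truth$decoys,
                pairs = ann$truth$pairs, motifs = ann$truth$motifs,
                expression_groups = as.list(expr$truth$groups),
                tissue_specific = expr$truth$tissue_specific,
                qpcr_fold = data.frame(gene_id = rownames(qp$truth$fold),
                                       as.data.frame(qp$truth$fold),
                                       stringsAsFactors = FALSE))
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  out <- list(annotation = ann, expression = expr, qpcr = qp,
              truth = truth)
  out$paths <- stats::setNames(
    vapply(c("genome.fa", "annotation.gff3", "domains.tsv", "proteins.fa",
             "cds.fa", "motif_catalog.tsv", "fpkm.tsv", "qpcr.csv",
             "truth.json"), p, character(1)),
    c("genome", "gff3", "domains", "proteins", "cds", "catalog", "fpkm",
      "qpcr", "truth"))
  invisible(out)
}
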