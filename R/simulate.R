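#' Configuration for the synthetic pangenome simulator
#'
#' Bundles and validates every knob of [simulate_pangenome()]. The defaults
#' are the package's reference simulation conditions: 10 species with 3
#' genomes each, 5 cognate toxin families each planted in 4 species (so every
#' architecture is conserved in at least two species), operon gaps uniform on
#' 0-80 nt, per-site substitution probability 0.05 with no indels, a
#' quarter of families in toxin-first order, half of each family's species
#' carrying a conserved accessory third gene, and one mobile-element decoy
#' family placed seed-adjacent in 2 genomes and at background positions in 18
#' others.
#'
#' @param rng_seed Integer seed; equal configs (including the seed) produce
#'   byte-identical output trees.
#' @param n_species,genomes_per_species Corpus dimensions.
#' @param genes_per_replicon Genes per genome (one replicon per genome).
#' @param background_gene_len Length range (aa) of unrelated background
#'   genes.
#' @param seed_profile_len Length (aa) of the seed antitoxin domain.
#' @param p_sub Per-site substitution probability within every planted
#'   family (`[0, 0.5)`); family evolution has no indels.
#' @param n_toxin_families Number of cognate toxin families.
#' @param species_per_family Species carrying each family (>= 2).
#' @param gap_distribution Intergenic gap range (nt) inside planted operons.
#' @param frac_toxin_first Probability that a family's fixed gene order is
#'   toxin-first (order is a family property so the conserved-architecture
#'   criterion is well-posed).
#' @param frac_with_accessory Fraction of a family's species whose genomes
#'   carry a conserved accessory third gene.
#' @param decoy_adjacent,decoy_background Decoy family placements: genomes
#'   with a seed-adjacent copy (in distinct species sharing one family) and
#'   genomes with a background copy.
#' @param frac_hth_extension,frac_pad1_extension Per-seed-protein
#'   probabilities of an N-terminal HTH-family or novel-domain (PAD1-like)
#'   extension.
#' @param frac_tm_toxins Fraction of toxin families whose members carry a
#'   transmembrane 25-Leu block.
#' @param toxin_len,accessory_len,decoy_len,hth_len,pad1_len Family ancestor
#'   lengths (aa).
#' @param tm_block_len Length of the spliced poly-Leu block.
#' @param background_gap Intergenic gap range (nt) between unrelated
#'   neighbors; its minimum exceeds the operon gap criterion so background
#'   adjacencies never chain into operons.
#' @param n_align_seqs Members emitted in the seed and HTH reference
#'   alignments.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(rng_seed = 1L, n_species = 10L,
                       genomes_per_species = 3L, genes_per_replicon = 30L,
                       background_gene_len = c(50L, 300L),
                       seed_profile_len = 120L, p_sub = 0.05,
                       n_toxin_families = 5L, species_per_family = 4L,
                       gap_distribution = c(0L, 80L),
                       frac_toxin_first = 0.25, frac_with_accessory = 0.5,
                       decoy_adjacent = 2L, decoy_background = 18L,
                       frac_hth_extension = 0.25, frac_pad1_extension = 0.15,
                       frac_tm_toxins = 0.2, toxin_len = 110L,
                       accessory_len = 90L, decoy_len = 220L, hth_len = 55L,
                       pad1_len = 60L, tm_block_len = 25L,
                       background_gap = c(150L, 400L), n_align_seqs = 8L) {
  cfg <- as.list(environment())
  fr <- c("frac_toxin_first", "frac_with_accessory", "frac_hth_extension",
          "frac_pad1_extension", "frac_tm_toxins")
  for (f in fr)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  if (p_sub < 0 || p_sub >= 0.5) stop("p_sub must be in [0, 0.5)")
  if (species_per_family < 2L)
    stop("species_per_family must be >= 2 (architectures must be conservable)")
  if (species_per_family > n_species)
    stop("species_per_family exceeds n_species")
  if (frac_hth_extension + frac_pad1_extension > 1)
    stop("extension fractions must sum to at most 1")
  if (gap_distribution[1L] < 0 || gap_distribution[2L] < gap_distribution[1L])
    stop("invalid gap_distribution")
  if (background_gap[1L] <= 100L)
    stop("background_gap minimum must exceed 100 nt")
  structure(cfg, class = "sim_config")
}

runif1 <- function() stats::runif(1L)

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# substitute each site independently with prob p_sub, always to a different
# residue, so p_sub is the realized expected divergence
mutate_seq <- function(seq, p_sub) {
  ch <- strsplit(seq, "")[[1L]]
  hit <- which(stats::runif(length(ch)) < p_sub)
  if (length(hit)) {
    cur <- match(ch[hit], AA20)
    shift <- sample.int(19L, length(hit), replace = TRUE)
    ch[hit] <- AA20[((cur - 1L + shift) %% 20L) + 1L]
  }
  paste(ch, collapse = "")
}

#' Simulate a seeded synthetic pangenome with planted ground truth
#'
#' Generates an annotated multi-species corpus emulating the statistical
#' structure the locus-calling analysis assumes: a seed antitoxin family,
#' cognate toxin partner families in tight same-strand operons, conserved
#' accessory third genes in subsets of genomes, a mobile-element decoy family
#' adjacent to seeds only occasionally, optional N-terminal extensions (HTH
#' or novel PAD1-like) on seed proteins, transmembrane toxin families, and
#' unrelated background genes. Only protein sequences and gene coordinates
#' are generated (gene length in nt is 3x the aa length); nucleotide
#' sequences are never needed downstream. Output is byte-identical for equal
#' configurations.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, the corpus
#'   ([write_corpus()] layout), the seed and HTH reference alignments, the
#'   ground-truth tables and the configuration are written there.
#' @return Invisibly, a list with `corpus`, `truth` (tables `loci`, `decoys`,
#'   `extensions`, `tm`), `seed_alignment`, `hth_alignment` and `config`.
#' @export
simulate_pangenome <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n_genomes <- cfg$n_species * cfg$genomes_per_species
  if (cfg$decoy_adjacent + cfg$decoy_background > n_genomes)
    stop("infeasible config: more decoy placements than genomes")
  set.seed(cfg$rng_seed)

  nf <- cfg$n_toxin_families
  seed_anc <- random_aa(cfg$seed_profile_len)
  toxin_anc <- replicate(nf, random_aa(cfg$toxin_len))
  acc_anc <- replicate(nf, random_aa(cfg$accessory_len))
  decoy_anc <- random_aa(cfg$decoy_len)
  hth_anc <- random_aa(cfg$hth_len)
  pad1_anc <- random_aa(cfg$pad1_len)
  seed_aln <- vapply(seq_len(cfg$n_align_seqs), function(i)
    mutate_seq(seed_anc, cfg$p_sub), character(1))
  names(seed_aln) <- sprintf("seed_ref_%02d", seq_along(seed_aln))
  hth_aln <- vapply(seq_len(cfg$n_align_seqs), function(i)
    mutate_seq(hth_anc, cfg$p_sub), character(1))
  names(hth_aln) <- sprintf("hth_ref_%02d", seq_along(hth_aln))

  fam_order <- ifelse(stats::runif(nf) < cfg$frac_toxin_first,
                      "toxin_first", "antitoxin_first")
  n_tm <- round(cfg$frac_tm_toxins * nf)
  fam_tm <- rep(FALSE, nf)
  if (n_tm > 0L) fam_tm[sample.int(nf, n_tm)] <- TRUE
  tm_pos <- floor(cfg$toxin_len / 2)
  spf <- cfg$species_per_family
  fam_species <- lapply(seq_len(nf), function(f)
    (((f - 1L) * spf + 0:(spf - 1L)) %% cfg$n_species) + 1L)
  fam_acc_species <- lapply(seq_len(nf), function(f) {
    n_acc <- round(cfg$frac_with_accessory * spf)
    if (n_acc == 0L) integer() else sort(sample(fam_species[[f]], n_acc))
  })

  # genes per genome demanded by the plant
  species_fams <- lapply(seq_len(cfg$n_species), function(s)
    which(vapply(fam_species, function(v) s %in% v, logical(1))))
  max_operon_genes <- max(vapply(seq_len(cfg$n_species), function(s) {
    fams <- species_fams[[s]]
    sum(2L + vapply(fams, function(f) as.integer(s %in% fam_acc_species[[f]]),
                    integer(1)))
  }, integer(1)))
  if (max_operon_genes + 1L > cfg$genes_per_replicon)
    stop("infeasible config: planted operons exceed genes_per_replicon")

  genome_tbl <- expand.grid(gj = seq_len(cfg$genomes_per_species),
                            si = seq_len(cfg$n_species))
  genome_tbl <- genome_tbl[, c("si", "gj")]
  genome_tbl$genome_id <- sprintf("s%02dg%02d", genome_tbl$si, genome_tbl$gj)

  # decoy attachment: a family with >= decoy_adjacent accessory-free species
  decoy_fam <- NA_integer_
  decoy_adj_hosts <- character()
  if (cfg$decoy_adjacent > 0L) {
    for (f in seq_len(nf)) {
      free <- setdiff(fam_species[[f]], fam_acc_species[[f]])
      if (length(free) >= cfg$decoy_adjacent) {
        decoy_fam <- f
        decoy_adj_hosts <- sprintf("s%02dg01",
                                   sort(free)[seq_len(cfg$decoy_adjacent)])
        break
      }
    }
    if (is.na(decoy_fam))
      stop("infeasible config: no family has enough accessory-free species ",
           "to host seed-adjacent decoys")
  }
  decoy_bg_hosts <- character()
  if (cfg$decoy_background > 0L) {
    pool <- setdiff(genome_tbl$genome_id, decoy_adj_hosts)
    decoy_bg_hosts <- sort(sample(pool, cfg$decoy_background))
  }

  draw_gap <- function() sample(cfg$gap_distribution[1L]:cfg$gap_distribution[2L], 1L)
  draw_bg_gap <- function() sample(cfg$background_gap[1L]:cfg$background_gap[2L], 1L)

  corpus <- list()
  truth_loci <- list()
  truth_decoys <- list()
  truth_ext <- list()
  truth_tm <- list()

  for (gi in seq_len(nrow(genome_tbl))) {
    si <- genome_tbl$si[gi]
    gid <- genome_tbl$genome_id[gi]
    species <- sprintf("species_%02d", si)
    blocks <- list()   # each: list of gene records (transcription order)
    for (f in species_fams[[si]]) {
      ext_u <- runif1()
      ext_label <- if (ext_u < cfg$frac_hth_extension) "hth" else
        if (ext_u < cfg$frac_hth_extension + cfg$frac_pad1_extension) "pad1"
        else "none"
      ext_seq <- switch(ext_label,
                        hth = mutate_seq(hth_anc, cfg$p_sub),
                        pad1 = mutate_seq(pad1_anc, cfg$p_sub), "")
      seed_seq <- paste0(ext_seq, mutate_seq(seed_anc, cfg$p_sub))
      tox_seq <- mutate_seq(toxin_anc[f], cfg$p_sub)
      if (fam_tm[f])
        tox_seq <- paste0(substr(tox_seq, 1L, tm_pos),
                          strrep("L", cfg$tm_block_len),
                          substr(tox_seq, tm_pos + 1L, cfg$toxin_len))
      seed_gene <- list(role = "seed", fam = f, seq = seed_seq,
                        product = "DUF4065 domain-containing protein",
                        ext_label = ext_label)
      tox_gene <- list(role = "toxin", fam = f, seq = tox_seq,
                       product = "hypothetical protein", tm = fam_tm[f])
      genes <- if (fam_order[f] == "antitoxin_first")
        list(seed_gene, tox_gene) else list(tox_gene, seed_gene)
      if (si %in% fam_acc_species[[f]]) {
        acc_gene <- list(role = "accessory", fam = f,
                         seq = mutate_seq(acc_anc[f], cfg$p_sub),
                         product = "helicase")
        # accessory sits on the outer side of the toxin, never seed-adjacent
        genes <- if (fam_order[f] == "antitoxin_first")
          c(genes, list(acc_gene)) else c(list(acc_gene), genes)
      }
      if (!is.na(decoy_fam) && f == decoy_fam && gid %in% decoy_adj_hosts) {
        decoy_gene <- list(role = "decoy", fam = NA_integer_,
                           seq = mutate_seq(decoy_anc, cfg$p_sub),
                           product = "transposase", adjacent = TRUE)
        # decoy on the seed's free side (opposite the toxin)
        genes <- if (fam_order[f] == "antitoxin_first")
          c(list(decoy_gene), genes) else c(genes, list(decoy_gene))
      }
      blocks[[length(blocks) + 1L]] <- genes
    }
    if (gid %in% decoy_bg_hosts)
      blocks[[length(blocks) + 1L]] <- list(list(
        role = "decoy", fam = NA_integer_,
        seq = mutate_seq(decoy_anc, cfg$p_sub), product = "transposase",
        adjacent = FALSE))
    n_planted <- sum(lengths(blocks))
    n_bg <- cfg$genes_per_replicon - n_planted
    if (n_bg < 0L) stop("infeasible config: operons exceed replicon capacity")
    for (b in seq_len(n_bg)) {
      len <- sample(cfg$background_gene_len[1L]:cfg$background_gene_len[2L], 1L)
      blocks[[length(blocks) + 1L]] <- list(list(
        role = "background", fam = NA_integer_, seq = random_aa(len),
        product = "hypothetical protein"))
    }
    blocks <- blocks[sample.int(length(blocks))]

    # left-to-right layout; a block's genes are listed in transcription
    # order, so on the minus strand they are laid out reversed
    rows <- list()
    pos <- 201L
    replicon_id <- paste0(gid, "_c1")
    for (bl in blocks) {
      strand <- sample(c("+", "-"), 1L)
      genes_lr <- if (strand == "+") bl else rev(bl)
      within_gaps <- if (length(genes_lr) > 1L)
        vapply(seq_len(length(genes_lr) - 1L), function(i) draw_gap(),
               integer(1)) else integer()
      for (i in seq_along(genes_lr)) {
        g <- genes_lr[[i]]
        len_nt <- 3L * nchar(g$seq)
        start <- pos
        end <- pos + len_nt - 1L
        g$start_nt <- start; g$end_nt <- end; g$strand <- strand
        rows[[length(rows) + 1L]] <- g
        pos <- if (i < length(genes_lr)) end + within_gaps[i] + 1L else
          end + draw_bg_gap() + 1L
      }
    }
    idx <- seq_along(rows)
    feature_id <- sprintf("%s_f%03d", gid, idx)
    protein_id <- sprintf("%s_p%03d", gid, idx)
    feats <- data.frame(
      feature_id = feature_id, replicon_id = replicon_id,
      start_nt = vapply(rows, `[[`, integer(1), "start_nt"),
      end_nt = vapply(rows, `[[`, integer(1), "end_nt"),
      strand = vapply(rows, `[[`, character(1), "strand"),
      protein_id = protein_id,
      product = vapply(rows, `[[`, character(1), "product"),
      aa_seq = vapply(rows, `[[`, character(1), "seq"),
      stringsAsFactors = FALSE)
    repl <- data.frame(replicon_id = replicon_id, kind = "chromosome",
                       length_nt = max(feats$end_nt) + 200L,
                       stringsAsFactors = FALSE)
    corpus[[gid]] <- ta_genome(gid, species, feats, repl,
                               phylum = "phylum_sim",
                               superkingdom = "bacteria", is_complete = TRUE)
    roles <- vapply(rows, `[[`, character(1), "role")
    fams <- vapply(rows, function(r) as.integer(r$fam %||% NA_integer_),
                   integer(1))
    for (f in species_fams[[si]]) {
      i_seed <- which(roles == "seed" & fams == f)
      i_tox <- which(roles == "toxin" & fams == f)
      i_acc <- which(roles == "accessory" & fams == f)
      gap <- intergenic_distance(feats[i_seed, ], feats[i_tox, ])
      truth_loci[[length(truth_loci) + 1L]] <- data.frame(
        genome_id = gid, species = species,
        antitoxin_feature = feature_id[i_seed],
        antitoxin_protein = protein_id[i_seed],
        toxin_feature = feature_id[i_tox], toxin_protein = protein_id[i_tox],
        family = sprintf("fam%02d", f), gap_nt = gap, order = fam_order[f],
        accessory = length(i_acc) > 0L,
        accessory_feature = if (length(i_acc)) feature_id[i_acc] else
          NA_character_, stringsAsFactors = FALSE)
      truth_ext[[length(truth_ext) + 1L]] <- data.frame(
        protein_id = protein_id[i_seed], genome_id = gid,
        label = rows[[i_seed]]$ext_label, stringsAsFactors = FALSE)
      truth_tm[[length(truth_tm) + 1L]] <- data.frame(
        protein_id = protein_id[i_tox], genome_id = gid,
        family = sprintf("fam%02d", f), tm = fam_tm[f],
        stringsAsFactors = FALSE)
    }
    for (i_dec in which(roles == "decoy"))
      truth_decoys[[length(truth_decoys) + 1L]] <- data.frame(
        genome_id = gid, feature_id = feature_id[i_dec],
        protein_id = protein_id[i_dec],
        adjacent_to_seed = isTRUE(rows[[i_dec]]$adjacent),
        stringsAsFactors = FALSE)
  }

  bindr <- function(x, proto) if (length(x))
    do.call(rbind, c(x, list(make.row.names = FALSE))) else proto
  truth <- list(
    loci = bindr(truth_loci, data.frame()),
    decoys = bindr(truth_decoys, data.frame(
      genome_id = character(), feature_id = character(),
      protein_id = character(), adjacent_to_seed = logical(),
      stringsAsFactors = FALSE)),
    extensions = bindr(truth_ext, data.frame()),
    tm = bindr(truth_tm, data.frame()))

  out <- list(corpus = corpus, truth = truth, seed_alignment = seed_aln,
              hth_alignment = hth_aln, config = cfg)
  if (!is.null(out_dir)) write_simulation(out, out_dir)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_corpus(sim$corpus, out_dir)
  write_fasta <- function(x, path)
    writeLines(as.vector(rbind(paste0(">", names(x)), unname(x))), path)
  write_fasta(sim$seed_alignment, file.path(out_dir, "seed_alignment.faa"))
  write_fasta(sim$hth_alignment, file.path(out_dir, "hth_alignment.faa"))
  tdir <- file.path(out_dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  for (nm in names(sim$truth))
    write.table(sim$truth[[nm]], file.path(tdir, paste0("truth_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  writeLines(vapply(names(cfg), function(k)
    paste0(k, "=", paste(cfg[[k]], collapse = ",")), character(1)),
    file.path(out_dir, "sim.cfg"))
  invisible(out_dir)
}

#' Read a simulation's ground truth back from disk
#'
#' @param dir Directory written by [simulate_pangenome()].
#' @return List of truth tables (`loci`, `decoys`, `extensions`, `tm`).
#' @export
read_truth <- function(dir) {
  tdir <- file.path(dir, "truth")
  nms <- c("loci", "decoys", "extensions", "tm")
  setNames(lapply(nms, function(nm)
    read.delim(file.path(tdir, paste0("truth_", nm, ".tsv")),
               stringsAsFactors = FALSE)), nms)
}
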