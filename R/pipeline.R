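#' Run the full TA-locus discovery pipeline on a corpus
#'
#' End-to-end driver: seed-domain scan (or injected hits), flank collection
#' within a `k`-gene window around every seed, homologous flank clustering,
#' candidate-pair calling under the three locus criteria (gap <=
#' `max_gap_nt`, architecture conserved in >= `min_species` species,
#' conserved operon no longer than `max_operon` genes), T-numbered toxin
#' cluster assignment, reciprocal-context filtering of partner and accessory
#' clusters, and (optionally) candidate annotation: N-terminal extension
#' extraction, two-pass HTH re-modelling, novel conserved-extension
#' discovery, and hydropathy TM segments on the final toxins.
#'
#' The pipeline is deterministic: identical inputs give identical results,
#' invariant to genome input order and to coordinate mirroring of every
#' replicon.
#'
#' @param corpus Named list of [ta_genome] objects (or a corpus directory for
#'   [read_corpus()]).
#' @param seed_alignment Seed-domain alignment (path, character vector or
#'   `AAStringSet`) used to build the scanning profile; ignored when
#'   `seed_profile` or `seed_hits` is given.
#' @param seed_profile Optional prebuilt [build_profile()] profile.
#' @param seed_hits Optional injected seed-hit table (e.g. from
#'   [parse_domain_table()]); skips the internal scan.
#' @param hth_alignment,hth_profile Optional initial HTH model for the
#'   two-pass extension annotation.
#' @param k Neighborhood window in genes per side (default 4).
#' @param max_gap_nt,min_species,max_operon The three locus criteria.
#' @param min_identity,min_coverage Flank-clustering (and homology)
#'   thresholds.
#' @param min_context_fraction,top_n Reciprocity-filter parameters.
#' @param min_ext_len Minimum N-terminal extension length (default 40 aa).
#' @param pad1_min_members,pad1_min_species Novel-extension reporting
#'   thresholds.
#' @param tm_window,tm_threshold Hydropathy TM parameters.
#' @param min_kmer_frac Alignment prescreen (see [cluster_flanks()]);
#'   0 disables.
#' @param require_same_strand Require operonic co-orientation (default TRUE).
#' @param annotate Run the annotation stage (default TRUE).
#' @return Object of class `ta_result`; see [corpus_summary()] and
#'   [write_ta_result()].
#' @export
ta_pipeline <- function(corpus, seed_alignment = NULL, seed_profile = NULL,
                        seed_hits = NULL, hth_alignment = NULL,
                        hth_profile = NULL, k = 4L, max_gap_nt = 100L,
                        min_species = 2L, max_operon = 3L,
                        min_identity = 0.3, min_coverage = 0.6,
                        min_context_fraction = 0.5, top_n = 20L,
                        min_ext_len = 40L, pad1_min_members = 5L,
                        pad1_min_species = 2L, tm_window = 19L,
                        tm_threshold = 1.6, min_kmer_frac = 0.05,
                        require_same_strand = TRUE, annotate = TRUE) {
  if (is.character(corpus) && length(corpus) == 1L)
    corpus <- read_corpus(corpus)
  corpus <- corpus[order(vapply(corpus, function(g) g$genome_id,
                                character(1)))]
  names(corpus) <- vapply(corpus, function(g) g$genome_id, character(1))
  load_aln <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x))
      as.character(Biostrings::readAAStringSet(x)) else x
  }
  if (is.null(seed_profile) && is.null(seed_hits)) {
    if (is.null(seed_alignment))
      stop("provide seed_alignment, seed_profile or seed_hits")
    seed_profile <- build_profile(load_aln(seed_alignment), name = "seed")
  }
  if (is.null(seed_hits))
    seed_hits <- scan_corpus(corpus, seed_profile)
  ft <- corpus_feature_table(corpus)
  ft_key <- paste(ft$genome_id, ft$protein_id)
  seed_key <- paste(seed_hits$genome_id, seed_hits$protein_id)

  # flank set: all genes within k ranks of a seed gene on its replicon,
  # excluding seed-domain genes themselves
  flank_keys <- character()
  for (si in which(ft_key %in% seed_key)) {
    seed <- ft[si, , drop = FALSE]
    same <- ft$genome_id == seed$genome_id &
      ft$replicon_id == seed$replicon_id &
      abs(ft$rank - seed$rank) <= k & ft$rank != seed$rank
    flank_keys <- c(flank_keys, ft_key[same])
  }
  flank_keys <- setdiff(unique(flank_keys), seed_key)
  flanks <- ft[ft_key %in% flank_keys,
               c("protein_id", "genome_id", "species", "aa_seq"), drop = FALSE]
  clusters <- if (nrow(flanks))
    cluster_flanks(flanks, min_identity = min_identity,
                   min_coverage = min_coverage,
                   min_kmer_frac = min_kmer_frac)
  else data.frame(cluster_id = integer(), protein_id = character(),
                  genome_id = character(), species = character(),
                  stringsAsFactors = FALSE)

  loci <- call_candidate_pairs(corpus, seed_hits, clusters,
                               max_gap_nt = max_gap_nt,
                               require_same_strand = require_same_strand)
  loci <- filter_conserved(loci, min_species = min_species)
  loci <- filter_operon_length(loci, corpus, clusters,
                               max_gap_nt = max_gap_nt,
                               min_species = min_species,
                               max_operon = max_operon, k = k)
  loci <- assign_toxin_cluster_ids(loci)
  recip <- ta_reciprocity_filter(loci, clusters, corpus, seed_hits,
                                 min_context_fraction = min_context_fraction,
                                 top_n = top_n, max_gap_nt = max_gap_nt,
                                 min_identity = min_identity,
                                 min_coverage = min_coverage,
                                 min_kmer_frac = min_kmer_frac)
  loci <- recip$loci
  attr(loci, "t_map") <- attr(recip$loci, "t_map")

  annotations <- NULL
  if (annotate) {
    prot_map <- setNames(ft$aa_seq, ft$protein_id)
    species_map <- setNames(ft$species, ft$genome_id)
    exts <- extract_nterm_extensions(seed_hits, prot_map,
                                     min_len = min_ext_len)
    if (is.null(hth_profile) && !is.null(hth_alignment))
      hth_profile <- build_profile(load_aln(hth_alignment), name = "hth")
    hth <- if (!is.null(hth_profile))
      remodel_and_detect_hth(exts, hth_profile)
    else list(profile = NULL,
              flags = setNames(logical(nrow(exts)), exts$protein_id),
              pass1_flags = setNames(logical(nrow(exts)), exts$protein_id))
    non_hth <- exts[!hth$flags[exts$protein_id], , drop = FALSE]
    pad1 <- discover_conserved_extensions(non_hth, species_map,
                                          min_members = pad1_min_members,
                                          min_species = pad1_min_species,
                                          min_identity = min_identity,
                                          min_coverage = min_coverage)
    pad1_proteins <- if (!is.null(pad1$clusters) && nrow(pad1$reported))
      pad1$clusters$protein_id[pad1$clusters$cluster_id %in%
                               pad1$reported$cluster_id] else character()
    final <- loci[loci$verdict == "pTA", , drop = FALSE]
    tox_prot <- sort(unique(final$partner_protein))
    tm <- lapply(setNames(tox_prot, tox_prot), function(p)
      predict_tm_segments(prot_map[[p]], window = tm_window,
                          threshold = tm_threshold))
    seed_ann <- data.frame(
      protein_id = seed_hits$protein_id, genome_id = seed_hits$genome_id,
      ext_len = ifelse(seed_hits$protein_id %in% exts$protein_id,
                       exts$ext_len[match(seed_hits$protein_id,
                                          exts$protein_id)], 0L),
      hth = unname(ifelse(seed_hits$protein_id %in% names(hth$flags),
                          hth$flags[seed_hits$protein_id], FALSE)),
      pad1 = seed_hits$protein_id %in% pad1_proteins,
      stringsAsFactors = FALSE)
    tox_ann <- data.frame(
      protein_id = tox_prot,
      n_tm_segments = vapply(tm, nrow, integer(1)),
      stringsAsFactors = FALSE)
    annotations <- list(extensions = exts, hth = hth, pad1 = pad1,
                        tm_segments = tm, seed = seed_ann, toxin = tox_ann)
  }

  res <- structure(list(
    corpus = corpus, profile = seed_profile, seed_hits = seed_hits,
    flanks = flanks, clusters = clusters, loci = loci,
    t_map = attr(loci, "t_map"),
    toxin_summary = toxin_cluster_summary(loci),
    reciprocity = recip$verdicts,
    accessory = detect_accessory(loci),
    annotations = annotations,
    params = list(k = k, max_gap_nt = max_gap_nt, min_species = min_species,
                  max_operon = max_operon, min_identity = min_identity,
                  min_coverage = min_coverage,
                  min_context_fraction = min_context_fraction,
                  top_n = top_n, min_kmer_frac = min_kmer_frac)),
    class = "ta_result")
  res$summary <- corpus_summary(res)
  res
}

#' @export
print.ta_result <- function(x, ...) {
  cat(sprintf("<ta_result> %d genomes, %d seed hits, %d flank clusters\n",
              length(x$corpus), nrow(x$seed_hits),
              attr(x$clusters, "n_clusters") %||% 0L))
  print(x$summary)
  invisible(x)
}

#' @export
summary.ta_result <- function(object, ...) object$summary

#' Write pipeline outputs as TSV tables
#'
#' Emits `seed_hits.tsv`, `clusters.tsv`, `loci.tsv`,
#' `toxin_clusters.tsv`, `reciprocity.tsv`, `accessory.tsv`,
#' `annotations_seed.tsv`, `annotations_toxin.tsv` and a key-value
#' `summary.tsv`. Every summary count can be recomputed from the written
#' tables; there is no hidden state.
#'
#' @param result A [ta_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_ta_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, nm) write.table(d, file.path(dir, nm), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  wt(result$seed_hits, "seed_hits.tsv")
  wt(result$clusters, "clusters.tsv")
  wt(result$loci, "loci.tsv")
  wt(result$toxin_summary, "toxin_clusters.tsv")
  wt(result$reciprocity, "reciprocity.tsv")
  wt(result$accessory, "accessory.tsv")
  if (!is.null(result$annotations)) {
    wt(result$annotations$seed, "annotations_seed.tsv")
    wt(result$annotations$toxin, "annotations_toxin.tsv")
  }
  s <- result$summary
  kv <- data.frame(
    key = c("n_seed_hits", "n_candidates", "n_pta", "n_spurious", "n_final",
            "n_toxin_clusters", "antitoxin_first", "toxin_first"),
    value = c(s$n_seed_hits, s$n_candidates, s$n_pta, s$n_spurious,
              s$n_final, s$n_toxin_clusters,
              s$order_counts["antitoxin_first"],
              s$order_counts["toxin_first"]), stringsAsFactors = FALSE)
  wt(kv, "summary.tsv")
  invisible(dir)
}

#' Score pipeline predictions against planted ground truth
#'
#' A predicted locus is a true positive iff its (genome, antitoxin feature,
#' toxin feature) triple matches a planted-truth row. Precision with zero
#' predictions is reported as `NA`. Cluster-level reciprocity scoring uses
#' the clusters containing planted decoy and cognate toxin proteins;
#' annotation accuracies compare predicted HTH/PAD1/TM labels with the
#' planted labels.
#'
#' @param result A [ta_pipeline()] result.
#' @param truth Truth list from [simulate_pangenome()] (or a simulation
#'   directory for [read_truth()]).
#' @return List of metrics.
#' @export
ta_evaluate <- function(result, truth) {
  if (is.character(truth) && length(truth) == 1L) truth <- read_truth(truth)
  tl <- truth$loci
  ft <- corpus_feature_table(result$corpus)
  known <- c(paste(ft$genome_id, ft$feature_id))
  bad <- setdiff(c(paste(tl$genome_id, tl$antitoxin_feature),
                   paste(tl$genome_id, tl$toxin_feature)), known)
  if (length(bad))
    stop("truth rows reference unknown features: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  final <- result$loci[result$loci$verdict == "pTA", , drop = FALSE]
  pred_key <- paste(final$genome_id, final$antitoxin_feature,
                    final$partner_feature)
  truth_key <- paste(tl$genome_id, tl$antitoxin_feature, tl$toxin_feature)
  tp <- sum(pred_key %in% truth_key)
  precision <- if (length(pred_key)) tp / length(pred_key) else NA_real_
  recall <- if (length(truth_key)) tp / length(truth_key) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_

  cl_of <- setNames(result$clusters$cluster_id,
                    paste(result$clusters$genome_id,
                          result$clusters$protein_id))
  status_of <- setNames(result$reciprocity$status,
                        result$reciprocity$cluster_id)
  decoy_cl <- unique(stats::na.omit(
    cl_of[paste(truth$decoys$genome_id, truth$decoys$protein_id)]))
  decoy_tested <- decoy_cl[as.character(decoy_cl) %in% names(status_of)]
  decoy_flag_rate <- if (length(decoy_tested))
    mean(status_of[as.character(decoy_tested)] == "spurious") else NA_real_
  cognate_cl <- unique(stats::na.omit(
    cl_of[paste(truth$tm$genome_id, truth$tm$protein_id)]))
  cognate_tested <- cognate_cl[as.character(cognate_cl) %in% names(status_of)]
  cognate_false_rate <- if (length(cognate_tested))
    mean(status_of[as.character(cognate_tested)] == "spurious") else NA_real_

  hth_acc <- pad1_acc <- tm_acc <- NA_real_
  if (!is.null(result$annotations)) {
    ann <- result$annotations$seed
    te <- truth$extensions
    m <- match(te$protein_id, ann$protein_id)
    pred_hth <- ifelse(is.na(m), FALSE, ann$hth[m])
    pred_pad1 <- ifelse(is.na(m), FALSE, ann$pad1[m])
    hth_acc <- mean(pred_hth == (te$label == "hth"))
    pad1_acc <- mean(pred_pad1 == (te$label == "pad1"))
    tt <- truth$tm
    ta <- result$annotations$toxin
    mt <- match(tt$protein_id, ta$protein_id)
    scored <- !is.na(mt)
    if (any(scored))
      tm_acc <- mean((ta$n_tm_segments[mt[scored]] > 0L) == tt$tm[scored])
  }
  list(tp = tp, n_predicted = length(pred_key), n_truth = length(truth_key),
       precision = precision, recall = recall, f1 = f1,
       decoy_flag_rate = decoy_flag_rate,
       cognate_false_spurious_rate = cognate_false_rate,
       hth_accuracy = hth_acc, pad1_accuracy = pad1_acc,
       tm_accuracy = tm_acc)
}
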