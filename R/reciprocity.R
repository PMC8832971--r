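#' Reciprocal genomic-context test for a partner cluster
#'
#' A genuine TA partner family should reciprocally sit next to seed-domain
#' genes wherever its homologs occur; mobile elements and housekeeping
#' families (transposases, integrases, ATPases) have many homologs far from
#' any seed. The test takes a representative member of the cluster (the
#' longest sequence, ties broken by lexicographically smallest protein id),
#' finds its `top_n` best-scoring homologs across all proteomes (pairwise
#' global alignment, identity and coverage above the clustering thresholds),
#' and computes the fraction of those homologs encoded within `max_gap_nt` of
#' a seed-domain gene. The cluster is flagged `spurious` when that fraction
#' falls below `min_context_fraction`. A cluster whose only homologs are its
#' own members is always retained: it cannot be convicted on absence of
#' evidence.
#'
#' @param cluster_members `data.frame` with `protein_id`, `genome_id` for the
#'   cluster's members.
#' @param corpus Named list of [ta_genome] objects (all proteomes).
#' @param seed_hits Seed-hit table.
#' @param min_context_fraction Spurious threshold on the seed-adjacent
#'   fraction (default 0.5).
#' @param top_n Number of best homologs examined (default 20).
#' @param max_gap_nt Adjacency radius in nucleotides (default 100).
#' @param min_identity,min_coverage Homology thresholds (defaults 0.3 / 0.6).
#' @param min_len_ratio,min_kmer_frac Alignment prefilters as in
#'   [cluster_flanks()].
#' @return One-row `data.frame`: `status` (`retained`/`spurious`),
#'   `context_fraction`, `n_homologs_examined`.
#' @export
reciprocal_context_test <- function(cluster_members, corpus, seed_hits,
                                    min_context_fraction = 0.5, top_n = 20L,
                                    max_gap_nt = 100L, min_identity = 0.3,
                                    min_coverage = 0.6, min_len_ratio = 0.5,
                                    min_kmer_frac = 0.05) {
  ft <- corpus_feature_table(corpus)
  ft$key <- paste(ft$genome_id, ft$protein_id)
  mem_key <- paste(cluster_members$genome_id, cluster_members$protein_id)
  mem <- ft[ft$key %in% mem_key, , drop = FALSE]
  if (!nrow(mem)) stop("cluster members not found in corpus")
  mem <- mem[order(-nchar(mem$aa_seq), mem$protein_id), , drop = FALSE]
  rep_row <- mem[1L, , drop = FALSE]
  others <- ft[ft$key != rep_row$key, , drop = FALSE]
  hits <- .align_batch_cpp(rep_row$aa_seq, others$aa_seq, blosum62_submat(),
                           11, 1, min_len_ratio, min_kmer_frac)
  is_hom <- !is.na(hits$identity) & hits$identity >= min_identity &
    hits$coverage >= min_coverage
  hom <- others[is_hom, , drop = FALSE]
  hom$score <- hits$score[is_hom]
  hom <- hom[order(-hom$score, hom$protein_id), , drop = FALSE]
  hom <- utils::head(hom, top_n)
  external <- setdiff(hom$key, mem_key)
  if (!nrow(hom) || !length(external)) {
    return(data.frame(status = "retained",
                      context_fraction = if (nrow(hom))
                        mean(seed_adjacent(hom, ft, seed_hits, max_gap_nt))
                        else NA_real_,
                      n_homologs_examined = nrow(cluster_members),
                      stringsAsFactors = FALSE))
  }
  frac <- mean(seed_adjacent(hom, ft, seed_hits, max_gap_nt))
  data.frame(status = if (frac < min_context_fraction) "spurious" else
               "retained",
             context_fraction = frac, n_homologs_examined = nrow(hom),
             stringsAsFactors = FALSE)
}

# For each feature row, TRUE when a seed-hit gene on the same replicon of the
# same genome lies within max_gap_nt.
seed_adjacent <- function(rows, ft, seed_hits, max_gap_nt) {
  seed_key <- paste(seed_hits$genome_id, seed_hits$protein_id)
  seeds <- ft[ft$key %in% seed_key, , drop = FALSE]
  vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, , drop = FALSE]
    s <- seeds[seeds$genome_id == r$genome_id &
               seeds$replicon_id == r$replicon_id, , drop = FALSE]
    if (!nrow(s)) return(FALSE)
    if (r$key %in% s$key) s <- s[s$key != r$key, , drop = FALSE]
    if (!nrow(s)) return(FALSE)
    any(vapply(seq_len(nrow(s)), function(j)
      intergenic_distance(r, s[j, , drop = FALSE]) <= max_gap_nt, logical(1)))
  }, logical(1))
}

#' Apply the reciprocity test to every tested cluster of a call set
#'
#' Tests the partner clusters of all pTA-verdict loci and, with the same
#' criterion, their accessory clusters. Loci whose partner cluster is flagged
#' spurious are downgraded to `spurious_partner`; accessory genes whose
#' cluster is flagged are detached from their loci (the locus itself
#' survives).
#'
#' @param loci Locus table with `t_id` assigned.
#' @param clusters Flank cluster table.
#' @inheritParams reciprocal_context_test
#' @return List with `loci` (verdicts updated) and `verdicts` (one row per
#'   tested cluster: `cluster_id`, `t_id`, `role`, `status`,
#'   `context_fraction`, `n_homologs_examined`).
#' @export
ta_reciprocity_filter <- function(loci, clusters, corpus, seed_hits,
                                  min_context_fraction = 0.5, top_n = 20L,
                                  max_gap_nt = 100L, min_identity = 0.3,
                                  min_coverage = 0.6, min_len_ratio = 0.5,
                                  min_kmer_frac = 0.05) {
  pta <- loci[loci$verdict == "pTA", , drop = FALSE]
  partner_cl <- sort(unique(pta$partner_cluster))
  acc_cl <- sort(unique(pta$accessory_cluster[!is.na(pta$accessory_cluster)]))
  acc_cl <- setdiff(acc_cl, partner_cl)
  test_one <- function(cl, role) {
    members <- clusters[clusters$cluster_id == cl, , drop = FALSE]
    v <- reciprocal_context_test(members, corpus, seed_hits,
                                 min_context_fraction, top_n, max_gap_nt,
                                 min_identity, min_coverage, min_len_ratio,
                                 min_kmer_frac)
    t_ids <- unique(pta$t_id[pta$partner_cluster == cl])
    data.frame(cluster_id = cl,
               t_id = if (role == "partner" && length(t_ids)) t_ids[1L]
                      else NA_character_,
               role = role, status = v$status,
               context_fraction = v$context_fraction,
               n_homologs_examined = v$n_homologs_examined,
               stringsAsFactors = FALSE)
  }
  verdicts <- rbind(
    if (length(partner_cl))
      do.call(rbind, lapply(partner_cl, test_one, role = "partner")),
    if (length(acc_cl))
      do.call(rbind, lapply(acc_cl, test_one, role = "accessory")))
  if (is.null(verdicts))
    verdicts <- data.frame(cluster_id = integer(), t_id = character(),
                           role = character(), status = character(),
                           context_fraction = numeric(),
                           n_homologs_examined = integer(),
                           stringsAsFactors = FALSE)
  spurious <- verdicts$cluster_id[verdicts$status == "spurious"]
  hit <- loci$verdict == "pTA" & loci$partner_cluster %in% spurious
  loci$verdict[hit] <- "spurious_partner"
  detach <- !is.na(loci$accessory_cluster) &
    loci$accessory_cluster %in% spurious
  loci$accessory_feature[detach] <- NA_character_
  loci$accessory_protein[detach] <- NA_character_
  loci$accessory_cluster[detach] <- NA_integer_
  list(loci = loci, verdicts = verdicts)
}

#' Keyword tally of product annotations by reciprocity status
#'
#' Diagnostic report (never a filter): counts configurable product-string
#' keyword classes among spurious versus retained clusters. Matching is
#' case-insensitive; a cluster's product is the most frequent member product,
#' ties broken lexicographically. Clusters matching no keyword count as
#' `other`.
#'
#' @param verdicts Verdict table from [ta_reciprocity_filter()].
#' @param clusters Flank cluster table.
#' @param corpus Named list of [ta_genome] objects (source of product
#'   strings).
#' @param keywords Keyword classes (default transposase, integrase, ATPase).
#' @return `data.frame` with `status`, `class`, `n`.
#' @export
annotate_spurious_classes <- function(verdicts, clusters, corpus,
                                      keywords = c("transposase", "integrase",
                                                   "ATPase")) {
  if (!nrow(verdicts))
    return(data.frame(status = character(), class = character(),
                      n = integer(), stringsAsFactors = FALSE))
  ft <- corpus_feature_table(corpus)
  prod_map <- setNames(ft$product, paste(ft$genome_id, ft$protein_id))
  cluster_product <- vapply(verdicts$cluster_id, function(cl) {
    mem <- clusters[clusters$cluster_id == cl, , drop = FALSE]
    pr <- unname(prod_map[paste(mem$genome_id, mem$protein_id)])
    pr <- pr[!is.na(pr)]
    if (!length(pr)) return("")
    tab <- sort(table(pr), decreasing = TRUE)
    names(tab)[tab == max(tab)][1L]
  }, character(1))
  cls <- rep("other", length(cluster_product))
  for (kw in keywords) {
    m <- grepl(kw, cluster_product, ignore.case = TRUE) & cls == "other"
    cls[m] <- kw
  }
  agg <- stats::aggregate(list(n = seq_along(cls)),
                          by = list(status = verdicts$status, class = cls),
                          FUN = length)
  agg <- agg[order(agg$status, agg$class), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
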