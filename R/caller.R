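#' Transcriptional order of an operonic gene pair
#'
#' `antitoxin_first` when the antitoxin (seed-domain) gene is transcribed
#' before its partner: on the `+` strand the antitoxin starts first, on the
#' `-` strand it starts last. Both genes must be co-oriented on the same
#' replicon; order is undefined across strands.
#'
#' @param antitoxin,partner Single feature rows.
#' @return `"antitoxin_first"` or `"toxin_first"`.
#' @export
classify_order <- function(antitoxin, partner) {
  if (antitoxin$replicon_id != partner$replicon_id)
    stop("genes are on different replicons")
  if (antitoxin$strand != partner$strand)
    stop("cannot define gene order for genes on different strands")
  if (antitoxin$strand == "+") {
    if (antitoxin$start_nt < partner$start_nt) "antitoxin_first" else "toxin_first"
  } else {
    if (antitoxin$start_nt > partner$start_nt) "antitoxin_first" else "toxin_first"
  }
}

empty_loci <- function() {
  data.frame(genome_id = character(), species = character(),
             replicon_id = character(), antitoxin_feature = character(),
             antitoxin_protein = character(), partner_feature = character(),
             partner_protein = character(), partner_cluster = integer(),
             gap_nt = integer(), strand = character(), order = character(),
             support_species = integer(), accessory_feature = character(),
             accessory_protein = character(), accessory_cluster = integer(),
             verdict = character(), t_id = character(),
             stringsAsFactors = FALSE)
}

#' Candidate antitoxin-partner pairs from seed neighborhoods
#'
#' For every seed-domain gene, each immediately adjacent gene (rank +/- 1 on
#' the same replicon) that is co-oriented and within `max_gap_nt` of the seed
#' becomes a candidate locus; a seed can therefore yield up to two candidates,
#' one per side. Co-orientation is required by default because these are
#' operonic loci; `require_same_strand = FALSE` relaxes it.
#'
#' @param corpus Named list of [ta_genome] objects.
#' @param seed_hits Seed-hit table ([scan_corpus()] /
#'   [parse_domain_table()]).
#' @param clusters Flank cluster table ([cluster_flanks()]).
#' @param max_gap_nt Maximum intergenic distance in nucleotides, inclusive
#'   (default 100).
#' @param require_same_strand Require co-orientation (default `TRUE`).
#' @return Locus `data.frame`, one row per candidate, `verdict = "pTA"`
#'   provisionally; downstream filters downgrade the verdict.
#' @export
call_candidate_pairs <- function(corpus, seed_hits, clusters,
                                 max_gap_nt = 100L,
                                 require_same_strand = TRUE) {
  ft <- corpus_feature_table(corpus)
  if (is.null(ft) || !nrow(seed_hits)) return(empty_loci())
  cl_map <- setNames(clusters$cluster_id,
                     paste(clusters$genome_id, clusters$protein_id))
  seed_key <- paste(seed_hits$genome_id, seed_hits$protein_id)
  ft_key <- paste(ft$genome_id, ft$protein_id)
  rows <- list()
  for (si in which(ft_key %in% seed_key)) {
    seed <- ft[si, , drop = FALSE]
    same <- ft[ft$genome_id == seed$genome_id &
               ft$replicon_id == seed$replicon_id, , drop = FALSE]
    for (dr in c(-1L, 1L)) {
      ni <- which(same$rank == seed$rank + dr)
      if (!length(ni)) next
      nb <- same[ni, , drop = FALSE]
      if (require_same_strand && nb$strand != seed$strand) next
      gap <- intergenic_distance(seed, nb)
      if (gap > max_gap_nt) next
      ord <- if (nb$strand == seed$strand) classify_order(seed, nb)
             else NA_character_
      cl <- unname(cl_map[paste(nb$genome_id, nb$protein_id)])
      if (is.na(cl)) next     # partner outside the clustered flank set
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = seed$genome_id, species = seed$species,
        replicon_id = seed$replicon_id,
        antitoxin_feature = seed$feature_id,
        antitoxin_protein = seed$protein_id,
        partner_feature = nb$feature_id, partner_protein = nb$protein_id,
        partner_cluster = as.integer(cl), gap_nt = as.integer(gap),
        strand = seed$strand, order = ord, support_species = NA_integer_,
        accessory_feature = NA_character_, accessory_protein = NA_character_,
        accessory_cluster = NA_integer_, verdict = "pTA",
        t_id = NA_character_, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_loci())
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$genome_id, out$antitoxin_protein, out$partner_protein), ,
      drop = FALSE]
}

# Architecture identity used for conservation counting: the partner's cluster
# together with its side relative to the seed in transcription direction.
arch_key <- function(loci) paste(loci$partner_cluster, loci$order)

#' Conservation filter: the architecture must occur in two or more species
#'
#' Sets `support_species` to the number of distinct species containing a
#' candidate with the same (partner cluster, gene order) architecture, and
#' downgrades candidates with support below `min_species` to
#' `rejected_support`. Two genomes of one species count once; the same
#' partner cluster in opposite gene orders counts as two independent
#' architectures, each needing its own support.
#'
#' @param candidates Locus table from [call_candidate_pairs()].
#' @param min_species Minimum distinct species (default 2).
#' @return The locus table with `support_species` filled in.
#' @export
filter_conserved <- function(candidates, min_species = 2L) {
  if (!nrow(candidates)) return(candidates)
  key <- arch_key(candidates)
  supp <- tapply(candidates$species, key, function(s) length(unique(s)))
  candidates$support_species <- as.integer(supp[key])
  downgrade <- candidates$verdict == "pTA" &
    candidates$support_species < min_species
  candidates$verdict[downgrade] <- "rejected_support"
  candidates
}

#' Operon-length filter and accessory-gene detection
#'
#' Walks outward from each surviving pair in both directions, chaining genes
#' that stay within `max_gap_nt` of the previous gene on the same strand. A
#' chained gene is *conserved* when its flank cluster co-occurs with the
#' pair's architecture in at least `min_species` species. Candidates whose
#' contiguous conserved chain exceeds `max_operon` genes are downgraded to
#' `rejected_operon_length`; a conserved chain of exactly three genes keeps
#' the pair and records the third gene as the accessory.
#'
#' @inheritParams call_candidate_pairs
#' @param candidates Locus table after [filter_conserved()].
#' @param min_species Species threshold for a chained gene to count as
#'   conserved (default 2).
#' @param max_operon Maximum conserved operon length in genes (default 3).
#' @param k Walk bound in genes beyond the pair on each side (default 4,
#'   matching the neighborhood window).
#' @return The locus table with verdicts and accessory fields updated.
#' @export
filter_operon_length <- function(candidates, corpus, clusters,
                                 max_gap_nt = 100L, min_species = 2L,
                                 max_operon = 3L, k = 4L) {
  if (!nrow(candidates)) return(candidates)
  ft <- corpus_feature_table(corpus)
  cl_map <- setNames(clusters$cluster_id,
                     paste(clusters$genome_id, clusters$protein_id))
  live <- which(candidates$verdict == "pTA")
  # per-candidate outward walks: list of (feature index in ft, cluster)
  walks <- vector("list", nrow(candidates))
  for (i in live) {
    cand <- candidates[i, , drop = FALSE]
    same <- ft[ft$genome_id == cand$genome_id &
               ft$replicon_id == cand$replicon_id, , drop = FALSE]
    same <- same[order(same$rank), , drop = FALSE]
    ra <- same$rank[same$feature_id == cand$antitoxin_feature]
    rp <- same$rank[same$feature_id == cand$partner_feature]
    lo <- min(ra, rp); hi <- max(ra, rp)
    strand <- cand$strand
    walk_dir <- function(from_rank, step) {
      out <- list()
      prev <- same[same$rank == from_rank, , drop = FALSE]
      r <- from_rank + step
      while (abs(r - from_rank) <= k) {
        idx <- which(same$rank == r)
        if (!length(idx)) break
        gene <- same[idx, , drop = FALSE]
        if (gene$strand != strand) break
        if (intergenic_distance(prev, gene) > max_gap_nt) break
        out[[length(out) + 1L]] <- list(
          feature_id = gene$feature_id, protein_id = gene$protein_id,
          cluster = unname(cl_map[paste(gene$genome_id, gene$protein_id)]))
        prev <- gene
        r <- r + step
      }
      out
    }
    walks[[i]] <- list(left = walk_dir(lo, -1L), right = walk_dir(hi, 1L))
  }
  # co-occurrence support of chained clusters per architecture
  co <- list()
  for (i in live) {
    chained <- c(walks[[i]]$left, walks[[i]]$right)
    for (g in chained)
      if (!is.na(g$cluster))
        co[[length(co) + 1L]] <- data.frame(
          key = paste(arch_key(candidates[i, , drop = FALSE]), g$cluster),
          species = candidates$species[i], stringsAsFactors = FALSE)
  }
  co_supp <- if (length(co)) {
    cdf <- do.call(rbind, co)
    tapply(cdf$species, cdf$key, function(s) length(unique(s)))
  } else numeric()
  for (i in live) {
    ak <- arch_key(candidates[i, , drop = FALSE])
    conserved_run <- function(side) {
      run <- list()
      for (g in side) {
        if (is.na(g$cluster)) break
        supp <- co_supp[paste(ak, g$cluster)]
        if (is.na(supp) || supp < min_species) break
        run[[length(run) + 1L]] <- g
      }
      run
    }
    runL <- conserved_run(walks[[i]]$left)
    runR <- conserved_run(walks[[i]]$right)
    total <- 2L + length(runL) + length(runR)
    if (total > max_operon) {
      candidates$verdict[i] <- "rejected_operon_length"
    } else if (total == 3L) {
      acc <- if (length(runL)) runL[[1L]] else runR[[1L]]
      candidates$accessory_feature[i] <- acc$feature_id
      candidates$accessory_protein[i] <- acc$protein_id
      candidates$accessory_cluster[i] <- as.integer(acc$cluster)
    }
  }
  candidates
}

#' Assign stable T-numbered toxin cluster ids
#'
#' Clusters of partner (putative toxin) proteins among pTA-verdict loci are
#' numbered `T1, T2, ...` by descending number of distinct partner proteins,
#' ties broken by the lexicographically smallest member protein id, so the
#' numbering is identical across reruns and input orders.
#'
#' @param loci Locus table.
#' @return The locus table with `t_id` filled for every row whose partner
#'   cluster hosts at least one pTA locus. The mapping is in attribute
#'   `"t_map"`.
#' @export
assign_toxin_cluster_ids <- function(loci) {
  pta <- loci[loci$verdict == "pTA", , drop = FALSE]
  if (!nrow(pta)) {
    attr(loci, "t_map") <- setNames(character(), character())
    return(loci)
  }
  by_cl <- split(pta$partner_protein, pta$partner_cluster)
  member_count <- vapply(by_cl, function(x) length(unique(x)), integer(1))
  example <- vapply(by_cl, min, character(1))
  ord <- order(-member_count, example)
  t_map <- setNames(paste0("T", seq_along(ord)), names(by_cl)[ord])
  loci$t_id <- unname(t_map[as.character(loci$partner_cluster)])
  attr(loci, "t_map") <- t_map
  loci
}

#' Aggregate accessory third genes per toxin cluster
#'
#' @param loci Locus table with accessory fields and `t_id` assigned.
#' @return `data.frame` with one row per (toxin cluster, accessory cluster):
#'   `t_id`, `accessory_cluster`, `n_species_with_accessory`.
#' @export
detect_accessory <- function(loci) {
  acc <- loci[loci$verdict == "pTA" & !is.na(loci$accessory_cluster), ,
              drop = FALSE]
  if (!nrow(acc))
    return(data.frame(t_id = character(), accessory_cluster = integer(),
                      n_species_with_accessory = integer(),
                      stringsAsFactors = FALSE))
  key <- paste(acc$t_id, acc$accessory_cluster)
  agg <- tapply(acc$species, key, function(s) length(unique(s)))
  parts <- do.call(rbind, strsplit(names(agg), " "))
  out <- data.frame(t_id = parts[, 1L],
                    accessory_cluster = as.integer(parts[, 2L]),
                    n_species_with_accessory = as.integer(agg),
                    stringsAsFactors = FALSE)
  out <- out[order(out$t_id, out$accessory_cluster), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summaries of called toxin clusters
#'
#' @param loci Locus table with `t_id` assigned.
#' @return One row per toxin cluster among pTA loci: `t_id`, `cluster_id`,
#'   `member_count` (distinct partner proteins), `n_genomes`, `n_species`,
#'   `example_protein_id`.
#' @export
toxin_cluster_summary <- function(loci) {
  pta <- loci[loci$verdict == "pTA" & !is.na(loci$t_id), , drop = FALSE]
  if (!nrow(pta))
    return(data.frame(t_id = character(), cluster_id = integer(),
                      member_count = integer(), n_genomes = integer(),
                      n_species = integer(), example_protein_id = character(),
                      stringsAsFactors = FALSE))
  sp <- split(pta, pta$t_id)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    t_id = d$t_id[1L], cluster_id = d$partner_cluster[1L],
    member_count = length(unique(d$partner_protein)),
    n_genomes = length(unique(d$genome_id)),
    n_species = length(unique(d$species)),
    example_protein_id = min(d$partner_protein), stringsAsFactors = FALSE)))
  out <- out[order(as.integer(sub("^T", "", out$t_id))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
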