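#' Seed-domain copy-number histogram per taxon
#'
#' Counts seed-domain proteins per species and tabulates how many species
#' carry 1, 2, 3, ... homologs. The taxon unit is the species string; when a
#' species has several genomes, the representative genome with the most
#' features stands for it (mirroring a one-proteome-per-species corpus).
#' Species with zero hits are absent from the histogram.
#'
#' @param corpus Named list of [ta_genome] objects.
#' @param seed_hits Seed-hit table.
#' @param per_strain Count every genome separately instead of collapsing to
#'   one representative per species (default `FALSE`).
#' @return Named integer vector: names are homolog counts, values are the
#'   number of taxa with that count.
#' @export
copy_number_table <- function(corpus, seed_hits, per_strain = FALSE) {
  if (!nrow(seed_hits)) return(setNames(integer(), character()))
  reps <- if (per_strain) names(corpus) else {
    info <- data.frame(
      genome_id = vapply(corpus, function(g) g$genome_id, character(1)),
      species = vapply(corpus, function(g) g$species, character(1)),
      n_feat = vapply(corpus, function(g) nrow(g$features), integer(1)),
      stringsAsFactors = FALSE)
    info <- info[order(info$species, -info$n_feat, info$genome_id), ,
                 drop = FALSE]
    info$genome_id[!duplicated(info$species)]
  }
  hits <- seed_hits[seed_hits$genome_id %in% reps, , drop = FALSE]
  if (!nrow(hits)) return(setNames(integer(), character()))
  counts <- table(hits$genome_id)
  hist <- table(as.integer(counts))
  setNames(as.integer(hist), names(hist))
}

#' Replicon localization of seed hits in complete genomes
#'
#' Restricted to genomes flagged complete (only there can chromosome versus
#' plasmid be trusted), counts seed-domain genes on chromosomes, plasmids and
#' replicons of other/unknown kind.
#'
#' @inheritParams copy_number_table
#' @return Named integer vector `c(n_chromosomal, n_plasmid, n_unknown)`.
#' @export
replicon_localization <- function(corpus, seed_hits) {
  out <- c(n_chromosomal = 0L, n_plasmid = 0L, n_unknown = 0L)
  if (!nrow(seed_hits)) return(out)
  for (g in corpus) {
    if (!g$is_complete) next
    h <- seed_hits[seed_hits$genome_id == g$genome_id, , drop = FALSE]
    if (!nrow(h)) next
    f <- g$features
    repl <- f$replicon_id[match(h$protein_id, f$protein_id)]
    kind <- g$replicons$kind[match(repl, g$replicons$replicon_id)]
    out["n_chromosomal"] <- out["n_chromosomal"] + sum(kind == "chromosome")
    out["n_plasmid"] <- out["n_plasmid"] + sum(kind == "plasmid")
    out["n_unknown"] <- out["n_unknown"] +
      sum(!(kind %in% c("chromosome", "plasmid")))
  }
  out
}

#' Gene-order tally over final loci
#'
#' @param loci Locus table; only pTA-verdict rows are counted.
#' @return Named integer vector `c(antitoxin_first, toxin_first)`.
#' @export
order_counts <- function(loci) {
  pta <- loci[loci$verdict == "pTA", , drop = FALSE]
  c(antitoxin_first = sum(pta$order == "antitoxin_first", na.rm = TRUE),
    toxin_first = sum(pta$order == "toxin_first", na.rm = TRUE))
}

#' Corpus-level summary of a pipeline run
#'
#' @param result A [ta_pipeline()] result.
#' @return List of class `ta_summary`: seed-hit count, copy-number histogram,
#'   replicon localization, order counts, locus counts by verdict, number of
#'   retained toxin clusters.
#' @export
corpus_summary <- function(result) {
  loci <- result$loci
  n_pta <- sum(loci$verdict %in% c("pTA", "spurious_partner"))
  n_spurious <- sum(loci$verdict == "spurious_partner")
  final <- loci[loci$verdict == "pTA", , drop = FALSE]
  structure(list(
    n_seed_hits = nrow(result$seed_hits),
    copy_number_histogram = copy_number_table(result$corpus,
                                              result$seed_hits),
    replicon_localization = replicon_localization(result$corpus,
                                                  result$seed_hits),
    order_counts = order_counts(loci),
    n_candidates = nrow(loci),
    n_pta = n_pta,
    n_spurious = n_spurious,
    n_final = n_pta - n_spurious,
    n_toxin_clusters = length(unique(final$t_id[!is.na(final$t_id)]))),
    class = "ta_summary")
}

#' @export
print.ta_summary <- function(x, ...) {
  cat("Corpus summary\n")
  cat(sprintf("  seed-domain proteins: %d\n", x$n_seed_hits))
  if (length(x$copy_number_histogram)) {
    cn <- paste(sprintf("%s:%d", names(x$copy_number_histogram),
                        x$copy_number_histogram), collapse = ", ")
    cat(sprintf("  copies per taxon (copies:taxa): %s\n", cn))
  }
  rl <- x$replicon_localization
  cat(sprintf("  localization (complete genomes): %d chromosomal, %d plasmid, %d unknown\n",
              rl["n_chromosomal"], rl["n_plasmid"], rl["n_unknown"]))
  cat(sprintf("  candidate pairs: %d; pTA loci: %d; spurious-partner: %d; final: %d\n",
              x$n_candidates, x$n_pta, x$n_spurious, x$n_final))
  oc <- x$order_counts
  cat(sprintf("  gene order among final loci: %d antitoxin-first vs %d toxin-first\n",
              oc["antitoxin_first"], oc["toxin_first"]))
  cat(sprintf("  retained toxin clusters: %d\n", x$n_toxin_clusters))
  invisible(x)
}
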