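#' Pairwise protein similarity
#'
#' Global (end-to-end) alignment of two protein sequences with BLOSUM62,
#' gap opening 11 and gap extension 1 (a gap run of length L costs
#' 11 + L). Identity is the fraction of identical aligned pairs over aligned
#' columns excluding terminal gaps; coverage is the fraction of the shorter
#' sequence aligned against a residue of the other.
#'
#' @param a,b Non-empty amino-acid strings.
#' @param gap_open,gap_ext Gap penalties (positive).
#' @return List with `score`, `identity`, `coverage`, `aligned_cols`,
#'   `matches`.
#' @export
pairwise_similarity <- function(a, b, gap_open = 11, gap_ext = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  .align_pair_cpp(toupper(a), toupper(b), blosum62_submat(), gap_open, gap_ext)
}

#' Cluster flanking proteins into homologous families
#'
#' All-vs-all global alignment followed by single-linkage clustering: an edge
#' joins two proteins when alignment identity and coverage both reach their
#' thresholds, and clusters are the connected components of that graph.
#' Single linkage mirrors the transitivity of iterative profile searches used
#' by flanking-gene clustering tools; the documented risk is chaining through
#' intermediate sequences. Cluster ids are assigned deterministically: by
#' descending member count, ties broken by the lexicographically smallest
#' member protein id, so the partition and the ids are invariant to input
#' order.
#'
#' @param proteins `data.frame` with columns `protein_id`, `genome_id`,
#'   `species`, `aa_seq` (non-empty).
#' @param min_identity,min_coverage Edge thresholds (defaults 0.3 / 0.6).
#' @param min_len_ratio Pairs whose length ratio (shorter/longer) is below
#'   this are skipped (default 0.5); such pairs cannot reach useful coverage.
#' @param min_kmer_frac Shared-4-mer prescreen fraction in `[0, 1]`: pairs
#'   sharing fewer distinct 4-mers than this fraction of the smaller 4-mer
#'   set are not aligned, the same seeding idea fast homology search tools
#'   rest on. The default 0.05 is far below the overlap of any pair near the
#'   identity threshold; 0 disables the prescreen.
#' @param gap_open,gap_ext Alignment gap penalties.
#' @return `data.frame` with `cluster_id`, `protein_id`, `genome_id`,
#'   `species`, ordered by cluster id then protein id. The attribute
#'   `"n_clusters"` gives the number of clusters.
#' @export
cluster_flanks <- function(proteins, min_identity = 0.3, min_coverage = 0.6,
                           min_len_ratio = 0.5, min_kmer_frac = 0.05,
                           gap_open = 11, gap_ext = 1) {
  stopifnot(nrow(proteins) >= 1L)
  p <- as.data.frame(proteins, stringsAsFactors = FALSE)
  p <- p[order(p$protein_id), , drop = FALSE]
  if (anyDuplicated(p$protein_id))
    stop("protein_id must be unique across the flank set")
  n <- nrow(p)
  edges <- .align_all_pairs_cpp(p$aa_seq, blosum62_submat(), gap_open, gap_ext,
                                min_len_ratio, min_kmer_frac)
  keep <- edges$identity >= min_identity & edges$coverage >= min_coverage
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (any(keep))
    g <- igraph::add_edges(g, rbind(edges$i[keep], edges$j[keep]))
  comp <- igraph::components(g)$membership
  # deterministic ids: size desc, tie by smallest member protein_id
  sizes <- tabulate(comp)
  smallest <- tapply(p$protein_id, comp, min)
  ord <- order(-sizes, smallest)
  relabel <- integer(length(ord))
  relabel[ord] <- seq_along(ord)
  out <- data.frame(cluster_id = relabel[comp], protein_id = p$protein_id,
                    genome_id = p$genome_id, species = p$species,
                    stringsAsFactors = FALSE)
  out <- out[order(out$cluster_id, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_clusters") <- length(ord)
  out
}
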