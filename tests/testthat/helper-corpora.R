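# Hand-built corpora with hand-assigned seed hits and clusters: these
# isolate the caller's logic from scanning and alignment.

pair_corpus <- function(gap, strands = c("+", "+"), n_species = 2L,
                        order_by_species = NULL) {
  genomes <- lapply(seq_len(n_species), function(i) {
    ord <- if (is.null(order_by_species)) "antitoxin_first" else
      order_by_species[i]
    core <- if (ord == "antitoxin_first") c("seed", "tox") else c("tox", "seed")
    lay_genome(sprintf("g%02d", i), sprintf("sp%02d", i), data.frame(
      protein_id = c("bgA", core, "bgB"),
      len_aa = c(70, 60, 50, 80),
      gap_before = c(NA, 300, gap, 400),
      strand = c("+", strands[1], strands[2], "-"),
      stringsAsFactors = FALSE))
  })
  setNames(genomes, vapply(genomes, function(g) g$genome_id, character(1)))
}

caller_inputs <- function(corpus) {
  hits <- hand_hits(corpus, "seed")
  cl <- hand_clusters(corpus, list(`1` = "tox", `2` = "bgA", `3` = "bgB"))
  list(hits = hits, clusters = cl)
}

cassette_corpus <- function(n_extra, extra_conserved = TRUE) {
  # seed, toxin, then n_extra chained genes on the same strand at small gaps
  genomes <- lapply(1:2, function(i) {
    extra_ids <- if (extra_conserved) sprintf("x%d", seq_len(n_extra)) else
      sprintf("x%d_g%d", seq_len(n_extra), i)
    ids <- c("bgA", "seed", "tox", extra_ids, "bgB")
    lay_genome(sprintf("g%02d", i), sprintf("sp%02d", i), data.frame(
      protein_id = ids,
      len_aa = c(70, 60, 50, rep(45, n_extra), 80),
      gap_before = c(NA, 300, 50, rep(50, n_extra), 400),
      strand = c("-", rep("+", 2 + n_extra), "-"),
      stringsAsFactors = FALSE))
  })
  setNames(genomes, vapply(genomes, function(g) g$genome_id, character(1)))
}

cassette_clusters <- function(corpus, n_extra, extra_conserved = TRUE) {
  asn <- list(`1` = "tox", `2` = "bgA", `3` = "bgB")
  nxt <- 4L
  for (e in seq_len(n_extra)) {
    if (extra_conserved) {
      asn[[as.character(nxt)]] <- sprintf("x%d", e)
      nxt <- nxt + 1L
    } else {
      # one singleton cluster per genome: the third gene is not conserved
      for (i in 1:2) {
        asn[[as.character(nxt)]] <- sprintf("x%d_g%d", e, i)
        nxt <- nxt + 1L
      }
    }
  }
  hand_clusters(corpus, asn)
}

run_caller <- function(corpus, clusters, hits = hand_hits(corpus, "seed")) {
  loci <- call_candidate_pairs(corpus, hits, clusters)
  loci <- filter_conserved(loci)
  filter_operon_length(loci, corpus, clusters)
}
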