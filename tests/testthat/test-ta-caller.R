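test_that("the 100 nt gap criterion is inclusive at the boundary", {
  set.seed(81)
  corp <- pair_corpus(gap = 100)
  inp <- caller_inputs(corp)
  cands <- call_candidate_pairs(corp, inp$hits, inp$clusters)
  expect_equal(nrow(cands), 2L)
  expect_equal(unique(cands$gap_nt), 100L)
  loci <- filter_conserved(cands)
  expect_true(all(loci$verdict == "pTA"))
  expect_true(all(loci$support_species == 2L))
})

test_that("a 101 nt gap or an opposite-strand neighbor yields no candidate", {
  set.seed(82)
  corp101 <- pair_corpus(gap = 101)
  inp <- caller_inputs(corp101)
  expect_equal(nrow(call_candidate_pairs(corp101, inp$hits, inp$clusters)), 0L)
  corp_anti <- pair_corpus(gap = 10, strands = c("+", "-"))
  inp2 <- caller_inputs(corp_anti)
  expect_equal(nrow(call_candidate_pairs(corp_anti, inp2$hits,
                                         inp2$clusters)), 0L)
  relaxed <- call_candidate_pairs(corp_anti, inp2$hits, inp2$clusters,
                                  require_same_strand = FALSE)
  expect_equal(nrow(relaxed), 2L)
  expect_true(all(is.na(relaxed$order)))
})

test_that("support counts species, not genomes", {
  set.seed(83)
  corp <- pair_corpus(gap = 40)
  # two genomes of one species only
  corp[[2]]$species <- corp[[1]]$species
  inp <- caller_inputs(corp)
  loci <- filter_conserved(call_candidate_pairs(corp, inp$hits, inp$clusters))
  expect_true(all(loci$support_species == 1L))
  expect_true(all(loci$verdict == "rejected_support"))
})

test_that("opposite gene orders are independent architectures", {
  set.seed(84)
  corp <- pair_corpus(gap = 40, n_species = 2,
                      order_by_species = c("antitoxin_first", "toxin_first"))
  inp <- caller_inputs(corp)
  loci <- filter_conserved(call_candidate_pairs(corp, inp$hits, inp$clusters))
  expect_equal(sort(loci$order), c("antitoxin_first", "toxin_first"))
  expect_true(all(loci$support_species == 1L))
  expect_true(all(loci$verdict == "rejected_support"))
  # same partner cluster with matching order in 2 species does pass
  corp2 <- pair_corpus(gap = 40, n_species = 2,
                       order_by_species = c("toxin_first", "toxin_first"))
  inp2 <- caller_inputs(corp2)
  loci2 <- filter_conserved(call_candidate_pairs(corp2, inp2$hits,
                                                 inp2$clusters))
  expect_true(all(loci2$verdict == "pTA"))
})




test_that("a conserved four-gene cassette is rejected as too long an operon", {
  set.seed(85)
  corp <- cassette_corpus(n_extra = 2, extra_conserved = TRUE)
  cl <- cassette_clusters(corp, 2, TRUE)
  loci <- run_caller(corp, cl)
  expect_true(all(loci$verdict == "rejected_operon_length"))
})

test_that("a non-conserved third neighbor leaves the pair without accessory", {
  set.seed(86)
  corp <- cassette_corpus(n_extra = 1, extra_conserved = FALSE)
  cl <- cassette_clusters(corp, 1, FALSE)
  loci <- run_caller(corp, cl)
  expect_true(all(loci$verdict == "pTA"))
  expect_true(all(is.na(loci$accessory_cluster)))
})

test_that("a conserved third gene is recorded as the accessory", {
  set.seed(87)
  corp <- cassette_corpus(n_extra = 1, extra_conserved = TRUE)
  cl <- cassette_clusters(corp, 1, TRUE)
  loci <- run_caller(corp, cl)
  expect_true(all(loci$verdict == "pTA"))
  expect_true(all(!is.na(loci$accessory_cluster)))
  expect_equal(unique(loci$accessory_protein), "x1")
  loci <- assign_toxin_cluster_ids(loci)
  acc <- detect_accessory(loci)
  expect_equal(nrow(acc), 1L)
  expect_equal(acc$n_species_with_accessory, 2L)
})

test_that("two distinct accessory clusters give one report row each", {
  set.seed(88)
  corp4 <- c(cassette_corpus(1, TRUE), cassette_corpus(1, TRUE))
  names(corp4) <- sprintf("g%02d", 1:4)
  for (i in 1:4) {
    corp4[[i]]$genome_id <- sprintf("g%02d", i)
    corp4[[i]]$species <- sprintf("sp%02d", i)
  }
  # species 3 and 4 share a different accessory family
  asn <- list(`1` = "tox", `2` = "bgA", `3` = "bgB")
  cl <- hand_clusters(corp4, asn)
  x1 <- do.call(rbind, lapply(corp4, function(g) {
    f <- g$features[g$features$protein_id == "x1", , drop = FALSE]
    data.frame(protein_id = "x1", genome_id = g$genome_id,
               species = g$species, stringsAsFactors = FALSE)
  }))
  x1$cluster_id <- ifelse(x1$genome_id %in% c("g01", "g02"), 4L, 5L)
  cl <- rbind(cl, x1[, c("cluster_id", "protein_id", "genome_id", "species")])
  loci <- assign_toxin_cluster_ids(run_caller(corp4, cl))
  acc <- detect_accessory(loci)
  expect_equal(nrow(acc), 2L)
  expect_equal(sort(acc$accessory_cluster), c(4L, 5L))
  expect_equal(acc$n_species_with_accessory, c(2L, 2L))
})

test_that("gene order classification respects strand orientation", {
  at <- function(s1, e1, s2, e2, strand) {
    a <- list(replicon_id = "c", start_nt = s1, end_nt = e1, strand = strand)
    p <- list(replicon_id = "c", start_nt = s2, end_nt = e2, strand = strand)
    classify_order(a, p)
  }
  expect_equal(at(100, 400, 450, 900, "+"), "antitoxin_first")
  expect_equal(at(450, 900, 100, 400, "-"), "antitoxin_first")
  expect_equal(at(450, 900, 100, 400, "+"), "toxin_first")
  expect_equal(at(100, 400, 450, 900, "-"), "toxin_first")
  expect_error(classify_order(
    list(replicon_id = "c", start_nt = 1, end_nt = 9, strand = "+"),
    list(replicon_id = "c", start_nt = 20, end_nt = 30, strand = "-")),
    "different strands")
})

test_that("T numbering is by size, tie-broken by example id, and stable", {
  mk <- function(cl, prot, sp) data.frame(
    genome_id = paste0("g_", sp), species = sp, replicon_id = "c",
    antitoxin_feature = paste0("fa_", prot), antitoxin_protein = paste0("a_", prot),
    partner_feature = paste0("fp_", prot), partner_protein = prot,
    partner_cluster = cl, gap_nt = 10L, strand = "+",
    order = "antitoxin_first", support_species = 2L,
    accessory_feature = NA_character_, accessory_protein = NA_character_,
    accessory_cluster = NA_integer_, verdict = "pTA", t_id = NA_character_,
    stringsAsFactors = FALSE)
  rows <- rbind(
    do.call(rbind, lapply(1:10, function(i) mk(7L, sprintf("ccc%02d", i), i))),
    do.call(rbind, lapply(1:7, function(i) mk(3L, sprintf("aaa%02d", i), i))),
    do.call(rbind, lapply(1:7, function(i) mk(5L, sprintf("bbb%02d", i), i))))
  out <- assign_toxin_cluster_ids(rows)
  t_map <- attr(out, "t_map")
  expect_equal(unname(t_map[c("7", "3", "5")]), c("T1", "T2", "T3"))
  shuffled <- rows[rev(seq_len(nrow(rows))), ]
  expect_equal(attr(assign_toxin_cluster_ids(shuffled), "t_map"), t_map)
})

test_that("caller output is invariant under replicon mirroring", {
  set.seed(89)
  corp <- cassette_corpus(n_extra = 1, extra_conserved = TRUE)
  cl <- cassette_clusters(corp, 1, TRUE)
  loci <- run_caller(corp, cl)
  mirrored <- lapply(corp, mirror_genome)
  loci_m <- run_caller(mirrored, cl)
  cols <- c("genome_id", "antitoxin_protein", "partner_protein",
            "partner_cluster", "gap_nt", "order", "support_species",
            "accessory_protein", "verdict")
  expect_equal(loci_m[order(loci_m$genome_id), cols],
               loci[order(loci$genome_id), cols])
})

test_that("every pTA locus satisfies all three criteria on a simulated corpus", {
  sim <- simulate_pangenome(sim_config(rng_seed = 90, n_species = 6,
                                       genomes_per_species = 1,
                                       genes_per_replicon = 20,
                                       decoy_adjacent = 0,
                                       decoy_background = 0))
  res <- ta_pipeline(sim$corpus, seed_alignment = sim$seed_alignment,
                     annotate = FALSE)
  pta <- res$loci[res$loci$verdict == "pTA", ]
  expect_gt(nrow(pta), 0L)
  expect_true(all(pta$gap_nt <= 100L))
  expect_true(all(pta$support_species >= 2L))
  ev <- ta_evaluate(res, sim$truth)
  expect_equal(ev$recall, 1.0)
})
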