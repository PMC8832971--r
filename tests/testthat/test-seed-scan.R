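test_that("profile scores follow the pseudocount closed form", {
  aln <- rep("ACDE", 3)
  prof <- build_profile(aln, pseudocount = 1)
  # three identical sequences, uniform background 1/20:
  # consensus column score = log2(((3 + 0.05) / 4) / 0.05)
  expected <- log2(((3 + 0.05) / 4) / 0.05)
  expect_equal(unname(prof$log_odds["A", 1]), expected, tolerance = 1e-12)
  expect_equal(unname(prof$log_odds["C", 2]), expected, tolerance = 1e-12)
  # absent residue score = log2(((0 + 0.05) / 4) / 0.05)
  expect_equal(unname(prof$log_odds["W", 1]), log2((0.05 / 4) / 0.05),
               tolerance = 1e-12)
  expect_equal(prof$consensus, "ACDE")
  cons_score <- sum(prof$log_odds[cbind(match(c("A", "C", "D", "E"), rownames(prof$log_odds)), 1:4)])
  expect_equal(prof$gathering_bits, 0.6 * cons_score)
})

test_that("observed residues score positive and unobserved negative", {
  prof <- build_profile(c("A", "A"))
  expect_gt(prof$log_odds["A", 1], 0)
  expect_lt(prof$log_odds["W", 1], 0)
})

test_that("gap-majority columns are discarded and degenerate alignments error", {
  aln <- c("A-C", "A-C", "AEC", "A-C", "ADC")   # column 2 is 60% gaps
  prof <- build_profile(aln)
  expect_equal(prof$length, 2L)
  expect_error(build_profile(c("AC", "ACD")), "ragged")
  expect_error(build_profile(c("--", "--", "A-")), "gap-majority")
})

test_that("scanning equals exhaustive window enumeration", {
  set.seed(61)
  for (t in 1:20) {
    W <- sample(8:25, 1)
    aln <- replicate(4, mut_aa(rand_aa(W), 0.1))
    prof <- build_profile(aln)
    seq <- rand_aa(sample((W + 1):120, 1))
    got <- scan_protein(seq, prof, threshold = -Inf)
    want <- oracle_scan(seq, prof)
    expect_equal(got$bits, want$bits, tolerance = 1e-9)
    # the chosen placement must itself be an optimal window under the oracle
    expect_equal(oracle_window_score(seq, prof, got$env_start), want$bits,
                 tolerance = 1e-9)
    expect_equal(got$env_end - got$env_start + 1L, prof$length)
  }
})

test_that("the consensus sequence scores the sum of column maxima over its own window", {
  set.seed(62)
  aln <- replicate(5, mut_aa(rand_aa(30), 0.05))
  prof <- build_profile(aln)
  embedded <- paste0(rand_aa(15), prof$consensus, rand_aa(20))
  hit <- scan_protein(embedded, prof)
  expect_false(is.null(hit))
  expect_equal(hit$bits, sum(apply(prof$log_odds, 2, max)), tolerance = 1e-9)
  expect_equal(hit$env_start, 16L)
  expect_equal(hit$env_end, 45L)
  # window equal to consensus alone: envelope covers the full protein
  solo <- scan_protein(prof$consensus, prof)
  expect_equal(c(solo$env_start, solo$env_end), c(1L, 30L))
})

test_that("background sequences rarely reach the gathering threshold", {
  set.seed(63)
  aln <- replicate(5, mut_aa(rand_aa(80), 0.05))
  prof <- build_profile(aln)
  hits <- sum(vapply(1:200, function(i)
    !is.null(scan_protein(rand_aa(400), prof)), logical(1)))
  expect_lte(hits, 10L)   # no hit in at least 95% of trials
})

test_that("sequences shorter than the profile never hit", {
  prof <- build_profile(replicate(3, rand_aa(50)))
  expect_null(scan_protein(rand_aa(49), prof))
  expect_null(scan_protein("", prof))
})

test_that("adding a constant per column shifts every window score linearly", {
  set.seed(64)
  prof <- build_profile(replicate(4, mut_aa(rand_aa(20), 0.1)))
  seq <- rand_aa(80)
  base <- scan_protein(seq, prof, threshold = -Inf)
  shifted <- prof
  shifted$log_odds <- prof$log_odds + 0.37
  got <- scan_protein(seq, shifted, threshold = -Inf)
  expect_equal(got$bits, base$bits + 0.37 * prof$length, tolerance = 1e-9)
  expect_equal(got$env_start, base$env_start)
})

test_that("no single-point mutant outscores the consensus", {
  set.seed(65)
  prof <- build_profile(replicate(5, mut_aa(rand_aa(25), 0.1)))
  cons <- prof$consensus
  cons_bits <- scan_protein(cons, prof, threshold = -Inf)$bits
  for (t in 1:50) {
    pos <- sample(nchar(cons), 1)
    ch <- strsplit(cons, "")[[1]]
    ch[pos] <- sample(setdiff(aa20, ch[pos]), 1)
    mut_bits <- scan_protein(paste(ch, collapse = ""), prof,
                             threshold = -Inf)$bits
    expect_lte(mut_bits, cons_bits + 1e-9)
  }
})

domtbl_row <- function(target, score, env_from, env_to) {
  tok <- c(target, "-", "200", "seedHMM", "-", "120", "1e-30", score, "0.1",
           "1", "1", "1e-30", "1e-30", score, "0.1", "1", "120",
           "5", "124", env_from, env_to, "0.95", "description here")
  paste(tok, collapse = " ")
}

test_that("domtblout parsing extracts scores and envelopes", {
  d <- withr::local_tempdir()
  p <- file.path(d, "hits.domtbl")
  writeLines(c("# comment line", domtbl_row("protA", "55.2", "4", "110"),
               domtbl_row("protB", "18.0", "10", "100"),
               domtbl_row("protC", "92.1", "1", "119"), "#"), p)
  hits <- parse_domain_table(p)
  expect_equal(hits$protein_id, c("protA", "protB", "protC"))
  expect_equal(hits$bits, c(55.2, 18.0, 92.1))
  expect_equal(hits$env_start, c(4L, 10L, 1L))
  expect_equal(hits$env_end, c(110L, 100L, 119L))
  filt <- parse_domain_table(p, min_bits = 50)
  expect_equal(filt$protein_id, c("protA", "protC"))
  mapped <- parse_domain_table(p, genome_map = c(protA = "g1", protB = "g2",
                                                 protC = "g1"))
  expect_equal(mapped$genome_id, c("g1", "g2", "g1"))
})

test_that("domtblout comment-only files and malformed rows are handled", {
  d <- withr::local_tempdir()
  p1 <- file.path(d, "empty.domtbl")
  writeLines(c("# only", "# comments"), p1)
  expect_equal(nrow(parse_domain_table(p1)), 0L)
  p2 <- file.path(d, "bad.domtbl")
  writeLines(c(domtbl_row("ok", "10", "1", "50"), "too short row"), p2)
  expect_error(parse_domain_table(p2), "line 2")
  p3 <- file.path(d, "nonnum.domtbl")
  writeLines(domtbl_row("prot", "notanumber", "1", "50"), p3)
  expect_error(parse_domain_table(p3), "line 1")
})
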