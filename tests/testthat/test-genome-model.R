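gff3_fixture <- function(dir) {
  gff <- file.path(dir, "g1.gff3")
  faa <- file.path(dir, "g1.faa")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chr1 1 5000",
    "chr1\ttest\tCDS\t201\t500\t.\t+\t0\tID=p1;protein_id=p1;product=alpha toxin",
    "chr1\ttest\tCDS\t701\t1000\t.\t-\t0\tID=p2;protein_id=p2;product=beta",
    "chr1\ttest\tCDS\t1200\t1400\t.\t+\t0\tID=p3;protein_id=p3;product=gamma"),
    gff)
  writeLines(c(">p1", strrep("MKVA", 25), ">p2", strrep("LSTG", 25),
               ">p3", strrep("WYHD", 16)), faa)
  list(gff = gff, faa = faa)
}

test_that("GFF3 + FASTA loads features with ranks and metadata", {
  d <- withr::local_tempdir()
  fx <- gff3_fixture(d)
  g <- read_genome(fx$gff, fx$faa, genome_id = "g1", species = "sp1")
  expect_s3_class(g, "ta_genome")
  expect_equal(nrow(g$features), 3L)
  expect_equal(g$features$rank, 0:2)
  expect_equal(g$features$protein_id, c("p1", "p2", "p3"))
  expect_equal(g$features$product[1], "alpha toxin")
  expect_equal(g$features$aa_seq[2], strrep("LSTG", 25))
  expect_equal(g$replicons$length_nt, 5000L)
  expect_equal(g$load_report$dropped_no_translation, 0L)
})

test_that("GenBank flat file loads identically to the GFF3 encoding", {
  d <- withr::local_tempdir()
  fx <- gff3_fixture(d)
  gb <- file.path(d, "g1.gbk")
  writeLines(c(
    "LOCUS       chr1                5000 bp    DNA     linear   BCT 01-JAN-2000",
    "DEFINITION  synthetic fixture.",
    "FEATURES             Location/Qualifiers",
    "     source          1..5000",
    "     CDS             201..500",
    "                     /protein_id=\"p1\"",
    "                     /product=\"alpha toxin\"",
    paste0("                     /translation=\"", strrep("MKVA", 25), "\""),
    "     CDS             complement(701..1000)",
    "                     /protein_id=\"p2\"",
    "                     /product=\"beta\"",
    paste0("                     /translation=\"", strrep("LSTG", 25), "\""),
    "     CDS             1200..1400",
    "                     /protein_id=\"p3\"",
    "                     /product=\"gamma\"",
    paste0("                     /translation=\"", strrep("WYHD", 16), "\""),
    "ORIGIN",
    "//"), gb)
  g_gff <- read_genome(fx$gff, fx$faa, genome_id = "g1", species = "sp1")
  g_gb <- read_genome(gb, genome_id = "g1", species = "sp1")
  cols <- c("feature_id", "replicon_id", "start_nt", "end_nt", "strand",
            "protein_id", "product", "aa_seq", "rank")
  expect_equal(g_gb$features[, cols], g_gff$features[, cols])
  expect_equal(g_gb$replicons$length_nt, g_gff$replicons$length_nt)
})

test_that("features without a translation are dropped and counted", {
  d <- withr::local_tempdir()
  fx <- gff3_fixture(d)
  faa2 <- file.path(d, "partial.faa")
  writeLines(c(">p1", strrep("MKVA", 25), ">p3", strrep("WYHD", 16)), faa2)
  g <- read_genome(fx$gff, faa2, genome_id = "g1", species = "sp1")
  expect_equal(nrow(g$features), 2L)
  expect_equal(g$load_report$dropped_no_translation, 1L)
  expect_equal(g$features$rank, 0:1)   # ranks reassigned after the drop
})

test_that("duplicate protein ids in the FASTA are an error naming them", {
  d <- withr::local_tempdir()
  fx <- gff3_fixture(d)
  dup <- file.path(d, "dup.faa")
  writeLines(c(">p1", "MKV", ">p1", "MKW", ">p2", "LST", ">p3", "WYH"), dup)
  expect_error(read_genome(fx$gff, dup, genome_id = "g1"), "p1")
})

test_that("write_genome/read_genome round trip preserves all feature fields", {
  set.seed(11)
  g <- lay_genome("gx", "spx", data.frame(
    protein_id = c("a", "b", "c"), len_aa = c(60, 45, 80),
    gap_before = c(NA, 120, 40), strand = c("+", "-", "+"),
    product = c("alpha; beta=tricky", "plain", "third one"),
    stringsAsFactors = FALSE))
  d <- withr::local_tempdir()
  write_genome(g, file.path(d, "gx.gff3"), file.path(d, "gx.faa"))
  g2 <- read_genome(file.path(d, "gx.gff3"), file.path(d, "gx.faa"),
                    genome_id = "gx", species = "spx",
                    replicons = g$replicons)
  expect_equal(g2$features, g$features)
  expect_equal(g2$replicons, g$replicons)
})

test_that("intergenic distance follows the clamped definition and is symmetric", {
  f <- function(s1, e1, s2, e2) {
    a <- list(replicon_id = "c", start_nt = s1, end_nt = e1)
    b <- list(replicon_id = "c", start_nt = s2, end_nt = e2)
    c(intergenic_distance(a, b), intergenic_distance(b, a))
  }
  expect_equal(f(50, 100, 131, 200), c(30L, 30L))
  expect_equal(f(50, 100, 101, 200), c(0L, 0L))
  expect_equal(f(1, 200, 150, 400), c(0L, 0L))    # overlap clamps to zero
  set.seed(21)
  for (i in 1:40) {
    s1 <- sample(1:500, 1); e1 <- s1 + sample(0:300, 1)
    s2 <- sample(1:500, 1); e2 <- s2 + sample(0:300, 1)
    d <- f(s1, e1, s2, e2)
    expect_true(d[1] >= 0)
    expect_identical(d[1], d[2])
  }
  expect_error(intergenic_distance(
    list(replicon_id = "c1", start_nt = 1, end_nt = 10),
    list(replicon_id = "c2", start_nt = 20, end_nt = 30)),
    "different replicons")
})

test_that("neighborhoods truncate at replicon ends and never wrap", {
  set.seed(31)
  g <- lay_genome("gn", "spn", data.frame(
    protein_id = sprintf("p%d", 1:7), len_aa = 50,
    gap_before = c(NA, rep(200, 6)), strand = "+",
    stringsAsFactors = FALSE))
  nb <- neighborhood(g, g$features[1, ], k = 4)
  expect_equal(nrow(nb$upstream), 0L)
  expect_equal(nb$downstream$protein_id, sprintf("p%d", 2:5))
  nb2 <- neighborhood(g, g$features[4, ], k = 2)
  expect_equal(nb2$upstream$protein_id, c("p3", "p2"))  # nearest first
  expect_equal(nb2$downstream$protein_id, c("p5", "p6"))
  g3 <- lay_genome("g3", "sp3", data.frame(
    protein_id = c("x", "y", "z"), len_aa = 40,
    gap_before = c(NA, 200, 200), strand = "+", stringsAsFactors = FALSE))
  nb3 <- neighborhood(g3, g3$features[2, ], k = 1)
  expect_equal(nrow(nb3$upstream), 1L)
  expect_equal(nrow(nb3$downstream), 1L)
})

test_that("ranks and neighborhoods are invariant to feature input order", {
  set.seed(41)
  feats <- lay_genome("go", "spo", data.frame(
    protein_id = sprintf("p%d", 1:6), len_aa = 50,
    gap_before = c(NA, rep(150, 5)), strand = "+",
    stringsAsFactors = FALSE))$features
  shuffled <- feats[sample(nrow(feats)), setdiff(names(feats), "rank")]
  g1 <- ta_genome("go", "spo", feats[, setdiff(names(feats), "rank")])
  g2 <- ta_genome("go", "spo", shuffled)
  expect_equal(g1$features, g2$features)
  nb1 <- neighborhood(g1, "go_p3", k = 2)
  nb2 <- neighborhood(g2, "go_p3", k = 2)
  expect_equal(nb1$upstream$protein_id, nb2$upstream$protein_id)
  expect_equal(nb1$downstream$protein_id, nb2$downstream$protein_id)
})

test_that("mirroring a genome twice is the identity", {
  set.seed(51)
  g <- lay_genome("gm", "spm", data.frame(
    protein_id = sprintf("p%d", 1:4), len_aa = c(40, 60, 30, 50),
    gap_before = c(NA, 120, 80, 300), strand = c("+", "-", "+", "+"),
    stringsAsFactors = FALSE))
  gm <- mirror_genome(mirror_genome(g))
  expect_equal(gm$features, g$features)
})
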