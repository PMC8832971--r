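# Shared fixtures and independent oracles used across the suite.

aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_aa <- function(n) paste(sample(aa20, n, replace = TRUE), collapse = "")

mut_aa <- function(seq, p) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < p)
  if (length(hit)) {
    cur <- match(ch[hit], aa20)
    ch[hit] <- aa20[((cur - 1L + sample.int(19L, length(hit), TRUE)) %% 20L) + 1L]
  }
  paste(ch, collapse = "")
}

blosum62_test <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Independent R-level Gotoh DP oracle for global affine-gap alignment.
# Same scoring convention as the implementation (gap run of L costs
# open + L * ext) but written separately in plain R.
oracle_align <- function(a, b, open = 11, ext = 1) {
  B <- blosum62_test
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca)
  m <- length(cb)
  NEG <- -1e18
  M <- X <- Y <- matrix(NEG, n + 1L, m + 1L)
  tM <- tX <- tY <- matrix(0L, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  for (i in seq_len(n) + 1L) {
    X[i, 1L] <- -(open + ext * (i - 1L))
    tX[i, 1L] <- if (i == 2L) 0L else 1L
  }
  for (j in seq_len(m) + 1L) {
    Y[1L, j] <- -(open + ext * (j - 1L))
    tY[1L, j] <- if (j == 2L) 0L else 2L
  }
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      s <- B[ca[i - 1L], cb[j - 1L]]
      v <- c(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      k <- which.max(v); M[i, j] <- v[k] + s; tM[i, j] <- k - 1L
      v <- c(M[i - 1L, j] - (open + ext), X[i - 1L, j] - ext,
             Y[i - 1L, j] - (open + ext))
      k <- which.max(v); X[i, j] <- v[k]; tX[i, j] <- k - 1L
      v <- c(M[i, j - 1L] - (open + ext), X[i, j - 1L] - (open + ext),
             Y[i, j - 1L] - ext)
      k <- which.max(v); Y[i, j] <- v[k]; tY[i, j] <- k - 1L
    }
  }
  v <- c(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  st <- which.max(v) - 1L
  sc <- v[st + 1L]
  i <- n; j <- m; A <- character(); Bc <- character()
  while (i > 0L || j > 0L) {
    if (st == 0L) {
      tb <- tM[i + 1L, j + 1L]; A <- c(ca[i], A); Bc <- c(cb[j], Bc)
      i <- i - 1L; j <- j - 1L; st <- tb
    } else if (st == 1L) {
      tb <- tX[i + 1L, j + 1L]; A <- c(ca[i], A); Bc <- c("-", Bc)
      i <- i - 1L; st <- tb
    } else {
      tb <- tY[i + 1L, j + 1L]; A <- c("-", A); Bc <- c(cb[j], Bc)
      j <- j - 1L; st <- tb
    }
  }
  nong <- A != "-" & Bc != "-"
  first <- which(nong)[1L]
  last <- rev(which(nong))[1L]
  cols <- last - first + 1L
  matches <- sum(A[first:last] == Bc[first:last] & A[first:last] != "-")
  list(score = sc, identity = matches / cols,
       coverage = sum(nong) / min(n, m))
}

# Exhaustive enumeration of every global alignment (tiny sequences only):
# optimal score plus the set of identities achieved by optimal alignments.
oracle_enum <- function(a, b, open = 11, ext = 1) {
  B <- blosum62_test
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca)
  m <- length(cb)
  env <- new.env()
  env$best <- -Inf
  env$ids <- numeric()
  rec <- function(i, j, sc, prev, A, Bc) {
    if (i > n && j > m) {
      if (sc > env$best + 1e-9) { env$best <- sc; env$ids <- numeric() }
      if (abs(sc - env$best) <= 1e-9) {
        nong <- A != "-" & Bc != "-"
        f <- which(nong)[1L]
        l <- rev(which(nong))[1L]
        id <- sum(A[f:l] == Bc[f:l] & A[f:l] != "-") / (l - f + 1L)
        env$ids <- unique(c(env$ids, id))
      }
      return(invisible())
    }
    if (i <= n && j <= m)
      rec(i + 1L, j + 1L, sc + B[ca[i], cb[j]], "M", c(A, ca[i]), c(Bc, cb[j]))
    if (i <= n)
      rec(i + 1L, j, sc - (if (prev == "X") ext else open + ext), "X",
          c(A, ca[i]), c(Bc, "-"))
    if (j <= m)
      rec(i, j + 1L, sc - (if (prev == "Y") ext else open + ext), "Y",
          c(A, "-"), c(Bc, cb[j]))
  }
  rec(1L, 1L, 0, "S", character(), character())
  list(score = env$best, identities = env$ids)
}

# Brute-force window scan oracle: score every placement explicitly.
oracle_scan <- function(seq, profile) {
  ch <- strsplit(seq, "")[[1]]
  W <- profile$length
  L <- length(ch)
  if (L < W) return(NULL)
  S <- profile$log_odds
  best <- -Inf
  best_i <- NA_integer_
  for (s in seq_len(L - W + 1L)) {
    sc <- 0
    for (j in seq_len(W)) {
      aa <- ch[s + j - 1L]
      if (aa %in% rownames(S)) sc <- sc + unname(S[aa, j])
    }
    if (sc > best) { best <- sc; best_i <- s }
  }
  list(bits = best, env_start = best_i, env_end = best_i + W - 1L)
}

# score of one explicit window placement (for tie-aware comparisons: near-tied
# windows can differ in argmax by floating summation order)
oracle_window_score <- function(seq, profile, s) {
  ch <- strsplit(seq, "")[[1]]
  S <- profile$log_odds
  sc <- 0
  for (j in seq_len(profile$length)) {
    aa <- ch[s + j - 1L]
    if (aa %in% rownames(S)) sc <- sc + unname(S[aa, j])
  }
  sc
}

# Build a genome from an ordered gene layout. `genes` columns: protein_id,
# len_aa (or aa_seq), gap_before (nt to the previous gene; first row
# ignored), strand, optional product.
lay_genome <- function(genome_id, species, genes, replicon_id = "c1",
                       kind = "chromosome", is_complete = TRUE) {
  pos <- 201L
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    aa <- if ("aa_seq" %in% names(genes) && !is.na(genes$aa_seq[i]))
      genes$aa_seq[i] else rand_aa(genes$len_aa[i])
    if (i > 1L) pos <- rows[[i - 1L]]$end_nt + genes$gap_before[i] + 1L
    rows[[i]] <- data.frame(
      feature_id = paste0(genome_id, "_", genes$protein_id[i]),
      replicon_id = replicon_id, start_nt = pos,
      end_nt = pos + 3L * nchar(aa) - 1L, strand = genes$strand[i],
      protein_id = genes$protein_id[i],
      product = if ("product" %in% names(genes)) genes$product[i] else
        "hypothetical protein",
      aa_seq = aa, stringsAsFactors = FALSE)
  }
  feats <- do.call(rbind, rows)
  repl <- data.frame(replicon_id = replicon_id, kind = kind,
                     length_nt = max(feats$end_nt) + 200L,
                     stringsAsFactors = FALSE)
  ta_genome(genome_id, species, feats, repl, is_complete = is_complete)
}

# Seed-hit rows for hand-built corpora (full-length envelope).
hand_hits <- function(corpus, protein_ids) {
  do.call(rbind, lapply(names(corpus), function(g) {
    f <- corpus[[g]]$features
    f <- f[f$protein_id %in% protein_ids, , drop = FALSE]
    if (!nrow(f)) return(NULL)
    data.frame(protein_id = f$protein_id, genome_id = g, bits = 100,
               env_start = 1L, env_end = nchar(f$aa_seq),
               stringsAsFactors = FALSE)
  }))
}

# Hand-assigned cluster table: named list cluster_id -> protein ids.
hand_clusters <- function(corpus, assignment) {
  ft <- do.call(rbind, lapply(corpus, function(g)
    data.frame(protein_id = g$features$protein_id, genome_id = g$genome_id,
               species = g$species, stringsAsFactors = FALSE)))
  rows <- lapply(names(assignment), function(cl) {
    d <- ft[ft$protein_id %in% assignment[[cl]], , drop = FALSE]
    d$cluster_id <- as.integer(cl)
    d
  })
  out <- do.call(rbind, rows)
  out[, c("cluster_id", "protein_id", "genome_id", "species")]
}
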