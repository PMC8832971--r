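#' Build a position-specific scoring profile from an alignment
#'
#' Constructs an ungapped log-odds profile (bits) from a gapped amino-acid
#' alignment, the internal stand-in for a full profile HMM. Columns with more
#' than 50% gap occupancy are discarded. The per-column score of amino acid
#' `a` is
#' `log2( (count(a) + pseudocount * background(a)) / (n_eff + pseudocount) / background(a) )`
#' where `n_eff` is the number of non-gap residues observed in the column.
#' The acceptance threshold (`gathering_bits`, by analogy with Pfam gathering
#' cutoffs) defaults to `gathering_frac` times the score of the profile's own
#' consensus sequence.
#'
#' @param alignment Character vector or `AAStringSet` of equal-length gapped
#'   sequences (gap characters `-` or `.`); at least 2 sequences.
#' @param pseudocount Dirichlet-style pseudocount mass (default 1).
#' @param background Named length-20 vector of amino-acid frequencies summing
#'   to 1; uniform 1/20 when `NULL`.
#' @param name Profile name.
#' @param gathering_frac Fraction of the consensus score used as the default
#'   gathering threshold (default 0.6).
#' @return An object of class `ta_profile` with elements `name`, `length`,
#'   `log_odds` (20 x length matrix, rows named by amino acid), `background`,
#'   `gathering_bits` and `consensus`.
#' @export
build_profile <- function(alignment, pseudocount = 1, background = NULL,
                          name = "profile", gathering_frac = 0.6) {
  if (inherits(alignment, "XStringSet")) alignment <- as.character(alignment)
  alignment <- toupper(unname(alignment))
  if (length(alignment) < 2L)
    stop("need at least 2 aligned sequences")
  w <- unique(nchar(alignment))
  if (length(w) != 1L)
    stop("ragged alignment: sequence lengths ", paste(w, collapse = ", "))
  if (is.null(background)) background <- setNames(rep(1 / 20, 20), AA20)
  background <- background[AA20]
  if (anyNA(background) || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9)
    stop("background must be strictly positive over the 20 amino acids and sum to 1")
  m <- do.call(rbind, strsplit(alignment, ""))
  is_gap <- m == "-" | m == "."
  gap_frac <- colMeans(is_gap)
  keep <- gap_frac <= 0.5
  if (!any(keep)) stop("all alignment columns are gap-majority")
  m <- m[, keep, drop = FALSE]
  is_gap <- is_gap[, keep, drop = FALSE]
  L <- ncol(m)
  log_odds <- matrix(NA_real_, nrow = 20L, ncol = L, dimnames = list(AA20, NULL))
  for (j in seq_len(L)) {
    col <- m[!is_gap[, j], j]
    col <- col[col %in% AA20]            # X and other ambiguity codes ignored
    n_eff <- length(col)
    counts <- tabulate(match(col, AA20), nbins = 20L)
    log_odds[, j] <- log2((counts + pseudocount * background) /
                          (n_eff + pseudocount) / background)
  }
  cons_idx <- apply(log_odds, 2L, which.max)   # ties: alphabetically first
  consensus <- paste(AA20[cons_idx], collapse = "")
  cons_score <- sum(log_odds[cbind(cons_idx, seq_len(L))])
  structure(list(name = name, length = L, log_odds = log_odds,
                 background = background,
                 gathering_bits = gathering_frac * cons_score,
                 consensus = consensus),
            class = "ta_profile")
}

#' @export
print.ta_profile <- function(x, ...) {
  cat(sprintf("<ta_profile> %s: %d columns, gathering threshold %.2f bits\n",
              x$name, x$length, x$gathering_bits))
  invisible(x)
}

#' Scan a protein with a scoring profile
#'
#' Slides the full (ungapped) profile along the protein and reports the
#' best-scoring placement, returned only if its bit score reaches the
#' threshold. One hit per protein: the scan counts seed-domain proteins, not
#' domains per protein. Proteins shorter than the profile yield no hit.
#'
#' @param seq Amino-acid string.
#' @param profile A [build_profile()] object.
#' @param threshold Bit-score threshold; `NULL` uses the profile's
#'   `gathering_bits`.
#' @return `NULL`, or a list with `bits`, `env_start`, `env_end` (1-based
#'   inclusive window on the protein).
#' @export
scan_protein <- function(seq, profile, threshold = NULL) {
  if (is.null(threshold)) threshold <- profile$gathering_bits
  L <- nchar(seq)
  W <- profile$length
  if (L < W) return(NULL)
  idx <- match(strsplit(toupper(seq), "")[[1L]], AA20)
  S <- profile$log_odds
  # A[i, j] = score of residue i at profile column j; residues outside the
  # 20-letter alphabet (e.g. X) contribute 0 bits
  A <- matrix(0, nrow = L, ncol = W)
  ok <- !is.na(idx)
  if (any(ok)) A[ok, ] <- S[idx[ok], , drop = FALSE]
  nwin <- L - W + 1L
  D <- vapply(seq_len(W), function(j) A[j:(j + nwin - 1L), j], numeric(nwin))
  if (nwin == 1L) D <- matrix(D, nrow = 1L)
  scores <- rowSums(D)
  best <- which.max(scores)
  if (scores[best] < threshold) return(NULL)
  list(bits = scores[best], env_start = as.integer(best),
       env_end = as.integer(best + W - 1L))
}

#' Scan every protein of a corpus for the seed domain
#'
#' @param corpus Named list of [ta_genome] objects.
#' @param profile A [build_profile()] profile.
#' @param threshold Optional override of the gathering threshold.
#' @return `data.frame` of seed hits: `protein_id`, `genome_id`, `bits`,
#'   `env_start`, `env_end`.
#' @export
scan_corpus <- function(corpus, profile, threshold = NULL) {
  ft <- corpus_feature_table(corpus)
  rows <- vector("list", if (is.null(ft)) 0L else nrow(ft))
  if (!is.null(ft)) {
    for (i in seq_len(nrow(ft))) {
      h <- scan_protein(ft$aa_seq[i], profile, threshold)
      if (!is.null(h))
        rows[[i]] <- data.frame(protein_id = ft$protein_id[i],
                                genome_id = ft$genome_id[i], bits = h$bits,
                                env_start = h$env_start, env_end = h$env_end,
                                stringsAsFactors = FALSE)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(protein_id = character(), genome_id = character(),
                      bits = numeric(), env_start = integer(),
                      env_end = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$genome_id, out$protein_id), , drop = FALSE]
}

#' Parse an HMMER3 per-domain table (domtblout)
#'
#' Injection path for real profile-HMM scans: reads the whitespace-delimited
#' HMMER3 `--domtblout` dialect (target name in column 1, full-sequence bit
#' score in column 8, envelope from/to in columns 20-21). `#` comment lines
#' are ignored. Rows below `min_bits` are dropped.
#'
#' @param path Path to the tabular file.
#' @param min_bits Bit-score threshold applied to column 8 (default 0).
#' @param genome_map Optional named character vector mapping protein id to
#'   genome id; unmapped proteins get `NA`.
#' @return `data.frame` of seed hits (same shape as [scan_corpus()]).
#' @export
parse_domain_table <- function(path, min_bits = 0, genome_map = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  out <- lapply(rows, function(i) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(tok) < 21L)
      stop("parse error at line ", i, ": expected >= 21 whitespace-delimited ",
           "columns, found ", length(tok))
    bits <- suppressWarnings(as.numeric(tok[8L]))
    env_start <- suppressWarnings(as.integer(tok[20L]))
    env_end <- suppressWarnings(as.integer(tok[21L]))
    if (is.na(bits) || is.na(env_start) || is.na(env_end))
      stop("parse error at line ", i, ": non-numeric score or envelope")
    data.frame(protein_id = tok[1L], genome_id = NA_character_, bits = bits,
               env_start = env_start, env_end = env_end,
               stringsAsFactors = FALSE)
  })
  hits <- if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE)))
          else data.frame(protein_id = character(), genome_id = character(),
                          bits = numeric(), env_start = integer(),
                          env_end = integer(), stringsAsFactors = FALSE)
  hits <- hits[hits$bits >= min_bits, , drop = FALSE]
  if (!is.null(genome_map) && nrow(hits))
    hits$genome_id <- unname(genome_map[hits$protein_id])
  rownames(hits) <- NULL
  hits
}
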