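#' Extract N-terminal extensions preceding the seed-domain envelope
#'
#' Antitoxins often carry extra N-terminal regions in front of the seed
#' domain (DNA-binding HTH domains, or novel conserved domains). The
#' extension of a protein is everything before the seed-hit envelope start;
#' it is recorded only when at least `min_len` residues long, the default 40
#' being short enough to retain a typical 50-60 aa helix-turn-helix.
#'
#' @param seed_hits Seed-hit table with `env_start`.
#' @param proteins Named character vector of protein sequences keyed by
#'   `protein_id` (or a `data.frame` with `protein_id`, `aa_seq`).
#' @param min_len Minimum extension length in residues (default 40).
#' @return `data.frame`: `protein_id`, `genome_id`, `ext_seq`, `ext_len`.
#' @export
extract_nterm_extensions <- function(seed_hits, proteins, min_len = 40L) {
  if (is.data.frame(proteins))
    proteins <- setNames(proteins$aa_seq, proteins$protein_id)
  out <- data.frame(protein_id = character(), genome_id = character(),
                    ext_seq = character(), ext_len = integer(),
                    stringsAsFactors = FALSE)
  if (!nrow(seed_hits)) return(out)
  seqs <- unname(proteins[seed_hits$protein_id])
  if (anyNA(seqs)) stop("seed-hit proteins missing from sequence set")
  if (any(seed_hits$env_end > nchar(seqs)))
    stop("seed-hit envelope exceeds protein length")
  ext_len <- seed_hits$env_start - 1L
  keep <- ext_len >= min_len
  if (!any(keep)) return(out)
  data.frame(protein_id = seed_hits$protein_id[keep],
             genome_id = seed_hits$genome_id[keep],
             ext_seq = substr(seqs[keep], 1L, ext_len[keep]),
             ext_len = as.integer(ext_len[keep]), stringsAsFactors = FALSE)
}

#' Two-pass HTH detection with profile re-modelling
#'
#' Pass 1 scans every extension with an initial helix-turn-helix profile
#' (built from any HTH seed alignment; the procedure is model-agnostic).
#' Pass 2 collects the pass-1 hit regions, rebuilds a sharper profile from
#' them with [build_profile()], and rescans all extensions, which can recover
#' borderline family members the generic initial model misses. With zero
#' pass-1 hits the initial profile is returned unchanged and all flags are
#' `FALSE`.
#'
#' @param extensions Extension table from [extract_nterm_extensions()].
#' @param initial_profile Initial HTH [build_profile()] profile.
#' @param pseudocount,background,gathering_frac Passed to the pass-2
#'   [build_profile()] rebuild.
#' @return List with `profile` (the updated profile), `flags` (named logical
#'   per extension protein, pass-2 verdicts) and `pass1_flags`.
#' @export
remodel_and_detect_hth <- function(extensions, initial_profile,
                                   pseudocount = 1, background = NULL,
                                   gathering_frac = 0.6) {
  n <- nrow(extensions)
  flags0 <- setNames(logical(n), extensions$protein_id)
  if (!n) return(list(profile = initial_profile, flags = flags0,
                      pass1_flags = flags0))
  pass1 <- lapply(extensions$ext_seq, scan_protein, profile = initial_profile)
  hit1 <- !vapply(pass1, is.null, logical(1))
  pass1_flags <- setNames(hit1, extensions$protein_id)
  if (!any(hit1))
    return(list(profile = initial_profile, flags = flags0,
                pass1_flags = pass1_flags))
  regions <- mapply(function(seq, h) substr(seq, h$env_start, h$env_end),
                    extensions$ext_seq[hit1], pass1[hit1])
  if (sum(hit1) < 2L) {
    # cannot rebuild a profile from a single region; keep the initial model
    return(list(profile = initial_profile, flags = pass1_flags,
                pass1_flags = pass1_flags))
  }
  updated <- build_profile(unname(regions), pseudocount = pseudocount,
                           background = background, name = "hth_updated",
                           gathering_frac = gathering_frac)
  pass2 <- lapply(extensions$ext_seq, scan_protein, profile = updated)
  flags <- setNames(!vapply(pass2, is.null, logical(1)),
                    extensions$protein_id)
  list(profile = updated, flags = flags, pass1_flags = pass1_flags)
}

#' Discover novel conserved N-terminal extension families
#'
#' Clusters the extensions that carry no known-domain (HTH) hit with the
#' flank-clustering machinery and reports families supported by at least
#' `min_members` proteins spanning at least `min_species` species - the
#' procedure that surfaces novel widely conserved domains such as PAD1.
#'
#' @param extensions Extension table (HTH-flagged rows already excluded).
#' @param species Named character vector mapping `genome_id` to species.
#' @param min_members Minimum family size (default 5).
#' @param min_species Minimum distinct species (default 2).
#' @param min_identity,min_coverage Clustering thresholds.
#' @return List with `clusters` (full cluster table over the extensions) and
#'   `reported` (one row per qualifying family: `cluster_id`, `n_members`,
#'   `n_species`, `example_protein_id`).
#' @export
discover_conserved_extensions <- function(extensions, species,
                                          min_members = 5L, min_species = 2L,
                                          min_identity = 0.3,
                                          min_coverage = 0.6) {
  empty <- data.frame(cluster_id = integer(), n_members = integer(),
                      n_species = integer(), example_protein_id = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(extensions)) return(list(clusters = NULL, reported = empty))
  prot <- data.frame(protein_id = extensions$protein_id,
                     genome_id = extensions$genome_id,
                     species = unname(species[extensions$genome_id]),
                     aa_seq = extensions$ext_seq, stringsAsFactors = FALSE)
  cl <- cluster_flanks(prot, min_identity = min_identity,
                       min_coverage = min_coverage)
  sp <- split(cl, cl$cluster_id)
  rep_rows <- lapply(sp, function(d) data.frame(
    cluster_id = d$cluster_id[1L], n_members = nrow(d),
    n_species = length(unique(d$species)),
    example_protein_id = min(d$protein_id), stringsAsFactors = FALSE))
  rep_df <- do.call(rbind, rep_rows)
  rep_df <- rep_df[rep_df$n_members >= min_members &
                   rep_df$n_species >= min_species, , drop = FALSE]
  rownames(rep_df) <- NULL
  list(clusters = cl, reported = if (nrow(rep_df)) rep_df else empty)
}

# Kyte-Doolittle hydropathy scale
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

#' Predict transmembrane segments by sliding-window hydropathy
#'
#' Kyte-Doolittle hydropathy stand-in for dedicated TM topology predictors:
#' every window of `window` residues whose mean hydropathy reaches
#' `threshold` is kept, and overlapping qualifying windows are merged into
#' segments (window 19, threshold 1.6 are the standard settings for membrane-
#' spanning helices). External TM predictions can be injected instead as a
#' table of (protein_id, start, end).
#'
#' @param seq Amino-acid string.
#' @param window Window length in residues (default 19).
#' @param threshold Mean-hydropathy threshold (default 1.6).
#' @return `data.frame` with `start_aa`, `end_aa` (1-based inclusive, merged
#'   bounds) and `mean_hydropathy` over the merged segment. Sequences shorter
#'   than the window give zero rows.
#' @export
predict_tm_segments <- function(seq, window = 19L, threshold = 1.6) {
  empty <- data.frame(start_aa = integer(), end_aa = integer(),
                      mean_hydropathy = numeric(), stringsAsFactors = FALSE)
  L <- nchar(seq)
  if (L < window) return(empty)
  h <- KD_SCALE[strsplit(toupper(seq), "")[[1L]]]
  h[is.na(h)] <- 0     # unknown residues are hydropathy-neutral
  cs <- c(0, cumsum(h))
  means <- (cs[(window + 1L):(L + 1L)] - cs[seq_len(L - window + 1L)]) / window
  starts <- which(means >= threshold)
  if (!length(starts)) return(empty)
  ends <- starts + window - 1L
  # merge overlapping windows
  seg_start <- starts[1L]; seg_end <- ends[1L]
  segs <- list()
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= seg_end) {
      seg_end <- ends[i]
    } else {
      segs[[length(segs) + 1L]] <- c(seg_start, seg_end)
      seg_start <- starts[i]; seg_end <- ends[i]
    }
  }
  segs[[length(segs) + 1L]] <- c(seg_start, seg_end)
  out <- do.call(rbind, lapply(segs, function(s) data.frame(
    start_aa = s[1L], end_aa = s[2L],
    mean_hydropathy = mean(h[s[1L]:s[2L]]), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Per-column conservation profile of an alignment
#'
#' Normalized Shannon-entropy score per alignment column:
#' `1 - H / log2(20)` with `H` the entropy (bits) of the non-gap residues, so
#' an invariant column scores 1 and a column uniform over all 20 residues
#' scores 0. Columns with non-gap occupancy below 0.5 score 0. This replaces
#' phylogeny-aware conservation scoring; it is sufficient to rank invariant
#' motif columns (e.g. a GPV-type signature) at the top.
#'
#' @param alignment Character vector or `AAStringSet` of equal-length gapped
#'   sequences (>= 2).
#' @return `data.frame` with `column`, `score` in `[0, 1]` and `occupancy`.
#' @export
conservation_profile <- function(alignment) {
  if (inherits(alignment, "XStringSet")) alignment <- as.character(alignment)
  alignment <- toupper(unname(alignment))
  if (length(alignment) < 2L) stop("need at least 2 sequences")
  if (length(unique(nchar(alignment))) != 1L)
    stop("ragged alignment")
  m <- do.call(rbind, strsplit(alignment, ""))
  L <- ncol(m)
  score <- numeric(L)
  occ <- numeric(L)
  for (j in seq_len(L)) {
    col <- m[, j]
    res <- col[col != "-" & col != "."]
    occ[j] <- length(res) / length(col)
    if (occ[j] < 0.5) { score[j] <- 0; next }
    p <- table(res) / length(res)
    H <- -sum(p * log2(p))
    score[j] <- 1 - H / log2(20)
  }
  data.frame(column = seq_len(L), score = score, occupancy = occ)
}
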