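#' Annotated-genome data model
#'
#' A `ta_genome` holds one annotated prokaryotic genome: its replicons and its
#' protein-coding features with 1-based inclusive coordinates (GenBank
#' convention; GFF3 maps directly). Features are ranked 0-based along each
#' replicon in order of increasing start coordinate; all neighborhood and
#' distance computations work on these ranks and coordinates, never on
#' nucleotide sequence.
#'
#' @param genome_id Genome identifier.
#' @param species Species name; species is the unit used for conservation
#'   counting, so two genomes with equal species strings count once.
#' @param features `data.frame` with columns `feature_id`, `replicon_id`,
#'   `start_nt`, `end_nt`, `strand` (`"+"`/`"-"`), `protein_id`, `product`,
#'   `aa_seq`.
#' @param replicons `data.frame` with columns `replicon_id`, `kind`
#'   (`chromosome`, `plasmid`, `phage` or `unknown`) and `length_nt`; derived
#'   from the features when `NULL`.
#' @param phylum,superkingdom,is_complete Genome metadata.
#' @param load_report Named list of load diagnostics (e.g. number of features
#'   dropped for lacking a translation).
#' @return An object of class `ta_genome`.
#' @export
ta_genome <- function(genome_id, species = genome_id, features,
                      replicons = NULL, phylum = NA_character_,
                      superkingdom = "bacteria", is_complete = TRUE,
                      load_report = list(dropped_no_translation = 0L)) {
  need <- c("feature_id", "replicon_id", "start_nt", "end_nt", "strand",
            "protein_id", "product", "aa_seq")
  miss <- setdiff(need, names(features))
  if (length(miss))
    stop("features is missing columns: ", paste(miss, collapse = ", "))
  features <- as.data.frame(features, stringsAsFactors = FALSE)[, need]
  if (nrow(features)) {
    if (any(features$start_nt < 1L) || any(features$end_nt < features$start_nt))
      stop("invalid feature coordinates: need 1 <= start_nt <= end_nt")
    if (!all(features$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
    if (any(!nzchar(features$aa_seq)))
      stop("aa_seq must be non-empty for every feature")
    dup <- features$protein_id[duplicated(features$protein_id)]
    if (length(dup))
      stop("duplicate protein ids: ", paste(unique(dup), collapse = ", "))
  }
  if (is.null(replicons)) {
    if (nrow(features)) {
      agg <- tapply(features$end_nt, features$replicon_id, max)
      replicons <- data.frame(replicon_id = names(agg),
                              kind = "unknown",
                              length_nt = as.integer(unname(agg)),
                              stringsAsFactors = FALSE)
    } else {
      replicons <- data.frame(replicon_id = character(), kind = character(),
                              length_nt = integer(), stringsAsFactors = FALSE)
    }
  }
  replicons <- as.data.frame(replicons, stringsAsFactors = FALSE)
  if (anyDuplicated(replicons$replicon_id))
    stop("replicon_id must be unique within a genome")
  if (nrow(replicons) && any(replicons$length_nt < 1L))
    stop("replicon length_nt must be >= 1")
  if (nrow(features)) {
    unresolved <- setdiff(features$replicon_id, replicons$replicon_id)
    if (length(unresolved))
      stop("features reference unknown replicons: ",
           paste(unresolved, collapse = ", "))
    rl <- setNames(replicons$length_nt, replicons$replicon_id)
    if (any(features$end_nt > rl[features$replicon_id]))
      stop("feature coordinates exceed replicon length")
  }
  if (!nzchar(species) || is.na(species))
    stop("species must be non-empty")
  features <- assign_ranks(features)
  structure(list(genome_id = genome_id, species = species, phylum = phylum,
                 superkingdom = superkingdom, is_complete = isTRUE(is_complete),
                 replicons = replicons, features = features,
                 load_report = load_report),
            class = "ta_genome")
}

# Sort features by (replicon, start, end, feature_id) and assign 0-based ranks.
assign_ranks <- function(features) {
  if (!nrow(features)) {
    features$rank <- integer()
    return(features)
  }
  o <- order(features$replicon_id, features$start_nt, features$end_nt,
             features$feature_id)
  features <- features[o, , drop = FALSE]
  features$rank <- as.integer(
    stats::ave(features$start_nt, features$replicon_id,
               FUN = function(x) seq_along(x) - 1L))
  rownames(features) <- NULL
  features
}

#' @export
print.ta_genome <- function(x, ...) {
  cat(sprintf("<ta_genome> %s (%s), %d replicon(s), %d feature(s)\n",
              x$genome_id, x$species, nrow(x$replicons), nrow(x$features)))
  if (x$load_report$dropped_no_translation > 0L)
    cat(sprintf("  %d feature(s) dropped at load (no translation)\n",
                x$load_report$dropped_no_translation))
  invisible(x)
}

#' Read an annotated genome from GFF3 or GenBank
#'
#' Loads CDS features from a GFF3 file (protein sequences resolved from a
#' matching FASTA via the `protein_id` attribute, falling back to `ID`) or
#' from a GenBank flat file (`/translation` qualifiers; an external FASTA may
#' still override). Features without a resolvable protein sequence are dropped
#' and counted in the genome's `load_report` rather than treated as fatal:
#' real annotations contain pseudogenes.
#'
#' @param annotation_path Path to a GFF3 (`.gff`, `.gff3`) or GenBank
#'   (`.gb`, `.gbk`, `.gbff`) file; the format is sniffed from the content
#'   when the extension is ambiguous.
#' @param proteins_path Optional protein FASTA; record names are the first
#'   whitespace-delimited token of each header. Duplicate record names are an
#'   error listing the duplicates.
#' @param genome_id Genome identifier; defaults to the file base name.
#' @inheritParams ta_genome
#' @return A [ta_genome] object.
#' @export
read_genome <- function(annotation_path, proteins_path = NULL,
                        genome_id = NULL, species = NULL,
                        phylum = NA_character_, superkingdom = "bacteria",
                        is_complete = TRUE, replicons = NULL) {
  if (!file.exists(annotation_path))
    stop("annotation file not found: ", annotation_path)
  if (is.null(genome_id))
    genome_id <- sub("\\.[^.]+$", "", basename(annotation_path))
  if (is.null(species)) species <- genome_id
  proteins <- NULL
  if (!is.null(proteins_path)) {
    aa <- Biostrings::readAAStringSet(proteins_path)
    nm <- sub("\\s.*$", "", names(aa))
    dup <- unique(nm[duplicated(nm)])
    if (length(dup))
      stop("duplicate protein ids in ", proteins_path, ": ",
           paste(dup, collapse = ", "))
    proteins <- setNames(as.character(aa), nm)
  }
  gb <- is_genbank(annotation_path)
  raw <- if (gb) parse_genbank_cds(annotation_path) else
    parse_gff3_cds(annotation_path)
  feats <- raw$features
  if (!is.null(proteins)) {
    ext <- unname(proteins[feats$protein_id])
    feats$aa_seq <- ifelse(is.na(ext), feats$aa_seq, ext)
  }
  dropped <- is.na(feats$aa_seq) | !nzchar(feats$aa_seq)
  n_dropped <- sum(dropped)
  feats <- feats[!dropped, , drop = FALSE]
  if (is.null(replicons)) replicons <- raw$replicons
  ta_genome(genome_id = genome_id, species = species, features = feats,
            replicons = replicons, phylum = phylum,
            superkingdom = superkingdom, is_complete = is_complete,
            load_report = list(dropped_no_translation = as.integer(n_dropped)))
}

is_genbank <- function(path) {
  if (grepl("\\.(gb|gbk|gbff)$", path, ignore.case = TRUE)) return(TRUE)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) return(FALSE)
  head1 <- readLines(path, n = 5L, warn = FALSE)
  any(grepl("^LOCUS\\s", head1))
}

parse_gff3_cds <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   stop("unparseable GFF3 file ", path, ": ",
                        conditionMessage(e)))
  gr <- gr[as.character(gr$type) == "CDS"]
  mc <- S4Vectors::mcols(gr)
  get_attr <- function(name, default) {
    if (name %in% names(mc)) {
      v <- mc[[name]]
      if (is(v, "List") || is.list(v))
        v <- vapply(v, function(z) if (length(z)) as.character(z[[1L]])
                    else NA_character_, character(1))
      v <- as.character(v)
      ifelse(is.na(v), default, v)
    } else rep(default, length(gr))
  }
  ids <- get_attr("ID", NA_character_)
  if (anyNA(ids))
    ids[is.na(ids)] <- sprintf("cds_%04d", which(is.na(ids)))
  pid <- get_attr("protein_id", NA_character_)
  pid <- ifelse(is.na(pid), ids, pid)
  features <- data.frame(
    feature_id = ids,
    replicon_id = as.character(GenomicRanges::seqnames(gr)),
    start_nt = GenomicRanges::start(gr),
    end_nt = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    protein_id = pid,
    product = get_attr("product", ""),
    aa_seq = NA_character_,
    stringsAsFactors = FALSE)
  # replicon lengths from ##sequence-region directives (rtracklayer does not
  # surface them in seqinfo on import)
  hdr <- grep("^##sequence-region\\s", readLines(path, warn = FALSE),
              value = TRUE)
  sl <- integer()
  if (length(hdr)) {
    tok <- strsplit(trimws(hdr), "\\s+")
    sl <- setNames(vapply(tok, function(x) as.integer(x[4L]), integer(1)),
                   vapply(tok, function(x) x[2L], character(1)))
  }
  known <- !is.na(sl)
  replicons <- NULL
  if (length(sl) && any(known)) {
    replicons <- data.frame(replicon_id = names(sl)[known], kind = "unknown",
                            length_nt = as.integer(sl[known]),
                            stringsAsFactors = FALSE)
    extra <- setdiff(unique(features$replicon_id), replicons$replicon_id)
    if (length(extra)) {
      mx <- vapply(extra, function(r)
        max(features$end_nt[features$replicon_id == r]), numeric(1))
      replicons <- rbind(replicons,
                         data.frame(replicon_id = extra, kind = "unknown",
                                    length_nt = as.integer(mx),
                                    stringsAsFactors = FALSE))
    }
  }
  list(features = features, replicons = replicons)
}

# Minimal GenBank flat-file CDS parser (LOCUS / FEATURES / CDS with
# /protein_id, /product and /translation qualifiers; complement() locations).
# No installed R package parses local GenBank flat files, hence hand-rolled.
parse_genbank_cds <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_lines <- grep("^LOCUS\\s", lines)
  if (!length(locus_lines))
    stop("unparseable GenBank file ", path, ": no LOCUS line (line 1)")
  feats <- list()
  repls <- list()
  for (li in seq_along(locus_lines)) {
    from <- locus_lines[li]
    to <- if (li < length(locus_lines)) locus_lines[li + 1L] - 1L else length(lines)
    block <- lines[from:to]
    locus_tok <- strsplit(trimws(block[1L]), "\\s+")[[1L]]
    replicon_id <- locus_tok[2L]
    length_nt <- suppressWarnings(as.integer(locus_tok[3L]))
    if (is.na(length_nt))
      stop("unparseable GenBank LOCUS line ", from, " in ", path)
    repls[[length(repls) + 1L]] <- data.frame(
      replicon_id = replicon_id, kind = "unknown", length_nt = length_nt,
      stringsAsFactors = FALSE)
    fstart <- grep("^FEATURES", block)
    if (!length(fstart)) next
    fend <- grep("^(ORIGIN|CONTIG|//)", block)
    fend <- if (length(fend)) min(fend[fend > fstart[1L]]) - 1L else length(block)
    fb <- block[(fstart[1L] + 1L):fend]
    key_idx <- grep("^ {5}\\S", fb)
    for (ki in seq_along(key_idx)) {
      first <- key_idx[ki]
      lastl <- if (ki < length(key_idx)) key_idx[ki + 1L] - 1L else length(fb)
      ftxt <- fb[first:lastl]
      key <- strsplit(trimws(ftxt[1L]), "\\s+")[[1L]][1L]
      if (key != "CDS") next
      loc <- sub("^\\s*CDS\\s+", "", ftxt[1L])
      qstart <- grep("^\\s{10,}/", ftxt)
      if (length(qstart) && qstart[1L] > 2L)
        loc <- paste0(loc, paste(trimws(ftxt[2:(qstart[1L] - 1L)]),
                                 collapse = ""))
      strand <- if (grepl("complement", loc)) "-" else "+"
      nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1L]]
      if (length(nums) < 2L)
        stop("unparseable CDS location near line ", from + fstart[1L] + first - 1L,
             " in ", path)
      start_nt <- as.integer(nums[1L])
      end_nt <- as.integer(nums[length(nums)])
      quals <- parse_gb_qualifiers(ftxt[-1L])
      pid <- quals[["protein_id"]]
      if (is.null(pid)) pid <- sprintf("%s_cds_%d", replicon_id, first)
      feats[[length(feats) + 1L]] <- data.frame(
        feature_id = pid, replicon_id = replicon_id, start_nt = start_nt,
        end_nt = end_nt, strand = strand, protein_id = pid,
        product = if (is.null(quals[["product"]])) "" else quals[["product"]],
        aa_seq = if (is.null(quals[["translation"]])) NA_character_ else
          quals[["translation"]],
        stringsAsFactors = FALSE)
    }
  }
  list(features = if (length(feats)) do.call(rbind, feats) else
         data.frame(feature_id = character(), replicon_id = character(),
                    start_nt = integer(), end_nt = integer(),
                    strand = character(), protein_id = character(),
                    product = character(), aa_seq = character(),
                    stringsAsFactors = FALSE),
       replicons = do.call(rbind, repls))
}

parse_gb_qualifiers <- function(lines) {
  lines <- trimws(lines)
  starts <- grep("^/", lines)
  out <- list()
  for (si in seq_along(starts)) {
    from <- starts[si]
    to <- if (si < length(starts)) starts[si + 1L] - 1L else length(lines)
    txt <- paste(lines[from:to], collapse = "")
    m <- regmatches(txt, regexec('^/([A-Za-z_]+)=?"?([^"]*)"?', txt))[[1L]]
    if (length(m) == 3L) out[[m[2L]]] <- m[3L]
  }
  if (!is.null(out[["translation"]]))
    out[["translation"]] <- gsub("\\s", "", out[["translation"]])
  out
}

#' Write a genome back to GFF3 + protein FASTA
#'
#' Inverse of [read_genome()] for the GFF3 encoding; the round trip preserves
#' all feature fields. Attribute values are percent-encoded where GFF3
#' requires it.
#'
#' @param genome A [ta_genome].
#' @param annotation_path,proteins_path Output paths.
#' @return Invisibly, the genome.
#' @export
write_genome <- function(genome, annotation_path, proteins_path) {
  stopifnot(inherits(genome, "ta_genome"))
  enc <- function(x) {
    x <- gsub("%", "%25", x, fixed = TRUE)
    x <- gsub(";", "%3B", x, fixed = TRUE)
    x <- gsub("=", "%3D", x, fixed = TRUE)
    x <- gsub("&", "%26", x, fixed = TRUE)
    x <- gsub(",", "%2C", x, fixed = TRUE)
    x
  }
  f <- genome$features
  header <- c("##gff-version 3",
              sprintf("##sequence-region %s 1 %d",
                      genome$replicons$replicon_id, genome$replicons$length_nt))
  body <- if (nrow(f)) sprintf(
    "%s\tpantascan\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;protein_id=%s;product=%s",
    f$replicon_id, f$start_nt, f$end_nt, f$strand, enc(f$feature_id),
    enc(f$protein_id), enc(f$product)) else character()
  writeLines(c(header, body), annotation_path)
  fasta <- if (nrow(f)) as.vector(rbind(paste0(">", f$protein_id), f$aa_seq))
           else character()
  writeLines(fasta, proteins_path)
  invisible(genome)
}

#' Read or write a corpus of genomes with a metadata sidecar
#'
#' A corpus directory holds `metadata.tsv` (one row per replicon: `genome_id`,
#' `species`, `phylum`, `superkingdom`, `is_complete`, `replicon_id`,
#' `replicon_kind`, `replicon_length_nt`), `genomes/<genome_id>.gff3` and
#' `proteins/<genome_id>.faa`.
#'
#' @param dir Corpus directory.
#' @return `read_corpus()`: a named list of [ta_genome] objects, ordered by
#'   `genome_id`.
#' @export
read_corpus <- function(dir) {
  meta_path <- file.path(dir, "metadata.tsv")
  if (!file.exists(meta_path)) stop("metadata.tsv not found in ", dir)
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  ids <- sort(unique(meta$genome_id))
  genomes <- lapply(ids, function(g) {
    m <- meta[meta$genome_id == g, , drop = FALSE]
    read_genome(
      annotation_path = file.path(dir, "genomes", paste0(g, ".gff3")),
      proteins_path = file.path(dir, "proteins", paste0(g, ".faa")),
      genome_id = g, species = m$species[1L], phylum = m$phylum[1L],
      superkingdom = m$superkingdom[1L], is_complete = m$is_complete[1L],
      replicons = data.frame(replicon_id = m$replicon_id,
                             kind = m$replicon_kind,
                             length_nt = m$replicon_length_nt,
                             stringsAsFactors = FALSE))
  })
  setNames(genomes, ids)
}

#' @rdname read_corpus
#' @param corpus Named list of [ta_genome] objects.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(file.path(dir, "genomes"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "proteins"), recursive = TRUE, showWarnings = FALSE)
  meta <- do.call(rbind, lapply(corpus, function(g) {
    data.frame(genome_id = g$genome_id, species = g$species,
               phylum = g$phylum, superkingdom = g$superkingdom,
               is_complete = g$is_complete,
               replicon_id = g$replicons$replicon_id,
               replicon_kind = g$replicons$kind,
               replicon_length_nt = g$replicons$length_nt,
               stringsAsFactors = FALSE)
  }))
  meta <- meta[order(meta$genome_id, meta$replicon_id), , drop = FALSE]
  write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (g in corpus)
    write_genome(g, file.path(dir, "genomes", paste0(g$genome_id, ".gff3")),
                 file.path(dir, "proteins", paste0(g$genome_id, ".faa")))
  invisible(dir)
}

#' Intergenic distance between two genes
#'
#' Number of nucleotides strictly between two features on the same replicon:
#' `max(0, later_start - earlier_end - 1)`. Overlapping or book-ended genes
#' clamp to 0 so that a "gap at most N" criterion stays monotone. Symmetric in
#' its arguments.
#'
#' @param a,b Single feature rows (one-row `data.frame` or list with
#'   `replicon_id`, `start_nt`, `end_nt`).
#' @return Integer distance in nucleotides (>= 0).
#' @export
intergenic_distance <- function(a, b) {
  if (a$replicon_id != b$replicon_id)
    stop("features are on different replicons: ", a$replicon_id, " vs ",
         b$replicon_id)
  first_end <- min(a$end_nt, b$end_nt)
  later_start <- max(a$start_nt, b$start_nt)
  max(0L, as.integer(later_start) - as.integer(first_end) - 1L)
}

#' Gene neighborhood around a focal feature
#'
#' Up to `k` genes on either side of the focal gene by rank along its
#' replicon, truncated at replicon ends; neighborhoods never wrap around and
#' never cross replicon (contig) boundaries. `upstream` are lower-rank genes
#' and `downstream` higher-rank genes, each ordered by increasing distance
#' from the focal gene.
#'
#' @param genome A [ta_genome].
#' @param focal A feature row of `genome` or a `feature_id` string.
#' @param k Positive window size in genes per side (default 4).
#' @return List of class `ta_neighborhood` with `focal`, `upstream`,
#'   `downstream` feature data frames.
#' @export
neighborhood <- function(genome, focal, k = 4L) {
  stopifnot(inherits(genome, "ta_genome"), k >= 1L)
  f <- genome$features
  if (is.character(focal)) {
    idx <- which(f$feature_id == focal)
    if (!length(idx)) stop("focal feature not in genome: ", focal)
    focal <- f[idx[1L], , drop = FALSE]
  }
  same <- f[f$replicon_id == focal$replicon_id, , drop = FALSE]
  r <- focal$rank
  up <- same[same$rank < r & same$rank >= r - k, , drop = FALSE]
  up <- up[order(-up$rank), , drop = FALSE]
  dn <- same[same$rank > r & same$rank <= r + k, , drop = FALSE]
  dn <- dn[order(dn$rank), , drop = FALSE]
  structure(list(focal = focal, upstream = up, downstream = dn),
            class = "ta_neighborhood")
}

#' Mirror every replicon of a genome
#'
#' Coordinate-reversal utility for symmetry checks: each feature at
#' `[s, e]` on a replicon of length `L` maps to `[L - e + 1, L - s + 1]` with
#' its strand flipped; ranks are reassigned. Pipeline output is invariant
#' under this transformation.
#'
#' @param genome A [ta_genome].
#' @return The mirrored [ta_genome].
#' @export
mirror_genome <- function(genome) {
  f <- genome$features
  L <- setNames(genome$replicons$length_nt, genome$replicons$replicon_id)
  len <- L[f$replicon_id]
  s <- len - f$end_nt + 1L
  e <- len - f$start_nt + 1L
  f$start_nt <- as.integer(s)
  f$end_nt <- as.integer(e)
  f$strand <- ifelse(f$strand == "+", "-", "+")
  ta_genome(genome$genome_id, genome$species, f, genome$replicons,
            genome$phylum, genome$superkingdom, genome$is_complete,
            genome$load_report)
}

# Flat per-corpus feature table with genome metadata columns attached.
corpus_feature_table <- function(corpus) {
  do.call(rbind, c(lapply(corpus, function(g) {
    f <- g$features
    if (!nrow(f)) return(NULL)
    f$genome_id <- g$genome_id
    f$species <- g$species
    f
  }), list(make.row.names = FALSE)))
}
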