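#' Parameters for the antisense seed-and-extend aligner
#'
#' The aligner finds highly complementary regions between transcript pairs by
#' aligning A against the reverse complement of B: exact `seed_len`-mer seeds,
#' grouped by diagonal, are extended by a local affine-gap alignment restricted
#' to a window around the seed group.
#'
#' @param seed_len Exact-match seed length (nt), at least 8.
#' @param match,mismatch,gap_open,gap_extend blastn-style local alignment
#'   scores; gap penalties are negative and a gap of length L scores
#'   `gap_open + L * gap_extend`.
#' @param min_score Minimum local alignment score for a reported region.
#' @param band Seeds whose diagonals differ by at most `band` are grouped.
#' @param window_pad Extension window margin (nt) around a seed group.
#' @param max_pairs_per_transcript Optional cap on reported partners per
#'   transcript (`Inf` = unlimited).
#' @return A list of class `aligner_params`.
#' @export
aligner_params <- function(seed_len = 12L, match = 1, mismatch = -2,
                           gap_open = -5, gap_extend = -2, min_score = 60,
                           band = 20L, window_pad = 50L,
                           max_pairs_per_transcript = Inf) {
  stopifnot(seed_len >= 8L, min_score > 0, match > 0, mismatch < 0,
            gap_open <= 0, gap_extend <= 0)
  structure(list(seed_len = as.integer(seed_len), match = match,
                 mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_score = min_score,
                 band = as.integer(band), window_pad = as.integer(window_pad),
                 max_pairs_per_transcript = max_pairs_per_transcript),
            class = "aligner_params")
}

empty_matches <- function() {
  data.frame(id_a = character(), id_b = character(),
             a_start = integer(), a_end = integer(),
             b_start = integer(), b_end = integer(),
             aln_len = integer(), identity = numeric(),
             longest_contig_block = integer(), longest_perfect_block = integer(),
             score = numeric(), stringsAsFactors = FALSE)
}

kmer_positions <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(list(kmer = character(), pos = integer()))
  pos <- seq_len(n - k + 1L)
  list(kmer = substring(seq, pos, pos + k - 1L), pos = pos)
}

# Seeds between a and revcomp(b): positions (i in a, j in rcb) sharing an
# exact k-mer, excluding k-mers containing N.
find_seeds <- function(a, rcb, k) {
  ka <- kmer_positions(a, k)
  kb <- kmer_positions(rcb, k)
  keep_a <- !grepl("N", ka$kmer, fixed = TRUE)
  idx <- split(ka$pos[keep_a], ka$kmer[keep_a])
  keep_b <- !grepl("N", kb$kmer, fixed = TRUE) & kb$kmer %in% names(idx)
  if (!any(keep_b)) return(data.frame(i = integer(), j = integer()))
  jj <- kb$pos[keep_b]
  hits <- idx[kb$kmer[keep_b]]
  data.frame(i = unlist(hits, use.names = FALSE),
             j = rep(jj, lengths(hits)))
}

# Align one ordered pair: a vs revcomp(b). Returns match rows with b
# coordinates mapped back to B's forward strand.
align_antisense_pair <- function(id_a, a, id_b, b, params) {
  k <- params$seed_len
  if (nchar(a) < k || nchar(b) < k) return(empty_matches())
  rcb <- revcomp(b)
  seeds <- find_seeds(a, rcb, k)
  if (nrow(seeds) == 0L) return(empty_matches())
  seeds$diag <- seeds$i - seeds$j
  seeds <- seeds[order(seeds$diag, seeds$i), , drop = FALSE]
  grp <- cumsum(c(1L, diff(seeds$diag) > params$band))
  nb <- nchar(b)
  out <- list()
  for (g in split(seeds, grp)) {
    wa <- c(max(1L, min(g$i) - params$window_pad),
            min(nchar(a), max(g$i) + k - 1L + params$window_pad))
    wb <- c(max(1L, min(g$j) - params$window_pad),
            min(nb, max(g$j) + k - 1L + params$window_pad))
    r <- .sw_local(substr(a, wa[1], wa[2]), substr(rcb, wb[1], wb[2]),
                   params$match, params$mismatch,
                   params$gap_open, params$gap_extend)
    if (r$score < params$min_score) next
    rc_start <- wb[1] + r$b_start - 1L
    rc_end <- wb[1] + r$b_end - 1L
    out[[length(out) + 1L]] <- data.frame(
      id_a = id_a, id_b = id_b,
      a_start = wa[1] + r$a_start - 1L, a_end = wa[1] + r$a_end - 1L,
      b_start = nb - rc_end + 1L, b_end = nb - rc_start + 1L,
      aln_len = r$n_cols, identity = r$n_match / r$n_cols,
      longest_contig_block = r$longest_block,
      longest_perfect_block = r$longest_perfect,
      score = r$score, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty_matches())
  res <- do.call(rbind, out)
  dedupe_matches(res)
}

interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

# Drop regions that duplicate a higher-scoring one (>= 50% reciprocal overlap
# of the shorter interval on both transcripts); distinct regions between the
# same pair are kept.
dedupe_matches <- function(res) {
  res <- res[order(-res$score, res$a_start, res$b_start), , drop = FALSE]
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))[-1]) {
    for (j in which(keep[seq_len(i - 1L)])) {
      ova <- interval_overlap(res$a_start[i], res$a_end[i], res$a_start[j], res$a_end[j])
      ovb <- interval_overlap(res$b_start[i], res$b_end[i], res$b_start[j], res$b_end[j])
      la <- min(res$a_end[i] - res$a_start[i], res$a_end[j] - res$a_start[j]) + 1L
      lb <- min(res$b_end[i] - res$b_start[i], res$b_end[j] - res$b_start[j]) + 1L
      if (ova >= 0.5 * la && ovb >= 0.5 * lb) { keep[i] <- FALSE; break }
    }
  }
  res <- res[keep, , drop = FALSE]
  res[order(res$a_start, res$b_start), , drop = FALSE]
}

#' Find highly complementary transcript pairs
#'
#' Searches every unordered transcript pair for antisense (reverse-complement)
#' local alignments with score at least `params$min_score`. Coordinates of
#' both transcripts are reported on their forward strands, 1-based inclusive,
#' with `id_a < id_b` lexicographically.
#'
#' @param transcripts Transcript `data.frame` from [read_fasta()].
#' @param params An [aligner_params()] object.
#' @return A `data.frame` of complementary matches: one row per distinct
#'   region, columns `id_a`, `id_b`, `a_start`, `a_end`, `b_start`, `b_end`,
#'   `aln_len` (alignment columns), `identity` (fraction of columns that are
#'   complementary), `longest_contig_block` (longest gap-free block, nt),
#'   `longest_perfect_block` (longest mismatch-free block), `score`.
#' @export
find_complementary_pairs <- function(transcripts, params = aligner_params()) {
  if (is.null(transcripts) || nrow(transcripts) < 2L) return(empty_matches())
  short <- transcripts$length < params$seed_len
  if (any(short))
    message(sprintf("skipping %d transcript(s) shorter than the %d-nt seed",
                    sum(short), params$seed_len))
  tr <- transcripts[!short, , drop = FALSE]
  tr <- tr[order(tr$id), , drop = FALSE]
  n <- nrow(tr)
  if (n < 2L) return(empty_matches())
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m <- align_antisense_pair(tr$id[i], tr$seq[i], tr$id[j], tr$seq[j], params)
      if (nrow(m)) out[[length(out) + 1L]] <- m
    }
  }
  if (length(out) == 0L) return(empty_matches())
  res <- do.call(rbind, out)
  if (is.finite(params$max_pairs_per_transcript)) {
    res <- res[order(-res$score), , drop = FALSE]
    cnt <- new.env(parent = emptyenv())
    take <- vapply(seq_len(nrow(res)), function(r) {
      ca <- mget(res$id_a[r], cnt, ifnotfound = 0L)[[1]]
      cb <- mget(res$id_b[r], cnt, ifnotfound = 0L)[[1]]
      if (ca >= params$max_pairs_per_transcript ||
          cb >= params$max_pairs_per_transcript) return(FALSE)
      assign(res$id_a[r], ca + 1L, cnt); assign(res$id_b[r], cb + 1L, cnt)
      TRUE
    }, logical(1))
    res <- res[take, , drop = FALSE]
  }
  rownames(res) <- NULL
  res[order(res$id_a, res$id_b, res$a_start), , drop = FALSE]
}

#' Parameters for NAT classification
#'
#' @param hc_fraction Coverage fraction above which a pair is "HC" (high
#'   coverage); the complementary span must be strictly longer than
#'   `hc_fraction` times a transcript's length.
#' @param hc_mode Whether coverage of `"any_transcript"` (default) or of
#'   `"both_transcripts"` is required for HC.
#' @param nt100_min_len Minimum consecutive complementary length (nt) for the
#'   "100-nt" class; the threshold is inclusive (100 nt or longer).
#' @param nt100_perfect If `TRUE`, the consecutive block must also be
#'   mismatch-free; by default mismatches are allowed within the gap-free
#'   block (trans-NAT annealed regions usually contain mismatches).
#' @return A list of class `classify_params`.
#' @export
classify_params <- function(hc_fraction = 0.5,
                            hc_mode = c("any_transcript", "both_transcripts"),
                            nt100_min_len = 100L, nt100_perfect = FALSE) {
  stopifnot(hc_fraction > 0, hc_fraction < 1, nt100_min_len >= 1L)
  structure(list(hc_fraction = hc_fraction, hc_mode = match.arg(hc_mode),
                 nt100_min_len = as.integer(nt100_min_len),
                 nt100_perfect = isTRUE(nt100_perfect)),
            class = "classify_params")
}

#' Classify a complementary match as HC and/or 100-nt
#'
#' "HC" (high coverage): the complementary region is longer than 50% of a
#' transcript of the pair. "NT100": the consecutive complementary region is
#' 100 nt or longer. A match can be `both` or `none`; `none` pairs are
#' dropped downstream.
#'
#' @param m One match (a 1-row `data.frame` or list with the match fields).
#' @param len_a,len_b Lengths (nt) of the two transcripts.
#' @param params A [classify_params()] object.
#' @return One of `"HC"`, `"NT100"`, `"both"`, `"none"`.
#' @export
classify_match <- function(m, len_a, len_b, params = classify_params()) {
  span_a <- m$a_end - m$a_start + 1L
  span_b <- m$b_end - m$b_start + 1L
  cov <- c(span_a > params$hc_fraction * len_a,
           span_b > params$hc_fraction * len_b)
  hc <- if (params$hc_mode == "any_transcript") any(cov) else all(cov)
  block <- if (params$nt100_perfect) m$longest_perfect_block else m$longest_contig_block
  nt100 <- block >= params$nt100_min_len
  if (hc && nt100) "both" else if (hc) "HC" else if (nt100) "NT100" else "none"
}

#' Classify all matches against their transcripts
#'
#' @param matches Match `data.frame` from [find_complementary_pairs()].
#' @param transcripts Transcript `data.frame` (for lengths).
#' @param params A [classify_params()] object.
#' @return `matches` with an added `nat_class` column.
#' @export
classify_matches <- function(matches, transcripts, params = classify_params()) {
  len <- setNames(transcripts$length, transcripts$id)
  matches$nat_class <- vapply(seq_len(nrow(matches)), function(r)
    classify_match(matches[r, ], len[[matches$id_a[r]]], len[[matches$id_b[r]]],
                   params), character(1))
  matches
}

#' Read BLAST tabular (outfmt 6) antisense hits
#'
#' Escape hatch for users who ran an external blastn search: parses outfmt-6
#' lines (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore), keeping minus-strand hits (`sstart > send`) and
#' converting them to the match table layout of [find_complementary_pairs()].
#' `longest_contig_block` is approximated by the gapless lower bound
#' `length - gapopen` since the tabular format has no per-gap detail.
#'
#' @param path Path to a BLAST outfmt-6 file.
#' @return A match `data.frame` (see [find_complementary_pairs()]).
#' @export
read_blast_tab <- function(path) {
  tb <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tb) < 12L) parse_error(sprintf("%s: expected 12 outfmt-6 columns", path))
  names(tb)[1:12] <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                       "gapopen", "qstart", "qend", "sstart", "send",
                       "evalue", "bitscore")
  tb <- tb[tb$sstart > tb$send & tb$qseqid != tb$sseqid, , drop = FALSE]
  if (nrow(tb) == 0L) return(empty_matches())
  swap <- tb$qseqid > tb$sseqid
  res <- data.frame(
    id_a = ifelse(swap, tb$sseqid, tb$qseqid),
    id_b = ifelse(swap, tb$qseqid, tb$sseqid),
    a_start = ifelse(swap, tb$send, tb$qstart),
    a_end = ifelse(swap, tb$sstart, tb$qend),
    b_start = ifelse(swap, tb$qstart, tb$send),
    b_end = ifelse(swap, tb$qend, tb$sstart),
    aln_len = tb$length,
    identity = tb$pident / 100,
    longest_contig_block = pmax(1L, tb$length - tb$gapopen),
    longest_perfect_block = NA_integer_,
    score = tb$bitscore, stringsAsFactors = FALSE)
  res[order(res$id_a, res$id_b, res$a_start), , drop = FALSE]
}
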