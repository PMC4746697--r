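#' Parameters for duplex-structure validation
#'
#' The structure stage re-examines each complementary match with an
#' inter-molecular duplex alignment that maximizes
#' `pairs - lambda * bubble_columns` (base-pair maximization): a column is
#' either a Watson-Crick / G:U pair or part of a bubble; a mismatched
#' opposition counts as a 1+1 bubble. This combinatorial objective is used to
#' confirm annealing and locate bubbles and perfectly annealed segments; it
#' does not estimate folding free energies.
#'
#' @param lambda Penalty per unpaired interior nucleotide (default 1).
#' @param gu Allow G:U wobble pairs (default `TRUE`, RNA duplex behavior).
#' @param pad Window padding (nt) beyond the alignment-predicted region so the
#'   structure stage can extend slightly past the seed alignment (default 10).
#' @param overlap_min Retention criterion 1: the structure-predicted annealed
#'   region must overlap the alignment-predicted complementary region at this
#'   fraction or more, on both transcripts (default 0.8).
#' @param bubble_max_frac Retention criterion 2: no bubble may be larger than
#'   this fraction of the annealed region (default 0.10).
#' @param bubble_denominator Annealed-region length used as the criterion-2
#'   denominator: strand A's region length (`"a"`, default; the two strands
#'   differ only by bubble asymmetry) or the longer of the two (`"max_strand"`).
#' @return A list of class `duplex_params`.
#' @export
duplex_params <- function(lambda = 1, gu = TRUE, pad = 10L, overlap_min = 0.8,
                          bubble_max_frac = 0.10,
                          bubble_denominator = c("a", "max_strand")) {
  stopifnot(lambda > 0, pad >= 0L, overlap_min > 0, overlap_min <= 1,
            bubble_max_frac > 0, bubble_max_frac < 1)
  structure(list(lambda = lambda, gu = isTRUE(gu), pad = as.integer(pad),
                 overlap_min = overlap_min, bubble_max_frac = bubble_max_frac,
                 bubble_denominator = match.arg(bubble_denominator)),
            class = "duplex_params")
}

empty_segments <- function() {
  data.frame(a_start = integer(), a_end = integer(),
             b_start = integer(), b_end = integer(), length = integer())
}

empty_bubbles <- function() {
  data.frame(a_after = integer(), b_before = integer(),
             a_gap_len = integer(), b_gap_len = integer(), size = integer())
}

# Derive bubbles and maximal perfect segments from the paired columns
# (pos_a ascending, pos_b descending).
structure_from_pairs <- function(pairs) {
  np <- nrow(pairs)
  if (np == 0L)
    return(list(pairs = pairs, bubbles = empty_bubbles(),
                segments = empty_segments()))
  a_gap <- diff(pairs$pos_a) - 1L
  b_gap <- -diff(pairs$pos_b) - 1L
  brk <- which(a_gap > 0L | b_gap > 0L)
  bubbles <- if (length(brk)) data.frame(
    a_after = pairs$pos_a[brk], b_before = pairs$pos_b[brk],
    a_gap_len = a_gap[brk], b_gap_len = b_gap[brk],
    size = pmax(a_gap[brk], b_gap[brk])) else empty_bubbles()
  seg_id <- cumsum(c(1L, as.integer(a_gap > 0L | b_gap > 0L)))
  first <- !duplicated(seg_id)
  last <- !duplicated(seg_id, fromLast = TRUE)
  segments <- data.frame(
    a_start = pairs$pos_a[first], a_end = pairs$pos_a[last],
    b_start = pairs$pos_b[last], b_end = pairs$pos_b[first])
  segments$length <- segments$a_end - segments$a_start + 1L
  list(pairs = pairs, bubbles = bubbles, segments = segments)
}

#' Predict the duplex structure of a complementary match
#'
#' Runs the base-pair-maximization duplex alignment on the match region of
#' both transcripts, padded by `params$pad` nt, and reports the annealed
#' region, its paired columns, bubbles, and maximal perfectly annealed
#' segments (no mismatch, no gap, every column paired).
#'
#' @param a_seq,b_seq Full sequences of the two transcripts (forward strands).
#' @param match One complementary match row (from
#'   [find_complementary_pairs()]).
#' @param params A [duplex_params()] object.
#' @return An object of class `duplex_structure`: a list with `pair`,
#'   `a_region`/`b_region` (1-based inclusive, forward strands), `pairs`
#'   (paired columns, `pos_a` ascending and `pos_b` descending), `bubbles`
#'   (`a_gap_len`, `b_gap_len`, `size = max` of the two), `segments`
#'   (perfect segments), `n_perfect_segments` and `score`.
#' @export
predict_duplex <- function(a_seq, b_seq, match, params = duplex_params()) {
  wa <- c(max(1L, match$a_start - params$pad),
          min(nchar(a_seq), match$a_end + params$pad))
  wb <- c(max(1L, match$b_start - params$pad),
          min(nchar(b_seq), match$b_end + params$pad))
  if (wa[1] > wa[2] || wb[1] > wb[2]) stop("empty duplex window")
  awin <- substr(a_seq, wa[1], wa[2])
  bwin <- substr(b_seq, wb[1], wb[2])
  brev <- paste(rev(strsplit(bwin, NULL, fixed = TRUE)[[1]]), collapse = "")
  r <- .duplex_local(awin, brev, params$lambda, params$gu)
  wb_len <- wb[2] - wb[1] + 1L
  pairs <- data.frame(pos_a = wa[1] + r$pairs[, "pos_a"] - 1L,
                      pos_b = wb[1] + (wb_len - r$pairs[, "pos_br"]))
  st <- structure_from_pairs(pairs)
  structure(list(
    pair = c(match$id_a, match$id_b),
    a_region = if (nrow(pairs)) range(pairs$pos_a) else c(NA_integer_, NA_integer_),
    b_region = if (nrow(pairs)) range(pairs$pos_b) else c(NA_integer_, NA_integer_),
    pairs = st$pairs, bubbles = st$bubbles, segments = st$segments,
    n_perfect_segments = nrow(st$segments), score = r$score),
    class = "duplex_structure")
}

#' @export
print.duplex_structure <- function(x, ...) {
  cat(sprintf("duplex %s | %s: A %d..%d, B %d..%d; %d paired, %d bubble(s), %d perfect segment(s)\n",
              x$pair[1], x$pair[2], x$a_region[1], x$a_region[2],
              x$b_region[1], x$b_region[2], nrow(x$pairs), nrow(x$bubbles),
              x$n_perfect_segments))
  invisible(x)
}

#' Retention filter comparing alignment- and structure-predicted regions
#'
#' A candidate NAT pair is retained only if (1) the structure-predicted
#' annealed region overlaps the alignment-predicted complementary region at
#' `overlap_min` (default 80%) or more on both transcripts, and (2) every
#' bubble within the annealed region is no larger than `bubble_max_frac`
#' (default 10%) of the region.
#'
#' @param match One complementary match row.
#' @param duplex The corresponding [predict_duplex()] result.
#' @param params A [duplex_params()] object.
#' @return `TRUE` to retain, `FALSE` to drop.
#' @export
retention_filter <- function(match, duplex, params = duplex_params()) {
  if (nrow(duplex$pairs) == 0L) return(FALSE)
  len_a <- duplex$a_region[2] - duplex$a_region[1] + 1L
  len_b <- duplex$b_region[2] - duplex$b_region[1] + 1L
  ov_a <- interval_overlap(duplex$a_region[1], duplex$a_region[2],
                           match$a_start, match$a_end) / len_a
  ov_b <- interval_overlap(duplex$b_region[1], duplex$b_region[2],
                           match$b_start, match$b_end) / len_b
  if (ov_a < params$overlap_min || ov_b < params$overlap_min) return(FALSE)
  denom <- if (params$bubble_denominator == "a") len_a else max(len_a, len_b)
  all(duplex$bubbles$size <= params$bubble_max_frac * denom)
}

#' Flag cis-NAT candidates
#'
#' Without genome coordinates, a NAT pair whose predicted duplex consists of a
#' single perfectly annealed region (one perfect segment spanning the whole
#' annealed region, no bubbles) is flagged as a cis-NAT candidate.
#'
#' @param duplex A `duplex_structure`.
#' @return Logical.
#' @export
flag_cis_candidate <- function(duplex) {
  nrow(duplex$segments) == 1L && nrow(duplex$bubbles) == 0L &&
    duplex$segments$a_start[1] == duplex$a_region[1] &&
    duplex$segments$a_end[1] == duplex$a_region[2]
}

#' Build validated NAT pairs from classified matches
#'
#' For every match with a NAT class, predicts the duplex structure, applies
#' the retention filter and flags cis candidates.
#'
#' @param transcripts Transcript `data.frame`.
#' @param matches Classified match `data.frame` (with `nat_class`); rows with
#'   class `"none"` are skipped.
#' @param params A [duplex_params()] object.
#' @param keep_dropped Keep pairs failing the retention filter (with
#'   `retained = FALSE`) instead of discarding them.
#' @return A list of `nat_pair` objects: `id_a`, `id_b`, `match` (1-row
#'   data.frame), `duplex`, `segments`, `retained`, `is_cis_candidate`.
#' @export
build_nat_pairs <- function(transcripts, matches, params = duplex_params(),
                            keep_dropped = FALSE) {
  seqs <- setNames(transcripts$seq, transcripts$id)
  out <- list()
  for (r in seq_len(nrow(matches))) {
    m <- matches[r, ]
    if (!is.null(m$nat_class) && m$nat_class == "none") next
    dx <- predict_duplex(seqs[[m$id_a]], seqs[[m$id_b]], m, params)
    retained <- retention_filter(m, dx, params)
    if (!retained && !keep_dropped) next
    out[[length(out) + 1L]] <- structure(list(
      id_a = m$id_a, id_b = m$id_b, match = m, duplex = dx,
      segments = dx$segments, retained = retained,
      is_cis_candidate = retained && flag_cis_candidate(dx)),
      class = "nat_pair")
  }
  # a pair with more than one retained annealed region cannot be a single
  # perfectly annealed region, hence is never a cis candidate
  key <- vapply(out, function(x) paste(x$id_a, x$id_b), character(1))
  ret <- vapply(out, `[[`, logical(1), "retained")
  multi <- names(which(table(key[ret]) > 1L))
  for (i in which(key %in% multi)) out[[i]]$is_cis_candidate <- FALSE
  out
}

#' Summarize NAT pairs as a table
#' @param nats A list of `nat_pair` objects from [build_nat_pairs()].
#' @return A `data.frame` with one row per pair.
#' @export
nat_table <- function(nats) {
  if (length(nats) == 0L)
    return(data.frame(id_a = character(), id_b = character(),
                      nat_class = character(), a_region_start = integer(),
                      a_region_end = integer(), b_region_start = integer(),
                      b_region_end = integer(), n_perfect_segments = integer(),
                      longest_perfect_segment = integer(), n_bubbles = integer(),
                      retained = logical(), is_cis_candidate = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(nats, function(x) data.frame(
    id_a = x$id_a, id_b = x$id_b,
    nat_class = if (is.null(x$match$nat_class)) NA_character_ else x$match$nat_class,
    a_region_start = x$duplex$a_region[1], a_region_end = x$duplex$a_region[2],
    b_region_start = x$duplex$b_region[1], b_region_end = x$duplex$b_region[2],
    n_perfect_segments = x$duplex$n_perfect_segments,
    longest_perfect_segment = if (nrow(x$segments)) max(x$segments$length) else 0L,
    n_bubbles = nrow(x$duplex$bubbles),
    retained = x$retained, is_cis_candidate = x$is_cis_candidate,
    stringsAsFactors = FALSE)))
}

#' Parse an RNAplex duplex output line
#'
#' Populates the annealed-region coordinates from a duplex line of the form
#' `.(((...))).  (i,j) : (k,l)  (-12.3)` when a user supplies external
#' structure predictions; the paired columns are reconstructed from the
#' dot-bracket string.
#'
#' @param line One RNAplex output line.
#' @param id_a,id_b Transcript IDs for the query/target of the line.
#' @return A `duplex_structure` (score is the printed energy).
#' @export
parse_rnaplex_line <- function(line, id_a = "query", id_b = "target") {
  m <- regexec("^([.()&]+)\\s+(\\d+),(\\d+)\\s*:\\s*(\\d+),(\\d+)\\s*\\((\\s*-?[0-9.]+)\\)",
               line)
  g <- regmatches(line, m)[[1]]
  if (length(g) != 7L) parse_error("not an RNAplex duplex line")
  halves <- strsplit(g[2], "&", fixed = TRUE)[[1]]
  if (length(halves) != 2L) parse_error("dot-bracket lacks the '&' strand separator")
  qs <- as.integer(g[3]); qe <- as.integer(g[4])
  ts <- as.integer(g[5]); te <- as.integer(g[6])
  open_pos <- qs + which(strsplit(halves[1], NULL)[[1]] == "(") - 1L
  close_pos <- ts + which(strsplit(halves[2], NULL)[[1]] == ")") - 1L
  if (length(open_pos) != length(close_pos))
    parse_error("unbalanced duplex dot-bracket")
  pairs <- data.frame(pos_a = open_pos, pos_b = rev(close_pos))
  st <- structure_from_pairs(pairs)
  structure(list(pair = c(id_a, id_b),
                 a_region = c(qs, qe), b_region = c(ts, te),
                 pairs = st$pairs, bubbles = st$bubbles, segments = st$segments,
                 n_perfect_segments = nrow(st$segments),
                 score = as.numeric(g[7])),
            class = "duplex_structure")
}
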