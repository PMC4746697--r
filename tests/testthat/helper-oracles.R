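# Independent oracles and small utilities shared across the suite.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

transcript_df <- function(...) {
  seqs <- c(...)
  data.frame(id = names(seqs), seq = unname(seqs), length = nchar(seqs),
             stringsAsFactors = FALSE)
}

# Full local-alignment oracle for the antisense search: Biostrings
# Smith-Waterman on A vs revcomp(B), same scoring scheme, full sequences
# (no seeding, no windows).
sw_oracle_score <- function(a, b, match = 1, mismatch = -2,
                            gap_open = 5, gap_extend = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  as.numeric(Biostrings::pairwiseAlignment(
    a, revcomp(b), type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE))
}

pair_ok <- function(a, b, gu = TRUE) {
  switch(a,
         A = b == "T",
         T = b == "A" || (gu && b == "G"),
         G = b == "C" || (gu && b == "T"),
         C = b == "G",
         FALSE)
}

# Exhaustive-search oracle for the duplex objective: maximize
# pairs - lambda * interior-unpaired over all non-crossing monotone pairings
# of a and the reversed bottom strand br. g(i, j) = best region whose first
# pair is (i, j), explored over every possible next pair.
duplex_oracle_score <- function(a, br, lambda = 1, gu = TRUE) {
  av <- strsplit(a, NULL)[[1]]; bv <- strsplit(br, NULL)[[1]]
  n <- length(av); m <- length(bv)
  P <- matrix(FALSE, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) P[i, j] <- pair_ok(av[i], bv[j], gu)
  if (!any(P)) return(0)
  g <- matrix(-Inf, n, m)
  for (i in n:1) for (j in m:1) {
    if (!P[i, j]) next
    best_ext <- 0
    if (i < n && j < m) {
      for (i2 in (i + 1):n) for (j2 in (j + 1):m) {
        if (!P[i2, j2] || !is.finite(g[i2, j2])) next
        v <- g[i2, j2] - lambda * ((i2 - i - 1) + (j2 - j - 1))
        if (v > best_ext) best_ext <- v
      }
    }
    g[i, j] <- 1 + best_ext
  }
  max(g[P])
}

# Naive scan oracle for exact sense-strand mapping.
naive_map_starts <- function(read, tseq) {
  nr <- nchar(read); nt <- nchar(tseq)
  if (nr > nt) return(integer())
  which(vapply(seq_len(nt - nr + 1L),
               function(i) substr(tseq, i, i + nr - 1L) == read, logical(1)))
}

# Brute-force enumeration of every (register, run) combination for the
# phase-run search: for each register, every slot window is tested directly
# for full evidence and maximality.
phase_oracle <- function(segment, hits_a, hits_b, n, params) {
  res <- list()
  ha <- hits_a[hits_a$length == n & hits_a$start >= segment$a_start &
                 hits_a$end <= segment$a_end, , drop = FALSE]
  hb <- hits_b[hits_b$length == n & hits_b$start >= segment$b_start &
                 hits_b$end <= segment$b_end, , drop = FALSE]
  if (segment$length < params$min_region_len)
    return(data.frame(register = integer(), first_slot_start = integer(),
                      n_phases = integer()))
  for (r in 0:(n - 1L)) {
    if (segment$a_start + r + n - 1L > segment$a_end) next
    starts <- seq.int(segment$a_start + r, segment$a_end - n + 1L, by = n)
    anti <- segment$b_start + (segment$a_end - (starts + n - 3L))
    ev <- (starts %in% ha$start) | (anti %in% hb$start)
    k <- length(ev)
    for (s in seq_len(k)) for (e in s:k) {
      if (e - s + 1L < params$min_duplexes) next
      if (!all(ev[s:e])) next
      if (s > 1L && ev[s - 1L]) next
      if (e < k && ev[e + 1L]) next
      res[[length(res) + 1L]] <- data.frame(
        register = r, first_slot_start = starts[s], n_phases = e - s + 1L)
    }
  }
  if (length(res)) do.call(rbind, res)
  else data.frame(register = integer(), first_slot_start = integer(),
                  n_phases = integer())
}

# Synthetic mapped-hit rows for phase tests (no sequences needed beyond
# uniqueness).
fake_hits <- function(transcript_id, starts, n, library = "leaf") {
  if (length(starts) == 0L) return(natphase:::empty_mapped())
  data.frame(read_id = sprintf("%s_h%d", transcript_id, seq_along(starts)),
             seq = sprintf("S%s%d", transcript_id, starts), length = n,
             count = 1, library = library, transcript_id = transcript_id,
             start = as.integer(starts), end = as.integer(starts) + n - 1L,
             stringsAsFactors = FALSE)
}

run_fixture_pipeline <- function(fx, ...) {
  run_pipeline(run_config(transcripts = fx$transcripts, srna = fx$srna,
                          degradome = fx$degradome, quiet = TRUE, ...))
}
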