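#' Specification for a synthetic NAT / phased-sRNA fixture
#'
#' Describes one planted NAT pair (with optional defects), decoy transcripts,
#' phased sRNA reads laid out with 2-nt 3' overhang duplex geometry, and
#' degradome tags — all generated deterministically from a single seed with
#' exact ground-truth coordinates.
#'
#' Defect construction pins the duplex alignment: mismatch columns and bubble
#' inserts are built from bases that cannot pair (including G:U) with any
#' neighboring column, and four non-pairing guard columns flank the planted
#' region, so the optimal alignment and structure are unique and the truth
#' coordinates are exact.
#'
#' @param seed Integer seed driving all randomness.
#' @param region_len Length (bp) of the planted complementary core.
#' @param n_duplex Number of consecutive phased sRNA duplexes planted.
#' @param srna_len sRNA length n (nt).
#' @param register_offset Phase register r (nt offset of the first sense slot
#'   from the segment start; at least 2 so the first antisense overhang stays
#'   inside the region).
#' @param mismatches Core column positions carrying a mismatch (each becomes a
#'   size-1 bubble at the structure stage); pairwise distance must be >= 3.
#' @param bubble `NULL`, or `list(pos, a_len, b_len)`: an unpaired insertion of
#'   `a_len` nt in A (or `b_len` in B; one side only) after core column `pos`.
#' @param n_decoys Number of decoy transcripts, rejection-sampled to share no
#'   seed k-mer with the reverse complement of any other sequence.
#' @param decoy_len Length range of decoys.
#' @param flank_a,flank_b Flank lengths (5', 3') around the planted regions.
#' @param libraries Named numeric: sRNA library -> per-read count.
#' @param slot_strands Per-duplex evidence pattern: `"both"`, `"sense"` or
#'   `"antisense"` (recycled; default `"both"`).
#' @param degradome Generate degradome tags (default `TRUE`).
#' @param degradome_slots Which duplex slots receive a 5'-end degradome tag.
#' @param degradome_len Degradome tag length (nt).
#' @param deg_libraries Named numeric: degradome library -> per-tag count.
#' @param seed_len Seed length used for decoy/flank rejection sampling.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, region_len = 120L, n_duplex = 4L,
                         srna_len = 21L, register_offset = 2L,
                         mismatches = integer(), bubble = NULL,
                         n_decoys = 5L, decoy_len = c(150L, 300L),
                         flank_a = c(60L, 60L), flank_b = c(40L, 40L),
                         libraries = c(leaf = 10), slot_strands = "both",
                         degradome = TRUE, degradome_slots = 1L,
                         degradome_len = 20L, deg_libraries = c(root = 5),
                         seed_len = 12L) {
  stopifnot(region_len > srna_len + 2L, register_offset >= 0L,
            n_duplex >= 1L, length(libraries) >= 1L)
  defects <- c(mismatches, if (!is.null(bubble)) bubble$pos)
  if (length(defects)) {
    if (any(defects < 3L) || any(defects > region_len - 3L))
      stop("defect positions must lie strictly inside the core region")
    if (length(defects) > 1L && min(diff(sort(defects))) < 3L)
      stop("defect positions must be at least 3 nt apart")
  }
  if (!is.null(bubble)) {
    bubble <- list(pos = as.integer(bubble$pos),
                   a_len = as.integer(bubble$a_len %||% 0L),
                   b_len = as.integer(bubble$b_len %||% 0L))
    if (bubble$a_len < 0L || bubble$b_len < 0L ||
        bubble$a_len + bubble$b_len < 1L)
      stop("bubble must insert at least one unpaired base")
    if (min(bubble$a_len, bubble$b_len) > 0L)
      stop("bubble inserts on one strand only (a_len or b_len)")
  }
  structure(list(seed = as.integer(seed), region_len = as.integer(region_len),
                 n_duplex = as.integer(n_duplex), srna_len = as.integer(srna_len),
                 register_offset = as.integer(register_offset),
                 mismatches = sort(as.integer(mismatches)), bubble = bubble,
                 n_decoys = as.integer(n_decoys),
                 decoy_len = as.integer(decoy_len),
                 flank_a = as.integer(flank_a), flank_b = as.integer(flank_b),
                 libraries = libraries,
                 slot_strands = rep_len(slot_strands, n_duplex),
                 degradome = isTRUE(degradome),
                 degradome_slots = as.integer(degradome_slots),
                 degradome_len = as.integer(degradome_len),
                 deg_libraries = deg_libraries,
                 seed_len = as.integer(seed_len)),
            class = "fixture_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
# duplex partners including G:U wobble
PARTNERS <- list(A = "T", C = "G", G = c("C", "T"), T = c("A", "G"))

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

shares_kmer <- function(x, y, k) {
  # any exact k-mer shared between x and y?
  kx <- kmer_positions(x, k)$kmer
  ky <- kmer_positions(y, k)$kmer
  length(kx) > 0 && length(ky) > 0 && any(kx %in% ky)
}

# Core generator (RNG already seeded by the caller). Builds the column-space
# strands u (A core) and v (facing B bases), applies defects, and derives
# exact truth coordinates.
gen_nat_pair <- function(spec) {
  L <- spec$region_len
  u <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  for (p in spec$mismatches) {
    u[p - 1L] <- sample(c("A", "T"), 1L)
    u[p + 1L] <- sample(c("A", "T"), 1L)
    u[p] <- "C"
  }
  q <- if (is.null(spec$bubble)) NA_integer_ else spec$bubble$pos
  if (!is.na(q)) {
    u[q] <- sample(c("A", "T"), 1L)
    u[q + 1L] <- sample(c("A", "T"), 1L)
  }
  v <- unname(COMP[u])
  for (p in spec$mismatches) v[p] <- "C"
  a_len <- if (is.na(q)) 0L else spec$bubble$a_len
  b_len <- if (is.na(q)) 0L else spec$bubble$b_len
  u2 <- if (!is.na(q) && a_len > 0L) append(u, rep("C", a_len), after = q) else u
  v2 <- if (!is.na(q) && b_len > 0L) append(v, rep("C", b_len), after = q) else v

  core_a <- paste(u2, collapse = "")
  region_b <- paste(rev(v2), collapse = "")

  guard <- function(side_len) {
    # random flank whose 4 bases adjacent to the region are non-pairing 'A'
    flank <- sample(c("A", "C", "G", "T"), side_len, replace = TRUE)
    flank
  }
  for (try in 1:100) {
    fa1 <- guard(spec$flank_a[1]); fa2 <- guard(spec$flank_a[2])
    fb1 <- guard(spec$flank_b[1]); fb2 <- guard(spec$flank_b[2])
    fa1[(length(fa1) - 3L):length(fa1)] <- "A"
    fa2[1:4] <- "A"
    fb1[(length(fb1) - 3L):length(fb1)] <- "A"
    fb2[1:4] <- "A"
    a <- paste0(paste(fa1, collapse = ""), core_a, paste(fa2, collapse = ""))
    b <- paste0(paste(fb1, collapse = ""), region_b, paste(fb2, collapse = ""))
    # every shared seed k-mer between A and revcomp(B) must come from the core
    seeds <- find_seeds(a, revcomp(b), spec$seed_len)
    a_core <- c(spec$flank_a[1] + 1L, spec$flank_a[1] + nchar(core_a))
    ok <- all(seeds$i >= a_core[1] & seeds$i + spec$seed_len - 1L <= a_core[2])
    if (ok && nrow(seeds) > 0L) break
    if (try == 100L) stop("could not sample non-interacting flanks")
  }

  a_start <- spec$flank_a[1] + 1L
  b_start <- spec$flank_b[1] + 1L
  len_v2 <- length(v2)
  # map core column c to transcript coordinates
  a_pos <- function(c) a_start + c - 1L + ifelse(!is.na(q) & c > q, a_len, 0L)
  b_pos <- function(c) {
    col_v <- c + ifelse(!is.na(q) & c > q, b_len, 0L)
    b_start + (len_v2 - col_v)
  }

  # perfect segments: split 1..L at mismatch columns and at the bubble cut
  keep <- setdiff(seq_len(L), spec$mismatches)
  brk <- diff(keep) > 1L
  if (!is.na(q)) brk <- brk | keep[-length(keep)] == q
  grp <- cumsum(c(1L, as.integer(brk)))
  segs <- split(keep, grp)
  segments <- do.call(rbind, lapply(segs, function(cc) data.frame(
    a_start = a_pos(min(cc)), a_end = a_pos(max(cc)),
    b_start = b_pos(max(cc)), b_end = b_pos(min(cc)),
    length = length(cc))))
  segments <- segments[order(segments$a_start), , drop = FALSE]
  rownames(segments) <- NULL

  bubble_sizes <- c(rep(1L, length(spec$mismatches)),
                    if (!is.na(q)) max(a_len, b_len))
  n_mm <- length(spec$mismatches)
  aln_len <- L + a_len + b_len
  block_lens <- if (is.na(q)) aln_len else c(q, L - q)
  truth <- list(
    match = data.frame(
      id_a = "natA", id_b = "natB",
      a_start = a_start, a_end = a_start + nchar(core_a) - 1L,
      b_start = b_start, b_end = b_start + nchar(region_b) - 1L,
      aln_len = aln_len, identity = (L - n_mm) / aln_len,
      longest_contig_block = max(block_lens),
      score = (L - n_mm) - 2 * n_mm -
        (if (is.na(q)) 0 else 5 + 2 * (a_len + b_len)),
      stringsAsFactors = FALSE),
    segments = segments,
    bubble_sizes = sort(unname(bubble_sizes)),
    is_cis = length(bubble_sizes) == 0L,
    region_len = L, a_len = a_len, b_len = b_len)

  list(transcripts = data.frame(id = c("natA", "natB"), seq = c(a, b),
                                length = c(nchar(a), nchar(b)),
                                stringsAsFactors = FALSE),
       truth = truth)
}

gen_decoys <- function(spec, existing) {
  if (spec$n_decoys == 0L)
    return(data.frame(id = character(), seq = character(), length = integer(),
                      stringsAsFactors = FALSE))
  seqs <- existing
  out <- character(spec$n_decoys)
  for (d in seq_len(spec$n_decoys)) {
    len <- sample(spec$decoy_len[1]:spec$decoy_len[2], 1L)
    for (try in 1:200) {
      cand <- random_dna(len)
      bad <- any(vapply(seqs, function(s)
        shares_kmer(cand, revcomp(s), spec$seed_len), logical(1)))
      if (!bad) break
      if (try == 200L) stop("could not sample a seed-free decoy")
    }
    out[d] <- cand
    seqs <- c(seqs, cand)
  }
  data.frame(id = sprintf("decoy%02d", seq_len(spec$n_decoys)), seq = out,
             length = nchar(out), stringsAsFactors = FALSE)
}

#' Generate a synthetic NAT pair with ground truth
#'
#' @param spec A [fixture_spec()].
#' @return A list with `transcripts` (the two NAT transcripts, IDs `natA`,
#'   `natB`) and `truth` (expected complementary match, perfect segments,
#'   bubble sizes, cis flag). Same seed, same bytes.
#' @export
make_nat_pair <- function(spec) {
  with_local_seed(spec$seed, gen_nat_pair(spec))
}

# Phased reads are deterministic substrings of the planted transcripts:
# sense slot j starts at i_j = seg_start + r + (j-1) n; its antisense partner
# is the B substring opposing sense coordinates [i_j - 2, i_j + n - 3]
# (2-nt 3' overhangs at both duplex ends).
gen_phased_reads <- function(pair, spec) {
  n <- spec$srna_len; k <- spec$n_duplex; r <- spec$register_offset
  truth <- pair$truth
  seg <- truth$segments[which.max(truth$segments$length), ]
  if (r < 2L) stop("register_offset must be >= 2 so the first antisense overhang stays inside the region")
  if (r + k * n > seg$length)
    stop(sprintf("%d duplexes of %d nt at register %d do not fit in the %d-bp segment",
                 k, n, r, seg$length))
  a <- pair$transcripts$seq[1]; b <- pair$transcripts$seq[2]
  starts <- seg$a_start + r + (seq_len(k) - 1L) * n
  anti_b <- seg$b_start + (seg$a_end - (starts + n - 3L))
  strands <- spec$slot_strands
  base <- list()
  for (j in seq_len(k)) {
    if (strands[j] %in% c("both", "sense"))
      base[[length(base) + 1L]] <- data.frame(
        id = sprintf("sr%02ds", j), seq = substr(a, starts[j], starts[j] + n - 1L),
        slot = j, strand = "sense", stringsAsFactors = FALSE)
    if (strands[j] %in% c("both", "antisense"))
      base[[length(base) + 1L]] <- data.frame(
        id = sprintf("sr%02da", j), seq = substr(b, anti_b[j], anti_b[j] + n - 1L),
        slot = j, strand = "antisense", stringsAsFactors = FALSE)
  }
  base <- do.call(rbind, base)
  reads <- do.call(rbind, lapply(names(spec$libraries), function(lib) {
    data.frame(id = paste0(lib, "_", base$id), seq = base$seq,
               length = nchar(base$seq), count = unname(spec$libraries[[lib]]),
               library = lib, kind = "srna", stringsAsFactors = FALSE)
  }))

  tags <- NULL; deg_truth <- NULL
  if (spec$degradome) {
    dl <- spec$degradome_len
    sense_slots <- intersect(spec$degradome_slots,
                             which(strands %in% c("both", "sense")))
    anti_slots <- intersect(spec$degradome_slots, which(strands == "antisense"))
    pos_a <- starts[sense_slots]
    pos_b <- anti_b[anti_slots]
    sense_det <- which(strands %in% c("both", "sense"))
    term_a <- if (length(sense_det)) max(starts[sense_det]) + n else NULL
    tag_pos <- data.frame(
      transcript_id = c(rep("natA", length(pos_a)), rep("natB", length(pos_b)),
                        if (!is.null(term_a)) "natA"),
      pos = c(pos_a, pos_b, term_a),
      slot = c(as.character(sense_slots), as.character(anti_slots),
               if (!is.null(term_a)) "terminus"),
      strand = c(rep("sense", length(pos_a)), rep("antisense", length(pos_b)),
                 if (!is.null(term_a)) "sense"),
      stringsAsFactors = FALSE)
    seqs <- ifelse(tag_pos$transcript_id == "natA",
                   substring(a, tag_pos$pos, tag_pos$pos + dl - 1L),
                   substring(b, tag_pos$pos, tag_pos$pos + dl - 1L))
    if (any(nchar(seqs) < dl)) stop("degradome tag extends past the transcript")
    tags <- do.call(rbind, lapply(names(spec$deg_libraries), function(lib) {
      data.frame(id = sprintf("%s_dg%02d", lib, seq_len(nrow(tag_pos))),
                 seq = seqs, length = dl,
                 count = unname(spec$deg_libraries[[lib]]), library = lib,
                 kind = "degradome", stringsAsFactors = FALSE)
    }))
    deg_truth <- tag_pos
  }

  cluster <- list(
    id_a = "natA", id_b = "natB",
    segment = seg, srna_len = n, register = r %% n,
    slot_starts = starts, anti_b_starts = anti_b,
    slot_strands = strands, n_phases = k,
    n_srnas = nrow(base),
    detectable = k >= 4L)
  list(reads = reads, tags = tags, cluster = cluster, degradome = deg_truth)
}

#' Generate phased sRNA reads (and degradome tags) for a planted pair
#'
#' @param pair Result of [make_nat_pair()].
#' @param spec The same [fixture_spec()].
#' @return A list: `reads` (collapsed sRNA rows per library), `tags`
#'   (degradome rows or `NULL`), `cluster` (ground-truth cluster geometry),
#'   `degradome` (expected evidence positions).
#' @export
make_phased_reads <- function(pair, spec) gen_phased_reads(pair, spec)

#' Generate a complete synthetic input bundle with ground truth
#'
#' One planted NAT pair (optionally with mismatch/bubble defects), seed-free
#' decoys, phased sRNA libraries and degradome tags, plus the truth records
#' every stage is expected to recover. Deterministic in `spec$seed`.
#'
#' @param spec A [fixture_spec()].
#' @param with_reads Generate sRNA/degradome reads (set `FALSE` for NAT-only
#'   fixtures, e.g. when defects leave no segment large enough for phasing).
#' @return A list: `transcripts`, `srna`, `srna_stats`, `degradome`,
#'   `degradome_stats`, `truth` (match, segments, bubbles, cis flag, cluster,
#'   degradome evidence), `spec`.
#' @export
make_fixture <- function(spec, with_reads = TRUE) {
  with_local_seed(spec$seed, {
    pair <- gen_nat_pair(spec)
    decoys <- gen_decoys(spec, pair$transcripts$seq)
    transcripts <- rbind(pair$transcripts, decoys)
    phased <- if (with_reads) gen_phased_reads(pair, spec) else NULL
    truth <- pair$truth
    truth$cluster <- phased$cluster
    truth$degradome <- phased$degradome
    srna_stats <- if (!is.null(phased)) {
      agg <- tapply(phased$reads$count, phased$reads$library, sum)
      data.frame(library = names(agg), total_reads = as.numeric(agg),
                 stringsAsFactors = FALSE)
    } else NULL
    deg_stats <- if (!is.null(phased$tags)) {
      agg <- tapply(phased$tags$count, phased$tags$library, sum)
      data.frame(library = names(agg), total_reads = as.numeric(agg),
                 stringsAsFactors = FALSE)
    } else NULL
    list(transcripts = transcripts, srna = phased$reads,
         srna_stats = srna_stats, degradome = phased$tags,
         degradome_stats = deg_stats, truth = truth, spec = spec)
  })
}

#' Write a fixture bundle to disk in the pipeline's input formats
#'
#' @param fx A [make_fixture()] bundle.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths (`transcripts`, per-library `srna_*`
#'   and `degradome_*` collapsed FASTA, `truth` JSON), invisibly.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(transcripts = file.path(dir, "transcripts.fa"))
  write_fasta(fx$transcripts, paths$transcripts)
  if (!is.null(fx$srna)) {
    for (lib in unique(fx$srna$library)) {
      p <- file.path(dir, sprintf("srna_%s.fa", lib))
      write_collapsed_reads(fx$srna[fx$srna$library == lib, ], p)
      paths[[paste0("srna_", lib)]] <- p
    }
  }
  if (!is.null(fx$degradome)) {
    for (lib in unique(fx$degradome$library)) {
      p <- file.path(dir, sprintf("degradome_%s.fa", lib))
      write_collapsed_reads(fx$degradome[fx$degradome$library == lib, ], p)
      paths[[paste0("degradome_", lib)]] <- p
    }
  }
  paths$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(fx$truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(paths)
}
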