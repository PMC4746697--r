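#' Parameters for phased nat-siRNA detection
#'
#' @param min_region_len Minimum perfectly annealed region length searched, in
#'   bp. The default 81 implements the "longer than 80 bp" rule: an 80-bp
#'   segment is skipped, an 81-bp segment is searched.
#' @param min_duplexes Minimum number of consecutive evidenced phase slots
#'   (sRNA duplexes) for a reported cluster (default 4).
#' @param srna_len_set sRNA lengths (nt) searched; one length per phase grid,
#'   lengths are searched independently (default 21 and 24).
#' @param evidence_mode `"either"` (default): a phase slot is evidenced by a
#'   read on either strand of the duplex; `"both"` requires both strands.
#' @param allow_edge_overhang If `TRUE`, the antisense partner's 2-nt 3'
#'   overhang may extend up to 2 nt beyond the perfect segment; by default the
#'   whole partner footprint must stay inside the annealed region.
#' @return A list of class `phasing_params`. The 2-nt 3' overhang of Dicer
#'   processing is fixed, not a parameter.
#' @export
phasing_params <- function(min_region_len = 81L, min_duplexes = 4L,
                           srna_len_set = c(21L, 24L),
                           evidence_mode = c("either", "both"),
                           allow_edge_overhang = FALSE) {
  stopifnot(min_duplexes >= 2L, min_region_len >= 1L, all(srna_len_set >= 15L))
  structure(list(min_region_len = as.integer(min_region_len),
                 min_duplexes = as.integer(min_duplexes),
                 srna_len_set = sort(unique(as.integer(srna_len_set))),
                 evidence_mode = match.arg(evidence_mode),
                 allow_edge_overhang = isTRUE(allow_edge_overhang),
                 overhang = 2L),
            class = "phasing_params")
}

empty_mapped <- function() {
  data.frame(read_id = character(), seq = character(), length = integer(),
             count = numeric(), library = character(),
             transcript_id = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

#' Strand-specific exact mapping of collapsed reads onto transcripts
#'
#' Reports every exact sense-orientation occurrence of each read on each
#' transcript (multi-mapping allowed, every locus counts). A read matching the
#' reverse complement of a transcript is not reported there: in a NAT pair it
#' is a sense-strand substring of the partner transcript, where it is found.
#'
#' @param reads Collapsed-read `data.frame` (from [read_collapsed_reads()]).
#' @param transcripts Transcript `data.frame` (typically the NAT transcripts).
#' @return A `data.frame` of perfect sense hits: `read_id`, `seq`, `length`,
#'   `count`, `library`, `transcript_id`, `start`, `end` (1-based inclusive).
#' @export
map_srnas <- function(reads, transcripts) {
  if (is.null(reads) || nrow(reads) == 0L || nrow(transcripts) == 0L)
    return(empty_mapped())
  out <- list()
  for (t in seq_len(nrow(transcripts))) {
    subject <- Biostrings::DNAString(transcripts$seq[t])
    for (r in seq_len(nrow(reads))) {
      if (reads$length[r] > transcripts$length[t]) next
      hits <- Biostrings::matchPattern(reads$seq[r], subject, fixed = TRUE)
      st <- Biostrings::start(hits)
      if (length(st) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        read_id = reads$id[r], seq = reads$seq[r], length = reads$length[r],
        count = reads$count[r], library = reads$library[r],
        transcript_id = transcripts$id[t],
        start = st, end = st + reads$length[r] - 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty_mapped())
  res <- do.call(rbind, out)
  res <- res[order(res$transcript_id, res$start, res$read_id, res$library), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Map a position across a perfectly annealed segment
#'
#' Converts a position on transcript A inside a perfect segment to the
#' opposing position on transcript B: `b_start + (a_end - x)`. The map is an
#' involution of the segment.
#'
#' @param x Position on transcript A, within `[a_start, a_end]`.
#' @param segment A perfect segment (list or 1-row data.frame with `a_start`,
#'   `a_end`, `b_start`, `b_end`).
#' @return The corresponding position on transcript B.
#' @export
cross_coordinate <- function(x, segment) {
  if (any(x < segment$a_start | x > segment$a_end))
    stop("position outside the perfect segment")
  segment$b_start + (segment$a_end - x)
}

# Slot geometry for register r (0-based) in a segment, sRNA length n.
# Sense slot k occupies [i, i + n - 1]; its antisense partner occupies
# sense-coordinates [i - 2, i + n - 3] (the 2-nt 3' overhangs at both duplex
# ends force the antisense 5' end to sense-coordinate i + n - 3).
slot_starts <- function(segment, n, r) {
  first <- segment$a_start + r
  if (first + n - 1L > segment$a_end) return(integer())
  seq.int(first, segment$a_end - n + 1L, by = n)
}

#' Enumerate phased runs within one perfect segment
#'
#' For every phase register, builds the grid of duplex slots of sRNA length
#' `n`, marks each slot evidenced when a perfectly mapped read's 5' end
#' coincides with the slot's 5' end on the sense strand (transcript A) or on
#' the antisense strand (a sense hit on partner transcript B whose 5' end maps
#' across the segment to sense-coordinate `i + n - 3`), and reports every
#' maximal run of at least `params$min_duplexes` consecutive evidenced slots.
#'
#' @param segment A perfect segment (with `a_start`, `a_end`, `b_start`,
#'   `b_end`, `length`).
#' @param hits_a Mapped reads on transcript A (sense strand).
#' @param hits_b Mapped reads on transcript B (the antisense evidence).
#' @param n sRNA length (nt) of this grid.
#' @param params A [phasing_params()] object.
#' @return A list of clusters; each has `srna_len`, `register`, `n_phases`,
#'   `slots` (per-slot intervals and evidence), `hits` (reads with slot index
#'   and strand), and `n_srnas` (distinct read sequences).
#' @export
enumerate_phase_runs <- function(segment, hits_a, hits_b, n,
                                 params = phasing_params()) {
  if (segment$length < params$min_region_len) return(list())
  if (segment$length < n + 2L) return(list())
  ha <- hits_a[hits_a$length == n &
                 hits_a$start >= segment$a_start &
                 hits_a$end <= segment$a_end, , drop = FALSE]
  slack <- if (params$allow_edge_overhang) params$overhang else 0L
  hb <- hits_b[hits_b$length == n &
                 hits_b$start >= segment$b_start &
                 hits_b$end <= segment$b_end + slack, , drop = FALSE]
  clusters <- list()
  for (r in 0:(n - 1L)) {
    starts <- slot_starts(segment, n, r)
    if (length(starts) == 0L) next
    # antisense partner 5' end on B for sense slot starting at i
    anti_b <- segment$b_start + (segment$a_end - (starts + n - 3L))
    sense_ev <- starts %in% ha$start
    anti_ev <- anti_b %in% hb$start
    ev <- if (params$evidence_mode == "either") sense_ev | anti_ev
          else sense_ev & anti_ev
    runs <- rle(ev)
    stops <- cumsum(runs$lengths)
    for (q in which(runs$values & runs$lengths >= params$min_duplexes)) {
      idx <- (stops[q] - runs$lengths[q] + 1L):stops[q]
      slots <- data.frame(
        index = seq_along(idx),
        sense_start = starts[idx], sense_end = starts[idx] + n - 1L,
        anti_b_start = anti_b[idx], anti_b_end = anti_b[idx] + n - 1L,
        sense_evidenced = sense_ev[idx], anti_evidenced = anti_ev[idx])
      ha_sub <- ha[ha$start %in% starts[idx], , drop = FALSE]
      hb_sub <- hb[hb$start %in% anti_b[idx], , drop = FALSE]
      ha_sub$strand <- rep("sense", nrow(ha_sub))
      hb_sub$strand <- rep("antisense", nrow(hb_sub))
      ha_sub$slot_index <- match(ha_sub$start, starts[idx])
      hb_sub$slot_index <- match(hb_sub$start, anti_b[idx])
      hits <- rbind(ha_sub, hb_sub)
      clusters[[length(clusters) + 1L]] <- list(
        segment = segment, srna_len = n, register = r,
        first_slot_start = starts[idx[1]],
        n_phases = length(idx), slots = slots, hits = hits,
        n_srnas = length(unique(hits$seq)))
    }
  }
  clusters
}

#' Detect phased nat-siRNA clusters on validated NAT pairs
#'
#' Restricts NATs to retained pairs carrying perfectly annealed segments of at
#' least `params$min_region_len` bp, maps the sRNA reads strand-specifically,
#' and runs the phase-run search on every qualifying segment for every sRNA
#' length in `params$srna_len_set`. Evidence is the union across the supplied
#' libraries; per-library presence is retained for reporting.
#'
#' @param nats List of `nat_pair` objects (retained).
#' @param transcripts Transcript `data.frame`.
#' @param reads Collapsed sRNA reads (all libraries row-bound).
#' @param lib_stats Library stats `data.frame` (`library`, `total_reads`).
#' @param params A [phasing_params()] object.
#' @param mapped Optional pre-computed [map_srnas()] result.
#' @return A list of `phased_cluster` objects; each adds `id_a`, `id_b`,
#'   `cluster_id`, `libraries` (with presence), and `expression` (per distinct
#'   sRNA and library: count and RPM) to the [enumerate_phase_runs()] fields.
#' @export
find_phased_clusters <- function(nats, transcripts, reads, lib_stats,
                                 params = phasing_params(), mapped = NULL) {
  nats <- Filter(function(x) isTRUE(x$retained) &&
                   any(x$segments$length >= params$min_region_len), nats)
  if (length(nats) == 0L) return(list())
  ids <- unique(unlist(lapply(nats, function(x) c(x$id_a, x$id_b))))
  if (is.null(mapped))
    mapped <- map_srnas(reads, transcripts[transcripts$id %in% ids, , drop = FALSE])
  totals <- setNames(lib_stats$total_reads, lib_stats$library)
  clusters <- list()
  for (nat in nats) {
    hits_a <- mapped[mapped$transcript_id == nat$id_a, , drop = FALSE]
    hits_b <- mapped[mapped$transcript_id == nat$id_b, , drop = FALSE]
    segs <- nat$segments[nat$segments$length >= params$min_region_len, ,
                         drop = FALSE]
    for (s in seq_len(nrow(segs))) {
      for (n in params$srna_len_set) {
        found <- enumerate_phase_runs(segs[s, ], hits_a, hits_b, n, params)
        for (cl in found) {
          cl$id_a <- nat$id_a
          cl$id_b <- nat$id_b
          cl$cluster_id <- sprintf("%s|%s|%d-%d|n%d|r%d|p%d",
                                   nat$id_a, nat$id_b,
                                   cl$segment$a_start, cl$segment$a_end,
                                   n, cl$register, cl$first_slot_start)
          cl$libraries <- sort(unique(cl$hits$library))
          if (nrow(cl$hits)) {
            ex <- unique(cl$hits[, c("read_id", "seq", "library", "count", "strand")])
            ex$rpm <- ifelse(is.na(totals[ex$library]), NA_real_,
                             ex$count / totals[ex$library] * 1e6)
            rownames(ex) <- NULL
            cl$expression <- ex
          } else cl$expression <- NULL
          class(cl) <- "phased_cluster"
          clusters[[length(clusters) + 1L]] <- cl
        }
      }
    }
  }
  ord <- order(vapply(clusters, function(x) x$cluster_id, character(1)))
  clusters[ord]
}

#' @export
print.phased_cluster <- function(x, ...) {
  cat(sprintf("phased cluster %s: %d-nt register %d, %d phases, %d sRNA(s), libraries: %s\n",
              x$cluster_id, x$srna_len, x$register, x$n_phases, x$n_srnas,
              paste(x$libraries, collapse = ", ")))
  invisible(x)
}

#' Summarize phased clusters as a table
#' @param clusters List of `phased_cluster` objects.
#' @return One row per cluster.
#' @export
cluster_table <- function(clusters) {
  if (length(clusters) == 0L)
    return(data.frame(cluster_id = character(), id_a = character(),
                      id_b = character(), seg_a_start = integer(),
                      seg_a_end = integer(), seg_b_start = integer(),
                      seg_b_end = integer(), srna_len = integer(),
                      register = integer(), first_slot_start = integer(),
                      n_phases = integer(), n_srnas = integer(),
                      libraries = character(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(clusters, function(x) data.frame(
    cluster_id = x$cluster_id, id_a = x$id_a, id_b = x$id_b,
    seg_a_start = x$segment$a_start, seg_a_end = x$segment$a_end,
    seg_b_start = x$segment$b_start, seg_b_end = x$segment$b_end,
    srna_len = x$srna_len, register = x$register,
    first_slot_start = x$first_slot_start,
    n_phases = x$n_phases, n_srnas = x$n_srnas,
    libraries = paste(x$libraries, collapse = ","),
    stringsAsFactors = FALSE)))
}

#' Read Bowtie legacy mapping output as sense hits
#'
#' Converts default Bowtie output (read id, strand, reference, 0-based offset,
#' sequence, ...) into the mapped-read layout of [map_srnas()]; only
#' plus-strand records are kept (strand-specific mapping).
#'
#' @param path Path to a Bowtie legacy output file.
#' @param reads Optional collapsed-read `data.frame` used to recover counts
#'   and library labels by read id.
#' @return A mapped-read `data.frame`.
#' @export
read_bowtie_legacy <- function(path, reads = NULL) {
  tb <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tb) < 5L) parse_error(sprintf("%s: expected >= 5 bowtie columns", path))
  tb <- tb[tb[[2]] == "+", , drop = FALSE]
  if (nrow(tb) == 0L) return(empty_mapped())
  res <- data.frame(read_id = tb[[1]], seq = fold_seq(tb[[5]]),
                    length = nchar(tb[[5]]), count = NA_real_,
                    library = NA_character_, transcript_id = tb[[3]],
                    start = tb[[4]] + 1L,
                    end = tb[[4]] + nchar(tb[[5]]),
                    stringsAsFactors = FALSE)
  if (!is.null(reads)) {
    m <- match(res$read_id, reads$id)
    res$count <- reads$count[m]
    res$library <- reads$library[m]
  }
  res[order(res$transcript_id, res$start, res$read_id), , drop = FALSE]
}
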