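#' Map degradome tags onto NATs carrying phased clusters
#'
#' Strand-specific perfect-match mapping of degradome signatures, restricted
#' to the transcripts that carry at least one phased nat-siRNA cluster.
#'
#' @param tags Collapsed degradome reads (`data.frame`).
#' @param transcripts Transcript `data.frame`.
#' @param clusters Phased clusters from [find_phased_clusters()].
#' @return A mapped-read `data.frame` (see [map_srnas()]).
#' @export
map_degradome <- function(tags, transcripts, clusters) {
  ids <- unique(unlist(lapply(clusters, function(x) c(x$id_a, x$id_b))))
  map_srnas(tags, transcripts[transcripts$id %in% ids, , drop = FALSE])
}

empty_evidence <- function() {
  data.frame(tag_id = character(), library = character(),
             transcript_id = character(), five_prime_pos = integer(),
             count = numeric(), rpm = numeric(), cluster_id = character(),
             slot = character(), strand = character(), stringsAsFactors = FALSE)
}

#' Attach degradome processing evidence to phased clusters
#'
#' A mapped degradome tag supports a phased nat-siRNA when its 5' end
#' coincides with the siRNA's 5' end on that transcript, and supports a
#' cluster terminus when its 5' end sits on the nucleotide immediately 3' of
#' the last phased siRNA of a strand (3' end + 1, searched on both strands).
#' One tag may support several clusters.
#'
#' @param mapped_tags [map_degradome()] result.
#' @param clusters Phased clusters.
#' @param lib_stats Degradome library stats (`library`, `total_reads`) for RPM.
#' @param window Positional tolerance in nt (default 0: exact 5'-end match).
#' @return A `data.frame` of evidence rows: `tag_id`, `library`,
#'   `transcript_id`, `five_prime_pos`, `count`, `rpm`, `cluster_id`, `slot`
#'   (slot index as character, or `"terminus"`), `strand`.
#' @export
assign_degradome_evidence <- function(mapped_tags, clusters, lib_stats = NULL,
                                      window = 0L) {
  if (length(clusters) == 0L || is.null(mapped_tags) || nrow(mapped_tags) == 0L)
    return(empty_evidence())
  totals <- if (is.null(lib_stats)) numeric()
            else setNames(lib_stats$total_reads, lib_stats$library)
  out <- list()
  add <- function(tags, cluster_id, slot, strand) {
    if (nrow(tags) == 0L) return()
    tot <- unname(totals[tags$library])
    out[[length(out) + 1L]] <<- data.frame(
      tag_id = tags$read_id, library = tags$library,
      transcript_id = tags$transcript_id, five_prime_pos = tags$start,
      count = tags$count,
      rpm = ifelse(is.na(tot), NA_real_, tags$count / tot * 1e6),
      cluster_id = cluster_id, slot = slot, strand = strand,
      stringsAsFactors = FALSE)
  }
  for (cl in clusters) {
    n <- cl$srna_len
    tags_a <- mapped_tags[mapped_tags$transcript_id == cl$id_a, , drop = FALSE]
    tags_b <- mapped_tags[mapped_tags$transcript_id == cl$id_b, , drop = FALSE]
    sense <- cl$slots[cl$slots$sense_evidenced, , drop = FALSE]
    anti <- cl$slots[cl$slots$anti_evidenced, , drop = FALSE]
    for (k in seq_len(nrow(sense)))
      add(tags_a[abs(tags_a$start - sense$sense_start[k]) <= window, , drop = FALSE],
          cl$cluster_id, as.character(sense$index[k]), "sense")
    for (k in seq_len(nrow(anti)))
      add(tags_b[abs(tags_b$start - anti$anti_b_start[k]) <= window, , drop = FALSE],
          cl$cluster_id, as.character(anti$index[k]), "antisense")
    # terminus: position immediately 3' of the last phased siRNA, per strand
    if (nrow(sense)) {
      term_a <- max(sense$sense_end) + 1L
      add(tags_a[abs(tags_a$start - term_a) <= window, , drop = FALSE],
          cl$cluster_id, "terminus", "sense")
    }
    if (nrow(anti)) {
      term_b <- max(anti$anti_b_end) + 1L
      add(tags_b[abs(tags_b$start - term_b) <= window, , drop = FALSE],
          cl$cluster_id, "terminus", "antisense")
    }
  }
  if (length(out) == 0L) return(empty_evidence())
  res <- do.call(rbind, out)
  res <- res[order(res$cluster_id, res$strand, res$five_prime_pos, res$tag_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Count degradome-supported siRNAs and clusters
#'
#' A phased siRNA is degradome-supported when at least one evidence row marks
#' its slot and strand; a cluster is supported when it has any evidence
#' (slot or terminus). Supported counts are always nested within the phased
#' counts.
#'
#' @param clusters Phased clusters.
#' @param evidence Evidence `data.frame` from [assign_degradome_evidence()].
#' @return A list: `n_supported_sirnas`, `n_supported_clusters`,
#'   `supported_cluster_ids`.
#' @export
degradome_support <- function(clusters, evidence) {
  if (length(clusters) == 0L)
    return(list(n_supported_sirnas = 0L, n_supported_clusters = 0L,
                supported_cluster_ids = character()))
  slot_ev <- evidence[evidence$slot != "terminus", , drop = FALSE]
  n_sirnas <- 0L
  for (cl in clusters) {
    ev <- slot_ev[slot_ev$cluster_id == cl$cluster_id, , drop = FALSE]
    if (nrow(ev) == 0L) next
    key_ev <- unique(paste(ev$slot, ev$strand))
    det <- c(paste(cl$slots$index[cl$slots$sense_evidenced], "sense"),
             paste(cl$slots$index[cl$slots$anti_evidenced], "antisense"))
    n_sirnas <- n_sirnas + sum(det %in% key_ev)
  }
  sup <- unique(evidence$cluster_id)
  list(n_supported_sirnas = n_sirnas,
       n_supported_clusters = length(sup),
       supported_cluster_ids = sort(sup))
}
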