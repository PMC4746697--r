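#' @title Sequence input/output for transcripts and collapsed reads
#' @name seqio
#' @description Readers and writers for the two FASTA dialects the pipeline
#'   consumes: plain transcript FASTA, and collapsed small-RNA / degradome
#'   reads whose headers carry an abundance suffix (`>{id}_x{count}`).
#'   All sequences are folded to the upper-case DNA alphabet (U becomes T) so
#'   a single alphabet serves alignment and mapping; N is legal but never
#'   matches or pairs with anything.
NULL

parse_error <- function(msg, line = NA_integer_) {
  where <- if (is.na(line)) "" else sprintf(" (line %d)", line)
  stop(errorCondition(paste0(msg, where),
                      class = c("natphase_parse_error", "error")))
}

fold_seq <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

check_alphabet <- function(seq, id, line = NA_integer_) {
  if (grepl("[^ACGTN]", seq))
    parse_error(sprintf("record '%s': sequence contains characters outside A/C/G/T/U/N", id),
                line)
}

# Shared light FASTA scanner: returns data.frame(id, seq, line). Line-numbered
# errors are part of the reader contract, which rules out readDNAStringSet
# here; tests cross-check against Biostrings on well-formed files.
scan_fasta <- function(path) {
  if (!file.exists(path)) parse_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) parse_error(sprintf("%s: no FASTA records", path), 1L)
  if (hdr[1] != 1L && any(nzchar(trimws(lines[seq_len(hdr[1] - 1L)]))))
    parse_error(sprintf("%s: sequence data before first header", path), 1L)
  ends <- c(hdr[-1] - 1L, length(lines))
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  seqs <- character(length(hdr))
  for (k in seq_along(hdr)) {
    if (!nzchar(ids[k])) parse_error(sprintf("%s: empty FASTA header", path), hdr[k])
    if (ends[k] < hdr[k] + 1L)
      parse_error(sprintf("%s: record '%s' has no sequence", path, ids[k]), hdr[k])
    body <- lines[(hdr[k] + 1L):ends[k]]
    seqs[k] <- gsub("[ \t]", "", paste0(body, collapse = ""))
    if (!nzchar(seqs[k]))
      parse_error(sprintf("%s: record '%s' has an empty sequence", path, ids[k]), hdr[k])
  }
  data.frame(id = ids, seq = seqs, line = hdr, stringsAsFactors = FALSE)
}

#' Read assembled transcripts from FASTA
#'
#' @param path Path to a FASTA file of de novo assembled transcripts.
#' @return A `data.frame` with columns `id`, `seq` (upper-case DNA, U folded
#'   to T) and `length`, in file order.
#' @details Duplicate IDs, empty sequences and non-nucleotide characters raise
#'   a parse error naming the record and line.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">t1", "ACGU"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  rec <- scan_fasta(path)
  rec$seq <- fold_seq(rec$seq)
  for (k in seq_len(nrow(rec))) check_alphabet(rec$seq[k], rec$id[k], rec$line[k])
  dup <- duplicated(rec$id)
  if (any(dup)) {
    k <- which(dup)[1]
    parse_error(sprintf("%s: duplicate transcript ID '%s'", path, rec$id[k]), rec$line[k])
  }
  data.frame(id = rec$id, seq = rec$seq, length = nchar(rec$seq),
             stringsAsFactors = FALSE)
}

#' Write transcripts to FASTA
#'
#' @param transcripts A transcript `data.frame` (columns `id`, `seq`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(transcripts, path) {
  set <- Biostrings::DNAStringSet(setNames(transcripts$seq, transcripts$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a collapsed small-RNA or degradome library
#'
#' Collapsed reads are deduplicated sequences stored once with an abundance
#' count in the header: `>{id}_x{count}`.
#'
#' @param path Path to the collapsed-FASTA file.
#' @param library Library label (e.g. organ or replicate name).
#' @param kind `"srna"` or `"degradome"`.
#' @param min_len,max_len Legal sequence-length bounds for `kind = "srna"`
#'   (defaults 15 and 35 nt); degradome tags are not length-restricted.
#' @return A list with `reads` (`data.frame`: `id`, `seq`, `length`, `count`,
#'   `library`, `kind`) and `stats` (`data.frame`: `library`, `total_reads`,
#'   the RPM denominator).
#' @export
read_collapsed_reads <- function(path, library, kind = c("srna", "degradome"),
                                 min_len = 15L, max_len = 35L) {
  kind <- match.arg(kind)
  rec <- scan_fasta(path)
  m <- regmatches(rec$id, regexec("^(.*)_x([0-9]+)$", rec$id))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    k <- which(bad)[1]
    parse_error(sprintf("%s: header '%s' lacks the _x{count} abundance suffix",
                        path, rec$id[k]), rec$line[k])
  }
  ids <- vapply(m, `[`, "", 2L)
  counts <- as.numeric(vapply(m, `[`, "", 3L))
  if (any(counts < 1)) {
    k <- which(counts < 1)[1]
    parse_error(sprintf("%s: record '%s' has a non-positive count", path, ids[k]),
                rec$line[k])
  }
  seqs <- fold_seq(rec$seq)
  for (k in seq_along(seqs)) check_alphabet(seqs[k], ids[k], rec$line[k])
  len <- nchar(seqs)
  if (kind == "srna" && any(len < min_len | len > max_len)) {
    k <- which(len < min_len | len > max_len)[1]
    parse_error(sprintf("%s: sRNA record '%s' has length %d outside [%d, %d]",
                        path, ids[k], len[k], min_len, max_len), rec$line[k])
  }
  key <- paste(seqs, library, kind)
  if (anyDuplicated(key)) {
    k <- which(duplicated(key))[1]
    parse_error(sprintf("%s: sequence of record '%s' occurs more than once in library '%s'",
                        path, ids[k], library), rec$line[k])
  }
  reads <- data.frame(id = ids, seq = seqs, length = len, count = counts,
                      library = library, kind = kind, stringsAsFactors = FALSE)
  stats <- data.frame(library = library, total_reads = sum(counts),
                      stringsAsFactors = FALSE)
  list(reads = reads, stats = stats)
}

#' Write collapsed reads to FASTA
#' @param reads A collapsed-read `data.frame` (`id`, `seq`, `count`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_collapsed_reads <- function(reads, path) {
  writeLines(paste0(">", reads$id, "_x", format(reads$count, scientific = FALSE, trim = TRUE),
                    "\n", reads$seq), path)
  invisible(path)
}

#' Reads-per-million normalization
#'
#' @param count Read count(s).
#' @param total_reads Library size: either the total read count or a `stats`
#'   data.frame from [read_collapsed_reads()].
#' @return `count / total_reads * 1e6`.
#' @export
rpm <- function(count, total_reads) {
  if (is.data.frame(total_reads)) total_reads <- total_reads$total_reads[1]
  if (!is.numeric(total_reads) || length(total_reads) != 1L || total_reads <= 0)
    stop("total_reads must be a single positive number")
  count / total_reads * 1e6
}

#' Reverse complement of DNA strings
#' @param x Character vector of upper-case DNA sequences.
#' @return Character vector of reverse complements (N stays N).
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, NULL, fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}
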