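#' Configuration for a full pipeline run
#'
#' Validates all inputs and stage parameters before any stage runs; invalid
#' settings are reported together in a single error.
#'
#' @param transcripts Transcript FASTA path, or a transcript `data.frame`.
#' @param srna Named character vector of collapsed sRNA FASTA paths (names are
#'   library labels), or a collapsed-read `data.frame` with a `library`
#'   column. Optional: without sRNA data only NAT prediction runs.
#' @param degradome Same forms as `srna`, for degradome libraries. Optional;
#'   ignored unless `srna` is given.
#' @param libraries Optional character vector selecting which sRNA libraries
#'   contribute phasing evidence (default: all; evidence is their union).
#' @param aligner,classify,duplex,phasing Stage parameter objects
#'   ([aligner_params()], [classify_params()], [duplex_params()],
#'   [phasing_params()]).
#' @param degradome_window Positional tolerance (nt) for degradome 5'-end
#'   matching (default 0, exact).
#' @param out_dir Optional output directory for the TSV reports, the plain-text
#'   report and the serialized configuration.
#' @param quiet Suppress per-stage log messages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(transcripts, srna = NULL, degradome = NULL,
                       libraries = NULL, aligner = aligner_params(),
                       classify = classify_params(), duplex = duplex_params(),
                       phasing = phasing_params(), degradome_window = 0L,
                       out_dir = NULL, quiet = FALSE) {
  errs <- character()
  if (missing(transcripts) || is.null(transcripts))
    errs <- c(errs, "transcripts are required (sRNA data alone cannot be analysed)")
  else if (is.character(transcripts)) {
    missing_files <- transcripts[!file.exists(transcripts)]
    if (length(missing_files))
      errs <- c(errs, sprintf("transcript file not found: %s", missing_files))
  } else if (!is.data.frame(transcripts))
    errs <- c(errs, "transcripts must be a FASTA path or a data.frame")
  check_reads_arg <- function(x, what) {
    if (is.null(x)) return(character())
    if (is.character(x)) {
      e <- character()
      if (is.null(names(x)) || any(!nzchar(names(x))))
        e <- c(e, sprintf("%s paths must be named by library", what))
      e <- c(e, sprintf("%s file not found: %s", what, x[!file.exists(x)]))
      e
    } else if (is.data.frame(x)) {
      if (!"library" %in% names(x)) sprintf("%s data.frame needs a 'library' column", what)
      else character()
    } else sprintf("%s must be named paths or a data.frame", what)
  }
  errs <- c(errs, check_reads_arg(srna, "srna"), check_reads_arg(degradome, "degradome"))
  if (!is.null(degradome) && is.null(srna))
    errs <- c(errs, "degradome data require sRNA data (phasing runs first)")
  if (!inherits(aligner, "aligner_params")) errs <- c(errs, "aligner must be aligner_params()")
  if (!inherits(classify, "classify_params")) errs <- c(errs, "classify must be classify_params()")
  if (!inherits(duplex, "duplex_params")) errs <- c(errs, "duplex must be duplex_params()")
  if (!inherits(phasing, "phasing_params")) errs <- c(errs, "phasing must be phasing_params()")
  if (length(errs))
    stop(errorCondition(paste0("invalid configuration:\n  - ",
                               paste(errs, collapse = "\n  - ")),
                        class = c("natphase_config_error", "error")))
  structure(list(transcripts = transcripts, srna = srna, degradome = degradome,
                 libraries = libraries, aligner = aligner, classify = classify,
                 duplex = duplex, phasing = phasing,
                 degradome_window = as.integer(degradome_window),
                 out_dir = out_dir, quiet = isTRUE(quiet)),
            class = "run_config")
}

load_reads_input <- function(x, kind) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) {
    agg <- tapply(x$count, x$library, sum)
    return(list(reads = x,
                stats = data.frame(library = names(agg),
                                   total_reads = as.numeric(agg),
                                   stringsAsFactors = FALSE)))
  }
  parts <- lapply(names(x), function(lib)
    read_collapsed_reads(x[[lib]], library = lib, kind = kind))
  list(reads = do.call(rbind, lapply(parts, `[[`, "reads")),
       stats = do.call(rbind, lapply(parts, `[[`, "stats")))
}

#' Run the full NAT / phased nat-siRNA pipeline
#'
#' Stages run in order: antisense search, NAT classification, duplex-structure
#' prediction, retention filtering, cis-candidate flagging; then, when sRNA
#' data are present, strand-specific mapping and phased-cluster detection;
#' then, when degradome data are present, degradome mapping and evidence
#' assignment. All outputs are deterministically ordered.
#'
#' @param config A [run_config()].
#' @return A list of class `natphase_run`: `matches` (classified), `nats`
#'   (retained NAT pairs), `nat_table`, `clusters`, `cluster_table`,
#'   `evidence`, `summary` (named counts), `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!config$quiet) message(sprintf(...))

  transcripts <- if (is.character(config$transcripts))
    do.call(rbind, lapply(config$transcripts, read_fasta)) else config$transcripts
  if (anyDuplicated(transcripts$id))
    stop("duplicate transcript IDs across input files")
  say("loaded %d transcripts", nrow(transcripts))

  matches <- find_complementary_pairs(transcripts, config$aligner)
  say("antisense search: %d complementary region(s)", nrow(matches))
  matches <- classify_matches(matches, transcripts, config$classify)
  say("classification: %d HC, %d 100-nt, %d both, %d none",
      sum(matches$nat_class == "HC"), sum(matches$nat_class == "NT100"),
      sum(matches$nat_class == "both"), sum(matches$nat_class == "none"))

  nats <- build_nat_pairs(transcripts, matches, config$duplex)
  say("duplex validation: %d NAT pair region(s) retained, %d cis candidate(s)",
      length(nats), sum(vapply(nats, `[[`, logical(1), "is_cis_candidate")))

  srna <- load_reads_input(config$srna, "srna")
  if (!is.null(srna) && !is.null(config$libraries)) {
    srna$reads <- srna$reads[srna$reads$library %in% config$libraries, , drop = FALSE]
    srna$stats <- srna$stats[srna$stats$library %in% config$libraries, , drop = FALSE]
  }
  clusters <- list()
  n_regions <- sum(vapply(nats, function(x)
    sum(x$segments$length >= config$phasing$min_region_len), integer(1)))
  if (!is.null(srna)) {
    clusters <- find_phased_clusters(nats, transcripts, srna$reads, srna$stats,
                                     config$phasing)
    say("phasing: %d perfectly annealed region(s) searched, %d cluster(s)",
        n_regions, length(clusters))
  }

  evidence <- empty_evidence()
  deg <- NULL
  if (!is.null(config$degradome) && length(clusters)) {
    deg <- load_reads_input(config$degradome, "degradome")
    mapped_tags <- map_degradome(deg$reads, transcripts, clusters)
    evidence <- assign_degradome_evidence(mapped_tags, clusters, deg$stats,
                                          config$degradome_window)
    say("degradome: %d evidence row(s)", nrow(evidence))
  }
  support <- degradome_support(clusters, evidence)

  n_phased <- sum(vapply(clusters, function(x)
    sum(x$slots$sense_evidenced) + sum(x$slots$anti_evidenced), integer(1)))
  summary <- c(
    n_transcripts = nrow(transcripts),
    n_complementary_pairs = length(unique(paste(matches$id_a, matches$id_b))),
    n_complementary_regions = nrow(matches),
    n_class_hc = sum(matches$nat_class %in% c("HC", "both")),
    n_class_nt100 = sum(matches$nat_class %in% c("NT100", "both")),
    n_retained_nats = length(unique(vapply(nats, function(x)
      paste(x$id_a, x$id_b), character(1)))),
    n_cis_candidates = sum(vapply(nats, `[[`, logical(1), "is_cis_candidate")),
    n_regions_searched = if (is.null(srna)) 0L else n_regions,
    n_clusters = length(clusters),
    n_phased_sirnas = n_phased,
    n_supported_sirnas = support$n_supported_sirnas,
    n_supported_clusters = support$n_supported_clusters)

  run <- structure(list(transcripts = transcripts, matches = matches,
                        nats = nats, nat_table = nat_table(nats),
                        clusters = clusters,
                        cluster_table = cluster_table(clusters),
                        evidence = evidence, summary = summary,
                        config = config),
                   class = "natphase_run")
  if (!is.null(config$out_dir)) write_reports(run, config$out_dir)
  run
}

#' @export
print.natphase_run <- function(x, ...) {
  cat("natphase run\n")
  for (k in names(x$summary)) cat(sprintf("  %-24s %s\n", k, x$summary[[k]]))
  invisible(x)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write the summary/detail reports of a run
#'
#' Emits `summary.tsv` (stage counts), `nat_pairs.tsv`, `clusters.tsv`,
#' `cluster_expression.tsv` (per-sRNA per-library counts and RPM),
#' `degradome_evidence.tsv`, `report.txt` (human-readable rendering) and
#' `config.json`.
#'
#' @param run A `natphase_run`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_reports <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  paths$summary <- write_tsv(data.frame(metric = names(run$summary),
                                        value = unname(run$summary)),
                             file.path(dir, "summary.tsv"))
  paths$nat_pairs <- write_tsv(run$nat_table, file.path(dir, "nat_pairs.tsv"))
  paths$clusters <- write_tsv(run$cluster_table, file.path(dir, "clusters.tsv"))
  expr <- do.call(rbind, lapply(run$clusters, function(cl)
    if (is.null(cl$expression)) NULL
    else cbind(cluster_id = cl$cluster_id, cl$expression)))
  if (is.null(expr))
    expr <- data.frame(cluster_id = character(), read_id = character(),
                       seq = character(), library = character(),
                       count = numeric(), strand = character(), rpm = numeric())
  paths$expression <- write_tsv(expr, file.path(dir, "cluster_expression.tsv"))
  paths$evidence <- write_tsv(run$evidence,
                              file.path(dir, "degradome_evidence.tsv"))
  writeLines(render_report_text(run), file.path(dir, "report.txt"))
  paths$report <- file.path(dir, "report.txt")
  cfg <- run$config
  cfg$transcripts <- if (is.character(cfg$transcripts)) cfg$transcripts else "<in-memory>"
  for (f in c("srna", "degradome"))
    if (is.data.frame(cfg[[f]])) cfg[[f]] <- "<in-memory>"
  paths$config <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(cfg), paths$config, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(paths)
}

ordinal <- function(x) format(x, big.mark = ",")

#' Render a plain-text report of a run
#'
#' Human-readable rendering of the machine-readable tables: per NAT pair, (1)
#' the annealed region on both transcripts, (2) the phased nat-siRNA clusters
#' with per-library presence, (3) the degradome signatures supporting them.
#' Degradome libraries prepared from poly(A)-tailed RNA cannot report
#' processing signals of non-Pol II transcripts; the footer records this
#' caveat.
#'
#' @param run A `natphase_run`.
#' @return Character vector of report lines.
#' @export
render_report_text <- function(run) {
  out <- c("NAT pairs and phased nat-siRNA report", "")
  nt <- run$nat_table
  if (nrow(nt) == 0L) return(c(out, "No NAT pairs retained."))
  for (r in seq_len(nrow(nt))) {
    out <- c(out, sprintf("NAT pair %s | %s [%s]%s", nt$id_a[r], nt$id_b[r],
                          nt$nat_class[r],
                          if (nt$is_cis_candidate[r]) " (cis-NAT candidate)" else ""))
    out <- c(out, sprintf(
      "  (1) annealed region: %s from %sth to %sth nucleotide; %s from %sth to %sth nucleotide (%d perfect segment(s), %d bubble(s))",
      nt$id_a[r], ordinal(nt$a_region_start[r]), ordinal(nt$a_region_end[r]),
      nt$id_b[r], ordinal(nt$b_region_start[r]), ordinal(nt$b_region_end[r]),
      nt$n_perfect_segments[r], nt$n_bubbles[r]))
    cls <- Filter(function(cl) cl$id_a == nt$id_a[r] && cl$id_b == nt$id_b[r],
                  run$clusters)
    if (length(cls) == 0L) { out <- c(out, "  (2) no phased nat-siRNA cluster") }
    for (cl in cls) {
      out <- c(out, sprintf(
        "  (2) cluster %s: %d nat-siRNAs assigned to %d consecutive phases (%d-nt register %d); libraries: %s",
        cl$cluster_id, cl$n_srnas, cl$n_phases, cl$srna_len, cl$register,
        paste(cl$libraries, collapse = ", ")))
      ev <- run$evidence[run$evidence$cluster_id == cl$cluster_id, , drop = FALSE]
      if (nrow(ev)) {
        out <- c(out, sprintf(
          "  (3) degradome evidence: %s",
          paste(sprintf("%s (%s, pos %d, %s strand, slot %s, %.1f RPM)",
                        ev$tag_id, ev$library, ev$five_prime_pos, ev$strand,
                        ev$slot, ev$rpm), collapse = "; ")))
      } else out <- c(out, "  (3) no degradome evidence")
    }
    out <- c(out, "")
  }
  c(out, paste("Note: degradome libraries prepared from poly(A)-tailed RNAs cannot",
               "report processing signals from non-Pol II-transcribed NATs."))
}

#' Structural nesting checks for a run
#'
#' Verifies the count hierarchy every run must satisfy: degradome-supported
#' siRNAs never exceed phased siRNAs, supported clusters never exceed
#' clusters, and clusters only arise on searched regions of retained pairs.
#'
#' @param run A `natphase_run`.
#' @return `TRUE` (invisibly) or an error describing the violated nesting.
#' @export
check_count_nesting <- function(run) {
  s <- run$summary
  if (s[["n_supported_sirnas"]] > s[["n_phased_sirnas"]])
    stop("supported siRNAs exceed phased siRNAs")
  if (s[["n_supported_clusters"]] > s[["n_clusters"]])
    stop("supported clusters exceed clusters")
  if (!all(run$evidence$cluster_id %in%
           vapply(run$clusters, `[[`, character(1), "cluster_id")))
    stop("evidence attached to an unknown cluster")
  if (s[["n_clusters"]] > 0 && s[["n_regions_searched"]] == 0)
    stop("clusters without searched regions")
  invisible(TRUE)
}
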