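test_that("exact sense mapping reports every occurrence and nothing else", {
  set.seed(81)
  t1 <- rand_seq(120)
  read <- substr(t1, 10, 30)
  reads <- data.frame(id = "r1", seq = read, length = 21L, count = 4,
                      library = "leaf", kind = "srna", stringsAsFactors = FALSE)
  tr <- transcript_df(t1 = t1)
  hits <- map_srnas(reads, tr)
  expect_equal(nrow(hits), 1L)
  expect_equal(c(hits$start, hits$end), c(10L, 30L))
  # antisense orientation is not a hit on this transcript
  rc <- data.frame(id = "r2", seq = revcomp(read), length = 21L, count = 1,
                   library = "leaf", kind = "srna", stringsAsFactors = FALSE)
  expect_equal(nrow(map_srnas(rc, tr)), 0L)
  # a repeated occurrence is reported at every locus
  t2 <- paste0(rand_seq(15), read, rand_seq(9), read, rand_seq(12))
  hits2 <- map_srnas(reads, transcript_df(t2 = t2))
  expect_equal(hits2$start, naive_map_starts(read, t2))
  expect_equal(nrow(hits2), 2L)
})

test_that("mapping agrees with a naive scan on random reads", {
  set.seed(82)
  tr <- transcript_df(tA = rand_seq(300), tB = rand_seq(250))
  reads <- do.call(rbind, lapply(1:15, function(i) {
    src <- sample(1:2, 1)
    n <- sample(c(18L, 21L, 24L), 1)
    st <- sample(seq_len(tr$length[src] - n), 1)
    seq <- if (i %% 5 == 0) rand_seq(n) else substr(tr$seq[src], st, st + n - 1L)
    data.frame(id = sprintf("r%02d", i), seq = seq, length = n, count = 1,
               library = "leaf", kind = "srna", stringsAsFactors = FALSE)
  }))
  hits <- map_srnas(reads, tr)
  for (t in 1:2) for (r in seq_len(nrow(reads))) {
    expected <- naive_map_starts(reads$seq[r], tr$seq[t])
    got <- hits$start[hits$transcript_id == tr$id[t] & hits$read_id == reads$id[r]]
    expect_equal(sort(got), sort(expected))
  }
})

test_that("cross_coordinate is the segment involution", {
  seg <- list(a_start = 101L, a_end = 200L, b_start = 1L, b_end = 100L)
  expect_equal(cross_coordinate(101L, seg), 100L)
  expect_equal(cross_coordinate(200L, seg), 1L)
  expect_equal(cross_coordinate(150L, seg), 51L)
  # involution through the mirrored segment
  mirror <- list(a_start = 1L, a_end = 100L, b_start = 101L, b_end = 200L)
  for (x in c(101L, 137L, 200L))
    expect_equal(cross_coordinate(cross_coordinate(x, seg), mirror), x)
  expect_error(cross_coordinate(100L, seg), "outside")
  expect_error(cross_coordinate(201L, seg), "outside")
})

test_that("four planted 2-nt-overhang duplexes form exactly one 4-phase cluster", {
  fx <- make_fixture(fixture_spec(seed = 91))
  run <- run_fixture_pipeline(fx)
  expect_equal(length(run$clusters), 1L)
  cl <- run$clusters[[1]]
  expect_equal(cl$n_phases, 4L)
  expect_equal(cl$n_srnas, 8L)
  expect_equal(cl$register, fx$truth$cluster$register)
  expect_equal(cl$slots$sense_start, fx$truth$cluster$slot_starts)
  expect_equal(cl$slots$anti_b_start, fx$truth$cluster$anti_b_starts)
  expect_true(all(cl$slots$sense_evidenced & cl$slots$anti_evidenced))
})

test_that("either-strand evidence suffices; a both-strand mode is stricter", {
  fx <- make_fixture(fixture_spec(seed = 92, slot_strands = "sense",
                                  degradome = FALSE))
  run <- run_fixture_pipeline(fx)
  expect_equal(length(run$clusters), 1L)
  expect_equal(run$clusters[[1]]$n_phases, 4L)
  expect_equal(run$clusters[[1]]$n_srnas, 4L)
  expect_false(any(run$clusters[[1]]$slots$anti_evidenced))

  both <- run_pipeline(run_config(transcripts = fx$transcripts, srna = fx$srna,
                                  phasing = phasing_params(evidence_mode = "both"),
                                  quiet = TRUE))
  expect_equal(length(both$clusters), 0L)

  # three consecutive duplexes stay below the default threshold
  short <- make_fixture(fixture_spec(seed = 93, n_duplex = 3, degradome = FALSE))
  expect_equal(length(run_fixture_pipeline(short)$clusters), 0L)
})

test_that("shifting the planted reads shifts the register, phases unchanged", {
  base <- run_fixture_pipeline(make_fixture(fixture_spec(seed = 94,
                                                         register_offset = 2)))
  shift <- run_fixture_pipeline(make_fixture(fixture_spec(seed = 94,
                                                          register_offset = 3)))
  expect_equal(length(base$clusters), 1L)
  expect_equal(length(shift$clusters), 1L)
  expect_equal(shift$clusters[[1]]$register, base$clusters[[1]]$register + 1L)
  expect_equal(shift$clusters[[1]]$n_phases, base$clusters[[1]]$n_phases)
})

test_that("the >80 bp region rule is strict at the boundary", {
  skip_81 <- make_fixture(fixture_spec(seed = 95, region_len = 80L,
                                       srna_len = 19L, degradome = FALSE))
  expect_equal(skip_81$truth$segments$length, 80L)
  run80 <- run_pipeline(run_config(transcripts = skip_81$transcripts,
                                   srna = skip_81$srna,
                                   phasing = phasing_params(srna_len_set = 19L),
                                   quiet = TRUE))
  expect_equal(run80$summary[["n_regions_searched"]], 0L)
  expect_equal(length(run80$clusters), 0L)
  search_81 <- make_fixture(fixture_spec(seed = 95, region_len = 81L,
                                         srna_len = 19L, degradome = FALSE))
  run <- run_pipeline(run_config(transcripts = search_81$transcripts,
                                 srna = search_81$srna,
                                 phasing = phasing_params(srna_len_set = 19L),
                                 quiet = TRUE))
  expect_equal(length(run$clusters), 1L)
})

test_that("phase-run detection equals brute-force (register x run) enumeration", {
  set.seed(96)
  params <- phasing_params()
  for (case in 1:12) {
    seg_len <- sample(85:200, 1)
    seg <- data.frame(a_start = 101L, a_end = 100L + seg_len,
                      b_start = 501L, b_end = 500L + seg_len,
                      length = seg_len)
    n <- sample(c(21L, 24L), 1)
    r <- sample(0:(n - 1L), 1)
    all_starts <- seq.int(seg$a_start + r, seg$a_end - n + 1L, by = n)
    if (length(all_starts) < 4L) next
    on_a <- all_starts[runif(length(all_starts)) < 0.7]
    anti <- seg$b_start + (seg$a_end - (all_starts + n - 3L))
    anti_ok <- anti + n - 1L <= seg$b_end
    on_b <- anti[anti_ok & runif(length(anti)) < 0.5]
    noise <- sample(seg$a_start:(seg$a_end - n + 1L), 3L)
    hits_a <- fake_hits("A", c(on_a, noise), n)
    hits_b <- fake_hits("B", on_b, n)
    got <- enumerate_phase_runs(seg, hits_a, hits_b, n, params)
    got_df <- if (length(got)) data.frame(
      register = vapply(got, `[[`, integer(1), "register"),
      first_slot_start = vapply(got, `[[`, integer(1), "first_slot_start"),
      n_phases = vapply(got, `[[`, integer(1), "n_phases"))
      else data.frame(register = integer(), first_slot_start = integer(),
                      n_phases = integer())
    want <- phase_oracle(seg, hits_a, hits_b, n, params)
    o <- function(d) d[order(d$register, d$first_slot_start), , drop = FALSE]
    expect_equal(unname(as.matrix(o(got_df))), unname(as.matrix(o(want))),
                 info = sprintf("case %d", case))
    # maximality: no reported run extendable by an adjacent evidenced slot
    for (cl in got) {
      prev <- cl$first_slot_start - n
      nxt <- cl$first_slot_start + cl$n_phases * n
      ev_at <- function(i) {
        if (i < seg$a_start || i + n - 1L > seg$a_end) return(FALSE)
        ab <- seg$b_start + (seg$a_end - (i + n - 3L))
        (i %in% hits_a$start) ||
          (ab %in% hits_b$start && ab + n - 1L <= seg$b_end)
      }
      expect_false(ev_at(prev))
      expect_false(ev_at(nxt))
    }
  }
})

test_that("evidence is the union across libraries; selection restricts it", {
  fx <- make_fixture(fixture_spec(seed = 97, slot_strands = "sense",
                                  degradome = FALSE))
  reads <- fx$srna
  reads$library <- ifelse(reads$id %in% c("leaf_sr01s", "leaf_sr02s"),
                          "leaf", "root")
  reads$id <- paste0(reads$library, "_", sub("^leaf_", "", reads$id))
  union_run <- run_pipeline(run_config(transcripts = fx$transcripts,
                                       srna = reads, quiet = TRUE))
  expect_equal(length(union_run$clusters), 1L)
  expect_equal(sort(union_run$clusters[[1]]$libraries), c("leaf", "root"))
  leaf_only <- run_pipeline(run_config(transcripts = fx$transcripts,
                                       srna = reads, libraries = "leaf",
                                       quiet = TRUE))
  expect_equal(length(leaf_only$clusters), 0L)
})

test_that("bowtie legacy plus-strand records convert to mapped hits", {
  bt <- withr::local_tempfile(fileext = ".bwt")
  writeLines(c(
    paste(c("r1", "+", "tA", "9", "ACGTACGTACGTACGTACGTA"), collapse = "\t"),
    paste(c("r2", "-", "tA", "50", "ACGTACGTACGTACGTACGTA"), collapse = "\t")),
    bt)
  reads <- data.frame(id = c("r1", "r2"), seq = c("x", "y"), length = 21L,
                      count = c(7, 3), library = "leaf", kind = "srna",
                      stringsAsFactors = FALSE)
  hits <- read_bowtie_legacy(bt, reads)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$read_id, "r1")
  expect_equal(c(hits$start, hits$end), c(10L, 30L))
  expect_equal(hits$count, 7)
})
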