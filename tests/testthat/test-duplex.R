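fixture_duplex <- function(spec) {
  pair <- make_nat_pair(spec)
  m <- find_complementary_pairs(pair$transcripts)
  expect_equal(nrow(m), 1L)
  list(pair = pair,
       match = m,
       duplex = predict_duplex(pair$transcripts$seq[1], pair$transcripts$seq[2], m))
}

test_that("a perfect antisense region yields one perfect segment and no bubbles", {
  fd <- fixture_duplex(fixture_spec(seed = 51, region_len = 120))
  dx <- fd$duplex
  truth <- fd$pair$truth
  expect_equal(dx$n_perfect_segments, 1L)
  expect_equal(nrow(dx$bubbles), 0L)
  expect_equal(dx$segments$length, 120L)
  expect_equal(dx$segments, truth$segments)
  expect_equal(dx$a_region, c(truth$match$a_start, truth$match$a_end))
  expect_true(retention_filter(fd$match, dx))
  expect_true(flag_cis_candidate(dx))
})

test_that("insertions and mismatches become bubbles splitting perfect segments", {
  # 6-nt insertion in A at the midpoint: two segments, bubble 6+0
  fd <- fixture_duplex(fixture_spec(seed = 52, region_len = 120,
                                    bubble = list(pos = 60, a_len = 6, b_len = 0)))
  expect_equal(fd$duplex$n_perfect_segments, 2L)
  expect_equal(nrow(fd$duplex$bubbles), 1L)
  expect_equal(fd$duplex$bubbles$a_gap_len, 6L)
  expect_equal(fd$duplex$bubbles$b_gap_len, 0L)
  expect_equal(fd$duplex$bubbles$size, 6L)
  expect_equal(fd$duplex$segments, fd$pair$truth$segments)
  expect_false(flag_cis_candidate(fd$duplex))

  # one central mismatch: two segments, one 1+1 bubble of size 1
  fm <- fixture_duplex(fixture_spec(seed = 53, region_len = 121,
                                    mismatches = 61))
  expect_equal(fm$duplex$n_perfect_segments, 2L)
  expect_equal(fm$duplex$bubbles$size, 1L)
  expect_equal(fm$duplex$bubbles$a_gap_len, 1L)
  expect_equal(fm$duplex$bubbles$b_gap_len, 1L)
  expect_equal(fm$duplex$segments$length, c(60L, 60L))
  expect_equal(fm$duplex$segments, fm$pair$truth$segments)
})

test_that("duplex DP equals exhaustive non-crossing enumeration on toys", {
  set.seed(77)
  for (case in 1:12) {
    na <- sample(8:20, 1); nb <- sample(8:20, 1)
    a <- rand_seq(na)
    b <- if (case %% 3 == 0) rand_seq(nb)
         else revcomp(a)  # mostly pairable toys, occasionally random
    if (case %% 4 == 0) substr(b, 5, 5) <- sample(c("A", "C", "G", "T"), 1)
    br <- paste(rev(strsplit(b, NULL)[[1]]), collapse = "")
    dp <- natphase:::.duplex_local(a, br, 1.0, TRUE)
    expect_equal(dp$score, duplex_oracle_score(a, br, 1, TRUE),
                 info = sprintf("case %d (gu)", case))
    dp2 <- natphase:::.duplex_local(a, br, 1.0, FALSE)
    expect_equal(dp2$score, duplex_oracle_score(a, br, 1, FALSE),
                 info = sprintf("case %d (wc)", case))
  }
})

test_that("paired columns and bubbles tile the annealed region on each strand", {
  specs <- list(fixture_spec(seed = 61, region_len = 100),
                fixture_spec(seed = 62, region_len = 140, mismatches = c(40, 90)),
                fixture_spec(seed = 63, region_len = 160,
                             bubble = list(pos = 80, a_len = 5, b_len = 0)),
                fixture_spec(seed = 64, region_len = 130,
                             bubble = list(pos = 50, a_len = 0, b_len = 7)))
  for (spec in specs) {
    fd <- fixture_duplex(spec)
    dx <- fd$duplex
    expect_equal(sum(dx$segments$length), nrow(dx$pairs))
    a_span <- dx$a_region[2] - dx$a_region[1] + 1L
    b_span <- dx$b_region[2] - dx$b_region[1] + 1L
    expect_equal(a_span, nrow(dx$pairs) + sum(dx$bubbles$a_gap_len))
    expect_equal(b_span, nrow(dx$pairs) + sum(dx$bubbles$b_gap_len))
    # pairs are monotone and non-crossing
    expect_true(all(diff(dx$pairs$pos_a) > 0))
    expect_true(all(diff(dx$pairs$pos_b) < 0))
    expect_equal(sort(dx$bubbles$size), fd$pair$truth$bubble_sizes)
  }
})

test_that("retention criteria apply their boundary percentages exactly", {
  mk_duplex <- function(region = c(1L, 100L), sizes = integer()) {
    structure(list(pair = c("a", "b"), a_region = region, b_region = region,
                   pairs = data.frame(pos_a = region[1], pos_b = region[2]),
                   bubbles = data.frame(a_after = integer(length(sizes)),
                                        b_before = integer(length(sizes)),
                                        a_gap_len = sizes,
                                        b_gap_len = integer(length(sizes)),
                                        size = sizes),
                   segments = data.frame(a_start = region[1], a_end = region[2],
                                         b_start = region[1], b_end = region[2],
                                         length = diff(region) + 1L),
                   n_perfect_segments = 1L, score = 0),
              class = "duplex_structure")
  }
  match_cov <- function(f) list(a_start = 1L, a_end = as.integer(f),
                                b_start = 1L, b_end = as.integer(f))
  # criterion 1: structure region must overlap the alignment region at >= 80%
  retained <- vapply(1:100, function(f)
    retention_filter(match_cov(f), mk_duplex()), logical(1))
  expect_equal(which(retained), 80:100)
  # criterion 2: every bubble <= 10% of the 100-column annealed region
  full <- match_cov(100)
  by_size <- vapply(1:15, function(s)
    retention_filter(full, mk_duplex(sizes = s)), logical(1))
  expect_equal(which(by_size), 1:10)
  expect_false(retention_filter(full, mk_duplex(sizes = c(3L, 11L))))
})

test_that("cis candidacy requires a single perfectly annealed region", {
  # one pair with two disjoint validated regions is not a cis candidate
  p1 <- make_nat_pair(fixture_spec(seed = 71, region_len = 100,
                                   flank_a = c(30, 200), flank_b = c(20, 160)))
  set.seed(99)
  core2 <- rand_seq(120)
  a2 <- paste0(p1$transcripts$seq[1], core2)
  b2 <- paste0(p1$transcripts$seq[2], strrep("A", 30), revcomp(core2),
               rand_seq(10))
  tr <- transcript_df(natA = a2, natB = b2)
  m <- classify_matches(find_complementary_pairs(tr), tr)
  expect_gte(nrow(m), 2L)
  nats <- build_nat_pairs(tr, m)
  expect_true(all(!vapply(nats, `[[`, logical(1), "is_cis_candidate")))
  # while a single perfect region remains cis
  single <- make_nat_pair(fixture_spec(seed = 72, region_len = 100))
  ms <- classify_matches(find_complementary_pairs(single$transcripts),
                         single$transcripts)
  ns <- build_nat_pairs(single$transcripts, ms)
  expect_equal(length(ns), 1L)
  expect_true(ns[[1]]$is_cis_candidate)
})

test_that("RNAplex duplex lines populate a structure", {
  dx <- parse_rnaplex_line("((((&))))  3,6  :  11,14  (-5.20)", "q", "t")
  expect_equal(dx$a_region, c(3L, 6L))
  expect_equal(dx$b_region, c(11L, 14L))
  expect_equal(nrow(dx$pairs), 4L)
  expect_equal(dx$pairs$pos_a, 3:6)
  expect_equal(dx$pairs$pos_b, 14:11)
  expect_equal(dx$n_perfect_segments, 1L)
  expect_equal(dx$score, -5.2)
  expect_error(parse_rnaplex_line("garbage"), class = "natphase_parse_error")
})
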