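test_that("cutoff walk reproduces hand-computed toy cases", {
  prof <- phylo_profile(stats::setNames(c("YES", "YES", "NO", "NO"),
                                        paste0("g", 1:4)))
  # hits from distinct genomes labelled YES, YES, NO at p = 0.5:
  # best cutoff is depth 2 with y = n = 2, score log10(1/4)
  hl <- hit_list("q", c("a", "b", "c"), c("g1", "g2", "g3"), c(30, 20, 10))
  r <- evaluate_prefixes(hl, prof)
  expect_equal(r$yes, 2L); expect_equal(r$total, 2L); expect_equal(r$depth, 2L)
  expect_equal(r$score, log10(0.25), tolerance = 1e-12)

  # three hits all from one YES genome at p = 0.1: deeper prefixes add no
  # genomes, so the shallowest cutoff wins with score log10(p)
  prof10 <- phylo_profile(stats::setNames(c("YES", rep("NO", 9)),
                                          paste0("g", 1:10)))
  hl2 <- hit_list("q", c("a", "b", "c"), rep("g1", 3), c(30, 20, 10))
  r2 <- evaluate_prefixes(hl2, prof10)
  expect_equal(r2[c("yes", "total", "depth")],
               list(yes = 1L, total = 1L, depth = 1L))
  expect_identical(r2$score, log10(0.1))

  # empty hit list: the empty cutoff, score exactly 0
  r3 <- evaluate_prefixes(empty_hit_list("q"), prof)
  expect_identical(r3$score, 0)
  expect_equal(r3$depth, 0L)

  # a hit list touching only NO genomes never beats the empty prefix
  hl4 <- hit_list("q", c("a", "b"), c("g3", "g4"), c(9, 8))
  expect_identical(evaluate_prefixes(hl4, prof)$score, 0)
})

test_that("tie blocks are atomic: a cutoff never splits equal scores", {
  prof <- phylo_profile(stats::setNames(c("YES", "NO", "NO", "NO"),
                                        paste0("g", 1:4)))
  # the YES genome leads, then a NO shares its score: the block must be
  # taken whole, so the best available cutoff includes the NO genome
  hl <- hit_list("q", c("a", "b", "c"), c("g1", "g2", "g3"), c(30, 30, 10))
  r <- evaluate_prefixes(hl, prof)
  expect_equal(r$depth, 2L)
  expect_equal(r$total, 2L)
  expect_equal(r$score, log10_binom_tail(1, 2, 0.25))
})

test_that("max_depth truncates without splitting a tie block", {
  prof <- phylo_profile(stats::setNames(c("YES", "YES", "YES", "NO"),
                                        paste0("g", 1:4)))
  hl <- hit_list("q", c("a", "b", "c"), c("g1", "g2", "g3"), c(30, 20, 20))
  # the block ending at depth 3 exceeds max_depth 2, so only depth 1 remains
  r <- evaluate_prefixes(hl, prof, ppp_config(max_depth = 2))
  expect_equal(r$depth, 1L)
  expect_identical(r$score, log10(0.75))
})

test_that("the self genome can be excluded from the tallies", {
  prof <- phylo_profile(stats::setNames(c("YES", "YES", "NO", "NO"),
                                        paste0("g", 1:4)))
  hl <- hit_list("q", c("self", "b"), c("g1", "g2"), c(30, 20))
  with_self <- evaluate_prefixes(hl, prof)
  expect_equal(with_self[c("yes", "total")], list(yes = 2L, total = 2L))
  no_self <- evaluate_prefixes(hl, prof,
                               ppp_config(count_self_genome = FALSE),
                               query_genome = "g1")
  expect_equal(no_self[c("yes", "total", "depth")],
               list(yes = 1L, total = 1L, depth = 2L))
})

test_that("cutoff walk equals the exhaustive prefix oracle on random lists", {
  set.seed(53)
  genomes <- paste0("g", 1:25)
  prof <- phylo_profile(stats::setNames(
    ifelse(seq_along(genomes) <= 6, "YES", "NO"), genomes))
  for (i in 1:200) {
    d <- sample(1:60, 1)
    g <- sample(genomes, d, replace = TRUE)
    bits <- sort(sample(seq(10, 200, by = 5), d, replace = TRUE),
                 decreasing = TRUE)
    hl <- hit_list("q", paste0("s", seq_len(d)), g, bits)
    got <- evaluate_prefixes(hl, prof)
    want <- ppp_oracle(hl$subject_genome, prof$labels[hl$subject_genome],
                       hl$score_bits, prof$prevalence)
    expect_equal(got$score, want$score, tolerance = 1e-9)
    expect_equal(got[c("yes", "total", "depth")],
                 want[c("yes", "total", "depth")])
  }
})

test_that("genome ranking is deterministic and sorted most-significant first", {
  col <- genome_collection(
    c(a1 = "MKLV", a2 = "MWHE", a3 = "MCGV"),
    c(a1 = "g1", a2 = "g1", a3 = "g1"))
  prof <- phylo_profile(stats::setNames(c("YES", "YES", "NO", "NO"),
                                        paste0("g", 1:4)))
  hits <- list(
    a1 = hit_list("a1", c("x", "y"), c("g1", "g2"), c(30, 20)),  # all YES
    a2 = hit_list("a2", c("u", "v"), c("g3", "g4"), c(30, 20)))  # all NO
  # a3 has no hit list at all: treated as empty
  tbl <- ppp_rank_genome("g1", hits, prof, col)
  expect_s3_class(tbl, "PPPTable")
  expect_equal(tbl$query, c("a1", "a2", "a3"))
  expect_lt(tbl$score[1], 0)
  expect_identical(tbl$score[2:3], c(0, 0))
  expect_true(!is.unsorted(tbl$score))

  # permuting the hit-list order leaves the table unchanged
  tbl2 <- ppp_rank_genome("g1", rev(hits), prof, col)
  expect_identical(tbl, tbl2)

  d <- withr::local_tempdir()
  f <- file.path(d, "ppp.tsv")
  write_ppp_table(tbl, f, meta = "toy")
  back <- read_tsv_meta(f)
  expect_equal(back$query, tbl$query)
  expect_equal(back$score, as.numeric(sprintf("%.6f", tbl$score)))
})

test_that("marker membership defines the profile", {
  col <- genome_collection(
    stats::setNames(rep("MKLV", 12), paste0("p", 1:12)),
    stats::setNames(paste0("g", c(1:10, 1, 2)), paste0("p", 1:12)))
  # members in 3 of 10 genomes
  prof <- profile_from_marker(col, c("p1", "p2", "p3"))
  expect_equal(prof$yes_count, 3L)
  expect_equal(prof$prevalence, 0.3)
  # two members in one genome count that genome once
  prof2 <- profile_from_marker(col, c("p1", "p11"))
  expect_equal(prof2$yes_count, 1L)
  # degenerate memberships are rejected
  expect_error(profile_from_marker(col, character()), "non-empty")
  expect_error(profile_from_marker(col, paste0("p", 1:10)), "uninformative")
})
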