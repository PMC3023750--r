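test_that("dereplication keeps one representative per near-identical group", {
  p <- scoring_params()
  s <- rand_aa(120)
  # two identical sequences collapse to one
  expect_length(dereplicate(c(a = s, b = s)), 1L)
  # two sequences at ~50% identity are both kept
  set.seed(61)
  t <- mutate_sequence(s, 0.5)
  expect_length(dereplicate(c(a = s, b = t)), 2L)

  # 30 sequences radiated from 3 ancestors at 95% within-group identity:
  # verify the pairwise identity structure first, then expect exactly 3 kept
  set.seed(67)
  anc <- replicate(3, rand_aa(150))
  fam <- unlist(lapply(1:3, function(k)
    stats::setNames(replicate(10, mutate_sequence(anc[k], 0.975)),
                    paste0("f", k, "_", 1:10))))
  grp <- rep(1:3, each = 10)
  within <- .global_identity(fam[[1]], fam[2:10], p)
  between <- .global_identity(fam[[1]], fam[11:30], p)
  expect_true(all(within > 0.80))
  expect_true(all(between < 0.80))
  kept <- dereplicate(fam, 0.80, p)
  expect_length(kept, 3L)
  expect_equal(unique(grp[match(names(kept), names(fam))]), 1:3)
})

test_that("training sets partition by genome trait and filter fragments", {
  set.seed(71)
  seqs <- stats::setNames(replicate(6, rand_aa(300)), paste0("m", 1:6))
  genomes <- paste0("g", 1:6)
  prof <- phylo_profile(stats::setNames(c("YES", "YES", rep("NO", 4)),
                                        genomes))
  tr <- build_training(seqs, genomes, prof)
  expect_length(tr$true_seqs, 2L)
  expect_length(tr$false_seqs, 4L)
  expect_equal(tr$p_t, 1 / 3)

  # a 10-residue fragment among ~300-residue members is removed
  seqs2 <- c(seqs, frag = rand_aa(10))
  tr2 <- build_training(seqs2, c(genomes, "g3"), prof)
  expect_false("frag" %in% names(tr2$false_seqs))
  expect_length(tr2$false_seqs, 4L)

  # training-set invariants
  expect_error(training_set(character(), seqs), "non-empty")
  expect_error(training_set(c(a = "MK"), c(a = "ML")), "both partitions")
})

test_that("window enumeration is triangular with the apex included", {
  # L = 10, min 8, steps 1/1: 3 + 2 + 1 windows
  w <- enumerate_windows(10, min_len = 8, len_step = 1, pos_step = 1)
  expect_equal(nrow(w), 6L)
  expect_equal(sum(w$length == 10), 1L)
  # L = min_len: exactly the apex
  w1 <- enumerate_windows(8, min_len = 8)
  expect_equal(nrow(w1), 1L)
  expect_equal(w1$start, 0L)
  expect_error(enumerate_windows(5, min_len = 8), "shorter")

  # arbitrary grids match the closed-form count
  for (L in c(23, 40, 61)) {
    for (steps in list(c(4, 2), c(3, 5))) {
      w <- enumerate_windows(L, 8, steps[1], steps[2])
      lens <- unique(c(seq(8, L, by = steps[1]), L))
      expect_equal(nrow(w),
                   sum(vapply(lens, function(l)
                     length(seq(0, L - l, by = steps[2])), numeric(1))))
      expect_equal(w$center, w$start + w$length / 2)
      # triangular occupancy: counts non-increasing with window length
      cnt <- table(factor(w$length, levels = sort(lens)))
      expect_true(all(diff(as.integer(cnt)) <= 0))
    }
  }
})

test_that("window scores follow the perfect-prefix identity and zero cases", {
  set.seed(73)
  # TRUE partition unalignable from the probe (poly-G scores negatively
  # against it): every window hits only FALSE sequences and scores 0
  probe <- paste(rep("W", 40), collapse = "")
  tr0 <- training_set(
    stats::setNames(rep(paste(rep("G", 40), collapse = ""), 3), paste0("t", 1:3)),
    stats::setNames(rep(probe, 5), paste0("f", 1:5)))
  expect_identical(score_window(substr(probe, 1, 12), tr0), 0)
  g0 <- simbal_heatmap(c(pr = probe), tr0)
  expect_true(all(g0$windows$score == 0))

  # a window exactly matching all TRUE members scores at least
  # -t * log10(p_t) (perfect-prefix identity at the TRUE block)
  core <- rand_aa(15)
  tr1 <- training_set(
    stats::setNames(paste0(replicate(4, rand_aa(20)), core,
                           replicate(4, rand_aa(20))), paste0("t", 1:4)),
    stats::setNames(replicate(8, rand_aa(55)), paste0("f", 1:8)))
  expect_gte(score_window(core, tr1), -4 * log10(4 / 12))
})

test_that("window scoring equals the exhaustive-cutoff oracle", {
  set.seed(79)
  anc <- rand_aa(80)
  tr <- training_set(
    stats::setNames(replicate(5, mutate_sequence(anc, 0.7)), paste0("t", 1:5)),
    stats::setNames(replicate(9, mutate_sequence(anc, 0.55)), paste0("f", 1:9)))
  for (i in 1:40) {
    st <- sample(0:60, 1)
    len <- sample(8:20, 1)
    w <- substr(anc, st + 1, min(st + len, 80))
    expect_equal(score_window(w, tr), window_oracle(w, tr), tolerance = 1e-9)
  }
})

test_that("heat maps localize a planted diagnostic window", {
  set.seed(83)
  anc <- rand_aa(90)
  win <- c(31, 45)  # 1-based planted window
  plant <- function(s, v) paste0(substr(s, 1, win[1] - 1), v,
                                 substr(s, win[2] + 1, nchar(s)))
  true_var <- substr(anc, win[1], win[2])
  false_var <- rand_aa(15)
  true_seqs <- stats::setNames(
    vapply(1:8, function(i) plant(mutate_sequence(anc, 0.7), true_var),
           character(1)), paste0("t", 1:8))
  false_seqs <- stats::setNames(
    vapply(1:16, function(i) plant(mutate_sequence(anc, 0.7), false_var),
           character(1)), paste0("f", 1:16))
  tr <- training_set(true_seqs, false_seqs)
  grid <- simbal_heatmap(c(probe = true_seqs[[1]]), tr)
  # exactly one full-length (apex) entry
  expect_equal(sum(grid$windows$length == grid$length), 1L)
  expect_equal(grid$apex_score,
               grid$windows$score[grid$windows$length == grid$length])
  mw <- max_window(grid)
  expect_true(mw$start + 1 <= win[2] && mw$start + mw$length >= win[1])
  # grids are deterministic
  grid2 <- simbal_heatmap(c(probe = true_seqs[[1]]), tr)
  expect_identical(grid$windows, grid2$windows)
})

test_that("apex score equals the full-length PPP-style score", {
  set.seed(89)
  anc <- rand_aa(60)
  tr <- training_set(
    stats::setNames(replicate(4, mutate_sequence(anc, 0.8)), paste0("t", 1:4)),
    stats::setNames(replicate(8, mutate_sequence(anc, 0.6)), paste0("f", 1:8)))
  probe <- mutate_sequence(anc, 0.8)
  apex <- score_window(probe, tr)
  # independent route: rank the training set as single-member genomes and
  # run the public PPP prefix evaluator
  seqs <- c(tr$true_seqs, tr$false_seqs)
  sc <- local_align_score(probe, seqs)
  keep <- sc > 0
  hl <- hit_list("probe", names(seqs)[keep], names(seqs)[keep], sc[keep])
  prof <- phylo_profile(stats::setNames(
    rep(c(TRUE, FALSE), c(4, 8)), names(seqs)))
  expect_identical(apex, -evaluate_prefixes(hl, prof)$score)
  # sign convention: heat-map scores non-negative, PPP table scores <= 0
  expect_gte(apex, 0)
})

test_that("windows map onto homologs through global alignment", {
  p <- scoring_params()
  probe <- "MKWVATHEGLRFCDNP"
  w <- list(start = 4, length = 6)  # probe residues 5..10
  # identical homolog: the interval is the window shifted to 1-based
  m1 <- map_window_to_homolog(w, probe, probe, p)
  expect_equal(c(m1$start, m1$end), c(5, 10))
  expect_false(m1$empty)
  # 5-residue N-terminal extension shifts the interval by +5
  m2 <- map_window_to_homolog(w, probe, paste0("AAAAA", probe), p)
  expect_equal(c(m2$start, m2$end), c(10, 15))
  # internal deletion removing residues 7..8 of the probe: the window maps
  # around the gap (hand-constructed alignment: 5,6 then 9,10 -> 5..8)
  hom <- paste0(substr(probe, 1, 6), substr(probe, 9, 16))
  m3 <- map_window_to_homolog(w, probe, hom, p)
  expect_equal(c(m3$start, m3$end), c(5, 8))
  expect_equal(m3$n_gapped, 2L)
})
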