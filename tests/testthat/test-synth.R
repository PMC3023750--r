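# Small spec used where full default scale is unnecessary.
small_spec <- function(seed = 5, ...) {
  synth_spec(seed = seed, n_genomes = 12, clade_size = 3, prevalence = 0.25,
             marker_genes = 2, dependent_families = 2,
             background_families = 10, dependent_length = 100,
             background_length = 80, marker_length = 90,
             contig_length = 1800, ...)
}

test_that("mutation hits its target identity deterministically", {
  anc <- rand_aa(300)
  expect_identical(mutate_sequence(anc, 1.0, seed = 3), anc)
  expect_identical(mutate_sequence(anc, 0.7, seed = 3),
                   mutate_sequence(anc, 0.7, seed = 3))
  # realized identity on a 300-mer stays within +/- 0.05 of target
  ident <- function(a, b) {
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }
  for (s in 1:100) {
    v <- mutate_sequence(anc, 0.7, seed = s)
    expect_true(ident(anc, v) >= 0.65 && ident(anc, v) <= 0.75)
  }
  # replacements never silently extend the alphabet
  expect_false(grepl("[^ACDEFGHIKLMNPQRSTVWY]", mutate_sequence(anc, 0.3, seed = 1)))
  expect_error(mutate_sequence("", 0.5), "non-empty")
  expect_error(mutate_sequence("MK", 1.2), "target_identity")
})

test_that("generation is deterministic, including on-disk output", {
  b1 <- generate_collection(small_spec())
  b2 <- generate_collection(small_spec())
  expect_identical(b1$collection$sequences, b2$collection$sequences)
  expect_identical(b1$contigs, b2$contigs)
  expect_identical(b1$truth, b2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synth_bundle(b1, d1)
  write_synth_bundle(b2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("planted truth satisfies the generator's invariants", {
  # 40 genomes at prevalence 0.3: 12 trait-positive, markers exactly there
  b <- generate_collection(synth_spec(n_genomes = 40, prevalence = 0.3,
                                      seed = 7, background_families = 20))
  tg <- b$truth$genomes
  expect_equal(sum(tg$trait), 12L)
  pr <- b$truth$proteins
  yes <- tg$genome[tg$trait]
  mk <- pr[pr$role == "marker", ]
  expect_setequal(unique(mk$genome), yes)
  for (fam in unique(mk$family))
    expect_setequal(mk$genome[mk$family == fam], yes)
  # dependent families occur only in trait-positive genomes
  dep <- pr[pr$role == "dependent", ]
  expect_true(all(dep$genome %in% yes))
  # the recovered marker profile equals the generation truth
  prof <- profile_from_marker(b$collection,
                              mk$protein[mk$family == mk$family[1]])
  expect_identical(prof$labels[tg$genome],
                   stats::setNames(tg$trait, tg$genome))
  expect_identical(b$profile$labels[tg$genome], prof$labels[tg$genome])
  # precursor genes sit in trait-positive genomes only; decoys everywhere
  prec <- b$truth$precursors
  expect_setequal(prec$genome[prec$role == "precursor"], yes)
  expect_setequal(prec$genome[prec$role == "decoy"], tg$genome)
  # degenerate specs are rejected
  expect_error(generate_collection(synth_spec(n_genomes = 10,
                                              prevalence = 0.01)),
               "no trait-positive")
})

test_that("dependent members carry the diagnostic window, sisters do not", {
  b <- generate_collection(small_spec())
  pr <- b$truth$proteins
  dg <- b$truth$diagnostic
  for (d in seq_len(nrow(dg))) {
    fam <- dg$family[d]
    win <- function(s) substr(s, dg$start[d], dg$start[d] + dg$length[d] - 1)
    dep_seqs <- b$collection$sequences[pr$protein[pr$family == fam]]
    expect_true(all(vapply(dep_seqs, win, character(1)) == dg$true_variant[d]))
    sis <- sub("^dep", "sis", fam)
    sis_seqs <- b$collection$sequences[pr$protein[pr$family == sis]]
    expect_true(all(vapply(sis_seqs, win, character(1)) == dg$false_variant[d]))
  }
})

test_that("planted precursor genes are well-formed genes in their contigs", {
  b <- generate_collection(small_spec())
  prec <- b$truth$precursors
  for (i in seq_len(nrow(prec))) {
    expect_identical(orf_peptide(b$contigs, prec[i, ]), prec$peptide[i])
  }
  pp <- prec$peptide[prec$role == "precursor"]
  expect_true(all(endsWith(pp, "CGVY")))
  expect_false(any(endsWith(prec$peptide[prec$role == "decoy"], "CGVY")))
  # right-aligned conserved tails: at least 7 of the last 8 positions
  # invariant, including the C-terminal suffix
  tails <- substring(pp, nchar(pp) - 22)
  cons <- column_conservation(stats::setNames(tails, seq_along(tails)))
  expect_gte(conservation_summary(cons, 8)$invariant, 7L)
  expect_true(all(cons$invariant[20:23]))
})

test_that("model-based hit tables have the documented structure", {
  b <- generate_collection(small_spec())
  pr <- b$truth$proteins
  q <- pr$protein[pr$role == "background"][1]
  # zero noise: the hit list is exactly the homology group, by identity
  hl0 <- synth_hit_lists(b, queries = q, noise_sd = 0)[[1]]
  grp_members <- pr$protein[pr$group == pr$group[pr$protein == q]]
  expect_setequal(hl0$subject, grp_members)
  expect_equal(hl0$subject[1], q)  # self-hit on top
  expect_true(all(diff(hl0$score_bits) <= 0))

  # with noise: tables parse losslessly through the tabular reader and the
  # family mean stays above the cross-group mean
  d <- withr::local_tempdir()
  f <- file.path(d, "hits.tsv")
  emit_hit_tables(b, f, queries = q)
  back <- read_search_tabular(f, b$collection)[[q]]
  hl <- synth_hit_lists(b, queries = q)[[1]]
  expect_equal(back$subject, hl$subject)
  expect_equal(back$score_bits, hl$score_bits)
  fam_mean <- mean(hl$score_bits[hl$subject %in% grp_members])
  cross_mean <- mean(hl$score_bits[!hl$subject %in% grp_members])
  expect_gt(fam_mean, cross_mean)
})
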