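# Synthetic genome-collection generator.
#
# Emulates the statistical structure that phylogenetic-profile mining
# assumes: a sporadically distributed marker gene system present in a
# minority of genomes, trait-restricted paralog families expanded only in
# trait-positive genomes, a sister clade of homologs present everywhere
# that differs from the trait-linked clade in a short diagnostic window,
# clade-structured background families, and short precursor genes with an
# invariant C-terminus embedded in nucleotide contigs.

#' Synthetic collection specification
#'
#' Defaults describe a desk-scale collection that preserves the profiling
#' regime of real prokaryote collections: 40 genomes in 10 clades of 4,
#' trait prevalence 0.10 (the regime of a sparsely distributed cofactor
#' system, giving 4 trait-positive genomes in distinct clades), ~200
#' proteins per genome, marker genes in all and only trait-positive
#' genomes, and dependent families whose members carry an invariant
#' 15-residue diagnostic window absent from their trait-neutral sister
#' clade. A 3% prevalence mirrors rarer systems but needs a larger
#' `n_genomes` to keep more than a couple of trait-positive genomes.
#'
#' @param seed master RNG seed; all generation randomness derives from it.
#' @param n_genomes number of genomes.
#' @param clade_size genomes per clade (background families are more
#'   similar within than between clades).
#' @param prevalence trait prevalence in (0, 1); trait-positive genomes
#'   are placed in distinct clades while clades remain.
#' @param marker_genes marker families per cluster (1 copy in every
#'   trait-positive genome, absent elsewhere).
#' @param dependent_families trait-restricted paralog families.
#' @param dependent_copies integer range of per-genome copy number for
#'   dependent families in trait-positive genomes.
#' @param background_families families present in every genome (1 copy).
#' @param marker_length,dependent_length,background_length sequence lengths.
#' @param family_identity member-to-ancestor identity for marker/dependent/
#'   sister families.
#' @param within_clade_identity,between_clade_identity background-family
#'   identity structure.
#' @param diagnostic_start,diagnostic_length 1-based window on the
#'   dependent-family ancestor that is held invariant within the
#'   trait-linked clade and replaced by a different invariant residue set
#'   in the sister clade.
#' @param precursor_len_range peptide length range of planted precursor
#'   genes (trait-positive genomes only).
#' @param precursor_suffix invariant C-terminal residues of the precursor.
#' @param contig_length nucleotide contig length per genome.
#' @param noise_sd Gaussian noise (score units) added to model-based hit
#'   table scores.
#' @return object of class `SynthSpec`.
#' @export
synth_spec <- function(seed = 1L, n_genomes = 40L, clade_size = 4L,
                       prevalence = 0.10, marker_genes = 3L,
                       dependent_families = 4L, dependent_copies = c(1L, 6L),
                       background_families = 186L,
                       marker_length = 250L, dependent_length = 150L,
                       background_length = 200L,
                       family_identity = 0.70,
                       within_clade_identity = 0.90,
                       between_clade_identity = 0.65,
                       diagnostic_start = 61L, diagnostic_length = 15L,
                       precursor_len_range = c(30L, 45L),
                       precursor_suffix = "CGVY",
                       contig_length = 2000L, noise_sd = 2) {
  spec <- list(seed = as.integer(seed), n_genomes = as.integer(n_genomes),
               clade_size = as.integer(clade_size), prevalence = prevalence,
               marker_genes = as.integer(marker_genes),
               dependent_families = as.integer(dependent_families),
               dependent_copies = as.integer(dependent_copies),
               background_families = as.integer(background_families),
               marker_length = as.integer(marker_length),
               dependent_length = as.integer(dependent_length),
               background_length = as.integer(background_length),
               family_identity = family_identity,
               within_clade_identity = within_clade_identity,
               between_clade_identity = between_clade_identity,
               diagnostic_start = as.integer(diagnostic_start),
               diagnostic_length = as.integer(diagnostic_length),
               precursor_len_range = as.integer(precursor_len_range),
               precursor_suffix = toupper(precursor_suffix),
               contig_length = as.integer(contig_length),
               noise_sd = noise_sd)
  if (spec$prevalence <= 0 || spec$prevalence >= 1)
    stop("prevalence must lie strictly in (0, 1)")
  ident <- c(spec$family_identity, spec$within_clade_identity,
             spec$between_clade_identity)
  if (any(ident <= 0 | ident > 1)) stop("identities must lie in (0, 1]")
  if (spec$diagnostic_start + spec$diagnostic_length - 1L > spec$dependent_length)
    stop("diagnostic window exceeds the dependent-family length")
  class(spec) <- "SynthSpec"
  spec
}

# substitution-matrix-weighted replacement proposals: P[orig, alt]
# proportional to exp(BLOSUM62 / 2), original residue excluded
.mutation_proposals <- function() {
  if (is.null(.pkg_cache$proposals)) {
    b <- .blosum62()[AA20, AA20]
    w <- exp(b / 2)
    diag(w) <- 0
    .pkg_cache$proposals <- w / rowSums(w)
  }
  .pkg_cache$proposals
}

# row-wise cumulative proposals, for inverse-CDF sampling of replacements
.mutation_cum <- function() {
  if (is.null(.pkg_cache$proposals_cum))
    .pkg_cache$proposals_cum <- t(apply(.mutation_proposals(), 1, cumsum))
  .pkg_cache$proposals_cum
}

#' Mutate a sequence to a target identity
#'
#' Substitutes residues at `round(n * (1 - target_identity))` positions
#' chosen uniformly without replacement; replacements are drawn with
#' substitution-matrix weights (`exp(BLOSUM62/2)`, original residue
#' excluded), so the realized identity equals the target to within half a
#' position. No indels are introduced.
#'
#' @param ancestor non-empty protein sequence.
#' @param target_identity in (0, 1]; 1 returns an identical copy.
#' @param seed optional seed for a self-contained deterministic call; the
#'   caller's RNG state is restored afterwards.
#' @return the mutated sequence.
#' @export
mutate_sequence <- function(ancestor, target_identity, seed = NULL) {
  if (!nzchar(ancestor)) stop("ancestor must be non-empty")
  if (target_identity <= 0 || target_identity > 1)
    stop("target_identity must lie in (0, 1]")
  with_seed(seed, {
    n <- nchar(ancestor)
    k <- round(n * (1 - target_identity))
    if (k == 0L) return(ancestor)
    chars <- strsplit(ancestor, "")[[1L]]
    pos <- sample.int(n, k)
    orig <- chars[pos]
    io <- match(orig, AA20)
    u <- runif(k)
    # inverse-CDF draw from each original residue's proposal row;
    # X (or any non-standard) residue falls back to a uniform draw
    Pc <- .mutation_cum()
    alt <- integer(k)
    known <- !is.na(io)
    if (any(known))
      alt[known] <- pmin(20L,
        rowSums(Pc[io[known], , drop = FALSE] < u[known]) + 1L)
    if (any(!known))
      alt[!known] <- ceiling(u[!known] * 20)
    chars[pos] <- AA20[alt]
    paste(chars, collapse = "")
  })
}

random_protein <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# codons per amino acid for reverse translation (stop codons excluded)
.aa_codons <- function(code_id = "11") {
  key <- paste0("rc", code_id)
  if (is.null(.pkg_cache[[key]])) {
    code <- .codon_table(code_id)
    .pkg_cache[[key]] <- split(names(code), unname(code))
  }
  .pkg_cache[[key]]
}

.reverse_translate <- function(peptide) {
  tab <- .aa_codons()
  aa <- strsplit(peptide, "")[[1L]]
  paste(vapply(aa, function(a) {
    cands <- tab[[a]]
    cands[sample.int(length(cands), 1L)]
  }, character(1)), collapse = "")
}

# overwrite `cassette` into `contig` starting at 1-based `at`
.splice <- function(contig, cassette, at) {
  paste0(substring(contig, 1L, at - 1L), cassette,
         substring(contig, at + nchar(cassette), nchar(contig)))
}

#' Generate a synthetic genome collection with planted truth
#'
#' Produces the full input bundle for an end-to-end profiling run:
#' per-genome proteomes with marker, dependent, sister and background
#' families; nucleotide contigs with planted precursor genes
#' (trait-positive genomes only) and shuffled-suffix decoy genes (all
#' genomes); the trait profile; and truth labels recording every planted
#' feature. Byte-identical output for identical specs.
#'
#' @param spec a [synth_spec()].
#' @return object of class `SynthBundle`: list with `collection`
#'   (a `GenomeCollection`), `contigs` (named character), `profile`
#'   (a `PhyloProfile`), `truth` (list of data.frames: `genomes`,
#'   `proteins`, `diagnostic`, `precursors`) and `spec`.
#' @export
generate_collection <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "SynthSpec"))
  set.seed(spec$seed)
  N <- spec$n_genomes
  genomes <- sprintf("g%02d", seq_len(N))
  clade <- ceiling(seq_len(N) / spec$clade_size)
  K <- round(N * spec$prevalence)
  if (K < 1L) stop("spec yields no trait-positive genome")
  if (K >= N) stop("spec yields no trait-negative genome")
  # sporadic trait: one positive genome per clade while clades remain
  n_clades <- max(clade)
  yes_idx <- integer()
  pick_clades <- sample(seq_len(n_clades), min(K, n_clades))
  for (cl in pick_clades) {
    cand <- which(clade == cl)
    yes_idx <- c(yes_idx, cand[sample.int(length(cand), 1L)])
  }
  if (K > n_clades)
    yes_idx <- c(yes_idx, sample(setdiff(seq_len(N), yes_idx), K - n_clades))
  trait <- stats::setNames(seq_len(N) %in% yes_idx, genomes)
  yes_genomes <- genomes[trait]

  acc <- vector("list", 0L)
  add <- function(id, s, g, f, r, hgrp) {
    acc[[length(acc) + 1L]] <<- c(id, s, g, f, r, hgrp)
  }

  # marker cluster: one copy per trait-positive genome, absent elsewhere
  for (m in seq_len(spec$marker_genes)) {
    anc <- random_protein(spec$marker_length)
    fid <- sprintf("mark%d", m)
    for (g in yes_genomes)
      add(sprintf("%s_%s", g, fid),
          mutate_sequence(anc, spec$family_identity), g, fid, "marker", fid)
  }

  # dependent families plus their trait-neutral sister clades; both share
  # one ancestor outside the diagnostic window, so only that window (and
  # genome of origin) separates the clades
  dws <- spec$diagnostic_start
  dwe <- spec$diagnostic_start + spec$diagnostic_length - 1L
  diag_rows <- vector("list", spec$dependent_families)
  plant_window <- function(s, variant) {
    paste0(substring(s, 1L, dws - 1L), variant,
           substring(s, dwe + 1L, nchar(s)))
  }
  for (d in seq_len(spec$dependent_families)) {
    anc <- random_protein(spec$dependent_length)
    true_var <- substring(anc, dws, dwe)
    false_var <- random_protein(spec$diagnostic_length)
    dep_id <- sprintf("dep%d", d)
    sis_id <- sprintf("sis%d", d)
    hgrp <- sprintf("oxid%d", d)
    diag_rows[[d]] <- data.frame(family = dep_id, start = dws,
                                 length = spec$diagnostic_length,
                                 true_variant = true_var,
                                 false_variant = false_var,
                                 stringsAsFactors = FALSE)
    for (g in yes_genomes) {
      nc <- sample(seq(spec$dependent_copies[1L], spec$dependent_copies[2L]), 1L)
      for (cp in seq_len(nc))
        add(sprintf("%s_%s_%d", g, dep_id, cp),
            plant_window(mutate_sequence(anc, spec$family_identity), true_var),
            g, dep_id, "dependent", hgrp)
    }
    sis_anc <- plant_window(anc, false_var)
    for (g in genomes)
      add(sprintf("%s_%s", g, sis_id),
          plant_window(mutate_sequence(sis_anc, spec$family_identity), false_var),
          g, sis_id, "background", hgrp)
  }

  # clade-structured background families: one copy per genome
  for (bfam in seq_len(spec$background_families)) {
    anc <- random_protein(spec$background_length)
    fid <- sprintf("bg%03d", bfam)
    for (cl in seq_len(n_clades)) {
      cl_anc <- mutate_sequence(anc, spec$between_clade_identity)
      for (g in genomes[clade == cl])
        add(sprintf("%s_%s", g, fid),
            mutate_sequence(cl_anc, spec$within_clade_identity),
            g, fid, "background", fid)
    }
  }

  m <- matrix(unlist(acc), ncol = 6L, byrow = TRUE)
  ids <- m[, 1L]; seqs <- m[, 2L]; gmap <- m[, 3L]
  fam <- m[, 4L]; role <- m[, 5L]; grp <- m[, 6L]
  names(seqs) <- ids
  collection <- genome_collection(seqs, stats::setNames(gmap, ids))
  profile <- phylo_profile(stats::setNames(ifelse(trait, "YES", "NO"), genomes))

  # contigs: conserved 23-residue precursor tail, ending in the invariant
  # suffix, with one variable position among the last eight (so seven of
  # the last eight positions are invariant across planted genes)
  tail_len <- 23L
  sfx <- spec$precursor_suffix
  tail_tpl <- paste0(random_protein(tail_len - nchar(sfx)), sfx)
  var_pos <- tail_len - 7L + 3L   # 5th position from the C-terminus
  decoy_sfx <- paste(rev(strsplit(sfx, "")[[1L]]), collapse = "")
  make_tail <- function(decoy = FALSE) {
    ch <- strsplit(tail_tpl, "")[[1L]]
    mut <- which(runif(tail_len - 8L) < 0.15)
    for (i in mut) ch[i] <- sample(AA20, 1L)
    if (runif(1) < 0.5) ch[var_pos] <- sample(AA20, 1L)
    if (decoy)
      ch[(tail_len - nchar(sfx) + 1L):tail_len] <- strsplit(decoy_sfx, "")[[1L]]
    paste(ch, collapse = "")
  }
  make_gene <- function(decoy = FALSE) {
    plen <- sample(seq(spec$precursor_len_range[1L],
                       spec$precursor_len_range[2L]), 1L)
    pep <- paste0("M", random_protein(plen - 1L - tail_len), make_tail(decoy))
    dna <- paste0("ATG", .reverse_translate(substring(pep, 2L)), "TAA")
    list(peptide = pep, dna = dna)
  }
  contigs <- character(); prec_rows <- list()
  for (g in genomes) {
    contig <- random_dna(spec$contig_length)
    cid <- paste0(g, "_contig1")
    plant <- function(contig, gene, at, strand) {
      cassette <- paste0("TAA", gene$dna)   # in-frame stop upstream of ATG
      glen <- nchar(gene$dna)
      if (strand == "+") {
        contig <- .splice(contig, cassette, at)
        coords <- c(at + 3L, at + 3L + glen - 1L)
      } else {
        contig <- .splice(contig, .revcomp(cassette), at)
        coords <- c(at, at + glen - 1L)
      }
      list(contig = contig, start = coords[1L], end = coords[2L])
    }
    dec <- make_gene(decoy = TRUE)
    st1 <- sample(c("+", "-"), 1L)
    p1 <- plant(contig, dec, sample(100:500, 1L), st1)
    contig <- p1$contig
    prec_rows[[length(prec_rows) + 1L]] <- data.frame(
      genome = g, contig = cid, role = "decoy", strand = st1,
      start = p1$start, end = p1$end, peptide = dec$peptide,
      stringsAsFactors = FALSE)
    if (trait[[g]]) {
      gene <- make_gene()
      st2 <- sample(c("+", "-"), 1L)
      p2 <- plant(contig, gene, sample(1000:1500, 1L), st2)
      contig <- p2$contig
      prec_rows[[length(prec_rows) + 1L]] <- data.frame(
        genome = g, contig = cid, role = "precursor", strand = st2,
        start = p2$start, end = p2$end, peptide = gene$peptide,
        stringsAsFactors = FALSE)
    }
    contigs[[cid]] <- contig
  }

  truth <- list(
    genomes = data.frame(genome = genomes, clade = clade,
                         trait = unname(trait), stringsAsFactors = FALSE),
    proteins = data.frame(protein = ids, genome = gmap, family = fam,
                          role = role, group = grp, stringsAsFactors = FALSE),
    diagnostic = do.call(rbind, diag_rows),
    precursors = do.call(rbind, prec_rows))

  structure(list(collection = collection, contigs = contigs,
                 profile = profile, truth = truth, spec = spec),
            class = "SynthBundle")
}

#' @export
print.SynthBundle <- function(x, ...) {
  cat(sprintf(paste0("SynthBundle: %d genomes (%d trait-positive), ",
                     "%d proteins, seed %d\n"),
              n_genomes(x$collection), x$profile$yes_count,
              length(x$collection$sequences), x$spec$seed))
  invisible(x)
}

#' Model-based hit lists for a synthetic collection
#'
#' Stands in for precomputed all-vs-all similarity searches: within each
#' homology group, pairwise scores are `2 * L * identity` (identity
#' measured position-wise, since the generator introduces no indels) plus
#' Gaussian noise, so within-family scores exceed cross-clade and
#' cross-family scores. With `noise_sd = 0` each hit list is exactly the
#' query's homology group ordered by identity; with noise, a few
#' low-scoring cross-group hits are appended as well.
#'
#' @param bundle a `SynthBundle`.
#' @param queries protein identifiers (default: every protein); a single
#'   genome identifier selects that genome's proteome.
#' @param noise_sd score noise (default: from the spec).
#' @param seed RNG seed for the noise (default: spec seed + 1000).
#' @param cross_hits number of random cross-group hits per query when
#'   `noise_sd > 0`.
#' @return named list of [hit_list()] objects.
#' @export
synth_hit_lists <- function(bundle, queries = NULL, noise_sd = NULL,
                            seed = NULL, cross_hits = 5L) {
  stopifnot(inherits(bundle, "SynthBundle"))
  noise_sd <- noise_sd %||% bundle$spec$noise_sd
  seed <- seed %||% (bundle$spec$seed + 1000L)
  pr <- bundle$truth$proteins
  if (is.null(queries)) queries <- pr$protein
  if (length(queries) == 1L && queries %in% bundle$collection$genomes)
    queries <- pr$protein[pr$genome == queries]
  col <- bundle$collection
  grp <- stats::setNames(pr$group, pr$protein)
  members <- split(pr$protein, pr$group)
  chars <- new.env(parent = emptyenv())
  char_mat <- function(g) {
    if (is.null(chars[[g]])) {
      mm <- members[[g]]
      chars[[g]] <- do.call(rbind, strsplit(unname(col$sequences[mm]), ""))
      rownames(chars[[g]]) <- mm
    }
    chars[[g]]
  }
  with_seed(seed, {
    out <- vector("list", length(queries))
    names(out) <- queries
    for (q in queries) {
      g <- grp[[q]]
      m <- char_mat(g)
      ident <- rowMeans(m == rep(m[q, ], each = nrow(m)))
      L <- ncol(m)
      bits <- 2 * L * ident
      if (noise_sd > 0) bits <- bits + rnorm(length(bits), sd = noise_sd)
      subj <- rownames(m)
      sg <- genome_of(col, subj)
      if (noise_sd > 0 && cross_hits > 0L) {
        pool <- pr$protein[pr$group != g]
        xs <- pool[sample.int(length(pool), min(cross_hits, length(pool)))]
        xl <- nchar(col$sequences[xs])
        xb <- 2 * xl * runif(length(xs), 0.05, 0.15) +
          rnorm(length(xs), sd = noise_sd)
        subj <- c(subj, xs)
        sg <- c(sg, genome_of(col, xs))
        bits <- c(bits, xb)
      }
      out[[q]] <- hit_list(q, subj, sg, round(pmax(bits, 1), 1))
    }
    out
  })
}

#' Write model-based hit tables in BLAST tabular dialect
#'
#' Generates [synth_hit_lists()] and serializes them with
#' [write_search_tabular()], so a profiling run can be exercised from
#' files alone.
#'
#' @inheritParams synth_hit_lists
#' @param file output path.
#' @return invisibly, `file`.
#' @export
emit_hit_tables <- function(bundle, file, queries = NULL, noise_sd = NULL,
                            seed = NULL, cross_hits = 5L) {
  hl <- synth_hit_lists(bundle, queries, noise_sd, seed, cross_hits)
  write_search_tabular(hl, file, bundle$collection)
}

#' Write a synthetic bundle to disk
#'
#' Emits per-genome proteome FASTA files plus the genome map (under
#' `proteomes/`), the trait profile TSV, the contig FASTA and the truth
#' tables, i.e. every input the profiling stages read, plus the metadata
#' needed to regenerate the bundle.
#'
#' @param bundle a `SynthBundle`.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_synth_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_collection(bundle$collection, file.path(dir, "proteomes"))
  write_profile(bundle$profile, file.path(dir, "trait.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(bundle$contigs),
    file.path(dir, "contigs.fna"), width = 70L)
  meta <- sprintf("seed %d", bundle$spec$seed)
  write_tsv_meta(bundle$truth$genomes, file.path(dir, "truth_genomes.tsv"), meta)
  write_tsv_meta(bundle$truth$proteins, file.path(dir, "truth_proteins.tsv"), meta)
  write_tsv_meta(bundle$truth$diagnostic, file.path(dir, "truth_diagnostic.tsv"), meta)
  write_tsv_meta(bundle$truth$precursors, file.path(dir, "truth_precursors.tsv"), meta)
  jsonlite::write_json(unclass(bundle$spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
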