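#' Genome collection: proteomes with a genome-of-origin index
#'
#' A `GenomeCollection` holds the amino-acid sequences of one or more
#' proteomes together with an explicit protein-to-genome map. The map is
#' always supplied as data (a named vector or a two-column table), never
#' parsed out of FASTA headers, so genome resolution is deterministic.
#'
#' @param sequences named character vector (or `AAStringSet`) of protein
#'   sequences; names are protein identifiers and must be unique. Sequences
#'   are uppercased; letters outside the 20 standard residues become `X`
#'   with a warning.
#' @param protein_genome named character vector mapping protein identifier
#'   to genome identifier; must cover every sequence.
#' @return an object of class `GenomeCollection` with elements `sequences`
#'   (named character), `protein_index` (protein -> genome) and `genomes`
#'   (unique genome identifiers).
#' @seealso [read_fasta_collection()], [write_collection()]
#' @export
genome_collection <- function(sequences, protein_genome) {
  if (methods::is(sequences, "XStringSet"))
    sequences <- as.character(sequences)
  if (length(sequences) == 0L) stop("collection must contain at least one protein")
  ids <- names(sequences)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("all sequences must be named by a protein identifier")
  if (anyDuplicated(ids))
    stop("duplicate protein identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(nchar(sequences) == 0L)) stop("empty sequence(s) in collection")
  sequences <- sanitize_aa(sequences)
  missing <- setdiff(ids, names(protein_genome))
  if (length(missing))
    stop("no genome mapping for protein(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  idx <- as.character(protein_genome[ids])
  names(idx) <- ids
  structure(
    list(sequences = sequences, protein_index = idx,
         genomes = unique(unname(idx))),
    class = "GenomeCollection"
  )
}

#' @export
print.GenomeCollection <- function(x, ...) {
  cat(sprintf("GenomeCollection: %d proteins across %d genomes\n",
              length(x$sequences), length(x$genomes)))
  invisible(x)
}

#' Number of genomes / protein identifiers of a collection
#' @param x a `GenomeCollection`.
#' @return `n_genomes()`: integer; `proteins()`: character vector of ids.
#' @export
n_genomes <- function(x) length(x$genomes)

#' @rdname n_genomes
#' @export
proteins <- function(x) names(x$sequences)

#' Genome of origin for protein identifiers
#' @param x a `GenomeCollection`.
#' @param ids protein identifiers.
#' @return character vector of genome identifiers (errors on unknown ids).
#' @export
genome_of <- function(x, ids) {
  g <- x$protein_index[ids]
  if (anyNA(g)) stop("unknown protein identifier(s): ",
                     paste(utils::head(ids[is.na(g)], 5L), collapse = ", "))
  unname(g)
}

#' Read proteome FASTA files plus a genome map into a collection
#'
#' @param fasta_files paths to protein FASTA files. Record identifiers are
#'   the first whitespace-delimited token of each header.
#' @param map_file two-column TSV with a header (`protein`, `genome`)
#'   mapping every record identifier to its genome.
#' @return a [genome_collection()].
#' @export
read_fasta_collection <- function(fasta_files, map_file) {
  seqs <- character()
  for (f in fasta_files) {
    s <- Biostrings::readAAStringSet(f)
    if (length(s) == 0L) stop("empty FASTA file: ", f)
    names(s) <- sub("\\s.*$", "", names(s))
    s <- as.character(s)
    dup <- intersect(names(s), names(seqs))
    if (length(dup) || anyDuplicated(names(s)))
      stop("duplicate protein identifier(s) across FASTA input: ",
           paste(utils::head(c(dup, names(s)[duplicated(names(s))]), 5L),
                 collapse = ", "))
    seqs <- c(seqs, s)
  }
  map <- read_tsv_meta(map_file)
  if (ncol(map) < 2L) stop("genome map must have two columns (protein, genome)")
  pg <- stats::setNames(as.character(map[[2L]]), as.character(map[[1L]]))
  genome_collection(seqs, pg)
}

#' Write a collection as per-genome FASTA files plus a genome map
#'
#' @param collection a `GenomeCollection`.
#' @param dir output directory (created if needed). One
#'   `<genome>.faa` per genome plus `genome_map.tsv`.
#' @return invisibly, the paths of the FASTA files written.
#' @export
write_collection <- function(collection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (g in collection$genomes) {
    ids <- names(collection$protein_index)[collection$protein_index == g]
    p <- file.path(dir, paste0(g, ".faa"))
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(collection$sequences[ids]), p, width = 70L)
    paths <- c(paths, p)
  }
  map <- data.frame(protein = proteins(collection),
                    genome = unname(collection$protein_index),
                    stringsAsFactors = FALSE)
  write_tsv_meta(map, file.path(dir, "genome_map.tsv"))
  invisible(paths)
}

#' Phylogenetic profile: per-genome trait labels
#'
#' A YES/NO trait vector over the genomes of a collection, with the trait
#' prevalence `p = K / N` used as the binomial null in PPP scoring. A
#' profile with no YES or no NO genomes carries no information and is
#' rejected.
#'
#' @param labels named logical vector (or character `"YES"`/`"NO"`), one
#'   entry per genome.
#' @param override_prevalence optional prevalence in (0, 1) replacing the
#'   empirical `K / N`; used to calibrate scoring against a reference
#'   profile whose exact genome composition is not available.
#' @return an object of class `PhyloProfile` with elements `labels`
#'   (named logical), `yes_count`, `total` and `prevalence`.
#' @export
phylo_profile <- function(labels, override_prevalence = NULL) {
  if (is.character(labels)) {
    up <- toupper(labels)
    if (!all(up %in% c("YES", "NO")))
      stop("trait labels must be YES or NO")
    labels <- stats::setNames(up == "YES", names(labels))
  }
  if (!is.logical(labels) || is.null(names(labels)) || anyNA(labels))
    stop("labels must be a complete named logical vector")
  if (anyDuplicated(names(labels)))
    stop("genome(s) labelled more than once: ",
         paste(unique(names(labels)[duplicated(names(labels))]), collapse = ", "))
  K <- sum(labels); N <- length(labels)
  if (K == 0L || K == N)
    stop("uninformative profile: need at least one YES and one NO genome")
  p <- K / N
  if (!is.null(override_prevalence)) {
    if (override_prevalence <= 0 || override_prevalence >= 1)
      stop("override_prevalence must lie strictly in (0, 1)")
    p <- override_prevalence
  }
  structure(list(labels = labels, yes_count = K, total = N,
                 prevalence = p),
            class = "PhyloProfile")
}

#' @export
print.PhyloProfile <- function(x, ...) {
  cat(sprintf("PhyloProfile: %d YES / %d genomes (prevalence %.4f)\n",
              x$yes_count, x$total, x$prevalence))
  invisible(x)
}

#' Read a trait profile TSV against a collection
#'
#' @param file two-column TSV with header (`genome`, `trait`), trait
#'   being `YES` or `NO`. Every genome of the collection must be labelled
#'   exactly once, and no extra genomes may appear.
#' @param collection a `GenomeCollection`.
#' @return a [phylo_profile()].
#' @export
read_profile <- function(file, collection) {
  tab <- read_tsv_meta(file)
  if (ncol(tab) < 2L) stop("profile must have two columns (genome, trait)")
  g <- as.character(tab[[1L]])
  unknown <- setdiff(g, collection$genomes)
  if (length(unknown))
    stop("profile labels genome(s) not in the collection: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  unlabelled <- setdiff(collection$genomes, g)
  if (length(unlabelled))
    stop("genome(s) without a trait label: ",
         paste(utils::head(unlabelled, 5L), collapse = ", "))
  phylo_profile(stats::setNames(as.character(tab[[2L]]), g))
}

#' Write a trait profile TSV
#' @param profile a `PhyloProfile`.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_profile <- function(profile, file) {
  df <- data.frame(genome = names(profile$labels),
                   trait = ifelse(profile$labels, "YES", "NO"),
                   stringsAsFactors = FALSE)
  write_tsv_meta(df, file,
                 meta = sprintf("prevalence %d/%d = %.6f",
                                profile$yes_count, profile$total,
                                profile$prevalence))
}
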