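#' Configuration for the PPP cutoff walk
#'
#' @param max_depth maximum number of hits to traverse (default: the full
#'   list). A tie block is never split: candidate cutoffs beyond
#'   `max_depth` are discarded even when the block containing `max_depth`
#'   extends past it.
#' @param count_self_genome should the query's own genome count toward the
#'   trait-positive and total genome tallies (default `TRUE`, matching
#'   published score tables where perfect rows include the query genome).
#' @return an object of class `PPPConfig`.
#' @export
ppp_config <- function(max_depth = Inf, count_self_genome = TRUE) {
  if (is.finite(max_depth) && max_depth < 1) stop("max_depth must be >= 1")
  structure(list(max_depth = max_depth,
                 count_self_genome = isTRUE(count_self_genome)),
            class = "PPPConfig")
}

# Shared cutoff walk over a ranked, labelled hit sequence.
#
# unit:  profile unit of each hit (genome id for PPP, sequence id for
#        window scoring); a unit contributes once to y/n however often it
#        is hit, while every traversed hit counts toward depth.
# label: logical, is the hit's unit trait-positive.
# bits:  non-increasing scores; equal values form atomic tie blocks.
# count: logical, does the hit's unit count toward y/n at all.
#
# Candidate cutoffs are the tie-block boundaries plus the empty prefix.
# Returns the cutoff minimizing log10_binom_tail(y, n, p); exact score
# ties resolve to the shallower cutoff (candidates are scanned in depth
# order and which.min takes the first minimum).
.walk_cutoffs <- function(unit, label, bits, p, count = TRUE,
                          max_depth = Inf) {
  d <- length(bits)
  if (d == 0L)
    return(list(yes = 0L, total = 0L, depth = 0L, score = 0))
  count <- rep_len(count, d)
  first <- !duplicated(unit) & count
  cn <- cumsum(first)
  cy <- cumsum(first & label)
  b <- c(which(diff(bits) < 0), d)
  if (is.finite(max_depth)) b <- b[b <= max_depth]
  cand_depth <- c(0L, b)
  cand_score <- c(0, if (length(b)) log10_binom_tail(cy[b], cn[b], p))
  i <- which.min(cand_score)
  list(yes = if (i == 1L) 0L else as.integer(cy[b[i - 1L]]),
       total = if (i == 1L) 0L else as.integer(cn[b[i - 1L]]),
       depth = as.integer(cand_depth[i]),
       score = cand_score[i])
}

#' Optimal-cutoff binomial enrichment score for one hit list
#'
#' The per-protein computation of Partial Phylogenetic Profiling: walk the
#' ranked hit list over every admissible score cutoff (tie blocks are
#' atomic), and at each cutoff count the distinct genomes seen (`total`),
#' the distinct trait-positive genomes (`yes`) and the hits traversed
#' (`depth`); the reported cutoff minimizes the log10 binomial upper-tail
#' probability of `yes` successes in `total` draws at the profile
#' prevalence. On exact score ties the shallower cutoff wins, and the
#' empty prefix (score 0) is a legal outcome.
#'
#' @param hitlist a `HitList`; every subject genome must be covered by the
#'   profile.
#' @param profile a `PhyloProfile`.
#' @param config a [ppp_config()].
#' @param query_genome genome of the query protein; only needed when
#'   `config$count_self_genome` is `FALSE`.
#' @return an object of class `PPPResult`: list with `query`, `yes`,
#'   `total`, `depth`, `score`.
#' @export
evaluate_prefixes <- function(hitlist, profile, config = ppp_config(),
                              query_genome = NULL) {
  stopifnot(inherits(profile, "PhyloProfile"))
  qid <- attr(hitlist, "query") %||% (if (nrow(hitlist)) hitlist$query[1L] else NA_character_)
  lab <- profile$labels[hitlist$subject_genome]
  if (anyNA(lab))
    stop("profile does not cover genome(s): ",
         paste(utils::head(unique(hitlist$subject_genome[is.na(lab)]), 5L),
               collapse = ", "))
  count <- TRUE
  if (!config$count_self_genome) {
    if (is.null(query_genome))
      stop("query_genome required when count_self_genome = FALSE")
    count <- hitlist$subject_genome != query_genome
  }
  res <- .walk_cutoffs(hitlist$subject_genome, unname(lab),
                       hitlist$score_bits, profile$prevalence,
                       count = count, max_depth = config$max_depth)
  structure(c(list(query = qid), res), class = "PPPResult")
}

#' @export
print.PPPResult <- function(x, ...) {
  cat(sprintf("%s: yes %d / total %d (depth %d), score %.3f\n",
              x$query, x$yes, x$total, x$depth, x$score))
  invisible(x)
}

#' Rank every protein of a genome by PPP score
#'
#' Applies [evaluate_prefixes()] to each protein encoded by the target
#' genome and returns the per-protein score table sorted most-significant
#' first (ascending score; ties broken by protein identifier, so the table
#' is invariant to input protein order).
#'
#' @param genome target genome identifier.
#' @param hits named list of `HitList` objects (e.g. from
#'   [read_search_tabular()] or [synth_hit_lists()]); proteins without an
#'   entry are treated as having an empty hit list.
#' @param profile a `PhyloProfile`.
#' @param collection the `GenomeCollection` defining the genome's proteins.
#' @param config a [ppp_config()].
#' @return data.frame of class `PPPTable` with columns `query`, `yes`,
#'   `total`, `depth`, `score`.
#' @export
ppp_rank_genome <- function(genome, hits, profile, collection,
                            config = ppp_config()) {
  if (!genome %in% collection$genomes)
    stop("genome not in collection: ", genome)
  prots <- names(collection$protein_index)[collection$protein_index == genome]
  rows <- lapply(prots, function(pid) {
    hl <- hits[[pid]] %||% empty_hit_list(pid)
    r <- evaluate_prefixes(hl, profile, config, query_genome = genome)
    data.frame(query = pid, yes = r$yes, total = r$total,
               depth = r$depth, score = r$score, stringsAsFactors = FALSE)
  })
  tbl <- do.call(rbind, rows)
  tbl <- tbl[order(tbl$score, tbl$query), , drop = FALSE]
  rownames(tbl) <- NULL
  class(tbl) <- c("PPPTable", "data.frame")
  tbl
}

#' Write a PPP score table as TSV
#'
#' Mirrors the published table layout: one row per query with `yes`,
#' `total`, `depth` and the score to six decimals, preceded by
#' `#`-prefixed metadata lines.
#'
#' @param tbl a `PPPTable`.
#' @param file output path.
#' @param meta character vector of metadata lines.
#' @return invisibly, `file`.
#' @export
write_ppp_table <- function(tbl, file, meta = character()) {
  out <- tbl
  out$score <- sprintf("%.6f", out$score)
  write_tsv_meta(out, file, meta)
}

#' Build a trait profile from marker-family membership
#'
#' Labels a genome trait-positive iff it encodes at least one member of
#' the marker family; the resulting profile is the query for
#' [ppp_rank_genome()].
#'
#' @param collection a `GenomeCollection`.
#' @param members non-empty character vector of marker protein identifiers.
#' @return a [phylo_profile()]; errors if the marker covers no genome or
#'   every genome (uninformative profile).
#' @export
profile_from_marker <- function(collection, members) {
  if (!length(members)) stop("marker membership must be non-empty")
  yes <- unique(genome_of(collection, members))
  labels <- stats::setNames(collection$genomes %in% yes, collection$genomes)
  phylo_profile(labels)
}
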