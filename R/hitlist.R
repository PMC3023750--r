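#' Ranked similarity hit list for one query protein
#'
#' A `HitList` is a data.frame of similarity hits for a single query,
#' sorted by non-increasing bit score with 1-based consecutive ranks.
#' Ties in bit score keep their input order (stable sort), so equal-score
#' hits form contiguous blocks that the PPP cutoff walk treats as atomic.
#'
#' @param query query protein identifier.
#' @param subject character vector of subject protein identifiers.
#' @param subject_genome genome of origin of each subject.
#' @param score_bits finite numeric similarity scores.
#' @return a data.frame of class `HitList` with columns `query`, `subject`,
#'   `subject_genome`, `score_bits`, `rank`, and attribute `query`.
#' @export
hit_list <- function(query, subject, subject_genome, score_bits) {
  n <- length(subject)
  if (length(subject_genome) != n || length(score_bits) != n)
    stop("subject, subject_genome and score_bits must have equal length")
  if (n && any(!is.finite(score_bits)))
    stop("hit scores must be finite")
  o <- order(-score_bits)   # radix sort: stable within ties
  df <- data.frame(query = rep_len(as.character(query), n),
                   subject = as.character(subject)[o],
                   subject_genome = as.character(subject_genome)[o],
                   score_bits = as.numeric(score_bits)[o],
                   rank = seq_len(n),
                   stringsAsFactors = FALSE)
  attr(df, "query") <- as.character(query)
  class(df) <- c("HitList", "data.frame")
  df
}

#' @rdname hit_list
#' @export
empty_hit_list <- function(query) {
  hit_list(query, character(), character(), numeric())
}

#' Read BLAST tabular (outfmt 6) search output into hit lists
#'
#' Parses 12-column tab-separated search results (query, subject, percent
#' identity, alignment length, mismatches, gap opens, qstart, qend, sstart,
#' send, evalue, bit score), groups rows by query, re-sorts each group by
#' descending bit score (stable within ties) and resolves each subject's
#' genome through the collection's protein index. Lines starting with `#`
#' are ignored.
#'
#' @param file path to the tabular file.
#' @param collection a `GenomeCollection` used to resolve subject genomes.
#' @param unknown_subject `"error"` (default) to fail on subjects absent
#'   from the collection, or `"skip"` to drop them with one warning.
#' @return named list of [hit_list()] objects, in order of first appearance
#'   of each query.
#' @export
read_search_tabular <- function(file, collection,
                                unknown_subject = c("error", "skip")) {
  unknown_subject <- match.arg(unknown_subject)
  lines <- readLines(file)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  idx <- which(keep)
  if (!length(idx)) return(list())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- idx[which(nf != 12L)[1L]]
    stop(sprintf("line %d of %s: expected 12 tab-separated columns, found %d",
                 bad, file, nf[which(nf != 12L)[1L]]))
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  qid <- m[, 1L]; sid <- m[, 2L]
  bits <- as.numeric(m[, 12L])
  if (anyNA(bits)) stop("non-numeric bit score in ", file)
  sg <- collection$protein_index[sid]
  if (anyNA(sg)) {
    if (unknown_subject == "error")
      stop("subject(s) not in collection: ",
           paste(utils::head(unique(sid[is.na(sg)]), 5L), collapse = ", "))
    warning(sum(is.na(sg)), " hit(s) with unknown subject skipped", call. = FALSE)
    ok <- !is.na(sg)
    qid <- qid[ok]; sid <- sid[ok]; bits <- bits[ok]; sg <- sg[ok]
  }
  out <- lapply(split(seq_along(qid), factor(qid, levels = unique(qid))),
                function(i) hit_list(qid[i[1L]], sid[i], unname(sg[i]), bits[i]))
  out
}

#' Write hit lists in BLAST tabular (outfmt 6) dialect
#'
#' Columns the package does not model (coordinates, mismatches) are filled
#' with consistent placeholder values derived from the subject length and
#' score, so that files round-trip through [read_search_tabular()].
#'
#' @param hitlists list of `HitList` objects.
#' @param file output path.
#' @param collection optional `GenomeCollection` supplying subject lengths.
#' @return invisibly, `file`.
#' @export
write_search_tabular <- function(hitlists, file, collection = NULL) {
  con <- file(file, open = "wt")
  on.exit(close(con))
  for (hl in hitlists) {
    if (!nrow(hl)) next
    len <- if (!is.null(collection)) nchar(collection$sequences[hl$subject])
           else rep(100L, nrow(hl))
    pid <- pmax(0, pmin(100, round(100 * hl$score_bits / (2 * len), 1)))
    ev <- signif(10^(-hl$score_bits / 10), 3)
    writeLines(sprintf("%s\t%s\t%.1f\t%d\t%d\t0\t1\t%d\t1\t%d\t%.3g\t%.1f",
                       hl$query, hl$subject, pid, len,
                       as.integer(round((1 - pid / 100) * len)),
                       len, len, ev, hl$score_bits), con)
  }
  invisible(file)
}
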