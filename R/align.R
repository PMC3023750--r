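#' Scoring parameters for the built-in local-alignment backend
#'
#' @param matrix substitution matrix: the name of a matrix shipped with
#'   Biostrings (default `"BLOSUM62"`) or a symmetric numeric matrix with
#'   residue dimnames.
#' @param gap_open positive gap-opening penalty. A gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @param gap_extend positive per-residue gap-extension penalty.
#' @param score_floor minimum raw score for a hit to be reported by
#'   [rank_hits()]; the default 0 reports every positive-scoring subject.
#' @return an object of class `ScoringParams`.
#' @export
scoring_params <- function(matrix = "BLOSUM62", gap_open = 11,
                           gap_extend = 1, score_floor = 0) {
  if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    mat <- e[[matrix]]
    name <- matrix
  } else {
    mat <- matrix
    name <- "custom"
  }
  if (!isSymmetric(unname(mat)))
    stop("substitution matrix must be symmetric")
  if (gap_open <= 0 || gap_extend <= 0)
    stop("gap penalties must be positive")
  storage.mode(mat) <- "double"
  structure(list(matrix = mat, matrix_name = name,
                 alphabet = paste(rownames(mat), collapse = ""),
                 gap_open = gap_open, gap_extend = gap_extend,
                 score_floor = score_floor),
            class = "ScoringParams")
}

#' Smith-Waterman local alignment score
#'
#' Optimal local alignment score with affine gap penalties, computed by the
#' standard three-state dynamic programme (match, gap-in-a, gap-in-b). The
#' score is symmetric in its arguments and floored at 0, as for any local
#' alignment. Raw scores are used directly for ranking; no bit-score
#' conversion is applied, since the profiling machinery consumes only the
#' ordering and cutoff structure of hit lists.
#'
#' @param a,b non-empty protein sequences. `b` may be a vector, in which
#'   case one score per element is returned.
#' @param params a [scoring_params()] object.
#' @return numeric score(s), `>= 0`.
#' @export
local_align_score <- function(a, b, params = scoring_params()) {
  if (length(a) != 1L || !nzchar(a) || any(!nzchar(b)) || length(b) == 0L)
    stop("sequences must be non-empty")
  a <- sanitize_aa(a, warn = FALSE)
  b <- sanitize_aa(b, warn = FALSE)
  .sw_score_many(a, as.character(b), params$matrix, params$alphabet,
                 params$gap_open, params$gap_extend)
}

#' Rank all collection proteins by similarity to a query
#'
#' Scores the query against every protein in the collection with the
#' built-in Smith-Waterman backend and returns the hits above the score
#' floor as a [hit_list()] (stable descending order; the self-hit is
#' included when the query belongs to the collection).
#'
#' @param query a protein identifier present in `collection`, or a raw
#'   sequence (then supply `query_id`).
#' @param collection a `GenomeCollection`.
#' @param params a [scoring_params()] object.
#' @param query_id identifier recorded in the hit list when `query` is a
#'   raw sequence.
#' @return a `HitList` (possibly empty).
#' @export
rank_hits <- function(query, collection, params = scoring_params(),
                      query_id = NULL) {
  if (query %in% proteins(collection)) {
    qseq <- collection$sequences[[query]]
    qid <- query
  } else {
    qseq <- query
    qid <- query_id %||% "query"
  }
  subjects <- proteins(collection)
  if (!length(subjects)) return(empty_hit_list(qid))
  sc <- local_align_score(qseq, collection$sequences, params)
  keep <- sc > params$score_floor
  hit_list(qid, subjects[keep],
           unname(collection$protein_index[subjects[keep]]), sc[keep])
}
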