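#' Trait-partitioned training set for subsequence mapping
#'
#' @param true_seqs named character vector of sequences from trait-positive
#'   genomes.
#' @param false_seqs named character vector of sequences from trait-negative
#'   genomes. Names must not overlap `true_seqs`.
#' @return an object of class `TrainingSet` with elements `true_seqs`,
#'   `false_seqs` and the sequence-level prevalence
#'   `p_t = |TRUE| / (|TRUE| + |FALSE|)`.
#' @export
training_set <- function(true_seqs, false_seqs) {
  if (!length(true_seqs) || !length(false_seqs))
    stop("both training partitions must be non-empty")
  if (is.null(names(true_seqs)) || is.null(names(false_seqs)))
    stop("training sequences must be named")
  both <- intersect(names(true_seqs), names(false_seqs))
  if (length(both))
    stop("sequence(s) in both partitions: ", paste(both, collapse = ", "))
  structure(list(true_seqs = true_seqs, false_seqs = false_seqs,
                 p_t = length(true_seqs) /
                   (length(true_seqs) + length(false_seqs))),
            class = "TrainingSet")
}

#' @export
print.TrainingSet <- function(x, ...) {
  cat(sprintf("TrainingSet: %d TRUE / %d FALSE (p_t = %.4f)\n",
              length(x$true_seqs), length(x$false_seqs), x$p_t))
  invisible(x)
}

#' Greedy dereplication at an identity ceiling
#'
#' Thins a sequence set so that no kept pair exceeds `max_identity`.
#' Sequences are scanned in input order; a sequence is kept iff its
#' identity to every already-kept sequence is `<= max_identity` (the
#' threshold itself is kept, i.e. only *strictly greater* identity is
#' removed). Identity is matches over aligned columns of a global
#' alignment, end gaps included.
#'
#' @param sequences named character vector.
#' @param max_identity identity ceiling in (0, 1], default 0.80.
#' @param params a [scoring_params()] used for the global alignment.
#' @return the kept subset, in input order.
#' @export
dereplicate <- function(sequences, max_identity = 0.80,
                        params = scoring_params()) {
  if (!length(sequences)) stop("need at least one sequence")
  sequences <- sanitize_aa(sequences, warn = FALSE)
  kept <- sequences[1L]
  for (i in seq_along(sequences)[-1L]) {
    ids <- .global_identity(sequences[[i]], kept, params)
    if (all(ids <= max_identity)) kept <- c(kept, sequences[i])
  }
  kept
}

# Global-alignment identity of one sequence against a set:
# matches / alignment columns (all gaps counted).
.global_identity <- function(seq, set, params = scoring_params()) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(as.character(set)),
    subject = seq,
    type = "global",
    substitutionMatrix = params$matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  Biostrings::pid(pa, type = "PID1") / 100
}

#' Build a SIMBAL training set from a labelled protein family
#'
#' Splits family members into TRUE and FALSE partitions by the trait label
#' of their genome of origin, drops fragmentary sequences (shorter than
#' `min_length_frac` of the partition's median length) and dereplicates
#' each partition independently at `max_identity`.
#'
#' @param sequences named character vector of family member sequences.
#' @param genomes genome of origin for each sequence (recycled names are
#'   not allowed; supply one genome per sequence). Alternatively pass
#'   `collection` and leave `genomes = NULL` to resolve by protein id.
#' @param profile a `PhyloProfile` covering every genome of origin.
#' @param collection optional `GenomeCollection` for genome resolution.
#' @param min_length_frac fragment filter threshold (default 0.5).
#' @param max_identity dereplication ceiling (default 0.80).
#' @param params a [scoring_params()].
#' @return a [training_set()]; errors if either partition is empty after
#'   filtering.
#' @export
build_training <- function(sequences, genomes = NULL, profile,
                           collection = NULL, min_length_frac = 0.5,
                           max_identity = 0.80, params = scoring_params()) {
  if (is.null(genomes)) {
    if (is.null(collection))
      stop("supply either `genomes` or a `collection` to resolve them")
    genomes <- genome_of(collection, names(sequences))
  }
  if (length(genomes) != length(sequences))
    stop("one genome per sequence required")
  lab <- profile$labels[genomes]
  if (anyNA(lab))
    stop("profile does not cover genome(s): ",
         paste(utils::head(unique(genomes[is.na(lab)]), 5L), collapse = ", "))
  prep <- function(seqs, what) {
    if (!length(seqs)) stop("empty ", what, " partition")
    keep <- nchar(seqs) >= min_length_frac * stats::median(nchar(seqs))
    seqs <- seqs[keep]
    if (!length(seqs)) stop("empty ", what, " partition after length filter")
    dereplicate(seqs, max_identity, params)
  }
  training_set(prep(sequences[lab], "TRUE"),
               prep(sequences[!lab], "FALSE"))
}

#' Enumerate subsequence windows of a probe
#'
#' All (start, length) windows with lengths `min_len, min_len + len_step,
#' ...` plus the full probe length (the apex), and starts stepped by
#' `pos_step`. Starts are 0-based; `center = start + length / 2`.
#'
#' @param probe_length probe length L (must be `>= min_len`).
#' @param min_len smallest window (default 8).
#' @param len_step length increment (default 4).
#' @param pos_step start increment (default 2).
#' @return data.frame with columns `start`, `length`, `center`.
#' @export
enumerate_windows <- function(probe_length, min_len = 8, len_step = 4,
                              pos_step = 2) {
  if (probe_length < min_len)
    stop("probe shorter than the minimum window length")
  lens <- unique(c(seq(min_len, probe_length, by = len_step), probe_length))
  out <- do.call(rbind, lapply(lens, function(l) {
    st <- seq(0L, probe_length - l, by = pos_step)
    data.frame(start = st, length = l)
  }))
  out$center <- out$start + out$length / 2
  rownames(out) <- NULL
  out
}

#' Score one subsequence window against a training set
#'
#' Ranks every training sequence by local-alignment similarity to the
#' window and walks score cutoffs exactly as [evaluate_prefixes()] does,
#' except that each training sequence is its own profile unit (label =
#' its partition) and the null prevalence is the training set's `p_t`.
#' Reported on the display scale: `-(best log10 tail) >= 0`, so hotter is
#' larger. A window with no positive-scoring hit returns 0.
#'
#' @param window_seq the window's amino-acid sequence.
#' @param training a `TrainingSet`.
#' @param params a [scoring_params()].
#' @param config a [ppp_config()] (depth cap only; the self-genome switch
#'   has no meaning here).
#' @return non-negative numeric score.
#' @export
score_window <- function(window_seq, training, params = scoring_params(),
                         config = ppp_config()) {
  seqs <- c(training$true_seqs, training$false_seqs)
  lab <- rep(c(TRUE, FALSE),
             c(length(training$true_seqs), length(training$false_seqs)))
  sc <- local_align_score(window_seq, seqs, params)
  keep <- sc > params$score_floor
  if (!any(keep)) return(0)
  o <- order(-sc[keep])
  ids <- names(seqs)[keep][o]
  res <- .walk_cutoffs(ids, lab[keep][o], sc[keep][o], training$p_t,
                       max_depth = config$max_depth)
  -res$score
}

#' SIMBAL heat map: score every window of a probe
#'
#' Scores each window from [enumerate_windows()] with [score_window()],
#' yielding the triangular (center x length) score surface whose single
#' full-length point is the apex. The apex score equals the full-length
#' enrichment score, i.e. minus the PPP-style score of the whole probe
#' against the training set with each sequence as its own profile unit.
#'
#' @param probe single named character: the probe sequence.
#' @param training a `TrainingSet`.
#' @param params a [scoring_params()].
#' @param min_len,len_step,pos_step window grid, see [enumerate_windows()].
#' @param config a [ppp_config()].
#' @return object of class `SimbalGrid`: list with `probe`, `length`,
#'   `windows` (data.frame start/length/center/score) and `apex_score`.
#' @export
simbal_heatmap <- function(probe, training, params = scoring_params(),
                           min_len = 8, len_step = 4, pos_step = 2,
                           config = ppp_config()) {
  pseq <- sanitize_aa(as.character(probe)[1L], warn = FALSE)
  L <- nchar(pseq)
  w <- enumerate_windows(L, min_len, len_step, pos_step)
  wseq <- substring(pseq, w$start + 1L, w$start + w$length)
  # batch path: sanitize the training set once, then score each window
  seqs <- sanitize_aa(c(training$true_seqs, training$false_seqs), warn = FALSE)
  lab <- rep(c(TRUE, FALSE),
             c(length(training$true_seqs), length(training$false_seqs)))
  w$score <- vapply(wseq, function(ws) {
    sc <- .sw_score_many(ws, seqs, params$matrix, params$alphabet,
                         params$gap_open, params$gap_extend)
    keep <- sc > params$score_floor
    if (!any(keep)) return(0)
    o <- order(-sc[keep])
    -.walk_cutoffs(names(seqs)[keep][o], lab[keep][o], sc[keep][o],
                   training$p_t, max_depth = config$max_depth)$score
  }, numeric(1), USE.NAMES = FALSE)
  structure(list(probe = names(probe) %||% "probe", length = L,
                 min_len = min_len, len_step = len_step,
                 pos_step = pos_step, windows = w,
                 apex_score = w$score[w$length == L]),
            class = "SimbalGrid")
}

#' @export
print.SimbalGrid <- function(x, ...) {
  cat(sprintf("SimbalGrid: probe %s (L = %d), %d windows, apex %.3f, max %.3f\n",
              x$probe, x$length, nrow(x$windows), x$apex_score,
              max(x$windows$score)))
  invisible(x)
}

#' Highest-scoring window of a SIMBAL grid
#'
#' Ties resolve to the shortest window, then the smallest start, i.e. the
#' most localized signal.
#'
#' @param grid a `SimbalGrid`.
#' @return one-row data.frame (start, length, center, score).
#' @export
max_window <- function(grid) {
  w <- grid$windows
  w <- w[order(-w$score, w$length, w$start), , drop = FALSE]
  w[1L, , drop = FALSE]
}

#' Write a SIMBAL grid as TSV
#' @param grid a `SimbalGrid`.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_simbal_grid <- function(grid, file) {
  write_tsv_meta(grid$windows, file,
                 meta = c(sprintf("probe %s length %d", grid$probe, grid$length),
                          sprintf("grid min_len %d len_step %d pos_step %d",
                                  grid$min_len, grid$len_step, grid$pos_step),
                          sprintf("apex_score %.6f", grid$apex_score)))
}

#' Plot a SIMBAL grid as a triangular heat map
#'
#' @param x a `SimbalGrid`.
#' @param ... passed to [graphics::plot.default()].
#' @return invisibly, `x`.
#' @export
plot.SimbalGrid <- function(x, ...) {
  w <- x$windows
  pal <- grDevices::colorRampPalette(
    c("blue3", "cyan3", "green3", "yellow", "orange", "red"))(64)
  sc <- w$score - min(w$score)
  col <- pal[pmax(1L, ceiling(64 * sc / max(sc, .Machine$double.eps)))]
  graphics::plot(w$center, w$length, col = col, pch = 15, cex = 0.6,
                 xlab = "window center (residue)", ylab = "window length",
                 main = sprintf("%s (apex %.1f, max %.1f)",
                                x$probe, x$apex_score, max(w$score)), ...)
  invisible(x)
}

#' Map a probe window onto a homolog by global alignment
#'
#' Globally aligns the probe to a homolog and reports the homolog residue
#' interval aligned to the window (1-based, inclusive), together with how
#' many window positions aligned to residues vs. gaps.
#'
#' @param window list or one-row data.frame with `start` (0-based) and
#'   `length` on the probe.
#' @param probe probe sequence.
#' @param homolog homolog sequence.
#' @param params a [scoring_params()].
#' @return list with `start`, `end` (NA when the window falls entirely in
#'   a gap, with `empty = TRUE`), `n_aligned`, `n_gapped`, `empty`.
#' @export
map_window_to_homolog <- function(window, probe, homolog,
                                  params = scoring_params()) {
  probe <- sanitize_aa(as.character(probe)[1L], warn = FALSE)
  homolog <- sanitize_aa(as.character(homolog)[1L], warn = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = probe, subject = homolog, type = "global",
    substitutionMatrix = params$matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  ppos <- cumsum(ap != "-")
  spos <- cumsum(as_ != "-")
  lo <- window$start + 1L
  hi <- window$start + window$length
  cols <- which(ap != "-" & ppos >= lo & ppos <= hi)
  hit <- cols[as_[cols] != "-"]
  if (!length(hit))
    return(list(start = NA_integer_, end = NA_integer_,
                n_aligned = 0L, n_gapped = length(cols), empty = TRUE))
  list(start = spos[hit[1L]], end = spos[hit[length(hit)]],
       n_aligned = length(hit), n_gapped = length(cols) - length(hit),
       empty = FALSE)
}
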