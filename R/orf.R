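# Six-frame ORF scanning, C-terminal motif matching, and alignment
# conservation statistics for short peptide (precursor) discovery.

# codon -> amino acid lookup for a genetic code id; codons containing N
# (or any unresolved base) translate to X. Cached per code id.
.codon_table <- function(code_id = "11") {
  key <- paste0("gc", code_id)
  if (is.null(.pkg_cache[[key]]))
    .pkg_cache[[key]] <- Biostrings::getGeneticCode(code_id)
  .pkg_cache[[key]]
}

.translate_codons <- function(codons, code = .codon_table()) {
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  aa
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Six-frame translation short-ORF finder
#'
#' Scans all six reading frames of each contig for maximal start-to-stop
#' open reading frames whose peptide length (stop excluded) lies within
#' `[min_aa, max_aa]`. Only ORFs terminated by an in-frame stop codon
#' before the contig end are reported. By default the most upstream
#' qualifying start per stop is reported; `all_starts = TRUE` adds every
#' internal start as well (start-site predictions for short peptides are
#' unreliable, so downstream motif scans may want the nested set).
#'
#' Translation uses the bacterial/archaeal genetic code (table 11 by
#' default); alternative start codons (`GTG`, `TTG`) translate to `M` when
#' used as the start. Codons containing `N` translate to `X` and never act
#' as start or stop. Coordinates are 1-based, inclusive, on the forward
#' strand, and include the stop codon.
#'
#' @param contigs named character vector, `DNAStringSet`, or single string
#'   of DNA over `A, C, G, T, N`.
#' @param min_aa,max_aa peptide length bounds (defaults 20 and 120,
#'   bracketing typical short precursor peptides with margin).
#' @param starts permitted start codons.
#' @param code_id NCBI genetic code identifier (default `"11"`).
#' @param all_starts report internal starts too (default `FALSE`).
#' @return data.frame of class `OrfTable` with columns `contig`, `strand`,
#'   `frame` (1..3 per strand), `start`, `end`, `length_nt`, `peptide`.
#' @export
six_frame_orfs <- function(contigs, min_aa = 20, max_aa = 120,
                           starts = c("ATG", "GTG", "TTG"),
                           code_id = "11", all_starts = FALSE) {
  if (methods::is(contigs, "XStringSet")) contigs <- as.character(contigs)
  if (is.null(names(contigs)))
    names(contigs) <- if (length(contigs) == 1L) "contig" else
      paste0("contig", seq_along(contigs))
  contigs <- toupper(contigs)
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) stop("contig(s) contain letters outside {A,C,G,T,N}: ",
                     paste(utils::head(names(contigs)[bad], 5L), collapse = ", "))
  code <- .codon_table(code_id)
  stops <- names(code)[code == "*"]
  out <- vector("list", 0L)
  for (cid in names(contigs)) {
    for (strand in c("+", "-")) {
      dna <- if (strand == "+") contigs[[cid]] else .revcomp(contigs[[cid]])
      L <- nchar(dna)
      for (f in 1:3) {
        ncod <- (L - f + 1L) %/% 3L
        if (ncod < min_aa + 1L) next
        pos <- f + 3L * (seq_len(ncod) - 1L)
        codons <- substring(dna, pos, pos + 2L)
        is_stop <- codons %in% stops
        stop_idx <- which(is_stop)
        if (!length(stop_idx)) next
        is_start <- codons %in% starts
        seg_begin <- c(1L, utils::head(stop_idx, -1L) + 1L)
        for (k in seq_along(stop_idx)) {
          s0 <- seg_begin[k]; s1 <- stop_idx[k] - 1L
          if (s1 < s0) next
          starts_in <- which(is_start[s0:s1]) + s0 - 1L
          if (!length(starts_in)) next
          use <- if (all_starts) starts_in else starts_in[1L]
          for (st in use) {
            plen <- stop_idx[k] - st
            if (plen < min_aa || plen > max_aa) next
            aa <- .translate_codons(codons[st:(stop_idx[k] - 1L)], code)
            aa[1L] <- "M"
            nt_start <- pos[st]
            nt_end <- pos[stop_idx[k]] + 2L
            if (strand == "-") {
              tmp <- nt_start
              nt_start <- L - nt_end + 1L
              nt_end <- L - tmp + 1L
            }
            out[[length(out) + 1L]] <- data.frame(
              contig = cid, strand = strand, frame = f,
              start = nt_start, end = nt_end,
              length_nt = nt_end - nt_start + 1L,
              peptide = paste(aa, collapse = ""),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(contig = character(), strand = character(),
               frame = integer(), start = integer(), end = integer(),
               length_nt = integer(), peptide = character(),
               stringsAsFactors = FALSE)
  res <- res[order(res$contig, res$start, res$strand, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("OrfTable", "data.frame")
  res
}

#' Re-translate the genomic interval of an ORF hit
#'
#' Extracts the reported interval from the contig, reverse-complements it
#' for minus-strand hits, translates it and strips the stop. Used to
#' verify that every reported ORF reproduces its peptide.
#'
#' @param contigs the contig set given to [six_frame_orfs()].
#' @param hit one row of an `OrfTable`.
#' @param code_id genetic code identifier.
#' @return the peptide string.
#' @export
orf_peptide <- function(contigs, hit, code_id = "11") {
  if (methods::is(contigs, "XStringSet")) contigs <- as.character(contigs)
  dna <- substring(toupper(contigs[[hit$contig]]), hit$start, hit$end)
  if (hit$strand == "-") dna <- .revcomp(dna)
  pos <- seq(1L, nchar(dna) - 2L, by = 3L)
  aa <- .translate_codons(substring(dna, pos, pos + 2L), .codon_table(code_id))
  aa[1L] <- "M"
  paste(utils::head(aa, -1L), collapse = "")
}

#' C-terminal motif specification
#'
#' @param pattern residue pattern; uppercase letters are literal, `x`
#'   matches any residue (e.g. `"CGxxxCGVY"`). Must be non-empty.
#' @param mode `"suffix"` (literal/positional match anchored at the
#'   C-terminus) is the only matching semantics; literal-suffix and
#'   position-pattern motifs are expressed by the presence or absence of
#'   `x` wildcards.
#' @param max_distance how many residues may follow the pattern before the
#'   peptide's C-terminus (default 0: the pattern is the suffix).
#' @return object of class `MotifSpec`.
#' @export
motif_spec <- function(pattern, mode = "suffix", max_distance = 0) {
  if (!nzchar(pattern)) stop("motif pattern must be non-empty")
  if (grepl("[^A-Zx]", pattern))
    stop("pattern may contain residue letters and the wildcard `x` only")
  structure(list(pattern = pattern, mode = mode,
                 max_distance = as.integer(max_distance)),
            class = "MotifSpec")
}

.motif_regex <- function(motif) {
  body <- chartr("x", ".", motif$pattern)
  tail <- if (motif$max_distance > 0)
    sprintf(".{0,%d}$", motif$max_distance) else "$"
  paste0(body, tail)
}

#' Scan ORF peptides for a C-terminal motif
#'
#' @param orfs an `OrfTable` (or any data.frame with a `peptide` column).
#' @param motif a [motif_spec()] or a bare pattern string.
#' @return the matching subset of `orfs`.
#' @export
scan_cterm_motif <- function(orfs, motif) {
  if (is.character(motif)) motif <- motif_spec(motif)
  rx <- .motif_regex(motif)
  out <- orfs[grepl(rx, orfs$peptide), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-column conservation of a multiple sequence alignment
#'
#' For each alignment column, the dominant residue and its fraction among
#' non-gap rows, plus an invariant flag (fraction exactly 1 over at least
#' one non-gap row). Dominant-residue ties resolve alphabetically.
#'
#' @param msa aligned sequences: `AAStringSet`, named character vector of
#'   equal-length rows, or path to an aligned FASTA file. Gap characters
#'   are `-` and `.`.
#' @return data.frame of class `ConservationProfile` with columns `column`,
#'   `dominant`, `fraction`, `n_seqs`, `invariant`.
#' @export
column_conservation <- function(msa) {
  if (is.character(msa) && length(msa) == 1L && file.exists(msa))
    msa <- Biostrings::readAAStringSet(msa)
  if (methods::is(msa, "XStringSet")) msa <- as.character(msa)
  if (length(msa) < 2L) stop("alignment needs at least two rows")
  if (length(unique(nchar(msa))) != 1L)
    stop("ragged alignment: rows differ in length")
  m <- do.call(rbind, strsplit(toupper(msa), ""))
  nc <- ncol(m)
  rows <- lapply(seq_len(nc), function(j) {
    col <- m[, j]
    col <- col[!col %in% c("-", ".")]
    if (!length(col))
      return(data.frame(column = j, dominant = NA_character_,
                        fraction = NA_real_, n_seqs = 0L,
                        invariant = FALSE, stringsAsFactors = FALSE))
    tab <- sort(table(col), decreasing = TRUE)
    top <- tab[tab == tab[1L]]
    dom <- sort(names(top))[1L]
    frac <- unname(tab[1L]) / length(col)
    data.frame(column = j, dominant = dom, fraction = frac,
               n_seqs = length(col), invariant = frac == 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ConservationProfile", "data.frame")
  out
}

#' Summarize invariant columns in the tail of an alignment
#'
#' Reports how many of the last `last_m` columns are invariant -- the
#' "k invariant among the last m positions" statistic used to describe
#' strongly conserved C-terminal peptide motifs.
#'
#' @param profile a `ConservationProfile`.
#' @param last_m number of trailing columns to summarize.
#' @return list with `invariant` (count) and `last_m`.
#' @export
conservation_summary <- function(profile, last_m) {
  n <- nrow(profile)
  if (last_m > n) stop("alignment has fewer than `last_m` columns")
  tail_rows <- profile[(n - last_m + 1L):n, , drop = FALSE]
  list(invariant = sum(tail_rows$invariant), last_m = as.integer(last_m))
}

#' Write an ORF table as TSV
#' @param orfs an `OrfTable`.
#' @param file output path.
#' @param meta metadata lines.
#' @return invisibly, `file`.
#' @export
write_orf_table <- function(orfs, file, meta = character()) {
  write_tsv_meta(orfs, file, meta)
}
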