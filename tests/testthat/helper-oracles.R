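# Independent oracles and small fixture builders used across the suite.

aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_aa <- function(n) paste(sample(aa20, n, replace = TRUE), collapse = "")

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Quadratic-space three-state Smith-Waterman DP, coded independently of the
# package's C++ kernel. Full matrices, integer-encoded residues.
sw_oracle <- function(a, b, mat = blosum62, open = 11, ext = 1) {
  ai <- match(strsplit(a, "")[[1]], rownames(mat))
  bi <- match(strsplit(b, "")[[1]], rownames(mat))
  m <- length(ai); n <- length(bi)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m) + 1) {
    for (j in seq_len(n) + 1) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      h <- max(0, H[i - 1, j - 1] + mat[ai[i - 1], bi[j - 1]],
               E[i, j], F[i, j])
      H[i, j] <- h
      if (h > best) best <- h
    }
  }
  best
}

# Exhaustive prefix-scoring oracle for the PPP cutoff walk: scores every
# tie-block boundary directly with stats::pbinom, keeping the shallowest
# strict improvement. Counts are recomputed from scratch per prefix.
ppp_oracle <- function(genome, label, bits, p) {
  d <- length(bits)
  best <- 0; bd <- 0L; by <- 0L; bn <- 0L
  for (dep in seq_len(d)) {
    if (dep < d && bits[dep + 1] == bits[dep]) next  # inside a tie block
    g <- genome[seq_len(dep)]
    y <- length(unique(g[label[seq_len(dep)]]))
    n <- length(unique(g))
    sc <- stats::pbinom(y - 1, n, p, lower.tail = FALSE, log.p = TRUE) / log(10)
    if (sc < best) { best <- sc; bd <- dep; by <- y; bn <- n }
  }
  list(yes = by, total = bn, depth = bd, score = best)
}

# Exhaustive-cutoff oracle for window scoring: enumerates every distinct
# positive similarity value as a cutoff and takes the best binomial tail,
# with no ranked walk at all.
window_oracle <- function(window_seq, training, params = scoring_params()) {
  seqs <- c(training$true_seqs, training$false_seqs)
  lab <- rep(c(TRUE, FALSE),
             c(length(training$true_seqs), length(training$false_seqs)))
  sc <- local_align_score(window_seq, seqs, params)
  cuts <- unique(sc[sc > params$score_floor])
  if (!length(cuts)) return(0)
  best <- 0
  for (cc in cuts) {
    idx <- sc >= cc
    val <- stats::pbinom(sum(lab[idx]) - 1, sum(idx), training$p_t,
                         lower.tail = FALSE, log.p = TRUE) / log(10)
    if (val < best) best <- val
  }
  -best
}

# Brute-force six-frame ORF scan, coded independently: walks every frame
# position by position with its own codon handling.
orf_oracle <- function(contig, min_aa = 20, max_aa = 120,
                       starts = c("ATG", "GTG", "TTG")) {
  code <- Biostrings::getGeneticCode("11")
  revcomp <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  rows <- list()
  for (strand in c("+", "-")) {
    dna <- if (strand == "+") contig else revcomp(contig)
    L <- nchar(dna)
    for (f in 1:3) {
      i <- f
      seg_start <- NA
      while (i + 2 <= L) {
        cod <- substr(dna, i, i + 2)
        aa <- code[cod]
        if (!is.na(aa) && aa == "*") {
          if (!is.na(seg_start)) {
            # first start codon in the closed segment
            j <- seg_start
            while (j < i) {
              if (substr(dna, j, j + 2) %in% starts) break
              j <- j + 3
            }
            if (j < i) {
              plen <- (i - j) / 3
              if (plen >= min_aa && plen <= max_aa) {
                pep <- character(plen)
                for (k in seq_len(plen)) {
                  ck <- substr(dna, j + 3 * (k - 1), j + 3 * k - 1)
                  pep[k] <- if (is.na(code[ck])) "X" else code[ck]
                }
                pep[1] <- "M"
                st <- j; en <- i + 2
                if (strand == "-") { tmp <- st; st <- L - en + 1; en <- L - tmp + 1 }
                rows[[length(rows) + 1]] <- data.frame(
                  strand = strand, frame = f, start = st, end = en,
                  peptide = paste(pep, collapse = ""),
                  stringsAsFactors = FALSE)
              }
            }
          }
          seg_start <- NA
        } else if (is.na(seg_start)) {
          seg_start <- i
        }
        i <- i + 3
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(strand = character(), frame = integer(), start = integer(),
               end = integer(), peptide = character(), stringsAsFactors = FALSE)
  out[order(out$start, out$strand, out$frame), , drop = FALSE]
}

# Tiny two-genome collection used by several I/O tests.
toy_collection <- function() {
  genome_collection(
    c(p1 = "MKLVAT", p2 = "MKAVST", p3 = "MWWWHE"),
    c(p1 = "g1", p2 = "g1", p3 = "g2"))
}
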