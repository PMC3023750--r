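# Shared internal helpers: alphabet handling, seeded evaluation, TSV I/O.

# the 20 standard amino acids, alphabetical
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.pkg_cache <- new.env(parent = emptyenv())

# BLOSUM62 from Biostrings, cached
.blosum62 <- function() {
  if (is.null(.pkg_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$BLOSUM62 <- e$BLOSUM62
  }
  .pkg_cache$BLOSUM62
}

# Uppercase and restrict to the 20 standard residues plus X; anything else
# becomes X with a warning. Vectorized over sequences.
sanitize_aa <- function(x, warn = TRUE) {
  x <- toupper(x)
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", x)
  if (any(bad)) {
    if (warn) {
      warning(sum(bad), " sequence(s) contain non-standard residues; mapped to X",
              call. = FALSE)
    }
    x[bad] <- gsub("[^ACDEFGHIKLMNPQRSTVWYX]", "X", x[bad])
  }
  x
}

# Run expr under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Write a data.frame as TSV with "#"-prefixed metadata lines and a header.
write_tsv_meta <- function(df, file, meta = character()) {
  con <- file(file, open = "wt")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(file)
}

# Read a TSV written by write_tsv_meta (or any headered TSV; "#" lines skipped).
read_tsv_meta <- function(file) {
  utils::read.delim(file, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
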