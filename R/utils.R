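#' @importFrom methods is
#' @importFrom stats quantile runif setNames
#' @importFrom utils read.table write.table head
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

# reverse complement of a plain character vector (keeps N)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N}: %s",
                 what, paste(utils::head(which(bad), 3), collapse = ", ")))
  }
  invisible(TRUE)
}

# All tabular outputs share one convention: a single header line starting "#",
# tab separation, no quoting.
write_tsv_hash <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df)) {
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

read_tsv_hash <- function(path, colClasses = NA) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#")) stop("expected a '#'-prefixed header line in ", path)
  cols <- strsplit(sub("^#", "", header), "\t", fixed = TRUE)[[1]]
  n <- length(readLines(path)) - 1L
  if (n == 0L) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                        stringsAsFactors = FALSE)
    return(df)
  }
  df <- read.table(path, sep = "\t", skip = 1L, col.names = cols,
                   stringsAsFactors = FALSE, comment.char = "",
                   colClasses = colClasses)
  df
}

# data.frame construction without the validation overhead of data.frame();
# used on hot paths where columns are known-good equal-length vectors
fast_df <- function(...) {
  cols <- list(...)
  structure(cols, class = "data.frame",
            row.names = if (length(cols)) seq_along(cols[[1]]) else integer(0))
}

# Deterministic 31-bit sub-seed derived from a master seed and a text tag,
# so every simulated library has its own reproducible stream.
sub_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

random_dna <- function(n, len) {
  vapply(rep_len(len, n), function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

# per-base substitution errors at rate p; returns modified strings
inject_errors <- function(seqs, p) {
  if (p <= 0) return(seqs)
  vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(ch)) < p & ch %in% c("A", "C", "G", "T"))
    for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
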