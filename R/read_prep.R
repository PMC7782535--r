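# Pre-alignment stage: reconstruct one sequence per overlapping read pair,
# then strip the small-RNA library adapters.

#' Merge parameters
#'
#' Controls overlap-consensus merging of paired-end reads. The defaults mirror
#' a pear run with `-n 30 -p 1.0`: a minimum overlap of 30 nt and the
#' statistical significance test disabled (a significance level of 1 accepts
#' everything, so the merger reduces to pure overlap scanning).
#'
#' @param min_overlap minimum read-pair overlap, nt.
#' @param max_mismatch_rate maximum fraction of mismatching bases tolerated in
#'   the chosen overlap. Not specified by the upstream tooling; 0.1 is robust
#'   at the simulator's 1% substitution-error rate.
#' @param statistical_test_enabled retained for interface completeness; the
#'   overlap-significance test is not implemented and must stay `FALSE`.
#' @return a `MergeParams` list.
#' @export
merge_params <- function(min_overlap = 30L, max_mismatch_rate = 0.1,
                         statistical_test_enabled = FALSE) {
  stopifnot(min_overlap >= 1, max_mismatch_rate >= 0, max_mismatch_rate <= 1)
  if (isTRUE(statistical_test_enabled)) {
    stop("the overlap significance test is not implemented (disabled upstream by -p 1.0)")
  }
  structure(list(min_overlap = as.integer(min_overlap),
                 max_mismatch_rate = max_mismatch_rate,
                 statistical_test_enabled = FALSE),
            class = "MergeParams")
}

#' Library adapter specification
#'
#' Defaults are the small-RNA library adapters flanking every insert, stored
#' in DNA form (U converted to T): 3' adapter `TCTGGAATTCTCGGGTGCCAAGGAACTCC`
#' and 5' adapter `GTTCAGAGTTCTACAGTCCGACGATC`.
#'
#' @param three_prime 3' adapter (DNA).
#' @param five_prime 5' adapter (DNA).
#' @param min_adapter_match minimum match length to trim, nt (matches of
#'   fewer than 10 nt must be exact).
#' @param max_error_rate mismatch fraction tolerated in an adapter match
#'   (sequencing errors land in adapters too; untrimmed adapter residues
#'   otherwise seed spurious alignment arms). 0 requires exact matches.
#' @return an `AdapterSpec` list.
#' @export
adapter_spec <- function(three_prime = "TCTGGAATTCTCGGGTGCCAAGGAACTCC",
                         five_prime = "GTTCAGAGTTCTACAGTCCGACGATC",
                         min_adapter_match = 8L, max_error_rate = 0.1) {
  three_prime <- toupper(chartr("Uu", "Tt", three_prime))
  five_prime <- toupper(chartr("Uu", "Tt", five_prime))
  stopifnot(nzchar(three_prime), nzchar(five_prime), min_adapter_match >= 1,
            max_error_rate >= 0, max_error_rate < 0.5)
  structure(list(three_prime = three_prime, five_prime = five_prime,
                 min_adapter_match = as.integer(min_adapter_match),
                 max_error_rate = max_error_rate),
            class = "AdapterSpec")
}

merge_one <- function(r1, r2, q1, q2, params) {
  l1 <- nchar(r1); l2 <- nchar(r2)
  rc2 <- revcomp(r2)
  a <- utf8ToInt(r1)
  b <- utf8ToInt(rc2)
  qa <- if (!is.null(q1) && !is.na(q1)) utf8ToInt(q1) else NULL
  qb <- if (!is.null(q2) && !is.na(q2)) rev(utf8ToInt(q2)) else NULL
  omax <- min(l1, l2)
  if (params$min_overlap > omax) {
    return(list(sequence = NA_character_, overlap_len = 0L, merged = FALSE))
  }
  best_o <- 0L; best_mm <- Inf
  for (o in params$min_overlap:omax) {
    mm <- sum(a[(l1 - o + 1L):l1] != b[seq_len(o)])
    if (mm < best_mm || (mm == best_mm && o > best_o)) {
      best_mm <- mm; best_o <- o
    }
  }
  if (best_mm / best_o > params$max_mismatch_rate) {
    return(list(sequence = NA_character_, overlap_len = 0L, merged = FALSE))
  }
  o <- best_o
  ov_a <- a[(l1 - o + 1L):l1]
  ov_b <- b[seq_len(o)]
  cons <- ov_a
  diff <- which(ov_a != ov_b)
  if (length(diff) && !is.null(qa) && !is.null(qb)) {
    qa_ov <- qa[(l1 - o + 1L):l1]
    qb_ov <- qb[seq_len(o)]
    take_b <- diff[qb_ov[diff] > qa_ov[diff]]
    cons[take_b] <- ov_b[take_b]
  } # absent qualities, the r1 base wins
  seq <- paste0(if (l1 > o) intToUtf8(a[seq_len(l1 - o)]) else "",
                intToUtf8(cons),
                if (l2 > o) intToUtf8(b[(o + 1L):l2]) else "")
  list(sequence = seq, overlap_len = o, merged = TRUE)
}

#' Merge overlapping paired-end reads into single sequences
#'
#' Scans every candidate overlap `o` between the end of read 1 and the start
#' of the reverse complement of read 2, from `min_overlap` up to the shorter
#' read length, and keeps the `o` with the fewest mismatches (ties go to the
#' largest overlap). If the best overlap's mismatch rate is within tolerance
#' the pair is merged into a consensus (at mismatching positions the base with
#' the higher quality wins; without qualities, the read-1 base wins);
#' otherwise the pair is flagged unmerged and dropped downstream.
#'
#' @param pairs data.frame with columns `id`, `r1_seq`, `r2_seq` and optional
#'   `r1_qual`, `r2_qual`.
#' @param params a [merge_params()] object.
#' @return data.frame with columns `id`, `sequence`, `overlap_len`, `merged`.
#' @export
merge_pairs <- function(pairs, params = merge_params()) {
  stopifnot(all(c("id", "r1_seq", "r2_seq") %in% names(pairs)))
  if (any(!nzchar(pairs$r1_seq)) || any(!nzchar(pairs$r2_seq))) {
    stop("empty read sequence in pair input")
  }
  has_q <- all(c("r1_qual", "r2_qual") %in% names(pairs))
  if (has_q) {
    okq <- nchar(pairs$r1_qual) == nchar(pairs$r1_seq) &
      nchar(pairs$r2_qual) == nchar(pairs$r2_seq)
    if (!all(okq)) stop("quality string length does not match read length")
  }
  n <- nrow(pairs)
  seqs <- character(n); ov <- integer(n); mg <- logical(n)
  for (i in seq_len(n)) {
    m <- merge_one(pairs$r1_seq[i], pairs$r2_seq[i],
                   if (has_q) pairs$r1_qual[i] else NULL,
                   if (has_q) pairs$r2_qual[i] else NULL, params)
    seqs[i] <- m$sequence; ov[i] <- m$overlap_len; mg[i] <- m$merged
  }
  data.frame(id = pairs$id, sequence = seqs, overlap_len = ov, merged = mg,
             stringsAsFactors = FALSE)
}

#' Merge a single read pair
#'
#' @param pair list or one-row data.frame with `id`, `r1_seq`, `r2_seq` and
#'   optional `r1_qual`, `r2_qual`.
#' @param params a [merge_params()] object.
#' @return one-row data.frame as in [merge_pairs()].
#' @export
merge_pair <- function(pair, params = merge_params()) {
  merge_pairs(as.data.frame(pair, stringsAsFactors = FALSE), params)
}

# allowed mismatches in a k-long adapter match; short matches must be exact
adapter_mm_allowed <- function(k, rate) {
  ifelse(k < 10L, 0L, as.integer(floor(k * rate)))
}

trim_one <- function(s, spec) {
  n5 <- nchar(spec$five_prime); n3 <- nchar(spec$three_prime)
  sv <- utf8ToInt(s)
  a5 <- utf8ToInt(spec$five_prime)
  a3 <- utf8ToInt(spec$three_prime)
  L <- length(sv)
  # 5' end: longest read prefix matching a suffix of the 5' adapter
  kmax <- min(L, n5)
  if (kmax >= spec$min_adapter_match) {
    for (k in kmax:spec$min_adapter_match) {
      mm <- sum(sv[seq_len(k)] != a5[(n5 - k + 1L):n5])
      if (mm <= adapter_mm_allowed(k, spec$max_error_rate)) {
        sv <- sv[-seq_len(k)]
        L <- L - k
        break
      }
    }
  }
  # 3' end: longest read suffix matching a prefix of the 3' adapter
  kmax <- min(L, n3)
  if (kmax >= spec$min_adapter_match) {
    for (k in kmax:spec$min_adapter_match) {
      mm <- sum(sv[(L - k + 1L):L] != a3[seq_len(k)])
      if (mm <= adapter_mm_allowed(k, spec$max_error_rate)) {
        sv <- sv[seq_len(L - k)]
        break
      }
    }
  }
  intToUtf8(sv)
}

#' Trim library adapters from merged reads
#'
#' Removes a 5' prefix matching a suffix of the 5' adapter and a 3' suffix
#' matching a prefix of the 3' adapter (read-through), requiring at least
#' `min_adapter_match` matching bases; the longest match wins. Matches of
#' 10 nt or more tolerate a `max_error_rate` fraction of mismatches so that
#' sequencing errors inside an adapter do not leave residues behind. Reads
#' shorter than `min_len` after trimming are flagged `pass = FALSE` and
#' excluded by downstream stages. The operation is idempotent on its output
#' for any read whose trimmed sequence does not itself end/start with an
#' adapter fragment.
#'
#' @param reads data.frame from [merge_pairs()] (only `merged = TRUE` rows are
#'   trimmed; unmerged rows are passed through with `pass = FALSE`).
#' @param spec an [adapter_spec()].
#' @param min_len minimum post-trim length, nt.
#' @return the input data.frame with `sequence` trimmed and a logical `pass`
#'   column.
#' @export
trim_adapters <- function(reads, spec = adapter_spec(), min_len = 18L) {
  out <- reads
  idx <- which(reads$merged)
  out$sequence[idx] <- vapply(reads$sequence[idx], trim_one, character(1),
                              spec = spec, USE.NAMES = FALSE)
  out$pass <- out$merged & nchar(out$sequence) >= min_len & !is.na(out$sequence)
  out
}

#' Read a pair of FASTQ files into the pair table used by [merge_pairs()]
#'
#' @param r1_path,r2_path FASTQ paths (plain or gzipped).
#' @return data.frame with `id`, `r1_seq`, `r2_seq`, `r1_qual`, `r2_qual`.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  # the reader warns about dropping (empty) metadata columns; harmless
  r1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r1_path))
  r2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r2_path))
  if (length(r1) != length(r2)) stop("R1/R2 FASTQ files differ in read count")
  id1 <- sub("[/ ].*$", "", names(r1))
  data.frame(id = id1,
             r1_seq = as.character(r1), r2_seq = as.character(r2),
             r1_qual = as.character(Biostrings::quality(r1)),
             r2_qual = as.character(Biostrings::quality(r2)),
             stringsAsFactors = FALSE)
}

#' Write merged reads to FASTQ
#'
#' @param reads merged/trimmed read data.frame (rows with `pass = FALSE` or
#'   `merged = FALSE` are skipped).
#' @param path output FASTQ path.
#' @return the path, invisibly.
#' @export
write_fastq_merged <- function(reads, path) {
  keep <- if ("pass" %in% names(reads)) reads$pass else reads$merged
  r <- reads[keep, , drop = FALSE]
  x <- Biostrings::DNAStringSet(r$sequence)
  names(x) <- r$id
  qual <- Biostrings::BStringSet(strrep("I", nchar(r$sequence)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Write a pair table to two FASTQ files
#'
#' @param pairs pair data.frame (as from the simulator).
#' @param r1_path,r2_path output FASTQ paths.
#' @return named character vector of the two paths, invisibly.
#' @export
write_fastq_pairs <- function(pairs, r1_path, r2_path) {
  q1 <- if ("r1_qual" %in% names(pairs)) pairs$r1_qual else strrep("I", nchar(pairs$r1_seq))
  q2 <- if ("r2_qual" %in% names(pairs)) pairs$r2_qual else strrep("I", nchar(pairs$r2_seq))
  x1 <- Biostrings::DNAStringSet(pairs$r1_seq); names(x1) <- pairs$id
  x2 <- Biostrings::DNAStringSet(pairs$r2_seq); names(x2) <- pairs$id
  Biostrings::writeXStringSet(x1, r1_path, format = "fastq",
                              qualities = Biostrings::BStringSet(q1))
  Biostrings::writeXStringSet(x2, r2_path, format = "fastq",
                              qualities = Biostrings::BStringSet(q2))
  invisible(c(r1 = r1_path, r2 = r2_path))
}
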