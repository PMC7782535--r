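# Seeded local alignment of merged reads against the miRNA and transcript
# references, plus an end-to-end "contiguity" filter that removes reads
# explainable as a single contiguous reference match. The affine-gap DP is
# delegated to Biostrings::pairwiseAlignment; seeding, strand handling,
# E-values and emission rules live here.

#' Alignment parameters
#'
#' Defaults reproduce a classic megablast-free blastn search: +2/-3
#' match/mismatch, affine gaps -5 open / -2 extend, word size 7, both strands
#' searched. The two searches of the pipeline differ only in `evalue_max`:
#' 10 for the miRNA class and 0.1 for the mRNA class. `ka_lambda`/`ka_K` are
#' ungapped Karlin-Altschul estimates for the +2/-3 scheme, used only to put
#' scores on an E-value scale; tests rely on monotonicity, never on agreement
#' with an external aligner.
#'
#' @param match,mismatch,gap_open,gap_extend alignment scores (penalties
#'   negative).
#' @param word_size exact-word seed length, nt. Words containing `N` never
#'   seed.
#' @param evalue_max maximum E-value for an emitted hit.
#' @param search_both_strands search the reverse complement of each subject
#'   as well.
#' @param min_arm_len minimum read-interval width of an emitted hit, nt.
#' @param ka_lambda,ka_K Karlin-Altschul parameters.
#' @return an `AlignParams` list.
#' @export
align_params <- function(match = 2, mismatch = -3, gap_open = -5,
                         gap_extend = -2, word_size = 7L, evalue_max = 10,
                         search_both_strands = TRUE, min_arm_len = 12L,
                         ka_lambda = 0.625, ka_K = 0.41) {
  stopifnot(word_size >= 4, evalue_max > 0, min_arm_len >= word_size,
            match > 0, mismatch < 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, word_size = as.integer(word_size),
                 evalue_max = evalue_max,
                 search_both_strands = isTRUE(search_both_strands),
                 min_arm_len = as.integer(min_arm_len),
                 ka_lambda = ka_lambda, ka_K = ka_K),
            class = "AlignParams")
}

# 5x5 substitution matrix; N matches nothing (scores as a mismatch)
substitution_matrix <- function(match, mismatch) {
  m <- matrix(mismatch, 5, 5, dimnames = list(DNA_ALPHABET, DNA_ALPHABET))
  diag(m) <- match
  m["N", "N"] <- mismatch
  m
}

seq_kmers <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(character(0))
  km <- substring(s, seq_len(L - k + 1L), k:L)
  unique(km[!grepl("N", km, fixed = TRUE)])
}

# kmer -> integer vector of subject indices
build_kmer_index <- function(seqs, k) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(seqs)) {
    for (km in seq_kmers(seqs[[i]], k)) {
      env[[km]] <- c(env[[km]], i)
    }
  }
  env
}

lookup_candidates <- function(read_seq, index, k) {
  km <- seq_kmers(read_seq, k)
  if (!length(km)) return(integer(0))
  hit <- unlist(mget(km, envir = index, ifnotfound = list(NULL)),
                use.names = FALSE)
  sort(unique(hit))
}

ka_evalue <- function(score, m, n_total, params) {
  params$ka_K * m * n_total * exp(-params$ka_lambda * score)
}

empty_hits_df <- function() {
  data.frame(read_id = character(0), subject_id = character(0),
             subject_class = character(0), strand = character(0),
             qstart = integer(0), qend = integer(0),
             sstart = integer(0), send = integer(0),
             length = integer(0), mismatches = integer(0), gaps = integer(0),
             identity = numeric(0), score = numeric(0), evalue = numeric(0),
             stringsAsFactors = FALSE)
}

#' Seeded local alignment of reads against one reference class
#'
#' Exact `word_size`-mers shared between a read and a subject seed a full
#' affine-gap local alignment of the read against that subject (and, when
#' `search_both_strands`, its reverse complement). Per (read, subject, strand)
#' the single best-scoring local alignment is reported; overlapping hits to
#' the same subject on opposite strands are reduced to the best-scoring one.
#' A hit is emitted when its read interval is at least `min_arm_len` wide, its
#' score is positive, and its E-value `K * m * n * exp(-lambda * score)` is at
#' most `evalue_max`, where `m` is the read length and `n` the total subject
#' length of the searched class (doubled when both strands are searched).
#'
#' @param reads data.frame with `id` and `sequence` (use rows that survived
#'   [filter_contiguous()]).
#' @param refs a `ReferenceSet`.
#' @param params an [align_params()]; use `evalue_max = 10` for the miRNA
#'   class and `0.1` for the mRNA class.
#' @param subject_class `"miRNA"` (aligns against `refs$mirnas`) or `"mRNA"`
#'   (against `refs$transcripts`).
#' @return a hit data.frame (0-based half-open `qstart`/`qend` on the read and
#'   `sstart`/`send` on the subject's plus strand; `strand` records which
#'   subject strand matched).
#' @export
local_align <- function(reads, refs, params = align_params(),
                        subject_class = c("miRNA", "mRNA")) {
  subject_class <- match.arg(subject_class)
  subjects <- if (subject_class == "miRNA") refs$mirnas else refs$transcripts
  if (!nrow(reads) || !length(subjects)) return(empty_hits_df())
  k <- params$word_size
  n_total <- sum(nchar(subjects)) * (if (params$search_both_strands) 2 else 1)
  submat <- substitution_matrix(params$match, params$mismatch)
  strands <- if (params$search_both_strands) c("+", "-") else "+"

  hits <- list()
  for (strand in strands) {
    sseqs <- if (strand == "+") subjects else setNames(revcomp(subjects), names(subjects))
    index <- build_kmer_index(sseqs, k)
    # read index -> candidate subject indices
    cand <- lapply(reads$sequence, lookup_candidates, index = index, k = k)
    pairs_r <- rep.int(seq_len(nrow(reads)), lengths(cand))
    pairs_s <- unlist(cand, use.names = FALSE)
    if (!length(pairs_s)) next
    for (si in unique(pairs_s)) {
      ri <- pairs_r[pairs_s == si]
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(reads$sequence[ri]),
        subject = Biostrings::DNAString(sseqs[[si]]),
        type = "local", substitutionMatrix = submat,
        gapOpening = abs(params$gap_open), gapExtension = abs(params$gap_extend))
      sc <- Biostrings::score(pa)
      qs <- Biostrings::start(Biostrings::pattern(pa)) - 1L
      qe <- Biostrings::end(Biostrings::pattern(pa))
      ss <- Biostrings::start(Biostrings::subject(pa)) - 1L
      se <- Biostrings::end(Biostrings::subject(pa))
      if (strand == "-") {
        L <- nchar(subjects[[si]])
        ss_new <- L - se
        se_new <- L - ss
        ss <- ss_new; se <- se_new
      }
      nmm <- Biostrings::nmismatch(pa)
      nma <- Biostrings::nmatch(pa)
      ind <- Biostrings::nindel(pa)
      gapw <- Biostrings::insertion(ind)[, "WidthSum"] +
        Biostrings::deletion(ind)[, "WidthSum"]
      m_len <- nchar(reads$sequence[ri])
      ev <- ka_evalue(sc, m_len, n_total, params)
      keep <- (qe - qs) >= params$min_arm_len & sc > 0 & ev <= params$evalue_max
      if (!any(keep)) next
      hits[[length(hits) + 1L]] <- data.frame(
        read_id = reads$id[ri][keep], subject_id = names(subjects)[si],
        subject_class = subject_class, strand = strand,
        qstart = qs[keep], qend = qe[keep], sstart = ss[keep], send = se[keep],
        length = (qe - qs)[keep], mismatches = nmm[keep],
        gaps = as.integer(gapw)[keep],
        identity = (nma / pmax(nma + nmm + gapw, 1))[keep],
        score = sc[keep], evalue = ev[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(empty_hits_df())
  out <- do.call(rbind, hits)
  reduce_overlapping_hits(out)
}

# among hits of one read to one subject, drop any hit whose read interval
# overlaps a higher-scoring hit (ties: "+" strand, then smaller qstart)
reduce_overlapping_hits <- function(hits) {
  if (nrow(hits) < 2) return(hits)
  ord <- order(hits$read_id, hits$subject_id, -hits$score,
               hits$strand != "+", hits$qstart)
  hits <- hits[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  key <- paste(hits$read_id, hits$subject_id)
  for (grp in split(seq_len(nrow(hits)), key)) {
    if (length(grp) < 2) next
    taken_s <- integer(0); taken_e <- integer(0)
    for (i in grp) {
      if (any(hits$qstart[i] < taken_e & hits$qend[i] > taken_s)) {
        keep[i] <- FALSE
      } else {
        taken_s <- c(taken_s, hits$qstart[i])
        taken_e <- c(taken_e, hits$qend[i])
      }
    }
  }
  out <- hits[keep, , drop = FALSE]
  out <- out[order(out$read_id, out$qstart, out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

contiguous_candidates <- function(reads, refs, seed_size) {
  subjects <- c(refs$transcripts, refs$mirnas)
  res <- vector("list", 2L)
  names(res) <- c("+", "-")
  for (strand in c("+", "-")) {
    sseqs <- if (strand == "+") subjects else setNames(revcomp(subjects), names(subjects))
    index <- build_kmer_index(sseqs, seed_size)
    res[[strand]] <- lapply(reads$sequence, lookup_candidates,
                            index = index, k = seed_size)
  }
  res
}

# Align every read end-to-end (read global, subject local) against each
# candidate subject; returns per read the best passing placement, or NA.
contiguous_best <- function(reads, refs, max_mismatch_rate, seed_size,
                            max_indel_len, params) {
  subjects <- c(refs$transcripts, refs$mirnas)
  submat <- substitution_matrix(params$match, params$mismatch)
  cand <- contiguous_candidates(reads, refs, seed_size)
  n <- nrow(reads)
  best <- data.frame(idx = seq_len(n), subject_id = NA_character_,
                     strand = NA_character_, sstart = NA_integer_,
                     send = NA_integer_, score = -Inf,
                     stringsAsFactors = FALSE)
  for (strand in c("+", "-")) {
    pairs_r <- rep.int(seq_len(n), lengths(cand[[strand]]))
    pairs_s <- unlist(cand[[strand]], use.names = FALSE)
    if (!length(pairs_s)) next
    for (si in unique(pairs_s)) {
      ri <- pairs_r[pairs_s == si]
      sseq <- if (strand == "+") subjects[[si]] else revcomp(subjects[[si]])
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(reads$sequence[ri]),
        subject = Biostrings::DNAString(sseq),
        type = "global-local", substitutionMatrix = submat,
        gapOpening = abs(params$gap_open), gapExtension = abs(params$gap_extend))
      nmm <- Biostrings::nmismatch(pa)
      nma <- Biostrings::nmatch(pa)
      rlen <- nchar(reads$sequence[ri])
      ind <- Biostrings::indel(pa)
      ins <- Biostrings::insertion(ind)
      del <- Biostrings::deletion(ind)
      wmax <- mapply(function(a, b) max(0L, IRanges::width(a), IRanges::width(b)),
                     as.list(ins), as.list(del))
      ins_w <- Biostrings::insertion(Biostrings::nindel(pa))[, "WidthSum"]
      # terminal pattern overhang beyond the subject is penalized in the
      # score but absent from indel(); an end-to-end explanation has none
      overhang <- rlen - nma - nmm - ins_w
      ok <- nmm / rlen <= max_mismatch_rate & wmax <= max_indel_len &
        overhang == 0L
      if (!any(ok)) next
      sc <- Biostrings::score(pa)
      ss <- Biostrings::start(Biostrings::subject(pa)) - 1L
      se <- Biostrings::end(Biostrings::subject(pa))
      if (strand == "-") {
        L <- nchar(subjects[[si]])
        tmp <- L - se; se <- L - ss; ss <- tmp
      }
      for (j in which(ok)) {
        i <- ri[j]
        if (sc[j] > best$score[i]) {
          best$score[i] <- sc[j]
          best$subject_id[i] <- names(subjects)[si]
          best$strand[i] <- strand
          best$sstart[i] <- ss[j]
          best$send[i] <- se[j]
        }
      }
    }
  }
  best
}

#' Remove reads explainable as one contiguous reference match
#'
#' A read is removed when some single contiguous window of any transcript or
#' miRNA (either strand) aligns end-to-end to the whole read with a mismatch
#' rate at most `max_mismatch_rate` and no indel longer than `max_indel_len`.
#' Candidate windows are found with an exact `seed_size`-mer prefilter and
#' verified by end-to-end affine alignment, mirroring the intent of a
#' very-sensitive short-read mapping step: non-chimeric reads drop out,
#' ligation chimeras survive. Survivors are returned in input order.
#'
#' @param reads data.frame with `id` and `sequence`.
#' @param refs a `ReferenceSet`.
#' @param max_mismatch_rate maximum per-read mismatch fraction for removal.
#' @param seed_size exact seed length of the prefilter, nt.
#' @param max_indel_len longest indel tolerated in a contiguous explanation.
#' @param params scoring parameters (defaults shared with [local_align()]).
#' @return the surviving rows of `reads`, in input order.
#' @export
filter_contiguous <- function(reads, refs, max_mismatch_rate = 0.06,
                              seed_size = 12L, max_indel_len = 2L,
                              params = align_params()) {
  if (!nrow(reads)) return(reads)
  best <- contiguous_best(reads, refs, max_mismatch_rate, seed_size,
                          max_indel_len, params)
  out <- reads[!is.finite(best$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Place reads end-to-end on transcripts (IP counting mode)
#'
#' The same end-to-end engine as [filter_contiguous()], used constructively:
#' each read is assigned its best contiguous transcript placement (highest
#' alignment score among placements passing the mismatch/indel bounds).
#' Reads with no passing placement are dropped.
#'
#' @inheritParams filter_contiguous
#' @return data.frame `id`, `transcript_id`, `start`, `end`, `strand`
#'   (0-based half-open transcript coordinates).
#' @export
place_reads <- function(reads, refs, max_mismatch_rate = 0.06,
                        seed_size = 12L, max_indel_len = 2L,
                        params = align_params()) {
  if (!nrow(reads)) {
    return(data.frame(id = character(0), transcript_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  refs_tx <- refs
  refs_tx$mirnas <- setNames(character(0), character(0))
  best <- contiguous_best(reads, refs_tx, max_mismatch_rate, seed_size,
                          max_indel_len, params)
  ok <- is.finite(best$score)
  data.frame(id = reads$id[ok], transcript_id = best$subject_id[ok],
             start = best$sstart[ok], end = best$send[ok],
             strand = best$strand[ok], stringsAsFactors = FALSE)
}

#' Write / read an alignment hit table (blast tabular style)
#'
#' Twelve columns in the classic tabular-report order: read id, subject id,
#' percent identity, alignment length, mismatches, gap bases, query start/end,
#' subject start/end, E-value, score. File coordinates are 1-based inclusive;
#' on the minus strand subject start > subject end. Internal coordinates stay
#' 0-based half-open and are converted at this boundary.
#'
#' @param hits hit data.frame from [local_align()].
#' @param out output path.
#' @return the path, invisibly.
#' @export
write_hits_table <- function(hits, out) {
  df <- data.frame(read_id = hits$read_id, subject_id = hits$subject_id,
                   identity = round(100 * hits$identity, 2),
                   length = hits$length, mismatches = hits$mismatches,
                   gaps = hits$gaps,
                   qstart = hits$qstart + 1L, qend = hits$qend,
                   sstart = ifelse(hits$strand == "+", hits$sstart + 1L, hits$send),
                   send = ifelse(hits$strand == "+", hits$send, hits$sstart + 1L),
                   evalue = signif(hits$evalue, 6), score = hits$score,
                   stringsAsFactors = FALSE)
  write_tsv_hash(df, out)
  invisible(out)
}

#' @rdname write_hits_table
#' @param path path to a hit table.
#' @param subject_class class label to attach (`"miRNA"` or `"mRNA"`).
#' @export
read_hits_table <- function(path, subject_class = NA_character_) {
  df <- read_tsv_hash(path)
  if (!nrow(df)) {
    out <- empty_hits_df()
    return(out)
  }
  minus <- df$sstart > df$send
  data.frame(read_id = as.character(df$read_id),
             subject_id = as.character(df$subject_id),
             subject_class = subject_class,
             strand = ifelse(minus, "-", "+"),
             qstart = as.integer(df$qstart) - 1L, qend = as.integer(df$qend),
             sstart = as.integer(ifelse(minus, df$send, df$sstart)) - 1L,
             send = as.integer(ifelse(minus, df$sstart, df$send)),
             length = as.integer(df$length),
             mismatches = as.integer(df$mismatches),
             gaps = as.integer(df$gaps),
             identity = as.numeric(df$identity) / 100,
             score = as.numeric(df$score), evalue = as.numeric(df$evalue),
             stringsAsFactors = FALSE)
}

# Maximum score of any alignment anchored at the start of both q and s
# (affine gaps, local end). Used by the simulator to verify that no
# positive-scoring extension can cross a ligation junction.
ext_max_score <- function(q, s, match = 2, mismatch = -3,
                          gap_open = 5, gap_extend = 2) {
  nq <- nchar(q); ns <- nchar(s)
  if (nq == 0L || ns == 0L) return(-Inf)
  qv <- strsplit(q, "", fixed = TRUE)[[1]]
  sv <- strsplit(s, "", fixed = TRUE)[[1]]
  NEG <- -1e9
  M <- matrix(NEG, nq + 1L, ns + 1L)
  Ix <- matrix(NEG, nq + 1L, ns + 1L)  # gap in s (consumes q)
  Iy <- matrix(NEG, nq + 1L, ns + 1L)  # gap in q (consumes s)
  M[1, 1] <- 0
  for (i in seq_len(nq)) Ix[i + 1L, 1L] <- -gap_open - i * gap_extend
  for (j in seq_len(ns)) Iy[1L, j + 1L] <- -gap_open - j * gap_extend
  for (i in seq_len(nq)) {
    for (j in seq_len(ns)) {
      sc <- if (qv[i] == sv[j] && qv[i] != "N") match else mismatch
      M[i + 1L, j + 1L] <- max(M[i, j], Ix[i, j], Iy[i, j]) + sc
      Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] - gap_open - gap_extend,
                                Ix[i, j + 1L] - gap_extend)
      Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] - gap_open - gap_extend,
                                Iy[i + 1L, j] - gap_extend)
    }
  }
  M[1, 1] <- NEG
  max(M, Ix, Iy)
}
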