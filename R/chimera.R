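# Chimera selection: a merged read is called chimeric when it carries one
# miRNA arm and one mRNA arm whose read intervals do not overlap.

#' Call miRNA-mRNA chimeras from arm alignments
#'
#' For each read, all (miRNA arm, mRNA arm) pairs are enumerated and a pair is
#' admissible when (1) one arm aligns to a mature miRNA and the other to an
#' mRNA, and (2) the two read intervals are disjoint, with an inter-arm gap of
#' at most `max_gap` nt. Among admissible pairs the one maximizing the total
#' alignment score wins; ties are broken by the smaller gap, then
#' lexicographically by (miRNA id, transcript id). By default at most one
#' chimera is emitted per read; `all_pairs = TRUE` emits every admissible
#' pair. Orientation records which arm starts first on the read.
#'
#' @param arms hit data.frame from [local_align()] runs of both subject
#'   classes (rows with `subject_class` `"miRNA"` and `"mRNA"`), or a list of
#'   such data.frames.
#' @param max_gap maximum nt between the two arm intervals on the read; 0
#'   reproduces the strictest reading of the non-overlap rule.
#' @param all_pairs emit all admissible pairs instead of the single best.
#' @return a chimera-call data.frame (see [write_chimera_table()] for the
#'   columns).
#' @export
call_chimeras <- function(arms, max_gap = 10L, all_pairs = FALSE) {
  if (is.list(arms) && !is.data.frame(arms)) arms <- do.call(rbind, arms)
  empty <- read_chimera_table_empty()
  if (is.null(arms) || !nrow(arms)) return(empty)
  mir <- arms[arms$subject_class == "miRNA", , drop = FALSE]
  mrn <- arms[arms$subject_class == "mRNA", , drop = FALSE]
  if (!nrow(mir) || !nrow(mrn)) return(empty)
  out <- list()
  for (rid in intersect(unique(mir$read_id), unique(mrn$read_id))) {
    m <- mir[mir$read_id == rid, , drop = FALSE]
    t <- mrn[mrn$read_id == rid, , drop = FALSE]
    grid <- expand.grid(i = seq_len(nrow(m)), j = seq_len(nrow(t)))
    ms <- m$qstart[grid$i]; me <- m$qend[grid$i]
    ts <- t$qstart[grid$j]; te <- t$qend[grid$j]
    gap <- ifelse(me <= ts, ts - me, ifelse(te <= ms, ms - te, -1L))
    keep <- gap >= 0L & gap <= max_gap
    if (!any(keep)) next
    grid <- grid[keep, , drop = FALSE]
    gap <- gap[keep]
    total <- m$score[grid$i] + t$score[grid$j]
    ord <- order(-total, gap, m$subject_id[grid$i], t$subject_id[grid$j])
    take <- if (all_pairs) ord else ord[1L]
    for (p in take) {
      i <- grid$i[p]; j <- grid$j[p]
      stopifnot(m$qend[i] <= t$qstart[j] || t$qend[j] <= m$qstart[i])
      out[[length(out) + 1L]] <- data.frame(
        read_id = rid,
        mirna_id = m$subject_id[i], mirna_qstart = m$qstart[i],
        mirna_qend = m$qend[i], mirna_sstart = m$sstart[i],
        mirna_send = m$send[i], mirna_strand = m$strand[i],
        mirna_score = m$score[i], mirna_evalue = m$evalue[i],
        transcript_id = t$subject_id[j], mrna_qstart = t$qstart[j],
        mrna_qend = t$qend[j], mrna_sstart = t$sstart[j],
        mrna_send = t$send[j], mrna_strand = t$strand[j],
        mrna_score = t$score[j], mrna_evalue = t$evalue[j],
        inter_arm_gap = gap[p],
        orientation = if (m$qstart[i] < t$qstart[j]) "miRNA-5prime" else "miRNA-3prime",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

read_chimera_table_empty <- function() {
  cols <- list(read_id = character(0),
               mirna_id = character(0), mirna_qstart = integer(0),
               mirna_qend = integer(0), mirna_sstart = integer(0),
               mirna_send = integer(0), mirna_strand = character(0),
               mirna_score = numeric(0), mirna_evalue = numeric(0),
               transcript_id = character(0), mrna_qstart = integer(0),
               mrna_qend = integer(0), mrna_sstart = integer(0),
               mrna_send = integer(0), mrna_strand = character(0),
               mrna_score = numeric(0), mrna_evalue = numeric(0),
               inter_arm_gap = integer(0), orientation = character(0))
  as.data.frame(cols, stringsAsFactors = FALSE)
}

#' Subset chimera calls to one miRNA of interest
#'
#' @param calls chimera-call data.frame.
#' @param mirna_id miRNA identifier; if absent from the calls a warning is
#'   raised and an empty subset returned.
#' @return the matching rows, order preserved.
#' @export
select_mirna_hybrids <- function(calls, mirna_id) {
  hit <- calls$mirna_id == mirna_id
  if (!any(hit) && nrow(calls)) {
    warning("no chimera carries miRNA '", mirna_id, "'")
  }
  out <- calls[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate chimera calls per (miRNA, transcript)
#'
#' @param calls chimera-call data.frame.
#' @return data.frame `mirna_id`, `transcript_id`, `hybrid_count`,
#'   `distinct_site_intervals` (number of distinct mRNA-arm subject
#'   intervals), ordered by count descending, then ids.
#' @export
aggregate_hybrids <- function(calls) {
  if (!nrow(calls)) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      hybrid_count = integer(0),
                      distinct_site_intervals = integer(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(calls$mirna_id, calls$transcript_id, sep = "\r")
  splt <- split(seq_len(nrow(calls)), key)
  out <- do.call(rbind, lapply(splt, function(idx) {
    data.frame(mirna_id = calls$mirna_id[idx[1]],
               transcript_id = calls$transcript_id[idx[1]],
               hybrid_count = length(idx),
               distinct_site_intervals = length(unique(
                 paste(calls$mrna_sstart[idx], calls$mrna_send[idx]))),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$hybrid_count, out$mirna_id, out$transcript_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
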