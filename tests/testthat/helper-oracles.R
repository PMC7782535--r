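# Independent oracles, deliberately written as naive/brute-force code paths
# distinct from the package implementation.

# Full Smith-Waterman local alignment with affine gaps (gap of length L costs
# open + L * ext). Returns the best local score (0 if nothing positive).
sw_oracle <- function(q, s, match = 2, mismatch = -3, open = 5, ext = 2) {
  qv <- strsplit(q, "", fixed = TRUE)[[1]]
  sv <- strsplit(s, "", fixed = TRUE)[[1]]
  nq <- length(qv); ns <- length(sv)
  NEG <- -1e9
  M <- matrix(0, nq + 1, ns + 1)
  Ix <- matrix(NEG, nq + 1, ns + 1)
  Iy <- matrix(NEG, nq + 1, ns + 1)
  best <- 0
  for (i in seq_len(nq)) {
    for (j in seq_len(ns)) {
      sub <- if (qv[i] == sv[j] && qv[i] != "N") match else mismatch
      M[i + 1, j + 1] <- max(0, M[i, j] + sub, Ix[i, j] + sub, Iy[i, j] + sub)
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Iy[i + 1, j] - ext)
      if (M[i + 1, j + 1] > best) best <- M[i + 1, j + 1]
    }
  }
  best
}

# Brute-force TMM: same definition as tmm_factors but coded via explicit
# sorting and index dropping rather than ranks.
tmm_oracle <- function(mat, m_trim = 0.30, a_trim = 0.05) {
  libs <- colSums(mat)
  uq <- apply(mat, 2, function(x) unname(quantile(x, 0.75))) / libs
  ref <- which.min(abs(uq - mean(uq)))
  r <- mat[, ref]; Nr <- libs[ref]
  f <- numeric(ncol(mat))
  for (s in seq_len(ncol(mat))) {
    if (s == ref) { f[s] <- 1; next }
    x <- mat[, s]; N <- libs[s]
    keep <- which(x > 0 & r > 0)
    if (!length(keep)) { f[s] <- 1; next }
    M <- log2((x[keep] / N) / (r[keep] / Nr))
    A <- 0.5 * log2((x[keep] / N) * (r[keep] / Nr))
    w <- (N - x[keep]) / (N * x[keep]) + (Nr - r[keep]) / (Nr * r[keep])
    n <- length(M)
    dropM <- floor(n * m_trim); dropA <- floor(n * a_trim)
    oM <- order(M); oA <- order(A)
    inM <- logical(n); inM[oM[seq.int(dropM + 1, n - dropM)]] <- TRUE
    inA <- logical(n); inA[oA[seq.int(dropA + 1, n - dropA)]] <- TRUE
    sel <- inM & inA
    f[s] <- if (any(sel)) 2^(sum(M[sel] / w[sel]) / sum(1 / w[sel])) else 1
  }
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(mat))
}

# Exhaustive chimera caller: all (miRNA, mRNA) arm pairs, rules (1)+(2),
# gap <= max_gap, best total score, ties by gap then (miRNA id, transcript id).
chimera_oracle <- function(arms, max_gap = 10L) {
  out <- list()
  for (rid in unique(arms$read_id)) {
    a <- arms[arms$read_id == rid, , drop = FALSE]
    m <- a[a$subject_class == "miRNA", , drop = FALSE]
    t <- a[a$subject_class == "mRNA", , drop = FALSE]
    best <- NULL
    for (i in seq_len(nrow(m))) for (j in seq_len(nrow(t))) {
      if (m$qend[i] <= t$qstart[j]) gap <- t$qstart[j] - m$qend[i]
      else if (t$qend[j] <= m$qstart[i]) gap <- m$qstart[i] - t$qend[j]
      else next
      if (gap > max_gap) next
      cand <- list(total = m$score[i] + t$score[j], gap = gap,
                   mid = m$subject_id[i], tid = t$subject_id[j], i = i, j = j)
      if (is.null(best) ||
          cand$total > best$total ||
          (cand$total == best$total && cand$gap < best$gap) ||
          (cand$total == best$total && cand$gap == best$gap &&
           (cand$mid < best$mid ||
            (cand$mid == best$mid && cand$tid < best$tid)))) {
        best <- cand
      }
    }
    if (!is.null(best)) {
      out[[length(out) + 1L]] <- data.frame(
        read_id = rid, mirna_id = best$mid, transcript_id = best$tid,
        mirna_qstart = m$qstart[best$i], mrna_qstart = t$qstart[best$j],
        inter_arm_gap = best$gap, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# Brute-force TAR/NT3UTR counting: per read, per region, literal rule check.
count_oracle <- function(placements, regions, sample_ids) {
  rows <- c(paste0("TAR:", regions$tar$site_id),
            paste0("NT3UTR:", unique(regions$nt3utr$transcript_id)))
  mat <- matrix(0L, length(rows), length(sample_ids),
                dimnames = list(rows, sample_ids))
  for (i in seq_len(nrow(placements))) {
    tx <- placements$transcript_id[i]
    rs <- placements$start[i]; re <- placements$end[i]
    tt <- regions$tar[regions$tar$transcript_id == tx, , drop = FALSE]
    ov <- pmin(re, tt$end) - pmax(rs, tt$start)
    smp <- placements$sample_id[i]
    if (nrow(tt) && any(ov > 0)) {
      cand <- which(ov == max(ov) & ov > 0)
      pick <- cand[which.min(tt$start[cand])]
      mat[paste0("TAR:", tt$site_id[pick]), smp] <-
        mat[paste0("TAR:", tt$site_id[pick]), smp] + 1L
    } else {
      nn <- regions$nt3utr[regions$nt3utr$transcript_id == tx, , drop = FALSE]
      if (nrow(nn) && any(pmin(re, nn$end) - pmax(rs, nn$start) > 0)) {
        mat[paste0("NT3UTR:", tx), smp] <- mat[paste0("NT3UTR:", tx), smp] + 1L
      }
    }
  }
  mat
}

# random arm table for caller tests
random_arms <- function(n_reads, max_arms = 6L, read_len = 80L) {
  rows <- list()
  for (r in seq_len(n_reads)) {
    k <- sample.int(max_arms, 1)
    for (a in seq_len(k)) {
      qs <- sample.int(read_len - 12L, 1) - 1L
      qe <- qs + sample(12:30, 1)
      cls <- sample(c("miRNA", "mRNA"), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = sprintf("r%03d", r),
        subject_id = paste0(ifelse(cls == "miRNA", "miR-", "TX"),
                            sample.int(5, 1)),
        subject_class = cls, strand = "+",
        qstart = qs, qend = min(qe, read_len),
        sstart = 0L, send = min(qe, read_len) - qs,
        length = min(qe, read_len) - qs, mismatches = 0L, gaps = 0L,
        identity = 1, score = sample(10:60, 1),
        evalue = runif(1, 0, 0.1), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# small deterministic reference fixture used across unit tests
tiny_refs <- function(seed = 42L) {
  set.seed(seed)
  cfg <- sim_config(seed = seed, n_mirnas = 3L, n_transcripts = 6L,
                    n_true_sites = 3L, n_decoy_sites = 3L,
                    utr3_len = 300L, n_clash_reads = 0L,
                    n_ip_reads_per_sample = 0L)
  gen_references(cfg)
}
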