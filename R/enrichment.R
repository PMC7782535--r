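# AGO2-IP target-enrichment statistic: extend each predicted site to a
# 100 nt TAR, count reads in TAR vs the rest of the 3'-UTR (NT3UTR), compute
# per-sample local enrichment log2(TAR/NT3UTR), and rank targets by the
# WT - KO contrast.

#' Extend target sites to TARs and derive NT3UTR intervals
#'
#' The 5' end of each predicted site is moved upstream until the region is
#' `width` nt wide, truncating at the 3'-UTR boundary: TAR =
#' `[max(utr3_start, end - width), end)`. Sites already at least `width` wide
#' are returned unchanged. The NT3UTR of a transcript is its 3'-UTR minus the
#' union of all TARs on that transcript.
#'
#' @param sites site data.frame (`site_id`, `transcript_id`, `start`, `end`).
#' @param utr UTR data.frame (`transcript_id`, `utr3_start`, `utr3_end`).
#' @param width TAR width, nt.
#' @return list of class `RegionSet` with `tar` (data.frame `site_id`,
#'   `transcript_id`, `start`, `end`) and `nt3utr` (data.frame
#'   `transcript_id`, `start`, `end`; possibly several intervals per
#'   transcript).
#' @export
extend_target_regions <- function(sites, utr, width = 100L) {
  iu <- match(sites$transcript_id, utr$transcript_id)
  if (any(is.na(iu))) stop("site transcript missing from UTR table")
  u0 <- utr$utr3_start[iu]
  tar_start <- pmax(u0, sites$end - width)
  wide <- (sites$end - sites$start) >= width
  tar_start[wide] <- sites$start[wide]
  tar <- fast_df(site_id = sites$site_id,
                 transcript_id = sites$transcript_id,
                 start = as.integer(tar_start), end = as.integer(sites$end))
  nt_tx <- character(0); nt_s <- integer(0); nt_e <- integer(0)
  tar_by_tx <- split(seq_len(nrow(tar)), tar$transcript_id)
  for (i in seq_len(nrow(utr))) {
    tx <- utr$transcript_id[i]
    u0i <- utr$utr3_start[i]; u1i <- utr$utr3_end[i]
    idx <- tar_by_tx[[tx]]
    if (is.null(idx)) {
      nt_tx <- c(nt_tx, tx); nt_s <- c(nt_s, u0i); nt_e <- c(nt_e, u1i)
      next
    }
    # merge overlapping TARs, then take the complement within the UTR
    o <- idx[order(tar$start[idx])]
    ts <- tar$start[o]; te <- tar$end[o]
    ms <- ts[1]; me <- te[1]
    seg_s <- integer(0); seg_e <- integer(0)
    for (j in seq_along(ts)[-1]) {
      if (ts[j] <= me) {
        me <- max(me, te[j])
      } else {
        seg_s <- c(seg_s, ms); seg_e <- c(seg_e, me)
        ms <- ts[j]; me <- te[j]
      }
    }
    seg_s <- c(seg_s, ms); seg_e <- c(seg_e, me)
    gs <- c(u0i, seg_e); ge <- c(seg_s, u1i)
    keep <- ge > gs
    if (any(keep)) {
      nt_tx <- c(nt_tx, rep(tx, sum(keep)))
      nt_s <- c(nt_s, gs[keep]); nt_e <- c(nt_e, ge[keep])
    }
  }
  nt <- fast_df(transcript_id = nt_tx, start = nt_s, end = nt_e)
  structure(list(tar = tar, nt3utr = nt), class = "RegionSet")
}

#' Count read placements into TAR and NT3UTR regions
#'
#' A read counts toward a region when its interval overlaps it by at least
#' 1 nt. A read overlapping both a TAR and NT3UTR counts toward the TAR only;
#' a read overlapping several TARs on one transcript counts toward the TAR
#' with the largest overlap (ties to the leftmost). Each read counts at most
#' once per transcript. Row names are `TAR:<site_id>` and
#' `NT3UTR:<transcript_id>` (the NT3UTR is shared by all sites of a
#' transcript).
#'
#' @param placements data.frame `sample_id`, `transcript_id`, `start`, `end`
#'   (0-based half-open transcript intervals of aligned IP reads).
#' @param regions a `RegionSet` from [extend_target_regions()].
#' @param sample_ids optional sample ordering for the columns.
#' @return integer count matrix, regions x samples.
#' @export
count_regions <- function(placements, regions, sample_ids = NULL) {
  tar <- regions$tar
  nt <- regions$nt3utr
  if (is.null(sample_ids)) sample_ids <- sort(unique(placements$sample_id))
  rows <- c(paste0("TAR:", tar$site_id),
            paste0("NT3UTR:", unique(nt$transcript_id)))
  mat <- matrix(0L, nrow = length(rows), ncol = length(sample_ids),
                dimnames = list(rows, sample_ids))
  if (!nrow(placements)) return(mat)

  # map all transcripts into one offset coordinate space
  txs <- unique(c(tar$transcript_id, nt$transcript_id, placements$transcript_id))
  offs <- setNames(cumsum(c(0, rep(2^26, length(txs) - 1))), txs)
  gread <- IRanges::IRanges(placements$start + offs[placements$transcript_id] + 1L,
                            placements$end + offs[placements$transcript_id])
  gtar <- IRanges::IRanges(tar$start + offs[tar$transcript_id] + 1L,
                           tar$end + offs[tar$transcript_id])
  gnt <- IRanges::IRanges(nt$start + offs[nt$transcript_id] + 1L,
                          nt$end + offs[nt$transcript_id])

  ov <- IRanges::findOverlaps(gread, gtar)
  assigned_row <- rep(NA_integer_, length(gread))
  if (length(ov)) {
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    w <- IRanges::width(IRanges::pintersect(gread[qh], gtar[sh]))
    # per read: largest overlap wins, ties to leftmost TAR
    ord <- order(qh, -w, IRanges::start(gtar)[sh])
    first <- !duplicated(qh[ord])
    assigned_row[qh[ord][first]] <- sh[ord][first]
  }
  row_idx <- ifelse(is.na(assigned_row), NA_integer_, assigned_row)
  tally <- function(ridx, smp) {
    tb <- table(factor(ridx, levels = seq_along(rows)),
                factor(smp, levels = seq_along(sample_ids)))
    matrix(as.integer(tb), nrow = length(rows))
  }
  # remaining reads -> NT3UTR of their transcript if overlapping
  rest <- which(is.na(row_idx))
  if (length(rest)) {
    ov2 <- IRanges::findOverlaps(gread[rest], gnt)
    if (length(ov2)) {
      qh2 <- rest[S4Vectors::queryHits(ov2)]
      tx2 <- nt$transcript_id[S4Vectors::subjectHits(ov2)]
      dup <- duplicated(paste(qh2, tx2))  # once per transcript
      qh2 <- qh2[!dup]; tx2 <- tx2[!dup]
      mat <- mat + tally(match(paste0("NT3UTR:", tx2), rows),
                         match(placements$sample_id[qh2], sample_ids))
    }
  }
  hit <- which(!is.na(row_idx))
  if (length(hit)) {
    mat <- mat + tally(match(paste0("TAR:", tar$site_id[row_idx[hit]]), rows),
                       match(placements$sample_id[hit], sample_ids))
  }
  mat
}

#' Trimmed-mean-of-M-values (TMM) normalization factors
#'
#' Computes one scale factor per sample relative to a reference sample (the
#' one whose upper-quartile/library-size ratio is closest to the mean such
#' ratio). For each sample, gene-wise log-ratios
#' `M = log2((x/N) / (r/Nref))` and abundances
#' `A = 0.5 * log2((x/N) * (r/Nref))` are computed over genes with nonzero
#' counts in both samples; the top and bottom `m_trim` fraction of M and
#' `a_trim` fraction of A are trimmed, and the factor is `2^` the
#' delta-method-weighted mean of the surviving M values. Factors are reported
#' normalized so their geometric mean is 1.
#'
#' @param mat non-negative integer count matrix, features x samples.
#' @param m_trim,a_trim trim fractions for M and A.
#' @return named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(mat, m_trim = 0.30, a_trim = 0.05) {
  stopifnot(ncol(mat) >= 2)
  libs <- colSums(mat)
  if (any(libs == 0)) stop("all-zero sample in count matrix")
  uq <- apply(mat, 2, function(x) quantile(x, 0.75)) / libs
  ref <- which.min(abs(uq - mean(uq)))
  r <- mat[, ref]; Nr <- libs[ref]
  f <- vapply(seq_len(ncol(mat)), function(s) {
    if (s == ref) return(1)
    x <- mat[, s]; N <- libs[s]
    keep <- x > 0 & r > 0
    x <- x[keep]; rr <- r[keep]
    if (!length(x)) return(1)
    M <- log2((x / N) / (rr / Nr))
    A <- 0.5 * log2((x / N) * (rr / Nr))
    w <- (N - x) / (N * x) + (Nr - rr) / (Nr * rr)
    n <- length(M)
    loM <- floor(n * m_trim) + 1L; hiM <- n - floor(n * m_trim)
    loA <- floor(n * a_trim) + 1L; hiA <- n - floor(n * a_trim)
    rM <- rank(M, ties.method = "first")
    rA <- rank(A, ties.method = "first")
    kp <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(kp)) return(1)
    2^(sum(M[kp] / w[kp]) / sum(1 / w[kp]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(mat))
}

#' Relative TMM-effective library sizes
#'
#' `f_s = N_s * TMM_s / geomean(N * TMM)`: the per-sample divisor used inside
#' [local_enrichment()]. Relative (geometric mean 1), so that counts stay on
#' their native scale and the pseudocount keeps its meaning.
#'
#' @param mat count matrix, features x samples.
#' @param factors TMM factors from [tmm_factors()]; recomputed if `NULL`.
#' @return named numeric vector, geometric mean 1.
#' @export
effective_size_factors <- function(mat, factors = NULL) {
  if (is.null(factors)) factors <- tmm_factors(mat)
  eff <- colSums(mat) * factors
  setNames(eff / exp(mean(log(eff))), colnames(mat))
}

#' Local enrichment of a TAR relative to its NT3UTR
#'
#' `LE = log2((tar/f + c) / (nt3utr/f + c))` where `f` is the sample's
#' relative TMM-effective library size and `c` a pseudocount guarding the
#' ratio at zero counts. With `c = 0`, `f = 1` and equal counts the statistic
#' is exactly 0.
#'
#' @param tar,nt3utr non-negative counts (vectorized).
#' @param pseudocount `c`; 0 reproduces the bare log-ratio.
#' @param f scale factor(s).
#' @return numeric vector of LE values.
#' @export
local_enrichment <- function(tar, nt3utr, pseudocount = 0.5, f = 1) {
  log2((tar / f + pseudocount) / (nt3utr / f + pseudocount))
}

#' Build per-site enrichment records from a region count matrix
#'
#' @param counts matrix from [count_regions()].
#' @param regions the `RegionSet` used for counting.
#' @param genotype named character vector mapping sample id to `"IPWT"` or
#'   `"IPKO"`.
#' @param pseudocount passed to [local_enrichment()].
#' @param factors TMM factors (`NULL` to compute from `counts`; a scalar 1 to
#'   disable scaling).
#' @return data.frame with one row per site: TAR interval, per-sample
#'   `tar.<s>` / `nt3utr.<s>` counts and `le.<s>` values, `le_wt`, `le_ko`
#'   means and `delta = le_wt - le_ko`.
#' @export
enrichment_records <- function(counts, regions, genotype, pseudocount = 0.5,
                               factors = NULL) {
  samples <- colnames(counts)
  if (!all(samples %in% names(genotype))) {
    stop("genotype label missing for sample: ",
         setdiff(samples, names(genotype))[1])
  }
  geno <- genotype[samples]
  if (!all(geno %in% c("IPWT", "IPKO"))) stop("genotype must be IPWT or IPKO")
  f <- if (is.null(factors)) effective_size_factors(counts)
       else if (length(factors) == 1L) setNames(rep(factors, length(samples)), samples)
       else effective_size_factors(counts, factors)
  tar <- regions$tar
  rec <- data.frame(site_id = tar$site_id, transcript_id = tar$transcript_id,
                    tar_start = tar$start, tar_end = tar$end,
                    stringsAsFactors = FALSE)
  le <- matrix(NA_real_, nrow(rec), length(samples),
               dimnames = list(rec$site_id, samples))
  for (s in samples) {
    tc <- counts[paste0("TAR:", rec$site_id), s]
    nc <- counts[paste0("NT3UTR:", rec$transcript_id), s]
    rec[[paste0("tar.", s)]] <- as.integer(tc)
    rec[[paste0("nt3utr.", s)]] <- as.integer(nc)
    le[, s] <- local_enrichment(tc, nc, pseudocount, f[[s]])
    rec[[paste0("le.", s)]] <- le[, s]
  }
  wt <- samples[geno == "IPWT"]; ko <- samples[geno == "IPKO"]
  if (!length(wt) || !length(ko)) stop("need at least one IPWT and one IPKO sample")
  rec$le_wt <- rowMeans(le[, wt, drop = FALSE])
  rec$le_ko <- rowMeans(le[, ko, drop = FALSE])
  rec$delta <- rec$le_wt - rec$le_ko
  rec
}

#' Filter and rank candidate target sites
#'
#' Applies the local-enrichment filter, then ranks the surviving sites by
#' `delta = mean LE(WT) - mean LE(KO)` descending, so rank 1 is the site whose
#' AGO2 binding is most depleted in the knockout. Ties are broken by the WT
#' mean LE descending, then by site id. Filter modes: `wt_min` (default)
#' keeps sites whose mean WT LE is at least `le_filter_threshold` — a bona
#' fide target is locally enriched in the WT IP; `ko_max` keeps sites whose
#' mean KO LE is at most the threshold; `literal_lt` keeps sites with mean WT
#' LE strictly below the threshold (the published sentence taken verbatim).
#'
#' @param records data.frame from [enrichment_records()].
#' @param le_filter_threshold filter threshold on LE.
#' @param filter_mode one of `"wt_min"`, `"ko_max"`, `"literal_lt"`.
#' @return the filtered records with a `rank` column, ordered by rank.
#' @export
rank_targets <- function(records, le_filter_threshold = 1.0,
                         filter_mode = c("wt_min", "ko_max", "literal_lt")) {
  filter_mode <- match.arg(filter_mode)
  keep <- switch(filter_mode,
                 wt_min = records$le_wt >= le_filter_threshold,
                 ko_max = records$le_ko <= le_filter_threshold,
                 literal_lt = records$le_wt < le_filter_threshold)
  out <- records[keep, , drop = FALSE]
  ord <- order(-out$delta, -out$le_wt, out$site_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
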