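# Synthetic world with planted ground truth: references with seed-matched
# target sites, WT/KO AGO2-IP libraries whose reads pile up at true-site TARs
# with genotype-dependent intensity, and CLASH libraries of adapter-flanked
# miRNA+target ligation chimeras over a background of contiguous fragments.

#' Simulation configuration
#'
#' Defaults state the simulated world once: two replicates per genotype,
#' 20,000 IP reads per sample, 8-fold WT TAR enrichment versus 1-fold in the
#' knockout, 2,000 CLASH reads of which 20% are true hybrids, 1% substitution
#' error, 101 bp paired-end reads. One target site is planted per transcript
#' (so `n_true_sites + n_decoy_sites` must not exceed `n_transcripts`);
#' 400 nt 3'-UTRs with one 100 nt TAR give a bona fide WT target a local
#' enrichment comfortably above the filter threshold of 1 while decoys stay
#' below it.
#'
#' @param seed master seed; every library derives its own reproducible
#'   sub-stream from it.
#' @param n_mirnas,n_transcripts,cds_len,utr3_len reference dimensions, nt.
#' @param n_true_sites,n_decoy_sites planted true target sites (seed-matched
#'   to a miRNA) and decoy sites (no seed complement).
#' @param wt_tar_fold,ko_tar_fold sampling-density multiplier inside a true
#'   site's TAR for WT and KO IP libraries.
#' @param n_ip_reads_per_sample,n_samples_per_genotype IP design.
#' @param n_clash_reads,chimera_fraction,background_fraction CLASH design;
#'   the two fractions must sum to 1.
#' @param error_rate per-base substitution probability applied independently
#'   to each mate.
#' @param read_len read length, nt.
#' @param fragment_len_range IP fragment lengths (uniform), nt.
#' @param clash_arm_len_range target-fragment (mRNA arm) lengths in CLASH
#'   hybrids, nt.
#' @param tar_width TAR width used by the enrichment model, nt.
#' @return a `SimConfig` list.
#' @export
sim_config <- function(seed = 1L, n_mirnas = 5L, n_transcripts = 20L,
                       cds_len = 200L, utr3_len = 400L,
                       n_true_sites = 5L, n_decoy_sites = 15L,
                       wt_tar_fold = 8, ko_tar_fold = 1,
                       n_ip_reads_per_sample = 20000L,
                       n_samples_per_genotype = 2L,
                       n_clash_reads = 2000L, chimera_fraction = 0.2,
                       background_fraction = 1 - chimera_fraction,
                       error_rate = 0.01, read_len = 101L,
                       fragment_len_range = c(60L, 90L),
                       clash_arm_len_range = c(25L, 50L),
                       tar_width = 100L) {
  stopifnot(wt_tar_fold >= 1, ko_tar_fold >= 1,
            chimera_fraction >= 0, chimera_fraction <= 1,
            background_fraction >= 0, background_fraction <= 1,
            error_rate >= 0, error_rate <= 1, read_len >= 20,
            length(fragment_len_range) == 2, length(clash_arm_len_range) == 2)
  if (abs(chimera_fraction + background_fraction - 1) > 1e-9) {
    stop("chimera_fraction + background_fraction must equal 1")
  }
  if (n_true_sites + n_decoy_sites > n_transcripts) {
    stop("one site is planted per transcript: need n_true_sites + n_decoy_sites <= n_transcripts")
  }
  if (utr3_len < tar_width + 40L) {
    stop("utr3_len too small for the requested sites (need >= tar_width + 40)")
  }
  structure(list(seed = as.integer(seed), n_mirnas = as.integer(n_mirnas),
                 n_transcripts = as.integer(n_transcripts),
                 cds_len = as.integer(cds_len), utr3_len = as.integer(utr3_len),
                 n_true_sites = as.integer(n_true_sites),
                 n_decoy_sites = as.integer(n_decoy_sites),
                 wt_tar_fold = wt_tar_fold, ko_tar_fold = ko_tar_fold,
                 n_ip_reads_per_sample = as.integer(n_ip_reads_per_sample),
                 n_samples_per_genotype = as.integer(n_samples_per_genotype),
                 n_clash_reads = as.integer(n_clash_reads),
                 chimera_fraction = chimera_fraction,
                 background_fraction = background_fraction,
                 error_rate = error_rate, read_len = as.integer(read_len),
                 fragment_len_range = as.integer(fragment_len_range),
                 clash_arm_len_range = as.integer(clash_arm_len_range),
                 tar_width = as.integer(tar_width)),
            class = "SimConfig")
}

mirna_seed_rc <- function(m) revcomp(substr(m, 2, 8))

#' Generate references with planted target sites
#'
#' miRNAs are random 20-23mers; transcripts are random sequences whose last
#' `utr3_len` nt form the 3'-UTR. A true site emulates a canonical duplex:
#' the reverse complement of the owning miRNA's 3'-compensatory region
#' (nt 13-19), a short spacer, the reverse complement of the seed (nt 2-8),
#' and a terminal A. Decoy sites are random 3'-UTR intervals verified to
#' contain no seed complement of any miRNA. One site per transcript;
#' positions leave room for a full-width TAR.
#'
#' @param cfg a [sim_config()].
#' @return list with `refs` (a `ReferenceSet`) and `truth` (data.frame
#'   `site_id`, `transcript_id`, `mirna_id`, `is_true`, `wt_fold`,
#'   `ko_fold`).
#' @export
gen_references <- function(cfg) {
  set.seed(sub_seed(cfg$seed, "refs"))
  mir_ids <- sprintf("miR-%02d", seq_len(cfg$n_mirnas))
  mirnas <- setNames(random_dna(cfg$n_mirnas, sample(20:23, cfg$n_mirnas,
                                                     replace = TRUE)), mir_ids)
  tx_ids <- sprintf("TX%03d", seq_len(cfg$n_transcripts))
  tx_len <- cfg$cds_len + cfg$utr3_len
  transcripts <- setNames(random_dna(cfg$n_transcripts, tx_len), tx_ids)
  utr <- data.frame(transcript_id = tx_ids, utr3_start = cfg$cds_len,
                    utr3_end = tx_len, stringsAsFactors = FALSE)
  n_sites <- cfg$n_true_sites + cfg$n_decoy_sites
  site_tx <- sample(tx_ids, n_sites)
  seed_rcs <- vapply(mirnas, mirna_seed_rc, character(1))

  sites <- list(); truth <- list()
  for (i in seq_len(n_sites)) {
    tx <- site_tx[i]
    is_true <- i <= cfg$n_true_sites
    u0 <- cfg$cds_len; u1 <- tx_len
    width <- 19L
    if (is_true) {
      mid <- mir_ids[(i - 1L) %% cfg$n_mirnas + 1L]
      m <- mirnas[[mid]]
      site_seq <- paste0(revcomp(substr(m, 13, 19)), random_dna(1, 4),
                         revcomp(substr(m, 2, 8)), "A")
      end <- sample((u0 + cfg$tar_width):u1, 1)
      start <- end - width
      transcripts[[tx]] <- paste0(substr(transcripts[[tx]], 1, start),
                                  site_seq,
                                  substr(transcripts[[tx]], end + 1L, tx_len))
    } else {
      mid <- NA_character_
      for (try in 1:200) {
        end <- sample((u0 + cfg$tar_width):u1, 1)
        start <- end - width
        sub <- substr(transcripts[[tx]], start + 1L, end)
        if (!any(vapply(seed_rcs, grepl, logical(1), x = sub, fixed = TRUE))) break
        if (try == 200) stop("could not place a decoy site without a seed match")
      }
    }
    sid <- sprintf("site_%02d", i)
    sites[[i]] <- data.frame(site_id = sid, transcript_id = tx,
                             start = start, end = end,
                             source_label = if (is_true) "true" else "decoy",
                             stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(site_id = sid, transcript_id = tx,
                             mirna_id = mid, is_true = is_true,
                             wt_fold = if (is_true) cfg$wt_tar_fold else 1,
                             ko_fold = if (is_true) cfg$ko_tar_fold else 1,
                             stringsAsFactors = FALSE)
  }
  refs <- reference_set(mirnas, transcripts, utr, do.call(rbind, sites))
  list(refs = refs, truth = do.call(rbind, truth))
}

# (tx, start, length) universe of admissible UTR fragments with TAR weights
ip_fragment_universe <- function(refs, truth, cfg, fold) {
  tars <- extend_target_regions(refs$sites, refs$utr, cfg$tar_width)$tar
  tars <- tars[tars$site_id %in% truth$site_id[truth$is_true], , drop = FALSE]
  lmin <- cfg$fragment_len_range[1]; lmax <- cfg$fragment_len_range[2]
  out <- vector("list", nrow(refs$utr))
  for (i in seq_len(nrow(refs$utr))) {
    tx <- refs$utr$transcript_id[i]
    u0 <- refs$utr$utr3_start[i]; u1 <- refs$utr$utr3_end[i]
    lens <- lmin:lmax
    lens <- lens[lens <= u1 - u0]
    counts <- (u1 - u0) - lens + 1L
    len_rep <- rep.int(lens, counts)
    start <- u0 + sequence(counts) - 1L
    w <- rep(1, length(start))
    tt <- tars[tars$transcript_id == tx, , drop = FALSE]
    if (nrow(tt)) {
      ovl <- rep(FALSE, length(start))
      for (j in seq_len(nrow(tt))) {
        ovl <- ovl | (start < tt$end[j] & start + len_rep > tt$start[j])
      }
      w[ovl] <- fold
    }
    out[[i]] <- data.frame(transcript_id = tx, start = start,
                           len = len_rep, w = w, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate one AGO2-IP library
#'
#' Fragments are drawn uniformly over all admissible (transcript, start,
#' length) 3'-UTR placements, except that placements overlapping a true
#' site's TAR carry weight `wt_tar_fold` (WT) or `ko_tar_fold` (KO). Each
#' fragment is optionally materialized as an overlapping read pair with
#' substitution errors. The returned placements are the exact ground-truth
#' input of [count_regions()].
#'
#' @param refs,truth from [gen_references()].
#' @param cfg a [sim_config()].
#' @param genotype `"WT"` or `"KO"`.
#' @param sample_id label for this replicate (also seeds its RNG stream).
#' @param reads materialize read pairs (`FALSE` returns placements only,
#'   which is how large replicate sweeps are run).
#' @return list with `placements` (data.frame `sample_id`, `transcript_id`,
#'   `start`, `end`) and, when `reads = TRUE`, `pairs` (FASTQ-ready pair
#'   data.frame).
#' @export
simulate_ip_library <- function(refs, truth, cfg, genotype = c("WT", "KO"),
                                sample_id = paste0(genotype, "-A-IP"),
                                reads = TRUE) {
  genotype <- match.arg(genotype)
  set.seed(sub_seed(cfg$seed, paste0("ip:", genotype, ":", sample_id)))
  fold <- if (genotype == "WT") cfg$wt_tar_fold else cfg$ko_tar_fold
  uni <- ip_fragment_universe(refs, truth, cfg, fold)
  n <- cfg$n_ip_reads_per_sample
  if (n == 0L) {
    placements <- data.frame(sample_id = character(0),
                             transcript_id = character(0),
                             start = integer(0), end = integer(0),
                             stringsAsFactors = FALSE)
    return(list(placements = placements,
                pairs = if (reads) empty_pairs_df() else NULL,
                sample_id = sample_id, genotype = genotype))
  }
  pick <- sample.int(nrow(uni), n, replace = TRUE, prob = uni$w)
  placements <- data.frame(sample_id = sample_id,
                           transcript_id = uni$transcript_id[pick],
                           start = uni$start[pick],
                           end = uni$start[pick] + uni$len[pick],
                           stringsAsFactors = FALSE)
  res <- list(placements = placements, sample_id = sample_id,
              genotype = genotype)
  if (reads) {
    frags <- substr(refs$transcripts[placements$transcript_id],
                    placements$start + 1L, placements$end)
    ids <- sprintf("ip_%s_%06d", sample_id, seq_len(n))
    res$pairs <- fragments_to_pairs(frags, ids, cfg$read_len, cfg$error_rate)
  }
  res
}

empty_pairs_df <- function() {
  data.frame(id = character(0), r1_seq = character(0), r2_seq = character(0),
             r1_qual = character(0), r2_qual = character(0),
             stringsAsFactors = FALSE)
}

fragments_to_pairs <- function(frags, ids, read_len, error_rate) {
  if (!length(frags)) return(empty_pairs_df())
  L <- nchar(frags)
  r1 <- substr(frags, 1L, pmin(read_len, L))
  r2 <- revcomp(substr(frags, pmax(1L, L - read_len + 1L), L))
  r1 <- inject_errors(r1, error_rate)
  r2 <- inject_errors(r2, error_rate)
  data.frame(id = ids, r1_seq = r1, r2_seq = r2,
             r1_qual = strrep("I", nchar(r1)), r2_qual = strrep("I", nchar(r2)),
             stringsAsFactors = FALSE)
}

# TRUE when no positive-scoring alignment extension can cross either ligation
# junction of the insert (checked with a small anchored affine DP on the
# error-free sequences; see the methods vignette).
junction_clean <- function(m, k, tx_seq, s, f, mir_first, win = 12L) {
  arm <- substr(m, 1, k)
  frag <- substr(tx_seq, s + 1L, s + f)
  if (mir_first) {
    # miRNA arm may extend right into the fragment (only if truncated)
    if (k < nchar(m)) {
      ext_s <- substr(m, k + 1L, min(nchar(m), k + win))
      if (ext_max_score(substr(frag, 1, win), ext_s) >= 0) return(FALSE)
    }
    # mRNA arm may extend left into the miRNA arm
    if (s > 0) {
      left_s <- substr(tx_seq, max(1L, s - win + 1L), s)
      rq <- paste(rev(strsplit(substr(arm, max(1L, k - win + 1L), k), "")[[1]]), collapse = "")
      rs <- paste(rev(strsplit(left_s, "")[[1]]), collapse = "")
      if (ext_max_score(rq, rs) >= 0) return(FALSE)
    }
  } else {
    # fragment arm may extend right into the miRNA arm
    if (s + f < nchar(tx_seq)) {
      ext_s <- substr(tx_seq, s + f + 1L, min(nchar(tx_seq), s + f + win))
      if (ext_max_score(substr(arm, 1, win), ext_s) >= 0) return(FALSE)
    }
    # miRNA arm starts at subject position 1: no leftward extension possible
  }
  TRUE
}

#' Simulate a CLASH library with planted hybrids
#'
#' A hybrid read is a full or 3'-truncated miRNA (at least 14 nt) ligated to
#' a target-proximal 3'-UTR fragment covering the planted site (orientation
#' random), flanked by the 5' and 3' library adapters, substitution-error
#' injected, and split into an overlapping read pair. Background reads are
#' contiguous 3'-UTR or miRNA fragments with the same adapters. Hybrids are
#' constructed junction-unambiguous: a candidate is resampled when a
#' positive-scoring alignment extension could cross the ligation junction,
#' which would otherwise make the two arms overlap on the read and trip the
#' non-overlap rule regardless of caller correctness.
#'
#' @param refs,truth from [gen_references()].
#' @param cfg a [sim_config()].
#' @param adapters an [adapter_spec()].
#' @return list with `pairs` (FASTQ-ready pair data.frame) and `truth_reads`
#'   (data.frame `read_id`, `label`, `mirna_id`, `transcript_id`, `site_id`).
#' @export
simulate_clash_library <- function(refs, truth, cfg, adapters = adapter_spec()) {
  set.seed(sub_seed(cfg$seed, "clash"))
  n <- cfg$n_clash_reads
  n_hyb <- round(n * cfg$chimera_fraction)
  true_sites <- truth[truth$is_true, , drop = FALSE]
  if (n_hyb > 0 && !nrow(true_sites)) stop("no true sites to build hybrids from")
  lmin <- cfg$clash_arm_len_range[1]; lmax <- cfg$clash_arm_len_range[2]

  inserts <- character(n)
  lab <- data.frame(read_id = sprintf("clash_%06d", seq_len(n)),
                    label = rep("background", n),
                    mirna_id = rep(NA_character_, n),
                    transcript_id = rep(NA_character_, n),
                    site_id = rep(NA_character_, n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (i <= n_hyb) {
      st <- true_sites[sample.int(nrow(true_sites), 1), ]
      m <- refs$mirnas[[st$mirna_id]]
      tx_seq <- refs$transcripts[[st$transcript_id]]
      iu <- match(st$transcript_id, refs$utr$transcript_id)
      u0 <- refs$utr$utr3_start[iu]; u1 <- refs$utr$utr3_end[iu]
      si <- refs$sites[refs$sites$site_id == st$site_id, ]
      ok <- FALSE
      for (try in 1:100) {
        k <- sample(14:nchar(m), 1)
        f <- sample(lmin:lmax, 1)
        smin <- max(u0, si$end - f)
        smax <- min(si$start, u1 - f)
        if (smax < smin) next
        s <- if (smax > smin) sample(smin:smax, 1) else smin
        mir_first <- runif(1) < 0.5
        if (junction_clean(m, k, tx_seq, s, f, mir_first)) { ok <- TRUE; break }
      }
      if (!ok) next  # leave as background (never observed at default sizes)
      arm <- substr(m, 1, k)
      frag <- substr(tx_seq, s + 1L, s + f)
      inserts[i] <- if (mir_first) paste0(arm, frag) else paste0(frag, arm)
      lab$label[i] <- "hybrid"
      lab$mirna_id[i] <- st$mirna_id
      lab$transcript_id[i] <- st$transcript_id
      lab$site_id[i] <- st$site_id
    } else if (runif(1) < 0.25 && length(refs$mirnas)) {
      mid <- sample(names(refs$mirnas), 1)
      inserts[i] <- refs$mirnas[[mid]]
    } else {
      iu <- sample.int(nrow(refs$utr), 1)
      u0 <- refs$utr$utr3_start[iu]; u1 <- refs$utr$utr3_end[iu]
      f <- sample(30:70, 1)
      s <- sample(u0:(u1 - f), 1)
      inserts[i] <- substr(refs$transcripts[[refs$utr$transcript_id[iu]]],
                           s + 1L, s + f)
    }
  }
  if (n == 0L) return(list(pairs = empty_pairs_df(), truth_reads = lab))
  full <- paste0(adapters$five_prime, inserts, adapters$three_prime)
  pairs <- fragments_to_pairs(full, lab$read_id, cfg$read_len, cfg$error_rate)
  list(pairs = pairs, truth_reads = lab)
}
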