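simple_utr <- function(end = 400L) {
  data.frame(transcript_id = "T1", utr3_start = 0L, utr3_end = end,
             stringsAsFactors = FALSE)
}

test_that("extend_target_region widens the 5' end to 100 nt", {
  sites <- data.frame(site_id = "s1", transcript_id = "T1",
                      start = 200L, end = 222L, stringsAsFactors = FALSE)
  rg <- extend_target_regions(sites, simple_utr())
  expect_equal(rg$tar$start, 122L)
  expect_equal(rg$tar$end, 222L)
  expect_equal(rg$tar$end - rg$tar$start, 100L)
  # truncation at the UTR boundary
  near <- data.frame(site_id = "s2", transcript_id = "T1",
                     start = 10L, end = 30L, stringsAsFactors = FALSE)
  rg2 <- extend_target_regions(near, simple_utr())
  expect_equal(rg2$tar$start, 0L)
  expect_equal(rg2$tar$end, 30L)
  # sites already >= width are unchanged
  wide <- data.frame(site_id = "s3", transcript_id = "T1",
                     start = 100L, end = 250L, stringsAsFactors = FALSE)
  rg3 <- extend_target_regions(wide, simple_utr())
  expect_equal(rg3$tar$start, 100L)
  expect_equal(rg3$tar$end, 250L)
})

test_that("NT3UTR excludes all TARs and the region algebra closes", {
  sites <- data.frame(site_id = c("a", "b"), transcript_id = "T1",
                      start = c(120L, 300L), end = c(140L, 320L),
                      stringsAsFactors = FALSE)
  rg <- extend_target_regions(sites, simple_utr())
  tar_w <- sum(rg$tar$end - rg$tar$start)
  nt_w <- sum(rg$nt3utr$end - rg$nt3utr$start)
  expect_equal(nt_w + tar_w, 400L)
  for (i in seq_len(nrow(rg$tar))) {
    expect_true(all(pmin(rg$nt3utr$end, rg$tar$end[i]) -
                      pmax(rg$nt3utr$start, rg$tar$start[i]) <= 0))
  }
})

test_that("count_regions matches the brute-force overlap oracle", {
  gen <- tiny_refs()
  rg <- extend_target_regions(gen$refs$sites, gen$refs$utr)
  set.seed(51)
  n <- 300
  tx <- sample(names(gen$refs$transcripts), n, replace = TRUE)
  st <- sample(150:450, n, replace = TRUE)
  plc <- data.frame(sample_id = sample(c("s1", "s2"), n, replace = TRUE),
                    transcript_id = tx, start = st,
                    end = pmin(st + sample(20:80, n, replace = TRUE), 500L),
                    stringsAsFactors = FALSE)
  got <- count_regions(plc, rg, sample_ids = c("s1", "s2"))
  want <- count_oracle(plc, rg, c("s1", "s2"))
  expect_equal(got, want)
  # no reads -> all zeros
  zero <- count_regions(plc[0, ], rg, sample_ids = c("s1", "s2"))
  expect_true(all(zero == 0L))
  # single-read TAR overlap rule
  one <- data.frame(sample_id = "s1", transcript_id = rg$tar$transcript_id[1],
                    start = rg$tar$start[1] + 5L, end = rg$tar$start[1] + 30L)
  m1 <- count_regions(one, rg, sample_ids = "s1")
  expect_equal(m1[paste0("TAR:", rg$tar$site_id[1]), "s1"], 1L)
  expect_equal(sum(m1), 1L)
})

test_that("conservation: TAR + NT3UTR counts never exceed reads in the UTR", {
  gen <- tiny_refs()
  rg <- extend_target_regions(gen$refs$sites, gen$refs$utr)
  cfg <- sim_config(seed = 52, n_mirnas = 3L, n_transcripts = 6L,
                    n_true_sites = 3L, n_decoy_sites = 3L, utr3_len = 300L,
                    n_ip_reads_per_sample = 2000L)
  lib <- simulate_ip_library(gen$refs, gen$truth, cfg, "WT", "W1", reads = FALSE)
  cm <- count_regions(lib$placements, rg, sample_ids = "W1")
  expect_lte(sum(cm), nrow(lib$placements))
  # all simulated fragments lie inside a 3'-UTR, so equality holds here
  expect_equal(sum(cm), nrow(lib$placements))
})

test_that("TMM factors are exactly 1 for identical or scaled columns", {
  set.seed(53)
  x <- matrix(rpois(40, 50) + 1L, ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  x[, 2] <- x[, 1]
  expect_equal(unname(tmm_factors(x)), c(1, 1))
  x[, 2] <- 2L * x[, 1]
  expect_equal(unname(tmm_factors(x)), c(1, 1))
})

test_that("tmm_factors matches the brute-force oracle on random matrices", {
  set.seed(54)
  for (trial in 1:12) {
    ng <- sample(8:20, 1); ns <- sample(2:4, 1)
    m <- matrix(rpois(ng * ns, lambda = sample(20:200, 1)), ng, ns,
                dimnames = list(NULL, paste0("s", seq_len(ns))))
    m[sample(length(m), round(0.08 * length(m)))] <- 0L
    # inflate one gene in one sample
    m[sample(ng, 1), sample(ns, 1)] <- 5000L
    if (any(colSums(m) == 0)) next
    expect_equal(tmm_factors(m), tmm_oracle(m), tolerance = 1e-9,
                 info = paste("trial", trial))
  }
  expect_error(tmm_factors(cbind(a = c(0L, 0L), b = c(1L, 2L))), "all-zero")
})

test_that("local enrichment matches its closed forms and is monotone", {
  expect_equal(local_enrichment(8, 2, pseudocount = 0, f = 1), 2.0)
  expect_equal(local_enrichment(7, 7, pseudocount = 0.5, f = 1), 0.0)
  expect_equal(local_enrichment(0, 7, pseudocount = 0.5, f = 1),
               log2(0.5 / 7.5))
  le_tar <- local_enrichment(0:50, 10, pseudocount = 0.5)
  expect_true(all(diff(le_tar) > 0))
  le_nt <- local_enrichment(10, 0:50, pseudocount = 0.5)
  expect_true(all(diff(le_nt) < 0))
})

test_that("rank_targets reproduces the worked filtering/ranking example", {
  rec <- data.frame(site_id = c("site1", "site2", "site3"),
                    transcript_id = "T", tar_start = 0L, tar_end = 100L,
                    le_wt = c(2.5, 1.2, 3.0), le_ko = c(0.1, 1.1, 2.9),
                    stringsAsFactors = FALSE)
  rec$delta <- rec$le_wt - rec$le_ko
  rk <- rank_targets(rec, le_filter_threshold = 1, filter_mode = "wt_min")
  expect_equal(rk$site_id, c("site1", "site3", "site2"))
  expect_equal(rk$rank, 1:3)
  expect_equal(rk$delta[1], 2.4)
  # literal reading of the published filter keeps LE < 1
  lit <- rank_targets(rec, le_filter_threshold = 1, filter_mode = "literal_lt")
  expect_equal(nrow(lit), 0)
  lo <- rank_targets(rec, le_filter_threshold = 3.5, filter_mode = "literal_lt")
  expect_equal(nrow(lo), 3)
  # identical sites rank by site id; single site gets rank 1
  same <- rec; same$le_wt <- 2; same$le_ko <- 1; same$delta <- 1
  expect_equal(rank_targets(same)$site_id, c("site1", "site2", "site3"))
  expect_equal(rank_targets(rec[1, , drop = FALSE])$rank, 1L)
})

test_that("enrichment_records wires counts, factors and genotypes together", {
  gen <- tiny_refs()
  rg <- extend_target_regions(gen$refs$sites, gen$refs$utr)
  cfg <- sim_config(seed = 55, n_mirnas = 3L, n_transcripts = 6L,
                    n_true_sites = 3L, n_decoy_sites = 3L, utr3_len = 300L,
                    n_ip_reads_per_sample = 4000L)
  plc <- rbind(
    simulate_ip_library(gen$refs, gen$truth, cfg, "WT", "W1", reads = FALSE)$placements,
    simulate_ip_library(gen$refs, gen$truth, cfg, "WT", "W2", reads = FALSE)$placements,
    simulate_ip_library(gen$refs, gen$truth, cfg, "KO", "K1", reads = FALSE)$placements,
    simulate_ip_library(gen$refs, gen$truth, cfg, "KO", "K2", reads = FALSE)$placements)
  cm <- count_regions(plc, rg, sample_ids = c("W1", "W2", "K1", "K2"))
  geno <- c(W1 = "IPWT", W2 = "IPWT", K1 = "IPKO", K2 = "IPKO")
  rec <- enrichment_records(cm, rg, geno)
  expect_equal(nrow(rec), nrow(gen$refs$sites))
  expect_equal(rec$delta, rec$le_wt - rec$le_ko)
  true_ids <- gen$truth$site_id[gen$truth$is_true]
  expect_true(min(rec$delta[rec$site_id %in% true_ids]) >
                max(rec$delta[!rec$site_id %in% true_ids]))
  expect_error(enrichment_records(cm, rg, geno[1:3]), "genotype")
  expect_error(enrichment_records(cm, rg,
                                  setNames(rep("IPWT", 4), names(geno))),
               "IPKO")
})
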