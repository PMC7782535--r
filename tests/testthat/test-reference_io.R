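write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  path
}

make_ref_files <- function(dir, mirnas, transcripts, utr, sites) {
  dir.create(dir, showWarnings = FALSE)
  paths <- list(
    mir = write_fasta(mirnas, file.path(dir, "mir.fa")),
    tx = write_fasta(transcripts, file.path(dir, "tx.fa")),
    utr = file.path(dir, "utr.tsv"),
    sites = file.path(dir, "sites.tsv"))
  mirclash:::write_tsv_hash(utr, paths$utr)
  mirclash:::write_tsv_hash(sites, paths$sites)
  paths
}

base_inputs <- function() {
  set.seed(1)
  list(
    mirnas = c(`miR-a` = "GUAAUGCUAAUCGUGAUAGGGGUU",
               `miR-b` = "ACGGUACGAUCGGAUCCAAGG"),
    transcripts = setNames(mirclash:::random_dna(3, 600),
                           c("T1", "T2", "T3")),
    utr = data.frame(transcript_id = c("T1", "T2", "T3"),
                     utr3_start = c(100L, 150L, 200L),
                     utr3_end = c(480L, 600L, 600L)),
    sites = data.frame(transcript_id = c("T1", "T1", "T2", "T3"),
                       start = c(150L, 300L, 400L, 500L),
                       end = c(172L, 322L, 422L, 522L),
                       site_id = paste0("s", 1:4),
                       source = "pred"))
}

test_that("load_references ingests, converts U->T, and reports counts", {
  b <- base_inputs()
  p <- make_ref_files(withr::local_tempdir(), b$mirnas, b$transcripts, b$utr, b$sites)
  refs <- load_references(p$mir, p$tx, p$utr, p$sites, quiet = TRUE)
  expect_s3_class(refs, "ReferenceSet")
  expect_length(refs$mirnas, 2)
  expect_length(refs$transcripts, 3)
  expect_equal(nrow(refs$sites), 4)
  # U->T conversion on ingest
  expect_equal(unname(refs$mirnas[["miR-a"]]), "GTAATGCTAATCGTGATAGGGGTT")
  expect_false(any(grepl("U", refs$mirnas)))
})

test_that("duplicate ids and unknown transcripts are hard errors", {
  b <- base_inputs()
  dup <- c(b$mirnas, `miR-a` = "ACGUACGUACGUACGUACGU")
  p <- make_ref_files(withr::local_tempdir(), dup, b$transcripts, b$utr, b$sites)
  expect_error(load_references(p$mir, p$tx, p$utr, p$sites, quiet = TRUE),
               "miR-a")
  bad_sites <- rbind(b$sites,
                     data.frame(transcript_id = "TX_MISSING", start = 1L,
                                end = 10L, site_id = "s9", source = "pred"))
  p2 <- make_ref_files(withr::local_tempdir(), b$mirnas, b$transcripts, b$utr, bad_sites)
  expect_error(load_references(p2$mir, p2$tx, p2$utr, p2$sites, quiet = TRUE),
               "unknown transcript")
})

test_that("sites outside the 3'-UTR are clipped or dropped with a warning", {
  b <- base_inputs()
  # [500,520) on T1 whose UTR is [100,480): empty after clipping -> dropped
  b$sites <- rbind(b$sites,
                   data.frame(transcript_id = "T1", start = 500L, end = 520L,
                              site_id = "s_out", source = "pred"))
  p <- make_ref_files(withr::local_tempdir(), b$mirnas, b$transcripts, b$utr, b$sites)
  expect_warning(expect_warning(
    refs <- load_references(p$mir, p$tx, p$utr, p$sites, quiet = TRUE),
    "clipped"), "dropped")
  expect_false("s_out" %in% refs$sites$site_id)
  expect_equal(nrow(refs$sites), 4)
  # straddling site is clipped, not dropped
  b2 <- base_inputs()
  b2$sites$start[1] <- 90L  # UTR starts at 100
  p2 <- make_ref_files(withr::local_tempdir(), b2$mirnas, b2$transcripts, b2$utr, b2$sites)
  expect_warning(refs2 <- load_references(p2$mir, p2$tx, p2$utr, p2$sites,
                                          quiet = TRUE), "clipped")
  expect_equal(refs2$sites$start[refs2$sites$site_id == "s1"], 100L)
})

test_that("loading is order-independent up to record ordering", {
  b <- base_inputs()
  p1 <- make_ref_files(withr::local_tempdir(), b$mirnas, b$transcripts, b$utr, b$sites)
  p2 <- make_ref_files(withr::local_tempdir(), rev(b$mirnas),
                       b$transcripts[c(2, 3, 1)], b$utr, b$sites)
  r1 <- load_references(p1$mir, p1$tx, p1$utr, p1$sites, quiet = TRUE)
  r2 <- load_references(p2$mir, p2$tx, p2$utr, p2$sites, quiet = TRUE)
  expect_equal(r1$mirnas[sort(names(r1$mirnas))], r2$mirnas[sort(names(r2$mirnas))])
  expect_equal(r1$transcripts[sort(names(r1$transcripts))],
               r2$transcripts[sort(names(r2$transcripts))])
  expect_equal(r1$sites[order(r1$sites$site_id), ],
               r2$sites[order(r2$sites$site_id), ])
})

test_that("chimera table writes deterministically and round-trips", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  empty <- mirclash:::read_chimera_table_empty()
  write_chimera_table(empty, tmp)
  expect_equal(length(readLines(tmp)), 1L)  # header-only
  expect_true(startsWith(readLines(tmp)[1], "#"))

  gen <- tiny_refs()
  cfg <- sim_config(seed = 5, n_mirnas = 3L, n_transcripts = 6L,
                    n_true_sites = 3L, n_decoy_sites = 3L, utr3_len = 300L,
                    n_clash_reads = 60L, error_rate = 0)
  cl <- simulate_clash_library(gen$refs, gen$truth, cfg)
  tr <- trim_adapters(merge_pairs(cl$pairs))
  surv <- filter_contiguous(tr[tr$pass, c("id", "sequence")], gen$refs)
  calls <- call_chimeras(rbind(
    local_align(surv, gen$refs, align_params(evalue_max = 10), "miRNA"),
    local_align(surv, gen$refs, align_params(evalue_max = 0.1), "mRNA")))
  expect_gt(nrow(calls), 2)
  write_chimera_table(calls, tmp)
  expect_equal(length(readLines(tmp)), nrow(calls) + 1L)
  back <- read_chimera_table(tmp)
  ord <- order(calls$read_id, pmin(calls$mirna_qstart, calls$mrna_qstart))
  sorted <- calls[ord, ]
  rownames(sorted) <- NULL
  expect_equal(back[names(sorted)], sorted, tolerance = 1e-6)
})

test_that("write_references round-trips through load_references", {
  gen <- tiny_refs()
  dir <- withr::local_tempdir()
  p <- write_references(gen$refs, dir)
  back <- load_references(p[["mirna_fasta"]], p[["transcript_fasta"]],
                          p[["utr_table"]], p[["site_table"]], quiet = TRUE)
  expect_equal(back$mirnas, gen$refs$mirnas)
  expect_equal(back$transcripts, gen$refs$transcripts)
  expect_equal(back$sites, gen$refs$sites)
  expect_equal(back$utr, gen$refs$utr)
})
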