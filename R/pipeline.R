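# Orchestration: configuration, staged execution with a funnel log, a
# run manifest, and the command-line entry point.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline in one validated object. The two
#' alignment parameter sets default to the printed search thresholds:
#' E-value at most 10 for the miRNA class and 0.1 for the mRNA class.
#'
#' @param mirna_fasta,transcript_fasta,utr_table,site_table reference inputs
#'   (see [load_references()]).
#' @param clash_r1,clash_r2 CLASH paired FASTQ files (clash / all modes).
#' @param ip_samples data.frame `sample_id`, `genotype` (`IPWT`/`IPKO`) and
#'   either `r1`,`r2` FASTQ paths or a `placements` TSV path per sample
#'   (ip-enrich / all modes).
#' @param out_dir output directory.
#' @param merge a [merge_params()].
#' @param adapters an [adapter_spec()]; `trim = FALSE` disables trimming.
#' @param trim trim adapters after merging.
#' @param align_mirna,align_mrna [align_params()] for the two searches.
#' @param max_gap maximum inter-arm gap for [call_chimeras()].
#' @param focus_mirna optional miRNA id for a dedicated hybrid table.
#' @param tar_width,pseudocount,m_trim,a_trim,filter_mode,le_threshold
#'   enrichment parameters (see [extend_target_regions()], [tmm_factors()],
#'   [rank_targets()]).
#' @param seed seed recorded in the manifest.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(mirna_fasta, transcript_fasta, utr_table,
                            site_table, clash_r1 = NULL, clash_r2 = NULL,
                            ip_samples = NULL, out_dir = "mirclash_out",
                            merge = merge_params(), adapters = adapter_spec(),
                            trim = TRUE,
                            align_mirna = align_params(evalue_max = 10),
                            align_mrna = align_params(evalue_max = 0.1),
                            max_gap = 10L, focus_mirna = NULL,
                            tar_width = 100L, pseudocount = 0.5,
                            m_trim = 0.30, a_trim = 0.05,
                            filter_mode = "wt_min", le_threshold = 1.0,
                            seed = 1L) {
  cfg <- structure(list(mirna_fasta = mirna_fasta,
                        transcript_fasta = transcript_fasta,
                        utr_table = utr_table, site_table = site_table,
                        clash_r1 = clash_r1, clash_r2 = clash_r2,
                        ip_samples = ip_samples, out_dir = out_dir,
                        merge = merge, adapters = adapters, trim = isTRUE(trim),
                        align_mirna = align_mirna, align_mrna = align_mrna,
                        max_gap = as.integer(max_gap),
                        focus_mirna = focus_mirna,
                        tar_width = as.integer(tar_width),
                        pseudocount = pseudocount, m_trim = m_trim,
                        a_trim = a_trim, filter_mode = filter_mode,
                        le_threshold = le_threshold, seed = as.integer(seed)),
                   class = "PipelineConfig")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  for (f in c(cfg$mirna_fasta, cfg$transcript_fasta, cfg$utr_table,
              cfg$site_table, cfg$clash_r1, cfg$clash_r2)) {
    if (!is.null(f) && !file.exists(f)) stop("configured file does not exist: ", f)
  }
  if (!is.null(cfg$ip_samples)) {
    stopifnot(all(c("sample_id", "genotype") %in% names(cfg$ip_samples)))
    if (!all(cfg$ip_samples$genotype %in% c("IPWT", "IPKO"))) {
      stop("ip_samples$genotype must be IPWT or IPKO")
    }
  }
  invisible(TRUE)
}

stage <- function(name, log, expr) {
  log(sprintf("[%s] start", name))
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the pipeline
#'
#' `clash` mode: merge pairs, trim adapters, remove contiguously-explained
#' reads, align arms against both reference classes, call chimeras, and write
#' the chimera and aggregate hybrid tables. `ip-enrich` mode: place each IP
#' sample's reads on the transcripts (or load pre-computed placements), count
#' TAR/NT3UTR, TMM-normalize, compute local enrichment and write the ranked
#' target table. `all` runs both and writes a combined report
#' cross-referencing chimera-supported sites with enrichment ranks. Every run
#' writes a `manifest.json` with the configuration hash, seed, stage counts
#' and output checksums, sufficient to reproduce the run bit-for-bit.
#'
#' @param config a [pipeline_config()].
#' @param mode `"clash"`, `"ip-enrich"` or `"all"`.
#' @param quiet suppress stage log messages.
#' @return (invisibly) the output directory, with attribute `"outputs"`
#'   naming the files written.
#' @export
run_pipeline <- function(config, mode = c("all", "clash", "ip-enrich"),
                         quiet = FALSE) {
  mode <- match.arg(mode)
  validate_pipeline_config(config)
  log <- if (quiet) function(...) invisible() else function(msg) message(msg)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  counts <- list()

  refs <- stage("references", log,
                load_references(config$mirna_fasta, config$transcript_fasta,
                                config$utr_table, config$site_table,
                                quiet = TRUE))
  counts$mirnas <- length(refs$mirnas)
  counts$transcripts <- length(refs$transcripts)
  counts$sites <- nrow(refs$sites)

  calls <- NULL
  if (mode %in% c("all", "clash")) {
    if (is.null(config$clash_r1)) stop("clash mode needs clash_r1/clash_r2")
    pairs <- stage("read-fastq", log,
                   read_fastq_pairs(config$clash_r1, config$clash_r2))
    counts$clash_pairs_in <- nrow(pairs)
    merged <- stage("merge", log, merge_pairs(pairs, config$merge))
    counts$clash_merged <- sum(merged$merged)
    trimmed <- if (config$trim) {
      stage("trim", log, trim_adapters(merged, config$adapters))
    } else {
      merged$pass <- merged$merged
      merged
    }
    counts$clash_pass_trim <- sum(trimmed$pass)
    f_merged <- file.path(config$out_dir, "merged_trimmed.fastq")
    write_fastq_merged(trimmed, f_merged)
    outputs <- c(outputs, f_merged)
    reads <- trimmed[trimmed$pass, c("id", "sequence")]
    surv <- stage("contiguity-filter", log, filter_contiguous(reads, refs))
    counts$clash_noncontiguous <- nrow(surv)
    log(sprintf("[funnel] pairs %d -> merged %d -> trimmed %d -> non-contiguous %d",
                counts$clash_pairs_in, counts$clash_merged,
                counts$clash_pass_trim, counts$clash_noncontiguous))
    hits_mir <- stage("align-miRNA", log,
                      local_align(surv, refs, config$align_mirna, "miRNA"))
    hits_mrna <- stage("align-mRNA", log,
                       local_align(surv, refs, config$align_mrna, "mRNA"))
    f_hm <- file.path(config$out_dir, "hits_mirna.tsv")
    f_ht <- file.path(config$out_dir, "hits_mrna.tsv")
    write_hits_table(hits_mir, f_hm)
    write_hits_table(hits_mrna, f_ht)
    outputs <- c(outputs, f_hm, f_ht)
    calls <- stage("chimera", log,
                   call_chimeras(rbind(hits_mir, hits_mrna),
                                 max_gap = config$max_gap))
    counts$chimeras <- nrow(calls)
    f_ch <- file.path(config$out_dir, "chimeras.tsv")
    write_chimera_table(calls, f_ch)
    agg <- aggregate_hybrids(calls)
    f_ag <- file.path(config$out_dir, "hybrids_by_pair.tsv")
    write_tsv_hash(agg, f_ag)
    outputs <- c(outputs, f_ch, f_ag)
    if (!is.null(config$focus_mirna)) {
      sel <- select_mirna_hybrids(calls, config$focus_mirna)
      f_sel <- file.path(config$out_dir,
                         paste0("hybrids_", config$focus_mirna, ".tsv"))
      write_chimera_table(sel, f_sel)
      outputs <- c(outputs, f_sel)
    }
  }

  ranked <- NULL
  if (mode %in% c("all", "ip-enrich")) {
    if (is.null(config$ip_samples)) stop("ip-enrich mode needs ip_samples")
    smp <- config$ip_samples
    regions <- stage("regions", log,
                     extend_target_regions(refs$sites, refs$utr,
                                           config$tar_width))
    plc <- stage("place-reads", log, do.call(rbind, lapply(
      seq_len(nrow(smp)), function(i) {
        if (!is.null(smp$placements) && !is.na(smp$placements[i])) {
          p <- read_tsv_hash(smp$placements[i])
          p$start <- as.integer(p$start); p$end <- as.integer(p$end)
        } else {
          pr <- read_fastq_pairs(smp$r1[i], smp$r2[i])
          mg <- merge_pairs(pr, config$merge)
          p <- place_reads(mg[mg$merged, c("id", "sequence")], refs)
          p <- p[, c("transcript_id", "start", "end")]
        }
        p$sample_id <- smp$sample_id[i]
        p[, c("sample_id", "transcript_id", "start", "end")]
      })))
    counts$ip_placements <- nrow(plc)
    cmat <- stage("count", log,
                  count_regions(plc, regions, sample_ids = smp$sample_id))
    fac <- stage("tmm", log,
                 tmm_factors(cmat, m_trim = config$m_trim,
                             a_trim = config$a_trim))
    f_fac <- file.path(config$out_dir, "tmm_factors.tsv")
    write_tsv_hash(data.frame(sample_id = names(fac), factor = fac), f_fac)
    f_cm <- file.path(config$out_dir, "region_counts.tsv")
    write_tsv_hash(data.frame(region = rownames(cmat),
                              as.data.frame(cmat, check.names = FALSE)), f_cm)
    genotype <- setNames(smp$genotype, smp$sample_id)
    rec <- stage("enrichment", log,
                 enrichment_records(cmat, regions, genotype,
                                    pseudocount = config$pseudocount,
                                    factors = fac))
    ranked <- rank_targets(rec, config$le_threshold, config$filter_mode)
    counts$ranked_sites <- nrow(ranked)
    f_en <- file.path(config$out_dir, "enrichment_ranked.tsv")
    write_enrichment_table(ranked, f_en)
    outputs <- c(outputs, f_fac, f_cm, f_en)
  }

  if (mode == "all" && !is.null(calls) && !is.null(ranked)) {
    report <- stage("report", log, combined_report(calls, ranked))
    f_rep <- file.path(config$out_dir, "combined_report.tsv")
    write_tsv_hash(report, f_rep)
    outputs <- c(outputs, f_rep)
  }

  manifest <- list(
    package = "mirclash",
    version = as.character(utils::packageVersion("mirclash")),
    mode = mode, seed = config$seed,
    config_md5 = config_md5(config),
    counts = counts,
    outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                               basename(outputs))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res <- config$out_dir
  attr(res, "outputs") <- outputs
  invisible(res)
}

config_md5 <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Cross-reference chimera support with enrichment ranks
#'
#' For every ranked site, counts the chimeras whose mRNA arm falls on the
#' site's transcript and overlaps its TAR — the convergent-evidence view:
#' a true target should both be ligated to its miRNA in CLASH and lose IP
#' coverage in the knockout.
#'
#' @param calls chimera-call data.frame.
#' @param ranked ranked enrichment table from [rank_targets()].
#' @return the ranked table with `chimera_support` and `chimera_mirnas`
#'   columns.
#' @export
combined_report <- function(calls, ranked) {
  support <- integer(nrow(ranked))
  mirnas <- character(nrow(ranked))
  for (i in seq_len(nrow(ranked))) {
    hit <- calls$transcript_id == ranked$transcript_id[i] &
      calls$mrna_sstart < ranked$tar_end[i] &
      calls$mrna_send > ranked$tar_start[i]
    support[i] <- sum(hit)
    mirnas[i] <- paste(sort(unique(calls$mirna_id[hit])), collapse = ",")
  }
  cbind(ranked[, c("site_id", "transcript_id", "tar_start", "tar_end",
                   "le_wt", "le_ko", "delta", "rank")],
        data.frame(chimera_support = support, chimera_mirnas = mirnas,
                   stringsAsFactors = FALSE))
}
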