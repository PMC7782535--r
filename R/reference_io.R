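#' Load miRNA/transcript references and the target-site table
#'
#' Reads the four reference inputs of the pipeline and validates them into a
#' `ReferenceSet`: mature miRNA sequences (FASTA, `U` converted to `T` on
#' ingest), transcript sequences (FASTA), a 3'-UTR interval table, and a
#' BED-like predicted target-site table. All intervals are 0-based half-open
#' in transcript coordinates; the pipeline operates entirely in transcript
#' space (genomic coordinates are assumed pre-mapped by the user or by the
#' simulator).
#'
#' @param mirna_fasta path to a FASTA of mature miRNA sequences (RNA or DNA
#'   alphabet; `U`/`u` are converted to `T`).
#' @param transcript_fasta path to a FASTA of transcript sequences.
#' @param utr_table path to a 3-column TSV (`transcript_id`, `utr3_start`,
#'   `utr3_end`) with a single `#`-prefixed header line.
#' @param site_table path to a BED-like TSV (`transcript_id`, `start`, `end`,
#'   `site_id`, `source`) with a `#` header line. Sites extending outside the
#'   transcript's 3'-UTR are clipped with a warning; sites that become empty
#'   are dropped with a warning.
#' @param quiet suppress the load report message.
#' @return an object of class `ReferenceSet`: a list with elements `mirnas`
#'   (named character vector of DNA sequences), `transcripts` (named character
#'   vector), `utr` (data.frame `transcript_id`, `utr3_start`, `utr3_end`) and
#'   `sites` (data.frame `site_id`, `transcript_id`, `start`, `end`,
#'   `source_label`).
#' @export
load_references <- function(mirna_fasta, transcript_fasta, utr_table,
                            site_table, quiet = FALSE) {
  for (f in c(mirna_fasta, transcript_fasta, utr_table, site_table)) {
    if (!file.exists(f)) stop("input file does not exist: ", f)
  }
  mir_raw <- Biostrings::readBStringSet(mirna_fasta)
  mirnas <- toupper(chartr("Uu", "Tt", as.character(mir_raw)))
  tx_raw <- Biostrings::readBStringSet(transcript_fasta)
  transcripts <- toupper(as.character(tx_raw))
  utr <- read_tsv_hash(utr_table)
  utr$utr3_start <- as.integer(utr$utr3_start)
  utr$utr3_end <- as.integer(utr$utr3_end)
  sites <- read_tsv_hash(site_table)
  if (nrow(sites)) {
    sites <- data.frame(site_id = as.character(sites$site_id),
                        transcript_id = as.character(sites$transcript_id),
                        start = as.integer(sites$start),
                        end = as.integer(sites$end),
                        source_label = as.character(sites$source),
                        stringsAsFactors = FALSE)
  } else {
    sites <- empty_sites_df()
  }
  reference_set(mirnas, transcripts, utr, sites, quiet = quiet)
}

empty_sites_df <- function() {
  data.frame(site_id = character(0), transcript_id = character(0),
             start = integer(0), end = integer(0),
             source_label = character(0), stringsAsFactors = FALSE)
}

#' Construct and validate a ReferenceSet from in-memory components
#'
#' @param mirnas named character vector of mature miRNA DNA sequences.
#' @param transcripts named character vector of transcript DNA sequences.
#' @param utr data.frame with `transcript_id`, `utr3_start`, `utr3_end`
#'   (0-based half-open).
#' @param sites data.frame with `site_id`, `transcript_id`, `start`, `end`,
#'   `source_label`.
#' @param quiet suppress the load report.
#' @return a validated `ReferenceSet`.
#' @export
reference_set <- function(mirnas, transcripts, utr, sites = empty_sites_df(),
                          quiet = TRUE) {
  if (anyDuplicated(names(mirnas))) {
    stop("duplicate miRNA id: ",
         names(mirnas)[duplicated(names(mirnas))][1])
  }
  if (anyDuplicated(names(transcripts))) {
    stop("duplicate transcript id: ",
         names(transcripts)[duplicated(names(transcripts))][1])
  }
  if (any(nchar(mirnas) == 0)) stop("empty miRNA sequence")
  check_dna(mirnas, "miRNA sequence")
  check_dna(transcripts, "transcript sequence")
  atypical <- nchar(mirnas) < 18 | nchar(mirnas) > 25
  if (any(atypical)) {
    warning(sum(atypical), " miRNA(s) outside the typical 18-25 nt range")
  }
  if (anyDuplicated(utr$transcript_id)) stop("duplicate transcript id in UTR table")
  missing_utr <- setdiff(names(transcripts), utr$transcript_id)
  if (length(missing_utr)) {
    stop("UTR table lacks an interval for transcript: ", missing_utr[1])
  }
  txlen <- nchar(transcripts)[match(utr$transcript_id, names(transcripts))]
  if (any(is.na(txlen))) {
    stop("UTR table references unknown transcript: ",
         utr$transcript_id[which(is.na(txlen))[1]])
  }
  bad <- utr$utr3_start < 0 | utr$utr3_start >= utr$utr3_end | utr$utr3_end > txlen
  if (any(bad)) {
    stop("invalid 3'-UTR interval for transcript: ",
         utr$transcript_id[which(bad)[1]])
  }

  if (nrow(sites)) {
    if (anyDuplicated(sites$site_id)) {
      stop("duplicate site id: ", sites$site_id[duplicated(sites$site_id)][1])
    }
    unk <- setdiff(sites$transcript_id, names(transcripts))
    if (length(unk)) stop("site references unknown transcript: ", unk[1])
    iu <- match(sites$transcript_id, utr$transcript_id)
    s0 <- pmax(sites$start, utr$utr3_start[iu])
    e0 <- pmin(sites$end, utr$utr3_end[iu])
    clipped <- s0 != sites$start | e0 != sites$end
    if (any(clipped)) {
      warning(sum(clipped), " site(s) extended outside the 3'-UTR and were clipped")
    }
    keep <- s0 < e0
    if (!all(keep)) {
      warning(sum(!keep), " site(s) empty after clipping to the 3'-UTR; dropped")
    }
    sites$start <- s0
    sites$end <- e0
    sites <- sites[keep, , drop = FALSE]
    rownames(sites) <- NULL
    key <- paste(sites$transcript_id, sites$start, sites$end)
    if (anyDuplicated(key)) {
      stop("duplicate (transcript, interval) site: ", key[duplicated(key)][1])
    }
  }

  refs <- structure(list(mirnas = mirnas, transcripts = transcripts,
                         utr = utr, sites = sites),
                    class = "ReferenceSet")
  if (!quiet) {
    message(sprintf("loaded references: %d miRNAs, %d transcripts, %d sites",
                    length(mirnas), length(transcripts), nrow(sites)))
  }
  refs
}

#' @export
print.ReferenceSet <- function(x, ...) {
  cat(sprintf("ReferenceSet: %d miRNAs, %d transcripts, %d target sites\n",
              length(x$mirnas), length(x$transcripts), nrow(x$sites)))
  invisible(x)
}

#' Write a ReferenceSet to FASTA/TSV files
#'
#' Materializes the four reference inputs in the formats accepted by
#' [load_references()]. Used mainly to persist simulated references.
#'
#' @param refs a `ReferenceSet`.
#' @param dir output directory (created if needed).
#' @return named character vector of the four file paths.
#' @export
write_references <- function(refs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mirna_fasta = file.path(dir, "mirnas.fa"),
             transcript_fasta = file.path(dir, "transcripts.fa"),
             utr_table = file.path(dir, "utr3.tsv"),
             site_table = file.path(dir, "sites.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(refs$mirnas),
                              paths["mirna_fasta"])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(refs$transcripts),
                              paths["transcript_fasta"])
  write_tsv_hash(refs$utr, paths["utr_table"])
  st <- refs$sites
  bed <- data.frame(transcript_id = st$transcript_id, start = st$start,
                    end = st$end, site_id = st$site_id,
                    source = st$source_label, stringsAsFactors = FALSE)
  write_tsv_hash(bed, paths["site_table"])
  paths
}

CHIMERA_COLS <- c("read_id",
                  "mirna_id", "mirna_qstart", "mirna_qend", "mirna_sstart",
                  "mirna_send", "mirna_strand", "mirna_score", "mirna_evalue",
                  "transcript_id", "mrna_qstart", "mrna_qend", "mrna_sstart",
                  "mrna_send", "mrna_strand", "mrna_score", "mrna_evalue",
                  "inter_arm_gap", "orientation")

#' Write a chimera-call table
#'
#' One row per called chimera: the read, the miRNA arm (read interval, subject
#' interval, strand, score, E-value), the mRNA arm, the inter-arm gap on the
#' read, and the orientation (`miRNA-5prime` when the miRNA arm comes first on
#' the read). Intervals are 0-based half-open. Rows are ordered by read id,
#' then by the start of the first arm, so the output is deterministic.
#'
#' @param calls chimera-call data.frame from [call_chimeras()].
#' @param out output path.
#' @return the output path, invisibly.
#' @export
write_chimera_table <- function(calls, out) {
  if (is.null(calls) || nrow(calls) == 0) {
    calls <- as.data.frame(setNames(rep(list(character(0)), length(CHIMERA_COLS)),
                                    CHIMERA_COLS), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(CHIMERA_COLS %in% names(calls)))
    calls <- calls[, CHIMERA_COLS, drop = FALSE]
    first_arm <- pmin(calls$mirna_qstart, calls$mrna_qstart)
    calls <- calls[order(calls$read_id, first_arm), , drop = FALSE]
  }
  write_tsv_hash(calls, out)
  invisible(out)
}

#' Read back a chimera-call table written by [write_chimera_table()]
#' @param path path to the TSV.
#' @return a data.frame with the chimera-call columns.
#' @export
read_chimera_table <- function(path) {
  df <- read_tsv_hash(path)
  if (!nrow(df)) {
    for (cc in CHIMERA_COLS) df[[cc]] <- character(0)
    df <- df[, CHIMERA_COLS, drop = FALSE]
  }
  int_cols <- c("mirna_qstart", "mirna_qend", "mirna_sstart", "mirna_send",
                "mrna_qstart", "mrna_qend", "mrna_sstart", "mrna_send",
                "inter_arm_gap")
  num_cols <- c("mirna_score", "mirna_evalue", "mrna_score", "mrna_evalue")
  for (cc in int_cols) df[[cc]] <- as.integer(df[[cc]])
  for (cc in num_cols) df[[cc]] <- as.numeric(df[[cc]])
  df
}

#' Write / read the per-site enrichment table
#'
#' Columns: site identity, TAR interval, per-sample TAR and NT3UTR counts,
#' per-sample local enrichment, the WT-KO contrast `delta`, and `rank`.
#' Per-sample columns are named `<stat>.<sample_id>`.
#'
#' @param tab ranked enrichment data.frame from [rank_targets()].
#' @param out output path.
#' @return the output path, invisibly.
#' @export
write_enrichment_table <- function(tab, out) {
  write_tsv_hash(tab, out)
  invisible(out)
}

#' @rdname write_enrichment_table
#' @param path path to a TSV written by [write_enrichment_table()].
#' @export
read_enrichment_table <- function(path) {
  df <- read_tsv_hash(path)
  for (cc in names(df)) {
    if (grepl("^(tar|nt3utr)\\.", cc) || cc %in% c("tar_start", "tar_end", "rank")) {
      df[[cc]] <- as.integer(df[[cc]])
    } else if (grepl("^le\\.", cc) || cc %in% c("delta", "le_wt", "le_ko")) {
      df[[cc]] <- as.numeric(df[[cc]])
    }
  }
  df
}
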