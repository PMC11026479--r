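## Synthetic sequencing: UMI-family counts and structured paired-end reads.

## Gamma-Poisson family counts for one sample. Returns an integer vector per
## oligo row.
nb_counts <- function(mu, dispersion) {
  if (dispersion <= 0) return(as.integer(rpois(length(mu), mu)))
  as.integer(rnbinom(length(mu), size = 1 / dispersion, mu = mu))
}

## Expected family count per oligo for a library type.
oligo_mu <- function(oligos, truth, config, library_type) {
  tt <- truth[match(oligos$variant_id, truth$variant_id), ]
  if (library_type == "DNA") {
    rep(config$dna_depth, nrow(oligos))
  } else {
    config$rna_depth * tt$baseline_abundance *
      exp(ifelse(oligos$allele == "alt", tt$true_lnFC, 0))
  }
}

#' Simulate deduplicated UMI-family counts directly
#'
#' Draws the same gamma-Poisson family counts as [simulate_reads()] without
#' emitting reads: DNA families are overdispersed around `dna_depth`, RNA
#' families around `rna_depth * baseline * exp(true_lnFC)` for the alternative
#' allele. Use this for statistical calibration at depths where read-level
#' simulation is unnecessary.
#'
#' @param oligos Oligo table from [assemble_oligos()].
#' @param truth Truth table from [simulate_truth()].
#' @param config A [sim_config()].
#' @return Long-format count table: `oligo_id`, `variant_id`, `allele`,
#'   `library_type`, `replicate`, `raw`, `dedup` (raw equals dedup here).
#' @export
simulate_counts <- function(oligos, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  assert_that(nrow(oligos) > 0, "empty oligo table")
  set.seed(stage_seed(config, 3L))
  out <- list()
  for (lt in c("DNA", "RNA")) {
    mu <- oligo_mu(oligos, truth, config, lt)
    for (r in seq_len(config$n_replicates)) {
      fam <- nb_counts(mu, config$dispersion)
      out[[length(out) + 1L]] <- data.frame(
        oligo_id = oligos$oligo_id, variant_id = oligos$variant_id,
        allele = oligos$allele, library_type = lt, replicate = r,
        raw = fam, dedup = fam, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

## Inject substitution errors into a character vector of reads.
inject_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0) return(reads)
  len <- nchar(reads[1])
  n_err <- rbinom(length(reads), len, error_rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    p <- sample.int(len, n_err[i])
    ch <- strsplit(reads[i], "")[[1]]
    ch[p] <- vapply(ch[p], function(b) sample(setdiff(DNA_BASES, b), 1), "")
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Simulate structured paired-end reads
#'
#' For every oligo, library type and replicate, UMI families are drawn from
#' the gamma-Poisson model and each family is emitted
#' `1 + Poisson(pcr_duplication_rate - 1)` times (every copy shares the
#' family's 15-nt UMI). Read 1 is UMI + RT primer + REC2 + subpool primer +
#' the first 100 nt of the designed sequence; read 2 is the reverse complement
#' of the designed strand (first 150 nt). Substitution errors are injected at
#' `error_rate` per base across both reads.
#'
#' @inheritParams simulate_counts
#' @param primers Subpool primers used in read 1 (must match the oligos).
#' @param rlayout A [read_layout()].
#' @param read2_len Read-2 length in nt.
#' @return List with class `sim_reads`: `samples` (list of
#'   `library_type`/`replicate`/`reads` data.frames with truth columns
#'   `oligo_id` and `umi`), `family_counts` (as [simulate_counts()]), `config`.
#' @export
simulate_reads <- function(oligos, truth, config,
                           primers = default_subpool_primers(config$flank_design),
                           rlayout = read_layout(), read2_len = 150L) {
  stopifnot(inherits(config, "sim_config"))
  assert_that(nrow(oligos) > 0, "empty oligo table")
  set.seed(stage_seed(config, 4L))
  prefix <- paste0(RT_PRIMER_SEQ, REC2_SEQ, primers$fwd)
  stopifnot(nchar(prefix) == rlayout$rt_primer_len + rlayout$rec2_len +
              rlayout$subpool_len)
  frag <- substr(oligos$full_sequence, 1L, rlayout$design_frag_len)
  r2 <- substr(revcomp(oligos$full_sequence), 1L, read2_len)

  samples <- list()
  fam_rows <- list()
  for (lt in c("DNA", "RNA")) {
    mu <- oligo_mu(oligos, truth, config, lt)
    for (rep_i in seq_len(config$n_replicates)) {
      fam <- nb_counts(mu, config$dispersion)
      fam_rows[[length(fam_rows) + 1L]] <- data.frame(
        oligo_id = oligos$oligo_id, variant_id = oligos$variant_id,
        allele = oligos$allele, library_type = lt, replicate = rep_i,
        raw = fam, dedup = fam, stringsAsFactors = FALSE)
      oi <- rep.int(seq_len(nrow(oligos)), fam)
      n_fam <- length(oi)
      umi <- random_dna(n_fam, rlayout$umi_len)
      copies <- if (config$pcr_duplication_rate == 1) {
        rep(1L, n_fam)
      } else {
        1L + rpois(n_fam, config$pcr_duplication_rate - 1)
      }
      ri <- rep.int(seq_len(n_fam), copies)
      read1 <- inject_errors(paste0(umi[ri], prefix, frag[oi][ri]),
                             config$error_rate)
      read2 <- inject_errors(r2[oi][ri], config$error_rate)
      samples[[paste(lt, rep_i, sep = "_rep")]] <- list(
        library_type = lt, replicate = rep_i,
        reads = data.frame(
          read_id = sprintf("%s_rep%d_read%06d", lt, rep_i, seq_along(ri)),
          read1 = read1, read2 = read2,
          oligo_id = oligos$oligo_id[oi][ri], umi = umi[ri],
          stringsAsFactors = FALSE))
    }
  }
  structure(list(samples = samples,
                 family_counts = do.call(rbind, fam_rows),
                 config = config),
            class = "sim_reads")
}

#' Write simulated reads as paired FASTQ plus a run manifest
#'
#' One R1/R2 FASTQ pair per (library type, replicate); 4-line records with
#' constant Phred+33 quality `"I"`. All generator parameters are echoed to
#' `manifest.yaml`.
#'
#' @param sim A `sim_reads` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a data.frame listing the files written.
#' @export
write_sim_fastq <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_reads"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (nm in names(sim$samples)) {
    s <- sim$samples[[nm]]
    for (mate in 1:2) {
      seqs <- s$reads[[paste0("read", mate)]]
      path <- file.path(dir, sprintf("%s_R%d.fastq", nm, mate))
      qual <- strrep("I", nchar(seqs))
      writeLines(paste0("@", s$reads$read_id, "/", mate, "\n", seqs, "\n+\n",
                        qual), path)
      files[[length(files) + 1L]] <- data.frame(
        sample = nm, mate = mate, path = path, n_reads = length(seqs),
        stringsAsFactors = FALSE)
    }
  }
  yaml::write_yaml(unclass(sim$config), file.path(dir, "manifest.yaml"))
  invisible(do.call(rbind, files))
}

#' Read a paired FASTQ sample back into memory
#'
#' @param r1_path,r2_path Paths to the R1/R2 FASTQ files (optionally gzipped).
#' @return data.frame with `read_id`, `read1`, `read2`.
#' @export
read_fastq_pair <- function(r1_path, r2_path) {
  r1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq")
  stopifnot(length(r1) == length(r2))
  data.frame(read_id = sub("/1$", "", names(r1)),
             read1 = as.character(r1), read2 = as.character(r2),
             stringsAsFactors = FALSE, row.names = NULL)
}
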