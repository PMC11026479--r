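## From raw paired reads to deduplicated per-allele UMI counts.
##
## The matcher replaces a general-purpose aligner: references are short, fixed
## and enumerable, so exact hashing of the read-1 design fragment and of the
## read-2 window implements the screen's rule directly -- assign a read pair
## to a reference iff it has at most 1 mismatch across the compared bases and
## no mismatch falls on that reference's designed SNP position. With at most
## one substitution, at least one of the two mates matches some reference
## exactly, so hash lookups enumerate every viable candidate.

#' Slice read 1 into its structured segments
#'
#' Fixed-width slicing: UMI, RT primer, REC2 site, subpool primer, design
#' fragment. No sequence validation is performed here; reads shorter than the
#' layout are flagged for QC.
#'
#' @param read1 Character vector of read-1 sequences.
#' @param layout A [read_layout()].
#' @return data.frame with `umi`, `rt`, `rec2`, `subpool`, `frag`, `ok`
#'   (FALSE for short reads, whose segments are NA).
#' @export
parse_read1 <- function(read1, layout = read_layout()) {
  ok <- nchar(read1) >= layout$total
  b <- cumsum(c(0L, layout$umi_len, layout$rt_primer_len, layout$rec2_len,
                layout$subpool_len, layout$design_frag_len))
  seg <- function(i) ifelse(ok, substr(read1, b[i] + 1L, b[i + 1L]), NA)
  data.frame(umi = seg(1), rt = seg(2), rec2 = seg(3), subpool = seg(4),
             frag = seg(5), ok = ok, stringsAsFactors = FALSE)
}

#' Build the matching index over a designed oligo library
#'
#' Both alleles of every variant are distinct references. The index hashes the
#' exact read-1 design fragment (first `design_frag_len` nt of the full
#' sequence) and the read-2 window (last `read2_len` nt, on the designed
#' strand) of every reference.
#'
#' @param oligos Oligo table from [assemble_oligos()].
#' @param rlayout A [read_layout()].
#' @param read2_len Read-2 length in nt.
#' @return An index list used by [match_to_library()].
#' @export
build_library_index <- function(oligos, rlayout = read_layout(),
                                read2_len = 150L) {
  lay <- oligo_layout(oligos$layout[1])
  full <- oligos$full_sequence
  L <- nchar(full[1])
  stopifnot(all(nchar(full) == L))
  frag <- substr(full, 1L, rlayout$design_frag_len)
  r2_start <- L - read2_len + 1L
  r2win <- substr(full, r2_start, L)
  snp_pos <- lay$fwd_primer_len + lay$sites[["EcoRI"]] +
    oligos$variant_offset + 1L   # 1-based position in the full sequence
  hash_groups <- function(keys) {
    e <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_along(keys)) {
      e[[keys[i]]] <- c(e[[keys[i]]], i)
    }
    e
  }
  list(oligos = oligos, full = full, L = L, frag = frag, r2win = r2win,
       r2_start = r2_start, read2_len = read2_len,
       frag_len = rlayout$design_frag_len, snp_pos = snp_pos,
       frag_hash = hash_groups(frag), r2_hash = hash_groups(r2win),
       fwd_primer_len = lay$fwd_primer_len,
       rev_primer_len = lay$rev_primer_len)
}

## Mismatch positions (1-based within the compared window) between one read
## segment and one reference segment.
mm_positions <- function(obs, ref) {
  a <- strsplit(obs, "", fixed = TRUE)[[1]]
  b <- strsplit(ref, "", fixed = TRUE)[[1]]
  n <- min(length(a), length(b))
  which(a[seq_len(n)] != b[seq_len(n)])
}

## Evaluate one read pair against one candidate reference index.
eval_candidate <- function(idx, i, frag, r2c) {
  mm1 <- mm_positions(frag, idx$frag[i])                 # full coords = pos
  mm2 <- if (is.null(r2c)) integer(0) else
    mm_positions(r2c, idx$r2win[i]) + idx$r2_start - 1L  # map to full coords
  list(total = length(mm1) + length(mm2),
       pos = c(mm1, mm2),
       at_snp = any(c(mm1, mm2) == idx$snp_pos[i]))
}

#' Match one read (pair) to the oligo library
#'
#' A read pair is assigned to a reference iff the total number of mismatches
#' across the compared bases of read 1's design fragment and read 2 is at most
#' `max_mismatch` and no mismatch falls on that reference's designed SNP
#' position. Ambiguity (two or more references at the equal best distance) and
#' read-pair disagreement yield `"unmapped"` / `"ambiguous"`; these are
#' categories, not errors. Read-2 orientation is auto-detected by trying the
#' reverse complement first.
#'
#' @param frag Design fragment from [parse_read1()].
#' @param read2 Read-2 sequence, or `NA`/`NULL` for fragment-only matching.
#' @param index Index from [build_library_index()].
#' @param max_mismatch Maximum total mismatches (screen rule: 1).
#' @return List with `oligo_id` (NA when unassigned), `status`
#'   (`mapped`/`unmapped`/`ambiguous`), `n_mismatch`, `mismatch_pos` (1-based
#'   positions in the full designed sequence).
#' @export
match_to_library <- function(frag, read2, index, max_mismatch = 1L) {
  try_orientation <- function(r2c) {
    cand <- c(index$frag_hash[[frag]],
              if (!is.null(r2c)) index$r2_hash[[r2c]])
    if (is.null(r2c) && is.null(cand) && max_mismatch >= 1L) {
      ## fragment-only mode: probe the 1-substitution neighborhood
      ch <- strsplit(frag, "", fixed = TRUE)[[1]]
      for (p in seq_along(ch)) {
        for (b in setdiff(DNA_BASES, ch[p])) {
          probe <- frag
          substr(probe, p, p) <- b
          cand <- c(cand, index$frag_hash[[probe]])
        }
      }
    }
    cand <- unique(cand)
    if (!length(cand)) return(NULL)
    evals <- lapply(cand, eval_candidate, idx = index, frag = frag, r2c = r2c)
    ok <- vapply(evals, function(e) e$total <= max_mismatch && !e$at_snp,
                 logical(1))
    n_at_snp <- sum(vapply(evals, function(e)
      e$total <= max_mismatch && e$at_snp, logical(1)))
    if (!any(ok)) {
      return(list(oligo_id = NA_character_,
                  status = if (n_at_snp >= 2) "ambiguous" else "unmapped",
                  n_mismatch = NA_integer_, mismatch_pos = integer(0)))
    }
    tot <- vapply(evals, function(e) e$total, integer(1))
    best <- min(tot[ok])
    hits <- which(ok & tot == best)
    if (length(hits) > 1) {
      return(list(oligo_id = NA_character_, status = "ambiguous",
                  n_mismatch = best, mismatch_pos = integer(0)))
    }
    list(oligo_id = index$oligos$oligo_id[cand[hits]], status = "mapped",
         n_mismatch = best, mismatch_pos = evals[[hits]]$pos,
         oligo_idx = cand[hits])
  }
  has_r2 <- !is.null(read2) && !is.na(read2)
  res <- try_orientation(if (has_r2) revcomp(read2) else NULL)
  if (has_r2 && (is.null(res) || res$status != "mapped")) {
    ## orientation auto-detect: retry with read 2 taken as the designed strand
    res2 <- try_orientation(read2)
    if (!is.null(res2) && res2$status == "mapped") res <- res2
  }
  if (is.null(res)) {
    res <- list(oligo_id = NA_character_, status = "unmapped",
                n_mismatch = NA_integer_, mismatch_pos = integer(0))
  }
  res
}

#' Deduplicate UMI assignments into molecule counts
#'
#' The count per oligo is the number of distinct (UMI, oligo) pairs; a UMI
#' reused across different oligos contributes once to each.
#'
#' @param assignments data.frame with `umi` and `oligo_id` columns (one row
#'   per mapped read).
#' @return data.frame with `oligo_id`, `raw` (reads) and `dedup` (distinct
#'   UMI families).
#' @export
dedup_umis <- function(assignments) {
  if (nrow(assignments) == 0) {
    return(data.frame(oligo_id = character(0), raw = integer(0),
                      dedup = integer(0)))
  }
  raw <- table(assignments$oligo_id)
  uu <- unique(assignments[, c("umi", "oligo_id")])
  dd <- table(uu$oligo_id)
  ids <- sort(unique(assignments$oligo_id))
  data.frame(oligo_id = ids,
             raw = as.integer(raw[ids]),
             dedup = as.integer(dd[ids]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Process one sequencing sample into counts, QC and a mismatch profile
#'
#' Runs [parse_read1()], [match_to_library()] and [dedup_umis()] over a table
#' of read pairs.
#'
#' @param reads data.frame with `read1` and (optionally) `read2` columns.
#' @param index Index from [build_library_index()].
#' @param rlayout A [read_layout()].
#' @param max_mismatch Maximum total mismatches per read pair.
#' @return List with `counts` (oligo_id, raw, dedup for every library oligo,
#'   zeros included), `qc` (totals, drops, unmapped/ambiguous tallies) and
#'   `matches` (per-read assignment detail used by [mismatch_profile()]).
#' @export
process_sample <- function(reads, index, rlayout = read_layout(),
                           max_mismatch = 1L) {
  parsed <- parse_read1(reads$read1, rlayout)
  n_short <- sum(!parsed$ok)
  keep <- which(parsed$ok)
  has_r2 <- "read2" %in% names(reads)
  status <- character(length(keep))
  oligo_id <- character(length(keep))
  mm_list <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    m <- match_to_library(parsed$frag[i],
                          if (has_r2) reads$read2[i] else NULL,
                          index, max_mismatch)
    status[j] <- m$status
    oligo_id[j] <- m$oligo_id %||% NA_character_
    mm_list[[j]] <- m$mismatch_pos
  }
  mapped <- status == "mapped"
  assignments <- data.frame(umi = parsed$umi[keep][mapped],
                            oligo_id = oligo_id[mapped],
                            stringsAsFactors = FALSE)
  cc <- dedup_umis(assignments)
  all_ids <- index$oligos$oligo_id
  counts <- data.frame(oligo_id = all_ids,
                       raw = ifelse(all_ids %in% cc$oligo_id,
                                    cc$raw[match(all_ids, cc$oligo_id)], 0L),
                       dedup = ifelse(all_ids %in% cc$oligo_id,
                                      cc$dedup[match(all_ids, cc$oligo_id)], 0L),
                       stringsAsFactors = FALSE)
  list(
    counts = counts,
    qc = list(n_reads = nrow(reads), n_short = n_short,
              n_mapped = sum(mapped), n_unmapped = sum(status == "unmapped"),
              n_ambiguous = sum(status == "ambiguous"),
              mapped_fraction = sum(mapped) / max(1, length(keep))),
    matches = list(mapped = mapped, mismatch_pos = mm_list[mapped],
                   has_read2 = has_r2)
  )
}

#' Per-position mismatch-rate profile
#'
#' For each position of the designed sequence covered by mapped reads, the
#' mismatch rate is `100 * mismatching / covering`. The terminal 15-nt primer
#' regions of the designed sequence are excluded; uncovered positions are
#' reported as `NA`, not 0.
#'
#' @param sample_result Result of [process_sample()].
#' @param index Index from [build_library_index()].
#' @return data.frame with `position` (1-based in the full designed sequence),
#'   `covering`, `mismatching`, `rate_percent`.
#' @export
mismatch_profile <- function(sample_result, index) {
  m <- sample_result$matches
  n_mapped <- sum(m$mapped)
  L <- index$L
  covering <- integer(L)
  covering[seq_len(index$frag_len)] <-
    covering[seq_len(index$frag_len)] + n_mapped
  if (m$has_read2) {
    covering[index$r2_start:L] <- covering[index$r2_start:L] + n_mapped
  }
  mismatching <- tabulate(unlist(m$mismatch_pos), nbins = L)
  keep <- seq.int(index$fwd_primer_len + 1L, L - index$rev_primer_len)
  data.frame(
    position = keep,
    covering = covering[keep],
    mismatching = mismatching[keep],
    rate_percent = ifelse(covering[keep] > 0,
                          100 * mismatching[keep] / covering[keep], NA_real_)
  )
}

#' Build the full count table from simulated or processed samples
#'
#' Convenience wrapper running [process_sample()] over every sample of a
#' [simulate_reads()] object (or any named list of read tables).
#'
#' @param sim A `sim_reads` object.
#' @param index Index from [build_library_index()].
#' @param ... Passed to [process_sample()].
#' @return Long count table (`oligo_id`, `variant_id`, `allele`,
#'   `library_type`, `replicate`, `raw`, `dedup`) with a `qc` attribute.
#' @export
count_sim_reads <- function(sim, index, ...) {
  out <- list()
  qc <- list()
  for (nm in names(sim$samples)) {
    s <- sim$samples[[nm]]
    res <- process_sample(s$reads, index, ...)
    cc <- res$counts
    cc$variant_id <- index$oligos$variant_id[match(cc$oligo_id,
                                                   index$oligos$oligo_id)]
    cc$allele <- index$oligos$allele[match(cc$oligo_id, index$oligos$oligo_id)]
    cc$library_type <- s$library_type
    cc$replicate <- s$replicate
    out[[nm]] <- cc[, c("oligo_id", "variant_id", "allele", "library_type",
                        "replicate", "raw", "dedup")]
    qc[[nm]] <- res$qc
  }
  counts <- do.call(rbind, out)
  rownames(counts) <- NULL
  attr(counts, "qc") <- qc
  counts
}

#' Per-variant allele frequency from counts
#'
#' AF = alt / (alt + ref) on deduplicated counts, per variant, library type
#' and replicate; undefined (NA) when both allele counts are 0.
#'
#' @param counts Long count table with `variant_id`, `allele`,
#'   `library_type`, `replicate`, `dedup`.
#' @return data.frame with `variant_id`, `library_type`, `replicate`, `af`.
#' @export
allele_frequency <- function(counts) {
  wide <- merge(
    counts[counts$allele == "ref",
           c("variant_id", "library_type", "replicate", "dedup")],
    counts[counts$allele == "alt",
           c("variant_id", "library_type", "replicate", "dedup")],
    by = c("variant_id", "library_type", "replicate"),
    suffixes = c("_ref", "_alt"))
  tot <- wide$dedup_ref + wide$dedup_alt
  wide$af <- ifelse(tot > 0, wide$dedup_alt / tot, NA_real_)
  wide[, c("variant_id", "library_type", "replicate", "af")]
}
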