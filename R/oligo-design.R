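## Oligo library design: variant selection and assembly of synthesis-ready
## 200-nt oligos.
##
## Variant tables are data.frames with columns:
##   variant_id, chrom, pos (1-based), ref, alt, adjAF, gene, strand,
##   sources (comma-separated tags), cosmic_cnt, driver_role.
## UTR annotation intervals follow BED convention (0-based half-open).

#' Read a BED file of 3' UTR intervals
#'
#' Expects at least chrom/start/end; optional name (gene), score, strand
#' columns. Malformed lines (non-integer coordinates, end <= start) raise an
#' error that reports the offending line number.
#'
#' @param path Path to a plain-text BED file.
#' @return data.frame with columns chrom, start, end, gene, score, strand.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(fields, length, integer(1))
  bad <- which(n < 3)
  if (length(bad)) stop("malformed BED line ", bad[1], ": fewer than 3 fields")
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad)) stop("malformed BED line ", bad[1], ": bad coordinates")
  data.frame(
    chrom = vapply(fields, `[`, "", 1),
    start = start,
    end = end,
    gene = ifelse(n >= 4, vapply(fields, function(f) f[4] %||% NA_character_, ""), NA),
    score = ifelse(n >= 5, vapply(fields, function(f) f[5] %||% NA_character_, ""), NA),
    strand = ifelse(n >= 6, vapply(fields, function(f) f[6] %||% NA_character_, ""), "+"),
    stringsAsFactors = FALSE
  )
}

## 0-based point-in-interval overlap via IRanges; returns the index of the
## first overlapping interval per point (NA if none), plus the count.
point_interval_overlap <- function(chrom, pos0, intervals) {
  hit <- rep(NA_integer_, length(pos0))
  nhit <- integer(length(pos0))
  for (ch in unique(chrom)) {
    vi <- which(chrom == ch)
    ii <- which(intervals$chrom == ch)
    if (!length(ii)) next
    q <- IRanges::IRanges(start = pos0[vi] + 1L, width = 1L)
    s <- IRanges::IRanges(start = intervals$start[ii] + 1L,
                          end = intervals$end[ii])
    ov <- IRanges::findOverlaps(q, s)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    if (length(qh)) {
      first <- tapply(sh, qh, min)
      hit[vi[as.integer(names(first))]] <- ii[as.integer(first)]
      cnt <- table(qh)
      nhit[vi[as.integer(names(cnt))]] <- as.integer(cnt)
    }
  }
  list(first = hit, n = nhit)
}

#' Restrict a variant table to 3' UTR variants
#'
#' Keeps variants whose 0-based position (`pos - 1`) falls inside at least one
#' UTR interval, and annotates gene and strand from the first overlapping
#' interval (alternative overlaps are counted in the `n_overlaps` column).
#'
#' @param variants Variant table (1-based `pos`).
#' @param utr_intervals BED-style data.frame (0-based half-open), e.g. from
#'   [read_bed()].
#' @return The retained variants with `gene`, `strand`, `n_overlaps` columns.
#' @export
extract_utr_variants <- function(variants, utr_intervals) {
  stopifnot(all(c("chrom", "pos") %in% names(variants)),
            all(c("chrom", "start", "end") %in% names(utr_intervals)))
  ov <- point_interval_overlap(variants$chrom, variants$pos - 1L, utr_intervals)
  keep <- !is.na(ov$first)
  out <- variants[keep, , drop = FALSE]
  idx <- ov$first[keep]
  out$gene <- ifelse(is.na(utr_intervals$gene[idx]),
                     out$gene %||% NA_character_, utr_intervals$gene[idx])
  out$strand <- ifelse(is.na(utr_intervals$strand[idx]), "+",
                       utr_intervals$strand[idx])
  out$n_overlaps <- ov$n[keep]
  rownames(out) <- NULL
  out
}

#' Filter variants for library inclusion
#'
#' Population mode keeps single-nucleotide variants with adjusted minor allele
#' frequency strictly below `max_af` (variants with missing adjAF are dropped
#' and counted). Somatic mode instead requires a COSMIC-style sample count
#' (`cosmic_cnt`) strictly greater than `min_cnt`, so every retained mutation
#' is supported by at least two samples.
#'
#' @param variants Variant table.
#' @param max_af Strict upper bound on adjAF (population mode).
#' @param mode `"population"` or `"somatic"`.
#' @param min_cnt Strict lower bound on cosmic_cnt (somatic mode).
#' @param require_snv Drop records whose ref or alt is not a single base.
#' @return Filtered variant table; attribute `n_dropped_missing_af` counts
#'   population variants dropped for missing adjAF.
#' @export
filter_rare_variants <- function(variants, max_af = 0.01,
                                 mode = c("population", "somatic"),
                                 min_cnt = 1L, require_snv = TRUE) {
  mode <- match.arg(mode)
  keep <- rep(TRUE, nrow(variants))
  if (require_snv) {
    keep <- keep & nchar(variants$ref) == 1 & nchar(variants$alt) == 1 &
      variants$ref %in% DNA_BASES & variants$alt %in% DNA_BASES
  }
  n_missing <- 0L
  if (mode == "population") {
    af <- variants$adjAF
    miss <- is.na(af)
    n_missing <- sum(miss & keep)
    if (n_missing > 0) {
      warning(n_missing, " population variant(s) dropped for missing adjAF")
    }
    keep <- keep & !miss & af < max_af
  } else {
    cnt <- variants$cosmic_cnt
    keep <- keep & !is.na(cnt) & cnt > min_cnt
  }
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_missing_af") <- n_missing
  out
}

#' Screen insert sequences for forbidden substrings
#'
#' An insert fails if it, or its reverse complement, contains any forbidden
#' substring (restriction sites, subpool primers). Both strands are checked
#' because a site on either strand is cut/primed.
#'
#' @param inserts Character vector of insert sequences (names used as ids).
#' @param forbidden Named character vector of forbidden substrings; see
#'   [forbidden_substrings()].
#' @return List with `pass` (character vector) and `fail` (data.frame with
#'   `insert`, `reason`).
#' @export
screen_sequences <- function(inserts, forbidden = forbidden_substrings()) {
  assert_that(length(forbidden) > 0, "forbidden substring set is empty")
  if (is.null(names(forbidden))) names(forbidden) <- forbidden
  rc <- revcomp(inserts)
  reason <- rep(NA_character_, length(inserts))
  for (i in seq_along(forbidden)) {
    hit <- grepl(forbidden[i], inserts, fixed = TRUE) |
      grepl(forbidden[i], rc, fixed = TRUE)
    reason[hit & is.na(reason)] <- names(forbidden)[i]
  }
  ids <- names(inserts) %||% as.character(seq_along(inserts))
  list(
    pass = inserts[is.na(reason)],
    fail = data.frame(insert_id = ids[!is.na(reason)],
                      insert = unname(inserts[!is.na(reason)]),
                      reason = reason[!is.na(reason)],
                      stringsAsFactors = FALSE)
  )
}

## Fetch genome sequence, 1-based inclusive. `genome` is either a named
## character vector / DNAStringSet of chromosome sequences, or a
## function(chrom, start, end).
genome_fetch <- function(genome, chrom, start, end) {
  if (is.function(genome)) return(genome(chrom, start, end))
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  s <- genome[[chrom]]
  if (is.null(s)) stop("chromosome ", chrom, " not in genome")
  if (start < 1 || end > nchar(s)) {
    stop("variant context [", start, ",", end, "] extends beyond available ",
         "sequence for ", chrom,
         "; extend beyond annotated 3' UTR required (supply longer context)")
  }
  substr(s, start, end)
}

#' Assemble the reference and alternative oligo for one variant
#'
#' The insert is the variant-centered window of `layout$insert_len` nt taken
#' from the transcribed strand (minus-strand variants are reverse-complemented
#' and the complementary alleles substituted). The full synthesis sequence is
#' forward primer + EcoRI + insert (+ BamHI for design1) + reverse primer.
#'
#' @param variant One-row variant table (1-based `pos`, `ref`/`alt` on the
#'   plus strand, `strand` either `"+"` or `"-"`).
#' @param genome Named character vector / `DNAStringSet` of chromosome
#'   sequences, or a `function(chrom, start, end)` accessor (1-based
#'   inclusive).
#' @param layout An [oligo_layout()].
#' @param primers List with `fwd`/`rev` primer sequences.
#' @param subpool_id Subpool label recorded on the output.
#' @return Two-row data.frame (`allele` = ref, alt) with `oligo_id`,
#'   `variant_id`, `subpool_id`, `full_sequence`, `insert_sequence`,
#'   `variant_offset` and the genomic annotation columns.
#' @export
assemble_oligo <- function(variant, genome, layout = oligo_layout("design2"),
                           primers = default_subpool_primers(layout$name),
                           subpool_id = "SP1") {
  stopifnot(nrow(variant) == 1)
  minus <- identical(variant$strand, "-")
  off <- layout$variant_offset
  ## offset of the variant within the plus-strand genomic window so that it
  ## lands at `off` on the transcribed strand
  off_plus <- if (minus) layout$insert_len - 1L - off else off
  start <- variant$pos - off_plus
  end <- start + layout$insert_len - 1L
  win <- genome_fetch(genome, variant$chrom, start, end)
  if (toupper(substr(win, off_plus + 1L, off_plus + 1L)) != variant$ref) {
    stop("reference base mismatch for ", variant$variant_id, " at ",
         variant$chrom, ":", variant$pos)
  }
  make_insert <- function(base_plus) {
    s <- win
    substr(s, off_plus + 1L, off_plus + 1L) <- base_plus
    if (minus) revcomp(s) else s
  }
  inserts <- c(ref = make_insert(variant$ref), alt = make_insert(variant$alt))
  full <- vapply(inserts, function(ins) {
    mid <- paste0(layout$site_seqs[["EcoRI"]], ins)
    if ("BamHI" %in% names(layout$sites)) {
      mid <- paste0(mid, layout$site_seqs[["BamHI"]])
    }
    paste0(primers$fwd, mid, primers$rev)
  }, character(1))
  data.frame(
    oligo_id = paste0(variant$variant_id, "_", c("ref", "alt")),
    variant_id = variant$variant_id,
    allele = c("ref", "alt"),
    subpool_id = subpool_id,
    full_sequence = unname(full),
    insert_sequence = unname(inserts),
    variant_offset = off,
    layout = layout$name,
    gene = variant$gene %||% NA_character_,
    strand = variant$strand %||% "+",
    stringsAsFactors = FALSE
  )
}

#' Assemble oligos for a whole variant table
#'
#' @inheritParams assemble_oligo
#' @param variants Variant table.
#' @return Oligo table (two rows per variant). Variants whose context cannot
#'   be fetched raise an error.
#' @export
assemble_oligos <- function(variants, genome,
                            layout = oligo_layout("design2"),
                            primers = default_subpool_primers(layout$name),
                            subpool_id = "SP1") {
  out <- lapply(seq_len(nrow(variants)), function(i) {
    assemble_oligo(variants[i, , drop = FALSE], genome, layout, primers,
                   subpool_id)
  })
  do.call(rbind, out)
}

#' Saturation-mutagenesis panel for a known motif
#'
#' Produces one reference oligo insert plus, for every position of the motif
#' and its flanks, the three possible single-base substitutions:
#' `1 + 3 * (motif_len + flank_up + flank_down)` sequences in total.
#'
#' @param motif_id Identifier for the motif.
#' @param motif_sequence Motif sequence (A/C/G/T; U accepted and mapped to T).
#' @param context Sequence containing the motif with at least `flank_up` /
#'   `flank_down` nt of context on each side.
#' @param motif_start 1-based start of the motif within `context`.
#' @param flank_up,flank_down Flank widths in nt (22-23 in the screen design).
#' @return data.frame with `oligo_id`, `motif_id`, `position` (1-based within
#'   the panel region), `alt`, `insert_sequence`, `is_reference`.
#' @export
design_saturation_panel <- function(motif_id, motif_sequence, context,
                                    motif_start, flank_up = 22L,
                                    flank_down = 22L) {
  motif_sequence <- chartr("U", "T", toupper(motif_sequence))
  context <- toupper(context)
  assert_that(!grepl("[^ACGT]", context), "ambiguous base in context")
  assert_that(flank_up >= 0 && flank_down >= 0, "negative flank")
  mlen <- nchar(motif_sequence)
  region_start <- motif_start - flank_up
  region_end <- motif_start + mlen - 1L + flank_down
  assert_that(region_start >= 1 && region_end <= nchar(context),
              "context does not cover motif plus flanks")
  assert_that(substr(context, motif_start, motif_start + mlen - 1L) ==
                motif_sequence, "motif_sequence not found at motif_start")
  region <- substr(context, region_start, region_end)
  rlen <- nchar(region)
  rows <- list(data.frame(
    oligo_id = paste0(motif_id, "_ref"), motif_id = motif_id,
    position = NA_integer_, alt = NA_character_,
    insert_sequence = region, is_reference = TRUE,
    stringsAsFactors = FALSE))
  chars <- seq_chars(region)[[1]]
  for (p in seq_len(rlen)) {
    for (b in setdiff(DNA_BASES, chars[p])) {
      s <- region
      substr(s, p, p) <- b
      rows[[length(rows) + 1L]] <- data.frame(
        oligo_id = paste0(motif_id, "_p", p, b), motif_id = motif_id,
        position = p, alt = b, insert_sequence = s, is_reference = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write oligos to FASTA
#'
#' Headers follow `oligo_id|variant_id|allele|subpool`.
#'
#' @param oligos Oligo table from [assemble_oligos()].
#' @param path Output FASTA path.
#' @export
write_oligo_fasta <- function(oligos, path) {
  seqs <- Biostrings::DNAStringSet(oligos$full_sequence)
  names(seqs) <- paste(oligos$oligo_id, oligos$variant_id, oligos$allele,
                       oligos$subpool_id, sep = "|")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
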