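## Plain-text table IO helpers shared by the command-line wrappers.

#' Write a data.frame as TSV
#'
#' @param x data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV with a header
#'
#' @param path Input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             comment.char = "")
}

#' Read a variant table (VCF-like TSV)
#'
#' Expects at least chrom, pos, ref, alt; optional adjAF, gene, strand,
#' sources, cosmic_cnt, driver_role, variant_id. Missing optional columns are
#' added as NA; missing variant ids are synthesized as chrom_pos_ref_alt.
#'
#' @param path Input path.
#' @return Variant table.
#' @export
read_variants_tsv <- function(path) {
  v <- read_tsv(path)
  need <- c("chrom", "pos", "ref", "alt")
  assert_that(all(need %in% names(v)),
              paste("variant table must have columns:",
                    paste(need, collapse = ", ")))
  for (col in c("adjAF", "gene", "strand", "sources", "cosmic_cnt",
                "driver_role")) {
    if (!col %in% names(v)) v[[col]] <- NA
  }
  if (!"variant_id" %in% names(v)) {
    v$variant_id <- paste(v$chrom, v$pos, v$ref, v$alt, sep = "_")
  }
  v$strand[is.na(v$strand)] <- "+"
  v
}
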