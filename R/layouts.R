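## Oligo and read layouts.
##
## All synthesis layouts are 200 nt total:
##   design1: fwd subpool primer (15) + EcoRI (6) + insert (158) + BamHI (6) + rev primer (15)
##   design2: fwd subpool primer (15) + EcoRI (6) + insert (164) + rev primer (15)
##   motif:   fwd primer (21) + EcoRI (6) + insert (158) + rev primer (15)
## The tested variant sits at 0-based insert offset floor((insert_len - 1) / 2),
## i.e. 78 for a 158-nt insert and 81 for a 164-nt insert (81 nt upstream,
## 82 nt downstream; parity choice for even-length inserts is configurable).

RESTRICTION_SITES <- c(EcoRI = "GAATTC", BamHI = "GGATCC")

#' Oligo synthesis layout
#'
#' Returns the segment structure of a 200-nt synthesis oligo. `"design1"`
#' carries a 158-nt tested insert between EcoRI and BamHI sites; `"design2"`
#' carries a 164-nt insert and a single EcoRI site; `"motif"` is the
#' saturation-mutagenesis layout (21-nt forward primer, 158-nt insert).
#'
#' @param name One of `"design1"`, `"design2"`, `"motif"`.
#' @param variant_offset 0-based offset of the variant base within the insert;
#'   default centers the variant, placing the extra base of an even-length
#'   insert downstream.
#' @return A list with fields `name`, `fwd_primer_len`, `rev_primer_len`,
#'   `sites` (named vector of restriction-site lengths), `site_seqs`,
#'   `insert_len`, `total_len`, `variant_offset`.
#' @examples
#' oligo_layout("design2")$insert_len  # 164
#' @export
oligo_layout <- function(name = c("design2", "design1", "motif"),
                         variant_offset = NULL) {
  name <- match.arg(name)
  lay <- switch(name,
    design1 = list(name = "design1", fwd_primer_len = 15L, rev_primer_len = 15L,
                   sites = c(EcoRI = 6L, BamHI = 6L), insert_len = 158L),
    design2 = list(name = "design2", fwd_primer_len = 15L, rev_primer_len = 15L,
                   sites = c(EcoRI = 6L), insert_len = 164L),
    motif   = list(name = "motif", fwd_primer_len = 21L, rev_primer_len = 15L,
                   sites = c(EcoRI = 6L), insert_len = 158L))
  lay$site_seqs <- RESTRICTION_SITES[names(lay$sites)]
  lay$total_len <- lay$fwd_primer_len + lay$rev_primer_len +
    sum(lay$sites) + lay$insert_len
  stopifnot(lay$total_len == 200L)
  lay$variant_offset <- if (is.null(variant_offset)) {
    as.integer(floor((lay$insert_len - 1) / 2))
  } else {
    as.integer(variant_offset)
  }
  assert_that(lay$variant_offset >= 0 && lay$variant_offset < lay$insert_len,
              "variant_offset outside insert")
  class(lay) <- "oligo_layout"
  lay
}

#' Default subpool amplification primers
#'
#' Fixed 15-mer forward/reverse primer pairs (and a 21-mer forward primer for
#' the motif layout) used when the caller does not supply their own. All are
#' free of EcoRI/BamHI sites on both strands.
#'
#' @param layout_name Layout the primers are for.
#' @return List with `fwd` and `rev` primer strings.
#' @export
default_subpool_primers <- function(layout_name = "design2") {
  if (identical(layout_name, "motif")) {
    list(fwd = "ACGCTGAAGTCTGCAACGTTG", rev = "CATGGCTAGTTCACG")
  } else {
    list(fwd = "ACGCTGAAGTCTGCA", rev = "CATGGCTAGTTCACG")
  }
}

#' Default forbidden substrings for insert screening
#'
#' Restriction-enzyme recognition sites plus the subpool primer sequences;
#' inserts containing any of these (on either strand) are incompatible with
#' the cloning strategy.
#'
#' @param primers Optional list/vector of additional primer sequences.
#' @return Named character vector of forbidden substrings.
#' @export
forbidden_substrings <- function(primers = default_subpool_primers()) {
  c(RESTRICTION_SITES, unlist(primers))
}

#' Structured read-1 layout
#'
#' Read 1 of the sequencing libraries is UMI (15 nt) + RT primer (14 nt) +
#' REC2 restriction site (6 nt) + subpool primer (15 nt) + the first 100 nt of
#' the designed sequence. Read 2 is the reverse complement of the designed
#' strand.
#'
#' @param umi_len,rt_primer_len,rec2_len,subpool_len,design_frag_len Segment
#'   lengths in nt.
#' @return A list of segment lengths with class `read_layout`.
#' @export
read_layout <- function(umi_len = 15L, rt_primer_len = 14L, rec2_len = 6L,
                        subpool_len = 15L, design_frag_len = 100L) {
  lay <- list(umi_len = as.integer(umi_len),
              rt_primer_len = as.integer(rt_primer_len),
              rec2_len = as.integer(rec2_len),
              subpool_len = as.integer(subpool_len),
              design_frag_len = as.integer(design_frag_len))
  assert_that(all(unlist(lay) > 0), "read layout lengths must be positive")
  lay$total <- sum(unlist(lay[1:5]))
  class(lay) <- "read_layout"
  lay
}

## Fixed non-design segments emitted by the simulator (RT primer and REC2).
RT_PRIMER_SEQ <- "GTGACTGGAGTTCA"
REC2_SEQ <- "GGATCC"
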