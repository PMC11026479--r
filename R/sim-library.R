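## Synthetic reference library: UTR contexts, variant table and ground truth.

#' Simulate UTR sequences and a variant table
#'
#' Generates one random UTR context per variant (free of restriction-site and
#' primer substrings across the design window, both strands) and places a
#' single SNV at its center with distinct ref/alt alleles. Population
#' annotations (adjAF < 0.01, sources, driver roles) are drawn so that
#' downstream filtering and clinical layers have realistic inputs.
#'
#' @param config A [sim_config()].
#' @return List with `utrs` (named character vector of UTR sequences, one per
#'   simulated gene) and `variants` (variant table; `pos` is 1-based within
#'   the UTR sequence).
#' @export
simulate_reference_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, 1L))
  lay <- oligo_layout(config$flank_design)
  forb <- forbidden_substrings(default_subpool_primers(lay$name))
  n <- config$n_variants
  pos <- as.integer(floor(config$utr_length / 2))
  win_start <- pos - lay$variant_offset
  win_end <- win_start + lay$insert_len - 1L

  utrs <- character(n)
  ref <- character(n)
  alt <- character(n)
  for (i in seq_len(n)) {
    repeat {
      s <- random_dna(1, config$utr_length)
      r <- substr(s, pos, pos)
      a <- sample(setdiff(DNA_BASES, r), 1)
      s_alt <- s
      substr(s_alt, pos, pos) <- a
      wins <- c(substr(s, win_start, win_end), substr(s_alt, win_start, win_end))
      if (length(screen_sequences(wins, forb)$pass) == 2L) {
        utrs[i] <- s; ref[i] <- r; alt[i] <- a
        break
      }
    }
  }
  genes <- sprintf("GENE%04d", seq_len(n))
  names(utrs) <- genes
  src <- sample(c("gnomad", "cosmic"), n, replace = TRUE, prob = c(0.7, 0.3))
  variants <- data.frame(
    variant_id = sprintf("var%04d", seq_len(n)),
    chrom = genes,
    pos = pos,
    ref = ref,
    alt = alt,
    adjAF = ifelse(src == "gnomad", runif(n, 1e-6, 0.0099), NA_real_),
    gene = genes,
    strand = "+",
    sources = src,
    cosmic_cnt = ifelse(src == "cosmic", 1L + rpois(n, 3), NA_integer_),
    driver_role = sample(c("oncogene", "tsg", "ambiguous", "none"), n,
                         replace = TRUE, prob = c(0.2, 0.2, 0.1, 0.5)),
    stringsAsFactors = FALSE
  )
  list(utrs = utrs, variants = variants)
}

#' Simulate the ground-truth effect table
#'
#' A configured fraction of variants is functional with |true lnFC| drawn
#' uniformly from `[effect_min, effect_max]` and random sign; the rest have
#' lnFC exactly 0. Baseline abundance is log-normal around 1.
#'
#' @param variants Variant table from [simulate_reference_library()].
#' @param config A [sim_config()].
#' @return data.frame with `variant_id`, `true_lnFC`, `is_functional`,
#'   `baseline_abundance`.
#' @export
simulate_truth <- function(variants, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, 2L))
  n <- nrow(variants)
  is_fun <- runif(n) < config$frac_functional
  mag <- runif(n, config$effect_min, config$effect_max)
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  data.frame(
    variant_id = variants$variant_id,
    true_lnFC = ifelse(is_fun, sgn * mag, 0),
    is_functional = is_fun,
    baseline_abundance = rlnorm(n, 0, config$baseline_sd),
    stringsAsFactors = FALSE
  )
}
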