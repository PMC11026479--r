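#' Simulation configuration
#'
#' One object holds every tunable of the synthetic-data generator. The seed
#' fully determines all generator output (each generator stage derives its own
#' stream from `seed` plus a fixed stage offset, so stages are independently
#' reproducible).
#'
#' The count-noise model is gamma-Poisson (negative binomial) per UMI-family
#' count with a single `dispersion` parameter; the screen itself states no
#' generative noise model, so this choice is a configurable stand-in matching
#' standard MPRA noise assumptions.
#'
#' @param seed Integer seed; determines all output.
#' @param n_variants Number of simulated variants.
#' @param utr_length Length of each simulated UTR context (nt); must allow a
#'   full insert flank around the variant.
#' @param flank_design Oligo layout name (`"design2"` default, 164-nt insert).
#' @param n_replicates Biological replicates per library type (>= 1).
#' @param dna_depth,rna_depth Mean UMI families per oligo.
#' @param pcr_duplication_rate Mean reads per UMI family (>= 1).
#' @param error_rate Per-base substitution probability in emitted reads.
#' @param frac_functional Fraction of variants with a true effect.
#' @param effect_min,effect_max Range of |true lnFC| for functional variants
#'   (magnitude drawn uniformly, sign random); null variants have lnFC 0.
#' @param dispersion Negative-binomial dispersion of UMI-family counts
#'   (variance = mu + dispersion * mu^2). UMI deduplication removes PCR
#'   amplification noise, so family counts sit close to Poisson; the default
#'   adds slight overdispersion.
#' @param baseline_sd SD of log baseline abundance across variants.
#' @return A validated list with class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_variants = 200L, utr_length = 400L,
                       flank_design = "design2", n_replicates = 3L,
                       dna_depth = 300, rna_depth = 300,
                       pcr_duplication_rate = 1.5, error_rate = 0.001,
                       frac_functional = 0.3, effect_min = 0.25,
                       effect_max = 1.0, dispersion = 0.002,
                       baseline_sd = 0.3) {
  cfg <- list(seed = as.integer(seed), n_variants = as.integer(n_variants),
              utr_length = as.integer(utr_length),
              flank_design = flank_design,
              n_replicates = as.integer(n_replicates),
              dna_depth = dna_depth, rna_depth = rna_depth,
              pcr_duplication_rate = pcr_duplication_rate,
              error_rate = error_rate, frac_functional = frac_functional,
              effect_min = effect_min, effect_max = effect_max,
              dispersion = dispersion, baseline_sd = baseline_sd)
  assert_that(cfg$n_variants >= 1, "n_variants must be >= 1")
  assert_that(cfg$n_replicates >= 1, "n_replicates must be >= 1")
  assert_that(cfg$dna_depth > 0 && cfg$rna_depth > 0, "depths must be positive")
  assert_that(cfg$pcr_duplication_rate >= 1, "pcr_duplication_rate must be >= 1")
  assert_that(cfg$error_rate >= 0 && cfg$error_rate <= 1,
              "error_rate must be in [0, 1]")
  assert_that(cfg$frac_functional >= 0 && cfg$frac_functional <= 1,
              "frac_functional must be in [0, 1]")
  assert_that(cfg$effect_min >= 0 && cfg$effect_max >= cfg$effect_min,
              "effect range invalid")
  assert_that(cfg$dispersion >= 0, "dispersion must be >= 0")
  lay <- oligo_layout(cfg$flank_design)
  if (cfg$utr_length < lay$insert_len + 2L) {
    stop("utr_length ", cfg$utr_length, " too short for a full ",
         lay$insert_len, "-nt insert flank")
  }
  class(cfg) <- "sim_config"
  cfg
}

## Derived, stage-specific seeds keep generator stages independently
## reproducible (all < 2^31 for any int seed).
stage_seed <- function(cfg, stage) {
  (cfg$seed %% 1000000L) * 1000L + stage
}
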