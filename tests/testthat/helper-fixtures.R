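## Shared fixtures and independent brute-force oracles. Everything is built
## in code at test time; no stored data.

## Small end-to-end simulated screen (library + oligos + index).
tiny_screen <- function(seed = 11, n_variants = 30, dna_depth = 60,
                        rna_depth = 60, error_rate = 0,
                        pcr_duplication_rate = 1, utr_length = 300, ...) {
  cfg <- sim_config(seed = seed, n_variants = n_variants,
                    dna_depth = dna_depth, rna_depth = rna_depth,
                    error_rate = error_rate,
                    pcr_duplication_rate = pcr_duplication_rate,
                    utr_length = utr_length, ...)
  lib <- simulate_reference_library(cfg)
  truth <- simulate_truth(lib$variants, cfg)
  oligos <- assemble_oligos(lib$variants, lib$utrs)
  list(cfg = cfg, lib = lib, truth = truth, oligos = oligos,
       index = build_library_index(oligos))
}

## Two-allele toy library on the design1 layout (SNP falls inside the 100-nt
## read-1 fragment there).
toy_two_allele_library <- function(seed = 5) {
  set.seed(seed)
  utr <- setNames(random_dna(1, 300), "chrT")
  pos <- 150L
  ref <- substr(utr, pos, pos)
  variant <- data.frame(variant_id = "v1", chrom = "chrT", pos = pos,
                        ref = ref, alt = setdiff(c("A", "C", "G", "T"), ref)[1],
                        gene = "G1", strand = "+", stringsAsFactors = FALSE)
  oligos <- assemble_oligo(variant, utr, oligo_layout("design1"))
  list(utr = utr, variant = variant, oligos = oligos,
       index = build_library_index(oligos))
}

## Oracle: rank-mean quantile normalization (independent implementation);
## tied input values receive the mean of the target values at their ranks.
bf_quantile_normalize <- function(m) {
  target <- rowMeans(apply(m, 2, sort))
  apply(m, 2, function(col) {
    v <- numeric(length(col))
    v[order(col)] <- target
    stats::ave(v, col, FUN = mean)
  })
}

## Oracle: motif strength as a naive per-base product loop.
bf_motif_strength <- function(seq, pwm, start) {
  n <- ncol(pwm)
  s <- 1
  for (i in seq_len(n)) {
    b <- substr(seq, start + i - 1L, start + i - 1L)
    s <- s * pwm[b, i]
  }
  s / 0.25^n
}

## Oracle: brute-force point-in-interval join (0-based half-open intervals,
## 1-based points).
bf_interval_join <- function(chrom, pos, ichrom, istart, iend) {
  hits <- list()
  for (v in seq_along(pos)) {
    for (i in seq_along(istart)) {
      if (chrom[v] == ichrom[i] && (pos[v] - 1) >= istart[i] &&
          (pos[v] - 1) < iend[i]) {
        hits[[length(hits) + 1L]] <- c(v, i)
      }
    }
  }
  if (!length(hits)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, hits)
}

## Oracle: nearest-peak distance by exhaustive scan.
bf_nearest_distance <- function(p0, starts, ends) {
  best <- Inf
  for (i in seq_along(starts)) {
    d <- if (starts[i] <= p0 && p0 < ends[i]) 0 else
      min(abs(p0 - starts[i]), abs(p0 - (ends[i] - 1)))
    best <- min(best, d)
  }
  best
}

## Oracle: two-sided Fisher p by hypergeometric enumeration.
bf_fisher_two_sided <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## Oracle: textbook two-group log-rank statistic.
bf_logrank <- function(time, event, group) {
  times <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in times) {
    at1 <- sum(time >= t & group == 1)
    at0 <- sum(time >= t & group == 0)
    d1 <- sum(time == t & event == 1 & group == 1)
    d0 <- sum(time == t & event == 1 & group == 0)
    d <- d1 + d0; n <- at1 + at0
    if (n < 2) next
    O1 <- O1 + d1
    E1 <- E1 + d * at1 / n
    V <- V + d * (at1 / n) * (at0 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}
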