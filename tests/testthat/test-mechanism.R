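consensus_pwm <- function(seq) {
  seq <- chartr("U", "T", toupper(seq))
  n <- nchar(seq)
  p <- matrix(0, 4, n, dimnames = list(c("A", "C", "G", "T"), NULL))
  ch <- strsplit(seq, "")[[1]]
  p[cbind(match(ch, rownames(p)), seq_len(n))] <- 1
  p
}

random_pwm <- function(n) {
  p <- matrix(rgamma(4 * n, 1), 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  sweep(p, 2, colSums(p), "/")
}

test_that("motif strength follows the closed-form product score", {
  ## consensus PWM scored on its own consensus: S = 1 / 0.25^3 = 64
  pwm <- consensus_pwm("ACG")
  ms <- motif_strength("ACG", "ACG", pwm, offset = 1)
  expect_equal(ms$S_ref, 64)
  expect_equal(ms$delta, 0)
  ## uniform PWM scores every sequence at exactly 1
  up <- matrix(0.25, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  ms <- motif_strength("ACGT", "TTTT", up, offset = 1)
  expect_equal(ms$S_ref, 1)
  expect_equal(ms$S_var, 1)
  expect_equal(ms$delta, 0)
  ## a variant outside the motif window leaves delta at 0
  pwm6 <- random_pwm(6)
  s_ref <- "ACGTACGTACGTACGT"
  s_var <- s_ref
  substr(s_var, 15, 15) <- "A"   # outside window [3, 8]
  expect_equal(motif_strength(s_ref, s_var, pwm6, offset = 3)$delta, 0)
  ## zero-probability base gives S = 0 (allowed)
  expect_equal(motif_strength("TTT", "TTT", consensus_pwm("ACG"), 1)$S_ref, 0)
})

test_that("motif strength matches the naive product oracle on random pairs", {
  set.seed(71)
  max_rel <- 0
  for (i in 1:300) {
    n <- sample(4:8, 1)
    pwm <- random_pwm(n)
    L <- n + sample(0:10, 1)
    seq <- random_dna(1, L)
    start <- sample(seq_len(L - n + 1), 1)
    got <- motif_strength(seq, seq, pwm, start)$S_ref
    want <- bf_motif_strength(seq, pwm, start)
    max_rel <- max(max_rel, abs(got - want) / max(want, .Machine$double.eps))
  }
  expect_lt(max_rel, 1e-12)
})

test_that("PWM validation and shuffling preserve the required structure", {
  bad <- matrix(c(0.5, 0.5, 0.1, 0.1), 4, 2)
  rownames(bad) <- c("A", "C", "G", "T")
  expect_error(validate_pwm(bad), "sum to 1")
  set.seed(5)
  pwm <- random_pwm(6)
  sh <- shuffle_pwm(pwm)
  expect_equal(sort(colSums(sh)), sort(colSums(pwm)))
  ## column shuffle permutes position profiles intact
  expect_true(all(apply(sh, 2, function(cl)
    any(apply(pwm, 2, function(c2) all(abs(cl - c2) < 1e-12))))))
  ## a column-asymmetric PWM scores differently after shuffling for some
  ## sequence (contract: shuffle changes S unless permutation-invariant)
  set.seed(6)
  seqs <- random_dna(50, 6)
  s1 <- vapply(seqs, function(s) motif_strength(s, s, pwm, 1)$S_ref, 0)
  s2 <- vapply(seqs, function(s) motif_strength(s, s, sh, 1)$S_ref, 0)
  expect_gt(max(abs(s1 - s2)), 0)
})

test_that("sequence groups assign the higher-expressed allele window to 'up'", {
  s <- tiny_screen(seed = 63, n_variants = 20, dna_depth = 200,
                   rna_depth = 200, frac_functional = 0.8, effect_min = 0.5,
                   effect_max = 1)
  counts <- simulate_counts(s$oligos, s$truth, s$cfg)
  calls <- mpra_call(counts)
  groups <- build_sequence_groups(calls, s$oligos)
  expect_gt(nrow(groups), 0)
  up <- groups[groups$group == "up", ]
  down <- groups[groups$group == "down", ]
  ## one entry per functional variant in each group
  expect_setequal(up$variant_id, down$variant_id)
  expect_equal(nrow(up), nrow(down))
  for (i in seq_len(nrow(up))) {
    lnfc <- calls$lnFC[calls$variant_id == up$variant_id[i]]
    expect_equal(up$allele[i], if (lnfc > 0) "alt" else "ref")
  }
  ## windows are 11 nt and centered on the variant base
  expect_true(all(nchar(up$window) == 11))
  expect_false(any(up$trimmed))
})

test_that("hexamer enrichment finds a planted motif and respects counts", {
  set.seed(73)
  n <- 100
  fore <- random_dna(n, 11)
  back <- random_dna(n, 11)
  planted <- "ATTTAT"   # DNA alphabet; U equivalent on input
  sel <- 1:(n / 2)
  for (i in sel) {
    p <- sample(1:6, 1)
    substr(fore[i], p, p + 5) <- planted
  }
  back <- gsub(planted, "ACGCGT", back, fixed = TRUE)
  res <- hexamer_enrichment(fore, back)
  expect_equal(res$hexamer[1], planted)
  expect_lt(res$p[1], 1e-6)
  ## containment counts never exceed group sizes
  expect_true(all(res$n_fore <= n & res$n_back <= n))
  ## U input is folded onto T
  res_u <- hexamer_enrichment(chartr("T", "U", fore), back)
  expect_equal(res_u$hexamer[1], planted)
  ## identical groups yield no discoveries
  null_res <- hexamer_enrichment(back, back)
  expect_false(any(null_res$fdr < 0.05))
})

test_that("shuffled-PWM and control-sample nulls are well behaved", {
  set.seed(77)
  pwm <- random_pwm(6)
  pairs <- function(m) {
    sr <- random_dna(m, 11)
    sv <- sr
    for (i in seq_len(m)) {
      p <- sample(3:9, 1)
      old <- substr(sv[i], p, p)
      substr(sv[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    }
    data.frame(seq_ref = sr, seq_var = sv, offset = 3, stringsAsFactors = FALSE)
  }
  fp <- pairs(40); np <- pairs(200)
  res <- motif_strength_null(fp, np, pwm, seed = 1)
  expect_length(res$delta_functional, 40)
  expect_length(res$delta_nonfunc, 40)   # count-matched
  expect_true(res$ks_shuffled$p >= 0 && res$ks_shuffled$p <= 1)
  ## identical samples: D = 0, p = 1
  d <- res$delta_functional
  ks <- suppressWarnings(ks.test(d, d))
  expect_equal(unname(ks$statistic), 0)
  expect_equal(ks$p.value, 1)
  ## functional set drawn from the same generator as controls: the
  ## nonfunctional-control KS test should rarely reject
  ps <- vapply(1:30, function(sd) {
    set.seed(sd + 100)
    motif_strength_null(pairs(30), pairs(120), pwm, seed = sd)$ks_nonfunc$p
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.2)
  expect_error(motif_strength_null(fp[1:5, ], np, pwm), ">= 10")
})

test_that("miRNA site overlap respects the percentile filter and boundaries", {
  sites <- data.frame(chrom = "c1", start = c(100L, 300L), end = c(120L, 320L),
                      site_id = c("s_low", "s_hi"),
                      percentile = c(49, 50))
  v <- data.frame(variant_id = c("in_hi", "edge_out", "in_low"),
                  chrom = "c1", pos = c(301L, 321L, 101L))
  pairs <- overlap_mirna_sites(v, sites)
  ## percentile 49 site excluded entirely; percentile 50 retained
  expect_equal(pairs$variant_id, "in_hi")
  expect_equal(pairs$site_id, "s_hi")
  ## a variant 1 nt outside the interval is no pair: pos 321 -> 0-based 320
  expect_false("edge_out" %in% pairs$variant_id)
  ## missing percentile dropped with warning
  sites$percentile[1] <- NA
  expect_warning(overlap_mirna_sites(v, sites), "missing percentile")
})

test_that("miRNA site overlap equals a brute-force join", {
  set.seed(83)
  sites <- data.frame(chrom = sample(c("c1", "c2"), 15, TRUE),
                      start = sample(0:400, 15))
  sites$end <- sites$start + sample(5:40, 15, TRUE)
  sites$site_id <- sprintf("s%02d", 1:15)
  sites$percentile <- sample(40:100, 15, TRUE)
  v <- data.frame(variant_id = sprintf("v%02d", 1:50),
                  chrom = sample(c("c1", "c2"), 50, TRUE),
                  pos = sample(1:450, 50))
  pairs <- overlap_mirna_sites(v, sites)
  keep <- sites[sites$percentile >= 50, ]
  bf <- bf_interval_join(v$chrom, v$pos, keep$chrom, keep$start, keep$end)
  got <- sort(paste(pairs$variant_id, pairs$site_id))
  want <- sort(paste(v$variant_id[bf[, 1]], keep$site_id[bf[, 2]]))
  expect_equal(got, want)
})

test_that("direction bias test detects upward shifts and flips with sign", {
  set.seed(89)
  bg <- rnorm(150, 0, 0.4)
  ov <- rnorm(80, 0.3, 0.4)
  up <- direction_bias_test(ov, bg)
  expect_lt(up$p, 0.01)
  ## negating all values moves significance to the opposite tail
  dn <- direction_bias_test(-ov, -bg)
  expect_gt(dn$p, 0.5)
  dn2 <- direction_bias_test(-ov, -bg, alternative = "less")
  expect_equal(dn2$p, up$p)
  ## identical distributions are unremarkable
  same <- direction_bias_test(bg, bg)
  expect_gt(same$p, 0.4)
  ## one-sample mode against zero
  one <- direction_bias_test(ov, NULL)
  expect_lt(one$p, 0.01)
})

test_that("RBP delta comparison reports the max of the two control tests", {
  set.seed(97)
  mk <- function(rbp, n, scale) {
    rbind(data.frame(rbp = rbp, class = "functional",
                     delta = rnorm(n, 0, scale)),
          data.frame(rbp = rbp, class = "nonfunctional", delta = rnorm(n)),
          data.frame(rbp = rbp, class = "random", delta = rnorm(n)))
  }
  deltas <- rbind(mk("INFLATED", 200, 3), mk("NULLRBP", 200, 1),
                  mk("TINY", 5, 1))
  res <- rbp_delta_compare(deltas)
  inf <- res[res$rbp == "INFLATED", ]
  expect_lt(inf$p, 1e-4)
  expect_gte(inf$p, inf$p_nonfunc)
  expect_gte(inf$p, inf$p_random)
  expect_true(res$skipped[res$rbp == "TINY"])
  expect_false(res$skipped[res$rbp == "NULLRBP"])
})

test_that("eCLIP distances follow the coordinate convention and an oracle", {
  peaks <- data.frame(chrom = "c1", start = c(100L, 500L), end = c(120L, 520L))
  v <- data.frame(variant_id = c("inside", "right_of_peak", "no_chrom"),
                  chrom = c("c1", "c1", "cX"), pos = c(110L, 150L, 10L))
  res <- eclip_distance_test(v, peaks, functional = c(TRUE, FALSE, FALSE))
  d <- res$distances
  expect_equal(d$distance[d$variant_id == "inside"], 0)
  ## pos 150 (1-based) -> 0-based 149; nearest covered base of [100,120) is
  ## 119 -> distance 30
  expect_equal(d$distance[d$variant_id == "right_of_peak"], 30)
  expect_true(is.na(d$distance[d$variant_id == "no_chrom"]))
  ## random positions match the exhaustive scan
  set.seed(101)
  peaks2 <- data.frame(chrom = "c1", start = sample(0:900, 10))
  peaks2$end <- peaks2$start + sample(5:50, 10, TRUE)
  pos <- sample(1:1000, 60)
  v2 <- data.frame(variant_id = sprintf("v%02d", 1:60), chrom = "c1",
                   pos = pos)
  res2 <- eclip_distance_test(v2, peaks2, functional = rep(c(TRUE, FALSE), 30))
  for (i in seq_len(60)) {
    expect_equal(res2$distances$distance[i],
                 bf_nearest_distance(pos[i] - 1, peaks2$start, peaks2$end))
  }
  ## functional variants placed inside peaks test closer than the rest
  inpeak <- unlist(lapply(1:10, function(i) peaks2$start[i] + 2))
  v3 <- data.frame(variant_id = sprintf("f%02d", 1:20), chrom = "c1",
                   pos = c(inpeak + 1, sample(1:1000, 10)))
  res3 <- eclip_distance_test(v3, peaks2,
                              functional = rep(c(TRUE, FALSE), each = 10))
  expect_equal(res3$median_functional, 0)
  expect_lt(res3$p, 0.05)
})
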