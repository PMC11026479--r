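test_that("variant effect classes follow the driver-role definitions", {
  expect_equal(classify_variant_effect(TRUE, "up", "oncogene"), "detrimental")
  expect_equal(classify_variant_effect(TRUE, "down", "tsg"), "detrimental")
  expect_equal(classify_variant_effect(TRUE, "up", "tsg"), "benign")
  expect_equal(classify_variant_effect(TRUE, "down", "oncogene"), "benign")
  expect_equal(classify_variant_effect(TRUE, "up", "ambiguous"), "ambiguous")
  expect_equal(classify_variant_effect(FALSE, "up", "oncogene"), "none")
  expect_equal(classify_variant_effect(TRUE, "up", "none"), "none")
})

test_that("uTMB categories match a brute-force count on a toy patient", {
  calls <- data.frame(
    variant_id = sprintf("v%d", 1:6),
    functional = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
    direction = c("up", "down", "up", "up", "down", "down"),
    driver_role = c("oncogene", "tsg", "none", "oncogene", "none", "oncogene"))
  ## patient carries v1 (func, oncogene, up -> detrimental), v2 (func, tsg,
  ## down -> detrimental), v3 (func, non-driver), v4 (nonfunc, driver)
  mut <- data.frame(patient = "P1", variant_id = c("v1", "v2", "v3", "v4"))
  u <- compute_utmb(mut, calls)
  expect_equal(u$utmb_func_overall, 3)
  expect_equal(u$utmb_driver_func_overall, 2)
  expect_equal(u$utmb_driver_func_detrimental, 2)
  expect_equal(u$utmb_driver_func_benign, 0)
  expect_equal(u$utmb_nonfunc, 1)
  expect_equal(u$utmb_driver_nonfunc, 1)
  ## patient with no overlapping mutations: all zeros
  u0 <- compute_utmb(mut, calls, patients = c("P1", "P2"))
  expect_true(all(u0[u0$patient == "P2", -1] == 0))
})

test_that("uTMB inequalities hold across simulated cohorts", {
  for (sd in 1:3) {
    s <- tiny_screen(seed = sd * 7, n_variants = 25, dna_depth = 150,
                     rna_depth = 150)
    counts <- simulate_counts(s$oligos, s$truth, s$cfg)
    calls <- mpra_call(counts,
                       annotation = s$lib$variants[, c("variant_id", "gene",
                                                       "driver_role")])
    co <- simulate_cohort(s$cfg, calls, n_patients = 40, mean_mutations = 4)
    u <- compute_utmb(co$mutations, calls, patients = co$patients$patient)
    expect_true(all(u$utmb_driver_func_overall <= u$utmb_func_overall))
    expect_true(all(u$utmb_driver_func_detrimental + u$utmb_driver_func_benign
                    <= u$utmb_driver_func_overall))
    expect_true(all(u$utmb_driver_nonfunc <= u$utmb_nonfunc))
  }
})

test_that("tertile grouping splits ranks into near-equal thirds", {
  g <- tertile_groups(1:9, ids = letters[1:9])
  expect_equal(g$group[g$value %in% 1:3], rep("low", 3))
  expect_equal(g$group[g$value %in% 7:9], rep("high", 3))
  expect_equal(g$group[g$value %in% 4:6], rep("mid", 3))
  ## sizes differ by at most 1 for distinct values
  for (n in c(7, 10, 11, 23)) {
    gg <- tertile_groups(sample(n), ids = as.character(1:n))
    expect_lte(diff(range(table(gg$group))), 1)
  }
  ## boundary ties resolved by stable id order
  t1 <- tertile_groups(c(1, 1, 1, 1, 1, 2), ids = letters[1:6])
  t2 <- tertile_groups(c(1, 1, 1, 1, 1, 2), ids = letters[1:6])
  expect_identical(t1, t2)
  expect_equal(sum(t1$group == "low"), 2)
  ## degenerate: all equal
  expect_warning(gd <- tertile_groups(rep(3, 6)), "single group")
  expect_true(all(gd$group == "all"))
})

test_that("log-rank test matches identity and a hand-computed oracle", {
  a <- data.frame(time = c(2, 4, 6, 8), event = c(1, 0, 1, 1))
  same <- logrank_test(a, a)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)
  ## 5-subject worked example against the textbook formula
  b <- data.frame(time = c(1, 3, 5), event = c(1, 1, 0))
  cc <- data.frame(time = c(2, 6), event = c(1, 1))
  got <- logrank_test(b, cc)
  want <- bf_logrank(c(b$time, cc$time), c(b$event, cc$event),
                     c(0, 0, 0, 1, 1))
  expect_equal(got$statistic, want, tolerance = 1e-10)
  ## larger random instance against the same oracle
  set.seed(131)
  g1 <- data.frame(time = round(rexp(30, 0.2), 3), event = rbinom(30, 1, 0.8))
  g2 <- data.frame(time = round(rexp(30, 0.5), 3), event = rbinom(30, 1, 0.8))
  got2 <- logrank_test(g1, g2)
  want2 <- bf_logrank(c(g1$time, g2$time), c(g1$event, g2$event),
                      rep(0:1, each = 30))
  expect_equal(got2$statistic, want2, tolerance = 1e-8)
  expect_error(logrank_test(g1[0, ], g2), "zero subjects")
})

test_that("log-rank has power under a strong hazard ratio", {
  hits <- vapply(1:20, function(sd) {
    set.seed(sd)
    a <- data.frame(time = rexp(100, 0.1), event = 1)
    b <- data.frame(time = rexp(100, 0.3), event = 1)
    logrank_test(a, b)$p < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("outlier detection uses the reference-homozygous baseline", {
  set.seed(137)
  vals <- c(rnorm(20, 10, 2), 10, 10 + 3 * 2, 10 - 5 * 2)
  names(vals) <- sprintf("P%02d", seq_along(vals))
  geno <- c(rep("refhom", 20), "het", "het", "althom")
  ref_mean <- mean(vals[1:20]); ref_sd <- sd(vals[1:20])
  out <- detect_outliers(vals, geno, lnfc = 0.8)
  expect_equal(nrow(out), 3)
  expect_equal(out$z, (vals[21:23] - ref_mean) / ref_sd,
               ignore_attr = TRUE)
  ## carrier at the reference mean is no outlier
  z1 <- out$z[out$patient == "P21"]
  expect_lt(abs(z1), 2)
  expect_false(out$outlier[out$patient == "P21"])
  ## high outlier with positive lnFC is direction-consistent
  expect_true(out$outlier[out$patient == "P22"])
  expect_true(out$consistent[out$patient == "P22"])
  ## low outlier contradicts a positive lnFC
  expect_true(out$outlier[out$patient == "P23"])
  expect_false(out$consistent[out$patient == "P23"])
  ## guards: small or constant reference group
  expect_warning(r <- detect_outliers(vals[18:23], geno[18:23], 0.5),
                 "reference group")
  expect_null(r)
  flat <- c(rep(5, 6), 9)
  expect_warning(r2 <- detect_outliers(flat, c(rep("refhom", 6), "het"), 0.5),
                 "zero variance")
  expect_null(r2)
})

test_that("outlier proportion test equals hypergeometric enumeration", {
  bal <- outlier_proportion_test(5, 10, 5, 10)
  expect_equal(bal$odds_ratio, 1, tolerance = 1e-9)
  expect_equal(bal$p, 1)
  sk <- outlier_proportion_test(9, 10, 1, 10)
  expect_equal(sk$p, bf_fisher_two_sided(matrix(c(9, 1, 1, 9), 2,
                                                byrow = TRUE)),
               tolerance = 1e-9)
  expect_equal(sk$p, 0.00115, tolerance = 0.01)
  ## swapping rows inverts the odds ratio, preserves p
  sw <- outlier_proportion_test(1, 10, 9, 10)
  expect_equal(sw$p, sk$p, tolerance = 1e-12)
  expect_equal(log(sw$odds_ratio), -log(sk$odds_ratio), tolerance = 1e-6)
  ## empty margin: flagged, p = 1
  em <- outlier_proportion_test(0, 0, 2, 10)
  expect_true(em$degenerate)
  expect_equal(em$p, 1)
})

test_that("co-occurrence counts match a brute-force grouping", {
  calls <- data.frame(variant_id = sprintf("v%d", 1:5),
                      gene = c("A", "A", "B", "B", "C"),
                      functional = c(TRUE, TRUE, TRUE, FALSE, TRUE),
                      direction = c("up", "down", "up", "up", "down"))
  empty <- cooccurrence_counts(data.frame(patient = character(0),
                                          variant_id = character(0)), calls)
  expect_equal(nrow(empty$per_patient), 0)
  mut <- data.frame(patient = c("P1", "P1", "P1", "P2", "P2"),
                    variant_id = c("v1", "v2", "v4", "v3", "v5"))
  res <- cooccurrence_counts(mut, calls)
  p1a <- res$per_patient[res$per_patient$patient == "P1" &
                           res$per_patient$gene == "A", ]
  expect_equal(p1a$n, 2)       # v1 + v2; v4 is nonfunctional
  expect_equal(p1a$n_up, 1)
  expect_equal(p1a$n_down, 1)
  expect_equal(res$per_gene$n_total[res$per_gene$gene == "A"], 2)
  ## brute force on a random instance
  set.seed(139)
  mut2 <- data.frame(patient = sample(c("P1", "P2", "P3"), 40, TRUE),
                     variant_id = sample(calls$variant_id, 40, TRUE))
  mut2 <- unique(mut2)
  res2 <- cooccurrence_counts(mut2, calls)
  fun <- calls[calls$functional, ]
  for (i in seq_len(nrow(res2$per_patient))) {
    row <- res2$per_patient[i, ]
    want <- sum(mut2$patient == row$patient &
                  mut2$variant_id %in%
                    fun$variant_id[fun$gene == row$gene])
    expect_equal(row$n, want)
  }
})

test_that("cohort survival is hazard-linked to uTMB when configured", {
  s <- tiny_screen(seed = 41, n_variants = 30, dna_depth = 200,
                   rna_depth = 200, frac_functional = 0.6, effect_min = 0.5,
                   effect_max = 1.2)
  counts <- simulate_counts(s$oligos, s$truth, s$cfg)
  calls <- mpra_call(counts, annotation = s$lib$variants[, c("variant_id",
                                                             "gene",
                                                             "driver_role")])
  co <- simulate_cohort(s$cfg, calls, n_patients = 150, mean_mutations = 4,
                        utmb_hazard = 0.8)
  u <- compute_utmb(co$mutations, calls, patients = co$patients$patient)
  g <- tertile_groups(u$utmb_func_overall, ids = u$patient)
  surv <- co$survival
  hi <- surv[surv$patient %in% g$id[g$group == "high"], ]
  lo <- surv[surv$patient %in% g$id[g$group == "low"], ]
  res <- logrank_test(hi, lo)
  expect_lt(res$p, 0.05)
})
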