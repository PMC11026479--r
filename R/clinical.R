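## Patient-level analytics: variant effect classes, uTMB, expression
## outliers, tertile grouping and log-rank survival comparison.
##
## uTMB (untranslated tumor mutational burden) counts, per patient, the
## somatic mutations that are also functional screen variants, in six
## categories: all functional, functional in cancer driver genes, detrimental
## (up in an oncogene / down in a tumor suppressor), benign (the opposite),
## and the nonfunctional analogues of the first two as controls.

#' Classify a variant's expected tumor effect
#'
#' Detrimental = functional and (oncogene & up) or (tsg & down); benign =
#' functional and (oncogene & down) or (tsg & up); ambiguous driver roles stay
#' ambiguous; nonfunctional variants are "none".
#'
#' @param functional Logical vector.
#' @param direction `"up"`/`"down"` per variant.
#' @param driver_role `"oncogene"`, `"tsg"`, `"ambiguous"` or `"none"`.
#' @return Character vector: detrimental/benign/ambiguous/none.
#' @export
classify_variant_effect <- function(functional, direction, driver_role) {
  out <- rep("none", length(functional))
  f <- functional & !is.na(direction) & direction %in% c("up", "down")
  role <- ifelse(is.na(driver_role), "none", driver_role)
  det <- f & ((role == "oncogene" & direction == "up") |
                (role == "tsg" & direction == "down"))
  ben <- f & ((role == "oncogene" & direction == "down") |
                (role == "tsg" & direction == "up"))
  out[f & role == "ambiguous"] <- "ambiguous"
  out[det] <- "detrimental"
  out[ben] <- "benign"
  out
}

#' Per-patient untranslated tumor mutational burden
#'
#' Counts each patient's somatic mutations that are also screen variants, in
#' six categories. Category invariants: driver counts never exceed overall
#' counts and detrimental + benign never exceeds the driver functional count.
#'
#' @param mutations data.frame with `patient`, `variant_id`.
#' @param calls Call table with `variant_id`, `functional`, `direction` and
#'   `driver_role`.
#' @param patients Optional vector of patient ids to report (defaults to
#'   those present in `mutations`); patients without overlapping mutations
#'   get all-zero rows.
#' @return data.frame with the six uTMB columns per patient.
#' @export
compute_utmb <- function(mutations, calls, patients = NULL) {
  patients <- patients %||% sort(unique(mutations$patient))
  effect <- classify_variant_effect(calls$functional, calls$direction,
                                    calls$driver_role)
  is_driver <- !is.na(calls$driver_role) &
    calls$driver_role %in% c("oncogene", "tsg", "ambiguous")
  lk <- data.frame(variant_id = calls$variant_id,
                   functional = calls$functional,
                   driver = is_driver, effect = effect,
                   stringsAsFactors = FALSE)
  m <- merge(mutations, lk, by = "variant_id")
  one <- function(p) {
    d <- m[m$patient == p, , drop = FALSE]
    data.frame(
      patient = p,
      utmb_func_overall = sum(d$functional),
      utmb_driver_func_overall = sum(d$functional & d$driver),
      utmb_driver_func_detrimental = sum(d$effect == "detrimental"),
      utmb_driver_func_benign = sum(d$effect == "benign"),
      utmb_nonfunc = sum(!d$functional),
      utmb_driver_nonfunc = sum(!d$functional & d$driver),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(patients, one))
  rownames(out) <- NULL
  out
}

#' Tertile groups of a burden metric
#'
#' Patients are ordered by (value, id) and split into three groups of sizes
#' differing by at most 1 ("low" = bottom, "high" = top tertile; boundary
#' ties are resolved by the stable id order). If all values are equal a
#' single group is returned with a warning and the comparison should be
#' skipped.
#'
#' @param values Numeric vector (e.g. a uTMB column).
#' @param ids Identifiers aligned with `values`.
#' @return data.frame with `id`, `value`, `group` (low/mid/high, or `"all"`
#'   in the degenerate case).
#' @export
tertile_groups <- function(values, ids = names(values)) {
  assert_that(length(values) >= 3, "need >= 3 patients for tertiles")
  ids <- ids %||% as.character(seq_along(values))
  if (length(unique(values)) == 1) {
    warning("all values equal; single group returned")
    return(data.frame(id = ids, value = values, group = "all",
                      stringsAsFactors = FALSE))
  }
  ord <- order(values, ids)
  n <- length(values)
  base <- n %/% 3L
  rem <- n %% 3L
  sizes <- c(base + (rem >= 1L), base, base + (rem >= 2L))  # low, mid, high
  grp <- rep(c("low", "mid", "high"), times = sizes)
  out <- data.frame(id = ids[ord], value = values[ord], group = grp,
                    stringsAsFactors = FALSE)
  out[match(ids, out$id), ]
}

#' Two-group log-rank test
#'
#' Standard two-sided log-rank comparison (observed vs expected events under
#' the pooled risk set at each event time; statistic ~ chi-squared(1)),
#' via [survival::survdiff()].
#'
#' @param a,b data.frames with `time` and `event` columns.
#' @return List with `statistic`, `p`, `n` (group sizes).
#' @export
logrank_test <- function(a, b) {
  assert_that(nrow(a) > 0 && nrow(b) > 0, "a group has zero subjects")
  assert_that(sum(a$event) + sum(b$event) >= 1, "no events in either group")
  d <- rbind(data.frame(time = a$time, event = a$event, g = 0L),
             data.frame(time = b$time, event = b$event, g = 1L))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
  list(statistic = unname(sd_$chisq),
       p = pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
       n = c(nrow(a), nrow(b)))
}

#' Expression outliers among variant carriers
#'
#' z-scores of carrier expression against the mean/sd of reference-homozygous
#' patients (minimum reference group size `min_ref`); outlier iff |z| > 2.
#' The consistency flag records whether the direction of the outlier matches
#' the sign of the screen lnFC.
#'
#' @param values Named numeric vector of expression values (one gene),
#'   names = patient ids.
#' @param genotype Character vector aligned with `values`: `"refhom"`,
#'   `"het"`, `"althom"` or `"missing"`.
#' @param lnfc The variant's screen lnFC (for the consistency flag).
#' @param min_ref Minimum reference-homozygous group size.
#' @param z_cut Outlier threshold (default 2).
#' @return data.frame for carriers: `patient`, `value`, `z`, `outlier`,
#'   `consistent`; or NULL when the reference group is too small or has
#'   zero variance (skipped with a warning).
#' @export
detect_outliers <- function(values, genotype, lnfc, min_ref = 5L, z_cut = 2) {
  ref <- values[genotype == "refhom"]
  if (length(ref) < min_ref) {
    warning("reference group smaller than ", min_ref, "; gene skipped")
    return(NULL)
  }
  if (sd(ref) == 0) {
    warning("zero variance in reference group; gene skipped")
    return(NULL)
  }
  carrier <- genotype %in% c("het", "althom")
  z <- (values[carrier] - mean(ref)) / sd(ref)
  data.frame(patient = names(values)[carrier] %||% which(carrier),
             value = values[carrier], z = z, outlier = abs(z) > z_cut,
             consistent = abs(z) > z_cut & sign(z) == sign(lnfc),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fisher test on outlier proportions
#'
#' Two-sided Fisher exact test of the 2x2 table (carrier vs reference, outlier
#' vs not). Empty margins return p = 1 with a flag rather than an error.
#'
#' @param carrier_outliers,carrier_total Carrier counts.
#' @param ref_outliers,ref_total Reference-homozygous counts.
#' @return List with `odds_ratio`, `p`, `degenerate`.
#' @export
outlier_proportion_test <- function(carrier_outliers, carrier_total,
                                    ref_outliers, ref_total) {
  tab <- matrix(c(carrier_outliers, carrier_total - carrier_outliers,
                  ref_outliers, ref_total - ref_outliers),
                nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(odds_ratio = NA_real_, p = 1, degenerate = TRUE))
  }
  ft <- fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, degenerate = FALSE)
}

#' Co-occurrence of functional variants per gene and patient
#'
#' Counts functional screen variants among each patient's somatic mutations,
#' grouped by gene, with an up/down direction breakdown and a per-gene
#' summary.
#'
#' @param mutations data.frame with `patient`, `variant_id`.
#' @param calls Call table with `variant_id`, `gene`, `functional`,
#'   `direction`.
#' @return List with `per_patient` (patient, gene, n, n_up, n_down) and
#'   `per_gene` (gene, n_patients, n_total, n_up, n_down).
#' @export
cooccurrence_counts <- function(mutations, calls) {
  fun <- calls[calls$functional, c("variant_id", "gene", "direction")]
  m <- merge(mutations, fun, by = "variant_id")
  if (nrow(m) == 0) {
    return(list(per_patient = data.frame(patient = character(0),
                                         gene = character(0), n = integer(0),
                                         n_up = integer(0), n_down = integer(0)),
                per_gene = data.frame(gene = character(0),
                                      n_patients = integer(0),
                                      n_total = integer(0),
                                      n_up = integer(0), n_down = integer(0))))
  }
  key <- paste(m$patient, m$gene, sep = "\r")
  pp <- do.call(rbind, lapply(split(m, key), function(d) {
    data.frame(patient = d$patient[1], gene = d$gene[1], n = nrow(d),
               n_up = sum(d$direction == "up"),
               n_down = sum(d$direction == "down"),
               stringsAsFactors = FALSE)
  }))
  pp <- pp[order(pp$patient, pp$gene), ]
  rownames(pp) <- NULL
  pg <- do.call(rbind, lapply(split(pp, pp$gene), function(d) {
    data.frame(gene = d$gene[1], n_patients = nrow(d), n_total = sum(d$n),
               n_up = sum(d$n_up), n_down = sum(d$n_down),
               stringsAsFactors = FALSE)
  }))
  pg <- pg[order(-pg$n_total, pg$gene), ]
  rownames(pg) <- NULL
  list(per_patient = pp, per_gene = pg)
}
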