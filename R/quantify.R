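## Normalization, activity scoring and functional calling.
##
## Activity score of an allele: A = C_RNA / C_DNA on quantile-normalized,
## replicate-summed UMI counts. Relative activity of a variant:
## lnFC = ln(A_alt / A_ref). A variant is called functional when
## BH FDR <= 0.10 and |lnFC| >= 0.10.

## Rank-mean quantile normalization of a matrix; tied values in a column
## receive the mean of the target values at their ranks. (This exact tie rule
## differs from limma::normalizeQuantiles, which interpolates at average
## ranks; the two agree on tie-free data.)
qn_matrix <- function(m) {
  target <- rowMeans(apply(m, 2, sort))
  out <- m * 0
  for (j in seq_len(ncol(m))) {
    v <- numeric(nrow(m))
    v[order(m[, j])] <- target
    out[, j] <- stats::ave(v, m[, j], FUN = mean)
  }
  out
}

#' Quantile-normalize counts across replicates
#'
#' Classic rank-mean quantile normalization applied separately within each
#' library type across its replicate columns; ties receive the mean of the
#' tied target values.
#'
#' @param counts Long count table with `oligo_id`, `library_type`,
#'   `replicate`, `dedup`.
#' @return The same table with a `norm` column added.
#' @export
quantile_normalize <- function(counts) {
  counts$norm <- NA_real_
  for (lt in unique(counts$library_type)) {
    sel <- counts$library_type == lt
    sub <- counts[sel, ]
    reps <- sort(unique(sub$replicate))
    assert_that(length(reps) >= 2, "quantile normalization needs >= 2 replicates")
    ids <- unique(sub$oligo_id)
    m <- matrix(0, length(ids), length(reps), dimnames = list(ids, reps))
    m[cbind(match(sub$oligo_id, ids), match(sub$replicate, reps))] <- sub$dedup
    if (any(colSums(m) == 0)) {
      stop("replicate with all-zero counts in ", lt, " library")
    }
    nm <- qn_matrix(m)
    counts$norm[sel] <- nm[cbind(match(sub$oligo_id, ids),
                                 match(sub$replicate, reps))]
  }
  counts
}

#' Per-allele activity scores
#'
#' A = C_RNA / C_DNA on replicate-summed normalized counts. Alleles whose
#' total deduplicated DNA count falls below `min_dna` are flagged and excluded
#' from downstream calling.
#'
#' @param counts Normalized count table from [quantile_normalize()].
#' @param min_dna Minimum deduplicated DNA UMIs per allele, summed over
#'   replicates.
#' @return data.frame with `variant_id`, `allele`, `C_DNA`, `C_RNA`, `A`,
#'   `dna_dedup`, `pass_coverage`.
#' @export
activity_score <- function(counts, min_dna = 10) {
  agg <- function(lt, col) {
    x <- counts[counts$library_type == lt, ]
    stats::aggregate(x[[col]],
                     by = list(variant_id = x$variant_id, allele = x$allele),
                     FUN = sum)
  }
  dna <- agg("DNA", "norm"); names(dna)[3] <- "C_DNA"
  rna <- agg("RNA", "norm"); names(rna)[3] <- "C_RNA"
  dnad <- agg("DNA", "dedup"); names(dnad)[3] <- "dna_dedup"
  out <- merge(merge(dna, rna, by = c("variant_id", "allele")), dnad,
               by = c("variant_id", "allele"))
  out$pass_coverage <- out$dna_dedup >= min_dna
  out$A <- ifelse(out$C_DNA > 0, out$C_RNA / out$C_DNA, NA_real_)
  out[order(out$variant_id, out$allele), ]
}

#' Relative activity score
#'
#' lnFC = ln(A_alt / A_ref). Returns `Inf`/`-Inf` when one activity is zero
#' (callers that need a finite display value use the pseudocount path in
#' [variant_scores()]).
#'
#' @param A_ref,A_alt Activity scores of the two alleles.
#' @return Numeric lnFC (antisymmetric in the two arguments).
#' @export
relative_activity <- function(A_ref, A_alt) log(A_alt / A_ref)

#' Per-variant score table
#'
#' Collapses per-allele activities to one row per variant with A_ref, A_alt
#' and lnFC. When either allele has a zero normalized count, lnFC is
#' recomputed with a 0.5 pseudocount on the normalized RNA and DNA totals
#' (display only; testing uses raw counts) and flagged.
#'
#' @param activity Output of [activity_score()].
#' @return data.frame with `variant_id`, `A_ref`, `A_alt`, `lnFC`,
#'   `lnfc_pseudo`, `pass_coverage`.
#' @export
variant_scores <- function(activity) {
  r <- activity[activity$allele == "ref", ]
  a <- activity[activity$allele == "alt", ]
  m <- merge(r, a, by = "variant_id", suffixes = c("_ref", "_alt"))
  lnfc <- relative_activity(m$A_ref, m$A_alt)
  pseudo <- !is.finite(lnfc)
  if (any(pseudo)) {
    lnfc[pseudo] <- log(((m$C_RNA_alt[pseudo] + 0.5) / (m$C_DNA_alt[pseudo] + 0.5)) /
                          ((m$C_RNA_ref[pseudo] + 0.5) / (m$C_DNA_ref[pseudo] + 0.5)))
  }
  data.frame(variant_id = m$variant_id,
             A_ref = m$A_ref, A_alt = m$A_alt, lnFC = lnfc,
             lnfc_pseudo = pseudo,
             pass_coverage = m$pass_coverage_ref & m$pass_coverage_alt,
             stringsAsFactors = FALSE)
}

#' Pooled dispersion estimate for the count model
#'
#' Method-of-moments estimate of the conditional negative-binomial dispersion
#' of RNA counts given DNA counts, pooled across all (variant, allele) cells:
#' for each cell the squared coefficient of variation of the replicate
#' RNA/DNA ratios, minus the Poisson contribution `1/mean(RNA)`, estimates
#' `1/theta`; the pooled value is the mean over cells. Pooling borrows
#' strength across the library, which keeps the per-variant likelihood-ratio
#' test calibrated at small replicate numbers.
#'
#' @param counts Long count table (`dedup` column used).
#' @return Dispersion (1/theta), floored at 1e-8.
#' @export
estimate_dispersion <- function(counts) {
  dna <- counts[counts$library_type == "DNA", ]
  rna <- counts[counts$library_type == "RNA", ]
  m <- merge(dna[, c("variant_id", "allele", "replicate", "dedup")],
             rna[, c("variant_id", "allele", "replicate", "dedup")],
             by = c("variant_id", "allele", "replicate"),
             suffixes = c("_dna", "_rna"))
  m <- m[m$dedup_dna > 0, ]
  key <- paste(m$variant_id, m$allele)
  vals <- vapply(split(m, key), function(d) {
    if (nrow(d) < 2 || sum(d$dedup_rna) == 0) return(NA_real_)
    r <- d$dedup_rna / d$dedup_dna
    if (mean(r) == 0) return(NA_real_)
    var(r) / mean(r)^2 - 1 / mean(d$dedup_rna)
  }, numeric(1))
  max(mean(vals, na.rm = TRUE), 1e-8)
}

## NB log-link LRT for one variant with fixed dispersion. Counts enter as
## vectors over 2 * n_replicates cells; x is the allele indicator.
nb_lrt_fixed <- function(rna, dna, theta) {
  x <- rep(c(0, 1), each = length(rna) / 2)
  off <- log(pmax(dna, 0.5))
  nll0 <- function(b0) -sum(dnbinom(rna, size = theta,
                                    mu = exp(b0 + off), log = TRUE))
  nllA <- function(b) -sum(dnbinom(rna, size = theta,
                                   mu = exp(b[1] + b[2] * x + off), log = TRUE))
  b0 <- log((sum(rna) + 0.5) / (sum(dna) + 0.5))
  o0 <- optimize(nll0, interval = b0 + c(-8, 8))
  r0 <- log((sum(rna[x == 0]) + 0.5) / (sum(dna[x == 0]) + 0.5))
  r1 <- log((sum(rna[x == 1]) + 0.5) / (sum(dna[x == 1]) + 0.5))
  oA <- try(optim(c(r0, r1 - r0), nllA, method = "BFGS"), silent = TRUE)
  if (inherits(oA, "try-error") || !is.finite(oA$value)) return(NULL)
  stat <- max(0, 2 * (o0$objective - oA$value))
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE),
       coef = oA$par[2])
}

## Per-variant ML over (b0, b1, log theta); anti-conservative at small
## replicate numbers, provided for completeness.
nb_lrt_ml <- function(rna, dna) {
  x <- rep(c(0, 1), each = length(rna) / 2)
  off <- log(pmax(dna, 0.5))
  nll <- function(par, with_x) {
    mu <- exp(par[1] + (if (with_x) par[2] * x else 0) + off)
    th <- exp(par[length(par)])
    -sum(dnbinom(rna, size = th, mu = mu, log = TRUE))
  }
  b0 <- log((sum(rna) + 0.5) / (sum(dna) + 0.5))
  o0 <- try(optim(c(b0, 3), nll, with_x = FALSE, method = "Nelder-Mead"),
            silent = TRUE)
  oA <- try(optim(c(b0, 0, 3), nll, with_x = TRUE, method = "Nelder-Mead",
                  control = list(maxit = 1000)), silent = TRUE)
  if (inherits(o0, "try-error") || inherits(oA, "try-error")) return(NULL)
  stat <- max(0, 2 * (o0$value - oA$value))
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE),
       coef = oA$par[2])
}

#' Test one variant for differential allele activity
#'
#' Negative-binomial log-link model of RNA counts with the log DNA count as
#' offset, intercept plus allele indicator; likelihood-ratio test of the
#' allele term against chi-squared(1). The dispersion is held fixed (supply a
#' pooled estimate from [estimate_dispersion()]). On failure, falls back to a
#' Welch t-test on per-replicate log activity ratios (flagged).
#'
#' @param dna_ref,dna_alt,rna_ref,rna_alt Per-replicate deduplicated counts.
#' @param dispersion Negative-binomial dispersion (1/theta).
#' @param method `"pooled"` (fixed dispersion) or `"per_variant_ml"`.
#' @return List with `statistic`, `p`, `method`.
#' @export
test_variant <- function(dna_ref, dna_alt, rna_ref, rna_alt,
                         dispersion = 0.01,
                         method = c("pooled", "per_variant_ml")) {
  method <- match.arg(method)
  if (identical(rna_ref, rna_alt) && identical(dna_ref, dna_alt)) {
    return(list(statistic = 0, p = 1, method = "nb_lrt"))
  }
  rna <- c(rna_ref, rna_alt)
  dna <- c(dna_ref, dna_alt)
  fit <- if (method == "pooled") {
    nb_lrt_fixed(rna, dna, theta = 1 / max(dispersion, 1e-8))
  } else {
    nb_lrt_ml(rna, dna)
  }
  if (!is.null(fit) && is.finite(fit$p)) {
    return(list(statistic = fit$statistic, p = fit$p, method = "nb_lrt"))
  }
  ## Welch fallback on log activity ratios
  la_ref <- log((rna_ref + 0.5) / (dna_ref + 0.5))
  la_alt <- log((rna_alt + 0.5) / (dna_alt + 0.5))
  tt <- try(t.test(la_alt, la_ref), silent = TRUE)
  if (inherits(tt, "try-error")) {
    return(list(statistic = NA_real_, p = NA_real_, method = "failed"))
  }
  list(statistic = unname(tt$statistic), p = tt$p.value, method = "welch_t")
}

#' Test all variants in a count table
#'
#' @param counts Long count table (dedup counts used).
#' @param dispersion Optional dispersion; estimated by
#'   [estimate_dispersion()] when `NULL`.
#' @param min_dna Coverage threshold (summed dedup DNA UMIs per allele).
#' @param method Passed to [test_variant()].
#' @return data.frame with `variant_id`, `statistic`, `p`, `method`,
#'   `tested`; attribute `dispersion` records the value used.
#' @export
test_variants <- function(counts, dispersion = NULL, min_dna = 10,
                          method = c("pooled", "per_variant_ml")) {
  method <- match.arg(method)
  if (is.null(dispersion)) dispersion <- estimate_dispersion(counts)
  reps <- sort(unique(counts$replicate))
  wide <- function(lt, al) {
    x <- counts[counts$library_type == lt & counts$allele == al, ]
    ids <- sort(unique(counts$variant_id))
    m <- matrix(0L, length(ids), length(reps), dimnames = list(ids, reps))
    m[cbind(match(x$variant_id, ids), match(x$replicate, reps))] <- x$dedup
    m
  }
  DR <- wide("DNA", "ref"); DA <- wide("DNA", "alt")
  RR <- wide("RNA", "ref"); RA <- wide("RNA", "alt")
  ids <- rownames(DR)
  tested <- rowSums(DR) >= min_dna & rowSums(DA) >= min_dna
  res <- lapply(seq_along(ids), function(i) {
    if (!tested[i]) {
      return(list(statistic = NA_real_, p = NA_real_, method = "low_coverage"))
    }
    test_variant(DR[i, ], DA[i, ], RR[i, ], RA[i, ], dispersion, method)
  })
  out <- data.frame(
    variant_id = ids,
    statistic = vapply(res, function(r) r$statistic, numeric(1)),
    p = vapply(res, function(r) r$p, numeric(1)),
    method = vapply(res, function(r) r$method, character(1)),
    tested = tested,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "dispersion") <- dispersion
  out
}

#' Call functional variants
#'
#' Benjamini-Hochberg FDR across all tested variants in the run; a variant is
#' functional iff FDR <= `fdr_cut` and |lnFC| >= `effect_cut`; direction is
#' the sign of lnFC.
#'
#' @param scores Output of [variant_scores()].
#' @param tests Output of [test_variants()].
#' @param fdr_cut FDR threshold (default 0.10).
#' @param effect_cut Minimum |lnFC| (default 0.10).
#' @param cell_line Label recorded on the calls.
#' @return Call table: `variant_id`, `A_ref`, `A_alt`, `lnFC`, `statistic`,
#'   `p`, `fdr`, `functional`, `direction`, `cell_line`.
#' @export
call_functional <- function(scores, tests, fdr_cut = 0.10, effect_cut = 0.10,
                            cell_line = "sim") {
  m <- merge(scores, tests, by = "variant_id")
  m$fdr <- NA_real_
  sel <- m$tested & !is.na(m$p)
  m$fdr[sel] <- p.adjust(m$p[sel], method = "BH")
  m$functional <- !is.na(m$fdr) & m$fdr <= fdr_cut & abs(m$lnFC) >= effect_cut
  m$direction <- ifelse(m$lnFC > 0, "up", ifelse(m$lnFC < 0, "down", "none"))
  m$cell_line <- cell_line
  m <- m[order(m$variant_id),
         c("variant_id", "A_ref", "A_alt", "lnFC", "statistic", "p", "fdr",
           "functional", "direction", "cell_line")]
  rownames(m) <- NULL
  m
}

#' Full calling pipeline from a count table
#'
#' Quantile normalization, activity scoring, pooled-dispersion testing and
#' functional calling in one step.
#'
#' @inheritParams call_functional
#' @inheritParams test_variants
#' @param annotation Optional data.frame keyed by `variant_id` (e.g. gene,
#'   driver_role) merged onto the calls.
#' @return Call table as [call_functional()].
#' @export
mpra_call <- function(counts, annotation = NULL, min_dna = 10,
                      fdr_cut = 0.10, effect_cut = 0.10, cell_line = "sim",
                      dispersion = NULL) {
  norm <- quantile_normalize(counts)
  act <- activity_score(norm, min_dna = min_dna)
  scores <- variant_scores(act)
  tests <- test_variants(counts, dispersion = dispersion, min_dna = min_dna)
  calls <- call_functional(scores, tests, fdr_cut, effect_cut, cell_line)
  if (!is.null(annotation)) {
    calls <- merge(calls, annotation, by = "variant_id", all.x = TRUE,
                   sort = TRUE)
  }
  calls
}

#' Compare effect sizes between two variant groups
#'
#' Wilcoxon rank-sum test on lnFC values (or their absolute values), one- or
#' two-tailed.
#'
#' @param a,b Numeric lnFC vectors.
#' @param alternative Passed to [stats::wilcox.test()] (`a` versus `b`).
#' @param on_abs Compare |lnFC| instead of signed values.
#' @return List with `statistic` (W) and `p`.
#' @export
compare_groups <- function(a, b, alternative = "two.sided", on_abs = FALSE) {
  assert_that(length(a) >= 2 && length(b) >= 2, "group size < 2")
  if (on_abs) { a <- abs(a); b <- abs(b) }
  w <- wilcox.test(a, b, alternative = alternative, exact = FALSE)
  list(statistic = unname(w$statistic), p = w$p.value)
}

#' Replicate concordance of activity scores
#'
#' Per-replicate oligo-level activity (normalized RNA / normalized DNA) and
#' pairwise Spearman correlations between replicates.
#'
#' @param norm_counts Output of [quantile_normalize()].
#' @return data.frame with `rep_a`, `rep_b`, `rho`, `p`.
#' @export
replicate_qc <- function(norm_counts) {
  reps <- sort(unique(norm_counts$replicate))
  assert_that(length(reps) >= 2, "need >= 2 replicates")
  ids <- sort(unique(norm_counts$oligo_id))
  act <- sapply(reps, function(r) {
    d <- norm_counts[norm_counts$replicate == r & norm_counts$library_type == "DNA", ]
    rn <- norm_counts[norm_counts$replicate == r & norm_counts$library_type == "RNA", ]
    dn <- d$norm[match(ids, d$oligo_id)]
    rv <- rn$norm[match(ids, rn$oligo_id)]
    ifelse(dn > 0, rv / dn, NA_real_)
  })
  pairs <- utils::combn(seq_along(reps), 2)
  out <- apply(pairs, 2, function(ij) {
    ct <- suppressWarnings(cor.test(act[, ij[1]], act[, ij[2]],
                                    method = "spearman"))
    c(rho = unname(ct$estimate), p = ct$p.value)
  })
  data.frame(rep_a = reps[pairs[1, ]], rep_b = reps[pairs[2, ]],
             rho = out["rho", ], p = out["p", ])
}
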