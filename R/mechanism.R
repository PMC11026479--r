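## Mechanistic statistics on called variants: sequence groups, hexamer
## enrichment, PWM motif-strength change with shuffled nulls, miRNA
## target-site overlap, RBP binding-delta and eCLIP distance comparisons.
##
## Motif strength of a sequence window against a PWM, assuming a uniform
## background base distribution: S = prod(p_i) / 0.25^n, where p_i is the PWM
## probability of the observed base at motif position i and n is the motif
## length. The strength change caused by a variant is delta = |S_var - S_ref|.

#' Validate a position weight matrix
#'
#' A PWM is a 4 x n matrix of base probabilities with rownames A, C, G, T
#' (U is accepted as an alias for T); every column must sum to 1.
#'
#' @param pwm Numeric matrix.
#' @return The validated PWM (rownames normalized to A/C/G/T).
#' @export
validate_pwm <- function(pwm) {
  stopifnot(is.matrix(pwm), nrow(pwm) == 4)
  rn <- chartr("U", "T", toupper(rownames(pwm) %||% c("A", "C", "G", "T")))
  assert_that(setequal(rn, DNA_BASES), "PWM rows must be A, C, G, T/U")
  rownames(pwm) <- rn
  pwm <- pwm[DNA_BASES, , drop = FALSE]
  assert_that(ncol(pwm) >= 2, "motif length must be >= 2")
  assert_that(all(abs(colSums(pwm) - 1) < 1e-9), "PWM columns must sum to 1")
  pwm
}

## Strength of the motif window starting at `start` (1-based) in `seq`.
pwm_strength <- function(seq, pwm, start) {
  n <- ncol(pwm)
  assert_that(start >= 1 && start + n - 1 <= nchar(seq),
              "sequence does not cover the PWM window")
  win <- chartr("U", "T", toupper(substr(seq, start, start + n - 1L)))
  bases <- strsplit(win, "", fixed = TRUE)[[1]]
  assert_that(all(bases %in% DNA_BASES), "ambiguous base in motif window")
  prod(pwm[cbind(match(bases, rownames(pwm)), seq_len(n))]) / 0.25^n
}

#' Motif-strength change caused by a variant
#'
#' Scores the reference and variant sequences against the PWM over the window
#' starting at `offset` and returns the absolute strength change.
#'
#' @param seq_ref,seq_var Reference and variant sequences (same coordinates).
#' @param pwm A validated PWM (see [validate_pwm()]).
#' @param offset 1-based start of the motif window within the sequences.
#' @return List with `S_ref`, `S_var`, `delta`.
#' @export
motif_strength <- function(seq_ref, seq_var, pwm, offset = 1L) {
  pwm <- validate_pwm(pwm)
  s_ref <- pwm_strength(seq_ref, pwm, offset)
  s_var <- pwm_strength(seq_var, pwm, offset)
  list(S_ref = s_ref, S_var = s_var, delta = abs(s_var - s_ref))
}

#' Shuffle a PWM
#'
#' Column shuffle permutes motif positions while preserving each position's
#' base distribution (and hence the per-position information content);
#' within-column shuffle permutes the base probabilities inside each position.
#'
#' @param pwm A PWM.
#' @param axis `"columns"` (default) or `"within_column"`.
#' @return Shuffled PWM.
#' @export
shuffle_pwm <- function(pwm, axis = c("columns", "within_column")) {
  axis <- match.arg(axis)
  pwm <- validate_pwm(pwm)
  if (axis == "columns") {
    pwm[, sample(ncol(pwm)), drop = FALSE]
  } else {
    apply(pwm, 2, sample)
  }
}

#' Motif-strength deltas against shuffled-PWM and nonfunctional-variant nulls
#'
#' Scores functional variant pairs with the true PWM, then (null 1) rescores
#' the same pairs under a shuffled PWM and (null 2) scores a count-matched
#' random sample of nonfunctional variant pairs with the true PWM; each null
#' is compared to the functional deltas with a two-sided Kolmogorov-Smirnov
#' test.
#'
#' @param func_pairs data.frame with `seq_ref`, `seq_var`, `offset` for
#'   functional variants.
#' @param nonfunc_pairs Same columns for nonfunctional variants.
#' @param pwm A PWM.
#' @param seed Seed for the shuffle and the control sample.
#' @param shuffle_axis Passed to [shuffle_pwm()].
#' @return List with `delta_functional`, `delta_shuffled`, `delta_nonfunc`,
#'   and `ks_shuffled` / `ks_nonfunc` (each a list with `D`, `p`).
#' @export
motif_strength_null <- function(func_pairs, nonfunc_pairs, pwm, seed = 1L,
                                shuffle_axis = "columns") {
  assert_that(nrow(func_pairs) >= 10, "need >= 10 functional deltas")
  assert_that(nrow(nonfunc_pairs) >= 10, "insufficient nonfunctional controls")
  pwm <- validate_pwm(pwm)
  set.seed(seed)
  deltas <- function(pairs, p) {
    vapply(seq_len(nrow(pairs)), function(i) {
      motif_strength(pairs$seq_ref[i], pairs$seq_var[i], p,
                     pairs$offset[i])$delta
    }, numeric(1))
  }
  d_fun <- deltas(func_pairs, pwm)
  d_shuf <- deltas(func_pairs, shuffle_pwm(pwm, shuffle_axis))
  idx <- sample(nrow(nonfunc_pairs),
                min(nrow(func_pairs), nrow(nonfunc_pairs)))
  d_non <- deltas(nonfunc_pairs[idx, , drop = FALSE], pwm)
  ks1 <- suppressWarnings(ks.test(d_fun, d_shuf))
  ks2 <- suppressWarnings(ks.test(d_fun, d_non))
  list(delta_functional = d_fun, delta_shuffled = d_shuf,
       delta_nonfunc = d_non,
       ks_shuffled = list(D = unname(ks1$statistic), p = ks1$p.value),
       ks_nonfunc = list(D = unname(ks2$statistic), p = ks2$p.value))
}

#' Up- and down-regulating sequence groups around functional variants
#'
#' For every functional variant the window (variant +/- `flank` nt) of the
#' higher-expressed allele joins the upregulating group and the window of the
#' lower-expressed allele joins the downregulating group: for lnFC > 0 the
#' alternative-allele window is "up" and the reference window is "down", and
#' vice versa. Windows truncated by the insert boundary are flagged.
#'
#' @param calls Call table (functional rows used).
#' @param oligos Oligo table supplying `insert_sequence` and `variant_offset`
#'   per (variant, allele).
#' @param flank Window half-width in nt (default 5, 11-nt windows).
#' @return data.frame with `variant_id`, `group` (up/down), `allele`,
#'   `window`, `trimmed`.
#' @export
build_sequence_groups <- function(calls, oligos, flank = 5L) {
  fun <- calls[calls$functional & calls$lnFC != 0, , drop = FALSE]
  rows <- lapply(seq_len(nrow(fun)), function(i) {
    vid <- fun$variant_id[i]
    up_allele <- if (fun$lnFC[i] > 0) "alt" else "ref"
    out <- lapply(c(up = up_allele,
                    down = setdiff(c("ref", "alt"), up_allele)),
                  function(al) {
      o <- oligos[oligos$variant_id == vid & oligos$allele == al, ]
      if (nrow(o) == 0) return(NULL)
      center <- o$variant_offset[1] + 1L
      lo <- max(1L, center - flank)
      hi <- min(nchar(o$insert_sequence[1]), center + flank)
      data.frame(variant_id = vid, allele = al,
                 window = substr(o$insert_sequence[1], lo, hi),
                 trimmed = (hi - lo + 1L) < (2L * flank + 1L),
                 stringsAsFactors = FALSE)
    })
    out <- out[!vapply(out, is.null, logical(1))]
    if (length(out) < 2) return(NULL)
    cbind(group = names(out), do.call(rbind, out))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

## All hexamers contained in a window (as a character set).
window_hexamers <- function(window, k = 6L) {
  n <- nchar(window)
  if (n < k) return(character(0))
  unique(substring(window, 1:(n - k + 1L), k:n))
}

#' Hexamer over-representation between two window groups
#'
#' For every hexamer observed in either group, counts the windows containing
#' it and applies a one-sided Fisher exact test (enrichment in the foreground)
#' with BH correction across hexamers. T and U are equivalent (windows are
#' handled in DNA alphabet).
#'
#' @param foreground,background Character vectors of sequence windows.
#' @param k Word length (default 6).
#' @return data.frame ranked by p: `hexamer`, `n_fore`, `n_back`,
#'   `odds_ratio`, `p`, `fdr`.
#' @export
hexamer_enrichment <- function(foreground, background, k = 6L) {
  assert_that(length(foreground) > 0 && length(background) > 0,
              "both groups must be non-empty")
  foreground <- chartr("U", "T", toupper(foreground))
  background <- chartr("U", "T", toupper(background))
  hf <- lapply(foreground, window_hexamers, k = k)
  hb <- lapply(background, window_hexamers, k = k)
  words <- sort(unique(c(unlist(hf), unlist(hb))))
  cf <- table(factor(unlist(hf), levels = words))
  cb <- table(factor(unlist(hb), levels = words))
  nf <- length(foreground); nb <- length(background)
  res <- lapply(seq_along(words), function(i) {
    a <- as.integer(cf[i]); b <- as.integer(cb[i])
    ft <- fisher.test(matrix(c(a, nf - a, b, nb - b), 2, byrow = TRUE),
                      alternative = "greater")
    c(p = ft$p.value, or = unname(ft$estimate))
  })
  out <- data.frame(hexamer = words,
                    n_fore = as.integer(cf), n_back = as.integer(cb),
                    odds_ratio = vapply(res, `[[`, 0, "or"),
                    p = vapply(res, `[[`, 0, "p"),
                    stringsAsFactors = FALSE)
  out$fdr <- p.adjust(out$p, "BH")
  out <- out[order(out$p, out$hexamer), ]
  rownames(out) <- NULL
  out
}

#' Overlap variants with predicted miRNA target sites
#'
#' Sites are filtered to a minimum context++ score percentile (default 50);
#' sites with a missing percentile are dropped with a warning. A pair is
#' reported when the variant's reference-allele position (0-based `pos - 1`)
#' lies inside the half-open site interval.
#'
#' @param variants Variant table (`chrom`, 1-based `pos`, `variant_id`).
#' @param sites BED-style data.frame with `chrom`, `start`, `end`, `site_id`
#'   (or `gene`), `percentile`.
#' @param min_percentile Minimum context++ percentile.
#' @return data.frame of variant-site pairs.
#' @export
overlap_mirna_sites <- function(variants, sites, min_percentile = 50) {
  miss <- is.na(sites$percentile)
  if (any(miss)) {
    warning(sum(miss), " site(s) dropped for missing percentile")
    sites <- sites[!miss, , drop = FALSE]
  }
  sites <- sites[sites$percentile >= min_percentile, , drop = FALSE]
  if (nrow(sites) == 0 || nrow(variants) == 0) {
    return(data.frame(variant_id = character(0), site_id = character(0)))
  }
  pairs <- list()
  for (ch in unique(variants$chrom)) {
    vi <- which(variants$chrom == ch)
    si <- which(sites$chrom == ch)
    if (!length(si)) next
    q <- IRanges::IRanges(start = variants$pos[vi], width = 1L) # 1-based point
    s <- IRanges::IRanges(start = sites$start[si] + 1L, end = sites$end[si])
    ov <- IRanges::findOverlaps(q, s)
    if (length(ov)) {
      pairs[[ch]] <- data.frame(
        variant_id = variants$variant_id[vi[S4Vectors::queryHits(ov)]],
        site_id = (sites$site_id %||% rownames(sites))[si[S4Vectors::subjectHits(ov)]],
        percentile = sites$percentile[si[S4Vectors::subjectHits(ov)]],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, pairs) %||%
    data.frame(variant_id = character(0), site_id = character(0))
  rownames(out) <- NULL
  out
}

#' Direction bias of variants overlapping miRNA target sites
#'
#' One-tailed Wilcoxon rank-sum test of whether overlapping variants' lnFC
#' values are shifted upward relative to a comparison set (disrupting a
#' repressive miRNA site is expected to raise mRNA abundance). With
#' `lnfc_background = NULL` a one-sample signed-rank test against zero is
#' used instead.
#'
#' @param lnfc_overlapping lnFC of functional variants inside target sites.
#' @param lnfc_background lnFC of the comparison set (non-overlapping
#'   functional variants), or `NULL`.
#' @param alternative Test direction (default `"greater"`).
#' @return List with `statistic`, `p`.
#' @export
direction_bias_test <- function(lnfc_overlapping, lnfc_background = NULL,
                                alternative = "greater") {
  assert_that(length(lnfc_overlapping) > 0, "empty overlapping set")
  w <- if (is.null(lnfc_background)) {
    wilcox.test(lnfc_overlapping, mu = 0, alternative = alternative,
                exact = FALSE)
  } else {
    assert_that(length(lnfc_background) > 0, "empty background set")
    wilcox.test(lnfc_overlapping, lnfc_background,
                alternative = alternative, exact = FALSE)
  }
  list(statistic = unname(w$statistic), p = w$p.value)
}

#' Compare predicted RBP binding changes of functional variants to controls
#'
#' Per RBP, two-sided KS tests of |binding delta| for functional variants
#' against nonfunctional variants and against random-SNV controls; the
#' reported p is the maximum of the two (the conservative convention), with BH
#' correction across RBPs. RBPs with fewer than `min_n` values in any arm are
#' skipped and flagged.
#'
#' @param deltas data.frame with `rbp`, `class` (one of
#'   `functional`/`nonfunctional`/`random`) and `delta`.
#' @param min_n Minimum arm size.
#' @return data.frame: `rbp`, `n_functional`, `D_nonfunc`, `p_nonfunc`,
#'   `D_random`, `p_random`, `p` (max), `fdr`, `skipped`.
#' @export
rbp_delta_compare <- function(deltas, min_n = 10L) {
  out <- lapply(split(deltas, deltas$rbp), function(d) {
    f <- abs(d$delta[d$class == "functional"])
    nf <- abs(d$delta[d$class == "nonfunctional"])
    rnd <- abs(d$delta[d$class == "random"])
    if (min(length(f), length(nf), length(rnd)) < min_n) {
      return(data.frame(rbp = d$rbp[1], n_functional = length(f),
                        D_nonfunc = NA, p_nonfunc = NA, D_random = NA,
                        p_random = NA, p = NA, skipped = TRUE))
    }
    k1 <- suppressWarnings(ks.test(f, nf))
    k2 <- suppressWarnings(ks.test(f, rnd))
    data.frame(rbp = d$rbp[1], n_functional = length(f),
               D_nonfunc = unname(k1$statistic), p_nonfunc = k1$p.value,
               D_random = unname(k2$statistic), p_random = k2$p.value,
               p = max(k1$p.value, k2$p.value), skipped = FALSE)
  })
  res <- do.call(rbind, out)
  res$fdr <- NA_real_
  res$fdr[!res$skipped] <- p.adjust(res$p[!res$skipped], "BH")
  rownames(res) <- NULL
  res
}

## Distance from a 0-based point to a half-open interval [s, e): 0 inside,
## else distance to the nearest covered base.
point_peak_distance <- function(p0, starts, ends) {
  vapply(p0, function(p) {
    inside <- starts <= p & p < ends
    if (any(inside)) return(0)
    min(pmin(abs(p - starts), abs(p - (ends - 1L))))
  }, numeric(1))
}

#' Distance of variants to the nearest eCLIP peak, by functional status
#'
#' Distances are computed from the 0-based variant point to the nearest peak
#' (0 inside a peak); variants on chromosomes without peaks get `NA`. A
#' one-tailed rank-sum test asks whether functional variants lie closer to
#' peaks than nonfunctional ones.
#'
#' @param variants Variant table with `chrom`, `pos` (1-based), `variant_id`.
#' @param peaks BED-style data.frame (`chrom`, `start`, `end`).
#' @param functional Logical vector aligned with `variants`.
#' @return List with `distances` (per-variant data.frame), `median_functional`,
#'   `median_nonfunctional`, `p`.
#' @export
eclip_distance_test <- function(variants, peaks, functional) {
  stopifnot(length(functional) == nrow(variants))
  d <- rep(NA_real_, nrow(variants))
  for (ch in unique(variants$chrom)) {
    vi <- which(variants$chrom == ch)
    pi <- which(peaks$chrom == ch)
    if (!length(pi)) next
    d[vi] <- point_peak_distance(variants$pos[vi] - 1L,
                                 peaks$start[pi], peaks$end[pi])
  }
  df <- data.frame(variant_id = variants$variant_id, distance = d,
                   functional = functional, stringsAsFactors = FALSE)
  fd <- d[functional & !is.na(d)]
  nd <- d[!functional & !is.na(d)]
  p <- if (length(fd) >= 2 && length(nd) >= 2) {
    wilcox.test(fd, nd, alternative = "less", exact = FALSE)$p.value
  } else {
    NA_real_
  }
  list(distances = df,
       median_functional = stats::median(fd),
       median_nonfunctional = stats::median(nd),
       p = p)
}
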