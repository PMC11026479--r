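## Permutation-based term enrichment (GO or disease) with the
## sampling-and-normal-fit p-value scheme, plain or length/GC-matched.

#' Query gene set from the top-ranked variants
#'
#' Merges calls from multiple cell lines, deduplicates variants keeping the
#' maximum |lnFC| across lines, ranks by |lnFC| (ties broken by variant id,
#' ascending, for determinism) and maps the top `top_n` variants to their
#' unique genes.
#'
#' @param calls Call table(s); concatenate cell lines before calling. Must
#'   carry `variant_id`, `gene`, `lnFC`.
#' @param top_n Number of top variants (default 500); if fewer are available
#'   all are used with a warning.
#' @param functional_only Restrict to functional calls first.
#' @return List with `variants` (ranked data.frame) and `genes` (character).
#' @export
rank_top_variants <- function(calls, top_n = 500L, functional_only = TRUE) {
  d <- calls
  if (functional_only) d <- d[d$functional, , drop = FALSE]
  d <- d[!is.na(d$lnFC), c("variant_id", "gene", "lnFC")]
  d$abs_lnfc <- abs(d$lnFC)
  d <- d[order(d$variant_id, -d$abs_lnfc), ]
  d <- d[!duplicated(d$variant_id), ]          # unique variants, max |lnFC|
  d <- d[order(-d$abs_lnfc, d$variant_id), ]
  if (nrow(d) < top_n) {
    warning("only ", nrow(d), " variants available for top_n = ", top_n)
    top_n <- nrow(d)
  }
  top <- d[seq_len(top_n), ]
  list(variants = top, genes = unique(top$gene[!is.na(top$gene)]))
}

#' Sample control gene sets
#'
#' Draws `n_sets` control sets, each the size of the query, from the
#' background excluding all query genes. In matched mode each query gene is
#' replaced by a background gene whose length and GC content are within the
#' relative tolerance (default +/-10%); when no match exists the tolerance is
#' widened stepwise (x1.5) with a warning.
#'
#' @param query Character vector of query genes.
#' @param background Character vector of background genes (query genes are
#'   excluded automatically).
#' @param n_sets Number of control sets.
#' @param matching `"none"` or `"length_gc"`.
#' @param metrics data.frame with `gene`, `length`, `gc` (matched mode).
#' @param tol Relative tolerance for matched mode.
#' @param seed Seed for reproducible sampling.
#' @return Character matrix, `n_sets` rows x `length(query)` columns.
#' @export
sample_controls <- function(query, background, n_sets = 10000L,
                            matching = c("none", "length_gc"),
                            metrics = NULL, tol = 0.10, seed = 1L) {
  matching <- match.arg(matching)
  pool <- setdiff(background, query)
  assert_that(length(pool) >= length(query),
              "background (minus query) smaller than query")
  set.seed(seed)
  q <- length(query)
  if (matching == "none") {
    out <- t(replicate(n_sets, sample(pool, q)))
    colnames(out) <- query
    return(out)
  }
  assert_that(!is.null(metrics), "matched mode requires gene metrics")
  met <- metrics[match(c(query, pool), metrics$gene), ]
  qm <- met[seq_len(q), ]
  pm <- met[-seq_len(q), ]
  eligible <- lapply(seq_len(q), function(i) {
    t <- tol
    repeat {
      ok <- abs(pm$length - qm$length[i]) <= t * qm$length[i] &
        abs(pm$gc - qm$gc[i]) <= t * qm$gc[i]
      if (any(ok)) return(pool[ok])
      t <- t * 1.5
      warning("no length/GC match for ", query[i],
              "; widening tolerance to ", signif(t, 2))
    }
  })
  out <- t(vapply(seq_len(n_sets), function(s) {
    vapply(eligible, function(e) e[sample.int(length(e), 1)], character(1))
  }, character(q)))
  colnames(out) <- query
  out
}

#' Permutation enrichment of terms in a query gene set
#'
#' For each term, the occurrence k is the number of query genes annotated with
#' it; a normal distribution is fitted to the occurrences of the same term
#' across the control sets and the upper-tail p-value `1 - Phi((k - mu)/sigma)`
#' is reported. When sigma is 0 the add-one empirical p
#' `(r + 1)/(n_sets + 1)` (r = controls with occurrence >= k) is used.
#' BH correction across terms; a term is significant iff FDR < `fdr_cut` and
#' k >= `min_occurrence`. Terms absent from the query and every control set
#' are dropped.
#'
#' @param query Character vector of query genes.
#' @param controls Control matrix from [sample_controls()].
#' @param term_map data.frame with `gene`, `term`.
#' @param fdr_cut Significance FDR threshold (default 0.05).
#' @param min_occurrence Minimum query occurrence (default 5).
#' @return data.frame: `term`, `k`, `mu`, `sigma`, `p`, `fdr`, `significant`.
#' @export
permutation_enrichment <- function(query, controls, term_map,
                                   fdr_cut = 0.05, min_occurrence = 5L) {
  universe <- unique(c(query, as.vector(controls), term_map$gene))
  qi <- match(query, universe)
  ci <- matrix(match(controls, universe), nrow = nrow(controls))
  terms <- sort(unique(term_map$term))
  res <- lapply(terms, function(tm) {
    memb <- logical(length(universe))
    memb[match(unique(term_map$gene[term_map$term == tm]), universe)] <- TRUE
    k <- sum(memb[qi])
    occ <- rowSums(matrix(memb[ci], nrow = nrow(ci)))
    if (k == 0 && all(occ == 0)) return(NULL)
    mu <- mean(occ); s <- sd(occ)
    p <- if (s == 0) (sum(occ >= k) + 1) / (length(occ) + 1)
         else pnorm((k - mu) / s, lower.tail = FALSE)
    data.frame(term = tm, k = k, mu = mu, sigma = s, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    return(data.frame(term = character(0), k = integer(0), mu = numeric(0),
                      sigma = numeric(0), p = numeric(0), fdr = numeric(0),
                      significant = logical(0)))
  }
  res$fdr <- p.adjust(res$p, "BH")
  res$significant <- res$fdr < fdr_cut & res$k >= min_occurrence
  res <- res[order(res$p, res$term), ]
  rownames(res) <- NULL
  res
}

#' Diseases most represented among query genes
#'
#' Ranks disease terms by the number of query genes annotated with them.
#'
#' @param query Character vector of query genes.
#' @param disease_map data.frame with `gene`, `term`.
#' @param top_k Number of diseases to report.
#' @return data.frame with `term`, `n_genes`, ranked.
#' @export
count_disease_representation <- function(query, disease_map, top_k = 10L) {
  d <- disease_map[disease_map$gene %in% query, , drop = FALSE]
  d <- unique(d[, c("gene", "term")])
  if (nrow(d) == 0) {
    return(data.frame(term = character(0), n_genes = integer(0)))
  }
  tab <- sort(table(d$term), decreasing = TRUE)
  out <- data.frame(term = names(tab), n_genes = as.integer(tab),
                    stringsAsFactors = FALSE)
  head(out[order(-out$n_genes, out$term), ], top_k)
}
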