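# Weighted Kolmogorov-Smirnov gene-set enrichment: ranking, running-sum
# enrichment score, gene-label permutation p-value, leading-edge subset.

#' Rank genes by log2 treated/control ratio
#'
#' The ranking metric for each gene is the mean log2 intensity in the
#' treated samples minus the mean in the controls; genes are sorted by
#' descending metric with ties broken alphabetically so the order is
#' deterministic across platforms. Genes with missing values are excluded
#' with a warning.
#'
#' @param expr An [expression_matrix()].
#' @return Tibble with `gene` and `metric`, in ranking order.
#' @export
rank_by_log2_ratio <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  treated <- expr$values[, expr$condition == "treated", drop = FALSE]
  control <- expr$values[, expr$condition == "control", drop = FALSE]
  metric <- rowMeans(treated) - rowMeans(control)
  bad <- !is.finite(metric)
  if (any(bad)) {
    rlang::warn(sprintf("%d gene(s) with missing values excluded.", sum(bad)))
    metric <- metric[!bad]
  }
  ord <- order(-metric, names(metric), method = "radix")
  tibble::tibble(gene = names(metric)[ord], metric = unname(metric[ord]))
}

# Core running-sum computation over a 0/1 hit indicator.
# Weight exponent w: hit steps are |metric|^w normalized over set members;
# a degenerate all-zero weight sum falls back to equal steps.
ks_running_sum <- function(hit, metric, weight_exponent) {
  n <- length(hit)
  m <- sum(hit)
  if (m == 0L) {
    rlang::abort("No gene-set member present in the ranked list.",
                 class = "synlethal_undefined_score_error")
  }
  inc <- numeric(n)
  if (weight_exponent == 0) {
    inc[hit] <- 1 / m
  } else {
    w <- abs(metric[hit])^weight_exponent
    total <- sum(w)
    inc[hit] <- if (total > 0) w / total else 1 / m
  }
  if (m < n) inc[!hit] <- -1 / (n - m)
  cumsum(inc)
}

signed_extremum <- function(rs) {
  hi <- max(rs)
  lo <- min(rs)
  # ties in |extremum| resolve toward the positive deviation
  if (hi >= -lo) hi else lo
}

#' Weighted KS enrichment score and running sum
#'
#' Walks the ranked list accumulating a running sum that rises by the
#' (metric-weighted) hit increment at set members and falls by `1/(N - m)`
#' elsewhere; the enrichment score is the signed maximum deviation from
#' zero, in `[-1, 1]`. With `weight_exponent = 0` this is the classic
#' Kolmogorov-Smirnov statistic; the default `1` weights each hit by its
#' ranking metric, emphasizing sets concentrated among the most regulated
#' genes.
#'
#' @param ranked Tibble from [rank_by_log2_ratio()] (columns `gene`,
#'   `metric`, ranking order).
#' @param geneset Character vector of member symbols.
#' @param weight_exponent Exponent on `|metric|` for hit increments.
#' @return List with `es`, `running_sum` (per position) and `hit`
#'   (logical per position).
#' @export
enrichment_score <- function(ranked, geneset, weight_exponent = 1) {
  geneset <- unique(toupper(geneset))
  hit <- ranked$gene %in% geneset
  rs <- ks_running_sum(hit, ranked$metric, weight_exponent)
  list(es = signed_extremum(rs), running_sum = rs, hit = hit)
}

#' Gene-label permutation p-value for an enrichment score
#'
#' The null keeps the ranking fixed and reassigns set membership uniformly
#' at random (preserving set size); appropriate when the ranking comes from
#' a single treated-vs-control contrast without replicate-level phenotype
#' labels to permute. The p-value is computed against the permuted scores
#' of the same sign as the observed score (the usual GSEA convention — it
#' is what makes null p-values uniform), with an add-one numerator and
#' denominator so p is never zero:
#' `p = (1 + #{same-sign ES_perm at least as extreme}) / (1 + #{same-sign ES_perm})`.
#' The result is fully determined by the seed.
#'
#' @inheritParams enrichment_score
#' @param n_perm Number of permutations.
#' @param seed RNG seed (mandatory; results are reproducible bit-for-bit).
#' @return List with `es`, `p_perm`, `n_perm`, `seed`.
#' @export
permutation_p <- function(ranked, geneset, n_perm = 999, seed,
                          weight_exponent = 1) {
  if (missing(seed)) abort_config("`seed` is required for permutation_p().")
  stopifnot(n_perm >= 1)
  obs <- enrichment_score(ranked, geneset, weight_exponent)
  n <- nrow(ranked)
  m <- sum(obs$hit)
  metric <- ranked$metric
  es_perm <- local_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      hit_b <- logical(n)
      hit_b[sample.int(n, m)] <- TRUE
      signed_extremum(ks_running_sum(hit_b, metric, weight_exponent))
    }, numeric(1))
  })
  if (obs$es >= 0) {
    same_side <- es_perm >= 0
    extreme <- sum(es_perm >= obs$es)
  } else {
    same_side <- es_perm < 0
    extreme <- sum(es_perm <= obs$es)
  }
  list(
    es = obs$es,
    p_perm = (1 + extreme) / (1 + sum(same_side)),
    n_perm = as.integer(n_perm),
    seed = seed
  )
}

#' Leading-edge subset of a gene set
#'
#' For a positive enrichment score, the set members ranked at or before the
#' running-sum maximum; for a negative score, those at or after the
#' minimum. These are the genes that drive the score.
#'
#' @inheritParams enrichment_score
#' @param score Optional result of [enrichment_score()] (recomputed when
#'   omitted).
#' @return Character vector of leading-edge genes, in ranking order.
#' @export
leading_edge <- function(ranked, geneset, score = NULL) {
  if (is.null(score)) score <- enrichment_score(ranked, geneset)
  rs <- score$running_sum
  if (score$es >= 0) {
    cut <- which.max(rs)
    idx <- which(score$hit & seq_along(rs) <= cut)
  } else {
    cut <- which.min(rs)
    idx <- which(score$hit & seq_along(rs) >= cut)
  }
  ranked$gene[idx]
}

#' One-call GSEA of a single gene set
#'
#' Ranks, scores, permutes and extracts the leading edge in one call.
#'
#' @param expr An [expression_matrix()].
#' @param geneset Character vector of member symbols.
#' @param n_perm,seed,weight_exponent See [permutation_p()].
#' @return List of class `gsea_result`: `es`, `p_perm`, `leading_edge`,
#'   `running_sum`, `ranked`, `n_perm`, `seed`.
#' @export
gsea <- function(expr, geneset, n_perm = 999, seed, weight_exponent = 1) {
  ranked <- rank_by_log2_ratio(expr)
  score <- enrichment_score(ranked, geneset, weight_exponent)
  perm <- permutation_p(ranked, geneset, n_perm = n_perm, seed = seed,
                        weight_exponent = weight_exponent)
  structure(
    list(
      es = score$es, p_perm = perm$p_perm,
      leading_edge = leading_edge(ranked, geneset, score),
      running_sum = score$running_sum, ranked = ranked,
      n_perm = perm$n_perm, seed = seed
    ),
    class = "gsea_result"
  )
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("GSEA: ES = %.4f, p = %.4g (%d permutations, seed %s)\n",
              x$es, x$p_perm, x$n_perm, format(x$seed)))
  cat(sprintf("Leading edge: %d gene(s): %s\n", length(x$leading_edge),
              paste(utils::head(x$leading_edge, 10L), collapse = ", ")))
  invisible(x)
}
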