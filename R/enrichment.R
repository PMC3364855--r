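# Hypergeometric over-representation of hit lists against gene-set maps,
# and calibration of an unknown annotation universe from published p-values.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of drawing at
#' least `k` members of a `K`-gene map when sampling `n` genes from a
#' universe of `N`. Computed exactly in log space, stable for `N` up to at
#' least `1e6`. This is the standard over-representation tail, inclusive of
#' the observed overlap.
#'
#' @param N Universe size.
#' @param K Genes in the map.
#' @param n Genes drawn (hits tested).
#' @param k Observed overlap.
#' @return `P(X >= k)`; vectorized over its arguments.
#' @examples
#' hypergeom_tail(10, 4, 3, 2) # 40/120
#' @export
hypergeom_tail <- function(N, K, n, k) {
  args <- vctrs_recycle(N = N, K = K, n = n, k = k)
  with(args, {
    if (any(c(N, K, n, k) != floor(c(N, K, n, k))) || any(c(N, K, n, k) < 0)) {
      abort_domain("N, K, n, k must be non-negative integers.")
    }
    if (any(K > N) || any(n > N)) {
      abort_domain("K and n must not exceed N.")
    }
    if (any(k > pmin(K, n))) {
      abort_domain("k must not exceed min(K, n).")
    }
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  })
}

vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, rep_len, length.out = n)
}

#' Over-representation of a hit list in gene-set maps
#'
#' One row per map with at least one overlapping hit, carrying the
#' hypergeometric counts `(N, K, n, k)` and the upper-tail p-value, sorted
#' by ascending p (ties broken by map name). Maps are intersected with the
#' universe before counting when the universe is a gene list.
#'
#' @param hits Character vector of hit gene symbols.
#' @param maps A `gene_set_collection` (or named list of symbol vectors).
#' @param universe Either a character vector of gene symbols (e.g. the
#'   screened library) or a single integer universe size.
#' @param adjust Add a Benjamini-Hochberg `p_adj` column (off by default;
#'   published map tables typically print raw p).
#' @return Tibble with `map_name`, `K`, `k`, `n`, `N`, `p` (and optionally
#'   `p_adj`).
#' @export
enrich_maps <- function(hits, maps, universe, adjust = FALSE) {
  maps <- as_gene_set_collection(maps)
  hits <- unique(toupper(hits))
  if (length(hits) == 0L) {
    rlang::warn("Empty hit list; returning no enrichment rows.")
    return(tibble::tibble(map_name = character(), K = integer(),
                          k = integer(), n = integer(), N = integer(),
                          p = numeric()))
  }
  if (is.character(universe)) {
    universe <- unique(toupper(universe))
    stray <- setdiff(hits, universe)
    if (length(stray) > 0L) {
      abort_validation(sprintf(
        "Hit(s) outside the universe: %s",
        paste(utils::head(stray, 5L), collapse = ", ")
      ))
    }
    members <- lapply(maps, function(s) intersect(s$genes, universe))
    N <- length(universe)
  } else {
    if (!is.numeric(universe) || length(universe) != 1L) {
      abort_config("`universe` must be a gene vector or a single size.")
    }
    members <- lapply(maps, function(s) s$genes)
    N <- as.integer(universe)
  }
  n <- length(hits)
  rows <- purrr::imap(members, function(genes, nm) {
    K <- length(genes)
    k <- length(intersect(genes, hits))
    if (k == 0L || K == 0L) return(NULL)
    tibble::tibble(map_name = nm, K = K, k = k, n = n, N = N,
                   p = hypergeom_tail(N, K, n, k))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(out)
  out <- dplyr::arrange(out, .data$p, .data$map_name)
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Calibrate the annotation universe behind published enrichment p-values
#'
#' Curated pathway databases test over-representation against their own
#' (often unpublished) gene universe. Given published rows of map size `K`,
#' overlap `k`, hit-list size `n` and printed p-value, this recovers the
#' integer universe `N*` minimizing the sum of squared log10-p deviations
#' between the hypergeometric model and the printed values. Ties go to the
#' smallest `N`.
#'
#' @param rows Data frame with columns `K`, `k`, `n`, `p`.
#' @param n_max Upper search bound for `N`.
#' @return Integer `N*`.
#' @export
calibrate_universe <- function(rows, n_max = 1e5) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1L)
  if (!all(c("K", "k", "n", "p") %in% names(rows))) {
    abort_config("`rows` needs columns K, k, n, p.")
  }
  if (any(rows$p <= 0 | rows$p >= 1)) {
    abort_domain("Printed p-values must lie in (0, 1).")
  }
  if (any(rows$k > pmin(rows$K, rows$n))) {
    abort_domain("Infeasible row: k exceeds min(K, n).")
  }
  n_min <- max(rows$K, rows$n)
  if (n_min > n_max) {
    rlang::abort("No feasible universe size within the search bound.",
                 class = "synlethal_calibration_error")
  }
  Ns <- seq.int(n_min, n_max)
  sse <- numeric(length(Ns))
  for (i in seq_len(nrow(rows))) {
    p_model <- stats::phyper(rows$k[i] - 1, rows$K[i], Ns - rows$K[i],
                             rows$n[i], lower.tail = FALSE)
    sse <- sse + (log10(p_model) - log10(rows$p[i]))^2
  }
  Ns[which.min(sse)]
}

#' Leave-one-out prediction of a published enrichment p-value
#'
#' Calibrates the universe on all rows except `held_out`, then evaluates
#' the hypergeometric tail for the held-out row's counts at the calibrated
#' `N*`. Agreement with the printed value validates both the calibration
#' and the enrichment model.
#'
#' @param rows Data frame with columns `K`, `k`, `n`, `p`.
#' @param held_out Row index to hold out.
#' @param n_max Upper search bound for `N`.
#' @return List with `N_star`, `p_pred` and `p_printed`.
#' @export
loo_predict <- function(rows, held_out, n_max = 1e5) {
  stopifnot(held_out >= 1L, held_out <= nrow(rows), nrow(rows) >= 2L)
  N_star <- calibrate_universe(rows[-held_out, , drop = FALSE], n_max = n_max)
  r <- rows[held_out, ]
  list(
    N_star = N_star,
    p_pred = hypergeom_tail(N_star, r$K, r$n, r$k),
    p_printed = r$p
  )
}
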