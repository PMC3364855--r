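# Viability normalization, siRNA-by-drug interaction ratios, enhancer hit
# calling, the three-round screening funnel, and qPCR knockdown checks.

#' Normalize well signals to the untreated control of the same plate
#'
#' Relative viability `v_rel` of each (gene, siRNA, dose) condition is the
#' mean replicate signal divided by the mean untreated-control signal on the
#' same plate, so plate-to-plate scale differences cancel. When a condition
#' appears on several plates the per-plate ratios are combined by a
#' replicate-weighted mean.
#'
#' @param wells Tibble of well measurements as returned by
#'   [read_plate_table()] or [simulate_screen()].
#' @param untreated_tag Gene tag of the untreated control wells.
#' @return Tibble with `gene`, `sirna_id`, `dose`, `v_rel`, `sd`, `n_rep`.
#'   Control pseudo-genes (e.g. `SCRAMBLE`) are retained as rows so that
#'   downstream ratio computations can use them.
#' @export
normalize_viability <- function(wells, untreated_tag = "UNTREATED") {
  stopifnot(is.data.frame(wells))
  plates <- unique(wells$plate_id)
  ctrl <- wells |>
    dplyr::filter(.data$gene == untreated_tag) |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::summarise(ctrl_mean = mean(.data$signal), .groups = "drop")
  missing_ctrl <- setdiff(plates, ctrl$plate_id)
  if (length(missing_ctrl) > 0L) {
    abort_validation(sprintf(
      "No untreated control wells on plate(s): %s",
      paste(utils::head(missing_ctrl, 5L), collapse = ", ")
    ))
  }
  bad <- ctrl$plate_id[!is.finite(ctrl$ctrl_mean) | ctrl$ctrl_mean <= 0]
  if (length(bad) > 0L) {
    abort_domain(sprintf(
      "Untreated control mean is zero or non-finite on plate(s): %s",
      paste(utils::head(bad, 5L), collapse = ", ")
    ))
  }
  per_plate <- wells |>
    dplyr::left_join(ctrl, by = "plate_id") |>
    dplyr::group_by(.data$plate_id, .data$gene, .data$sirna_id, .data$dose) |>
    dplyr::summarise(
      v_rel = mean(.data$signal) / .data$ctrl_mean[1],
      sd = stats::sd(.data$signal) / .data$ctrl_mean[1],
      n_rep = dplyr::n(),
      .groups = "drop"
    )
  per_plate$sd[is.na(per_plate$sd)] <- 0
  per_plate |>
    dplyr::group_by(.data$gene, .data$sirna_id, .data$dose) |>
    dplyr::summarise(
      v_rel = stats::weighted.mean(.data$v_rel, .data$n_rep),
      sd = sqrt(stats::weighted.mean(.data$sd^2, .data$n_rep)),
      n_rep = sum(.data$n_rep),
      .groups = "drop"
    )
}

#' Interaction ratio of an siRNA with the drug
#'
#' The default `"interaction"` mode compares the observed combined growth to
#' a multiplicative (Bliss-style) null built from the siRNA-alone and
#' drug-alone effects:
#' \deqn{r(g,d) = \frac{v(g,d)/v(g,0)}{v(ctrl,d)/v(ctrl,0)}}
#' where `ctrl` is the scrambled-siRNA control. A ratio below 1 means the
#' knockdown potentiates the drug beyond what either single effect predicts.
#' The `"simple"` mode is the plain within-gene fold `v(g,d)/v(g,0)`.
#'
#' Ratios are undefined (NA, `flagged`) when any denominator is missing or
#' non-positive — including total-kill wells with `v_rel = 0`.
#'
#' @param nv Normalized viability tibble from [normalize_viability()].
#' @param mode `"interaction"` (default) or `"simple"`.
#' @param control_gene Pseudo-gene holding the drug-alone response
#'   (scrambled-siRNA wells).
#' @param exclude Tags never treated as screened genes.
#' @return Tibble with `gene`, `sirna_id`, `dose` (nonzero), `ratio`,
#'   `flagged`.
#' @export
enhancer_ratio <- function(nv, mode = c("interaction", "simple"),
                           control_gene = "SCRAMBLE",
                           exclude = c("UNTREATED", "DRUG_ONLY")) {
  mode <- match.arg(mode)
  ctrl <- nv |> dplyr::filter(.data$gene == control_gene)
  ctrl_by_dose <- stats::setNames(ctrl$v_rel, format(ctrl$dose, digits = 15))
  ctrl0 <- ctrl$v_rel[ctrl$dose == 0]
  ctrl0 <- if (length(ctrl0) == 1L) ctrl0 else NA_real_

  genes <- nv |>
    dplyr::filter(!.data$gene %in% c(control_gene, exclude))
  base <- genes |>
    dplyr::filter(.data$dose == 0) |>
    dplyr::select("gene", "sirna_id", v0 = "v_rel")
  out <- genes |>
    dplyr::filter(.data$dose > 0) |>
    dplyr::left_join(base, by = c("gene", "sirna_id")) |>
    dplyr::mutate(
      ctrl_d = unname(ctrl_by_dose[format(.data$dose, digits = 15)]),
      ratio = if (mode == "interaction") {
        (.data$v_rel / .data$v0) / (.data$ctrl_d / ctrl0)
      } else {
        .data$v_rel / .data$v0
      },
      flagged =
        is.na(.data$v0) | .data$v0 <= 0 |
        (mode == "interaction" &
           (is.na(.data$ctrl_d) | .data$ctrl_d <= 0 |
              is.na(ctrl0) | ctrl0 <= 0))
    ) |>
    dplyr::mutate(ratio = ifelse(.data$flagged, NA_real_, .data$ratio)) |>
    dplyr::select("gene", "sirna_id", "dose", "ratio", "flagged") |>
    dplyr::arrange(.data$gene, .data$sirna_id, .data$dose)
  out
}

#' Call enhancer genes from interaction ratios
#'
#' A dose "passes" when the gene-level interaction ratio is at or below
#' `threshold` (the criterion is inclusive: r = 0.8 is a hit at the default
#' threshold). Per-gene ratios collapse the gene's siRNAs with `sirna_rule`:
#' `"any"` keeps the most potentiating reagent (minimum ratio per dose),
#' `"both"` requires every reagent to pass (maximum ratio per dose). The
#' `dose_rule` then decides the gene call: `"any"` (default — a hit at any
#' one dose), `"all"`, or `"min_k"` (at least `min_k` doses).
#'
#' @param ratios Tibble from [enhancer_ratio()].
#' @param round_id Integer screen-round label carried into the calls.
#' @param threshold Hit criterion on the ratio, in (0, 1].
#' @param dose_rule,min_k,sirna_rule Call-collapsing rules (see above).
#' @return Tibble with `gene`, `round_id`, list-columns `ratios` (named by
#'   dose) and `passed_doses`, and `is_hit`.
#' @export
call_enhancers <- function(ratios, round_id = 1L, threshold = 0.8,
                           dose_rule = c("any", "all", "min_k"), min_k = 2L,
                           sirna_rule = c("any", "both")) {
  dose_rule <- match.arg(dose_rule)
  sirna_rule <- match.arg(sirna_rule)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    abort_config("`threshold` must be a single number in (0, 1].")
  }
  collapse <- if (sirna_rule == "any") min else max
  usable <- dplyr::filter(ratios, !.data$flagged)
  if (nrow(usable) == 0L) {
    return(tibble::tibble(gene = character(), round_id = integer(),
                          ratios = list(), passed_doses = list(),
                          is_hit = logical()))
  }
  gene_ratios <- usable |>
    dplyr::group_by(.data$gene, .data$dose) |>
    dplyr::summarise(ratio = collapse(.data$ratio), .groups = "drop")
  n_doses <- length(unique(ratios$dose))
  calls <- gene_ratios |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      ratios = list(stats::setNames(.data$ratio, .data$dose)),
      passed_doses = list(.data$dose[.data$ratio <= threshold]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      round_id = as.integer(round_id),
      is_hit = vapply(.data$passed_doses, function(p) {
        switch(dose_rule,
          any = length(p) >= 1L,
          all = length(p) == n_doses,
          min_k = length(p) >= min_k
        )
      }, logical(1))
    ) |>
    dplyr::select("gene", "round_id", "ratios", "passed_doses", "is_hit") |>
    dplyr::arrange(.data$gene)
  calls
}

#' Run the multi-round enhancer-screen funnel
#'
#' Candidate genes are re-screened with independent siRNA reagents in
#' successive rounds; only genes called in every round survive. Later rounds
#' must be measured on (a subset of) the previous round's hits — the funnel
#' is a cascade, and the hit lists are nested by construction.
#'
#' @param ratio_tables List of per-round ratio tibbles (round 1 first), each
#'   as returned by [enhancer_ratio()].
#' @param threshold,dose_rule,min_k,sirna_rule Passed to [call_enhancers()].
#' @return A list of class `funnel_result` with `calls` (per-round call
#'   tibbles), `hits` (per-round hit gene vectors) and `final_hits`.
#' @export
run_funnel <- function(ratio_tables, threshold = 0.8,
                       dose_rule = "any", min_k = 2L, sirna_rule = "any") {
  stopifnot(is.list(ratio_tables), length(ratio_tables) >= 1L)
  calls <- vector("list", length(ratio_tables))
  hits <- vector("list", length(ratio_tables))
  for (i in seq_along(ratio_tables)) {
    if (i > 1L) {
      measured <- unique(ratio_tables[[i]]$gene)
      stray <- setdiff(measured, hits[[i - 1L]])
      if (length(stray) > 0L) {
        abort_validation(sprintf(
          "Round %d measures gene(s) that were not round-%d hits: %s",
          i, i - 1L, paste(utils::head(stray, 5L), collapse = ", ")
        ))
      }
    }
    calls[[i]] <- call_enhancers(
      ratio_tables[[i]], round_id = i, threshold = threshold,
      dose_rule = dose_rule, min_k = min_k, sirna_rule = sirna_rule
    )
    hits[[i]] <- calls[[i]]$gene[calls[[i]]$is_hit]
  }
  structure(
    list(calls = calls, hits = hits,
         final_hits = sort(Reduce(intersect, hits))),
    class = "funnel_result"
  )
}

#' @export
print.funnel_result <- function(x, ...) {
  cat("Enhancer-screen funnel:", length(x$hits), "rounds\n")
  for (i in seq_along(x$hits)) {
    cat(sprintf("  round %d: %d hit(s)\n", i, length(x$hits[[i]])))
  }
  cat("  final:", length(x$final_hits), "gene(s):",
      paste(utils::head(x$final_hits, 12L), collapse = ", "), "\n")
  invisible(x)
}

#' Relative expression by the comparative threshold-cycle method
#'
#' Computes `2^-ddCT` with
#' `ddCT = (CT_target,case - CT_ref,case) - (CT_target,ctrl - CT_ref,ctrl)`,
#' the standard relative quantification of a target transcript against a
#' reference gene and a control condition. Used to confirm siRNA knockdown.
#'
#' @param ct_target_case,ct_ref_case,ct_target_ctrl,ct_ref_ctrl CT values
#'   (vectors recycle).
#' @return Fold expression of the target in the case condition.
#' @examples
#' ddct_fold_expression(25, 20, 22, 20) # 0.125
#' @export
ddct_fold_expression <- function(ct_target_case, ct_ref_case,
                                 ct_target_ctrl, ct_ref_ctrl) {
  args <- list(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl)
  if (!all(vapply(args, function(a) all(is.finite(a)), logical(1)))) {
    abort_domain("All CT values must be finite.")
  }
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}

#' Knockdown fold change from a replicated CT table
#'
#' Averages CT values per (condition, gene) and applies
#' [ddct_fold_expression()].
#'
#' @param ct_table Tibble with `condition` ("treated"/"control"), `gene`,
#'   `ct` (and optionally `replicate`).
#' @param target,reference Gene labels of the target and reference assays.
#' @return Single fold-expression value.
#' @export
ddct_fold_from_table <- function(ct_table, target = "TARGET",
                                 reference = "REF") {
  mean_ct <- function(cond, g) {
    v <- ct_table$ct[ct_table$condition == cond & ct_table$gene == g]
    if (length(v) == 0L) {
      abort_validation(sprintf("No CT rows for %s / %s.", cond, g))
    }
    mean(v)
  }
  ddct_fold_expression(
    mean_ct("treated", target), mean_ct("treated", reference),
    mean_ct("control", target), mean_ct("control", reference)
  )
}
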