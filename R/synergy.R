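# Median-effect dose-response model, Dx inversion, Chou-Talalay combination
# index and normalized isobolograms.

#' Fit the median-effect dose-response model
#'
#' The median-effect equation `fa/(1-fa) = (D/Dm)^m` is linear in log-log
#' coordinates: `log10(fa/(1-fa)) = m*log10(D) - m*log10(Dm)`. The fit is
#' unweighted least squares on that linearized plot (the classical
#' procedure), giving slope `m` (sigmoidicity) and `Dm`, the dose for half
#' effect — the model-based IC50.
#'
#' Observed fractions affected outside `[0.01, 0.99]` are excluded from
#' fitting rather than clipped: near the boundaries the log-odds transform
#' amplifies measurement error without bound, and clipped points would
#' dominate the least squares. Exclusions are reported via a message.
#'
#' @param dose Doses (uM, all positive).
#' @param fa Fractions affected in `[0, 1]` (fa = 1 - relative viability).
#' @return Object of class `median_effect_fit`: `Dm`, `m`, `r2`,
#'   `n_points`, `n_excluded`.
#' @examples
#' median_effect_fit(c(1, 2, 4), c(1/3, 0.5, 2/3)) # Dm = 2, m = 1
#' @export
median_effect_fit <- function(dose, fa) {
  if (is.data.frame(dose)) {
    fa <- dose$fa
    dose <- dose$dose
  }
  stopifnot(length(dose) == length(fa))
  if (any(dose <= 0)) abort_domain("Doses must be strictly positive for fitting.")
  if (any(fa < 0 | fa > 1)) abort_domain("fa must lie in [0, 1].")
  usable <- fa >= 0.01 & fa <= 0.99
  if (sum(!usable) > 0L) {
    message(sprintf(
      "%d point(s) with fa outside [0.01, 0.99] excluded from the median-effect fit.",
      sum(!usable)
    ))
  }
  dose <- dose[usable]
  fa <- fa[usable]
  if (length(dose) < 2L) {
    rlang::abort("Fewer than 2 usable points for the median-effect fit.",
                 class = "synlethal_fit_error")
  }
  x <- log10(dose)
  y <- log10(fa / (1 - fa))
  fit <- stats::lm(y ~ x)
  m <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  if (!is.finite(m) || m <= 0) {
    rlang::warn("Non-positive median-effect slope; dose-response is not monotone increasing.")
  }
  tss <- sum((y - mean(y))^2)
  r2 <- if (length(dose) == 2L || tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  structure(
    list(Dm = 10^(-b / m), m = m, r2 = r2,
         n_points = length(dose), n_excluded = sum(!usable)),
    class = "median_effect_fit"
  )
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat(sprintf("Median-effect fit: Dm = %.4g uM, m = %.4g, r2 = %.4f (%d points)\n",
              x$Dm, x$m, x$r2, x$n_points))
  invisible(x)
}

as_me_fit <- function(fit) {
  if (inherits(fit, "median_effect_fit")) return(fit)
  if (is.list(fit) && all(c("Dm", "m") %in% names(fit))) {
    return(structure(list(Dm = fit$Dm, m = fit$m, r2 = NA_real_,
                          n_points = NA_integer_, n_excluded = 0L),
                     class = "median_effect_fit"))
  }
  abort_config("Expected a median_effect_fit or a list with Dm and m.")
}

#' Dose producing a given effect level
#'
#' Inverts the median-effect model: `Dx = Dm * (fa/(1-fa))^(1/m)` is the
#' single-agent dose producing fraction affected `fa`.
#'
#' @param fit A [median_effect_fit()] (or list with `Dm`, `m`).
#' @param fa Effect level(s) in (0, 1).
#' @return Dose(s), same unit as the fit.
#' @export
dose_for_effect <- function(fit, fa) {
  fit <- as_me_fit(fit)
  if (any(fa <= 0 | fa >= 1)) abort_domain("fa must lie strictly in (0, 1).")
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Effect level at a given dose
#'
#' Forward median-effect model: `fa = (D/Dm)^m / (1 + (D/Dm)^m)`.
#'
#' @inheritParams dose_for_effect
#' @param dose Dose(s) > 0.
#' @return Fraction(s) affected in (0, 1).
#' @export
effect_at_dose <- function(fit, dose) {
  fit <- as_me_fit(fit)
  if (any(dose <= 0)) abort_domain("Dose must be strictly positive.")
  r <- (dose / fit$Dm)^fit$m
  r / (1 + r)
}

classify_ci <- function(ci, additive_band) {
  dplyr::case_when(
    abs(ci - 1) <= additive_band ~ "additive",
    ci < 1 ~ "synergy",
    TRUE ~ "antagonism"
  )
}

#' Chou-Talalay combination index at measured combination points
#'
#' For each combination `(d1, d2)` with observed fraction affected `fa`,
#' the combination index is
#' \deqn{CI = d_1 / Dx_1(fa) + d_2 / Dx_2(fa)}
#' where `Dx_i(fa)` is the dose of drug i alone producing the same effect
#' under its median-effect fit. CI < 1 indicates synergy (less drug needed
#' than Loewe additivity predicts), CI = 1 additivity, CI > 1 antagonism.
#' Each point is evaluated at its own measured `fa` (the
#' mutually-exclusive-drugs form). Points with fa at 0 or 1 are rejected,
#' not silently clipped.
#'
#' @param combos Data frame with columns `d1`, `d2`, `fa`.
#' @param fit1,fit2 Median-effect fits for the two single agents.
#' @param additive_band Half-width of the reporting band around CI = 1
#'   labelled "additive" (a reporting convention only).
#' @return Tibble with `d1`, `d2`, `fa`, `dx1`, `dx2`, `ci`, `class_label`.
#' @export
combination_index <- function(combos, fit1, fit2, additive_band = 0.05) {
  stopifnot(is.data.frame(combos),
            all(c("d1", "d2", "fa") %in% names(combos)))
  if (any(combos$d1 < 0 | combos$d2 < 0 | (combos$d1 == 0 & combos$d2 == 0))) {
    abort_domain("Combination doses must be non-negative and not both zero.")
  }
  deg <- which(combos$fa <= 0 | combos$fa >= 1)
  if (length(deg) > 0L) {
    abort_domain(sprintf(
      "fa at or beyond 0/1 leaves CI undefined (row(s) %s); remove or re-measure.",
      paste(utils::head(deg, 5L), collapse = ", ")
    ))
  }
  dx1 <- dose_for_effect(fit1, combos$fa)
  dx2 <- dose_for_effect(fit2, combos$fa)
  ci <- combos$d1 / dx1 + combos$d2 / dx2
  tibble::tibble(
    d1 = combos$d1, d2 = combos$d2, fa = combos$fa,
    dx1 = dx1, dx2 = dx2, ci = ci,
    class_label = classify_ci(ci, additive_band)
  )
}

#' Normalized isobologram coordinates
#'
#' Maps each combination point to `(x, y) = (d1/Dx1, d2/Dx2)`, the two
#' addends of its combination index. The diagonal `x + y = 1` is the Loewe
#' additivity line; synergistic points fall inside it, toward the origin.
#'
#' @param combos Data frame with `d1`, `d2`, `fa` (or the output of
#'   [combination_index()]).
#' @inheritParams combination_index
#' @return Tibble with `x`, `y`, `ci`, `class_label`.
#' @export
normalized_isobologram <- function(combos, fit1 = NULL, fit2 = NULL,
                                   additive_band = 0.05) {
  if (!all(c("dx1", "dx2", "ci") %in% names(combos))) {
    combos <- combination_index(combos, fit1, fit2, additive_band)
  }
  tibble::tibble(
    x = combos$d1 / combos$dx1,
    y = combos$d2 / combos$dx2,
    ci = combos$ci,
    class_label = combos$class_label
  )
}

#' IC50 from a single-agent dose grid
#'
#' The model IC50 is the `Dm` of the median-effect fit. For comparison a
#' model-free estimate is also reported: linear interpolation of fa against
#' log10 dose between the two grid points bracketing fa = 0.5 (NA when the
#' grid never crosses half effect).
#'
#' @param dose Doses (uM, positive).
#' @param fa Fractions affected.
#' @return List with `ic50_model`, `ic50_interp`, `fit`.
#' @export
ic50_from_grid <- function(dose, fa) {
  fit <- median_effect_fit(dose, fa)
  ord <- order(dose)
  d <- dose[ord]
  f <- fa[ord]
  ic50_interp <- NA_real_
  cross <- which(diff(f >= 0.5) != 0)
  if (any(f == 0.5)) {
    ic50_interp <- d[which(f == 0.5)[1]]
  } else if (length(cross) > 0L) {
    i <- cross[1]
    lx <- log10(d[i]) +
      (0.5 - f[i]) * (log10(d[i + 1]) - log10(d[i])) / (f[i + 1] - f[i])
    ic50_interp <- 10^lx
  }
  list(ic50_model = fit$Dm, ic50_interp = ic50_interp, fit = fit)
}
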