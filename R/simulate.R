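# Simulators with planted ground truth for every input the pipeline
# consumes: plate-format enhancer screens, drug-combination response
# surfaces, expression matrices and qPCR CT tables. Every generator is a
# pure function of (configuration, seed).

#' Configuration of a simulated enhancer screen
#'
#' Defaults emulate the geometry of a 418-gene apoptosis siRNA library
#' screened in triplicate with 2 siRNAs per gene against a topoisomerase-I
#' inhibitor: rounds 1-2 at drug doses \{0, 1, 5, 10\} uM, a confirmatory
#' round 3 at \{0, 0.01, 0.1, 1\} uM, and nine planted enhancer genes.
#' Planted enhancers multiply viability by `enhancer_interaction` (< 1)
#' beyond the product of the single effects, at the top `enhancer_doses`
#' nonzero doses of each round's grid. The drug-alone effect follows a
#' median-effect curve with `drug_dm` (uM) and slope `drug_m`; per-siRNA
#' knockdown toxicity is drawn uniformly from `knockdown_range`. Well noise
#' is multiplicative log-normal with log-scale `noise_sd`, matching the
#' positive support of luminescence readouts.
#'
#' @param seed RNG seed (mandatory).
#' @param n_genes,sirnas_per_gene,n_rep Library geometry.
#' @param dose_grids List of per-round dose grids (each starts at 0,
#'   strictly increasing).
#' @param planted_enhancers Explicit enhancer gene names, or `NULL` to
#'   sample `n_enhancers` from the library.
#' @param n_enhancers Number of planted enhancers when sampling.
#' @param enhancer_interaction Interaction multiplier in (0, 1] applied at
#'   affected doses.
#' @param enhancer_doses How many of the largest nonzero doses the planted
#'   interaction affects.
#' @param knockdown_range Range of the per-siRNA viability multiplier.
#' @param drug_dm,drug_m Median-effect parameters of the drug-alone curve.
#' @param baseline Mean untreated luminescence signal (arbitrary units).
#' @param noise_sd Log-scale standard deviation of well noise.
#' @return List of class `screen_sim_config`.
#' @export
screen_sim_config <- function(seed, n_genes = 418L, sirnas_per_gene = 2L,
                              n_rep = 3L,
                              dose_grids = list(c(0, 1, 5, 10),
                                                c(0, 1, 5, 10),
                                                c(0, 0.01, 0.1, 1)),
                              planted_enhancers = NULL, n_enhancers = 9L,
                              enhancer_interaction = 0.6,
                              enhancer_doses = 2L,
                              knockdown_range = c(0.7, 1),
                              drug_dm = 2, drug_m = 1,
                              baseline = 5e4, noise_sd = 0.1) {
  if (missing(seed)) abort_config("A `seed` is mandatory for simulation.")
  for (g in dose_grids) {
    if (length(g) < 2L || g[1] != 0 || any(diff(g) <= 0)) {
      abort_config("Each dose grid must start at 0 and be strictly increasing (>= 2 entries).")
    }
  }
  if (enhancer_interaction <= 0 || enhancer_interaction > 1) {
    abort_config("`enhancer_interaction` must lie in (0, 1].")
  }
  genes <- sprintf("G%04d", seq_len(n_genes))
  enhancers <- local_seed(seed, {
    if (is.null(planted_enhancers)) {
      sort(sample(genes, n_enhancers))
    } else {
      pe <- toupper(planted_enhancers)
      if (!all(pe %in% genes)) abort_config("Planted enhancers must be library genes.")
      sort(pe)
    }
  })
  structure(
    list(seed = seed, n_genes = as.integer(n_genes),
         sirnas_per_gene = as.integer(sirnas_per_gene),
         n_rep = as.integer(n_rep), dose_grids = dose_grids,
         genes = genes, enhancers = enhancers,
         enhancer_interaction = enhancer_interaction,
         enhancer_doses = as.integer(enhancer_doses),
         knockdown_range = knockdown_range,
         drug_dm = drug_dm, drug_m = drug_m,
         baseline = baseline, noise_sd = noise_sd),
    class = "screen_sim_config"
  )
}

drug_viability <- function(config, dose) {
  # drug-alone relative viability from the median-effect curve
  ifelse(dose == 0, 1, 1 / (1 + (dose / config$drug_dm)^config$drug_m))
}

interaction_effect <- function(config, gene, dose, grid) {
  top <- utils::tail(setdiff(grid, 0), config$enhancer_doses)
  ifelse(gene %in% config$enhancers & dose %in% top,
         config$enhancer_interaction, 1)
}

#' Simulate one round of a plate-format enhancer screen
#'
#' Generates well-level luminescence signals
#' `baseline * knockdown(g, siRNA) * drug(d) * i(g, d) * exp(noise)`
#' with `i(g, d) = 1` for non-enhancer genes, laid out on 96-well plates
#' (8 rows x 12 columns). Column 1 of every plate is reserved for controls:
#' untreated wells (no siRNA, no drug), scrambled-siRNA wells at the
#' plate's dose and drug-only wells at the plate's dose. Each plate carries
#' one dose; a condition's replicates share a plate.
#'
#' @param config A [screen_sim_config()].
#' @param round_id Which round's dose grid and siRNA set to use.
#' @param genes Genes to screen this round (default: the full library).
#' @return List with `wells` (a well-measurement tibble as
#'   [read_plate_table()] would return) and `truth` (planted enhancers,
#'   per-siRNA knockdown effects, drug-alone curve, interaction table).
#' @export
simulate_screen <- function(config, round_id = 1L, genes = NULL) {
  stopifnot(inherits(config, "screen_sim_config"))
  genes <- genes %||% config$genes
  grid <- config$dose_grids[[round_id]]
  n_rep <- config$n_rep

  pairs <- tidyr::expand_grid(
    gene = genes,
    sirna_idx = seq_len(config$sirnas_per_gene)
  ) |>
    dplyr::mutate(sirna_id = sprintf("si-%s-r%d%s", .data$gene, round_id,
                                     letters[.data$sirna_idx]))

  local_seed(config$seed + 1000L * round_id, {
    kd <- stats::setNames(
      stats::runif(nrow(pairs), config$knockdown_range[1], config$knockdown_range[2]),
      pairs$sirna_id
    )

    # 8 control wells in column 1; 88 sample wells hold 88 %/% n_rep conditions
    per_plate <- max(1L, 88L %/% n_rep)
    chunk <- ceiling(seq_len(nrow(pairs)) / per_plate)

    make_plate <- function(pair_block, dose, plate_id) {
      n_cond <- nrow(pair_block)
      # sample wells: columns 2..12, filled row-major, n_rep wells per condition
      slots <- seq_len(n_cond * n_rep)
      row <- LETTERS[((slots - 1L) %/% 11L) + 1L]
      col <- ((slots - 1L) %% 11L) + 2L
      smp <- tibble::tibble(
        plate_id = plate_id,
        well = sprintf("%s%02d", row, col),
        gene = rep(pair_block$gene, each = n_rep),
        sirna_id = rep(pair_block$sirna_id, each = n_rep),
        dose = dose,
        replicate = rep(seq_len(n_rep), times = n_cond)
      )
      ctrl <- tibble::tibble(
        plate_id = plate_id,
        well = sprintf("%s01", LETTERS[1:8]),
        gene = c(rep("UNTREATED", 3), rep("SCRAMBLE", 3), rep("DRUG_ONLY", 2)),
        sirna_id = NA_character_,
        dose = c(rep(0, 3), rep(dose, 5)),
        replicate = c(1:3, 1:3, 1:2)
      )
      dplyr::bind_rows(ctrl, smp)
    }

    blocks <- split(pairs, chunk)
    layout <- purrr::imap(blocks, function(block, bi) {
      purrr::imap(grid, function(dose, di) {
        make_plate(block, dose,
                   sprintf("R%d_D%02d_P%03d", round_id, di, as.integer(bi)))
      })
    })
    wells <- dplyr::bind_rows(purrr::flatten(layout))

    kd_w <- ifelse(is.na(wells$sirna_id), 1, kd[wells$sirna_id])
    kd_w[wells$gene == "UNTREATED"] <- 1
    drug_w <- drug_viability(config, wells$dose)
    int_w <- interaction_effect(config, wells$gene, wells$dose, grid)
    eps <- if (config$noise_sd > 0) {
      stats::rnorm(nrow(wells), 0, config$noise_sd)
    } else {
      0
    }
    wells$signal <- config$baseline * kd_w * drug_w * int_w * exp(eps)
    wells$is_control <- wells$gene %in% c("UNTREATED", "SCRAMBLE", "DRUG_ONLY")

    truth <- list(
      enhancers = config$enhancers,
      interaction = tidyr::expand_grid(gene = config$enhancers, dose = setdiff(grid, 0)) |>
        dplyr::mutate(i = interaction_effect(config, .data$gene, .data$dose, grid)),
      knockdown = tibble::tibble(sirna_id = names(kd), effect = unname(kd)),
      drug = tibble::tibble(dose = grid, v_rel = drug_viability(config, grid)),
      config = config
    )
    list(wells = wells, truth = truth)
  })
}

#' Simulate and analyse a full three-round screening funnel
#'
#' Rounds are sequential by construction: round 1 screens the full library,
#' each later round is simulated only for the previous round's called hits
#' (with fresh siRNA reagents), mirroring how a confirmatory cascade is
#' actually run. Hit calling between rounds uses the supplied criterion.
#'
#' @param config A [screen_sim_config()].
#' @param threshold,dose_rule,min_k,sirna_rule,ratio_mode Hit-calling
#'   parameters (see [call_enhancers()] and [enhancer_ratio()]).
#' @return List with `rounds` (per-round simulations), `ratio_tables`,
#'   `funnel` (a [run_funnel()] result) and `truth`.
#' @export
simulate_screen_funnel <- function(config, threshold = 0.8,
                                   dose_rule = "any", min_k = 2L,
                                   sirna_rule = "any",
                                   ratio_mode = "interaction") {
  stopifnot(inherits(config, "screen_sim_config"))
  n_rounds <- length(config$dose_grids)
  rounds <- vector("list", n_rounds)
  ratio_tables <- vector("list", n_rounds)
  genes <- config$genes
  for (r in seq_len(n_rounds)) {
    if (length(genes) == 0L) {
      rounds <- rounds[seq_len(r - 1L)]
      ratio_tables <- ratio_tables[seq_len(r - 1L)]
      break
    }
    rounds[[r]] <- simulate_screen(config, round_id = r, genes = genes)
    nv <- normalize_viability(rounds[[r]]$wells)
    ratio_tables[[r]] <- enhancer_ratio(nv, mode = ratio_mode)
    calls <- call_enhancers(ratio_tables[[r]], round_id = r,
                            threshold = threshold, dose_rule = dose_rule,
                            min_k = min_k, sirna_rule = sirna_rule)
    genes <- calls$gene[calls$is_hit]
  }
  funnel <- run_funnel(ratio_tables, threshold = threshold,
                       dose_rule = dose_rule, min_k = min_k,
                       sirna_rule = sirna_rule)
  list(rounds = rounds, ratio_tables = ratio_tables, funnel = funnel,
       truth = rounds[[1]]$truth)
}

#' Simulate a drug-combination response surface with known combination index
#'
#' For each grid point `(d1, d2)` the generated fraction affected solves
#' `d1/Dx1(fa) + d2/Dx2(fa) = planted_ci` by bracketed monotone
#' root-finding, so the surface obeys (planted_ci = 1) or deliberately
#' violates Loewe additivity by a known amount. Optional multiplicative
#' noise is applied on the relative-viability scale.
#'
#' @param fit1,fit2 Median-effect parameters of the single agents
#'   ([median_effect_fit()] objects or lists with `Dm`, `m`).
#' @param planted_ci The combination index every grid point should carry.
#' @param grid Data frame with columns `d1`, `d2` (both > 0).
#' @param noise_sd Log-scale sd of multiplicative noise on viability.
#' @param seed RNG seed (required when `noise_sd > 0`).
#' @return List with `combos` (tibble `d1`, `d2`, `fa`) and `truth`.
#' @export
simulate_combo <- function(fit1, fit2, planted_ci, grid, noise_sd = 0,
                           seed = NULL) {
  fit1 <- as_me_fit(fit1)
  fit2 <- as_me_fit(fit2)
  stopifnot(is.data.frame(grid), all(c("d1", "d2") %in% names(grid)))
  if (planted_ci <= 0) abort_config("`planted_ci` must be positive.")
  if (noise_sd > 0 && is.null(seed)) {
    abort_config("A `seed` is required when noise_sd > 0.")
  }
  solve_fa <- function(d1, d2) {
    f <- function(fa) {
      d1 / dose_for_effect(fit1, fa) + d2 / dose_for_effect(fit2, fa) - planted_ci
    }
    lo <- 1e-9
    hi <- 1 - 1e-9
    if (f(lo) < 0 || f(hi) > 0) return(NA_real_)
    stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
  }
  fa <- purrr::map2_dbl(grid$d1, grid$d2, solve_fa)
  dropped <- is.na(fa)
  if (any(dropped)) {
    rlang::warn(sprintf(
      "%d grid point(s) admit no effect level at the planted CI; dropped.",
      sum(dropped)
    ))
  }
  combos <- tibble::tibble(d1 = grid$d1[!dropped], d2 = grid$d2[!dropped],
                           fa = fa[!dropped])
  if (noise_sd > 0) {
    combos$fa <- local_seed(seed, {
      v <- (1 - combos$fa) * exp(stats::rnorm(nrow(combos), 0, noise_sd))
      pmin(pmax(1 - v, 0), 1)
    })
  }
  list(
    combos = combos,
    truth = list(planted_ci = planted_ci, fit1 = fit1, fit2 = fit2,
                 noise_sd = noise_sd, seed = seed)
  )
}

#' Simulate a log2 expression matrix with a planted up-regulated gene set
#'
#' Per-gene baseline log2 intensities are drawn once, control samples add
#' Gaussian noise around them, and treated samples additionally shift the
#' planted set by `log2_shift`. With `log2_shift = 0` the generator is an
#' exact null for enrichment testing.
#'
#' @param n_genes Number of genes.
#' @param set_size Size of the planted set.
#' @param log2_shift Mean treated-minus-control shift of the planted set.
#' @param n_samples Samples per condition.
#' @param noise_sd Per-observation Gaussian sd on the log2 scale.
#' @param seed RNG seed (mandatory).
#' @param baseline_mean,baseline_sd Distribution of per-gene baselines.
#' @return List with `expr` (an [expression_matrix()]) and `truth`
#'   (planted set members and shift).
#' @export
simulate_expression <- function(n_genes = 2000L, set_size = 50L,
                                log2_shift = 1, n_samples = 3L,
                                noise_sd = 0.25, seed,
                                baseline_mean = 7, baseline_sd = 1) {
  if (missing(seed)) abort_config("A `seed` is mandatory for simulation.")
  stopifnot(set_size <= n_genes, n_samples >= 1L)
  local_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    set_genes <- sort(sample(genes, set_size))
    mu <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
    n_s <- 2L * n_samples
    vals <- matrix(
      stats::rnorm(n_genes * n_s, mean = mu, sd = noise_sd),
      nrow = n_genes, ncol = n_s
    )
    treated_cols <- seq_len(n_samples)
    vals[genes %in% set_genes, treated_cols] <-
      vals[genes %in% set_genes, treated_cols] + log2_shift
    colnames(vals) <- c(sprintf("treated_%d", seq_len(n_samples)),
                        sprintf("control_%d", seq_len(n_samples)))
    rownames(vals) <- genes
    condition <- stats::setNames(
      rep(c("treated", "control"), each = n_samples), colnames(vals)
    )
    list(
      expr = expression_matrix(vals, condition),
      truth = list(set_genes = set_genes, log2_shift = log2_shift,
                   noise_sd = noise_sd, seed = seed)
    )
  })
}

#' Simulate a qPCR CT table with known knockdown
#'
#' Generates replicate threshold-cycle values for a target and a reference
#' assay in treated and control conditions, consistent in expectation with
#' `2^-ddCT = true_fold`.
#'
#' @param true_fold Planted fold expression of the target (e.g. 0.25 for a
#'   75 percent knockdown).
#' @param ct_noise_sd Gaussian sd added to every CT value.
#' @param n_rep Replicates per (condition, gene).
#' @param seed RNG seed (required when `ct_noise_sd > 0`).
#' @param target,reference Gene labels.
#' @param ct_ref,ct_target_ctrl Baseline CT values of the reference assay
#'   and of the target in the control condition.
#' @return List with `ct_table` (tibble `condition`, `gene`, `replicate`,
#'   `ct`) and `truth`.
#' @export
simulate_qpcr <- function(true_fold, ct_noise_sd = 0, n_rep = 3L,
                          seed = NULL, target = "TARGET", reference = "REF",
                          ct_ref = 20, ct_target_ctrl = 25) {
  if (true_fold <= 0) abort_domain("`true_fold` must be positive.")
  if (ct_noise_sd > 0 && is.null(seed)) {
    abort_config("A `seed` is required when ct_noise_sd > 0.")
  }
  ct_target_case <- ct_target_ctrl - log2(true_fold)
  base <- tidyr::expand_grid(
    condition = c("treated", "control"),
    gene = c(target, reference),
    replicate = seq_len(n_rep)
  )
  base$ct <- dplyr::case_when(
    base$gene == reference ~ ct_ref,
    base$condition == "control" ~ ct_target_ctrl,
    TRUE ~ ct_target_case
  )
  if (ct_noise_sd > 0) {
    base$ct <- local_seed(seed, {
      base$ct + stats::rnorm(nrow(base), 0, ct_noise_sd)
    })
  }
  list(ct_table = base,
       truth = list(true_fold = true_fold, ct_noise_sd = ct_noise_sd,
                    seed = seed))
}
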