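# Orchestration of the full chain (screen -> enrichment -> GSEA -> synergy)
# plus the small cross-experiment statistics used around it.

#' Median-center and combine intensity measurements across experiments
#'
#' Each experiment's values are (optionally log2-transformed and) centered
#' by subtracting the experiment's median, so experiments with different
#' overall scales can be pooled before a group comparison. Centering is
#' idempotent: centering already-centered values changes nothing.
#'
#' @param experiments A numeric vector, or a list of numeric vectors (one
#'   per experiment).
#' @param log2_transform If `TRUE` (default) inputs are raw positive
#'   intensities and are log2-transformed first; if `FALSE` inputs are
#'   already on the log2 scale.
#' @return Numeric vector of centered values, concatenated in input order;
#'   names record the source experiment.
#' @export
median_center_combine <- function(experiments, log2_transform = TRUE) {
  if (!is.list(experiments)) experiments <- list(experiments)
  centered <- purrr::imap(experiments, function(x, i) {
    if (!is.numeric(x) || length(x) == 0L) {
      abort_domain("Each experiment must be a non-empty numeric vector.")
    }
    if (log2_transform) {
      if (any(x <= 0)) abort_domain("Intensities must be strictly positive.")
      x <- log2(x)
    }
    out <- x - stats::median(x)
    names(out) <- rep(paste0("exp", i), length(out))
    out
  })
  unlist(centered, use.names = TRUE)
}

#' Compare two groups with a standard test
#'
#' Thin delegation to `stats::wilcox.test` (Mann-Whitney) or
#' `stats::t.test`, recording which test and sidedness were used. Both
#' groups need at least two observations.
#'
#' @param values Numeric vector of measurements.
#' @param labels Group labels (exactly two distinct values).
#' @param test `"mann_whitney"` or `"t_test"`.
#' @param alternative Sidedness, default two-sided.
#' @return Tibble with `test`, `alternative`, `statistic`, `p_value`,
#'   `effect` (difference of group medians for Mann-Whitney, of means for
#'   the t-test), `n1`, `n2`.
#' @export
compare_groups <- function(values, labels,
                           test = c("mann_whitney", "t_test"),
                           alternative = "two.sided") {
  test <- match.arg(test)
  stopifnot(length(values) == length(labels))
  groups <- split(values, factor(labels, levels = unique(labels)))
  if (length(groups) != 2L) {
    abort_validation("Exactly two groups are required.")
  }
  if (any(lengths(groups) < 2L)) {
    abort_validation(sprintf(
      "Each group needs at least 2 observations (got %s).",
      paste(lengths(groups), collapse = " and ")
    ))
  }
  x <- groups[[1]]
  y <- groups[[2]]
  res <- if (test == "mann_whitney") {
    suppressWarnings(stats::wilcox.test(x, y, alternative = alternative))
  } else {
    stats::t.test(x, y, alternative = alternative)
  }
  effect <- if (test == "mann_whitney") {
    stats::median(x) - stats::median(y)
  } else {
    mean(x) - mean(y)
  }
  tibble::tibble(
    test = test, alternative = alternative,
    statistic = unname(res$statistic), p_value = res$p.value,
    effect = effect, n1 = length(x), n2 = length(y)
  )
}

#' Run the whole pipeline from one configuration
#'
#' Executes screen simulation (or ingest), three-round hit calling,
#' pathway over-representation, gene-set enrichment of a simulated
#' expression contrast, and combination-index synergy analysis, writing
#' one TSV per stage plus a JSON manifest (package version, seed, full
#' configuration, configuration hash, per-stage status and the decision
#' flags in effect). Stage outputs already written are kept even when a
#' later stage fails; the failure is recorded in the manifest.
#'
#' @param config A named list, or the path to a YAML file holding one.
#'   Recognized top-level fields: `seed` (required), `out_dir`, `screen`
#'   (arguments to [screen_sim_config()] and hit-calling flags `threshold`,
#'   `dose_rule`, `sirna_rule`, `ratio_mode`), `expression` (arguments to
#'   [simulate_expression()] plus `n_perm`), `combo` (`dm1`, `m1`, `dm2`,
#'   `m2`, `planted_ci`, `doses1`, `doses2`, `noise_sd`), and optional
#'   `inputs` with paths (`plates`: per-round plate tables; `gmt`) used
#'   instead of simulation where given.
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_all <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      abort_config(sprintf("Config file not found: %s", config))
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$seed)) abort_config("`seed` is required in the run config.")
  out_dir <- out_dir %||% config$out_dir %||% abort_config("`out_dir` is required.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  paths <- as.character(unlist(config$inputs, use.names = FALSE))
  missing_paths <- paths[!file.exists(paths)]
  if (length(missing_paths) > 0L) {
    abort_config(sprintf(
      "Missing input file(s): %s", paste(missing_paths, collapse = ", ")
    ))
  }

  seed <- config$seed
  scr_cfg <- config$screen %||% list()
  hit_flags <- list(
    threshold = scr_cfg$threshold %||% 0.8,
    dose_rule = scr_cfg$dose_rule %||% "any",
    sirna_rule = scr_cfg$sirna_rule %||% "any",
    ratio_mode = scr_cfg$ratio_mode %||% "interaction"
  )
  status <- list()
  results <- list()
  outputs <- character()
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      status[[name]] <<- paste("error:", conditionMessage(res))
      NULL
    } else {
      status[[name]] <<- "ok"
      results[[name]] <<- res
      res
    }
  }
  emit <- function(tbl, file) {
    path <- file.path(out_dir, file)
    write_results(tbl, path)
    outputs <<- c(outputs, file)
  }

  funnel <- run_stage("screen", function() {
    if (!is.null(config$inputs$plates)) {
      ratio_tables <- purrr::map(config$inputs$plates, function(p) {
        enhancer_ratio(normalize_viability(read_plate_table(p)),
                       mode = hit_flags$ratio_mode)
      })
      fun <- run_funnel(ratio_tables, threshold = hit_flags$threshold,
                        dose_rule = hit_flags$dose_rule,
                        sirna_rule = hit_flags$sirna_rule)
      list(funnel = fun, truth = NULL)
    } else {
      sim_args <- scr_cfg[setdiff(names(scr_cfg), names(hit_flags))]
      sim_args$seed <- sim_args$seed %||% seed
      sim <- simulate_screen_funnel(
        do.call(screen_sim_config, sim_args),
        threshold = hit_flags$threshold, dose_rule = hit_flags$dose_rule,
        sirna_rule = hit_flags$sirna_rule, ratio_mode = hit_flags$ratio_mode
      )
      list(funnel = sim$funnel, truth = sim$truth)
    }
  })
  final_hits <- character()
  if (!is.null(funnel)) {
    for (i in seq_along(funnel$funnel$calls)) {
      calls <- funnel$funnel$calls[[i]]
      emit(
        tibble::tibble(
          gene = calls$gene, round_id = calls$round_id,
          min_ratio = vapply(calls$ratios, min, numeric(1)),
          n_passed = lengths(calls$passed_doses), is_hit = calls$is_hit
        ),
        sprintf("round%d_calls.tsv", i)
      )
    }
    final_hits <- funnel$funnel$final_hits
    emit(tibble::tibble(gene = final_hits), "final_hits.tsv")
  }

  run_stage("enrichment", function() {
    maps <- if (!is.null(config$inputs$gmt)) {
      read_gmt(config$inputs$gmt)
    } else if (!is.null(funnel$truth)) {
      # default demo map: the planted enhancer set plus decoys
      gene_set_collection(list(
        PLANTED_ENHANCERS = funnel$truth$enhancers,
        DECOY_SET = utils::head(setdiff(funnel$truth$config$genes,
                                        funnel$truth$enhancers), 30)
      ))
    } else {
      abort_config("Enrichment needs a GMT input when screening from files.")
    }
    universe <- funnel$truth$config$genes %||% config$enrichment$universe
    rows <- enrich_maps(final_hits, maps, universe)
    emit(rows, "enrichment.tsv")
    rows
  })

  run_stage("gsea", function() {
    ex_cfg <- config$expression %||% list()
    n_perm <- ex_cfg$n_perm %||% 999
    sim_args <- ex_cfg[setdiff(names(ex_cfg), "n_perm")]
    sim_args$seed <- sim_args$seed %||% (seed + 1)
    sim <- do.call(simulate_expression, sim_args)
    res <- gsea(sim$expr, sim$truth$set_genes, n_perm = n_perm,
                seed = seed + 2)
    emit(tibble::tibble(
      es = res$es, p_perm = res$p_perm, n_perm = res$n_perm,
      n_leading_edge = length(res$leading_edge),
      leading_edge = paste(res$leading_edge, collapse = ";")
    ), "gsea_summary.tsv")
    emit(tibble::tibble(
      position = seq_along(res$running_sum),
      gene = res$ranked$gene, metric = res$ranked$metric,
      hit = res$ranked$gene %in% toupper(sim$truth$set_genes),
      running_sum = res$running_sum
    ), "gsea_running_sum.tsv")
    res
  })

  run_stage("synergy", function() {
    co <- config$combo %||% list()
    fit1 <- list(Dm = co$dm1 %||% 2, m = co$m1 %||% 1)
    fit2 <- list(Dm = co$dm2 %||% 0.007, m = co$m2 %||% 1)
    planted_ci <- co$planted_ci %||% 0.6
    doses1 <- co$doses1 %||% (fit1$Dm * c(0.25, 0.5, 0.75))
    grid <- tibble::tibble(
      d1 = doses1,
      d2 = co$doses2 %||% (fit2$Dm * c(0.25, 0.5, 0.75))
    )
    sim <- simulate_combo(fit1, fit2, planted_ci, grid,
                          noise_sd = co$noise_sd %||% 0, seed = seed + 3)
    ci_tbl <- combination_index(sim$combos, fit1, fit2)
    emit(ci_tbl, "ci_table.tsv")
    emit(normalized_isobologram(ci_tbl), "isobologram.tsv")
    ci_tbl
  })

  manifest <- list(
    package = "synlethal",
    version = as.character(utils::packageVersion("synlethal")),
    r_version = as.character(getRversion()),
    seed = seed,
    config = config,
    config_hash = rlang::hash(config),
    decision_flags = hit_flags,
    stage_status = status,
    outputs = outputs
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(results = results, manifest = manifest))
}
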