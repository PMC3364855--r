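small_cfg <- function(seed = 1, noise_sd = 0, ...) {
  screen_sim_config(seed = seed, n_genes = 40, n_enhancers = 3,
                    noise_sd = noise_sd, ...)
}

test_that("simulators are pure functions of configuration and seed", {
  s1 <- simulate_screen(small_cfg(noise_sd = 0.1), round_id = 1)
  s2 <- simulate_screen(small_cfg(noise_sd = 0.1), round_id = 1)
  expect_identical(s1$wells, s2$wells)

  e1 <- simulate_expression(n_genes = 100, set_size = 10, seed = 5)
  e2 <- simulate_expression(n_genes = 100, set_size = 10, seed = 5)
  expect_identical(e1$expr$values, e2$expr$values)
  expect_false(identical(
    e1$expr$values,
    simulate_expression(n_genes = 100, set_size = 10, seed = 6)$expr$values
  ))

  expect_error(screen_sim_config(n_genes = 10), class = "synlethal_config_error")
  expect_error(simulate_expression(n_genes = 10, set_size = 2),
               class = "synlethal_config_error")
})

test_that("a screen with no planted interaction gives unit ratios everywhere", {
  cfg <- small_cfg(enhancer_interaction = 1)
  sim <- simulate_screen(cfg, round_id = 1)
  ratios <- enhancer_ratio(normalize_viability(sim$wells))
  expect_true(all(abs(ratios$ratio - 1) < 1e-9))
})

test_that("planted enhancers carry the planted interaction at the affected doses", {
  cfg <- small_cfg()
  sim <- simulate_screen(cfg, round_id = 1)
  ratios <- enhancer_ratio(normalize_viability(sim$wells))
  planted <- ratios[ratios$gene %in% cfg$enhancers & ratios$dose %in% c(5, 10), ]
  expect_true(all(abs(planted$ratio - 0.6) < 1e-9))
  others <- ratios[!ratios$gene %in% cfg$enhancers, ]
  expect_true(all(abs(others$ratio - 1) < 1e-9))
})

test_that("simulated wells have valid plate geometry and controls", {
  sim <- simulate_screen(small_cfg(), round_id = 1)
  w <- sim$wells
  expect_false(any(duplicated(w[c("plate_id", "well")])))
  per_plate <- split(w, w$plate_id)
  expect_true(all(vapply(per_plate, function(p) sum(p$gene == "UNTREATED") == 3,
                         logical(1))))
  expect_true(all(vapply(per_plate, function(p) sum(p$gene == "SCRAMBLE") == 3,
                         logical(1))))
  expect_true(all(w$signal >= 0))
  # round-trips through the plate reader
  path <- tempfile(fileext = ".csv")
  readr::write_csv(w[setdiff(names(w), "is_control")], path)
  back <- read_plate_table(path, plate_schema(plate = "plate_id"))
  expect_equal(back$signal, w$signal, tolerance = 1e-12)
})

test_that("the noise-free funnel is the identity on planted truth (master property)", {
  cfg <- small_cfg(seed = 3)
  sim <- simulate_screen_funnel(cfg)
  expect_identical(sim$funnel$final_hits, cfg$enhancers)
  # nesting along the cascade
  expect_true(all(sim$funnel$hits[[3]] %in% sim$funnel$hits[[2]]))
  expect_true(all(sim$funnel$hits[[2]] %in% sim$funnel$hits[[1]]))

  none <- screen_sim_config(seed = 4, n_genes = 40, n_enhancers = 0, noise_sd = 0)
  sim0 <- simulate_screen_funnel(none)
  expect_length(sim0$funnel$final_hits, 0)
})

test_that("screen sensitivity does not improve as noise grows", {
  sens <- vapply(c(0.02, 0.3), function(sd) {
    cfg <- screen_sim_config(seed = 11, n_genes = 40, n_enhancers = 5,
                             n_rep = 2, noise_sd = sd)
    sim <- simulate_screen_funnel(cfg)
    length(intersect(sim$funnel$final_hits, cfg$enhancers)) / 5
  }, numeric(1))
  expect_gte(sens[1], sens[2])
})

test_that("combination surfaces carry the planted CI exactly when noise-free", {
  fit1 <- list(Dm = 2, m = 1)
  fit2 <- list(Dm = 0.55, m = 2)
  grid <- tidyr::expand_grid(d1 = c(0.25, 0.5, 1), d2 = c(0.1, 0.2, 0.4))
  for (planted in c(0.6, 1)) {
    sim <- simulate_combo(fit1, fit2, planted, grid)
    ci <- combination_index(sim$combos, fit1, fit2)
    expect_equal(ci$ci, rep(planted, nrow(grid)), tolerance = 1e-6)
  }
  # drug against itself at planted CI 1 is the sham combination
  sham <- simulate_combo(fit1, fit1, 1, tibble::tibble(d1 = 0.8, d2 = 0.8))
  expect_equal(combination_index(sham$combos, fit1, fit1)$ci, 1,
               tolerance = 1e-9)
})

test_that("expression simulation plants the shift it reports", {
  sim <- simulate_expression(n_genes = 400, set_size = 30, log2_shift = 2,
                             noise_sd = 0.1, seed = 8)
  ranked <- rank_by_log2_ratio(sim$expr)
  in_set <- ranked$metric[ranked$gene %in% sim$truth$set_genes]
  out_set <- ranked$metric[!ranked$gene %in% sim$truth$set_genes]
  expect_equal(mean(in_set), 2, tolerance = 0.1)
  expect_equal(mean(out_set), 0, tolerance = 0.05)
})

test_that("qPCR simulation is the exact inverse of the ddCT analysis", {
  for (fold in c(0.25, 1, 3)) {
    sim <- simulate_qpcr(true_fold = fold)
    expect_equal(ddct_fold_from_table(sim$ct_table), fold, tolerance = 1e-12)
  }
  # noisy replicates recover the planted fold on average
  folds <- vapply(1:100, function(i) {
    sim <- simulate_qpcr(true_fold = 0.25, ct_noise_sd = 0.2, seed = 100 + i)
    ddct_fold_from_table(sim$ct_table)
  }, numeric(1))
  expect_equal(mean(log2(folds)), log2(0.25), tolerance = 0.1)
})
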