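nv_from_demo <- function() {
  normalize_viability(read_plate_table(write_plate_fixture(demo_plate_rows())))
}

test_that("normalization divides by the untreated plate mean", {
  nv <- nv_from_demo()
  get <- function(g, s, d) nv$v_rel[nv$gene == g & (is.na(s) | nv$sirna_id %in% s) & nv$dose == d]
  expect_equal(get("UNTREATED", NA, 0), 1)        # self-normalization
  expect_equal(get("GENEA", "si-A", 0), 0.9)
  expect_equal(get("GENEA", "si-A", 5), 0.45)
  expect_equal(get("GENEB", "si-B", 5), 0.6)
  expect_equal(get("SCRAMBLE", NA, 5), 0.7)
})

test_that("normalization fails clearly without a usable untreated control", {
  rows <- demo_plate_rows()
  no_ctrl <- rows[rows$gene != "UNTREATED", ]
  expect_error(normalize_viability(read_plate_table(write_plate_fixture(no_ctrl))),
               regexp = "P1", class = "synlethal_validation_error")
  zero <- rows
  zero$signal[rows$gene == "UNTREATED"] <- 0
  expect_error(normalize_viability(read_plate_table(write_plate_fixture(zero))),
               class = "synlethal_domain_error")
})

test_that("interaction ratio matches the multiplicative-null arithmetic", {
  nv <- tibble::tibble(
    gene = c("G1", "G1", "SCRAMBLE", "SCRAMBLE"),
    sirna_id = c("s1", "s1", NA, NA),
    dose = c(0, 5, 0, 5),
    v_rel = c(0.9, 0.5, 1, 0.7),
    sd = 0, n_rep = 3L
  )
  r <- enhancer_ratio(nv)
  expect_equal(r$ratio, (0.5 / 0.9) / 0.7, tolerance = 1e-12)
  expect_equal(round(r$ratio, 3), 0.794)
  # simple mode is the within-gene fold only
  expect_equal(enhancer_ratio(nv, mode = "simple")$ratio, 0.5 / 0.9)
})

test_that("a perfectly multiplicative combination gives ratio exactly 1", {
  nv <- tibble::tibble(
    gene = c("G1", "G1", "SCRAMBLE", "SCRAMBLE"),
    sirna_id = c("s1", "s1", NA, NA),
    dose = c(0, 5, 0, 5),
    v_rel = c(0.8, 0.8 * 0.7, 1, 0.7),
    sd = 0, n_rep = 3L
  )
  expect_equal(enhancer_ratio(nv)$ratio, 1, tolerance = 1e-12)
})

test_that("zero or missing denominators flag the gene instead of producing calls", {
  nv <- tibble::tibble(
    gene = c("G1", "G1", "G2", "SCRAMBLE", "SCRAMBLE"),
    sirna_id = c("s1", "s1", "s2", NA, NA),
    dose = c(0, 5, 5, 0, 5),
    v_rel = c(0, 0.5, 0.4, 1, 0.7),  # G1 total kill at baseline; G2 has no dose-0 row
    sd = 0, n_rep = 3L
  )
  r <- enhancer_ratio(nv)
  expect_true(all(r$flagged))
  expect_true(all(is.na(r$ratio)))
  calls <- call_enhancers(r)
  expect_equal(nrow(calls), 0)
})

test_that("the hit criterion is inclusive at the threshold and follows the dose rule", {
  ratios <- tibble::tibble(
    gene = rep(c("GBOUND", "GNULL", "GONE"), each = 3),
    sirna_id = "s1",
    dose = rep(c(1, 5, 10), 3),
    ratio = c(0.8, 0.95, 1.0,   # boundary at one dose
              1.0, 1.0, 1.0,    # null
              0.95, 0.79, 0.9), # sub-threshold at 5 uM only
    flagged = FALSE
  )
  calls <- call_enhancers(ratios)
  expect_true(calls$is_hit[calls$gene == "GBOUND"])   # <= 0.8 counts
  expect_false(calls$is_hit[calls$gene == "GNULL"])
  expect_true(calls$is_hit[calls$gene == "GONE"])
  expect_equal(calls$passed_doses[calls$gene == "GONE"][[1]], 5)

  expect_false(call_enhancers(ratios, dose_rule = "all")$is_hit[1])
  expect_false(call_enhancers(ratios, dose_rule = "min_k", min_k = 2)$is_hit[3])
  expect_error(call_enhancers(ratios, threshold = 1.2),
               class = "synlethal_config_error")
  expect_error(call_enhancers(ratios, threshold = 0),
               class = "synlethal_config_error")
})

test_that("siRNA collapse rule: any keeps the best reagent, both needs every reagent", {
  ratios <- tibble::tibble(
    gene = "G1", sirna_id = c("a", "b"), dose = 5,
    ratio = c(0.7, 0.9), flagged = FALSE
  )
  expect_true(call_enhancers(ratios, sirna_rule = "any")$is_hit)
  expect_false(call_enhancers(ratios, sirna_rule = "both")$is_hit)
})

test_that("calls are invariant to rescaling all signals on a plate", {
  rows <- demo_plate_rows()
  nv1 <- normalize_viability(read_plate_table(write_plate_fixture(rows)))
  rows$signal <- rows$signal * 37.5
  nv2 <- normalize_viability(read_plate_table(write_plate_fixture(rows)))
  expect_equal(nv1$v_rel, nv2$v_rel, tolerance = 1e-12)
  expect_equal(enhancer_ratio(nv1)$ratio, enhancer_ratio(nv2)$ratio,
               tolerance = 1e-12)
})

test_that("lowering combined viability never un-calls a hit (monotonicity)", {
  base <- tibble::tibble(
    gene = "G1", sirna_id = "s1", dose = 5, v_rel = 0.5, sd = 0, n_rep = 3L
  )
  ctrl <- tibble::tibble(
    gene = c("G1", "SCRAMBLE", "SCRAMBLE"), sirna_id = c("s1", NA, NA),
    dose = c(0, 0, 5), v_rel = c(0.9, 1, 0.7), sd = 0, n_rep = 3L
  )
  was_hit <- FALSE
  for (v in seq(0.55, 0.05, by = -0.05)) {
    nv <- dplyr::bind_rows(dplyr::mutate(base, v_rel = v), ctrl)
    hit <- call_enhancers(enhancer_ratio(nv))$is_hit
    expect_false(was_hit && !hit)
    was_hit <- hit
  }
  expect_true(was_hit)
})

test_that("the funnel enforces nesting and intersects the rounds", {
  mk <- function(genes, rmap) {
    tidyr::expand_grid(gene = genes, sirna_id = "s1", dose = c(1, 5, 10)) |>
      dplyr::mutate(ratio = unname(rmap[gene]), flagged = FALSE)
  }
  r1 <- mk(c("A", "B", "C"), c(A = 0.6, B = 0.7, C = 1))
  r2 <- mk(c("A", "B"), c(A = 0.6, B = 1))
  r3 <- mk("A", c(A = 0.6))
  res <- run_funnel(list(r1, r2, r3))
  expect_equal(res$hits[[1]], c("A", "B"))
  expect_equal(res$final_hits, "A")
  # nesting invariant on the chain
  expect_true(all(res$final_hits %in% res$hits[[2]]))
  expect_true(all(res$hits[[2]] %in% res$hits[[1]]))
  # round 2 measuring a non-hit of round 1 is a structural error
  expect_error(run_funnel(list(r1, mk("C", c(C = 0.5)))),
               class = "synlethal_validation_error")
})

test_that("comparative-CT fold expression follows the closed form", {
  expect_equal(ddct_fold_expression(25, 20, 22, 20), 0.125)
  expect_equal(ddct_fold_expression(20, 20, 23, 20), 8)
  expect_equal(ddct_fold_expression(21.3, 19.8, 21.3, 19.8), 1)
  expect_error(ddct_fold_expression(Inf, 20, 22, 20),
               class = "synlethal_domain_error")
})
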