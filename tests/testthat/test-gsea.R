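ranked_fixture <- function(metrics, genes = sprintf("g%02d", seq_along(metrics))) {
  ord <- order(-metrics, genes)
  tibble::tibble(gene = toupper(genes[ord]), metric = metrics[ord])
}

test_that("ranking is by mean treated minus mean control, ties alphabetical", {
  vals <- rbind(
    HIGH = c(6, 6, 5, 5),
    LOW  = c(4, 4, 5, 5),
    TIE_B = c(5, 5, 5, 5),
    TIE_A = c(5, 5, 5, 5)
  )
  colnames(vals) <- c("t1", "t2", "c1", "c2")
  expr <- expression_matrix(vals, c(t1 = "treated", t2 = "treated",
                                    c1 = "control", c2 = "control"))
  ranked <- rank_by_log2_ratio(expr)
  expect_equal(ranked$gene, c("HIGH", "TIE_A", "TIE_B", "LOW"))
  expect_equal(ranked$metric, c(1, 0, 0, -1))
})

test_that("unweighted enrichment score reproduces hand-computed running sums", {
  ranked <- ranked_fixture(c(4, 3, 2, 1))
  top1 <- enrichment_score(ranked, ranked$gene[1], weight_exponent = 0)
  expect_equal(top1$running_sum, c(1, 2 / 3, 1 / 3, 0))
  expect_equal(top1$es, 1)

  top2 <- enrichment_score(ranked, ranked$gene[1:2], weight_exponent = 0)
  expect_equal(top2$running_sum, c(0.5, 1, 0.5, 0))
  expect_equal(top2$es, 1)

  bottom <- enrichment_score(ranked, ranked$gene[3:4], weight_exponent = 0)
  expect_lt(bottom$es, 0)

  expect_error(enrichment_score(ranked, "ABSENT"),
               class = "synlethal_undefined_score_error")
})

test_that("unweighted ES equals the exhaustive walk oracle for every placement, n <= 8", {
  for (n in 2:8) {
    ranked <- ranked_fixture(rev(seq_len(n)) / n)
    for (m in 1:(n - 1)) {
      placements <- utils::combn(n, m)
      for (j in seq_len(ncol(placements))) {
        pos <- placements[, j]
        es <- enrichment_score(ranked, ranked$gene[pos], weight_exponent = 0)$es
        expect_equal(es, es_walk_oracle(n, pos), tolerance = 1e-12)
      }
    }
  }
})

test_that("ES is bounded by 1 and attains 1 exactly for a top block (weight 0)", {
  withr::with_seed(7, {
    for (rep in 1:25) {
      n <- sample(5:60, 1)
      m <- sample(1:(n - 1), 1)
      ranked <- ranked_fixture(stats::rnorm(n))
      pos <- sort(sample(n, m))
      es <- enrichment_score(ranked, ranked$gene[pos], weight_exponent = 0)$es
      expect_gte(es, -1)
      expect_lte(es, 1)
      es_top <- enrichment_score(ranked, ranked$gene[1:m], weight_exponent = 0)$es
      expect_equal(es_top, 1, tolerance = 1e-12)
    }
  })
})

test_that("weighted ES agrees with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  withr::with_seed(11, {
    for (rep in 1:10) {
      n <- 50
      ranked <- ranked_fixture(sort(stats::rnorm(n), decreasing = TRUE))
      pos <- sort(sample(n, 8))
      es <- enrichment_score(ranked, ranked$gene[pos], weight_exponent = 1)$es
      stats_vec <- stats::setNames(ranked$metric, ranked$gene)
      es_ref <- fgsea::calcGseaStat(stats_vec, pos, gseaParam = 1)
      expect_equal(es, es_ref, tolerance = 1e-9)
    }
  })
})

test_that("permutation p uses the add-one convention, is never 0, and is seed-reproducible", {
  withr::with_seed(3, {
    ranked <- ranked_fixture(c(sort(stats::rnorm(40), decreasing = TRUE)))
  })
  set_top <- ranked$gene[1:5]  # so extreme no permutation should beat it
  res <- permutation_p(ranked, set_top, n_perm = 999, seed = 42,
                       weight_exponent = 0)
  # nothing beats the observed score: add-one numerator over same-sign perms
  expect_gte(res$p_perm, 1 / 1000)
  expect_lte(res$p_perm, 1 / 500)  # about half the permuted scores are positive
  res2 <- permutation_p(ranked, set_top, n_perm = 999, seed = 42,
                        weight_exponent = 0)
  expect_identical(res$p_perm, res2$p_perm)
  expect_gt(permutation_p(ranked, ranked$gene[c(3, 18, 33)], n_perm = 99,
                          seed = 1)$p_perm, 0)
  expect_error(permutation_p(ranked, set_top, n_perm = 99),
               class = "synlethal_config_error")
})

test_that("the leading edge is the members at or before the running-sum peak", {
  ranked <- ranked_fixture(c(4, 3, 2, 1))
  sc <- enrichment_score(ranked, ranked$gene[1], weight_exponent = 0)
  expect_equal(leading_edge(ranked, ranked$gene[1], sc), ranked$gene[1])

  sc2 <- enrichment_score(ranked, ranked$gene[1:2], weight_exponent = 0)
  expect_equal(leading_edge(ranked, ranked$gene[1:2], sc2), ranked$gene[1:2])

  # for a positive ES the peak sits on a hit, so the leading edge is never empty
  withr::with_seed(5, {
    for (rep in 1:20) {
      n <- sample(6:40, 1)
      ranked_r <- ranked_fixture(stats::rnorm(n))
      pos <- sort(sample(n, sample(1:(n - 2), 1)))
      sc_r <- enrichment_score(ranked_r, ranked_r$gene[pos], weight_exponent = 0)
      if (sc_r$es >= 0) {
        expect_gt(length(leading_edge(ranked_r, ranked_r$gene[pos], sc_r)), 0)
      }
    }
  })
})

test_that("gsea() ties the pieces together on a strongly shifted planted set", {
  sim <- simulate_expression(n_genes = 300, set_size = 20, log2_shift = 3,
                             noise_sd = 0.1, seed = 9)
  res <- gsea(sim$expr, sim$truth$set_genes, n_perm = 199, seed = 10)
  expect_gt(res$es, 0.9)
  expect_lt(res$p_perm, 0.02)  # near the floor attainable at this n_perm
  expect_true(all(res$leading_edge %in% sim$truth$set_genes))
  expect_gt(length(res$leading_edge), 15)
})
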