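test_that("enrichment p agrees with hypergeometric enumeration", {
  # null-ish 10-of-100 table
  res <- category_enrichment(grouping = "up", k = 1, n = 10, K = 11,
                             N = 100)
  oracle <- sum(vapply(1:10, function(x) {
    if (x >= 1) dhyper(x, 11, 89, 10) else 0
  }, numeric(1)))
  expect_equal(res$p_value, oracle, tolerance = 1e-10)

  # enumeration across a grid of subset hit counts
  for (k in 0:6) {
    res <- category_enrichment(grouping = "up", k = k, n = 12, K = 9,
                               N = 60)
    oracle <- sum(dhyper(k:min(12, 9), 9, 51, 12))
    expect_equal(res$p_value, oracle, tolerance = 1e-10)
  }
})

test_that("enrichment p is monotone decreasing in the subset hit count", {
  ps <- vapply(1:8, function(k) {
    category_enrichment(grouping = "up", k = k, n = 20, K = 30,
                        N = 200)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("subset equal to the whole set is never enriched", {
  fit <- classify_all(growth_gene_expression())
  res <- category_enrichment(fit, fit, grouping = "up")
  expect_equal(res$p_value, 1)
  expect_error(category_enrichment(fit$assignments[0, ], fit,
                                   grouping = "up"), "empty subset")
})

test_that("enrichment counts derive correctly from assignment tables", {
  fit <- classify_all(growth_gene_expression())
  sub <- fit$assignments[fit$assignments$category %in% c("IV", "IX"), ]
  res <- category_enrichment(sub, fit$assignments, grouping = "maternalELD")
  expect_equal(res$subset_hits, sum(sub$category == "IX"))
  expect_equal(res$subset_size, nrow(sub))
  expect_equal(res$background_hits, 13)
  expect_equal(res$background_size, 45)
  expect_true(res$odds_ratio > 0)

  outside <- sub
  outside$gene_id[1] <- "not_in_background"
  expect_error(category_enrichment(outside, fit$assignments,
                                   grouping = "maternalELD"), "subset of")
})

test_that("both background constructions and the two-sided variant run", {
  a <- category_enrichment(grouping = "up", k = 4, n = 57, K = 70,
                           N = 13893, background = "rest")
  b <- category_enrichment(grouping = "up", k = 4, n = 57, K = 70,
                           N = 13893, background = "all")
  d <- category_enrichment(grouping = "up", k = 4, n = 57, K = 70,
                           N = 13893, alternative = "two.sided")
  expect_true(all(c(a$p_value, b$p_value, d$p_value) > 0))
  expect_true(all(c(a$p_value, b$p_value, d$p_value) <= 1))
})

test_that("proportion report reproduces printed growth-gene percentages", {
  fit <- classify_all(growth_gene_expression())
  rep57 <- proportion_report(fit, denominator = 57)
  pick <- function(lbl) rep57$percent_rounded[rep57$label == lbl]
  expect_equal(pick("maternalELD"), 22.8)
  expect_equal(pick("paternalELD"), 19.3)
  expect_equal(pick("up"), 7.0)
  # the 12 genes not printed in the table are carried as NoChange remainder
  expect_equal(rep57$n[rep57$label == "NoChange"], 12)
  expect_equal(sum(rep57$percent), 100)

  expect_error(proportion_report(fit, denominator = 10), "smaller")
  one <- proportion_report(fit$assignments[1, ])
  expect_equal(one$percent[one$label == "maternalELD"], 100) # cds2 is IX
})
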