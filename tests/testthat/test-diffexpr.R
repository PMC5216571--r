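test_that("binomial random-sampling test matches enumeration on key cases", {
  expect_equal(binomial_rs_test(5, 5, 1e6, 1e6), 1)
  expect_equal(binomial_rs_test(0, 10, 1e6, 1e6), 2 / 1024,
               tolerance = 1e-12)
  expect_equal(binomial_rs_test(4, 0, 1e6, 1e6), 2 / 16, tolerance = 1e-12)
  expect_warning(p0 <- binomial_rs_test(0, 0, 10, 10), "zero counts")
  expect_equal(p0, 1)
})

test_that("fisher engine matches hypergeometric enumeration on key cases", {
  expect_equal(fisher_de_test(0, 5, 5, 5), 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_de_test(3, 3, 10, 10), 1)
  # symmetry under swapping the libraries
  expect_equal(fisher_de_test(7, 2, 40, 35), fisher_de_test(2, 7, 35, 40))
  expect_error(fisher_de_test(11, 0, 10, 10), "exceed")
})

test_that("BH adjustment reproduces the hand step-up", {
  expect_equal(bh_fdr(c(0.001, 0.01, 0.03, 0.8)),
               c(0.004, 0.02, 0.04, 0.8))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(1:10, 1))
    expect_equal(bh_fdr(p), enum_bh(p))
  }
})

test_that("up/down calls apply strict thresholds", {
  expect_equal(de_call(2.3, 1e-5), "up")
  expect_equal(de_call(2.3, 0.01), "ns")     # FDR gate
  expect_equal(de_call(1.0, 1e-5), "ns")     # strict > at the lfc boundary
  expect_equal(de_call(-1.5, 1e-5), "down")
  expect_equal(de_call(Inf, 1e-5), "up")     # one-sided zero count
  expect_equal(de_call(0.5, 0.001, fdr_max = 0.001), "ns") # strict < on q
})

test_that("identical groups yield no calls; contrasts are antisymmetric", {
  counts <- tiny_counts()
  counts[paste0("hybrid_", 1:3)] <- counts[paste0("paternal_", 1:3)]
  de <- compare_groups(counts, tiny_groups(), "paternal", "hybrid")
  expect_true(all(de$call == "ns"))
  expect_true(all(de$m[de$tested] == 0))

  sim <- generate_dataset(simulation_config(n_genes = 150), seed = 7)
  ab <- compare_groups(sim$counts, sim$groups, "paternal", "maternal",
                       lib_sizes = sim$lib_sizes)
  ba <- compare_groups(sim$counts, sim$groups, "maternal", "paternal",
                       lib_sizes = sim$lib_sizes)
  expect_equal(ab$m, -ba$m)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  expect_equal(ab$call == "up", ba$call == "down")
})

test_that("a planted 8-fold gene is detected at depth 1e6", {
  counts <- tibble::tibble(
    gene_id = c("flat1", "flat2", "flat3", "planted"),
    length_bp = c(1000L, 1500L, 800L, 1200L),
    paternal_1 = c(100L, 150L, 90L, 800L),
    maternal_1 = c(100L, 150L, 90L, 100L),
    hybrid_1 = c(100L, 150L, 90L, 100L)
  )
  groups <- tibble::tibble(sample = c("paternal_1", "maternal_1", "hybrid_1"),
                           group = c("paternal", "maternal", "hybrid"))
  de <- compare_groups(counts, groups, "paternal", "maternal",
                       lib_sizes = c(paternal_1 = 1e6, maternal_1 = 1e6,
                                     hybrid_1 = 1e6))
  expect_equal(de$call, c("ns", "ns", "ns", "up"))
  # oracle confirms the planted p is below threshold
  expect_lt(enum_binom_p(800, 900, 0.5), 0.001)

  # both-zero genes are flagged untested and called ns
  counts$paternal_1[1] <- 0L
  counts$maternal_1[1] <- 0L
  counts$hybrid_1[1] <- 0L
  de0 <- compare_groups(counts, groups, "paternal", "maternal")
  expect_false(de0$tested[1])
  expect_equal(de0$call[1], "ns")
  expect_true(is.na(de0$m[1]))
})

test_that("raw-p thresholding variant is available", {
  counts <- tiny_counts()
  de_fdr <- compare_groups(counts, tiny_groups(), "paternal", "maternal")
  de_raw <- compare_groups(counts, tiny_groups(), "paternal", "maternal",
                           use_fdr = FALSE)
  expect_equal(de_fdr$p_value, de_raw$p_value)
  expect_error(compare_groups(counts, tiny_groups(), "paternal", "cousin"),
               "not present")
})
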