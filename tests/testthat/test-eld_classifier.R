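test_that("pairwise calls use the non-strict log2 threshold", {
  expect_equal(pairwise_call(4.68, 2.00), "higher")  # log2 = 1.23
  expect_equal(pairwise_call(3.3, 3.3), "equal")
  expect_equal(pairwise_call(6.95, 3.51), "equal")   # log2 = 0.986
  expect_equal(pairwise_call(1, 4.36), "lower")
  expect_equal(pairwise_call(2, 1, tau = 1), "equal") # exactly tau
  expect_error(pairwise_call(0, 1), "strictly positive")
})

test_that("single-gene classifications match worked examples", {
  expect_equal(classify_genes(1.28, 0.09, 0.05), "IX")     # cds2
  expect_equal(classify_genes(21.24, 19.72, 53.65), "IV")  # igf1
  expect_equal(classify_genes(5.83, 19.20, 18.91), "X")    # smad7
  expect_equal(classify_genes(1, 1, 1), "NoChange")
  expect_equal(classify_genes(4.0, 1.1, 2.1), "Ambiguous")
  expect_error(classify_genes(1, 0, 1), "strictly positive")
})

test_that("all 45 fixture genes reproduce their printed categories", {
  tab <- growth_gene_table()
  fit <- classify_all(growth_gene_expression())
  expect_equal(fit$assignments$category, tab$category)
  g <- glance(fit)
  expect_equal(g$paternalELD, 11)
  expect_equal(g$maternalELD, 13)
  expect_equal(g$mid, 11)
  expect_equal(g$up, 4)
  expect_equal(g$down, 6)
})

test_that("every positive triple maps to exactly one category", {
  tr <- random_triples(4000)
  cats <- classify_genes(tr$b, tr$g, tr$h)
  expect_false(anyNA(cats))
  expect_true(all(cats %in% c("I", "II", "III", "IV", "V", "VI", "VII",
                              "VIII", "IX", "X", "XI", "XII", "NoChange",
                              "Ambiguous")))
  # Unresolved is unreachable from a coherent expression triple
  expect_false(any(cats == "Unresolved"))
})

test_that("classification is scale invariant", {
  tr <- random_triples(2000, seed = 99)
  cats <- classify_genes(tr$b, tr$g, tr$h)
  for (c0 in c(1e-3, 7, 5e4)) {
    expect_equal(classify_genes(c0 * tr$b, c0 * tr$g, c0 * tr$h), cats)
  }
})

test_that("swapping parental roles mirrors the categories", {
  mirror <- c(I = "II", II = "I", III = "III", IV = "IV", V = "VI",
              VI = "V", VII = "X", VIII = "IX", IX = "VIII", X = "VII",
              XI = "XII", XII = "XI", NoChange = "NoChange",
              Ambiguous = "Ambiguous")
  tr <- random_triples(4000, seed = 31415)
  cats <- classify_genes(tr$b, tr$g, tr$h)
  swapped <- classify_genes(tr$g, tr$b, tr$h)
  expect_equal(swapped, unname(mirror[cats]))
})

test_that("silencing and novel detection follow the floor rules", {
  expect_true(detect_silenced(15, 12, 0))
  expect_false(detect_silenced(15, 5, 0))    # maternal below floor
  expect_false(detect_silenced(15, 12, 0.3)) # hybrid nonzero
  expect_false(detect_silenced(10, 12, 0))   # strict > floor

  expect_true(detect_novel(0, 0, 12))
  expect_false(detect_novel(0, 0, 4))        # below floor
  expect_false(detect_novel(0.2, 0, 12))     # parental expression present
  expect_false(any(detect_silenced(15, 12, 0) & detect_novel(15, 12, 0)))
})

test_that("classify_all routes zero-expression genes before ratio classification", {
  expr <- tibble::tibble(
    gene_id = c("sil", "nov", "excl1", "excl2", "ok"),
    chi_paternal = c(20, 0, 0.5, 0, 8),
    chi_maternal = c(15, 0, 0, 3, 1),
    at_elv = c(0, 25, 2, 0, 2.8)
  )
  fit <- classify_all(expr)
  expect_equal(fit$assignments$category,
               c("Silenced", "Novel", "Excluded", "Excluded", "XI"))
  s <- fit$summary
  expect_equal(s$n[s$label == "Silenced"], 1)
  expect_equal(s$n[s$label == "Excluded"], 2)
})

test_that("ambiguous tie-break assigns dominance to the nearer parent", {
  # P = higher, hybrid within tau of both parents (h in [2, 2.2])
  expect_equal(classify_genes(4.0, 1.1, 2.15, ambiguous_tiebreak = TRUE),
               "VII")
  expect_equal(classify_genes(4.0, 1.1, 2.05, ambiguous_tiebreak = TRUE),
               "IX")
  expect_equal(classify_genes(4.0, 1.1, 2.1), "Ambiguous")
})

test_that("statistical mode reproduces threshold-mode categories on well-separated data", {
  sim <- generate_dataset(simulation_config(n_genes = 400), seed = 5)
  expr <- group_means(sim$counts, sim$groups, sim$lib_sizes)
  de <- list(
    parental = compare_groups(sim$counts, sim$groups, "paternal",
                              "maternal", lib_sizes = sim$lib_sizes),
    hybrid_paternal = compare_groups(sim$counts, sim$groups, "hybrid",
                                     "paternal", lib_sizes = sim$lib_sizes),
    hybrid_maternal = compare_groups(sim$counts, sim$groups, "hybrid",
                                     "maternal", lib_sizes = sim$lib_sizes)
  )
  thr <- classify_all(expr)
  stat <- classify_all(expr, mode = "statistical", de_results = de)
  agree <- mean(thr$assignments$category == stat$assignments$category)
  expect_gt(agree, 0.8)
  expect_error(classify_all(expr, mode = "statistical"), "de_results")
})
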