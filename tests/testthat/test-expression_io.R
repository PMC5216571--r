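test_that("count matrix writer/reader round-trip is the identity", {
  counts <- tiny_counts()
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(counts, tf)
  back <- read_count_matrix(tf, tiny_groups())
  expect_equal(as.data.frame(back), as.data.frame(counts))
})

test_that("validation rejects malformed tables with informative errors", {
  counts <- tiny_counts()
  groups <- tiny_groups()

  neg <- counts
  neg$maternal_2[2] <- -3L
  expect_error(validate_counts(neg, groups), "g2.*maternal_2.*line 3")

  frac <- counts
  frac$hybrid_1[1] <- 1.5
  expect_error(validate_counts(frac, groups), "not a non-negative integer")

  dup <- counts
  dup$gene_id[3] <- "g1"
  expect_error(validate_counts(dup, groups), "duplicated gene_id 'g1'")

  expect_error(validate_counts(counts, groups[-1, ]),
               "missing from group map")
  expect_error(validate_counts(counts[, -(3:5)], groups),
               "group\\(s\\) with no samples: paternal")
  badlen <- counts
  badlen$length_bp[1] <- 0L
  expect_error(validate_counts(badlen, groups), "length_bp must be >= 1")
})

test_that("group maps load from TSV and YAML", {
  groups <- tiny_groups()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(groups, tsv, col_names = FALSE)
  expect_equal(read_group_map(tsv), groups)

  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(paste0(groups$sample, ": ", groups$group), yml)
  expect_equal(read_group_map(yml), groups)

  expect_error(as_group_map(tibble::tibble(sample = "s", group = "parentX")),
               "unknown group label")
})

test_that("growth-gene fixture matches the printed table digit-for-digit", {
  tab <- growth_gene_table()
  expect_equal(nrow(tab), 45)
  expect_true(all(tab$bsb_rpkm > 0 & tab$gb_rpkm > 0 & tab$gc_rpkm > 0))
  expect_false(anyDuplicated(tab$symbol) > 0)

  # spot checks transcribed independently of the shipped file
  expected <- tibble::tribble(
    ~symbol,    ~bsb_rpkm, ~gb_rpkm, ~gc_rpkm, ~category,
    "cds2",          1.28,     0.05,     0.09, "IX",
    "igf1",         21.24,    53.65,    19.72, "IV",
    "smad7",         5.83,    18.91,    19.20, "X",
    "igfbp1b",       0.06,     0.01,    17.17, "II",
    "igfbp5a",       0.02,     4.36,     2.07, "VI",
    "foxj2",        10.44,     4.68,     2.00, "XI",
    "bambia",        6.95,     1.36,     3.51, "III",
    "gdf6a",         0.67,     0.65,     0.09, "VII",
    "ppm1bb",        2.40,     0.16,     0.42, "I",
    "insra",         2.24,     8.00,     3.67, "IV",
    "igf2b",        30.01,    25.43,    11.67, "VII",
    "gpc4",          1.31,     3.00,     4.18, "X"
  )
  got <- tab[match(expected$symbol, tab$symbol),
             c("symbol", "bsb_rpkm", "gb_rpkm", "gc_rpkm", "category")]
  expect_equal(as.data.frame(got), as.data.frame(expected))

  # printed tallies of the table
  expect_equal(sum(tab$category %in% c("VII", "VIII")), 11)
  expect_equal(sum(tab$category %in% c("IX", "X")), 13)
  expect_equal(sum(tab$category %in% c("XI", "XII")), 11)
  expect_equal(sum(tab$category %in% c("IV", "V", "VI")), 4)
})

test_that("category results round-trip through TSV + JSON summary", {
  fit <- classify_all(growth_gene_expression())
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_category_results(fit, tf)
  back <- read_category_results(tf)
  expect_equal(nrow(back), 45)
  expect_equal(back$category, fit$assignments$category)

  js <- jsonlite::read_json(sub("\\.tsv$", ".json", tf))
  expect_equal(js$IX + js$X, 13)

  expect_error(write_category_results(fit$assignments[0, ], tf), "nonempty")
})
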