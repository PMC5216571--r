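#' Read a gene x sample read-count matrix
#'
#' Reads a tab-separated count table whose header row names the samples and
#' whose first two columns are `gene_id` and `length_bp` (transcript length in
#' base pairs), followed by one integer read-count column per sample. The
#' result is validated against the sample-to-group map: every sample column
#' must be assigned one of the roles `paternal`, `maternal` or `hybrid`.
#'
#' @param path Path to the TSV count file.
#' @param groups Sample-to-group map: a two-column data frame
#'   (`sample`, `group`), a named character vector (names = samples), or a
#'   path readable by [read_group_map()].
#' @return A tibble with columns `gene_id`, `length_bp` and one integer count
#'   column per sample, validated (unique gene ids, positive lengths,
#'   non-negative integer counts).
#' @export
#' @examples
#' sim <- generate_dataset(simulation_config(n_genes = 20), seed = 1)
#' tf <- tempfile(fileext = ".tsv")
#' write_count_matrix(sim$counts, tf)
#' counts <- read_count_matrix(tf, sim$groups)
read_count_matrix <- function(path, groups) {
  groups <- as_group_map(groups)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    length_bp = readr::col_double(),
    .default = readr::col_double()
  ), progress = FALSE)
  if (!identical(names(raw)[1:2], c("gene_id", "length_bp"))) {
    abort("count file must start with columns 'gene_id' and 'length_bp'")
  }
  validate_counts(raw, groups)
}

#' Write a count matrix to TSV
#'
#' Inverse of [read_count_matrix()]; writing then reading is the identity on
#' the table's content.
#'
#' @param counts Count tibble (`gene_id`, `length_bp`, sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read a sample-to-group map
#'
#' Accepts either a two-column TSV (`sample<TAB>group`, with or without a
#' header) or a YAML mapping `sample: group`.
#'
#' @param path Path to the map file.
#' @return A tibble with columns `sample` and `group`.
#' @export
read_group_map <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    m <- yaml::read_yaml(path)
    return(as_group_map(unlist(m)))
  }
  df <- readr::read_tsv(path, col_names = FALSE, col_types = "cc",
                        progress = FALSE)
  if (identical(tolower(unlist(df[1, ])), c("sample", "group"))) {
    df <- df[-1, ]
  }
  names(df) <- c("sample", "group")
  as_group_map(df)
}

# Normalize the accepted group-map representations to a validated tibble.
as_group_map <- function(groups) {
  if (is.character(groups) && length(groups) == 1 && is.null(names(groups)) &&
      file.exists(groups)) {
    return(read_group_map(groups))
  }
  if (is.character(groups) && !is.null(names(groups))) {
    groups <- tibble(sample = names(groups), group = unname(groups))
  }
  if (!is.data.frame(groups) || !all(c("sample", "group") %in% names(groups))) {
    abort("'groups' must be a data frame with columns 'sample' and 'group', a named character vector, or a file path")
  }
  groups <- as_tibble(groups[, c("sample", "group")])
  groups$group <- as.character(groups$group)
  groups$sample <- as.character(groups$sample)
  bad <- setdiff(unique(groups$group), GROUP_ROLES)
  if (length(bad)) {
    abort(paste0("unknown group label(s): ", paste(bad, collapse = ", "),
                 " (expected ", paste(GROUP_ROLES, collapse = "/"), ")"))
  }
  if (anyDuplicated(groups$sample)) {
    abort("duplicated sample name in group map")
  }
  groups
}

#' Validate a count tibble against a group map
#'
#' Checks the invariants of the count-matrix contract: unique gene ids,
#' lengths >= 1 bp, non-negative integer counts, every sample column assigned
#' to a group, every group non-empty. Errors name the offending gene or cell
#' and its line number in the source file (header = line 1).
#'
#' @param counts Count tibble (`gene_id`, `length_bp`, sample columns).
#' @param groups Sample-to-group map (any form accepted by
#'   [read_count_matrix()]).
#' @return The validated counts tibble, with count columns coerced to integer.
#' @export
validate_counts <- function(counts, groups) {
  groups <- as_group_map(groups)
  counts <- as_tibble(counts)
  sample_cols <- setdiff(names(counts), c("gene_id", "length_bp"))
  if (length(sample_cols) == 0) abort("no sample columns found")
  missing_grp <- setdiff(sample_cols, groups$sample)
  if (length(missing_grp)) {
    abort(paste0("sample(s) missing from group map: ",
                 paste(missing_grp, collapse = ", ")))
  }
  present <- groups$group[groups$sample %in% sample_cols]
  absent_roles <- setdiff(GROUP_ROLES, present)
  if (length(absent_roles)) {
    abort(paste0("group(s) with no samples: ", paste(absent_roles, collapse = ", ")))
  }
  dup <- counts$gene_id[duplicated(counts$gene_id)]
  if (length(dup)) {
    line <- which(duplicated(counts$gene_id))[1] + 1L
    abort(paste0("duplicated gene_id '", dup[1], "' at line ", line))
  }
  if (any(is.na(counts$length_bp)) || any(counts$length_bp < 1)) {
    line <- which(is.na(counts$length_bp) | counts$length_bp < 1)[1] + 1L
    abort(paste0("length_bp must be >= 1 (line ", line, ")"))
  }
  for (s in sample_cols) {
    v <- counts[[s]]
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad)) {
      abort(paste0("count for gene '", counts$gene_id[bad[1]], "' sample '", s,
                   "' is not a non-negative integer (line ", bad[1] + 1L, ")"))
    }
    counts[[s]] <- as.integer(v)
  }
  counts
}

# Per-sample library sizes: user-supplied named vector, or column sums.
library_sizes <- function(counts, lib_sizes = NULL) {
  sample_cols <- setdiff(names(counts), c("gene_id", "length_bp"))
  if (is.null(lib_sizes)) {
    lib_sizes <- vapply(counts[sample_cols], sum, numeric(1))
  } else {
    if (is.null(names(lib_sizes)) || !all(sample_cols %in% names(lib_sizes))) {
      abort("'lib_sizes' must be a named vector covering every sample")
    }
    lib_sizes <- lib_sizes[sample_cols]
  }
  if (any(lib_sizes < 1)) abort("library sizes must be >= 1")
  lib_sizes
}

#' Write per-gene category assignments and a JSON summary
#'
#' Writes the per-gene table (expression levels, the three pairwise calls and
#' the assigned category) as TSV, and a machine-readable JSON summary of
#' per-category counts alongside it (same path with extension `.json`).
#'
#' @param assignments Assignment tibble from [classify_all()] (or the
#'   `eld_classification` object itself).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_category_results <- function(assignments, path) {
  if (inherits(assignments, "eld_classification")) {
    assignments <- assignments$assignments
  }
  if (!is.data.frame(assignments) || nrow(assignments) == 0) {
    abort("'assignments' must be a nonempty data frame")
  }
  readr::write_tsv(assignments, path, progress = FALSE)
  counts <- table(factor(assignments$category, levels = ALL_CATEGORIES))
  json_path <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(as.list(counts), json_path, auto_unbox = TRUE)
  invisible(path)
}

#' Read back a category-results TSV
#'
#' @param path Path written by [write_category_results()].
#' @return The assignments tibble.
#' @export
read_category_results <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    category = readr::col_character(),
    .default = readr::col_guess()
  ), progress = FALSE)
}

#' Growth-gene expression table (in-paper fixture)
#'
#' The 45 differentially classified growth-annotated genes shipped with the
#' package: gene symbol, Ensembl protein id, mean RPKM in the paternal blunt
#' snout bream (BSB), the triploid hybrid (GB) and the maternal grass carp
#' (GC), and the printed expression category. Values are stored exactly as
#' printed (two decimals); no re-derivation from counts is attempted.
#'
#' @return A 45-row tibble with columns `symbol`, `protein_id`, `bsb_rpkm`,
#'   `gb_rpkm`, `gc_rpkm`, `category`.
#' @export
#' @examples
#' tab <- growth_gene_table()
#' classify_all(growth_gene_expression())
growth_gene_table <- function() {
  path <- system.file("extdata", "growth_genes_rpkm.tsv", package = "eldr")
  tab <- readr::read_tsv(path, col_types = "ccdddc", progress = FALSE)
  stopifnot(nrow(tab) == 45, all(tab$category %in% ROMAN_CATEGORIES))
  tab
}

#' Growth-gene fixture as a group-expression table
#'
#' Reshapes [growth_gene_table()] into the per-gene group-expression layout
#' used by the classifier and the dosage model (`chi_paternal`,
#' `chi_maternal`, `at_elv`).
#'
#' @return A 45-row tibble with columns `gene_id`, `chi_paternal`,
#'   `chi_maternal`, `at_elv`.
#' @export
growth_gene_expression <- function() {
  tab <- growth_gene_table()
  tibble(gene_id = tab$symbol,
         chi_paternal = tab$bsb_rpkm,
         chi_maternal = tab$gc_rpkm,
         at_elv = tab$gb_rpkm)
}
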