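#' Run the full analysis pipeline
#'
#' Sequential end-to-end run: RPKM normalization and group means, the three
#' pairwise differential-expression contrasts (paternal vs maternal, hybrid
#' vs paternal, hybrid vs maternal), the two dosage comparisons (actual
#' triploid level against the additive PT-ELV and the mid-parent PD-ELV),
#' the 12-category classification, and optional subset enrichment — plus a
#' reproducibility manifest (configuration echo, package version, input
#' checksum, per-stage row counts, timestamps). In threshold mode a rerun
#' with the same inputs reproduces identical outputs.
#'
#' @inheritParams compare_groups
#' @param tau,floor Classifier thresholds, see [classify_all()].
#' @param mode Classifier mode; in `"statistical"` mode the three DE
#'   contrasts feed the classifier.
#' @param subset Optional character vector of gene ids to test for category
#'   enrichment.
#' @param grouping Grouping tested for the subset, default `"up"`.
#' @param out_dir Optional directory; when given, writes `de_*.tsv`,
#'   `dosage_*.tsv`, `categories.tsv`, `summary.json` and `manifest.json`.
#' @param fixture `"table2"` runs the embedded growth-gene demonstration
#'   (no counts required; the DE stage is skipped because the fixture stores
#'   group means only).
#' @return A list: `expr`, `de` (list of three `eld_de` tibbles), `dosage`
#'   (list of two `dosage_comparison` tibbles), `classification`,
#'   `enrichment` (or NULL), `manifest`.
#' @export
#' @examples
#' res <- run_pipeline(fixture = "table2")
#' res$classification$summary
run_pipeline <- function(counts = NULL, groups = NULL, engine = "binomial",
                         fdr_max = 0.001, lfc_min = 1, use_fdr = TRUE,
                         tau = 1, floor = 10, mode = "rpkm-threshold",
                         subset = NULL, grouping = "up", out_dir = NULL,
                         lib_sizes = NULL, fixture = NULL) {
  t0 <- Sys.time()
  stage_rows <- list()
  if (!is.null(fixture)) {
    if (!identical(fixture, "table2")) abort("unknown fixture")
    expr <- growth_gene_expression()
    de <- NULL
    checksum <- unname(tools::md5sum(system.file(
      "extdata", "growth_genes_rpkm.tsv", package = "eldr")))
  } else {
    if (is.null(counts) || is.null(groups)) {
      abort("run_pipeline needs counts + groups, or fixture = \"table2\"")
    }
    groups <- as_group_map(groups)
    counts <- validate_counts(counts, groups)
    tmp <- tempfile(fileext = ".tsv")
    readr::write_tsv(counts, tmp, progress = FALSE)
    checksum <- unname(tools::md5sum(tmp))
    unlink(tmp)
    expr <- group_means(counts, groups, lib_sizes)
    de <- list(
      parental = compare_groups(counts, groups, "paternal", "maternal",
                                engine, fdr_max, lfc_min, use_fdr, lib_sizes),
      hybrid_paternal = compare_groups(counts, groups, "hybrid", "paternal",
                                       engine, fdr_max, lfc_min, use_fdr,
                                       lib_sizes),
      hybrid_maternal = compare_groups(counts, groups, "hybrid", "maternal",
                                       engine, fdr_max, lfc_min, use_fdr,
                                       lib_sizes)
    )
    stage_rows$de <- vapply(de, nrow, integer(1))
  }
  stage_rows$expr <- nrow(expr)

  dosage <- list(pt = dosage_comparison(expr, "pt", lfc_min),
                 pd = dosage_comparison(expr, "pd", lfc_min))
  stage_rows$dosage <- vapply(dosage, nrow, integer(1))

  classification <- classify_all(expr, tau = tau, floor = floor, mode = mode,
                                 de_results = de)
  stage_rows$classification <- nrow(classification$assignments)

  enrichment <- NULL
  if (!is.null(subset)) {
    sub <- classification$assignments[
      classification$assignments$gene_id %in% subset, ]
    enrichment <- category_enrichment(sub, classification$assignments,
                                      grouping = grouping)
    stage_rows$enrichment <- nrow(enrichment)
  }

  manifest <- list(
    tool = "eldr",
    version = as.character(utils::packageVersion("eldr")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input_md5 = checksum,
    config = list(engine = engine, fdr_max = fdr_max, lfc_min = lfc_min,
                  use_fdr = use_fdr, tau = tau, floor = floor, mode = mode,
                  grouping = grouping, fixture = fixture),
    stage_rows = stage_rows
  )

  res <- list(expr = expr, de = de, dosage = dosage,
              classification = classification, enrichment = enrichment,
              manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(res$de)) {
    for (nm in names(res$de)) {
      readr::write_tsv(as_tibble(res$de[[nm]]),
                       file.path(out_dir, paste0("de_", nm, ".tsv")),
                       progress = FALSE)
    }
  }
  for (nm in names(res$dosage)) {
    readr::write_tsv(as_tibble(res$dosage[[nm]]),
                     file.path(out_dir, paste0("dosage_", nm, ".tsv")),
                     progress = FALSE)
  }
  write_category_results(res$classification,
                         file.path(out_dir, "categories.tsv"))
  summary <- list(
    categories = setNames(as.list(res$classification$summary$n),
                          res$classification$summary$label),
    dosage = lapply(res$dosage, function(d) as.list(dosage_summary(d)))
  )
  if (!is.null(res$enrichment)) summary$enrichment <- as.list(res$enrichment)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
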