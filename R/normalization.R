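#' Reads per kilobase of transcript per million mapped reads
#'
#' RPKM = 1e9 * C / (N * L), where C is the per-gene read count, N the total
#' mapped reads of the library and L the transcript length in base pairs.
#' Vectorized over all three arguments.
#'
#' @param count Non-negative read count(s) C.
#' @param library_size Positive library size(s) N.
#' @param length_bp Positive transcript length(s) L in bp.
#' @return Non-negative numeric RPKM value(s); zero exactly when `count` is 0.
#' @export
#' @examples
#' rpkm(10, 1e6, 1000) # 10
rpkm <- function(count, library_size, length_bp) {
  if (any(library_size < 1)) abort("library_size must be >= 1")
  if (any(length_bp < 1)) abort("length_bp must be >= 1")
  if (any(count < 0)) abort("count must be non-negative")
  1e9 * count / (library_size * length_bp)
}

#' RPKM-normalize a count matrix
#'
#' @param counts Count tibble (`gene_id`, `length_bp`, sample columns).
#' @param lib_sizes Optional named per-sample library sizes; defaults to
#'   column sums of `counts`.
#' @return A tibble with `gene_id` and one RPKM column per sample.
#' @export
rpkm_matrix <- function(counts, lib_sizes = NULL) {
  sample_cols <- setdiff(names(counts), c("gene_id", "length_bp"))
  ns <- library_sizes(counts, lib_sizes)
  out <- tibble(gene_id = counts$gene_id)
  for (s in sample_cols) {
    out[[s]] <- rpkm(counts[[s]], ns[[s]], counts$length_bp)
  }
  out
}

#' Per-group mean expression levels
#'
#' Averages replicate RPKM within each group on the RPKM scale (replicates
#' are never summed here; pooling on the count scale happens only inside the
#' statistical tests). The hybrid group mean is the actual triploid
#' expression level (AT-ELV).
#'
#' @inheritParams rpkm_matrix
#' @param groups Sample-to-group map (see [read_count_matrix()]).
#' @return A tibble with columns `gene_id`, `chi_paternal`, `chi_maternal`,
#'   `at_elv`.
#' @export
#' @examples
#' sim <- generate_dataset(simulation_config(n_genes = 50), seed = 1)
#' expr <- group_means(sim$counts, sim$groups)
group_means <- function(counts, groups, lib_sizes = NULL) {
  groups <- as_group_map(groups)
  counts <- validate_counts(counts, groups)
  r <- rpkm_matrix(counts, lib_sizes)
  role_mean <- function(role) {
    cols <- groups$sample[groups$group == role]
    cols <- intersect(cols, names(r))
    if (length(cols) == 0) abort(paste0("group '", role, "' is empty"))
    rowMeans(as.matrix(r[cols]))
  }
  tibble(gene_id = r$gene_id,
         chi_paternal = role_mean("paternal"),
         chi_maternal = role_mean("maternal"),
         at_elv = role_mean("hybrid"))
}
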