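#' Simulation configuration for planted-category datasets
#'
#' Defaults describe the benchmark design: three groups (paternal, maternal,
#' hybrid) x 3 replicate libraries, sequencing depth 1e6 mapped reads per
#' replicate, negative-binomial noise with dispersion 0.05
#' (variance = mu + dispersion * mu^2), a planted log2 effect size of 3,
#' transcript lengths uniform on 400-4000 bp, and a hybrid dosage factor of
#' 2/3 (compensation from the additive triploid level to the diploid state;
#' 1 simulates no compensation). Baseline expression is log-normal with
#' median 50 RPKM (sdlog 0.6), a detectable-transcriptome baseline.
#' Category proportions default to 5% in each of the twelve categories, 34%
#' no-change, and 3% each silenced and novel.
#'
#' @param n_genes Number of genes.
#' @param category_proportions Named numeric summing to 1 over
#'   I-XII/NoChange/Silenced/Novel (any subset; omitted labels get 0).
#' @param base_meanlog,base_sdlog Log-normal location/scale of the baseline
#'   maternal RPKM.
#' @param effect_lfc Planted log2 effect size between differing levels.
#' @param dispersion Negative-binomial dispersion; 0 gives Poisson sampling.
#' @param library_size Mapped reads per replicate library.
#' @param replicates Replicates per group.
#' @param length_range Transcript length range in bp.
#' @param dosage_factor Multiplier applied to every hybrid expected level.
#' @param floor RPKM floor used when planting silenced/novel genes (the
#'   classifier's detection floor).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 2000,
                              category_proportions = NULL,
                              base_meanlog = log(50), base_sdlog = 0.6,
                              effect_lfc = 3, dispersion = 0.05,
                              library_size = 1e6, replicates = 3,
                              length_range = c(400, 4000),
                              dosage_factor = 2 / 3, floor = 10) {
  if (is.null(category_proportions)) {
    category_proportions <- c(
      setNames(rep(0.05, 12), ROMAN_CATEGORIES),
      NoChange = 0.34, Silenced = 0.03, Novel = 0.03
    )
  }
  ok_labels <- c(ROMAN_CATEGORIES, "NoChange", "Silenced", "Novel")
  bad <- setdiff(names(category_proportions), ok_labels)
  if (length(bad)) abort(paste0("unknown category in proportions: ",
                                paste(bad, collapse = ", ")))
  if (abs(sum(category_proportions) - 1) > 1e-8) {
    abort("category proportions must sum to 1")
  }
  if (dispersion < 0) abort("dispersion must be >= 0")
  if (effect_lfc <= 0) abort("effect_lfc must be positive")
  structure(list(n_genes = n_genes,
                 category_proportions = category_proportions,
                 base_meanlog = base_meanlog, base_sdlog = base_sdlog,
                 effect_lfc = effect_lfc, dispersion = dispersion,
                 library_size = library_size, replicates = replicates,
                 length_range = length_range, dosage_factor = dosage_factor,
                 floor = floor),
            class = "simulation_config")
}

# Expected (paternal, maternal, hybrid) RPKM for one planted category.
# base is the maternal baseline; f = 2^effect_lfc. The hybrid level follows
# the category geometry and is then scaled by the dosage factor.
planted_levels <- function(category, base, f, floor, dosage_factor) {
  g <- base
  b <- switch(category,
    I = , V = , VII = , IX = , XI = f * g,          # paternal above maternal
    II = , VI = , VIII = , X = , XII = g / f,       # maternal above paternal
    III = , IV = , NoChange = g,
    Silenced = base + 3 * floor,
    Novel = 0
  )
  if (category == "Silenced") g <- base + 3 * floor
  if (category == "Novel") g <- 0
  h0 <- switch(category,
    I = g / f,                  # below the lower parent
    II = b / f,
    III = b / f,
    IV = f * b,                 # above the higher parent
    V = f * b,
    VI = f * g,
    VII = b,                    # matches the paternal level
    VIII = b,
    IX = g,                     # matches the maternal level
    X = g,
    XI = (b + g) / 2,           # mid-parent
    XII = (b + g) / 2,
    NoChange = b,
    Silenced = 0,
    Novel = base + 3 * floor
  )
  c(paternal = b, maternal = g, hybrid = h0 * dosage_factor)
}

#' Generate a parent/hybrid count matrix with planted truth
#'
#' Draws a planted category and a baseline expression level per gene, sets
#' the three expected RPKM levels from the category geometry (see
#' [simulation_config()]), scales the hybrid level by the dosage factor,
#' converts expected RPKM to expected per-replicate counts via
#' mu = RPKM * N * L / 1e9, and samples negative-binomial (or Poisson)
#' counts. Deterministic given `seed`.
#'
#' The simulated genes stand for the detected, annotated subset of a
#' transcriptome, so their counts sum to less than the library's total
#' mapped reads; `lib_sizes` carries the true per-library totals, to be
#' passed as the library-size override when normalizing (column sums would
#' understate the depth and couple the planted effects across groups).
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return A list with `counts` (count tibble), `groups` (sample-to-group
#'   map), `lib_sizes` (named true library sizes) and `truth` (per-gene
#'   tibble: `gene_id`, `length_bp`, `category`, expected `chi_paternal`,
#'   `chi_maternal`, `hybrid_expected`).
#' @export
#' @examples
#' sim <- generate_dataset(simulation_config(n_genes = 100), seed = 42)
#' dplyr::count(sim$truth, category)
generate_dataset <- function(config = simulation_config(), seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$effect_lfc <= 1) {
    warn("effect_lfc <= 1 (the default classifier tau): planted categories may not be recoverable")
  }
  set.seed(as.integer(seed))
  n <- config$n_genes
  props <- config$category_proportions
  category <- sample(names(props), n, replace = TRUE, prob = props)
  length_bp <- as.integer(round(runif(n, config$length_range[1],
                                      config$length_range[2])))
  base <- rlnorm(n, config$base_meanlog, config$base_sdlog)
  f <- 2^config$effect_lfc
  levels <- t(vapply(seq_len(n), function(i) {
    planted_levels(category[i], base[i], f, config$floor,
                   config$dosage_factor)
  }, numeric(3)))

  reps <- config$replicates
  samples <- paste0(rep(c("paternal", "maternal", "hybrid"), each = reps),
                    "_", rep(seq_len(reps), 3))
  groups <- tibble(sample = samples,
                   group = rep(c("paternal", "maternal", "hybrid"),
                               each = reps))
  draw <- function(mu) {
    if (config$dispersion == 0) rpois(length(mu), mu)
    else rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
  }
  counts <- tibble(gene_id = sprintf("gene_%05d", seq_len(n)),
                   length_bp = length_bp)
  role_col <- c(paternal = 1, maternal = 2, hybrid = 3)
  for (s in samples) {
    role <- groups$group[groups$sample == s]
    mu <- levels[, role_col[[role]]] * config$library_size * length_bp / 1e9
    counts[[s]] <- as.integer(draw(mu))
  }
  truth <- tibble(gene_id = counts$gene_id, length_bp = length_bp,
                  category = category,
                  chi_paternal = levels[, 1], chi_maternal = levels[, 2],
                  hybrid_expected = levels[, 3])
  attr(truth, "feasible") <- config$effect_lfc > 1
  list(counts = counts, groups = groups,
       lib_sizes = setNames(rep(config$library_size, length(samples)),
                            samples),
       truth = truth)
}

#' Fraction of genes whose assigned category matches the planted one
#'
#' `Ambiguous`, `Unresolved` and `Excluded` assignments count as misses.
#'
#' @param truth Truth tibble from [generate_dataset()].
#' @param assignments Assignment tibble (or `eld_classification`) over the
#'   same gene set.
#' @return Recovery fraction in \[0, 1\].
#' @export
recovery_score <- function(truth, assignments) {
  assignments <- assignment_table(assignments)
  if (!setequal(truth$gene_id, assignments$gene_id)) {
    abort("truth and assignments must cover the same genes")
  }
  i <- match(truth$gene_id, assignments$gene_id)
  mean(assignments$category[i] == truth$category)
}
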