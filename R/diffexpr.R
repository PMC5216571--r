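#' Random-sampling exact test for two RNA-seq libraries
#'
#' Conditional on the total t = c1 + c2 for a gene, c1 is binomial with
#' success probability n1 / (n1 + n2) under the null of equal relative
#' expression in the two libraries. The two-sided p-value sums the point
#' probabilities of every outcome no more likely than the observed one
#' (the small-count-safe exact form of the MA-plot random-sampling model).
#' Vectorized over genes.
#'
#' @param c1,c2 Read counts in library 1 and 2.
#' @param n1,n2 Library sizes (total mapped reads) of library 1 and 2.
#' @return Two-sided p-value(s) in (0, 1]. A gene with c1 + c2 = 0 carries no
#'   information and is reported as p = 1 with a warning.
#' @export
#' @examples
#' binomial_rs_test(0, 10, 1e6, 1e6) # 2/1024
binomial_rs_test <- function(c1, c2, n1, n2) {
  if (any(n1 < 1) || any(n2 < 1)) abort("library sizes must be >= 1")
  if (any(c1 < 0) || any(c2 < 0)) abort("counts must be non-negative")
  n <- max(length(c1), length(c2), length(n1), length(n2))
  c1 <- rep_len(c1, n); c2 <- rep_len(c2, n)
  n1 <- rep_len(n1, n); n2 <- rep_len(n2, n)
  t <- c1 + c2
  if (any(t == 0)) warn("gene(s) with zero counts in both libraries: p set to 1")
  pr <- n1 / (n1 + n2)
  vapply(seq_len(n), function(i) {
    if (t[i] == 0) return(1)
    binom.test(c1[i], t[i], p = pr[i])$p.value
  }, numeric(1))
}

#' Fisher's exact test for two RNA-seq libraries
#'
#' Two-sided Fisher's exact test (point-probability method) on the 2x2 table
#' `[[c1, n1 - c1], [c2, n2 - c2]]`. Vectorized over genes.
#'
#' @inheritParams binomial_rs_test
#' @return Two-sided p-value(s) in (0, 1].
#' @export
fisher_de_test <- function(c1, c2, n1, n2) {
  if (any(n1 < 1) || any(n2 < 1)) abort("library sizes must be >= 1")
  if (any(c1 < 0) || any(c2 < 0)) abort("counts must be non-negative")
  if (any(c1 > n1) || any(c2 > n2)) abort("counts cannot exceed library sizes")
  n <- max(length(c1), length(c2), length(n1), length(n2))
  c1 <- rep_len(c1, n); c2 <- rep_len(c2, n)
  n1 <- rep_len(n1, n); n2 <- rep_len(n2, n)
  vapply(seq_len(n), function(i) {
    tab <- matrix(c(c1[i], n1[i] - c1[i], c2[i], n2[i] - c2[i]),
                  nrow = 2, byrow = TRUE)
    fisher.test(tab)$p.value
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the input.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Up/down/ns call from effect size and FDR
#'
#' Strict inequalities at both thresholds: a gene is `up` when
#' q < `fdr_max` and M > `lfc_min`, `down` when q < `fdr_max` and
#' M < -`lfc_min`, otherwise `ns`.
#'
#' @param m_value log2 expression ratio (may be +/-Inf for one-sided zeros).
#' @param q_value BH-adjusted p-value (or raw p if FDR control is off).
#' @param fdr_max FDR threshold, default 0.001.
#' @param lfc_min Minimum |log2 ratio|, default 1.
#' @return Character vector in `c("up", "down", "ns")`.
#' @export
de_call <- function(m_value, q_value, fdr_max = 0.001, lfc_min = 1) {
  if (fdr_max <= 0 || fdr_max > 1) abort("fdr_max must be in (0, 1]")
  if (lfc_min < 0) abort("lfc_min must be >= 0")
  dplyr::case_when(
    q_value < fdr_max & m_value > lfc_min ~ "up",
    q_value < fdr_max & m_value < -lfc_min ~ "down",
    TRUE ~ "ns"
  )
}

#' Pairwise differential expression between two groups
#'
#' Replicate counts are pooled by summation within each group (the exact
#' tests are two-library tests), M is the log2 ratio of the RPKM of the
#' pooled counts (group_a over group_b), A the mean log2 RPKM (NA when
#' either side is zero), p comes from the chosen exact engine, q from BH
#' adjustment across all tested genes, and the call from [de_call()]. Genes
#' with zero pooled counts on both sides are flagged untested and called ns.
#'
#' @inheritParams group_means
#' @param group_a,group_b Group roles to contrast (`paternal`, `maternal`,
#'   `hybrid`); M > 0 means higher in `group_a`.
#' @param engine `"binomial"` (random-sampling model, default) or
#'   `"fisher"`.
#' @param fdr_max,lfc_min Call thresholds, see [de_call()].
#' @param use_fdr If `FALSE`, calls are made on raw p-values instead of BH
#'   q-values (the raw-p variant of the thresholding).
#' @return A tibble of class `eld_de` with columns `gene_id`, `m`, `a`,
#'   `p_value`, `q_value`, `call`, `tested`.
#' @export
#' @examples
#' sim <- generate_dataset(simulation_config(n_genes = 100), seed = 1)
#' de <- compare_groups(sim$counts, sim$groups, "paternal", "maternal")
#' dplyr::count(de, call)
compare_groups <- function(counts, groups, group_a, group_b,
                           engine = c("binomial", "fisher"),
                           fdr_max = 0.001, lfc_min = 1, use_fdr = TRUE,
                           lib_sizes = NULL) {
  engine <- match.arg(engine)
  groups <- as_group_map(groups)
  counts <- validate_counts(counts, groups)
  for (g in c(group_a, group_b)) {
    if (!g %in% groups$group) abort(paste0("group '", g, "' not present"))
  }
  ns <- library_sizes(counts, lib_sizes)
  pool <- function(role) {
    cols <- intersect(groups$sample[groups$group == role], names(counts))
    list(c = rowSums(as.matrix(counts[cols])), n = sum(ns[cols]))
  }
  a <- pool(group_a)
  b <- pool(group_b)
  len <- counts$length_bp
  ra <- rpkm(a$c, a$n, len)
  rb <- rpkm(b$c, b$n, len)
  m <- log2(ra / rb)
  m[a$c == 0 & b$c == 0] <- NA_real_
  av <- ifelse(ra > 0 & rb > 0, (log2(ra) + log2(rb)) / 2, NA_real_)
  tested <- a$c + b$c > 0
  p <- rep(NA_real_, nrow(counts))
  if (any(tested)) {
    p[tested] <- switch(engine,
      binomial = binomial_rs_test(a$c[tested], b$c[tested], a$n, b$n),
      fisher   = fisher_de_test(a$c[tested], b$c[tested], a$n, b$n)
    )
  }
  q <- rep(NA_real_, nrow(counts))
  q[tested] <- bh_fdr(p[tested])
  crit <- if (use_fdr) q else p
  call <- rep("ns", nrow(counts))
  call[tested] <- de_call(m[tested], crit[tested], fdr_max, lfc_min)
  out <- tibble(gene_id = counts$gene_id, m = m, a = av,
                p_value = p, q_value = q, call = call, tested = tested)
  structure(out,
            class = c("eld_de", class(out)),
            contrast = c(group_a, group_b), engine = engine,
            fdr_max = fdr_max, lfc_min = lfc_min, use_fdr = use_fdr)
}
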