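#' Predicted triploid expression level (PT-ELV)
#'
#' The additive expectation for a triploid carrying one paternal and two
#' maternal genome copies: chi_triploid = 1/2 chi_paternal + chi_maternal.
#' The genome doses are parameterized so reciprocal ploidies can be modelled;
#' the defaults (1 paternal : 2 maternal, each dose expressed relative to the
#' diploid parent's two copies) reproduce the standard cross.
#'
#' @param chi_paternal,chi_maternal Non-negative mean expression (RPKM) of
#'   the paternal and maternal parent.
#' @param paternal_dose,maternal_dose Number of genome copies contributed to
#'   the hybrid by each parent (defaults 1 and 2).
#' @return Numeric predicted level(s).
#' @export
#' @examples
#' predicted_triploid_elv(2, 3) # 4
predicted_triploid_elv <- function(chi_paternal, chi_maternal,
                                   paternal_dose = 1, maternal_dose = 2) {
  if (any(chi_paternal < 0) || any(chi_maternal < 0)) {
    abort("expression levels must be non-negative")
  }
  (paternal_dose / 2) * chi_paternal + (maternal_dose / 2) * chi_maternal
}

#' Predicted diploid expression level (PD-ELV)
#'
#' The mid-parent (diploid-state) expectation:
#' chi_diploid = 1/2 chi_paternal + 1/2 chi_maternal.
#'
#' @inheritParams predicted_triploid_elv
#' @return Numeric predicted level(s).
#' @export
#' @examples
#' predicted_diploid_elv(2, 3) # 2.5
predicted_diploid_elv <- function(chi_paternal, chi_maternal) {
  if (any(chi_paternal < 0) || any(chi_maternal < 0)) {
    abort("expression levels must be non-negative")
  }
  0.5 * chi_paternal + 0.5 * chi_maternal
}

#' Compare actual triploid expression with an in-silico prediction
#'
#' For each gene, M = log2(AT-ELV / prediction), where the prediction is the
#' additive triploid level (PT-ELV) or the mid-parent diploid level (PD-ELV).
#' In the default threshold mode a gene is called `up` (actual above
#' prediction) when M > `lfc_min` and `down` when M < -`lfc_min`; predicted
#' levels have no replicate structure, so no test statistic is attached. In
#' statistical mode (counts supplied) a pseudo-library for the prediction is
#' formed as the same linear combination of the pooled parental counts,
#' rounded to the nearest integer, and the chosen exact engine is applied —
#' with the caveat that predicted counts are pseudo-observations.
#'
#' @param expr Group-expression tibble from [group_means()] (columns
#'   `gene_id`, `chi_paternal`, `chi_maternal`, `at_elv`).
#' @param prediction `"pt"` (additive triploid) or `"pd"` (mid-parent).
#' @param lfc_min Threshold on |M|, default 1 (log2 units).
#' @param counts,groups Optional count matrix and group map; supplying them
#'   switches on statistical mode.
#' @param engine,fdr_max Passed to the exact test in statistical mode.
#' @param paternal_dose,maternal_dose Genome doses, see
#'   [predicted_triploid_elv()].
#' @return A tibble of class `dosage_comparison` with columns `gene_id`,
#'   `at_elv`, `predicted`, `m`, `call`, `tested`; [glance()] gives the
#'   up/down tallies and fractions.
#' @export
#' @examples
#' expr <- growth_gene_expression()
#' glance(dosage_comparison(expr, "pt"))
dosage_comparison <- function(expr, prediction = c("pt", "pd"), lfc_min = 1,
                              counts = NULL, groups = NULL,
                              engine = c("binomial", "fisher"),
                              fdr_max = 0.001,
                              paternal_dose = 1, maternal_dose = 2) {
  prediction <- match.arg(prediction)
  engine <- match.arg(engine)
  if (nrow(expr) == 0) abort("'expr' must be nonempty")
  pred <- switch(prediction,
    pt = predicted_triploid_elv(expr$chi_paternal, expr$chi_maternal,
                                paternal_dose, maternal_dose),
    pd = predicted_diploid_elv(expr$chi_paternal, expr$chi_maternal)
  )
  at <- expr$at_elv
  tested <- !(at == 0 & pred == 0)
  m <- ifelse(tested, log2(at / pred), NA_real_)
  if (!is.null(counts)) {
    groups <- as_group_map(groups)
    counts <- validate_counts(counts, groups)
    if (!identical(counts$gene_id, expr$gene_id)) {
      abort("counts and expr must list the same genes in the same order")
    }
    ns <- library_sizes(counts)
    pool <- function(role) {
      cols <- intersect(groups$sample[groups$group == role], names(counts))
      list(c = rowSums(as.matrix(counts[cols])), n = sum(ns[cols]))
    }
    hy <- pool("hybrid"); pa <- pool("paternal"); ma <- pool("maternal")
    wp <- if (prediction == "pt") paternal_dose / 2 else 0.5
    wm <- if (prediction == "pt") maternal_dose / 2 else 0.5
    pc <- round(wp * pa$c + wm * ma$c)
    pn <- round(wp * pa$n + wm * ma$n)
    warn("statistical mode: predicted counts are pseudo-observations, not measured libraries")
    tested <- hy$c + pc > 0
    p <- rep(NA_real_, length(pc))
    p[tested] <- switch(engine,
      binomial = binomial_rs_test(hy$c[tested], pc[tested], hy$n, pn),
      fisher   = fisher_de_test(hy$c[tested], pc[tested], hy$n, pn)
    )
    q <- rep(NA_real_, length(pc))
    q[tested] <- bh_fdr(p[tested])
    call <- rep("ns", length(pc))
    call[tested] <- de_call(m[tested], q[tested], fdr_max, lfc_min)
    out <- tibble(gene_id = expr$gene_id, at_elv = at, predicted = pred,
                  m = m, p_value = p, q_value = q, call = call,
                  tested = tested)
  } else {
    call <- rep("ns", length(at))
    call[tested] <- dplyr::case_when(
      m[tested] > lfc_min ~ "up",
      m[tested] < -lfc_min ~ "down",
      TRUE ~ "ns"
    )
    out <- tibble(gene_id = expr$gene_id, at_elv = at, predicted = pred,
                  m = m, call = call, tested = tested)
  }
  structure(out, class = c("dosage_comparison", class(out)),
            prediction = toupper(prediction), lfc_min = lfc_min)
}

#' Summarize a dosage comparison
#'
#' Independent tally of the per-gene calls of a [dosage_comparison()]:
#' numbers and fractions of genes whose actual triploid level sits above
#' (`up`) or below (`down`) the prediction.
#'
#' @param x A `dosage_comparison` tibble.
#' @return A one-row tibble: `prediction`, `n_tested`, `n_up`, `n_down`,
#'   `n_ns`, `fraction_up`, `fraction_down`.
#' @export
dosage_summary <- function(x) {
  stopifnot(inherits(x, "dosage_comparison"))
  n_tested <- sum(x$tested)
  n_up <- sum(x$call == "up")
  n_down <- sum(x$call == "down")
  tibble(prediction = attr(x, "prediction"),
         n_tested = n_tested, n_up = n_up, n_down = n_down,
         n_ns = n_tested - n_up - n_down,
         fraction_up = if (n_tested > 0) n_up / n_tested else NA_real_,
         fraction_down = if (n_tested > 0) n_down / n_tested else NA_real_)
}
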