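#' Threshold-based pairwise expression call
#'
#' Two expression levels are judged equal when |log2(x/y)| <= tau (non-strict
#' at the threshold), otherwise `higher` or `lower` according to the sign of
#' the ratio. Vectorized.
#'
#' @param x,y Strictly positive expression levels (RPKM). Genes with zero
#'   expression must be routed to silencing/novel/exclusion first.
#' @param tau Log2-ratio equivalence threshold, default 1.
#' @return Character vector in `c("higher", "lower", "equal")`.
#' @export
#' @examples
#' pairwise_call(4.68, 2.00) # "higher" (log2 = 1.23)
pairwise_call <- function(x, y, tau = 1) {
  if (tau < 0) abort("tau must be >= 0")
  if (any(x <= 0) || any(y <= 0)) {
    abort("pairwise_call requires strictly positive expression; route zero-expression genes to silencing/novel detection first")
  }
  r <- log2(x / y)
  dplyr::case_when(
    abs(r) <= tau ~ "equal",
    r > 0 ~ "higher",
    TRUE ~ "lower"
  )
}

# Decision table mapping the three pairwise calls onto the twelve categories.
# P  = paternal vs maternal, Hb = hybrid vs paternal, Hg = hybrid vs maternal;
# values are h/l/e for higher/lower/equal. Rules are applied in order within
# each parental branch; combinations that are geometrically impossible for a
# single coherent expression triple (they can arise from independent tests in
# statistical mode) fall through to Unresolved.
category_from_calls <- function(P, Hb, Hg) {
  k <- function(v) substr(v, 1, 1)
  p <- k(P); hb <- k(Hb); hg <- k(Hg)
  dplyr::case_when(
    p == "h" & hb == "h" ~ "V",
    p == "h" & hg == "l" ~ "I",
    p == "h" & hb == "e" & hg == "h" ~ "VII",
    p == "h" & hg == "e" & hb == "l" ~ "IX",
    p == "h" & hb == "l" & hg == "h" ~ "XI",
    p == "h" & hb == "e" & hg == "e" ~ "Ambiguous",
    p == "h" ~ "Unresolved",
    p == "l" & hg == "h" ~ "VI",
    p == "l" & hb == "l" ~ "II",
    p == "l" & hb == "e" & hg == "l" ~ "VIII",
    p == "l" & hg == "e" & hb == "h" ~ "X",
    p == "l" & hb == "h" & hg == "l" ~ "XII",
    p == "l" & hb == "e" & hg == "e" ~ "Ambiguous",
    p == "l" ~ "Unresolved",
    hb == "h" & hg == "h" ~ "IV",
    hb == "l" & hg == "l" ~ "III",
    TRUE ~ "NoChange"
  )
}

#' Classify genes into the twelve expression categories
#'
#' Given strictly positive paternal, maternal and hybrid expression levels,
#' forms the three pairwise calls P = (paternal vs maternal),
#' Hb = (hybrid vs paternal), Hg = (hybrid vs maternal) with
#' [pairwise_call()] and maps them onto the twelve expression states:
#' transgressive down (I-III), transgressive up (IV-VI), paternal expression
#' level dominance (VII-VIII), maternal ELD (IX-X), mid-parent (XI-XII),
#' plus `NoChange`, `Ambiguous` (hybrid equal to both parents while the
#' parents differ) and `Unresolved` (inconsistent call triples, only
#' reachable in statistical mode). Vectorized.
#'
#' @param chi_paternal,chi_maternal,at_elv Strictly positive expression
#'   levels of the paternal parent, maternal parent and hybrid.
#' @param tau Log2 equivalence threshold, default 1.
#' @param ambiguous_tiebreak If `TRUE`, `Ambiguous` genes are re-assigned to
#'   the ELD category of the parent with the smaller |log2 ratio| to the
#'   hybrid.
#' @return Character vector of category labels.
#' @export
#' @examples
#' classify_genes(1.28, 0.09, 0.05) # "IX"
#' classify_genes(21.24, 19.72, 53.65) # "IV"
classify_genes <- function(chi_paternal, chi_maternal, at_elv, tau = 1,
                           ambiguous_tiebreak = FALSE) {
  b <- chi_paternal; g <- chi_maternal; h <- at_elv
  if (any(b <= 0) || any(g <= 0) || any(h <= 0)) {
    abort("classify_genes requires strictly positive levels; handle Silenced/Novel/Excluded upstream")
  }
  P <- pairwise_call(b, g, tau)
  Hb <- pairwise_call(h, b, tau)
  Hg <- pairwise_call(h, g, tau)
  cat <- category_from_calls(P, Hb, Hg)
  if (ambiguous_tiebreak && any(cat == "Ambiguous")) {
    i <- which(cat == "Ambiguous")
    to_pat <- abs(log2(h[i] / b[i])) < abs(log2(h[i] / g[i]))
    cat[i] <- ifelse(P[i] == "higher",
                     ifelse(to_pat, "VII", "IX"),
                     ifelse(to_pat, "VIII", "X"))
  }
  cat
}

#' Detect hybrid silencing
#'
#' A gene is silenced when the hybrid shows zero expression while both
#' parents exceed the expression floor.
#'
#' @inheritParams classify_genes
#' @param floor Minimum parental RPKM, default 10.
#' @return Logical vector.
#' @export
detect_silenced <- function(chi_paternal, chi_maternal, at_elv, floor = 10) {
  at_elv == 0 & chi_paternal > floor & chi_maternal > floor
}

#' Detect novel hybrid expression
#'
#' A gene shows novel expression when both parents have zero expression
#' while the hybrid exceeds the expression floor.
#'
#' @inheritParams detect_silenced
#' @return Logical vector.
#' @export
detect_novel <- function(chi_paternal, chi_maternal, at_elv, floor = 10) {
  chi_paternal == 0 & chi_maternal == 0 & at_elv > floor
}

#' Classify every gene of a group-expression table
#'
#' Routing order: `Silenced` and `Novel` genes are detected first; remaining
#' genes with any zero group mean are `Excluded` from ratio classification
#' (the analysis is restricted to genes expressed in parents and offspring);
#' all other genes are classified by [classify_genes()]. In statistical mode
#' the three pairwise calls come from differential-expression results for the
#' three contrasts instead of log2-ratio thresholding.
#'
#' @param expr Group-expression tibble (`gene_id`, `chi_paternal`,
#'   `chi_maternal`, `at_elv`).
#' @param tau Log2 equivalence threshold, default 1.
#' @param floor Silencing/novel RPKM floor, default 10.
#' @param mode `"rpkm-threshold"` (default) or `"statistical"`.
#' @param de_results Required in statistical mode: a named list of three
#'   `eld_de` results — `parental` (paternal vs maternal), `hybrid_paternal`
#'   (hybrid vs paternal), `hybrid_maternal` (hybrid vs maternal) — whose
#'   up/down/ns calls are mapped to higher/lower/equal.
#' @param ambiguous_tiebreak Passed to [classify_genes()].
#' @return An object of class `eld_classification`: a list with
#'   `assignments` (tibble: `gene_id`, the three expression levels, calls
#'   `call_p`, `call_hb`, `call_hg`, and `category`), `summary` (from
#'   [category_summary()]) and the configuration. [tidy()] returns the
#'   assignments, [glance()] the one-row grouped tallies.
#' @export
#' @examples
#' fit <- classify_all(growth_gene_expression())
#' glance(fit)
classify_all <- function(expr, tau = 1, floor = 10,
                         mode = c("rpkm-threshold", "statistical"),
                         de_results = NULL, ambiguous_tiebreak = FALSE) {
  mode <- match.arg(mode)
  if (!all(c("gene_id", "chi_paternal", "chi_maternal", "at_elv") %in% names(expr))) {
    abort("'expr' needs columns gene_id, chi_paternal, chi_maternal, at_elv")
  }
  if (nrow(expr) == 0) abort("'expr' must be nonempty")
  b <- expr$chi_paternal; g <- expr$chi_maternal; h <- expr$at_elv
  if (any(b < 0 | g < 0 | h < 0) || any(!is.finite(b) | !is.finite(g) | !is.finite(h))) {
    abort("expression levels must be finite and non-negative")
  }
  n <- nrow(expr)
  category <- rep(NA_character_, n)
  category[detect_silenced(b, g, h, floor)] <- "Silenced"
  category[detect_novel(b, g, h, floor) & is.na(category)] <- "Novel"
  category[is.na(category) & (b == 0 | g == 0 | h == 0)] <- "Excluded"
  pos <- is.na(category)

  call_p <- call_hb <- call_hg <- rep(NA_character_, n)
  if (mode == "rpkm-threshold") {
    if (any(pos)) {
      call_p[pos] <- pairwise_call(b[pos], g[pos], tau)
      call_hb[pos] <- pairwise_call(h[pos], b[pos], tau)
      call_hg[pos] <- pairwise_call(h[pos], g[pos], tau)
      category[pos] <- classify_genes(b[pos], g[pos], h[pos], tau,
                                      ambiguous_tiebreak)
    }
  } else {
    needed <- c("parental", "hybrid_paternal", "hybrid_maternal")
    if (is.null(de_results) || !all(needed %in% names(de_results))) {
      abort("statistical mode needs de_results = list(parental, hybrid_paternal, hybrid_maternal)")
    }
    de_call_for <- function(de, genes) {
      i <- match(genes, de$gene_id)
      if (any(is.na(i))) abort("de_results do not cover all genes")
      c(up = "higher", down = "lower", ns = "equal")[de$call[i]]
    }
    if (any(pos)) {
      gp <- expr$gene_id[pos]
      # contrast direction: first group of the call vs second; parental is
      # paternal-vs-maternal, the hybrid contrasts are hybrid-vs-parent.
      call_p[pos] <- de_call_for(de_results$parental, gp)
      call_hb[pos] <- de_call_for(de_results$hybrid_paternal, gp)
      call_hg[pos] <- de_call_for(de_results$hybrid_maternal, gp)
      category[pos] <- category_from_calls(call_p[pos], call_hb[pos], call_hg[pos])
    }
  }

  assignments <- tibble(gene_id = expr$gene_id,
                        chi_paternal = b, chi_maternal = g, at_elv = h,
                        call_p = call_p, call_hb = call_hb, call_hg = call_hg,
                        category = category)
  structure(list(assignments = assignments,
                 summary = category_summary(assignments),
                 config = list(tau = tau, floor = floor, mode = mode,
                               ambiguous_tiebreak = ambiguous_tiebreak)),
            class = "eld_classification")
}

#' Tally category assignments
#'
#' Counts per category plus the standard groupings: `down` = I-III,
#' `up` = IV-VI, `paternalELD` = VII-VIII, `maternalELD` = IX-X,
#' `mid` = XI-XII.
#'
#' @param assignments Assignment tibble (or `eld_classification`).
#' @return A tibble with columns `label`, `n`, and a logical `grouping`
#'   marking the aggregate rows.
#' @export
category_summary <- function(assignments) {
  if (inherits(assignments, "eld_classification")) {
    assignments <- assignments$assignments
  }
  counts <- table(factor(assignments$category, levels = ALL_CATEGORIES))
  per_cat <- tibble(label = names(counts), n = as.integer(counts),
                    grouping = FALSE)
  grp <- purrr::imap(CATEGORY_GROUPINGS, function(cats, name) {
    tibble(label = name, n = sum(per_cat$n[per_cat$label %in% cats]),
           grouping = TRUE)
  })
  dplyr::bind_rows(per_cat, dplyr::bind_rows(grp))
}

#' @export
print.eld_classification <- function(x, ...) {
  cat("ELD/HEB classification (", x$config$mode, " mode, tau = ",
      x$config$tau, ")\n", sep = "")
  cat(nrow(x$assignments), "genes\n")
  s <- x$summary
  print(s[s$n > 0, c("label", "n")], n = Inf)
  invisible(x)
}
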