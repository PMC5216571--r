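#' Category enrichment of a gene subset
#'
#' Tests whether a subset of genes (e.g. growth-annotated genes) is
#' over-represented in a category grouping relative to the full gene set.
#' Builds the 2x2 table (subset vs rest) x (in grouping vs not) and returns
#' the one-sided hypergeometric p-value for over-representation together
#' with the sample odds ratio (0.5 continuity correction when a cell is 0).
#'
#' Counts may be given directly (`k`, `n`, `K`, `N`) or derived from two
#' assignment tables.
#'
#' @param subset_assignments Assignment tibble for the subset (or
#'   `eld_classification`).
#' @param all_assignments Assignment tibble for the full gene set; subset
#'   gene ids must be contained in it.
#' @param grouping Either the name of a standard grouping (`"up"`, `"down"`,
#'   `"paternalELD"`, `"maternalELD"`, `"mid"`) or a character vector of
#'   category labels.
#' @param k,n,K,N Direct counts: subset hits, subset size, background hits,
#'   background size (ignore the assignment arguments when supplied).
#' @param background `"rest"` (default: subset compared against the
#'   non-subset remainder, the standard 2x2) or `"all"` (whole set as the
#'   comparator margin).
#' @param alternative `"greater"` (over-representation, default) or
#'   `"two.sided"`.
#' @return A one-row tibble: `grouping`, `subset_hits`, `subset_size`,
#'   `background_hits`, `background_size`, `odds_ratio`, `p_value`.
#' @export
#' @examples
#' category_enrichment(grouping = "up", k = 4, n = 57, K = 70, N = 13893)
category_enrichment <- function(subset_assignments = NULL,
                                all_assignments = NULL,
                                grouping, k = NULL, n = NULL, K = NULL,
                                N = NULL, background = c("rest", "all"),
                                alternative = c("greater", "two.sided")) {
  background <- match.arg(background)
  alternative <- match.arg(alternative)
  cats <- resolve_grouping(grouping)
  label <- if (is.character(grouping) && length(grouping) == 1) grouping else
    paste(cats, collapse = "+")
  if (is.null(k)) {
    sub <- assignment_table(subset_assignments)
    all <- assignment_table(all_assignments)
    if (nrow(sub) == 0) abort("empty subset")
    if (!all(sub$gene_id %in% all$gene_id)) {
      abort("subset gene ids must be a subset of the full gene set")
    }
    k <- sum(sub$category %in% cats)
    n <- nrow(sub)
    K <- sum(all$category %in% cats)
    N <- nrow(all)
  }
  if (!(k <= n && K <= N && k <= K && n <= N)) {
    abort("inconsistent contingency counts (need k <= n, K <= N, k <= K, n <= N)")
  }
  if (background == "rest") {
    tab <- matrix(c(k, n - k, K - k, (N - n) - (K - k)), nrow = 2,
                  byrow = TRUE)
  } else {
    tab <- matrix(c(k, n - k, K, N - K), nrow = 2, byrow = TRUE)
  }
  p <- fisher.test(tab, alternative = alternative)$p.value
  cc <- if (any(tab == 0)) 0.5 else 0
  or <- ((tab[1, 1] + cc) * (tab[2, 2] + cc)) /
    ((tab[1, 2] + cc) * (tab[2, 1] + cc))
  tibble(grouping = label, subset_hits = k, subset_size = n,
         background_hits = K, background_size = N,
         odds_ratio = or, p_value = p)
}

resolve_grouping <- function(grouping) {
  if (is.character(grouping) && length(grouping) == 1 &&
      grouping %in% names(CATEGORY_GROUPINGS)) {
    return(CATEGORY_GROUPINGS[[grouping]])
  }
  bad <- setdiff(grouping, ALL_CATEGORIES)
  if (length(bad) || length(grouping) == 0) {
    abort(paste0("unknown grouping/categories: ", paste(bad, collapse = ", ")))
  }
  grouping
}

assignment_table <- function(x) {
  if (inherits(x, "eld_classification")) x <- x$assignments
  if (!is.data.frame(x) || !all(c("gene_id", "category") %in% names(x))) {
    abort("assignments must have columns gene_id and category")
  }
  x
}

#' Per-grouping counts and percentages
#'
#' Reports, for each standard grouping (down I-III, up IV-VI, paternal ELD
#' VII-VIII, maternal ELD IX-X, mid XI-XII) and each remaining label, the
#' gene count and its percentage of the denominator. When the classified
#' table omits genes known only by count (e.g. no-change genes not printed
#' in a source table), `denominator` overrides the number of assignments and
#' the shortfall is reported as an implicit `NoChange` remainder.
#'
#' @param assignments Assignment tibble (or `eld_classification`).
#' @param denominator Optional total gene count >= `nrow(assignments)`.
#' @return A tibble with columns `label`, `n`, `percent` (full precision)
#'   and `percent_rounded` (one decimal, for report output).
#' @export
#' @examples
#' fit <- classify_all(growth_gene_expression())
#' proportion_report(fit, denominator = 57)
proportion_report <- function(assignments, denominator = NULL) {
  assignments <- assignment_table(assignments)
  if (nrow(assignments) == 0) abort("'assignments' must be nonempty")
  n_assigned <- nrow(assignments)
  if (is.null(denominator)) denominator <- n_assigned
  if (denominator < n_assigned) {
    abort("denominator smaller than the number of assignments")
  }
  s <- category_summary(assignments)
  grp <- s[s$grouping, c("label", "n")]
  other_labels <- setdiff(ALL_CATEGORIES, unlist(CATEGORY_GROUPINGS))
  other <- s[!s$grouping & s$label %in% other_labels & s$n > 0,
             c("label", "n")]
  extra <- denominator - n_assigned
  if (extra > 0) {
    if ("NoChange" %in% other$label) {
      other$n[other$label == "NoChange"] <- other$n[other$label == "NoChange"] + extra
    } else {
      other <- dplyr::bind_rows(other, tibble(label = "NoChange", n = extra))
    }
  }
  out <- dplyr::bind_rows(grp, other)
  out$percent <- 100 * out$n / denominator
  out$percent_rounded <- round(out$percent, 1)
  out
}
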