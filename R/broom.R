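#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @method tidy eld_classification
#' @export
tidy.eld_classification <- function(x, ...) x$assignments

#' @method glance eld_classification
#' @export
glance.eld_classification <- function(x, ...) {
  s <- x$summary
  pick <- function(lbl) s$n[s$label == lbl][1]
  tibble(n_genes = nrow(x$assignments),
         down = pick("down"), up = pick("up"),
         paternalELD = pick("paternalELD"), maternalELD = pick("maternalELD"),
         mid = pick("mid"), no_change = pick("NoChange"),
         ambiguous = pick("Ambiguous"), unresolved = pick("Unresolved"),
         silenced = pick("Silenced"), novel = pick("Novel"),
         excluded = pick("Excluded"))
}

strip_tbl <- function(x, cls) {
  class(x) <- setdiff(class(x), cls)
  as_tibble(x)
}

#' @method tidy dosage_comparison
#' @export
tidy.dosage_comparison <- function(x, ...) strip_tbl(x, "dosage_comparison")

#' @method glance dosage_comparison
#' @export
glance.dosage_comparison <- function(x, ...) dosage_summary(x)

#' @method tidy eld_de
#' @export
tidy.eld_de <- function(x, ...) strip_tbl(x, "eld_de")

#' @method glance eld_de
#' @export
glance.eld_de <- function(x, ...) {
  tibble(contrast = paste(attr(x, "contrast"), collapse = " vs "),
         engine = attr(x, "engine"),
         n_genes = nrow(x), n_tested = sum(x$tested),
         n_up = sum(x$call == "up"), n_down = sum(x$call == "down"),
         n_ns = sum(x$call == "ns"))
}

#' @method tidy qpcr_result
#' @export
tidy.qpcr_result <- function(x, ...) strip_tbl(x, "qpcr_result")

#' @method glance qpcr_result
#' @export
glance.qpcr_result <- function(x, ...) {
  tibble(n_replicates = nrow(x),
         mean_fold_change = mean(x$fold_change),
         sd_fold_change = if (nrow(x) > 1) sd(x$fold_change) else NA_real_)
}
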