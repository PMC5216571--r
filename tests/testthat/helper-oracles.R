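# Independent enumeration oracles. These deliberately avoid the package's
# code paths (and the stats tests behind them): plain sums over dbinom /
# dhyper point probabilities, and a literal step-up for BH.

# Two-sided exact binomial p by enumeration: sum point probabilities of all
# outcomes no more likely than the observed one. The 1 + 1e-7 relative
# fudge guards against ties broken by floating-point rounding.
enum_binom_p <- function(c1, t, pr) {
  probs <- dbinom(0:t, t, pr)
  sum(probs[probs <= probs[c1 + 1] * (1 + 1e-7)])
}

# Two-sided Fisher p for [[c1, n1-c1], [c2, n2-c2]] by hypergeometric
# enumeration conditional on both margins.
enum_fisher_p <- function(c1, c2, n1, n2) {
  t <- c1 + c2
  xs <- max(0, t - n2):min(t, n1)
  probs <- dhyper(xs, n1, n2, t)
  obs <- dhyper(c1, n1, n2, t)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Literal Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) * m / j.
enum_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Tiny deterministic 3-gene x 9-sample count table with all three roles.
tiny_counts <- function() {
  tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    length_bp = c(1000L, 2000L, 500L),
    paternal_1 = c(10L, 40L, 0L), paternal_2 = c(12L, 38L, 0L),
    paternal_3 = c(9L, 41L, 1L),
    maternal_1 = c(11L, 39L, 2L), maternal_2 = c(10L, 42L, 1L),
    maternal_3 = c(12L, 40L, 0L),
    hybrid_1 = c(10L, 39L, 1L), hybrid_2 = c(11L, 41L, 0L),
    hybrid_3 = c(9L, 40L, 2L)
  )
}

tiny_groups <- function() {
  tibble::tibble(
    sample = c(paste0("paternal_", 1:3), paste0("maternal_", 1:3),
               paste0("hybrid_", 1:3)),
    group = rep(c("paternal", "maternal", "hybrid"), each = 3)
  )
}

# Uniform random strictly positive expression triples on a wide log scale.
random_triples <- function(n, seed = 271828) {
  set.seed(seed)
  tibble::tibble(
    b = 2^runif(n, -6, 10),
    g = 2^runif(n, -6, 10),
    h = 2^runif(n, -6, 10)
  )
}
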