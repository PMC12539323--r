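# Independent brute-force oracles used to check the implementation paths,
# plus small shared fixtures built in code.

# Pearson r via the explicit sum formulas.
brute_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# Mann-Kendall S by double loop.
brute_mk_s <- function(x) {
  s <- 0
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) s <- s + sign(x[j] - x[i])
  }
  s
}

# Theil-Sen slope by explicit pair enumeration.
brute_sen <- function(x, t = seq_along(x)) {
  slopes <- c()
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) slopes <- c(slopes, (x[j] - x[i]) / (t[j] - t[i]))
  }
  median(slopes)
}

# Linear-interpolation percentile computed from first principles
# (h = (n-1)p + 1 on the sorted sample).
brute_percentile <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h)
  if (lo == length(xs)) return(xs[lo])
  xs[lo] + (h - lo) * (xs[lo + 1] - xs[lo])
}

# All permutations of a small integer vector.
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# Permutation-averaged Shapley values: mean marginal contribution of each
# feature over all |N|! orderings, via the package's value function only.
perm_shapley <- function(predictor, instance, background) {
  p <- length(predictor$feature_names)
  phi <- stats::setNames(numeric(p), predictor$feature_names)
  perms <- all_perms(seq_len(p))
  for (perm in perms) {
    pre <- integer(0)
    v0 <- value_function(predictor, instance, pre, background)
    for (i in perm) {
      v1 <- value_function(predictor, instance, c(pre, i), background)
      phi[i] <- phi[i] + (v1 - v0)
      pre <- c(pre, i)
      v0 <- v1
    }
  }
  phi / length(perms)
}

# Shared small landscape, generated once per test run.
.shared <- new.env(parent = emptyenv())
shared_landscape <- function() {
  if (is.null(.shared$ls)) {
    .shared$cfg <- synthetic_config(n_rows = 40, n_cols = 40, seed = 101)
    .shared$ls <- generate_landscape(.shared$cfg)
    .shared$es <- compute_es_stack(.shared$ls)
    .shared$labels <- classify_drought(.shared$ls$dynamic$SPEI)
    .shared$spei_f <- drought_frequency(.shared$labels)
  }
  .shared
}

# The drought-prone agricultural configuration used for stratified
# correlation recovery: a majority-cropland landscape whose agricultural
# bundles carry high extreme-drought proneness, so roughly 5,000 cropland
# cells experience extreme drought at a 160 x 160 grid.
drought_prone_config <- function(seed, n_rows = 160, n_cols = 160) {
  strat <- rbind(
    B1 = c(0.40, 0.30, 0.20, 0.07, 0.03),
    B2 = c(0.50, 0.30, 0.12, 0.05, 0.03),
    B3 = c(0.15, 0.15, 0.15, 0.15, 0.40),
    B4 = c(0.15, 0.15, 0.20, 0.20, 0.30))
  colnames(strat) <- c("none", "slight", "medium", "serious", "extreme")
  synthetic_config(n_rows = n_rows, n_cols = n_cols, seed = seed,
                   mixing_fractions = c(B1 = 0.15, B2 = 0.05,
                                        B3 = 0.55, B4 = 0.25),
                   stratum_by_bundle = strat)
}
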