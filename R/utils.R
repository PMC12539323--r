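# Small internal helpers shared across modules.

# Stop with a classed condition so callers/tests can distinguish error kinds.
stop_esd <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "esdrought_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# All grids in one dataset must agree in shape; NA encodes an invalid cell.
check_same_shape <- function(..., .names = NULL) {
  mats <- list(...)
  dims <- lapply(mats, function(m) dim(m)[1:2])
  ref <- dims[[1]]
  ok <- vapply(dims, function(d) identical(as.integer(d), as.integer(ref)), TRUE)
  if (!all(ok)) {
    bad <- if (!is.null(.names)) paste(.names[!ok], collapse = ", ") else "inputs"
    stop_esd("esd_dim_error", "grid shape mismatch: %s", bad)
  }
  invisible(ref)
}

# Clamp to [lo, hi]; keeps NA.
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same cells,
#' used to validate recovered ecosystem-service bundles against planted
#' cluster labels. 1 means identical partitions (up to relabeling), 0 the
#' expected agreement of independent random partitions.
#'
#' @param a,b integer or factor label vectors of equal length.
#' @return a single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_esd("esd_dim_error", "label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# Significance stars matching the reporting convention
# (* p<0.05, ** p<0.01, *** p<0.001).
p_stars <- function(p) {
  ifelse(is.na(p), "",
    ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

# Deterministic child seed derived from a user seed and a stage tag.
# Kept below 2^31 - 1.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
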