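#' @importFrom rlang %||% .data
#' @importFrom stats cor lm coef confint quantile rnorm runif sd var median
#' @importFrom utils combn
NULL

# mean absolute difference over all unordered pairs of x (length >= 2),
# computed from the sorted values: sum_{j<k} |x_j - x_k| =
# sum_i (2i - p - 1) * x_(i).
mean_abs_pairdiff <- function(x) {
  p <- length(x)
  x <- sort(x)
  sum((2 * seq_len(p) - p - 1) * x) / (p * (p - 1) / 2)
}

# Slot structure for permutation machinery: trait values of informative
# partners grouped into contiguous respondent blocks.
# values: numeric; group: integer block ids 1..n_groups (non-decreasing);
# sizes: partners per block (all >= 2).
new_slots <- function(values, group) {
  sizes <- tabulate(group)
  stopifnot(all(sizes[unique(group)] >= 2L))
  list(values = values, group = group, sizes = sizes,
       n_groups = max(group), n_slots = length(values))
}

# Population consistency index for a slot structure: the unweighted mean over
# respondents of the per-respondent mean absolute pairwise difference.
# Vectorized over all blocks via the sorted-weight identity.
slots_delta <- function(values, group, sizes) {
  ord <- order(group, values)
  v <- values[ord]
  g <- group[ord]
  p <- sizes[g]                      # block size, per slot
  k <- sequence(sizes)               # within-block rank, per slot
  contrib <- (2 * k - p - 1) * v / (p * (p - 1) / 2)
  mean(rowsum(contrib, g))
}

# Deterministic seed derivation: a stream of child seeds from a master seed.
# Pure function of (seed, n); children stay below 2^31.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
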