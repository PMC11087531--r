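# Shared fixtures, all generated in code.

onemax <- function(bits) sum(bits == 0)

# Random objective lookup table over {0,1}^d; the exhaustive minimum is
# the oracle for the binary optimizers.
random_table_objective <- function(d, seed) {
  tab <- qibgwo:::with_seed(seed, stats::runif(2^d))
  list(fn = function(bits) tab[sum(bits * 2^(seq_along(bits) - 1)) + 1],
       minimum = min(tab))
}

# Two well-separated Gaussian blobs in 2-D.
make_blobs <- function(n_per_class = 30, sep = 6, seed = 1) {
  qibgwo:::with_seed(seed, {
    x <- rbind(matrix(stats::rnorm(n_per_class * 2), ncol = 2),
               matrix(stats::rnorm(n_per_class * 2, mean = sep), ncol = 2))
    list(x = x, y = factor(rep(c("a", "b"), each = n_per_class)))
  })
}

# Brute-force AUC: concordant pairs plus half ties over all pos/neg pairs.
auc_by_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

tiny_phantom_spec <- function(...) {
  phantom_spec(image_size = 160, seed = 99, ...)
}
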