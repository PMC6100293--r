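# Shared fixture builders: small property sets and synthetic linear data.

# k property scales with deterministic values (no RNG): property i gives
# residue r the value sin(i * rank(r)) so columns are distinct and
# non-constant.
make_props <- function(k, prefix = "PROP") {
  res <- standard_residues()
  lapply(seq_len(k), function(i) {
    v <- sin(i * seq_along(res))
    names(v) <- res
    aaindex_entry(sprintf("%s%06d", prefix, i), sprintf("test scale %d", i), v)
  })
}

# Gaussian design matrix with named columns.
make_X <- function(n, p, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  X
}

# y = X[, support] %*% beta + noise, autoscaled on both sides.
make_linear_data <- function(n = 60, p = 20, support = 7, beta = 2,
                             noise_sd = 0.05, seed = 1) {
  X <- make_X(n, p, seed)
  y <- as.vector(X[, support, drop = FALSE] %*% beta) + rnorm(n, 0, noise_sd)
  sc <- autoscale(X, y)
  list(X = sc$X, y = sc$y, params = sc$params, X_raw = X, y_raw = y)
}

fixture_path <- function() {
  system.file("extdata", "aaindex_synthetic.txt", package = "pepqsar")
}
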