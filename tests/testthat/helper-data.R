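# Fixtures built in code, shared across test files.

# Small random raw function matrix with named columns.
random_function_matrix <- function(n = 20, p = 6, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * p, mean = 10, sd = 3), n, p,
              dimnames = list(sprintf("s%02d", 1:n), paste0("f", 1:p)))
  m
}

# A service map of given sizes over the columns of m.
service_map_of_sizes <- function(m, sizes) {
  stopifnot(sum(sizes) == ncol(m))
  idx <- split(colnames(m), rep(seq_along(sizes), sizes))
  names(idx) <- paste0("svc", seq_along(sizes))
  idx
}

# Simulate Gaussian data from the chain X -> M -> Y.
simulate_chain <- function(n, b_xm = 0.5, b_my = 0.5, b_xy = 0) {
  X <- rnorm(n)
  M <- b_xm * X + rnorm(n)
  Y <- b_my * M + b_xy * X + rnorm(n)
  data.frame(X = X, M = M, Y = Y)
}

# Independent two-stage mean: group means then mean of group means.
brute_force_weighted_emf <- function(std, service_map) {
  sapply(seq_len(nrow(std)), function(i) {
    mean(sapply(service_map, function(fns) mean(std[i, fns])))
  })
}
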