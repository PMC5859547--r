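# Shared fixtures and independent oracles, all built in code at test time.

rand_tree <- function(p, seed) {
  set.seed(seed)
  ape::rcoal(p, tip.label = paste0("O", seq_len(p)))
}

rand_counts <- function(n, p, seed, lambda = 6) {
  set.seed(seed)
  matrix(rpois(n * p, lambda), n, p,
         dimnames = list(paste0("S", seq_len(n)), paste0("O", seq_len(p))))
}

rand_comp <- function(n, p, seed) {
  set.seed(seed)
  m <- matrix(rgamma(n * p, 0.5), n, p,
              dimnames = list(paste0("S", seq_len(n)), paste0("O", seq_len(p))))
  m / rowSums(m)
}

# exhaustive k-medoids search: global minimum of total within-cluster
# distance-to-medoid over every medoid subset (feasible for p <= 12)
brute_force_medoids <- function(D, k) {
  combs <- utils::combn(nrow(D), k)
  costs <- apply(combs, 2L, function(s)
    sum(apply(D[, s, drop = FALSE], 1L, min)))
  j <- which.min(costs)
  list(medoids = sort(combs[, j]), cost = costs[j])
}

medoid_cost <- function(D, medoids) {
  sum(apply(D[, medoids, drop = FALSE], 1L, min))
}

# simple survival fixture with events and censoring
rand_surv <- function(n, seed, q = 1) {
  set.seed(seed)
  X <- if (q > 0) matrix(rnorm(n * q), n, q,
                         dimnames = list(NULL, paste0("x", seq_len(q))))
       else NULL
  eta <- if (q > 0) drop(X %*% rep(0.5, q)) else numeric(n)
  T_true <- rexp(n, rate = exp(eta))
  C <- runif(n, 0, quantile(T_true, 0.8) * 2)
  list(time = pmin(T_true, C), event = as.integer(T_true <= C), X = X)
}
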