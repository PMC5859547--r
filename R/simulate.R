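#' Method-of-moments fit of a Dirichlet-multinomial model
#'
#' Estimates the proportion-mean vector \eqn{\pi} and the overdispersion
#' parameter \eqn{\varphi} of a Dirichlet-multinomial count model.  Under
#' the model, sample proportions have
#' \eqn{Var(p_{ij}) = \pi_j (1-\pi_j)(\varphi + (1-\varphi)/N_i)}; the
#' moment estimator pools the per-OTU sample variances against that
#' identity (using the mean read depth), clamped to \[0, 1).
#'
#' @param counts Samples-by-OTUs count matrix with at least 2 samples.
#' @return A list of class `"dm_params"` with `pi` (simplex vector, named by
#'   OTU) and `phi` (scalar in \[0, 1)).
#' @export
fit_dirichlet_multinomial <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L) stop("at least two samples are required")
  N <- rowSums(counts)
  if (any(N <= 0)) stop("zero total count for some sample")
  P <- counts / N
  pi_hat <- colMeans(P)
  s2 <- apply(P, 2L, stats::var)
  v <- pi_hat * (1 - pi_hat)
  Nbar <- mean(N)
  num <- sum(s2 - v / Nbar)
  den <- sum(v * (1 - 1 / Nbar))
  phi_hat <- if (den > 0) num / den else 0
  phi_hat <- min(max(phi_hat, 0), 1 - 1e-12)
  structure(list(pi = pi_hat, phi = phi_hat), class = "dm_params")
}

#' Synthetic Dirichlet-multinomial parameters and tree
#'
#' Generates a documented stand-in for composition parameters estimated
#' from a real 16S survey: a heavy-tailed proportion-mean vector (log-normal
#' weights, so a few OTUs carry most of the abundance and a long tail of
#' rare OTUs remains), floored so that every OTU passes a 1e-4
#' mean-abundance filter, together with a random coalescent tree over the
#' OTUs.  These synthetic parameters are clearly labelled as such: they
#' reproduce the qualitative shape of real gut communities, not any
#' particular dataset.
#'
#' @param p Number of OTUs (>= 2); default 353.
#' @param phi Overdispersion, default 0.02.
#' @param sdlog Log-scale SD of the abundance weights, default 2.5 (gives
#'   max/median proportion ratios in the hundreds).
#' @param floor_prop Additive floor applied before renormalization so the
#'   rarest OTU keeps mean proportion above ~1.8e-4, default 2e-4.
#' @param seed Optional integer seed.
#' @return A list of class `"dm_params"` with `pi`, `phi` and `tree` (an
#'   [ape::phylo] whose tip labels are the OTU names `OTU1..OTUp`).
#' @export
synth_dm_params <- function(p = 353L, phi = 0.02, sdlog = 2.5,
                            floor_prop = 2e-4, seed = NULL) {
  if (p < 2L) stop("p must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  w <- exp(stats::rnorm(p, 0, sdlog))
  pi0 <- w / sum(w)
  pi <- (pi0 + floor_prop) / (1 + p * floor_prop)
  names(pi) <- paste0("OTU", seq_len(p))
  tree <- ape::rcoal(p, tip.label = paste0("OTU", seq_len(p)))
  structure(list(pi = pi, phi = phi, tree = tree), class = "dm_params")
}

#' Simulate OTU counts from a Dirichlet-multinomial model
#'
#' Per sample, proportions are drawn from
#' Dirichlet(\eqn{\pi (1-\varphi)/\varphi}) and counts from a multinomial
#' with `total_reads` trials.  As \eqn{\varphi \to 0} the Dirichlet
#' concentrates at \eqn{\pi} and only multinomial noise remains.
#'
#' @param params A `"dm_params"` object (or list with `pi`, `phi`).
#' @param n Number of samples.
#' @param total_reads Reads per sample, default 1000.
#' @param seed Optional integer seed.
#' @return n x p count matrix with rows `S1..Sn`, columns `names(pi)`.
#' @export
simulate_counts <- function(params, n, total_reads = 1000L, seed = NULL) {
  if (total_reads < 1L) stop("total_reads must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  pi <- params$pi
  phi <- params$phi
  p <- length(pi)
  if (phi > 0) {
    alpha <- pi * (1 - phi) / phi
    G <- matrix(stats::rgamma(n * p, shape = rep(alpha, each = n)), n, p)
    # numerically-degenerate rows (all gammas underflow) fall back to pi
    zero <- rowSums(G) == 0
    if (any(zero)) G[zero, ] <- rep(pi, each = sum(zero))
    prob <- G / rowSums(G)
  } else {
    prob <- matrix(pi, n, p, byrow = TRUE)
  }
  cnt <- t(vapply(seq_len(n),
                  function(i) stats::rmultinom(1L, total_reads, prob[i, ])[, 1L],
                  integer(p)))
  dimnames(cnt) <- list(paste0("S", seq_len(n)), names(pi))
  cnt
}

#' Simulate the two standard covariates
#'
#' Age ~ N(50, 5^2) and sex ~ Bernoulli(0.5).
#'
#' @param n Number of samples.
#' @param seed Optional integer seed.
#' @return List with numeric vectors `age` and `sex`.
#' @export
simulate_covariates <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  list(age = stats::rnorm(n, 50, 5), sex = stats::rbinom(n, 1L, 0.5))
}

#' Cluster OTUs by cophenetic distance with PAM
#'
#' Partitions the tips of a tree into k clusters by partitioning-around-
#' medoids on the cophenetic (tree-path) distances.  Used by the
#' phylogenetic association scenario, where one cluster's OTUs are made
#' jointly associated with survival.
#'
#' @param tree Rooted [ape::phylo] tree.
#' @param k Number of clusters, default 10.
#' @return Integer cluster assignment named by tip label.
#' @export
pam_clusters <- function(tree, k = 10L) {
  D <- stats::cophenetic(tree)
  cl <- cluster::pam(stats::as.dist(D), k = k, cluster.only = TRUE)
  stats::setNames(as.integer(cl), rownames(D))
}

#' Select the set of associated OTUs for a power scenario
#'
#' Scenarios: `"abundant10"` — the 10 largest mean abundances;
#' `"rare10"` — the 10 smallest; `"random10"` — 10 uniformly sampled OTUs;
#' `"pam_cluster"` — all OTUs of one cluster chosen uniformly at random
#' from a k=10 PAM partition of the cophenetic distances (re-randomized per
#' replicate to avoid an arbitrary fixed choice).
#'
#' @param scenario One of `"abundant10"`, `"random10"`, `"rare10"`,
#'   `"pam_cluster"`.
#' @param pi Proportion-mean vector (named by OTU).
#' @param tree Tree, required for `"pam_cluster"` unless `clusters` given.
#' @param clusters Optional precomputed [pam_clusters()] assignment.
#' @param n_assoc Number of associated OTUs for the first three scenarios.
#' @param seed Optional integer seed.
#' @return Integer vector of column indices into `pi`.
#' @export
select_associated_otus <- function(scenario = c("abundant10", "random10",
                                                "rare10", "pam_cluster"),
                                   pi, tree = NULL, clusters = NULL,
                                   n_assoc = 10L, seed = NULL) {
  scenario <- match.arg(scenario)
  p <- length(pi)
  if (scenario != "pam_cluster" && p < n_assoc) {
    stop("need at least ", n_assoc, " OTUs for scenario ", scenario)
  }
  if (!is.null(seed)) set.seed(seed)
  switch(scenario,
    abundant10 = order(pi, decreasing = TRUE)[seq_len(n_assoc)],
    rare10 = order(pi)[seq_len(n_assoc)],
    random10 = sample.int(p, n_assoc),
    pam_cluster = {
      if (is.null(clusters)) {
        if (is.null(tree)) stop("pam_cluster scenario requires a tree")
        clusters <- pam_clusters(tree)
      }
      clusters <- clusters[names(pi)]
      chosen <- sample(unique(clusters), 1L)
      which(clusters == chosen)
    })
}

#' Draw OTU effect coefficients
#'
#' Coefficients are zero outside the associated set; within it they are
#' sampled Unif(0, u) for the same-direction regime or Unif(-u, u) for the
#' mixed-direction regime.
#'
#' @param idx Indices of associated OTUs.
#' @param p Total number of OTUs.
#' @param direction `"same"` or `"mixed"`.
#' @param u Effect-size upper bound (1, 2 or 3 in the standard design).
#' @param seed Optional integer seed.
#' @return Numeric coefficient vector of length p.
#' @export
draw_effects <- function(idx, p, direction = c("same", "mixed"), u,
                         seed = NULL) {
  direction <- match.arg(direction)
  if (!is.null(seed)) set.seed(seed)
  beta <- numeric(p)
  lo <- if (direction == "same") 0 else -u
  beta[idx] <- stats::runif(length(idx), lo, u)
  beta
}

#' Simulate survival outcomes from composition under a Weibull baseline
#'
#' Inverts a Weibull(shape 2, scale 2) proportional hazards model:
#' \deqn{T_i = \sqrt{-4 \log U_i / \exp(0.5(age_i - 50) + 0.5\,sex_i +
#'   \sum_j \beta_j\, scale(Z_{ij}))}}
#' with \eqn{U_i \sim} Unif(0,1) and `scale()` the column-wise
#' (value - mean)/SD standardization (n-1 denominator SD).  Censoring times
#' are Unif(0, `censor_upper`); `censor_upper = 10` yields ~26% censoring
#' and `censor_upper = 5` ~40% under the null.  A zero-variance OTU column
#' with nonzero coefficient contributes 0 to the linear predictor, with a
#' warning.
#'
#' @param Z Samples-by-OTUs relative abundance matrix.
#' @param age,sex Covariate vectors.
#' @param beta OTU coefficient vector (length `ncol(Z)`).
#' @param censor_upper Upper bound of the uniform censoring distribution.
#' @param seed Optional integer seed.
#' @return A `"survival_data"` object (with `covariates = cbind(age, sex)`)
#'   carrying the true event time as attribute `"latent_time"`.
#' @export
simulate_survival <- function(Z, age, sex, beta, censor_upper = 10,
                              seed = NULL) {
  if (censor_upper <= 0) stop("censor_upper must be positive")
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (length(beta) != ncol(Z)) stop("beta length must equal ncol(Z)")
  if (!is.null(seed)) set.seed(seed)
  eta_z <- numeric(n)
  act <- which(beta != 0)
  if (length(act)) {
    Za <- Z[, act, drop = FALSE]
    mu <- colMeans(Za)
    sdv <- apply(Za, 2L, stats::sd)
    degen <- sdv == 0
    if (any(degen)) {
      warning("zero-variance OTU column(s) with nonzero effect; ",
              "scaled value set to 0")
      sdv[degen] <- 1
      mu[degen] <- 0
      Za[, degen] <- 0
    }
    eta_z <- drop(scale(Za, center = mu, scale = sdv) %*% beta[act])
  }
  eta <- 0.5 * (age - 50) + 0.5 * sex + eta_z
  U <- stats::runif(n)
  T_true <- sqrt(-4 * log(U) / exp(eta))
  C <- stats::runif(n, 0, censor_upper)
  out <- survival_data(time = pmin(T_true, C),
                       event = as.integer(T_true <= C),
                       covariates = cbind(age = age, sex = sex))
  attr(out, "latent_time") <- T_true
  out
}

#' Run a type-I-error or power experiment
#'
#' Monte-Carlo study of the full pipeline under the standard design: per
#' replicate, Dirichlet-multinomial counts (p OTUs, `total_reads` per
#' sample), age/sex covariates, a Weibull survival model with uniform
#' censoring, the Cox null fit adjusting for age and sex, and the adaptive
#' tests over the default candidate bank.  `scenario = "null"` sets all OTU
#' coefficients to zero (type I error); the other scenarios make 10 OTUs
#' (or one PAM cluster) associated, with per-replicate re-draws of the
#' random/cluster selection and of the effect coefficients.
#'
#' @param scenario `"null"`, `"abundant10"`, `"random10"`, `"rare10"` or
#'   `"pam_cluster"`.
#' @param direction Effect-direction regime (`"same"` or `"mixed"`),
#'   ignored for `"null"`.
#' @param u Effect-size upper bound, ignored for `"null"`.
#' @param censor_upper 10 (~26% censoring) or 5 (~40%).
#' @param n Samples per replicate.
#' @param reps Number of replicates.
#' @param B Permutations per test.
#' @param params `"dm_params"` (defaults to [synth_dm_params()] with the
#'   experiment seed).
#' @param total_reads Reads per sample.
#' @param alpha Significance level for the rejection-rate summary.
#' @param seed Integer seed; every random draw in the experiment is derived
#'   from it, so results are bit-reproducible.
#' @param gammas,kernels Candidate sets, as in [omisa_test()].
#' @return A data.frame of class `"omisurv_experiment"` with one row per
#'   test (8 individual + 3 adaptive): rejection rate, Monte-Carlo binomial
#'   SE and `reps`.  The per-replicate p-value matrix is attached as
#'   attribute `"p_matrix"`, the observed censoring proportion as
#'   `"censored_fraction"`.
#' @export
run_experiment <- function(scenario = c("null", "abundant10", "random10",
                                        "rare10", "pam_cluster"),
                           direction = c("same", "mixed"), u = 2,
                           censor_upper = 10, n = 100L, reps = 500L,
                           B = 1000L, params = NULL, total_reads = 1000L,
                           alpha = 0.05, seed = 1L,
                           gammas = c(1 / 4, 1 / 3, 1 / 2, 1),
                           kernels = c("u", "g0.5", "w", "bc")) {
  scenario <- match.arg(scenario)
  direction <- match.arg(direction)
  set.seed(seed)
  if (is.null(params)) params <- synth_dm_params(seed = seed)
  p <- length(params$pi)
  tree_idx <- tree_branch_index(params$tree)
  clusters <- if (scenario == "pam_cluster") pam_clusters(params$tree)
              else NULL
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 4L * reps),
                      nrow = reps)

  p_mat <- NULL
  censored <- numeric(reps)
  for (r in seq_len(reps)) {
    cnt <- simulate_counts(params, n, total_reads, seed = rep_seeds[r, 1L])
    Z <- to_composition(cnt)
    cov <- simulate_covariates(n, seed = rep_seeds[r, 2L])
    set.seed(rep_seeds[r, 3L])
    beta <- if (scenario == "null") numeric(p) else {
      idx <- select_associated_otus(scenario, params$pi, clusters = clusters,
                                    tree = params$tree)
      draw_effects(idx, p, direction, u)
    }
    sv <- suppressWarnings(
      simulate_survival(Z, cov$age, cov$sex, beta, censor_upper))
    censored[r] <- 1 - mean(sv$event)
    res <- omisa_test(Z, sv, tree = tree_idx, gammas = gammas,
                      kernels = kernels, B = B, seed = rep_seeds[r, 4L])
    pv <- c(res$p_value, res$p_adaptive)
    if (is.null(p_mat)) {
      p_mat <- matrix(NA_real_, reps, length(pv),
                      dimnames = list(NULL, names(pv)))
    }
    p_mat[r, ] <- pv
  }
  keep <- colSums(!is.na(p_mat)) > 0
  p_mat <- p_mat[, keep, drop = FALSE]
  rate <- colMeans(p_mat <= alpha)
  out <- data.frame(test = colnames(p_mat),
                    rejection_rate = unname(rate),
                    mc_se = unname(sqrt(rate * (1 - rate) / reps)),
                    reps = reps, stringsAsFactors = FALSE)
  attr(out, "p_matrix") <- p_mat
  attr(out, "censored_fraction") <- mean(censored)
  attr(out, "config") <- list(scenario = scenario, direction = direction,
                              u = u, censor_upper = censor_upper, n = n,
                              B = B, alpha = alpha, seed = seed,
                              total_reads = total_reads, p = p)
  class(out) <- c("omisurv_experiment", "data.frame")
  out
}
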