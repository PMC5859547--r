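#' Variance-component score statistic
#'
#' \eqn{U = r' M r} for a residual vector r and a symmetric PSD similarity
#' matrix M.  Under the variance-component formulation of the community
#' association null hypothesis (\eqn{H_0: \sigma^2 = 0} for random OTU
#' coefficients with correlation structure induced by M), U is the
#' unstandardized score statistic; its null distribution is obtained by
#' residual permutation, so no standardization is needed.
#'
#' @param r Numeric residual vector (martingale residuals of the null fit).
#' @param M Symmetric PSD matrix of matching dimension.
#' @return Non-negative scalar.
#' @export
score_statistic <- function(r, M) {
  r <- as.numeric(r)
  M <- as.matrix(M)
  if (nrow(M) != length(r) || ncol(M) != length(r)) {
    stop("dimension mismatch between residuals and similarity matrix")
  }
  max(0, drop(crossprod(r, M %*% r)))
}

#' Residual-permutation p-values for a bank of score tests
#'
#' Draws B uniform random permutations of the residual vector once and
#' shares them across every candidate matrix, so individual and adaptive
#' p-values come from the same ensemble ("no double permutation").  For
#' candidate c with observed statistic \eqn{U_c} and permuted statistics
#' \eqn{U_c^{(b)}}:
#' \deqn{p_c = (1 + \#\{b: U_c^{(b)} \ge U_c\}) / (B + 1).}
#' Each permutation also receives a per-candidate pseudo p-value by ranking
#' its statistic within the ensemble, \eqn{p_c^{(b)} = \#\{b': U_c^{(b')}
#' \ge U_c^{(b)}\} / B}; the adaptive statistic of a candidate group is the
#' observed minimum p over the group, \eqn{Q = \min_c p_c}, and its p-value
#' is \deqn{p_{adapt} = (1 + \#\{b: \min_c p_c^{(b)} \le Q\}) / (B + 1).}
#' Ties are counted in the conservative direction and the add-one form
#' guarantees p-values in (0, 1], always a positive multiple of 1/(B+1).
#'
#' @param r Residual vector.
#' @param bank A [build_kernel_bank()] object (or named list of symmetric
#'   matrices, each with a `"group"` attribute `"MiSALN"` or `"MiRKAT-S"`).
#' @param B Number of permutations (>= 1).
#' @param seed Optional integer seed; recorded in the result.
#' @return A list of class `"omisa_test"`: `statistic` and `p_value` (named
#'   per candidate), `Q` and `p_adaptive` (named `OMiSALN`, `OMiRKAT-S`,
#'   `OMiSA`; entries are `NA` for empty groups), `B`, `seed`, `n`.
#' @export
permutation_engine <- function(r, bank, B = 5000L, seed = NULL) {
  r <- as.numeric(r)
  n <- length(r)
  if (!length(bank)) stop("empty candidate bank")
  if (B < 1L) stop("B must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  labels <- names(bank)
  C <- length(bank)
  groups <- vapply(bank, function(m) attr(m, "group") %||% "MiSALN",
                   character(1L))

  perm <- vapply(seq_len(B), function(b) sample.int(n), integer(n))  # n x B
  Rp <- matrix(r[perm], nrow = n)

  U_obs <- numeric(C)
  p_ind <- numeric(C)
  pseudo <- matrix(0, B, C)
  for (cc in seq_len(C)) {
    M <- as.matrix(bank[[cc]])
    if (nrow(M) != n) stop("candidate '", labels[cc], "' has wrong dimension")
    U_obs[cc] <- max(0, drop(crossprod(r, M %*% r)))
    Up <- colSums(Rp * (M %*% Rp))
    p_ind[cc] <- (1 + sum(Up >= U_obs[cc])) / (B + 1)
    # #{b': U^(b') >= U^(b)} including b itself, via min-rank
    geq <- B - rank(Up, ties.method = "min") + 1
    pseudo[, cc] <- geq / B
  }
  names(U_obs) <- names(p_ind) <- labels

  adaptive <- function(sel) {
    if (!any(sel)) return(c(Q = NA_real_, p = NA_real_))
    Q <- min(p_ind[sel])
    minp <- if (sum(sel) == 1L) pseudo[, sel] else
      do.call(pmin, as.data.frame(pseudo[, sel, drop = FALSE]))
    c(Q = Q, p = (1 + sum(minp <= Q)) / (B + 1))
  }
  a_saln <- adaptive(groups == "MiSALN")
  a_rkat <- adaptive(groups == "MiRKAT-S")
  a_all <- adaptive(rep(TRUE, C))

  structure(list(
    statistic = U_obs,
    p_value = p_ind,
    Q = c("OMiSALN" = unname(a_saln["Q"]),
          "OMiRKAT-S" = unname(a_rkat["Q"]),
          "OMiSA" = unname(a_all["Q"])),
    p_adaptive = c("OMiSALN" = unname(a_saln["p"]),
                   "OMiRKAT-S" = unname(a_rkat["p"]),
                   "OMiSA" = unname(a_all["p"])),
    group = groups,
    B = as.integer(B),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    n = n), class = "omisa_test")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adaptive microbiome association test for survival outcomes
#'
#' End-to-end community-level test: fits the covariate-only Cox null model,
#' builds the candidate bank (MiSALN correlation matrices over `gammas`,
#' distance kernels over `kernels`) and calibrates individual and adaptive
#' p-values with one shared residual-permutation ensemble.  OMiSA's p-value
#' is the calibrated minimum over all candidates, adapting across both the
#' abundance-scale axis (which \eqn{\gamma}) and the distance-metric axis
#' (which ecological kernel).
#'
#' @param Z Samples-by-OTUs relative abundance matrix.  For a higher-level
#'   taxon, pass the column subset of the community matrix (abundances on
#'   the community scale, rows not re-normalized; see
#'   [taxon_composition()]).
#' @param time,event Observed times and 0/1 event indicators, aligned with
#'   the rows of `Z`.  `time` may instead be a `"survival_data"` object.
#' @param covariates Optional n x q covariate matrix (NULL = unadjusted).
#' @param tree Rooted [ape::phylo] or [tree_branch_index()]; required when
#'   UniFrac kernels are requested.
#' @param gammas MiSALN powers, default \eqn{\{1/4, 1/3, 1/2, 1\}}.
#' @param kernels Kernel codes, default `c("u", "g0.5", "w", "bc")`.
#' @param B Number of permutations (default 5000).
#' @param seed Optional integer seed for the permutation ensemble.
#' @param ties Tie handling for the Cox null fit.
#' @return An `"omisa_test"` object; see [permutation_engine()].  Also
#'   carries the null fit as attribute `"null_fit"`.
#' @examples
#' set.seed(1)
#' prm <- synth_dm_params(p = 40, seed = 1)
#' cnt <- simulate_counts(prm, n = 30, seed = 2)
#' Z <- to_composition(cnt)
#' cov <- simulate_covariates(30, seed = 3)
#' sv <- simulate_survival(Z, cov$age, cov$sex, beta = rep(0, 40),
#'                         censor_upper = 10, seed = 4)
#' res <- omisa_test(Z, sv$time, sv$event, covariates = sv$covariates,
#'                   tree = prm$tree, B = 99, seed = 5)
#' res$p_adaptive
#' @export
omisa_test <- function(Z, time, event = NULL, covariates = NULL, tree = NULL,
                       gammas = c(1 / 4, 1 / 3, 1 / 2, 1),
                       kernels = c("u", "g0.5", "w", "bc"),
                       B = 5000L, seed = NULL,
                       ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  Z <- as.matrix(Z)
  if (inherits(time, "survival_data")) {
    covariates <- time$covariates
    event <- time$event
    time <- time$time
  }
  if (length(time) != nrow(Z)) {
    stop("survival data and abundance matrix have different sample counts")
  }
  fit <- fit_null_model(time, event, covariates, ties = ties)
  bank <- build_kernel_bank(Z, tree, gammas = gammas, kernels = kernels)
  res <- permutation_engine(fit$residuals, bank, B = B, seed = seed)
  attr(res, "null_fit") <- fit
  res
}

#' @export
print.omisa_test <- function(x, ...) {
  cat(sprintf("Microbiome-survival association test (B = %d permutations%s)\n",
              x$B,
              if (is.na(x$seed)) "" else sprintf(", seed = %d", x$seed)))
  tab <- data.frame(statistic = signif(x$statistic, 4),
                    p = signif(x$p_value, 4))
  print(tab)
  cat("adaptive tests:\n")
  pa <- x$p_adaptive[!is.na(x$p_adaptive)]
  for (nm in names(pa)) cat(sprintf("  %-10s p = %s\n", nm, signif(pa[nm], 4)))
  invisible(x)
}

#' Export test results as a TSV table
#'
#' Writes one row per candidate (statistic and p-value) followed by the
#' adaptive tests.
#'
#' @param x An `"omisa_test"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_test_result <- function(x, path) {
  stopifnot(inherits(x, "omisa_test"))
  pa <- x$p_adaptive[!is.na(x$p_adaptive)]
  df <- rbind(
    data.frame(test = names(x$statistic), statistic = unname(x$statistic),
               p = unname(x$p_value), stringsAsFactors = FALSE),
    data.frame(test = names(pa), statistic = NA_real_, p = unname(pa),
               stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
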