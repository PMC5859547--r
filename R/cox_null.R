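#' Fit the covariate-only Cox proportional hazards null model
#'
#' Maximizes the Cox partial likelihood for the covariates alone (no
#' microbiome terms) by Newton-Raphson, using Efron's approximation for tied
#' event times, and returns the per-subject estimated cumulative hazard at
#' each observed time together with the martingale residuals
#' \eqn{r_i = \delta_i - \hat\Lambda_i} on which every score statistic in
#' the package is built.  With no covariates (`X = NULL`) the coefficient
#' vector is empty and the cumulative hazard reduces to the (Efron-adjusted)
#' Nelson-Aalen estimator.
#'
#' At a tied event time the Efron correction removes the tied events
#' fractionally from the risk set: the l-th of d tied events contributes
#' risk mass scaled by (1 - l/d).  Accordingly a subject failing at a tied
#' time accumulates hazard increments weighted (1 - l/d) at its own event
#' time, while every other at-risk subject receives the full increment; this
#' is the variant that agrees with `survival::coxph` residuals.
#'
#' @param time Positive observed times.
#' @param event 0/1 event indicators; at least two events are required.
#' @param X Optional n x q covariate matrix of full column rank.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param tol Convergence tolerance on the max absolute score.
#' @param maxit Maximum Newton-Raphson iterations.
#' @return A list of class `"cox_null"` with elements `coefficients`,
#'   `cumhaz` (\eqn{\hat\Lambda_i} at each subject's observed time),
#'   `residuals` (martingale), `linear_predictor`, `event_times`,
#'   `risk_sizes`, `loglik`, `iter`, `converged`, plus the inputs.
#' @examples
#' fit <- fit_null_model(c(1, 2, 3), c(1, 1, 1))
#' fit$cumhaz          # 1/3, 1/3 + 1/2, 1/3 + 1/2 + 1
#' sum(fit$residuals)  # 0
#' @export
fit_null_model <- function(time, event, X = NULL,
                           ties = c("efron", "breslow"),
                           tol = 1e-9, maxit = 50L) {
  ties <- match.arg(ties)
  if (inherits(time, "survival_data")) {
    sd_ <- time
    time <- sd_$time; event <- sd_$event; X <- sd_$covariates
  }
  n <- length(time)
  event <- as.integer(event)
  if (length(event) != n) stop("time and event lengths differ")
  if (any(time <= 0)) stop("observed times must be positive")
  if (!all(event %in% c(0L, 1L))) stop("event indicator must be 0/1")
  if (sum(event) < 2L) {
    stop("degenerate data: fewer than two events observed")
  }
  q <- 0L
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (nrow(X) != n) stop("covariate rows do not match n")
    q <- ncol(X)
    if (q > 0L && qr(X)$rank < q) {
      stop("covariate matrix is rank-deficient")
    }
  }

  tau <- sort(unique(time[event == 1L]))
  m <- length(tau)
  risk_list <- lapply(tau, function(t) which(time >= t))
  death_list <- lapply(tau, function(t) which(time == t & event == 1L))

  loglik_parts <- function(alpha, want = c("ll", "grad", "hess")) {
    eta <- if (q > 0L) drop(X %*% alpha) else numeric(n)
    w <- exp(eta)
    ll <- 0
    grad <- numeric(q)
    hess <- matrix(0, q, q)
    for (g in seq_len(m)) {
      Rg <- risk_list[[g]]; Dg <- death_list[[g]]; dg <- length(Dg)
      S0 <- sum(w[Rg]); S0d <- sum(w[Dg])
      if (q > 0L) {
        XR <- X[Rg, , drop = FALSE]; XD <- X[Dg, , drop = FALSE]
        S1 <- colSums(w[Rg] * XR); S1d <- colSums(w[Dg] * XD)
        S2 <- crossprod(XR, w[Rg] * XR); S2d <- crossprod(XD, w[Dg] * XD)
      }
      fr <- if (ties == "efron") (seq_len(dg) - 1) / dg else rep(0, dg)
      ll <- ll + sum(eta[Dg])
      for (l in seq_len(dg)) {
        phi <- S0 - fr[l] * S0d
        ll <- ll - log(phi)
        if (q > 0L && any(want %in% c("grad", "hess"))) {
          a1 <- S1 - fr[l] * S1d
          grad <- grad - a1 / phi
          hess <- hess - (S2 - fr[l] * S2d) / phi + tcrossprod(a1 / phi)
        }
      }
      if (q > 0L) grad <- grad + colSums(XD)
    }
    list(ll = ll, grad = grad, hess = hess)
  }

  alpha <- numeric(q)
  iter <- 0L
  converged <- TRUE
  if (q > 0L) {
    converged <- FALSE
    cur <- loglik_parts(alpha)
    for (iter in seq_len(maxit)) {
      if (max(abs(cur$grad)) < tol) { converged <- TRUE; break }
      step <- tryCatch(solve(-cur$hess, cur$grad),
                       error = function(e) stop("singular Hessian in Cox fit"))
      fac <- 1
      repeat {  # step-halving on likelihood decrease
        cand <- alpha + fac * step
        nxt <- loglik_parts(cand)
        if (is.finite(nxt$ll) && nxt$ll >= cur$ll - 1e-12) break
        fac <- fac / 2
        if (fac < 1e-10) stop("step-halving failed in Cox fit")
      }
      alpha <- alpha + fac * step
      cur <- nxt
    }
    if (!converged && max(abs(cur$grad)) < tol) converged <- TRUE
    if (!converged) {
      stop(sprintf("Cox fit did not converge in %d iterations (|score| = %g)",
                   maxit, max(abs(cur$grad))))
    }
  } else {
    cur <- loglik_parts(alpha)
  }

  eta <- if (q > 0L) drop(X %*% alpha) else numeric(n)
  w <- exp(eta)
  h_full <- numeric(m)
  h_event <- numeric(m)
  for (g in seq_len(m)) {
    Rg <- risk_list[[g]]; Dg <- death_list[[g]]; dg <- length(Dg)
    S0 <- sum(w[Rg]); S0d <- sum(w[Dg])
    if (ties == "efron") {
      fr <- (seq_len(dg) - 1) / dg
      phi <- S0 - fr * S0d
      h_full[g] <- sum(1 / phi)
      h_event[g] <- sum((1 - fr) / phi)
    } else {
      h_full[g] <- dg / S0
      h_event[g] <- dg / S0
    }
  }
  cum_full <- cumsum(h_full)
  Lam <- numeric(n)
  for (i in seq_len(n)) {
    g_i <- findInterval(time[i], tau)  # last tau_g <= Y_i
    if (g_i == 0L) next
    if (event[i] == 1L && time[i] == tau[g_i]) {
      Lam[i] <- w[i] * ((if (g_i > 1L) cum_full[g_i - 1L] else 0) +
                          h_event[g_i])
    } else {
      Lam[i] <- w[i] * cum_full[g_i]
    }
  }

  structure(list(coefficients = stats::setNames(alpha, colnames(X)),
                 cumhaz = Lam,
                 residuals = event - Lam,
                 linear_predictor = eta,
                 event_times = tau,
                 risk_sizes = lengths(risk_list),
                 loglik = cur$ll,
                 iter = iter, converged = converged,
                 ties = ties, time = time, event = event, X = X),
            class = "cox_null")
}

#' Martingale residuals of a fitted null model
#'
#' Returns \eqn{r = d - \hat\Lambda}; every element lies in \eqn{(-\infty, 1]}
#' and (without covariates and ties) the residuals sum to zero.
#'
#' @param fit A `"cox_null"` object from [fit_null_model()].
#' @return Numeric residual vector.
#' @export
martingale_residuals <- function(fit) {
  stopifnot(inherits(fit, "cox_null"))
  fit$residuals
}

#' @export
print.cox_null <- function(x, ...) {
  cat("Cox proportional hazards null model (", x$ties, " ties)\n", sep = "")
  cat(sprintf("  n = %d, events = %d, distinct event times = %d\n",
              length(x$time), sum(x$event), length(x$event_times)))
  if (length(x$coefficients)) {
    cat("  coefficients:\n")
    print(x$coefficients)
  } else {
    cat("  no covariates (Nelson-Aalen baseline)\n")
  }
  invisible(x)
}
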