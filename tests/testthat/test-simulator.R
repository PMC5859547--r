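test_that("Dirichlet-multinomial moment estimates recover known parameters", {
  set.seed(301)
  p <- 15
  pi0 <- rgamma(p, 5) + 2
  pi0 <- pi0 / sum(pi0)
  names(pi0) <- paste0("OTU", 1:p)
  prm <- structure(list(pi = pi0, phi = 0.05), class = "dm_params")
  cnt <- simulate_counts(prm, n = 4000, total_reads = 800, seed = 302)
  est <- fit_dirichlet_multinomial(cnt)
  expect_equal(sum(est$pi), 1, tolerance = 1e-12)
  expect_lt(max(abs(est$pi - pi0) / pi0), 0.10)
  expect_lt(abs(est$phi - 0.05) / 0.05, 0.10)

  flat <- matrix(rep(c(10L, 30L, 60L), each = 5), 5, 3)
  dimnames(flat) <- list(paste0("S", 1:5), paste0("O", 1:3))
  expect_lt(fit_dirichlet_multinomial(flat)$phi, 1e-8)
  expect_error(fit_dirichlet_multinomial(flat[1, , drop = FALSE]),
               "two samples")
})

test_that("synthetic parameters have the heavy-tailed filtered-community shape", {
  prm <- synth_dm_params(p = 353, seed = 311)
  expect_length(prm$pi, 353L)
  expect_equal(sum(prm$pi), 1, tolerance = 1e-12)
  expect_gt(max(prm$pi) / median(prm$pi), 50)
  expect_gt(min(prm$pi), 1e-4)       # every OTU passes the standard filter
  expect_setequal(prm$tree$tip.label, names(prm$pi))
  expect_equal(prm$phi, 0.02)

  prm2 <- synth_dm_params(p = 353, seed = 311)
  expect_identical(prm$pi, prm2$pi)
  expect_identical(prm$tree$edge.length, prm2$tree$edge.length)
})

test_that("simulated counts close to multinomial totals and DM moments", {
  prm <- synth_dm_params(p = 60, seed = 321)
  cnt <- simulate_counts(prm, n = 150, total_reads = 1000, seed = 322)
  expect_true(all(rowSums(cnt) == 1000))
  expect_identical(colnames(cnt), names(prm$pi))

  # moment check against the DM variance pi(1-pi)(phi + (1-phi)/N)
  P <- cnt / 1000
  top <- order(prm$pi, decreasing = TRUE)[1:5]
  expected_var <- prm$pi[top] * (1 - prm$pi[top]) *
    (prm$phi + (1 - prm$phi) / 1000)
  ratio <- apply(P[, top], 2, var) / expected_var
  expect_true(all(ratio > 0.5 & ratio < 2))

  # phi -> 0: only multinomial noise remains
  prm0 <- prm; prm0$phi <- 1e-9
  cnt0 <- simulate_counts(prm0, n = 150, total_reads = 1000, seed = 323)
  mult_var <- prm$pi[top] * (1 - prm$pi[top]) / 1000
  ratio0 <- apply((cnt0 / 1000)[, top], 2, var) / mult_var
  expect_true(all(ratio0 > 0.5 & ratio0 < 2))

  # mean proportions approach pi
  expect_lt(max(abs(colMeans(P)[top] - prm$pi[top]) / prm$pi[top]), 0.25)
})

test_that("covariate generator matches its stated moments", {
  cv <- simulate_covariates(20000, seed = 331)
  expect_equal(mean(cv$age), 50, tolerance = 0.15)
  expect_equal(sd(cv$age), 5, tolerance = 0.15)
  expect_equal(mean(cv$sex), 0.5, tolerance = 0.02)
  expect_identical(simulate_covariates(10, seed = 7),
                   simulate_covariates(10, seed = 7))
})

test_that("associated-OTU selection honours each scenario", {
  prm <- synth_dm_params(p = 40, seed = 341)
  top <- order(prm$pi, decreasing = TRUE)[1:10]
  expect_identical(sort(select_associated_otus("abundant10", prm$pi)),
                   sort(top))
  bottom <- order(prm$pi)[1:10]
  expect_identical(sort(select_associated_otus("rare10", prm$pi)),
                   sort(bottom))
  rnd <- select_associated_otus("random10", prm$pi, seed = 342)
  expect_length(unique(rnd), 10L)

  cl <- pam_clusters(prm$tree, k = 10)
  expect_length(unique(cl), 10L)
  expect_setequal(names(cl), prm$tree$tip.label)
  idx <- select_associated_otus("pam_cluster", prm$pi, clusters = cl,
                                seed = 343)
  expect_true(length(idx) >= 1)
  expect_equal(length(unique(cl[names(prm$pi)[idx]])), 1L)

  expect_error(select_associated_otus("rare10", prm$pi[1:5]), "at least")
})

test_that("PAM on tiny instances attains the exhaustive-medoid optimum", {
  for (seed in c(351, 352, 353)) {
    tr <- rand_tree(11, seed)
    D <- cophenetic(tr)
    for (k in 2:3) {
      pam_med <- cluster::pam(as.dist(D), k = k)$id.med
      bf <- brute_force_medoids(D, k)
      expect_equal(medoid_cost(D, pam_med), bf$cost, tolerance = 1e-9)
    }
  }
})

test_that("effect draws follow the requested direction and magnitude", {
  set.seed(361)
  idx <- c(2, 5, 9)
  b1 <- draw_effects(idx, 12, "same", u = 2, seed = 362)
  expect_true(all(b1[idx] >= 0 & b1[idx] <= 2))
  expect_true(all(b1[-idx] == 0))
  b0 <- draw_effects(idx, 12, "same", u = 0, seed = 363)
  expect_true(all(b0 == 0))

  same_means <- replicate(800, mean(draw_effects(idx, 12, "same", 3)[idx]))
  expect_equal(mean(same_means), 1.5, tolerance = 0.1)
  mixed_means <- replicate(800, mean(draw_effects(idx, 12, "mixed", 3)[idx]))
  expect_equal(mean(mixed_means), 0, tolerance = 0.15)
})

test_that("survival times invert the Weibull(2,2) hazard model", {
  # eta = 0: T = 2 sqrt(-log U); reproduce the uniform draws independently
  n <- 50
  Z <- matrix(0.5, n, 1, dimnames = list(NULL, "OTU1"))
  sv <- simulate_survival(Z, age = rep(50, n), sex = rep(0, n),
                          beta = 0, censor_upper = 10, seed = 371)
  set.seed(371)
  U <- runif(n)
  expect_equal(attr(sv, "latent_time"), 2 * sqrt(-log(U)),
               tolerance = 1e-12)
  expect_equal(2 * sqrt(log(2)), 1.6651, tolerance = 1e-4)  # U = 0.5 case

  # monotonicity: larger linear predictor shortens survival, same draws
  sv_hi <- simulate_survival(Z, age = rep(50, n), sex = rep(1, n),
                             beta = 0, censor_upper = 10, seed = 371)
  expect_true(all(attr(sv_hi, "latent_time") < attr(sv, "latent_time")))

  # censored fraction near the calibrated values (quick MC)
  cv <- simulate_covariates(20000, seed = 372)
  Zb <- matrix(0.5, 20000, 1, dimnames = list(NULL, "OTU1"))
  sv10 <- simulate_survival(Zb, cv$age, cv$sex, 0, 10, seed = 373)
  expect_equal(1 - mean(sv10$event), 0.258, tolerance = 0.012)
  sv5 <- simulate_survival(Zb, cv$age, cv$sex, 0, 5, seed = 374)
  expect_equal(1 - mean(sv5$event), 0.404, tolerance = 0.015)

  Zd <- cbind(Z, OTU2 = rep(0.25, n))
  expect_warning(simulate_survival(Zd, rep(50, n), rep(0, n),
                                   beta = c(0, 1), censor_upper = 10,
                                   seed = 375),
                 "zero-variance")
})

test_that("experiments are reproducible and report all eleven tests", {
  prm <- synth_dm_params(p = 30, seed = 381)
  ex1 <- run_experiment("null", n = 25, reps = 4, B = 99, params = prm,
                        seed = 382)
  ex2 <- run_experiment("null", n = 25, reps = 4, B = 99, params = prm,
                        seed = 382)
  expect_identical(attr(ex1, "p_matrix"), attr(ex2, "p_matrix"))
  expect_setequal(ex1$test,
                  c("MiSALN(1/4)", "MiSALN(1/3)", "MiSALN(1/2)", "MiSALN(1)",
                    "MiRKAT-S(K_U)", "MiRKAT-S(K_0.5)", "MiRKAT-S(K_W)",
                    "MiRKAT-S(K_BC)", "OMiSALN", "OMiRKAT-S", "OMiSA"))
  expect_true(all(ex1$rejection_rate >= 0 & ex1$rejection_rate <= 1))
  expect_true(is.numeric(attr(ex1, "censored_fraction")))

  ex3 <- run_experiment("abundant10", direction = "same", u = 3, n = 25,
                        reps = 3, B = 99, params = prm, seed = 383)
  expect_equal(nrow(ex3), 11L)
})
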