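test_that("Bray-Curtis matches hand values and the vegan implementation", {
  Z <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(bray_curtis(Z)["a", "b"], 1)
  Z2 <- rbind(a = c(0.5, 0.5), b = c(0.5, 0.5))
  expect_equal(bray_curtis(Z2)["a", "b"], 0)
  Z3 <- rbind(a = c(0.5, 0.5), b = c(0.25, 0.75))
  expect_equal(bray_curtis(Z3)["a", "b"], 0.25)

  for (seed in 1:3) {
    Z <- rand_comp(7, 11, seed)
    D <- bray_curtis(Z)
    ref <- as.matrix(vegan::vegdist(Z, "bray"))
    expect_equal(unname(D), unname(ref[rownames(Z), rownames(Z)]),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(D, t(D))
    expect_equal(unname(diag(D)), rep(0, 7))
  }
})

test_that("UniFrac trivial cases: identity and fully disjoint lineages", {
  star <- ape::read.tree(text = "(A:1,B:1);")
  Z <- rbind(s1 = c(A = 1, B = 0), s2 = c(A = 0, B = 1),
             s3 = c(A = 1, B = 0))
  Du <- unifrac(Z, star, "unweighted")
  expect_equal(Du["s1", "s2"], 1)
  expect_equal(Du["s1", "s3"], 0)
  for (v in c("unweighted", "weighted", "generalized")) {
    D <- unifrac(Z, star, v)
    expect_equal(D["s1", "s3"], 0)
    expect_equal(D["s1", "s2"], 1)  # full turnover on a star tree
  }
})

test_that("unweighted UniFrac depends only on presence/absence", {
  tr <- rand_tree(10, 61)
  Z <- rand_comp(6, 10, 62)
  Z[Z < 0.05] <- 0
  D1 <- unifrac(Z, tr, "unweighted")
  set.seed(63)
  Z2 <- Z * matrix(runif(length(Z), 0.2, 9), nrow(Z))  # rescale nonzeros
  D2 <- unifrac(Z2, tr, "unweighted")
  expect_equal(D1, D2, tolerance = 1e-12)
})

test_that("UniFrac matches the phyloseq implementation on random data", {
  for (seed in c(71, 72, 73)) {
    tr <- rand_tree(12, seed)
    cnt <- rand_counts(7, 12, seed + 100, lambda = 3)
    cnt[1, ] <- cnt[1, ] + 1  # no empty sample
    Z <- to_composition(cnt)
    ph <- phyloseq::phyloseq(
      phyloseq::otu_table(cnt, taxa_are_rows = FALSE),
      phyloseq::phy_tree(tr))
    ru <- as.matrix(phyloseq::UniFrac(ph, weighted = FALSE))
    rw <- as.matrix(phyloseq::UniFrac(ph, weighted = TRUE,
                                      normalized = TRUE))
    sn <- rownames(Z)
    expect_equal(unname(unifrac(Z, tr, "unweighted")),
                 unname(ru[sn, sn]), tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(unname(unifrac(Z, tr, "weighted")),
                 unname(rw[sn, sn]), tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("generalized UniFrac interpolates and hits its endpoints", {
  tr <- rand_tree(9, 81)
  Z <- rand_comp(5, 9, 82)
  expect_equal(unname(unifrac(Z, tr, "generalized", theta = 1)),
               unname(unifrac(Z, tr, "weighted")), tolerance = 1e-12,
               ignore_attr = TRUE)

  # hand oracle on a 2-tip star with unit branch lengths:
  # branch sums s_A = zA1+zA2, s_B = ...; d(theta) =
  # sum s^theta |diff|/s / sum s^theta
  star <- ape::read.tree(text = "(A:1,B:1);")
  Zs <- rbind(s1 = c(A = 0.3, B = 0.7), s2 = c(A = 0.6, B = 0.4))
  sA <- 0.9; dA <- 0.3; sB <- 1.1; dB <- 0.3
  th <- 0.5
  hand <- (sA^th * dA / sA + sB^th * dB / sB) / (sA^th + sB^th)
  expect_equal(unifrac(Zs, star, "generalized", theta = th)["s1", "s2"],
               hand, tolerance = 1e-12)

  # theta ordering in a simple two-sample case: smaller theta moves the
  # distance toward rare-lineage turnover (here monotone between samples
  # differing in a rare lineage)
  expect_error(unifrac(Z[, 1:5], tr, "weighted"), NA)  # pruned subtree ok
})

test_that("OTUs missing from the tree are reported", {
  tr <- rand_tree(6, 91)
  Z <- rand_comp(4, 8, 92)  # O7, O8 not in 6-tip tree
  expect_error(unifrac(Z, tr, "weighted"), "O7")
})

test_that("Gower centering with eigenvalue clamping yields PSD kernels", {
  K <- distance_to_kernel(matrix(c(0, 2, 2, 0), 2, 2))
  expect_equal(unname(K), matrix(c(1, -1, -1, 1), 2, 2))

  expect_equal(unname(distance_to_kernel(matrix(0, 3, 3))),
               matrix(0, 3, 3))

  # 4-point configuration violating the Euclidean embedding condition
  D <- matrix(c(0, 2, 2, 1,
                2, 0, 2, 1,
                2, 2, 0, 1,
                1, 1, 1, 0), 4, 4)
  J <- diag(4) - matrix(1 / 4, 4, 4)
  raw <- -0.5 * J %*% (D * D) %*% J
  expect_lt(min(eigen(raw, symmetric = TRUE)$values), -1e-8)
  K2 <- distance_to_kernel(D)
  expect_gte(min(eigen(K2, symmetric = TRUE)$values), -1e-10)

  # already-PSD case: repair is a no-op
  De <- as.matrix(dist(cbind(c(0, 3, 1, 2), c(0, 0, 2, 1))))
  Ke <- distance_to_kernel(De)
  rawe <- -0.5 * J %*% (De * De) %*% J
  expect_equal(unname(Ke), unname(rawe), tolerance = 1e-10)

  expect_error(distance_to_kernel(matrix(c(0, 1, 2, 0), 2, 2)),
               "symmetric")
})

test_that("MiSALN correlation structure follows the powered linear kernel", {
  Z <- rand_comp(5, 8, 101)
  expect_equal(misaln_correlation(Z, 1), tcrossprod(Z))
  expect_equal(misaln_correlation(matrix(c(0.25, 0.75), 1, 2), 0.5)[1, 1],
               1.0)
  Z0 <- Z; Z0[2, ] <- 0
  R <- misaln_correlation(Z0, 0.5)
  expect_equal(unname(R[2, ]), rep(0, 5))
  expect_error(misaln_correlation(Z, 0), "positive")
  expect_error(misaln_correlation(Z, -1), "positive")
})

test_that("the default kernel bank holds 8 labelled PSD candidates", {
  tr <- rand_tree(10, 111)
  Z <- rand_comp(8, 10, 112)
  bank <- build_kernel_bank(Z, tr)
  expect_length(bank, 8L)
  expect_setequal(names(bank),
                  c("MiSALN(1/4)", "MiSALN(1/3)", "MiSALN(1/2)", "MiSALN(1)",
                    "MiRKAT-S(K_U)", "MiRKAT-S(K_0.5)", "MiRKAT-S(K_W)",
                    "MiRKAT-S(K_BC)"))
  set.seed(113)
  r <- rnorm(8)
  for (nm in names(bank)) {
    M <- bank[[nm]]
    expect_lt(max(abs(M - t(M))), 1e-10)
    expect_gte(min(eigen(M, symmetric = TRUE)$values), -1e-10)
    expect_gte(drop(crossprod(r, M %*% r)), -1e-10)
    expect_true(attr(M, "group") %in% c("MiSALN", "MiRKAT-S"))
  }

  single <- build_kernel_bank(Z, gammas = 1, kernels = character(0))
  expect_length(single, 1L)
  expect_equal(unname(single[[1]]), unname(tcrossprod(Z)),
               ignore_attr = TRUE)

  expect_error(build_kernel_bank(Z, tree = NULL), "tree")
  expect_silent(build_kernel_bank(Z, tree = NULL, gammas = 1,
                                  kernels = "bc"))
})
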