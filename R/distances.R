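#' Precompute the tip-to-branch incidence of a rooted tree
#'
#' UniFrac distances are sums over branches of functions of the total
#' abundance descending from each branch.  This helper computes, once per
#' tree, the tips-by-branches 0/1 incidence matrix and the branch lengths,
#' so that per-sample branch abundances are a single matrix product
#' `Z[, tips] %*% incidence`.  Useful when many community matrices are
#' scored against the same tree (e.g., in simulations): pass the returned
#' object wherever a tree is accepted.
#'
#' @param tree A rooted [ape::phylo] tree with branch lengths.
#' @return A list of class `"branch_index"` with elements `incidence`
#'   (tips x branches), `length` (branch lengths) and `tip` (tip labels, the
#'   row order of `incidence`).
#' @export
tree_branch_index <- function(tree) {
  if (inherits(tree, "branch_index")) return(tree)
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("a rooted tree is required")
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; treating all as 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  po <- stats::reorder(tree, "postorder")
  ntip <- length(po$tip.label)
  E <- nrow(po$edge)
  inc <- matrix(0, ntip, E)
  node_tips <- vector("list", ntip + po$Nnode)
  for (e in seq_len(E)) {
    child <- po$edge[e, 2L]
    ts <- if (child <= ntip) child else node_tips[[child]]
    inc[ts, e] <- 1
    par <- po$edge[e, 1L]
    node_tips[[par]] <- c(node_tips[[par]], ts)
  }
  rownames(inc) <- po$tip.label
  structure(list(incidence = inc, length = po$edge.length,
                 tip = po$tip.label),
            class = "branch_index")
}

# Align abundance columns to tree tips (by name) and return the per-sample
# branch abundance matrix plus branch lengths.  Tips of the tree that carry
# no column in Z are an error for community-level input; extra tree tips are
# pruned so taxon-level subsets use the subtree spanned by their members.
branch_abundance <- function(Z, tree) {
  if (inherits(tree, "branch_index")) {
    idx <- tree
    missing_tips <- setdiff(colnames(Z), idx$tip)
    if (length(missing_tips)) {
      stop("OTU(s) absent from tree: ", paste(missing_tips, collapse = ", "))
    }
    if (length(setdiff(idx$tip, colnames(Z)))) {
      stop("prebuilt branch index covers tips not in Z; ",
           "prune the tree and rebuild the index")
    }
  } else {
    missing_tips <- setdiff(colnames(Z), tree$tip.label)
    if (length(missing_tips)) {
      stop("OTU(s) absent from tree: ", paste(missing_tips, collapse = ", "))
    }
    extra <- setdiff(tree$tip.label, colnames(Z))
    if (length(extra)) tree <- ape::keep.tip(tree, colnames(Z))
    idx <- tree_branch_index(tree)
  }
  A <- Z[, idx$tip, drop = FALSE] %*% idx$incidence
  list(A = A, len = idx$length)
}

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{D_{ab} = \sum_j |Z_{aj} - Z_{bj}| / \sum_j (Z_{aj} + Z_{bj})},
#' computed on relative abundances.  A pair of samples with no abundance at
#' all (possible for taxon subsets) gets distance 0 with a warning.
#'
#' @param Z Samples-by-OTUs non-negative abundance matrix.
#' @return Symmetric n x n matrix with zero diagonal and
#'   `attr(, "metric") = "bray-curtis"`.
#' @export
bray_curtis <- function(Z) {
  Z <- as.matrix(Z)
  if (any(Z < 0)) stop("abundances must be non-negative")
  n <- nrow(Z)
  D <- matrix(0, n, n, dimnames = list(rownames(Z), rownames(Z)))
  empty_pair <- FALSE
  for (i in seq_len(n - 1L)) {
    M <- Z[(i + 1L):n, , drop = FALSE]
    num <- rowSums(abs(sweep(M, 2L, Z[i, ], "-")))
    den <- rowSums(sweep(M, 2L, Z[i, ], "+"))
    bad <- den == 0
    if (any(bad)) { empty_pair <- TRUE; num[bad] <- 0; den[bad] <- 1 }
    D[i, (i + 1L):n] <- num / den
    D[(i + 1L):n, i] <- D[i, (i + 1L):n]
  }
  if (empty_pair) warning("pair(s) of all-zero samples; distance set to 0")
  attr(D, "metric") <- "bray-curtis"
  D
}

#' UniFrac distances between samples
#'
#' Branch-wise phylogenetic beta-diversity.  With \eqn{p_a^b} the total
#' abundance in sample a descending from branch b (length \eqn{l_b}):
#' \describe{
#'   \item{unweighted}{\eqn{\sum_b l_b |I(p_a^b>0) - I(p_{a'}^b>0)| /
#'     \sum_b l_b I(p_a^b>0 \lor p_{a'}^b>0)} — lineage presence/absence
#'     only (Lozupone & Knight 2005).}
#'   \item{weighted}{normalized abundance-weighted form
#'     \eqn{\sum_b l_b |p_a^b - p_{a'}^b| / \sum_b l_b (p_a^b + p_{a'}^b)}
#'     (Lozupone et al. 2007).}
#'   \item{generalized}{\eqn{\sum_b l_b (p_a^b+p_{a'}^b)^\theta
#'     \frac{|p_a^b-p_{a'}^b|}{p_a^b+p_{a'}^b} \big/
#'     \sum_b l_b (p_a^b+p_{a'}^b)^\theta} (Chen et al. 2012);
#'     \eqn{\theta = 1} recovers the weighted normalized form and small
#'     \eqn{\theta} down-weights abundant lineages.}
#' }
#'
#' Abundance columns are matched to tree tips by name; the tree is pruned to
#' the columns of `Z`, so taxon-level matrices carrying community-scale
#' (non-unit-sum) abundances are handled as-is on the taxon subtree.
#'
#' @param Z Samples-by-OTUs abundance matrix; column names are tip labels.
#' @param tree Rooted [ape::phylo] tree, or a prebuilt [tree_branch_index()]
#'   whose tips match `colnames(Z)`.
#' @param variant `"unweighted"`, `"generalized"` or `"weighted"`.
#' @param theta Interpolation exponent in (0, 1] for the generalized form.
#' @return Symmetric n x n distance matrix with a `"metric"` attribute.
#' @export
unifrac <- function(Z, tree, variant = c("unweighted", "generalized",
                                         "weighted"),
                    theta = 0.5) {
  variant <- match.arg(variant)
  Z <- as.matrix(Z)
  ba <- branch_abundance(Z, tree)
  A <- ba$A
  l <- ba$len
  n <- nrow(A)
  sn <- rownames(Z)
  D <- matrix(0, n, n, dimnames = list(sn, sn))
  empty_pair <- FALSE
  if (variant == "unweighted") {
    P <- (A > 0) + 0
    Ls <- drop(P %*% l)              # branch length present per sample
    W <- P %*% (l * t(P))            # shared branch length per pair
    den <- outer(Ls, Ls, "+") - W    # union
    num <- outer(Ls, Ls, "+") - 2 * W  # symmetric difference
    bad <- den == 0
    if (any(bad & upper.tri(den))) empty_pair <- TRUE
    den[bad] <- 1
    D <- num / den
    diag(D) <- 0
    D <- (D + t(D)) / 2
    dimnames(D) <- list(sn, sn)
  } else {
    for (i in seq_len(n - 1L)) {
      M <- A[(i + 1L):n, , drop = FALSE]
      d_ <- abs(sweep(M, 2L, A[i, ], "-"))
      s_ <- sweep(M, 2L, A[i, ], "+")
      if (variant == "weighted") {
        num <- drop(d_ %*% l)
        den <- drop(s_ %*% l)
      } else {
        w <- s_^theta
        ratio <- d_ / s_
        ratio[s_ == 0] <- 0
        num <- drop((w * ratio) %*% l)
        den <- drop(w %*% l)
      }
      bad <- den == 0
      if (any(bad)) { empty_pair <- TRUE; num[bad] <- 0; den[bad] <- 1 }
      D[i, (i + 1L):n] <- num / den
      D[(i + 1L):n, i] <- D[i, (i + 1L):n]
    }
  }
  if (empty_pair) warning("pair(s) with no branch mass; distance set to 0")
  attr(D, "metric") <- switch(variant,
    unweighted = "unweighted-unifrac",
    weighted = "weighted-unifrac",
    generalized = sprintf("generalized-unifrac(%g)", theta))
  D
}

#' Convert a distance matrix to a positive semi-definite kernel
#'
#' Gower double-centering, \eqn{K = -\frac{1}{2}(I - \frac{11'}{n}) D^{\circ 2}
#' (I - \frac{11'}{n})} with \eqn{D^{\circ 2}} the element-wise square,
#' followed by a PSD repair: eigendecompose, clamp negative eigenvalues to
#' zero, reconstruct, and re-symmetrize to remove rounding asymmetry.  A
#' matrix whose centered form is already PSD is returned unchanged up to
#' numerical noise (the operation is idempotent on such input).
#'
#' @param D Symmetric distance matrix with zero diagonal.
#' @param tol Tolerance for the symmetry check.
#' @return Symmetric PSD kernel matrix of the same dimension.
#' @export
distance_to_kernel <- function(D, tol = 1e-8) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (ncol(D) != n) stop("distance matrix must be square")
  if (max(abs(D - t(D))) > tol) stop("distance matrix is not symmetric")
  if (max(abs(diag(D))) > tol) stop("distance matrix must have zero diagonal")
  J <- diag(n) - matrix(1 / n, n, n)
  K <- -0.5 * J %*% (D * D) %*% J
  K <- (K + t(K)) / 2
  eig <- eigen(K, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  K <- eig$vectors %*% (lam * t(eig$vectors))
  K <- (K + t(K)) / 2
  dimnames(K) <- dimnames(D)
  K
}

#' Powered-abundance correlation structure (MiSALN)
#'
#' \eqn{R_{(\gamma)} = Z^\gamma (Z^\gamma)^T} with element-wise powering and
#' \eqn{0^\gamma = 0}.  \eqn{\gamma = 1} is the linear kernel \eqn{ZZ^T} on
#' the original abundance scale; decreasing \eqn{\gamma} up-weights rare
#' OTUs.  The result is symmetric PSD by construction.
#'
#' @param Z Samples-by-OTUs abundance matrix with entries in \[0, 1\].
#' @param gamma Positive power.
#' @return n x n symmetric PSD matrix.
#' @export
misaln_correlation <- function(Z, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop("gamma must be a single positive number")
  }
  Z <- as.matrix(Z)
  if (any(Z < 0) || any(Z > 1)) stop("abundances must lie in [0, 1]")
  Zg <- Z^gamma
  tcrossprod(Zg)
}

format_gamma <- function(g) {
  known <- c(`0.25` = "1/4", `0.5` = "1/2", `1` = "1")
  if (isTRUE(all.equal(g, 1 / 3))) return("1/3")
  key <- as.character(g)
  if (key %in% names(known)) known[[key]] else format(g)
}

#' Build the bank of candidate similarity matrices
#'
#' Assembles, for one community matrix, every candidate correlation/kernel
#' matrix entering the adaptive tests: one MiSALN correlation matrix
#' \eqn{Z^\gamma Z^{\gamma T}} per \eqn{\gamma \in \Gamma} and one
#' Gower-centered PSD kernel per requested distance metric.  Defaults are
#' \eqn{\Gamma = \{1/4, 1/3, 1/2, 1\}} and the four metrics unweighted
#' UniFrac, generalized UniFrac (\eqn{\theta = 0.5}), weighted UniFrac and
#' Bray-Curtis, giving eight candidates.
#'
#' @param Z Samples-by-OTUs abundance matrix.
#' @param tree Rooted tree or [tree_branch_index()]; may be `NULL` when no
#'   UniFrac kernel is requested.
#' @param gammas Numeric vector of MiSALN powers (may be empty).
#' @param kernels Character vector of kernel codes: `"u"` (unweighted
#'   UniFrac), `"g<theta>"` (generalized, e.g. `"g0.5"`), `"w"` (weighted
#'   UniFrac), `"bc"` (Bray-Curtis).  May be empty.
#' @return A named list of class `"kernel_bank"`; each element carries
#'   `attr(, "group")` `"MiSALN"` or `"MiRKAT-S"`.
#' @export
build_kernel_bank <- function(Z, tree = NULL,
                              gammas = c(1 / 4, 1 / 3, 1 / 2, 1),
                              kernels = c("u", "g0.5", "w", "bc")) {
  Z <- as.matrix(Z)
  bank <- list()
  for (g in gammas) {
    R <- misaln_correlation(Z, g)
    attr(R, "group") <- "MiSALN"
    bank[[sprintf("MiSALN(%s)", format_gamma(g))]] <- R
  }
  for (code in kernels) {
    if (code == "bc") {
      D <- bray_curtis(Z)
      label <- "MiRKAT-S(K_BC)"
    } else {
      if (is.null(tree)) {
        stop("a phylogenetic tree is required for UniFrac kernel '",
             code, "'")
      }
      if (code == "u") {
        D <- unifrac(Z, tree, "unweighted")
        label <- "MiRKAT-S(K_U)"
      } else if (code == "w") {
        D <- unifrac(Z, tree, "weighted")
        label <- "MiRKAT-S(K_W)"
      } else if (grepl("^g", code)) {
        th <- as.numeric(sub("^g", "", code))
        if (is.na(th) || th <= 0 || th > 1) {
          stop("malformed generalized UniFrac code: ", code)
        }
        D <- unifrac(Z, tree, "generalized", theta = th)
        label <- sprintf("MiRKAT-S(K_%g)", th)
      } else {
        stop("unknown kernel code: ", code)
      }
    }
    K <- distance_to_kernel(D)
    attr(K, "group") <- "MiRKAT-S"
    bank[[label]] <- K
  }
  if (!length(bank)) stop("empty candidate set: no gammas and no kernels")
  structure(bank, class = "kernel_bank")
}
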