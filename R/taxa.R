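#' Filter OTUs on mean relative abundance
#'
#' Keeps OTUs whose mean relative abundance across samples exceeds
#' `threshold` (default 1e-4, the conventional cut for 16S count tables of
#' ~1000 reads/sample).  Proportions are computed per sample before
#' averaging, so samples with different sequencing depth contribute equally.
#'
#' @param counts Samples-by-OTUs count matrix.
#' @param threshold Proportional mean abundance cutoff in (0, 1), or 0 to
#'   keep every OTU with any nonzero count.
#' @return The column-filtered count matrix.  The number of dropped OTUs is
#'   reported with `message()`.
#' @export
filter_otus <- function(counts, threshold = 1e-4) {
  if (threshold < 0 || threshold >= 1) stop("threshold must lie in [0, 1)")
  P <- counts / rowSums(counts)
  keep <- colMeans(P) > threshold
  if (!any(keep)) stop("degenerate data: every OTU was filtered out")
  message(sprintf("filter_otus: kept %d of %d OTUs (mean proportion > %g)",
                  sum(keep), ncol(counts), threshold))
  counts[, keep, drop = FALSE]
}

#' Group OTUs by taxon at one taxonomic rank
#'
#' Partitions the OTUs into taxa according to their lineage label at the
#' given rank, omitting OTUs without an assignment at that rank.
#'
#' @param taxonomy Data frame from [read_taxonomy()] (columns `otu`,
#'   `phylum` ... `genus`).
#' @param rank One of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`.
#' @return Named list mapping taxon label to character vector of member OTU
#'   ids.  Empty (with a warning) when no OTU is assigned at the rank.
#' @export
taxon_subsets <- function(taxonomy,
                          rank = c("phylum", "class", "order", "family",
                                   "genus")) {
  rank <- match.arg(rank)
  lab <- taxonomy[[rank]]
  assigned <- !is.na(lab) & lab != ""
  if (!any(assigned)) {
    warning("no OTU has a taxonomy assignment at rank ", rank)
    return(stats::setNames(list(), character(0)))
  }
  split(taxonomy$otu[assigned], lab[assigned])
}

#' Extract a taxon's abundance sub-matrix on the community scale
#'
#' Column subset of the community-level composition matrix.  Rows are NOT
#' re-normalized: abundances stay relative to total reads in the entire
#' community, so a taxon's row sums equal its within-community totals.  The
#' `community` attribute is cleared to record that rows no longer sum to 1.
#'
#' @param Z Community-level composition matrix ([to_composition()]).
#' @param members Character vector of member OTU ids (non-empty, all present
#'   in `colnames(Z)`).
#' @return The n x |members| abundance matrix.
#' @export
taxon_composition <- function(Z, members) {
  if (!length(members)) stop("empty taxon member set")
  miss <- setdiff(members, colnames(Z))
  if (length(miss)) {
    stop("member OTU(s) absent from community matrix: ",
         paste(miss, collapse = ", "))
  }
  out <- Z[, members, drop = FALSE]
  attr(out, "community") <- FALSE
  out
}

#' Univariate Cox test for a single-OTU taxon
#'
#' Wald p-value for the abundance coefficient in a Cox proportional hazards
#' model `Surv(time, event) ~ z + X`, the fallback used by [scan_taxa()]
#' for taxa represented by a single OTU (a community test over one OTU is
#' not meaningful).
#'
#' @param time,event Survival outcome, aligned with `z`.
#' @param z Abundance vector of the single OTU.
#' @param X Optional covariate matrix.
#' @return The Wald p-value.
#' @export
univariate_cox_test <- function(time, event, z, X = NULL) {
  if (sum(event) < 2L) stop("degenerate data: fewer than two events")
  if (stats::var(z) == 0) {
    stop("degenerate abundance: identical across samples")
  }
  df <- data.frame(z = as.numeric(z))
  if (!is.null(X)) df <- cbind(df, as.data.frame(X))
  fit <- survival::coxph(survival::Surv(time, event) ~ ., data = df)
  unname(summary(fit)$coefficients["z", "Pr(>|z|)"])
}

#' Scan the community and every taxon at each taxonomic rank
#'
#' Runs the full association workflow: low-abundance OTU filtering,
#' conversion to composition, a community-level adaptive test, then per
#' rank (phylum .. genus) one test per taxon — the adaptive community test
#' for taxa with at least `min_otus` member OTUs (on community-scale
#' abundances and the taxon subtree) and a univariate Cox Wald test for
#' singleton taxa.  Raw p-values are corrected within each rank
#' (Benjamini-Hochberg by default); the community-level p-value is reported
#' unadjusted as it is a single test.
#'
#' @param counts Samples-by-OTUs count matrix.
#' @param time,event Survival outcome aligned with `rownames(counts)`;
#'   `time` may be a `"survival_data"` object.
#' @param tree Rooted tree covering all OTUs (required for UniFrac kernels).
#' @param taxonomy Data frame from [read_taxonomy()].
#' @param covariates Optional covariate matrix (the typical workflow is
#'   unadjusted, `NULL`).
#' @param threshold Mean-proportion filter cutoff passed to [filter_otus()].
#' @param gammas,kernels,B Candidate sets and permutation count, as in
#'   [omisa_test()].
#' @param seed Integer seed; per-taxon permutation seeds are derived from it
#'   so the scan is reproducible end to end.
#' @param min_otus Minimum member count for the community test (default 2).
#' @param p_adjust_method Correction method (any [stats::p.adjust()] method).
#' @param alpha Significance level used only for the printed summary.
#' @return A list of class `"taxa_scan"`: `community` (an `"omisa_test"`),
#'   `taxa` (data.frame with rank, taxon, n_otu, test, p, p_adj), `alpha`.
#' @export
scan_taxa <- function(counts, time, event = NULL, tree = NULL,
                      taxonomy = NULL, covariates = NULL, threshold = 1e-4,
                      gammas = c(1 / 4, 1 / 3, 1 / 2, 1),
                      kernels = c("u", "g0.5", "w", "bc"),
                      B = 5000L, seed = NULL, min_otus = 2L,
                      p_adjust_method = "BH", alpha = 0.05) {
  if (inherits(time, "survival_data")) {
    covariates <- time$covariates
    event <- time$event
    time <- time$time
  }
  counts <- filter_otus(counts, threshold)
  Z <- to_composition(counts)
  if (!is.null(seed)) set.seed(seed)
  seed_pool <- sample.int(.Machine$integer.max - 1L, 4096L)
  s_i <- 0L
  next_seed <- function() {
    s_i <<- s_i + 1L
    seed_pool[s_i]
  }

  community <- omisa_test(Z, time, event, covariates = covariates,
                          tree = tree, gammas = gammas, kernels = kernels,
                          B = B, seed = next_seed())

  ranks <- c("phylum", "class", "order", "family", "genus")
  rows <- list()
  if (!is.null(taxonomy)) {
    taxonomy <- taxonomy[taxonomy$otu %in% colnames(Z), , drop = FALSE]
    for (rk in ranks) {
      subsets <- suppressWarnings(taxon_subsets(taxonomy, rk))
      if (!length(subsets)) next
      p_raw <- numeric(length(subsets))
      test_type <- character(length(subsets))
      n_otu <- lengths(subsets)
      for (k in seq_along(subsets)) {
        members <- subsets[[k]]
        if (length(members) >= min_otus) {
          Zt <- taxon_composition(Z, members)
          res <- omisa_test(Zt, time, event, covariates = covariates,
                            tree = tree, gammas = gammas, kernels = kernels,
                            B = B, seed = next_seed())
          p_raw[k] <- res$p_adaptive[["OMiSA"]]
          test_type[k] <- "OMiSA"
        } else {
          p_raw[k] <- tryCatch(
            univariate_cox_test(time, event, Z[, members], covariates),
            error = function(e) NA_real_)
          test_type[k] <- "univariate-Cox"
        }
      }
      rows[[rk]] <- data.frame(rank = rk, taxon = names(subsets),
                               n_otu = as.integer(n_otu), test = test_type,
                               p = p_raw,
                               p_adj = stats::p.adjust(p_raw,
                                                       p_adjust_method),
                               stringsAsFactors = FALSE)
    }
  }
  taxa <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rank = character(), taxon = character(),
               n_otu = integer(), test = character(),
               p = numeric(), p_adj = numeric())
  rownames(taxa) <- NULL
  taxa <- taxa[order(match(taxa$rank, ranks), taxa$p_adj, taxa$p), ]
  structure(list(community = community, taxa = taxa, alpha = alpha,
                 p_adjust_method = p_adjust_method),
            class = "taxa_scan")
}

#' @export
print.taxa_scan <- function(x, ...) {
  cat("Community-level adaptive test:\n")
  pa <- x$community$p_adaptive
  for (nm in names(pa)[!is.na(pa)]) {
    cat(sprintf("  %-10s p = %s\n", nm, signif(pa[nm], 4)))
  }
  if (nrow(x$taxa)) {
    hits <- x$taxa[!is.na(x$taxa$p_adj) & x$taxa$p_adj <= x$alpha, ]
    cat(sprintf("\n%d taxa tested across ranks; %d with %s-adjusted p <= %g\n",
                nrow(x$taxa), nrow(hits), x$p_adjust_method, x$alpha))
    if (nrow(hits)) print(hits, row.names = FALSE)
  }
  invisible(x)
}

#' Write a taxon scan report as TSV
#'
#' @param x A `"taxa_scan"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_report <- function(x, path) {
  stopifnot(inherits(x, "taxa_scan"))
  utils::write.table(x$taxa, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
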