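#' Read an OTU count table
#'
#' Reads a samples-by-OTUs table of non-negative read counts from a
#' tab-separated file or a BIOM file.  The canonical internal orientation is
#' samples in rows and OTUs in columns; set `otus_in_rows = TRUE` when the
#' file stores the transpose (the common BIOM convention, applied
#' automatically for `format = "biom"`).
#'
#' All-zero OTU columns are retained: low-abundance removal is the job of
#' the explicit [filter_otus()] step so that filtering stays auditable.
#'
#' @param path Path to the input file.
#' @param format `"tsv"` (tab-separated, header row, row names in the first
#'   column) or `"biom"` (read via the biomformat package).
#' @param otus_in_rows Logical; transpose on read.  Ignored for BIOM input,
#'   which always stores OTUs in rows.
#' @return A numeric matrix (samples x OTUs) with unique row and column
#'   names.
#' @seealso [write_count_table()], [to_composition()], [filter_otus()]
#' @export
read_count_table <- function(path, format = c("tsv", "biom"),
                             otus_in_rows = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("count table file not found: ", path)
  }
  if (format == "biom") {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    m <- t(m)  # biom stores taxa x samples
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df)
    if (otus_in_rows) m <- t(m)
  }
  validate_count_table(m)
}

validate_count_table <- function(m) {
  if (!is.numeric(m)) {
    bad <- which(!apply(m, 2, is.numeric))
    stop("non-numeric count cells in column(s): ",
         paste(colnames(m)[bad], collapse = ", "))
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("count table must carry sample (row) and OTU (column) identifiers")
  }
  if (nrow(m) < 1L || ncol(m) < 1L) {
    stop("count table needs at least one sample and one OTU")
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicate OTU identifiers: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  }
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    stop(sprintf("negative count at sample '%s', OTU '%s'",
                 rownames(m)[neg[1L, 1L]], colnames(m)[neg[1L, 2L]]))
  }
  if (anyNA(m)) stop("count table contains missing values")
  m
}

#' Write an OTU count table as TSV
#'
#' @param counts Samples-by-OTUs numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' Divides each sample's counts by its total so that rows sum to one; the
#' result is the community-level composition matrix Z on which all tests
#' operate.
#'
#' @param counts Samples-by-OTUs count matrix with positive row totals.
#' @return Numeric matrix of the same shape with rows on the unit simplex;
#'   carries `attr(, "community") = TRUE` to mark that rows sum to 1 (taxon
#'   subsets extracted later keep community-scale values and clear the
#'   flag).
#' @export
to_composition <- function(counts) {
  tot <- rowSums(counts)
  if (any(tot <= 0)) {
    stop("zero total count for sample(s): ",
         paste(rownames(counts)[tot <= 0], collapse = ", "))
  }
  z <- counts / tot
  attr(z, "community") <- TRUE
  z
}

#' Read a rooted phylogenetic tree
#'
#' Thin wrapper over [ape::read.tree()] that enforces the invariants the
#' UniFrac machinery needs: unique tip labels and non-negative branch
#' lengths.  Missing branch lengths are set to zero with a warning (a
#' zero-length branch simply contributes nothing to any UniFrac sum).
#'
#' @param path Newick file.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick tree from ", path)
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; treating all as 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) {
    warning("missing branch lengths treated as 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0)) stop("negative branch lengths in tree")
  tr
}

#' Read survival metadata and align it to a sample ordering
#'
#' Reads a TSV with one row per sample and extracts the observed time,
#' the 0/1 event indicator and optional covariate columns.  When
#' `sample_ids` is supplied (typically `rownames` of the community matrix)
#' the rows are joined to that ordering, so the result is invariant to the
#' row order of the file.
#'
#' @param path TSV file with a header; sample identifiers in `id_col`.
#' @param time_col,event_col Column names for observed time and event
#'   indicator.
#' @param covariate_cols Character vector of covariate column names
#'   (may be empty / NULL for an unadjusted analysis).
#' @param id_col Sample identifier column (default first column).
#' @param sample_ids Optional character vector giving the required sample
#'   order.
#' @return A list of class `"survival_data"` with elements `time`, `event`,
#'   `covariates` (matrix or NULL) and `sample_id`.
#' @export
read_survival_metadata <- function(path, time_col, event_col,
                                   covariate_cols = NULL, id_col = NULL,
                                   sample_ids = NULL) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(id_col)) id_col <- names(df)[1L]
  need <- c(id_col, time_col, event_col, covariate_cols)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing metadata column(s): ",
                         paste(miss, collapse = ", "))
  if (!is.null(sample_ids)) {
    idx <- match(sample_ids, df[[id_col]])
    if (anyNA(idx)) {
      stop("sample id(s) absent from metadata: ",
           paste(sample_ids[is.na(idx)], collapse = ", "))
    }
    df <- df[idx, , drop = FALSE]
  }
  survival_data(time = df[[time_col]], event = df[[event_col]],
                covariates = if (length(covariate_cols))
                  as.matrix(df[covariate_cols]) else NULL,
                sample_id = as.character(df[[id_col]]))
}

#' Construct a survival data object
#'
#' @param time Positive observed times (event or censoring).
#' @param event 0/1 event indicators.
#' @param covariates Optional numeric covariate matrix (n x q).
#' @param sample_id Optional sample identifiers.
#' @return A list of class `"survival_data"`.
#' @export
survival_data <- function(time, event, covariates = NULL, sample_id = NULL) {
  if (!all(event %in% c(0, 1))) {
    stop("event indicator must be coded 0/1; found: ",
         paste(unique(event[!event %in% c(0, 1)]), collapse = ", "))
  }
  if (any(time <= 0)) stop("observed times must be positive")
  n <- length(time)
  if (length(event) != n) stop("time and event lengths differ")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariate rows do not match n")
    rownames(covariates) <- NULL
  }
  structure(list(time = as.numeric(time), event = as.integer(event),
                 covariates = covariates, sample_id = sample_id),
            class = "survival_data")
}

#' Read a taxonomy table
#'
#' Expects a TSV with an OTU identifier column followed by lineage labels
#' at the ranks phylum, class, order, family and genus.  Empty cells and
#' `NA` mean "unassigned at this rank".
#'
#' @param path TSV file.
#' @param otu_col Name of the OTU identifier column (default first column).
#' @return A data.frame with columns `otu`, `phylum`, `class`, `order`,
#'   `family`, `genus`.
#' @export
read_taxonomy <- function(path, otu_col = NULL) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  if (is.null(otu_col)) otu_col <- names(df)[1L]
  ranks <- c("phylum", "class", "order", "family", "genus")
  miss <- setdiff(ranks, tolower(names(df)))
  if (length(miss)) stop("taxonomy file lacks rank column(s): ",
                         paste(miss, collapse = ", "))
  names(df) <- tolower(names(df))
  out <- data.frame(otu = as.character(df[[tolower(otu_col)]]),
                    df[ranks], stringsAsFactors = FALSE)
  if (anyDuplicated(out$otu)) stop("duplicate OTU ids in taxonomy table")
  out
}
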