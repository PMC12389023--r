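#' Construct a species-by-sample count matrix
#'
#' Light validation wrapper around a non-negative integer matrix with species
#' in rows and samples in columns. Row and column names carry the species and
#' sample identifiers and must be unique.
#'
#' @param counts Numeric matrix (species x samples), non-negative, integral.
#' @param species_ids,sample_ids Optional identifier vectors; default to the
#'   existing dimnames.
#' @return The validated matrix with class `taxa_counts`.
#' @export
taxa_counts <- function(counts, species_ids = rownames(counts),
                        sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(species_ids) || is.null(sample_ids)) {
    stop("taxa_counts: species and sample identifiers are required")
  }
  if (anyDuplicated(species_ids) || anyDuplicated(sample_ids)) {
    stop("taxa_counts: identifiers must be unique")
  }
  if (length(species_ids) != nrow(counts) || length(sample_ids) != ncol(counts)) {
    stop("taxa_counts: identifier lengths do not match matrix dimensions")
  }
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("taxa_counts: counts must be non-negative and non-missing")
  }
  if (max(abs(counts - round(counts))) > 1e-8) {
    stop("taxa_counts: counts must be integers")
  }
  dimnames(counts) <- list(species_ids, sample_ids)
  class(counts) <- c("taxa_counts", class(counts))
  counts
}

#' Filter species by prevalence and mean abundance
#'
#' Retains species observed (raw count > 0) in strictly more than
#' `prevalence_min` of samples AND whose mean raw count strictly exceeds
#' `mean_count_min`. Both inequalities are strict, so a species present in
#' exactly 20% of samples is dropped at the default threshold. Species order
#' is preserved.
#'
#' @param counts Species x sample count matrix (see [taxa_counts()]).
#' @param prevalence_min Minimum fraction of samples with a nonzero count;
#'   default 0.20.
#' @param mean_count_min Minimum mean raw count across all samples; default 50.
#' @return The filtered count matrix. Emits a warning (not an error) when no
#'   species survive.
#' @export
filter_species <- function(counts, prevalence_min = 0.20, mean_count_min = 50) {
  if (ncol(counts) < 1) stop("filter_species: need at least one sample")
  prev <- rowMeans(counts > 0)
  mu <- rowMeans(counts)
  keep <- prev > prevalence_min & mu > mean_count_min
  if (!any(keep)) {
    warning("filter_species: no species pass the thresholds")
  }
  out <- counts[keep, , drop = FALSE]
  class(out) <- class(counts)
  out
}

#' Centered log-ratio transform of a count matrix
#'
#' Adds a pseudocount to every cell, takes natural logs, and centers each
#' sample (column) on its mean over the retained species, giving the matrix
#' `X` used by the gut microbiome score. Every column of the result sums to
#' zero by construction. Filtering is expected to happen before this call so
#' the CLR geometry is defined over the retained species only; pass the
#' unfiltered matrix first if the alternative closure is wanted.
#'
#' @param counts Species x sample count matrix.
#' @param pseudocount Positive value added to all counts before the log;
#'   default 0.5. A zero pseudocount is permitted only on zero-free matrices.
#' @return Matrix of CLR values with the same dimnames, plus attributes
#'   `pseudocount` and class `clr_matrix`.
#' @export
clr_transform <- function(counts, pseudocount = 0.5) {
  if (nrow(counts) < 2) {
    stop("clr_transform: CLR is undefined for fewer than 2 species")
  }
  if (pseudocount < 0) stop("clr_transform: pseudocount must be >= 0")
  if (pseudocount == 0 && any(counts == 0)) {
    stop("clr_transform: zero pseudocount requires a zero-free matrix")
  }
  lg <- log(unclass(counts) + pseudocount)
  x <- sweep(lg, 2L, colMeans(lg), `-`)
  attr(x, "pseudocount") <- pseudocount
  class(x) <- c("clr_matrix", "matrix", "array")
  x
}

#' Read a species-by-sample count table
#'
#' Reads a TSV with species identifiers in the first column and one column
#' per sample, or a BIOM file (requires the `biomformat` package) when the
#' path ends in `.biom`.
#'
#' @param path File path.
#' @return A [taxa_counts()] matrix.
#' @export
read_taxa_counts <- function(path) {
  if (grepl("\\.biom$", path)) {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("read_taxa_counts: reading BIOM requires the biomformat package")
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(taxa_counts(m))
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  taxa_counts(m)
}

#' Write a species-by-sample matrix as TSV
#'
#' @param x Matrix with species rownames and sample colnames.
#' @param path Output file path.
#' @param id_col Name for the identifier column; default `"species_id"`.
#' @export
write_taxa_matrix <- function(x, path, id_col = "species_id") {
  df <- data.frame(rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
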