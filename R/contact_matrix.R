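#' Residue-residue contact free-energy matrix
#'
#' Container for a symmetric 20x20 matrix of pairwise contact free
#' energies on a dimensionless RT-like scale, as produced by Boltzmann
#' inversion of contact statistics (e.g. the Miyazawa-Jernigan potential
#' or beta-strand pairing potentials). Values are stored against an
#' explicit residue label order; every computation in the package indexes
#' by label, so matrices with different source orderings interoperate.
#'
#' @param values Numeric 20x20 (or n x n) matrix. Symmetrized on
#'   construction; asymmetries larger than `tol` are an error.
#' @param labels Character vector of one-letter residue codes, one per
#'   row/column. Defaults to the dimnames of `values`.
#' @param name Free-text provenance tag.
#' @param tol Maximum allowed absolute asymmetry before symmetrization.
#'
#' @return An object of class `contact_matrix`: list with `labels`,
#'   `values` (exactly symmetric, dimnames set) and `name`.
#' @examples
#' v <- matrix(rnorm(400), 20, 20); v <- (v + t(v)) / 2
#' m <- contact_matrix(v, residue_alphabet(), name = "toy")
#' @export
contact_matrix <- function(values, labels = rownames(values),
                           name = "", tol = 1e-9) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("values must be a square matrix")
  if (is.null(labels)) stop("labels are required")
  labels <- as.character(labels)
  if (length(labels) != n) stop("need one label per row")
  if (anyDuplicated(labels)) {
    stop("duplicate residue labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (!is.numeric(values) || anyNA(values)) {
    stop("values must be numeric and free of NA")
  }
  asym <- max(abs(values - t(values)))
  if (asym > tol) {
    idx <- which(abs(values - t(values)) == asym, arr.ind = TRUE)[1, ]
    stop(sprintf("matrix is asymmetric at (%s,%s): |e_ij - e_ji| = %g",
                 labels[idx[1]], labels[idx[2]], asym))
  }
  values <- (values + t(values)) / 2
  dimnames(values) <- list(labels, labels)
  structure(list(labels = labels, values = values, name = name),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  n <- length(x$labels)
  cat("Contact matrix", if (nzchar(x$name)) paste0("\"", x$name, "\""),
      sprintf("(%d x %d, %d unique elements)\n", n, n, n * (n + 1) / 2))
  s <- summary_stats(x)
  cat(sprintf("  mean %.3f  sd %.3f  range [%.3f, %.3f]\n",
              s$mean, s$sd, s$min, s$max))
  invisible(x)
}

#' Unique elements of a symmetric contact matrix
#'
#' Returns the n(n+1)/2 unique elements (upper triangle including the
#' diagonal) in the row-major order of the lower triangle, i.e. the same
#' order as the lower-triangle file dialect: (1,1), (2,1), (2,2),
#' (3,1), ... For 20 residues this is 210 values.
#'
#' @param matrix A [contact_matrix], or a square symmetric matrix.
#' @return Numeric vector of length n(n+1)/2.
#' @export
unique_elements <- function(matrix) {
  v <- if (inherits(matrix, "contact_matrix")) matrix$values else matrix
  v[upper.tri(v, diag = TRUE)]
}

#' Index table of unique residue pairs
#'
#' Row/column indices of the unique elements, in the order used by
#' [unique_elements()].
#'
#' @param n Matrix dimension.
#' @return Data frame with integer columns `i`, `j` (`j <= i`).
#' @keywords internal
pair_index <- function(n) {
  idx <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  # upper-triangle column-major (r,c) corresponds to lower-triangle
  # row-major (c,r); report as (i, j) with j <= i
  data.frame(i = idx[, "col"], j = idx[, "row"])
}

#' Mean and spread of the unique matrix elements
#'
#' Summary of the distribution of the 210 unique contact free energies.
#' The standard deviation is the population value (divide by N), the
#' maximum-likelihood Gaussian fit to the element distribution; this
#' convention is fixed so that distribution summaries are reproducible.
#'
#' @param matrix A [contact_matrix].
#' @return List with `mean`, `sd` (population), `min`, `max`, `n`.
#' @examples
#' m <- contact_matrix(matrix(1, 20, 20), residue_alphabet())
#' summary_stats(m)$sd  # 0
#' @export
summary_stats <- function(matrix) {
  u <- unique_elements(matrix)
  list(mean = mean(u),
       sd = sqrt(mean((u - mean(u))^2)),
       min = min(u), max = max(u), n = length(u))
}

#' Boltzmann inversion of contact probabilities
#'
#' Converts a matrix of observed pair probabilities and a reference-state
#' matrix into contact free energies `e_ij = -log(p_ij / ref_ij)` in RT
#' units, the standard quasi-chemical construction of knowledge-based
#' potentials.
#'
#' @param pair_probabilities Positive 20x20 matrix of observed contact
#'   probabilities (or frequencies).
#' @param reference Positive matrix of the same shape: the expected
#'   probabilities under the reference state.
#' @param labels Residue labels; default from dimnames.
#' @param name Provenance tag for the result.
#' @return A [contact_matrix].
#' @export
boltzmann_invert <- function(pair_probabilities, reference,
                             labels = rownames(pair_probabilities),
                             name = "boltzmann") {
  p <- as.matrix(pair_probabilities)
  r <- as.matrix(reference)
  if (!all(dim(p) == dim(r))) stop("probability matrices differ in shape")
  if (any(p <= 0) || any(r <= 0)) {
    stop("all probabilities must be strictly positive for Boltzmann inversion")
  }
  contact_matrix(-log(p / r), labels = labels, name = name, tol = 1e-9)
}

#' Rescale the proline row and column of a contact matrix
#'
#' Divides every Pro-X element (proline row and column, including the
#' Pro-Pro diagonal) by `factor`, leaving all other elements untouched.
#' A "k-fold reduction" of the destabilising Pro-X free energies of a
#' strand-pairing potential is `scale_pro_contacts(m, k)`.
#'
#' @param matrix A [contact_matrix] whose labels include `"P"`.
#' @param factor Positive fold-reduction factor; 1 is the identity.
#' @return A [contact_matrix] with scaled Pro-X elements.
#' @export
scale_pro_contacts <- function(matrix, factor) {
  stopifnot(inherits(matrix, "contact_matrix"))
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0) {
    stop("factor must be a single positive number")
  }
  if (!"P" %in% matrix$labels) stop("matrix has no proline row")
  v <- matrix$values
  v["P", ] <- v["P", ] / factor
  v[, "P"] <- matrix$values[, "P"] / factor
  v["P", "P"] <- matrix$values["P", "P"] / factor
  contact_matrix(v, matrix$labels,
                 name = sprintf("%s/proX%g", matrix$name, factor))
}
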