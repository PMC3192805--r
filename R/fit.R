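#' Fitting options
#'
#' Options shared by [fit_two_body()] and [fit_full()]. The fit is
#' ordinary least squares over the 210 unique matrix elements, each pair
#' counted once and unweighted; the sign convention is fixed so that the
#' eta coefficients are positive stabilization magnitudes entering the
#' model with a minus sign:
#' `e_ij = eta0 - (eta_HH HH_ij + eta_HP HP_ij + eta_HB HB_ij) [+ q_i + q_j]`.
#'
#' @param excluded_pairs Optional list of residue pairs (length-2
#'   character vectors) whose unique elements are dropped from the fit,
#'   e.g. `list(c("C", "C"))` to ignore the disulfide element.
#' @param ss_regressor If `TRUE`, add a binary indicator column for the
#'   Cys-Cys element (a dedicated disulfide regressor).
#' @return Object of class `fit_options`.
#' @export
fit_options <- function(excluded_pairs = NULL, ss_regressor = FALSE) {
  if (!is.null(excluded_pairs)) {
    ok <- vapply(excluded_pairs,
                 function(p) is.character(p) && length(p) == 2L,
                 logical(1))
    if (!all(ok)) stop("excluded_pairs must be length-2 character vectors")
  }
  structure(list(excluded_pairs = excluded_pairs,
                 ss_regressor = isTRUE(ss_regressor)),
            class = "fit_options")
}

# Align a contact matrix onto the label order of a basis set.
align_to_basis <- function(matrix, basis) {
  stopifnot(inherits(matrix, "contact_matrix"),
            inherits(basis, "basis_set"))
  if (!setequal(matrix$labels, basis$labels)) {
    stop("matrix and basis do not share residue labels")
  }
  matrix$values[basis$labels, basis$labels]
}

# Rows of the unique-element design shared by both model variants.
# Columns are named; eta columns carry the minus sign of the model.
two_body_design <- function(basis, opts) {
  ut <- upper.tri(basis$HH, diag = TRUE)
  X <- cbind(eta0 = 1,
             eta_hh = -basis$HH[ut],
             eta_hp = -basis$HP[ut],
             eta_hb = -basis$HB[ut])
  if (opts$ss_regressor) {
    cc <- outer(basis$labels == "C", basis$labels == "C", "&") * 1
    X <- cbind(X, ss_cys = cc[ut])
  }
  X
}

# Reduced-parameter columns for the one-body terms under the class-wise
# zero-sum gauge: one free parameter per residue except the last residue
# of each hydropathy class, whose value is minus the sum of its
# classmates. Column for residue r is c_r - c_z, where c_r counts the
# occurrences of r in the pair (2 on the diagonal) and z is the
# eliminated residue of r's class.
onebody_design <- function(basis) {
  labels <- basis$labels
  n <- length(labels)
  pairs <- pair_index(n)
  counts <- vapply(seq_len(n), function(k) {
    (pairs$i == k) + (pairs$j == k)
  }, numeric(nrow(pairs)))
  colnames(counts) <- labels
  cl <- basis$classification
  free <- list()
  for (set in list(cl$hydrophobic, cl$hydrophilic)) {
    members <- labels[labels %in% set]
    z <- members[length(members)]
    for (r in members[-length(members)]) {
      free[[paste0("q_", r)]] <- counts[, r] - counts[, z]
    }
  }
  list(X = do.call(cbind, free),
       free_labels = sub("^q_", "", names(free)))
}

# Expand reduced one-body coefficients back to the full gauge-satisfying
# 20-vector, and the linear map used for standard errors.
expand_q <- function(coef_q, basis) {
  labels <- basis$labels
  cl <- basis$classification
  A <- matrix(0, length(labels), length(coef_q),
              dimnames = list(labels, names(coef_q)))
  for (set in list(cl$hydrophobic, cl$hydrophilic)) {
    members <- labels[labels %in% set]
    z <- members[length(members)]
    for (r in members[-length(members)]) {
      A[r, paste0("q_", r)] <- 1
      A[z, paste0("q_", r)] <- -1
    }
  }
  list(q = drop(A %*% coef_q), A = A)
}

ols_solve <- function(X, y, what) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("rank-deficient design in ", what,
         ": the classification makes some regressors collinear")
  }
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  XtX_inv <- chol2inv(qr.R(qrX))
  dimnames(XtX_inv) <- list(colnames(X), colnames(X))
  list(beta = beta, fitted = fitted, rss = sum(res^2),
       sigma2 = sigma2, cov = sigma2 * XtX_inv, df = df)
}

fit_rows_kept <- function(basis, opts) {
  n <- length(basis$labels)
  pairs <- pair_index(n)
  keep <- rep(TRUE, nrow(pairs))
  for (p in opts$excluded_pairs) {
    ii <- match(p, basis$labels)
    if (anyNA(ii)) stop("excluded pair names unknown residue: ",
                        paste(p, collapse = ","))
    keep[(pairs$i == ii[1] & pairs$j == ii[2]) |
           (pairs$i == ii[2] & pairs$j == ii[1])] <- FALSE
  }
  keep
}

#' Two-body decomposition of a contact matrix
#'
#' Fits the coarse-grained hydrophobic / hydrogen-bonding model
#' `e_ij = eta0 - (eta_HH HH_ij + eta_HP HP_ij + eta_HB HB_ij)`
#' to the 210 unique elements of a contact free-energy matrix by
#' ordinary least squares. `eta_HH` and `eta_HP` measure the free energy
#' gained by forming hydrophobic contacts relative to a polar-polar
#' contact, `eta_HB` the gain from backbone hydrogen-bond formation, and
#' `eta0` shifts the polar-polar reference; with this convention the
#' fitted polar-polar (non-proline) class mean is `eta0 - eta_HB`.
#'
#' @param matrix A [contact_matrix].
#' @param basis A [build_basis()] result sharing the matrix's labels.
#' @param opts A [fit_options()] object.
#' @return Object of class `two_body_fit`: coefficients `eta_hh`,
#'   `eta_hp`, `eta_hb`, `eta0`, OLS standard errors `se_hh`, `se_hp`,
#'   `se_hb`, `se_e0`, fit metrics `pearson_r` and `rmsd` over the fitted
#'   unique elements, plus bookkeeping fields.
#' @examples
#' b <- build_basis(hydropathy_classification("dill"))
#' truth <- ground_truth(eta_hh = 2, eta_hp = 1, eta_hb = 1, eta0 = 0.5,
#'                       noise_sd = 0)
#' m <- generate_matrix(truth)$matrix
#' fit_two_body(m, b)$eta_hh  # 2
#' @export
fit_two_body <- function(matrix, basis, opts = fit_options()) {
  vals <- align_to_basis(matrix, basis)
  keep <- fit_rows_kept(basis, opts)
  X <- two_body_design(basis, opts)[keep, , drop = FALSE]
  y <- vals[upper.tri(vals, diag = TRUE)][keep]
  sol <- ols_solve(X, y, "fit_two_body")
  se <- sqrt(diag(sol$cov))
  structure(list(
    eta_hh = unname(sol$beta["eta_hh"]),
    eta_hp = unname(sol$beta["eta_hp"]),
    eta_hb = unname(sol$beta["eta_hb"]),
    eta0 = unname(sol$beta["eta0"]),
    se_hh = unname(se["eta_hh"]), se_hp = unname(se["eta_hp"]),
    se_hb = unname(se["eta_hb"]), se_e0 = unname(se["eta0"]),
    ss_cys = if (opts$ss_regressor) unname(sol$beta["ss_cys"]) else NULL,
    pearson_r = stats::cor(y, sol$fitted),
    rmsd = sqrt(mean((y - sol$fitted)^2)),
    rss = sol$rss, n_fitted = length(y),
    classification = basis$classification,
    labels = basis$labels, opts = opts,
    matrix_name = matrix$name
  ), class = "two_body_fit")
}

#' Two-body plus one-body decomposition of a contact matrix
#'
#' Extends [fit_two_body()] with residue-specific one-body terms:
#' `e_ij = eta0 - (eta_HH HH_ij + eta_HP HP_ij + eta_HB HB_ij) + q_i + q_j`.
#' Without constraints the one-body terms are degenerate with the
#' two-body coefficients (a constant moved into the q of one hydropathy
#' class can be absorbed by `eta_HH`, `eta_HP` and `eta0`); the fit
#' therefore imposes the class-wise zero-sum gauge
#' `sum(q[hydrophobic]) = sum(q[hydrophilic]) = 0`, eliminating both
#' degeneracies while leaving the reconstruction unchanged. The model is
#' linear in all 24 parameters, so the constrained least-squares problem
#' is solved in closed form on a reduced parameterization.
#'
#' @inheritParams fit_two_body
#' @param gauge Gauge constraint; only `"classwise_zero_sum"` is defined.
#' @return Object of class `full_fit` (inherits `two_body_fit`), with the
#'   additional fields `q` (a [one_body_scale] of fitted one-body terms),
#'   `se_q` (their standard errors) and `gauge`.
#' @export
fit_full <- function(matrix, basis, gauge = "classwise_zero_sum",
                     opts = fit_options()) {
  gauge <- match.arg(gauge, "classwise_zero_sum")
  vals <- align_to_basis(matrix, basis)
  keep <- fit_rows_kept(basis, opts)
  ob <- onebody_design(basis)
  X <- cbind(two_body_design(basis, opts), ob$X)[keep, , drop = FALSE]
  y <- vals[upper.tri(vals, diag = TRUE)][keep]
  sol <- ols_solve(X, y, "fit_full")
  se <- sqrt(diag(sol$cov))
  qcols <- grep("^q_", colnames(X), value = TRUE)
  exp_q <- expand_q(sol$beta[qcols], basis)
  cov_q <- exp_q$A %*% sol$cov[qcols, qcols] %*% t(exp_q$A)
  structure(list(
    eta_hh = unname(sol$beta["eta_hh"]),
    eta_hp = unname(sol$beta["eta_hp"]),
    eta_hb = unname(sol$beta["eta_hb"]),
    eta0 = unname(sol$beta["eta0"]),
    se_hh = unname(se["eta_hh"]), se_hp = unname(se["eta_hp"]),
    se_hb = unname(se["eta_hb"]), se_e0 = unname(se["eta0"]),
    ss_cys = if (opts$ss_regressor) unname(sol$beta["ss_cys"]) else NULL,
    q = one_body_scale(exp_q$q, basis$labels,
                       name = paste0("q[", matrix$name, "]")),
    se_q = sqrt(diag(cov_q)),
    gauge = gauge,
    pearson_r = stats::cor(y, sol$fitted),
    rmsd = sqrt(mean((y - sol$fitted)^2)),
    rss = sol$rss, n_fitted = length(y),
    classification = basis$classification,
    labels = basis$labels, opts = opts,
    matrix_name = matrix$name
  ), class = c("full_fit", "two_body_fit"))
}

#' @export
print.two_body_fit <- function(x, ...) {
  kind <- if (inherits(x, "full_fit")) "two-body + one-body" else "two-body"
  cat(sprintf("%s decomposition of \"%s\" (%s classification)\n",
              kind, x$matrix_name, x$classification$name))
  cat(sprintf("  eta_HH = %6.3f (se %.3f)\n", x$eta_hh, x$se_hh))
  cat(sprintf("  eta_HP = %6.3f (se %.3f)\n", x$eta_hp, x$se_hp))
  cat(sprintf("  eta_HB = %6.3f (se %.3f)\n", x$eta_hb, x$se_hb))
  cat(sprintf("  eta_0  = %6.3f (se %.3f)\n", x$eta0, x$se_e0))
  cat(sprintf("  eta_HB/eta_HH = %.3f\n", hb_hh_ratio(x)))
  cat(sprintf("  r = %.4f, rmsd = %.4f over %d unique elements\n",
              x$pearson_r, x$rmsd, x$n_fitted))
  invisible(x)
}

#' Reconstruct a contact matrix from a fitted decomposition
#'
#' Evaluates the fitted model over all residue pairs, returning the
#' low-dimensional approximation of the original matrix.
#'
#' @param fit A `two_body_fit` or `full_fit`.
#' @param basis The [build_basis()] result the fit was made with.
#' @return A [contact_matrix] of fitted elements.
#' @export
reconstruct <- function(fit, basis) {
  stopifnot(inherits(fit, "two_body_fit"), inherits(basis, "basis_set"))
  if (!identical(fit$classification$hydrophobic,
                 basis$classification$hydrophobic)) {
    stop("fit and basis use different classifications")
  }
  v <- fit$eta0 - (fit$eta_hh * basis$HH + fit$eta_hp * basis$HP +
                     fit$eta_hb * basis$HB)
  if (!is.null(fit$ss_cys)) {
    cc <- outer(basis$labels == "C", basis$labels == "C", "&") * 1
    v <- v + fit$ss_cys * cc
  }
  if (inherits(fit, "full_fit")) {
    q <- fit$q$values[basis$labels]
    v <- v + outer(q, q, "+")
  }
  contact_matrix(v, basis$labels,
                 name = paste0("reconstructed[", fit$matrix_name, "]"))
}

#' Agreement between two contact matrices
#'
#' Pearson correlation and root-mean-square deviation over the unique
#' elements, the metrics used to judge how well a decomposition
#' reproduces the original potential.
#'
#' @param original,reconstructed [contact_matrix] objects on the same
#'   residues.
#' @return List with `pearson_r` and `rmsd`.
#' @export
fit_metrics <- function(original, reconstructed) {
  stopifnot(inherits(original, "contact_matrix"),
            inherits(reconstructed, "contact_matrix"))
  if (!setequal(original$labels, reconstructed$labels)) {
    stop("matrices do not share residue labels")
  }
  a <- unique_elements(original)
  b_vals <- reconstructed$values[original$labels, original$labels]
  b <- b_vals[upper.tri(b_vals, diag = TRUE)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("Pearson correlation undefined: an input has zero variance")
  }
  list(pearson_r = stats::cor(a, b), rmsd = sqrt(mean((a - b)^2)))
}

#' Ratio of hydrogen-bonding to hydrophobic stabilization
#'
#' The headline statistic of the decomposition: `eta_HB / eta_HH`.
#' Values below 1 indicate hydrophobic-dominated (native-fold-like)
#' stabilization, values above 1 hydrogen-bond-dominated (amyloid-like)
#' stabilization.
#'
#' @param fit A `two_body_fit` or `full_fit`.
#' @return Numeric scalar.
#' @export
hb_hh_ratio <- function(fit) {
  stopifnot(inherits(fit, "two_body_fit"))
  if (fit$eta_hh == 0) stop("eta_HH is zero; ratio undefined")
  fit$eta_hb / fit$eta_hh
}

#' Effective contact energy of a sequence with a given contact set
#'
#' Evaluates the contact-approximation effective Hamiltonian: the sum of
#' fitted pair energies `e_hat(a_i, a_j)` over an externally supplied
#' list of residue-residue contacts (the spatial adjacency is the
#' caller's concern).
#'
#' @param sequence Character string (or vector) of one-letter residue
#'   codes.
#' @param contacts List of length-2 integer vectors, or a 2-column
#'   matrix, of 1-based sequence positions in contact. `i == j` is
#'   rejected.
#' @param fit A `two_body_fit` or `full_fit`.
#' @param basis The matching [build_basis()] result.
#' @return Total effective energy (RT units).
#' @export
effective_energy <- function(sequence, contacts, fit, basis) {
  seqv <- if (length(sequence) == 1L) {
    strsplit(sequence, "")[[1]]
  } else {
    as.character(sequence)
  }
  if (!all(seqv %in% basis$labels)) {
    stop("sequence has non-standard residues: ",
         paste(setdiff(seqv, basis$labels), collapse = ","))
  }
  if (is.matrix(contacts)) {
    contacts <- lapply(seq_len(nrow(contacts)), function(k) contacts[k, ])
  }
  if (length(contacts) == 0L) return(0)
  eh <- reconstruct(fit, basis)$values
  total <- 0
  for (ct in contacts) {
    ij <- as.integer(ct)
    if (length(ij) != 2L || anyNA(ij)) stop("contacts must be index pairs")
    if (any(ij < 1L) || any(ij > length(seqv))) {
      stop("contact index out of range: ", paste(ij, collapse = ","))
    }
    if (ij[1] == ij[2]) stop("self-contact i == j is not allowed")
    total <- total + eh[seqv[ij[1]], seqv[ij[2]]]
  }
  total
}
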