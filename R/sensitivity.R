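#' Find the proline-contact reduction matching a target ratio
#'
#' Bisects on the fold-reduction factor applied to the Pro-X elements
#' (see [scale_pro_contacts()]) until the refitted two-body
#' `eta_HB/eta_HH` ratio equals `target_ratio`. Used to quantify how
#' strongly the destabilising Pro-X free energies of a strand-pairing
#' potential drive its hydrogen-bonding dominance: the factor needed to
#' bring its ratio down to that of a native-fold potential.
#'
#' Monotonicity of the ratio in the factor over `bounds` is checked
#' numerically before bisection.
#'
#' @param matrix A [contact_matrix].
#' @param basis The matching [build_basis()] result.
#' @param target_ratio Target `eta_HB/eta_HH` value.
#' @param bounds Length-2 numeric bracket of factors, default `c(1, 20)`.
#' @param tol Bisection tolerance on the ratio, default 1e-3.
#' @param opts A [fit_options()] object.
#' @return The factor (numeric scalar).
#' @export
find_pro_factor <- function(matrix, basis, target_ratio,
                            bounds = c(1, 20), tol = 1e-3,
                            opts = fit_options()) {
  if (tol <= 0) stop("tol must be positive")
  ratio_at <- function(f) {
    hb_hh_ratio(fit_two_body(scale_pro_contacts(matrix, f), basis, opts))
  }
  lo <- bounds[1]
  hi <- bounds[2]
  r_lo <- ratio_at(lo)
  r_hi <- ratio_at(hi)
  if ((r_lo - target_ratio) * (r_hi - target_ratio) > 0) {
    stop(sprintf(paste0("bounds do not bracket the target ratio %.4g: ",
                        "ratio(%g) = %.4g, ratio(%g) = %.4g"),
                 target_ratio, lo, r_lo, hi, r_hi))
  }
  grid <- seq(lo, hi, length.out = 9)
  rg <- vapply(grid, ratio_at, numeric(1))
  if (is.unsorted(rg) && is.unsorted(rev(rg))) {
    stop("ratio is not monotone in the factor over the bracket")
  }
  increasing <- r_hi > r_lo
  for (it in seq_len(200)) {
    mid <- (lo + hi) / 2
    r_mid <- ratio_at(mid)
    if (abs(r_mid - target_ratio) <= tol) return(mid)
    if ((r_mid < target_ratio) == increasing) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Ratio table under alternative hydropathy classifications
#'
#' Refits the two-body decomposition of one or more matrices under each
#' of a set of hydropathy classifications and tabulates the
#' `eta_HB/eta_HH` ratio, the robustness control for the
#' hydrophobic-vs-hydrogen-bonding balance.
#'
#' @param matrices A [contact_matrix] or named list of them.
#' @param variants List of [hydropathy_classification] objects (or names
#'   of built-ins).
#' @param opts A [fit_options()] object.
#' @return Data frame with one row per (matrix, classification) pair and
#'   columns `matrix`, `classification`, `eta_hh`, `eta_hp`, `eta_hb`,
#'   `eta0`, `hb_hh_ratio`, `pearson_r`.
#' @export
classification_battery <- function(matrices,
                                   variants = list("dill", "pro_polar",
                                                   "pro_ala_polar"),
                                   opts = fit_options()) {
  if (inherits(matrices, "contact_matrix")) {
    matrices <- stats::setNames(list(matrices), matrices$name)
  }
  variants <- lapply(variants, function(v) {
    if (inherits(v, "hydropathy_classification")) v
    else hydropathy_classification(v)
  })
  rows <- list()
  for (mn in names(matrices)) {
    for (cl in variants) {
      fit <- fit_two_body(matrices[[mn]], build_basis(cl), opts)
      rows[[length(rows) + 1L]] <- data.frame(
        matrix = mn, classification = cl$name,
        eta_hh = fit$eta_hh, eta_hp = fit$eta_hp,
        eta_hb = fit$eta_hb, eta0 = fit$eta0,
        hb_hh_ratio = hb_hh_ratio(fit),
        pearson_r = fit$pearson_r
      )
    }
  }
  do.call(rbind, rows)
}

#' Two-body refit with explicit disulfide handling
#'
#' The Cys-Cys element of a contact potential can carry a covalent
#' disulfide contribution that the hydropathy/hydrogen-bond model does
#' not represent. Two treatments are provided:
#' * `"exclude_cys_cys"` - drop the (C,C) unique element from the fit;
#' * `"ss_regressor"` - keep it, but add a dedicated binary (C,C)
#'   indicator column so the disulfide energy is absorbed by its own
#'   coefficient.
#'
#' In both modes the fit metrics are computed over the element set the
#' model was fitted on.
#'
#' @param matrix A [contact_matrix].
#' @param basis The matching [build_basis()] result.
#' @param mode `"exclude_cys_cys"` (default) or `"ss_regressor"`.
#' @return A `two_body_fit`.
#' @export
refit_with_disulfide <- function(matrix, basis,
                                 mode = c("exclude_cys_cys",
                                          "ss_regressor")) {
  mode <- match.arg(mode)
  opts <- if (mode == "exclude_cys_cys") {
    fit_options(excluded_pairs = list(c("C", "C")))
  } else {
    fit_options(ss_regressor = TRUE)
  }
  fit_two_body(matrix, basis, opts)
}

#' Sensitivity report for a set of contact matrices
#'
#' Bundles the robustness controls into one deterministic report: the
#' baseline `eta_HB/eta_HH` ratio per matrix, the ratio under each
#' reclassification variant, the Pro-X fold-reduction needed to reach a
#' target ratio, and the disulfide-variant metrics.
#'
#' @param matrices Named list of [contact_matrix] objects.
#' @param variants Classification variants for
#'   [classification_battery()].
#' @param pro_target Optional target ratio for [find_pro_factor()]
#'   (applied to every matrix whose baseline ratio exceeds it).
#' @param pro_bounds Bracket for the factor search.
#' @return Object of class `sensitivity_report`: list with `battery`
#'   (data frame), `pro_factors` (named numeric), `disulfide` (data
#'   frame with both modes per matrix).
#' @export
sensitivity_report <- function(matrices,
                               variants = list("dill", "pro_polar",
                                               "pro_ala_polar"),
                               pro_target = NULL,
                               pro_bounds = c(1, 20)) {
  if (inherits(matrices, "contact_matrix")) {
    matrices <- stats::setNames(list(matrices), matrices$name)
  }
  basis <- build_basis(hydropathy_classification("dill"))
  battery <- classification_battery(matrices, variants)
  pro_factors <- NULL
  if (!is.null(pro_target)) {
    pro_factors <- vapply(matrices, function(m) {
      base <- hb_hh_ratio(fit_two_body(m, basis))
      if (abs(base - pro_target) <= 1e-3) return(1)
      tryCatch(find_pro_factor(m, basis, pro_target, pro_bounds),
               error = function(e) NA_real_)
    }, numeric(1))
  }
  disulfide <- do.call(rbind, lapply(names(matrices), function(mn) {
    do.call(rbind, lapply(c("exclude_cys_cys", "ss_regressor"),
      function(md) {
        f <- refit_with_disulfide(matrices[[mn]], basis, md)
        data.frame(matrix = mn, mode = md, pearson_r = f$pearson_r,
                   rmsd = f$rmsd, hb_hh_ratio = hb_hh_ratio(f))
      }))
  }))
  structure(list(battery = battery, pro_factors = pro_factors,
                 disulfide = disulfide),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Sensitivity report\n\nReclassification battery:\n")
  print(x$battery[, c("matrix", "classification", "hb_hh_ratio")],
        row.names = FALSE)
  if (!is.null(x$pro_factors)) {
    cat("\nPro-X fold reductions to target ratio:\n")
    print(round(x$pro_factors, 2))
  }
  cat("\nDisulfide handling:\n")
  print(x$disulfide, row.names = FALSE)
  invisible(x)
}
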