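#' Solvation correction of a per-residue free-energy scale
#'
#' Splits a 20-residue scale into its hydrophobic and hydrophilic classes
#' and subtracts each class's mean, interpreting the removed means as
#' average solvation free energies (the hydrophobic cost / hydrophilic
#' gain of exposing a residue class to water) and the centred remainder
#' as the residue-specific secondary-structure component.
#'
#' Because proline cannot donate a backbone amide hydrogen bond, its
#' treatment is an explicit policy rather than a fixed choice:
#' * `"in_hydrophobic"` - proline stays in the hydrophobic class (the
#'   plain Dill grouping);
#' * `"in_hydrophilic"` - proline is grouped with the hydrophilic
#'   residues;
#' * `"excluded"` - proline is dropped from the correction entirely
#'   (appropriate for beta-sheet scales, where its value reflects
#'   hydrogen-bond incapacity rather than solvation).
#'
#' @param scale A [one_body_scale] covering the retained residues.
#' @param classification A [hydropathy_classification].
#' @param proline_policy One of `"in_hydrophobic"`, `"in_hydrophilic"`,
#'   `"excluded"`.
#' @return Object of class `solvation_decomposition`: list with
#'   `corrected` (class-centred [one_body_scale]), `shift_hydrophobic`
#'   and `shift_hydrophilic` (the removed class means), the class
#'   memberships used, and `proline_policy`.
#' @examples
#' sc <- table2_scales()$qvalues_li
#' solvation_correct(sc, hydropathy_classification("dill"),
#'                   "in_hydrophobic")$shift_hydrophobic  # -1.449
#' @export
solvation_correct <- function(scale, classification,
                              proline_policy = c("in_hydrophobic",
                                                 "in_hydrophilic",
                                                 "excluded")) {
  stopifnot(inherits(scale, "one_body_scale"),
            inherits(classification, "hydropathy_classification"))
  proline_policy <- match.arg(proline_policy)
  hyd <- classification$hydrophobic
  phl <- classification$hydrophilic
  if (proline_policy == "in_hydrophilic") {
    hyd <- setdiff(hyd, "P")
    phl <- union(phl, "P")
  } else if (proline_policy == "excluded") {
    hyd <- setdiff(hyd, "P")
    phl <- setdiff(phl, "P")
  }
  hyd <- intersect(scale$labels, hyd)
  phl <- intersect(scale$labels, phl)
  if (!length(hyd) || !length(phl)) {
    stop("a retained hydropathy class is empty")
  }
  shift_h <- mean(scale$values[hyd])
  shift_p <- mean(scale$values[phl])
  corrected <- scale$values[c(hyd, phl)]
  corrected[hyd] <- corrected[hyd] - shift_h
  corrected[phl] <- corrected[phl] - shift_p
  structure(list(
    corrected = one_body_scale(corrected, names(corrected),
                               name = paste0(scale$name, "|centered")),
    shift_hydrophobic = shift_h,
    shift_hydrophilic = shift_p,
    hydrophobic = hyd, hydrophilic = phl,
    proline_policy = proline_policy
  ), class = "solvation_decomposition")
}

#' @export
print.solvation_decomposition <- function(x, ...) {
  cat("Solvation decomposition (proline policy:", x$proline_policy, ")\n")
  cat(sprintf("  hydrophobic class mean removed: %+.4f (%d residues)\n",
              x$shift_hydrophobic, length(x$hydrophobic)))
  cat(sprintf("  hydrophilic class mean removed: %+.4f (%d residues)\n",
              x$shift_hydrophilic, length(x$hydrophilic)))
  invisible(x)
}

#' Agreement between two per-residue scales
#'
#' Pearson correlation and root-mean-square deviation over a retained
#' residue set, the comparison used to judge whether a fitted one-body
#' term reproduces a solvation-corrected secondary-structure scale.
#'
#' @param a,b [one_body_scale] objects.
#' @param residues Residues to compare over; defaults to the labels
#'   common to both scales. At least 3 required.
#' @return List with `pearson_r`, `rmsd` and `n`.
#' @export
compare_scales <- function(a, b,
                           residues = intersect(a$labels, b$labels)) {
  stopifnot(inherits(a, "one_body_scale"), inherits(b, "one_body_scale"))
  residues <- as.character(residues)
  if (length(residues) < 3L) stop("need at least 3 residues to compare")
  if (!all(residues %in% a$labels) || !all(residues %in% b$labels)) {
    stop("residues missing from a scale: ",
         paste(setdiff(residues, intersect(a$labels, b$labels)),
               collapse = ","))
  }
  va <- a$values[residues]
  vb <- b$values[residues]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("Pearson correlation undefined: a scale has zero variance")
  }
  list(pearson_r = stats::cor(va, vb),
       rmsd = sqrt(mean((va - vb)^2)),
       n = length(residues))
}

#' Secondary-structure component of a fitted one-body term
#'
#' Removes the class-level solvation shifts from a fitted one-body scale,
#' leaving the per-residue free energy of forming hydrogen-bonded
#' secondary structure (the decomposition `q = dG_ss + dG_solv` read in
#' reverse).
#'
#' @param fitted_q A [one_body_scale] of fitted one-body terms.
#' @param solvation A [solvation_correct()] result carrying the class
#'   shifts and memberships.
#' @return A [one_body_scale] over the residues the solvation policy
#'   retains.
#' @export
secondary_structure_component <- function(fitted_q, solvation) {
  stopifnot(inherits(fitted_q, "one_body_scale"),
            inherits(solvation, "solvation_decomposition"))
  keep <- c(solvation$hydrophobic, solvation$hydrophilic)
  missing <- setdiff(keep, fitted_q$labels)
  if (length(missing)) {
    stop("fitted scale missing residues: ", paste(missing, collapse = ","))
  }
  v <- fitted_q$values[keep]
  v[solvation$hydrophobic] <- v[solvation$hydrophobic] -
    solvation$shift_hydrophobic
  v[solvation$hydrophilic] <- v[solvation$hydrophilic] -
    solvation$shift_hydrophilic
  one_body_scale(v, keep, name = paste0(fitted_q$name, "|ss"))
}
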