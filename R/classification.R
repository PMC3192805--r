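#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter residue codes in the package's canonical
#' (alphabetical) order. I/O functions preserve the label order of their
#' source; all computations index by label, so ordering never matters
#' beyond presentation.
#'
#' @return Character vector of length 20.
#' @export
residue_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Hydropathy classification of the 20 residues
#'
#' A partition of the standard amino acids into a hydrophobic and a
#' hydrophilic set. Three named classifications are built in:
#'
#' * `"dill"` — hydrophobic \{C,F,L,W,V,I,M,Y,A,P\}, hydrophilic
#'   \{H,G,N,T,S,R,Q,D,K,E\}. This is the default used throughout.
#' * `"pro_polar"` — as `"dill"` but with proline moved to the
#'   hydrophilic set.
#' * `"pro_ala_polar"` — proline and alanine both hydrophilic.
#'
#' @param hydrophobic Character vector of one-letter codes, or a single
#'   string naming a built-in classification.
#' @param hydrophilic Character vector with the remaining codes. Ignored
#'   when `hydrophobic` names a built-in.
#' @param name Tag recorded on the object.
#'
#' @return An object of class `hydropathy_classification` with elements
#'   `hydrophobic`, `hydrophilic` and `name`.
#' @examples
#' cl <- hydropathy_classification("dill")
#' length(cl$hydrophobic)  # 10
#' @export
hydropathy_classification <- function(hydrophobic,
                                      hydrophilic = NULL,
                                      name = NULL) {
  builtins <- list(
    dill = c("C", "F", "L", "W", "V", "I", "M", "Y", "A", "P"),
    pro_polar = c("C", "F", "L", "W", "V", "I", "M", "Y", "A"),
    pro_ala_polar = c("C", "F", "L", "W", "V", "I", "M", "Y")
  )
  if (length(hydrophobic) == 1L && hydrophobic %in% names(builtins)) {
    nm <- hydrophobic
    hydrophobic <- builtins[[nm]]
    hydrophilic <- setdiff(residue_alphabet(), hydrophobic)
    if (is.null(name)) name <- nm
  }
  hydrophobic <- as.character(hydrophobic)
  if (is.null(hydrophilic)) {
    hydrophilic <- setdiff(residue_alphabet(), hydrophobic)
  }
  hydrophilic <- as.character(hydrophilic)
  all20 <- sort(c(hydrophobic, hydrophilic))
  if (length(intersect(hydrophobic, hydrophilic)) > 0L) {
    stop("hydrophobic and hydrophilic sets overlap: ",
         paste(intersect(hydrophobic, hydrophilic), collapse = ", "))
  }
  if (!identical(all20, residue_alphabet())) {
    stop("classification must partition the 20 standard residues; got: ",
         paste(all20, collapse = ""))
  }
  structure(
    list(hydrophobic = hydrophobic, hydrophilic = hydrophilic,
         name = if (is.null(name)) "custom" else name),
    class = "hydropathy_classification"
  )
}

#' @export
print.hydropathy_classification <- function(x, ...) {
  cat("Hydropathy classification \"", x$name, "\"\n", sep = "")
  cat("  hydrophobic (", length(x$hydrophobic), "): ",
      paste(x$hydrophobic, collapse = ","), "\n", sep = "")
  cat("  hydrophilic (", length(x$hydrophilic), "): ",
      paste(x$hydrophilic, collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Binary interaction basis matrices for a hydropathy classification
#'
#' Builds the three 20x20 symmetric indicator matrices that span the
#' coarse-grained contact model:
#'
#' * `HH` — 1 where both residues are hydrophobic;
#' * `HP` — 1 where exactly one residue of the pair is hydrophobic;
#' * `HB` — 1 where both residues can donate a backbone amide hydrogen
#'   bond, i.e. where neither residue is proline.
#'
#' `HH + HP + PP` (with `PP` the implicit polar-polar indicator)
#' partitions all residue pairs. Under the `"dill"` classification the
#' unique-pair counts are 55 (HH), 100 (HP), 55 (PP) and 190 (HB).
#'
#' @param classification A [hydropathy_classification].
#' @param labels Label order for the matrices; defaults to the canonical
#'   alphabetical order.
#' @return An object of class `basis_set`: list with binary matrices
#'   `HH`, `HP`, `HB`, the `labels` and the `classification`.
#' @examples
#' b <- build_basis(hydropathy_classification("dill"))
#' sum(b$HH[upper.tri(b$HH, diag = TRUE)])  # 55
#' @export
build_basis <- function(classification, labels = residue_alphabet()) {
  stopifnot(inherits(classification, "hydropathy_classification"))
  labels <- as.character(labels)
  if (!identical(sort(labels), residue_alphabet())) {
    stop("labels must be a permutation of the 20 standard residues")
  }
  is_h <- labels %in% classification$hydrophobic
  hh <- outer(is_h, is_h, "&") * 1
  hp <- (outer(is_h, is_h, "+") == 1) * 1
  not_p <- labels != "P"
  hb <- outer(not_p, not_p, "&") * 1
  dimnames(hh) <- dimnames(hp) <- dimnames(hb) <- list(labels, labels)
  structure(
    list(HH = hh, HP = hp, HB = hb, labels = labels,
         classification = classification),
    class = "basis_set"
  )
}

#' @export
print.basis_set <- function(x, ...) {
  ut <- upper.tri(x$HH, diag = TRUE)
  cat("Basis set over classification \"", x$classification$name,
      "\"\n", sep = "")
  cat("  unique pairs: HH=", sum(x$HH[ut]), " HP=", sum(x$HP[ut]),
      " PP=", 210 - sum(x$HH[ut]) - sum(x$HP[ut]),
      " HB=", sum(x$HB[ut]), "\n", sep = "")
  invisible(x)
}
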