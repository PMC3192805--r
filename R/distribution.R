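#' Partition the unique elements by hydropathy pair class
#'
#' Splits the 210 unique contact free energies into hydrophobic-
#' hydrophobic (H-H), hydrophobic-polar (H-P) and polar-polar (P-P)
#' values. Under the `"dill"` classification the class sizes are
#' 55 / 100 / 55.
#'
#' @param matrix A [contact_matrix].
#' @param classification A [hydropathy_classification].
#' @return Named list of numeric vectors `HH`, `HP`, `PP`.
#' @export
class_partition <- function(matrix, classification) {
  stopifnot(inherits(matrix, "contact_matrix"),
            inherits(classification, "hydropathy_classification"))
  labels <- matrix$labels
  pairs <- pair_index(length(labels))
  u <- unique_elements(matrix)
  nh <- (labels[pairs$i] %in% classification$hydrophobic) +
    (labels[pairs$j] %in% classification$hydrophobic)
  list(HH = u[nh == 2], HP = u[nh == 1], PP = u[nh == 0])
}

#' Class-resolved Gaussian summary of a contact free-energy distribution
#'
#' Describes the distribution of the unique matrix elements as a mixture
#' of three Gaussians, one per hydropathy pair class (H-H, H-P, P-P).
#' The "fit" is the Gaussian maximum-likelihood estimate per class
#' (sample mean and population standard deviation) - deterministic and
#' bin-free, rather than a histogram least-squares fit. Mixture weights
#' are the class-size fractions of the 210 unique elements
#' (`element_count` convention).
#'
#' @inheritParams class_partition
#' @param weighting Weight convention; only `"element_count"` is defined.
#' @return Object of class `gaussian_components`: data frame with one
#'   row per class (`HH`, `HP`, `PP`) and columns `weight`, `mean`, `sd`,
#'   `n`, plus an attribute `weighting`.
#' @export
class_gaussians <- function(matrix, classification,
                            weighting = "element_count") {
  weighting <- match.arg(weighting, "element_count")
  parts <- class_partition(matrix, classification)
  if (any(lengths(parts) == 0L)) {
    stop("empty hydropathy class: ",
         paste(names(parts)[lengths(parts) == 0L], collapse = ", "))
  }
  n_total <- sum(lengths(parts))
  out <- data.frame(
    class = names(parts),
    weight = lengths(parts) / n_total,
    mean = vapply(parts, mean, numeric(1)),
    sd = vapply(parts, function(x) sqrt(mean((x - mean(x))^2)), numeric(1)),
    n = lengths(parts),
    row.names = NULL
  )
  structure(out, weighting = weighting, class = c("gaussian_components",
                                                  "data.frame"))
}

#' Single-Gaussian summary of a contact free-energy distribution
#'
#' Mean and population standard deviation over the 210 unique elements:
#' the maximum-likelihood single-Gaussian description of the
#' distribution, appropriate for potentials (such as beta-strand pairing
#' matrices) whose polar and non-polar contacts fall in one narrow mode.
#'
#' @param matrix A [contact_matrix].
#' @return List with `mean` and `sd`.
#' @export
single_gaussian <- function(matrix) {
  s <- summary_stats(matrix)
  list(mean = s$mean, sd = s$sd)
}

#' Histogram of the unique matrix elements
#'
#' Bins the 210 unique contact free energies on a regular grid of width
#' `bin_width` anchored at zero (bin k covers `[k*w, (k+1)*w)`), for
#' export or plotting. Counts always sum to the number of unique
#' elements.
#'
#' @param matrix A [contact_matrix].
#' @param bin_width Positive bin width (RT units).
#' @return Data frame with `bin_left`, `bin_center`, `count`.
#' @export
histogram_export <- function(matrix, bin_width = 0.25) {
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("bin_width must be positive")
  }
  u <- unique_elements(matrix)
  k <- floor(u / bin_width)
  tab <- table(k)
  kk <- as.integer(names(tab))
  data.frame(bin_left = kk * bin_width,
             bin_center = (kk + 0.5) * bin_width,
             count = as.integer(tab))
}
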