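#' Ground truth for synthetic contact matrices
#'
#' Parameter set for the generative form of the decomposition model:
#' two-body coefficients, a gauge-satisfying one-body vector, a
#' classification, and the standard deviation of iid Gaussian noise
#' applied to the 210 unique elements. The defaults mimic the
#' decomposition of a native-fold (MJ-like) potential: eta_HH 3.64,
#' eta_HP 1.48, eta_HB 1.76, eta0 0.07, noise 0.23 RT (the residual
#' scale of the full fit to the MJ matrix). A `"parallel"` preset with
#' eta_HH 1.40, eta_HP 0.21, eta_HB 2.23, eta0 2.97 and noise 0.42
#' mimics a parallel strand-pairing potential.
#'
#' If `q` is supplied it is re-centred to the class-wise zero-sum gauge;
#' `q = NULL` means all-zero one-body terms.
#'
#' @param eta_hh,eta_hp,eta_hb,eta0 Two-body coefficients (RT units).
#' @param q Optional [one_body_scale] (or named vector) of one-body
#'   terms.
#' @param classification A [hydropathy_classification].
#' @param noise_sd Noise standard deviation (>= 0), RT units.
#' @param preset `"mj"` (default values above) or `"parallel"`; explicit
#'   arguments override preset values.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(eta_hh = NULL, eta_hp = NULL, eta_hb = NULL,
                         eta0 = NULL, q = NULL,
                         classification = hydropathy_classification("dill"),
                         noise_sd = NULL, preset = c("mj", "parallel")) {
  preset <- match.arg(preset)
  def <- switch(preset,
    mj = list(eta_hh = 3.64, eta_hp = 1.48, eta_hb = 1.76, eta0 = 0.07,
              noise_sd = 0.23),
    parallel = list(eta_hh = 1.40, eta_hp = 0.21, eta_hb = 2.23,
                    eta0 = 2.97, noise_sd = 0.42)
  )
  pick <- function(x, d) if (is.null(x)) d else x
  eta_hh <- pick(eta_hh, def$eta_hh)
  eta_hp <- pick(eta_hp, def$eta_hp)
  eta_hb <- pick(eta_hb, def$eta_hb)
  eta0 <- pick(eta0, def$eta0)
  noise_sd <- pick(noise_sd, def$noise_sd)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  stopifnot(inherits(classification, "hydropathy_classification"))
  if (!is.null(q)) {
    if (inherits(q, "one_body_scale")) q <- q$values
    if (is.null(names(q)) || !setequal(names(q), residue_alphabet())) {
      stop("q must be named over the 20 standard residues")
    }
    q <- q[residue_alphabet()]
    hyd <- names(q) %in% classification$hydrophobic
    q[hyd] <- q[hyd] - mean(q[hyd])
    q[!hyd] <- q[!hyd] - mean(q[!hyd])
  } else {
    q <- stats::setNames(numeric(20), residue_alphabet())
  }
  structure(list(eta_hh = eta_hh, eta_hp = eta_hp, eta_hb = eta_hb,
                 eta0 = eta0,
                 q = one_body_scale(q, names(q), name = "truth"),
                 classification = classification, noise_sd = noise_sd),
            class = "ground_truth")
}

#' Generate a synthetic contact matrix from known parameters
#'
#' Builds `e_ij = eta0 - (eta_HH HH_ij + eta_HP HP_ij + eta_HB HB_ij)
#' + q_i + q_j + eps_ij`, with `eps` drawn iid Normal(0, noise_sd^2)
#' once per unique element and mirrored across the diagonal (matching
#' the 210-independent-variable model of a symmetric potential). The
#' output is a deterministic function of the seed.
#'
#' @param truth A [ground_truth()] object.
#' @param seed Integer seed for the noise draw.
#' @param name Provenance tag for the matrix.
#' @return List with `matrix` (a [contact_matrix]) and `truth` (the
#'   input, with `seed` recorded).
#' @examples
#' tr <- ground_truth(noise_sd = 0)
#' fit <- fit_full(generate_matrix(tr)$matrix,
#'                 build_basis(tr$classification))
#' abs(fit$eta_hh - tr$eta_hh) < 1e-9
#' @export
generate_matrix <- function(truth, seed = 1L, name = "synthetic") {
  stopifnot(inherits(truth, "ground_truth"))
  basis <- build_basis(truth$classification)
  labels <- basis$labels
  q <- truth$q$values[labels]
  clean <- truth$eta0 -
    (truth$eta_hh * basis$HH + truth$eta_hp * basis$HP +
       truth$eta_hb * basis$HB) +
    outer(q, q, "+")
  n <- length(labels)
  set.seed(as.integer(seed))
  eps <- stats::rnorm(n * (n + 1) / 2, 0, truth$noise_sd)
  noise <- matrix(0, n, n)
  noise[upper.tri(noise, diag = TRUE)] <- eps
  noise <- noise + t(noise) - diag(diag(noise))
  truth$seed <- as.integer(seed)
  list(matrix = contact_matrix(clean + noise, labels, name = name),
       truth = truth)
}

#' Generate a synthetic per-residue scale with class structure
#'
#' Draws one value per residue as its hydropathy-class mean plus iid
#' Gaussian within-class scatter: the generative form assumed by the
#' solvation correction.
#'
#' @param class_means Length-2 numeric `c(s_H, s_P)`: hydrophobic and
#'   hydrophilic class means (RT units).
#' @param within_sd Within-class standard deviation (>= 0).
#' @param classification A [hydropathy_classification].
#' @param seed Integer seed.
#' @return A [one_body_scale].
#' @export
generate_scale <- function(class_means = c(-1.45, -0.07),
                           within_sd = 0.5,
                           classification = hydropathy_classification("dill"),
                           seed = 1L) {
  if (within_sd < 0) stop("within_sd must be non-negative")
  stopifnot(inherits(classification, "hydropathy_classification"))
  labels <- residue_alphabet()
  means <- ifelse(labels %in% classification$hydrophobic,
                  class_means[1], class_means[2])
  set.seed(as.integer(seed))
  one_body_scale(means + stats::rnorm(20, 0, within_sd), labels,
                 name = sprintf("synthetic_scale(seed %d)", seed))
}
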