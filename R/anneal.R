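#' Annealing schedule
#'
#' Geometric cooling schedule for [anneal_refine()]: the temperature
#' starts at `t0` and is multiplied by `cooling` after every proposal.
#' Proposals perturb one randomly chosen parameter by a Gaussian step of
#' standard deviation `proposal_sd`.
#'
#' The proposal width itself decays geometrically from `proposal_sd`
#' down to `proposal_sd_final` across the run, independently of the
#' temperature: wide steps early so the walk can travel to the basin of
#' the optimum, narrow steps late so the minimum can be resolved below
#' the target precision.
#'
#' @param t0 Initial temperature (> 0), on the squared-residual scale.
#' @param cooling Multiplicative cooling factor in (0, 1).
#' @param steps Number of proposals (> 0).
#' @param proposal_sd Initial Gaussian proposal standard deviation.
#' @param proposal_sd_final Final proposal standard deviation
#'   (0 < final <= initial).
#' @return Object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(t0 = 1.0, cooling = 0.995, steps = 2e5,
                            proposal_sd = 0.05,
                            proposal_sd_final = 1e-4) {
  if (t0 <= 0) stop("t0 must be positive")
  if (cooling <= 0 || cooling >= 1) stop("cooling must lie in (0, 1)")
  if (steps <= 0) stop("steps must be positive")
  if (proposal_sd <= 0) stop("proposal_sd must be positive")
  if (proposal_sd_final <= 0 || proposal_sd_final > proposal_sd) {
    stop("proposal_sd_final must lie in (0, proposal_sd]")
  }
  structure(list(t0 = t0, cooling = cooling, steps = as.integer(steps),
                 proposal_sd = proposal_sd,
                 proposal_sd_final = proposal_sd_final),
            class = "anneal_schedule")
}

#' Stochastic refinement of the full decomposition
#'
#' Minimises the same residual sum of squares as [fit_full()] by
#' seeded simulated annealing over the 22 free parameters (four two-body
#' terms plus the one-body terms in the class-wise zero-sum gauge's
#' reduced parameterization, so the gauge holds exactly throughout).
#' Because the model is linear, the closed-form [fit_full()] solution is
#' the global optimum; the annealer exists as an independent route to the
#' same minimum and for verifying that the closed-form solver is correct.
#' The best visited state is always retained, so the result is never
#' worse than the initialization.
#'
#' @param matrix A [contact_matrix].
#' @param basis The matching [build_basis()] result.
#' @param init A `full_fit` to start from, or `NULL` to start from zeros.
#' @param schedule An [anneal_schedule()].
#' @param seed Integer seed; the trajectory is a deterministic function
#'   of it.
#' @param opts A [fit_options()] object.
#' @return A `full_fit` whose coefficients are the best state visited;
#'   the field `objective` carries the final residual sum of squares.
#' @export
anneal_refine <- function(matrix, basis, init = NULL,
                          schedule = anneal_schedule(), seed = 1L,
                          opts = fit_options()) {
  stopifnot(inherits(schedule, "anneal_schedule"))
  vals <- align_to_basis(matrix, basis)
  keep <- fit_rows_kept(basis, opts)
  ob <- onebody_design(basis)
  X <- cbind(two_body_design(basis, opts), ob$X)[keep, , drop = FALSE]
  y <- vals[upper.tri(vals, diag = TRUE)][keep]
  p <- ncol(X)

  theta <- numeric(p)
  names(theta) <- colnames(X)
  if (!is.null(init)) {
    stopifnot(inherits(init, "full_fit"))
    theta[c("eta0", "eta_hh", "eta_hp", "eta_hb")] <-
      c(init$eta0, init$eta_hh, init$eta_hp, init$eta_hb)
    qcols <- grep("^q_", colnames(X), value = TRUE)
    theta[qcols] <- init$q$values[sub("^q_", "", qcols)]
  }

  set.seed(as.integer(seed))
  resid <- y - drop(X %*% theta)
  obj <- sum(resid^2)
  best <- theta
  best_obj <- obj
  temp <- schedule$t0
  sd_s <- schedule$proposal_sd
  sd_decay <- (schedule$proposal_sd_final /
                 schedule$proposal_sd)^(1 / schedule$steps)
  ks <- sample.int(p, schedule$steps, replace = TRUE)
  zs <- stats::rnorm(schedule$steps)
  us <- stats::runif(schedule$steps)
  for (s in seq_len(schedule$steps)) {
    k <- ks[s]
    new_resid <- resid - X[, k] * (zs[s] * sd_s)
    new_obj <- sum(new_resid^2)
    if (new_obj < obj || us[s] < exp((obj - new_obj) / temp)) {
      theta[k] <- theta[k] + zs[s] * sd_s
      resid <- new_resid
      obj <- new_obj
      if (obj < best_obj) {
        best <- theta
        best_obj <- obj
      }
    }
    temp <- temp * schedule$cooling
    sd_s <- sd_s * sd_decay
  }

  exp_q <- expand_q(best[grep("^q_", names(best))], basis)
  fitted <- drop(X %*% best)
  out <- structure(list(
    eta_hh = unname(best["eta_hh"]), eta_hp = unname(best["eta_hp"]),
    eta_hb = unname(best["eta_hb"]), eta0 = unname(best["eta0"]),
    se_hh = NA_real_, se_hp = NA_real_, se_hb = NA_real_, se_e0 = NA_real_,
    ss_cys = if (opts$ss_regressor) unname(best["ss_cys"]) else NULL,
    q = one_body_scale(exp_q$q, basis$labels,
                       name = paste0("q[", matrix$name, "|anneal]")),
    se_q = rep(NA_real_, length(basis$labels)),
    gauge = "classwise_zero_sum",
    pearson_r = stats::cor(y, fitted),
    rmsd = sqrt(mean((y - fitted)^2)),
    rss = best_obj, n_fitted = length(y),
    objective = best_obj,
    seed = as.integer(seed), schedule = schedule,
    classification = basis$classification,
    labels = basis$labels, opts = opts,
    matrix_name = matrix$name
  ), class = c("full_fit", "two_body_fit"))
  out
}
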