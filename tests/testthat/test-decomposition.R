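# Independent normal-equations solver used as the oracle for the OLS fits.
oracle_ols <- function(y, X) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / (length(y) - ncol(X))
  list(beta = drop(beta), se = sqrt(diag(sigma2 * solve(XtX))))
}

design_two_body <- function(basis) {
  ut <- upper.tri(basis$HH, diag = TRUE)
  cbind(1, -basis$HH[ut], -basis$HP[ut], -basis$HB[ut])
}

test_that("noiseless two-body matrices are recovered exactly", {
  m <- noiseless_matrix(eta_hh = 2, eta_hp = 1, eta_hb = 1, eta0 = 0.5)
  fit <- fit_two_body(m, dill_basis)
  expect_equal(fit$eta_hh, 2, tolerance = 1e-9)
  expect_equal(fit$eta_hp, 1, tolerance = 1e-9)
  expect_equal(fit$eta_hb, 1, tolerance = 1e-9)
  expect_equal(fit$eta0, 0.5, tolerance = 1e-9)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-9)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
})

test_that("noisy two-body coefficients match the normal-equations oracle and land within 3 SE of truth", {
  truth <- ground_truth(eta_hh = 3.64, eta_hp = 1.48, eta_hb = 1.76,
                        eta0 = 0.07, noise_sd = 0.3)
  m <- generate_matrix(truth, seed = 1)$matrix
  fit <- fit_two_body(m, dill_basis)
  orc <- oracle_ols(unique_elements(m), design_two_body(dill_basis))
  expect_equal(c(fit$eta0, fit$eta_hh, fit$eta_hp, fit$eta_hb),
               unname(orc$beta), tolerance = 1e-10)
  expect_equal(c(fit$se_e0, fit$se_hh, fit$se_hp, fit$se_hb),
               unname(orc$se), tolerance = 1e-10)
  expect_lt(abs(fit$eta_hh - truth$eta_hh), 3 * fit$se_hh)
  expect_lt(abs(fit$eta_hp - truth$eta_hp), 3 * fit$se_hp)
  expect_lt(abs(fit$eta_hb - truth$eta_hb), 3 * fit$se_hb)
})

test_that("full fit recovers gauge-satisfying truth exactly at zero noise", {
  q <- table2_scales()$q_mj
  m <- noiseless_matrix(eta_hh = 3.64, eta_hp = 1.48, eta_hb = 1.76,
                        eta0 = 0.07, q = q)
  fit <- fit_full(m, dill_basis)
  expect_equal(fit$eta_hh, 3.64, tolerance = 1e-9)
  expect_equal(fit$eta_hp, 1.48, tolerance = 1e-9)
  expect_equal(fit$eta_hb, 1.76, tolerance = 1e-9)
  expect_equal(fit$eta0, 0.07, tolerance = 1e-9)
  expect_equal(fit$q$values[q$labels], q$values, tolerance = 1e-9)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-9)
})

test_that("fitted one-body terms satisfy the class-wise zero-sum gauge", {
  m <- generate_matrix(ground_truth(q = table2_scales()$q_mj),
                       seed = 5)$matrix
  fit <- fit_full(m, dill_basis)
  expect_lt(abs(sum(fit$q$values[dill$hydrophobic])), 1e-9)
  expect_lt(abs(sum(fit$q$values[dill$hydrophilic])), 1e-9)
})

test_that("the full fit is at least as correlated as the nested two-body fit", {
  for (seed in 1:5) {
    m <- generate_matrix(ground_truth(q = table2_scales()$q_parallel,
                                      preset = "parallel"),
                         seed = seed)$matrix
    expect_gte(fit_full(m, dill_basis)$pearson_r,
               fit_two_body(m, dill_basis)$pearson_r)
  }
})

test_that("adding a constant moves only eta0; the HB/HH ratio is invariant", {
  m <- generate_matrix(ground_truth(q = table2_scales()$q_mj),
                       seed = 2)$matrix
  shifted <- contact_matrix(m$values + 1.3, m$labels)
  for (fitter in list(fit_two_body, fit_full)) {
    f0 <- fitter(m, dill_basis)
    f1 <- fitter(shifted, dill_basis)
    expect_equal(f1$eta0, f0$eta0 + 1.3, tolerance = 1e-9)
    expect_equal(f1$eta_hh, f0$eta_hh, tolerance = 1e-9)
    expect_equal(f1$eta_hp, f0$eta_hp, tolerance = 1e-9)
    expect_equal(f1$eta_hb, f0$eta_hb, tolerance = 1e-9)
    expect_equal(hb_hh_ratio(f1), hb_hh_ratio(f0), tolerance = 1e-12)
  }
  f <- fit_full(m, dill_basis)
  f1 <- fit_full(shifted, dill_basis)
  expect_equal(f1$q$values, f$q$values, tolerance = 1e-9)
})

test_that("reconstruction follows the closed-form class values and is a projection", {
  m <- generate_matrix(ground_truth(q = table2_scales()$q_mj),
                       seed = 4)$matrix
  fit <- fit_two_body(m, dill_basis)
  rec <- reconstruct(fit, dill_basis)
  expect_identical(rec$values, t(rec$values))
  # proline-involving polar pair: HB = 0, HP = 1
  expect_equal(rec$values["P", "E"], fit$eta0 - fit$eta_hp,
               tolerance = 1e-12)
  # non-proline polar-polar pair: HB = 1, HH = HP = 0
  expect_equal(rec$values["D", "E"], fit$eta0 - fit$eta_hb,
               tolerance = 1e-12)
  # hydrophobic non-proline pair: HH = 1, HB = 1
  expect_equal(rec$values["L", "I"],
               fit$eta0 - fit$eta_hh - fit$eta_hb, tolerance = 1e-12)
  # refitting a reconstruction reproduces it: projection idempotence
  fit2 <- fit_two_body(rec, dill_basis)
  rec2 <- reconstruct(fit2, dill_basis)
  expect_equal(rec2$values, rec$values, tolerance = 1e-12)
})

test_that("fit metrics match the direct formulas and reject degenerate input", {
  m <- noiseless_matrix()
  expect_equal(fit_metrics(m, m), list(pearson_r = 1, rmsd = 0))
  a <- toy_matrix(matrix(c(1, 2, 2, 4), 2), c("A", "C"))
  b <- toy_matrix(matrix(c(2, 1, 1, 5), 2), c("A", "C"))
  got <- fit_metrics(a, b)
  # direct textbook formulas over the unique elements (1,2,4) vs (2,1,5)
  x <- c(1, 2, 4)
  y <- c(2, 1, 5)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$pearson_r, r_direct, tolerance = 1e-12)
  expect_equal(got$rmsd, sqrt(mean((x - y)^2)), tolerance = 1e-12)
  flat <- toy_matrix(matrix(1, 2, 2), c("A", "C"))
  expect_error(fit_metrics(flat, a), "zero variance")
})

test_that("hb_hh_ratio is the coefficient quotient", {
  m <- noiseless_matrix(eta_hh = 2, eta_hb = 2)
  expect_equal(hb_hh_ratio(fit_two_body(m, dill_basis)), 1,
               tolerance = 1e-9)
  m2 <- noiseless_matrix(eta_hh = 2, eta_hb = 1)
  expect_equal(hb_hh_ratio(fit_two_body(m2, dill_basis)), 0.5,
               tolerance = 1e-9)
})

test_that("effective energy sums fitted pair energies over supplied contacts", {
  m <- generate_matrix(ground_truth(q = table2_scales()$q_mj),
                       seed = 6)$matrix
  fit <- fit_full(m, dill_basis)
  expect_equal(effective_energy("ACDEF", list(), fit, dill_basis), 0)
  f2 <- fit_two_body(m, dill_basis)
  # one contact between two non-proline polar residues
  expect_equal(effective_energy("DE", list(c(1, 2)), f2, dill_basis),
               f2$eta0 - f2$eta_hb, tolerance = 1e-12)
  # random contact set against a brute-force per-pair sum
  set.seed(9)
  seqv <- sample(residue_alphabet(), 30, replace = TRUE)
  contacts <- replicate(10, sample(30, 2), simplify = FALSE)
  eh <- reconstruct(fit, dill_basis)$values
  brute <- sum(vapply(contacts, function(ct) {
    eh[seqv[ct[1]], seqv[ct[2]]]
  }, numeric(1)))
  expect_equal(effective_energy(seqv, contacts, fit, dill_basis), brute,
               tolerance = 1e-12)
  expect_error(effective_energy("AC", list(c(1, 3)), fit, dill_basis),
               "out of range")
  expect_error(effective_energy("AC", list(c(2, 2)), fit, dill_basis),
               "self-contact")
})

test_that("gauge-respecting parameter shifts leave the reconstruction unchanged", {
  m <- generate_matrix(ground_truth(q = table2_scales()$q_mj),
                       seed = 8)$matrix
  fit <- fit_full(m, dill_basis)
  rec <- reconstruct(fit, dill_basis)
  # move a constant c from the hydrophobic one-body terms into the
  # two-body coefficients: q_H += c, eta_hh += 2c, eta_hp += c
  cshift <- 0.37
  shifted <- fit
  shifted$q$values[dill$hydrophobic] <-
    shifted$q$values[dill$hydrophobic] + cshift
  shifted$eta_hh <- shifted$eta_hh + 2 * cshift
  shifted$eta_hp <- shifted$eta_hp + cshift
  rec2 <- reconstruct(shifted, dill_basis)
  expect_lt(max(abs(rec2$values - rec$values)), 1e-9)
})
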