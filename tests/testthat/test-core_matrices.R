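test_that("hydropathy classifications partition the 20 residues", {
  expect_setequal(dill$hydrophobic,
                  c("C", "F", "L", "W", "V", "I", "M", "Y", "A", "P"))
  expect_setequal(dill$hydrophilic,
                  c("H", "G", "N", "T", "S", "R", "Q", "D", "K", "E"))
  pp <- hydropathy_classification("pro_polar")
  expect_true("P" %in% pp$hydrophilic)
  pap <- hydropathy_classification("pro_ala_polar")
  expect_true(all(c("P", "A") %in% pap$hydrophilic))
  expect_error(hydropathy_classification(c("A", "C"), c("A", "D")),
               "overlap")
  expect_error(hydropathy_classification(c("A", "C"), c("D", "E")),
               "partition")
})

test_that("basis matrices are binary, symmetric, with the expected pair counts", {
  counts <- function(b) {
    ut <- upper.tri(b$HH, diag = TRUE)
    c(hh = sum(b$HH[ut]), hp = sum(b$HP[ut]),
      pp = 210 - sum(b$HH[ut]) - sum(b$HP[ut]), hb = sum(b$HB[ut]))
  }
  for (m in list(dill_basis$HH, dill_basis$HP, dill_basis$HB)) {
    expect_true(all(m %in% c(0, 1)))
    expect_identical(m, t(m))
  }
  expect_equal(counts(dill_basis),
               c(hh = 55, hp = 100, pp = 55, hb = 190))
  expect_equal(counts(build_basis(hydropathy_classification("pro_polar"))),
               c(hh = 45, hp = 99, pp = 66, hb = 190))
  # HH + HP + PP partitions all pairs
  pp_mat <- 1 - dill_basis$HH - dill_basis$HP
  expect_true(all(pp_mat %in% c(0, 1)))
})

test_that("basis pair counts match closed-form combinatorics for random partitions", {
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(1:19, 1)
    hyd <- sample(residue_alphabet(), k)
    cl <- hydropathy_classification(hyd, name = "random")
    b <- build_basis(cl)
    ut <- upper.tri(b$HH, diag = TRUE)
    expect_equal(sum(b$HH[ut]), pairs_within(k))
    expect_equal(sum(b$HP[ut]), k * (20 - k))
    expect_equal(sum(b$HB[ut]), pairs_within(19))
  }
})

test_that("contact_matrix enforces symmetry and label sanity", {
  v <- matrix(rnorm(400), 20, 20)
  expect_error(contact_matrix(v, residue_alphabet()), "asymmetric")
  v <- (v + t(v)) / 2
  m <- contact_matrix(v, residue_alphabet())
  expect_identical(m$values, t(m$values))
  expect_length(unique_elements(m), 210)
  expect_error(contact_matrix(v, rep("A", 20)), "duplicate")
  # n(n+1)/2 in general
  m3 <- toy_matrix(diag(3), c("A", "C", "D"))
  expect_length(unique_elements(m3), 6)
})

test_that("square TSV writer/reader round-trips and validates", {
  m <- noiseless_matrix(q = table2_scales()$q_mj)
  tmp <- tempfile(fileext = ".tsv")
  write_contact_matrix(m, tmp, "square_tsv")
  m2 <- read_contact_matrix(tmp, "square_tsv")
  expect_equal(m2$values, m$values, tolerance = 1e-12)
  expect_identical(m2$labels, m$labels)
  # asymmetric square input is an error naming the cell
  lines <- readLines(tmp)
  bad <- strsplit(lines[2], "\t")[[1]]
  bad[3] <- "99.9"
  lines[2] <- paste(bad, collapse = "\t")
  expect_error(read_contact_matrix(lines, "square_tsv"), "asymmetric")
  # non-numeric cell is named
  bad[3] <- "xyz"
  lines[2] <- paste(bad, collapse = "\t")
  expect_error(read_contact_matrix(lines, "square_tsv"), "non-numeric")
  # missing residue detected
  lines <- readLines(tmp)
  lines <- sub("^A\t", "B\t", sub("\tA\t", "\tB\t", lines))
  expect_error(read_contact_matrix(lines, "square_tsv"), "missing")
})

test_that("lower-triangle dialect matches the square serialization", {
  m <- noiseless_matrix(q = table2_scales()$q_parallel)
  t1 <- tempfile()
  t2 <- tempfile()
  write_contact_matrix(m, t1, "lower_triangle")
  write_contact_matrix(m, t2, "square_tsv")
  m1 <- read_contact_matrix(t1, "lower_triangle")
  m2 <- read_contact_matrix(t2, "square_tsv")
  expect_equal(m1$values, m2$values, tolerance = 1e-12)
  # 3x3 toy -> exactly 6 values in the body
  m3 <- toy_matrix(matrix(c(1, 2, 3, 2, 4, 5, 3, 5, 6), 3),
                   c("A", "C", "D"))
  lines <- write_contact_matrix(m3, dialect = "lower_triangle")
  body <- unlist(strsplit(lines[-1], "\t"))
  expect_length(body, 6)
  # permuted label order preserves the unique element multiset
  perm <- c(20:1)
  mp <- contact_matrix(m$values[perm, perm], m$labels[perm])
  expect_equal(sort(unique_elements(mp)), sort(unique_elements(m)))
})

test_that("AAindex matrix entries parse as declared", {
  mock <- c(
    "H TEST0001",
    "D Mock 3-residue lower-triangle entry",
    "M rows = ARN, cols = ARN",
    "  1.0",
    "  0.5  2.0",
    "  0.3  0.4  3.0",
    "//"
  )
  m <- read_contact_matrix(mock, "aaindex")
  expect_identical(m$labels, c("A", "R", "N"))
  # (A, R) is the first value of body row 2
  expect_equal(m$values["A", "R"], 0.5)
  expect_equal(m$values["R", "A"], 0.5)
  expect_equal(unname(diag(m$values)), c(1, 2, 3))
  expect_error(read_contact_matrix(mock[-3], "aaindex"), "M rows")
  mock_na <- mock
  mock_na[5] <- "  -  2.0"
  expect_error(read_contact_matrix(mock_na, "aaindex"), "missing cells")
})

test_that("Boltzmann inversion is the inverse of exponentiating ratios", {
  set.seed(7)
  ref <- matrix(runif(400, 0.5, 1.5), 20, 20)
  ref <- (ref + t(ref)) / 2
  e <- matrix(rnorm(400), 20, 20)
  e <- (e + t(e)) / 2
  p <- ref * exp(-e)
  m <- boltzmann_invert(p, ref, labels = residue_alphabet())
  expect_equal(m$values, e, tolerance = 1e-12, ignore_attr = TRUE)
  # p == ref -> all-zero matrix; ratio e^2 -> element -2
  expect_true(all(boltzmann_invert(ref, ref,
                                   residue_alphabet())$values == 0))
  p2 <- ref
  p2[1, 2] <- p2[2, 1] <- ref[1, 2] * exp(2)
  expect_equal(boltzmann_invert(p2, ref,
                                residue_alphabet())$values[1, 2], -2)
  p2[1, 2] <- p2[2, 1] <- 0
  expect_error(boltzmann_invert(p2, ref, residue_alphabet()), "positive")
})

test_that("summary_stats uses population sd over the unique elements", {
  m <- contact_matrix(matrix(3.5, 20, 20), residue_alphabet())
  s <- summary_stats(m)
  expect_equal(s$mean, 3.5)
  expect_equal(s$sd, 0)
  expect_equal(s$n, 210)
  m2 <- noiseless_matrix()
  u <- unique_elements(m2)
  expect_equal(summary_stats(m2)$sd, sqrt(mean((u - mean(u))^2)))
})
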