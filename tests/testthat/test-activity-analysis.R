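test_that("position frequency matrices are column-normalized counts", {
  pfm <- position_frequency_matrix(c("DDDD", "DDDD"))
  expect_true(all(unclass(pfm)["D", ] == 1))
  expect_equal(unname(colSums(unclass(pfm))), rep(1, 4))
  expect_identical(attr(pfm, "n"), 2L)

  pfm2 <- position_frequency_matrix(c("ADKS", "ADKA"))
  expect_equal(unclass(pfm2)["A", "pos1"], 1)
  expect_equal(unclass(pfm2)["A", "pos4"], 0.5)
  expect_error(position_frequency_matrix(character(0)), "no peptides")
  expect_error(position_frequency_matrix(c("AAAA", "AAA")), "equal length")
})

test_that("uniform random peptides give near-uniform frequencies", {
  peps <- random_peptides(20000, seed = 111)
  pfm <- position_frequency_matrix(peps)
  expect_true(all(abs(unclass(pfm) - 0.05) < 0.01))
})

test_that("a pooled PFM is the count-weighted mixture of its parts", {
  a <- random_peptides(300, seed = 121)
  b <- random_peptides(200, seed = 122)
  pa <- unclass(position_frequency_matrix(a))
  pb <- unclass(position_frequency_matrix(b))
  pu <- unclass(position_frequency_matrix(c(a, b)))
  expect_equal(pu, (300 * pa + 200 * pb) / 500, ignore_attr = "n")
})

test_that("information content spans zero (uniform) to log2(20) (point mass)", {
  point <- position_frequency_matrix(rep("DDDD", 5))
  expect_equal(unname(information_content(point)), rep(log2(20), 4))
  uniform <- position_frequency_matrix(
    apply(matrix(rep(aa_alphabet(), 4), 20), 1, paste, collapse = ""))
  expect_equal(unname(information_content(uniform)), rep(0, 4), tolerance = 1e-12)

  # closed form for a 0.75/0.25 two-residue column
  mixed <- position_frequency_matrix(c("DAAA", "DAAA", "DAAA", "NAAA"))
  expected <- log2(20) + 0.75 * log2(0.75) + 0.25 * log2(0.25)
  expect_equal(unname(information_content(mixed)[1]), expected)
  # small-sample correction only lowers the estimate
  expect_true(all(information_content(mixed, correct = TRUE) <=
                  information_content(mixed)))
})

test_that("dipeptide adjacency counts ordered pairs over three junctions", {
  adj <- dipeptide_adjacency("NNDD")
  expect_identical(adj["N", "N"], 1L)
  expect_identical(adj["N", "D"], 1L)
  expect_identical(adj["D", "D"], 1L)
  expect_identical(sum(adj), 3L)

  peps <- random_peptides(500, seed = 131)
  expect_identical(sum(dipeptide_adjacency(peps)), 1500L)

  # planted NN-rich set puts NN among the top pairs
  set.seed(132)
  planted <- c(replicate(60, paste0("NN", paste(sample(aa_alphabet(), 2, TRUE),
                                                collapse = ""))),
               random_peptides(40, seed = 133))
  top <- top_dipeptides(dipeptide_adjacency(planted), 5)
  expect_true("NN" %in% top$pair)
})

test_that("residue-property regression reproduces exact linear relations", {
  prop <- load_property_table()
  act_same <- prop
  fit <- suppressWarnings(residue_property_regression(act_same, prop))
  expect_equal(fit$slope, 1)
  expect_equal(fit$r_squared, 1)
  act_inv <- -2 * prop + 5
  fit2 <- suppressWarnings(residue_property_regression(act_inv, prop))
  expect_equal(fit2$slope, -2)
  expect_equal(fit2$intercept, 5)
  expect_equal(fit2$r_squared, 1)
  expect_lt(fit2$slope, 0)
})

test_that("regression R^2 is invariant to affine property rescaling", {
  prop <- load_property_table()
  set.seed(141)
  act <- 0.5 * prop + rnorm(20, sd = 0.5)
  f1 <- residue_property_regression(act, prop)
  f2 <- residue_property_regression(act, 3.7 * prop - 11)
  expect_equal(f1$r_squared, f2$r_squared)
})

test_that("unrelated activities and properties rarely fit well", {
  prop <- load_property_table()
  r2 <- vapply(1:10, function(s) {
    set.seed(150 + s)
    act <- stats::setNames(stats::rnorm(20), names(prop))
    residue_property_regression(act, prop)$r_squared
  }, numeric(1))
  expect_lt(stats::median(r2), 0.3)
})

test_that("degenerate and undersized inputs are flagged", {
  act <- c(A = 1, C = 2, D = 3)
  expect_true(residue_property_regression(act, c(A = 1, C = 1, D = 1))$degenerate)
  expect_error(residue_property_regression(act[1:2], c(A = 1, C = 2)), "3")
})

test_that("logo plotting and TSV export run cleanly", {
  pfm <- position_frequency_matrix(random_peptides(50, seed = 161))
  f <- tempfile(fileext = ".tsv")
  write_matrix_tsv(pfm, f)
  back <- utils::read.delim(f, row.names = 1)
  expect_equal(as.matrix(back), unclass(pfm), ignore_attr = TRUE)
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(pfm))
})
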