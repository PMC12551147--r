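test_that("bundled scales have the canonical dimensions", {
  expect_identical(vapply(test_scales, ncol, 0L),
                   c(zscale = 5L, tscale = 5L, stscale = 8L, vhse = 8L))
  expect_true(all(vapply(test_scales, nrow, 0L) == 20L))
  expect_identical(sum(vapply(test_scales, ncol, 0L)), 26L)
  for (s in test_scales) expect_identical(rownames(s), aa_alphabet())
})

test_that("corrupted scale tables are rejected with the offending entry named", {
  dir <- tempfile()
  dir.create(dir)
  src <- system.file("extdata", "scales", package = "teploop")
  file.copy(list.files(src, full.names = TRUE), dir)
  t <- utils::read.delim(file.path(dir, "zscale.tsv"), comment.char = "#")
  utils::write.table(t[t$aa != "W", ], file.path(dir, "zscale.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_scales(dir), "W")

  file.copy(file.path(src, "zscale.tsv"), file.path(dir, "zscale.tsv"),
            overwrite = TRUE)
  t <- utils::read.delim(file.path(dir, "tscale.tsv"), comment.char = "#")
  utils::write.table(t[, 1:4], file.path(dir, "tscale.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_scales(dir), "tscale")
})

test_that("feature vectors have 157 uniquely named entries with the suffix convention", {
  nm <- feature_names(test_scales)
  expect_length(nm, 157L)
  expect_identical(anyDuplicated(nm), 0L)
  expect_identical(sum(nm == "energy"), 1L)
  # 26 positional blocks of 5 + 26 averages + energy
  expect_identical(sum(grepl("_[0-4]$", nm)), 130L)

  v <- encode_peptide("SKIK", test_scales, energy = -2.5)
  expect_length(v, 157L)
  expect_identical(names(v), nm)
  expect_identical(unname(v["energy"]), -2.5)
  # the unsuffixed value is the mean of its five positional values
  for (cc in c("z1", "T3", "ST7", "VHSE5")) {
    expect_equal(unname(v[cc]), mean(v[paste0(cc, "_", 0:4)]))
  }
  # spot-check positional lookups against the raw tables
  expect_identical(unname(v["z1_0"]), test_scales$zscale["M", "z1"])
  expect_identical(unname(v["z1_1"]), test_scales$zscale["S", "z1"])
  expect_identical(unname(v["ST5_4"]), test_scales$stscale["K", "ST5"])
})

test_that("encoding aligns rows with peptides and handles edge cases", {
  peps <- random_peptides(158, seed = 5)
  x <- encode_table(peps, test_scales, energies = numeric(158))
  expect_identical(dim(x), c(158L, 157L))
  expect_identical(rownames(x), peps)
  # position-0 (initiator Met) features constant across peptides
  pos0 <- x[, grepl("_0$", colnames(x))]
  expect_true(all(apply(pos0, 2, function(col) length(unique(col)) == 1L)))

  x0 <- encode_table(character(0), test_scales, energies = numeric(0))
  expect_identical(dim(x0), c(0L, 157L))
  expect_identical(colnames(x0), feature_names(test_scales))

  expect_error(encode_table(c("SKIK", "AAAA"), test_scales, energies = 0),
               "mismatch")
  expect_error(encode_table("SKIB", test_scales, energies = 0), "invalid")
})

test_that("distinct residue multisets give distinct average feature blocks", {
  set.seed(11)
  avg_cols <- setdiff(feature_names(test_scales),
                      c("energy", grep("_[0-4]$", feature_names(test_scales),
                                       value = TRUE)))
  for (i in 1:25) {
    p1 <- random_peptides(1, seed = 100 + i)
    p2 <- random_peptides(1, seed = 200 + i)
    comp1 <- paste(sort(strsplit(p1, "")[[1]]), collapse = "")
    comp2 <- paste(sort(strsplit(p2, "")[[1]]), collapse = "")
    if (comp1 == comp2) next
    x <- encode_table(c(p1, p2), test_scales, energies = c(0, 0))
    expect_false(isTRUE(all.equal(x[1, avg_cols], x[2, avg_cols],
                                  check.attributes = FALSE)))
  }
})

test_that("feature matrices round-trip through CSV", {
  peps <- random_peptides(5, seed = 13)
  x <- encode_table(peps, test_scales, energies = rnorm(5))
  f <- tempfile(fileext = ".csv")
  write_features(x, f)
  expect_equal(read_features(f), x)
})
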