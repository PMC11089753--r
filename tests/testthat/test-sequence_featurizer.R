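test_that("one-hot encoding indexes the standard residues alphabetically", {
  ala <- one_hot_residue("ALA")
  expect_equal(which(ala == 1), 1L)
  expect_equal(sum(ala), 1)
  expect_equal(which(one_hot_residue("VAL") == 1), 20L)
  expect_equal(which(one_hot_residue("MSE") == 1), 21L) # non-standard slot
  for (nm in c("LYS", "XXX", "TRP")) {
    expect_equal(sum(one_hot_residue(nm)), 1)
    expect_length(one_hot_residue(nm), 21L)
  }
})

test_that("HHM transform follows the printed frequency formulas", {
  raw <- rep(0, 30)
  f <- transform_hhm_row(raw)
  expect_equal(f[1:27], rep(1, 27)) # 2^0
  expect_equal(f[28:30], rep(0, 3))
  raw[1] <- 1000
  expect_equal(transform_hhm_row(raw)[1], 0.5) # 2^-1
  raw[28] <- 10000
  expect_equal(transform_hhm_row(raw)[28], 0.5) # 0.001*10000/20
  raw[2] <- Inf # the '*' sentinel
  expect_equal(transform_hhm_row(raw)[2], 0)
  # monotone: decreasing in p for emissions, increasing for diversities
  p <- seq(0, 5000, by = 500)
  f1 <- vapply(p, function(v) transform_hhm_row(c(v, rep(0, 29)))[1], 1.0)
  f28 <- vapply(p, function(v) transform_hhm_row(c(rep(0, 27), v, 0, 0))[28], 1.0)
  expect_false(is.unsorted(rev(f1)))
  expect_false(is.unsorted(f28))
})

test_that("hhm files round-trip through the writer and parser", {
  hhm <- synthetic_hhm(5, seed = 2)
  path <- tempfile(fileext = ".hhm")
  write_hhm(hhm, path)
  back <- parse_hhm(path)
  expect_equal(back$length, 5L)
  expect_equal(back$rows, hhm$rows)
})

test_that("malformed hhm files raise parse errors with location", {
  hhm <- synthetic_hhm(3, seed = 1)
  path <- tempfile(fileext = ".hhm")
  write_hhm(hhm, path)
  lines <- readLines(path)
  no_footer <- fixture_file(lines[lines != "//"], ".hhm")
  expect_error(parse_hhm(no_footer), "footer")
  no_header <- fixture_file(lines[!grepl("^HMM", lines)], ".hhm")
  expect_error(parse_hhm(no_header), "HMM header")
  truncated <- fixture_file(head(lines, length(lines) - 2), ".hhm")
  expect_error(parse_hhm(truncated), "malformed")
})

test_that("physicochemical lookup zeroes non-standard residues", {
  tab <- physchem_table()
  expect_equal(dim(tab), c(20L, 7L))
  expect_equal(physchem_vector("MSE", tab), rep(0, 7))
  expect_equal(physchem_vector("ALA", tab), as.numeric(tab["ALA", ]))
  expect_length(physchem_vector("GLY", tab), 7L)
})

test_that("protein matrix has fixed shape with zero padding or truncation", {
  hhm60 <- synthetic_hhm(60, seed = 3)
  m <- build_protein_matrix(rep("LYS", 60), hhm60)
  expect_equal(dim(m), c(500L, 58L))
  expect_equal(attr(m, "n_real"), 60L)
  expect_true(all(m[61:500, ] == 0))
  expect_true(all(rowSums(abs(m[1:60, ])) > 0))

  hhm600 <- synthetic_hhm(600, seed = 4)
  m2 <- build_protein_matrix(rep("SER", 600), hhm600)
  expect_equal(dim(m2), c(500L, 58L))
  expect_equal(attr(m2, "n_real"), 500L)

  # row layout: 21 one-hot + 30 hhm + 7 physchem
  row <- m[1, ]
  expect_equal(sum(row[1:21]), 1)
  expect_equal(row[52:58], physchem_vector("LYS"), ignore_attr = TRUE)
})

test_that("protein matrix uses original sequence positions for HHM lookup", {
  prot <- multi_residue_protein(c("GLY", "LYS", "GLY"))
  sel <- select_interaction_residues(prot)
  hhm <- synthetic_hhm(3, seed = 5)
  m <- build_protein_matrix(sel, hhm)
  expect_equal(m[1, 22:51], transform_hhm_row(hhm$rows[2, ]),
    ignore_attr = TRUE
  ) # LYS sits at position 2
  short <- synthetic_hhm(1, seed = 5)
  expect_error(build_protein_matrix(sel, short), "misaligned")
})

test_that("a missing profile falls back to a zero HHM block with a warning", {
  expect_warning(m <- build_protein_matrix(rep("LYS", 3), NULL), "zero")
  expect_equal(m[1, 22:51], rep(0, 30), ignore_attr = TRUE)
})

test_that("non-standard residues zero the HHM block too", {
  hhm <- synthetic_hhm(2, seed = 6)
  m <- build_protein_matrix(c("MSE", "LYS"), hhm)
  expect_equal(m[1, 22:51], rep(0, 30), ignore_attr = TRUE)
  expect_equal(m[1, 21], 1)
})

test_that("SMILES vocabulary is injective and pins the worked example", {
  vocab <- smiles_vocab()
  expect_length(unclass(vocab), 64L)
  expect_equal(sort(as.integer(vocab)), 1:64)
  expect_equal(
    head(encode_smiles("HC(O=)N", vocab), 7),
    c(12L, 42L, 1L, 48L, 40L, 31L, 14L)
  )
})

test_that("SMILES encoding pads, truncates and catches unknown characters", {
  enc <- encode_smiles("HC(O=)N")
  expect_length(enc, 150L)
  expect_equal(enc[8:150], rep(0L, 143L))
  expect_equal(encode_smiles(""), rep(0L, 150L))
  long <- paste(rep("C", 200), collapse = "")
  enc2 <- encode_smiles(long)
  expect_length(enc2, 150L)
  expect_true(all(enc2 == 42L))
  expect_warning(enc3 <- encode_smiles("CéC"), "catch-all")
  expect_equal(enc3[2], 64L)
  # deterministic
  expect_identical(encode_smiles("c1ccccc1N=O"), encode_smiles("c1ccccc1N=O"))
})
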