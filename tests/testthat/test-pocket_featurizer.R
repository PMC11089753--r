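test_that("bin_distance implements the half-Angstrom scheme with overflow", {
  expect_equal(bin_distance(0.2), 1L)
  expect_equal(bin_distance(10.0), 21L) # floor(10/0.5)+1
  expect_equal(bin_distance(25.0), 41L)
  expect_equal(bin_distance(20.0), 41L) # boundary goes to the overflow bin
  expect_equal(bin_distance(19.99), 40L)
  expect_equal(bin_distance(0.5), 2L) # bins are left-closed, right-open
  expect_error(bin_distance(-1), "non-negative")
  expect_error(bin_distance(NaN), "finite")
  # monotone in distance
  d <- sort(runif(100, 0, 30))
  expect_false(is.unsorted(bin_distance(d)))
})

test_that("donor-acceptor map has no cutoff and exact distances", {
  donors <- typed_set_at(c(0, 0, 0), "donor", element = "N")
  acceptors <- typed_set_at(c(3, 4, 0), "acceptor", "ligand", element = "O")
  lig <- read_ligand(ethanol_sdf())
  map <- donor_acceptor_map(donors, lig, acceptors)
  expect_equal(map$d[1, 1], 5.0) # 3-4-5 triangle
  expect_true(map$present[1, 1])
  far <- typed_set_at(c(100, 0, 0), "acceptor", "ligand", element = "O")
  expect_true(donor_acceptor_map(donors, lig, far)$present[1, 1])
})

test_that("acceptor-free ligands fall back to all heavy atoms", {
  benzene <- read_ligand(benzene_sdf())
  sets <- classify_ligand_atoms(benzene)
  donors <- typed_set_at(c(0, 0, 0), "donor", element = "N")
  map <- donor_acceptor_map(donors, benzene, sets$acceptor)
  expect_equal(ncol(map$d), 6L)
  expect_equal(map$ligand_atom_ids, benzene$atoms$serial)
})

test_that("zero donors produce an empty but valid map", {
  none <- typed_set_at(matrix(numeric(), 0, 3), "donor")
  benzene <- read_ligand(benzene_sdf())
  map <- donor_acceptor_map(none, benzene, classify_ligand_atoms(benzene)$acceptor)
  expect_equal(dim(map$d), c(0L, 6L))
  expect_equal(build_pocket_vector(map, map, map), rep(0L, 1000L))
})

test_that("hydrophobic and pi-stacking thresholds are strict", {
  at0 <- typed_set_at(c(0, 0, 0))
  pair_at <- function(d) typed_set_at(c(d, 0, 0), side = "ligand")
  expect_true(hydrophobic_map(at0, pair_at(4.4))$present[1, 1])
  expect_false(hydrophobic_map(at0, pair_at(4.5))$present[1, 1])
  expect_false(hydrophobic_map(at0, pair_at(4.6))$present[1, 1])
  expect_true(pi_stacking_map(at0, pair_at(3.9))$present[1, 1])
  expect_false(pi_stacking_map(at0, pair_at(4.0))$present[1, 1])
  empty <- typed_set_at(matrix(numeric(), 0, 3))
  expect_equal(sum(hydrophobic_map(empty, empty)$present), 0L)
})

test_that("distance matrices match a brute-force oracle", {
  set.seed(42)
  a <- typed_set_at(matrix(runif(6, 0, 10), 2, 3), "donor", element = "N")
  b <- typed_set_at(matrix(runif(9, 0, 10), 3, 3), "acceptor", "ligand", "O")
  lig <- read_ligand(ethanol_sdf())
  map <- donor_acceptor_map(a, lig, b)
  for (i in 1:2) {
    for (j in 1:3) {
      d <- sqrt(sum((unlist(a$atoms[i, c("x", "y", "z")]) -
        unlist(b$atoms[j, c("x", "y", "z")]))^2))
      expect_equal(map$d[i, j], d, tolerance = 1e-9)
    }
  }
  # threshold filter equals oracle filter
  h <- hydrophobic_map(
    typed_set_at(matrix(runif(30, 0, 8), 10, 3)),
    typed_set_at(matrix(runif(15, 0, 8), 5, 3), side = "ligand")
  )
  expect_equal(h$present, h$d < 4.5)
})

test_that("pocket vector concatenates DA, piS, HP row-major with pad/truncate", {
  donors <- typed_set_at(c(0, 0, 0), "donor", element = "N")
  acceptors <- typed_set_at(c(5, 0, 0), "acceptor", "ligand", element = "O")
  lig <- read_ligand(ethanol_sdf())
  da <- donor_acceptor_map(donors, lig, acceptors)
  empty <- typed_set_at(matrix(numeric(), 0, 3))
  ps <- pi_stacking_map(empty, empty)
  hp <- hydrophobic_map(empty, empty)
  v <- build_pocket_vector(da, ps, hp)
  expect_equal(v[1], 11L) # floor(5/0.5)+1
  expect_equal(v[-1], rep(0L, 999L))

  # row-major: protein atom 1's pairs come before protein atom 2's
  d2 <- typed_set_at(rbind(c(0, 0, 0), c(1, 0, 0)), "donor", element = "N")
  a2 <- typed_set_at(rbind(c(5, 0, 0), c(9, 0, 0)), "acceptor", "ligand", "O")
  da2 <- donor_acceptor_map(d2, lig, a2)
  v2 <- build_pocket_vector(da2, ps, hp)
  expect_equal(v2[1:4], bin_distance(c(5, 9, 4, 8)))

  # truncation: a 40 x 30 grid has 1200 pairs -> first 1000 kept
  pa <- typed_set_at(cbind(seq_len(40), 0, 0))
  la <- typed_set_at(cbind(seq_len(30) * 0.1, 0.2, 0), side = "ligand")
  hp_big <- hydrophobic_map(pa, la, threshold = Inf)
  v3 <- build_pocket_vector(da, ps, hp_big)
  expect_length(v3, 1000L)
  expect_true(all(v3 > 0L))
})

test_that("pocket codes equal the brute-force oracle on random complexes", {
  for (seed in c(11, 23, 37)) {
    cx <- generate_complex(synthetic_complex_spec(seed = seed))
    f <- featurize_complex(cx$protein, cx$ligand, hhm = cx$hhm, smiles = cx$smiles)
    expect_identical(f$pocket, oracle_pocket_vector(cx$protein, cx$ligand))
  }
})

test_that("maps are invariant under a joint rigid-body motion", {
  cx <- generate_complex(synthetic_complex_spec(seed = 19))
  f1 <- featurize_complex(cx$protein, cx$ligand, hhm = cx$hhm, smiles = cx$smiles)
  # rotate both partners by the same rotation + translation
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
  shift <- c(5, -3, 2)
  move <- function(at) {
    xyz <- as.matrix(at[, c("x", "y", "z")]) %*% rot
    at$x <- xyz[, 1] + shift[1]
    at$y <- xyz[, 2] + shift[2]
    at$z <- xyz[, 3] + shift[3]
    at
  }
  prot2 <- cx$protein
  for (i in seq_along(prot2$residues)) {
    prot2$residues[[i]]$atoms <- move(prot2$residues[[i]]$atoms)
  }
  lig2 <- cx$ligand
  lig2$atoms <- move(lig2$atoms)
  f2 <- featurize_complex(prot2, lig2, hhm = cx$hhm, smiles = cx$smiles)
  expect_identical(f1$pocket, f2$pocket)
})
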