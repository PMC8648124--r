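# Synthetic fixture generators: ideal scaffolds, planted sites,
# perturbations and Bernoulli match matrices.

test_that("generated scaffolds have ideal geometry and are deterministic", {
  h <- make_scaffold(20, "helix")
  ca <- t(vapply(h$residues, function(r) r$ca, numeric(3)))
  steps <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(steps - 3.8) < 0.1))

  h2 <- make_scaffold(20, "helix")
  expect_identical(lapply(h$residues, function(r) r$atoms),
                   lapply(h2$residues, function(r) r$atoms))

  expect_error(make_scaffold(3, "helix"), ">= 4")
  expect_error(make_scaffold(20, "sheet"), "arg")

  # every residue carries a full N, CA, C, O, CB set
  expect_true(all(vapply(h$residues, function(r)
    all(c("N", "CA", "C", "O", "CB") %in% r$atoms$name), TRUE)))

  # round trip through PDB and the analysis layer without error
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(h, f)
  back <- read_pdb(f)
  expect_length(back$residues, 20)
  expect_s3_class(assign_layers(back), "LayerAssignment")

  b <- make_scaffold(40, "two_helix_bundle")
  expect_length(b$residues, 40)
  ca1 <- t(vapply(b$residues[1:20], function(r) r$ca, numeric(3)))
  ca2 <- t(vapply(b$residues[21:40], function(r) r$ca, numeric(3)))
  gap <- min(as.matrix(stats::dist(rbind(ca1, ca2)))[1:20, 21:40])
  expect_gt(gap, 4); expect_lt(gap, 12)
})

test_that("generated dihedrals agree with the secondary-structure windows", {
  h <- make_scaffold(16, "helix")
  expect_true(all(assign_secondary_structure(h)[2:15] == "helix"))
  s <- make_scaffold(16, "strand")
  expect_true(all(assign_secondary_structure(s)[2:15] == "strand"))
})

test_that("planted sites satisfy their geometric contract", {
  for (seed in 1:5) {
    fx <- planted_fixture(seed, "helix")
    site <- fx$site
    lx <- atom_coords(site$ligand$atoms)
    res_xyz <- lapply(site$residues, function(r) atom_coords(r$atoms))
    # every ligand atom within 5 A of some site residue atom
    for (i in seq_len(nrow(lx))) {
      dmin <- min(vapply(res_xyz, function(m)
        min(sqrt(rowSums(sweep(m, 2, lx[i, ])^2))), 0))
      expect_lte(dmin, 5)
    }
    # the planted site fast-matches its own scaffold at the true positions
    fm <- fast_match_site(site, fx$scaffold)
    expect_true(paste(fx$correspondence, collapse = ",") %in% match_signature(fm))
    # and site extraction recovers at least the planted residues
    s <- new_structure("x", fx$scaffold$residues, list(site$ligand), 1.5)
    ex <- extract_binding_sites(s)
    expect_gte(length(ex), 1)
    got <- vapply(ex[[1]]$residues, function(r) r$seq_index, 0L)
    expect_true(all(fx$correspondence %in% got))
  }
  fx <- planted_fixture(2, "two_helix_bundle")
  expect_equal(site_size(fx$site), 3)
})

test_that("perturb adds seeded Gaussian noise with the expected magnitude", {
  s <- make_scaffold(12, "helix")
  expect_identical(perturb(s, 0), s)
  p1 <- perturb(s, 0.1, seed = 3)
  p2 <- perturb(s, 0.1, seed = 3)
  expect_identical(lapply(p1$residues, function(r) r$atoms),
                   lapply(p2$residues, function(r) r$atoms))
  p3 <- perturb(s, 0.1, seed = 4)
  expect_false(identical(p1$residues[[1]]$atoms, p3$residues[[1]]$atoms))
  # derived fields are refreshed
  expect_equal(p1$residues[[3]]$ca,
               unlist(p1$residues[[3]]$atoms[2, c("x", "y", "z")]),
               ignore_attr = TRUE)

  # RMS displacement of many atoms approaches sigma * sqrt(3)
  big <- make_scaffold(700, "strand")  # 3500 atoms
  pb <- perturb(big, 0.1, seed = 5)
  delta <- do.call(rbind, lapply(seq_along(big$residues), function(i)
    atom_coords(pb$residues[[i]]$atoms) - atom_coords(big$residues[[i]]$atoms)))
  rms <- sqrt(mean(rowSums(delta^2)))
  expect_lt(abs(rms - 0.1 * sqrt(3)) / (0.1 * sqrt(3)), 0.05)
})

test_that("random match matrices have consistent encounters and rates", {
  mm1 <- make_match_matrix(10, 6, p_match = 1, seed = 1)
  expect_true(all(mm1$encounter == 1L))
  mm0 <- make_match_matrix(10, 6, p_match = 0, seed = 1)
  expect_true(all(is.na(mm0$encounter)))

  # empirical matched fraction within 3 sigma of 1 - (1-p)^n
  p <- 0.05; nsc <- 10; nsites <- 800
  mm <- make_match_matrix(nsites, nsc, p, seed = 2)
  frac <- mean(!is.na(mm$encounter))
  ptrue <- 1 - (1 - p)^nsc
  expect_lt(abs(frac - ptrue), 3 * sqrt(ptrue * (1 - ptrue) / nsites))

  # encounter consistency with row contents
  first <- apply(mm$fast, 1, function(r) if (any(r)) which(r)[1] else NA_integer_)
  expect_equal(unname(mm$encounter), unname(first))
  expect_error(make_match_matrix(2, 2, 1.5), "p_match")
})

test_that("dihedral jitter deforms geometry deterministically per seed", {
  a <- make_scaffold(20, "helix", seed = 5, dihedral_sigma = 4)
  b <- make_scaffold(20, "helix", seed = 5, dihedral_sigma = 4)
  expect_identical(lapply(a$residues, function(r) r$atoms),
                   lapply(b$residues, function(r) r$atoms))
  c <- make_scaffold(20, "helix", seed = 6, dihedral_sigma = 4)
  expect_false(identical(a$residues[[10]]$atoms, c$residues[[10]]$atoms))
  # covalent geometry stays ideal: consecutive CA-CA still ~3.8 A
  ca <- t(vapply(a$residues, function(r) r$ca, numeric(3)))
  expect_true(all(abs(sqrt(rowSums(diff(ca)^2)) - 3.8) < 0.1))
  # zero sigma reproduces the ideal scaffold exactly
  expect_identical(
    lapply(make_scaffold(8, "helix", seed = 9)$residues, function(r) r$atoms),
    lapply(make_scaffold(8, "helix", seed = 2)$residues, function(r) r$atoms))
})
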