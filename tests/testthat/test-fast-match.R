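# The fast-match pipeline: anchoring, nearest-residue search, gates, clash
# check, library matching and encounter numbers.

test_that("anchoring onto the source residue is the identity and rigid", {
  fx <- planted_fixture(1, "helix")
  site <- fx$site
  anchored <- anchor_align(site, 1, fx$scaffold$residues[[fx$correspondence[1]]])
  expect_equal(atom_coords(anchored$ligand$atoms),
               atom_coords(site$ligand$atoms), tolerance = 1e-9)

  # anchoring elsewhere preserves all intra-site distances
  moved <- anchor_align(site, 2, fx$scaffold$residues[[2]])
  all_atoms <- function(s) rbind(atom_coords(s$ligand$atoms),
                                 do.call(rbind, lapply(s$residues, function(r)
                                   atom_coords(r$atoms))))
  d0 <- dist(all_atoms(site)); d1 <- dist(all_atoms(moved))
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-9)

  # and equals the explicit transform composition on the ligand centroid
  r <- site$residues[[2]]; sr <- fx$scaffold$residues[[2]]
  tf <- superpose(rbind(r$n, r$ca, r$c), rbind(sr$n, sr$ca, sr$c))$transform
  expect_equal(colMeans(atom_coords(moved$ligand$atoms)),
               transform_coords(tf, colMeans(atom_coords(site$ligand$atoms))),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("nearest-residue search equals exhaustive search with low-index ties", {
  set.seed(31)
  fx <- planted_fixture(2, "helix")
  scaffold <- fx$scaffold
  sg_ca <- t(vapply(scaffold$residues, function(r) r$ca, numeric(3)))

  # self-placed site maps to its own positions at distance 0
  nn <- nearest_scaffold_residues(fx$site, scaffold)
  expect_equal(nn$scaffold_res, fx$correspondence)
  expect_equal(nn$distance, rep(0, 3), tolerance = 1e-9)

  # random placements agree with an O(n*m) scan
  for (k in 1:50) {
    tf <- random_rigid()
    placed <- apply_transform(fx$site, tf)
    nn <- nearest_scaffold_residues(placed, scaffold)
    for (i in seq_len(site_size(placed))) {
      d <- sqrt(rowSums(sweep(sg_ca, 2, placed$residues[[i]]$ca)^2))
      expect_equal(nn$scaffold_res[i], which.min(d))
      expect_equal(nn$distance[i], min(d), tolerance = 1e-9)
    }
  }

  # exact tie: equidistant scaffold CAs resolve to the lower index
  r <- scaffold$residues[[1]]
  mk <- function(shift, idx) {
    at <- r$atoms; at$x <- at$x + shift
    new_residue("A", idx, "A", at)
  }
  twin <- new_structure("twin", list(mk(0, 1L), mk(10, 2L)))
  probe_at <- r$atoms; probe_at$x <- probe_at$x + 5
  probe_res <- list(new_residue("A", 1L, "A", probe_at),
                    new_residue("A", 2L, "A", r$atoms))
  probe <- new_binding_site(fx$site$ligand, probe_res, "probe")
  nn <- nearest_scaffold_residues(probe, twin)
  expect_equal(nn$scaffold_res[1], 1L)
})

test_that("a planted site self-matches exactly and invariantly", {
  fx <- planted_fixture(3, "helix")
  fm <- fast_match_site(fx$site, fx$scaffold)
  keys <- match_signature(fm)
  true_key <- paste(fx$correspondence, collapse = ",")
  expect_true(true_key %in% keys)
  hit <- Filter(function(m) identical(m$correspondence, fx$correspondence),
                fm$matches)[[1]]
  expect_lte(hit$backbone_rmsd, 1e-6)
  expect_true(all(hit$cb_cosines > 0.999))

  # rigid transform of the site leaves outcomes identical
  set.seed(32)
  for (k in 1:5) {
    moved <- apply_transform(fx$site, random_rigid())
    fm2 <- fast_match_site(moved, fx$scaffold)
    expect_equal(match_signature(fm2), keys)
    expect_equal(fm2$stage_counts, fm$stage_counts)
  }
})

test_that("displacing a matched scaffold CA rejects at the expected stages", {
  # beyond the CA gate: nearest-CA distance exceeds 2 A for every anchor
  fx <- two_residue_fixture(displacement = 2.5)
  fm <- fast_match_site(fx$site, fx$scaffold, diagnostics = TRUE)
  expect_length(fm$matches, 0)
  stages <- vapply(fm$anchors, function(a) a$rejected_stage, "")
  expect_true(all(stages %in% c("anchor_distance", "rmsd")))
  # anchored on the undisplaced residue the gate that fires is the CA distance
  a11 <- Filter(function(a) all(a$anchor == c(1, 1)), fm$anchors)[[1]]
  expect_equal(a11$rejected_stage, "anchor_distance")
})

test_that("clash detection applies the scaled radius-sum rule exactly", {
  fx <- two_residue_fixture()
  scaffold3 <- new_structure("s3", c(fx$scaffold$residues, list(
    new_residue("A", 3L, "A", {
      at <- fx$scaffold$residues[[2]]$atoms
      at$z <- at$z + 9
      at
    }))))
  bbC <- scaffold3$residues[[3]]$c  # backbone carbon, radius 2.0

  # detached site residues far below the scaffold: only the probe ligand can
  # ever come near the scaffold backbone
  far_res <- lapply(1:2, function(i) {
    at <- fx$site$residues[[i]]$atoms
    at$z <- at$z - 40
    new_residue("A", i, "A", at)
  })
  probe_site <- function(d) {
    lig <- new_ligand("LIG", data.frame(name = "C1", element = "C",
                                        x = bbC[1], y = bbC[2], z = bbC[3] + d,
                                        b = 20, stringsAsFactors = FALSE))
    new_binding_site(lig, far_res, "probe")
  }
  # carbon-carbon threshold: 0.6 * (2.0 + 2.0) = 2.4 A
  expect_false(clash_check(probe_site(2.39), scaffold3, c(1L, 2L)))
  expect_true(clash_check(probe_site(2.41), scaffold3, c(1L, 2L)))
  # the clash disappears when the clashing residue is part of the correspondence
  expect_true(clash_check(probe_site(0.5), scaffold3, c(1L, 3L)))
  # far site is clash-free
  expect_true(clash_check(probe_site(8), scaffold3, c(1L, 2L)))
  # unknown element errors by name
  bad <- probe_site(5)
  bad$ligand$atoms$element <- "XX"
  expect_error(clash_check(bad, scaffold3, c(1L, 2L)), "XX")
  expect_error(clash_check(probe_site(5), scaffold3, c(1L, 1L)), "injective")
})

test_that("loosening fast-match cutoffs never rejects an accepted match", {
  set.seed(33)
  for (seed in 1:6) {
    fx <- planted_fixture(seed, "helix")
    noisy <- perturb(fx$site, 0.15, seed = seed + 100)
    base_cfg <- fast_match_config()
    fm <- fast_match_site(noisy, fx$scaffold, base_cfg)
    keys <- match_signature(fm)
    for (cfg in list(fast_match_config(ca_distance_cutoff = 3),
                     fast_match_config(backbone_rmsd_cutoff = 1.5),
                     fast_match_config(cb_cosine_cutoff = 0.5),
                     fast_match_config(clash_scale = 0.4))) {
      expect_true(all(keys %in% match_signature(fast_match_site(noisy, fx$scaffold, cfg))))
    }
  }
})

test_that("match_library records outcomes and first-encounter numbers", {
  fx <- planted_fixture(4, "helix")
  strands <- lapply(1:3, function(i) {
    s <- make_scaffold(20, "strand", id = sprintf("strand%d", i))
    s
  })
  scaffolds <- c(strands[1:2], list(fx$scaffold), strands[3])

  # the helix site matches only its source scaffold; find its seed order
  mm <- match_library(list(fx$site), scaffolds, seed = 7)
  expect_s3_class(mm, "MatchMatrix")
  pos <- which(mm$scaffolds == fx$scaffold$id)
  expect_equal(unname(mm$encounter[1]), pos)
  expect_equal(unname(mm$fast[1, pos]), TRUE)
  expect_false(any(mm$fast[1, -pos], na.rm = TRUE))

  # five copies of the source scaffold: encounter number 1
  copies <- lapply(1:5, function(i) {
    s <- fx$scaffold; s$id <- sprintf("copy%d", i); s
  })
  mm1 <- match_library(list(fx$site), copies, seed = 3)
  expect_equal(unname(mm1$encounter[1]), 1L)

  # stop_at_first yields the same encounter but untested later cells
  mm_stop <- match_library(list(fx$site), scaffolds, stop_at_first = TRUE, seed = 7)
  expect_equal(mm_stop$encounter, mm$encounter)
  if (pos < length(scaffolds))
    expect_true(all(is.na(mm_stop$fast[1, (pos + 1):length(scaffolds)])))
  tested <- !is.na(mm_stop$fast[1, ])
  expect_equal(mm_stop$fast[1, tested], mm$fast[1, tested])
})

test_that("confirmed outcomes must be a subset of fast outcomes", {
  fast <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)
  ok <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  bad <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)
  expect_silent(new_match_matrix(fast, confirmed = ok))
  expect_error(new_match_matrix(fast, confirmed = bad), "subset")
})
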