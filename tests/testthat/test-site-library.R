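# Interaction-score proxy, binding-site extraction filters, top-k reduction,
# sequence-distance and composition statistics.

single_atom_ligand <- function(pos, element = "MG", resname = element) {
  new_ligand(resname, data.frame(name = element, element = element,
                                 x = pos[1], y = pos[2], z = pos[3], b = 20,
                                 stringsAsFactors = FALSE))
}

fixture_site_structure <- function(lig_b = 20, lig_atoms = 1, resolution = 1.5) {
  # helix plus a pseudo-ligand planted next to residues 5, 8, 9
  sc <- make_scaffold(14, "helix")
  ps <- plant_site(sc, c(5, 8, 9), ligand_atom_count = lig_atoms, seed = 5)
  lig <- ps$site$ligand
  lig$atoms$b <- lig_b
  new_structure(sc$id, sc$residues, list(lig), resolution = resolution)
}

test_that("interaction score components behave by construction", {
  sc <- make_scaffold(8, "helix")
  r <- sc$residues[[4]]

  far <- single_atom_ligand(r$ca + c(30, 0, 0), "C", "LIG")
  s_far <- score_interaction(r, far)
  expect_identical(s_far$total, 0)

  near <- single_atom_ligand(r$cb + 1.9 * unit(r$cb - r$ca), "C", "LIG")
  s_near <- score_interaction(r, near)
  expect_lte(s_near$attraction, 0)
  expect_equal(s_near$total,
               s_near$attraction + s_near$electrostatic + s_near$hbond,
               tolerance = 1e-9)

  # carboxylate oxygen ~2.8 A from an oppositely charged metal: favorable
  asp_atoms <- rbind(r$atoms,
                     data.frame(name = c("CG", "OD1", "OD2"), element = c("C", "O", "O"),
                                x = r$cb[1] + c(1.4, 2.2, 1.8),
                                y = r$cb[2] + c(0, 1.0, -1.1),
                                z = r$cb[3], b = 20, stringsAsFactors = FALSE))
  asp <- new_residue("A", 4L, "D", asp_atoms)
  od1 <- unlist(asp$atoms[asp$atoms$name == "OD1", c("x", "y", "z")])
  mg <- single_atom_ligand(od1 + c(0, 2.8, 0))
  expect_lt(score_interaction(asp, mg)$total, 0)
})

test_that("interaction score is invariant under joint rigid transforms", {
  set.seed(21)
  sc <- make_scaffold(8, "helix")
  r <- sc$residues[[4]]
  lig <- single_atom_ligand(r$cb + c(2.5, 0.5, 0), "C", "LIG")
  base <- score_interaction(r, lig)$total
  for (k in 1:10) {
    tf <- random_rigid()
    moved <- score_interaction(apply_transform(r, tf),
                               apply_transform(lig, tf))$total
    expect_equal(moved, base, tolerance = 1e-9)
  }
})

test_that("extraction finds the planted site and applies ligand filters", {
  s <- fixture_site_structure()
  sites <- extract_binding_sites(s)
  expect_length(sites, 1)
  idx <- vapply(sites[[1]]$residues, function(r) r$seq_index, 0L)
  expect_true(all(c(5, 8, 9) %in% idx))
  expect_true(all(sites[[1]]$scores < -1))

  # every site residue touches the ligand within the contact radius
  lx <- atom_coords(s$ligands[[1]]$atoms)
  for (r in sites[[1]]$residues) {
    rx <- atom_coords(r$atoms)
    dmin <- min(apply(lx, 1, function(p) min(sqrt(rowSums(sweep(rx, 2, p)^2)))))
    expect_lte(dmin, 5)
  }

  # average B-factor above 60 excludes the ligand
  expect_length(extract_binding_sites(fixture_site_structure(lig_b = 61)), 0)
  expect_length(extract_binding_sites(fixture_site_structure(lig_b = 60)), 1)

  # ligand heavy-atom count above the maximum excludes the site
  cfg_small <- library_config(max_ligand_heavy_atoms = 2)
  expect_length(extract_binding_sites(fixture_site_structure(lig_atoms = 3),
                                      cfg_small), 0)

  # resolution worse than the cutoff excludes the structure
  expect_length(extract_binding_sites(fixture_site_structure(resolution = 2.5)), 0)
  # missing resolution passes by default, is skipped when required
  s_nores <- fixture_site_structure(resolution = NA)
  expect_length(extract_binding_sites(s_nores), 1)
  expect_warning(
    out <- extract_binding_sites(s_nores, library_config(require_resolution = TRUE)),
    "resolution")
  expect_length(out, 0)
})

test_that("loosening extraction cutoffs never loses sites", {
  base_cfg <- library_config()
  loose <- list(
    library_config(max_ligand_heavy_atoms = 200),
    library_config(max_avg_bfactor = 120),
    library_config(resolution_cutoff = 4),
    library_config(contact_radius = 7),
    library_config(include_threshold = -0.5),
    library_config(residue_quality_cutoff = 100))
  for (seed in 1:5) {
    sc <- make_scaffold(16, "helix")
    ps <- plant_site(sc, c(5, 8, 9), ligand_atom_count = 1 + seed %% 3, seed = seed)
    s <- new_structure(paste0("m", seed), sc$residues, list(ps$site$ligand), 1.5)
    n_base <- length(extract_binding_sites(s, base_cfg))
    for (cfg in loose)
      expect_gte(length(extract_binding_sites(s, cfg)), n_base)
  }
})

test_that("select_top_k keeps the lowest-scoring residues (brute-force check)", {
  set.seed(22)
  sc <- make_scaffold(12, "helix")
  lig <- single_atom_ligand(sc$residues[[6]]$cb + c(2.5, 0, 0), "C", "LIG")
  for (n in c(4, 5, 8)) {
    scores <- round(rnorm(n), 3)
    site <- new_binding_site(lig, sc$residues[seq_len(n)], "fix", scores)
    for (k in 2:3) {
      top <- select_top_k(site, k)
      expect_equal(site_size(top), k)
      # oracle: no other k-subset has a lower score sum
      combs <- utils::combn(n, k)
      best <- min(apply(combs, 2, function(ix) sum(scores[ix])))
      expect_equal(sum(top$scores), best, tolerance = 1e-12)
    }
  }
  site3 <- new_binding_site(lig, sc$residues[1:3], "fix", c(-1, -2, -3))
  expect_identical(select_top_k(site3, 3), site3)
  site2 <- new_binding_site(lig, sc$residues[1:2], "fix", c(-1, -2))
  expect_null(select_top_k(site2, 3))
  expect_error(select_top_k(site3, 1), ">= 2")
})

test_that("select_top_k breaks score ties by sequence index", {
  sc <- make_scaffold(8, "helix")
  lig <- single_atom_ligand(sc$residues[[4]]$cb + c(2.5, 0, 0), "C", "LIG")
  site <- new_binding_site(lig, sc$residues[1:4], "fix", c(-2, -1, -1, -1))
  top <- select_top_k(site, 3)
  expect_equal(vapply(top$residues, function(r) r$seq_index, 0L), c(1L, 2L, 3L))
})

test_that("mean sequence distance matches hand-computed values", {
  sc <- make_scaffold(20, "helix")
  lig <- single_atom_ligand(sc$residues[[6]]$cb + c(2.5, 0, 0), "C", "LIG")
  msd <- function(pos) mean_sequence_distance(
    new_binding_site(lig, sc$residues[pos], "fix"))
  expect_equal(msd(c(6, 7, 8)), 4 / 3, tolerance = 1e-12)
  expect_equal(round(msd(c(6, 7, 8)), 2), 1.33)
  expect_equal(msd(c(4, 9)), 5)

  # residues (1, 71, 141): mean of (70, 70, 140)
  fake <- lapply(c(1, 71, 141), function(i)
    new_residue("A", i, "A", sc$residues[[1]]$atoms))
  expect_equal(mean_sequence_distance(new_binding_site(lig, fake, "fix")),
               280 / 3)

  mixed <- list(new_residue("A", 1L, "A", sc$residues[[1]]$atoms),
                new_residue("B", 2L, "A", sc$residues[[2]]$atoms))
  expect_error(mean_sequence_distance(new_binding_site(lig, mixed, "fix")),
               "different chains")
})

test_that("amino-acid composition counts residues and sums to one", {
  sc <- make_scaffold(8, "helix")
  lig <- single_atom_ligand(sc$residues[[4]]$cb + c(2.5, 0, 0), "C", "LIG")
  res <- sc$residues[1:3]
  res[[1]]$aa <- "W"; res[[2]]$aa <- "W"; res[[3]]$aa <- "H"
  comp <- aa_composition(list(new_binding_site(lig, res, "fix")))
  expect_equal(unname(comp["W"]), 2 / 3)
  expect_equal(unname(comp["H"]), 1 / 3)
  expect_equal(sum(comp), 1, tolerance = 1e-9)
  expect_error(aa_composition(list()), "at least one")
})
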