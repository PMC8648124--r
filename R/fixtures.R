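# Deterministic synthetic fixtures: idealized poly-alanine backbones
# (helix, strand, two-helix bundle), planted binding sites with pseudo-ligands,
# Gaussian coordinate perturbations, and Bernoulli match matrices. These stand
# in for curated scaffold sets so the full pipeline is exercisable offline.

# run expr with a temporary RNG state seeded by `seed` (NULL = use current RNG)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# ideal trans-peptide internal coordinates (Engh-Huber-like values)
BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                ang_ca_c_o = 120.1, omega = 180)

PHI_PSI <- list(helix = c(-57, -47), strand = c(-120, 120))

deg <- function(x) x * pi / 180

# build an n-residue ideal poly-alanine chain; phi/psi in degrees, recycled
# to length n (per-residue values allow smooth backbone variation)
build_ideal_chain <- function(n, phi, psi, chain_id = "A", seq_offset = 0L) {
  g <- BB_GEOM
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  N <- matrix(0, n, 3); CA <- matrix(0, n, 3); C <- matrix(0, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$n_ca, 0, 0)
  C[1, ] <- place_atom(c(0, 1, 0), N[1, ], CA[1, ], g$ca_c, deg(g$ang_n_ca_c), deg(phi[1]))
  for (i in seq_len(n - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$c_n, deg(g$ang_ca_c_n), deg(psi[i]))
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], g$n_ca, deg(g$ang_c_n_ca), deg(g$omega))
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], g$ca_c, deg(g$ang_n_ca_c), deg(phi[i + 1]))
  }
  residues <- vector("list", n)
  for (i in seq_len(n)) {
    o <- if (i < n) place_atom(N[i + 1, ], CA[i, ], C[i, ], g$c_o, deg(g$ang_ca_c_o), pi)
         else place_atom(N[i, ], CA[i, ], C[i, ], g$c_o, deg(g$ang_ca_c_o), deg(psi[i]) + pi)
    cb <- ideal_cb(N[i, ], CA[i, ], C[i, ])
    xyz <- rbind(N[i, ], CA[i, ], C[i, ], o, cb)
    residues[[i]] <- new_residue(chain_id, i + seq_offset, "A",
                                 atom_df(c("N", "CA", "C", "O", "CB"),
                                         c("N", "C", "C", "O", "C"),
                                         xyz[, 1], xyz[, 2], xyz[, 3], b = 20))
  }
  residues
}

#' Generate an idealized synthetic scaffold
#'
#' Full-backbone (N, CA, C, O, CB) poly-alanine with ideal bond geometry.
#' `"helix"` uses canonical alpha-helical dihedrals (phi -57, psi -47),
#' `"strand"` an extended conformation (phi -120, psi +120), and
#' `"two_helix_bundle"` two antiparallel helices of `n_residues / 2` each,
#' packed side by side on a single chain (with a chain break between them).
#' Deterministic for a fixed seed. `noise_sigma > 0` adds isotropic Gaussian
#' coordinate noise via [perturb()]; `dihedral_sigma > 0` draws per-residue
#' backbone dihedrals from a Gaussian around the topology's canonical values,
#' which deforms medium-range backbone geometry smoothly while keeping bond
#' lengths and angles ideal -- a simple emulation of the geometric variation
#' among members of one fold family.
#'
#' @param n_residues Number of residues (>= 4).
#' @param topology One of `"helix"`, `"strand"`, `"two_helix_bundle"`.
#' @param seed Integer seed controlling dihedral draws and noise.
#' @param noise_sigma Coordinate noise standard deviation in Angstrom.
#' @param dihedral_sigma Per-residue phi/psi standard deviation in degrees.
#' @param id Structure identifier.
#' @return A [new_structure()] with nominal resolution 1.5 Angstrom.
#' @export
make_scaffold <- function(n_residues, topology = c("helix", "strand", "two_helix_bundle"),
                          seed = 1L, noise_sigma = 0, dihedral_sigma = 0,
                          id = NULL) {
  topology <- match.arg(topology)
  if (n_residues < 4L) stop("n_residues must be >= 4")
  if (is.null(id)) id <- sprintf("%s_%d_s%d", topology, n_residues, seed)
  jitter <- function(base, n)
    if (dihedral_sigma > 0) stats::rnorm(n, base, dihedral_sigma) else base
  if (topology %in% c("helix", "strand")) {
    pp <- PHI_PSI[[topology]]
    residues <- with_seed(seed, build_ideal_chain(
      n_residues, jitter(pp[1], n_residues), jitter(pp[2], n_residues)))
  } else {
    n1 <- n_residues %/% 2L
    n2 <- n_residues - n1
    pp <- PHI_PSI$helix
    chains <- with_seed(seed, list(
      build_ideal_chain(n1, jitter(pp[1], n1), jitter(pp[2], n1)),
      build_ideal_chain(n2, jitter(pp[1], n2), jitter(pp[2], n2),
                        seq_offset = n1)))
    h1 <- chains[[1]]; h2 <- chains[[2]]
    # center helix 1, find its principal axis, place helix 2 antiparallel
    ca1 <- t(vapply(h1, function(r) r$ca, numeric(3)))
    ctr <- colMeans(ca1)
    pc <- prcomp(ca1, center = TRUE)
    u1 <- pc$rotation[, 1]; u3 <- pc$rotation[, 3]
    flip <- rotation_about_axis(pc$rotation[, 2], pi)
    tf1 <- rigid_transform(diag(3), -ctr)
    tf2 <- compose_transforms(rigid_transform(flip, 10.2 * u3 - c(flip %*% ctr)), tf1)
    h1 <- lapply(h1, apply_transform, tf = tf1)
    h2 <- lapply(h2, apply_transform, tf = tf2)
    residues <- c(h1, h2)
  }
  s <- new_structure(id, residues, resolution = 1.5)
  if (noise_sigma > 0) s <- perturb(s, noise_sigma, seed)
  s
}

rotation_about_axis <- function(axis, angle) {
  u <- unit(axis)
  k <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, byrow = TRUE)
  diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
}

#' Plant a synthetic binding site on a scaffold
#'
#' Copies the chosen scaffold residues (backbone plus C-beta side chain) and
#' places a pseudo-ligand of `ligand_atom_count` carbon atoms so that every
#' ligand atom lies within `contact_radius` of at least one site-residue atom,
#' every site residue has an atom within `contact_radius` of the ligand, and
#' no ligand atom comes closer than `clearance` to the backbone of any
#' non-site scaffold residue (so the planted site passes the fast-match clash
#' gate by construction).
#'
#' @param scaffold A [new_structure()] object.
#' @param positions Residue indices (into `scaffold$residues`) forming the site.
#' @param ligand_atom_count Number of ligand pseudo-atoms (>= 1).
#' @param seed Integer seed for the stochastic placement search.
#' @param contact_radius Site contact distance in Angstrom (default 5).
#' @param clearance Minimum ligand to non-site backbone distance (default 3.2).
#' @param min_score Placement is retried until every site residue's proxy
#'   interaction score with the ligand falls below this value (default -1,
#'   the library inclusion threshold), so planted sites are recoverable by
#'   [extract_binding_sites()] by construction.
#' @return A list with `site` (a [new_binding_site()], scored with the default
#'   interaction proxy) and `correspondence` (the true scaffold residue
#'   indices, equal to `positions`).
#' @export
plant_site <- function(scaffold, positions, ligand_atom_count = 1L, seed = 1L,
                       contact_radius = 5, clearance = 3.2, min_score = -1) {
  stopifnot(inherits(scaffold, "Structure"))
  positions <- as.integer(positions)
  if (any(positions < 1L | positions > length(scaffold$residues)))
    stop("positions out of range")
  if (anyDuplicated(positions)) stop("positions must be distinct")
  if (ligand_atom_count < 1L) stop("ligand_atom_count must be >= 1")
  site_res <- scaffold$residues[positions]
  res_xyz <- lapply(site_res, function(r) atom_coords(r$atoms))
  other_bb <- do.call(rbind, lapply(scaffold$residues[-positions], function(r) {
    atom_coords(r$atoms[r$atoms$name %in% c("N", "CA", "C", "O"), , drop = FALSE])
  }))
  cb <- t(vapply(site_res, function(r) r$cb, numeric(3)))
  ca <- t(vapply(site_res, function(r) r$ca, numeric(3)))
  # two seeding strategies: above the CB centroid (compact sites) and off the
  # first residue's CB (sequence-spread sites, where the centroid may be far
  # from every side chain)
  starts <- list(colMeans(cb) + 1.2 * unit(colMeans(cb) - colMeans(ca)),
                 cb[1, ] + 1.0 * unit(cb[1, ] - ca[1, ]))

  ok_atom <- function(p, placed) {
    if (!is.null(other_bb) && nrow(other_bb) > 0 &&
        min(sqrt(rowSums(sweep(other_bb, 2, p)^2))) < clearance) return(FALSE)
    dmin_any <- min(vapply(res_xyz, function(m)
      min(sqrt(rowSums(sweep(m, 2, p)^2))), 0))
    # lower bound keeps the pair out of the steep repulsive wall so planted
    # residues pass the library quality filter
    if (dmin_any > contact_radius || dmin_any < 3.2) return(FALSE)
    if (!is.null(placed) && nrow(placed) > 0 &&
        min(sqrt(rowSums(sweep(placed, 2, p)^2))) < 1.2) return(FALSE)
    TRUE
  }
  covers_all <- function(atoms) {
    all(vapply(res_xyz, function(m) {
      min(vapply(seq_len(nrow(atoms)), function(i)
        min(sqrt(rowSums(sweep(m, 2, atoms[i, ])^2))), 0)) <= contact_radius
    }, TRUE))
  }

  make_lig <- function(atoms) {
    new_ligand("LIG",
               atom_df(paste0("C", seq_len(nrow(atoms))),
                       rep("C", nrow(atoms)),
                       atoms[, 1], atoms[, 2], atoms[, 3], b = 20),
               source = paste0(scaffold$id, ":planted"))
  }
  site_scores <- function(lig)
    vapply(site_res, function(r) score_interaction(r, lig)$total, 0)

  found <- with_seed(seed, {
    out <- NULL
    for (attempt in seq_len(2000L)) {
      p1 <- starts[[1L + attempt %% 2L]] + stats::rnorm(3, sd = 1.1)
      if (!ok_atom(p1, NULL)) next
      placed <- matrix(p1, 1, 3)
      ok <- TRUE
      k <- 1L
      tries <- 0L
      while (k < ligand_atom_count) {
        tries <- tries + 1L
        if (tries > 1000L) { ok <- FALSE; break }
        # bias chain growth toward residues not yet within contact range so
        # multi-atom ligands can span sequence-spread sites
        uncovered <- which(vapply(res_xyz, function(m)
          min(vapply(seq_len(nrow(placed)), function(j)
            min(sqrt(rowSums(sweep(m, 2, placed[j, ])^2))), 0)) > contact_radius,
          TRUE))
        d <- if (length(uncovered) > 0) {
          target <- colMeans(res_xyz[[uncovered[1]]])
          unit(unit(target - placed[nrow(placed), ]) + 0.8 * stats::rnorm(3))
        } else unit(stats::rnorm(3))
        p <- placed[nrow(placed), ] + 1.5 * d
        if (ok_atom(p, placed)) { placed <- rbind(placed, p); k <- k + 1L }
      }
      if (!ok || !covers_all(placed)) next
      lig <- make_lig(placed)
      sc <- site_scores(lig)
      if (all(sc < min_score)) { out <- list(lig = lig, scores = sc); break }
    }
    out
  })
  if (is.null(found))
    stop("could not place ligand after 2000 attempts; try other positions")
  lig <- found$lig
  scores <- found$scores
  list(site = new_binding_site(lig, site_res, source_id = scaffold$id,
                               scores = scores),
       correspondence = positions)
}

#' Add isotropic Gaussian noise to every heavy-atom coordinate
#'
#' @param x A `Structure` or `BindingSite`.
#' @param sigma Noise standard deviation in Angstrom (0 = identity).
#' @param seed Integer seed; deterministic for a fixed seed.
#' @return Same class as `x`, with derived fields (backbone, C-beta) refreshed.
#' @export
perturb <- function(x, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(x)
  with_seed(seed, map_coords(x, function(m)
    m + matrix(stats::rnorm(length(m), sd = sigma), nrow(m), 3)))
}

#' Generate a random boolean match matrix
#'
#' Independent Bernoulli(p_match) site-by-scaffold outcomes with consistent
#' first-encounter numbers, for testing the statistics layer.
#'
#' @param n_sites,n_scaffolds Matrix dimensions.
#' @param p_match Per-cell match probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A `MatchMatrix` (see [match_library()]).
#' @export
make_match_matrix <- function(n_sites, n_scaffolds, p_match, seed = 1L) {
  if (p_match < 0 || p_match > 1) stop("p_match must be in [0, 1]")
  fast <- with_seed(seed, matrix(stats::runif(n_sites * n_scaffolds) < p_match,
                                 n_sites, n_scaffolds))
  new_match_matrix(fast,
                   sites = sprintf("site%03d", seq_len(n_sites)),
                   scaffolds = sprintf("scaf%03d", seq_len(n_scaffolds)))
}
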