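# Independent oracles and small fixture builders shared across tests.
# Each oracle re-derives a quantity by a route different from the package
# implementation it checks.

unit <- function(v) v / sqrt(sum(v * v))

# -- rotation utilities -------------------------------------------------------

euler_rotation <- function(e) {
  cz <- cos(e[1]); sz <- sin(e[1])
  cy <- cos(e[2]); sy <- sin(e[2])
  cx <- cos(e[3]); sx <- sin(e[3])
  rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  rz %*% ry %*% rx
}

random_rigid <- function() {
  rigid_transform(random_rotation(), stats::rnorm(3, sd = 10))
}

# brute-force superposition oracle: numeric minimization of RMSD over
# rotations (many random restarts + Nelder-Mead refinement), independent of
# the SVD route used by superpose()
oracle_min_rmsd <- function(mobile, target, n_starts = 60) {
  p <- sweep(mobile, 2, colMeans(mobile))
  q <- sweep(target, 2, colMeans(target))
  f <- function(e) {
    r <- euler_rotation(e)
    sqrt(mean(rowSums((p %*% t(r) - q)^2)))
  }
  best <- Inf
  for (k in seq_len(n_starts)) {
    start <- stats::runif(3, -pi, pi)
    opt <- stats::optim(start, f, method = "Nelder-Mead",
                        control = list(reltol = 1e-15, maxit = 5000))
    opt <- stats::optim(opt$par, f, method = "Nelder-Mead",
                        control = list(reltol = 1e-15, maxit = 5000))
    if (opt$value < best) best <- opt$value
  }
  best
}

# independent ideal-CB oracle: solve for the unit direction u with
# angle(N-CA, u) = angle(C-CA, u) = 110.4 deg, |CB-CA| = 1.521; of the two
# mirror solutions, L-amino-acid chirality has positive component along
# (CA-N) x (C-CA)
oracle_ideal_cb <- function(n, ca, c) {
  u1 <- (n - ca) / sqrt(sum((n - ca)^2))
  u2 <- (c - ca) / sqrt(sum((c - ca)^2))
  ct <- cos(110.4 * pi / 180)
  # u = a*u1 + b*u2 + g*w, w = unit(u1 x u2)
  g11 <- 1; g12 <- sum(u1 * u2)
  ab <- solve(matrix(c(g11, g12, g12, g11), 2), c(ct, ct))
  w <- c(u1[2] * u2[3] - u1[3] * u2[2],
         u1[3] * u2[1] - u1[1] * u2[3],
         u1[1] * u2[2] - u1[2] * u2[1])
  w <- w / sqrt(sum(w * w))
  base <- ab[1] * u1 + ab[2] * u2
  rest <- 1 - sum(base * base)
  stopifnot(rest > 0)
  chir <- ca - n
  axis <- c(chir[2] * (c - ca)[3] - chir[3] * (c - ca)[2],
            chir[3] * (c - ca)[1] - chir[1] * (c - ca)[3],
            chir[1] * (c - ca)[2] - chir[2] * (c - ca)[1])
  for (s in c(1, -1)) {
    u <- base + s * sqrt(rest) * w
    if (sum(u * axis) < 0) return(ca + 1.521 * u)
  }
  stop("no chiral solution found")
}

# naive Butina clustering, following the published procedure step by step;
# written independently of butina_cluster()
naive_butina <- function(fps, cutoff) {
  n <- length(fps)
  ids <- vapply(seq_len(n), function(i) {
    id <- fps[[i]]$ligand_id
    if (nzchar(id)) id else sprintf("lig%03d", i)
  }, "")
  d <- outer(seq_len(n), seq_len(n),
             Vectorize(function(i, j) tanimoto_distance(fps[[i]], fps[[j]])))
  nb <- lapply(seq_len(n), function(i) setdiff(which(d[i, ] <= cutoff), i))
  remaining <- rep(TRUE, n)
  clusters <- list()
  repeat {
    cand <- which(remaining)
    if (length(cand) == 0L) break
    cnt <- lengths(nb)[cand]
    pick <- cand[order(-cnt, ids[cand])][1]
    members <- c(pick, intersect(nb[[pick]], which(remaining)))
    members <- unique(members)
    remaining[members] <- FALSE
    clusters[[length(clusters) + 1L]] <- sort(ids[members])
  }
  clusters
}

cluster_signature <- function(member_lists) {
  sig <- vapply(member_lists, function(m) paste(sort(m), collapse = "|"), "")
  sort(sig)
}

random_fingerprints <- function(n, len = 64) {
  lapply(seq_len(n), function(i)
    new_fingerprint(stats::runif(len) < 0.3, sprintf("fp%02d", i)))
}

# -- fixture builders ---------------------------------------------------------

# a 2-residue scaffold taken from a strand so the residues are well separated,
# with a far-away single-atom ligand that can never clash
two_residue_fixture <- function(displacement = 0, rotate_cb = 0) {
  base <- make_scaffold(9, "strand")
  r1 <- base$residues[[3]]
  r2 <- base$residues[[7]]
  if (displacement != 0) {
    # displace the whole residue perpendicular to the chain direction
    at <- r2$atoms
    at$z <- at$z + displacement
    r2 <- new_residue(r2$chain_id, r2$seq_index, r2$aa, at)
  }
  if (rotate_cb != 0) {
    ax <- r2$cb - r2$ca
    perp <- c(-ax[2], ax[1], 0)
    rot <- rotation_matrix_about(perp, rotate_cb)
    cb_new <- r2$ca + c(rot %*% (r2$cb - r2$ca))
    at <- r2$atoms
    i <- match("CB", at$name)
    at$x[i] <- cb_new[1]; at$y[i] <- cb_new[2]; at$z[i] <- cb_new[3]
    r2 <- new_residue(r2$chain_id, r2$seq_index, r2$aa, at)
  }
  scaffold <- new_structure("pairfix", list(
    new_residue("A", 1L, "A", r1$atoms),
    new_residue("A", 2L, "A", r2$atoms)))
  site_res <- base$residues[c(3, 7)]
  lig_pos <- site_res[[1]]$cb + 4 * (site_res[[1]]$cb - site_res[[1]]$ca)
  lig <- new_ligand("LIG", data.frame(name = "C1", element = "C",
                                      x = lig_pos[1], y = lig_pos[2],
                                      z = lig_pos[3], b = 20,
                                      stringsAsFactors = FALSE))
  site <- new_binding_site(lig, list(
    new_residue("A", 1L, "A", site_res[[1]]$atoms),
    new_residue("A", 2L, "A", site_res[[2]]$atoms)), "pairsite")
  list(scaffold = scaffold, site = site)
}

rotation_matrix_about <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  k <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, byrow = TRUE)
  diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
}

# planted-site fixture on a helix or bundle; positions chosen to be spatially
# compact so ligand placement always succeeds
planted_fixture <- function(seed, topology = c("helix", "two_helix_bundle")) {
  topology <- match.arg(topology)
  if (topology == "helix") {
    sc <- make_scaffold(24, "helix")
    start <- 5 + (seed %% 12)
    pos <- c(start, start + 3, start + 4)
  } else {
    sc <- make_scaffold(40, "two_helix_bundle")
    start <- 4 + (seed %% 10)
    pos <- c(start, start + 3, start + 4)
  }
  c(plant_site(sc, pos, ligand_atom_count = 1 + (seed %% 3), seed = seed),
    list(scaffold = sc))
}

# generic accepted-correspondence signature of a FastMatchResult
match_signature <- function(fm) {
  sort(vapply(fm$matches, function(m) paste(m$correspondence, collapse = ","), ""))
}

build_ideal_chain_for_test <- function(n, phi, psi) {
  sitematch:::build_ideal_chain(n, phi, psi)
}

# bisection on a boolean predicate: returns the flip point of pred over
# [lo, hi], assuming pred(lo) != pred(hi)
bisect_flip <- function(lo, hi, pred, tol = 1e-5) {
  plo <- pred(lo)
  stopifnot(pred(hi) != plo)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pred(mid) == plo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
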