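# Geometric-constraint file writer for an external matcher. Each block pins
# the relative placement of a ligand and one binding-site residue through 6
# anchor heavy atoms: on the ligand side, the atom closest to the protein
# residue plus the two ligand atoms closest to it; mirrored on the residue
# side. The distance is constrained at its observed (ideal) value; the two
# angles and three torsions are sampled at the ideal value and +/- 10 degrees.

closest_pair <- function(a_xyz, b_xyz) {
  best <- c(Inf, 1L, 1L)
  for (i in seq_len(nrow(a_xyz))) {
    d <- sqrt(rowSums(sweep(b_xyz, 2, a_xyz[i, ])^2))
    j <- which.min(d)
    if (d[j] < best[1]) best <- c(d[j], i, j)
  }
  list(dist = best[1], i = as.integer(best[2]), j = as.integer(best[3]))
}

# first anchor atom plus its two nearest siblings, by increasing distance
anchor_triplet <- function(xyz, first) {
  d <- sqrt(rowSums(sweep(xyz, 2, xyz[first, ])^2))
  d[first] <- Inf
  ord <- order(d)
  c(first, ord[1], ord[2])
}

#' Write a geometric-constraint file for a binding site
#'
#' One constraint block per site residue, in the standard matcher constraint
#' format. Requires at least 3 ligand heavy atoms and 3 heavy atoms per
#' residue (6 anchor atoms define the relative placement). The output is
#' deterministic for a given site.
#'
#' @param site A [new_binding_site()] object.
#' @param path Output file path.
#' @param angle_sample Sampling half-width for angles/torsions in degrees
#'   (default 10; written as the tolerance with one sample on each side).
#' @return Invisibly, the lines written.
#' @export
write_constraint_file <- function(site, path, angle_sample = 10) {
  stopifnot(inherits(site, "BindingSite"))
  lig <- site$ligand
  lx <- atom_coords(lig$atoms)
  if (nrow(lx) < 3L)
    stop("constraint blocks need at least 3 ligand heavy atoms")
  aa31 <- names(AA3)
  lines <- character()
  for (r in site$residues) {
    rx <- atom_coords(r$atoms)
    if (nrow(rx) < 3L)
      stop("constraint blocks need at least 3 heavy atoms per residue")
    cp <- closest_pair(lx, rx)
    la <- anchor_triplet(lx, cp$i)   # L1 closest to residue, L2/L3 closest to L1
    pa <- anchor_triplet(rx, cp$j)   # P1 closest to ligand, P2/P3 closest to P1
    l1 <- lx[la[1], ]; l2 <- lx[la[2], ]; l3 <- lx[la[3], ]
    p1 <- rx[pa[1], ]; p2 <- rx[pa[2], ]; p3 <- rx[pa[3], ]
    rad <- 180 / pi
    res3 <- if (r$aa %in% AA3) aa31[match(r$aa, AA3)] else "UNK"
    block <- c(
      "CST::BEGIN",
      sprintf("  TEMPLATE::   ATOM_MAP: 1 atom_name: %s",
              paste(lig$atoms$name[la], collapse = " ")),
      sprintf("  TEMPLATE::   ATOM_MAP: 1 residue3: %s", lig$resname),
      "",
      sprintf("  TEMPLATE::   ATOM_MAP: 2 atom_name: %s",
              paste(r$atoms$name[pa], collapse = " ")),
      sprintf("  TEMPLATE::   ATOM_MAP: 2 residue3: %s", res3),
      "",
      sprintf("  CONSTRAINT:: distanceAB: %7.2f %7.2f %7.1f %5d %5d",
              vnorm(l1 - p1), 0.05, 100, 0L, 0L),
      sprintf("  CONSTRAINT::    angle_A: %7.2f %7.2f %7.1f %5.0f %5d",
              vector_angle(l2 - l1, p1 - l1) * rad, angle_sample, 100, 360, 1L),
      sprintf("  CONSTRAINT::    angle_B: %7.2f %7.2f %7.1f %5.0f %5d",
              vector_angle(l1 - p1, p2 - p1) * rad, angle_sample, 100, 360, 1L),
      sprintf("  CONSTRAINT::  torsion_A: %7.2f %7.2f %7.1f %5.0f %5d",
              dihedral_angle(l3, l2, l1, p1) * rad, angle_sample, 100, 360, 1L),
      sprintf("  CONSTRAINT:: torsion_AB: %7.2f %7.2f %7.1f %5.0f %5d",
              dihedral_angle(l2, l1, p1, p2) * rad, angle_sample, 100, 360, 1L),
      sprintf("  CONSTRAINT::  torsion_B: %7.2f %7.2f %7.1f %5.0f %5d",
              dihedral_angle(l1, p1, p2, p3) * rad, angle_sample, 100, 360, 1L),
      "CST::END",
      "")
    lines <- c(lines, block)
  }
  writeLines(lines, path)
  invisible(lines)
}
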