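# Side-chain-independent burial analysis: each residue gets a weighted count
# of neighbors falling in a cone along its CA->CB vector, and is classed as
# surface (< 2), boundary, or core (> 5.2). A dihedral-window 3-state
# secondary structure assigner supports descriptive analyses; it is NOT a
# hydrogen-bond-based (DSSP-equivalent) assignment.

#' Cone weight of a neighbor residue
#'
#' Distance factor `1 / (1 + exp(d - 9))` times angle factor
#' `((cos(theta) + 0.5) / 1.5)^2`, with the angle factor clamped to 0 when
#' `cos(theta) <= -0.5`. At d = 9 A and theta = 0 the weight is exactly 0.5.
#' Vectorized; values lie in `[0, 1]`.
#'
#' @param d Distance from the residue CA to the neighbor CA (Angstrom, >= 0).
#' @param theta Angle between the CA->CB vector and the CA->neighbor-CA
#'   vector (radians).
#' @return Numeric weight(s).
#' @export
neighbor_weight <- function(d, theta) {
  if (any(d < 0)) stop("d must be >= 0")
  dist_factor <- 1 / (1 + exp(d - 9))
  ang <- (cos(theta) + 0.5) / 1.5
  ang[ang <= 0] <- 0
  dist_factor * ang^2
}

#' Classify a weighted neighbor count into a burial layer
#'
#' @param count Weighted neighbor count(s).
#' @param surface_cutoff Below this: `"surface"` (default 2).
#' @param core_cutoff Above this: `"core"` (default 5.2); else `"boundary"`.
#' @return Character vector of layer labels.
#' @export
layer_label <- function(count, surface_cutoff = 2, core_cutoff = 5.2) {
  ifelse(count < surface_cutoff, "surface",
         ifelse(count > core_cutoff, "core", "boundary"))
}

#' Assign burial layers to all residues of a scaffold
#'
#' For each residue, sums [neighbor_weight()] over all other residues with
#' `d` the CA--CA distance and `theta` the angle between the residue's
#' CA->CB vector (ideal CB for glycine) and the CA->neighbor-CA vector.
#' Side-chain independent: only CA and (real or constructed) CB are used.
#'
#' @param scaffold A [new_structure()] with >= 2 matchable residues.
#' @param surface_cutoff,core_cutoff Layer thresholds (defaults 2 and 5.2).
#' @return An object of class `"LayerAssignment"`: a data frame with columns
#'   `chain_id`, `seq_index`, `neighbor_count`, `layer`, one row per residue
#'   of the scaffold (in residue order).
#' @export
assign_layers <- function(scaffold, surface_cutoff = 2, core_cutoff = 5.2) {
  stopifnot(inherits(scaffold, "Structure"))
  res <- scaffold$residues
  if (length(res) < 2L) stop("layer assignment needs at least 2 residues")
  ca <- t(vapply(res, function(r) r$ca, numeric(3)))
  cb <- t(vapply(res, function(r) r$cb, numeric(3)))
  n <- length(res)
  counts <- numeric(n)
  for (i in seq_len(n)) {
    v <- ca[-i, , drop = FALSE]
    dvec <- sweep(v, 2, ca[i, ])
    d <- sqrt(rowSums(dvec^2))
    u <- unit(cb[i, ] - ca[i, ])
    costh <- (dvec %*% u) / pmax(d, 1e-9)
    counts[i] <- sum(neighbor_weight(d, acos(pmax(-1, pmin(1, costh)))))
  }
  out <- data.frame(chain_id = vapply(res, function(r) r$chain_id, ""),
                    seq_index = vapply(res, function(r) r$seq_index, 0L),
                    neighbor_count = counts,
                    layer = layer_label(counts, surface_cutoff, core_cutoff),
                    stringsAsFactors = FALSE)
  attr(out, "surface_cutoff") <- surface_cutoff
  attr(out, "core_cutoff") <- core_cutoff
  class(out) <- c("LayerAssignment", "data.frame")
  out
}

#' Depth score of a matched binding site
#'
#' The number of boundary residues plus two times the number of core
#' residues, over the layers of the matched scaffold positions. A site
#' matched entirely to surface positions scores 0; a 3-residue site ranges
#' from 0 to 6.
#'
#' @param match A `MatchResult` (or an integer vector of matched scaffold
#'   residue indices).
#' @param layers A [assign_layers()] result for the scaffold.
#' @return Integer depth score.
#' @export
depth_score <- function(match, layers) {
  idx <- if (inherits(match, "MatchResult")) match$correspondence else as.integer(match)
  if (any(idx < 1L | idx > nrow(layers)))
    stop("matched position without a layer assignment")
  lay <- layers$layer[idx]
  as.integer(sum(lay == "boundary") + 2L * sum(lay == "core"))
}

#' Simplified 3-state secondary structure assignment
#'
#' Deterministic dihedral-window labels: residues with (phi, psi) in the
#' alpha-helical window (phi in \[-100, -30\], psi in \[-80, 0\] degrees) are
#' `"helix"`, in the extended window (phi in \[-170, -90\], psi in
#' \[90, 180\]) are `"strand"`, and everything else -- including chain
#' termini, where a dihedral is undefined -- is `"loop"`. This is a
#' backbone-dihedral heuristic, not a hydrogen-bond-based assignment, and
#' will disagree with DSSP near secondary-structure ends.
#'
#' @param scaffold A [new_structure()].
#' @return Character vector of per-residue labels (residue order).
#' @export
assign_secondary_structure <- function(scaffold) {
  stopifnot(inherits(scaffold, "Structure"))
  res <- scaffold$residues
  n <- length(res)
  labels <- rep("loop", n)
  if (n < 3L) return(labels)
  chains <- vapply(res, function(r) r$chain_id, "")
  for (i in seq_len(n)) {
    if (i == 1L || i == n) next
    prev <- res[[i - 1L]]; cur <- res[[i]]; nxt <- res[[i + 1L]]
    if (chains[i - 1L] != chains[i] || chains[i + 1L] != chains[i]) next
    if (!prev$matchable || !cur$matchable || !nxt$matchable) next
    phi <- dihedral_angle(prev$c, cur$n, cur$ca, cur$c) * 180 / pi
    psi <- dihedral_angle(cur$n, cur$ca, cur$c, nxt$n) * 180 / pi
    if (phi >= -100 && phi <= -30 && psi >= -80 && psi <= 0)
      labels[i] <- "helix"
    else if (phi >= -170 && phi <= -90 && psi >= 90 && psi <= 180)
      labels[i] <- "strand"
  }
  labels
}
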