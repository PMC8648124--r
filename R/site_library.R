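# Binding-site library construction. Sites are extracted from structures by
# quality filters (ligand size, B-factor, resolution, contact distance) and a
# per-residue interaction score. The score is a documented proxy on heavy
# atoms -- an attractive-only 6-12 well, Coulomb electrostatics with a
# distance-dependent dielectric on a small formal/partial charge table, and a
# distance-and-angle gated hydrogen-bond bonus -- standing in for a full
# molecular-mechanics two-body energy. Its scale is its own; the inclusion and
# quality thresholds are configurable for that reason, and library membership
# on real structures will not numerically match counts obtained with other
# energy functions.

#' Library construction configuration
#'
#' Defaults mirror the standard extraction filters: ligands with at most 100
#' heavy atoms, average heavy-atom B-factor at most 60 A^2, structures at
#' resolution better than 2 A, protein contacts within 5 A of the ligand,
#' residue inclusion below -1 energy units, residue quality rejection above
#' +50 energy units, and at least 2 residues per site.
#'
#' @param max_ligand_heavy_atoms,max_avg_bfactor,resolution_cutoff,contact_radius
#'   Ligand/structure filters (see above).
#' @param include_threshold A residue joins the site when its total proxy
#'   score is below this (negative) value.
#' @param residue_quality_cutoff Residues whose score including steric
#'   repulsion exceeds this are treated as poorly modeled and excluded.
#' @param min_site_residues Minimum residues per extracted site.
#' @param require_resolution If `TRUE`, ligands in structures without a
#'   resolution record are skipped (with a warning) instead of passing the
#'   resolution filter vacuously.
#' @return An object of class `"LibraryConfig"`.
#' @export
library_config <- function(max_ligand_heavy_atoms = 100L,
                           max_avg_bfactor = 60,
                           resolution_cutoff = 2.0,
                           contact_radius = 5.0,
                           include_threshold = -1.0,
                           residue_quality_cutoff = 50,
                           min_site_residues = 2L,
                           require_resolution = FALSE) {
  if (max_ligand_heavy_atoms <= 0 || max_avg_bfactor <= 0 ||
      resolution_cutoff <= 0 || contact_radius <= 0 ||
      residue_quality_cutoff <= 0 || min_site_residues <= 0)
    stop("all cutoffs must be strictly positive")
  if (include_threshold >= 0)
    stop("include_threshold must be negative (favorable interaction)")
  structure(list(max_ligand_heavy_atoms = as.integer(max_ligand_heavy_atoms),
                 max_avg_bfactor = max_avg_bfactor,
                 resolution_cutoff = resolution_cutoff,
                 contact_radius = contact_radius,
                 include_threshold = include_threshold,
                 residue_quality_cutoff = residue_quality_cutoff,
                 min_site_residues = as.integer(min_site_residues),
                 require_resolution = isTRUE(require_resolution)),
            class = "LibraryConfig")
}

#' Parameters of the interaction-score proxy
#'
#' @param lj_radii Named per-element radius table (Angstrom).
#' @param lj_eps Well depth of the 6-12 term (energy units).
#' @param lj_max_dist Pair cutoff for the 6-12 term (Angstrom).
#' @param coulomb_k Coulomb prefactor with the distance-dependent dielectric
#'   folded in (energy units x A^2 / e^2).
#' @param hb_bonus Hydrogen-bond bonus at ideal distance (negative).
#' @return An object of class `"ScoringParams"`.
#' @export
scoring_params <- function(lj_radii = default_lj_radii(), lj_eps = 0.5,
                           lj_max_dist = 8, coulomb_k = 33.2, hb_bonus = -1.0) {
  structure(list(lj_radii = lj_radii, lj_eps = lj_eps,
                 lj_max_dist = lj_max_dist, coulomb_k = coulomb_k,
                 hb_bonus = hb_bonus),
            class = "ScoringParams")
}

# formal/partial charges: protein side by residue + atom name (charged groups
# only), ligand side by element, single-atom metal ions by ionic charge
PROTEIN_CHARGES <- list(
  D = c(OD1 = -0.5, OD2 = -0.5),
  E = c(OE1 = -0.5, OE2 = -0.5),
  K = c(NZ = 1.0),
  R = c(NH1 = 0.5, NH2 = 0.5)
)

ELEMENT_CHARGES <- c(O = -0.3, N = 0.2, P = 0.4, S = -0.1,
                     F = -0.3, CL = -0.3, BR = -0.3, I = -0.3)

METAL_CHARGES <- c(MG = 2, ZN = 2, CA = 2, MN = 2, FE = 2, CU = 2, NI = 2,
                   CO = 2, "NA" = 1, K = 1)

residue_charges <- function(residue) {
  q <- rep(0, nrow(residue$atoms))
  tab <- PROTEIN_CHARGES[[residue$aa]]
  if (!is.null(tab)) {
    i <- match(names(tab), residue$atoms$name)
    q[i[!is.na(i)]] <- tab[!is.na(i)]
  }
  q
}

ligand_charges <- function(ligand) {
  el <- ligand$atoms$element
  if (nrow(ligand$atoms) == 1L && el %in% names(METAL_CHARGES))
    return(unname(METAL_CHARGES[el]))
  q <- ELEMENT_CHARGES[el]
  q[is.na(q)] <- 0
  unname(q)
}

# donor/acceptor heavy atoms: N and O on both partners
is_polar <- function(elements) elements %in% c("N", "O")

hb_distance_weight <- function(d) {
  w <- numeric(length(d))
  w[d >= 2.7 & d <= 3.1] <- 1
  ramp_lo <- d >= 2.4 & d < 2.7
  w[ramp_lo] <- (d[ramp_lo] - 2.4) / 0.3
  ramp_hi <- d > 3.1 & d <= 3.5
  w[ramp_hi] <- (3.5 - d[ramp_hi]) / 0.4
  w
}

#' Score the interaction between a protein residue and a ligand
#'
#' Heavy-atom pairwise proxy score with three components: `attraction`
#' (attractive-only 6-12 well, <= 0 by construction), `electrostatic`
#' (Coulomb with a distance-dependent dielectric on a small charge table) and
#' `hbond` (distance- and angle-gated donor/acceptor bonus). `total` is their
#' sum; `repulsion` (the positive part of the 6-12 term) is reported
#' separately and used only for residue quality filtering. The score is
#' invariant under joint rigid transforms of both partners, and exactly zero
#' for partners beyond all cutoffs.
#'
#' @param residue A [new_residue()] with heavy atoms.
#' @param ligand A non-empty [new_ligand()].
#' @param params A [scoring_params()] set.
#' @return An object of class `"InteractionScore"`.
#' @export
score_interaction <- function(residue, ligand, params = scoring_params()) {
  if (nrow(residue$atoms) == 0L || nrow(ligand$atoms) == 0L)
    stop("residue and ligand must have heavy atoms")
  rx <- atom_coords(residue$atoms)
  lx <- atom_coords(ligand$atoms)
  rrad <- element_radii(residue$atoms$element, params$lj_radii)
  lrad <- element_radii(ligand$atoms$element, params$lj_radii)
  rq <- residue_charges(residue)
  lq <- ligand_charges(ligand)

  d <- sqrt(outer(rowSums(rx^2), rep(1, nrow(lx))) +
            outer(rep(1, nrow(rx)), rowSums(lx^2)) - 2 * rx %*% t(lx))
  d <- pmax(d, 1e-6)

  rmin <- outer(rrad, lrad, "+")
  lj <- params$lj_eps * ((rmin / d)^12 - 2 * (rmin / d)^6)
  lj[d > params$lj_max_dist] <- 0
  attraction <- sum(pmin(lj, 0))
  repulsion <- sum(pmax(lj, 0))

  qq <- outer(rq, lq)
  elec <- params$coulomb_k * qq / d^2
  elec[d > params$lj_max_dist] <- 0
  electrostatic <- sum(elec)

  hbond <- 0
  polar_pairs <- which(outer(is_polar(residue$atoms$element),
                             is_polar(ligand$atoms$element), "&") &
                       d >= 2.4 & d <= 3.5, arr.ind = TRUE)
  if (nrow(polar_pairs) > 0) {
    for (k in seq_len(nrow(polar_pairs))) {
      i <- polar_pairs[k, 1]; j <- polar_pairs[k, 2]
      # angle gate at the ligand acceptor/donor: the contact must come from
      # the far side of its covalent neighbor (angle > 90 deg); single atoms
      # (no neighbor within 1.8 A) pass unconditionally
      ok <- TRUE
      if (nrow(lx) > 1) {
        dn <- sqrt(rowSums(sweep(lx, 2, lx[j, ])^2))
        dn[j] <- Inf
        nb <- which.min(dn)
        if (dn[nb] < 1.8)
          ok <- vector_angle(lx[nb, ] - lx[j, ], rx[i, ] - lx[j, ]) > pi / 2
      }
      if (ok) hbond <- hbond + params$hb_bonus * hb_distance_weight(d[i, j])
    }
  }

  structure(list(attraction = attraction, electrostatic = electrostatic,
                 hbond = hbond, total = attraction + electrostatic + hbond,
                 repulsion = repulsion),
            class = "InteractionScore")
}

#' @export
print.InteractionScore <- function(x, ...) {
  cat(sprintf("InteractionScore: total %.3f (attraction %.3f, electrostatic %.3f, hbond %.3f; repulsion %.3f)\n",
              x$total, x$attraction, x$electrostatic, x$hbond, x$repulsion))
  invisible(x)
}

residue_is_complete <- function(residue) {
  expected <- AA_HEAVY_COUNT[residue$aa]
  if (is.na(expected)) return(TRUE)   # non-standard: no reference count
  nrow(residue$atoms) >= expected
}

#' Extract ligand binding sites from a structure
#'
#' For each ligand passing the size, B-factor and resolution filters, site
#' residues are the protein residues with at least one heavy atom within
#' `contact_radius` of any ligand heavy atom whose total proxy score is below
#' `include_threshold`, excluding residues with missing heavy atoms or
#' clash-dominated scores above `residue_quality_cutoff`. Sites with fewer
#' than `min_site_residues` residues are dropped, and duplicate ligands in
#' one structure (same residue name and same binding-residue amino-acid
#' multiset) yield a single site.
#'
#' @param structure A [new_structure()] object.
#' @param config A [library_config()].
#' @param params A [scoring_params()] set.
#' @return List of [new_binding_site()] objects (possibly empty).
#' @export
extract_binding_sites <- function(structure, config = library_config(),
                                  params = scoring_params()) {
  stopifnot(inherits(structure, "Structure"))
  sites <- list()
  seen <- character()
  if (is.na(structure$resolution)) {
    if (config$require_resolution && length(structure$ligands) > 0L) {
      warning("structure '", structure$id,
              "' has no resolution record; skipping site extraction")
      return(sites)
    }
  } else if (structure$resolution > config$resolution_cutoff) {
    return(sites)
  }
  for (lg in structure$ligands) {
    nh <- ligand_heavy_atoms(lg)
    if (nh < 1L || nh > config$max_ligand_heavy_atoms) next
    if (mean(lg$atoms$b) > config$max_avg_bfactor) next
    lx <- atom_coords(lg$atoms)
    contact <- vapply(structure$residues, function(r) {
      rx <- atom_coords(r$atoms)
      min(sqrt(outer(rowSums(rx^2), rep(1, nrow(lx))) +
               outer(rep(1, nrow(rx)), rowSums(lx^2)) -
               2 * rx %*% t(lx))) <= config$contact_radius
    }, TRUE)
    if (!any(contact)) next
    idx <- which(contact)
    keep <- integer(); scores <- numeric()
    for (i in idx) {
      r <- structure$residues[[i]]
      if (!residue_is_complete(r)) next
      sc <- score_interaction(r, lg, params)
      if (sc$total + sc$repulsion > config$residue_quality_cutoff) next
      if (sc$total < config$include_threshold) {
        keep <- c(keep, i); scores <- c(scores, sc$total)
      }
    }
    if (length(keep) < config$min_site_residues) next
    key <- paste(lg$resname,
                 paste(sort(vapply(structure$residues[keep], function(r) r$aa, "")),
                       collapse = ""), sep = ":")
    if (key %in% seen) next
    seen <- c(seen, key)
    sites[[length(sites) + 1L]] <-
      new_binding_site(lg, structure$residues[keep],
                       source_id = structure$id, scores = scores)
  }
  sites
}

#' Reduce a binding site to its k strongest-interacting residues
#'
#' Keeps the `k` residues with the lowest total interaction scores (ties
#' broken by score then sequence index, ascending); the ligand is untouched.
#' Sites with fewer than `k` residues are rejected (`NULL`), matching the
#' construction of fixed-size site libraries which eliminates smaller sites.
#'
#' @param site A [new_binding_site()] with per-residue scores.
#' @param k Number of residues to keep (>= 2).
#' @return A `BindingSite` with exactly `k` residues, or `NULL`.
#' @export
select_top_k <- function(site, k = 3L) {
  stopifnot(inherits(site, "BindingSite"))
  if (k < 2L) stop("k must be >= 2")
  n <- site_size(site)
  if (n < k) return(NULL)
  if (n == k) return(site)
  if (anyNA(site$scores)) stop("site has no per-residue scores")
  seq_idx <- vapply(site$residues, function(r) r$seq_index, 0L)
  ord <- order(site$scores, seq_idx)[seq_len(k)]
  ord <- sort(ord)  # preserve residue order within the site
  new_binding_site(site$ligand, site$residues[ord], site$source_id,
                   site$scores[ord])
}

#' Mean primary-sequence distance between binding-site residues
#'
#' Mean over all unordered residue pairs of the absolute difference of their
#' sequential indices. Three consecutive residues (i, i+1, i+2) give
#' (1 + 1 + 2) / 3 = 4/3, i.e. 1.33.
#'
#' @param site A [new_binding_site()] with >= 2 residues on one chain.
#' @return Mean pairwise sequence separation (residues).
#' @export
mean_sequence_distance <- function(site) {
  stopifnot(inherits(site, "BindingSite"))
  if (site_size(site) < 2L) stop("need at least 2 residues")
  chains <- vapply(site$residues, function(r) r$chain_id, "")
  if (length(unique(chains)) > 1L)
    stop("sequence distance is undefined for residues on different chains")
  idx <- vapply(site$residues, function(r) r$seq_index, 0L)
  mean(abs(utils::combn(idx, 2, FUN = diff)))
}

#' Amino-acid composition of a set of binding sites
#'
#' @param sites Non-empty list of [new_binding_site()] objects.
#' @return Named numeric vector of frequencies over the residues of all
#'   sites (sums to 1); amino acids absent from the sites get 0.
#' @export
aa_composition <- function(sites) {
  if (length(sites) == 0L) stop("need at least one binding site")
  aa <- unlist(lapply(sites, function(s)
    vapply(s$residues, function(r) r$aa, "")))
  freq <- stats::setNames(rep(0, length(AA3)), unname(AA3))
  tab <- table(aa) / length(aa)
  freq[names(tab)] <- as.numeric(tab)
  freq
}

#' Write a site library to disk
#'
#' One PDB per site (ligand + residues) plus a TSV manifest with source id,
#' ligand name, heavy-atom count, residue list, total score and mean sequence
#' distance.
#'
#' @param sites List of [new_binding_site()] objects.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
write_site_library <- function(sites, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(sites), function(i) {
    s <- sites[[i]]
    fn <- sprintf("site_%04d.pdb", i)
    write_pdb(new_structure(sprintf("site_%04d", i), s$residues,
                            list(s$ligand), resolution = NA),
              file.path(dir, fn))
    msd <- tryCatch(mean_sequence_distance(s), error = function(e) NA_real_)
    data.frame(site = fn, source_id = s$source_id, ligand = s$ligand$resname,
               heavy_atoms = ligand_heavy_atoms(s$ligand),
               residues = paste(vapply(s$residues, function(r)
                 sprintf("%s%d", r$aa, r$seq_index), ""), collapse = ","),
               total_score = sum(s$scores), mean_seq_distance = msd,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
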