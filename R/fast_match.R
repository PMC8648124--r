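# The fast match protocol: rigid-body placement of a binding site onto a
# scaffold. For every (site residue, scaffold residue) anchor pair the site is
# superposed onto the scaffold via the anchor's N/CA/C atoms and then passes
# through four gates in order:
#   1. every site residue must have a scaffold CA within 2 A (and the
#      nearest-residue correspondence must be injective),
#   2. least-squares superposition of all site N/CA/C onto the corresponding
#      scaffold N/CA/C must give RMSD <= 1 A,
#   3. every corresponding CA->CB direction cosine must exceed 0.7,
#   4. the placed ligand and site side chains must not clash with the
#      backbone of scaffold residues outside the correspondence
#      (clash: distance < 0.6 x sum of Lennard-Jones radii).

#' Default per-element Lennard-Jones radii (Angstrom)
#'
#' Used by the clash gate and the interaction-score proxy. Carbon 2.0,
#' nitrogen 1.75, oxygen 1.55, sulfur 1.9, phosphorus 2.1, halogens at
#' standard van der Waals radii, common metals at ionic radii. Override by
#' passing a modified table in [fast_match_config()].
#' @return Named numeric vector of radii.
#' @export
default_lj_radii <- function() {
  c(C = 2.0, N = 1.75, O = 1.55, S = 1.9, P = 2.1,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
    MG = 0.72, ZN = 0.74, "NA" = 1.02, K = 1.38, CA = 1.0, MN = 0.83,
    FE = 0.78, CU = 0.73, NI = 0.69, CO = 0.75, SE = 1.9)
}

#' Fast-match configuration
#'
#' @param ca_distance_cutoff Nearest scaffold CA gate in Angstrom (default 2).
#' @param backbone_rmsd_cutoff Backbone N/CA/C RMSD gate in Angstrom (default 1).
#' @param cb_cosine_cutoff CA->CB direction cosine gate (default 0.7).
#' @param clash_scale Scale factor on the sum of Lennard-Jones radii
#'   defining a clash (default 0.6).
#' @param lj_radii Named per-element radius table ([default_lj_radii()]).
#' @return An object of class `"FastMatchConfig"`.
#' @export
fast_match_config <- function(ca_distance_cutoff = 2.0,
                              backbone_rmsd_cutoff = 1.0,
                              cb_cosine_cutoff = 0.7,
                              clash_scale = 0.6,
                              lj_radii = default_lj_radii()) {
  if (ca_distance_cutoff <= 0 || backbone_rmsd_cutoff <= 0)
    stop("distance cutoffs must be positive")
  if (cb_cosine_cutoff <= -1 || cb_cosine_cutoff >= 1)
    stop("cb_cosine_cutoff must be in (-1, 1)")
  if (clash_scale <= 0 || clash_scale > 1)
    stop("clash_scale must be in (0, 1]")
  structure(list(ca_distance_cutoff = ca_distance_cutoff,
                 backbone_rmsd_cutoff = backbone_rmsd_cutoff,
                 cb_cosine_cutoff = cb_cosine_cutoff,
                 clash_scale = clash_scale,
                 lj_radii = lj_radii),
            class = "FastMatchConfig")
}

element_radii <- function(elements, table) {
  r <- table[elements]
  if (anyNA(r))
    stop("element(s) missing from the Lennard-Jones radius table: ",
         paste(unique(elements[is.na(r)]), collapse = ", "))
  unname(r)
}

# ---- precomputed geometry --------------------------------------------------

# flatten the matchable residues of a scaffold into coordinate blocks
scaffold_geometry <- function(scaffold) {
  idx <- which(vapply(scaffold$residues, function(r) isTRUE(r$matchable), TRUE))
  if (length(idx) == 0L) stop("scaffold has no matchable residues")
  res <- scaffold$residues[idx]
  list(idx = idx,
       ca = t(vapply(res, function(r) r$ca, numeric(3))),
       bb = lapply(res, function(r) rbind(r$n, r$ca, r$c)),
       cb = t(vapply(res, function(r) r$cb, numeric(3))),
       bb_atoms = do.call(rbind, lapply(seq_along(res), function(i) {
         a <- res[[i]]$atoms[res[[i]]$atoms$name %in% c("N", "CA", "C", "O"), , drop = FALSE]
         cbind(atom_coords(a), res = idx[i])
       })),
       bb_elements = unlist(lapply(res, function(r)
         r$atoms$element[r$atoms$name %in% c("N", "CA", "C", "O")])))
}

# site geometry: backbone triads, CA, CB, and the mobile atoms for clashes
# (ligand heavy atoms + side-chain heavy atoms, i.e. atoms not named N/CA/C/O)
site_geometry <- function(site) {
  res <- site$residues
  ok <- vapply(res, function(r) isTRUE(r$matchable), TRUE)
  if (!all(ok)) stop("all binding-site residues must have full N, CA, C backbones")
  sc <- do.call(rbind, lapply(res, function(r) {
    a <- r$atoms[!(r$atoms$name %in% c("N", "CA", "C", "O")), , drop = FALSE]
    atom_coords(a)
  }))
  sc_elem <- unlist(lapply(res, function(r)
    r$atoms$element[!(r$atoms$name %in% c("N", "CA", "C", "O"))]))
  list(n = length(res),
       ca = t(vapply(res, function(r) r$ca, numeric(3))),
       bb = do.call(rbind, lapply(res, function(r) rbind(r$n, r$ca, r$c))),
       cb = t(vapply(res, function(r) r$cb, numeric(3))),
       mobile = rbind(atom_coords(site$ligand$atoms), sc),
       mobile_elem = c(site$ligand$atoms$element, sc_elem))
}

# ---- public operations -----------------------------------------------------

#' Anchor a binding site onto a scaffold residue
#'
#' Least-squares superposes the N, CA and C atoms of one binding-site residue
#' onto those of a scaffold residue and applies the resulting rigid transform
#' to the whole site (ligand and all residues).
#'
#' @param site A [new_binding_site()] object.
#' @param site_res Index of the anchor residue within the site.
#' @param scaffold_res A [new_residue()] (the scaffold anchor), with full
#'   backbone.
#' @return The transformed `BindingSite`.
#' @export
anchor_align <- function(site, site_res, scaffold_res) {
  r <- site$residues[[site_res]]
  if (!isTRUE(r$matchable) || !isTRUE(scaffold_res$matchable))
    stop("anchor residues must have N, CA and C atoms")
  tf <- superpose(rbind(r$n, r$ca, r$c),
                  rbind(scaffold_res$n, scaffold_res$ca, scaffold_res$c))$transform
  apply_transform(site, tf)
}

#' Nearest scaffold residue for each binding-site residue
#'
#' Distances are CA--CA; ties are broken by the lower scaffold residue index.
#' The site must already be placed in the scaffold coordinate frame.
#'
#' @param site A placed [new_binding_site()].
#' @param scaffold A [new_structure()] with at least one matchable residue.
#' @return Data frame with columns `site_res`, `scaffold_res` (index into
#'   `scaffold$residues`) and `distance` (Angstrom).
#' @export
nearest_scaffold_residues <- function(site, scaffold) {
  sg <- scaffold_geometry(scaffold)
  ca <- t(vapply(site$residues, function(r) r$ca, numeric(3)))
  nn <- nearest_from_geometry(ca, sg)
  data.frame(site_res = seq_len(nrow(ca)),
             scaffold_res = nn$idx, distance = nn$dist)
}

nearest_from_geometry <- function(site_ca, sg) {
  idx <- integer(nrow(site_ca)); dist <- numeric(nrow(site_ca))
  for (i in seq_len(nrow(site_ca))) {
    d2 <- rowSums(sweep(sg$ca, 2, site_ca[i, ])^2)
    j <- which.min(d2)  # which.min returns the first (lowest-index) minimum
    idx[i] <- sg$idx[j]; dist[i] <- sqrt(d2[j])
  }
  list(idx = idx, dist = dist, local = match(idx, sg$idx))
}

#' Steric clash check for a placed binding site
#'
#' Compares the ligand heavy atoms and site side-chain heavy atoms against
#' the backbone heavy atoms (N, CA, C, O) of scaffold residues that are not
#' part of the correspondence. Two atoms clash when their distance is less
#' than `clash_scale` times the sum of their Lennard-Jones radii. C-beta is
#' treated as designable side chain on the scaffold and is not part of the
#' backbone set.
#'
#' @param site A placed [new_binding_site()].
#' @param scaffold A [new_structure()].
#' @param correspondence Integer vector of scaffold residue indices matched
#'   to the site residues (must be injective).
#' @param config A [fast_match_config()].
#' @return `TRUE` when clash-free.
#' @export
clash_check <- function(site, scaffold, correspondence, config = fast_match_config()) {
  if (anyDuplicated(correspondence)) stop("correspondence must be injective")
  st <- site_geometry(site)
  sg <- scaffold_geometry(scaffold)
  clash_free(st$mobile, st$mobile_elem, sg, correspondence, config)
}

clash_free <- function(mobile, mobile_elem, sg, correspondence, config) {
  keep <- !(sg$bb_atoms[, "res"] %in% correspondence)
  if (!any(keep)) return(TRUE)
  bb <- sg$bb_atoms[keep, 1:3, drop = FALSE]
  rad_bb <- element_radii(sg$bb_elements[keep], config$lj_radii)
  rad_mb <- element_radii(mobile_elem, config$lj_radii)
  for (i in seq_len(nrow(mobile))) {
    d <- sqrt(rowSums(sweep(bb, 2, mobile[i, ])^2))
    if (any(d < config$clash_scale * (rad_mb[i] + rad_bb))) return(FALSE)
  }
  TRUE
}

new_match_result <- function(scaffold_id, anchor, correspondence,
                             backbone_rmsd, cb_cosines, transform,
                             rejected_stage) {
  structure(list(scaffold_id = scaffold_id, anchor = anchor,
                 correspondence = correspondence,
                 backbone_rmsd = backbone_rmsd, cb_cosines = cb_cosines,
                 transform = transform, rejected_stage = rejected_stage),
            class = "MatchResult")
}

#' @export
print.MatchResult <- function(x, ...) {
  if (x$rejected_stage == "none")
    cat(sprintf("MatchResult: accepted on '%s' at positions [%s], RMSD %.3f A, min cosine %.3f\n",
                x$scaffold_id, paste(x$correspondence, collapse = ","),
                x$backbone_rmsd, min(x$cb_cosines)))
  else
    cat(sprintf("MatchResult: rejected at stage '%s' (anchor %d->%d) on '%s'\n",
                x$rejected_stage, x$anchor[1], x$anchor[2], x$scaffold_id))
  invisible(x)
}

#' Fast match a binding site onto a scaffold
#'
#' Enumerates all (site residue, scaffold residue) anchor pairs and passes
#' each placement through the anchor-distance, backbone-RMSD, CA->CB cosine
#' and clash gates (see the package vignette). Accepted placements are
#' deduplicated by correspondence, keeping the lowest-RMSD representative.
#'
#' @param site A [new_binding_site()] with >= 2 residues with full backbones.
#' @param scaffold A [new_structure()].
#' @param config A [fast_match_config()].
#' @param diagnostics If `TRUE`, all per-anchor `MatchResult`s (including
#'   rejections) are kept in the `$anchors` element.
#' @return An object of class `"FastMatchResult"`: list with `matches`
#'   (accepted [new_match_result]s), `stage_counts` (named rejection tally
#'   over anchors) and optionally `anchors`.
#' @export
fast_match_site <- function(site, scaffold, config = fast_match_config(),
                            diagnostics = FALSE) {
  stopifnot(inherits(site, "BindingSite"), inherits(scaffold, "Structure"))
  if (site_size(site) < 2L) stop("binding site must have at least 2 residues")
  st <- site_geometry(site)
  sg <- scaffold_geometry(scaffold)
  stages <- c(none = 0L, anchor_distance = 0L, rmsd = 0L, cosine = 0L, clash = 0L)
  accepted <- list()
  anchors <- if (diagnostics) list() else NULL

  for (si in seq_len(st$n)) {
    a_bb <- st$bb[(3 * si - 2):(3 * si), , drop = FALSE]
    for (pj in seq_along(sg$idx)) {
      tf1 <- superpose(a_bb, sg$bb[[pj]])$transform
      ca1 <- transform_coords(tf1, st$ca)
      nn <- nearest_from_geometry(ca1, sg)
      res <- NULL
      if (any(nn$dist > config$ca_distance_cutoff) || anyDuplicated(nn$idx)) {
        stages["anchor_distance"] <- stages["anchor_distance"] + 1L
        res <- new_match_result(scaffold$id, c(si, sg$idx[pj]), nn$idx,
                                NA_real_, NULL, tf1, "anchor_distance")
      } else {
        target_bb <- do.call(rbind, sg$bb[nn$local])
        sp <- superpose(transform_coords(tf1, st$bb), target_bb)
        tf <- compose_transforms(sp$transform, tf1)
        if (sp$rmsd > config$backbone_rmsd_cutoff) {
          stages["rmsd"] <- stages["rmsd"] + 1L
          res <- new_match_result(scaffold$id, c(si, sg$idx[pj]), nn$idx,
                                  sp$rmsd, NULL, tf, "rmsd")
        } else {
          ca_f <- transform_coords(tf, st$ca)
          cb_f <- transform_coords(tf, st$cb)
          cosines <- vapply(seq_len(st$n), function(i) {
            u <- unit(cb_f[i, ] - ca_f[i, ])
            v <- unit(sg$cb[nn$local[i], ] - sg$ca[nn$local[i], ])
            sum(u * v)
          }, 0)
          if (any(cosines <= config$cb_cosine_cutoff)) {
            stages["cosine"] <- stages["cosine"] + 1L
            res <- new_match_result(scaffold$id, c(si, sg$idx[pj]), nn$idx,
                                    sp$rmsd, cosines, tf, "cosine")
          } else if (!clash_free(transform_coords(tf, st$mobile),
                                 st$mobile_elem, sg, nn$idx, config)) {
            stages["clash"] <- stages["clash"] + 1L
            res <- new_match_result(scaffold$id, c(si, sg$idx[pj]), nn$idx,
                                    sp$rmsd, cosines, tf, "clash")
          } else {
            stages["none"] <- stages["none"] + 1L
            res <- new_match_result(scaffold$id, c(si, sg$idx[pj]), nn$idx,
                                    sp$rmsd, cosines, tf, "none")
            key <- paste(nn$idx, collapse = ",")
            if (is.null(accepted[[key]]) ||
                res$backbone_rmsd < accepted[[key]]$backbone_rmsd)
              accepted[[key]] <- res
          }
        }
      }
      if (diagnostics) anchors[[length(anchors) + 1L]] <- res
    }
  }
  out <- list(matches = unname(accepted), stage_counts = stages,
              site_id = site$source_id, scaffold_id = scaffold$id)
  if (diagnostics) out$anchors <- anchors
  structure(out, class = "FastMatchResult")
}

#' @export
print.FastMatchResult <- function(x, ...) {
  cat(sprintf("FastMatchResult: %d accepted placement(s) of site [%s] on '%s'\n",
              length(x$matches), x$site_id, x$scaffold_id))
  sc <- x$stage_counts
  cat("  anchors:", sum(sc), "| rejected:",
      paste(sprintf("%s=%d", names(sc)[-1], sc[-1]), collapse = ", "), "\n")
  invisible(x)
}

# ---- match matrix ----------------------------------------------------------

#' Construct a match matrix
#'
#' @param fast Logical site-by-scaffold outcome matrix; `NA` marks untested
#'   cells (skipped after a first success).
#' @param sites,scaffolds Row / column identifiers.
#' @param confirmed Optional logical matrix of post-confirmation outcomes;
#'   must imply `fast` on every tested cell.
#' @return An object of class `"MatchMatrix"` with per-site first-encounter
#'   numbers (`$encounter`, `NA` when a site never matches). Columns are in
#'   the order scaffolds were tested.
#' @export
new_match_matrix <- function(fast, sites = rownames(fast),
                             scaffolds = colnames(fast), confirmed = NULL) {
  fast <- as.matrix(fast)
  if (is.null(sites)) sites <- sprintf("site%03d", seq_len(nrow(fast)))
  if (is.null(scaffolds)) scaffolds <- sprintf("scaf%03d", seq_len(ncol(fast)))
  dimnames(fast) <- list(sites, scaffolds)
  if (!is.null(confirmed)) {
    confirmed <- as.matrix(confirmed)
    bad <- confirmed & !fast
    if (any(bad, na.rm = TRUE))
      stop("confirmed matches must be a subset of fast matches")
    dimnames(confirmed) <- dimnames(fast)
  }
  encounter <- apply(fast, 1, function(row) {
    i <- which(row)
    if (length(i)) i[1] else NA_integer_
  })
  structure(list(sites = sites, scaffolds = scaffolds, fast = fast,
                 confirmed = confirmed, encounter = encounter),
            class = "MatchMatrix")
}

#' @export
print.MatchMatrix <- function(x, ...) {
  cat(sprintf("MatchMatrix: %d sites x %d scaffolds; %d site(s) matched; %d untested cell(s)\n",
              length(x$sites), length(x$scaffolds),
              sum(!is.na(x$encounter)), sum(is.na(x$fast))))
  invisible(x)
}

#' Match a library of binding sites against a set of scaffolds
#'
#' Scaffolds are tested in a seed-shuffled order (recorded in the column
#' order of the result); per site the boolean outcome and the first-encounter
#' number (1-based index of the first successful scaffold in that order) are
#' recorded. With `stop_at_first`, scaffolds after a site's first success are
#' skipped and marked untested (`NA`).
#'
#' @param sites List of [new_binding_site()] objects.
#' @param scaffolds List of [new_structure()] objects.
#' @param config A [fast_match_config()].
#' @param stop_at_first Skip remaining scaffolds after a site's first match.
#' @param seed Integer seed for the scaffold iteration order.
#' @return A `MatchMatrix` ([new_match_matrix()]).
#' @export
match_library <- function(sites, scaffolds, config = fast_match_config(),
                          stop_at_first = FALSE, seed = 1L) {
  if (length(sites) == 0L || length(scaffolds) == 0L)
    stop("sites and scaffolds must be non-empty")
  ord <- with_seed(seed, sample(length(scaffolds)))
  scaffolds <- scaffolds[ord]
  scaf_ids <- vapply(scaffolds, function(s) s$id, "")
  site_ids <- vapply(seq_along(sites), function(i) {
    id <- sites[[i]]$source_id
    if (nzchar(id)) sprintf("%s#%d", id, i) else sprintf("site%03d", i)
  }, "")
  fast <- matrix(NA, length(sites), length(scaffolds))
  for (i in seq_along(sites)) {
    for (j in seq_along(scaffolds)) {
      fm <- fast_match_site(sites[[i]], scaffolds[[j]], config)
      fast[i, j] <- length(fm$matches) > 0L
      if (stop_at_first && fast[i, j]) break
    }
  }
  new_match_matrix(fast, sites = site_ids, scaffolds = scaf_ids)
}

#' Tabulate fast-match results
#'
#' @param x A `FastMatchResult` (run with `diagnostics = TRUE` to include
#'   rejected anchors).
#' @param ... Unused.
#' @return Data frame with columns `site_id`, `scaffold_id`, `anchor_site`,
#'   `anchor_scaffold`, `correspondence`, `rmsd`, `min_cosine`, `accepted`,
#'   `rejected_stage`.
#' @export
as.data.frame.FastMatchResult <- function(x, ...) {
  rows <- if (!is.null(x$anchors)) x$anchors else x$matches
  if (length(rows) == 0L)
    return(data.frame(site_id = character(), scaffold_id = character(),
                      anchor_site = integer(), anchor_scaffold = integer(),
                      correspondence = character(), rmsd = numeric(),
                      min_cosine = numeric(), accepted = logical(),
                      rejected_stage = character(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(rows, function(m) {
    data.frame(site_id = x$site_id, scaffold_id = m$scaffold_id,
               anchor_site = m$anchor[1], anchor_scaffold = m$anchor[2],
               correspondence = paste(m$correspondence, collapse = ","),
               rmsd = m$backbone_rmsd,
               min_cosine = if (is.null(m$cb_cosines)) NA_real_ else min(m$cb_cosines),
               accepted = m$rejected_stage == "none",
               rejected_stage = m$rejected_stage, stringsAsFactors = FALSE)
  }))
}
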