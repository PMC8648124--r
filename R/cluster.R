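# Ligand clustering: fixed-length bit fingerprints of ligand 3D structure,
# Tanimoto distances, and Butina (greedy leader) clustering at a fixed
# distance cutoff. The default fingerprint backend is an in-repo 3D
# shell-hashing scheme -- for each atom, the multiset of (element, binned
# distance) pairs inside growing radial shells is hashed to a bit -- which is
# deterministic and rotation/translation invariant. Backends are pluggable so
# an external 3D fingerprint (e.g. an E3FP implementation) can be substituted.

#' Construct a fingerprint
#'
#' @param bits Logical (or 0/1) vector.
#' @param ligand_id Identifier string.
#' @return An object of class `"Fingerprint"`.
#' @export
new_fingerprint <- function(bits, ligand_id = "") {
  structure(list(bits = as.logical(bits), ligand_id = as.character(ligand_id)),
            class = "Fingerprint")
}

#' @export
print.Fingerprint <- function(x, ...) {
  cat(sprintf("Fingerprint '%s': %d/%d bits set\n",
              x$ligand_id, sum(x$bits), length(x$bits)))
  invisible(x)
}

# deterministic string hash into [1, nbits]; Horner scheme mod a Mersenne prime
hash_to_bit <- function(s, nbits) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  (h %% nbits) + 1L
}

#' Fingerprint a ligand
#'
#' @param ligand A [new_ligand()] with >= 1 heavy atom.
#' @param backend Fingerprint backend identifier; `"shell3d"` is the built-in
#'   scheme described above. Unknown backends raise an error.
#' @param nbits Fingerprint length (default 1024).
#' @param shell_width Radial shell width in Angstrom.
#' @param n_shells Number of shells per atom.
#' @param id Ligand identifier carried on the fingerprint.
#' @return A [new_fingerprint()].
#' @export
fingerprint_ligand <- function(ligand, backend = "shell3d", nbits = 1024L,
                               shell_width = 1.0, n_shells = 8L,
                               id = ligand$source) {
  stopifnot(inherits(ligand, "Ligand"))
  if (ligand_heavy_atoms(ligand) < 1L) stop("ligand has no heavy atoms")
  if (!identical(backend, "shell3d"))
    stop("unknown fingerprint backend: ", backend)
  xyz <- atom_coords(ligand$atoms)
  el <- ligand$atoms$element
  bits <- rep(FALSE, nbits)
  for (i in seq_len(nrow(xyz))) {
    d <- sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2))
    d[i] <- Inf
    for (s in seq_len(n_shells)) {
      inside <- which(d <= s * shell_width)
      env <- if (length(inside))
        paste(sort(paste0(el[inside], ":", round(d[inside] / 0.5) * 0.5)),
              collapse = ",") else ""
      key <- paste(el[i], s, env, sep = "|")
      bits[hash_to_bit(key, nbits)] <- TRUE
    }
  }
  new_fingerprint(bits, id)
}

#' Tanimoto distance between two fingerprints
#'
#' One minus the Tanimoto coefficient `|a AND b| / |a OR b|`. Two all-zero
#' fingerprints have distance 0 by convention.
#'
#' @param a,b [new_fingerprint()] objects of equal length.
#' @return Distance in `[0, 1]`.
#' @export
tanimoto_distance <- function(a, b) {
  ba <- if (inherits(a, "Fingerprint")) a$bits else as.logical(a)
  bb <- if (inherits(b, "Fingerprint")) b$bits else as.logical(b)
  if (length(ba) != length(bb)) stop("fingerprint lengths differ")
  u <- sum(ba | bb)
  if (u == 0L) return(0)
  1 - sum(ba & bb) / u
}

#' Butina clustering of fingerprints
#'
#' Greedy leader clustering: neighbor lists are computed at the distance
#' cutoff, candidates are sorted by neighbor count (descending; ties broken
#' by ligand id), and the largest-neighborhood unassigned point repeatedly
#' becomes a cluster centroid, absorbing its unassigned neighbors. Singletons
#' become their own clusters. Every member lies within `cutoff` of its
#' centroid by construction.
#'
#' @param fps Non-empty list of equal-length [new_fingerprint()] objects.
#' @param cutoff Distance cutoff in `(0, 1]` (default 0.65).
#' @return An object of class `"ClusterSet"`: list with `clusters` (each a
#'   list with `centroid`, `members`, `distances` -- ids and member-to-
#'   centroid distances), ordered by size descending, and `cutoff`.
#' @export
butina_cluster <- function(fps, cutoff = 0.65) {
  if (length(fps) == 0L) stop("need at least one fingerprint")
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]")
  n <- length(fps)
  ids <- vapply(seq_len(n), function(i) {
    id <- fps[[i]]$ligand_id
    if (nzchar(id)) id else sprintf("lig%03d", i)
  }, "")
  d <- matrix(0, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- tanimoto_distance(fps[[i]], fps[[j]])
    }
  }
  neighbors <- lapply(seq_len(n), function(i) setdiff(which(d[i, ] <= cutoff), i))
  counts <- lengths(neighbors)
  ord <- order(-counts, ids)
  assigned <- rep(FALSE, n)
  clusters <- list()
  for (i in ord) {
    if (assigned[i]) next
    members <- c(i, neighbors[[i]][!assigned[neighbors[[i]]]])
    assigned[members] <- TRUE
    clusters[[length(clusters) + 1L]] <-
      list(centroid = ids[i], members = ids[members],
           distances = d[i, members])
  }
  sizes <- vapply(clusters, function(cl) length(cl$members), 0L)
  cents <- vapply(clusters, function(cl) cl$centroid, "")
  clusters <- clusters[order(-sizes, cents)]
  structure(list(clusters = clusters, cutoff = cutoff), class = "ClusterSet")
}

#' @export
print.ClusterSet <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$members), 0L)
  cat(sprintf("ClusterSet: %d cluster(s) of %d ligand(s) at cutoff %.2f; sizes: %s\n",
              length(x$clusters), sum(sizes), x$cutoff,
              paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Cluster membership as a data frame
#'
#' @param x A [butina_cluster()] result.
#' @param ... Unused.
#' @return Data frame with columns `cluster_id`, `centroid`, `member`,
#'   `distance_to_centroid`.
#' @export
as.data.frame.ClusterSet <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$clusters), function(k) {
    cl <- x$clusters[[k]]
    data.frame(cluster_id = k, centroid = cl$centroid, member = cl$members,
               distance_to_centroid = cl$distances, stringsAsFactors = FALSE)
  }))
}
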