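# Data model for protein structures, ligands and binding sites, plus PDB
# reading/writing (via bio3d). Hydrogens are dropped on input: every distance
# threshold and clash check in the package operates on heavy atoms only.
# Author residue numbering is discarded; residues are renumbered 1..n per
# chain so that primary-sequence distances use contiguous counting.

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")

# heavy atom counts of complete standard residues (used as a completeness check)
AA_HEAVY_COUNT <- c(A = 5, R = 11, N = 8, D = 8, C = 6, Q = 9, E = 9, G = 4,
                    H = 10, I = 8, L = 8, K = 9, M = 8, F = 11, P = 7, S = 6,
                    T = 7, V = 7, W = 14, Y = 12)

guess_element <- function(name) {
  s <- gsub("[^A-Za-z]", "", name)
  two <- toupper(substr(s, 1, 2))
  known2 <- c("MG", "ZN", "FE", "MN", "NA", "CL", "BR", "CA", "CU", "NI",
              "CO", "SE", "CD", "HG")
  ifelse(two %in% known2 & nchar(s) == 2, two, toupper(substr(s, 1, 1)))
}

atom_df <- function(name, element, x, y, z, b = 0) {
  data.frame(name = as.character(name), element = toupper(as.character(element)),
             x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
             b = as.numeric(b), stringsAsFactors = FALSE)
}

#' Heavy-atom coordinates as a matrix
#'
#' @param atoms An atom data frame (columns `x`, `y`, `z`), e.g.
#'   `residue$atoms` or `ligand$atoms`.
#' @return An n x 3 numeric matrix.
#' @export
atom_coords <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

#' Construct a residue
#'
#' @param chain_id Chain identifier string.
#' @param seq_index 1-based sequential position within the chain.
#' @param aa One-letter amino-acid code (`"X"` for non-standard).
#' @param atoms Data frame with columns `name`, `element`, `x`, `y`, `z`, `b`
#'   (heavy atoms only).
#' @return An object of class `"Residue"`. The C-beta coordinate (`$cb`) is
#'   the real CB when present, else an ideal constructed CB; residues missing
#'   any of N, CA, C are flagged non-matchable (`$matchable = FALSE`).
#' @export
new_residue <- function(chain_id, seq_index, aa, atoms) {
  r <- structure(list(chain_id = as.character(chain_id),
                      seq_index = as.integer(seq_index),
                      aa = as.character(aa),
                      atoms = atoms),
                 class = "Residue")
  refresh_residue(r)
}

# recompute derived fields (backbone coords, CB) after any coordinate change
refresh_residue <- function(r) {
  get1 <- function(nm) {
    i <- match(nm, r$atoms$name)
    if (is.na(i)) NULL else c(r$atoms$x[i], r$atoms$y[i], r$atoms$z[i])
  }
  r$n <- get1("N"); r$ca <- get1("CA"); r$c <- get1("C"); r$o <- get1("O")
  r$matchable <- !is.null(r$n) && !is.null(r$ca) && !is.null(r$c)
  cb <- get1("CB")
  r$cb_real <- !is.null(cb)
  r$cb <- if (r$cb_real) cb else if (r$matchable) ideal_cb(r$n, r$ca, r$c) else NULL
  r
}

#' Construct an ideal C-beta for a residue
#'
#' Residue-level wrapper around [ideal_cb()]; requires backbone N, CA, C.
#' @param residue A [new_residue()] object.
#' @return The ideal C-beta position (3-vector, Angstrom).
#' @export
construct_ideal_cb <- function(residue) {
  stopifnot(inherits(residue, "Residue"))
  if (!residue$matchable)
    stop("residue is missing a backbone atom (N, CA or C)")
  ideal_cb(residue$n, residue$ca, residue$c)
}

#' Construct a ligand
#'
#' @param resname 3-letter residue code.
#' @param atoms Heavy-atom data frame (see [new_residue()]).
#' @param source Source identifier (structure id / chain).
#' @return An object of class `"Ligand"`.
#' @export
new_ligand <- function(resname, atoms, source = "") {
  structure(list(resname = as.character(resname), atoms = atoms,
                 source = as.character(source)),
            class = "Ligand")
}

#' Number of heavy atoms in a ligand
#' @param ligand A [new_ligand()] object.
#' @export
ligand_heavy_atoms <- function(ligand) nrow(ligand$atoms)

#' Construct a structure
#'
#' @param id Structure identifier.
#' @param residues List of [new_residue()] objects (protein residues only).
#' @param ligands List of [new_ligand()] objects.
#' @param resolution Crystallographic resolution in Angstrom, or `NA`.
#' @return An object of class `"Structure"`.
#' @export
new_structure <- function(id, residues, ligands = list(), resolution = NA_real_) {
  structure(list(id = as.character(id), residues = residues,
                 ligands = ligands, resolution = as.numeric(resolution)),
            class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  ch <- vapply(x$residues, function(r) r$chain_id, "")
  cat(sprintf("Structure '%s': %d residues in %d chain(s), %d ligand(s)",
              x$id, length(x$residues), length(unique(ch)), length(x$ligands)))
  if (!is.na(x$resolution)) cat(sprintf(", resolution %.2f A", x$resolution))
  cat("\n")
  invisible(x)
}

#' Construct a binding site
#'
#' A ligand plus its interacting protein residues, carried as one rigid unit
#' in a shared coordinate frame.
#'
#' @param ligand A [new_ligand()] object.
#' @param residues List of [new_residue()] objects (>= 2 for matching).
#' @param source_id Identifier of the source structure.
#' @param scores Optional per-residue interaction scores (parallel to
#'   `residues`; lower is more favorable).
#' @return An object of class `"BindingSite"`.
#' @export
new_binding_site <- function(ligand, residues, source_id = "",
                             scores = rep(NA_real_, length(residues))) {
  if (length(scores) != length(residues))
    stop("scores must be parallel to residues")
  structure(list(ligand = ligand, residues = residues,
                 source_id = as.character(source_id),
                 scores = as.numeric(scores)),
            class = "BindingSite")
}

#' @export
print.BindingSite <- function(x, ...) {
  labs <- vapply(x$residues, function(r)
    sprintf("%s%d%s", r$aa, r$seq_index, r$chain_id), "")
  cat(sprintf("BindingSite [%s] from '%s': ligand %s (%d heavy atoms), residues %s\n",
              x$source_id, x$ligand$source, x$ligand$resname,
              ligand_heavy_atoms(x$ligand), paste(labs, collapse = ", ")))
  invisible(x)
}

#' Number of protein residues in a binding site
#' @param site A [new_binding_site()] object.
#' @export
site_size <- function(site) length(site$residues)

# ---- coordinate plumbing ---------------------------------------------------

# apply f(coords_matrix) -> coords_matrix to every heavy atom of an object
map_coords <- function(x, f) UseMethod("map_coords")

#' @export
map_coords.Residue <- function(x, f) {
  xyz <- f(atom_coords(x$atoms))
  x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
  refresh_residue(x)
}

#' @export
map_coords.Ligand <- function(x, f) {
  xyz <- f(atom_coords(x$atoms))
  x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
  x
}

#' @export
map_coords.BindingSite <- function(x, f) {
  x$ligand <- map_coords(x$ligand, f)
  x$residues <- lapply(x$residues, map_coords, f = f)
  x
}

#' @export
map_coords.Structure <- function(x, f) {
  x$residues <- lapply(x$residues, map_coords, f = f)
  x$ligands <- lapply(x$ligands, map_coords, f = f)
  x
}

#' Apply a rigid transform to a structure, binding site, residue or ligand
#'
#' All heavy atoms (and derived C-beta positions) move jointly.
#' @param x A `Structure`, `BindingSite`, `Residue` or `Ligand`.
#' @param tf A [rigid_transform()].
#' @return The transformed object, same class.
#' @export
apply_transform <- function(x, tf) {
  stopifnot(inherits(tf, "RigidTransform"))
  map_coords(x, function(m) transform_coords(tf, m))
}

# ---- PDB I/O ---------------------------------------------------------------

#' Read a PDB file
#'
#' Parses ATOM/HETATM records through bio3d. Hydrogens are dropped; alternate
#' locations are resolved to the highest-occupancy conformer; waters are
#' excluded. Protein residues (standard amino acids in ATOM records) are
#' renumbered sequentially 1..n per chain, discarding author numbering and
#' insertion codes. Non-polymer, non-water HETATM groups become ligands.
#' Resolution is taken from a `REMARK   2 RESOLUTION.` record when present.
#'
#' @param path Path to a PDB file.
#' @return A [new_structure()] object.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
                  error = function(e) stop("PDB parse error in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("empty structure: ", path)
  elesy <- at$elesy
  elesy[is.na(elesy) | elesy == ""] <- guess_element(at$elety[is.na(elesy) | elesy == ""])
  elesy <- toupper(trimws(elesy))
  keep <- !(elesy %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]; elesy <- elesy[keep]
  if (nrow(at) == 0L) stop("empty structure (no heavy atoms): ", path)
  at$element <- elesy
  at$chain[is.na(at$chain) | at$chain == ""] <- "A"
  at$insert[is.na(at$insert)] <- ""
  at$o[is.na(at$o)] <- 1

  # altloc: keep the highest-occupancy conformer of each atom
  grp <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "|")
  ord <- order(grp, -at$o)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$resid,
                             at$elety, sep = "|")), , drop = FALSE]
  at <- at[order(match(rownames(at), rownames(pdb$atom))), , drop = FALSE]

  is_water <- at$resid %in% WATER_RESNAMES
  is_protein <- at$type == "ATOM" & at$resid %in% names(AA3)
  is_ligand <- !is_water & !is_protein & at$type == "HETATM"

  residues <- list()
  prot <- at[is_protein, , drop = FALSE]
  if (nrow(prot) > 0L) {
    rk <- paste(prot$chain, prot$resno, prot$insert, sep = "|")
    for (ch in unique(prot$chain)) {
      sub <- prot[prot$chain == ch, , drop = FALSE]
      keys <- unique(paste(sub$chain, sub$resno, sub$insert, sep = "|"))
      for (i in seq_along(keys)) {
        rows <- sub[paste(sub$chain, sub$resno, sub$insert, sep = "|") == keys[i], , drop = FALSE]
        residues[[length(residues) + 1L]] <-
          new_residue(ch, i, unname(AA3[rows$resid[1]]),
                      atom_df(trimws(rows$elety), rows$element,
                              rows$x, rows$y, rows$z, rows$b))
      }
    }
  }

  ligands <- list()
  lig <- at[is_ligand, , drop = FALSE]
  if (nrow(lig) > 0L) {
    lkeys <- unique(paste(lig$chain, lig$resno, lig$insert, lig$resid, sep = "|"))
    for (k in lkeys) {
      rows <- lig[paste(lig$chain, lig$resno, lig$insert, lig$resid, sep = "|") == k, , drop = FALSE]
      ligands[[length(ligands) + 1L]] <-
        new_ligand(rows$resid[1],
                   atom_df(trimws(rows$elety), rows$element,
                           rows$x, rows$y, rows$z, rows$b),
                   source = paste0(basename(path), ":", rows$chain[1]))
    }
  }

  if (length(residues) == 0L && length(ligands) == 0L)
    stop("empty structure: ", path)

  res_line <- grep("^REMARK   2 RESOLUTION", readLines(path, warn = FALSE), value = TRUE)
  resolution <- NA_real_
  if (length(res_line) > 0L) {
    m <- regmatches(res_line[1], regexpr("[0-9]+\\.[0-9]+", res_line[1]))
    if (length(m) == 1L) resolution <- as.numeric(m)
  }

  new_structure(sub("\\.pdb$", "", basename(path)), residues, ligands, resolution)
}

#' Write a structure to a PDB file
#'
#' ATOM records for protein residues (renumbered sequentially per chain)
#' followed by HETATM records for ligands; coordinates at standard PDB
#' precision (1e-3 Angstrom). A `REMARK   2 RESOLUTION.` record is emitted
#' when the structure carries a resolution.
#'
#' @param structure A [new_structure()] object (non-empty).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "Structure"))
  if (length(structure$residues) == 0L && length(structure$ligands) == 0L)
    stop("refusing to write an empty structure")
  rows <- list()
  aa31 <- names(AA3)
  for (r in structure$residues) {
    a <- r$atoms
    res3 <- if (r$aa %in% AA3) aa31[match(r$aa, AA3)] else "UNK"
    rows[[length(rows) + 1L]] <-
      data.frame(type = "ATOM", elety = a$name, resid = res3,
                 chain = r$chain_id, resno = r$seq_index,
                 x = a$x, y = a$y, z = a$z, b = a$b, elesy = a$element,
                 stringsAsFactors = FALSE)
  }
  hetno <- 900L
  for (lg in structure$ligands) {
    a <- lg$atoms
    hetno <- hetno + 1L
    rows[[length(rows) + 1L]] <-
      data.frame(type = "HETATM", elety = a$name, resid = lg$resname,
                 chain = "X", resno = hetno,
                 x = a$x, y = a$y, z = a$z, b = a$b, elesy = a$element,
                 stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(df[, c("x", "y", "z")]))),
                   type = df$type, resno = df$resno, resid = df$resid,
                   chain = df$chain, elety = df$elety, eleno = seq_len(nrow(df)),
                   o = rep(1, nrow(df)), b = df$b, elesy = df$elesy)
  if (!is.na(structure$resolution)) {
    lines <- readLines(path, warn = FALSE)
    writeLines(c(sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.",
                         structure$resolution), lines), path)
  }
  invisible(path)
}
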