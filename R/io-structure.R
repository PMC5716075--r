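#' Two-chain atomic structures
#'
#' Minimal coordinate container used by the interface-geometry and NOE
#' stages: a data frame of atoms (`chain`, `seqnum`, `resname`, `atom`,
#' `element`, `x`, `y`, `z` in Angstrom) plus a model number. Every atom
#' belongs to exactly one (chain, seqnum, atom) slot and coordinates must be
#' finite.
#'
#' @param atoms data frame with the columns above.
#' @param model_id model number (1 for single-model structures).
#' @return A `structure3d` object.
#' @export
structure3d <- function(atoms, model_id = 1L) {
  need <- c("chain", "seqnum", "resname", "atom", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop_ad("atoms missing columns: ",
                            paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms)[need]
  atoms$chain <- as.character(atoms$chain)
  atoms$resname <- toupper(as.character(atoms$resname))
  atoms$atom <- toupper(as.character(atoms$atom))
  atoms$element <- toupper(as.character(atoms$element))
  xyz <- as.matrix(atoms[c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop_ad("non-finite coordinates")
  key <- with(atoms, paste(chain, seqnum, atom))
  if (anyDuplicated(key))
    stop_ad("duplicate atom in same residue: ",
            key[duplicated(key)][1])
  structure(list(atoms = atoms, model_id = as.integer(model_id)),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d: %d atoms, chains %s, model %d\n",
              nrow(x$atoms),
              paste(sort(unique(x$atoms$chain)), collapse = "/"),
              x$model_id))
  invisible(x)
}

#' Number of atoms in a structure
#' @param s a [structure3d].
#' @export
n_atoms <- function(s) nrow(s$atoms)

# Coordinates of a subset of atoms as an n x 3 matrix.
#' @noRd
coords <- function(s, sel = TRUE) {
  as.matrix(s$atoms[sel, c("x", "y", "z"), drop = FALSE])
}

#' Read a PDB file into a structure3d
#'
#' Only `ATOM` records are used. Files carrying insertion codes or alternate
#' locations are rejected (synthetic fixtures never need them, and silent
#' picking would be worse than an error). Multi-model files yield the
#' requested model (first by default).
#'
#' @param path PDB file.
#' @param model model number to extract.
#' @return A [structure3d].
#' @export
read_structure <- function(path, model = 1L) {
  if (!file.exists(path)) stop_ad("no such file: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop_ad("no ATOM records in ", path)
  if (any(!is.na(at$insert) & at$insert != ""))
    stop_ad("insertion codes are not supported: ", path)
  if (any(!is.na(at$alt) & at$alt != ""))
    stop_ad("alternate locations are not supported: ", path)
  nmod <- nrow(pdb$xyz)
  if (model < 1 || model > nmod)
    stop_ad("model ", model, " not present (file has ", nmod, ")")
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  keep <- pdb$atom$type == "ATOM"
  xyz <- xyz[keep, , drop = FALSE]
  elem <- at$elesy
  fallback <- substr(gsub("[0-9]", "", at$elety), 1, 1)
  elem[is.na(elem) | elem == ""] <- fallback[is.na(elem) | elem == ""]
  structure3d(data.frame(chain = at$chain, seqnum = at$resno,
                         resname = at$resid, atom = at$elety,
                         element = elem,
                         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
              model_id = model)
}

#' Write a structure3d to a PDB file
#' @param s a [structure3d].
#' @param path output file.
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  xyz <- as.vector(t(as.matrix(a[c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = "ATOM",
                   resno = a$seqnum, resid = a$resname, chain = a$chain,
                   eleno = seq_len(nrow(a)), elety = a$atom,
                   elesy = a$element)
  invisible(path)
}
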