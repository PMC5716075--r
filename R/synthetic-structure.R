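#' Configuration for idealized beta-strand dimer fixtures
#'
#' Describes a two-chain beta-strand dimer built from idealized extended
#' backbone geometry (3.4 Angstrom rise per residue, hydrogen-bonding faces
#' alternating along the strand). Three geometries cover the symmetry
#' dichotomy of parallel-strand homodimer interfaces:
#'
#' * `c2_antiparallel` — chains related by an exact two-fold rotation
#'   perpendicular to the sheet plane; an antiparallel ladder with valid
#'   reciprocal inter-chain hydrogen bonds.
#' * `symmetric_parallel` — chains related by an exact two-fold rotation
#'   about the strand axis, strands parallel and in register; donor and
#'   acceptor positions are misaligned by construction, so no valid
#'   inter-chain backbone hydrogen bond can form.
#' * `offset_parallel` — chain B additionally shifted along the strand
#'   axis, producing a valid parallel beta-ladder (N...O about 2.9
#'   Angstrom) at the cost of breaking the two-fold symmetry.
#'
#' @param geometry one of the three geometries above.
#' @param n_strand_res residues per strand (>= 4).
#' @param register_offset residue-numbering offset of the parallel ladder
#'   (even, >= 2; the hydrogen-bonding faces alternate every other residue,
#'   so odd shifts cannot pair donors with acceptors).
#' @param strand_separation distance between the two backbone lines,
#'   Angstrom.
#' @param resid_start author number of the first residue in both chains
#'   (default 430, Loqs-like numbering).
#' @param aa_seq optional one-letter sequence applied to both chains.
#' @param face_phase parity (0 or 1) of the residue numbers whose amide
#'   H/carbonyl O face the partner strand; defaults to `resid_start %% 2`
#'   so the first residue is always on the bonded face.
#' @param seed kept for interface uniformity; the builder is deterministic.
#' @return A `sheet_dimer_config` list.
#' @export
sheet_dimer_config <- function(geometry = c("c2_antiparallel",
                                            "symmetric_parallel",
                                            "offset_parallel"),
                               n_strand_res = 11L, register_offset = 2L,
                               strand_separation = 4.1,
                               resid_start = 430L, aa_seq = NULL,
                               face_phase = resid_start %% 2, seed = 1L) {
  geometry <- match.arg(geometry)
  if (!is_count(n_strand_res) || n_strand_res < 4)
    stop_ad("n_strand_res must be >= 4")
  if (geometry == "offset_parallel" &&
      (!is_count(register_offset) || register_offset < 2 ||
       register_offset %% 2 != 0))
    stop_ad("register_offset must be even and >= 2 for offset_parallel")
  if (!is_number(strand_separation) || strand_separation < 3.5)
    stop_ad("strand_separation below 3.5 Angstrom would clash")
  if (!is.null(aa_seq) && nchar(aa_seq) != n_strand_res)
    stop_ad("aa_seq length must equal n_strand_res")
  structure(list(geometry = geometry, n_strand_res = as.integer(n_strand_res),
                 register_offset = as.integer(register_offset),
                 strand_separation = strand_separation,
                 resid_start = as.integer(resid_start), aa_seq = aa_seq,
                 face_phase = as.integer(face_phase) %% 2L, seed = seed),
            class = "sheet_dimer_config")
}

# Idealized extended-strand geometry constants (Angstrom).
.strand_geom <- list(rise = 3.4, n_x = 1.25, c_x = 1.25, o_y = 1.23,
                     h_y = 0.98, ca_pleat = 0.5, qb_z = 3.0)

# One extended strand along +x at y = 0; H/O of facing residues point +y.
build_strand <- function(resids, face_phase, aa_seq = NULL) {
  g <- .strand_geom
  f <- ifelse(resids %% 2 == face_phase, 1, -1)
  x0 <- g$rise * resids
  resname <- if (is.null(aa_seq)) rep("ALA", length(resids)) else
    unname(AA123[strsplit(toupper(aa_seq), "")[[1]]])
  resname[is.na(resname)] <- "UNK"
  per <- function(atom, element, x, y, z)
    data.frame(seqnum = resids, resname = resname, atom = atom,
               element = element, x = x, y = y, z = z)
  rbind(per("N",  "N", x0 - g$n_x, 0, 0),
        per("H",  "H", x0 - g$n_x, g$h_y * f, 0),
        per("CA", "C", x0, 0, g$ca_pleat * f),
        per("C",  "C", x0 + g$c_x, 0, 0),
        per("O",  "O", x0 + g$c_x, g$o_y * f, 0),
        per("QB", "C", x0, 0, g$qb_z * f))
}

#' Build an idealized two-chain beta-strand dimer
#'
#' Constructs chains A and B (backbone N, H, CA, C, O plus a QB side-chain
#' pseudo-atom per residue) according to the requested geometry; see
#' [sheet_dimer_config()]. Chain B is always an exact rigid-body image of
#' chain A: a two-fold rotation for the two symmetric geometries, the same
#' rotation followed by a strand-axis translation of
#' `register_offset - 1` residues for the register-shifted ladder. Any
#' non-bonded inter-atomic distance below 1.5 Angstrom aborts generation.
#'
#' @param cfg a [sheet_dimer_config()].
#' @return A [structure3d] with chains "A" and "B".
#' @export
build_sheet_dimer <- function(cfg) {
  stopifnot(inherits(cfg, "sheet_dimer_config"))
  g <- .strand_geom
  resids <- seq.int(cfg$resid_start, length.out = cfg$n_strand_res)
  a <- build_strand(resids, cfg$face_phase, cfg$aa_seq)
  b <- a
  sep <- cfg$strand_separation
  if (cfg$geometry == "c2_antiparallel") {
    # two-fold axis perpendicular to the sheet plane at x = rise * S / 2
    S <- sum(range(resids))
    S <- S - (S %% 2)
    b$x <- g$rise * S - a$x
    b$y <- sep - a$y
  } else {
    # two-fold about the strand axis: parallel strands, faces flipped
    b$y <- sep - a$y
    b$z <- -a$z
    if (cfg$geometry == "offset_parallel")
      b$x <- a$x - g$rise * (cfg$register_offset - 1)
  }
  a$chain <- "A"
  b$chain <- "B"
  s <- structure3d(rbind(a, b)[c("chain", "seqnum", "resname", "atom",
                                 "element", "x", "y", "z")])
  check_clashes(s)
  s
}

# Non-bonded clash guard: inter-chain pairs plus same-chain pairs at least
# two residues apart must stay >= 1.5 Angstrom.
check_clashes <- function(s, min_d = 1.5) {
  at <- s$atoms
  xyz <- coords(s)
  d <- as.matrix(stats::dist(xyz))
  same_chain <- outer(at$chain, at$chain, "==")
  near_seq <- abs(outer(at$seqnum, at$seqnum, "-")) < 2
  bonded_like <- same_chain & near_seq
  diag(d) <- Inf
  d[bonded_like] <- Inf
  if (any(d < min_d)) {
    i <- which(d < min_d, arr.ind = TRUE)[1, ]
    stop_ad(sprintf("steric clash: %s %s%d / %s %s%d at %.2f Angstrom",
                    at$atom[i[1]], at$chain[i[1]], at$seqnum[i[1]],
                    at$atom[i[2]], at$chain[i[2]], at$seqnum[i[2]],
                    d[i[1], i[2]]))
  }
  invisible(TRUE)
}

#' Simulate state-labelled NOE contacts from a dimer structure
#'
#' Enumerates proton/pseudo-atom pairs within the distance cutoff and
#' labels each endpoint with its chain's conformational state, emulating an
#' isotope-filtered NOESY that detects only intermolecular contacts. A 1
#' Angstrom pseudo-atom correction is added to the cutoff for contacts
#' involving side-chain pseudo-atoms (names starting with Q).
#'
#' @param s a [structure3d] containing amide protons (H) and/or pseudo
#'   side-chain atoms (QB).
#' @param state_of_chain named character vector mapping chain to state,
#'   e.g. `c(A = "A", B = "B")`.
#' @param cutoff distance cutoff, Angstrom.
#' @param mode `"filtered_intermolecular"` (inter-chain contacts only, the
#'   filtered experiment) or `"all"`.
#' @return A [noe_contacts] table.
#' @export
simulate_noe_peaks <- function(s, state_of_chain, cutoff = 5.5,
                               mode = c("filtered_intermolecular", "all")) {
  mode <- match.arg(mode)
  if (!is_number(cutoff) || cutoff <= 0) stop_ad("cutoff must be > 0")
  pairs <- enumerate_noe_pairs(s, cutoff,
                               intermolecular_only =
                                 mode == "filtered_intermolecular")
  label_noe_states(pairs, state_of_chain)
}
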