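#' Shrake-Rupley solvent-accessible surface area
#'
#' Numeric SASA with a deterministic golden-spiral sphere-point set: for
#' each atom, `n_points` points are placed on a sphere of radius
#' `r_vdw + probe` and a point counts as accessible when it lies outside
#' every neighbouring atom's probe-expanded sphere. Element van der Waals
#' radii (Angstrom): H 1.20, C 1.70, N 1.55, O 1.52, S 1.80, P 1.80.
#'
#' @param s a [structure3d].
#' @param probe probe radius, Angstrom (1.4 for water).
#' @param n_points sphere points per atom; 960 gives per-atom areas stable
#'   to well under 1%.
#' @return A `sasa_result`: list with `per_atom` and `per_residue` data
#'   frames (areas in Angstrom^2), `probe` and `n_points`.
#' @export
sasa <- function(s, probe = 1.4, n_points = 960L) {
  stopifnot(inherits(s, "structure3d"))
  radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
  at <- s$atoms
  r <- radii[at$element]
  if (anyNA(r)) {
    i <- which(is.na(r))[1]
    stop_ad("unknown element '", at$element[i], "' for atom ",
            at$atom[i], " ", at$chain[i], at$seqnum[i])
  }
  r <- unname(r) + probe
  xyz <- coords(s)
  pts <- golden_spiral_points(n_points)
  n <- nrow(at)
  # neighbour lists from the pairwise distance matrix
  D <- as.matrix(stats::dist(xyz))
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(D[i, ] < r[i] + r & seq_len(n) != i)
    if (!length(nb)) {
      area[i] <- 4 * pi * r[i]^2
      next
    }
    sp <- pts * r[i]
    sp <- sweep(sp, 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      d2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
            (sp[, 3] - xyz[j, 3])^2
      free <- free & d2 > r[j]^2
      if (!any(free)) break
    }
    area[i] <- 4 * pi * r[i]^2 * sum(free) / n_points
  }
  per_atom <- data.frame(chain = at$chain, seqnum = at$seqnum,
                         atom = at$atom, area = area)
  agg <- stats::aggregate(area ~ chain + seqnum, per_atom, sum)
  structure(list(per_atom = per_atom,
                 per_residue = agg[order(agg$chain, agg$seqnum), ],
                 probe = probe, n_points = as.integer(n_points)),
            class = "sasa_result")
}

# Deterministic quasi-uniform unit-sphere points (spherical Fibonacci).
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  rad <- sqrt(pmax(0, 1 - z^2))
  cbind(rad * cos(phi), rad * sin(phi), z)
}

#' Per-residue surface burial upon dimerization
#'
#' For each residue, the proportion of its isolated-chain SASA that is
#' buried in the complex: `(SASA_isolated - SASA_complex) / SASA_isolated`,
#' clamped to `[0, 1]`. Equivalent residues of the two subunits (same
#' author number) are averaged for the reported burial profile, while
#' interface membership sets `S_A`/`S_B` are taken per chain at
#' `burial >= threshold`. Residues with zero isolated SASA are reported as
#' missing.
#'
#' @param s a two-chain [structure3d].
#' @param chain_a,chain_b chain labels.
#' @param threshold burial fraction defining interface membership.
#' @param probe,n_points passed to [sasa()].
#' @return An `interface_map`: list with `buried_fraction` (data frame
#'   `seqnum`, `fraction` averaged over subunits), `per_chain` (data frame
#'   `chain`, `seqnum`, `fraction`), `interface_set_a`, `interface_set_b`,
#'   `missing` and `threshold`.
#' @export
buried_fraction <- function(s, chain_a = "A", chain_b = "B", threshold = 0.1,
                            probe = 1.4, n_points = 960L) {
  stopifnot(inherits(s, "structure3d"))
  if (!all(c(chain_a, chain_b) %in% s$atoms$chain))
    stop_ad("both chains must be present")
  if (threshold < 0 || threshold > 1) stop_ad("threshold must be in [0, 1]")
  res_complex <- sasa(s, probe, n_points)$per_residue
  per_chain <- lapply(c(chain_a, chain_b), function(ch) {
    iso <- structure3d(s$atoms[s$atoms$chain == ch, ], s$model_id)
    iso_res <- sasa(iso, probe, n_points)$per_residue
    cplx <- res_complex[res_complex$chain == ch, ]
    m <- merge(iso_res, cplx, by = c("chain", "seqnum"),
               suffixes = c("_iso", "_cplx"))
    m$fraction <- ifelse(m$area_iso > 0,
                         pmin(1, pmax(0, (m$area_iso - m$area_cplx) /
                                        m$area_iso)),
                         NA_real_)
    m[c("chain", "seqnum", "fraction")]
  })
  pc <- do.call(rbind, per_chain)
  avg <- stats::aggregate(fraction ~ seqnum, pc, mean, na.action = stats::na.omit)
  missing <- unique(pc$seqnum[is.na(pc$fraction)])
  set_of <- function(df) sort(df$seqnum[!is.na(df$fraction) &
                                        df$fraction >= threshold])
  structure(list(buried_fraction = avg[order(avg$seqnum), ],
                 per_chain = pc,
                 interface_set_a = set_of(per_chain[[1]]),
                 interface_set_b = set_of(per_chain[[2]]),
                 missing = missing, threshold = threshold,
                 chains = c(chain_a, chain_b)),
            class = "interface_map")
}

#' Detect backbone hydrogen bonds
#'
#' Geometric criteria: donor-acceptor N...O distance at most `max_d_no` and
#' N-H...O angle (vertex at H) at least `min_angle`. The amide proton is
#' taken from the structure when present, otherwise placed 0.98 Angstrom
#' from N along the bisector of the N-CA and N-C(i-1) directions; donors
#' that cannot be protonated (chain-initial residues without an H) are
#' skipped with a warning. Same-residue pairs are never counted.
#'
#' @param s a [structure3d].
#' @param max_d_no distance cutoff, Angstrom.
#' @param min_angle angle cutoff, degrees.
#' @param scope `"interchain"` (bonds between different chains only) or
#'   `"all"`.
#' @return Data frame of bonds sorted by donor chain/residue: columns
#'   `donor_chain`, `donor_seqnum`, `donor_atom`, `acceptor_chain`,
#'   `acceptor_seqnum`, `acceptor_atom`, `d_no`, `angle_nho`.
#' @export
detect_hbonds <- function(s, max_d_no = 3.5, min_angle = 120,
                          scope = c("interchain", "all")) {
  scope <- match.arg(scope)
  stopifnot(inherits(s, "structure3d"))
  at <- s$atoms
  don <- donor_table(s)
  acc <- at[at$atom == "O", c("chain", "seqnum", "x", "y", "z")]
  if (is.null(don) || !nrow(don) || !nrow(acc)) return(empty_hbonds())
  out <- list()
  for (i in seq_len(nrow(don))) {
    dx <- acc$x - don$nx[i]; dy <- acc$y - don$ny[i]; dz <- acc$z - don$nz[i]
    d_no <- sqrt(dx^2 + dy^2 + dz^2)
    keep <- d_no <= max_d_no &
      !(acc$chain == don$chain[i] & acc$seqnum == don$seqnum[i])
    if (scope == "interchain") keep <- keep & acc$chain != don$chain[i]
    if (!any(keep)) next
    hn <- c(don$nx[i] - don$hx[i], don$ny[i] - don$hy[i],
            don$nz[i] - don$hz[i])
    ho <- cbind(acc$x[keep] - don$hx[i], acc$y[keep] - don$hy[i],
                acc$z[keep] - don$hz[i])
    cosang <- (ho %*% hn) / (sqrt(rowSums(ho^2)) * sqrt(sum(hn^2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    ok <- ang >= min_angle
    if (!any(ok)) next
    ki <- which(keep)[ok]
    out[[length(out) + 1L]] <- data.frame(
      donor_chain = don$chain[i], donor_seqnum = don$seqnum[i],
      donor_atom = "N",
      acceptor_chain = acc$chain[ki], acceptor_seqnum = acc$seqnum[ki],
      acceptor_atom = "O", d_no = d_no[ki], angle_nho = ang[ok])
  }
  if (!length(out)) return(empty_hbonds())
  hb <- do.call(rbind, out)
  hb <- hb[order(hb$donor_chain, hb$donor_seqnum, hb$acceptor_chain,
                 hb$acceptor_seqnum), ]
  rownames(hb) <- NULL
  hb
}

empty_hbonds <- function() data.frame(
  donor_chain = character(), donor_seqnum = integer(),
  donor_atom = character(), acceptor_chain = character(),
  acceptor_seqnum = integer(), acceptor_atom = character(),
  d_no = numeric(), angle_nho = numeric())

# Donor table: backbone N with an observed or geometrically inferred H.
donor_table <- function(s) {
  at <- s$atoms
  ns <- at[at$atom == "N", ]
  if (!nrow(ns)) return(data.frame())
  rows <- lapply(seq_len(nrow(ns)), function(i) {
    ch <- ns$chain[i]; rs <- ns$seqnum[i]
    nxyz <- as.numeric(ns[i, c("x", "y", "z")])
    h <- at[at$chain == ch & at$seqnum == rs & at$atom == "H", ]
    if (nrow(h) == 1L) {
      hxyz <- as.numeric(h[c("x", "y", "z")])
    } else {
      ca <- at[at$chain == ch & at$seqnum == rs & at$atom == "CA", ]
      cprev <- at[at$chain == ch & at$seqnum == rs - 1 & at$atom == "C", ]
      if (nrow(ca) != 1L || nrow(cprev) != 1L) {
        warn_ad("residue ", ch, rs,
                ": no amide H and no geometry to infer one; donor skipped")
        return(NULL)
      }
      u1 <- nxyz - as.numeric(ca[c("x", "y", "z")])
      u2 <- nxyz - as.numeric(cprev[c("x", "y", "z")])
      u <- u1 / sqrt(sum(u1^2)) + u2 / sqrt(sum(u2^2))
      hxyz <- nxyz + 0.98 * u / sqrt(sum(u^2))
    }
    data.frame(chain = ch, seqnum = rs, nx = nxyz[1], ny = nxyz[2],
               nz = nxyz[3], hx = hxyz[1], hy = hxyz[2], hz = hxyz[3])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Infer beta-strand register and orientation from hydrogen bonds
#'
#' Restricted to inter-chain backbone bonds, residues linked by at least
#' one bond form the bridged pairing. Orientation comes from the dot
#' product of the two chains' strand direction vectors (first-to-last CA).
#' For parallel strands the register offset is the largest residue-number
#' offset `|j - i|` among bridged pairs: in a shifted parallel ladder the
#' rung connecting residue i of one chain to residue i + offset of the
#' other carries the shift, while symmetric geometries yield offset 0 by
#' construction. The `symmetric` flag records whether the pairing is an
#' involution under chain swap (every bridged pair (i, j) is matched by
#' (j, i)).
#'
#' @param hbonds bond table from [detect_hbonds()] (interchain scope).
#' @param s the [structure3d] the bonds came from.
#' @return A `register_report`: list with `orientation` (`"parallel"`,
#'   `"antiparallel"` or `"none"`), `pairing` (data frame `res_a`,
#'   `res_b`), `offset` (NA unless parallel) and `symmetric`.
#' @export
beta_register <- function(hbonds, s) {
  stopifnot(inherits(s, "structure3d"))
  hb <- hbonds[hbonds$donor_chain != hbonds$acceptor_chain, , drop = FALSE]
  if (!nrow(hb))
    return(structure(list(orientation = "none",
                          pairing = data.frame(res_a = integer(),
                                               res_b = integer()),
                          offset = NA_integer_, symmetric = NA),
                     class = "register_report"))
  chains <- sort(unique(c(hb$donor_chain, hb$acceptor_chain)))
  if (length(chains) != 2) stop_ad("expected bonds between exactly 2 chains")
  dir_of <- function(ch) {
    ca <- s$atoms[s$atoms$chain == ch & s$atoms$atom == "CA", ]
    ca <- ca[order(ca$seqnum), ]
    v <- as.numeric(ca[nrow(ca), c("x", "y", "z")]) -
         as.numeric(ca[1, c("x", "y", "z")])
    v / sqrt(sum(v^2))
  }
  orientation <- if (sum(dir_of(chains[1]) * dir_of(chains[2])) > 0)
    "parallel" else "antiparallel"
  # undirected residue-level bridged pairs, oriented chain1 -> chain2
  res_a <- ifelse(hb$donor_chain == chains[1], hb$donor_seqnum,
                  hb$acceptor_seqnum)
  res_b <- ifelse(hb$donor_chain == chains[1], hb$acceptor_seqnum,
                  hb$donor_seqnum)
  pairing <- unique(data.frame(res_a = res_a, res_b = res_b))
  pairing <- pairing[order(pairing$res_a, pairing$res_b), ]
  rownames(pairing) <- NULL
  offset <- if (orientation == "parallel")
    max(abs(pairing$res_b - pairing$res_a)) else NA_integer_
  key <- paste(pairing$res_a, pairing$res_b)
  swapped <- paste(pairing$res_b, pairing$res_a)
  structure(list(orientation = orientation, pairing = pairing,
                 offset = offset, symmetric = all(swapped %in% key)),
            class = "register_report")
}

#' @export
print.register_report <- function(x, ...) {
  cat(sprintf("register_report: %s, offset %s, %s\n", x$orientation,
              ifelse(is.na(x$offset), "-", x$offset),
              if (isTRUE(x$symmetric)) "symmetric pairing"
              else if (isFALSE(x$symmetric)) "asymmetric pairing"
              else "no pairing"))
  invisible(x)
}

#' Kabsch least-squares rigid superposition
#'
#' Optimal proper rotation and translation mapping point set `p` onto `q`
#' (SVD-based, determinant-corrected). Degenerate (collinear or smaller)
#' point sets are rejected because the rotation is then underdetermined.
#'
#' @param p,q n x 3 coordinate matrices, rows paired, n >= 3.
#' @return List with `rotation` (3 x 3), `translation` (length 3; the
#'   mapping is `x %*% rotation + translation`), `rmsd`, and `apply`, a
#'   function transforming an n x 3 matrix.
#' @export
kabsch_superpose <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (!all(dim(p) == dim(q)) || ncol(p) != 3 || nrow(p) < 3)
    stop_ad("need equal-length paired 3D coordinate sets with >= 3 points")
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)
  sv <- svd(crossprod(pc, qc))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12))
    stop_ad("degenerate (collinear) point set: rotation underdetermined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  tr <- cq - as.numeric(cp %*% R)
  moved <- sweep(p %*% R, 2, tr, "+")
  list(rotation = R, translation = tr,
       rmsd = sqrt(mean(rowSums((moved - q)^2))),
       apply = function(x) sweep(as.matrix(x) %*% R, 2, tr, "+"))
}

#' Score deviation from two-fold (C2) homodimer symmetry
#'
#' Superposes chain A onto chain B (Kabsch on sequence-equivalent CA
#' atoms), applies that transform to the whole dimer, swaps the chain
#' labels, and reports the RMSD between the transformed, swapped dimer and
#' the original over all matched atoms. An exact C2 dimer gives 0 (the
#' superposition transform is then an involution); a register-shifted
#' parallel dimer accumulates the full strand-axis shift and scores several
#' Angstrom.
#'
#' @param s a two-chain [structure3d].
#' @param chain_a,chain_b chain labels.
#' @param threshold swap-RMSD (Angstrom) below which the dimer is called
#'   symmetric.
#' @return A `symmetry_report`: list with `swap_rmsd`, `classification`
#'   (`"symmetric"`/`"asymmetric"`), `threshold` and `fit_rmsd` (residual
#'   of the A-onto-B superposition itself).
#' @export
symmetry_score <- function(s, chain_a = "A", chain_b = "B", threshold = 1.0) {
  stopifnot(inherits(s, "structure3d"))
  at <- s$atoms
  ca_a <- at[at$chain == chain_a & at$atom == "CA", ]
  ca_b <- at[at$chain == chain_b & at$atom == "CA", ]
  shared <- intersect(ca_a$seqnum, ca_b$seqnum)
  if (length(shared) < 3) stop_ad("fewer than 3 matched CA pairs")
  pa <- as.matrix(ca_a[match(shared, ca_a$seqnum), c("x", "y", "z")])
  pb <- as.matrix(ca_b[match(shared, ca_b$seqnum), c("x", "y", "z")])
  fit <- kabsch_superpose(pa, pb)
  # match atoms across chains by (seqnum, atom)
  a_idx <- which(at$chain == chain_a)
  b_idx <- which(at$chain == chain_b)
  key_a <- paste(at$seqnum[a_idx], at$atom[a_idx])
  key_b <- paste(at$seqnum[b_idx], at$atom[b_idx])
  ab <- match(key_a, key_b)
  ok <- !is.na(ab)
  xa <- coords(s, a_idx[ok])          # chain A atoms
  xb <- coords(s, b_idx[ab[ok]])      # their chain B equivalents
  ta <- fit$apply(xa)                 # T(A) should equal B
  tb <- fit$apply(xb)                 # T(B) should equal A if C2
  swap_rmsd <- sqrt(mean(c(rowSums((ta - xb)^2), rowSums((tb - xa)^2))))
  structure(list(swap_rmsd = swap_rmsd,
                 classification = if (swap_rmsd <= threshold) "symmetric"
                                  else "asymmetric",
                 threshold = threshold, fit_rmsd = fit$rmsd),
            class = "symmetry_report")
}

#' @export
print.symmetry_report <- function(x, ...) {
  cat(sprintf("symmetry_report: swap-RMSD %.3f Angstrom -> %s (threshold %g)\n",
              x$swap_rmsd, x$classification, x$threshold))
  invisible(x)
}

#' Interface overlap and fibril capability
#'
#' An asymmetric homodimer uses two different surfaces, S_A on one subunit
#' and S_B on the other. If those surfaces overlap on the common residue
#' numbering, a third subunit cannot bind an already-dimerized protomer and
#' growth stops at the dimer; disjoint surfaces would permit unbounded
#' head-to-tail polymerization. Overlap is quantified as
#' `|S_A intersect S_B| / min(|S_A|, |S_B|)`.
#'
#' @param m an `interface_map` from [buried_fraction()], or a list with
#'   `interface_set_a`/`interface_set_b`.
#' @param threshold overlap coefficient below which the interface pair is
#'   called fibril-capable.
#' @return List with `overlap`, `fibril_capable`, `n_a`, `n_b`,
#'   `n_shared`.
#' @export
interface_overlap <- function(m, threshold = 0.25) {
  sa <- m$interface_set_a
  sb <- m$interface_set_b
  if (!length(sa) || !length(sb)) {
    warn_ad("empty interface set: overlap undefined")
    return(list(overlap = NA_real_, fibril_capable = NA,
                n_a = length(sa), n_b = length(sb), n_shared = 0L))
  }
  ov <- length(intersect(sa, sb)) / min(length(sa), length(sb))
  list(overlap = ov, fibril_capable = ov < threshold,
       n_a = length(sa), n_b = length(sb),
       n_shared = length(intersect(sa, sb)))
}
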