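# Independent oracles and small fixture builders shared across tests.

# Matrix-exponential oracle for the two-site longitudinal propagator,
# independent of the closed-form implementation under test.
expm_oracle <- function(t, k_ex, p_a = 0.5, r1_a = 0, r1_b = r1_a) {
  k_ab <- k_ex * (1 - p_a)
  k_ba <- k_ex * p_a
  K <- matrix(c(r1_a + k_ab, -k_ab, -k_ba, r1_b + k_ba), 2, 2)
  as.matrix(Matrix::expm(-K * t))
}

# Horn quaternion absolute-orientation solution: independent route to the
# optimal rotation for paired point sets.
quat_superpose_rmsd <- function(p, q) {
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)
  M <- crossprod(pc, qc)
  S <- matrix(0, 4, 4)
  S[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  S[1, 2] <- S[2, 1] <- M[2, 3] - M[3, 2]
  S[1, 3] <- S[3, 1] <- M[3, 1] - M[1, 3]
  S[1, 4] <- S[4, 1] <- M[1, 2] - M[2, 1]
  S[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  S[2, 3] <- S[3, 2] <- M[1, 2] + M[2, 1]
  S[2, 4] <- S[4, 2] <- M[3, 1] + M[1, 3]
  S[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  S[3, 4] <- S[4, 3] <- M[2, 3] + M[3, 2]
  S[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  qv <- eigen(S, symmetric = TRUE)$vectors[, 1]
  w <- qv[1]; x <- qv[2]; y <- qv[3]; z <- qv[4]
  R <- t(matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3))
  moved <- sweep(pc %*% R, 2, cq, "+")
  sqrt(mean(rowSums((moved - q)^2)))
}

# Naive all-pairs hydrogen-bond enumeration (explicit H only), used as an
# oracle for the vectorized detector.
brute_hbonds <- function(s, max_d_no = 3.5, min_angle = 120,
                         interchain_only = TRUE) {
  at <- s$atoms
  found <- list()
  for (i in which(at$atom == "N")) {
    h <- which(at$chain == at$chain[i] & at$seqnum == at$seqnum[i] &
               at$atom == "H")
    if (length(h) != 1) next
    for (j in which(at$atom == "O")) {
      if (at$chain[j] == at$chain[i] && at$seqnum[j] == at$seqnum[i]) next
      if (interchain_only && at$chain[j] == at$chain[i]) next
      nv <- as.numeric(at[i, c("x", "y", "z")])
      hv <- as.numeric(at[h, c("x", "y", "z")])
      ov <- as.numeric(at[j, c("x", "y", "z")])
      d <- sqrt(sum((nv - ov)^2))
      if (d > max_d_no) next
      v1 <- nv - hv; v2 <- ov - hv
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (ang < min_angle) next
      found[[length(found) + 1]] <-
        sprintf("%s%d->%s%d", at$chain[i], at$seqnum[i],
                at$chain[j], at$seqnum[j])
    }
  }
  out <- unlist(found)
  if (is.null(out)) character(0) else sort(out)
}

# Residue-level "is residue a of chain 1 bonded to residue b of chain 2
# (either direction)" lookup on a detect_hbonds() table.
has_contact <- function(hb, res_a, res_b, chain_a = "A", chain_b = "B") {
  any((hb$donor_chain == chain_a & hb$donor_seqnum == res_a &
       hb$acceptor_chain == chain_b & hb$acceptor_seqnum == res_b) |
      (hb$donor_chain == chain_b & hb$donor_seqnum == res_b &
       hb$acceptor_chain == chain_a & hb$acceptor_seqnum == res_a))
}

# A three-peak-per-residue free test peaklist.
toy_peaklist <- function() {
  peaklist(data.frame(
    chain = "A",
    seqnum = c(283L, 283L, 285L, 285L, 290L),
    aa = c("V", "V", "H", "H", "G"),
    shift_h = c(8.10, 8.22, 7.90, 7.95, 8.40),
    shift_n = c(120.5, 121.3, 118.0, 118.6, 109.2),
    intensity = c(1.0, 1.1, 0.9, 0.95, 2.0),
    state = "unknown"))
}

# Apply a rigid motion (rotation about an arbitrary axis + translation).
rigid_move <- function(s, angle = 0.7, axis = c(1, 2, 3),
                       shift = c(5, -3, 11)) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  R <- c_ * diag(3) + s_ * rbind(c(0, -u[3], u[2]),
                                 c(u[3], 0, -u[1]),
                                 c(-u[2], u[1], 0)) +
    (1 - c_) * tcrossprod(u)
  xyz <- as.matrix(s$atoms[c("x", "y", "z")]) %*% t(R)
  at <- s$atoms
  at$x <- xyz[, 1] + shift[1]
  at$y <- xyz[, 2] + shift[2]
  at$z <- xyz[, 3] + shift[3]
  structure3d(at, s$model_id)
}

# Swap all A/B state labels in an exsy_dataset.
swap_exsy_labels <- function(data) {
  exsy_dataset(data.frame(residue = data$residue, t_mix = data$t_mix,
                          i_aa = data$i_bb, i_bb = data$i_aa,
                          i_ab = data$i_ba, i_ba = data$i_ab),
               ground_truth = attr(data, "ground_truth"))
}
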