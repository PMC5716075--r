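single_atom <- function(elem = "C") structure3d(data.frame(
  chain = "A", seqnum = 1L, resname = "ALA", atom = elem, element = elem,
  x = 0, y = 0, z = 0))

test_that("single-atom SASA equals the closed-form sphere area", {
  res <- sasa(single_atom("C"), probe = 1.4, n_points = 960)
  expect_equal(res$per_atom$area, 4 * pi * (1.7 + 1.4)^2,
               tolerance = 0.005)
  expect_equal(res$per_atom$area, res$per_residue$area)
})

test_that("distant atoms keep their isolated areas; cages bury completely", {
  two <- structure3d(data.frame(
    chain = "A", seqnum = 1:2, resname = "ALA", atom = "C", element = "C",
    x = c(0, 100), y = 0, z = 0))
  res <- sasa(two)
  expect_equal(res$per_atom$area, rep(4 * pi * 3.1^2, 2), tolerance = 0.005)
  # a golden-spiral cage of carbons at 3.0 A encloses the central atom
  dirs <- asymdimer:::golden_spiral_points(60) * 3.0
  cage <- structure3d(data.frame(
    chain = "A", seqnum = c(1L, rep(2L, 60)), resname = "ALA",
    atom = c("C", sprintf("C%02d", 1:60)), element = "C",
    x = c(0, dirs[, 1]), y = c(0, dirs[, 2]), z = c(0, dirs[, 3])))
  expect_equal(sasa(cage)$per_atom$area[1], 0)
})

test_that("unknown elements abort SASA with the atom named", {
  expect_error(sasa(single_atom("ZZ")), "unknown element")
})

test_that("complex SASA never exceeds the sum of isolated chains", {
  s <- build_sheet_dimer(sheet_dimer_config("offset_parallel"))
  total <- sum(sasa(s)$per_atom$area)
  iso <- sum(vapply(c("A", "B"), function(ch)
    sum(sasa(structure3d(s$atoms[s$atoms$chain == ch, ]))$per_atom$area),
    numeric(1)))
  expect_lte(total, iso)
  expect_gt(iso - total, 100)  # a real interface buries substantial area
})

test_that("burial maps separate interface from far-apart chains", {
  s <- build_sheet_dimer(sheet_dimer_config("offset_parallel",
                                            resid_start = 430))
  m <- buried_fraction(s)
  expect_true(all(m$buried_fraction$fraction >= 0 &
                  m$buried_fraction$fraction <= 1))
  # facing residues (even parity here) are buried well above threshold
  expect_gt(min(m$buried_fraction$fraction[
    m$buried_fraction$seqnum %in% c(434, 436)]), 0.1)
  expect_true(436 %in% m$interface_set_a)
  expect_true(436 %in% m$interface_set_b)

  far <- s$atoms
  far$y[far$chain == "B"] <- far$y[far$chain == "B"] + 100
  m0 <- buried_fraction(structure3d(far))
  expect_true(all(m0$buried_fraction$fraction == 0))
  expect_length(m0$interface_set_a, 0)
  expect_length(m0$interface_set_b, 0)
})

test_that("hydrogen-bond detection equals brute-force enumeration", {
  for (geom in c("offset_parallel", "c2_antiparallel", "symmetric_parallel")) {
    s <- build_sheet_dimer(sheet_dimer_config(geom))
    hb <- detect_hbonds(s)
    got <- sort(sprintf("%s%d->%s%d", hb$donor_chain, hb$donor_seqnum,
                        hb$acceptor_chain, hb$acceptor_seqnum))
    expect_equal(got, brute_hbonds(s), info = geom)
  }
})

test_that("the parallel-strand symmetry dichotomy holds geometrically", {
  # symmetric parallel: donors and acceptors cannot align
  sp <- build_sheet_dimer(sheet_dimer_config("symmetric_parallel"))
  expect_equal(nrow(detect_hbonds(sp)), 0)
  # offset parallel: valid ladder with at least 2 bonds per shared rung
  op <- build_sheet_dimer(sheet_dimer_config("offset_parallel"))
  hb <- detect_hbonds(op)
  expect_gt(nrow(hb), 4)
  expect_true(all(hb$d_no < 3.2))
  expect_true(all(hb$angle_nho > 120))
  # antiparallel control: symmetric reciprocal ladder
  ap <- build_sheet_dimer(sheet_dimer_config("c2_antiparallel",
                                             n_strand_res = 8))
  hba <- detect_hbonds(ap)
  expect_gte(nrow(hba), 3)
})

test_that("amide protons can be inferred from backbone geometry", {
  # CA and previous C placed symmetrically: inferred H points along +y
  s <- structure3d(data.frame(
    chain = c("A", "A", "A", "B"),
    seqnum = c(1L, 2L, 2L, 9L),
    resname = "ALA",
    atom = c("C", "N", "CA", "O"),
    element = c("C", "N", "C", "O"),
    x = c(-1.2, 0, 1.2, 0),
    y = c(-0.8, 0, -0.8, 3.4),
    z = 0))
  hb <- detect_hbonds(s, scope = "interchain")
  expect_equal(nrow(hb), 1)
  expect_equal(hb$d_no, 3.4)
  expect_gt(hb$angle_nho, 175)
  # a chain-initial N with no preceding carbonyl cannot donate
  s2 <- structure3d(s$atoms[-1, ])
  expect_warning(hb2 <- detect_hbonds(s2), "donor skipped")
  expect_equal(nrow(hb2), 0)
})

test_that("register analysis reads orientation, offset and symmetry", {
  op <- build_sheet_dimer(sheet_dimer_config("offset_parallel",
                                             resid_start = 430))
  hb <- detect_hbonds(op)
  reg <- beta_register(hb, op)
  expect_equal(reg$orientation, "parallel")
  expect_equal(reg$offset, 2)
  expect_false(reg$symmetric)
  # the quoted ladder around the 436-equivalent position
  expect_true(has_contact(hb, 436, 436))
  expect_true(has_contact(hb, 436, 438))
  expect_true(any(hb$donor_chain == "B" & hb$donor_seqnum == 436 &
                  hb$acceptor_seqnum == 434))

  ap <- build_sheet_dimer(sheet_dimer_config("c2_antiparallel"))
  rega <- beta_register(detect_hbonds(ap), ap)
  expect_equal(rega$orientation, "antiparallel")
  expect_true(rega$symmetric)
  expect_true(is.na(rega$offset))

  none <- beta_register(detect_hbonds(
    build_sheet_dimer(sheet_dimer_config("symmetric_parallel"))), op)
  expect_equal(none$orientation, "none")
})

test_that("Kabsch superposition recovers exact rigid motions", {
  set.seed(11)
  p <- matrix(rnorm(30), 10, 3)
  fit <- kabsch_superpose(p, p)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  q <- p %*% Rz
  fit2 <- kabsch_superpose(p, q)
  expect_equal(fit2$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit2$rotation, Rz, tolerance = 1e-8)
  expect_error(kabsch_superpose(cbind(1:5, 2 * (1:5), 3 * (1:5)),
                                cbind(1:5, 2 * (1:5), 3 * (1:5))),
               "collinear")
})

test_that("Kabsch RMSD matches the quaternion oracle on perturbed points", {
  set.seed(42)
  for (i in 1:10) {
    p <- matrix(rnorm(12), 4, 3)
    q <- p
    q[1, 1] <- q[1, 1] + 1
    expect_equal(kabsch_superpose(p, q)$rmsd, quat_superpose_rmsd(p, q),
                 tolerance = 1e-9)
  }
})

test_that("swap-RMSD separates exact C2 dimers from register shifts", {
  ap <- build_sheet_dimer(sheet_dimer_config("c2_antiparallel"))
  sym <- symmetry_score(ap)
  expect_lt(sym$swap_rmsd, 1e-6)
  expect_equal(sym$classification, "symmetric")

  sp <- build_sheet_dimer(sheet_dimer_config("symmetric_parallel"))
  expect_equal(symmetry_score(sp)$classification, "symmetric")

  op <- build_sheet_dimer(sheet_dimer_config("offset_parallel"))
  asym <- symmetry_score(op)
  expect_gt(asym$swap_rmsd, 1)
  expect_equal(asym$classification, "asymmetric")
  # a monomer duplicated in place is trivially symmetric
  a <- op$atoms[op$atoms$chain == "A", ]
  b <- a; b$chain <- "B"
  dup <- structure3d(rbind(a, b))
  expect_lt(symmetry_score(dup)$swap_rmsd, 1e-10)
})

test_that("symmetry classification is invariant under chain relabelling", {
  op <- build_sheet_dimer(sheet_dimer_config("offset_parallel"))
  at <- op$atoms
  at$chain <- ifelse(at$chain == "A", "B", "A")
  swapped <- structure3d(at)
  expect_equal(symmetry_score(swapped)$swap_rmsd,
               symmetry_score(op)$swap_rmsd, tolerance = 1e-9)
})

test_that("geometry outputs are invariant under global rigid motion", {
  op <- build_sheet_dimer(sheet_dimer_config("offset_parallel"))
  moved <- rigid_move(op)
  hb0 <- detect_hbonds(op); hb1 <- detect_hbonds(moved)
  expect_equal(hb1[c("donor_seqnum", "acceptor_seqnum")],
               hb0[c("donor_seqnum", "acceptor_seqnum")])
  expect_equal(hb1$d_no, hb0$d_no, tolerance = 1e-9)
  expect_equal(symmetry_score(moved)$swap_rmsd,
               symmetry_score(op)$swap_rmsd, tolerance = 1e-6)
  # numeric SASA re-samples the sphere in the rotated frame: agreement is
  # statistical, not exact
  expect_equal(sum(sasa(moved)$per_atom$area), sum(sasa(op)$per_atom$area),
               tolerance = 0.01)
})

test_that("interface overlap quantifies the fibril-blocking geometry", {
  mk <- function(a, b) list(interface_set_a = a, interface_set_b = b)
  same <- interface_overlap(mk(1:10, 1:10))
  expect_equal(same$overlap, 1)
  expect_false(same$fibril_capable)
  disj <- interface_overlap(mk(1:5, 6:10))
  expect_equal(disj$overlap, 0)
  expect_true(disj$fibril_capable)
  half <- interface_overlap(mk(1:10, 6:15))
  expect_equal(half$overlap, 0.5)
  expect_warning(und <- interface_overlap(mk(integer(), 1:3)), "undefined")
  expect_true(is.na(und$overlap))
})
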