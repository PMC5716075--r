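# The two experimentally observed intermolecular contact sets: an
# interface methyl pair and methyl-to-backbone contacts, states crossed.
paper_contacts <- function(s1 = "A", s2 = "B") noe_contacts(data.frame(
  res1 = c(283L, 273L, 273L), atom1 = c("QG1", "QD1", "QD1"), state1 = s1,
  res2 = c(282L, 304L, 305L), atom2 = c("QG2", "HA", "HB"), state2 = s2,
  intensity = c(1, 0.6, 0.5)))

rbind2_contacts <- function(a, b) noe_contacts(rbind(as.data.frame(a)[1:8],
                                                     as.data.frame(b)[1:8]))

test_that("cross-state contacts classify the dimer as asymmetric", {
  call <- classify_dimer(paper_contacts())
  expect_equal(call$verdict, "asymmetric")
  expect_equal(call$n_cross_state, 3)
  expect_equal(call$n_same_state, 0)
})

test_that("same-state relabelling flips the verdict to symmetric", {
  call <- classify_dimer(paper_contacts("A", "A"))
  expect_equal(call$verdict, "symmetric")
})

test_that("mixtures are ambiguous in strict mode, voted in majority mode", {
  mixed <- noe_contacts(data.frame(
    res1 = c(1L, 2L), atom1 = "H", state1 = c("A", "A"),
    res2 = c(5L, 6L), atom2 = "H", state2 = c("A", "B")))
  strict <- classify_dimer(mixed, "strict")
  expect_equal(strict$verdict, "ambiguous")
  expect_equal(c(strict$n_same_state, strict$n_cross_state), c(1, 1))
  maj <- classify_dimer(rbind2_contacts(mixed, paper_contacts()), "majority")
  expect_equal(maj$verdict, "asymmetric")
  expect_equal(maj$margin, 3)
})

test_that("classification requires labelled intermolecular contacts", {
  blank <- noe_contacts(data.frame(res1 = 1L, atom1 = "H",
                                   state1 = "unknown", res2 = 2L,
                                   atom2 = "H", state2 = "A"))
  expect_error(classify_dimer(blank), "uninformative")
})

test_that("verdicts are invariant under a global A/B relabelling", {
  flip <- function(x) c(A = "B", B = "A", unknown = "unknown")[x]
  cts <- paper_contacts()
  sw <- as.data.frame(cts)
  sw$state1 <- unname(flip(sw$state1))
  sw$state2 <- unname(flip(sw$state2))
  expect_equal(classify_dimer(noe_contacts(sw))$verdict,
               classify_dimer(cts)$verdict)
  same <- paper_contacts("B", "B")
  expect_equal(classify_dimer(same)$verdict,
               classify_dimer(paper_contacts("A", "A"))$verdict)
})

test_that("mirror validation exposes the register-shift asymmetry", {
  s <- build_sheet_dimer(sheet_dimer_config("offset_parallel",
                                            resid_start = 277))
  amide <- noe_contacts(data.frame(res1 = 283L, atom1 = "H", state1 = "A",
                                   res2 = 285L, atom2 = "H", state2 = "B"))
  v <- validate_against_structure(amide, s, c(A = "A", B = "B"))
  expect_true(v$details$satisfied)
  expect_equal(v$fraction_satisfied, 1)
  expect_true(v$mirror$mirror_violated)
  expect_gt(v$mirror$mirror_distance, 5.5)
})

test_that("distances govern satisfaction and cutoff is monotone", {
  s <- build_sheet_dimer(sheet_dimer_config("offset_parallel",
                                            resid_start = 277))
  far <- noe_contacts(data.frame(res1 = 278L, atom1 = "H", state1 = "A",
                                 res2 = 287L, atom2 = "H", state2 = "B"))
  v <- validate_against_structure(far, s, c(A = "A", B = "B"))
  expect_false(v$details$satisfied)
  vinf <- validate_against_structure(far, s, c(A = "A", B = "B"),
                                     cutoff = 1e6)
  expect_true(vinf$details$satisfied)
  cts <- predict_intermolecular_noes(s, c(A = "A", B = "B"), cutoff = 8)
  fr <- vapply(c(3, 4.5, 6, 8), function(cut)
    validate_against_structure(cts, s, c(A = "A", B = "B"),
                               cutoff = cut)$fraction_satisfied,
    numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("unmappable contacts are reported, not fatal", {
  s <- build_sheet_dimer(sheet_dimer_config("offset_parallel",
                                            resid_start = 277))
  v <- suppressWarnings(validate_against_structure(
    paper_contacts(), s, c(A = "A", B = "B")))
  expect_true(all(!v$details$mapped))
  expect_warning(validate_against_structure(paper_contacts(), s,
                                            c(A = "A", B = "B")),
                 "could not be mapped")
})

test_that("predicted contacts contain every satisfied observed contact", {
  s <- build_sheet_dimer(sheet_dimer_config("offset_parallel",
                                            resid_start = 277))
  cutoff <- 5.5
  pred <- predict_intermolecular_noes(s, c(A = "A", B = "B"), cutoff)
  expect_gt(nrow(pred), 0)
  expect_true(all(pred$state1 != pred$state2))
  amide <- noe_contacts(data.frame(res1 = 283L, atom1 = "H", state1 = "A",
                                   res2 = 285L, atom2 = "H", state2 = "B"))
  v <- validate_against_structure(amide, s, c(A = "A", B = "B"), cutoff)
  key <- c(paste(pred$res1, pred$atom1, pred$res2, pred$atom2),
           paste(pred$res2, pred$atom2, pred$res1, pred$atom1))
  sat <- v$details[v$details$satisfied, ]
  expect_true(all(paste(sat$res1, sat$atom1, sat$res2, sat$atom2) %in% key))
})

test_that("single chains cannot produce intermolecular NOEs", {
  s <- build_sheet_dimer(sheet_dimer_config("offset_parallel"))
  mono <- structure3d(s$atoms[s$atoms$chain == "A", ])
  expect_warning(p <- predict_intermolecular_noes(mono, c(A = "A")),
                 "single chain")
  expect_equal(nrow(p), 0)
})

test_that("NOE tables round-trip through TSV", {
  cts <- paper_contacts()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_noe_table(cts, path)
  back <- read_noe_table(path)
  expect_equal(as.data.frame(back)[1:7], as.data.frame(cts)[1:7])
})
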