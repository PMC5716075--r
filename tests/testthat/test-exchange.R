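test_that("pairing handles doubled, single and crowded residues", {
  doubled <- simulate_doubled_peaklist(pact_like_truth(), seed = 5)$peaks
  pairing <- pair_states(doubled)
  expect_equal(nrow(pairing$pairs), length(unique(doubled$seqnum)))
  expect_length(pairing$singletons, 0)
  expect_equal(nrow(pairing$unpaired), 0)
  # canonical labels: A is the lower 1H shift member
  expect_true(all(pairing$pairs$shift_h_a <= pairing$pairs$shift_h_b))

  three <- toy_peaklist()
  three$state <- "unknown"
  crowded <- peaklist(rbind(as.data.frame(three), data.frame(
    chain = "A", seqnum = 283L, aa = "V", shift_h = 9.4, shift_n = 130,
    intensity = 0.1, state = "unknown")))
  expect_warning(p3 <- pair_states(crowded), "paired the closest")
  expect_equal(nrow(p3$unpaired), 1)
  expect_equal(p3$unpaired$shift_h, 9.4)
  expect_equal(p3$singletons, 290)
})

test_that("compound shift formula reproduces worked values", {
  mk <- function(dh, dn) {
    pl <- peaklist(data.frame(
      chain = "A", seqnum = 1L, aa = "X",
      shift_h = c(8, 8 + dh), shift_n = c(110, 110 + dn),
      intensity = 1:2, state = c("A", "B")))
    compound_csp(pair_states(pl))$dd_comp
  }
  expect_lt(abs(mk(1e-9, 0) - 0), 1e-4)
  expect_lt(abs(mk(0.10, 0.65) - 0.1414), 1e-4)
  expect_lt(abs(mk(1e-12, 6.5) - 1.0), 1e-4)
})

test_that("csp profile is zero iff the states coincide, swap-invariant", {
  sim <- simulate_doubled_peaklist(pact_like_truth(), seed = 9)
  prof <- compound_csp(pair_states(sim$peaks))
  expect_true(all(prof$dd_comp > 0))
  expect_equal((prof$dd_comp == 0), (prof$dd_h == 0 & prof$dd_n == 0))
  # swapping state labels changes nothing (canonical relabelling)
  swapped <- sim$peaks
  swapped$state <- c(A = "B", B = "A", unknown = "unknown")[swapped$state]
  prof2 <- compound_csp(pair_states(peaklist(as.data.frame(swapped))))
  expect_equal(prof2$dd_comp, prof$dd_comp)
  # recovered profile equals the generating truth
  m <- match(prof$seqnum, sim$truth$seqnum)
  expect_equal(prof$dd_comp, sim$truth$dd_comp[m], tolerance = 1e-9)
})

test_that("asymmetry ranking breaks ties by residue number", {
  pl <- do.call(rbind, lapply(1:4, function(r) data.frame(
    chain = "A", seqnum = r, aa = "X", shift_h = c(8, 8.05),
    shift_n = c(110, 110.3), intensity = 1, state = c("A", "B"))))
  prof <- compound_csp(pair_states(peaklist(pl)))
  expect_equal(rank_asymmetry(prof)$seqnum, 1:4)
  expect_equal(nrow(rank_asymmetry(prof, 99)), 4)
})

test_that("population check flags imbalance and skips zero intensities", {
  sim <- simulate_doubled_peaklist(pact_like_truth(),
                                   intensity_imbalance = 1, seed = 4)
  pc <- equal_population_check(pair_states(sim$peaks))
  expect_equal(pc$median_ratio, 2, tolerance = 1e-9)
  expect_false(pc$balanced)
  empty <- pair_states(peaklist(data.frame(
    chain = character(), seqnum = integer(), aa = character(),
    shift_h = numeric(), shift_n = numeric(), intensity = numeric(),
    state = character())))
  expect_equal(nrow(equal_population_check(empty)$ratios), 0)
})

test_that("ratio statistic matches the matrix-exponential oracle", {
  cfg <- exsy_sim_config(t_mix = c(0, 0.5), noise_sd = 0, n_residues = 1)
  ds <- simulate_exsy_series(cfg)
  r <- ratio_statistic(ds)
  expect_equal(r[ds$t_mix == 0], 0)
  P <- expm_oracle(0.5, 0.71, 0.5, 1.2, 1.2)
  expect_equal(r[ds$t_mix == 0.5],
               (P[2, 1] + P[1, 2]) / (P[1, 1] + P[2, 2]),
               tolerance = 1e-9)
  expect_equal(r[ds$t_mix == 0.5], tanh(0.71 * 0.5 / 2), tolerance = 1e-9)
})

test_that("noiseless model ratio increases strictly with mixing time", {
  cfg <- exsy_sim_config(t_mix = seq(0.05, 2, length.out = 12),
                         noise_sd = 0, n_residues = 1)
  r <- ratio_statistic(simulate_exsy_series(cfg))
  expect_true(all(diff(r) > 0))
})

test_that("both estimators recover the truth exactly on noiseless data", {
  ds <- simulate_exsy_series(exsy_sim_config(noise_sd = 0, n_residues = 6,
                                             seed = 2))
  k1 <- fit_exchange_global(ds, "ratio_tanh")$k_ex_hat
  k2 <- fit_exchange_global(ds, "matrix_lsq")$k_ex_hat
  expect_equal(k1, 0.71, tolerance = 1e-6)
  expect_equal(k2, 0.71, tolerance = 1e-6)
  expect_equal(k1, k2, tolerance = 1e-6)
})

test_that("zero exchange is reported at the boundary with a warning", {
  ds <- simulate_exsy_series(exsy_sim_config(k_ex = 1e-12, noise_sd = 0,
                                             n_residues = 3))
  expect_warning(fit <- fit_exchange_global(ds), "boundary")
  expect_lt(fit$k_ex_hat, 1e-4)
})

test_that("matrix fit stays exact under unequal relaxation; ratio biased", {
  ds <- simulate_exsy_series(exsy_sim_config(r1_a = 0.8, r1_b = 2.4,
                                             noise_sd = 0, n_residues = 4))
  km <- fit_exchange_global(ds, "matrix_lsq")$k_ex_hat
  kr <- fit_exchange_global(ds, "ratio_tanh")$k_ex_hat
  expect_equal(km, 0.71, tolerance = 1e-3)
  expect_gt(abs(kr - 0.71), 10 * abs(km - 0.71))
})

test_that("fits are invariant under a global A/B label swap", {
  ds <- simulate_exsy_series(exsy_sim_config(seed = 13))
  sw <- swap_exsy_labels(ds)
  expect_equal(ratio_statistic(sw), ratio_statistic(ds))
  expect_equal(fit_exchange_global(sw)$k_ex_hat,
               fit_exchange_global(ds)$k_ex_hat, tolerance = 1e-12)
})

test_that("fit prerequisites are enforced", {
  ds <- simulate_exsy_series(exsy_sim_config(t_mix = 0.5, n_residues = 3))
  expect_error(fit_exchange_global(ds), "2 distinct mixing times")
})

test_that("bootstrap CI is degenerate on noiseless data, seeded otherwise", {
  ds0 <- simulate_exsy_series(exsy_sim_config(noise_sd = 0, n_residues = 8))
  fit0 <- bootstrap_ci(ds0, n_boot = 200, seed = 1)
  expect_equal(fit0$ci95[1], fit0$ci95[2], tolerance = 1e-6)
  expect_equal(fit0$ci95[1], 0.71, tolerance = 1e-6)

  ds <- simulate_exsy_series(exsy_sim_config(seed = 21))
  fit <- bootstrap_ci(ds, n_boot = 400, seed = 5)
  expect_lte(fit$ci95[1], fit$k_ex_hat)
  expect_gte(fit$ci95[2], fit$k_ex_hat)
  expect_true(fit$ci95[1] <= 0.71 && 0.71 <= fit$ci95[2])
  fit2 <- bootstrap_ci(ds, n_boot = 400, seed = 5)
  expect_identical(fit$ci95, fit2$ci95)
  expect_warning(bootstrap_ci(ds, n_boot = 50, seed = 1), "noisy")
})

test_that("per-residue diagnostic rates cluster around the global rate", {
  ds <- simulate_exsy_series(exsy_sim_config(seed = 31))
  fit <- fit_exchange_global(ds)
  expect_length(fit$per_residue_k, 60)
  expect_lt(abs(stats::median(fit$per_residue_k) - 0.71), 0.08)
})
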