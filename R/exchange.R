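#' Pair doubled peaks into conformational states
#'
#' Residues with exactly two peaks are paired and given canonical state
#' labels (A = lower 1H shift; ties broken by lower 15N shift). Residues
#' with one peak are reported as singletons — the signature of a
#' monomerized mutant, which shows one signal per site where the wild-type
#' dimer shows two. Residues with more than two peaks are reduced by greedy
#' nearest-neighbour pairing in tolerance-scaled shift space; leftovers are
#' reported unpaired with a warning.
#'
#' @param peaks a [peaklist].
#' @param tol_h,tol_n shift tolerances (ppm) used to scale distances when
#'   more than two peaks share a residue.
#' @return A `state_pairing`: list with `pairs` (data frame, one row per
#'   paired residue with A and B shifts/intensities), `singletons` (residue
#'   numbers) and `unpaired` (peak rows).
#' @export
pair_states <- function(peaks, tol_h = 0.05, tol_n = 0.3) {
  stopifnot(inherits(peaks, "peaklist"))
  if (!is_number(tol_h) || tol_h <= 0 || !is_number(tol_n) || tol_n <= 0)
    stop_ad("tolerances must be positive")
  split_idx <- split(seq_len(nrow(peaks)), peaks$seqnum)
  pairs <- list()
  singles <- integer()
  unpaired <- integer()
  for (res in names(split_idx)) {
    idx <- split_idx[[res]]
    if (length(idx) == 1L) {
      singles <- c(singles, peaks$seqnum[idx])
      next
    }
    use <- idx
    if (length(idx) > 2L) {
      # greedy nearest pairing in tolerance units; keep the closest pair
      cmb <- utils::combn(idx, 2)
      d <- sqrt(((peaks$shift_h[cmb[1, ]] - peaks$shift_h[cmb[2, ]]) / tol_h)^2 +
                ((peaks$shift_n[cmb[1, ]] - peaks$shift_n[cmb[2, ]]) / tol_n)^2)
      use <- cmb[, which.min(d)]
      unpaired <- c(unpaired, setdiff(idx, use))
      warn_ad("residue ", res, ": ", length(idx),
              " peaks; paired the closest two, rest left unpaired")
    }
    o <- order(peaks$shift_h[use], peaks$shift_n[use])
    ia <- use[o[1]]; ib <- use[o[2]]
    pairs[[res]] <- data.frame(
      seqnum = peaks$seqnum[ia], aa = peaks$aa[ia], chain = peaks$chain[ia],
      shift_h_a = peaks$shift_h[ia], shift_n_a = peaks$shift_n[ia],
      intensity_a = peaks$intensity[ia],
      shift_h_b = peaks$shift_h[ib], shift_n_b = peaks$shift_n[ib],
      intensity_b = peaks$intensity[ib])
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(seqnum = integer(), aa = character(), chain = character(),
               shift_h_a = numeric(), shift_n_a = numeric(),
               intensity_a = numeric(), shift_h_b = numeric(),
               shift_n_b = numeric(), intensity_b = numeric())
  pairs <- pairs[order(pairs$seqnum), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, singletons = sort(singles),
                 unpaired = peaks[unpaired, , drop = FALSE],
                 tol_h = tol_h, tol_n = tol_n),
            class = "state_pairing")
}

#' @export
print.state_pairing <- function(x, ...) {
  cat(sprintf("state_pairing: %d paired residues, %d singletons, %d unpaired peaks\n",
              nrow(x$pairs), length(x$singletons), nrow(x$unpaired)))
  invisible(x)
}

#' Compound chemical-shift asymmetry profile
#'
#' Per paired residue, the compound shift difference between the two states:
#' `sqrt(ddH^2 + (ddN/6.5)^2)` with `ddH`, `ddN` the absolute A-B 1H and
#' 15N differences. The 15N scaling constant 6.5 reflects the relative
#' dispersion of amide nitrogen shifts and is fixed. The profile is zero
#' exactly when the two states coincide, and is invariant under swapping
#' the A/B labels.
#'
#' @param pairing a `state_pairing` from [pair_states()].
#' @return A `csp_profile` data frame: `seqnum`, `aa`, `dd_h`, `dd_n`,
#'   `dd_comp` (all ppm).
#' @export
compound_csp <- function(pairing) {
  stopifnot(inherits(pairing, "state_pairing"))
  p <- pairing$pairs
  dd_h <- abs(p$shift_h_a - p$shift_h_b)
  dd_n <- abs(p$shift_n_a - p$shift_n_b)
  structure(data.frame(seqnum = p$seqnum, aa = p$aa,
                       dd_h = dd_h, dd_n = dd_n,
                       dd_comp = sqrt(dd_h^2 + (dd_n / 6.5)^2)),
            class = c("csp_profile", "data.frame"))
}

#' Rank residues by chemical-shift asymmetry
#'
#' Residues sorted by compound shift difference, descending; ties broken by
#' ascending residue number. The top of this list localizes the asymmetry
#' (in the dimer studied here it lands on the interface strand).
#'
#' @param profile a `csp_profile` from [compound_csp()].
#' @param top_k how many residues to return (capped at the profile length).
#' @return Data frame of the top residues with their `dd_comp`.
#' @export
rank_asymmetry <- function(profile, top_k = nrow(profile)) {
  stopifnot(inherits(profile, "csp_profile"))
  if (!nrow(profile)) stop_ad("empty profile")
  o <- order(-profile$dd_comp, profile$seqnum)
  out <- profile[o, , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, max(0L, as.integer(top_k)))
}

#' Check the equal-populations assumption from peak intensities
#'
#' Per paired residue the intensity ratio I_A/I_B, plus the median ratio; if
#' the median deviates from 1 by more than `tol` the equal-population
#' assumption is flagged. Residues with a zero intensity are skipped with a
#' warning.
#'
#' @param pairing a `state_pairing`.
#' @param tol flag tolerance on the median ratio's deviation from 1.
#' @return List with `ratios` (data frame), `median_ratio` and `balanced`.
#' @export
equal_population_check <- function(pairing, tol = 0.2) {
  stopifnot(inherits(pairing, "state_pairing"))
  p <- pairing$pairs
  ok <- p$intensity_a > 0 & p$intensity_b > 0
  if (any(!ok))
    warn_ad(sum(!ok), " residue(s) skipped (zero intensity)")
  ratios <- data.frame(seqnum = p$seqnum[ok],
                       ratio = p$intensity_a[ok] / p$intensity_b[ok])
  med <- if (nrow(ratios)) stats::median(ratios$ratio) else NA_real_
  list(ratios = ratios, median_ratio = med,
       balanced = if (is.na(med)) NA else abs(med - 1) <= tol)
}

#' EXSY auto/cross intensity ratio
#'
#' The per-measurement exchange statistic
#' `r = (I_AB + I_BA) / (I_AA + I_BB)`. Under the symmetric equal-R1
#' two-site model relaxation cancels and `E[r](t) = tanh(k_ex t / 2)`, so r
#' is 0 at t = 0 and approaches 1 as the states equilibrate. Measurements
#' with a non-positive auto-peak sum are undefined (NA) and are excluded
#' from fits.
#'
#' @param data an [exsy_dataset] (or any data frame with the intensity
#'   columns).
#' @return Numeric vector of ratios, NA where undefined.
#' @export
ratio_statistic <- function(data) {
  auto <- data$i_aa + data$i_bb
  r <- (data$i_ab + data$i_ba) / auto
  r[!(auto > 0)] <- NA_real_
  r
}

# Pooled-ratio least squares: intensities are summed across residues at
# each mixing time before the ratio is taken (amplitude-weighted pooling),
# so the denominator noise shrinks with the number of residues and the
# per-measurement ratio bias does not propagate into the fit.
tanh_sse <- function(k, t, r_pool) {
  g <- tanh(k * t / 2)
  sum((r_pool - g)^2)
}

fit_ratio_tanh <- function(t_all, auto, cross, k_max = 50) {
  ok <- is.finite(auto) & is.finite(cross) & auto > 0
  t_all <- t_all[ok]
  tg <- sort(unique(t_all))
  idx <- match(t_all, tg)
  a <- vapply(seq_along(tg), function(j) sum(auto[ok][idx == j]), numeric(1))
  cr <- vapply(seq_along(tg), function(j) sum(cross[ok][idx == j]), numeric(1))
  keep <- a > 0
  stats::optimize(tanh_sse, interval = c(0, k_max),
                  t = tg[keep], r_pool = cr[keep] / a[keep],
                  tol = 1e-10)$minimum
}

# Closed-form model intensities for one residue (amplitude separable).
matrix_model <- function(t, k_ex, p_a, r1_a, r1_b) {
  P <- two_site_propagator(t, k_ex, p_a, r1_a, r1_b)
  if (length(t) == 1L) P <- array(P, dim = c(1, 2, 2))
  cbind(i_aa = p_a * P[, 1, 1], i_bb = (1 - p_a) * P[, 2, 2],
        i_ab = p_a * P[, 2, 1], i_ba = (1 - p_a) * P[, 1, 2])
}

# Given k_ex, best (amp, r1_a, r1_b) fit for one residue; returns SSE.
residue_sse <- function(k_ex, t, Y, p_a, equal_r1 = FALSE) {
  obj <- function(par) {
    r1a <- exp(par[1])
    r1b <- if (equal_r1) r1a else exp(par[2])
    M <- matrix_model(t, k_ex, p_a, r1a, r1b)
    amp <- sum(M * Y) / sum(M * M)  # linear least squares in the amplitude
    sum((Y - amp * M)^2)
  }
  # crude R1 start from auto-peak decay
  auto <- Y[, "i_aa"] + Y[, "i_bb"]
  r1_0 <- 1
  if (length(t) >= 2 && all(auto > 0)) {
    sl <- stats::coef(stats::lm(log(auto) ~ t))[2]
    r1_0 <- max(0.05, -sl - k_ex / 2)
  }
  p0 <- if (equal_r1) log(r1_0) else c(log(r1_0), log(r1_0))
  fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-12))
  fit$value
}

#' Fit a global two-site exchange rate to an EXSY series
#'
#' Two estimators sharing one global `k_ex` across residues:
#' * `ratio_tanh` — least-squares fit of the pooled intensity ratios to
#'   `r(t) = tanh(k_ex t / 2)`, the closed form of the symmetric equal-R1
#'   model in which relaxation cancels. Fast and exact when the two states
#'   relax equally.
#' * `matrix_lsq` — least-squares fit of all four intensities per residue to
#'   the full exchange-relaxation propagator with per-residue amplitude and
#'   relaxation rates (R1 of the two states fitted separately) and a shared
#'   global rate. Exact for unequal R1, where the ratio estimator is biased.
#'
#' Populations are fixed at 1/2 (the equal-populations assumption) unless
#' `p_a` says otherwise. Per-residue rates are also fitted (ratio form) for
#' diagnostics.
#'
#' @param data an [exsy_dataset].
#' @param method `"ratio_tanh"` or `"matrix_lsq"`.
#' @param p_a assumed population of state A.
#' @param k_max upper bound of the rate search, s^-1.
#' @return An `exchange_fit` list: `k_ex_hat`, `method`, `per_residue_k`,
#'   `n_residues`, `n_times`; `ci95` is NULL until [bootstrap_ci()] fills
#'   it.
#' @export
fit_exchange_global <- function(data, method = c("ratio_tanh", "matrix_lsq"),
                                p_a = 0.5, k_max = 50) {
  method <- match.arg(method)
  stopifnot(inherits(data, "exsy_dataset"))
  times <- unique(data$t_mix)
  if (length(times) < 2) stop_ad("need at least 2 distinct mixing times")
  residues <- unique(data$residue)
  if (!length(residues)) stop_ad("need at least 1 residue")
  r <- ratio_statistic(data)
  if (any(is.na(r)))
    warn_ad(sum(is.na(r)), " measurement(s) excluded (non-positive auto sum)")
  auto <- data$i_aa + data$i_bb
  cross <- data$i_ab + data$i_ba
  k_hat <- if (method == "ratio_tanh") {
    fit_ratio_tanh(data$t_mix, auto, cross, k_max)
  } else {
    Ys <- lapply(split(seq_len(nrow(data)), data$residue), function(i)
      list(t = data$t_mix[i],
           Y = as.matrix(data[i, c("i_aa", "i_bb", "i_ab", "i_ba")])))
    obj <- function(k) sum(vapply(Ys, function(d)
      residue_sse(k, d$t, d$Y, p_a), numeric(1)))
    k0 <- fit_ratio_tanh(data$t_mix, auto, cross, k_max)  # warm start
    stats::optimize(obj, interval = c(max(0, k0 / 3 - 0.1),
                                      min(k_max, 3 * k0 + 0.5)),
                    tol = 1e-9)$minimum
  }
  if (k_hat < 1e-4)
    warn_ad("fitted exchange rate at the k = 0 boundary; ",
            "no resolvable exchange in these data")
  per_k <- vapply(split(seq_len(nrow(data)), data$residue), function(i)
    fit_ratio_tanh(data$t_mix[i], auto[i], cross[i], k_max), numeric(1))
  structure(list(k_ex_hat = k_hat, ci95 = NULL,
                 per_residue_k = per_k, method = method,
                 n_residues = length(residues), n_times = length(times),
                 n_boot = NULL, seed = NULL),
            class = "exchange_fit")
}

#' @export
print.exchange_fit <- function(x, ...) {
  cat(sprintf("exchange_fit (%s): k_ex = %.4g s^-1", x$method, x$k_ex_hat))
  if (!is.null(x$ci95))
    cat(sprintf(", 95%% CI (%.4g, %.4g) s^-1 [%d bootstrap replicates]",
                x$ci95[1], x$ci95[2], x$n_boot))
  cat(sprintf("\n  %d residues, %d mixing times\n", x$n_residues, x$n_times))
  invisible(x)
}

#' Bootstrap confidence interval for the global exchange rate
#'
#' Percentile 95% interval from resampling residues with replacement and
#' refitting the global rate on each replicate. Residues (not individual
#' time points) are the exchangeable unit: each residue contributes a full
#' mixing-time series.
#'
#' @param data an [exsy_dataset].
#' @param fit_method estimator to refit on each replicate (see
#'   [fit_exchange_global()]).
#' @param n_boot number of bootstrap replicates (values below 100 warn).
#' @param seed RNG seed for reproducibility.
#' @param level confidence level.
#' @return An `exchange_fit` with `ci95`, `n_boot` and `seed` filled in.
#' @export
bootstrap_ci <- function(data, fit_method = "ratio_tanh", n_boot = 1000,
                         seed = 1L, level = 0.95) {
  stopifnot(inherits(data, "exsy_dataset"))
  residues <- unique(data$residue)
  if (length(residues) < 2) stop_ad("need at least 2 residues to bootstrap")
  if (n_boot < 100) warn_ad("n_boot < 100: interval will be noisy")
  fit <- fit_exchange_global(data, method = fit_method)
  alpha <- (1 - level) / 2
  ks <- with_seed(seed, {
    if (fit_method == "ratio_tanh") {
      # sufficient statistics: per-(residue, time) pooled auto/cross sums
      tg <- sort(unique(data$t_mix))
      ti <- match(data$t_mix, tg)
      ri <- match(data$residue, residues)
      A <- matrix(0, length(residues), length(tg))
      CR <- matrix(0, length(residues), length(tg))
      auto <- data$i_aa + data$i_bb
      cross <- data$i_ab + data$i_ba
      ok <- is.finite(auto) & is.finite(cross) & auto > 0
      A[cbind(ri[ok], ti[ok])] <- auto[ok]
      CR[cbind(ri[ok], ti[ok])] <- cross[ok]
      vapply(seq_len(n_boot), function(b) {
        cnt <- tabulate(sample.int(length(residues), replace = TRUE),
                        length(residues))
        a <- as.vector(cnt %*% A)
        cr <- as.vector(cnt %*% CR)
        keep <- a > 0
        stats::optimize(tanh_sse, interval = c(0, 50), t = tg[keep],
                        r_pool = cr[keep] / a[keep], tol = 1e-10)$minimum
      }, numeric(1))
    } else {
      idx_by_res <- split(seq_len(nrow(data)), data$residue)
      vapply(seq_len(n_boot), function(b) {
        take <- sample(residues, replace = TRUE)
        rows <- do.call(rbind, lapply(seq_along(take), function(j) {
          d <- data[idx_by_res[[as.character(take[j])]], ]
          d$residue <- j  # keep resampled copies distinct
          d
        }))
        fit_exchange_global(exsy_dataset(rows), method = fit_method)$k_ex_hat
      }, numeric(1))
    }
  })
  fit$ci95 <- unname(stats::quantile(ks, c(alpha, 1 - alpha)))
  fit$n_boot <- as.integer(n_boot)
  fit$seed <- seed
  fit$boot_k <- ks
  fit
}
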