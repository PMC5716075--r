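#' Configuration for two-site EXSY simulation
#'
#' Describes a slow two-site conformational exchange experiment: a global
#' exchange rate `k_ex = k_AB + k_BA` (s^-1), equilibrium population `p_a`
#' of state A, longitudinal relaxation rates for the two states, a grid of
#' EXSY mixing times, and multiplicative Gaussian intensity noise. The
#' defaults are the desk-scale study conditions used throughout the package:
#' 60 residues, 10 mixing times spanning 0.05-1.0 s, equal populations,
#' equal R1 and 2% noise around a 0.71 s^-1 exchange rate.
#'
#' @param k_ex global exchange rate, s^-1 (sum of the two one-way rates).
#' @param p_a population of state A in (0, 1).
#' @param r1_a,r1_b longitudinal relaxation rates, s^-1.
#' @param t_mix mixing times, s.
#' @param n_residues number of simulated residues.
#' @param noise_sd fractional Gaussian noise (sd as a fraction of the
#'   per-residue amplitude).
#' @param seed RNG seed (NULL leaves the RNG alone).
#' @param first_residue author number of the first simulated residue.
#' @return An `exsy_sim_config` list.
#' @export
exsy_sim_config <- function(k_ex = 0.71, p_a = 0.5, r1_a = 1.2, r1_b = 1.2,
                            t_mix = seq(0.05, 1.0, length.out = 10),
                            n_residues = 60, noise_sd = 0.02, seed = 1L,
                            first_residue = 239L) {
  if (!is_number(k_ex) || k_ex < 0) stop_ad("k_ex must be >= 0")
  if (!is_number(p_a) || p_a <= 0 || p_a >= 1)
    stop_ad("p_a must be in (0, 1)")
  if (!is_number(r1_a) || r1_a < 0 || !is_number(r1_b) || r1_b < 0)
    stop_ad("relaxation rates must be >= 0")
  if (!length(t_mix) || any(!is.finite(t_mix)) || any(t_mix < 0))
    stop_ad("all t_mix must be >= 0")
  if (!is_count(n_residues)) stop_ad("n_residues must be a positive integer")
  if (!is_number(noise_sd) || noise_sd < 0) stop_ad("noise_sd must be >= 0")
  structure(list(k_ex = k_ex, p_a = p_a, r1_a = r1_a, r1_b = r1_b,
                 t_mix = as.numeric(t_mix), n_residues = as.integer(n_residues),
                 noise_sd = noise_sd, seed = seed,
                 first_residue = as.integer(first_residue)),
            class = "exsy_sim_config")
}

#' Longitudinal two-site exchange-relaxation propagator
#'
#' Closed-form matrix exponential `expm(-K t)` of the 2x2 longitudinal
#' evolution matrix
#' `K = [[r1_a + k_AB, -k_BA], [-k_AB, r1_b + k_BA]]`,
#' with one-way rates `k_AB = k_ex * p_b`, `k_BA = k_ex * p_a` (so that
#' detailed balance holds and `k_ex = k_AB + k_BA`). Element `[i, j]` is
#' the fraction of magnetization starting in state j found in state i
#' after time t.
#'
#' @param t mixing time(s), s.
#' @param k_ex,p_a,r1_a,r1_b model parameters as in [exsy_sim_config()].
#' @return A `length(t) x 2 x 2` array (dropped to 2x2 for scalar `t`).
#' @export
two_site_propagator <- function(t, k_ex, p_a = 0.5, r1_a = 0, r1_b = r1_a) {
  p_b <- 1 - p_a
  k_ab <- k_ex * p_b
  k_ba <- k_ex * p_a
  # M = -K t = [[a, b], [c, d]]
  a <- -(r1_a + k_ab) * t
  d <- -(r1_b + k_ba) * t
  b <- k_ba * t
  cc <- k_ab * t
  mu <- (a + d) / 2
  q <- sqrt(((a - d) / 2)^2 + b * cc)  # bc >= 0: q real
  sh <- ifelse(q < 1e-12, 1, sinh(q) / pmax(q, 1e-300))
  ch <- cosh(q)
  out <- array(0, dim = c(length(t), 2, 2))
  out[, 1, 1] <- exp(mu) * (ch + sh * (a - mu))
  out[, 1, 2] <- exp(mu) * sh * b
  out[, 2, 1] <- exp(mu) * sh * cc
  out[, 2, 2] <- exp(mu) * (ch + sh * (d - mu))
  if (length(t) == 1L) out[1, , ] else out
}

#' Simulate an EXSY auto/cross-peak intensity series
#'
#' For each residue and mixing time, the four intensities are computed from
#' the two-site propagator scaled by a per-residue amplitude and the state
#' populations, then perturbed by additive Gaussian noise with sd
#' `noise_sd * amplitude` (truncated at zero). The cross peaks `i_ab`
#' (magnetization starting in A detected in B) and `i_ba` vanish exactly at
#' `t = 0`. Ground-truth parameters and amplitudes are recorded for
#' recovery tests.
#'
#' @param cfg an [exsy_sim_config()].
#' @return An [exsy_dataset].
#' @export
simulate_exsy_series <- function(cfg) {
  stopifnot(inherits(cfg, "exsy_sim_config"))
  res <- seq.int(cfg$first_residue, length.out = cfg$n_residues)
  with_seed(cfg$seed, {
    amp <- stats::runif(cfg$n_residues, 0.5, 2.0)
    P <- two_site_propagator(cfg$t_mix, cfg$k_ex, cfg$p_a, cfg$r1_a, cfg$r1_b)
    if (length(cfg$t_mix) == 1L) P <- array(P, dim = c(1, 2, 2))
    grid <- expand.grid(ti = seq_along(cfg$t_mix), ri = seq_len(cfg$n_residues))
    p_b <- 1 - cfg$p_a
    m <- data.frame(
      residue = res[grid$ri],
      t_mix = cfg$t_mix[grid$ti],
      i_aa = amp[grid$ri] * cfg$p_a * P[grid$ti, 1, 1],
      i_bb = amp[grid$ri] * p_b * P[grid$ti, 2, 2],
      i_ab = amp[grid$ri] * cfg$p_a * P[grid$ti, 2, 1],
      i_ba = amp[grid$ri] * p_b * P[grid$ti, 1, 2])
    if (cfg$noise_sd > 0) {
      for (col in c("i_aa", "i_bb", "i_ab", "i_ba"))
        m[[col]] <- pmax(0, m[[col]] +
          stats::rnorm(nrow(m), sd = cfg$noise_sd * amp[grid$ri]))
    }
    exsy_dataset(m, ground_truth = list(k_ex = cfg$k_ex, p_a = cfg$p_a,
                                        r1_a = cfg$r1_a, r1_b = cfg$r1_b,
                                        amplitude = stats::setNames(amp, res)))
  })
}

#' EXSY measurement collections
#'
#' A data frame of per-residue auto/cross peak intensity quadruples over a
#' mixing-time grid: columns `residue`, `t_mix`, `i_aa`, `i_bb`, `i_ab`,
#' `i_ba`. Each (residue, t_mix) combination appears once. Simulated
#' datasets carry their generating parameters in the `ground_truth`
#' attribute.
#'
#' @param measurements data frame with the columns above.
#' @param ground_truth optional list of generating parameters.
#' @return An `exsy_dataset` (data frame subclass).
#' @export
exsy_dataset <- function(measurements, ground_truth = NULL) {
  need <- c("residue", "t_mix", "i_aa", "i_bb", "i_ab", "i_ba")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) stop_ad("exsy data missing columns: ",
                            paste(miss, collapse = ", "))
  m <- as.data.frame(measurements)[need]
  if (any(m$t_mix < 0)) stop_ad("t_mix must be >= 0")
  ints <- as.matrix(m[c("i_aa", "i_bb", "i_ab", "i_ba")])
  if (!all(is.finite(ints))) stop_ad("non-finite intensities")
  if (anyDuplicated(paste(m$residue, m$t_mix)))
    stop_ad("duplicate (residue, t_mix) measurement")
  structure(m, ground_truth = ground_truth,
            class = c("exsy_dataset", "data.frame"))
}

#' @export
print.exsy_dataset <- function(x, ...) {
  cat(sprintf("exsy_dataset: %d residues x %d mixing times\n",
              length(unique(x$residue)), length(unique(x$t_mix))))
  if (!is.null(attr(x, "ground_truth")))
    cat(sprintf("  ground truth: k_ex = %g s^-1, p_a = %g\n",
                attr(x, "ground_truth")$k_ex, attr(x, "ground_truth")$p_a))
  NextMethod()
}

#' Read/write EXSY intensity tables
#'
#' Tab-separated with header `residue t_mix I_AA I_BB I_AB I_BA`; comment
#' lines prefixed `#` are ignored.
#'
#' @param path file path.
#' @return [exsy_dataset] (reader) or `path` invisibly (writer).
#' @export
read_exsy_table <- function(path) {
  if (!file.exists(path)) stop_ad("no such file: ", path)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  names(df) <- sub("^I_AA$", "i_aa", sub("^I_BB$", "i_bb",
               sub("^I_AB$", "i_ab", sub("^I_BA$", "i_ba", names(df)))))
  exsy_dataset(df)
}

#' @rdname read_exsy_table
#' @param data an [exsy_dataset].
#' @export
write_exsy_table <- function(data, path) {
  df <- data.frame(residue = data$residue,
                   t_mix = sprintf("%.6g", data$t_mix),
                   I_AA = sprintf("%.8g", data$i_aa),
                   I_BB = sprintf("%.8g", data$i_bb),
                   I_AB = sprintf("%.8g", data$i_ab),
                   I_BA = sprintf("%.8g", data$i_ba))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) writeLines(do.call(paste, c(df, sep = "\t")), con)
  invisible(path)
}
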