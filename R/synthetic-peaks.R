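#' Simulate a two-state (doubled) peak list
#'
#' Emits two peaks per residue — states A and B separated by the requested
#' per-residue shift differences, centred on the base shifts — with
#' intensities equal up to `intensity_imbalance` (I_A = (1 + imbalance) *
#' I_B). Residues whose true shift difference is exactly zero collapse to a
#' single merged peak of unknown state, mimicking a monomerized mutant that
#' shows one signal per site. The generating table is attached for
#' recovery tests.
#'
#' @param true_csp data frame with columns `seqnum`, `aa` (optional),
#'   `dd_h`, `dd_n`: the true per-residue 1H/15N shift differences (ppm,
#'   >= 0). Duplicated residues are an error.
#' @param base_shifts optional data frame `seqnum`, `shift_h`, `shift_n` of
#'   state-averaged positions; random amide-window positions if omitted.
#' @param intensity_imbalance relative A/B intensity excess (0 = equal).
#' @param noise_sd fractional Gaussian noise applied to intensities.
#' @param seed RNG seed.
#' @return List with `peaks` (a [peaklist]) and `truth` (the generating
#'   table, including per-residue true compound shifts).
#' @export
simulate_doubled_peaklist <- function(true_csp, base_shifts = NULL,
                                      intensity_imbalance = 0,
                                      noise_sd = 0, seed = 1L) {
  need <- c("seqnum", "dd_h", "dd_n")
  if (!all(need %in% names(true_csp)))
    stop_ad("true_csp needs columns seqnum, dd_h, dd_n")
  if (anyDuplicated(true_csp$seqnum))
    stop_ad("residue duplicated in true_csp")
  if (any(true_csp$dd_h < 0) || any(true_csp$dd_n < 0))
    stop_ad("shift differences must be >= 0")
  n <- nrow(true_csp)
  aa <- true_csp$aa %||% rep("X", n)
  with_seed(seed, {
    if (is.null(base_shifts)) {
      base_shifts <- data.frame(seqnum = true_csp$seqnum,
                                shift_h = stats::runif(n, 7.0, 9.5),
                                shift_n = stats::runif(n, 105, 130))
    }
    bi <- match(true_csp$seqnum, base_shifts$seqnum)
    if (anyNA(bi)) stop_ad("base_shifts missing residues")
    h0 <- base_shifts$shift_h[bi]
    n0 <- base_shifts$shift_n[bi]
    i_b <- rep(1, n)
    i_a <- i_b * (1 + intensity_imbalance)
    doubled <- true_csp$dd_h > 0 | true_csp$dd_n > 0
    mk <- function(state, h, nn, int) data.frame(
      chain = "A", seqnum = true_csp$seqnum, aa = aa,
      shift_h = h, shift_n = nn, intensity = int, state = state)
    rows <- rbind(
      mk("A", h0 - true_csp$dd_h / 2, n0 - true_csp$dd_n / 2, i_a)[doubled, ],
      mk("B", h0 + true_csp$dd_h / 2, n0 + true_csp$dd_n / 2, i_b)[doubled, ],
      mk("unknown", h0, n0, i_a + i_b)[!doubled, ])
    if (noise_sd > 0)
      rows$intensity <- pmax(0, rows$intensity *
                               (1 + stats::rnorm(nrow(rows), sd = noise_sd)))
    rows <- rows[order(rows$seqnum, rows$state), ]
    truth <- data.frame(true_csp[need], aa = aa,
                        dd_comp = sqrt(true_csp$dd_h^2 +
                                       (true_csp$dd_n / 6.5)^2))
    list(peaks = peaklist(rows, source = "simulate_doubled_peaklist"),
         truth = truth)
  })
}

#' A PACT-like ground-truth asymmetry profile
#'
#' Deterministic per-residue shift-difference table over the construct
#' residues 239-313, shaped like the compound-shift asymmetry profile of a
#' Type B dsRBD homodimer: the largest differences at the interface strand
#' residues 283 and 285, intermediate values over the remaining interface
#' (273, 282, 300-305), and small differences elsewhere.
#'
#' @param first,last construct range (author numbering).
#' @return Data frame `seqnum`, `aa`, `dd_h`, `dd_n` usable as `true_csp`
#'   in [simulate_doubled_peaklist()].
#' @export
pact_like_truth <- function(first = 239L, last = 313L) {
  seqnum <- seq.int(first, last)
  n <- length(seqnum)
  dd_h <- rep(0.010, n)
  dd_n <- rep(0.060, n)
  set_res <- function(res, h, nn) {
    i <- match(res, seqnum)
    dd_h[i] <<- h; dd_n[i] <<- nn
  }
  # interface shell
  for (r in c(273, 282, 300, 301, 302, 303, 304, 305))
    set_res(r, 0.050, 0.350)
  # interface strand maxima
  set_res(283, 0.120, 0.800)
  set_res(285, 0.110, 0.750)
  aa <- rep("X", n)
  aa[match(c(273, 282, 283, 285, 304, 305), seqnum)] <-
    c("L", "T", "V", "H", "Q", "Y")
  data.frame(seqnum = seqnum, aa = aa, dd_h = dd_h, dd_n = dd_n)
}
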