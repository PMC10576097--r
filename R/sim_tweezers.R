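#' Worm-like-chain force from fractional extension (Marko-Siggia)
#'
#' Interpolation formula
#' `F = (kT / Lp) * (1 / (4 (1 - x)^2) - 1/4 + x)` with `x = extension /
#' contour length`.
#'
#' @param x_frac Fractional extension in `[0, 1)`.
#' @param Lp Persistence length (nm).
#' @param kT Thermal energy (pN nm); 4.114 at 25 C.
#' @return Force in pN.
#' @export
wlc_force <- function(x_frac, Lp = 50, kT = 4.114) {
  kT / Lp * (1 / (4 * (1 - x_frac)^2) - 0.25 + x_frac)
}

#' Worm-like-chain extension at a given force
#'
#' Numerically inverts the Marko-Siggia interpolation formula by bracketed
#' root finding, to an absolute tolerance of 1e-6 nm on the extension.
#'
#' @param force Stretching force in pN (> 0); vectorised.
#' @param L0 Contour length (nm).
#' @param Lp Persistence length (nm).
#' @param kT Thermal energy (pN nm).
#' @return Extension in nm (always < `L0`).
#' @export
#' @examples
#' wlc_extension(c(0.5, 5), L0 = 1000)
wlc_extension <- function(force, L0, Lp = 50, kT = 4.114) {
  vapply(force, function(f) {
    if (f <= 0) return(0)
    root <- stats::uniroot(function(x) wlc_force(x, Lp, kT) - f,
                           interval = c(0, 1 - 1e-12),
                           tol = 1e-6 / L0)$root
    root * L0
  }, numeric(1))
}

#' Parameters of the simulated magnetic-tweezer experiment
#'
#' Describes a single tether: a worm-like chain of contour length `L0`
#' whose effective contour shrinks to `(1 - compaction_fraction) * L0`
#' while a protein-compacted state is engaged. The compacted state can form
#' stochastically during low-force dwells of the force-decrease branch and
#' persists into the force-increase branch until the force exceeds
#' `unbind_force`.
#'
#' @param L0 Contour length (nm).
#' @param Lp Persistence length (nm).
#' @param kT Thermal energy (pN nm).
#' @param compaction_fraction Fraction of contour sequestered when bound,
#'   in `[0, 1)`.
#' @param binding_prob Probability of switching to the compacted state per
#'   eligible low-force dwell.
#' @param binding_force_max Forces at or below this are binding-eligible
#'   (pN).
#' @param unbind_force Force above which the compacted state is lost (pN).
#' @param noise_sd Gaussian noise per height sample (nm).
#' @param force_schedule List with components `decrease` (descending pN)
#'   and `increase` (ascending pN), all strictly positive.
#' @param dwell_s Dwell duration per force (s).
#' @param sample_hz Height sampling rate (Hz).
#' @return A list of class `tweezer_params`.
#' @export
tweezer_params <- function(L0 = 2000, Lp = 50, kT = 4.114,
                           compaction_fraction = 0.5,
                           binding_prob = 0.8,
                           binding_force_max = 1,
                           unbind_force = 4,
                           noise_sd = 2,
                           force_schedule = list(
                             decrease = c(8, 6, 5, 4, 3, 2.5, 2, 1.5,
                                          1, 0.7, 0.5, 0.3),
                             increase = rev(c(8, 6, 5, 4, 3, 2.5, 2, 1.5,
                                              1, 0.7, 0.5, 0.3))),
                           dwell_s = 20, sample_hz = 10) {
  if (compaction_fraction >= 1 || compaction_fraction < 0)
    stop("`compaction_fraction` must lie in [0, 1)", call. = FALSE)
  if (any(unlist(force_schedule) <= 0))
    stop("force schedule must be strictly positive", call. = FALSE)
  if (is.unsorted(rev(force_schedule$decrease), strictly = TRUE) ||
      is.unsorted(force_schedule$increase, strictly = TRUE))
    stop("decrease branch must be strictly descending and increase ",
         "branch strictly ascending", call. = FALSE)
  structure(list(L0 = L0, Lp = Lp, kT = kT,
                 compaction_fraction = compaction_fraction,
                 binding_prob = binding_prob,
                 binding_force_max = binding_force_max,
                 unbind_force = unbind_force,
                 noise_sd = noise_sd,
                 force_schedule = force_schedule,
                 dwell_s = dwell_s, sample_hz = sample_hz),
            class = "tweezer_params")
}

#' Simulate a force-decrease / force-increase scan of one tether
#'
#' Extension at each force follows the Marko-Siggia worm-like-chain
#' inversion of the effective contour length; with `protein_present`,
#' binding-eligible dwells stochastically switch the tether to the
#' compacted contour, a state that persists into the force-increase branch
#' until the unbinding force is exceeded. Gaussian noise of sd `noise_sd`
#' is added to every height sample.
#'
#' @param p A [tweezer_params()].
#' @param protein_present Is protein in the flow cell?
#' @param seed Integer seed.
#' @param force_binding Deterministically engage the compacted state at the
#'   first eligible dwell (for closed-form checks).
#' @param tether_id Identifier recorded in the output.
#' @return A `force_scan` data frame: `tether_id`, `branch`, `force_pN`,
#'   `time_s`, `height_nm`, plus a logical `bound` column per dwell.
#' @export
gen_force_scan <- function(p, protein_present = FALSE, seed = 1L,
                           force_binding = FALSE, tether_id = "tether1") {
  stopifnot(inherits(p, "tweezer_params"))
  local_stream(seed, "force_scan")
  n_samp <- max(2L, as.integer(p$dwell_s * p$sample_hz))
  steps <- rbind(
    data.frame(branch = "decrease", force_pN = p$force_schedule$decrease),
    data.frame(branch = "increase", force_pN = p$force_schedule$increase))
  bound <- FALSE
  t0 <- 0
  rows <- vector("list", nrow(steps))
  for (i in seq_len(nrow(steps))) {
    f <- steps$force_pN[i]
    if (protein_present && !bound && steps$branch[i] == "decrease" &&
        f <= p$binding_force_max) {
      bound <- force_binding || stats::runif(1) < p$binding_prob
    }
    if (bound && f > p$unbind_force) bound <- FALSE
    L_eff <- if (bound) (1 - p$compaction_fraction) * p$L0 else p$L0
    ext <- wlc_extension(f, L_eff, p$Lp, p$kT)
    h <- ext + if (p$noise_sd > 0)
      stats::rnorm(n_samp, 0, p$noise_sd) else numeric(n_samp)
    rows[[i]] <- data.frame(
      tether_id = tether_id, branch = steps$branch[i], force_pN = f,
      time_s = t0 + seq_len(n_samp) / p$sample_hz,
      height_nm = h, bound = bound, stringsAsFactors = FALSE)
    t0 <- t0 + p$dwell_s
  }
  out <- do.call(rbind, rows)
  class(out) <- c("force_scan", "data.frame")
  out
}
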