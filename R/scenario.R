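#' Define a latent arrest scenario
#'
#' An `arrest_scenario` is the single source of truth for all synthetic data
#' modalities. It couples everything to one latent ESR-strength trajectory
#' \eqn{s(t) \in [0,1]}: induced-ESR transcripts are upscaled and
#' repressed-ESR transcripts downscaled by `fold_shift^{\pm s(t)}`, the true
#' ribosomal mass fraction declines as
#' \eqn{f(t) = f_0 (1 - k\, s(t))}, the GEM diffusion coefficient rises as
#' \eqn{D(t) = D_0 (1 + \rho\, s(t))}, viability decays with \eqn{s(t)}, and
#' the true mean cell volume follows a capped exponential (with optional
#' linear transition) that plateaus the way arrested cdc-ts cultures do.
#'
#' @param label Free-text condition label, e.g. `"G1-arrest"`.
#' @param t_grid Sampling times in hours (non-negative, strictly increasing).
#' @param v0 Initial mean cell volume in fL.
#' @param doubling_time Volume doubling time in minutes; the reference
#'   exponential in the figures uses 90 min.
#' @param plateau_volume Volume ceiling in fL (`>= v0`); `Inf` disables the
#'   plateau.
#' @param esr_strength Function of time (hours) returning \eqn{s(t)} in
#'   `[0,1]`, or a numeric vector aligned with `t_grid`. Default
#'   \eqn{1 - e^{-t/3}}: strictly rising, near-saturated by 9 h, matching the
#'   qualitative time course of ESR activation during cdc-ts arrests.
#' @param fold_shift Maximal multiplicative transcript shift applied to ESR
#'   gene sets at `s = 1` (iESR multiplied by `fold_shift^s`, rESR divided).
#' @param rp_fraction0 Ribosomal mass fraction of the proteome at `t = 0`
#'   (yeast log-phase values are around 0.2).
#' @param rp_decline Maximal fractional decline `k` of the ribosome fraction
#'   (in `[0, 1)`), reached at `s = 1`.
#' @param diffusion0 GEM effective diffusion coefficient at `t = 0`, um^2/s.
#' @param diffusion_rise Fractional increase of `D` at `s = 1`; crowding
#'   relief in diluted cytoplasm makes tracer diffusion faster.
#' @param viability_drop Fraction of plated cells lost at `s = 1`; survival
#'   probability is `1 - viability_drop * s(t)`.
#' @param linear_from Volume (fL) above which growth switches from
#'   exponential to linear (slope continuous at the switch) before hitting
#'   the plateau; `NULL` keeps the pure capped exponential.
#' @param noise Named list of per-modality noise levels:
#'   `expression` (log-normal sdlog on TPM), `tmt` (CV of multiplicative
#'   peptide noise), `volume_cv` (CV of the log-normal cell-volume
#'   population), `localization` (static tracking error sigma, um),
#'   `viability` (`TRUE` for binomial counts, `FALSE` for deterministic).
#'   Omitted entries keep defaults.
#' @param seed Integer seed; identical seed + scenario gives bit-identical
#'   synthetic data.
#'
#' @return An object of class `arrest_scenario`.
#' @seealso [make_expression()], [make_tmt()], [make_volume_histograms()],
#'   [make_trajectories()], [make_viability()], [scenario_truth()]
#' @export
#' @examples
#' sc <- arrest_scenario("G1-arrest", t_grid = 0:9)
#' scenario_truth(sc)
arrest_scenario <- function(label = "G1-arrest",
                            t_grid = 0:9,
                            v0 = 60,
                            doubling_time = 90,
                            plateau_volume = 800,
                            esr_strength = function(t) 1 - exp(-t / 3),
                            fold_shift = 4,
                            rp_fraction0 = 0.2,
                            rp_decline = 0.5,
                            diffusion0 = 0.3,
                            diffusion_rise = 0.5,
                            viability_drop = 0.5,
                            linear_from = NULL,
                            noise = list(),
                            seed = 1L) {
  stopifnot(is.numeric(t_grid), length(t_grid) >= 1, all(t_grid >= 0),
            !is.unsorted(t_grid, strictly = TRUE))
  stopifnot(v0 > 0, doubling_time > 0)
  if (plateau_volume < v0)
    stop("plateau_volume must be >= v0")
  if (is.numeric(esr_strength)) {
    if (length(esr_strength) != length(t_grid))
      stop("numeric esr_strength must align with t_grid")
    s_vals <- esr_strength
    esr_strength <- stats::approxfun(t_grid, s_vals, rule = 2)
  }
  s <- esr_strength(t_grid)
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1))
    stop("esr_strength must map t_grid into [0, 1]")
  stopifnot(rp_fraction0 > 0, rp_fraction0 < 1,
            rp_decline >= 0, rp_decline < 1)
  if (rp_fraction0 * (1 - rp_decline) <= 0)
    stop("rp_fraction0 * (1 - rp_decline) must stay positive")
  stopifnot(diffusion0 >= 0, diffusion_rise >= 0,
            viability_drop >= 0, viability_drop <= 1, fold_shift > 0)

  default_noise <- list(expression = 0.1, tmt = 0.05, volume_cv = 0.2,
                        localization = 0, viability = TRUE)
  unknown <- setdiff(names(noise), names(default_noise))
  if (length(unknown))
    stop("unknown noise entries: ", paste(unknown, collapse = ", "))
  default_noise[names(noise)] <- noise

  structure(
    list(label = label, t_grid = as.numeric(t_grid), v0 = v0,
         doubling_time = doubling_time, plateau_volume = plateau_volume,
         esr_strength = esr_strength, fold_shift = fold_shift,
         rp_fraction0 = rp_fraction0, rp_decline = rp_decline,
         diffusion0 = diffusion0, diffusion_rise = diffusion_rise,
         viability_drop = viability_drop, linear_from = linear_from,
         noise = default_noise, seed = as.integer(seed)),
    class = "arrest_scenario"
  )
}

#' @export
print.arrest_scenario <- function(x, ...) {
  tr <- scenario_truth(x)
  cat("<arrest_scenario> ", x$label, "\n", sep = "")
  cat("  timepoints: ", length(x$t_grid), " (",
      min(x$t_grid), "-", max(x$t_grid), " h), seed ", x$seed, "\n", sep = "")
  cat(sprintf("  volume: %g -> %g fL (doubling %g min, plateau %g fL)\n",
              x$v0, tr$volume_fl[nrow(tr)], x$doubling_time,
              x$plateau_volume))
  cat(sprintf("  rp fraction: %.3f -> %.3f; D: %.3f -> %.3f um^2/s\n",
              tr$rp_fraction[1], tr$rp_fraction[nrow(tr)],
              tr$diffusion_um2s[1], tr$diffusion_um2s[nrow(tr)]))
  invisible(x)
}

#' True mean volume of a scenario at given times
#'
#' Capped exponential: \eqn{v(t) = \min(v_0 2^{60 t / T_d},\ V_{max})},
#' optionally passing through a linear segment (slope continuous) once the
#' exponential crosses `linear_from`.
#'
#' @param scenario An [arrest_scenario()].
#' @param t Times in hours (default the scenario grid).
#' @return Numeric vector of volumes in fL.
#' @export
scenario_volume <- function(scenario, t = scenario$t_grid) {
  v_exp <- exponential_reference(scenario$v0, scenario$doubling_time, t)
  v <- v_exp
  lf <- scenario$linear_from
  if (!is.null(lf) && lf < scenario$plateau_volume) {
    # time at which the exponential reaches the linear-transition volume
    t_star <- scenario$doubling_time / 60 * log2(lf / scenario$v0)
    slope <- lf * log(2) * 60 / scenario$doubling_time   # fL per hour
    lin <- lf + slope * (t - t_star)
    v <- ifelse(t > t_star, lin, v)
  }
  pmin(v, scenario$plateau_volume)
}

#' Ground-truth table for a scenario
#'
#' One row per timepoint with the latent quantities every generator uses:
#' ESR strength, true mean volume, ribosomal mass fraction, GEM diffusion
#' coefficient and survival probability.
#'
#' @param scenario An [arrest_scenario()].
#' @return A data.frame with columns `timepoint_h`, `esr_strength`,
#'   `volume_fl`, `rp_fraction`, `diffusion_um2s`, `survival`.
#' @export
scenario_truth <- function(scenario) {
  t <- scenario$t_grid
  s <- scenario$esr_strength(t)
  data.frame(
    timepoint_h = t,
    esr_strength = s,
    volume_fl = scenario_volume(scenario, t),
    rp_fraction = scenario$rp_fraction0 * (1 - scenario$rp_decline * s),
    diffusion_um2s = scenario$diffusion0 * (1 + scenario$diffusion_rise * s),
    survival = pmax(0, 1 - scenario$viability_drop * s)
  )
}

# Derive a reproducible sub-seed so the five generators draw from
# independent streams even when called in a different order.
scenario_seed <- function(scenario, offset) {
  (scenario$seed * 7L + as.integer(offset)) %% 2147483587L
}
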