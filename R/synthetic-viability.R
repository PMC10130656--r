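#' Generate synthetic colony-count viability data under an arrest scenario
#'
#' Emulates a plating assay: a fixed number of cells (default 300, the
#' standard protocol) is plated at each timepoint and the number of
#' colony-forming units is drawn binomially with survival probability
#' `1 - viability_drop * s(t)`. With `scenario$noise$viability = FALSE` the
#' counts are the rounded expectations (deterministic mode).
#'
#' @param scenario An [arrest_scenario()].
#' @param plated Cells plated per timepoint (default 300).
#' @param survival Optional function of time (hours) overriding the
#'   scenario's survival curve.
#' @return List with `counts` (data.frame: `timepoint_h`, `plated`,
#'   `colonies`) and `truth` (per-timepoint survival probability).
#' @export
make_viability <- function(scenario, plated = 300, survival = NULL) {
  stopifnot(inherits(scenario, "arrest_scenario"))
  if (plated <= 0) stop("plated must be positive")
  t <- scenario$t_grid
  p <- if (is.null(survival)) {
    pmax(0, 1 - scenario$viability_drop * scenario$esr_strength(t))
  } else {
    survival(t)
  }
  if (any(p < 0 | p > 1)) stop("survival probabilities must lie in [0, 1]")

  if (isTRUE(scenario$noise$viability)) {
    with_seed_local(scenario_seed(scenario, 71L), {
      colonies <- stats::rbinom(length(t), plated, p)
    })
  } else {
    colonies <- round(plated * p)
  }

  list(counts = data.frame(timepoint_h = t, plated = plated,
                           colonies = colonies),
       truth = data.frame(timepoint_h = t, survival = p))
}
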