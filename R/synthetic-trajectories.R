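#' Generate synthetic GEM particle trajectories under an arrest scenario
#'
#' Simulates 2D Brownian tracks at each timepoint with the scenario's true
#' diffusion coefficient \eqn{D(t) = D_0 (1 + \rho\, s(t))}: per-axis step
#' standard deviation \eqn{\sqrt{2 D \Delta t}}, optional static
#' localization error (`scenario$noise$localization`, um, added
#' independently per frame), and optional tracking dropout that truncates
#' tracks to a random length.
#'
#' @param scenario An [arrest_scenario()].
#' @param n_tracks Tracks per timepoint.
#' @param n_frames Frames per track; the default 400 matches 4 s at 100
#'   frames per second.
#' @param dt Frame interval in seconds (default 0.01).
#' @param dropout Probability per track of being truncated at a uniformly
#'   drawn length (at least 10 frames).
#' @return List with `tracks` (data.frame: `condition` timepoint label,
#'   `track_id`, `frame`, `x_um`, `y_um`) and `truth` (per-timepoint true
#'   D and the localization sigma).
#' @export
make_trajectories <- function(scenario, n_tracks = 200, n_frames = 400,
                              dt = 0.01, dropout = 0) {
  stopifnot(inherits(scenario, "arrest_scenario"))
  stopifnot(n_tracks > 0, n_frames >= 2, dt > 0, dropout >= 0, dropout < 1)
  t <- scenario$t_grid
  d_true <- scenario$diffusion0 *
    (1 + scenario$diffusion_rise * scenario$esr_strength(t))
  if (any(d_true < 0)) stop("diffusion coefficient must be non-negative")
  sigma <- scenario$noise$localization

  out <- vector("list", length(t))
  with_seed_local(scenario_seed(scenario, 53L), {
    for (j in seq_along(t)) {
      step_sd <- sqrt(2 * d_true[j] * dt)
      lengths <- rep(n_frames, n_tracks)
      if (dropout > 0) {
        cut <- stats::runif(n_tracks) < dropout
        lengths[cut] <- pmax(10L, as.integer(
          stats::runif(sum(cut), 10, n_frames)))
      }
      per_track <- lapply(seq_len(n_tracks), function(i) {
        n <- lengths[i]
        x <- cumsum(c(0, stats::rnorm(n - 1, 0, step_sd)))
        y <- cumsum(c(0, stats::rnorm(n - 1, 0, step_sd)))
        if (sigma > 0) {
          x <- x + stats::rnorm(n, 0, sigma)
          y <- y + stats::rnorm(n, 0, sigma)
        }
        data.frame(condition = sprintf("%gh", t[j]),
                   track_id = sprintf("t%g_track%04d", t[j], i),
                   frame = seq_len(n) - 1L, x_um = x, y_um = y)
      })
      out[[j]] <- do.call(rbind, per_track)
    }
  })

  list(tracks = do.call(rbind, out),
       truth = data.frame(timepoint_h = t, condition = sprintf("%gh", t),
                          diffusion_um2s = d_true,
                          localization_um = sigma))
}
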