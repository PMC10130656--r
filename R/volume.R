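#' Mean cell volume by the half-maximal-count rule
#'
#' Coulter histograms of arrested cultures carry debris and doublet tails;
#' the analysis convention is to keep only the bins whose count exceeds
#' half the maximal bin count and report the count-weighted mean volume of
#' those bins.
#'
#' @param histogram Data.frame with columns `bin_volume_fl` (strictly
#'   increasing) and `count` (non-negative, at least one positive).
#' @param inclusive Treat a bin exactly at half the maximum as retained
#'   (`>=` instead of the default strict `>`); only boundary histograms
#'   differ.
#' @return Mean volume in fL. A warning is emitted when the retained bins
#'   are non-contiguous (multimodal histogram).
#' @export
#' @examples
#' h <- data.frame(bin_volume_fl = c(10, 20, 30, 40, 50, 60),
#'                 count = c(1, 5, 10, 8, 4, 1))
#' mean_volume(h)  # 620/18 = 34.44 fL
mean_volume <- function(histogram, inclusive = FALSE) {
  stopifnot(all(c("bin_volume_fl", "count") %in% names(histogram)))
  v <- histogram$bin_volume_fl
  n <- histogram$count
  if (any(n < 0) || all(n == 0)) stop("need non-negative counts, not all zero")
  if (is.unsorted(v, strictly = TRUE)) stop("bin volumes must be strictly increasing")
  if (length(v) == 1) return(v)
  half <- max(n) / 2
  keep <- if (inclusive) n >= half else n > half
  # warn on genuine multimodality: a secondary retained run carrying a
  # substantial share of the retained counts (single-bin dips from
  # counting noise are tolerated silently)
  idx <- which(keep)
  runs <- split(idx, cumsum(c(1, diff(idx) > 1)))
  if (length(runs) > 1) {
    run_counts <- vapply(runs, function(i) sum(n[i]), numeric(1))
    if (max(run_counts) < 0.8 * sum(run_counts))
      warning("retained bins are non-contiguous; histogram looks multimodal")
  }
  sum(v[keep] * n[keep]) / sum(n[keep])
}

#' Exponential volume growth reference
#'
#' The theoretical perfect exponential growth curve drawn alongside arrest
#' trajectories: \eqn{v(t) = v_0\, 2^{60 t / T_d}} with `t` in hours and
#' the doubling time in minutes (90 min for budding yeast at 37 C).
#'
#' @param v0 Anchoring volume at `t = 0`, fL.
#' @param doubling_time_min Doubling time in minutes.
#' @param t_hours Times in hours.
#' @return Volumes in fL.
#' @export
#' @examples
#' exponential_reference(100, 90, c(0, 1.5, 9))  # 100, 200, 6400
exponential_reference <- function(v0, doubling_time_min, t_hours) {
  stopifnot(v0 > 0, doubling_time_min > 0)
  v0 * 2 ^ (60 * t_hours / doubling_time_min)
}

#' Growth attenuation profile against an exponential reference
#'
#' Quantifies how an observed mean-volume trajectory falls away from
#' perfect exponential growth: per-timepoint log2(observed / reference), a
#' plateau estimate (mean observed volume over a terminal window), and an
#' attenuation flag raised when the terminal growth slope drops below a
#' configurable fraction of the initial slope.
#'
#' @param series Data.frame with columns `timepoint_h` and `mean_volume_fl`.
#' @param doubling_time_min Reference doubling time (minutes; default 90).
#' @param v0 Reference anchor; defaults to the first observed volume.
#' @param plateau_window_h Width of the terminal window averaged for the
#'   plateau estimate (default the final 2 h).
#' @param attenuation_ratio Flag the series as attenuated when the terminal
#'   slope (fL/h over the plateau window) is below this fraction of the
#'   initial slope over the first two timepoints (default 0.25).
#' @return List with `deviations` (data.frame: `timepoint_h`,
#'   `mean_volume_fl`, `reference_fl`, `log2_deviation`), `plateau_fl`,
#'   `attenuated` (logical, `NA` when fewer than 3 timepoints), and the
#'   two slopes.
#' @export
attenuation_profile <- function(series, doubling_time_min = 90, v0 = NULL,
                                plateau_window_h = 2,
                                attenuation_ratio = 0.25) {
  stopifnot(all(c("timepoint_h", "mean_volume_fl") %in% names(series)))
  series <- series[order(series$timepoint_h), , drop = FALSE]
  t <- series$timepoint_h
  v <- series$mean_volume_fl
  if (is.null(v0)) v0 <- v[1]
  ref <- exponential_reference(v0, doubling_time_min, t - t[1])
  dev <- data.frame(timepoint_h = t, mean_volume_fl = v, reference_fl = ref,
                    log2_deviation = log2(v / ref))

  in_window <- t >= max(t) - plateau_window_h
  plateau <- mean(v[in_window])

  init_slope <- term_slope <- attenuated <- NA_real_
  if (length(t) >= 3) {
    init_slope <- (v[2] - v[1]) / (t[2] - t[1])
    tw <- t[in_window]; vw <- v[in_window]
    term_slope <- if (length(tw) >= 2) {
      unname(stats::coef(stats::lm(vw ~ tw))[2])
    } else {
      (v[length(v)] - v[length(v) - 1]) / (t[length(t)] - t[length(t) - 1])
    }
    attenuated <- term_slope < attenuation_ratio * init_slope
  }
  list(deviations = dev, plateau_fl = plateau,
       attenuated = attenuated, initial_slope = init_slope,
       terminal_slope = term_slope)
}

#' Protein-dilution metric: protein per cell volume
#'
#' Divides protein-per-cell by mean cell volume at matched timepoints and
#' normalizes to a matched control series in log2, quantifying cytoplasm
#' dilution — the decline of biomass per unit volume when volume growth
#' outpaces protein synthesis.
#'
#' @param protein_series Data.frame: `timepoint_h`, `protein_per_cell`.
#' @param volume_series Data.frame: `timepoint_h`, `mean_volume_fl`.
#' @param control Optional data.frame in the same joined layout
#'   (`timepoint_h`, `protein_per_cell`, `mean_volume_fl`) used for the
#'   log2 normalization; omitted, the log2 column is relative to the first
#'   timepoint.
#' @return Data.frame: `timepoint_h`, `protein_per_cell`,
#'   `mean_volume_fl`, `protein_per_volume`, `log2_relative`.
#' @export
dilution_metric <- function(protein_series, volume_series, control = NULL) {
  stopifnot(all(c("timepoint_h", "protein_per_cell") %in%
                  names(protein_series)),
            all(c("timepoint_h", "mean_volume_fl") %in%
                  names(volume_series)))
  joined <- merge(protein_series, volume_series, by = "timepoint_h")
  if (!nrow(joined) || nrow(joined) < nrow(protein_series))
    stop("protein and volume series have unmatched timepoints")
  joined <- joined[order(joined$timepoint_h), , drop = FALSE]
  joined$protein_per_volume <-
    joined$protein_per_cell / joined$mean_volume_fl

  if (!is.null(control)) {
    ctl <- control$protein_per_cell / control$mean_volume_fl
    ref <- ctl[match(joined$timepoint_h, control$timepoint_h)]
    if (any(is.na(ref)))
      stop("control series missing timepoint(s): ",
           paste(joined$timepoint_h[is.na(ref)], collapse = ", "))
  } else {
    ref <- joined$protein_per_volume[1]
  }
  joined$log2_relative <- log2(joined$protein_per_volume / ref)
  rownames(joined) <- NULL
  joined
}
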