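#' Time-averaged mean-square displacement of one trajectory
#'
#' For each lag \eqn{\tau = k\, dt}, averages the squared 2D displacement
#' over all (overlapping) frame pairs separated by exactly `k` frames.
#' Frame gaps from tracking dropouts are handled by pairing only frames at
#' the exact separation, with the number of contributing pairs recorded per
#' lag.
#'
#' @param track Data.frame with columns `frame` (strictly increasing
#'   integers), `x_um`, `y_um`.
#' @param dt Frame interval in seconds (default 0.01, i.e. 100 fps).
#' @param max_lag Largest lag in seconds (default the full span).
#' @return Data.frame: `lag_s`, `msd_um2`, `n_pairs` (lags with no
#'   available pair are omitted).
#' @export
#' @examples
#' tr <- data.frame(frame = 0:2, x_um = 0:2, y_um = 0)
#' time_averaged_msd(tr, dt = 0.01)  # MSD(0.01)=1, MSD(0.02)=4
time_averaged_msd <- function(track, dt = 0.01, max_lag = NULL) {
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(track)))
  f <- as.integer(track$frame)
  if (length(f) < 2) stop("need at least two positions")
  if (is.unsorted(f, strictly = TRUE))
    stop("frames must be strictly increasing")
  span <- f[length(f)] - f[1]
  k_max <- if (is.null(max_lag)) span else min(span, floor(max_lag / dt))
  if (k_max < 1) stop("max_lag below one frame interval")

  # index positions by frame number for gap-aware pairing
  offset <- f[1] - 1L
  pos <- rep(NA_integer_, span + 1L)
  pos[f - offset] <- seq_along(f)
  x <- track$x_um
  y <- track$y_um

  out <- lapply(seq_len(k_max), function(k) {
    i <- pos[seq_len(span + 1L - k)]
    j <- pos[seq_len(span + 1L - k) + k]
    ok <- !is.na(i) & !is.na(j)
    if (!any(ok)) return(NULL)
    d2 <- (x[j[ok]] - x[i[ok]])^2 + (y[j[ok]] - y[i[ok]])^2
    data.frame(lag_s = k * dt, msd_um2 = mean(d2), n_pairs = sum(ok))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Apparent diffusion coefficient from a short-lag MSD fit
#'
#' Ordinary least squares of MSD on lag over the short-timescale window
#' (default lags strictly below 0.1 s, i.e. below 100 ms): for 2D imaging
#' `MSD = 4 D tau + 4 sigma^2`, so `d_eff` is the slope over 4 and the
#' intercept absorbs the static localization error. A negative fitted
#' slope is clamped to `d_eff = 0` and flagged.
#'
#' @param msd_curve Data.frame from [time_averaged_msd()].
#' @param fit_window Two numbers `(lo, hi)`: lags with `lo < lag < hi`
#'   enter the fit (default `c(0, 0.1)` s).
#' @param zero_intercept Force the fit through the origin.
#' @param min_fit_points Minimum lags required inside the window.
#' @param track_id Label carried into the result.
#' @return One-row data.frame: `track_id`, `d_eff_um2s`, `intercept_um2`,
#'   `n_fit_lags`, `clamped`.
#' @export
fit_deff <- function(msd_curve, fit_window = c(0, 0.1),
                     zero_intercept = FALSE, min_fit_points = 3,
                     track_id = NA_character_) {
  sel <- msd_curve$lag_s > fit_window[1] & msd_curve$lag_s < fit_window[2]
  if (sum(sel) < min_fit_points)
    stop("track ", track_id, ": only ", sum(sel),
         " lag(s) inside the fit window")
  tau <- msd_curve$lag_s[sel]
  msd <- msd_curve$msd_um2[sel]
  if (zero_intercept) {
    slope <- sum(tau * msd) / sum(tau^2)
    intercept <- 0
  } else {
    fit <- stats::lsfit(tau, msd)
    intercept <- unname(fit$coefficients[1])
    slope <- unname(fit$coefficients[2])
  }
  clamped <- slope < 0
  data.frame(track_id = track_id,
             d_eff_um2s = max(slope, 0) / 4,
             intercept_um2 = intercept,
             n_fit_lags = sum(sel), clamped = clamped,
             stringsAsFactors = FALSE)
}

#' Per-track diffusion estimates for a whole track table
#'
#' Runs [time_averaged_msd()] and [fit_deff()] on every track; tracks
#' shorter than `min_frames` are skipped with a message.
#'
#' @param tracks Data.frame with columns `track_id`, `frame`, `x_um`,
#'   `y_um` and optionally `condition`.
#' @param dt Frame interval, s.
#' @param fit_window Short-timescale fit window, s.
#' @param min_frames Minimum frames per track (default 10).
#' @param zero_intercept Force fits through the origin.
#' @return Data.frame of per-track estimates (with `condition` when
#'   present).
#' @export
estimate_diffusion <- function(tracks, dt = 0.01, fit_window = c(0, 0.1),
                               min_frames = 10, zero_intercept = FALSE) {
  stopifnot(all(c("track_id", "frame", "x_um", "y_um") %in% names(tracks)))
  max_k <- ceiling(fit_window[2] / dt)
  pieces <- split(tracks, tracks$track_id)
  short <- vapply(pieces, nrow, integer(1)) < min_frames
  if (any(short))
    message(sum(short), " track(s) below ", min_frames, " frames skipped")
  pieces <- pieces[!short]
  if (!length(pieces)) stop("no track long enough to fit")

  out <- lapply(pieces, function(tr) {
    msd <- time_averaged_msd(tr, dt = dt, max_lag = max_k * dt)
    est <- fit_deff(msd, fit_window = fit_window,
                    zero_intercept = zero_intercept,
                    track_id = tr$track_id[1])
    if ("condition" %in% names(tr)) est$condition <- tr$condition[1]
    est
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Median diffusion coefficient per condition with bootstrap CI
#'
#' Conditions are summarized by the median of the per-track `d_eff`
#' estimates, the robust convention for skewed single-particle
#' distributions, with a percentile bootstrap over tracks.
#'
#' @param estimates Data.frame from [estimate_diffusion()]; a `condition`
#'   column splits the summary, otherwise one row is returned.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Seed for the bootstrap resampling.
#' @return Data.frame: `condition`, `median_d_eff_um2s`, `ci_lo`, `ci_hi`,
#'   `n_tracks`.
#' @export
condition_median <- function(estimates, n_boot = 1000, conf = 0.95,
                             seed = 1L) {
  stopifnot(nrow(estimates) >= 1)
  cond <- if ("condition" %in% names(estimates)) estimates$condition
          else rep("all", nrow(estimates))
  alpha <- (1 - conf) / 2
  with_seed_local(seed, {
    out <- lapply(unique(cond), function(cc) {
      d <- estimates$d_eff_um2s[cond == cc]
      boot <- replicate(n_boot, stats::median(sample(d, replace = TRUE)))
      data.frame(condition = cc, median_d_eff_um2s = stats::median(d),
                 ci_lo = unname(stats::quantile(boot, alpha)),
                 ci_hi = unname(stats::quantile(boot, 1 - alpha)),
                 n_tracks = length(d), stringsAsFactors = FALSE)
    })
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
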