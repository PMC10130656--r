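#' Ribosome-to-protein ratio from biochemical readings
#'
#' The sucrose-cushion assay reads ribosome concentration as the A260 of
#' the resuspended pellet (RNA absorbance, proportional to intact-ribosome
#' concentration) and total protein by Bradford assay. The ratio
#' `a260 / protein_mg_ml` is a relative ribosome concentration per unit
#' protein; the optional conversion `1 A260 ~ 40 ug/mL RNA` is off by
#' default because only normalized ratios are ever reported.
#'
#' @param measurements Data.frame with columns `protein_mg_ml` and `a260`
#'   (additional metadata columns such as `sample`, `timepoint_h` are
#'   carried through), or two numerics.
#' @param a260 When `measurements` is a single protein concentration, the
#'   matching A260 reading.
#' @param rna_conversion Multiply A260 by this factor (ug RNA per mL per
#'   absorbance unit) before forming the ratio; `NULL` (default) leaves
#'   A260 as a relative readout.
#' @return Numeric ratio(s); for data.frame input, the input with a `ratio`
#'   column appended.
#' @export
#' @examples
#' ribosome_protein_ratio(2.0, 1.0)  # 0.5
ribosome_protein_ratio <- function(measurements, a260 = NULL,
                                   rna_conversion = NULL) {
  if (is.data.frame(measurements)) {
    stopifnot(all(c("protein_mg_ml", "a260") %in% names(measurements)))
    prot <- measurements$protein_mg_ml
    rib <- measurements$a260
  } else {
    prot <- measurements
    rib <- a260
  }
  if (any(!is.finite(prot)) || any(prot <= 0))
    stop("protein concentration must be positive")
  if (any(!is.finite(rib)) || any(rib < 0))
    stop("A260 readings must be non-negative")
  if (!is.null(rna_conversion)) rib <- rib * rna_conversion
  ratio <- rib / prot
  if (is.data.frame(measurements)) {
    measurements$ratio <- ratio
    measurements
  } else {
    ratio
  }
}

#' Normalize a ratio series to a matched control series
#'
#' For each timepoint, divides the sample ratio by the control ratio at the
#' same timepoint and log2-transforms, reproducing the
#' normalized-to-cycling-control convention of arrest time courses.
#' Replicates at a timepoint are averaged first; dispersion is reported as
#' half the range for two replicates and the standard deviation for three
#' or more (the figure-legend convention).
#'
#' @param series Data.frame with columns `timepoint_h` and `ratio`
#'   (replicate rows allowed).
#' @param control_series Control data.frame in the same layout; every
#'   sample timepoint must be present.
#' @return Data.frame: `timepoint_h`, `ratio`, `control_ratio`,
#'   `log2_relative`, `dispersion`, `n_replicates`.
#' @export
normalize_to_control <- function(series, control_series) {
  stopifnot(all(c("timepoint_h", "ratio") %in% names(series)),
            all(c("timepoint_h", "ratio") %in% names(control_series)))
  missing <- setdiff(series$timepoint_h, control_series$timepoint_h)
  if (length(missing))
    stop("no matched control at timepoint(s): ",
         paste(sort(unique(missing)), collapse = ", "))

  summarize <- function(df) {
    tp <- sort(unique(df$timepoint_h))
    do.call(rbind, lapply(tp, function(t) {
      r <- df$ratio[df$timepoint_h == t]
      data.frame(timepoint_h = t, ratio = mean(r),
                 dispersion = replicate_dispersion(r),
                 n_replicates = length(r))
    }))
  }
  s <- summarize(series)
  ctl <- summarize(control_series)
  ctl_ratio <- ctl$ratio[match(s$timepoint_h, ctl$timepoint_h)]

  data.frame(timepoint_h = s$timepoint_h, ratio = s$ratio,
             control_ratio = ctl_ratio,
             log2_relative = log2(s$ratio / ctl_ratio),
             dispersion = s$dispersion, n_replicates = s$n_replicates)
}

# Figure-legend convention: range/2 for two replicates, sd for >= 3.
replicate_dispersion <- function(x) {
  if (length(x) < 2) return(NA_real_)
  if (length(x) == 2) return(diff(range(x)) / 2)
  stats::sd(x)
}
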