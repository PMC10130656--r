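#' Colony-count viability series normalized to a reference timepoint
#'
#' Viability is colonies over cells plated (default 300 per the plating
#' protocol), normalized to the reference timepoint of each experiment —
#' 2 h by default, with 0 h supported for designs normalized to the shift
#' itself. Replicate rows at a timepoint are averaged; dispersion follows
#' the two-replicate range convention of [normalize_to_control()].
#'
#' @param colony_counts Data.frame with columns `timepoint_h`, `colonies`
#'   and optionally `plated`.
#' @param plated Cells plated (used when the table has no `plated`
#'   column; default 300).
#' @param reference_timepoint Timepoint (h) whose viability defines 1
#'   (default 2).
#' @return Data.frame: `timepoint_h`, `colonies`, `plated`, `fraction`,
#'   `viability` (normalized), `dispersion`, `n_replicates`.
#' @export
#' @examples
#' counts <- data.frame(timepoint_h = c(2, 6, 9),
#'                      colonies = c(280, 250, 140))
#' viability(counts)  # 1.0, 0.893, 0.5
viability <- function(colony_counts, plated = 300, reference_timepoint = 2) {
  stopifnot(all(c("timepoint_h", "colonies") %in% names(colony_counts)))
  if (!"plated" %in% names(colony_counts)) colony_counts$plated <- plated
  if (any(colony_counts$colonies > colony_counts$plated))
    warning("colony count exceeds the number of cells plated")
  if (!reference_timepoint %in% colony_counts$timepoint_h)
    stop("reference timepoint ", reference_timepoint, " h not present")

  tp <- sort(unique(colony_counts$timepoint_h))
  rows <- lapply(tp, function(t) {
    sel <- colony_counts$timepoint_h == t
    fr <- colony_counts$colonies[sel] / colony_counts$plated[sel]
    data.frame(timepoint_h = t,
               colonies = mean(colony_counts$colonies[sel]),
               plated = mean(colony_counts$plated[sel]),
               fraction = mean(fr),
               dispersion = replicate_dispersion(fr),
               n_replicates = sum(sel))
  })
  out <- do.call(rbind, rows)
  ref <- out$fraction[out$timepoint_h == reference_timepoint]
  if (ref <= 0) stop("reference timepoint has zero viability")
  out$viability <- out$fraction / ref
  out[, c("timepoint_h", "colonies", "plated", "fraction", "viability",
          "dispersion", "n_replicates")]
}

#' Correlation between ESR strength and cell size
#'
#' Rank (Spearman) correlation between the induced-ESR projection and the
#' mean cell volume across joined samples, with a percentile bootstrap
#' confidence interval over samples. Rank correlation is the default
#' because the underlying claim is monotone association, not linearity;
#' Pearson is available.
#'
#' @param table Data.frame with the two columns named by `x` and `y`
#'   (defaults `iESR` and `mean_volume_fl`); rows with missing values are
#'   dropped.
#' @param x,y Column names to correlate.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param conf Confidence level.
#' @param seed Bootstrap seed.
#' @return List: `estimate`, `ci_lo`, `ci_hi`, `n`, `method`.
#' @export
esr_size_correlation <- function(table, x = "iESR", y = "mean_volume_fl",
                                 method = c("spearman", "pearson"),
                                 n_boot = 1000, conf = 0.95, seed = 1L) {
  method <- match.arg(method)
  stopifnot(all(c(x, y) %in% names(table)))
  ok <- stats::complete.cases(table[, c(x, y)])
  xs <- table[[x]][ok]
  ys <- table[[y]][ok]
  if (length(xs) < 4)
    stop("need at least 4 complete sample pairs; have ", length(xs))
  est <- stats::cor(xs, ys, method = method)
  alpha <- (1 - conf) / 2
  with_seed_local(seed, {
    boot <- replicate(n_boot, {
      i <- sample(length(xs), replace = TRUE)
      suppressWarnings(stats::cor(xs[i], ys[i], method = method))
    })
  })
  boot <- boot[is.finite(boot)]
  list(estimate = est,
       ci_lo = unname(stats::quantile(boot, alpha)),
       ci_hi = unname(stats::quantile(boot, 1 - alpha)),
       n = length(xs), method = method)
}

#' Run the full arrest-analysis pipeline over a sample sheet
#'
#' Orchestrates every stage on file inputs: ssGSEA projection of the ESR
#' gene sets from a GCT expression matrix, ribosomal proteome fractions
#' from a TMT peptide report, mean cell volumes from per-sample Coulter
#' histograms, per-condition median GEM diffusion from track tables, and
#' normalized colony-count viability; the stages are joined on
#' condition x timepoint into one cross-modality table and the ESR-vs-size
#' correlation is computed. Stage failures are isolated: a corrupt input
#' fails only its own columns, which stay `NA` in the joined table.
#'
#' @param sheet Data.frame with one row per sample: `sample`, `condition`,
#'   `timepoint_h`, plus path columns `expr_gct`, `gmt`, `tmt_csv`,
#'   `volume_csv`, `tracks_csv`, `viability_csv` (any may be `NA`; shared
#'   files are repeated across rows). Expression sample columns must be
#'   named as in `sample`; the TMT channel and track condition labels must
#'   be `"<timepoint>h"`.
#' @param config Named list of stage parameters; see
#'   [default_pipeline_config()] for the knobs and their defaults.
#' @param out_dir Optional directory; when given, per-stage TSV tables and
#'   a JSON run manifest are written there.
#' @return List of class `arrest_report`: `cross_modality` (joined table),
#'   per-stage tables (`projections`, `rp_fractions`, `volumes`,
#'   `diffusion`, `viability`), `correlation`, `errors` (named list of
#'   per-stage failure messages), and `manifest`.
#' @export
run_pipeline <- function(sheet, config = default_pipeline_config(),
                         out_dir = NULL) {
  required <- c("sample", "condition", "timepoint_h")
  if (!is.data.frame(sheet) || !nrow(sheet) ||
      !all(required %in% names(sheet)))
    stop("sample sheet must have rows and columns: ",
         paste(required, collapse = ", "))
  config <- utils::modifyList(default_pipeline_config(), config)
  errors <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  path_of <- function(col) {
    if (!col %in% names(sheet)) return(NA_character_)
    p <- unique(stats::na.omit(sheet[[col]]))
    if (!length(p)) NA_character_ else p[1]
  }

  # -- expression / ssGSEA ------------------------------------------------
  projections <- stage("expression", {
    gct <- path_of("expr_gct"); gmt <- path_of("gmt")
    if (is.na(gct) || is.na(gmt)) NULL else {
      em <- preprocess_tpm(read_expression(gct))
      project_gene_sets(em, read_gmt(gmt), alpha = config$alpha)
    }
  })

  # -- TMT ribosomal fraction --------------------------------------------
  rp_fractions <- stage("tmt", {
    p <- path_of("tmt_csv")
    if (is.na(p)) NULL else {
      pep <- read_peptides(p)
      pep <- filter_peptides(pep, config$min_mascot,
                             config$max_interference)
      pep <- normalize_channels(pep)
      prot <- rollup_proteins(pep, rp_list = config$rp_list)
      rp_fraction(prot, reference_channel = config$tmt_reference_channel,
                  min_tot_pep = config$min_tot_pep,
                  min_uni_pep = config$min_uni_pep)
    }
  })

  # -- Coulter volumes ----------------------------------------------------
  volumes <- stage("volume", {
    rows <- if ("volume_csv" %in% names(sheet)) which(!is.na(sheet$volume_csv))
            else integer(0)
    if (!length(rows)) NULL else {
      do.call(rbind, lapply(rows, function(i) {
        h <- read_volume_histogram(sheet$volume_csv[i])
        data.frame(condition = sheet$condition[i],
                   timepoint_h = sheet$timepoint_h[i],
                   mean_volume_fl = mean_volume(h))
      }))
    }
  })

  # -- GEM diffusion ------------------------------------------------------
  diffusion <- stage("gem", {
    p <- path_of("tracks_csv")
    if (is.na(p)) NULL else {
      est <- estimate_diffusion(read_tracks(p), dt = config$dt,
                                fit_window = config$fit_window,
                                min_frames = config$min_frames)
      condition_median(est, n_boot = config$n_boot, seed = config$seed)
    }
  })

  # -- viability ----------------------------------------------------------
  viability_tab <- stage("viability", {
    p <- path_of("viability_csv")
    if (is.na(p)) NULL else {
      viability(utils::read.csv(p), plated = config$plated,
                reference_timepoint = config$viability_reference_h)
    }
  })

  cross <- join_modalities(sheet, projections, rp_fractions, volumes,
                           diffusion, viability_tab)
  correlation <- stage("correlation", {
    if (is.null(projections) || is.null(volumes)) NULL
    else esr_size_correlation(cross, n_boot = config$n_boot,
                              seed = config$seed)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("arrestomics")),
    created = "run manifest", config = config[order(names(config))],
    sheet = sheet, n_samples = nrow(sheet),
    errors = errors
  )
  report <- structure(
    list(cross_modality = cross, projections = projections,
         rp_fractions = rp_fractions, volumes = volumes,
         diffusion = diffusion, viability = viability_tab,
         correlation = correlation, errors = errors, manifest = manifest),
    class = "arrest_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("cross_modality", "projections", "rp_fractions",
                 "volumes", "diffusion", "viability")) {
      if (!is.null(report[[nm]]))
        utils::write.table(report[[nm]],
                           file.path(out_dir, paste0(nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         dataframe = "columns", auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  }
  report
}

#' Default pipeline configuration
#'
#' All stage thresholds in one place, at their standard values: ssGSEA
#' exponent 0.75; Mascot >= 25 and isolation interference <= 30; TotPep >
#' 2 and UniPep > 1; TMT log2 reference channel `"1h"`; 0.01-s frame
#' interval with the D fit restricted to lags under 0.1 s; 300 cells
#' plated with the 2-h viability reference; seed 1 for every bootstrap.
#'
#' @return Named list of parameters accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(alpha = 0.75,
       min_mascot = 25, max_interference = 30,
       min_tot_pep = 2, min_uni_pep = 1,
       tmt_reference_channel = "1h",
       rp_list = yeast_rp_list(synthetic = TRUE),
       dt = 0.01, fit_window = c(0, 0.1), min_frames = 10,
       plated = 300, viability_reference_h = 2,
       n_boot = 1000, seed = 1L)
}

# Outer join of all stage outputs on condition x timepoint; one row per
# condition x timepoint present in the sheet, missingness explicit.
join_modalities <- function(sheet, projections, rp_fractions, volumes,
                            diffusion, viability_tab) {
  base <- unique(sheet[, c("condition", "timepoint_h")])
  base <- base[order(base$condition, base$timepoint_h), , drop = FALSE]
  base$channel <- sprintf("%gh", base$timepoint_h)

  if (!is.null(projections)) {
    smap <- sheet[, c("sample", "condition", "timepoint_h")]
    pr <- merge(projections, smap, by = "sample")
    wide <- stats::reshape(
      pr[, c("condition", "timepoint_h", "gene_set", "projection")],
      idvar = c("condition", "timepoint_h"), timevar = "gene_set",
      direction = "wide")
    names(wide) <- sub("^projection\\.", "", names(wide))
    base <- merge(base, wide, by = c("condition", "timepoint_h"),
                  all.x = TRUE)
  }
  if (!is.null(rp_fractions))
    base <- merge(base, rp_fractions[, c("channel", "rp_fraction")],
                  by = "channel", all.x = TRUE)
  if (!is.null(volumes))
    base <- merge(base, volumes, by = c("condition", "timepoint_h"),
                  all.x = TRUE)
  if (!is.null(diffusion))
    base <- merge(base,
                  stats::setNames(
                    diffusion[, c("condition", "median_d_eff_um2s")],
                    c("channel", "median_d_eff_um2s")),
                  by = "channel", all.x = TRUE)
  if (!is.null(viability_tab))
    base <- merge(base, viability_tab[, c("timepoint_h", "viability")],
                  by = "timepoint_h", all.x = TRUE)
  base <- base[order(base$condition, base$timepoint_h), , drop = FALSE]
  rownames(base) <- NULL
  base
}

#' Sample sheet for a scenario written by [write_scenario_data()]
#'
#' @param scenario The [arrest_scenario()] that generated the data.
#' @param paths The path list returned by [write_scenario_data()].
#' @return A sample-sheet data.frame accepted by [run_pipeline()].
#' @export
scenario_sample_sheet <- function(scenario, paths) {
  t <- scenario$t_grid
  data.frame(
    sample = sprintf("%s_%gh", scenario$label, t),
    condition = scenario$label,
    timepoint_h = t,
    expr_gct = paths$expression,
    gmt = paths$gene_sets,
    tmt_csv = paths$peptides,
    volume_csv = unname(paths$histograms[sprintf("%gh", t)]),
    tracks_csv = paths$tracks,
    viability_csv = paths$viability,
    stringsAsFactors = FALSE
  )
}

#' @export
print.arrest_report <- function(x, ...) {
  cat("<arrest_report>\n")
  cat("  cross-modality rows:", nrow(x$cross_modality), "\n")
  if (!is.null(x$correlation))
    cat(sprintf("  %s cor(iESR, volume) = %.3f [%.3f, %.3f], n = %d\n",
                x$correlation$method, x$correlation$estimate,
                x$correlation$ci_lo, x$correlation$ci_hi, x$correlation$n))
  if (length(x$errors))
    cat("  failed stages:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}
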