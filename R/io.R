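#' Read an expression matrix from GCT 1.2 or plain TSV
#'
#' GCT 1.2 is the three-header-line tab format used by GSEA tooling:
#' `#1.2`, then `n_genes<TAB>n_samples`, then a header row
#' `Name<TAB>Description<TAB>sample...`. Plain TSV is read as genes in the
#' first column and one column per sample.
#'
#' @param path File path; format chosen by extension (`.gct` vs anything
#'   else) unless `format` is given.
#' @param format `"gct"`, `"tsv"` or `NULL` (auto).
#' @param transform Transform state of the stored values (`"raw_tpm"` by
#'   default).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = NULL, transform = "raw_tpm") {
  if (is.null(format))
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  if (format == "gct") {
    header <- readLines(path, n = 2)
    if (!grepl("^#1\\.2", header[1]))
      stop("not a GCT 1.2 file: ", path)
    dims <- as.integer(strsplit(header[2], "\t")[[1]][1:2])
    df <- utils::read.delim(path, skip = 2, check.names = FALSE,
                            stringsAsFactors = FALSE)
    vals <- as.matrix(df[, -(1:2), drop = FALSE])
    rownames(vals) <- df[[1]]
    if (nrow(vals) != dims[1] || ncol(vals) != dims[2])
      stop("GCT dimension line disagrees with the table")
  } else {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    vals <- as.matrix(df[, -1, drop = FALSE])
    rownames(vals) <- df[[1]]
  }
  expression_matrix(vals, transform = transform)
}

#' Write an expression matrix as GCT 1.2
#'
#' @param matrix An [expression_matrix()].
#' @param path Output path.
#' @export
write_gct <- function(matrix, path) {
  stopifnot(inherits(matrix, "expr_matrix"))
  vals <- matrix$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(vals), ncol(vals), sep = "\t")), con)
  df <- data.frame(Name = rownames(vals), Description = "na",
                   vals, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expression matrix as TSV (genes in the first column)
#'
#' @param matrix An [expression_matrix()].
#' @param path Output path.
#' @export
write_expression_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "expr_matrix"))
  df <- data.frame(gene = rownames(matrix$values), matrix$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Delegates to the canonical reader in fgsea.
#'
#' @param path Path to a tab-separated GMT file (set name, description,
#'   then members).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field written for every set.
#' @export
write_gmt <- function(gene_sets, path, description = "na") {
  stopifnot(length(names(gene_sets)) == length(gene_sets))
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, description, gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a peptide-level TMT report from CSV/TSV
#'
#' Expects a headered table with peptide/protein identifiers, Mascot score,
#' isolation interference and one abundance column per channel. Column
#' names can be remapped to tolerate search-engine exports.
#'
#' @param path File path (comma- or tab-separated by extension).
#' @param column_map Named character vector mapping canonical names
#'   (`peptide_id`, `protein_id`, `mascot_score`, `isolation_interference`)
#'   to the file's headers, e.g.
#'   `c(mascot_score = "Ions.Score")`.
#' @param abundance_prefix Prefix identifying channel columns
#'   (default `"abundance_"`).
#' @return Data.frame in the canonical layout used by [filter_peptides()]
#'   and friends.
#' @export
read_peptides <- function(path, column_map = NULL,
                          abundance_prefix = "abundance_") {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      hit <- match(column_map[[canon]], names(df))
      if (is.na(hit))
        stop("mapped column not found: ", column_map[[canon]])
      names(df)[hit] <- canon
    }
  }
  needed <- c("peptide_id", "protein_id", "mascot_score",
              "isolation_interference")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("peptide table lacks columns: ", paste(missing, collapse = ", "))
  if (!any(startsWith(names(df), abundance_prefix)))
    stop("no channel columns with prefix '", abundance_prefix, "'")
  df
}

#' Read a Coulter histogram from two-column CSV
#'
#' @param path CSV with columns `bin_volume_fl` and `count` (extra metadata
#'   columns are kept).
#' @return Data.frame ordered by increasing bin volume.
#' @export
read_volume_histogram <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("bin_volume_fl", "count") %in% names(df)))
    stop("histogram CSV needs columns bin_volume_fl, count")
  df[order(df$bin_volume_fl), , drop = FALSE]
}

#' Read particle trajectories from CSV
#'
#' @param path CSV with columns `track_id`, `frame`, `x_um`, `y_um`
#'   (remappable via `column_map`, e.g. for Mosaic exports).
#' @param column_map Named character vector mapping the canonical names to
#'   the file's headers.
#' @return Data.frame with the canonical columns.
#' @export
read_tracks <- function(path, column_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      hit <- match(column_map[[canon]], names(df))
      if (is.na(hit)) stop("mapped column not found: ", column_map[[canon]])
      names(df)[hit] <- canon
    }
  }
  needed <- c("track_id", "frame", "x_um", "y_um")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("track table lacks columns: ", paste(missing, collapse = ", "))
  df
}

#' Write a generated scenario's datasets to a directory
#'
#' Materializes every modality of a scenario as the plain-text formats the
#' pipeline readers consume (GCT expression, GMT gene sets, CSV peptide /
#' histogram / track / colony tables) plus a JSON ground-truth sidecar.
#'
#' @param scenario An [arrest_scenario()].
#' @param dir Output directory (created if missing).
#' @param n_genes,n_proteins,n_cells,n_tracks Sizes passed to the
#'   generators.
#' @return Invisibly, a named list of the file paths written.
#' @export
write_scenario_data <- function(scenario, dir, n_genes = 2000,
                                n_proteins = 200, n_cells = 10000,
                                n_tracks = 200) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- make_expression(scenario, n_genes = n_genes)
  tmt <- make_tmt(scenario, n_proteins = n_proteins)
  vol <- make_volume_histograms(scenario, n_cells = n_cells)
  trj <- make_trajectories(scenario, n_tracks = n_tracks)
  via <- make_viability(scenario)

  paths <- list(
    expression = file.path(dir, "expression.gct"),
    gene_sets = file.path(dir, "esr_sets.gmt"),
    peptides = file.path(dir, "peptides.csv"),
    tracks = file.path(dir, "tracks.csv"),
    viability = file.path(dir, "colonies.csv"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_gct(expr$expression, paths$expression)
  write_gmt(expr$gene_sets, paths$gene_sets)
  utils::write.csv(tmt$peptides, paths$peptides, row.names = FALSE)
  utils::write.csv(trj$tracks, paths$tracks, row.names = FALSE)
  utils::write.csv(via$counts, paths$viability, row.names = FALSE)

  hist_paths <- character(0)
  for (nm in names(vol$histograms)) {
    p <- file.path(dir, sprintf("volume_%s.csv", nm))
    utils::write.csv(vol$histograms[[nm]], p, row.names = FALSE)
    hist_paths[nm] <- p
  }
  paths$histograms <- hist_paths

  truth <- list(scenario_label = scenario$label, seed = scenario$seed,
                latent = scenario_truth(scenario),
                expression = expr$truth, tmt = tmt$truth,
                volume = vol$truth, diffusion = trj$truth,
                viability = via$truth)
  jsonlite::write_json(truth, paths$truth, dataframe = "columns",
                       digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
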