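#' Default ESR gene universe for synthetic data
#'
#' Names a gene universe of `n_genes` identifiers in which the first 300 are
#' the induced-ESR set and the next 600 the repressed-ESR set, mirroring the
#' sizes of the classic stress-response sets (~300 induced, >600 repressed
#' genes).
#'
#' @param n_genes Total universe size (must fit both sets).
#' @param n_iesr,n_resr Set sizes; defaults 300 and 600.
#' @return List with character vectors `universe`, `iESR`, `rESR`.
#' @export
esr_gene_sets <- function(n_genes = 2000, n_iesr = 300, n_resr = 600) {
  if (n_genes < n_iesr + n_resr)
    stop("gene universe smaller than the two ESR sets combined")
  universe <- sprintf("gene%04d", seq_len(n_genes))
  list(universe = universe,
       iESR = universe[seq_len(n_iesr)],
       rESR = universe[n_iesr + seq_len(n_resr)])
}

#' Generate a synthetic TPM expression matrix under an arrest scenario
#'
#' Draws a log-normal baseline expression level per gene (shared across
#' samples), then at each timepoint multiplies induced-ESR genes by
#' `fold_shift^s(t)` and divides repressed-ESR genes by the same factor,
#' applies multiplicative log-normal noise, and renormalizes every column to
#' TPM (sum 1e6). Background genes are never shifted.
#'
#' @param scenario An [arrest_scenario()].
#' @param n_genes Size of the gene universe.
#' @param iesr_set,resr_set Disjoint character vectors of gene identifiers
#'   within the universe; defaults from [esr_gene_sets()].
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline parameters
#'   (heavy-tailed like real TPM).
#' @return List with `expression` (an [expression_matrix()] in `raw_tpm`
#'   state, one column per timepoint), `gene_sets` (list of iESR/rESR
#'   members), and `truth` (per-sample ESR strength and the log2 shift
#'   applied to each set).
#' @export
make_expression <- function(scenario, n_genes = 2000,
                            iesr_set = NULL, resr_set = NULL,
                            baseline_meanlog = log(50),
                            baseline_sdlog = 1.2) {
  stopifnot(inherits(scenario, "arrest_scenario"))
  if (n_genes <= 0) stop("n_genes must be positive")
  if (is.null(iesr_set) || is.null(resr_set)) {
    gs <- esr_gene_sets(n_genes)
    if (is.null(iesr_set)) iesr_set <- gs$iESR
    if (is.null(resr_set)) resr_set <- gs$rESR
  }
  if (length(intersect(iesr_set, resr_set)))
    stop("iESR and rESR sets must be disjoint")
  if (n_genes < length(iesr_set) + length(resr_set))
    stop("n_genes must accommodate both gene sets")
  universe <- sprintf("gene%04d", seq_len(n_genes))
  if (!all(c(iesr_set, resr_set) %in% universe))
    stop("gene sets must be subsets of the gene universe")

  t <- scenario$t_grid
  s <- scenario$esr_strength(t)
  sdlog <- scenario$noise$expression
  with_seed_local(scenario_seed(scenario, 11L), {
    baseline <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
    vals <- matrix(baseline, nrow = n_genes, ncol = length(t))
    i_idx <- match(iesr_set, universe)
    r_idx <- match(resr_set, universe)
    for (j in seq_along(t)) {
      shift <- scenario$fold_shift ^ s[j]
      vals[i_idx, j] <- vals[i_idx, j] * shift
      vals[r_idx, j] <- vals[r_idx, j] / shift
      if (sdlog > 0)
        vals[, j] <- vals[, j] * stats::rlnorm(n_genes, 0, sdlog)
    }
  })
  vals <- sweep(vals, 2, colSums(vals), "/") * 1e6
  dimnames(vals) <- list(universe, sprintf("%s_%gh", scenario$label, t))

  list(
    expression = expression_matrix(vals, "raw_tpm"),
    gene_sets = list(iESR = iesr_set, rESR = resr_set),
    truth = data.frame(
      sample = colnames(vals), timepoint_h = t, esr_strength = s,
      log2_shift_iesr = s * log2(scenario$fold_shift),
      log2_shift_resr = -s * log2(scenario$fold_shift)
    )
  )
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# the caller's RNG stream is untouched.
with_seed_local <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}
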