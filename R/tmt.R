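#' Identify the TMT channel columns of a peptide table
#'
#' @param peptides Peptide-level data.frame.
#' @param prefix Channel-column prefix (default `"abundance_"`).
#' @return Character vector of channel column names.
#' @export
tmt_channels <- function(peptides, prefix = "abundance_") {
  ch <- names(peptides)[startsWith(names(peptides), prefix)]
  if (!length(ch)) stop("no channel columns with prefix '", prefix, "'")
  ch
}

#' Median-normalize TMT channels
#'
#' Divides each channel by its median over peptides and rescales by the
#' grand median (the median of the per-channel medians), so after
#' normalization every channel shares the same median while the overall
#' signal magnitude is preserved. The operation is idempotent.
#'
#' @param peptides Peptide-level data.frame.
#' @param channels Channel column names (default auto-detected).
#' @return The table with normalized channel columns.
#' @export
normalize_channels <- function(peptides, channels = tmt_channels(peptides)) {
  med <- vapply(channels, function(ch) {
    stats::median(peptides[[ch]])
  }, numeric(1))
  bad <- channels[!is.finite(med) | med <= 0]
  if (length(bad))
    stop("channel(s) with non-positive median abundance: ",
         paste(bad, collapse = ", "))
  grand <- stats::median(med)
  for (ch in channels)
    peptides[[ch]] <- peptides[[ch]] / med[[ch]] * grand
  peptides
}

#' Filter peptides on Mascot score and isolation interference
#'
#' Retains exactly the rows with `mascot_score >= min_mascot` and
#' `isolation_interference <= max_interference`; both boundaries are
#' inclusive. The defaults (25 and 30) are the standard report-filtering
#' thresholds.
#'
#' @param peptides Peptide-level data.frame.
#' @param min_mascot Minimum Mascot score (kept if `>=`).
#' @param max_interference Maximum isolation interference in percent (kept
#'   if `<=`).
#' @return The retained rows, with attribute `filter_counts`
#'   (`kept`/`dropped`).
#' @export
filter_peptides <- function(peptides, min_mascot = 25,
                            max_interference = 30) {
  keep <- peptides$mascot_score >= min_mascot &
    peptides$isolation_interference <= max_interference
  out <- peptides[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out))
    warning("all peptides removed by the Mascot/interference filters")
  attr(out, "filter_counts") <- c(kept = sum(keep), dropped = sum(!keep))
  out
}

#' Roll peptides up to protein-level channel abundances
#'
#' Sums channel abundances per protein over the (filtered) peptide rows and
#' records TotPep (number of peptide-spectrum rows) and UniPep (number of
#' distinct peptide sequences). When the input carries `tot_pep` /
#' `uni_pep` columns (as search-engine exports do) those are used and
#' discrepancies against the recomputed values are reported via a message.
#'
#' @param peptides Filtered peptide-level data.frame.
#' @param rp_list Character vector of ribosomal-protein identifiers (40S,
#'   60S and 60S-acidic lists); default the packaged yeast list from
#'   [yeast_rp_list()].
#' @param channels Channel column names (default auto-detected).
#' @return Protein-level data.frame: `protein_id`, `is_ribosomal`,
#'   `tot_pep`, `uni_pep` and the summed channel columns.
#' @export
rollup_proteins <- function(peptides, rp_list = yeast_rp_list(),
                            channels = tmt_channels(peptides)) {
  unmapped <- is.na(peptides$protein_id) | peptides$protein_id == ""
  if (any(unmapped)) {
    message(sum(unmapped), " peptide row(s) with no protein mapping dropped")
    peptides <- peptides[!unmapped, , drop = FALSE]
  }
  if (!nrow(peptides)) stop("no mapped peptides to roll up")

  prot <- unique(peptides$protein_id)
  idx <- split(seq_len(nrow(peptides)), peptides$protein_id)[prot]
  sums <- vapply(idx, function(i) {
    colSums(as.matrix(peptides[i, channels, drop = FALSE]))
  }, numeric(length(channels)))
  sums <- if (length(channels) == 1L) matrix(sums, ncol = 1L) else t(sums)
  colnames(sums) <- channels

  tot_pep <- vapply(idx, length, integer(1))
  uni_pep <- vapply(idx, function(i) {
    length(unique(peptides$peptide_id[i]))
  }, integer(1))
  if (all(c("tot_pep", "uni_pep") %in% names(peptides))) {
    given_tot <- vapply(idx, function(i) peptides$tot_pep[i][1], numeric(1))
    given_uni <- vapply(idx, function(i) peptides$uni_pep[i][1], numeric(1))
    if (any(given_tot != tot_pep) || any(given_uni != uni_pep))
      message("TotPep/UniPep from the input table disagree with recomputed ",
              "values for ", sum(given_tot != tot_pep | given_uni != uni_pep),
              " protein(s); using the input values")
    tot_pep <- given_tot
    uni_pep <- given_uni
  }

  out <- data.frame(protein_id = prot,
                    is_ribosomal = prot %in% rp_list,
                    tot_pep = tot_pep, uni_pep = uni_pep,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(sums))
  rownames(out) <- NULL
  out
}

#' Ribosomal proteome fraction per channel
#'
#' Applies the eligibility gate TotPep > 2 and UniPep > 1 (both strict) to
#' numerator and denominator alike, then computes per channel
#' `[RP]/[Total Protein]` — the summed abundance of eligible ribosomal
#' proteins over the summed abundance of all eligible proteins — and the
#' log2 of each fraction relative to the reference channel (the 1-h
#' timepoint in the original design).
#'
#' @param proteins Protein-level data.frame from [rollup_proteins()].
#' @param reference_channel Channel column name (or its label without the
#'   abundance prefix) used as log2 reference.
#' @param min_tot_pep,min_uni_pep Eligibility thresholds; proteins are kept
#'   when strictly above them (defaults 2 and 1).
#' @param channels Channel column names (default auto-detected).
#' @return Data.frame: `channel`, `rp_fraction`, `normalized_log2`.
#' @export
rp_fraction <- function(proteins, reference_channel,
                        min_tot_pep = 2, min_uni_pep = 1,
                        channels = tmt_channels(proteins)) {
  if (!reference_channel %in% channels) {
    cand <- paste0("abundance_", reference_channel)
    if (!cand %in% channels)
      stop("reference channel not found: ", reference_channel)
    reference_channel <- cand
  }
  eligible <- proteins$tot_pep > min_tot_pep & proteins$uni_pep > min_uni_pep
  el <- proteins[eligible, , drop = FALSE]
  if (!nrow(el)) stop("no proteins pass the TotPep/UniPep eligibility gate")

  total <- vapply(channels, function(ch) sum(el[[ch]]), numeric(1))
  if (any(total <= 0))
    stop("zero total abundance in channel(s): ",
         paste(channels[total <= 0], collapse = ", "))
  rp <- vapply(channels, function(ch) {
    sum(el[[ch]][el$is_ribosomal])
  }, numeric(1))
  frac <- rp / total

  ref <- frac[[reference_channel]]
  norm <- if (ref > 0) log2(frac / ref) else rep(NA_real_, length(frac))
  norm[frac == 0] <- NA_real_

  data.frame(channel = sub("^abundance_", "", channels),
             rp_fraction = unname(frac),
             normalized_log2 = unname(norm),
             stringsAsFactors = FALSE)
}

#' Packaged yeast ribosomal-protein identifier list
#'
#' The 40S (RPS), 60S (RPL) and 60S-acidic (RPP) ribosomal protein gene
#' names of budding yeast, shipped as an editable text file in
#' `inst/extdata`. `synthetic = TRUE` returns the generic identifiers used
#' by [make_tmt()] instead.
#'
#' @param synthetic Return the synthetic generator's RP namespace rather
#'   than the curated yeast list.
#' @param n Number of synthetic identifiers (matched to the generator).
#' @return Character vector of protein identifiers.
#' @export
yeast_rp_list <- function(synthetic = FALSE, n = 40) {
  if (synthetic) return(sprintf("RPL%03dA", seq_len(n)))
  path <- system.file("extdata", "yeast_rp_genes.txt",
                      package = "arrestomics")
  if (path == "")  # during in-source development
    path <- file.path("inst", "extdata", "yeast_rp_genes.txt")
  out <- readLines(path)
  out[nzchar(out) & !startsWith(out, "#")]
}
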