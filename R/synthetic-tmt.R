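#' Generate a synthetic TMT peptide report under an arrest scenario
#'
#' Builds a peptide-level quantification table whose channels are the
#' scenario timepoints. Protein masses are drawn so that at channel j the
#' ribosomal proteins jointly hold exactly the scenario's true mass fraction
#' \eqn{f_0 (1 - k\, s(t_j))} of the total signal; each protein's mass is
#' split across its peptides, multiplicative noise (CV from
#' `scenario$noise$tmt`) is applied per peptide x channel, and a
#' configurable fraction of peptides is drawn to fail the standard quality
#' filters (Mascot score below 25 or isolation interference above 30).
#'
#' @param scenario An [arrest_scenario()].
#' @param n_proteins Number of proteins in the simulated proteome.
#' @param rp_names Identifiers of the ribosomal proteins; default the first
#'   20% of the universe, named after yeast RPL/RPS conventions.
#' @param peptides_per_protein Mean unique peptides per protein (at least 3
#'   are always drawn, so every protein can pass the TotPep>2 / UniPep>1
#'   eligibility gate).
#' @param fail_fraction Probability that a peptide row is drawn to fail the
#'   Mascot/interference filters.
#' @param total_signal Grand total isotopic abundance per channel before
#'   noise.
#' @return List with `peptides` (data.frame: `peptide_id`, `protein_id`,
#'   `mascot_score`, `isolation_interference`, one `abundance_<label>`
#'   column per channel), `channels` (channel labels), `rp_names`, and
#'   `truth` (per-channel true ribosomal mass fraction).
#' @export
make_tmt <- function(scenario, n_proteins = 200, rp_names = NULL,
                     peptides_per_protein = 4, fail_fraction = 0,
                     total_signal = 1e6) {
  stopifnot(inherits(scenario, "arrest_scenario"))
  if (n_proteins < 5) stop("need at least 5 proteins")
  stopifnot(fail_fraction >= 0, fail_fraction < 1)

  t <- scenario$t_grid
  s <- scenario$esr_strength(t)
  frac <- scenario$rp_fraction0 * (1 - scenario$rp_decline * s)
  if (any(frac <= 0 | frac >= 1))
    stop("true ribosomal mass fraction must stay inside (0, 1)")
  channels <- sprintf("%gh", t)

  if (is.null(rp_names)) {
    n_rp <- max(2L, round(0.2 * n_proteins))
    rp_names <- sprintf("RPL%03dA", seq_len(n_rp))
  }
  n_rp <- length(rp_names)
  if (n_rp >= n_proteins) stop("rp_names must be a strict subset")
  other <- sprintf("PRT%04d", seq_len(n_proteins - n_rp))
  proteins <- c(rp_names, other)
  is_rp <- c(rep(TRUE, n_rp), rep(FALSE, length(other)))

  cv <- scenario$noise$tmt
  with_seed_local(scenario_seed(scenario, 23L), {
    # relative protein weights, normalized within group so the group mass
    # fractions are exact by construction
    w <- stats::rlnorm(n_proteins, 0, 1)
    w[is_rp] <- w[is_rp] / sum(w[is_rp])
    w[!is_rp] <- w[!is_rp] / sum(w[!is_rp])
    prot_ab <- sapply(seq_along(channels), function(j) {
      total_signal * ifelse(is_rp, frac[j] * w, (1 - frac[j]) * w)
    })

    n_pep <- pmax(3L, stats::rpois(n_proteins, peptides_per_protein))
    pep_protein <- rep(proteins, n_pep)
    pep_id <- unlist(lapply(seq_len(n_proteins), function(i)
      sprintf("%s_pep%02d", proteins[i], seq_len(n_pep[i]))))
    # split each protein's channel mass across its peptides
    split_w <- unlist(lapply(n_pep, function(k) {
      u <- stats::runif(k, 0.5, 1.5)
      u / sum(u)
    }))
    ab <- prot_ab[rep(seq_len(n_proteins), n_pep), , drop = FALSE] * split_w
    if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      noise <- matrix(stats::rlnorm(length(ab), -sdlog^2 / 2, sdlog),
                      nrow = nrow(ab))
      ab <- ab * noise
    }

    n_rows <- length(pep_id)
    fails <- stats::runif(n_rows) < fail_fraction
    # half of the failing rows fail on interference, the rest on score
    fail_on_int <- fails & (stats::runif(n_rows) < 0.5)
    fail_on_score <- fails & !fail_on_int
    mascot <- stats::runif(n_rows, 25, 90)
    interference <- stats::runif(n_rows, 0, 30)
    mascot[fail_on_score] <- stats::runif(sum(fail_on_score), 5, 24.9)
    interference[fail_on_int] <- stats::runif(sum(fail_on_int), 30.1, 100)
  })

  peptides <- data.frame(peptide_id = pep_id, protein_id = pep_protein,
                         mascot_score = mascot,
                         isolation_interference = interference,
                         stringsAsFactors = FALSE)
  ab <- as.data.frame(ab)
  names(ab) <- paste0("abundance_", channels)
  peptides <- cbind(peptides, ab)
  rownames(peptides) <- NULL

  list(peptides = peptides, channels = channels, rp_names = rp_names,
       truth = data.frame(channel = channels, timepoint_h = t,
                          rp_fraction = frac))
}
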