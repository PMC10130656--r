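# Independent brute-force ssGSEA oracle: an explicit position-by-position
# ECDF walk, kept deliberately loop-based and separate from the package's
# vectorized implementation. At alpha = 0 the in-set ECDF is an integer
# count over the set size, so the walk is exact.
oracle_ssgsea <- function(values, set, alpha = 0) {
  genes <- names(values)
  ord <- order(-values, genes, method = "radix")
  ranked <- genes[ord]
  n <- length(ranked)
  in_set <- ranked %in% set
  m <- sum(in_set)
  stopifnot(m > 0, m < n)

  if (alpha == 0) {
    # exact integer-scaled walk: projection * m * (n - m) is an integer,
    # so the oracle value is the correctly rounded rational result
    cum_in <- 0L; cum_out <- 0L; s_int <- 0
    for (i in seq_len(n)) {
      if (in_set[i]) cum_in <- cum_in + 1L else cum_out <- cum_out + 1L
      s_int <- s_int + ((n - m) * cum_in - m * cum_out)
    }
    return(s_int / (m * (n - m)))
  }
  w <- numeric(n)
  for (i in seq_len(n)) w[i] <- ((n - i + 1) / n) ^ alpha
  denom <- 0
  for (i in seq_len(n)) if (in_set[i]) denom <- denom + w[i]
  cum_in <- 0; cum_out <- 0L; proj <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) cum_in <- cum_in + w[i] else cum_out <- cum_out + 1L
    proj <- proj + (cum_in / denom - cum_out / (n - m))
  }
  proj
}

# Noise-free scenario used across recovery tests.
quiet_scenario <- function(..., seed = 101L) {
  arrest_scenario(...,
                  noise = list(expression = 0, tmt = 0, volume_cv = 0,
                               localization = 0, viability = FALSE),
                  seed = seed)
}

# Scenario whose three TMT channels carry true RP fractions 0.20/0.15/0.10.
three_channel_scenario <- function(tmt_cv = 0, seed = 1L) {
  noise <- list(expression = 0, tmt = tmt_cv, volume_cv = 0,
                localization = 0, viability = FALSE)
  arrest_scenario(t_grid = c(0, 1, 2),
                  esr_strength = c(0, 0.5, 1),
                  rp_fraction0 = 0.2, rp_decline = 0.5,
                  noise = noise, seed = seed)
}

# 5-peptide quality-filter fixture: scores/interference chosen so exactly
# rows 1 and 2 pass Mascot >= 25 with interference <= 30 (row 2 sits on
# both boundaries).
peptide_filter_fixture <- function() {
  data.frame(
    peptide_id = paste0("pep", 1:5),
    protein_id = paste0("prot", 1:5),
    mascot_score = c(30, 25, 20, 40, 25),
    isolation_interference = c(10, 30, 5, 35, 31),
    abundance_0h = c(1, 2, 3, 4, 5),
    abundance_1h = c(5, 4, 3, 2, 1)
  )
}
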