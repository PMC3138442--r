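# Independent grid-search likelihood oracle for the two-point
# recombination fraction: writes the class probabilities directly from the
# gamete model and scans r over [0, 0.5] at step 1e-4.
grid_two_point_r <- function(tab, sex_model = "symmetric", step = 1e-4) {
  probs <- function(r) {
    if (sex_model == "symmetric") {
      p <- (1 - r) / 2
      q <- r / 2
      matrix(c(p^2, 2 * p * q, q^2,
               2 * p * q, 2 * (p^2 + q^2), 2 * p * q,
               q^2, 2 * p * q, p^2), 3, 3, byrow = TRUE)
    } else {
      matrix(c((1 - r) / 4, r / 4, 0,
               r / 4, (1 - r) / 2, r / 4,
               0, r / 4, (1 - r) / 4), 3, 3, byrow = TRUE)
    }
  }
  grid <- seq(0, 0.5, by = step)
  ll <- vapply(grid, function(r) {
    pr <- probs(r)
    keep <- tab > 0
    if (any(keep & pr == 0)) return(-Inf)
    sum(tab[keep] * log(pr[keep]))
  }, 0)
  grid[which.max(ll)]
}

# Multinomial draw of a two-locus F2 count table at true male-map fraction
# r under the stated gamete model.
draw_pair_table <- function(n, r, sex_model = "symmetric") {
  pr <- if (sex_model == "symmetric") {
    p <- (1 - r) / 2
    q <- r / 2
    c(p^2, 2 * p * q, q^2, 2 * p * q, 2 * (p^2 + q^2), 2 * p * q,
      q^2, 2 * p * q, p^2)
  } else {
    c((1 - r) / 4, r / 4, 0, r / 4, (1 - r) / 2, r / 4, 0, r / 4, (1 - r) / 4)
  }
  # probabilities listed row-wise; rebuild column-major 3x3
  matrix(rmultinom(1, n, pr), 3, 3, byrow = TRUE)
}

# Minimal genotype matrix fixture.
tiny_gm <- function(calls, cohort = "f2_nauplii", sex = "unknown") {
  calls <- as.matrix(calls)
  ind <- data.frame(id = sprintf("i%02d", seq_len(nrow(calls))),
                    cohort = cohort, family = "F1P01", sex = sex)
  mk <- data.frame(name = if (is.null(colnames(calls)))
    sprintf("m%d", seq_len(ncol(calls))) else colnames(calls))
  genotype_matrix(ind, mk, calls)
}

# Layout of n_unlinked single-marker chromosomes: every marker segregates
# independently, giving exact binomial replicate tests.
unlinked_layout <- function(n_markers) {
  data.frame(name = sprintf("U%03d", seq_len(n_markers)),
             chromosome = sprintf("chrU%03d", seq_len(n_markers)),
             position_cM = 0,
             marker_class = "snp")
}
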