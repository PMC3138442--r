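# Two-locus genotype class probabilities for a phase-known F1 x F1
# intercross in coupling. Rows/cols index genotypes at the two markers in
# the order HOM_P1, HET, HOM_P2.
#
# symmetric: both F1 parents recombine with fraction r, gamete classes
# parental (1-r)/2 each and recombinant r/2 each.
# female_achiasmatic: the female transmits an intact parental haplotype
# (1/2 each); only the male gamete can recombine, so the double-homozygote
# repulsion classes (HOM_P1/HOM_P2 and HOM_P2/HOM_P1) are impossible.
.two_point_probs <- function(r, sex_model) {
  if (sex_model == "symmetric") {
    p <- (1 - r) / 2
    q <- r / 2
    matrix(c(p^2, 2 * p * q, q^2,
             2 * p * q, 2 * (p^2 + q^2), 2 * p * q,
             q^2, 2 * p * q, p^2),
           3, 3, byrow = TRUE)
  } else {
    matrix(c((1 - r) / 4, r / 4, 0,
             r / 4, (1 - r) / 2, r / 4,
             0, r / 4, (1 - r) / 4),
           3, 3, byrow = TRUE)
  }
}

.two_point_loglik <- function(r, counts, sex_model) {
  pr <- .two_point_probs(r, sex_model)
  keep <- counts > 0
  sum(counts[keep] * log(pr[keep]))
}

#' Two-point recombination fraction by EM
#'
#' Maximum-likelihood estimate of the recombination fraction between two
#' codominant markers in a phase-known F2 intercross (both F1 parents
#' heterozygous, coupling phase), from the 3 x 3 table of joint genotype
#' counts. Most genotype classes determine the number of recombinant
#' gametes they carry; the double-heterozygote class is ambiguous between a
#' both-parental and a both-recombinant gamete pair, and the EM E-step
#' splits it with weights `(1-r)^2 / ((1-r)^2 + r^2)` and
#' `r^2 / ((1-r)^2 + r^2)`. The M-step divides the expected recombinant
#' gamete count by `2n` under the `symmetric` model (both parents
#' recombine) or by `n` under `female_achiasmatic` (the female transmits
#' intact chromosomes, so only male gametes can recombine and the
#' double-heterozygote class carries no recombinants at all). Iteration
#' starts from `r = 0.25` and stops when the update moves less than `tol`.
#'
#' Under `female_achiasmatic` the two double-homozygote repulsion classes
#' have probability zero; individuals observed there (possible only through
#' genotyping error) are dropped with a warning.
#'
#' @param counts 3 x 3 numeric matrix of joint genotype counts, rows =
#'   first marker, columns = second marker, both in the order
#'   (HOM_P1, HET, HOM_P2).
#' @param sex_model `"symmetric"` (default; what a standard mapping package
#'   assumes) or `"female_achiasmatic"` (the true generative model when
#'   females do not recombine).
#' @param tol,max_iter EM convergence tolerance on `r` and iteration cap.
#' @return An object of class `"two_point"`: list with `r_hat` (in
#'   `[0, 0.5]`), `lod` (log10 likelihood ratio against `r = 0.5`),
#'   `p_linkage` (chi-square 1 df upper tail of the likelihood-ratio
#'   statistic), `n_informative`, `sex_model` and `n_iter`.
#' @seealso [two_point_scan()] for all pairs of a genotype matrix;
#'   [kosambi_cm()] for converting `r_hat` to map distance.
#' @export
#' @examples
#' tab <- matrix(c(25, 0, 0, 0, 50, 0, 0, 0, 25), 3, 3)
#' estimate_two_point(tab)  # complete linkage: r_hat ~ 0
estimate_two_point <- function(counts,
                               sex_model = c("symmetric", "female_achiasmatic"),
                               tol = 1e-8, max_iter = 100L) {
  sex_model <- match.arg(sex_model)
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3L, 3L))) stop("counts must be a 3 x 3 table")
  if (any(counts < 0)) stop("negative genotype counts")
  if (sum(counts) == 0) stop("empty two-locus count table")
  if (sex_model == "female_achiasmatic" && counts[1, 3] + counts[3, 1] > 0) {
    warning("dropping ", counts[1, 3] + counts[3, 1], " individual(s) in ",
            "double-homozygote repulsion classes, impossible under female ",
            "achiasmy")
    counts[1, 3] <- 0
    counts[3, 1] <- 0
    if (sum(counts) == 0) stop("no informative individuals remain")
  }
  n <- sum(counts)
  n_single <- counts[1, 2] + counts[2, 1] + counts[2, 3] + counts[3, 2]
  n_double <- counts[1, 3] + counts[3, 1]
  n_dhet <- counts[2, 2]
  r <- 0.25
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (sex_model == "symmetric") {
      w2 <- r^2 / ((1 - r)^2 + r^2)
      r_new <- (n_single + 2 * n_double + 2 * n_dhet * w2) / (2 * n)
    } else {
      r_new <- n_single / n
    }
    r_new <- min(max(r_new, 0), 0.5)
    done <- abs(r_new - r) < tol || iter >= max_iter
    r <- r_new
    if (done) break
  }
  ll_hat <- .two_point_loglik(r, counts, sex_model)
  ll_null <- .two_point_loglik(0.5, counts, sex_model)
  g <- max(2 * (ll_hat - ll_null), 0)
  structure(list(r_hat = r,
                 lod = g / (2 * log(10)),
                 p_linkage = pchisq(g, df = 1, lower.tail = FALSE),
                 n_informative = n,
                 sex_model = sex_model,
                 n_iter = iter),
            class = "two_point")
}

#' @export
print.two_point <- function(x, ...) {
  cat(sprintf("two_point: r_hat = %.4f, LOD = %.2f, p = %.3g, n = %d (%s)\n",
              x$r_hat, x$lod, x$p_linkage, x$n_informative, x$sex_model))
  invisible(x)
}

# Pairwise-complete 3x3 count table for a pair of columns of an
# integer-coded genotype matrix.
.pair_table <- function(ga, gb) {
  ok <- !is.na(ga) & !is.na(gb)
  matrix(tabulate(ga[ok] + 3L * (gb[ok] - 1L), 9L), 3L, 3L)
}

#' Two-point scan over all marker pairs
#'
#' Runs [estimate_two_point()] on every pair of markers in a cohort, using
#' pairwise-complete observations (an individual missing either call is
#' dropped for that pair only).
#'
#' @inheritParams genotype_counts
#' @inheritParams estimate_two_point
#' @return Data frame with one row per marker pair: `marker_a`, `marker_b`,
#'   `r_hat`, `lod`, `p_linkage`, `n_informative`.
#' @export
two_point_scan <- function(gm, cohort,
                           sex_model = c("symmetric", "female_achiasmatic")) {
  sex_model <- match.arg(sex_model)
  g <- .cohort_geno(gm, cohort)
  m <- ncol(g)
  if (m < 2L) stop("need at least two markers")
  pairs <- combn(m, 2L)
  res <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]
    j <- pairs[2L, k]
    tab <- .pair_table(g[, i], g[, j])
    if (sum(tab) == 0) {
      res[[k]] <- data.frame(marker_a = colnames(g)[i],
                             marker_b = colnames(g)[j],
                             r_hat = 0.5, lod = 0, p_linkage = 1,
                             n_informative = 0L)
      next
    }
    tp <- suppressWarnings(estimate_two_point(tab, sex_model))
    res[[k]] <- data.frame(marker_a = colnames(g)[i],
                           marker_b = colnames(g)[j],
                           r_hat = tp$r_hat, lod = tp$lod,
                           p_linkage = tp$p_linkage,
                           n_informative = tp$n_informative)
  }
  out <- do.call(rbind, res)
  attr(out, "sex_model") <- sex_model
  out
}
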