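# Significance tier conventions shared by the scans: three stars at the
# scan-wide Bonferroni threshold, then p < 0.01 and p < 0.05.
.tier <- function(p, bonferroni) {
  ifelse(p < bonferroni, "bonferroni",
         ifelse(p < 0.01, "p01", ifelse(p < 0.05, "p05", "ns")))
}

.direction_flags <- function(obs, expected, classes) {
  d <- obs - expected
  flags <- character(0)
  for (k in seq_along(classes)) {
    if (d[k] > 0) flags <- c(flags, paste0(classes[k], "_excess"))
    if (d[k] < 0) flags <- c(flags, paste0(classes[k], "_deficit"))
  }
  flags
}

#' Single-locus segregation distortion test for an F2 cohort
#'
#' Pearson chi-square goodness-of-fit of observed genotype counts against
#' the Mendelian F2 expectation 2:1:1 (HET : HOM_P1 : HOM_P2), i.e. the
#' Hardy-Weinberg proportions at allele frequency 1/2. Missing calls are
#' excluded; expectations use the marker's own non-missing total.
#'
#' @param counts Named numeric vector with elements `n_het`, `n_hom_p1`,
#'   `n_hom_p2` (an `n_missing` element, as produced by
#'   [genotype_counts()], is ignored).
#' @param n_tests Number of tests in the enclosing scan; the Bonferroni
#'   tier uses threshold `0.05 / n_tests`.
#' @return Object of class `"distortion_test"`: observed and expected
#'   counts, `chi2`, `df = 2`, `p`, significance `tier` (`"ns"`, `"p05"`,
#'   `"p01"`, `"bonferroni"`) and `direction` flags such as
#'   `"het_excess"` or `"hom_p1_deficit"`.
#' @export
#' @examples
#' f2_distortion_test(c(n_het = 90, n_hom_p1 = 70, n_hom_p2 = 40))
f2_distortion_test <- function(counts, n_tests = 1L) {
  obs <- as.numeric(counts[c("n_het", "n_hom_p1", "n_hom_p2")])
  if (anyNA(obs)) stop("counts must contain n_het, n_hom_p1 and n_hom_p2")
  n <- sum(obs)
  if (n == 0) stop("no non-missing calls")
  p0 <- c(0.5, 0.25, 0.25)
  ct <- suppressWarnings(chisq.test(obs, p = p0))
  expected <- n * p0
  structure(list(observed = stats::setNames(obs, c("het", "hom_p1", "hom_p2")),
                 expected = stats::setNames(expected,
                                            c("het", "hom_p1", "hom_p2")),
                 chi2 = unname(ct$statistic), df = 2L,
                 p = unname(ct$p.value),
                 tier = .tier(unname(ct$p.value), 0.05 / n_tests),
                 direction = .direction_flags(obs, expected,
                                              c("het", "hom_p1", "hom_p2"))),
            class = "distortion_test")
}

#' @export
print.distortion_test <- function(x, ...) {
  cat(sprintf("distortion_test: chi2 = %.2f (df %d), p = %.3g [%s]\n",
              x$chi2, x$df, x$p, x$tier))
  if (length(x$direction)) cat("  direction:", paste(x$direction, collapse = ", "), "\n")
  invisible(x)
}

#' Genome scan for single-locus segregation distortion
#'
#' Applies [f2_distortion_test()] to every marker of an F2 cohort, each
#' with its own non-missing sample size, with a scan-wide Bonferroni
#' threshold of `0.05 / m` for `m` markers tested.
#'
#' @inheritParams genotype_counts
#' @return Data frame (class `"distortion_scan"`) with one row per marker:
#'   counts, expected counts, `chi2`, `df`, `p`, `tier` and collapsed
#'   `direction` flags. Attributes `bonferroni` (the threshold),
#'   `frac_p05` (fraction of markers with p < 0.05) and `n_bonferroni`
#'   (markers beyond the Bonferroni threshold) summarize the scan.
#' @export
scan_f2 <- function(gm, cohort) {
  markers <- gm$markers$name
  n_tests <- length(markers)
  rows <- lapply(markers, function(mk) {
    cnt <- genotype_counts(gm, mk, cohort)
    t <- f2_distortion_test(cnt, n_tests = n_tests)
    data.frame(marker = mk, cohort = cohort,
               n_het = cnt[["n_het"]], n_hom_p1 = cnt[["n_hom_p1"]],
               n_hom_p2 = cnt[["n_hom_p2"]], n_missing = cnt[["n_missing"]],
               exp_het = t$expected[["het"]],
               exp_hom_p1 = t$expected[["hom_p1"]],
               exp_hom_p2 = t$expected[["hom_p2"]],
               chi2 = t$chi2, df = t$df, p = t$p, tier = t$tier,
               direction = paste(t$direction, collapse = ","))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("distortion_scan", "data.frame")
  attr(out, "bonferroni") <- 0.05 / n_tests
  attr(out, "frac_p05") <- mean(out$p < 0.05)
  attr(out, "n_bonferroni") <- sum(out$p < 0.05 / n_tests)
  out
}

#' @export
summary.distortion_scan <- function(object, ...) {
  cat(sprintf(paste0("distortion scan: %d markers, %.1f%% at p < 0.05, ",
                     "%d beyond Bonferroni (p < %.5f)\n"),
              nrow(object), 100 * attr(object, "frac_p05"),
              attr(object, "n_bonferroni"), attr(object, "bonferroni")))
  invisible(object)
}

#' Genome-wide allele ratio test
#'
#' Pools two alleles per non-missing call over all markers and individuals
#' of a cohort (a heterozygote contributes one allele of each type) and
#' tests the P1:P2 allele count against 1:1 with a 1-df chi-square,
#' `chi2 = (n_p1 - n_p2)^2 / (n_p1 + n_p2)`. As in the original single
#' pooled test, non-independence of alleles across linked markers and
#' within individuals is ignored; the test is a coarse directional summary,
#' not an independent-sample chi-square.
#'
#' @inheritParams genotype_counts
#' @return Object of class `"allele_ratio"`: `n_p1_alleles`,
#'   `n_p2_alleles`, `chi2`, `df = 1`, `p`, and `direction`
#'   (`"p1_excess"`, `"p2_excess"` or `"balanced"`).
#' @export
allele_ratio_test <- function(gm, cohort) {
  g <- .cohort_geno(gm, cohort)
  n_p1 <- 2 * sum(g == 1L, na.rm = TRUE) + sum(g == 2L, na.rm = TRUE)
  n_p2 <- 2 * sum(g == 3L, na.rm = TRUE) + sum(g == 2L, na.rm = TRUE)
  if (n_p1 + n_p2 == 0) stop("no non-missing calls in cohort '", cohort, "'")
  chi2 <- (n_p1 - n_p2)^2 / (n_p1 + n_p2)
  structure(list(n_p1_alleles = n_p1, n_p2_alleles = n_p2,
                 chi2 = chi2, df = 1L,
                 p = pchisq(chi2, df = 1, lower.tail = FALSE),
                 direction = if (n_p1 > n_p2) "p1_excess"
                             else if (n_p2 > n_p1) "p2_excess"
                             else "balanced"),
            class = "allele_ratio")
}

#' @export
print.allele_ratio <- function(x, ...) {
  cat(sprintf("allele_ratio: %d P1 vs %d P2 alleles, chi2 = %.2f, p = %.3g (%s)\n",
              x$n_p1_alleles, x$n_p2_alleles, x$chi2, x$p, x$direction))
  invisible(x)
}

#' Chromosome-level distortion test for the non-recombinant backcross
#'
#' In an NR-BC each chromosome is inherited intact from the F1 mother, so
#' every chromosome is either fully heterozygous or fully homozygous P2;
#' the Mendelian expectation is 1:1. Tests the observed heterozygote /
#' homozygote split with a 1-df chi-square.
#'
#' @param n_het,n_hom_p2 Chromosome-state counts.
#' @param n_tests Number of chromosome tests in the enclosing scan (the
#'   original design scans 12 chromosomes, giving a Bonferroni threshold
#'   of 0.05/12, printed as 0.004).
#' @return A `"distortion_test"` object with `df = 1`.
#' @export
#' @examples
#' nrbc_chromosome_test(10, 29, n_tests = 12)
nrbc_chromosome_test <- function(n_het, n_hom_p2, n_tests = 1L) {
  n <- n_het + n_hom_p2
  if (n == 0) stop("no chromosome states to test")
  obs <- c(n_het, n_hom_p2)
  ct <- suppressWarnings(chisq.test(obs, p = c(0.5, 0.5)))
  expected <- rep(n / 2, 2)
  structure(list(observed = stats::setNames(obs, c("het", "hom_p2")),
                 expected = stats::setNames(expected, c("het", "hom_p2")),
                 chi2 = unname(ct$statistic), df = 1L,
                 p = unname(ct$p.value),
                 tier = .tier(unname(ct$p.value), 0.05 / n_tests),
                 direction = .direction_flags(obs, expected,
                                              c("het", "hom_p2"))),
            class = "distortion_test")
}

#' Summarize NR-BC genotypes to one state per chromosome
#'
#' Because NR-BC chromosomes are inherited without recombination, all
#' markers on a chromosome share one true state. Each individual's state
#' per chromosome is the majority call (`"AB"` vs `"BB"`) across that
#' chromosome's markers; ties and all-missing chromosomes give `NA`, and
#' artifact `"AA"` calls do not vote.
#'
#' @inheritParams write_genotype_table
#' @param chromosomes Optional named character vector mapping marker name
#'   to chromosome; defaults to the `chromosome` column of the marker
#'   table.
#' @return Character matrix, NR-BC individuals x chromosomes, entries
#'   `"AB"`, `"BB"` or `NA`.
#' @export
nrbc_chromosome_states <- function(gm, chromosomes = NULL) {
  if (is.null(chromosomes)) {
    chromosomes <- stats::setNames(gm$markers$chromosome, gm$markers$name)
  }
  if (anyNA(chromosomes[gm$markers$name])) {
    stop("chromosome assignment missing for some markers; supply a marker ",
         "map or a 'chromosomes' vector")
  }
  rows <- gm$individuals$cohort == "nrbc_adult_male"
  if (!any(rows)) stop("no NR-BC individuals")
  calls <- gm$calls[rows, , drop = FALSE]
  chrom <- chromosomes[colnames(calls)]
  out <- sapply(unique(chrom), function(cc) {
    sub <- calls[, chrom == cc, drop = FALSE]
    n_ab <- rowSums(sub == "AB", na.rm = TRUE)
    n_bb <- rowSums(sub == "BB", na.rm = TRUE)
    ifelse(n_ab > n_bb, "AB", ifelse(n_bb > n_ab, "BB", NA_character_))
  })
  out <- matrix(out, nrow = sum(rows),
                dimnames = list(gm$individuals$id[rows], unique(chrom)))
  out
}

#' Scan all chromosomes of an NR-BC cohort for distortion
#'
#' Summarizes each chromosome to per-individual states with
#' [nrbc_chromosome_states()] and applies [nrbc_chromosome_test()] with a
#' Bonferroni threshold of 0.05 divided by the number of chromosomes.
#'
#' @inheritParams nrbc_chromosome_states
#' @return Data frame (class `"distortion_scan"`) with one row per
#'   chromosome, plus the same summary attributes as [scan_f2()].
#' @export
scan_nrbc <- function(gm, chromosomes = NULL) {
  st <- nrbc_chromosome_states(gm, chromosomes)
  n_tests <- ncol(st)
  rows <- lapply(colnames(st), function(cc) {
    n_het <- sum(st[, cc] == "AB", na.rm = TRUE)
    n_bb <- sum(st[, cc] == "BB", na.rm = TRUE)
    t <- nrbc_chromosome_test(n_het, n_bb, n_tests = n_tests)
    data.frame(chromosome = cc, cohort = "nrbc_adult_male",
               n_het = n_het, n_hom_p2 = n_bb,
               n_untyped = sum(is.na(st[, cc])),
               chi2 = t$chi2, df = t$df, p = t$p, tier = t$tier,
               direction = paste(t$direction, collapse = ","))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("distortion_scan", "data.frame")
  attr(out, "bonferroni") <- 0.05 / n_tests
  attr(out, "frac_p05") <- mean(out$p < 0.05)
  attr(out, "n_bonferroni") <- sum(out$p < 0.05 / n_tests)
  out
}
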