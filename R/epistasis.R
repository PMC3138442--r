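# Class labels for two-locus genotype combinations. ordered9 keeps the 9
# ordered (locus a, locus b) cells; pooled6 pools the mixed combinations
# (e.g. AA at one locus with AB at the other, in either order) into the six
# unordered classes.
.ordered9_labels <- as.vector(outer(.geno_tokens, .geno_tokens,
                                    function(a, b) paste(a, b, sep = "/")))
.pooled6_pairs <- list(c("AA", "AA"), c("AA", "AB"), c("AA", "BB"),
                       c("AB", "AB"), c("AB", "BB"), c("BB", "BB"))
.pooled6_labels <- vapply(.pooled6_pairs, paste, "", collapse = "/")

#' Expected two-locus genotype class frequencies
#'
#' Multiplicative (independence) expectation for the joint genotype classes
#' of two unlinked loci, from their single-locus genotype frequencies.
#' `ordered9` keeps all nine ordered combinations,
#' `p_a(g) * p_b(h)`; `pooled6` pools each mixed combination over its two
#' ordered assignments (e.g. the AA/AB class gets
#' `p_a(AA) p_b(AB) + p_a(AB) p_b(AA)`), giving the six unordered classes.
#'
#' @param marginals_a,marginals_b Numeric triples of genotype frequencies
#'   (HOM_P1, HET, HOM_P2), each summing to 1.
#' @param class_mode `"ordered9"` (default) or `"pooled6"`.
#' @return Named numeric vector of class frequencies summing to 1.
#' @export
expected_pair_frequencies <- function(marginals_a, marginals_b,
                                      class_mode = c("ordered9", "pooled6")) {
  class_mode <- match.arg(class_mode)
  for (m in list(marginals_a, marginals_b)) {
    if (length(m) != 3L || abs(sum(m) - 1) > 1e-9 || any(m < 0)) {
      stop("marginals must be non-negative genotype frequency triples summing to 1")
    }
  }
  pa <- stats::setNames(as.numeric(marginals_a), .geno_tokens)
  pb <- stats::setNames(as.numeric(marginals_b), .geno_tokens)
  if (class_mode == "ordered9") {
    out <- as.vector(outer(pa, pb))
    names(out) <- .ordered9_labels
  } else {
    out <- vapply(.pooled6_pairs, function(cl) {
      if (cl[1L] == cl[2L]) pa[cl[1L]] * pb[cl[2L]]
      else pa[cl[1L]] * pb[cl[2L]] + pa[cl[2L]] * pb[cl[1L]]
    }, 0)
    names(out) <- .pooled6_labels
  }
  out
}

#' Two-locus epistasis goodness-of-fit test
#'
#' Tests a pair of physically unlinked markers for deviation from
#' multiplicative joint genotype frequencies. Expected class counts are the
#' product of the observed single-locus marginals (computed from the table
#' itself) times the pairwise-complete sample size; the statistic is a
#' Pearson chi-square over the classes with `df = #classes - 1` (8 for
#' `ordered9`, 5 for `pooled6`) — the goodness-of-fit convention of the
#' original analysis, with no df reduction for the estimated marginals.
#' Each class also receives a signed contribution
#' `sign(obs - exp) * (obs - exp)^2 / exp`, so a negative value flags a
#' combination rarer than chance; the contributions sum in absolute value
#' to the total chi-square. Classes with zero expectation contribute
#' nothing; any expected count below 5 sets the `low_expected` flag rather
#' than triggering silent pooling.
#'
#' @param counts 3 x 3 joint genotype count table, rows = marker a,
#'   columns = marker b, both ordered (HOM_P1, HET, HOM_P2).
#' @inheritParams expected_pair_frequencies
#' @return Object of class `"epistasis_test"`: observed and expected class
#'   counts, `chi2`, `df`, `p`, signed `contributions`, `n` and
#'   `low_expected`.
#' @export
pair_epistasis_test <- function(counts, class_mode = c("ordered9", "pooled6")) {
  class_mode <- match.arg(class_mode)
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3L, 3L))) stop("counts must be a 3 x 3 table")
  if (any(counts < 0)) stop("negative counts")
  n <- sum(counts)
  if (n == 0) stop("empty two-locus count table")
  exp_freq <- expected_pair_frequencies(rowSums(counts) / n,
                                        colSums(counts) / n, class_mode)
  if (class_mode == "ordered9") {
    obs <- stats::setNames(as.vector(counts), .ordered9_labels)
  } else {
    dimnames(counts) <- list(.geno_tokens, .geno_tokens)
    obs <- vapply(.pooled6_pairs, function(cl) {
      if (cl[1L] == cl[2L]) counts[cl[1L], cl[2L]]
      else counts[cl[1L], cl[2L]] + counts[cl[2L], cl[1L]]
    }, 0)
    names(obs) <- .pooled6_labels
  }
  expected <- exp_freq * n
  contrib <- numeric(length(obs))
  nz <- expected > 0
  contrib[nz] <- sign(obs[nz] - expected[nz]) *
    (obs[nz] - expected[nz])^2 / expected[nz]
  names(contrib) <- names(obs)
  chi2 <- sum(abs(contrib))
  df <- length(obs) - 1L
  structure(list(observed = obs, expected = expected,
                 contributions = contrib, chi2 = chi2, df = df,
                 p = pchisq(chi2, df = df, lower.tail = FALSE),
                 n = n, class_mode = class_mode,
                 low_expected = any(nz & expected < 5)),
            class = "epistasis_test")
}

#' @export
print.epistasis_test <- function(x, ...) {
  cat(sprintf("epistasis_test (%s): chi2 = %.2f (df %d), p = %.3g, n = %d%s\n",
              x$class_mode, x$chi2, x$df, x$p, x$n,
              if (x$low_expected) " [low expected counts]" else ""))
  invisible(x)
}

#' Pairwise epistasis scan between linkage groups
#'
#' Applies [pair_epistasis_test()] to every pair of markers assigned to
#' different linkage groups, using pairwise-complete counts. The scan
#' summary reports the count of pairs at p < 0.05 and a Bonferroni
#' denominator equal to the number of ordered pairs of distinct groups
#' (`g * (g - 1)`; 132 for 12 groups), the multiple-testing convention of
#' the original analysis.
#'
#' @inheritParams genotype_counts
#' @param groups Named character vector mapping each marker to its linkage
#'   group (e.g. the `assignment` of [build_map()]); defaults to the
#'   `chromosome` column of the marker table.
#' @inheritParams expected_pair_frequencies
#' @return Data frame (class `"epistasis_scan"`) with one row per
#'   between-group pair: markers, groups, `n`, `chi2`, `df`, `p`,
#'   `low_expected` and one signed contribution column per class.
#'   Attributes `bonferroni_denominator`, `bonferroni`, `n_p05`.
#' @export
scan_pairs <- function(gm, cohort, groups = NULL,
                       class_mode = c("ordered9", "pooled6")) {
  class_mode <- match.arg(class_mode)
  if (is.null(groups)) {
    groups <- stats::setNames(gm$markers$chromosome, gm$markers$name)
  }
  if (anyNA(groups[gm$markers$name])) {
    stop("group assignment missing for some markers")
  }
  g <- .cohort_geno(gm, cohort)
  markers <- colnames(g)
  pairs <- combn(length(markers), 2L)
  res <- list()
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]
    j <- pairs[2L, k]
    if (groups[markers[i]] == groups[markers[j]]) next
    tab <- .pair_table(g[, i], g[, j])
    if (sum(tab) == 0) next
    t <- pair_epistasis_test(tab, class_mode)
    row <- data.frame(marker_a = markers[i], marker_b = markers[j],
                      group_a = unname(groups[markers[i]]),
                      group_b = unname(groups[markers[j]]),
                      n = t$n, chi2 = t$chi2, df = t$df, p = t$p,
                      low_expected = t$low_expected)
    contrib <- as.data.frame(as.list(t$contributions))
    names(contrib) <- paste0("c_", gsub("/", "_", names(t$contributions)))
    res[[length(res) + 1L]] <- cbind(row, contrib)
  }
  if (!length(res)) stop("no between-group marker pairs to test")
  out <- do.call(rbind, res)
  n_groups <- length(unique(groups[markers]))
  class(out) <- c("epistasis_scan", "data.frame")
  attr(out, "class_mode") <- class_mode
  attr(out, "bonferroni_denominator") <- n_groups * (n_groups - 1L)
  attr(out, "bonferroni") <- 0.05 / (n_groups * (n_groups - 1L))
  attr(out, "n_p05") <- sum(out$p < 0.05)
  out
}

#' @export
summary.epistasis_scan <- function(object, ...) {
  cat(sprintf(paste0("epistasis scan (%s): %d between-group pairs, %d at ",
                     "p < 0.05; Bonferroni denominator %d (threshold %.5f)\n"),
              attr(object, "class_mode"), nrow(object),
              attr(object, "n_p05"), attr(object, "bonferroni_denominator"),
              attr(object, "bonferroni")))
  invisible(object)
}

#' Inter-chromosome linkage disequilibrium test in the NR-BC
#'
#' Pearson chi-square of independence (1 df, no continuity correction) on
#' the 2 x 2 table of chromosome states (HET vs HOM_P2) for a pair of
#' chromosomes in the non-recombinant backcross. A table with an empty row
#' or column margin is flagged untestable rather than raising an error.
#'
#' @param counts 2 x 2 numeric table, rows = chromosome a state (HET,
#'   HOM_P2), columns = chromosome b state.
#' @return Object of class `"ld_test"`: `counts`, `chi2`, `df = 1`, `p`,
#'   `untestable`.
#' @export
#' @examples
#' nrbc_ld_test(matrix(c(15, 5, 5, 15), 2, 2))
nrbc_ld_test <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("counts must be a 2 x 2 table")
  if (any(counts < 0)) stop("negative counts")
  if (sum(counts) == 0) stop("empty table")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    return(structure(list(counts = counts, chi2 = NA_real_, df = 1L,
                          p = NA_real_, untestable = TRUE),
                     class = "ld_test"))
  }
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  structure(list(counts = counts, chi2 = unname(ct$statistic), df = 1L,
                 p = unname(ct$p.value), untestable = FALSE),
            class = "ld_test")
}

#' @export
print.ld_test <- function(x, ...) {
  if (x$untestable) cat("ld_test: untestable (empty margin)\n")
  else cat(sprintf("ld_test: chi2 = %.2f (df 1), p = %.3g\n", x$chi2, x$p))
  invisible(x)
}

#' Pairwise inter-chromosome LD scan for the NR-BC cohort
#'
#' Summarizes chromosomes to per-individual states with
#' [nrbc_chromosome_states()] and applies [nrbc_ld_test()] to every
#' chromosome pair (complete cases per pair).
#'
#' @inheritParams nrbc_chromosome_states
#' @return Data frame with one row per chromosome pair: `chrom_a`,
#'   `chrom_b`, the four state counts, `n`, `chi2`, `df`, `p`,
#'   `untestable`.
#' @export
scan_nrbc_ld <- function(gm, chromosomes = NULL) {
  st <- nrbc_chromosome_states(gm, chromosomes)
  chroms <- colnames(st)
  if (length(chroms) < 2L) stop("need at least two chromosomes")
  pairs <- combn(length(chroms), 2L)
  res <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- st[, pairs[1L, k]]
    b <- st[, pairs[2L, k]]
    ok <- !is.na(a) & !is.na(b)
    tab <- matrix(c(sum(a[ok] == "AB" & b[ok] == "AB"),
                    sum(a[ok] == "BB" & b[ok] == "AB"),
                    sum(a[ok] == "AB" & b[ok] == "BB"),
                    sum(a[ok] == "BB" & b[ok] == "BB")), 2L, 2L)
    t <- if (sum(tab) > 0) nrbc_ld_test(tab) else
      list(chi2 = NA_real_, p = NA_real_, untestable = TRUE)
    res[[k]] <- data.frame(chrom_a = chroms[pairs[1L, k]],
                           chrom_b = chroms[pairs[2L, k]],
                           n_hh = tab[1, 1], n_bh = tab[2, 1],
                           n_hb = tab[1, 2], n_bb = tab[2, 2],
                           n = sum(tab), chi2 = t$chi2, df = 1L, p = t$p,
                           untestable = t$untestable)
  }
  out <- do.call(rbind, res)
  attr(out, "n_p05") <- sum(out$p < 0.05, na.rm = TRUE)
  out
}
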