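#' Default genome layout for the mapping-cross design
#'
#' A marker panel emulating the study design: 53 codominant markers (45
#' SNPs plus 8 microsatellites anchoring chromosomes 1-8) on 12
#' chromosomes — eleven multi-marker groups carrying 52 markers and one
#' chromosome represented by a single unlinked marker. Positions are
#' male-map centimorgans (females are achiasmatic, so only the male map
#' has non-zero length). The default spacing is calibrated so that a
#' standard symmetric-model F2 analysis of achiasmatic data — in which the
#' estimated fraction converges to `1 - sqrt(1 - r_m)` for true male-map
#' fraction `r_m` — recovers a mean observed spacing of 6.5 cM:
#' `spacing = kosambi_cm(1 - (1 - kosambi_r(6.5))^2)`, about 12.8 cM.
#'
#' @param spacing_cM Male-map distance between adjacent markers; `NULL`
#'   (default) uses the calibration above.
#' @return Marker map data frame (`name`, `chromosome`, `position_cM`,
#'   `marker_class`) usable as a simulator layout and writable with
#'   [write_marker_map()].
#' @export
default_genome_layout <- function(spacing_cM = NULL) {
  if (is.null(spacing_cM)) {
    spacing_cM <- kosambi_cm(1 - (1 - kosambi_r(6.5))^2)
  }
  sizes <- c(6L, 5L, 5L, 5L, 5L, 4L, 5L, 4L, 4L, 4L, 5L, 1L)
  chroms <- sprintf("chr%02d", seq_along(sizes))
  rows <- lapply(seq_along(sizes), function(i) {
    m <- sizes[i]
    data.frame(name = sprintf("L%02d.%d", i, seq_len(m)),
               chromosome = chroms[i],
               position_cM = (seq_len(m) - 1) * spacing_cM,
               marker_class = "snp")
  })
  out <- do.call(rbind, rows)
  # one anchoring microsatellite on each of chromosomes 1-8
  out$marker_class[match(sprintf("L%02d.1", 1:8), out$name)] <- "microsatellite"
  out
}

.validate_layout <- function(layout) {
  need <- c("name", "chromosome", "position_cM")
  miss <- setdiff(need, names(layout))
  if (length(miss)) stop("layout lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(layout$name)) stop("duplicate marker names in layout")
  for (cc in unique(layout$chromosome)) {
    pos <- layout$position_cM[layout$chromosome == cc]
    if (any(diff(pos) <= 0) && length(pos) > 1L) {
      stop("positions must be strictly increasing within chromosome '", cc, "'")
    }
  }
  invisible(layout)
}

#' Genotyping error model
#'
#' Two artifact processes observed in real codominant assays: heterozygote
#' undercalling (a true HET reported as a homozygote, as seen for
#' difficult SNP assays and microsatellites with large allele-size
#' differences) and outright call failure.
#'
#' @param het_undercall_rate Probability a HET call is rewritten as a
#'   random homozygote.
#' @param missing_rate Per-call probability of a missing call.
#' @return List of class `"error_model"`.
#' @export
error_model <- function(het_undercall_rate = 0.02, missing_rate = 0.02) {
  if (het_undercall_rate < 0 || het_undercall_rate > 1 ||
      missing_rate < 0 || missing_rate > 1) {
    stop("error rates must lie in [0, 1]")
  }
  structure(list(het_undercall_rate = het_undercall_rate,
                 missing_rate = missing_rate),
            class = "error_model")
}

#' Stage-specific viability selection regime
#'
#' Relative viabilities acting either before hatching or between hatching
#' and adulthood. Single-locus entries give the fitness of
#' (HOM_P1, HET, HOM_P2); epistatic pairs give a 3 x 3 viability table
#' indexed the same way for the two markers. An individual's survival
#' probability is the product of its viabilities across all entries,
#' normalized by the maximum achievable product (so the fittest genotype
#' survives with probability 1).
#'
#' @param single_locus Named list: marker name -> numeric triple of
#'   viabilities in `[0, 1]`.
#' @param epistatic_pairs List of `list(markers = c(a, b), table = 3x3)`.
#' @param stage `"pre_hatching"` or `"hatching_to_adult"`.
#' @return List of class `"selection_regime"`.
#' @export
selection_regime <- function(single_locus = list(), epistatic_pairs = list(),
                             stage = c("hatching_to_adult", "pre_hatching")) {
  stage <- match.arg(stage)
  for (mk in names(single_locus)) {
    w <- single_locus[[mk]]
    if (length(w) != 3L || any(w < 0) || any(w > 1)) {
      stop("viabilities for '", mk, "' must be a triple in [0, 1]")
    }
    if (max(w) == 0) stop("every viability is zero at '", mk, "'")
  }
  for (pr in epistatic_pairs) {
    if (is.null(pr$markers) || length(pr$markers) != 2L || is.null(pr$table)) {
      stop("each epistatic pair needs 'markers' (length 2) and 'table' (3 x 3)")
    }
    tb <- as.matrix(pr$table)
    if (!all(dim(tb) == c(3L, 3L)) || any(tb < 0) || any(tb > 1)) {
      stop("epistatic viability table must be 3 x 3 in [0, 1]")
    }
    if (max(tb) == 0) stop("every viability is zero in an epistatic table")
  }
  structure(list(single_locus = single_locus,
                 epistatic_pairs = epistatic_pairs, stage = stage),
            class = "selection_regime")
}

#' Preset selection regimes
#'
#' Encodes the qualitative adult distortion patterns of the study system:
#' `"chr10_sd_deficit"` gives `HOM_P1` viability 0.05 at every marker of
#' chromosome 10 (near-lethality of the maternal-line homozygote);
#' `"het_excess_2_7"` gives `HOM_P2` viability 0.5 at chromosomes 2 and 7
#' (heterozygote excess through selection against the paternal-line
#' homozygote); `"null"` applies no selection.
#'
#' @param name One of `"null"`, `"chr10_sd_deficit"`, `"het_excess_2_7"`.
#' @param layout Genome layout the regime refers to.
#' @return A list of `"selection_regime"` objects (empty for `"null"`),
#'   all acting between hatching and adulthood.
#' @export
regime_preset <- function(name = c("null", "chr10_sd_deficit",
                                   "het_excess_2_7"),
                          layout = default_genome_layout()) {
  name <- match.arg(name)
  on_chrom <- function(chroms) layout$name[layout$chromosome %in% chroms]
  switch(name,
         null = list(),
         chr10_sd_deficit = list(selection_regime(
           single_locus = stats::setNames(
             rep(list(c(0.05, 1, 1)), length(on_chrom("chr10"))),
             on_chrom("chr10")),
           stage = "hatching_to_adult")),
         het_excess_2_7 = list(selection_regime(
           single_locus = stats::setNames(
             rep(list(c(1, 1, 0.5)), length(on_chrom(c("chr02", "chr07")))),
             on_chrom(c("chr02", "chr07"))),
           stage = "hatching_to_adult")))
}

#' Cross simulation configuration
#'
#' Bundles the genome layout, selection regimes, cohort sizes, F1 pair
#' counts, genotyping error model and RNG seed. Defaults reproduce the
#' study design: 190 genotyped F2 nauplii from 4 F1 pairs, 205 F2 adult
#' males from 25 pairs, 39 NR-BC adult males from 7 pairs.
#'
#' @param layout Marker map data frame (see [default_genome_layout()]).
#' @param regimes A `"selection_regime"` or list of them.
#' @param n_nauplii,n_adult_males,n_nrbc_males Cohort sizes.
#' @param n_f1_pairs Named vector with elements `nauplii`, `adult`, `nrbc`.
#' @param error_model An [error_model()].
#' @param seed Integer RNG seed; fixing it fixes every output byte.
#' @return List of class `"cross_config"`.
#' @export
cross_config <- function(layout = default_genome_layout(),
                         regimes = list(),
                         n_nauplii = 190L, n_adult_males = 205L,
                         n_nrbc_males = 39L,
                         n_f1_pairs = c(nauplii = 4L, adult = 25L, nrbc = 7L),
                         error_model = segscan::error_model(),
                         seed = 1L) {
  .validate_layout(layout)
  if (inherits(regimes, "selection_regime")) regimes <- list(regimes)
  for (reg in regimes) {
    stopifnot(inherits(reg, "selection_regime"))
    used <- c(names(reg$single_locus),
              unlist(lapply(reg$epistatic_pairs, `[[`, "markers")))
    bad <- setdiff(used, layout$name)
    if (length(bad)) {
      stop("selection regime references unknown marker(s): ",
           paste(bad, collapse = ", "))
    }
  }
  if (any(c(n_nauplii, n_adult_males, n_nrbc_males) <= 0)) {
    stop("cohort sizes must be positive")
  }
  if (!all(c("nauplii", "adult", "nrbc") %in% names(n_f1_pairs))) {
    stop("n_f1_pairs needs elements nauplii, adult and nrbc")
  }
  stopifnot(inherits(error_model, "error_model"))
  structure(list(layout = layout, regimes = regimes,
                 n_nauplii = as.integer(n_nauplii),
                 n_adult_males = as.integer(n_adult_males),
                 n_nrbc_males = as.integer(n_nrbc_males),
                 n_f1_pairs = n_f1_pairs, error_model = error_model,
                 seed = as.integer(seed)),
            class = "cross_config")
}

#' Female meiosis: achiasmatic transmission
#'
#' Females transmit one of the two parental chromosome haplotypes intact
#' (probability 1/2 each); no crossover ever occurs.
#'
#' @param haplotypes 2 x m matrix, one row per homolog, marker alleles
#'   coded 0 (P1) / 1 (P2).
#' @return One gamete haplotype (length-m vector).
#' @export
meiosis_female <- function(haplotypes) {
  haplotypes <- as.matrix(haplotypes)
  stopifnot(nrow(haplotypes) == 2L)
  haplotypes[rbinom(1L, 1L, 0.5) + 1L, ]
}

#' Male meiosis: Markov crossover walk
#'
#' Builds a recombinant gamete by starting on a random homolog and
#' switching homologs between adjacent markers independently with the
#' given interval probabilities (a no-interference Markov chain; interval
#' probabilities normally come from the inverse Kosambi transform of
#' adjacent map distances).
#'
#' @inheritParams meiosis_female
#' @param r Numeric vector of interval recombination probabilities, length
#'   `m - 1`, each in `[0, 0.5)` (or `[0, 0.5]`; 0.5 makes adjacent
#'   markers independent).
#' @return One gamete haplotype (length-m vector).
#' @export
meiosis_male <- function(haplotypes, r) {
  haplotypes <- as.matrix(haplotypes)
  m <- ncol(haplotypes)
  stopifnot(nrow(haplotypes) == 2L, length(r) == m - 1L)
  if (any(r < 0) || any(r > 0.5)) stop("interval probabilities must lie in [0, 0.5]")
  switches <- c(rbinom(1L, 1L, 0.5),
                if (m > 1L) rbinom(m - 1L, 1L, r))
  homolog <- cumsum(switches) %% 2L
  haplotypes[cbind(homolog + 1L, seq_len(m))]
}

# Vectorized F2 zygote generation over the whole layout: returns an
# integer matrix (n x markers) of P2-allele dosages 0/1/2. The maternal
# gamete is an intact parental haplotype per chromosome (achiasmy); the
# paternal gamete follows the Markov crossover walk.
.f2_zygotes <- function(n, layout) {
  geno <- matrix(0L, n, nrow(layout))
  colnames(geno) <- layout$name
  for (cc in unique(layout$chromosome)) {
    idx <- which(layout$chromosome == cc)
    m <- length(idx)
    mat <- matrix(rbinom(n, 1L, 0.5), n, m)  # whole-haplotype choice
    start <- rbinom(n, 1L, 0.5)
    if (m > 1L) {
      r <- kosambi_r(diff(layout$position_cM[idx]))
      sw <- matrix(rbinom(n * (m - 1L), 1L, rep(r, each = n)), n, m - 1L)
      pat <- matrix(0L, n, m)
      cur <- start
      pat[, 1L] <- cur
      for (j in seq_len(m - 1L)) {
        cur <- (cur + sw[, j]) %% 2L
        pat[, j + 1L] <- cur
      }
    } else {
      pat <- matrix(start, n, 1L)
    }
    geno[, idx] <- mat + pat
  }
  geno
}

# NR-BC zygotes: maternal chromosome intact (P1 or P2), paternal
# chromosome whole-P2, so the dosage is uniform 1 (HET) or 2 (HOM_P2)
# along each chromosome.
.nrbc_zygotes <- function(n, layout) {
  geno <- matrix(0L, n, nrow(layout))
  colnames(geno) <- layout$name
  for (cc in unique(layout$chromosome)) {
    idx <- which(layout$chromosome == cc)
    geno[, idx] <- matrix(1L + rbinom(n, 1L, 0.5), n, length(idx))
  }
  geno
}

# Relative survival probability for each row of a dosage matrix under the
# regimes acting at the given stage; normalized by the maximum achievable
# viability product.
.survival_prob <- function(geno, layout, regimes, stage) {
  p <- rep(1, nrow(geno))
  max_p <- 1
  for (reg in regimes) {
    if (reg$stage != stage) next
    for (mk in names(reg$single_locus)) {
      w <- reg$single_locus[[mk]]
      p <- p * w[geno[, mk] + 1L]
      max_p <- max_p * max(w)
    }
    for (pr in reg$epistatic_pairs) {
      tb <- as.matrix(pr$table)
      p <- p * tb[cbind(geno[, pr$markers[1L]] + 1L,
                        geno[, pr$markers[2L]] + 1L)]
      max_p <- max_p * max(tb)
    }
  }
  p / max_p
}

# Rejection-sample a cohort of n_target survivors; stages is the sequence
# of selection stages survived, need_male filters to Bernoulli(0.5) males.
.sample_cohort <- function(config, n_target, stages, need_male, zygote_fun) {
  layout <- config$layout
  kept <- NULL
  guard <- 0L
  while (is.null(kept) || nrow(kept) < n_target) {
    guard <- guard + 1L
    if (guard > 10000L) stop("survival probability too low to fill the cohort")
    b <- max(256L, 2L * n_target)
    z <- zygote_fun(b, layout)
    alive <- rep(TRUE, b)
    for (st in stages) {
      pr <- .survival_prob(z, layout, config$regimes, st)
      alive <- alive & (runif(b) < pr)
    }
    if (need_male) alive <- alive & (rbinom(b, 1L, 0.5) == 1L)
    z <- z[alive, , drop = FALSE]
    kept <- if (is.null(kept)) z else rbind(kept, z)
  }
  kept[seq_len(n_target), , drop = FALSE]
}

.dosage_to_calls <- function(geno) {
  calls <- matrix(.geno_tokens[geno + 1L], nrow(geno), ncol(geno))
  colnames(calls) <- colnames(geno)
  calls
}

.make_individuals <- function(n, prefix, cohort, sex, n_pairs) {
  data.frame(id = sprintf("%s%04d", prefix, seq_len(n)),
             cohort = cohort,
             family = rep_len(sprintf("F1P%02d", seq_len(n_pairs)), n),
             sex = sex, mito = "P1")
}

#' Simulate F2 nauplii and adult-male cohorts
#'
#' Gene-drop through the SD x SC-style design: every F1 is heterozygous at
#' every marker (one whole-P1 and one whole-P2 homolog); each F2 receives
#' an intact maternal haplotype per chromosome (female achiasmy) and a
#' recombinant paternal gamete (Markov walk with inverse-Kosambi interval
#' probabilities). Pre-hatching selection acts before the nauplii
#' snapshot; hatching-to-adult selection and a Bernoulli(0.5) male filter
#' produce the adult cohort; the genotyping error model is applied last.
#' Family labels cycle over the configured number of F1 pairs. All
#' individuals carry the maternal (`P1`) mitochondrial haplotype.
#'
#' @param config A [cross_config()].
#' @param cohorts Which cohorts to generate (both by default).
#' @return Named list of [genotype_matrix()] objects (`nauplii`,
#'   `adult_males`).
#' @export
simulate_f2_cohorts <- function(config,
                                cohorts = c("nauplii", "adult_males")) {
  stopifnot(inherits(config, "cross_config"))
  cohorts <- match.arg(cohorts, several.ok = TRUE)
  set.seed(config$seed)
  out <- list()
  if ("nauplii" %in% cohorts) {
    z <- .sample_cohort(config, config$n_nauplii, "pre_hatching",
                        need_male = FALSE, zygote_fun = .f2_zygotes)
    ind <- .make_individuals(config$n_nauplii, "N", "f2_nauplii", "unknown",
                             config$n_f1_pairs[["nauplii"]])
    gm <- genotype_matrix(ind, config$layout, .dosage_to_calls(z))
    out$nauplii <- apply_genotyping_artifacts(gm, config$error_model)
  }
  if ("adult_males" %in% cohorts) {
    z <- .sample_cohort(config, config$n_adult_males,
                        c("pre_hatching", "hatching_to_adult"),
                        need_male = TRUE, zygote_fun = .f2_zygotes)
    ind <- .make_individuals(config$n_adult_males, "A", "f2_adult_male",
                             "male", config$n_f1_pairs[["adult"]])
    gm <- genotype_matrix(ind, config$layout, .dosage_to_calls(z))
    out$adult_males <- apply_genotyping_artifacts(gm, config$error_model)
  }
  out
}

#' Simulate the non-recombinant backcross cohort
#'
#' F1 females (achiasmatic) backcrossed to P2-line males: each offspring
#' chromosome pairs an intact maternal haplotype (whole-P1 or whole-P2,
#' probability 1/2, independent across chromosomes) with a whole-P2
#' paternal chromosome, so each chromosome is uniformly HET or HOM_P2.
#' Both selection stages and the error model are applied as in
#' [simulate_f2_cohorts()]. The RNG stream is seeded at `config$seed + 1`
#' so one configuration drives F2 and NR-BC draws without replaying the
#' same stream.
#'
#' @inheritParams simulate_f2_cohorts
#' @return A [genotype_matrix()] of NR-BC adult males.
#' @export
simulate_nrbc <- function(config) {
  stopifnot(inherits(config, "cross_config"))
  set.seed(config$seed + 1L)
  z <- .sample_cohort(config, config$n_nrbc_males,
                      c("pre_hatching", "hatching_to_adult"),
                      need_male = TRUE, zygote_fun = .nrbc_zygotes)
  stopifnot(all(z >= 1L))  # design invariant: no HOM_P1 before artifacts
  ind <- .make_individuals(config$n_nrbc_males, "B", "nrbc_adult_male",
                           "male", config$n_f1_pairs[["nrbc"]])
  gm <- genotype_matrix(ind, config$layout, .dosage_to_calls(z))
  apply_genotyping_artifacts(gm, config$error_model)
}

#' Apply genotyping artifacts to a genotype matrix
#'
#' Each HET call is independently rewritten to a random homozygote (equal
#' odds) with probability `het_undercall_rate`; each call is then
#' independently set missing with probability `missing_rate`.
#'
#' @inheritParams write_genotype_table
#' @param em An [error_model()].
#' @param seed Optional seed; by default the current RNG stream is used
#'   (as inside the simulators).
#' @return The corrupted genotype matrix.
#' @export
apply_genotyping_artifacts <- function(gm, em, seed = NULL) {
  stopifnot(inherits(em, "error_model"))
  if (!is.null(seed)) set.seed(seed)
  calls <- gm$calls
  if (em$het_undercall_rate > 0) {
    het <- !is.na(calls) & calls == "AB"
    flip <- het & (runif(length(calls)) < em$het_undercall_rate)
    n_flip <- sum(flip)
    if (n_flip) {
      calls[flip] <- c("AA", "BB")[rbinom(n_flip, 1L, 0.5) + 1L]
    }
  }
  if (em$missing_rate > 0) {
    calls[runif(length(calls)) < em$missing_rate] <- NA_character_
  }
  gm$calls <- calls
  gm
}
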