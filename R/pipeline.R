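#' Simulate all cohorts and write the run to disk
#'
#' Generates the F2 nauplii, F2 adult-male and NR-BC cohorts under one
#' configuration and writes the genotype CSVs, the marker map TSV and a
#' run-metadata record (seed, configuration digest, file manifest).
#'
#' @param config A [cross_config()] or path to a YAML config file.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the named list of output paths.
#' @export
run_simulation <- function(config, out_dir) {
  if (is.character(config)) config <- read_cross_config(config)
  stopifnot(inherits(config, "cross_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f2 <- simulate_f2_cohorts(config)
  nrbc <- simulate_nrbc(config)
  paths <- list(
    nauplii = file.path(out_dir, "nauplii.csv"),
    adult_males = file.path(out_dir, "adult_males.csv"),
    nrbc = file.path(out_dir, "nrbc.csv"),
    marker_map = file.path(out_dir, "marker_map.tsv"),
    metadata = file.path(out_dir, "run_metadata.yaml"))
  write_genotype_table(f2$nauplii, paths$nauplii)
  write_genotype_table(f2$adult_males, paths$adult_males)
  write_genotype_table(nrbc, paths$nrbc)
  write_marker_map(config$layout, paths$marker_map)
  yaml::write_yaml(list(seed = config$seed,
                        config_digest = config_digest(config),
                        n_nauplii = config$n_nauplii,
                        n_adult_males = config$n_adult_males,
                        n_nrbc_males = config$n_nrbc_males,
                        files = lapply(paths[1:4], basename)),
                   paths$metadata)
  invisible(paths)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis pipeline on a genotype table
#'
#' For each F2 cohort present: two-point linkage map ([build_map()]), map
#' summary, single-locus distortion scan ([scan_f2()]), pooled allele
#' ratio test and between-group epistasis scan ([scan_pairs()]). For an
#' NR-BC cohort: chromosome-level distortion ([scan_nrbc()]) and
#' inter-chromosome LD ([scan_nrbc_ld()]), using the marker map's
#' chromosomes when supplied and otherwise the linkage groups inferred
#' from an F2 cohort. Absent cohorts are skipped and marked absent in the
#' report. All result tables are written as TSV next to a JSON and a plain
#' text report; every threshold actually applied (linkage alpha,
#' Bonferroni denominators) is recorded.
#'
#' @param genotypes A [genotype_matrix()] or path to a genotype CSV.
#' @param out_dir Output directory (created if absent).
#' @param marker_map Optional marker map data frame or TSV path; attaches
#'   chromosome assignments used for the NR-BC tests.
#' @param sex_model,alpha_linkage,group_max_r Passed to [build_map()].
#' @param class_mode Passed to [scan_pairs()].
#' @return Invisibly, the report (class `"run_report"`): nested list of
#'   summaries plus a file manifest.
#' @export
run_analysis <- function(genotypes, out_dir, marker_map = NULL,
                         sex_model = c("symmetric", "female_achiasmatic"),
                         class_mode = c("ordered9", "pooled6"),
                         alpha_linkage = 0.001, group_max_r = 0.35) {
  sex_model <- match.arg(sex_model)
  class_mode <- match.arg(class_mode)
  gm <- if (is.character(genotypes)) read_genotype_table(genotypes) else genotypes
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.character(marker_map)) marker_map <- read_marker_map(marker_map)
  if (!is.null(marker_map)) gm <- attach_marker_map(gm, marker_map)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  present <- intersect(.cohorts, unique(gm$individuals$cohort))
  report <- list(options = list(sex_model = sex_model,
                                class_mode = class_mode,
                                alpha_linkage = alpha_linkage,
                                group_max_r = group_max_r),
                 cohorts = list(), files = character(0))
  f2_groups <- NULL
  for (cohort in intersect(c("f2_nauplii", "f2_adult_male"), present)) {
    sec <- list()
    map <- build_map(gm, cohort, sex_model = sex_model,
                     alpha = alpha_linkage, group_max_r = group_max_r)
    if (is.null(f2_groups)) f2_groups <- map$assignment
    f <- .write_tsv(map$groups, file.path(out_dir, paste0("map_", cohort, ".tsv")))
    report$files <- c(report$files, f)
    f <- .write_tsv(map$pairwise,
                    file.path(out_dir, paste0("twopoint_", cohort, ".tsv")))
    report$files <- c(report$files, f)
    sec$map <- tryCatch(unclass(map_summary(map)),
                        error = function(e) list(note = conditionMessage(e)))
    sec$map$n_groups_found <- nrow(map$lengths)
    dist <- scan_f2(gm, cohort)
    f <- .write_tsv(dist, file.path(out_dir, paste0("distortion_", cohort, ".tsv")))
    report$files <- c(report$files, f)
    sec$distortion <- list(n_markers = nrow(dist),
                           frac_p05 = attr(dist, "frac_p05"),
                           bonferroni = attr(dist, "bonferroni"),
                           n_bonferroni = attr(dist, "n_bonferroni"))
    ar <- allele_ratio_test(gm, cohort)
    sec$allele_ratio <- unclass(ar)
    ep <- scan_pairs(gm, cohort, groups = map$assignment,
                     class_mode = class_mode)
    f <- .write_tsv(ep, file.path(out_dir, paste0("epistasis_", cohort, ".tsv")))
    report$files <- c(report$files, f)
    sec$epistasis <- list(n_pairs = nrow(ep), n_p05 = attr(ep, "n_p05"),
                          bonferroni_denominator =
                            attr(ep, "bonferroni_denominator"),
                          bonferroni = attr(ep, "bonferroni"))
    report$cohorts[[cohort]] <- sec
  }
  if ("nrbc_adult_male" %in% present) {
    chroms <- NULL
    if (all(!is.na(gm$markers$chromosome))) {
      chroms <- stats::setNames(gm$markers$chromosome, gm$markers$name)
    } else if (!is.null(f2_groups)) {
      chroms <- f2_groups
    }
    if (is.null(chroms)) {
      report$cohorts$nrbc_adult_male <-
        list(note = "no chromosome assignment available; NR-BC tests skipped")
    } else {
      sec <- list()
      nd <- scan_nrbc(gm, chroms)
      f <- .write_tsv(nd, file.path(out_dir, "nrbc_chromosome.tsv"))
      report$files <- c(report$files, f)
      sec$distortion <- list(n_chromosomes = nrow(nd),
                             frac_p05 = attr(nd, "frac_p05"),
                             bonferroni = attr(nd, "bonferroni"),
                             n_bonferroni = attr(nd, "n_bonferroni"))
      ld <- scan_nrbc_ld(gm, chroms)
      f <- .write_tsv(ld, file.path(out_dir, "nrbc_ld.tsv"))
      report$files <- c(report$files, f)
      sec$ld <- list(n_pairs = nrow(ld),
                     n_p05 = attr(ld, "n_p05"),
                     n_untestable = sum(ld$untestable))
      report$cohorts$nrbc_adult_male <- sec
    }
  }
  absent <- setdiff(.cohorts, present)
  for (cohort in absent) report$cohorts[[cohort]] <- list(note = "absent")
  class(report) <- "run_report"
  jsonlite::write_json(unclass(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(utils::capture.output(print(report)),
             file.path(out_dir, "report.txt"))
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("segscan run report\n")
  cat("  options: sex_model =", x$options$sex_model,
      "| class_mode =", x$options$class_mode,
      "| linkage alpha =", x$options$alpha_linkage,
      "| group max r =", x$options$group_max_r, "\n")
  for (cohort in names(x$cohorts)) {
    sec <- x$cohorts[[cohort]]
    cat(cohort, ":\n", sep = "")
    if (!is.null(sec$note)) {
      cat("  ", sec$note, "\n")
      next
    }
    if (!is.null(sec$map) && is.null(sec$map$note)) {
      cat(sprintf(paste0("  map: %d groups, total %.1f cM, spacing %.1f cM,",
                         " corrected %.1f cM, coverage %.1f%%\n"),
                  sec$map$n_groups_found, sec$map$total_length, sec$map$d,
                  sec$map$corrected_length, 100 * sec$map$coverage))
    }
    if (!is.null(sec$distortion)) {
      n_lab <- sec$distortion$n_markers %||% sec$distortion$n_chromosomes
      cat(sprintf(paste0("  distortion: %d tests, %.1f%% at p < 0.05, %d ",
                         "beyond Bonferroni (p < %.5f)\n"),
                  n_lab, 100 * sec$distortion$frac_p05,
                  sec$distortion$n_bonferroni, sec$distortion$bonferroni))
    }
    if (!is.null(sec$allele_ratio)) {
      cat(sprintf("  allele ratio: %d P1 vs %d P2, chi2 = %.2f, p = %.3g (%s)\n",
                  sec$allele_ratio$n_p1_alleles, sec$allele_ratio$n_p2_alleles,
                  sec$allele_ratio$chi2, sec$allele_ratio$p,
                  sec$allele_ratio$direction))
    }
    if (!is.null(sec$epistasis)) {
      cat(sprintf(paste0("  epistasis: %d pairs, %d at p < 0.05, Bonferroni ",
                         "denominator %d\n"),
                  sec$epistasis$n_pairs, sec$epistasis$n_p05,
                  sec$epistasis$bonferroni_denominator))
    }
    if (!is.null(sec$ld)) {
      cat(sprintf("  NR-BC LD: %d chromosome pairs, %d at p < 0.05, %d untestable\n",
                  sec$ld$n_pairs, sec$ld$n_p05, sec$ld$n_untestable))
    }
  }
  if (length(x$files)) cat("files:", length(x$files), "result tables written\n")
  invisible(x)
}
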