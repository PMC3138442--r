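test_that("female meiosis transmits intact haplotypes with equal odds", {
  hap <- rbind(rep(0L, 6), rep(1L, 6))
  set.seed(1)
  draws <- replicate(10000, meiosis_female(hap)[1])
  # never a recombinant: every gamete all-0 or all-1
  gam <- replicate(200, meiosis_female(hap))
  expect_true(all(apply(gam, 2, function(g) all(g == g[1]))))
  expect_lt(abs(mean(draws) - 0.5), 0.02)
  # homozygous chromosome: both choices identical
  expect_equal(meiosis_female(rbind(c(0, 1, 0), c(0, 1, 0))), c(0, 1, 0))
})

test_that("male meiosis is a Markov crossover walk with the given rates", {
  hap <- rbind(rep(0L, 4), rep(1L, 4))
  set.seed(2)
  # r = 0: intact haplotypes only
  gam0 <- replicate(100, meiosis_male(hap, rep(0, 3)))
  expect_true(all(apply(gam0, 2, function(g) all(g == g[1]))))
  # r = 0.5: adjacent states independent fair coins
  gam5 <- replicate(20000, meiosis_male(hap, rep(0.5, 3)))
  expect_lt(abs(mean(gam5[1, ] != gam5[2, ]) - 0.5), 0.01)
  expect_lt(abs(cor(gam5[1, ], gam5[2, ])), 0.02)
  # intermediate r recovered from the recombinant fraction
  r <- c(0.2, 0.05, 0.4)
  gam <- replicate(20000, meiosis_male(hap, r))
  for (j in 1:3) {
    expect_lt(abs(mean(gam[j, ] != gam[j + 1, ]) - r[j]), 0.01)
  }
  expect_error(meiosis_male(hap, c(0.2, 0.2, 0.7)), "0, 0.5")
})

test_that("no-selection F2 single-locus frequencies are Mendelian 2:1:1", {
  cfg <- cross_config(n_nauplii = 10000, seed = 21,
                      error_model = error_model(0, 0))
  gm <- simulate_f2_cohorts(cfg, "nauplii")$nauplii
  for (mk in c("L01.1", "L05.3", "L12.1")) {
    cnt <- genotype_counts(gm, mk, "f2_nauplii")
    expect_lt(abs(cnt[["n_het"]] / 10000 - 0.5), 0.02)
    expect_lt(abs(cnt[["n_hom_p1"]] / 10000 - 0.25), 0.02)
    expect_lt(abs(cnt[["n_hom_p2"]] / 10000 - 0.25), 0.02)
  }
  expect_true(all(gm$individuals$mito == "P1"))
})

test_that("markers on different chromosomes are independent without selection", {
  cfg <- cross_config(n_nauplii = 4000, seed = 22,
                      error_model = error_model(0, 0))
  gm <- simulate_f2_cohorts(cfg, "nauplii")$nauplii
  a <- match(gm$calls[, "L03.1"], c("AA", "AB", "BB"))
  b <- match(gm$calls[, "L08.2"], c("AA", "AB", "BB"))
  expect_gt(suppressWarnings(chisq.test(table(a, b))$p.value), 1e-4)
})

test_that("zero-viability genotypes never survive selection", {
  lay <- default_genome_layout()
  lethal <- regime_preset("chr10_sd_deficit", lay)
  lethal[[1]]$single_locus[["L10.1"]] <- c(0, 1, 1)
  cfg <- cross_config(layout = lay, regimes = lethal, n_adult_males = 400,
                      seed = 23, error_model = error_model(0, 0))
  gm <- simulate_f2_cohorts(cfg, "adult_males")$adult_males
  expect_equal(sum(gm$calls[, "L10.1"] == "AA"), 0)
  # nauplii snapshot precedes hatching-to-adult selection
  gm_n <- simulate_f2_cohorts(cfg, "nauplii")$nauplii
  expect_gt(sum(gm_n$calls[, "L10.1"] == "AA"), 0)
})

test_that("epistatic viability tables act on joint genotypes", {
  pair <- selection_regime(
    epistatic_pairs = list(list(markers = c("L03.1", "L05.1"),
                                table = matrix(c(0, rep(1, 8)), 3, 3))),
    stage = "hatching_to_adult")
  cfg <- cross_config(regimes = list(pair), n_adult_males = 500, seed = 24,
                      error_model = error_model(0, 0))
  gm <- simulate_f2_cohorts(cfg, "adult_males")$adult_males
  expect_equal(sum(gm$calls[, "L03.1"] == "AA" & gm$calls[, "L05.1"] == "AA"), 0)
})

test_that("simulation is deterministic in the seed", {
  cfg <- cross_config(seed = 77, n_nauplii = 50, n_adult_males = 40,
                      n_nrbc_males = 20)
  a <- simulate_f2_cohorts(cfg)
  b <- simulate_f2_cohorts(cfg)
  expect_identical(a$nauplii$calls, b$nauplii$calls)
  expect_identical(a$adult_males$calls, b$adult_males$calls)
  expect_identical(simulate_nrbc(cfg)$calls, simulate_nrbc(cfg)$calls)
  cfg2 <- cross_config(seed = 78, n_nauplii = 50, n_adult_males = 40)
  expect_false(identical(a$nauplii$calls,
                         simulate_f2_cohorts(cfg2)$nauplii$calls))
})

test_that("NR-BC chromosomes are intact and uniformly HET or HOM_P2", {
  cfg <- cross_config(seed = 31, n_nrbc_males = 200,
                      error_model = error_model(0, 0))
  gm <- simulate_nrbc(cfg)
  expect_true(all(gm$calls %in% c("AB", "BB")))
  lay <- cfg$layout
  for (cc in unique(lay$chromosome)) {
    sub <- gm$calls[, lay$name[lay$chromosome == cc], drop = FALSE]
    expect_true(all(apply(sub, 1, function(x) length(unique(x)) == 1L)))
  }
})

test_that("NR-BC per-chromosome heterozygote fraction is one half at large n", {
  cfg <- cross_config(seed = 32, n_nrbc_males = 10000,
                      error_model = error_model(0, 0))
  gm <- simulate_nrbc(cfg)
  lay <- cfg$layout
  for (cc in c("chr01", "chr07", "chr12")) {
    first <- lay$name[lay$chromosome == cc][1]
    expect_lt(abs(mean(gm$calls[, first] == "AB") - 0.5), 0.02)
  }
})

test_that("genotyping artifacts behave as specified", {
  gm <- tiny_gm(matrix("AB", 100, 100))
  # (0, 0) is the identity
  expect_identical(apply_genotyping_artifacts(gm, error_model(0, 0))$calls,
                   gm$calls)
  # undercall rate 1 leaves no HET
  out <- apply_genotyping_artifacts(gm, error_model(1, 0), seed = 1)
  expect_equal(sum(out$calls == "AB"), 0)
  expect_gt(sum(out$calls == "AA"), 0)
  expect_gt(sum(out$calls == "BB"), 0)
  # rate 0.1 rewrites close to 10% of HET calls
  out <- apply_genotyping_artifacts(gm, error_model(0.1, 0), seed = 2)
  expect_lt(abs(mean(out$calls != "AB") - 0.1), 0.01)
  # missingness applied after undercalling
  out <- apply_genotyping_artifacts(gm, error_model(0, 0.25), seed = 3)
  expect_lt(abs(mean(is.na(out$calls)) - 0.25), 0.02)
  expect_error(error_model(-0.1, 0), "\\[0, 1\\]")
  expect_error(error_model(0, 1.5), "\\[0, 1\\]")
})

test_that("configs validate their regimes and sizes", {
  expect_error(cross_config(regimes = selection_regime(
    single_locus = list(NOPE = c(1, 1, 1)))), "unknown marker")
  expect_error(cross_config(n_nauplii = 0), "positive")
  expect_error(selection_regime(single_locus = list(L01.1 = c(0, 0, 0))),
               "zero")
  expect_error(selection_regime(single_locus = list(L01.1 = c(1, 2, 1))),
               "\\[0, 1\\]")
  # defaults reproduce the study cohort sizes
  cfg <- cross_config()
  expect_equal(cfg$n_nauplii, 190L)
  expect_equal(cfg$n_adult_males, 205L)
  expect_equal(cfg$n_nrbc_males, 39L)
  expect_equal(nrow(cfg$layout), 53L)
  expect_equal(length(unique(cfg$layout$chromosome)), 12L)
  expect_equal(sum(cfg$layout$marker_class == "microsatellite"), 8L)
})

test_that("cross config YAML round trip preserves the configuration", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 42",
    "n_nauplii: 60",
    "n_adult_males: 50",
    "n_nrbc_males: 15",
    "error_model: {het_undercall_rate: 0.0, missing_rate: 0.05}",
    "layout: default",
    "regimes:",
    "  - preset: chr10_sd_deficit",
    "  - stage: hatching_to_adult",
    "    single_locus:",
    "      L01.1: [1.0, 1.0, 0.5]"), f)
  cfg <- read_cross_config(f)
  expect_s3_class(cfg, "cross_config")
  expect_equal(cfg$seed, 42L)
  expect_equal(cfg$n_nauplii, 60L)
  expect_length(cfg$regimes, 2L)
  expect_equal(cfg$regimes[[2]]$single_locus$L01.1, c(1, 1, 0.5))
  expect_equal(cfg$error_model$missing_rate, 0.05)
  expect_match(config_digest(cfg), "^[0-9a-f]{32}$")
  expect_identical(config_digest(cfg), config_digest(read_cross_config(f)))
})
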