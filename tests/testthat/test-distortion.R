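test_that("F2 distortion test reproduces chi-square arithmetic", {
  # exact Mendelian ratios
  t0 <- f2_distortion_test(c(n_het = 100, n_hom_p1 = 50, n_hom_p2 = 50))
  expect_equal(t0$chi2, 0)
  expect_equal(t0$p, 1)
  expect_length(t0$direction, 0)
  expect_equal(t0$tier, "ns")

  # (90, 70, 40) at n = 200: chi2 = 11, p = exp(-5.5) at 2 df
  t1 <- f2_distortion_test(c(n_het = 90, n_hom_p1 = 70, n_hom_p2 = 40))
  expect_equal(t1$chi2, 11)
  expect_equal(t1$p, exp(-5.5), tolerance = 1e-9)
  expect_setequal(t1$direction,
                  c("het_deficit", "hom_p1_excess", "hom_p2_deficit"))

  # extreme heterozygote deficit beyond the Bonferroni tier
  t2 <- f2_distortion_test(c(n_het = 0, n_hom_p1 = 100, n_hom_p2 = 100),
                           n_tests = 53)
  expect_lt(t2$p, 0.05 / 53)
  expect_equal(t2$tier, "bonferroni")
  expect_true("het_deficit" %in% t2$direction)

  expect_error(f2_distortion_test(c(n_het = 0, n_hom_p1 = 0, n_hom_p2 = 0)),
               "no non-missing")
})

test_that("distortion test is invariant under swapping the homozygote classes", {
  a <- f2_distortion_test(c(n_het = 80, n_hom_p1 = 70, n_hom_p2 = 30))
  b <- f2_distortion_test(c(n_het = 80, n_hom_p1 = 30, n_hom_p2 = 70))
  expect_equal(a$chi2, b$chi2)
  expect_equal(a$p, b$p)
  mirror <- function(fl) {
    fl <- sub("hom_p1", "HOLD", fl)
    fl <- sub("hom_p2", "hom_p1", fl)
    sub("HOLD", "hom_p2", fl)
  }
  expect_setequal(mirror(a$direction), b$direction)
})

test_that("scan_f2 applies per-marker sample sizes and the Bonferroni tier", {
  cfg <- cross_config(seed = 501)
  gm <- simulate_f2_cohorts(cfg, "nauplii")$nauplii
  sc <- scan_f2(gm, "f2_nauplii")
  expect_equal(nrow(sc), 53L)
  expect_equal(attr(sc, "bonferroni"), 0.05 / 53)
  expect_equal(round(attr(sc, "bonferroni"), 5), 0.00094)
  # per-marker totals conserved (pairwise-complete n per marker)
  expect_true(all(sc$n_het + sc$n_hom_p1 + sc$n_hom_p2 + sc$n_missing == 190))
  expect_equal(attr(sc, "frac_p05"), mean(sc$p < 0.05))
  expect_true(all(sc$tier[sc$p >= 0.05] == "ns"))
})

test_that("chr10 homozygote-deficit regime is detected beyond Bonferroni", {
  cfg <- cross_config(regimes = regime_preset("chr10_sd_deficit"), seed = 502)
  gm <- simulate_f2_cohorts(cfg, "adult_males")$adult_males
  sc <- scan_f2(gm, "f2_adult_male")
  chr10 <- cfg$layout$name[cfg$layout$chromosome == "chr10"]
  hit <- sc[sc$marker %in% chr10, ]
  expect_true(all(hit$tier == "bonferroni"))
  expect_true(all(grepl("hom_p1_deficit", hit$direction)))
})

test_that("allele ratio test pools two alleles per call and is conserved", {
  gm <- tiny_gm(matrix(c("AA", "AB", "BB", "AB"), 2, 2))
  ar <- allele_ratio_test(gm, "f2_nauplii")
  expect_equal(ar$n_p1_alleles + ar$n_p2_alleles,
               2 * sum(!is.na(gm$calls)))
  expect_equal(ar$n_p1_alleles, 4)  # AA + two hets
  expect_equal(ar$n_p2_alleles, 4)
  expect_equal(ar$chi2, 0)
  expect_equal(ar$direction, "balanced")

  # 420 vs 380 -> chi2 = 2, p ~ 0.157
  calls <- matrix(c(rep("AA", 20), rep("AB", 380)), ncol = 1)
  ar <- allele_ratio_test(tiny_gm(calls), "f2_nauplii")
  expect_equal(c(ar$n_p1_alleles, ar$n_p2_alleles), c(420, 380))
  expect_equal(ar$chi2, 2)
  expect_equal(round(ar$p, 3), 0.157)

  # one-sided extreme
  ar <- allele_ratio_test(tiny_gm(matrix(rep("BB", 50), ncol = 1)),
                          "f2_nauplii")
  expect_equal(ar$chi2, 100)
  expect_lt(ar$p, 0.001)
  expect_equal(ar$direction, "p2_excess")
})

test_that("NR-BC chromosome test matches 1:1 chi-square arithmetic", {
  expect_equal(nrbc_chromosome_test(20, 20)$chi2, 0)
  t <- nrbc_chromosome_test(10, 29, n_tests = 12)
  expect_equal(t$chi2, 2 * 9.5^2 / 19.5, tolerance = 1e-12)
  expect_lt(t$p, 0.05 / 12)
  expect_equal(t$tier, "bonferroni")
  expect_setequal(t$direction, c("het_deficit", "hom_p2_excess"))
  expect_error(nrbc_chromosome_test(0, 0), "no chromosome states")
})

test_that("NR-BC chromosome states use majority calls with NA on ties", {
  calls <- rbind(c("AB", "AB", "BB", "BB", "BB"),
                 c("AB", "BB", NA,   "AB", "BB"),
                 c(NA,   NA,   NA,   "AB", "BB"))
  colnames(calls) <- c("x1", "x2", "x3", "y1", "y2")
  gm <- tiny_gm(calls, cohort = "nrbc_adult_male", sex = "male")
  chroms <- c(x1 = "cX", x2 = "cX", x3 = "cX", y1 = "cY", y2 = "cY")
  st <- nrbc_chromosome_states(gm, chroms)
  expect_equal(unname(st[1, ]), c("AB", "BB"))  # 2 AB vs 1 BB; 2 BB
  expect_equal(unname(st[2, "cX"]), NA_character_)  # 1 vs 1 tie
  expect_equal(unname(st[3, "cX"]), NA_character_)  # all missing
  sc <- scan_nrbc(gm, chroms)
  expect_equal(nrow(sc), 2L)
  expect_equal(attr(sc, "bonferroni"), 0.025)
})

test_that("the 12-chromosome NR-BC scan uses the 0.05/12 threshold", {
  cfg <- cross_config(seed = 503)
  gm <- simulate_nrbc(cfg)
  sc <- scan_nrbc(gm)
  expect_equal(nrow(sc), 12L)
  expect_equal(attr(sc, "bonferroni"), 0.05 / 12)
  expect_equal(round(attr(sc, "bonferroni"), 3), 0.004)
  expect_true(all(sc$n_het + sc$n_hom_p2 + sc$n_untyped == 39))
})

test_that("type-I error of the F2 scan is near nominal under the null", {
  # 2,000 independent replicate markers (single-marker chromosomes)
  lay <- unlinked_layout(50)
  hits <- 0L
  n_tests <- 0L
  for (rep in 1:40) {
    cfg <- cross_config(layout = lay, n_nauplii = 190, seed = 600 + rep,
                        error_model = error_model(0, 0.02))
    gm <- simulate_f2_cohorts(cfg, "nauplii")$nauplii
    sc <- scan_f2(gm, "f2_nauplii")
    hits <- hits + sum(sc$p < 0.05)
    n_tests <- n_tests + nrow(sc)
  }
  expect_equal(n_tests, 2000L)
  half_width <- 2.576 * sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(hits / n_tests - 0.05), half_width)
})
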