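test_that("Kosambi transform matches its closed form and inverts", {
  expect_equal(kosambi_cm(0), 0)
  expect_equal(kosambi_cm(0.1), 25 * log(1.2 / 0.8), tolerance = 1e-12)
  expect_equal(round(kosambi_cm(0.1), 2), 10.14)
  expect_equal(kosambi_r(0), 0)
  r <- seq(0.01, 0.49, by = 0.02)
  expect_equal(kosambi_r(kosambi_cm(r)), r, tolerance = 1e-10)
  expect_error(kosambi_cm(0.5), "0, 0.5")
  expect_error(kosambi_cm(-0.01), "0, 0.5")
  expect_error(kosambi_r(-1), "non-negative")
})

test_that("two-point EM handles the canonical degenerate tables", {
  # fully parental classes: complete linkage
  tab <- diag(c(25, 50, 25))
  tp <- estimate_two_point(tab)
  expect_lt(tp$r_hat, 1e-6)
  expect_lt(tp$p_linkage, 1e-10)
  expect_gt(tp$lod, 3)

  # independence: counts proportional to the product of 2:1:1 marginals
  tab <- outer(c(0.25, 0.5, 0.25), c(0.25, 0.5, 0.25)) * 400
  tp <- estimate_two_point(tab)
  expect_equal(tp$r_hat, 0.5, tolerance = 1e-6)
  expect_equal(tp$lod, 0, tolerance = 1e-9)
  expect_equal(tp$p_linkage, 1)

  expect_error(estimate_two_point(matrix(0, 3, 3)), "empty")
  expect_error(estimate_two_point(matrix(-1, 3, 3)), "negative")
  # impossible classes under achiasmy are dropped with a warning
  tab <- diag(c(10, 20, 10)); tab[1, 3] <- 2
  expect_warning(estimate_two_point(tab, "female_achiasmatic"), "impossible")
})

test_that("EM estimates agree with the grid-search likelihood oracle", {
  set.seed(101)
  for (model in c("symmetric", "female_achiasmatic")) {
    for (i in 1:60) {
      r <- runif(1, 0.01, 0.49)
      tab <- draw_pair_table(500, r, model)
      em <- estimate_two_point(tab, model)$r_hat
      expect_lt(abs(em - grid_two_point_r(tab, model)), 1e-3)
    }
  }
})

test_that("lod and p_linkage are coherent", {
  set.seed(102)
  tab <- draw_pair_table(300, 0.15)
  tp <- estimate_two_point(tab)
  expect_gte(tp$lod, 0)
  expect_true(tp$p_linkage > 0 && tp$p_linkage <= 1)
  # p decreases as linkage strengthens at fixed n
  p_tight <- estimate_two_point(draw_pair_table(300, 0.05))$p_linkage
  p_loose <- estimate_two_point(draw_pair_table(300, 0.45))$p_linkage
  expect_lt(p_tight, p_loose)
})

test_that("grouping is the single-linkage closure of the significance relation", {
  pw <- data.frame(marker_a = c("a", "b", "c"), marker_b = c("b", "c", "d"),
                   p_linkage = c(1e-5, 1e-4, 0.5), r_hat = c(0.1, 0.2, 0.45))
  g <- group_markers(pw, c("a", "b", "c", "d"))
  expect_equal(unname(g["a"]), unname(g["c"]))  # transitive through b
  expect_false(unname(g["a"]) == unname(g["d"]))
  # no pair significant: all singletons
  g <- group_markers(pw, c("a", "b", "c", "d"), alpha = 1e-10)
  expect_equal(length(unique(g)), 4L)
  # alpha = 1: one group
  g <- group_markers(pw, c("a", "b", "c", "d"), alpha = 1)
  expect_equal(length(unique(g)), 1L)
  # max_r criterion can veto a significant pair
  g <- group_markers(pw, c("a", "b", "c", "d"), alpha = 1, max_r = 0.35)
  expect_false(unname(g["c"]) == unname(g["d"]))
})

test_that("SARF ordering recovers simulated marker order", {
  # positions 0, 10, 20 cM: recovered order matches positional order
  markers <- c("mA", "mB", "mC")
  r <- kosambi_r(c(10, 20, 10))
  rmat <- matrix(0.5, 3, 3, dimnames = list(markers, markers))
  diag(rmat) <- 0
  rmat["mA", "mB"] <- rmat["mB", "mA"] <- r[1]
  rmat["mA", "mC"] <- rmat["mC", "mA"] <- r[2]
  rmat["mB", "mC"] <- rmat["mC", "mB"] <- r[3]
  expect_equal(order_group(markers, rmat), c("mA", "mB", "mC"))
  expect_equal(order_group(c("mC", "mA", "mB"), rmat), c("mA", "mB", "mC"))
  expect_error(order_group("mA", rmat), "at least two")

  # m = 2 canonical order
  expect_equal(order_group(c("mB", "mA"), rmat), c("mA", "mB"))

  # returned order beats random permutations, including for large greedy groups
  set.seed(7)
  m <- 11
  nm <- sprintf("g%02d", 1:m)
  pos <- sort(runif(m, 0, 60))
  big <- outer(pos, pos, function(a, b) kosambi_r(abs(a - b)))
  dimnames(big) <- list(nm, nm)
  ord <- order_group(sample(nm), big)
  sarf <- function(o) sum(big[cbind(o[-length(o)], o[-1])])
  best <- sarf(ord)
  for (i in 1:100) expect_lte(best, sarf(sample(nm)) + 1e-12)
  expect_equal(ord, nm[order(pos)][if (nm[order(pos)][1] > nm[order(pos)][m]) m:1 else 1:m])
})

test_that("build_map recovers the simulated genome structure", {
  cfg <- cross_config(seed = 301, error_model = error_model(0.02, 0.02))
  gm <- simulate_f2_cohorts(cfg, "adult_males")$adult_males
  map <- build_map(gm, "f2_adult_male")
  expect_equal(nrow(map$lengths), 12L)
  # each inferred group contains exactly the markers of one chromosome
  truth <- split(cfg$layout$name, cfg$layout$chromosome)
  inferred <- split(names(map$assignment), map$assignment)
  match_one <- vapply(inferred, function(mem) {
    any(vapply(truth, function(tr) setequal(tr, mem), TRUE))
  }, TRUE)
  expect_true(all(match_one))
  # within-group order matches the layout (up to orientation)
  for (gid in map$lengths$group[map$lengths$m >= 3]) {
    ord <- map$groups$marker[map$groups$group == gid]
    true_ord <- cfg$layout$name[cfg$layout$chromosome ==
                                  cfg$layout$chromosome[cfg$layout$name == ord[1]]]
    expect_true(identical(ord, true_ord) || identical(ord, rev(true_ord)))
  }
  # deterministic: same input, same map
  map2 <- build_map(gm, "f2_adult_male")
  expect_identical(map$groups, map2$groups)
})

test_that("unlinked markers map to singleton groups", {
  set.seed(44)
  calls <- matrix(sample(c("AA", "AB", "BB"), 400, TRUE, c(0.25, 0.5, 0.25)),
                  200, 2, dimnames = list(NULL, c("u1", "u2")))
  gm <- tiny_gm(calls)
  map <- build_map(gm, "f2_nauplii")
  expect_equal(nrow(map$lengths), 2L)
  expect_true(all(map$lengths$m == 1L))
  expect_error(map_summary(map), "singleton")
})

test_that("map summary reproduces the published formula arithmetic", {
  # one group, length 20 cM, 5 markers: corrected (20+2)*6/4 = 33
  map <- map_from_positions(list(g1 = c(0, 5, 10, 15, 20)))
  s <- map_summary(map)
  expect_equal(s$corrected_length, 33)
  expect_equal(s$total_length, 20)
  expect_equal(s$d, 5)

  # published map dimensions: 266.7 cM over 41 intervals -> d = 6.5
  map <- map_from_positions(list(g = seq(0, 266.7, length.out = 42)))
  s <- map_summary(map)
  expect_equal(round(s$d, 1), 6.5)

  # published coverage: d = 6.5, n = 52, L = 484.8 -> 75.2%
  expect_equal(round(100 * genome_coverage(6.5, 52, 484.8), 1), 75.2)

  # coverage is monotone and bounded
  expect_gt(genome_coverage(7, 52, 484.8), genome_coverage(6.5, 52, 484.8))
  expect_gt(genome_coverage(6.5, 53, 484.8), genome_coverage(6.5, 52, 484.8))
  expect_lt(genome_coverage(6.5, 52, 500), genome_coverage(6.5, 52, 484.8))
  expect_true(genome_coverage(100, 1000, 10) <= 1)
})

test_that("achiasmy attenuates the symmetric-model estimate as predicted", {
  lay <- default_genome_layout()
  cfg <- cross_config(layout = lay, n_nauplii = 10000, seed = 303,
                      error_model = error_model(0, 0))
  gm <- simulate_f2_cohorts(cfg, "nauplii")$nauplii
  g <- match(gm$calls[, c("L01.1", "L01.2")], c("AA", "AB", "BB"))
  g <- matrix(g, ncol = 2)
  tab <- table(factor(g[, 1], 1:3), factor(g[, 2], 1:3))
  r_m <- kosambi_r(diff(lay$position_cM[1:2]))
  sym <- estimate_two_point(unclass(tab), "symmetric")$r_hat
  ach <- estimate_two_point(unclass(tab), "female_achiasmatic")$r_hat
  expect_lt(abs(sym - (1 - sqrt(1 - r_m))), 0.01)
  expect_lt(abs(ach - r_m), 0.01)
})
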