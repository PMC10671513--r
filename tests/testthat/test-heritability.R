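test_that("one-way ANOVA matches hand-computed sums of squares", {
  a <- oneWayAnova(list(g1 = c(1, 1), g2 = c(2, 2)))
  expect_equal(a$ssBetween, 1)
  expect_equal(a$ssWithin, 0)
  expect_equal(a$msBetween, 1)
  expect_equal(a$msWithin, 0)
  expect_equal(a$dfBetween, 1L)
  expect_equal(a$dfWithin, 2L)

  # duplicating one group gives no between-group signal
  b <- oneWayAnova(list(g1 = c(3, 5, 7), g2 = c(3, 5, 7)))
  expect_equal(b$ssBetween, 0)

  expect_error(oneWayAnova(list(g1 = 1:3)), "at least 2 groups")
  expect_error(oneWayAnova(list(g1 = 1, g2 = 2)), "N > k")
})

test_that("ANOVA equals the brute-force oracle and stats::anova on random data", {
  set.seed(101)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    groups <- lapply(seq_len(k), function(j)
      rnorm(sample(2:8, 1), mean = rnorm(1, 0, 2)))
    names(groups) <- paste0("g", seq_len(k))
    a <- oneWayAnova(groups)
    o <- bruteForceAnova(groups)
    expect_equal(a$ssBetween, o$ssBetween, tolerance = 1e-9)
    expect_equal(a$ssWithin, o$ssWithin, tolerance = 1e-9)
    # SS conservation about the grand mean
    all <- unlist(groups)
    expect_equal(a$ssBetween + a$ssWithin, sum((all - mean(all))^2),
                 tolerance = 1e-9)
  }
  # independent cross-check against the stock linear-model ANOVA
  groups <- list(a = rnorm(5, 1), b = rnorm(7, 2), c = rnorm(4))
  a <- oneWayAnova(groups)
  df <- data.frame(y = unlist(groups),
                   g = rep(names(groups), lengths(groups)))
  ref <- anova(lm(y ~ g, df))
  expect_equal(a$ssBetween, ref$`Sum Sq`[1], tolerance = 1e-10)
  expect_equal(a$ssWithin, ref$`Sum Sq`[2], tolerance = 1e-10)
})

test_that("effective group size handles balanced and unbalanced designs", {
  expect_equal(effectiveN(c(5, 5, 5)), 5)
  expect_equal(effectiveN(c(3, 5, 7)), (15 - 83 / 15) / 2)
  expect_equal(effectiveN(c(1, 1)), 1)
  expect_error(effectiveN(c(5)), "k >= 2")
})

test_that("variance components reproduce published ANOVA-summary arithmetic", {
  # female wild-type %dBW 16-6 summary row
  vc <- varianceComponents(582.107, 170.343, 8)
  expect_equal(vc$vg, 51.47049, tolerance = 1e-6)
  expect_equal(vc$h2, 0.232044, tolerance = 1e-5)
  # female wild-type %dBW 32-6 summary row
  vc2 <- varianceComponents(5380.415, 464.75, 8)
  expect_equal(vc2$h2, 0.56936, tolerance = 1e-5)
})

test_that("variance-component conventions hold at the boundaries", {
  eqv <- varianceComponents(100, 100, 5)
  expect_equal(eqv$vg, 0)
  expect_equal(eqv$h2, 0)
  # MS_between < MS_within truncates Vg at 0
  expect_equal(varianceComponents(50, 100, 5)$vg, 0)
  # no within-line variance: heritability 1
  expect_equal(varianceComponents(10, 0, 5)$h2, 1)
  expect_equal(varianceComponents(0, 0, 5)$h2, 0)
  expect_error(varianceComponents(1, 1, 0), "nEff")
})

test_that("H2 is monotone in MS_between and invariant to trait rescaling", {
  h2s <- vapply(seq(100, 1000, by = 100), function(msb)
    varianceComponents(msb, 170, 8)$h2, numeric(1))
  expect_true(all(diff(h2s) >= 0))

  set.seed(5)
  groups <- lapply(1:6, function(i) rnorm(8, mean = i))
  a1 <- oneWayAnova(groups)
  c2 <- 3.2^2
  a2 <- oneWayAnova(lapply(groups, `*`, 3.2))
  n0 <- effectiveN(lengths(groups))
  v1 <- varianceComponents(a1$msBetween, a1$msWithin, n0)
  v2 <- varianceComponents(a2$msBetween, a2$msWithin, n0)
  expect_equal(v2$vg, c2 * v1$vg, tolerance = 1e-9)
  expect_equal(v2$ve, c2 * v1$ve, tolerance = 1e-9)
  expect_equal(v2$h2, v1$h2, tolerance = 1e-12)
})

test_that("trait-mode generation recovers the generative heritability", {
  # closed form: H2 = Vg / (Vg + Ve) = 0.5; modest k/n here, the full-size
  # recovery check lives in the acceptance suite
  h2 <- vapply(1:10, function(s) {
    g <- simulateTraitData(TraitSimParam(kGroups = 50, groupSizes = 20,
                                         Vg = 1, Ve = 1, seed = s))
    a <- oneWayAnova(g)
    varianceComponents(a$msBetween, a$msWithin,
                       effectiveN(lengths(g)))$h2
  }, numeric(1))
  expect_equal(mean(h2), 0.5, tolerance = 0.05)
})

test_that("heritability table has the stratum x trait shape contract", {
  co <- simulateCohort(TrajectorySimParam(micePerCell = 3L, seed = 31L))
  tab <- heritabilityTable(co)
  expect_equal(nrow(tab), 4 * 4)
  expect_true(all(tab$estimable))
  expect_true(all(tab$h2 >= 0 & tab$h2 <= 1))
  expect_true(all(tab$vg >= 0))
  expect_equal(tab$h2, tab$vg / (tab$vg + tab$ve), tolerance = 1e-12)

  # identical values everywhere -> H2 = 0
  flat <- makeCohort(matrix(20, 8, 14), line = rep(c("A", "B"), 4),
                     sex = rep("F", 8), genotype = rep(0L, 8))
  tf <- heritabilityTable(flat, toWeeks = 48)
  row <- tf[tf$sex == "F" & tf$genotype == 0L, ]
  expect_equal(row$h2, 0)

  # a stratum with < 2 usable lines is flagged not estimable
  oneLine <- makeCohort(matrix(rnorm(5 * 14, 25, 1), 5), sex = rep("F", 5),
                        genotype = rep(0L, 5))
  t1 <- heritabilityTable(oneLine, toWeeks = 48)
  expect_false(t1$estimable[t1$sex == "F" & t1$genotype == 0L])
  expect_true(is.na(t1$h2[t1$sex == "F" & t1$genotype == 0L]))
})
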