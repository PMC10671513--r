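test_that("counts conserve totals and margins on the study design table", {
  co <- designCohort()
  s <- summarizeCounts(co)
  expect_equal(s$total, 391L)
  expect_equal(sum(s$cells$n), 391L)
  expect_equal(s$byGenotype$n[s$byGenotype$genotype == 1], 203L)
  expect_equal(s$byGenotype$percent[s$byGenotype$genotype == 1], 51.9)
  expect_equal(s$bySex$n[s$bySex$sex == "F"], 202L)
  expect_equal(s$bySex$percent[s$bySex$sex == "F"], 51.7)
  expect_equal(sum(s$byGenotype$n), s$total)
  expect_equal(sum(s$bySex$n), s$total)
})

test_that("degenerate cohorts summarize sensibly", {
  co <- designCohort()
  empty <- co[, 0]
  s0 <- summarizeCounts(empty)
  expect_equal(s0$total, 0L)
  expect_equal(sum(s0$byGenotype$n), 0L)

  one <- makeCohort(matrix(25, 1, 14), sex = "F", genotype = 0L)
  s1 <- summarizeCounts(one)
  expect_equal(s1$byGenotype$percent, c(100, 0))
  expect_equal(s1$bySex$percent, c(100, 0))
})

test_that("percent gain matches hand arithmetic and flags incomplete records", {
  w <- matrix(20, nrow = 3, ncol = 14)
  w[1, 14] <- 20; w[2, 14] <- 40; w[3, 14] <- 43
  co <- makeCohort(w)
  pg <- percentGain(co, 48)
  expect_equal(pg$value, c(0, 100, 115))

  w[2, 14] <- NA
  co2 <- makeCohort(w)
  expect_warning(pg2 <- percentGain(co2, 48), "incomplete.*m02")
  expect_true(is.na(pg2$value[2]))
  expect_equal(pg2$value[c(1, 3)], c(0, 115))
  expect_error(percentGain(co, 47), "not in the schedule")
})

test_that("percent gain is invariant under rescaling all weights", {
  set.seed(1)
  w <- matrix(runif(5 * 14, 18, 45), nrow = 5)
  v1 <- percentGain(makeCohort(w), 32)$value
  v2 <- percentGain(makeCohort(3.7 * w), 32)$value
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("group trajectory returns means and SEMs per arm", {
  w <- rbind(rep(20, 14), rep(20, 14), rep(22, 14), rep(20, 14))
  co <- makeCohort(w, genotype = c(0L, 0L, 0L, 1L), sex = rep("F", 4))
  tr <- groupTrajectory(co, "IL72", stratum = "F")
  wt <- tr[tr$genotype == 0L, ]
  expect_equal(unique(wt$n), 3L)
  # weights {20, 20, 22}: mean 62/3, SEM = sd/sqrt(3)
  expect_equal(unique(wt$mean), 62 / 3)
  expect_equal(unique(wt$sem), sd(c(20, 20, 22)) / sqrt(3))
  # two identical mice -> SEM 0 at every week
  expect_equal(unique(tr[tr$genotype == 1L, ]$n), 1L)

  two <- makeCohort(rbind(rep(20, 14), rep(22, 14)),
                    genotype = c(0L, 0L), sex = c("F", "F"))
  expect_warning(tr2 <- groupTrajectory(two, "IL72", stratum = "F"),
                 "no data")
  expect_equal(unique(tr2[tr2$genotype == 0L, ]$mean), 21)
  expect_equal(unique(tr2[tr2$genotype == 0L, ]$sem), 1)

  ident <- makeCohort(rbind(rep(20, 14), rep(20, 14)),
                      genotype = c(1L, 1L), sex = c("M", "M"))
  tr3 <- suppressWarnings(groupTrajectory(ident, "IL72", stratum = "M"))
  expect_equal(unique(tr3[tr3$genotype == 1L, ]$sem), 0)
})

test_that("overall stratum equals pooling female and male records", {
  co <- simulateCohort(TrajectorySimParam(lineNames = "IL72",
                                          micePerCell = 4L, seed = 8L))
  ov <- groupTrajectory(co, "IL72", "overall")
  f <- groupTrajectory(co, "IL72", "F")
  m <- groupTrajectory(co, "IL72", "M")
  expect_equal(ov$n, f$n + m$n)
  expect_equal(ov$mean * ov$n, f$mean * f$n + m$mean * m$n,
               tolerance = 1e-12)
})

test_that("Welch timepoint test matches stats::t.test and stars thresholds", {
  g0 <- c(10.1, 10.2, 10.3, 10.4); g1 <- c(20.1, 20.2, 20.3, 20.4)
  co <- makeCohort(matrix(rep(c(g0, g1), 14), ncol = 14),
                   genotype = rep(c(0L, 1L), each = 4), sex = rep("F", 8))
  res <- timepointTest(co, "IL72", 6, "F")
  ref <- t.test(g0, g1)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
  expect_lt(res$p, 0.01)
  expect_equal(res$star, "**")

  # symmetric inputs give p = 1, no star
  sym <- makeCohort(matrix(rep(c(1, 2, 3, 1, 2, 3), 14), ncol = 14),
                    genotype = rep(c(0L, 1L), each = 3), sex = rep("F", 6))
  res2 <- timepointTest(sym, "IL72", 6, "F")
  expect_equal(res2$p, 1)
  expect_equal(res2$star, "")

  # identical constant groups: degenerate convention t = 0, p = 1
  ident <- makeCohort(matrix(20, 4, 14), genotype = c(0L, 0L, 1L, 1L),
                      sex = rep("F", 4))
  res3 <- timepointTest(ident, "IL72", 6, "F")
  expect_equal(res3$t, 0)
  expect_equal(res3$p, 1)

  expect_error(timepointTest(ident[, 1:3], "IL72", 6, "F"),
               class = "ccweight_insufficient_data")
})

test_that("Welch test is symmetric and shift-invariant", {
  set.seed(7)
  g0 <- rnorm(6, 20); g1 <- rnorm(8, 23)
  co <- function(a, b) makeCohort(
    matrix(rep(c(a, b), 14), ncol = 14),
    genotype = rep(c(0L, 1L), c(length(a), length(b))),
    sex = rep("F", length(a) + length(b)))
  r1 <- timepointTest(co(g0, g1), "IL72", 6, "F")
  r2 <- timepointTest(co(g1, g0), "IL72", 6, "F")
  expect_equal(r1$p, r2$p)
  expect_equal(r1$t, -r2$t)
  r3 <- timepointTest(co(g0 + 100, g1 + 100), "IL72", 6, "F")
  expect_equal(r1$p, r3$p, tolerance = 1e-12)
})
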