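# Fixture builders shared across test files. All fixtures are generated in
# code; nothing is read from disk except the shipped study-design table.

# minimal cohort from a mice x weeks weight matrix
makeCohort <- function(w, line = "IL72", sex = NULL, genotype = NULL,
                       ids = NULL, schedule = defaultSchedule()) {
  n <- nrow(w)
  BWCohort(t(w),
           line = rep_len(line, n),
           sex = if (is.null(sex)) rep_len(c("F", "M"), n) else sex,
           genotype = if (is.null(genotype)) rep_len(c(0L, 1L), n)
                      else genotype,
           mouseIds = if (is.null(ids)) sprintf("m%02d", seq_len(n)) else ids,
           schedule = schedule)
}

# noiseless additive fixture: w_k = w_6 + 2 * (position of k) with varying
# baselines; exactly linear so chained forecasts are exact
makeAdditiveCohort <- function(n = 24, schedule = defaultSchedule(),
                               step = 2, seed = 42) {
  set.seed(seed)
  base <- seq(16, 26, length.out = n)
  w <- outer(base, (seq_along(schedule) - 1) * step, `+`)
  makeCohort(w, sex = sample(rep_len(c("F", "M"), n)),
             genotype = sample(rep_len(c(0L, 1L), n)), schedule = schedule)
}

# one-line cohort where genotype is determined by week-48 weight with a
# wide margin (linearly separable)
makeSeparableCohort <- function(n = 60, seed = 1) {
  set.seed(seed)
  sched <- defaultSchedule()
  geno <- rep(c(0L, 1L), each = n / 2)
  w <- matrix(NA_real_, nrow = n, ncol = length(sched))
  for (i in seq_len(n)) {
    base <- 20 + rnorm(1, 0, 1)
    curve <- base + 0.5 * (sched - 6) + rnorm(length(sched), 0, 0.5)
    if (geno[i] == 1L) curve <- curve + 15  # wide margin at every week
    w[i, ] <- curve
  }
  makeCohort(w, sex = sample(rep_len(c("F", "M"), n)), genotype = geno)
}

# one-line cohort with no genotype signal at all
makeNullCohort <- function(n = 60, seed = 1) {
  set.seed(seed)
  sched <- defaultSchedule()
  w <- matrix(NA_real_, nrow = n, ncol = length(sched))
  for (i in seq_len(n))
    w[i, ] <- 20 + rnorm(1, 0, 2) + 0.5 * (sched - 6) +
      rnorm(length(sched), 0, 1)
  makeCohort(w, sex = sample(rep_len(c("F", "M"), n)),
             genotype = sample(rep(c(0L, 1L), each = n / 2)))
}

# expand the shipped study-design cell counts into a cohort with dummy
# (constant) weights; weights are irrelevant to composition summaries
designCohort <- function() {
  design <- utils::read.csv(
    system.file("extdata", "cohort_design.csv", package = "ccweight"),
    stringsAsFactors = FALSE)
  n <- sum(design$n)
  line <- rep(design$line, design$n)
  sex <- rep(design$sex, design$n)
  geno <- rep(design$genotype, design$n)
  w <- matrix(25, nrow = length(defaultSchedule()), ncol = n)
  BWCohort(w, line = line, sex = sex, genotype = geno,
           mouseIds = sprintf("m%03d", seq_len(n)))
}

# brute-force one-way ANOVA sums of squares by explicit double loops
bruteForceAnova <- function(groups) {
  all <- unlist(groups, use.names = FALSE)
  gm <- mean(all)
  ssb <- 0; ssw <- 0
  for (g in groups) {
    m <- mean(g)
    for (v in g) ssw <- ssw + (v - m)^2
    ssb <- ssb + length(g) * (m - gm)^2
  }
  k <- length(groups); N <- length(all)
  list(ssBetween = ssb, ssWithin = ssw,
       msBetween = ssb / (k - 1), msWithin = ssw / (N - k))
}

# brute-force pairwise-concordance AUC
bruteForceAuc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
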