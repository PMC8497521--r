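controlPair <- function(seed = 111L, n = 3000L) {
  list(
    carrier = simulateFacsEvents(facsTruth(nEvents = n, freeFraction = 0,
                                           debrisFraction = 0, seed = seed)),
    free = simulateFacsEvents(facsTruth(nEvents = n, freeFraction = 1,
                                        debrisFraction = 0, seed = seed + 1L)))
}

test_that("gates from clean controls classify the controls almost perfectly", {
  ctl <- controlPair()
  gates <- buildGates(ctl$carrier, ctl$free)
  expect_s3_class(gates, "GateSet")
  expect_gte(mean(classifyEvents(ctl$carrier, gates) == "carrier"), 0.99)
  expect_gte(mean(classifyEvents(ctl$free, gates) == "free"), 0.99)
})

test_that("inseparable control populations are rejected", {
  ctl <- controlPair()
  expect_error(buildGates(ctl$carrier, ctl$carrier), "not separable")
})

test_that("loss fractions are gated counts with a Wilson interval", {
  ctl <- controlPair(seed = 115L)
  gates <- buildGates(ctl$carrier, ctl$free)
  ev <- simulateFacsEvents(facsTruth(nEvents = 4000L, freeFraction = 0.1,
                                     debrisFraction = 0, seed = 117L))
  lf <- lossFraction(ev, gates)
  trueFrac <- mean(ev$trueClass == "free")
  expect_lt(abs(lf$fraction - trueFrac), 0.02)
  expect_true(lf$ci["lower"] <= lf$fraction && lf$fraction <= lf$ci["upper"])
  ## all-carrier sample: fraction 0 with a one-sided interval from 0
  lf0 <- lossFraction(ctl$carrier, gates)
  expect_lt(lf0$fraction, 0.01)
})

test_that("gating is invariant to a joint monotone rescaling of both channels", {
  ctl <- controlPair(seed = 119L)
  gates <- buildGates(ctl$carrier, ctl$free)
  ev <- simulateFacsEvents(facsTruth(nEvents = 2000L, freeFraction = 0.4,
                                     seed = 121L))
  cls <- classifyEvents(ev, gates)
  ## scaling all intensities by 10 shifts log-space by 1; rebuild the gates
  ## from equally scaled controls and the classification is unchanged
  scale10 <- function(d) {
    d$green <- d$green * 10
    d$red <- d$red * 10
    d
  }
  gates10 <- buildGates(scale10(ctl$carrier), scale10(ctl$free))
  expect_identical(classifyEvents(scale10(ev), gates10), cls)
})

test_that("trajectory aggregation averages technical then summarizes biological replicates", {
  base <- expand.grid(strain = "WT", plasmid = "p1", day = 1L,
                      bioRep = 1L, techRep = 1:3)
  base$fraction <- c(0.1, 0.2, 0.3)
  agg <- aggregateTrajectory(base)
  expect_equal(agg$replicates$fraction, 0.2)
  same <- base
  same$fraction <- 0.25
  expect_equal(aggregateTrajectory(same)$replicates$fraction, 0.25)
  ## SEM across biological replicates against the direct formula
  multi <- expand.grid(strain = "WT", plasmid = "p1", day = 2L,
                       bioRep = 1:4, techRep = 1L)
  multi$fraction <- c(0.1, 0.2, 0.3, 0.4)
  s <- aggregateTrajectory(multi)$summary
  expect_equal(s$mean, 0.25)
  expect_equal(s$sem, sd(c(0.1, 0.2, 0.3, 0.4)) / sqrt(4))
  expect_identical(s$nBioReps, 4L)
})

test_that("trajectory aggregation commutes with relabeling technical replicates", {
  set.seed(123)
  d <- expand.grid(strain = c("WT", "MRB1"), plasmid = "p1", day = 0:2,
                   bioRep = 1:3, techRep = 1:3)
  d$fraction <- runif(nrow(d))
  shuffled <- d
  shuffled$techRep <- sample(shuffled$techRep)
  expect_equal(aggregateTrajectory(d)$replicates,
               aggregateTrajectory(shuffled)$replicates)
})

test_that("trend comparison recovers a noiseless slope difference exactly", {
  d <- expand.grid(day = 0:3, strain = c("WT", "MRB1"), bioRep = 1:2)
  d$plasmid <- "p1"
  d$fraction <- ifelse(d$strain == "WT", 0.1 + 0.07 * d$day,
                       0.1 + 0.02 * d$day)
  tc <- suppressWarnings(compareTrends(d))  # noiseless: perfect-fit warning
  expect_equal(abs(tc$interaction), 0.05, tolerance = 1e-12)
  expect_lt(tc$p, 1e-10)
})

test_that("the trend interaction equals the normal-equations closed form", {
  set.seed(127)
  d <- expand.grid(day = 0:3, strain = c("WT", "MRB1"), bioRep = 1:4)
  d$plasmid <- "p1"
  d$fraction <- 0.05 + 0.03 * d$day + 0.02 * d$day * (d$strain == "MRB1") +
    rnorm(nrow(d), 0, 0.01)
  tc <- compareTrends(d)
  X <- cbind(1, d$day, d$strain == "MRB1", d$day * (d$strain == "MRB1"))
  beta <- solve(t(X) %*% X, t(X) %*% d$fraction)
  expect_equal(unname(tc$interaction), beta[4, 1], tolerance = 1e-9)
})

test_that("the trend difference agrees with the estimated marginal trends route", {
  set.seed(129)
  d <- expand.grid(day = 0:4, strain = c("WT", "MRB1"), bioRep = 1:3)
  d$plasmid <- "p1"
  d$fraction <- 0.02 + 0.04 * d$day + 0.015 * d$day * (d$strain == "MRB1") +
    rnorm(nrow(d), 0, 0.015)
  tc <- compareTrends(d)
  em <- emmeans::emtrends(tc$fit, ~strain, var = "day")
  pr <- as.data.frame(emmeans::contrast(em, "pairwise"))
  ## WT - MRB1 trend difference is minus the day:strainMRB1 coefficient
  expect_equal(pr$estimate[1], -tc$interaction, tolerance = 1e-9)
  expect_equal(pr$p.value[1], tc$p, tolerance = 1e-9)
})

test_that("Welch's t test handles identical samples and equal-variance shifts", {
  x <- c(1, 2, 3)
  w0 <- welchT(x, x)
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
  y <- x + 10
  w <- welchT(x, y)
  ## equal variances and sizes: Welch statistic equals the pooled-t formula
  sp <- sqrt((var(x) + var(y)) / 2)
  tPooled <- (mean(x) - mean(y)) / (sp * sqrt(2 / 3))
  expect_equal(w$t, tPooled, tolerance = 1e-12)
  ## direct Welch formula on unequal samples
  set.seed(131)
  a <- rnorm(8, 0, 1)
  b <- rnorm(20, 1, 3)
  wf <- welchT(a, b)
  se <- sqrt(var(a) / 8 + var(b) / 20)
  tManual <- (mean(a) - mean(b)) / se
  dfManual <- se^4 / ((var(a) / 8)^2 / 7 + (var(b) / 20)^2 / 19)
  expect_equal(wf$t, tManual, tolerance = 1e-12)
  expect_equal(wf$df, dfManual, tolerance = 1e-9)
  expect_equal(wf$p, 2 * pt(-abs(tManual), dfManual), tolerance = 1e-12)
})

test_that("relative fitness follows the Malthusian-ratio convention", {
  expect_equal(relativeFitness(1e4, 1e6, 2e4, 2e6)$w, 1)
  expect_equal(relativeFitness(100, 100 * exp(4), 100, 100 * exp(2))$w, 2)
  ## swapping competitors inverts the fitness exactly
  f <- relativeFitness(120, 9000, 200, 5000)
  g <- relativeFitness(200, 5000, 120, 9000)
  expect_equal(f$w, 1 / g$w)
  expect_error(relativeFitness(0, 10, 10, 10), "positive")
  expect_warning(relativeFitness(10, 100, 10, 9), "did not grow")
})

test_that("fitness on simulated competition counts matches the growth-model prediction", {
  set.seed(137)
  s <- 0.05
  G <- 12
  n0 <- 5e5
  nFree1 <- rpois(1, n0 * (2 * (1 + s))^G)
  nCar1 <- rpois(1, n0 * 2^G)
  w <- relativeFitness(n0, nFree1, n0, nCar1)$w
  expect_equal(w, 1 + log(1 + s) / log(2), tolerance = 0.01)
})
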