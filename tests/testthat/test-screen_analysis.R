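test_that("survival fractions are DMSO-mean normalized per plate", {
  ps <- onePlate(treated = 500, dmso = c(900, 1100))
  sf <- survivalFraction(ps)
  expect_equal(sf$sf[sf$role == "treated"], 0.5)
  # DMSO wells average to SF 1 by construction
  expect_equal(mean(sf$sf[sf$role == "dmso"]), 1)

  zero <- onePlate(treated = 500, dmso = c(0, 0))
  expect_error(survivalFraction(zero), "PL1")
})

test_that("z scores count DMSO standard deviations from the DMSO mean", {
  ps <- onePlate(treated = c(717.2, 1000), dmso = c(900, 1100))
  z <- sfZscore(ps)
  sdDmso <- sd(c(0.9, 1.1))
  expect_equal(z$zscore[1], (0.7172 - 1) / sdDmso)
  expect_equal(z$zscore[1], -2, tolerance = 1e-3)
  expect_equal(z$zscore[2], 0)  # at the DMSO mean

  single <- onePlate(treated = 500, dmso = 1000)
  expect_warning(z1 <- sfZscore(single), "undefined")
  expect_true(is.na(z1$zscore[1]))
})

test_that("dose AUC is the normalized log-concentration trapezoid", {
  conc <- c(3, 30, 300, 3000)
  expect_equal(as.numeric(doseAUC(c(1, 1, 1, 1), conc)), 1)
  expect_equal(as.numeric(doseAUC(c(0, 0, 0, 0), conc)), 0)
  expect_equal(as.numeric(doseAUC(c(1, 1, 0, 0), conc)), 0.5)
  expect_error(doseAUC(c(1, NA, 0, 0), conc), "missing")

  # cross-check against pracma's trapezoid on random profiles; bounds and
  # invariance under a uniform dose relabeling that preserves log-spacing
  skip_if_not_installed("pracma")
  set.seed(26)
  for (rep in 1:20) {
    sf <- runif(4, 0, 1.2)
    a <- doseAUC(sf, conc)
    expect_equal(attr(a, "raw"), pracma::trapz(log10(conc), sf))
    expect_gte(as.numeric(a), min(sf) - 1e-12)
    expect_lte(as.numeric(a), max(sf) + 1e-12)
    expect_equal(as.numeric(doseAUC(sf, conc * 10)), as.numeric(a))
  }
})

test_that("the background mixture recovers planted parameters", {
  set.seed(5)
  pure <- rnorm(2000, 1, 0.05)
  fit <- fitBackgroundMixture(pure)
  expect_lte(abs(backgroundMean(fit) - 1), 0.01)
  expect_true(all(diff(fit@loglikTrace) >= -1e-8))

  mix <- c(rnorm(1800, 1, 0.05), rnorm(200, 0.3, 0.10))
  fit2 <- fitBackgroundMixture(mix)
  expect_lte(abs(fit2@means[3 - fit2@backgroundIndex] - 0.3), 0.05)
  expect_lte(abs(activeWeight(fit2) - 0.1), 0.05)
  expect_true(all(diff(fit2@loglikTrace) >= -1e-8))

  expect_error(fitBackgroundMixture(rnorm(10)), "at least 20")
})

test_that("the mixture fit agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  set.seed(41)
  v <- c(rnorm(1500, 1, 0.05), rnorm(500, 0.4, 0.08))
  fit <- fitBackgroundMixture(v)
  withr::local_package("mclust")  # Mclust resolves helpers via the search path
  ref <- Mclust(v, G = 2, modelNames = "V", verbose = FALSE)
  ord <- order(ref$parameters$mean)
  mine <- order(fit@means)
  expect_equal(fit@means[mine], as.numeric(ref$parameters$mean[ord]),
               tolerance = 0.02)
  expect_equal(fit@weights[mine], as.numeric(ref$parameters$pro[ord]),
               tolerance = 0.02)
  expect_equal(fit@loglik, ref$loglik, tolerance = 1e-3)
})

test_that("activity thresholds are analytic background quantiles", {
  fit <- new("MixtureFit", patientId = NA_character_,
             concentrationNM = NA_real_, weights = c(0.9, 0.1),
             means = c(1, 0.3), sds = c(0.05, 0.1), backgroundIndex = 1L,
             loglik = 0, loglikTrace = 0, threshold = NA_real_,
             fallback = FALSE)
  expect_equal(activityThreshold(fit, 0.01), 1 + qnorm(1e-4) * 0.05)
  expect_equal(activityThreshold(fit, 0.01), 0.8140, tolerance = 1e-4)
  expect_equal(activityThreshold(fit, 50), 1)  # the median is the mean

  # monotone in the percentile and in the background sd
  ps <- c(0.01, 0.1, 1, 5, 25)
  thr <- vapply(ps, function(p) activityThreshold(fit, p), numeric(1))
  expect_true(all(diff(thr) > 0))
  fitWide <- fit
  fitWide@sds <- c(0.1, 0.1)
  expect_lt(activityThreshold(fitWide, 0.01), activityThreshold(fit, 0.01))
})

test_that("strong hits require being under the threshold at every dose", {
  profiles <- expand.grid(
    patient_id = "P1", compound_id = c("hit", "partial", "edge"),
    concentration_nM = c(3, 30, 300, 3000), stringsAsFactors = FALSE)
  profiles <- profiles[order(profiles$compound_id), ]
  thr <- data.frame(patient_id = "P1",
                    concentration_nM = c(3, 30, 300, 3000),
                    threshold = c(0.80, 0.81, 0.82, 0.83))
  sf <- c(hit = 0.5, partial = 0.5, edge = 0.5)
  profiles$sf <- sf[profiles$compound_id]
  profiles$zscore <- NA_real_
  # partial misses one dose; edge sits exactly on one threshold
  profiles$sf[profiles$compound_id == "partial" &
              profiles$concentration_nM == 3] <- 0.9
  profiles$sf[profiles$compound_id == "edge" &
              profiles$concentration_nM == 30] <- 0.81
  out <- classifyStrongHits(profiles, thr, ScreenConfig())
  expect_equal(out$hits, "hit")
  calls <- out$calls
  expect_false(calls$is_strong_hit[calls$compound_id == "partial"])
  # strict inequality: equality with the threshold is not "under" it
  expect_false(calls$is_strong_hit[calls$compound_id == "edge"])
  expect_equal(calls$n_below[calls$compound_id == "edge"], 3L)

  expect_error(classifyStrongHits(profiles, thr[-1, ], ScreenConfig()),
               "missing threshold")
})

test_that("the end-to-end screen analysis recovers planted hits", {
  scr <- synthScreen(SynthScreenConfig(seed = 61L))
  res <- runScreenAnalysis(scr$plates, ScreenConfig(), seed = 61L)
  truthHits <- scr$truth$compound_id[scr$truth$is_active]
  sens <- mean(truthHits %in% res$hits)
  expect_gte(sens, 0.9)
  fpHits <- setdiff(res$hits, truthHits)
  expect_lte(length(fpHits), 0.01 * sum(!scr$truth$is_active))
  # every fitted stratum keeps a non-decreasing EM trace
  for (fit in res$fits) expect_true(all(diff(fit@loglikTrace) >= -1e-8))
  # thresholds sit far below the background centre
  expect_true(all(res$thresholds$threshold < 0.95))
  # AUC separates actives from background on average
  auc <- res$auc
  expect_lt(mean(auc$auc[auc$compound_id %in% truthHits]),
            mean(auc$auc[!(auc$compound_id %in% truthHits)]))
})

test_that("zscore readout mode calls hits from z-score mixtures", {
  scr <- synthScreen(SynthScreenConfig(seed = 17L))
  cfgZ <- ScreenConfig(readout = "zscore")
  res <- runScreenAnalysis(scr$plates, cfgZ, seed = 17L)
  truthHits <- scr$truth$compound_id[scr$truth$is_active]
  expect_gte(mean(truthHits %in% res$hits), 0.9)
  expect_true(all(res$thresholds$threshold < 0))
})
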