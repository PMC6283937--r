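test_that("performance profiles summarize survival and survivor gains", {
  df <- rbind(
    makeTrialDf(10, plant = "oak",
                survived = c(rep(TRUE, 7), rep(FALSE, 3))),
    makeTrialDf(2, plant = "fir", survived = c(TRUE, TRUE),
                gain = c(0.01, 0.03)),
    makeTrialDf(3, plant = "lilac", survived = rep(FALSE, 3)))
  trials <- FeedingTrialTable(df)
  prof <- performanceProfile(trials, "Tcri")
  oak <- prof[prof$plant == "oak", ]
  expect_equal(oak$survival, 0.7)
  fir <- prof[prof$plant == "fir", ]
  expect_equal(fir$mean_gain, 0.02)
  lilac <- prof[prof$plant == "lilac", ]
  expect_equal(lilac$survival, 0)          # survival kept at 0
  expect_true(is.na(lilac$mean_gain))      # weight gain missing: all dead

  ## equal survival across plants -> fundamental tau = 1
  eq <- FeedingTrialTable(rbind(
    makeTrialDf(10, plant = "a", survived = c(rep(TRUE, 9), FALSE)),
    makeTrialDf(10, plant = "b", survived = c(rep(TRUE, 9), FALSE)),
    makeTrialDf(10, plant = "c", survived = c(rep(TRUE, 9), FALSE))))
  expect_equal(tau(fundamentalTau(performanceProfile(eq, "Tcri"),
                                  "survival")), 1)
})

test_that("weight-gain ANOVA matches the closed-form balanced oracle", {
  set.seed(31)
  for (rep in 1:20) {
    nCell <- 4
    plants <- c("oak", "fir", "lilac")
    gm <- rbind(sexual = rnorm(3, 0.02, 0.01),
                asexual = rnorm(3, 0.02, 0.01))
    colnames(gm) <- plants
    trials <- makeGlmTrials(
      pSurv = matrix(1, 2, 3, dimnames = list(c("sexual", "asexual"), plants)),
      nPerCell = nCell, gainMeans = gm, sigma = 0.008)
    res <- weightGainANOVA(trials)
    df <- records(trials)
    oracle <- anovaOracleBalanced(df$final_mass - df$initial_mass,
                                  df$reproductive_mode, df$plant_treatment)
    expect_equal(res@terms$statistic, unname(oracle$F), tolerance = 1e-10)
    expect_equal(res@terms$df, unname(oracle$df))
    expect_equal(res@terms$df2, rep(oracle$dfRes, 3))
  }
})

test_that("ANOVA F is invariant to adding a constant to all responses", {
  set.seed(32)
  plants <- c("oak", "fir")
  trials <- makeGlmTrials(
    pSurv = matrix(1, 2, 2, dimnames = list(c("sexual", "asexual"), plants)),
    nPerCell = 6,
    gainMeans = matrix(rnorm(4, 0.02, 0.01), 2, 2,
                       dimnames = list(c("sexual", "asexual"), plants)))
  res1 <- weightGainANOVA(trials)
  df <- records(trials)
  df$final_mass <- df$final_mass + 5
  res2 <- weightGainANOVA(FeedingTrialTable(df, plants = plants))
  expect_equal(res1@terms$statistic, res2@terms$statistic, tolerance = 1e-8)
})

test_that("survival GLM: null limit and single-mode plant exclusion", {
  ## identical survival in every cell, large n -> interaction deviance ~ 0
  plants <- c("oak", "fir", "lilac", "mz")
  p <- matrix(0.6, 2, 4, dimnames = list(c("sexual", "asexual"), plants))
  df <- do.call(rbind, lapply(c("sexual", "asexual"), function(m) {
    do.call(rbind, lapply(plants, function(pl) {
      makeTrialDf(100, species = paste0("sp_", m), mode = m, plant = pl,
                  survived = rep(c(TRUE, FALSE), times = c(60, 40)))
    }))
  }))
  res <- survivalInteractionGLM(FeedingTrialTable(df, plants = plants))
  it <- res@terms[res@terms$term == "interaction", ]
  expect_lt(it$statistic, 1e-8)
  expect_equal(it$df, 3)

  ## a plant tested in one mode only is reported and shrinks the
  ## interaction df
  extra <- makeTrialDf(20, species = "sp_sexual", mode = "sexual",
                       plant = "redwood",
                       survived = rep(c(TRUE, FALSE), 10))
  res2 <- survivalInteractionGLM(
    FeedingTrialTable(rbind(df, extra), plants = c(plants, "redwood")))
  expect_identical(res2@excluded, "redwood")
  it2 <- res2@terms[res2@terms$term == "interaction", ]
  expect_equal(it2$df, 3)  # still only 3 estimable interaction contrasts

  expect_error(survivalInteractionGLM(
    FeedingTrialTable(df[df$reproductive_mode == "sexual", ])),
    "both reproductive modes")
})

test_that("GLM LRT rejection decision agrees with a permutation re-check", {
  set.seed(33)
  plants <- c("oak", "fir", "lilac")
  pNull <- matrix(c(0.8, 0.5, 0.3, 0.8, 0.5, 0.3), 2, 3, byrow = TRUE,
                  dimnames = list(c("sexual", "asexual"), plants))
  pAlt <- matrix(c(0.9, 0.5, 0.1, 0.1, 0.5, 0.9), 2, 3, byrow = TRUE,
                 dimnames = list(c("sexual", "asexual"), plants))
  permP <- function(trials, nPerm = 999) {
    df <- records(trials)
    obs <- survivalInteractionGLM(trials)@terms
    obs <- obs$statistic[obs$term == "interaction"]
    strata <- split(seq_len(nrow(df)), df$plant_treatment)
    stat <- replicate(nPerm, {
      d2 <- df
      for (ii in strata) {
        d2$reproductive_mode[ii] <- sample(d2$reproductive_mode[ii])
      }
      t <- survivalInteractionGLM(
        FeedingTrialTable(d2, plants = colnames(pNull)))@terms
      t$statistic[t$term == "interaction"]
    })
    (1 + sum(stat >= obs - 1e-12)) / (nPerm + 1)
  }
  tNull <- makeGlmTrials(pNull, nPerCell = 25)
  tAlt <- makeGlmTrials(pAlt, nPerCell = 25)
  lrtNull <- survivalInteractionGLM(tNull)@terms
  lrtAlt <- survivalInteractionGLM(tAlt)@terms
  pLrtNull <- lrtNull$p[lrtNull$term == "interaction"]
  pLrtAlt <- lrtAlt$p[lrtAlt$term == "interaction"]
  pPermNull <- permP(tNull, nPerm = 199)
  pPermAlt <- permP(tAlt, nPerm = 199)
  expect_identical(pLrtNull < 0.05, pPermNull < 0.05)
  expect_identical(pLrtAlt < 0.05, pPermAlt < 0.05)
  expect_lt(pLrtAlt, 0.05)
  expect_gt(pLrtNull, 0.05)
})

test_that("interaction models recover their generating cell effects", {
  set.seed(34)
  plants <- c("oak", "fir")
  pTrue <- matrix(c(0.9, 0.3, 0.3, 0.9), 2, 2, byrow = TRUE,
                  dimnames = list(c("sexual", "asexual"), plants))
  gTrue <- matrix(c(0.03, 0.01, 0.01, 0.03), 2, 2, byrow = TRUE,
                  dimnames = list(c("sexual", "asexual"), plants))
  trials <- makeGlmTrials(pTrue, nPerCell = 100, gainMeans = gTrue,
                          sigma = 0.008)
  df <- records(trials)
  for (m in rownames(pTrue)) {
    for (pl in plants) {
      cell <- df[df$reproductive_mode == m & df$plant_treatment == pl, ]
      expect_lt(abs(mean(cell$survived) - pTrue[m, pl]), 0.15)
      g <- (cell$final_mass - cell$initial_mass)[cell$survived]
      expect_lt(abs(mean(g) - gTrue[m, pl]), 0.003)
    }
  }
  ## both tests flag the strong antagonistic interaction
  sv <- survivalInteractionGLM(trials)@terms
  wg <- weightGainANOVA(trials)@terms
  expect_lt(sv$p[sv$term == "interaction"], 1e-4)
  expect_lt(wg$p[wg$term == "interaction"], 1e-4)
})

test_that("Levene's test behaves under construction, scaling and centering", {
  vals <- c(0, 0, 0, 0, 0.24, 0.48)
  grp <- rep(c("A", "B"), each = 3)
  lt <- leveneVarTest(vals, grp)
  expect_gt(unname(lt$statistic), 0)
  expect_equal(unname(lt$parameter), c(1, 4))

  ## doubling the values leaves F unchanged
  lt2 <- leveneVarTest(2 * vals, grp)
  expect_equal(unname(lt2$statistic), unname(lt$statistic), tolerance = 1e-10)

  ## all deviations zero -> flagged undefined
  lt0 <- leveneVarTest(c(1, 1, 2, 2), c("A", "A", "B", "B"))
  expect_true(is.na(lt0$statistic))

  expect_error(leveneVarTest(1:3, c("A", "A", "A")), "2 groups")
  expect_error(leveneVarTest(1:3, c("A", "A", "B")), "at least 2 values")
})

test_that("Levene's test matches car::leveneTest for both centers", {
  skip_if_not_installed("car")
  set.seed(35)
  vals <- c(rnorm(12, sd = 1), rnorm(15, sd = 3))
  grp <- rep(c("sexual", "asexual"), c(12, 15))
  for (ctr in c("median", "mean")) {
    mine <- leveneVarTest(vals, grp, center = ctr)
    ref <- car::leveneTest(vals, factor(grp), center = get(ctr))
    expect_equal(unname(mine$statistic), ref[1, "F value"], tolerance = 1e-10)
    expect_equal(mine$p.value, ref[1, "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("Pearson wrapper: exact limits, oracle value, degenerate errors", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(unname(pearsonCorTest(x, x)$estimate), 1)
  expect_equal(unname(pearsonCorTest(x, -x)$estimate), -1)
  y <- c(2, 1, 4, 3, 6)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(unname(pearsonCorTest(x, y)$estimate), r, tolerance = 1e-12)
  expect_error(pearsonCorTest(x, rep(1, 5)), "zero variance")
  expect_error(pearsonCorTest(1:2, 2:3), "at least 3")
})
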