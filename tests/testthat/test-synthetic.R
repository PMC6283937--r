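test_that("generators are pure functions of (scenario, seed)", {
  scen <- genPairScenario("FNV", seed = 5)
  expect_identical(records(genOccurrences(scen)), records(genOccurrences(scen)))
  expect_identical(records(genFeedingTrials(scen)),
                   records(genFeedingTrials(scen)))
  expect_identical(records(genMorphCounts(scen)),
                   records(genMorphCounts(scen)))
  scen2 <- genPairScenario("FNV", seed = 6)
  expect_false(identical(records(genOccurrences(scen)),
                         records(genOccurrences(scen2))))
  tree <- readSpeciesTree("((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
  expect_identical(genBrownianTraits(tree, seed = 2),
                   genBrownianTraits(tree, seed = 2))
})

test_that("generated tables satisfy their type invariants across scenarios", {
  set.seed(41)
  for (i in 1:10) {
    k <- sample(3:7, 1)
    pi <- rgamma(k, 1); pi <- pi / sum(pi)
    scen <- syntheticScenario(list(popA = pi, popB = rep(1 / k, k)),
                              N = sample(c(50, 200, 500), 1),
                              theta = sample(c(Inf, 20), 1), seed = 400 + i)
    occ <- genOccurrences(scen)
    expect_true(validObject(occ))
    expect_equal(sum(records(occ)$count), 2 * scen@N[[1]])
    trials <- genFeedingTrials(scen)
    expect_true(validObject(trials))
    d <- records(trials)
    expect_true(all(d$survived == !is.na(d$final_mass)))
    expect_true(all(d$final_mass - d$initial_mass >= -0.05 - 1e-9,
                    na.rm = TRUE))
    morphs <- genMorphCounts(scen)
    expect_true(validObject(morphs))
  }
})

test_that("degenerate compositions produce the exact tau limits", {
  scen <- syntheticScenario(list(pop1 = c(1, 0, 0)), N = 50, seed = 1)
  occ <- genOccurrences(scen)
  expect_equal(records(occ)$count, c(50L, 0L, 0L))
  ## evaluated over the scenario's full plant list as availability
  expect_equal(
    populationRealizedTau(occ, availability = list(L1 = scen@plants))$tau, 0)
  expect_equal(unname(scen@trueTau), 0)

  scenU <- syntheticScenario(list(pop1 = rep(0.25, 4)), N = 200000, seed = 2)
  tauHat <- populationRealizedTau(genOccurrences(scenU))$tau
  expect_gt(tauHat, 0.98)  # law-of-large-numbers limit
})

test_that("sample tau is consistent for its composition's true value", {
  pi <- c(0.6, 0.3, 0.1)
  trueTau <- tauOracle(pi)
  taus <- vapply(1:100, function(i) {
    scen <- syntheticScenario(list(p = pi), N = 5000, seed = 7000 + i)
    populationRealizedTau(genOccurrences(scen))$tau
  }, numeric(1))
  expect_lt(abs(mean(taus) - trueTau), 0.02)
})

test_that("FNV narrows and GPG broadens the asexual composition", {
  fnv <- genPairScenario("FNV", piSexual = c(0.4, 0.3, 0.2, 0.1), seed = 3)
  expect_lt(fnv@trueTau[["pop_asexual"]], fnv@trueTau[["pop_sexual"]])
  expect_equal(sum(fnv@compositions$pop_asexual > 0), 2)

  gpg <- genPairScenario("GPG", piSexual = c(0.4, 0.3, 0.2, 0.1), seed = 3)
  expect_gt(gpg@trueTau[["pop_asexual"]], gpg@trueTau[["pop_sexual"]])

  ## identity presets: full support retained / no flattening
  fnvId <- genPairScenario("FNV", subsetSize = 4, seed = 3)
  expect_equal(fnvId@compositions$pop_asexual, fnvId@compositions$pop_sexual)
  gpgId <- genPairScenario("GPG", flatten = 0, seed = 3)
  expect_equal(gpgId@compositions$pop_asexual, gpgId@compositions$pop_sexual)

  expect_error(genPairScenario("FNV", piSexual = c(0.5, 0.5)), "at least 3")
  expect_error(genPairScenario("FNV", subsetSize = 1), "at least 2")
})

test_that("trial generator honors its design contracts", {
  scen <- genPairScenario("FNV", seed = 9)
  td <- scen@trialDesign
  ## probability-1 survival: everyone survives
  td$logits[] <- 50
  scen@trialDesign <- td
  trials <- genFeedingTrials(scen)
  expect_true(all(records(trials)$survived))
  ## per-cell sizes inside the declared 10-20 range
  tab <- table(records(trials)$reproductive_mode,
               records(trials)$plant_treatment)
  expect_true(all(tab >= 10 & tab <= 20))
  ## sigma must be positive
  td$sigma <- 0
  scen@trialDesign <- td
  expect_error(genFeedingTrials(scen), "sigma")

  ## known cell probabilities, large n: observed proportions concentrate
  scen2 <- genPairScenario("FNV", seed = 10)
  td2 <- scen2@trialDesign
  td2$nPerCell <- 1000L
  scen2@trialDesign <- td2
  d <- records(genFeedingTrials(scen2))
  for (m in rownames(td2$logits)) {
    for (pl in colnames(td2$logits)) {
      obs <- mean(d$survived[d$reproductive_mode == m &
                             d$plant_treatment == pl])
      expect_lt(abs(obs - plogis(td2$logits[m, pl])), 0.04)
    }
  }
})

test_that("brownian trait generator inverts the PGLS model", {
  tree <- readSpeciesTree("((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
  ## noiseless limit: exact slope recovery, |r| = 1
  d0 <- genBrownianTraits(tree, beta = 2, sigmaResid = 0, seed = 1)
  fit <- pglsFit(setNames(d0$x, d0$species), setNames(d0$y, d0$species),
                 brownianVCV(tree, d0$species))
  expect_equal(unname(coef(fit)["slope"]), 2, tolerance = 1e-10)
  expect_equal(abs(fit@r), 1, tolerance = 1e-10)
  expect_error(genBrownianTraits(tree, sigmaResid = -1), "sigmaResid")

  ## unbiased slope recovery across replicates
  set.seed(44)
  big <- ape::rcoal(20)
  betas <- vapply(1:100, function(i) {
    d <- genBrownianTraits(big, beta = 1, sigmaResid = 0.5, seed = 5000 + i)
    fit <- pglsFit(setNames(d$x, d$species), setNames(d$y, d$species),
                   brownianVCV(big, d$species))
    unname(coef(fit)["slope"])
  }, numeric(1))
  expect_lt(abs(mean(betas) - 1), 0.05)
})

test_that("simulateScenario writes re-readable inputs plus a truth sidecar", {
  dir <- withr::local_tempdir()
  scen <- genPairScenario("GPG", seed = 12)
  paths <- simulateScenario(scen, dir)
  expect_true(all(file.exists(paths)))
  occ <- readOccurrenceTable(paths[["occurrence"]])
  expect_identical(records(occ), records(genOccurrences(scen)))
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$true_tau$pop_sexual,
               unname(scen@trueTau["pop_sexual"]), tolerance = 1e-12)
})
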