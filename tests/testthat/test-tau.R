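test_that("tau endpoints: single-plant specialist is 0, equal use is 1", {
  expect_identical(tau(tauInversed(c(10, 0, 0, 0))), 0)
  expect_identical(tau(tauInversed(c(5, 5, 5, 5))), 1)
  expect_equal(tau(tauInversed(c(8, 4, 0))), 0.25)
})

test_that("tau matches the loop oracle on random profiles", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(2:8, 1)
    x <- rgamma(n, shape = 0.7)
    if (runif(1) < 0.3) x[sample(n, 1)] <- 0
    if (max(x) == 0) x[1] <- 1
    expect_equal(tau(tauInversed(x)), tauOracle(x), tolerance = 1e-12)
  }
})

test_that("tau is scale- and permutation-invariant and bounded in [0,1]", {
  set.seed(102)
  for (i in 1:50) {
    x <- rgamma(sample(2:7, 1), shape = 1)
    t0 <- tau(tauInversed(x))
    expect_gte(t0, 0); expect_lte(t0, 1)
    expect_equal(tau(tauInversed(x * runif(1, 0.01, 100))), t0,
                 tolerance = 1e-12)
    expect_equal(tau(tauInversed(sample(x))), t0, tolerance = 1e-12)
    ## 0 iff exactly one positive; 1 iff all equal positive
    expect_identical(t0 == 0, sum(x > 0) == 1L)
    expect_identical(abs(t0 - 1) < 1e-12, diff(range(x)) < 1e-12)
  }
})

test_that("adding an unused available plant strictly decreases a positive tau", {
  set.seed(103)
  for (i in 1:50) {
    x <- rgamma(sample(2:6, 1), shape = 1) + 0.05
    t0 <- tau(tauInversed(x))
    t1 <- tau(tauInversed(c(x, 0)))
    if (t0 > 0) expect_lt(t1, t0)
    expect_equal(t1, tauOracle(c(x, 0)), tolerance = 1e-12)
  }
})

test_that("tau input contracts: undefined below 2 plants, error on empty niche", {
  res <- tauInversed(c(onlyPlant = 3))
  expect_true(is.na(tau(res)))
  expect_equal(res@nPlants, 1L)
  expect_error(tauInversed(c(0, 0, 0)), "no positive")
  expect_error(tauInversed(c(-1, 2)), "nonnegative")
  expect_error(tauInversed(numeric(0)), "non-empty")
})

test_that("population tau uses the location availability set", {
  occ <- OccurrenceTable(data.frame(
    species_id = c("s1", "s1", "s2", "s2", "s2"),
    location_id = "L1",
    population_id = c("P1", "P1", "P2", "P2", "P2"),
    plant_taxon = c("A", "B", "A", "B", "C"),
    count = c(12L, 0L, 9L, 3L, 0L)))
  ## observed-use union at L1 is {A, B} (C never carries an individual)
  res <- populationRealizedTau(occ)
  expect_equal(res$tau[res$population_id == "P1"], 0)
  expect_equal(res$n_plants, c(2L, 2L))

  ## explicit availability widens the set: P2 over {A,B,C} = 1 - (0+2/3+1)/2
  res2 <- populationRealizedTau(occ, availability = list(L1 = c("A", "B", "C")))
  expect_equal(res2$tau[res2$population_id == "P2"], 1 / 6, tolerance = 1e-12)
  expect_equal(res2$tau[res2$population_id == "P1"], 0)

  ## generalist limit
  occ2 <- OccurrenceTable(data.frame(
    species_id = "s1", location_id = "L1", population_id = "P1",
    plant_taxon = c("A", "B"), count = c(6L, 6L)))
  expect_equal(populationRealizedTau(occ2)$tau, 1)

  ## single available plant: flagged missing, not 0 or 1
  occ3 <- OccurrenceTable(data.frame(
    species_id = "s1", location_id = "L1", population_id = "P1",
    plant_taxon = "A", count = 5L))
  expect_true(is.na(populationRealizedTau(occ3)$tau))

  ## observed plant absent from an explicit availability list
  expect_error(
    populationRealizedTau(occ, availability = list(L1 = c("A"))),
    "absent from the availability list")
})

test_that("species breadth counts genera and pools counts", {
  occ <- OccurrenceTable(data.frame(
    species_id = "s1", location_id = c("L1", "L2"),
    population_id = c("P1", "P2"),
    plant_taxon = c("Ceanothus thyrsiflorus", "Adenostoma fasciculatum"),
    count = c(3L, 4L)))
  res <- speciesRealizedBreadth(occ)
  expect_equal(res$n_genera, 2L)

  ## pooling (3,0) and (0,3) over the same two genera gives tau 1
  occ2 <- OccurrenceTable(data.frame(
    species_id = "s1", location_id = "L1",
    population_id = c("P1", "P1", "P2", "P2"),
    plant_taxon = rep(c("Ceanothus sp", "Quercus sp"), 2),
    count = c(3L, 0L, 0L, 3L)))
  res2 <- speciesRealizedBreadth(occ2)
  expect_equal(res2$n_genera, 2L)
  expect_equal(res2$tau_pooled, 1)

  ## explicit taxonomy map and unmapped-taxon error
  res3 <- speciesRealizedBreadth(occ, taxonomy = c(
    "Ceanothus thyrsiflorus" = "Ceanothus",
    "Adenostoma fasciculatum" = "Adenostoma"))
  expect_equal(res3$n_genera, 2L)
  expect_error(
    speciesRealizedBreadth(occ, taxonomy = c(
      "Ceanothus thyrsiflorus" = "Ceanothus")),
    "no genus mapping")
})
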