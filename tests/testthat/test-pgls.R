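test_that("brownian covariance matches hand-traced and oracle values", {
  V2 <- brownianVCV(readSpeciesTree("(A:1,B:1);"))
  expect_equal(unname(V2), diag(2))

  V3 <- brownianVCV(readSpeciesTree("((A:1,B:1):1,C:2);"))
  expect_equal(unname(diag(V3)), c(2, 2, 2))
  expect_equal(unname(V3["A", "B"]), 1)
  expect_equal(unname(V3["A", "C"]), 0)

  ## star tree: t * Identity
  star <- readSpeciesTree("(A:3,B:3,C:3,D:3);")
  expect_equal(unname(brownianVCV(star)), 3 * diag(4))

  set.seed(5)
  tree <- ape::rtree(10)
  expect_equal(brownianVCV(tree)[tree$tip.label, tree$tip.label],
               vcvOracle(tree), tolerance = 1e-12)

  expect_error(brownianVCV(tree, species = c(tree$tip.label, "ghost")),
               "ghost")
})

test_that("brownian covariance is permutation-equivariant in species order", {
  set.seed(6)
  tree <- ape::rtree(8)
  sp <- tree$tip.label
  perm <- sample(sp)
  V <- brownianVCV(tree, sp)
  Vp <- brownianVCV(tree, perm)
  expect_equal(Vp, V[perm, perm])
})

test_that("identity covariance reduces PGLS to OLS", {
  set.seed(8)
  x <- rnorm(12); y <- 0.7 * x + rnorm(12)
  fit <- pglsFit(x, y, diag(12))
  ols <- lm(y ~ x)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(unname(fit@se), unname(summary(ols)$coefficients[, 2]),
               tolerance = 1e-8)
  expect_equal(fit@r, unname(cor(x, y)), tolerance = 1e-8)
  expect_equal(fit@pValue, summary(ols)$coefficients[2, 4], tolerance = 1e-8)
})

test_that("perfect linear relation gives r = 1 and exact coefficients", {
  set.seed(9)
  tree <- ape::rcoal(8)
  V <- brownianVCV(tree)
  x <- rnorm(8)
  fit <- pglsFit(x, 2 * x + 1, V)
  expect_equal(unname(coef(fit)), c(1, 2), tolerance = 1e-10)
  expect_equal(fit@r, 1, tolerance = 1e-10)
})

test_that("4-species fit matches the explicit matrix-algebra oracle", {
  V <- matrix(c(2, 1, 0, 0,
                1, 2, 0, 0,
                0, 0, 2, 1,
                0, 0, 1, 2), 4, 4)
  x <- c(1, 2, 3, 5)
  y <- c(2, 3, 7, 9)
  fit <- pglsFit(x, y, V)
  expect_equal(unname(coef(fit)), unname(pglsOracle(x, y, V)),
               tolerance = 1e-10)
})

test_that("pglsFit agrees with nlme::gls under a Brownian correlation", {
  skip_if_not_installed("nlme")
  set.seed(10)
  tree <- ape::rcoal(12)
  d <- genBrownianTraits(tree, beta = 1.5, sigmaResid = 0.8, seed = 3)
  V <- brownianVCV(tree, d$species)
  fit <- pglsFit(setNames(d$x, d$species), setNames(d$y, d$species), V)
  g <- nlme::gls(y ~ x, data = d,
                 correlation = ape::corBrownian(1, tree, form = ~species))
  tt <- summary(g)$tTable
  expect_equal(unname(coef(fit)), unname(coef(g)), tolerance = 1e-6)
  expect_equal(unname(fit@se), unname(tt[, "Std.Error"]), tolerance = 1e-6)
  expect_equal(fit@pValue, tt["x", "p-value"], tolerance = 1e-6)
})

test_that("branch-length rescaling leaves slope, r, t and p unchanged", {
  set.seed(12)
  tree <- ape::rcoal(10)
  d <- genBrownianTraits(tree, beta = 1, sigmaResid = 1, seed = 4)
  x <- setNames(d$x, d$species); y <- setNames(d$y, d$species)
  f1 <- pglsFit(x, y, brownianVCV(tree, d$species))
  tree2 <- tree
  tree2$edge.length <- tree$edge.length * 7.3
  f2 <- pglsFit(x, y, brownianVCV(tree2, d$species))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
  expect_equal(f1@r, f2@r, tolerance = 1e-10)
  expect_equal(f1@tStat, f2@tStat, tolerance = 1e-10)
  expect_equal(f1@pValue, f2@pValue, tolerance = 1e-10)
  expect_equal(f2@sigma2, f1@sigma2 / 7.3, tolerance = 1e-10)
})

test_that("pgls input contracts", {
  expect_error(pglsFit(c(1, 1, 1, 1), rnorm(4), diag(4)), "constant")
  expect_error(pglsFit(1:2, 1:2, diag(2)), "at least 3")
  ## star tree wrapper reduces to the Pearson test
  star <- readSpeciesTree("(A:1,B:1,C:1,D:1,E:1);")
  set.seed(13)
  x <- setNames(rnorm(5), star$tip.label)
  y <- setNames(rnorm(5), star$tip.label)
  res <- pglsCorrelation(x, y, star)
  ct <- cor.test(x, y)
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-8)
  expect_equal(res$p, ct$p.value, tolerance = 1e-8)
})

test_that("naive Pearson inflates type I error on Brownian traits, PGLS does not", {
  set.seed(14)
  tree <- ape::rcoal(20)
  reps <- 300
  rejP <- 0L; rejG <- 0L
  for (i in 1:reps) {
    d <- genBrownianTraits(tree, beta = 0, sigmaResid = 1, seed = 20000 + i)
    ct <- cor.test(d$x, d$y)
    if (ct$p.value < 0.05) rejP <- rejP + 1L
    fit <- pglsCorrelation(setNames(d$x, d$species), setNames(d$y, d$species),
                           tree)
    if (fit$p < 0.05) rejG <- rejG + 1L
  }
  expect_gt(rejP / reps, 0.10)          # Pearson inflated on shared phylogeny
  expect_lt(abs(rejG / reps - 0.05), 0.04)  # PGLS near nominal
})
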