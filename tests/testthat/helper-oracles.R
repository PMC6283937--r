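## Independent brute-force oracles, kept deliberately naive and separate
## from the package's computational paths.

## Tau by the literal definition: explicit loop over plants.
tauOracle <- function(x) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  m <- max(x)
  s <- 0
  for (xi in x) s <- s + (1 - xi / m)
  1 - s / (n - 1)
}

## Brownian covariance by tip-pair MRCA depth (root-to-node path lengths),
## a different route than ape::vcv.phylo's traversal.
vcvOracle <- function(tree) {
  tips <- tree$tip.label
  depths <- ape::node.depth.edgelength(tree)
  mr <- ape::mrca(tree)
  V <- matrix(0, length(tips), length(tips), dimnames = list(tips, tips))
  for (i in seq_along(tips)) {
    for (j in seq_along(tips)) {
      V[i, j] <- depths[mr[tips[i], tips[j]]]
    }
  }
  V
}

## Sequential (Type I) two-way ANOVA for a BALANCED design, from the
## textbook closed-form sums-of-squares decomposition over group means.
anovaOracleBalanced <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  grand <- mean(y)
  ssA <- sum(tapply(y, A, function(v) length(v) * (mean(v) - grand)^2))
  ssB <- sum(tapply(y, B, function(v) length(v) * (mean(v) - grand)^2))
  cellMean <- tapply(y, list(A, B), mean)
  nCell <- tapply(y, list(A, B), length)
  aMean <- tapply(y, A, mean); bMean <- tapply(y, B, mean)
  ssAB <- 0
  for (a in levels(A)) {
    for (b in levels(B)) {
      ssAB <- ssAB + nCell[a, b] *
        (cellMean[a, b] - aMean[a] - bMean[b] + grand)^2
    }
  }
  fittedCell <- cellMean[cbind(as.character(A), as.character(B))]
  ssRes <- sum((y - fittedCell)^2)
  dfA <- nlevels(A) - 1; dfB <- nlevels(B) - 1; dfAB <- dfA * dfB
  dfRes <- length(y) - nlevels(A) * nlevels(B)
  ms <- ssRes / dfRes
  list(F = c(A = (ssA / dfA) / ms, B = (ssB / dfB) / ms,
             AB = (ssAB / dfAB) / ms),
       df = c(dfA, dfB, dfAB), dfRes = dfRes)
}

## GLS slope by explicit dense matrix algebra (solve(V) directly).
pglsOracle <- function(x, y, V) {
  X <- cbind(1, x)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi %*% y
  drop(beta)
}

## Small valid tables used across tests ------------------------------------

makeOccLines <- function() {
  c("species_id,location_id,population_id,plant_taxon,count",
    "Tcri,L1,P1,Ceanothus thyrsiflorus,5",
    "Tcri,L1,P1,Adenostoma fasciculatum,0",
    "Tcri,L1,P1,Quercus agrifolia,2")
}

makeTrialDf <- function(n = 8, species = "Tcri", mode = "sexual",
                        plant = "oak", survived = rep(TRUE, n),
                        gain = rep(0.02, n)) {
  initial <- rep(0.045, n)
  data.frame(species_id = species, reproductive_mode = mode,
             population_id = paste0("exp_", species),
             plant_treatment = plant, survived = survived,
             initial_mass = initial,
             final_mass = ifelse(survived, initial + gain, NA_real_),
             duration_days = 10L)
}

## Bernoulli-cell trial table for interaction simulations: one row per
## (mode, plant) insect with given survival probability matrix.
makeGlmTrials <- function(pSurv, nPerCell, gainMeans = NULL, sigma = 0.01) {
  modes <- rownames(pSurv); plants <- colnames(pSurv)
  rows <- list()
  for (m in modes) {
    for (pl in plants) {
      surv <- runif(nPerCell) < pSurv[m, pl]
      g <- if (is.null(gainMeans)) rep(0.02, nPerCell) else
        rnorm(nPerCell, gainMeans[m, pl], sigma)
      rows[[paste(m, pl)]] <- makeTrialDf(
        n = nPerCell, species = paste0("sp_", m), mode = m, plant = pl,
        survived = surv, gain = g)
    }
  }
  FeedingTrialTable(do.call(rbind, rows), plants = plants)
}
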