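## Synthetic-data generators with known ground truth. A scenario bundles
## per-population host-use compositions (multinomial sampling, optional
## Dirichlet-multinomial overdispersion), colour-morph frequencies, a
## feeding-trial design (survival logits and weight-gain cell means), and a
## tree with a true regression slope for Brownian tip traits. One top-level
## seed expands into named child streams so each table can be regenerated
## independently.

#' SyntheticScenario: generator parameters with stored ground truth
#'
#' @slot seed top-level RNG seed; child seeds are derived per stream.
#' @slot preset `"custom"`, `"FNV"` (frozen niche variation: the asexual
#'   composition is the sexual one restricted to a subset of its host
#'   plants) or `"GPG"` (general-purpose genotype: the asexual composition
#'   is flattened toward uniform).
#' @slot plants host-plant labels shared by all populations.
#' @slot populations data.frame: `population_id`, `species_id`,
#'   `location_id`, `reproductive_mode`.
#' @slot compositions named list (by population) of true host-use
#'   probability vectors over `plants` (each sums to 1).
#' @slot N named integer: individuals sampled per population.
#' @slot theta Dirichlet-multinomial overdispersion concentration;
#'   `Inf` (default) = exact multinomial sampling.
#' @slot morphs morph registry labels.
#' @slot morphFreqs named list (by species) of morph frequency vectors.
#' @slot morphN individuals scored for colour morph per population.
#' @slot trialDesign list: `plants`, `nPerCell` (scalar or c(min, max) range
#'   from which per-cell sizes are drawn), `logits` (mode x plant survival
#'   logits), `gainMeans` (mode x plant mean weight gain, grams), `sigma`
#'   (gain SD, grams), `gainFloor` (truncation floor, grams),
#'   `species` (named by mode: species id per mode).
#' @slot tree a `phylo` (or NULL) for Brownian trait simulation.
#' @slot beta,sigmaResid true slope and residual scale for the trait pair.
#' @slot trueTau named numeric: the true inversed Tau of each population's
#'   composition over the full plant list.
#' @aliases SyntheticScenario
#' @export
setClass("SyntheticScenario",
         representation(seed = "integer", preset = "character",
                        plants = "character", populations = "data.frame",
                        compositions = "list", N = "integer",
                        theta = "numeric", morphs = "character",
                        morphFreqs = "list", morphN = "integer",
                        trialDesign = "list", tree = "ANY",
                        beta = "numeric", sigmaResid = "numeric",
                        trueTau = "numeric"))

setValidity("SyntheticScenario", function(object) {
  for (pop in names(object@compositions)) {
    pi <- object@compositions[[pop]]
    if (length(pi) != length(object@plants)) {
      return(sprintf("composition of '%s' not aligned to the plant list", pop))
    }
    if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8) {
      return(sprintf("composition of '%s' is not a probability vector", pop))
    }
  }
  if (any(object@N < 1L)) return("N must be >= 1 per population")
  for (sp in names(object@morphFreqs)) {
    f <- object@morphFreqs[[sp]]
    if (any(f < 0) || abs(sum(f) - 1) > 1e-8) {
      return(sprintf("morph frequencies of '%s' are not a probability vector",
                     sp))
    }
  }
  td <- object@trialDesign
  if (length(td)) {
    if (!is.null(td$sigma) && td$sigma <= 0) return("trial sigma must be > 0")
    if (any(unlist(td$nPerCell) < 1)) return("n per cell must be >= 1")
  }
  TRUE
})

setMethod("show", "SyntheticScenario", function(object) {
  cat(sprintf("SyntheticScenario (%s): %d populations over %d plants, seed %d\n",
              object@preset, nrow(object@populations),
              length(object@plants), object@seed))
  if (length(object@trueTau)) {
    cat("  true tau:",
        paste(sprintf("%s=%.3f", names(object@trueTau), object@trueTau),
              collapse = ", "), "\n")
  }
})

## default 3-per-mode Dirichlet morph frequencies; k morphs in 1..8
.defaultMorphFreqs <- function(species, seed) {
  .withSeed(.childSeed(seed, "morph-setup"), {
    out <- lapply(species, function(sp) {
      k <- sample(1:8, 1)
      f <- rgamma(k, shape = 2)
      f <- f / sum(f)
      setNames(f, paste0("m", seq_len(k)))
    })
    names(out) <- species
    out
  })
}

#' Construct a synthetic scenario
#'
#' Builds a [SyntheticScenario-class] from explicit compositions. The true
#' inversed Tau of every composition (over the full plant list) is computed
#' and stored for recovery tests.
#'
#' @param compositions named list (by population id) of probability vectors
#'   over `plants`.
#' @param plants host-plant labels; default taken from the first
#'   composition's names.
#' @param populations optional data.frame (`population_id`, `species_id`,
#'   `location_id`, `reproductive_mode`); by default one population per
#'   composition, all at one location, alternating species ids.
#' @param N individuals per population (recycled; default 500).
#' @param theta Dirichlet-multinomial concentration (`Inf` = multinomial).
#' @param seed top-level seed.
#' @param preset scenario tag.
#' @param morphFreqs optional named list of morph frequency vectors per
#'   species; defaults to random vectors with 1-8 morphs per species.
#' @param morphN morph-scored individuals per population (default 30).
#' @param trialDesign optional feeding-trial design list (see the class
#'   documentation); a default 2-mode x 7-plant design with no interaction
#'   is built when omitted.
#' @param tree optional `phylo` for trait simulation.
#' @param beta,sigmaResid true slope and residual scale for
#'   [genBrownianTraits()].
#' @return A [SyntheticScenario-class].
#' @export
syntheticScenario <- function(compositions, plants = NULL, populations = NULL,
                              N = 500, theta = Inf, seed = 1,
                              preset = "custom", morphFreqs = NULL,
                              morphN = 30, trialDesign = NULL, tree = NULL,
                              beta = 1, sigmaResid = 0.5) {
  if (is.null(plants)) plants <- names(compositions[[1]])
  if (is.null(plants)) {
    plants <- paste0("plant", seq_along(compositions[[1]]))
  }
  compositions <- lapply(compositions, function(pi) {
    setNames(as.numeric(pi), plants)
  })
  if (is.null(names(compositions))) {
    names(compositions) <- paste0("pop", seq_along(compositions))
  }
  pops <- names(compositions)
  if (is.null(populations)) {
    populations <- data.frame(
      population_id = pops,
      species_id = paste0("sp", seq_along(pops)),
      location_id = "L1",
      reproductive_mode = rep(c("sexual", "asexual"), length.out = length(pops)))
  }
  N <- setNames(as.integer(rep(N, length.out = length(pops))), pops)
  species <- unique(populations$species_id)
  if (is.null(morphFreqs)) morphFreqs <- .defaultMorphFreqs(species, seed)
  morphs <- sort(unique(unlist(lapply(morphFreqs, names))))
  if (is.null(trialDesign)) trialDesign <- .defaultTrialDesign(populations)
  trueTau <- vapply(compositions, .tauInv, numeric(1))
  new("SyntheticScenario", seed = as.integer(seed), preset = preset,
      plants = plants, populations = populations,
      compositions = compositions, N = N, theta = as.numeric(theta),
      morphs = morphs, morphFreqs = morphFreqs,
      morphN = as.integer(morphN), trialDesign = trialDesign,
      tree = tree, beta = beta, sigmaResid = sigmaResid, trueTau = trueTau)
}

## Default feeding design: the experiment's seven plants, 10-20 females per
## (species, plant) cell, plant main effects on survival and weight gain,
## no mode effect and no interaction unless the caller sets them.
.defaultTrialDesign <- function(populations) {
  plants <- c("lilac", "chamise", "oak", "manzanita", "douglas_fir",
              "white_fir", "redwood")
  modes <- c("sexual", "asexual")
  sp <- vapply(modes, function(m) {
    hit <- populations$species_id[populations$reproductive_mode == m]
    if (length(hit)) hit[1] else paste0("sp_", m)
  }, character(1))
  plantLogit <- seq(-1.5, 1.5, length.out = length(plants))
  logits <- rbind(sexual = 0.5 + plantLogit, asexual = 0.5 + plantLogit)
  colnames(logits) <- plants
  gainPlant <- seq(0.005, 0.035, length.out = length(plants))
  gains <- rbind(sexual = gainPlant, asexual = gainPlant)
  colnames(gains) <- plants
  list(plants = plants, nPerCell = c(10L, 20L), logits = logits,
       gainMeans = gains, sigma = 0.01, gainFloor = -0.05, species = sp)
}

## Dirichlet draw via normalized gammas (used for overdispersed sampling).
.rdirichlet <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha)
  if (sum(g) <= 0) {
    i <- sample.int(length(alpha), 1, prob = alpha)
    g[i] <- 1
  }
  g / sum(g)
}

#' Generate an occurrence table from a scenario
#'
#' Samples each population's counts over the scenario's plant list:
#' `counts ~ Multinomial(N, pi)` (or Dirichlet-multinomial when the
#' scenario's `theta` is finite: `p ~ Dirichlet(theta * pi)` per
#' population, then multinomial). Zero-count rows are emitted so that the
#' location's full plant list is recorded. Deterministic given the
#' scenario's seed.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param population optional subset of population ids.
#' @return An [OccurrenceTable-class].
#' @export
genOccurrences <- function(scenario, population = NULL) {
  stopifnot(is(scenario, "SyntheticScenario"))
  pops <- scenario@populations
  if (!is.null(population)) {
    pops <- pops[pops$population_id %in% population, ]
  }
  if (!nrow(pops)) stop("no populations selected", call. = FALSE)
  rows <- lapply(seq_len(nrow(pops)), function(i) {
    pop <- pops$population_id[i]
    N <- scenario@N[[pop]]
    if (is.na(N) || N == 0L) {
      stop(sprintf("population '%s' has N = 0", pop), call. = FALSE)
    }
    pi <- scenario@compositions[[pop]]
    counts <- .withSeed(.childSeed(scenario@seed, paste0("occ:", pop)), {
      p <- if (is.finite(scenario@theta)) {
        .rdirichlet(scenario@theta * pi + 1e-12)
      } else pi
      drop(rmultinom(1, size = N, prob = p))
    })
    data.frame(species_id = pops$species_id[i],
               location_id = pops$location_id[i],
               population_id = pop,
               plant_taxon = scenario@plants,
               count = as.integer(counts))
  })
  OccurrenceTable(do.call(rbind, rows))
}

#' Frozen-niche-variation / general-purpose-genotype pair scenarios
#'
#' Builds a two-population scenario (one sexual, one asexual, same
#' location) from a base sexual composition:
#' \describe{
#'   \item{FNV}{the asexual composition is the sexual one restricted to a
#'     random subset of its host plants (renormalized; zeros elsewhere),
#'     giving a strictly narrower true niche when the subset is proper.}
#'   \item{GPG}{the asexual composition is flattened toward the uniform
#'     distribution, `(1 - flatten) * pi + flatten / n`, giving a broader
#'     true niche when `flatten > 0` and the base is non-uniform.}
#' }
#' Both true Tau values (over the full plant list) are stored in the
#' scenario.
#'
#' @param preset `"FNV"` or `"GPG"`.
#' @param piSexual base sexual composition (>= 3 plants with positive
#'   mass); default `c(0.4, 0.3, 0.2, 0.1)`.
#' @param N individuals per population (default 500).
#' @param seed top-level seed.
#' @param subsetSize FNV: size of the retained host subset (default 2;
#'   must be >= 2; equal to the full support leaves the composition
#'   unchanged).
#' @param flatten GPG: mixing weight toward uniform in \[0, 1\] (default
#'   0.5; 0 leaves the composition unchanged).
#' @param ... further arguments to [syntheticScenario()].
#' @return A [SyntheticScenario-class] with populations `pop_sexual`,
#'   `pop_asexual`.
#' @export
genPairScenario <- function(preset = c("FNV", "GPG"),
                            piSexual = c(0.4, 0.3, 0.2, 0.1), N = 500,
                            seed = 1, subsetSize = 2, flatten = 0.5, ...) {
  preset <- match.arg(preset)
  piSexual <- piSexual / sum(piSexual)
  support <- which(piSexual > 0)
  if (length(support) < 3L) {
    stop("base composition needs at least 3 plants with positive mass",
         call. = FALSE)
  }
  if (preset == "FNV") {
    if (subsetSize < 2L) {
      stop("FNV subset must keep at least 2 plants (tau undefined otherwise)",
           call. = FALSE)
    }
    subsetSize <- min(subsetSize, length(support))
    keep <- .withSeed(.childSeed(seed, "fnv-subset"),
                      sort(sample(support, subsetSize)))
    piAsex <- numeric(length(piSexual))
    piAsex[keep] <- piSexual[keep] / sum(piSexual[keep])
  } else {
    if (flatten < 0 || flatten > 1) stop("flatten must be in [0, 1]",
                                         call. = FALSE)
    piAsex <- (1 - flatten) * piSexual + flatten / length(piSexual)
  }
  syntheticScenario(
    compositions = list(pop_sexual = piSexual, pop_asexual = piAsex),
    populations = data.frame(
      population_id = c("pop_sexual", "pop_asexual"),
      species_id = c("sp_sexual", "sp_asexual"),
      location_id = "L1",
      reproductive_mode = c("sexual", "asexual")),
    N = N, seed = seed, preset = preset, ...)
}

## inverse-CDF sampling from a normal truncated below at `floor`
.rtnorm <- function(n, mean, sd, floor) {
  lo <- pnorm(floor, mean, sd)
  u <- runif(n, lo, 1)
  qnorm(pmin(u, 1 - 1e-15), mean, sd)
}

#' Generate feeding trials from a scenario
#'
#' For every (mode, plant) cell of the scenario's trial design, draws the
#' cell size (uniform over the design's `nPerCell` range), survival as
#' Bernoulli with probability `plogis(logit)` from the design's logit
#' table, and survivor weight gain from a normal truncated below at the
#' design's gain floor. Deterministic given the scenario's seed.
#'
#' @param scenario a [SyntheticScenario-class] with a `trialDesign`.
#' @return A [FeedingTrialTable-class].
#' @export
genFeedingTrials <- function(scenario) {
  stopifnot(is(scenario, "SyntheticScenario"))
  td <- scenario@trialDesign
  if (!length(td)) stop("scenario has no trial design", call. = FALSE)
  if (td$sigma <= 0) stop("trial sigma must be > 0", call. = FALSE)
  modes <- rownames(td$logits)
  plants <- colnames(td$logits)
  rows <- .withSeed(.childSeed(scenario@seed, "trials"), {
    out <- list()
    for (m in modes) {
      for (pl in plants) {
        nCell <- if (length(td$nPerCell) == 2L) {
          sample(td$nPerCell[1]:td$nPerCell[2], 1)
        } else as.integer(td$nPerCell)
        pSurv <- plogis(td$logits[m, pl])
        survived <- runif(nCell) < pSurv
        initial <- rlnorm(nCell, meanlog = log(0.045), sdlog = 0.1)
        gain <- rep(NA_real_, nCell)
        if (any(survived)) {
          gain[survived] <- .rtnorm(sum(survived), td$gainMeans[m, pl],
                                    td$sigma, td$gainFloor)
        }
        out[[paste(m, pl)]] <- data.frame(
          species_id = td$species[[m]],
          reproductive_mode = m,
          population_id = paste0("exp_", td$species[[m]]),
          plant_treatment = pl,
          survived = survived,
          initial_mass = round(initial, 5),
          final_mass = ifelse(survived, round(initial + gain, 5), NA_real_),
          duration_days = 10L)
      }
    }
    do.call(rbind, out)
  })
  FeedingTrialTable(rows, plants = plants)
}

#' Generate colour-morph counts from a scenario
#'
#' Per population, morph counts are a multinomial draw of the scenario's
#' `morphN` individuals from the species' morph frequency vector.
#'
#' @param scenario a [SyntheticScenario-class].
#' @return A [MorphTable-class].
#' @export
genMorphCounts <- function(scenario) {
  stopifnot(is(scenario, "SyntheticScenario"))
  pops <- scenario@populations
  rows <- lapply(seq_len(nrow(pops)), function(i) {
    sp <- pops$species_id[i]
    f <- scenario@morphFreqs[[sp]]
    if (is.null(f)) {
      stop(sprintf("no morph frequencies for species '%s'", sp),
           call. = FALSE)
    }
    counts <- .withSeed(
      .childSeed(scenario@seed, paste0("morph:", pops$population_id[i])),
      drop(rmultinom(1, size = scenario@morphN, prob = f)))
    data.frame(species_id = sp, population_id = pops$population_id[i],
               morph_id = names(f), count = as.integer(counts))
  })
  MorphTable(do.call(rbind, rows), morphs = scenario@morphs)
}

#' Simulate a correlated trait pair under Brownian motion
#'
#' Draws `x ~ MVN(0, V)` with `V` the tree's Brownian covariance, and
#' `y = beta * x + e` with `e ~ MVN(0, sigmaResid^2 * V)`, so that a PGLS
#' of `y` on `x` under the same tree is correctly specified with true slope
#' `beta`.
#'
#' @param tree a `phylo` with branch lengths (positive root-to-tip depths).
#' @param beta true slope.
#' @param sigmaResid residual scale (>= 0; 0 gives an exact linear
#'   relation).
#' @param seed RNG seed.
#' @return data.frame: `species`, `x`, `y`.
#' @export
genBrownianTraits <- function(tree, beta = 1, sigmaResid = 0.5, seed = 1) {
  V <- brownianVCV(tree)
  if (any(diag(V) <= 0)) {
    stop("tree has zero-depth tips: Brownian covariance is degenerate",
         call. = FALSE)
  }
  if (sigmaResid < 0) stop("sigmaResid must be >= 0", call. = FALSE)
  L <- t(chol(V))
  n <- nrow(V)
  .withSeed(seed, {
    x <- drop(L %*% rnorm(n))
    e <- if (sigmaResid > 0) drop(L %*% rnorm(n)) * sigmaResid else 0
    data.frame(species = rownames(V), x = x, y = beta * x + e)
  })
}

#' Write a scenario's generated inputs to a directory
#'
#' Generates the occurrence, morph and feeding-trial tables (and the tree,
#' if the scenario carries one), writes them as TSV/Newick next to a
#' `truth.json` sidecar holding the scenario's ground truth (true Tau per
#' population, preset, seed, true slope).
#'
#' @param scenario a [SyntheticScenario-class].
#' @param dir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
simulateScenario <- function(scenario, dir) {
  stopifnot(is(scenario, "SyntheticScenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(occurrence = file.path(dir, "occurrence.tsv"),
             morphs = file.path(dir, "morphs.tsv"),
             trials = file.path(dir, "trials.tsv"),
             truth = file.path(dir, "truth.json"))
  writeOccurrenceTable(genOccurrences(scenario), paths[["occurrence"]])
  writeMorphTable(genMorphCounts(scenario), paths[["morphs"]])
  writeFeedingTrials(genFeedingTrials(scenario), paths[["trials"]])
  if (!is.null(scenario@tree)) {
    paths[["tree"]] <- file.path(dir, "tree.nwk")
    writeSpeciesTree(scenario@tree, paths[["tree"]])
  }
  truth <- list(preset = scenario@preset, seed = scenario@seed,
                true_tau = as.list(scenario@trueTau),
                beta = scenario@beta, sigma_resid = scenario@sigmaResid)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  paths
}
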