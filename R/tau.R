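## The inversed Tau specialization index.
##
## For a profile x_1..x_n over the n host plants available at a location
## (frequencies of occurrence for realized niches; survival or weight gain
## for fundamental niches):
##
##   tau_inv = 1 - sum_i (1 - x_i / max(x)) / (n - 1)
##
## 0 = pure specialist (all use on one plant), 1 = complete generalist
## (equal use of every plant). The index is invariant to rescaling x and to
## the order of plants, and is undefined for n < 2 (denominator vanishes).

## Fast scalar kernel; assumes x already validated (finite, nonnegative,
## max > 0). Returns NA for n < 2.
.tauInv <- function(x) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m <- max(x)
  1 - (n - sum(x) / m) / (n - 1)
}

## Column-wise kernel for bootstrap/simulation loops: X is an n x B matrix
## of profiles, every column with a positive maximum.
.tauInvCols <- function(X) {
  n <- nrow(X)
  m <- X[cbind(max.col(t(X), ties.method = "first"), seq_len(ncol(X)))]
  1 - (n - colSums(X) / m) / (n - 1)
}

#' Inversed Tau specialization index
#'
#' Computes the inversed Tau niche-breadth index of a host-use profile:
#' \deqn{\tau_{inv} = 1 - \frac{\sum_{i=1}^n (1 - x_i/\max_j x_j)}{n - 1}}
#' where \eqn{n} is the number of host plants available at the location and
#' \eqn{x_i} the frequency of occurrence on (or performance on) plant
#' \eqn{i}. The index ranges from 0 (pure specialist: a single plant used)
#' to 1 (complete generalist: all plants used equally), counting unused
#' available plants against breadth.
#'
#' @param x nonnegative numeric profile (counts, frequencies, survival
#'   proportions or mean weight gains), optionally named by plant. Zeros are
#'   meaningful (available but unused plants); at least one value must be
#'   positive.
#' @param basis what the profile measures: `"occurrence"`, `"survival"` or
#'   `"weight_gain"`.
#' @return A [TauResult-class]; `tau(x)` is NA (undefined) when fewer than
#'   two plants are in the profile.
#' @examples
#' tau(tauInversed(c(10, 0, 0, 0)))  # 0: pure specialist
#' tau(tauInversed(c(5, 5, 5, 5)))   # 1: complete generalist
#' tau(tauInversed(c(8, 4, 0)))      # 0.25
#' @export
tauInversed <- function(x, basis = c("occurrence", "survival", "weight_gain")) {
  basis <- match.arg(basis)
  if (!is.numeric(x) || length(x) < 1L) {
    stop("profile must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("profile values must be finite and nonnegative", call. = FALSE)
  }
  if (max(x) <= 0) {
    stop("profile has no positive value: tau is undefined for an empty niche",
         call. = FALSE)
  }
  new("TauResult", tau = .tauInv(x), basis = basis,
      nPlants = length(x), profile = x)
}

## Resolve the availability plant set per location: an explicit per-location
## list wins; otherwise the union of plants recorded with any individual
## from any population at that location (observed-use union).
.availabilityByLocation <- function(df, availability = NULL) {
  locs <- unique(df$location_id)
  out <- lapply(locs, function(loc) {
    if (!is.null(availability)) {
      if (is.null(availability[[loc]])) {
        stop(sprintf("no availability list supplied for location '%s'", loc),
             call. = FALSE)
      }
      as.character(availability[[loc]])
    } else {
      sub <- df[df$location_id == loc, ]
      sort(unique(sub$plant_taxon[sub$count > 0]))
    }
  })
  names(out) <- locs
  out
}

## Per-population count profiles over the location availability sets.
## Returns a list keyed by population id of named count vectors (zeros for
## available-but-unused plants), with the population metadata as an
## attribute.
.populationProfiles <- function(occ, availability = NULL) {
  df <- records(occ)
  if (!nrow(df)) stop("occurrence table is empty", call. = FALSE)
  avail <- .availabilityByLocation(df, availability)
  pops <- unique(df[, c("population_id", "species_id", "location_id")])
  out <- lapply(seq_len(nrow(pops)), function(i) {
    pop <- pops$population_id[i]
    loc <- pops$location_id[i]
    plants <- avail[[loc]]
    sub <- df[df$population_id == pop & df$species_id == pops$species_id[i], ]
    extra <- setdiff(sub$plant_taxon[sub$count > 0], plants)
    if (length(extra)) {
      stop(sprintf(
        "population '%s' recorded on plant '%s' absent from the availability list for location '%s'",
        pop, extra[1], loc), call. = FALSE)
    }
    x <- setNames(numeric(length(plants)), plants)
    hit <- sub$plant_taxon %in% plants
    x[sub$plant_taxon[hit]] <- sub$count[hit]
    x
  })
  names(out) <- pops$population_id
  attr(out, "meta") <- pops
  out
}

#' Realized niche breadth per population
#'
#' Builds, for each population, its host-use profile over the plants
#' available at its location and evaluates the inversed Tau index. By
#' default a location's available plants are those on which any individual
#' (from any population) was recorded there; an explicit per-location plant
#' list (e.g. surveyed availability) overrides this. Plants available but
#' unused by a population enter its profile as zeros. Populations whose
#' location offers a single plant get an NA (undefined) Tau.
#'
#' @param occ an [OccurrenceTable-class].
#' @param availability optional named list, `location_id` -> character vector
#'   of available plants.
#' @return data.frame with one row per population: `population_id`,
#'   `species_id`, `location_id`, `n_plants`, `n_individuals`, `tau`.
#' @export
populationRealizedTau <- function(occ, availability = NULL) {
  stopifnot(is(occ, "OccurrenceTable"))
  profiles <- .populationProfiles(occ, availability)
  pops <- attr(profiles, "meta")
  res <- lapply(seq_len(nrow(pops)), function(i) {
    x <- profiles[[pops$population_id[i]]]
    data.frame(population_id = pops$population_id[i],
               species_id = pops$species_id[i],
               location_id = pops$location_id[i], n_plants = length(x),
               n_individuals = as.integer(sum(x)),
               tau = if (length(x) >= 2L && max(x) > 0) .tauInv(x)
                     else NA_real_)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Realized niche breadth per species (genus level)
#'
#' Pools a species' occurrence counts across its populations at the genus
#' level and reports (i) the number of distinct host-plant genera the
#' species uses, and (ii) an auxiliary inversed Tau on the genus-pooled
#' frequencies, over the genera observed (by any species) at the locations
#' the focal species occupies.
#'
#' @param occ an [OccurrenceTable-class].
#' @param taxonomy named character vector mapping `plant_taxon` to genus. By
#'   default the genus is the first whitespace-delimited token of the taxon
#'   label (binomial convention). Every plant with a positive count must be
#'   mappable.
#' @return data.frame with one row per species: `species_id`, `n_genera`,
#'   `n_individuals`, `tau_pooled`, `n_genera_available`.
#' @export
speciesRealizedBreadth <- function(occ, taxonomy = NULL) {
  stopifnot(is(occ, "OccurrenceTable"))
  df <- records(occ)
  if (!nrow(df)) stop("occurrence table is empty", call. = FALSE)
  toGenus <- function(plants) {
    if (is.null(taxonomy)) {
      vapply(strsplit(plants, "\\s+"), `[[`, character(1), 1L)
    } else {
      unmapped <- setdiff(plants, names(taxonomy))
      if (length(unmapped)) {
        stop(sprintf("plant taxon '%s' has no genus mapping", unmapped[1]),
             call. = FALSE)
      }
      unname(taxonomy[plants])
    }
  }
  df$genus <- toGenus(df$plant_taxon)
  species <- unique(df$species_id)
  res <- lapply(species, function(sp) {
    spdf <- df[df$species_id == sp, ]
    locs <- unique(spdf$location_id)
    there <- df[df$location_id %in% locs & df$count > 0, ]
    genera <- sort(unique(there$genus))
    x <- setNames(numeric(length(genera)), genera)
    pooled <- tapply(spdf$count, spdf$genus, sum)
    x[names(pooled)] <- pooled
    data.frame(species_id = sp,
               n_genera = as.integer(sum(x > 0)),
               n_individuals = as.integer(sum(x)),
               tau_pooled = if (length(x) >= 2L && max(x) > 0) .tauInv(x)
                            else NA_real_,
               n_genera_available = length(genera))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pooled occurrence counts for one species
#'
#' Convenience: the species' counts summed per plant over the plants
#' available at the locations it occupies (zeros kept), suitable for
#' [tauInversed()], [bootstrapTauCI()] and [pairTauTest()].
#'
#' @param occ an [OccurrenceTable-class].
#' @param species a species id present in the table.
#' @param availability optional per-location plant list (see
#'   [populationRealizedTau()]).
#' @return named numeric vector of counts per plant.
#' @export
speciesOccurrenceCounts <- function(occ, species, availability = NULL) {
  stopifnot(is(occ, "OccurrenceTable"))
  df <- records(occ)
  spdf <- df[df$species_id == species, ]
  if (!nrow(spdf)) stop(sprintf("species '%s' not in table", species),
                        call. = FALSE)
  locs <- unique(spdf$location_id)
  avail <- .availabilityByLocation(df[df$location_id %in% locs, ],
                                   availability)
  plants <- sort(unique(unlist(avail)))
  x <- setNames(numeric(length(plants)), plants)
  pooled <- tapply(spdf$count, spdf$plant_taxon, sum)
  pooled <- pooled[names(pooled) %in% plants]
  x[names(pooled)] <- pooled
  x
}
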