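## Core S4 containers. Tables carry a validated data.frame in @records plus,
## where the type needs one, a closed registry of admissible labels.

setOldClass("phylo")

#' OccurrenceTable: host-plant occurrence counts
#'
#' Individual counts per (species, location, population, host-plant taxon),
#' the basis of realized feeding niches. Explicit zero-count rows are
#' permitted and record surveyed plant availability at a location.
#'
#' Invariants enforced by the validity method: counts are nonnegative
#' integers; (species_id, population_id, plant_taxon) keys are unique; every
#' population maps to exactly one location.
#'
#' @slot records data.frame with columns `species_id`, `location_id`,
#'   `population_id`, `plant_taxon`, `count`.
#' @aliases OccurrenceTable
#' @export
setClass("OccurrenceTable", representation(records = "data.frame"))

.OCC_COLS <- c("species_id", "location_id", "population_id", "plant_taxon",
               "count")

setValidity("OccurrenceTable", function(object) {
  df <- object@records
  if (!identical(names(df), .OCC_COLS)) {
    return(sprintf("columns must be exactly [%s]",
                   paste(.OCC_COLS, collapse = ", ")))
  }
  if (!is.integer(df$count)) return("count must be integer")
  if (any(df$count < 0)) return("count must be nonnegative")
  keys <- paste(df$species_id, df$population_id, df$plant_taxon, sep = "\r")
  if (anyDuplicated(keys)) {
    return("duplicate (species_id, population_id, plant_taxon) key")
  }
  locPerPop <- tapply(df$location_id, df$population_id,
                      function(l) length(unique(l)))
  if (any(locPerPop > 1)) {
    return(sprintf("population '%s' maps to more than one location",
                   names(locPerPop)[which(locPerPop > 1)[1]]))
  }
  TRUE
})

#' @param records data.frame of occurrence records (see slot documentation).
#' @rdname OccurrenceTable-class
#' @export
OccurrenceTable <- function(records) {
  records <- .checkColumns(as.data.frame(records), .OCC_COLS, "OccurrenceTable")
  records$count <- .checkCounts(records$count, "OccurrenceTable")
  for (col in .OCC_COLS[1:4]) records[[col]] <- as.character(records[[col]])
  keys <- paste(records$species_id, records$population_id,
                records$plant_taxon, sep = "\r")
  .checkNoDuplicates(keys, "OccurrenceTable")
  rownames(records) <- NULL
  new("OccurrenceTable", records = records)
}

#' MorphTable: colour-morph counts
#'
#' Counts of discrete cryptic colour morphs per (species, population). The
#' morph registry is the closed set of admissible morph labels; by default it
#' is taken from the data.
#'
#' @slot records data.frame with columns `species_id`, `population_id`,
#'   `morph_id`, `count`.
#' @slot morphs character registry of admissible morph labels.
#' @aliases MorphTable
#' @export
setClass("MorphTable",
         representation(records = "data.frame", morphs = "character"))

.MORPH_COLS <- c("species_id", "population_id", "morph_id", "count")

setValidity("MorphTable", function(object) {
  df <- object@records
  if (!identical(names(df), .MORPH_COLS)) {
    return(sprintf("columns must be exactly [%s]",
                   paste(.MORPH_COLS, collapse = ", ")))
  }
  if (!is.integer(df$count) || any(df$count < 0)) {
    return("count must be a nonnegative integer")
  }
  keys <- paste(df$species_id, df$population_id, df$morph_id, sep = "\r")
  if (anyDuplicated(keys)) return("morph_id duplicated within (species, population)")
  unknown <- setdiff(df$morph_id, object@morphs)
  if (length(unknown)) {
    return(sprintf("morph_id '%s' not in the declared morph registry",
                   unknown[1]))
  }
  TRUE
})

#' @param records data.frame of morph-count records.
#' @param morphs optional character registry; defaults to the morph ids
#'   observed in `records`.
#' @rdname MorphTable-class
#' @export
MorphTable <- function(records, morphs = NULL) {
  records <- .checkColumns(as.data.frame(records), .MORPH_COLS, "MorphTable")
  records$count <- .checkCounts(records$count, "MorphTable")
  for (col in .MORPH_COLS[1:3]) records[[col]] <- as.character(records[[col]])
  keys <- paste(records$species_id, records$population_id, records$morph_id,
                sep = "\r")
  .checkNoDuplicates(keys, "MorphTable")
  if (is.null(morphs)) morphs <- sort(unique(records$morph_id))
  rownames(records) <- NULL
  new("MorphTable", records = records, morphs = as.character(morphs))
}

#' FeedingTrialTable: individual-level feeding-trial records
#'
#' One record per experimental female: plant treatment, survival after the
#' trial period, and initial/final mass (grams). Final mass is present if
#' and only if the insect survived; weight gain is `final_mass -
#' initial_mass` for survivors.
#'
#' @slot records data.frame with columns `species_id`, `reproductive_mode`
#'   (`"sexual"` or `"asexual"`), `population_id`, `plant_treatment`,
#'   `survived` (logical), `initial_mass`, `final_mass` (NA unless survived),
#'   `duration_days`.
#' @slot plants character registry: the experiment's declared plant list.
#' @aliases FeedingTrialTable
#' @export
setClass("FeedingTrialTable",
         representation(records = "data.frame", plants = "character"))

.TRIAL_COLS <- c("species_id", "reproductive_mode", "population_id",
                 "plant_treatment", "survived", "initial_mass", "final_mass",
                 "duration_days")
.MODES <- c("sexual", "asexual")

setValidity("FeedingTrialTable", function(object) {
  df <- object@records
  if (!identical(names(df), .TRIAL_COLS)) {
    return(sprintf("columns must be exactly [%s]",
                   paste(.TRIAL_COLS, collapse = ", ")))
  }
  if (!all(df$reproductive_mode %in% .MODES)) {
    bad <- setdiff(unique(df$reproductive_mode), .MODES)
    return(sprintf("reproductive_mode '%s' invalid; allowed values: %s",
                   bad[1], paste(.MODES, collapse = ", ")))
  }
  if (!is.logical(df$survived)) return("survived must be logical")
  if (any(df$survived & is.na(df$final_mass))) {
    return("final_mass missing for a surviving insect")
  }
  if (any(!df$survived & !is.na(df$final_mass))) {
    return("final_mass present for a dead insect")
  }
  if (any(!is.finite(df$duration_days) | df$duration_days <= 0)) {
    return("duration_days must be a positive integer")
  }
  unknown <- setdiff(df$plant_treatment, object@plants)
  if (length(unknown)) {
    return(sprintf("plant_treatment '%s' not in the declared plant list",
                   unknown[1]))
  }
  TRUE
})

#' @param records data.frame of trial records.
#' @param plants optional declared plant list; defaults to the treatments
#'   observed in `records`.
#' @rdname FeedingTrialTable-class
#' @export
FeedingTrialTable <- function(records, plants = NULL) {
  records <- .checkColumns(as.data.frame(records), .TRIAL_COLS,
                           "FeedingTrialTable")
  for (col in c("species_id", "reproductive_mode", "population_id",
                "plant_treatment")) {
    records[[col]] <- as.character(records[[col]])
  }
  bad <- setdiff(unique(records$reproductive_mode), .MODES)
  if (length(bad)) {
    stop(sprintf(
      "FeedingTrialTable: reproductive_mode '%s' invalid; allowed values: %s",
      bad[1], paste(.MODES, collapse = ", ")), call. = FALSE)
  }
  if (is.character(records$survived)) {
    records$survived <- tolower(records$survived) %in% c("true", "t", "1", "yes")
  }
  records$survived <- as.logical(records$survived)
  records$initial_mass <- .parseMass(records$initial_mass, "FeedingTrialTable")
  records$final_mass <- .parseMass(records$final_mass, "FeedingTrialTable")
  records$duration_days <- .checkCounts(records$duration_days,
                                        "FeedingTrialTable duration_days")
  if (is.null(plants)) plants <- sort(unique(records$plant_treatment))
  rownames(records) <- NULL
  new("FeedingTrialTable", records = records, plants = as.character(plants))
}

## ---- result objects --------------------------------------------------------

#' TauResult: an inversed Tau niche-breadth estimate
#'
#' The inversed Tau specialization index ranges from 0 (pure specialist) to 1
#' (complete generalist). It is undefined when fewer than two plants are
#' available (`tau` is NA and `defined` is FALSE).
#'
#' @slot tau numeric in \[0, 1\], or NA when undefined.
#' @slot basis one of `"occurrence"`, `"survival"`, `"weight_gain"`.
#' @slot nPlants integer, the number of plants n in the profile.
#' @slot profile the named frequency-or-performance vector the index was
#'   computed from.
#' @aliases TauResult
#' @export
setClass("TauResult",
         representation(tau = "numeric", basis = "character",
                        nPlants = "integer", profile = "numeric"))

setValidity("TauResult", function(object) {
  if (length(object@tau) != 1L) return("tau must be a scalar")
  if (!is.na(object@tau) && (object@tau < -1e-12 || object@tau > 1 + 1e-12)) {
    return("tau must lie in [0, 1]")
  }
  if (object@nPlants < 2L && !is.na(object@tau)) {
    return("tau must be NA (undefined) when fewer than 2 plants are available")
  }
  TRUE
})

#' MorphDiversity: Gini-Simpson colour-polymorphism diversity
#'
#' `simpson` is \eqn{1 - \sum p_i^2} over morph relative frequencies: 0 for a
#' monomorphic population, approaching 1 for many equally frequent morphs.
#'
#' @slot simpson numeric in \[0, 1).
#' @slot p named numeric morph relative frequencies (sum to 1).
#' @slot kMorphs integer count of morphs with positive frequency.
#' @aliases MorphDiversity
#' @export
setClass("MorphDiversity",
         representation(simpson = "numeric", p = "numeric",
                        kMorphs = "integer"))

setValidity("MorphDiversity", function(object) {
  if (abs(sum(object@p) - 1) > 1e-12) return("morph frequencies must sum to 1")
  if (object@simpson < 0 || object@simpson >= 1) {
    return("simpson must lie in [0, 1)")
  }
  if ((object@simpson == 0) != (object@kMorphs == 1L)) {
    return("simpson is 0 iff exactly one morph is present")
  }
  TRUE
})

#' BootstrapCI: percentile bootstrap interval for a Tau estimate
#'
#' @slot estimate point estimate on the full data.
#' @slot lower,upper percentile interval bounds (lower <= upper).
#' @slot level confidence level (default 0.95).
#' @slot B number of bootstrap resamples.
#' @slot seed RNG seed used, for reproducibility.
#' @slot basis Tau basis the interval refers to.
#' @aliases BootstrapCI
#' @export
setClass("BootstrapCI",
         representation(estimate = "numeric", lower = "numeric",
                        upper = "numeric", level = "numeric", B = "integer",
                        seed = "integer", basis = "character"))

setValidity("BootstrapCI", function(object) {
  if (object@lower > object@upper + 1e-12) return("lower must be <= upper")
  if (object@level <= 0 || object@level >= 1) return("level must be in (0,1)")
  TRUE
})

#' PairTauComparison: sexual vs. asexual Tau contrast for one species pair
#'
#' @slot labels names of the two members (first minus second defines
#'   `difference`; pass the sexual member first for sexual - asexual).
#' @slot tauValues the two Tau point estimates.
#' @slot ci 2 x 2 matrix of bootstrap CI bounds (rows = members).
#' @slot difference tauValues[1] - tauValues[2].
#' @slot pValue two-sided permutation p-value for |difference|.
#' @slot nPerm number of permutations.
#' @slot alpha significance level.
#' @slot significant pValue < alpha.
#' @slot ciOverlap secondary flag: do the two bootstrap CIs overlap?
#' @aliases PairTauComparison
#' @export
setClass("PairTauComparison",
         representation(labels = "character", tauValues = "numeric",
                        ci = "matrix", difference = "numeric",
                        pValue = "numeric", nPerm = "integer",
                        alpha = "numeric", significant = "logical",
                        ciOverlap = "logical"))

setValidity("PairTauComparison", function(object) {
  if (object@pValue < 0 || object@pValue > 1) return("p-value must be in [0,1]")
  d <- object@tauValues[1] - object@tauValues[2]
  if (!isTRUE(all.equal(unname(d), unname(object@difference), tolerance = 1e-8))) {
    return("difference must equal tauValues[1] - tauValues[2]")
  }
  TRUE
})

#' PGLSFit: phylogenetic generalized least squares fit
#'
#' Simple regression y ~ x under a Brownian-motion error covariance V. The
#' correlation `r` is sign(slope) times the square root of the GLS R-squared
#' (V-inverse-weighted sums of squares about the GLS mean); with an identity
#' covariance the fit reduces exactly to ordinary least squares and `r` to
#' Pearson's r.
#'
#' @slot coefficients named numeric: `(Intercept)`, `slope`.
#' @slot se standard errors of the coefficients.
#' @slot sigma2 residual variance estimate (per unit branch length).
#' @slot r GLS correlation, in \[-1, 1\].
#' @slot tStat t statistic for the slope.
#' @slot pValue two-sided p-value on n - 2 degrees of freedom.
#' @slot df residual degrees of freedom.
#' @slot n number of species.
#' @aliases PGLSFit
#' @export
setClass("PGLSFit",
         representation(coefficients = "numeric", se = "numeric",
                        sigma2 = "numeric", r = "numeric", tStat = "numeric",
                        pValue = "numeric", df = "integer", n = "integer"))

setValidity("PGLSFit", function(object) {
  if (abs(object@r) > 1 + 1e-8) return("|r| must be <= 1")
  if (!is.na(object@pValue) && (object@pValue <= 0 || object@pValue > 1)) {
    return("p-value must be in (0, 1]")
  }
  TRUE
})

#' InteractionTestResult: term tests from a feeding-experiment model
#'
#' Sequential (Type I) per-term tests from a binomial survival GLM (deviance
#' chi-square) or a weight-gain ANOVA (F), in the order reproductive mode,
#' feeding treatment, interaction.
#'
#' @slot response `"survival"` or `"weight_gain"`.
#' @slot terms data.frame with columns `term`, `statistic`, `df`, `df2`
#'   (residual df, NA for chi-square tests), `p`.
#' @slot excluded plants absent from one reproductive mode and hence not
#'   contributing estimable interaction contrasts.
#' @slot notes character vector of fitting warnings (e.g. complete
#'   separation).
#' @aliases InteractionTestResult
#' @export
setClass("InteractionTestResult",
         representation(response = "character", terms = "data.frame",
                        excluded = "character", notes = "character"))

## ---- accessors and show ----------------------------------------------------

#' Extract the record data.frame from a table object
#'
#' @param x an OccurrenceTable, MorphTable or FeedingTrialTable.
#' @return The underlying data.frame of validated records.
#' @name records
NULL

#' @rdname records
#' @export
setMethod("records", "OccurrenceTable", function(x) x@records)
#' @rdname records
#' @export
setMethod("records", "MorphTable", function(x) x@records)
#' @rdname records
#' @export
setMethod("records", "FeedingTrialTable", function(x) x@records)

#' Extract the inversed Tau value
#'
#' @param x a TauResult or BootstrapCI.
#' @return Numeric Tau value (NA when undefined).
#' @name tau
NULL

#' @rdname tau
#' @export
setMethod("tau", "TauResult", function(x) x@tau)
#' @rdname tau
#' @export
setMethod("tau", "BootstrapCI", function(x) x@estimate)

#' Extract the Gini-Simpson diversity value
#'
#' @param x a MorphDiversity object.
#' @return Numeric diversity in \[0, 1).
#' @name simpson
NULL

#' @rdname simpson
#' @export
setMethod("simpson", "MorphDiversity", function(x) x@simpson)

#' @describeIn PGLSFit-class regression coefficients (intercept, slope).
#' @param object a PGLSFit.
#' @export
setMethod("coef", "PGLSFit", function(object) object@coefficients)

#' @describeIn BootstrapCI-class the percentile interval as a length-2 vector.
#' @param object a BootstrapCI.
#' @param parm,level ignored (the level is fixed at construction).
#' @param ... ignored.
#' @export
setMethod("confint", "BootstrapCI", function(object, parm, level, ...) {
  c(lower = object@lower, upper = object@upper)
})

setMethod("show", "OccurrenceTable", function(object) {
  df <- object@records
  cat(sprintf("OccurrenceTable: %d records, %d species, %d populations, %d plant taxa, %d individuals\n",
              nrow(df), length(unique(df$species_id)),
              length(unique(df$population_id)),
              length(unique(df$plant_taxon)), sum(df$count)))
})

setMethod("show", "MorphTable", function(object) {
  df <- object@records
  cat(sprintf("MorphTable: %d records, %d species, registry of %d morphs\n",
              nrow(df), length(unique(df$species_id)), length(object@morphs)))
})

setMethod("show", "FeedingTrialTable", function(object) {
  df <- object@records
  cat(sprintf("FeedingTrialTable: %d trials, %d species, %d plants, survival %.2f\n",
              nrow(df), length(unique(df$species_id)), length(object@plants),
              mean(df$survived)))
})

setMethod("show", "TauResult", function(object) {
  if (is.na(object@tau)) {
    cat(sprintf("TauResult (%s): undefined (n_plants = %d < 2)\n",
                object@basis, object@nPlants))
  } else {
    cat(sprintf("TauResult (%s): tau = %.4f over %d plants\n",
                object@basis, object@tau, object@nPlants))
  }
})

setMethod("show", "MorphDiversity", function(object) {
  cat(sprintf("MorphDiversity: Gini-Simpson = %.4f over %d morphs\n",
              object@simpson, object@kMorphs))
})

setMethod("show", "BootstrapCI", function(object) {
  cat(sprintf("BootstrapCI (%s): %.4f [%.4f, %.4f] (%.0f%%, B = %d)\n",
              object@basis, object@estimate, object@lower, object@upper,
              100 * object@level, object@B))
})

setMethod("show", "PairTauComparison", function(object) {
  cat(sprintf("PairTauComparison: %s tau = %.4f vs %s tau = %.4f\n",
              object@labels[1], object@tauValues[1], object@labels[2],
              object@tauValues[2]))
  cat(sprintf("  difference = %.4f, permutation p = %.4g (%d permutations)%s\n",
              object@difference, object@pValue, object@nPerm,
              if (object@significant) " *" else ""))
  cat(sprintf("  bootstrap CIs %s\n",
              if (object@ciOverlap) "overlap" else "do not overlap"))
})

setMethod("show", "PGLSFit", function(object) {
  cat(sprintf("PGLSFit: n = %d species\n", object@n))
  cat(sprintf("  intercept = %.4f (se %.4f), slope = %.4f (se %.4f)\n",
              object@coefficients[1], object@se[1], object@coefficients[2],
              object@se[2]))
  cat(sprintf("  r = %.4f, t(%d) = %.3f, p = %.4g\n",
              object@r, object@df, object@tStat, object@pValue))
})

setMethod("show", "InteractionTestResult", function(object) {
  cat(sprintf("InteractionTestResult (%s):\n", object@response))
  print(object@terms, row.names = FALSE)
  if (length(object@excluded)) {
    cat("  plants excluded from the interaction (single-mode):",
        paste(object@excluded, collapse = ", "), "\n")
  }
  if (length(object@notes)) cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})
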