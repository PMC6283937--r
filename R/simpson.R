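## Colour-polymorphism diversity: the Gini-Simpson index 1 - sum(p_i^2),
## the probability that two individuals drawn at random carry different
## colour morphs. Exactly 0 for a monomorphic population; 1 - 1/k for k
## equally frequent morphs. No small-sample correction is applied.

#' Gini-Simpson diversity of colour morphs
#'
#' @param x morph counts: a named nonnegative numeric vector, or a
#'   [MorphTable-class] together with `species` (and optionally
#'   `population`) selecting the slice whose counts are pooled.
#' @param species,population selectors used when `x` is a MorphTable;
#'   omitting `population` pools the species' counts across populations.
#' @return A [MorphDiversity-class].
#' @examples
#' simpson(simpsonDiversity(c(green = 14)))          # 0: monomorphic
#' simpson(simpsonDiversity(c(green = 7, grey = 7))) # 0.5
#' @export
simpsonDiversity <- function(x, species = NULL, population = NULL) {
  if (is(x, "MorphTable")) {
    df <- records(x)
    if (!is.null(species)) df <- df[df$species_id %in% species, ]
    if (!is.null(population)) df <- df[df$population_id %in% population, ]
    if (!nrow(df)) stop("no morph records match the selection", call. = FALSE)
    counts <- tapply(df$count, df$morph_id, sum)
    x <- setNames(as.numeric(counts), names(counts))
  }
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop("morph counts must be finite and nonnegative", call. = FALSE)
  }
  total <- sum(x)
  if (total <= 0) stop("all morph counts are zero", call. = FALSE)
  p <- x / total
  new("MorphDiversity", simpson = 1 - sum(p^2), p = p,
      kMorphs = as.integer(sum(p > 0)))
}

#' Per-population and per-species polymorphism summary
#'
#' @param morphs a [MorphTable-class].
#' @param level `"population"` or `"species"` (species pools counts across
#'   populations).
#' @return data.frame with `species_id`, (`population_id`,) `n_individuals`,
#'   `k_morphs`, `simpson`.
#' @export
polymorphismSummary <- function(morphs, level = c("population", "species")) {
  stopifnot(is(morphs, "MorphTable"))
  level <- match.arg(level)
  df <- records(morphs)
  if (!nrow(df)) stop("morph table is empty", call. = FALSE)
  if (level == "population") {
    groups <- unique(df[, c("species_id", "population_id")])
    res <- lapply(seq_len(nrow(groups)), function(i) {
      sel <- df$species_id == groups$species_id[i] &
        df$population_id == groups$population_id[i]
      d <- simpsonDiversity(morphs, species = groups$species_id[i],
                            population = groups$population_id[i])
      data.frame(species_id = groups$species_id[i],
                 population_id = groups$population_id[i],
                 n_individuals = as.integer(sum(df$count[sel])),
                 k_morphs = d@kMorphs, simpson = d@simpson)
    })
  } else {
    species <- unique(df$species_id)
    res <- lapply(species, function(sp) {
      d <- simpsonDiversity(morphs, species = sp)
      data.frame(species_id = sp,
                 n_individuals = as.integer(sum(df$count[df$species_id == sp])),
                 k_morphs = d@kMorphs, simpson = d@simpson)
    })
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
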