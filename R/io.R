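## Readers and writers for the tabular and tree formats the pipeline travels
## in. CSV or TSV is auto-detected from the header line (tab wins if present);
## writers emit UTF-8 TSV with LF line endings. Trees are Newick via ape,
## with branch lengths required (the Brownian covariance needs them).

#' Read a host-plant occurrence table
#'
#' Expects a delimited file (comma or tab, auto-detected) with header columns
#' `species_id, location_id, population_id, plant_taxon, count`. Counts must
#' be nonnegative integers; `(species_id, population_id, plant_taxon)` keys
#' must be unique. Zero-count rows are allowed and document plant
#' availability at a location.
#'
#' @param source a file path, connection, or character vector of lines.
#' @return An [OccurrenceTable-class].
#' @examples
#' lines <- c("species_id,location_id,population_id,plant_taxon,count",
#'            "Tcri,L1,P1,Ceanothus thyrsiflorus,5",
#'            "Tcri,L1,P1,Adenostoma fasciculatum,0",
#'            "Tcri,L1,P1,Quercus agrifolia,2")
#' occ <- readOccurrenceTable(lines)
#' sum(records(occ)$count)  # 7 individuals
#' @export
readOccurrenceTable <- function(source) {
  df <- .readDelimited(source, "occurrence table")
  OccurrenceTable(.checkColumns(df, .OCC_COLS, "occurrence table"))
}

#' Write an OccurrenceTable as TSV
#' @param x an [OccurrenceTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeOccurrenceTable <- function(x, path) {
  stopifnot(is(x, "OccurrenceTable"))
  .writeDelimited(records(x), path)
}

#' Read a colour-morph count table
#'
#' Columns `species_id, population_id, morph_id, count`. The morph registry
#' defaults to the observed morph ids; pass `morphs` to declare a closed set.
#'
#' @param source file path, connection or lines.
#' @param morphs optional character registry of admissible morphs.
#' @return A [MorphTable-class].
#' @export
readMorphTable <- function(source, morphs = NULL) {
  df <- .readDelimited(source, "morph table")
  MorphTable(.checkColumns(df, .MORPH_COLS, "morph table"), morphs = morphs)
}

#' Write a MorphTable as TSV
#' @param x a [MorphTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMorphTable <- function(x, path) {
  stopifnot(is(x, "MorphTable"))
  .writeDelimited(records(x), path)
}

#' Read feeding-trial records
#'
#' Columns `species_id, reproductive_mode, population_id, plant_treatment,
#' survived, initial_mass, final_mass, duration_days`. `reproductive_mode`
#' must be `sexual` or `asexual`; `final_mass` must be present exactly for
#' survivors (missing values may be encoded as an empty field, `NA` or `-`,
#' and are written back as empty). Masses are grams.
#'
#' @param source file path, connection or lines.
#' @param plants optional declared plant list for the experiment.
#' @return A [FeedingTrialTable-class].
#' @export
readFeedingTrials <- function(source, plants = NULL) {
  df <- .readDelimited(source, "feeding-trial table")
  FeedingTrialTable(.checkColumns(df, .TRIAL_COLS, "feeding-trial table"),
                    plants = plants)
}

#' Write a FeedingTrialTable as TSV
#' @param x a [FeedingTrialTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFeedingTrials <- function(x, path) {
  stopifnot(is(x, "FeedingTrialTable"))
  df <- records(x)
  df$survived <- ifelse(df$survived, "true", "false")
  .writeDelimited(df, path)
}

#' Read a species phylogeny from Newick
#'
#' Parses standard Newick with a terminating semicolon. Branch lengths are
#' required on every edge (the Brownian-motion covariance is built from
#' them); unlabelled internal nodes are fine.
#'
#' @param source a file path or a Newick string.
#' @return An `ape` `phylo` object.
#' @examples
#' tr <- readSpeciesTree("((A:1,B:1):1,C:2);")
#' @export
readSpeciesTree <- function(source) {
  text <- if (length(source) == 1L && !grepl("[(;]", source) &&
              file.exists(source)) {
    paste(readLines(source, warn = FALSE), collapse = "")
  } else {
    paste(source, collapse = "")
  }
  text <- trimws(text)
  ## structural pre-checks with positions, before handing to ape
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("Newick parse error: unbalanced ')' at position %d", i),
             call. = FALSE)
      }
    }
  }
  if (depth > 0L) {
    stop(sprintf("Newick parse error: %d unclosed '(' at end of input", depth),
         call. = FALSE)
  }
  if (!grepl(";\\s*$", text)) {
    stop(sprintf("Newick parse error: missing terminating semicolon (position %d)",
                 nchar(text)), call. = FALSE)
  }
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("Newick parse error", call. = FALSE)
  if (is.null(tree$edge.length)) {
    stop("Newick tree has no branch lengths; lengths are required",
         call. = FALSE)
  }
  if (any(!is.finite(tree$edge.length))) {
    stop("Newick tree has a missing branch length; lengths are required on every edge",
         call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("Newick tree has a negative branch length", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("Newick tree has duplicated tip labels", call. = FALSE)
  }
  tree
}

#' Write a phylogeny as Newick
#' @param tree a `phylo` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSpeciesTree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}

#' Define the sexual-asexual species pairs
#'
#' @param sexual,asexual character vectors of species ids (parallel).
#' @param pair_id integer ranks ordering pairs from the youngest to the most
#'   ancient transition to asexuality; defaults to input order.
#' @return data.frame with columns `pair_id`, `sexual_species`,
#'   `asexual_species`.
#' @export
speciesPairs <- function(sexual, asexual, pair_id = seq_along(sexual)) {
  stopifnot(length(sexual) == length(asexual),
            length(pair_id) == length(sexual))
  if (any(sexual == asexual)) {
    stop("a species pair must have two distinct members", call. = FALSE)
  }
  if (anyDuplicated(pair_id)) stop("pair_id must be unique", call. = FALSE)
  data.frame(pair_id = as.integer(pair_id),
             sexual_species = as.character(sexual),
             asexual_species = as.character(asexual))[order(pair_id), ]
}

#' Read species-pair definitions
#'
#' Delimited file with columns `pair_id, sexual_species, asexual_species`.
#'
#' @param source file path, connection or lines.
#' @return data.frame as from [speciesPairs()].
#' @export
readSpeciesPairs <- function(source) {
  df <- .readDelimited(source, "species-pair table")
  df <- .checkColumns(df, c("pair_id", "sexual_species", "asexual_species"),
                      "species-pair table")
  speciesPairs(df$sexual_species, df$asexual_species,
               as.integer(df$pair_id))
}
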