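## Feeding-experiment statistics: per-plant performance summaries feeding
## the fundamental-niche Tau, the reproductive-mode x plant interaction
## tests (binomial GLM for survival, two-way ANOVA for weight gain, both
## with sequential Type I term tests in the order mode, plant, interaction),
## Levene's variance test, and a Pearson correlation wrapper.

#' Per-plant performance profile of one species
#'
#' Summarizes feeding trials per plant: survival proportion and, over
#' survivors only, mean weight gain (`final_mass - initial_mass`, grams).
#' Dead insects contribute to survival only; a plant whose insects all died
#' keeps survival 0 but gets a missing weight-gain entry. Plants from the
#' experiment's declared list with no trials for the species are flagged
#' missing in both.
#'
#' @param trials a [FeedingTrialTable-class].
#' @param species species id to summarize.
#' @return data.frame per plant: `plant`, `n_trials`, `n_survived`,
#'   `survival`, `mean_gain`, `n_gain`.
#' @export
performanceProfile <- function(trials, species) {
  stopifnot(is(trials, "FeedingTrialTable"))
  df <- records(trials)
  df <- df[df$species_id == species, ]
  if (!nrow(df)) stop(sprintf("species '%s' has no trials", species),
                      call. = FALSE)
  plants <- trials@plants
  res <- lapply(plants, function(pl) {
    sub <- df[df$plant_treatment == pl, ]
    if (!nrow(sub)) {
      return(data.frame(plant = pl, n_trials = 0L, n_survived = 0L,
                        survival = NA_real_, mean_gain = NA_real_,
                        n_gain = 0L))
    }
    gains <- (sub$final_mass - sub$initial_mass)[sub$survived]
    data.frame(plant = pl, n_trials = nrow(sub),
               n_survived = as.integer(sum(sub$survived)),
               survival = mean(sub$survived),
               mean_gain = if (length(gains)) mean(gains) else NA_real_,
               n_gain = length(gains))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Fundamental-niche Tau from a performance profile
#'
#' Evaluates the inversed Tau index on a species' per-plant survival
#' proportions or mean weight gains (plants with no trials, or no survivors
#' for the weight-gain basis, are dropped; negative mean gains are treated
#' as zero performance).
#'
#' @param profile data.frame from [performanceProfile()].
#' @param basis `"survival"` or `"weight_gain"`.
#' @return A [TauResult-class].
#' @export
fundamentalTau <- function(profile, basis = c("survival", "weight_gain")) {
  basis <- match.arg(basis)
  if (basis == "survival") {
    x <- profile$survival[!is.na(profile$survival)]
    names(x) <- profile$plant[!is.na(profile$survival)]
  } else {
    keep <- !is.na(profile$mean_gain)
    x <- pmax(profile$mean_gain[keep], 0)
    names(x) <- profile$plant[keep]
  }
  if (length(x) < 2L) {
    return(new("TauResult", tau = NA_real_, basis = basis,
               nPlants = length(x), profile = as.numeric(x)))
  }
  tauInversed(x, basis = basis)
}

.termTable <- function(an, statCol, response) {
  terms <- rownames(an)
  terms <- terms[terms != "Residuals" & terms != "NULL"]
  data.frame(
    term = c("reproductive_mode", "feeding_treatment", "interaction")[
      seq_along(terms)],
    statistic = an[terms, statCol],
    df = an[terms, "Df"],
    df2 = if ("Residuals" %in% rownames(an)) {
      rep(an["Residuals", "Df"], length(terms))
    } else rep(NA_integer_, length(terms)),
    p = an[terms, grep("^Pr", colnames(an), value = TRUE)[1]]
  )
}

## An interaction with no estimable contrast is dropped from R's anova
## table; re-insert it as a flagged-missing row.
.padInteraction <- function(out) {
  if (nrow(out) < 3L) {
    out <- rbind(out, data.frame(term = "interaction", statistic = NA_real_,
                                 df = NA_integer_, df2 = NA_integer_,
                                 p = NA_real_))
  }
  out
}

## Plants observed under only one reproductive mode cannot contribute
## estimable interaction contrasts (their interaction coefficients alias to
## the main effects); R drops the aliased columns and the sequential tests
## carry the reduced df automatically. We report which plants those are.
.singleModePlants <- function(df) {
  tab <- table(df$plant_treatment, df$reproductive_mode)
  rownames(tab)[rowSums(tab > 0) < 2L]
}

#' Survival interaction test (binomial GLM)
#'
#' Fits `survived ~ reproductive_mode * plant_treatment` with binomial error
#' and logit link for one species pair and reports sequential
#' likelihood-ratio (deviance) chi-square tests per term. A significant
#' mode:plant interaction indicates that the sexual and asexual members
#' differ in fundamental feeding niche. Plants tested in only one mode are
#' reported in `@excluded`; their interaction contrasts are inestimable and
#' the interaction df shrinks accordingly. Complete separation is flagged in
#' `@notes` (the LRT p is still reported).
#'
#' @param trials a [FeedingTrialTable-class] restricted to the two members
#'   of one pair (both modes present, >= 2 shared plants).
#' @return An [InteractionTestResult-class].
#' @export
survivalInteractionGLM <- function(trials) {
  stopifnot(is(trials, "FeedingTrialTable"))
  df <- records(trials)
  if (length(unique(df$reproductive_mode)) < 2L) {
    stop("both reproductive modes must be present", call. = FALSE)
  }
  shared <- names(which(rowSums(table(df$plant_treatment,
                                      df$reproductive_mode) > 0) == 2L))
  if (length(shared) < 2L) {
    stop("need at least 2 plant treatments tested in both modes",
         call. = FALSE)
  }
  df$reproductive_mode <- factor(df$reproductive_mode, levels = .MODES)
  df$plant_treatment <- factor(df$plant_treatment)
  notes <- character(0)
  fit <- withCallingHandlers(
    glm(survived ~ reproductive_mode + plant_treatment +
          reproductive_mode:plant_treatment,
        family = binomial(link = "logit"), data = df),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)) {
    notes <- c(notes, "fitted probabilities of 0 or 1 (possible separation)")
  }
  an <- anova(fit, test = "Chisq")
  out <- .termTable(an, "Deviance", "survival")
  out$df2 <- NA_integer_
  out <- .padInteraction(out)
  new("InteractionTestResult", response = "survival", terms = out,
      excluded = .singleModePlants(df), notes = unique(notes))
}

#' Weight-gain interaction test (two-way ANOVA)
#'
#' Two-way fixed-effects ANOVA of survivor weight gain on reproductive mode,
#' plant treatment and their interaction, with sequential (Type I) sums of
#' squares in that order. Dead insects are excluded (no final mass). Cells
#' empty in one mode reduce the interaction df; an inestimable interaction
#' (0 df) is flagged missing.
#'
#' @param trials a [FeedingTrialTable-class] restricted to one species pair.
#' @return An [InteractionTestResult-class].
#' @export
weightGainANOVA <- function(trials) {
  stopifnot(is(trials, "FeedingTrialTable"))
  df <- records(trials)
  df <- df[df$survived, ]
  if (length(unique(df$reproductive_mode)) < 2L ||
      length(unique(df$plant_treatment)) < 2L) {
    stop("need survivors from both modes on at least 2 plants", call. = FALSE)
  }
  df$gain <- df$final_mass - df$initial_mass
  df$reproductive_mode <- factor(df$reproductive_mode, levels = .MODES)
  df$plant_treatment <- factor(df$plant_treatment)
  fit <- lm(gain ~ reproductive_mode + plant_treatment +
              reproductive_mode:plant_treatment, data = df)
  an <- anova(fit)
  out <- .padInteraction(.termTable(an, "F value", "weight_gain"))
  if (nrow(out) >= 3L && (is.na(out$df[3]) || out$df[3] == 0)) {
    out$statistic[3] <- NA_real_
    out$p[3] <- NA_real_
  }
  new("InteractionTestResult", response = "weight_gain", terms = out,
      excluded = .singleModePlants(records(trials)), notes = character(0))
}

#' Levene's test for homogeneity of variance
#'
#' One-way ANOVA on absolute deviations of the values from their group
#' center; the center is the group median by default (the Brown-Forsythe
#' variant, robust to non-normality) or the mean. Used to ask whether
#' sexual populations vary more than asexual ones in their degree of
#' specialization.
#'
#' @param values numeric vector (e.g. per-population Tau indices).
#' @param groups grouping factor (e.g. reproductive mode), >= 2 groups with
#'   >= 2 values each.
#' @param center `"median"` or `"mean"`.
#' @return An object of class `htest` with the F statistic, numerator and
#'   denominator df, and p-value. If every deviation is zero the statistic
#'   is undefined and returned as NA.
#' @export
leveneVarTest <- function(values, groups, center = c("median", "mean")) {
  center <- match.arg(center)
  groups <- factor(groups)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L)) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  centerFun <- if (center == "median") median else mean
  dev <- abs(values - ave(values, groups, FUN = centerFun))
  dataName <- paste(deparse(substitute(values)), "by",
                    deparse(substitute(groups)))
  ## degenerate: no within-group variation in the deviations (e.g. all
  ## deviations zero, or two values per group) -> F undefined
  ssWithin <- sum((dev - ave(dev, groups))^2)
  if (ssWithin < max(1, sum(dev^2)) * 1e-12) {
    return(structure(list(
      statistic = c(F = NA_real_),
      parameter = c(df1 = nlevels(groups) - 1L,
                    df2 = length(values) - nlevels(groups)),
      p.value = NA_real_,
      method = sprintf(
        "Levene's test (center = %s); degenerate: no within-group deviation variance",
        center),
      data.name = dataName), class = "htest"))
  }
  an <- anova(lm(dev ~ groups))
  structure(list(
    statistic = c(F = an[1, "F value"]),
    parameter = c(df1 = an[1, "Df"], df2 = an[2, "Df"]),
    p.value = an[1, "Pr(>F)"],
    method = sprintf("Levene's test (center = %s)", center),
    data.name = dataName), class = "htest")
}

#' Pearson correlation test
#'
#' Sample Pearson correlation with the two-sided t test on n - 2 degrees of
#' freedom; errors on degenerate input rather than returning NA.
#'
#' @param x,y paired numeric vectors (n >= 3 complete pairs).
#' @return The `htest` from [stats::cor.test()].
#' @export
pearsonCorTest <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired finite values",
                           call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance in x or y: correlation undefined", call. = FALSE)
  }
  stats::cor.test(x, y, method = "pearson")
}
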