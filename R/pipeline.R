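## Pipeline drivers: compose the IO, index, trial-statistics and
## comparative modules end to end, writing TSV tables, a per-stage Markdown
## report, and a machine-readable run manifest. All stochastic steps take
## their seeds from the config, so a rerun with the same config is
## byte-identical. Progress is logged to stderr via message().

.CONFIG_DEFAULTS <- list(bootstrap_B = 2000L, n_perm = 999L, alpha = 0.05,
                         seed = 1L, out_dir = ".")

#' Read and validate a pipeline configuration
#'
#' YAML with keys: input paths (`occurrence`, `morphs`, `trials`, `tree`,
#' `pairs`, optional `availability` — a mapping location -> plant list),
#' `bootstrap_B` (>= 200), `n_perm`, `alpha` in (0,1), `seed`, `out_dir`.
#'
#' @param config a YAML file path or a named list.
#' @return validated config list with defaults filled in.
#' @export
readPipelineConfig <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config must be a list or a YAML path", call. = FALSE)
  for (key in names(.CONFIG_DEFAULTS)) {
    if (is.null(cfg[[key]])) cfg[[key]] <- .CONFIG_DEFAULTS[[key]]
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  if (cfg$bootstrap_B < 200) stop("bootstrap_B must be >= 200", call. = FALSE)
  for (key in c("occurrence", "morphs", "trials", "tree", "pairs")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop(sprintf("config input '%s' does not exist: %s", key, cfg[[key]]),
           call. = FALSE)
    }
  }
  cfg
}

.writeManifest <- function(cfg, stage, outputs) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("nicheBreadth")),
    seed = cfg$seed, alpha = cfg$alpha, bootstrap_B = cfg$bootstrap_B,
    n_perm = cfg$n_perm,
    inputs = cfg[intersect(names(cfg),
                           c("occurrence", "morphs", "trials", "tree",
                             "pairs"))],
    outputs = as.list(basename(outputs)))  # relative: reruns stay identical
  path <- file.path(cfg$out_dir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

.modeOfSpecies <- function(pairs) {
  c(setNames(rep("sexual", nrow(pairs)), pairs$sexual_species),
    setNames(rep("asexual", nrow(pairs)), pairs$asexual_species))
}

.mdTable <- function(df, digits = 4) {
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) formatC(col, digits = digits, format = "g") else
      as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1)
  lines <- c(paste0("| ", paste(names(df), collapse = " | "), " |"),
             paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
             apply(fmt, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                              " |")))
  paste(lines, collapse = "\n")
}

#' Run the realized-niche stage
#'
#' Reads the occurrence table (and pair definitions, if given), computes
#' per-population Tau with bootstrap CIs, species-level breadth, the
#' sexual-asexual permutation comparison per pair on species-pooled counts,
#' and Levene's test on the within-mode spread of population Tau. Writes
#' `population_tau.tsv`, `species_breadth.tsv`, `pair_comparisons.tsv`,
#' `report_realized.md` and a manifest to the config's `out_dir`.
#'
#' @param config config list or YAML path (see [readPipelineConfig()]);
#'   must name an `occurrence` input.
#' @return invisibly, a list of the result data.frames.
#' @export
runRealized <- function(config) {
  cfg <- readPipelineConfig(config)
  if (is.null(cfg$occurrence)) stop("config needs an 'occurrence' input",
                                    call. = FALSE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  message("[realized] reading occurrence table: ", cfg$occurrence)
  occ <- readOccurrenceTable(cfg$occurrence)
  pairs <- if (!is.null(cfg$pairs)) readSpeciesPairs(cfg$pairs) else NULL
  availability <- cfg$availability

  popTau <- populationRealizedTau(occ, availability)
  profiles <- .populationProfiles(occ, availability)
  cis <- lapply(popTau$population_id, function(pop) {
    x <- profiles[[pop]]
    if (length(x) < 2L || sum(x) == 0) return(c(NA_real_, NA_real_))
    ci <- bootstrapTauCI(x, B = cfg$bootstrap_B,
                         seed = .childSeed(cfg$seed, paste0("ci:", pop)))
    c(ci@lower, ci@upper)
  })
  popTau$ci_lower <- vapply(cis, `[`, numeric(1), 1)
  popTau$ci_upper <- vapply(cis, `[`, numeric(1), 2)
  popTau$B <- cfg$bootstrap_B
  message(sprintf("[realized] %d populations, tau range [%.3f, %.3f]",
                  nrow(popTau), min(popTau$tau, na.rm = TRUE),
                  max(popTau$tau, na.rm = TRUE)))
  spBreadth <- speciesRealizedBreadth(occ, taxonomy = cfg$taxonomy)

  pairCmp <- NULL
  levene <- NULL
  if (!is.null(pairs)) {
    modeOf <- .modeOfSpecies(pairs)
    pairCmp <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      sx <- pairs$sexual_species[i]; ax <- pairs$asexual_species[i]
      present <- c(sx, ax) %in% records(occ)$species_id
      if (!all(present)) {
        warning(sprintf("pair %d: species '%s' absent from occurrence table; skipped",
                        pairs$pair_id[i], c(sx, ax)[!present][1]),
                call. = FALSE)
        return(NULL)
      }
      cmp <- pairTauTest(speciesOccurrenceCounts(occ, sx, availability),
                         speciesOccurrenceCounts(occ, ax, availability),
                         nPerm = cfg$n_perm, B = cfg$bootstrap_B,
                         seed = .childSeed(cfg$seed, paste0("pair:", i)),
                         alpha = cfg$alpha, labels = c(sx, ax))
      data.frame(pair_id = pairs$pair_id[i], sexual_species = sx,
                 asexual_species = ax,
                 tau_sexual = cmp@tauValues[1], tau_asexual = cmp@tauValues[2],
                 difference = cmp@difference, p_value = cmp@pValue,
                 significant = cmp@significant, ci_overlap = cmp@ciOverlap)
    }))
    popTau$reproductive_mode <- unname(modeOf[popTau$species_id])
    ok <- !is.na(popTau$tau) & !is.na(popTau$reproductive_mode)
    if (sum(ok) >= 4L && length(unique(popTau$reproductive_mode[ok])) == 2L) {
      lt <- leveneVarTest(popTau$tau[ok], popTau$reproductive_mode[ok])
      levene <- data.frame(test = "levene_population_tau",
                           statistic = unname(lt$statistic),
                           df1 = unname(lt$parameter["df1"]),
                           df2 = unname(lt$parameter["df2"]),
                           p = lt$p.value)
    }
  }

  outputs <- c(population_tau = file.path(cfg$out_dir, "population_tau.tsv"),
               species_breadth = file.path(cfg$out_dir, "species_breadth.tsv"))
  .writeDelimited(popTau, outputs[["population_tau"]])
  .writeDelimited(spBreadth, outputs[["species_breadth"]])
  if (!is.null(pairCmp)) {
    outputs[["pair_comparisons"]] <- file.path(cfg$out_dir,
                                               "pair_comparisons.tsv")
    .writeDelimited(pairCmp, outputs[["pair_comparisons"]])
  }
  report <- c("# Realized feeding niche breadth", "",
              "## Per-population inversed Tau", "", .mdTable(popTau), "",
              "## Species-level breadth (host genera)", "",
              .mdTable(spBreadth))
  if (!is.null(pairCmp)) {
    report <- c(report, "", "## Sexual vs asexual pair comparisons", "",
                .mdTable(pairCmp))
  }
  if (!is.null(levene)) {
    report <- c(report, "",
                "## Levene's test: spread of population Tau by mode", "",
                .mdTable(levene))
  }
  outputs[["report"]] <- file.path(cfg$out_dir, "report_realized.md")
  writeLines(report, outputs[["report"]])
  .writeManifest(cfg, "realized", outputs)
  message("[realized] wrote ", length(outputs), " outputs to ", cfg$out_dir)
  invisible(list(population_tau = popTau, species_breadth = spBreadth,
                 pair_comparisons = pairCmp, levene = levene))
}

#' Run the fundamental-niche stage
#'
#' Reads the feeding trials and pair definitions; per pair fits the
#' survival GLM and weight-gain ANOVA interaction tests; per species
#' computes performance profiles, fundamental Tau (both bases) with
#' bootstrap CIs, and the pair permutation Tau tests. A pair with a member
#' absent from the trials is skipped with a warning. Writes
#' `term_tests.tsv`, `fundamental_tau.tsv`, `fundamental_pairs.tsv`,
#' `report_fundamental.md` and a manifest.
#'
#' @param config config list or YAML path; must name `trials` and `pairs`
#'   inputs.
#' @return invisibly, a list of the result data.frames.
#' @export
runFundamental <- function(config) {
  cfg <- readPipelineConfig(config)
  if (is.null(cfg$trials) || is.null(cfg$pairs)) {
    stop("config needs 'trials' and 'pairs' inputs", call. = FALSE)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  message("[fundamental] reading trials: ", cfg$trials)
  trials <- readFeedingTrials(cfg$trials)
  pairs <- readSpeciesPairs(cfg$pairs)
  df <- records(trials)

  termRows <- list(); tauRows <- list(); pairRows <- list()
  for (i in seq_len(nrow(pairs))) {
    sx <- pairs$sexual_species[i]; ax <- pairs$asexual_species[i]
    present <- c(sx, ax) %in% df$species_id
    if (!all(present)) {
      warning(sprintf(
        "pair %d: species '%s' has no feeding trials; pair skipped",
        pairs$pair_id[i], c(sx, ax)[!present][1]), call. = FALSE)
      next
    }
    sub <- FeedingTrialTable(df[df$species_id %in% c(sx, ax), ],
                             plants = trials@plants)
    for (fitFun in list(survivalInteractionGLM, weightGainANOVA)) {
      res <- fitFun(sub)
      t <- res@terms
      t$pair_id <- pairs$pair_id[i]
      t$response <- res@response
      termRows[[length(termRows) + 1L]] <-
        t[, c("pair_id", "response", "term", "statistic", "df", "df2", "p")]
    }
    for (sp in c(sx, ax)) {
      spTrials <- FeedingTrialTable(df[df$species_id == sp, ],
                                    plants = trials@plants)
      prof <- performanceProfile(trials, sp)
      for (basis in c("survival", "weight_gain")) {
        tr <- fundamentalTau(prof, basis)
        ci <- tryCatch(
          bootstrapTauCI(spTrials, basis = basis, B = cfg$bootstrap_B,
                         seed = .childSeed(cfg$seed, paste0(sp, ":", basis))),
          error = function(e) NULL)
        tauRows[[length(tauRows) + 1L]] <- data.frame(
          species_id = sp, basis = basis, tau = tau(tr),
          n_plants = tr@nPlants,
          ci_lower = if (is.null(ci)) NA_real_ else ci@lower,
          ci_upper = if (is.null(ci)) NA_real_ else ci@upper,
          B = cfg$bootstrap_B)
      }
    }
    for (basis in c("survival", "weight_gain")) {
      cmp <- pairTauTest(
        FeedingTrialTable(df[df$species_id == sx, ], plants = trials@plants),
        FeedingTrialTable(df[df$species_id == ax, ], plants = trials@plants),
        basis = basis, nPerm = cfg$n_perm, B = cfg$bootstrap_B,
        seed = .childSeed(cfg$seed, paste0("fpair:", i, ":", basis)),
        alpha = cfg$alpha, labels = c(sx, ax))
      pairRows[[length(pairRows) + 1L]] <- data.frame(
        pair_id = pairs$pair_id[i], basis = basis, sexual_species = sx,
        asexual_species = ax, tau_sexual = cmp@tauValues[1],
        tau_asexual = cmp@tauValues[2], difference = cmp@difference,
        p_value = cmp@pValue, significant = cmp@significant,
        ci_overlap = cmp@ciOverlap)
    }
    message(sprintf("[fundamental] pair %d (%s / %s) done",
                    pairs$pair_id[i], sx, ax))
  }
  if (!length(termRows)) stop("no pair could be analyzed", call. = FALSE)
  terms <- do.call(rbind, termRows)
  taus <- do.call(rbind, tauRows)
  pairCmp <- do.call(rbind, pairRows)
  rownames(terms) <- rownames(taus) <- rownames(pairCmp) <- NULL

  outputs <- c(term_tests = file.path(cfg$out_dir, "term_tests.tsv"),
               fundamental_tau = file.path(cfg$out_dir, "fundamental_tau.tsv"),
               fundamental_pairs = file.path(cfg$out_dir,
                                             "fundamental_pairs.tsv"),
               report = file.path(cfg$out_dir, "report_fundamental.md"))
  .writeDelimited(terms, outputs[["term_tests"]])
  .writeDelimited(taus, outputs[["fundamental_tau"]])
  .writeDelimited(pairCmp, outputs[["fundamental_pairs"]])
  writeLines(c("# Fundamental feeding niche breadth", "",
               "## Interaction term tests (sequential)", "", .mdTable(terms),
               "", "## Fundamental Tau with bootstrap CIs", "",
               .mdTable(taus), "", "## Pair comparisons", "",
               .mdTable(pairCmp)),
             outputs[["report"]])
  .writeManifest(cfg, "fundamental", outputs)
  invisible(list(term_tests = terms, fundamental_tau = taus,
                 pair_comparisons = pairCmp))
}

#' Run the comparative stage
#'
#' Species-level synthesis: Gini-Simpson colour polymorphism and realized
#' breadth per species, PGLS (Brownian motion on the input tree) of
#' polymorphism against realized breadth, and Pearson correlations between
#' Tau variants (survival vs weight gain) and between fundamental and
#' realized breadth where trials are available. Writes `comparative.tsv`,
#' `report_comparative.md` and a manifest.
#'
#' @param config config list or YAML path; must name `occurrence`, `morphs`
#'   and `tree` inputs (`trials` optional).
#' @return invisibly, the comparative results data.frame.
#' @export
runComparative <- function(config) {
  cfg <- readPipelineConfig(config)
  for (key in c("occurrence", "morphs", "tree")) {
    if (is.null(cfg[[key]])) {
      stop(sprintf("config needs a '%s' input", key), call. = FALSE)
    }
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  occ <- readOccurrenceTable(cfg$occurrence)
  morphs <- readMorphTable(cfg$morphs)
  tree <- readSpeciesTree(cfg$tree)

  breadth <- speciesRealizedBreadth(occ, taxonomy = cfg$taxonomy)
  poly <- polymorphismSummary(morphs, level = "species")
  merged <- merge(breadth, poly, by = "species_id")
  missing <- setdiff(merged$species_id, tree$tip.label)
  if (length(missing)) {
    stop(sprintf("species '%s' is missing from the tree", missing[1]),
         call. = FALSE)
  }
  rows <- list()
  addRow <- function(test, r, p, n) {
    rows[[length(rows) + 1L]] <<- data.frame(test = test, r = r, p = p, n = n)
  }
  x <- setNames(merged$n_genera, merged$species_id)
  for (resp in c("k_morphs", "simpson")) {
    y <- setNames(merged[[resp]], merged$species_id)
    fit <- tryCatch(pglsCorrelation(x, y, tree), error = function(e) {
      warning(sprintf("PGLS %s vs realized breadth failed: %s", resp,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(fit)) {
      addRow(sprintf("pgls_%s_vs_n_genera", resp), fit$r, fit$p, fit$n)
    }
  }
  if (!is.null(cfg$trials)) {
    trials <- readFeedingTrials(cfg$trials)
    sp <- intersect(unique(records(trials)$species_id), merged$species_id)
    fund <- do.call(rbind, lapply(sp, function(s) {
      prof <- performanceProfile(trials, s)
      data.frame(species_id = s,
                 tau_survival = tau(fundamentalTau(prof, "survival")),
                 tau_gain = tau(fundamentalTau(prof, "weight_gain")))
    }))
    if (!is.null(fund) && nrow(fund) >= 3L) {
      ht <- pearsonCorTest(fund$tau_survival, fund$tau_gain)
      addRow("pearson_tau_survival_vs_weight_gain",
             unname(ht$estimate), ht$p.value, nrow(fund))
      m2 <- merge(fund, merged, by = "species_id")
      if (nrow(m2) >= 3L && sd(m2$tau_survival) > 0 && sd(m2$n_genera) > 0) {
        ht2 <- pearsonCorTest(m2$tau_survival, m2$n_genera)
        addRow("pearson_fundamental_vs_realized",
               unname(ht2$estimate), ht2$p.value, nrow(m2))
      }
    }
  }
  out <- do.call(rbind, rows)
  outputs <- c(comparative = file.path(cfg$out_dir, "comparative.tsv"),
               report = file.path(cfg$out_dir, "report_comparative.md"))
  .writeDelimited(out, outputs[["comparative"]])
  writeLines(c("# Comparative analyses", "",
               "## Species-level summary", "", .mdTable(merged), "",
               "## Correlations", "", .mdTable(out)),
             outputs[["report"]])
  .writeManifest(cfg, "comparative", outputs)
  message("[comparative] wrote outputs to ", cfg$out_dir)
  invisible(out)
}
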