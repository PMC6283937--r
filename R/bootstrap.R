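## Nonparametric uncertainty for the Tau index: percentile bootstrap CIs
## from individual-level resampling, and permutation tests for the
## sexual-asexual difference within a species pair. Both are deterministic
## given (seed, B) and leave the caller's RNG stream untouched.

.checkB <- function(B) {
  if (!is.numeric(B) || B < 200) {
    stop("B must be at least 200 resamples", call. = FALSE)
  }
  as.integer(B)
}

.percentileCI <- function(draws, level) {
  a <- (1 - level) / 2
  unname(quantile(draws, c(a, 1 - a), names = FALSE, type = 7))
}

#' @param B number of bootstrap resamples (>= 200; default 2000).
#' @param seed RNG seed; the same (seed, B) always yields the same interval.
#' @param level confidence level (default 0.95).
#' @rdname bootstrapTauCI
#' @export
setMethod("bootstrapTauCI", "numeric",
  function(x, B = 2000, seed = 1, level = 0.95, ...) {
    B <- .checkB(B)
    if (length(x) < 2L) {
      stop("tau is undefined with fewer than 2 plants; no interval to bootstrap",
           call. = FALSE)
    }
    est <- tauInversed(x)
    N <- sum(x)
    if (N <= 0) stop("no individuals to resample", call. = FALSE)
    ## resampling N individuals with replacement from the empirical
    ## plant distribution == one multinomial draw per resample
    draws <- .withSeed(seed, {
      X <- rmultinom(B, size = N, prob = x / N)
      .tauInvCols(X)
    })
    ci <- .percentileCI(draws, level)
    new("BootstrapCI", estimate = tau(est), lower = ci[1], upper = ci[2],
        level = level, B = B, seed = as.integer(seed), basis = "occurrence")
  })

## Per-plant survival proportions or survivor mean weight gains from a
## trial index split; negative mean gains are clamped to 0 (no measurable
## performance) and plants with no survivors drop out of the weight-gain
## profile.
.trialProfile <- function(survived, gain, plantIdx, basis) {
  if (basis == "survival") {
    vapply(plantIdx, function(ii) mean(survived[ii]), numeric(1))
  } else {
    x <- vapply(plantIdx, function(ii) {
      g <- gain[ii][survived[ii]]
      if (!length(g)) NA_real_ else mean(g)
    }, numeric(1))
    pmax(x[!is.na(x)], 0)
  }
}

#' @param basis Tau basis for trial data: `"survival"` or `"weight_gain"`.
#' @rdname bootstrapTauCI
#' @export
setMethod("bootstrapTauCI", "FeedingTrialTable",
  function(x, basis = c("survival", "weight_gain"), B = 2000, seed = 1,
           level = 0.95, ...) {
    basis <- match.arg(basis)
    B <- .checkB(B)
    df <- records(x)
    if (length(unique(df$species_id)) != 1L) {
      stop("bootstrapTauCI expects trials for a single species; subset first",
           call. = FALSE)
    }
    plantIdx <- split(seq_len(nrow(df)), df$plant_treatment)
    gain <- df$final_mass - df$initial_mass
    x0 <- .trialProfile(df$survived, gain, plantIdx, basis)
    if (length(x0) < 2L || max(x0) <= 0) {
      stop("observed performance profile does not support a defined tau",
           call. = FALSE)
    }
    est <- .tauInv(x0)
    draws <- .withSeed(seed, {
      out <- numeric(B)
      attempts <- 0L
      b <- 1L
      while (b <= B) {
        attempts <- attempts + 1L
        if (attempts > 10L * B) {
          stop("bootstrap resampling failed: too many degenerate resamples",
               call. = FALSE)
        }
        ## resample trials within their plant stratum
        idx <- lapply(plantIdx, function(ii) ii[sample.int(length(ii),
                                                           replace = TRUE)])
        xb <- .trialProfile(df$survived, gain, idx, basis)
        if (length(xb) < 2L || max(xb) <= 0) next  # redraw degenerate resample
        out[b] <- .tauInv(xb)
        b <- b + 1L
      }
      out
    })
    ci <- .percentileCI(draws, level)
    new("BootstrapCI", estimate = est, lower = ci[1], upper = ci[2],
        level = level, B = B, seed = as.integer(seed), basis = basis)
  })

.pairComparison <- function(labels, tauA, tauB, ciA, ciB, pValue, nPerm,
                            alpha, nTotal) {
  if (nTotal < 20) {
    warning(sprintf(
      "pair comparison based on only %d individuals: low power", nTotal),
      call. = FALSE)
  }
  overlap <- ciA@lower <= ciB@upper && ciB@lower <= ciA@upper
  new("PairTauComparison", labels = labels,
      tauValues = setNames(c(tauA, tauB), labels),
      ci = matrix(c(ciA@lower, ciA@upper, ciB@lower, ciB@upper), nrow = 2,
                  byrow = TRUE, dimnames = list(labels, c("lower", "upper"))),
      difference = tauA - tauB, pValue = pValue, nPerm = as.integer(nPerm),
      alpha = alpha, significant = pValue < alpha, ciOverlap = overlap)
}

#' @param plants optional plant universe (union of names by default); both
#'   profiles are evaluated over this common availability set.
#' @param nPerm number of permutations (default 9999).
#' @param B bootstrap resamples for the member CIs.
#' @param seed RNG seed.
#' @param alpha significance level (default 0.05).
#' @param labels names for the two members (e.g. the species ids, sexual
#'   first).
#' @rdname pairTauTest
#' @export
setMethod("pairTauTest", signature("numeric", "numeric"),
  function(x, y, plants = NULL, nPerm = 9999, B = 2000, seed = 1,
           alpha = 0.05, labels = c("A", "B"), ...) {
    if (is.null(plants)) plants <- union(names(x), names(y))
    if (is.null(plants) || !length(plants)) {
      stop("profiles must be named by plant (or pass `plants`)", call. = FALSE)
    }
    fill <- function(v) {
      out <- setNames(numeric(length(plants)), plants)
      out[names(v)] <- v
      out
    }
    x <- fill(x); y <- fill(y)
    nA <- sum(x); nB <- sum(y)
    tauA <- tau(tauInversed(x)); tauB <- tau(tauInversed(y))
    obs <- abs(tauA - tauB)
    np <- length(plants)
    ## permutation: pool the individuals (plant index each), shuffle group
    ## labels, tabulate each group's profile, recompute |dtau|
    pooled <- rep(seq_len(np), times = x + y)
    perm <- .withSeed(.childSeed(seed, "perm"), {
      vapply(seq_len(nPerm), function(i) {
        pick <- sample.int(length(pooled), nA)
        ca <- tabulate(pooled[pick], nbins = np)
        cb <- tabulate(pooled[-pick], nbins = np)
        abs(.tauInv(ca) - .tauInv(cb))
      }, numeric(1))
    })
    p <- (1 + sum(perm >= obs - 1e-12)) / (nPerm + 1)
    ciA <- bootstrapTauCI(x, B = B, seed = .childSeed(seed, "bootA"))
    ciB <- bootstrapTauCI(y, B = B, seed = .childSeed(seed, "bootB"))
    .pairComparison(labels, tauA, tauB, ciA, ciB, p, nPerm, alpha, nA + nB)
  })

#' @param basis Tau basis for trial data (`"survival"` or `"weight_gain"`);
#'   permutations shuffle individuals between the two species within each
#'   plant stratum.
#' @rdname pairTauTest
#' @export
setMethod("pairTauTest", signature("FeedingTrialTable", "FeedingTrialTable"),
  function(x, y, basis = c("survival", "weight_gain"), nPerm = 9999,
           B = 2000, seed = 1, alpha = 0.05, labels = NULL, ...) {
    basis <- match.arg(basis)
    dfA <- records(x); dfB <- records(y)
    if (is.null(labels)) {
      labels <- c(unique(dfA$species_id)[1], unique(dfB$species_id)[1])
    }
    tauOf <- function(df) {
      plantIdx <- split(seq_len(nrow(df)), df$plant_treatment)
      prof <- .trialProfile(df$survived, df$final_mass - df$initial_mass,
                            plantIdx, basis)
      if (length(prof) < 2L || max(prof) <= 0) return(NA_real_)
      .tauInv(prof)
    }
    tauA <- tauOf(dfA); tauB <- tauOf(dfB)
    if (is.na(tauA) || is.na(tauB)) {
      stop("a member's performance profile does not support a defined tau",
           call. = FALSE)
    }
    obs <- abs(tauA - tauB)
    pool <- rbind(dfA, dfB)
    grpA <- c(rep(TRUE, nrow(dfA)), rep(FALSE, nrow(dfB)))
    strata <- split(seq_len(nrow(pool)), pool$plant_treatment)
    perm <- .withSeed(.childSeed(seed, "perm"), {
      vapply(seq_len(nPerm), function(i) {
        g <- grpA
        for (ii in strata) g[ii] <- g[ii][sample.int(length(ii))]
        abs(tauOf(pool[g, , drop = FALSE]) - tauOf(pool[!g, , drop = FALSE]))
      }, numeric(1))
    })
    perm <- perm[!is.na(perm)]
    p <- (1 + sum(perm >= obs - 1e-12)) / (length(perm) + 1)
    ciA <- bootstrapTauCI(x, basis = basis, B = B,
                          seed = .childSeed(seed, "bootA"))
    ciB <- bootstrapTauCI(y, basis = basis, B = B,
                          seed = .childSeed(seed, "bootB"))
    .pairComparison(labels, tauA, tauB, ciA, ciB, p, length(perm), alpha,
                    nrow(pool))
  })
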