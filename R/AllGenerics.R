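#' @rdname records
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname tau
#' @export
setGeneric("tau", function(x) standardGeneric("tau"))

#' @rdname simpson
#' @export
setGeneric("simpson", function(x) standardGeneric("simpson"))

#' Bootstrap a percentile confidence interval for the inversed Tau index
#'
#' Resamples individual-level records (individual insects for occurrence
#' data, experimental females within their plant stratum for feeding trials)
#' and returns the percentile interval of the inversed Tau distribution over
#' the resamples.
#'
#' @param x occurrence counts (a named nonnegative numeric vector aligned to
#'   the available plants, zeros allowed) or a [FeedingTrialTable-class]
#'   restricted to one species.
#' @param ... passed to methods.
#' @return A [BootstrapCI-class] object.
#' @export
setGeneric("bootstrapTauCI", function(x, ...) standardGeneric("bootstrapTauCI"))

#' Permutation comparison of two inversed Tau indices
#'
#' Tests the difference between the Tau indices of two groups (typically the
#' sexual and asexual members of a species pair) by pooling their
#' individual-level records and permuting group labels; the two-sided p-value
#' is for |tau_A - tau_B| under exchangeability. Bootstrap confidence
#' intervals for each member are reported alongside, with their overlap as a
#' secondary flag.
#'
#' @param x,y the two datasets: named occurrence-count vectors over host
#'   plants, or two [FeedingTrialTable-class] objects (one species each).
#' @param ... passed to methods.
#' @return A [PairTauComparison-class] object.
#' @export
setGeneric("pairTauTest", function(x, y, ...) standardGeneric("pairTauTest"))
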