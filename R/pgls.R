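## Phylogenetic generalized least squares under a Brownian-motion trait
## model. Tip covariance equals shared root-to-tip path length; the GLS fit
## is computed in closed form through the Cholesky factor of that matrix.

#' Brownian-motion covariance matrix from a phylogeny
#'
#' Entry (i, j) is the summed branch length shared by the root-to-tip paths
#' of species i and j (the depth of their most recent common ancestor);
#' diagonal entries are tip depths. This is the trait covariance implied by
#' Brownian motion with unit rate.
#'
#' @param tree a `phylo` object with branch lengths (see
#'   [readSpeciesTree()]).
#' @param species optional ordered species vector; the matrix rows/columns
#'   follow it. All must be tips of the tree.
#' @return numeric matrix, species x species.
#' @examples
#' brownianVCV(readSpeciesTree("((A:1,B:1):1,C:2);"))
#' @export
brownianVCV <- function(tree, species = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  V <- ape::vcv.phylo(tree)
  if (is.null(species)) species <- tree$tip.label
  missing <- setdiff(species, rownames(V))
  if (length(missing)) {
    stop(sprintf("species '%s' is not a tip of the tree", missing[1]),
         call. = FALSE)
  }
  V[species, species, drop = FALSE]
}

#' Fit a simple PGLS regression
#'
#' Generalized least squares of `y` on `x` with error covariance
#' proportional to `V`: \eqn{\hat\beta = (X^T V^{-1} X)^{-1} X^T V^{-1} y}
#' with \eqn{X = [1, x]}. The correlation is
#' \eqn{r = \mathrm{sign}(\hat\beta_1)\sqrt{R^2_{GLS}}}, where
#' \eqn{R^2_{GLS}} uses \eqn{V^{-1}}-weighted sums of squares about the GLS
#' mean of `y`; the slope is tested two-sided on n - 2 degrees of freedom.
#' With `V = diag(n)` the fit equals ordinary least squares and `r` equals
#' Pearson's r.
#'
#' @param x,y per-species traits (aligned to `V`'s row order; names checked
#'   against V's dimnames when both are present).
#' @param V covariance matrix from [brownianVCV()] (any positive definite
#'   matrix is accepted; a numerically singular V falls back to a
#'   pseudoinverse with a warning).
#' @return A [PGLSFit-class].
#' @export
pglsFit <- function(x, y, V) {
  n <- length(y)
  if (length(x) != n || nrow(V) != n || ncol(V) != n) {
    stop("x, y and V must be conformable", call. = FALSE)
  }
  if (n < 3L) stop("PGLS needs at least 3 species (residual df)", call. = FALSE)
  if (!is.null(names(x)) && !is.null(rownames(V)) &&
      !identical(names(x), rownames(V))) {
    stop("names of x do not match the row order of V", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, slope = as.numeric(x))
  y <- as.numeric(y)
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (!is.null(L)) {
    ## whiten: solve L^T z = v  =>  z^T z = v^T V^{-1} v
    wX <- backsolve(L, X, transpose = TRUE)
    wy <- backsolve(L, y, transpose = TRUE)
    w1 <- wX[, 1]
  } else {
    warning("V is numerically singular; using a pseudoinverse", call. = FALSE)
    s <- svd(V)
    keep <- s$d > max(s$d) * 1e-12
    W <- diag(1 / sqrt(s$d[keep]), sum(keep)) %*% t(s$u[, keep, drop = FALSE])
    wX <- W %*% X
    wy <- drop(W %*% y)
    w1 <- wX[, 1]
  }
  XtX <- crossprod(wX)
  gVarX <- XtX[2, 2] - XtX[1, 2]^2 / XtX[1, 1]
  if (gVarX <= max(XtX[2, 2], 1) * 1e-12) {
    stop("x has zero GLS variance (constant predictor)", call. = FALSE)
  }
  XtXinv <- solve(XtX)
  beta <- drop(XtXinv %*% crossprod(wX, wy))
  names(beta) <- colnames(X)
  resid <- wy - wX %*% beta
  rss <- sum(resid^2)
  dfRes <- n - 2L
  sigma2 <- rss / dfRes
  se <- sqrt(diag(XtXinv) * sigma2)
  ## GLS mean of y and total V^{-1}-weighted SS about it
  muY <- sum(w1 * wy) / sum(w1^2)
  tss <- sum((wy - muY * w1)^2)
  R2 <- if (tss > 0) max(0, min(1, 1 - rss / tss)) else NA_real_
  r <- sign(beta[2]) * sqrt(R2)
  tStat <- beta[2] / se[2]
  p <- 2 * pt(-abs(tStat), dfRes)
  new("PGLSFit", coefficients = beta, se = setNames(se, names(beta)),
      sigma2 = sigma2, r = unname(r), tStat = unname(tStat),
      pValue = unname(p), df = as.integer(dfRes), n = as.integer(n))
}

#' PGLS correlation between two species-level traits
#'
#' Convenience wrapper: builds the Brownian covariance from the tree and
#' returns the GLS correlation and its slope p-value.
#'
#' @param x,y named per-species traits; names must be tips of the tree.
#' @param tree a `phylo` with branch lengths.
#' @return list with elements `r`, `p`, `n`, and the underlying `fit`.
#' @export
pglsCorrelation <- function(x, y, tree) {
  if (is.null(names(x)) || is.null(names(y))) {
    stop("x and y must be named by species", call. = FALSE)
  }
  species <- intersect(names(x), names(y))
  V <- brownianVCV(tree, species)
  fit <- pglsFit(x[species], y[species], V)
  list(r = fit@r, p = fit@pValue, n = fit@n, fit = fit)
}
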