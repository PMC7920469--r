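## Knockoff statistics: path entry values on the augmented design and the
## signed-max combination W_j = max(Z_j, Zt_j) * sign(Z_j - Zt_j).  Large
## positive W_j means the original entered the path well before its knockoff.

#' Logistic path entry values on the augmented design
#'
#' Sweeps an l1-penalized logistic regression (unpenalized intercept) over a
#' descending log-spaced penalty grid on \code{[X, Xtilde]}, with warm starts,
#' and reports for each variable the largest grid penalty at which its
#' coefficient is nonzero. The grid starts at the smallest penalty giving the
#' all-zero solution, \eqn{\lambda_{max} = \max_j |A_j'(y - \bar y)| / n},
#' and runs down to \code{lambdaMinRatio} times that.
#'
#' @param X n x p design matrix (originals).
#' @param Xtilde n x p knockoff matrix.
#' @param y length-n binary outcome (0/1), both classes present.
#' @param nlambda grid size (default 100).
#' @param lambdaMinRatio ratio of smallest to largest grid value
#'   (default \code{1e-3}).
#' @param lambda optional explicit descending positive grid, overriding the
#'   two parameters above.
#' @return list with components \code{Z}, \code{Ztilde} (length-p, on the
#'   glmnet lambda scale) and \code{lambda} (the grid used).
#' @export
logisticEntryTimes <- function(X, Xtilde, y, nlambda = 100,
                               lambdaMinRatio = 1e-3, lambda = NULL) {
  .assertMatrix(X); .assertMatrix(Xtilde, "Xtilde")
  if (!all(dim(X) == dim(Xtilde)))
    stop("X and Xtilde must have identical dimensions", call. = FALSE)
  y <- as.numeric(y)
  if (length(y) != nrow(X))
    stop("length(y) must equal nrow(X)", call. = FALSE)
  if (!all(y %in% c(0, 1)))
    stop("y must be binary (0/1) for the logistic loss", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("y contains a single class; logistic path undefined", call. = FALSE)
  A <- cbind(X, Xtilde)
  n <- nrow(A); p <- ncol(X)
  if (is.null(lambda)) {
    lamMax <- max(abs(crossprod(A, y - mean(y)))) / n
    lambda <- exp(seq(log(lamMax), log(lamMax * lambdaMinRatio),
                      length.out = nlambda))
  } else {
    if (any(lambda <= 0) || is.unsorted(rev(lambda)))
      stop("lambda must be a descending positive grid", call. = FALSE)
  }
  fit <- glmnet::glmnet(A, y, family = "binomial", lambda = lambda,
                        standardize = FALSE, intercept = TRUE,
                        thresh = 1e-9)
  B <- as.matrix(fit$beta)                       # 2p x n_lambda
  lamUsed <- fit$lambda
  firstNZ <- apply(abs(B) > 1e-8, 1, function(nz)
    if (any(nz)) max(lamUsed[nz]) else 0)
  list(Z = firstNZ[seq_len(p)], Ztilde = firstNZ[p + seq_len(p)],
       lambda = lambda)
}

#' Signed-max knockoff statistic
#'
#' \code{W[j] = max(Z[j], Ztilde[j]) * sign(Z[j] - Ztilde[j])}; in particular
#' \code{W[j] = 0} on ties, and swapping \code{Z[j]} with \code{Ztilde[j]}
#' flips the sign of \code{W[j]} while preserving its magnitude.
#'
#' @param Z,Ztilde equal-length nonnegative entry-value vectors.
#' @return numeric vector W of the same length.
#' @examples
#' signedMaxStatistic(c(3, 0, 1), c(1, 2, 1))  # 3 -2 0
#' @export
signedMaxStatistic <- function(Z, Ztilde) {
  if (length(Z) != length(Ztilde))
    stop("Z and Ztilde must have equal length", call. = FALSE)
  if (any(Z < 0) || any(Ztilde < 0))
    stop("entry values must be nonnegative", call. = FALSE)
  pmax(Z, Ztilde) * sign(Z - Ztilde)
}

#' Knockoff statistics for a design/knockoff pair
#'
#' Computes the path entry values on the augmented design \code{[X, Xtilde]}
#' — the exact lasso path for the linear family, a warm-started penalized
#' logistic grid for the logistic family — and combines them into the
#' signed-max statistic.
#'
#' @param X n x p design matrix.
#' @param Xtilde n x p knockoff matrix.
#' @param y outcome: numeric (linear) or 0/1 (logistic).
#' @param family "linear" or "logistic".
#' @param ... further arguments passed to [logisticEntryTimes()]
#'   (\code{nlambda}, \code{lambdaMinRatio}, \code{lambda}).
#' @return a [KnockoffStatistics-class] object.
#' @export
knockoffStatistics <- function(X, Xtilde, y,
                               family = c("linear", "logistic"), ...) {
  family <- match.arg(family)
  if (family == "linear") {
    et <- lassoEntryTimes(X, Xtilde, y)
    lambda <- numeric(0)
  } else {
    et <- logisticEntryTimes(X, Xtilde, y, ...)
    lambda <- et$lambda
  }
  new("KnockoffStatistics",
      Z = et$Z, Ztilde = et$Ztilde,
      W = signedMaxStatistic(et$Z, et$Ztilde),
      family = family, lambda = lambda)
}
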