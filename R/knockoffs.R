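## Gaussian knockoff construction.
##
## For rows x_i ~ N(0, Sigma), a knockoff row is drawn from the conditional
## law  xt_i | x_i ~ N(x_i - x_i Sigma^{-1} diag(a),  V)  with
## V = 2 diag(a) - diag(a) Sigma^{-1} diag(a), so that the joint covariance
## of (x_i, xt_i) is G = [[Sigma, Sigma - diag(a)], [Sigma - diag(a), Sigma]]
## and originals and knockoffs are exchangeable for null variables.

.symmetrize <- function(m) (m + t(m)) / 2

.minEigen <- function(m) min(eigen(.symmetrize(m), symmetric = TRUE,
                                   only.values = TRUE)$values)

.PD_TOL <- 1e-8

#' Decorrelation vector for Gaussian knockoffs
#'
#' Computes the vector \code{a} entering the knockoff conditional law. The
#' only requirement on \code{a} is that the conditional covariance
#' \eqn{V = 2 diag(a) - diag(a) \Sigma^{-1} diag(a)} stays positive definite;
#' the equicorrelated choice takes every entry equal to
#' \eqn{\min(2\lambda_{\min}(\Sigma), \min_j \Sigma_{jj})}, shrunk by a small
#' slack so V is strictly positive definite. On a correlation matrix this is
#' the familiar \eqn{\min(2\lambda_{\min}, 1)}.
#'
#' @param sigma p x p symmetric positive-definite covariance matrix.
#' @param method "equi" (closed-form equicorrelated choice, default) or
#'   "sdp". No semidefinite-programming solver is available to this package,
#'   so "sdp" falls back to "equi" with a warning.
#' @param eps relative shrinkage applied to the equicorrelated value to keep
#'   V strictly positive definite. Default \code{1e-6}.
#' @return length-p strictly positive numeric vector.
#' @examples
#' computeSVector(diag(3))               # ~ (1, 1, 1)
#' computeSVector(matrix(c(1, .9, .9, 1), 2))  # ~ (0.2, 0.2)
#' @export
computeSVector <- function(sigma, method = c("equi", "sdp"), eps = 1e-6) {
  method <- match.arg(method)
  .assertMatrix(sigma, "sigma")
  if (nrow(sigma) != ncol(sigma)) stop("sigma must be square", call. = FALSE)
  sigma <- .symmetrize(sigma)
  lmin <- .minEigen(sigma)
  if (lmin < .PD_TOL)
    stop("sigma is not positive definite (minimum eigenvalue ",
         format(lmin, digits = 4), ")", call. = FALSE)
  if (method == "sdp") {
    warning("no SDP solver available; falling back to method = 'equi'",
            call. = FALSE)
  }
  aval <- min(2 * lmin, min(diag(sigma))) * (1 - eps)
  rep(aval, nrow(sigma))
}

#' Build a Gaussian knockoff model
#'
#' Precomputes the conditional-law parameters for sampling knockoffs:
#' \code{condShift} = \eqn{\Sigma^{-1} diag(a)} (so the conditional mean of a
#' knockoff row is \code{x - x \%*\% condShift}) and
#' \code{condCov} = \eqn{V = 2 diag(a) - diag(a) \Sigma^{-1} diag(a)},
#' with its Cholesky factor cached.
#'
#' @param sigma p x p symmetric positive-definite covariance matrix.
#' @param a length-p strictly positive decorrelation vector; defaults to
#'   [computeSVector()] on \code{sigma}.
#' @return a [KnockoffModel-class] object.
#' @examples
#' m <- knockoffModel(diag(4))   # identity: knockoffs are fresh N(0, I) rows
#' @export
knockoffModel <- function(sigma, a = computeSVector(sigma)) {
  .assertMatrix(sigma, "sigma")
  sigma <- .symmetrize(sigma)
  p <- nrow(sigma)
  if (length(a) != p)
    stop("length(a) must equal the dimension of sigma", call. = FALSE)
  if (any(a <= 0))
    stop("decorrelation vector a must be strictly positive", call. = FALSE)
  lmin <- .minEigen(sigma)
  if (lmin < .PD_TOL)
    stop("sigma is not positive definite (minimum eigenvalue ",
         format(lmin, digits = 4), ")", call. = FALSE)
  siginvA <- solve(sigma, diag(a, p))        # Sigma^{-1} diag(a)
  condCov <- .symmetrize(diag(2 * a, p) - diag(a, p) %*% siginvA)
  vmin <- .minEigen(condCov)
  if (vmin < .PD_TOL)
    stop("conditional covariance V is not positive definite ",
         "(minimum eigenvalue ", format(vmin, digits = 4),
         "); choose a smaller decorrelation vector a", call. = FALSE)
  new("KnockoffModel",
      sigma = sigma, a = as.numeric(a),
      condShift = siginvA, condCov = condCov,
      condChol = chol(condCov))
}

#' Sample knockoff copies of a design matrix
#'
#' Draws each knockoff row independently from the model's Gaussian
#' conditional law. Deterministic given \code{seed}.
#'
#' @param X n x p numeric design matrix.
#' @param model a [KnockoffModel-class] of matching dimension.
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @return n x p matrix of knockoffs.
#' @examples
#' m <- knockoffModel(diag(3))
#' X <- matrix(rnorm(30), 10, 3)
#' Xt <- sampleKnockoffs(X, m, seed = 1)
#' @export
sampleKnockoffs <- function(X, model, seed = NULL) {
  .assertMatrix(X)
  if (!is(model, "KnockoffModel")) stop("model must be a KnockoffModel",
                                        call. = FALSE)
  p <- length(model@a)
  if (ncol(X) != p)
    stop("X has ", ncol(X), " columns but the model expects ", p,
         call. = FALSE)
  mu <- X - X %*% model@condShift
  withSeed(seed, {
    noise <- matrix(stats::rnorm(nrow(X) * p), nrow(X), p) %*% model@condChol
    mu + noise
  })
}

#' Covariance estimation for knockoff construction
#'
#' "empirical" is the sample covariance; "shrinkage" (default for data mode)
#' is an analytic Ledoit-Wolf-style convex combination of the sample
#' covariance with a scaled identity, which is strictly positive definite
#' even when p >= n.
#'
#' @param X n x p numeric matrix with n >= 2 rows.
#' @param method "shrinkage" (default) or "empirical".
#' @return p x p symmetric covariance estimate.
#' @export
estimateCovariance <- function(X, method = c("shrinkage", "empirical")) {
  method <- match.arg(method)
  .assertMatrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop("need at least 2 rows to estimate a covariance",
                  call. = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  S <- crossprod(Xc) / n            # ML sample covariance
  if (method == "empirical") return(.symmetrize(S * n / (n - 1)))
  ## Ledoit-Wolf (2004) shrinkage toward mu * I
  mu <- sum(diag(S)) / p
  d2 <- sum((S - diag(mu, p))^2) / p
  b2bar <- sum(apply(Xc, 1, function(x) sum((tcrossprod(x) - S)^2))) / (n^2 * p)
  b2 <- min(b2bar, d2)
  w <- if (d2 > 0) b2 / d2 else 1
  .symmetrize(w * diag(mu, p) + (1 - w) * S)
}
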