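#' @import methods
NULL

.checkSquare <- function(m, what) {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m))
    return(sprintf("%s must be a square numeric matrix", what))
  NULL
}

#' Gaussian knockoff model
#'
#' Holds everything needed to sample knockoff copies of a design whose rows
#' are (approximately) N(0, sigma): the covariance \code{sigma}, the positive
#' decorrelation vector \code{a}, and the conditional-law parameters.  Given a
#' row \eqn{x_i}, its knockoff is drawn from
#' \eqn{N(x_i - x_i \Sigma^{-1} diag(a),\; 2 diag(a) - diag(a) \Sigma^{-1} diag(a))}.
#'
#' @slot sigma p x p positive-definite covariance matrix.
#' @slot a length-p strictly positive decorrelation vector; the joint
#'   covariance of an original/knockoff pair is
#'   \eqn{[[\Sigma, \Sigma - diag(a)], [\Sigma - diag(a), \Sigma]]}.
#' @slot condShift p x p matrix \eqn{\Sigma^{-1} diag(a)}; the conditional mean
#'   of the knockoff row is \code{x - x \%*\% condShift}.
#' @slot condCov p x p conditional covariance
#'   \eqn{V = 2 diag(a) - diag(a) \Sigma^{-1} diag(a)}, positive definite.
#' @slot condChol upper-triangular Cholesky factor of \code{condCov}, cached
#'   for sampling.
#'
#' @seealso [knockoffModel()], [sampleKnockoffs()], [computeSVector()]
#' @export
setClass("KnockoffModel",
  representation(
    sigma = "matrix",
    a = "numeric",
    condShift = "matrix",
    condCov = "matrix",
    condChol = "matrix"
  )
)

setValidity("KnockoffModel", function(object) {
  msgs <- c(
    .checkSquare(object@sigma, "sigma"),
    .checkSquare(object@condShift, "condShift"),
    .checkSquare(object@condCov, "condCov")
  )
  p <- nrow(object@sigma)
  if (length(object@a) != p)
    msgs <- c(msgs, "length(a) must equal nrow(sigma)")
  if (any(object@a <= 0))
    msgs <- c(msgs, "decorrelation vector a must be strictly positive")
  if (max(abs(object@sigma - t(object@sigma))) > 1e-8)
    msgs <- c(msgs, "sigma must be symmetric")
  if (length(msgs)) msgs else TRUE
})

#' Path-entry knockoff statistics
#'
#' Per-variable entry values along the regularization path of a penalized fit
#' on the augmented design \code{[X, Xtilde]}: \code{Z[j]} is the largest
#' penalty at which original variable j has a nonzero coefficient,
#' \code{Ztilde[j]} the same for its knockoff, and
#' \code{W[j] = max(Z[j], Ztilde[j]) * sign(Z[j] - Ztilde[j])} the signed-max
#' statistic fed to the selection threshold.
#'
#' @slot Z,Ztilde length-p nonnegative entry values (0 = never entered).
#' @slot W length-p signed-max statistic.
#' @slot family "linear" (lasso path) or "logistic" (l1-penalized logistic).
#' @slot lambda descending penalty grid used for the logistic path;
#'   empty for the linear family, whose path is computed exactly.
#'
#' @seealso [knockoffStatistics()], [signedMaxStatistic()]
#' @export
setClass("KnockoffStatistics",
  representation(
    Z = "numeric",
    Ztilde = "numeric",
    W = "numeric",
    family = "character",
    lambda = "numeric"
  )
)

setValidity("KnockoffStatistics", function(object) {
  msgs <- NULL
  p <- length(object@Z)
  if (length(object@Ztilde) != p || length(object@W) != p)
    msgs <- c(msgs, "Z, Ztilde and W must have equal length")
  if (any(object@Z < 0) || any(object@Ztilde < 0))
    msgs <- c(msgs, "entry values must be nonnegative")
  if (!object@family %in% c("linear", "logistic"))
    msgs <- c(msgs, "family must be 'linear' or 'logistic'")
  if (p > 0) {
    wref <- pmax(object@Z, object@Ztilde) * sign(object@Z - object@Ztilde)
    if (max(abs(object@W - wref)) > 1e-6)
      msgs <- c(msgs, "W inconsistent with signed-max of (Z, Ztilde)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Result of a single knockoff selection
#'
#' @slot q target FDR level in [0, 1].
#' @slot threshold the data-dependent threshold; \code{Inf} when no candidate
#'   satisfies the level (empty selection).
#' @slot selected integer vector of selected variable indices (1-based),
#'   \code{\{j : W[j] >= threshold\}}.
#' @slot plus logical; TRUE for the knockoff+ threshold (the variant with
#'   exact finite-sample FDR control).
#'
#' @seealso [knockoffSelect()], [knockoffThreshold()]
#' @export
setClass("SelectionResult",
  representation(
    q = "numeric",
    threshold = "numeric",
    selected = "integer",
    plus = "logical"
  )
)

setValidity("SelectionResult", function(object) {
  msgs <- NULL
  if (length(object@q) != 1 || object@q < 0 || object@q > 1)
    msgs <- c(msgs, "q must be a single level in [0, 1]")
  if (length(object@threshold) != 1 || object@threshold < 0)
    msgs <- c(msgs, "threshold must be a single nonnegative value")
  if (is.infinite(object@threshold) && length(object@selected) > 0)
    msgs <- c(msgs, "infinite threshold must give an empty selection")
  if (length(msgs)) msgs else TRUE
})

#' Per-run level schedule for aggregation
#'
#' The per-run target levels q_1 >= ... >= q_k used by the aggregation scheme.
#' Mode "geometric" is the recommended halving sequence q_i = q / 2^(i-1)
#' (which sums to slightly more than q for k >= 2); mode "strict" rescales it
#' so the levels sum to q exactly, the condition under which the union of
#' knockoff+ selections provably controls FDR at q.
#'
#' @slot q total target level.
#' @slot k number of runs.
#' @slot levels length-k strictly decreasing levels in (0, 1].
#' @slot mode "geometric" or "strict".
#'
#' @seealso [makeSchedule()]
#' @export
setClass("LevelSchedule",
  representation(
    q = "numeric",
    k = "integer",
    levels = "numeric",
    mode = "character"
  )
)

setValidity("LevelSchedule", function(object) {
  msgs <- NULL
  if (length(object@q) != 1 || object@q <= 0 || object@q > 1)
    msgs <- c(msgs, "q must be a single level in (0, 1]")
  if (length(object@k) != 1 || object@k < 1L)
    msgs <- c(msgs, "k must be a positive integer")
  if (length(object@levels) != object@k)
    msgs <- c(msgs, "levels must have length k")
  if (any(object@levels <= 0) || any(object@levels > 1))
    msgs <- c(msgs, "levels must lie in (0, 1]")
  if (object@k > 1 && any(diff(object@levels) >= 0))
    msgs <- c(msgs, "levels must be strictly decreasing")
  if (!object@mode %in% c("geometric", "strict"))
    msgs <- c(msgs, "mode must be 'geometric' or 'strict'")
  if (identical(object@mode, "strict") &&
      abs(sum(object@levels) - object@q) > 1e-12)
    msgs <- c(msgs, "strict schedule must sum to q within 1e-12")
  if (length(msgs)) msgs else TRUE
})

#' Result of the k-run knockoff aggregation
#'
#' @slot selected union of the per-run selected index sets (sorted, 1-based).
#' @slot perRun list of k [SelectionResult-class] objects, one per run.
#' @slot statistics list of k [KnockoffStatistics-class] objects, one per run.
#' @slot schedule the [LevelSchedule-class] used.
#' @slot plus logical; whether the knockoff+ threshold was used in every run.
#' @slot seed master seed of the run.
#'
#' @seealso [aggregateKnockoffs()]
#' @export
setClass("AggregationResult",
  representation(
    selected = "integer",
    perRun = "list",
    statistics = "list",
    schedule = "LevelSchedule",
    plus = "logical",
    seed = "integer"
  )
)

setValidity("AggregationResult", function(object) {
  msgs <- NULL
  k <- object@schedule@k
  if (length(object@perRun) != k)
    msgs <- c(msgs, "perRun must hold one SelectionResult per scheduled run")
  if (!all(vapply(object@perRun, is, logical(1), class2 = "SelectionResult")))
    msgs <- c(msgs, "perRun entries must be SelectionResult objects")
  uni <- sort(unique(unlist(lapply(object@perRun, function(r) r@selected))))
  if (!identical(object@selected, as.integer(uni)))
    msgs <- c(msgs, "selected must equal the union of the per-run selections")
  if (length(msgs)) msgs else TRUE
})
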