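## The k-run aggregation scheme: run the knockoff (or knockoff+) filter k
## times at levels q_1 >= ... >= q_k and take the union of the selected sets.
## When the levels sum to the total target q and every run uses knockoff+,
## the union controls FDR at q by subadditivity of the per-run bounds.

#' Per-run level schedule
#'
#' "geometric" is the recommended halving sequence \eqn{q_i = q / 2^{i-1}}
#' (its sum exceeds q slightly for k >= 2 but works well in practice);
#' "strict" rescales the same sequence so the levels sum to q exactly,
#' \eqn{q_i = q \cdot 2^{1-i} / (2 - 2^{1-k})}, which is the condition under
#' which the aggregated knockoff+ FDR bound is certified.
#'
#' @param q total target FDR level in (0, 1].
#' @param k number of runs (>= 1). Default 5.
#' @param mode "geometric" (default) or "strict".
#' @return a [LevelSchedule-class] object.
#' @examples
#' scheduleLevels(makeSchedule(0.1, 5))  # 0.1 0.05 0.025 0.0125 0.00625
#' sum(scheduleLevels(makeSchedule(0.1, 5, "strict")))  # exactly 0.1
#' @export
makeSchedule <- function(q, k = 5L, mode = c("geometric", "strict")) {
  mode <- match.arg(mode)
  if (length(q) != 1 || is.na(q) || q <= 0 || q > 1)
    stop("q must be a single level in (0, 1]", call. = FALSE)
  k <- as.integer(k)
  if (length(k) != 1 || is.na(k) || k < 1L)
    stop("k must be a positive integer", call. = FALSE)
  geo <- q / 2^(seq_len(k) - 1)
  levels <- if (mode == "geometric") geo else geo * (q / sum(geo))
  new("LevelSchedule", q = q, k = k, levels = levels, mode = mode)
}

#' Aggregated knockoff selection
#'
#' Runs the knockoff (or knockoff+) filter once per scheduled level — each
#' run with a freshly sampled knockoff matrix by default — and returns the
#' union of the per-run selected sets along with every per-run result.
#' Fully reproducible given \code{seed}: run i draws its knockoffs with a
#' deterministic child seed of the master seed.
#'
#' When \code{sigma} is \code{NULL} the design is centered and scaled to unit
#' column variance and the covariance is estimated on the correlation scale
#' by analytic shrinkage ([estimateCovariance()]); supply \code{sigma} when
#' the sampling covariance is known (e.g. in simulations).
#'
#' @param X n x p numeric design matrix.
#' @param y outcome vector: numeric (linear) or 0/1 (logistic).
#' @param q total target FDR level. Default 0.1.
#' @param k number of runs. Default 5; \code{k = 1} reduces to the plain
#'   knockoff filter at level q.
#' @param family "linear" or "logistic".
#' @param sigma known p x p covariance of the rows of \code{X}, or
#'   \code{NULL} (default) to standardize X and estimate it by shrinkage.
#' @param plus logical; use the knockoff+ threshold in every run.
#'   Default \code{FALSE}.
#' @param scheduleMode "geometric" (default) or "strict"; see
#'   [makeSchedule()].
#' @param sVector optional decorrelation vector; defaults to
#'   [computeSVector()] on the (estimated) covariance.
#' @param sharedKnockoffs logical; if TRUE every run reuses the first run's
#'   knockoff matrix (ablation mode). Default FALSE (fresh knockoffs per
#'   run).
#' @param seed master integer seed. Default 1.
#' @param ... further arguments passed to [knockoffStatistics()] (e.g.
#'   \code{nlambda} for the logistic grid).
#' @return an [AggregationResult-class] object.
#' @examples
#' sim <- generateLinear(n = 120, p = 30, rho = 0.5, nSignal = 5,
#'                       snr = 5, seed = 7)
#' res <- aggregateKnockoffs(sim$X, sim$y, q = 0.2, k = 3,
#'                           sigma = ar1Covariance(30, 0.5), seed = 7)
#' selectedVariables(res)
#' @export
aggregateKnockoffs <- function(X, y, q = 0.1, k = 5L,
                               family = c("linear", "logistic"),
                               sigma = NULL, plus = FALSE,
                               scheduleMode = c("geometric", "strict"),
                               sVector = NULL, sharedKnockoffs = FALSE,
                               seed = 1L, ...) {
  family <- match.arg(family)
  scheduleMode <- match.arg(scheduleMode)
  .assertMatrix(X)
  schedule <- makeSchedule(q, k, scheduleMode)
  if (is.null(sigma)) {
    X <- scale(X)
    if (anyNA(X))
      stop("constant column in X; drop zero-variance variables first",
           call. = FALSE)
    sigma <- estimateCovariance(X, "shrinkage")
  } else {
    .assertMatrix(sigma, "sigma")
    if (ncol(sigma) != ncol(X))
      stop("sigma dimension does not match ncol(X)", call. = FALSE)
  }
  if (is.null(sVector)) sVector <- computeSVector(sigma)
  model <- knockoffModel(sigma, sVector)
  seeds <- childSeeds(seed, schedule@k)
  perRun <- vector("list", schedule@k)
  stats <- vector("list", schedule@k)
  XtShared <- NULL
  for (i in seq_len(schedule@k)) {
    Xt <- if (sharedKnockoffs && !is.null(XtShared)) XtShared
          else sampleKnockoffs(X, model, seed = seeds[i])
    if (sharedKnockoffs && is.null(XtShared)) XtShared <- Xt
    st <- tryCatch(
      knockoffStatistics(X, Xt, y, family = family, ...),
      error = function(e)
        stop("knockoff run ", i, " of ", schedule@k, " failed: ",
             conditionMessage(e), call. = FALSE))
    stats[[i]] <- st
    perRun[[i]] <- knockoffSelect(st@W, schedule@levels[i], plus)
  }
  union <- sort(unique(unlist(lapply(perRun, function(r) r@selected))))
  new("AggregationResult",
      selected = as.integer(union), perRun = perRun, statistics = stats,
      schedule = schedule, plus = isTRUE(plus), seed = as.integer(seed))
}
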