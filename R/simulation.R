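## Simulation designs used to validate the aggregation scheme: AR(1)
## correlated Gaussian designs with a sparse unit-coefficient signal rescaled
## to a target signal-to-noise ratio, under linear or logistic outcomes.

#' AR(1) covariance matrix
#'
#' \eqn{\Sigma_{ij} = \rho^{|i-j|}}; positive definite for |rho| < 1.
#'
#' @param p dimension.
#' @param rho correlation factor in (-1, 1).
#' @return p x p covariance (correlation) matrix.
#' @export
ar1Covariance <- function(p, rho) {
  if (length(rho) != 1 || is.na(rho) || abs(rho) >= 1)
    stop("rho must lie in (-1, 1)", call. = FALSE)
  idx <- seq_len(p)
  rho^abs(outer(idx, idx, "-"))
}

#' Sparse unit coefficient vector
#'
#' Places \code{nSignal} unit coefficients at positions drawn uniformly at
#' random without replacement; the rest are zero.
#'
#' @param p dimension.
#' @param nSignal number of nonzero coefficients (<= p).
#' @param seed optional integer seed; \code{NULL} uses the current RNG state.
#' @return list with \code{beta} (length-p 0/1 vector) and \code{support}
#'   (sorted indices of the nonzero entries).
#' @export
sparseBeta <- function(p, nSignal, seed = NULL) {
  if (nSignal > p) stop("nSignal must not exceed p", call. = FALSE)
  if (nSignal < 0) stop("nSignal must be nonnegative", call. = FALSE)
  support <- withSeed(seed, sort(sample.int(p, nSignal)))
  beta <- numeric(p)
  beta[support] <- 1
  list(beta = beta, support = as.integer(support))
}

#' Rescale coefficients to a target signal-to-noise ratio
#'
#' Returns \eqn{\beta' = c\,\beta} with
#' \eqn{c = \sqrt{snr \cdot n \sigma^2 / \|X\beta\|^2}}, so that
#' \eqn{\|X\beta'\|^2 / (n \sigma^2) = snr} exactly.
#'
#' @param X n x p design matrix.
#' @param beta length-p coefficient vector with \code{X \%*\% beta} not
#'   identically zero.
#' @param snr target signal-to-noise ratio (> 0).
#' @param sigma2 noise variance. Default 1.
#' @return rescaled coefficient vector.
#' @export
rescaleToSnr <- function(X, beta, snr, sigma2 = 1) {
  if (snr <= 0) stop("snr must be positive", call. = FALSE)
  xb2 <- sum((X %*% beta)^2)
  if (xb2 == 0)
    stop("X %*% beta is identically zero; cannot attain a positive SNR",
         call. = FALSE)
  beta * sqrt(snr * nrow(X) * sigma2 / xb2)
}

.drawDesign <- function(n, p, rho) {
  matrix(stats::rnorm(n * p), n, p) %*% chol(ar1Covariance(p, rho))
}

#' Generate one linear-model simulation dataset
#'
#' Rows of X are i.i.d. N(0, Sigma) with AR(1) covariance; \code{nSignal}
#' unit coefficients at random positions are rescaled to the target SNR and
#' \code{y = X beta + u} with \code{u ~ N(0, sigma2 I)}.
#'
#' @param n,p sample and variable counts.
#' @param rho AR(1) correlation.
#' @param nSignal number of nonzero coefficients.
#' @param snr target signal-to-noise ratio \eqn{\|X\beta\|^2/(n\sigma^2)}.
#' @param sigma2 noise variance. Default 1.
#' @param seed optional integer seed.
#' @return list with \code{X}, \code{y}, \code{beta} (rescaled) and
#'   \code{support}.
#' @export
generateLinear <- function(n, p, rho, nSignal, snr, sigma2 = 1, seed = NULL) {
  withSeed(seed, {
    X <- .drawDesign(n, p, rho)
    sb <- sparseBeta(p, nSignal)
    beta <- if (nSignal > 0) rescaleToSnr(X, sb$beta, snr, sigma2) else sb$beta
    y <- drop(X %*% beta) + stats::rnorm(n, sd = sqrt(sigma2))
    list(X = X, y = y, beta = beta, support = sb$support)
  })
}

#' Generate one logistic-model simulation dataset
#'
#' Same design and SNR-rescaled coefficients as [generateLinear()]; outcomes
#' are drawn as \eqn{y_i \sim Bernoulli(1 / (1 + e^{-x_i'\beta}))}. If the
#' draw is degenerate (a single class), it is redrawn once with a warning;
#' a second degenerate draw is an error.
#'
#' @inheritParams generateLinear
#' @return list with \code{X}, \code{y} (0/1), \code{beta} and \code{support}.
#' @export
generateLogistic <- function(n, p, rho, nSignal, snr, sigma2 = 1,
                             seed = NULL) {
  withSeed(seed, {
    X <- .drawDesign(n, p, rho)
    sb <- sparseBeta(p, nSignal)
    beta <- if (nSignal > 0) rescaleToSnr(X, sb$beta, snr, sigma2) else sb$beta
    prob <- stats::plogis(drop(X %*% beta))
    y <- stats::rbinom(n, 1, prob)
    if (length(unique(y)) < 2) {
      warning("degenerate single-class outcome; redrawing once",
              call. = FALSE)
      y <- stats::rbinom(n, 1, prob)
      if (length(unique(y)) < 2)
        stop("outcome degenerate after redraw", call. = FALSE)
    }
    list(X = X, y = y, beta = beta, support = sb$support)
  })
}

#' False discovery and true positive proportions of a selection
#'
#' \code{fdp = |selected \\ support| / max(|selected|, 1)}. The true-positive
#' proportion divides by the support size by default
#' (\code{tpp = |selected ∩ support| / max(|support|, 1)});
#' \code{denominator = "selected"} divides by the selection size instead.
#'
#' @param selected integer vector of selected indices.
#' @param support integer vector of truly active indices.
#' @param denominator "support" (default) or "selected" for the power
#'   denominator.
#' @return named numeric vector \code{c(fdp = , tpp = )}.
#' @examples
#' evaluateSelection(c(1, 2, 3), c(2, 3, 4, 5))  # fdp 1/3, tpp 1/2
#' @export
evaluateSelection <- function(selected, support,
                              denominator = c("support", "selected")) {
  denominator <- match.arg(denominator)
  selected <- unique(as.integer(selected))
  support <- unique(as.integer(support))
  nFalse <- length(setdiff(selected, support))
  nTrue <- length(intersect(selected, support))
  denom <- if (denominator == "support") length(support) else length(selected)
  c(fdp = nFalse / max(1, length(selected)),
    tpp = nTrue / max(1, denom))
}

#' Simulation configuration
#'
#' Bundles and validates the settings of one simulation experiment. The
#' defaults are the linear-design settings used throughout the validation
#' study: n = 200, p = 100, AR(1) rho = 0.5, 20 unit signals rescaled to
#' SNR 5 with unit noise variance, k = 5 runs.
#'
#' @param n,p sample and variable counts.
#' @param rho AR(1) correlation.
#' @param nSignal number of nonzero coefficients.
#' @param snr target signal-to-noise ratio.
#' @param sigma2 noise variance.
#' @param family "linear" or "logistic".
#' @param qGrid target FDR levels to sweep.
#' @param k number of aggregated runs.
#' @param scheduleMode "geometric" or "strict".
#' @param reps repetition count.
#' @param seed master seed.
#' @param nlambda logistic penalty-grid size (ignored for linear).
#' @return an object of class \code{"SimulationConfig"} (a validated list).
#' @export
simulationConfig <- function(n = 200, p = 100, rho = 0.5, nSignal = 20,
                             snr = 5, sigma2 = 1,
                             family = c("linear", "logistic"),
                             qGrid = c(0.05, 0.1, 0.15, 0.2, 0.25, 0.3),
                             k = 5L,
                             scheduleMode = c("geometric", "strict"),
                             reps = 30L, seed = 1L, nlambda = 50L) {
  family <- match.arg(family)
  scheduleMode <- match.arg(scheduleMode)
  stopifnot(n >= 2, p >= 1, nSignal <= p, snr > 0, sigma2 > 0,
            abs(rho) < 1, k >= 1, reps >= 1, nlambda >= 2,
            all(qGrid > 0), all(qGrid <= 1))
  structure(list(n = n, p = p, rho = rho, nSignal = nSignal, snr = snr,
                 sigma2 = sigma2, family = family, qGrid = sort(qGrid),
                 k = as.integer(k), scheduleMode = scheduleMode,
                 reps = as.integer(reps), seed = as.integer(seed),
                 nlambda = as.integer(nlambda)),
            class = "SimulationConfig")
}

#' Run a repeated knockoff/aggregation experiment
#'
#' For each repetition: generates a dataset, samples k independent knockoff
#' matrices from the known AR(1) covariance, computes the signed-max
#' statistic for each, and evaluates — at every level of \code{qGrid}, for
#' the single-run filter (KO, the first run's statistic) and the k-run
#' aggregation (AKO), with both the standard and the knockoff+ threshold —
#' the false discovery and true positive proportions against the true
#' support. KO and AKO share the same datasets and knockoff draws, so their
#' comparison is paired.
#'
#' @param config a [simulationConfig()] object.
#' @return data.frame with columns \code{q}, \code{method} ("KO"/"AKO"),
#'   \code{plus}, \code{mean_fdr}, \code{se_fdr}, \code{mean_power},
#'   \code{se_power}, \code{reps}; repetitions that failed (e.g. a
#'   degenerate logistic outcome) are excluded and counted in the
#'   \code{"failures"} attribute.
#' @export
runExperiment <- function(config) {
  if (!inherits(config, "SimulationConfig"))
    stop("config must come from simulationConfig()", call. = FALSE)
  sigma <- ar1Covariance(config$p, config$rho)
  model <- knockoffModel(sigma, computeSVector(sigma))
  schedules <- lapply(config$qGrid, makeSchedule,
                      k = config$k, mode = config$scheduleMode)
  repSeeds <- childSeeds(config$seed, config$reps)
  grid <- expand.grid(q = config$qGrid, method = c("KO", "AKO"),
                      plus = c(FALSE, TRUE), stringsAsFactors = FALSE)
  fdpAcc <- matrix(NA_real_, config$reps, nrow(grid))
  tppAcc <- matrix(NA_real_, config$reps, nrow(grid))
  failures <- 0L
  for (r in seq_len(config$reps)) {
    res <- tryCatch({
      ss <- childSeeds(repSeeds[r], config$k + 1L)
      dat <- if (config$family == "linear")
        generateLinear(config$n, config$p, config$rho, config$nSignal,
                       config$snr, config$sigma2, seed = ss[config$k + 1L])
      else
        generateLogistic(config$n, config$p, config$rho, config$nSignal,
                         config$snr, config$sigma2, seed = ss[config$k + 1L])
      Wlist <- lapply(seq_len(config$k), function(i) {
        Xt <- sampleKnockoffs(dat$X, model, seed = ss[i])
        st <- knockoffStatistics(dat$X, Xt, dat$y, family = config$family,
                                 nlambda = config$nlambda)
        st@W
      })
      list(Wlist = Wlist, support = dat$support)
    }, error = function(e) NULL)
    if (is.null(res)) { failures <- failures + 1L; next }
    for (g in seq_len(nrow(grid))) {
      qi <- grid$q[g]; plus <- grid$plus[g]
      sel <- if (grid$method[g] == "KO") {
        knockoffSelect(res$Wlist[[1L]], qi, plus)@selected
      } else {
        lv <- schedules[[match(qi, config$qGrid)]]@levels
        sort(unique(unlist(lapply(seq_len(config$k), function(i)
          knockoffSelect(res$Wlist[[i]], lv[i], plus)@selected))))
      }
      ev <- evaluateSelection(sel, res$support)
      fdpAcc[r, g] <- ev[["fdp"]]
      tppAcc[r, g] <- ev[["tpp"]]
    }
  }
  nOk <- colSums(!is.na(fdpAcc))
  out <- data.frame(
    q = grid$q, method = grid$method, plus = grid$plus,
    mean_fdr = colMeans(fdpAcc, na.rm = TRUE),
    se_fdr = apply(fdpAcc, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(nOk, 1)),
    mean_power = colMeans(tppAcc, na.rm = TRUE),
    se_power = apply(tppAcc, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(nOk, 1)),
    reps = nOk
  )
  attr(out, "failures") <- failures
  out
}
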