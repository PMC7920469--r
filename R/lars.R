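## Exact lasso regularization path (LARS homotopy with drops).
##
## Only the entry values are needed downstream: for each column j of A,
## entry[j] is the largest penalty lambda (on the ||A'r||_inf scale, i.e.
## the loss is ||y - A b||^2 / 2 + lambda ||b||_1) at which coefficient j
## is nonzero.  The solution path is piecewise linear in lambda, so entry
## points are breakpoints of the path and are computed exactly rather than
## read off a grid.

lassoEntryPath <- function(A, y, tol = 1e-8) {
  n <- nrow(A); m <- ncol(A)
  y <- y - mean(y)
  G <- crossprod(A)
  cvec <- drop(crossprod(A, y))
  entry <- numeric(m)
  lam <- max(abs(cvec))
  if (!is.finite(lam) || lam <= tol) return(entry)
  active <- integer(0)
  beta <- numeric(m)
  justDropped <- integer(0)
  maxActive <- min(n - 1L, m)
  steps <- 0L
  repeat {
    steps <- steps + 1L
    if (steps > 10L * m || lam <= tol * max(1, entry[1], max(entry))) break
    ## variables at the correlation boundary join the active set
    inact <- setdiff(seq_len(m), c(active, justDropped))
    hit <- inact[abs(cvec[inact]) >= lam - 1e-9 * max(1, lam)]
    if (length(hit)) {
      active <- c(active, hit)
      newcomers <- hit[entry[hit] == 0]
      entry[newcomers] <- lam
    }
    justDropped <- integer(0)
    if (length(active) == 0L || length(active) >= maxActive) break
    s <- sign(cvec[active])
    d <- tryCatch(solve(G[active, active, drop = FALSE], s),
                  error = function(e) NULL)
    if (is.null(d)) break
    ## as lambda decreases by delta: beta_A += delta * d,
    ## c_j -= delta * (G[, A] d)_j, active |c| tracks lam - delta
    slope <- drop(G[, active, drop = FALSE] %*% d)
    inact <- setdiff(seq_len(m), active)
    cands <- lam   # path can always run down to lambda = 0
    if (length(inact)) {
      d1 <- (lam - cvec[inact]) / (1 - slope[inact])
      d2 <- (lam + cvec[inact]) / (1 + slope[inact])
      dj <- c(d1, d2)
      cands <- c(cands, dj[is.finite(dj) & dj > 1e-12])
    }
    dd <- -beta[active] / d
    ddOk <- dd[is.finite(dd) & dd > 1e-12]
    cands <- c(cands, ddOk)
    delta <- min(cands)
    if (!is.finite(delta) || delta <= 0) break
    beta[active] <- beta[active] + delta * d
    cvec <- cvec - delta * slope
    lam <- lam - delta
    ## drop variables whose coefficient reached zero at this breakpoint
    hitZero <- which(abs(beta[active]) < 1e-10 * max(1, max(abs(beta))))
    if (length(hitZero) && length(ddOk) && abs(delta - min(ddOk)) < 1e-12) {
      dropped <- active[hitZero]
      beta[dropped] <- 0
      active <- setdiff(active, dropped)
      justDropped <- dropped
    }
    if (length(active) == 0L && lam <= tol) break
  }
  entry
}

#' Lasso path entry values on the augmented design
#'
#' Fits the exact lasso regularization path on \code{[X, Xtilde]} with the
#' outcome centered and no intercept, and returns for each variable the
#' largest penalty at which its coefficient is nonzero (0 if it never enters).
#' Entry values are breakpoints of the piecewise-linear path, on the
#' \eqn{\max_j |A_j' y|} scale.
#'
#' @param X n x p design matrix (originals).
#' @param Xtilde n x p knockoff matrix.
#' @param y length-n numeric outcome.
#' @return list with components \code{Z} (originals) and \code{Ztilde}
#'   (knockoffs), both length-p and nonnegative.
#' @seealso [knockoffStatistics()] for the full statistic object.
#' @export
lassoEntryTimes <- function(X, Xtilde, y) {
  .assertMatrix(X); .assertMatrix(Xtilde, "Xtilde")
  if (!all(dim(X) == dim(Xtilde)))
    stop("X and Xtilde must have identical dimensions", call. = FALSE)
  if (length(y) != nrow(X))
    stop("length(y) must equal nrow(X)", call. = FALSE)
  if (nrow(X) < 2) stop("need at least 2 observations", call. = FALSE)
  sds <- apply(cbind(X, Xtilde), 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column in the augmented design; ",
         "standardize or drop constant columns first", call. = FALSE)
  p <- ncol(X)
  entry <- lassoEntryPath(cbind(X, Xtilde), as.numeric(y))
  list(Z = entry[seq_len(p)], Ztilde = entry[p + seq_len(p)])
}
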