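## Data-dependent knockoff threshold and selection rule.
##
## T_q  = min{ t in {|W_j| > 0} :      #{j: W_j <= -t} / (#{j: W_j >= t} v 1) <= q }
## T_q+ = min{ t in {|W_j| > 0} : (1 + #{j: W_j <= -t}) / (#{j: W_j >= t} v 1) <= q }
##
## with T = +Inf (empty selection) when no candidate satisfies the level.
## Candidates are the strictly positive magnitudes: W_j = 0 carries no
## evidence either way and is never selected.

#' Knockoff selection threshold
#'
#' @param W numeric vector of signed-max statistics.
#' @param q target FDR level in [0, 1].
#' @param plus logical; TRUE for the knockoff+ variant, whose numerator adds
#'   1 and which controls FDR exactly in finite samples.
#' @return the minimal threshold satisfying the level, or \code{Inf} if none
#'   does (including when all W are zero or W is empty).
#' @examples
#' knockoffThreshold(c(3, -1, 2, -2, 1), q = 0.5)              # 2
#' knockoffThreshold(c(3, -1, 2, -2, 1), q = 0.5, plus = TRUE) # Inf
#' @export
knockoffThreshold <- function(W, q, plus = FALSE) {
  if (length(q) != 1 || is.na(q) || q < 0 || q > 1)
    stop("q must be a single level in [0, 1]", call. = FALSE)
  W <- as.numeric(W)
  if (anyNA(W) || any(!is.finite(W)))
    stop("W must be finite", call. = FALSE)
  cand <- sort(unique(abs(W[W != 0])))
  offset <- if (plus) 1 else 0
  for (t in cand) {
    ratio <- (offset + sum(W <= -t)) / max(1, sum(W >= t))
    if (ratio <= q) return(t)
  }
  Inf
}

#' Run the knockoff selection rule
#'
#' Applies [knockoffThreshold()] and returns the selected set
#' \code{\{j : W[j] >= threshold\}} together with the level and variant used.
#'
#' @inheritParams knockoffThreshold
#' @return a [SelectionResult-class] object.
#' @examples
#' selectedVariables(knockoffSelect(c(3, -1, 2, -2, 1), q = 0.5))  # 1 3
#' @export
knockoffSelect <- function(W, q, plus = FALSE) {
  thr <- knockoffThreshold(W, q, plus)
  sel <- if (is.finite(thr)) which(W >= thr) else integer(0)
  new("SelectionResult", q = q, threshold = thr,
      selected = as.integer(sel), plus = isTRUE(plus))
}
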