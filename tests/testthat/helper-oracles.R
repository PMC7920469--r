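# Independent brute-force oracles used across the suite.

# Exhaustive minimization of the knockoff threshold over every candidate t.
bruteThreshold <- function(W, q, plus = FALSE) {
  cand <- sort(unique(abs(W[W != 0])))
  for (t in cand) {
    neg <- sum(W <= -t)
    pos <- sum(W >= t)
    if (((if (plus) 1 else 0) + neg) / max(1, pos) <= q) return(t)
  }
  Inf
}

# Lasso entry values read off a very fine glmnet grid (grid-based reference
# for the exact path), on the ||A'y||_inf penalty scale.
glmnetEntryTimes <- function(X, Xtilde, y, nlambda = 2000,
                             minRatio = 1e-4) {
  A <- cbind(X, Xtilde)
  yc <- y - mean(y)
  n <- nrow(A)
  lmax <- max(abs(crossprod(A, yc))) / n
  grid <- exp(seq(log(lmax), log(lmax * minRatio), length.out = nlambda))
  fit <- glmnet::glmnet(A, yc, lambda = grid, standardize = FALSE,
                        intercept = FALSE, thresh = 1e-12)
  B <- as.matrix(fit$beta)
  ent <- apply(abs(B) > 1e-7, 1, function(nz)
    if (any(nz)) max(fit$lambda[nz]) else 0) * n
  p <- ncol(X)
  list(Z = ent[seq_len(p)], Ztilde = ent[p + seq_len(p)])
}

# Small correlated linear instance with knockoffs sampled from the truth.
makeLinearInstance <- function(n = 50, p = 5, rho = 0.5, nSignal = 2,
                               snr = 5, seed = 1) {
  sim <- generateLinear(n, p, rho, nSignal, snr, seed = seed)
  model <- knockoffModel(ar1Covariance(p, rho))
  Xt <- sampleKnockoffs(sim$X, model, seed = seed + 1000L)
  c(sim, list(Xtilde = Xt, model = model))
}
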