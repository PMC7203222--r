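# Independent oracles. These re-derive expected values by different routes
# than the production code and must stay independent of it.

# Classic NIPALS PLS1 on an unfolded (samples x variables) matrix:
# w = X'y / |X'y|, t = X w, loading deflation p = X't / t't, y deflated by
# its projection on the scores. Predictions regress the centered response
# on all scores jointly, as any PLS1 variant ultimately does.
nipals_pls1 <- function(X, y, n_lvs) {
  Xc <- sweep(X, 2, colMeans(X))
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  yc <- y - y_mean
  y_res <- yc
  W <- P <- matrix(0, ncol(X), 0)
  Tm <- matrix(0, nrow(X), 0)
  for (f in seq_len(n_lvs)) {
    w <- drop(crossprod(Xc, y_res))
    w <- w / sqrt(sum(w^2))
    t_f <- drop(Xc %*% w)
    p <- drop(crossprod(Xc, t_f)) / sum(t_f^2)
    W <- cbind(W, w)
    P <- cbind(P, p)
    Tm <- cbind(Tm, t_f)
    b <- qr.coef(qr(Tm), yc)
    y_res <- yc - drop(Tm %*% b)
    Xc <- Xc - t_f %*% t(p)
  }
  b <- qr.coef(qr(Tm), yc)
  list(fitted = y_mean + drop(Tm %*% b),
       predict = function(Xnew) {
         Xc_new <- sweep(Xnew, 2, x_mean)
         Tn <- matrix(0, nrow(Xnew), ncol(Tm))
         for (f in seq_len(ncol(Tm))) {
           t_f <- drop(Xc_new %*% W[, f])
           Tn[, f] <- t_f
           Xc_new <- Xc_new - t_f %*% t(P[, f])
         }
         y_mean + drop(Tn %*% b)
       })
}

# Brute-force RMSECV: an explicit leave-one-out loop that refits a model of
# exactly size f from scratch for every left-out sample and every f.
brute_force_rmsecv <- function(dataset, y, max_lvs) {
  n <- length(dataset$samples)
  sapply(seq_len(max_lvs), function(f) {
    errs <- vapply(seq_len(n), function(i) {
      fit <- suppressWarnings(
        fit_npls(dataset_subset(dataset, setdiff(seq_len(n), i)), y[-i],
                 n_lvs = f))
      pred <- suppressWarnings(predict(fit, dataset_subset(dataset, i)))
      y[i] - pred
    }, numeric(1))
    sqrt(mean(errs^2))
  })
}

# Unfold an eem_dataset to a samples x cells matrix over included cells.
unfold_dataset <- function(dataset) {
  idx <- which(!dataset$global_missing)
  matrix(dataset$tensor, nrow = length(dataset$samples))[, idx, drop = FALSE]
}
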