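# Shared fixtures and independent brute-force oracles used across the suite.

feature_cols <- c("pf", "q50", "ent", "q50start", "q50end", "q50min",
                  "dur", "q50maxloc")

# well-separated prototypes for recovery experiments: shrink the within-type
# spread until the smallest between-type gap is at least 6 within-type sds
# (checked by separation_ratio below)
separated_prototypes <- function(sd_scale = 0.1) call_prototypes(sd_scale)

# favorable-condition situation mixtures for recovery experiments: pairwise
# clearly distinct type mixtures (5 near-corners, 5 two-type blends, one
# uniform), unlike the realistic defaults where several situations share
# almost the same mixture
distinct_situation_mixtures <- function() {
  m <- rbind(
    CA = c(0.85, 0.05, 0.04, 0.03, 0.03),
    CR = c(0.05, 0.85, 0.04, 0.03, 0.03),
    AR = c(0.04, 0.03, 0.85, 0.05, 0.03),
    FI = c(0.03, 0.04, 0.05, 0.85, 0.03),
    BN = c(0.03, 0.03, 0.04, 0.05, 0.85),
    AN = c(0.45, 0.45, 0.04, 0.03, 0.03),
    MN = c(0.03, 0.45, 0.45, 0.04, 0.03),
    HU = c(0.03, 0.04, 0.45, 0.44, 0.04),
    IS = c(0.04, 0.03, 0.03, 0.45, 0.45),
    RE = c(0.45, 0.03, 0.04, 0.03, 0.45),
    SU = c(0.20, 0.20, 0.20, 0.20, 0.20))
  colnames(m) <- c("LFs", "LFm", "LFt", "HFs", "HFm")
  m / rowSums(m)
}

# min between-type distance over max within-type sd, in standardized units
separation_ratio <- function(prototypes) {
  mu <- t(vapply(prototypes, function(p) p$mean_features, numeric(8)))
  sds <- t(vapply(prototypes, function(p) p$feature_sd, numeric(8)))
  scale <- apply(mu, 2, stats::sd)
  mu_z <- sweep(mu, 2, scale, "/")
  d <- as.matrix(stats::dist(mu_z))
  diag(d) <- Inf
  min(d) / max(sds / rep(scale, each = nrow(sds)))
}

# exhaustive best-WSS bipartition for small n (oracle for k-means, k = 2)
brute_force_wss2 <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (m in seq_len(2^(n - 1) - 1)) {
    a <- as.integer(intToBits(m))[seq_len(n)] + 1L
    if (length(unique(a)) < 2) next
    w <- 0
    for (g in 1:2) {
      xg <- x[a == g, , drop = FALSE]
      w <- w + sum(sweep(xg, 2, colMeans(xg))^2)
    }
    best <- min(best, w)
  }
  best
}

# best label agreement over all permutations of cluster ids (K small)
best_label_agreement <- function(assign, truth) {
  truth <- as.integer(as.factor(truth))
  assign <- as.integer(as.factor(assign))
  k <- max(truth, assign)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  best <- 0
  for (p in perms(seq_len(k)))
    best <- max(best, mean(p[assign] == truth))
  best
}

# direct Wilks lambda from scatter matrices
wilks_oracle <- function(x, y) {
  y <- as.factor(y)
  gm <- colMeans(x)
  Tm <- crossprod(sweep(x, 2, gm))
  W <- matrix(0, ncol(x), ncol(x))
  for (lv in levels(y)) {
    xg <- x[y == lv, , drop = FALSE]
    W <- W + crossprod(sweep(xg, 2, colMeans(xg)))
  }
  det(W) / det(Tm)
}

# closed-form Gaussian posterior for equal-covariance classes
bayes_posterior_oracle <- function(x, means, cov, prior) {
  covi <- solve(cov)
  ll <- vapply(seq_len(nrow(means)), function(g) {
    d <- sweep(x, 2, means[g, ])
    -0.5 * rowSums((d %*% covi) * d) + log(prior[g])
  }, numeric(nrow(x)))
  e <- exp(ll - apply(ll, 1, max))
  e / rowSums(e)
}

# Lance-Williams agglomeration with the Ward (d2) update, tracking merges
ward_merge_heights_oracle <- function(x) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  active <- seq_len(n)
  sizes <- rep(1, n)
  heights <- numeric(0)
  while (length(active) > 1) {
    da <- d[active, active]
    diag(da) <- Inf
    ij <- which(da == min(da), arr.ind = TRUE)[1, ]
    i <- active[ij[1]]; j <- active[ij[2]]
    heights <- c(heights, d[i, j])
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      d[i, k] <- d[k, i] <- sqrt(
        ((ni + nk) * d[i, k]^2 + (nj + nk) * d[j, k]^2 -
           nk * d[i, j]^2) / (ni + nj + nk))
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

# tiny labelled gaussian dataset for classifier tests
toy_classes <- function(n_per = 20, p = 3, shift = 3, g = 3, seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(g * n_per * p), g * n_per, p) +
    rep(seq(0, by = shift, length.out = g), each = n_per)
  colnames(x) <- paste0("v", seq_len(p))
  list(x = x, y = rep(letters[seq_len(g)], each = n_per))
}
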