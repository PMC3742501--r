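# Repertoire clustering: k-means partitions over the standardized feature
# space, EtaK/PreK cluster-validity curves, representative calls and
# post-hoc naming of the 2- and 5-cluster solutions.

# squared Euclidean distances between rows of x and rows of centers
dist2_to_centers <- function(x, centers) {
  outer(rowSums(x^2), rep(1, nrow(centers))) -
    2 * x %*% t(centers) +
    outer(rep(1, nrow(x)), rowSums(centers^2))
}

# one Lloyd run from given initial centers; empty clusters are reseeded
# from the point currently farthest from its assigned center
lloyd_run <- function(x, centers, max_iter = 100) {
  k <- nrow(centers)
  assign_old <- rep(0L, nrow(x))
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to_centers(x, centers)
    assign <- max.col(-d2, ties.method = "first")
    chosen <- d2[cbind(seq_len(nrow(x)), assign)]
    empty <- setdiff(seq_len(k), unique(assign))
    for (e in empty) {
      far <- which.max(chosen)
      centers[e, ] <- x[far, ]
      assign[far] <- e
      chosen[far] <- 0
    }
    if (identical(assign, assign_old) && length(empty) == 0) break
    assign_old <- assign
    for (g in seq_len(k))
      centers[g, ] <- colMeans(x[assign == g, , drop = FALSE])
  }
  d2 <- dist2_to_centers(x, centers)
  assign <- max.col(-d2, ties.method = "first")
  for (g in seq_len(k))
    centers[g, ] <- colMeans(x[assign == g, , drop = FALSE])
  wss <- sum((x - centers[assign, , drop = FALSE])^2)
  list(assignments = assign, centers = centers, wss = wss)
}

#' Best-of-restarts k-means partition
#'
#' Lloyd's algorithm run from \code{n_restarts} seeded random
#' initializations (initial centroids drawn without replacement from the
#' data); the solution with the lowest total within-cluster sum of squares
#' is kept. Empty clusters arising during iteration are repaired by
#' reseeding from the farthest point. Optionally, extra user-supplied
#' initial center matrices are also tried, which [validity_curve()] uses to
#' keep WSS non-increasing in K.
#'
#' @param x numeric matrix of (standardized) features, calls in rows.
#' @param k number of clusters.
#' @param n_restarts random initializations.
#' @param seed integer seed; results are deterministic given the seed.
#' @param extra_inits optional list of k-by-p matrices of additional
#'   initial centers.
#' @return object of class \code{"cluster_solution"}: list with \code{k},
#'   \code{assignments}, \code{centers}, \code{wss}.
#' @export
kmeans_partition <- function(x, k, n_restarts = 50, seed = 1,
                             extra_inits = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("k = ", k, " exceeds the number of calls (", n, ")")
  n_distinct <- nrow(unique(x))
  if (k > n_distinct)
    stop("k = ", k, " exceeds the number of distinct points (",
         n_distinct, ")")
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      init <- x[sample(n, k), , drop = FALSE]
      fit <- lloyd_run(x, init)
      if (is.null(best) || fit$wss < best$wss) best <- fit
    }
  })
  for (init in extra_inits) {
    fit <- lloyd_run(x, as.matrix(init))
    if (is.null(best) || fit$wss < best$wss) best <- fit
  }
  structure(list(k = k, assignments = best$assignments,
                 centers = best$centers, wss = best$wss),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("k-means partition: k =", x$k, ", n =", length(x$assignments),
      ", WSS =", format(x$wss, digits = 6), "\n")
  print(table(cluster = x$assignments))
  invisible(x)
}

#' EtaK/PreK cluster-validity curve
#'
#' Runs k-means for K = 2..Kmax and reports, per K, the total
#' within-cluster sum of squares WSS_K together with the validity indices
#' EtaK = 1 - WSS_K / WSS_1 (relative variance reduction against the
#' unpartitioned data) and PreK = 1 - WSS_K / WSS_(K-1) (improvement over
#' the previous solution). WSS_1 is the total sum of squares about the
#' grand mean. To keep WSS non-increasing in K, each K additionally tries
#' an initialization made of the previous solution's centers plus the
#' farthest point.
#'
#' @param x numeric matrix of standardized features.
#' @param kmax largest number of clusters (>= 2).
#' @param n_restarts,seed passed to [kmeans_partition()]; the seed for each
#'   K is derived deterministically from \code{seed}.
#' @return object of class \code{"validity_curve"}: a list with
#'   \code{table} (data.frame K, wss, etaK, preK) and \code{solutions}
#'   (the \code{"cluster_solution"} per K).
#' @export
validity_curve <- function(x, kmax = 15, n_restarts = 50, seed = 1) {
  x <- as.matrix(x)
  if (kmax < 2) stop("kmax must be at least 2")
  wss1 <- sum(sweep(x, 2, colMeans(x))^2)
  wss <- numeric(kmax)
  wss[1] <- wss1
  solutions <- vector("list", kmax)
  prev_centers <- matrix(colMeans(x), 1)
  prev_assign <- rep(1L, nrow(x))
  for (k in 2:kmax) {
    # grow the previous centers by the point farthest from its center:
    # guarantees WSS_K <= WSS_(K-1)
    d <- rowSums((x - prev_centers[prev_assign, , drop = FALSE])^2)
    grown <- rbind(prev_centers, x[which.max(d), ])
    sol <- kmeans_partition(x, k, n_restarts, seed = seed + k,
                            extra_inits = list(grown))
    wss[k] <- sol$wss
    solutions[[k]] <- sol
    prev_centers <- sol$centers
    prev_assign <- sol$assignments
  }
  tab <- data.frame(K = seq_len(kmax), wss = wss,
                    etaK = 1 - wss / wss1,
                    preK = c(NA, 1 - wss[-1] / wss[-kmax]))
  structure(list(table = tab, wss1 = wss1, solutions = solutions,
                 kmax = kmax),
            class = "validity_curve")
}

#' @export
print.validity_curve <- function(x, ...) {
  cat("Cluster-validity curve, K = 1..", x$kmax, "\n", sep = "")
  print(transform(x$table, wss = signif(wss, 6), etaK = round(etaK, 4),
                  preK = round(preK, 4)), row.names = FALSE)
  invisible(x)
}

#' @export
plot.validity_curve <- function(x, ...) {
  tab <- x$table
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(tab$K, tab$etaK, type = "b", pch = 16,
                 xlab = "number of clusters K", ylab = "EtaK",
                 ylim = c(0, 1), ...)
  graphics::par(new = TRUE)
  graphics::plot(tab$K, tab$preK, type = "b", pch = 1, lty = 2,
                 axes = FALSE, xlab = "", ylab = "",
                 ylim = range(tab$preK, na.rm = TRUE))
  graphics::axis(4)
  graphics::mtext("PreK", side = 4, line = 2.5)
  invisible(x)
}

#' Representative call of a cluster
#'
#' The cluster member with the smallest Euclidean distance to its centroid;
#' ties are broken to the lowest call index.
#'
#' @param x feature matrix used for clustering.
#' @param solution a \code{"cluster_solution"}.
#' @param cluster cluster id.
#' @return row index (or row name, if \code{x} has them) of the
#'   representative call.
#' @export
representative_call <- function(x, solution, cluster) {
  x <- as.matrix(x)
  members <- which(solution$assignments == cluster)
  if (length(members) == 0) stop("cluster ", cluster, " is empty")
  d <- rowSums((x[members, , drop = FALSE] -
                  matrix(solution$centers[cluster, ], length(members),
                         ncol(x), byrow = TRUE))^2)
  idx <- members[which.min(d)]
  if (!is.null(rownames(x))) rownames(x)[idx] else idx
}

#' Name the clusters of a 2- or 5-cluster solution
#'
#' Applies the repertoire naming convention. K = 2: the cluster with the
#' higher mean q50 is HF, the other LF. K = 5: the two highest-q50 clusters
#' are the HF pair, split by frequency modulation (mean q50end - q50start)
#' into HFm (modulated) and HFs (stable); among the three LF clusters the
#' most tonal one (lowest mean entropy) is LFt, the most modulated of the
#' remaining two is LFm and the last is LFs. For any other K generic names
#' C1..CK are returned with a warning.
#'
#' @param solution a \code{"cluster_solution"}.
#' @param features_natural data.frame of features in natural units (needs
#'   \code{q50}, \code{ent}, \code{q50start}, \code{q50end}), one row per
#'   clustered call.
#' @return named character vector mapping cluster id to label.
#' @export
name_call_types <- function(solution, features_natural) {
  k <- solution$k
  a <- solution$assignments
  stopifnot(nrow(features_natural) == length(a))
  agg <- function(v) tapply(features_natural[[v]], a, mean)
  if (k == 2) {
    q50 <- agg("q50")
    lab <- c("LF", "HF")[rank(q50)]
    names(lab) <- names(q50)
    return(lab)
  }
  if (k == 5) {
    q50 <- agg("q50")
    mod <- agg("q50end") - agg("q50start")
    ent <- agg("ent")
    ids <- names(q50)
    hf <- ids[order(q50, decreasing = TRUE)][1:2]
    lf <- setdiff(ids, hf)
    lab <- character(5)
    names(lab) <- ids
    lab[hf[which.max(mod[hf])]] <- "HFm"
    lab[setdiff(hf, hf[which.max(mod[hf])])] <- "HFs"
    lft <- lf[which.min(ent[lf])]
    lab[lft] <- "LFt"
    rest <- setdiff(lf, lft)
    lfm <- rest[which.max(abs(mod[rest]))]
    lab[lfm] <- "LFm"
    lab[setdiff(rest, lfm)] <- "LFs"
    return(lab)
  }
  warning("naming convention defined for K of 2 or 5 only; using C1..C", k)
  stats::setNames(paste0("C", seq_len(k)),
                  as.character(sort(unique(a))))
}

#' Cross-tabulate the nesting of two cluster solutions
#'
#' For the same set of calls, the proportion of each cluster of solution
#' \code{b} that falls into each cluster of solution \code{a}. Rows (the
#' \code{b} clusters) sum to 1, so perfect nesting shows as rows with a
#' single unit entry.
#'
#' @param a,b \code{"cluster_solution"} objects (or assignment vectors)
#'   over the same calls.
#' @return matrix of proportions, rows = clusters of \code{b}, columns =
#'   clusters of \code{a}.
#' @export
nesting_crosstab <- function(a, b) {
  aa <- if (inherits(a, "cluster_solution")) a$assignments else a
  bb <- if (inherits(b, "cluster_solution")) b$assignments else b
  if (length(aa) != length(bb))
    stop("solutions cover different call sets (", length(aa), " vs ",
         length(bb), " calls)")
  tab <- table(b = bb, a = aa)
  prop.table(tab, margin = 1)
}

#' Discriminant-function loadings for a cluster solution
#'
#' Solves the generalized eigenproblem of the between-cluster against the
#' pooled within-cluster covariance and reports, per discriminant function
#' (ordered by eigenvalue), the standardized coefficients: raw
#' coefficients normalized to unit pooled within-class variance, scaled by
#' the pooled within-class standard deviation of each variable.
#'
#' @param x feature matrix.
#' @param labels cluster/type label per call; >= 2 labels with >= 2 members
#'   each.
#' @return list with \code{eigenvalues}, \code{coef_raw} and
#'   \code{coef_std} (variables x functions).
#' @export
cluster_dfa_loadings <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  cnt <- table(labels)
  if (length(cnt) < 2) stop("need at least 2 clusters")
  if (any(cnt < 2)) stop("every cluster needs at least 2 members")
  n <- nrow(x); g <- length(cnt); p <- ncol(x)
  gm <- colMeans(x)
  means <- rowsum(x, labels) / as.vector(cnt)
  W <- matrix(0, p, p)
  for (lv in levels(labels)) {
    xc <- sweep(x[labels == lv, , drop = FALSE], 2, means[lv, ])
    W <- W + crossprod(xc)
  }
  Sw <- W / (n - g)
  B <- crossprod(sweep(means, 2, gm) * sqrt(as.vector(cnt)))
  Swi <- tryCatch(solve(Sw), error = function(e)
    stop("pooled within-cluster covariance is singular; ",
         "drop collinear variables or add a ridge"))
  es <- eigen(Swi %*% B)
  nf <- min(g - 1, p)
  vals <- Re(es$values)[seq_len(nf)]
  vec <- Re(es$vectors)[, seq_len(nf), drop = FALSE]
  # unit within-class variance, deterministic sign
  for (j in seq_len(nf)) {
    vj <- vec[, j]
    vj <- vj / sqrt(drop(t(vj) %*% Sw %*% vj))
    if (vj[which.max(abs(vj))] < 0) vj <- -vj
    vec[, j] <- vj
  }
  rownames(vec) <- colnames(x)
  colnames(vec) <- paste0("DF", seq_len(nf))
  list(eigenvalues = vals, coef_raw = vec,
       coef_std = vec * sqrt(diag(Sw)))
}
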