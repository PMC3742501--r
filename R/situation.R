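# Situation-level analyses: mean acoustic / call-type profiles per
# situation, Ward dendrograms of situation similarity, call-type x
# situation association with Pearson residuals, and valence models
# (Spearman correlations, quasi-binomial regressions) under BH-FDR control.

#' Per-situation profiles
#'
#' Summarizes calls by situation, either as the mean of each acoustic
#' variable (natural units) or as the proportion of each call type.
#'
#' @param data data.frame with a \code{situation} column and either the
#'   feature columns (acoustic mode) or a \code{type} column (types mode).
#' @param mode \code{"acoustic"} or \code{"types"}.
#' @param features feature columns to average in acoustic mode.
#' @return matrix, situations in rows; in types mode rows sum to 1. The
#'   per-situation call count is attached as attribute \code{"n_calls"}.
#' @export
situation_profiles <- function(data, mode = c("acoustic", "types"),
                               features = feature_names()) {
  mode <- match.arg(mode)
  stopifnot("situation" %in% names(data))
  sit <- as.factor(data$situation)
  if (any(table(sit) < 1)) stop("empty situation level")
  if (mode == "acoustic") {
    miss <- setdiff(features, names(data))
    if (length(miss))
      stop("missing feature column(s): ", paste(miss, collapse = ", "))
    m <- as.matrix(data[, features, drop = FALSE])
    prof <- rowsum(m, sit) / as.vector(table(sit))
  } else {
    if (!"type" %in% names(data)) stop("types mode needs a 'type' column")
    tab <- table(sit, data$type)
    prof <- unclass(prop.table(tab, margin = 1))
  }
  attr(prof, "n_calls") <- as.vector(table(sit))
  attr(prof, "mode") <- mode
  prof
}

#' Ward dendrogram of situation similarity
#'
#' Agglomerative hierarchical clustering of situation profiles with
#' Euclidean distance and Ward's minimum-variance criterion. Acoustic
#' profiles are standardized column-wise first (so variables on different
#' scales contribute equally); type-proportion profiles are used as is.
#'
#' @param profiles matrix from [situation_profiles()] (situations in
#'   rows, unique row names).
#' @param standardize standardize columns before computing distances;
#'   defaults to TRUE for acoustic profiles and FALSE for type profiles.
#' @return object of class \code{"situation_dendrogram"}: list with the
#'   \code{hclust} fit, \code{merges} (merge table with heights) and the
#'   tree serialized as a \code{newick} string.
#' @export
ward_dendrogram <- function(profiles,
                            standardize =
                              identical(attr(profiles, "mode"), "acoustic")) {
  m <- as.matrix(profiles)
  if (nrow(m) < 2) stop("need at least 2 situation profiles")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("profiles need unique situation codes as row names")
  if (standardize) {
    sds <- apply(m, 2, stats::sd)
    m <- m[, sds > 0, drop = FALSE]
    m <- scale(m)
  }
  hc <- stats::hclust(stats::dist(m), method = "ward.D2")
  newick <- ape::write.tree(ape::as.phylo(hc))
  merges <- data.frame(step = seq_len(nrow(hc$merge)),
                       left = hc$merge[, 1], right = hc$merge[, 2],
                       height = hc$height)
  structure(list(hclust = hc, merges = merges, newick = newick),
            class = "situation_dendrogram")
}

#' @export
print.situation_dendrogram <- function(x, ...) {
  cat("Ward/Euclidean situation dendrogram (",
      length(x$hclust$labels), " situations)\n", sep = "")
  cat("newick:", x$newick, "\n")
  invisible(x)
}

#' @export
plot.situation_dendrogram <- function(x, ...) {
  graphics::plot(x$hclust, xlab = "", sub = "",
                 main = "Situation similarity (Ward)", ...)
  invisible(x)
}

#' Call-type by situation association
#'
#' Tests whether call types are distributed at random over situations. The
#' asymptotic Pearson chi-square is used when all expected counts are at
#' least 5; otherwise the p-value is simulated by a Monte-Carlo permutation
#' test holding both table margins fixed. Pearson residuals
#' (obs - exp) / sqrt(exp) are reported with flags at the conventional
#' evidence tiers |r| > 2 and |r| > 4.
#'
#' @param type_labels call type per call (or an already tabulated
#'   contingency table of type x situation).
#' @param situations situation per call (ignored when a table is given).
#' @param n_mc Monte-Carlo replicates (default 2000).
#' @param seed integer seed for the Monte-Carlo draw.
#' @return object of class \code{"association_result"}: list with
#'   \code{table}, \code{statistic}, \code{df} (NA when simulated),
#'   \code{p_value}, \code{monte_carlo}, \code{residuals}, \code{flag2},
#'   \code{flag4}.
#' @export
association_test <- function(type_labels, situations = NULL, n_mc = 2000,
                             seed = 1) {
  tab <- if (is.table(type_labels) || is.matrix(type_labels)) {
    as.table(as.matrix(type_labels))
  } else {
    table(type = type_labels, situation = situations)
  }
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need at least 2 call types and 2 situations")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate margins: empty row or column in the table")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  mc <- any(expected < 5)
  ct <- if (mc) {
    with_seed(seed, suppressWarnings(
      stats::chisq.test(tab, simulate.p.value = TRUE, B = n_mc)))
  } else {
    stats::chisq.test(tab, correct = FALSE)
  }
  res <- ct$residuals
  structure(list(table = tab, statistic = unname(ct$statistic),
                 df = if (mc) NA_real_ else unname(ct$parameter),
                 p_value = unname(ct$p.value), monte_carlo = mc,
                 n_mc = if (mc) n_mc else 0L,
                 residuals = res,
                 flag2 = abs(res) > 2, flag4 = abs(res) > 4),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  if (x$monte_carlo) {
    cat("Chi-square (Monte-Carlo, ", x$n_mc, " replicates): X2 = ",
        round(x$statistic, 1), ", p = ",
        format.pval(x$p_value, digits = 3), "\n", sep = "")
  } else {
    cat("Pearson chi-square: X2 = ", round(x$statistic, 1), ", df = ",
        x$df, ", p = ", format.pval(x$p_value, digits = 3), "\n", sep = "")
  }
  cat("cells with |Pearson residual| > 2:", sum(x$flag2),
      "; > 4:", sum(x$flag4), "\n")
  invisible(x)
}

#' Spearman correlation of situation profiles with valence
#'
#' Correlates each per-situation mean acoustic variable with the mean
#' expert negativity rank (rank 1 = most negative), with exact permutation
#' p-values for small numbers of situations (no ties) and the t
#' approximation otherwise, adjusted across variables by Benjamini-
#' Hochberg.
#'
#' @param profiles situations-by-variables matrix from
#'   [situation_profiles()] (acoustic mode).
#' @param valence named numeric vector of mean ranks, or the data.frame
#'   from [mean_valence()].
#' @return data.frame of class \code{"valence_result"}: one row per
#'   variable with \code{estimate} (rho), \code{p_value}, \code{p_adj},
#'   \code{note}.
#' @export
valence_feature_correlation <- function(profiles, valence) {
  v <- valence_vector(valence)
  m <- as.matrix(profiles)
  if (nrow(m) < 4) stop("need at least 4 situations")
  common <- intersect(rownames(m), names(v))
  if (length(common) < 4)
    stop("fewer than 4 situations shared between profiles and valence")
  m <- m[common, , drop = FALSE]
  v <- v[common]
  rows <- lapply(colnames(m), function(var) {
    xi <- m[, var]
    if (stats::sd(xi) == 0)
      return(data.frame(variable = var, estimate = NA_real_,
                        p_value = NA_real_,
                        note = "constant variable; rho undefined",
                        stringsAsFactors = FALSE))
    ct <- suppressWarnings(
      stats::cor.test(xi, v, method = "spearman",
                      exact = length(v) <= 11 && !anyDuplicated(xi) &&
                        !anyDuplicated(v)))
    data.frame(variable = var, estimate = unname(ct$estimate),
               p_value = ct$p.value, note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  class(out) <- c("valence_result", "data.frame")
  attr(out, "test") <- "spearman"
  out
}

valence_vector <- function(valence) {
  if (is.data.frame(valence)) {
    stopifnot(all(c("situation", "mean_rank") %in% names(valence)))
    stats::setNames(valence$mean_rank, valence$situation)
  } else {
    stopifnot(!is.null(names(valence)))
    valence
  }
}

#' Quasi-binomial regression of call-type use on valence
#'
#' For each call type, regresses the per-situation proportion of calls of
#' that type on the mean expert negativity rank with a logit-link binomial
#' family whose dispersion is estimated from the Pearson chi-square
#' (quasi-binomial), weighting situations by their call totals. The slope
#' is tested by a drop-in-deviance F test with S - 2 residual degrees of
#' freedom; p-values are Benjamini-Hochberg adjusted across types.
#'
#' @param type_counts situations-by-types count matrix (e.g.
#'   \code{table(situation, type)}).
#' @param valence named mean-rank vector or [mean_valence()] output.
#' @return data.frame of class \code{"valence_result"}: per type the slope
#'   \code{estimate} (logit per rank unit), \code{f_value}, \code{df},
#'   \code{dispersion}, \code{p_value}, \code{p_adj}, \code{note}.
#' @export
valence_type_regression <- function(type_counts, valence) {
  v <- valence_vector(valence)
  counts <- as.matrix(type_counts)
  if (nrow(counts) < 4) stop("need at least 4 situations")
  common <- intersect(rownames(counts), names(v))
  if (length(common) < 4)
    stop("fewer than 4 situations shared between counts and valence")
  counts <- counts[common, , drop = FALSE]
  v <- v[common]
  totals <- rowSums(counts)
  if (any(totals <= 0)) stop("situation(s) with zero calls")
  rows <- lapply(colnames(counts), function(tp) {
    k <- counts[, tp]
    prop <- k / totals
    note <- ""
    if (all(prop == 0) || all(prop == 1))
      note <- "complete separation; estimate unreliable"
    fit <- suppressWarnings(
      stats::glm(cbind(k, totals - k) ~ v, family = stats::quasibinomial()))
    an <- suppressWarnings(stats::anova(fit, test = "F"))
    data.frame(type = tp, estimate = unname(stats::coef(fit)[2]),
               f_value = an$F[2], df = fit$df.residual,
               dispersion = summary(fit)$dispersion,
               p_value = an$`Pr(>F)`[2], note = note,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  class(out) <- c("valence_result", "data.frame")
  attr(out, "test") <- "quasibinomial"
  out
}

#' @export
print.valence_result <- function(x, ...) {
  cat("Valence model (", attr(x, "test"), "), BH-adjusted p-values:\n",
      sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(col) signif(col, 3))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
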