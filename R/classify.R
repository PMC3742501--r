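# Situation classification: Gaussian equal-covariance discriminant analysis
# (with an optional ridge for the singular indicator-matrix case), half-split
# holdout validation, label-permutation and subject-permutation (pDFA)
# significance, MANOVA, and the multi-call accuracy simulation.

#' Fit a linear discriminant model
#'
#' Gaussian discriminant with a pooled within-class covariance shared by
#' all classes. Priors default to the training class frequencies. A ridge
#' term can be added to the pooled covariance, which is required when the
#' predictors are a call-type indicator matrix (singular by construction).
#'
#' @param x numeric predictor matrix, calls in rows.
#' @param y class labels (factor or character); every class needs >= 2
#'   members.
#' @param prior \code{"proportions"} (training frequencies) or
#'   \code{"uniform"}.
#' @param ridge non-negative value added to the diagonal of the pooled
#'   covariance.
#' @return object of class \code{"lda_model"}.
#' @export
lda_fit <- function(x, y, prior = c("proportions", "uniform"), ridge = 0) {
  x <- as.matrix(x)
  y <- as.factor(y)
  prior <- match.arg(prior)
  cnt <- table(y)
  if (length(cnt) < 2) stop("need at least 2 classes")
  if (any(cnt < 2))
    stop("class(es) with fewer than 2 calls: ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  fit <- lda_core(x, as.integer(y), length(cnt),
                  prior_prop = (prior == "proportions"), ridge = ridge)
  structure(c(fit, list(classes = levels(y), vars = colnames(x))),
            class = "lda_model")
}

# matrix-only fitting path shared by all resampling loops
lda_core <- function(x, yi, g, prior_prop = TRUE, ridge = 0) {
  n <- nrow(x); p <- ncol(x)
  cnt <- tabulate(yi, g)
  means <- rowsum(x, yi) / cnt
  W <- crossprod(x - means[yi, , drop = FALSE]) / (n - g)
  if (ridge > 0) W <- W + diag(ridge, p)
  coef <- tryCatch(solve(W, t(means)), error = function(e)
    stop("pooled covariance is singular; supply ridge > 0 ",
         "(e.g. ridge = 1e-8)"))
  prior <- if (prior_prop) cnt / n else rep(1 / g, g)
  const <- -0.5 * colSums(t(means) * coef) + log(prior)
  list(means = means, cov = W, prior = prior, coef = coef, const = const)
}

#' @export
print.lda_model <- function(x, ...) {
  cat("Linear discriminant model:", length(x$classes), "classes,",
      nrow(x$coef), "variables\n")
  cat("classes:", paste(x$classes, collapse = ", "), "\n")
  cat("priors:", paste(signif(x$prior, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Predict classes or posteriors from a discriminant model
#'
#' Scores each call against every class and returns the argmax class
#' (exact ties go to the class listed earlier) or the Gaussian posterior
#' probabilities.
#'
#' @param model an \code{"lda_model"}.
#' @param x matrix of new calls; columns must match the training
#'   dimension.
#' @param type \code{"class"} or \code{"posterior"}.
#' @return character vector of classes, or an n-by-G posterior matrix.
#' @export
lda_predict <- function(model, x, type = c("class", "posterior")) {
  type <- match.arg(type)
  x <- as.matrix(x)
  if (ncol(x) != nrow(model$coef))
    stop("predictor dimension mismatch: model has ", nrow(model$coef),
         " variables, data has ", ncol(x))
  scores <- x %*% model$coef +
    matrix(model$const, nrow(x), length(model$const), byrow = TRUE)
  if (type == "class")
    return(model$classes[max.col(scores, ties.method = "first")])
  e <- exp(scores - apply(scores, 1, max))
  post <- e / rowSums(e)
  colnames(post) <- model$classes
  post
}

#' Indicator (dummy) coding of call types
#'
#' One column per call type, each row carrying a single 1 in the column of
#' its type: with types A, B, C a type-C call is coded A = 0, B = 0, C = 1.
#'
#' @param type_labels type label per call.
#' @param levels optional fixed type set; labels outside it are an error
#'   (the predict-time contract).
#' @return integer matrix, one row per call, one column per type; row sums
#'   are all 1.
#' @export
dummy_code_types <- function(type_labels, levels = NULL) {
  type_labels <- as.character(type_labels)
  if (is.null(levels)) levels <- sort(unique(type_labels))
  if (length(levels) < 2)
    stop("need at least 2 call types for indicator coding")
  unseen <- setdiff(unique(type_labels), levels)
  if (length(unseen))
    stop("unseen call type(s): ", paste(unseen, collapse = ", "))
  m <- vapply(levels, function(l) as.integer(type_labels == l),
              integer(length(type_labels)))
  m <- matrix(m, ncol = length(levels),
              dimnames = list(NULL, levels))
  m
}

# half split with every class in both halves; bounded retries
half_split <- function(yi, g, max_attempts = 100) {
  n <- length(yi)
  cnt <- tabulate(yi, g)
  if (any(cnt < 2))
    stop("class(es) too small to appear in both halves: class ",
         paste(which(cnt < 2), collapse = ", "))
  for (a in seq_len(max_attempts)) {
    cal <- sample(n, n %/% 2)
    if (length(unique(yi[cal])) == g &&
        length(unique(yi[-cal])) == g) return(cal)
  }
  stop("could not split data with every class in both halves after ",
       max_attempts, " attempts")
}

# single holdout run on integer labels; returns percent correct (+ pieces)
holdout_core <- function(x, yi, g, ridge = 0, prior_prop = TRUE,
                         details = FALSE) {
  cal <- half_split(yi, g)
  fit <- lda_core(x[cal, , drop = FALSE], yi[cal], g,
                  prior_prop = prior_prop, ridge = ridge)
  xv <- x[-cal, , drop = FALSE]
  scores <- xv %*% fit$coef +
    matrix(fit$const, nrow(xv), g, byrow = TRUE)
  pred <- max.col(scores, ties.method = "first")
  truth <- yi[-cal]
  pct <- 100 * mean(pred == truth)
  if (!details) return(pct)
  list(percent_correct = pct, pred = pred, truth = truth, cal = cal)
}

#' Holdout (half-split) classification of calls to situations
#'
#' Splits the calls into two halves (re-drawn until every class appears in
#' both, at most 100 attempts), fits the discriminant on the calibration
#' half and classifies the validation half.
#'
#' @param x predictor matrix (standardized features or type indicators).
#' @param y class labels.
#' @param seed integer seed controlling the split.
#' @param ridge ridge for the pooled covariance (use > 0 for indicator
#'   predictors).
#' @param prior \code{"proportions"} or \code{"uniform"}.
#' @return object of class \code{"classification_report"} with the
#'   confusion matrix (true x predicted), overall and per-class percent
#'   correct.
#' @export
holdout_classification <- function(x, y, seed = 1, ridge = 0,
                                   prior = c("proportions", "uniform")) {
  prior <- match.arg(prior)
  x <- as.matrix(x)
  y <- as.factor(y)
  g <- nlevels(y)
  res <- with_seed(seed, holdout_core(x, as.integer(y), g, ridge = ridge,
                                      prior_prop = prior == "proportions",
                                      details = TRUE))
  confusion <- table(
    true = factor(levels(y)[res$truth], levels = levels(y)),
    predicted = factor(levels(y)[res$pred], levels = levels(y)))
  per_class <- 100 * diag(confusion) / pmax(1, rowSums(confusion))
  structure(list(confusion = confusion,
                 percent_correct = res$percent_correct,
                 per_class = per_class, n_validation = length(res$truth),
                 chance_percent = NA_real_, p_value = NA_real_,
                 n_permutations = 0L, seed = seed),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Holdout classification:", round(x$percent_correct, 1),
      "% correct over", x$n_validation, "validation calls\n")
  if (x$n_permutations > 0)
    cat("chance level:", round(x$chance_percent, 1), "% (",
        x$n_permutations, "permutations ), p =",
        format.pval(x$p_value, digits = 3), "\n")
  cat("\nConfusion matrix (true x predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' Label-permutation significance of holdout classification
#'
#' Computes the observed holdout accuracy, then rebuilds the null
#' distribution by permuting class labels across calls and repeating the
#' full holdout procedure (fresh half-split per permutation). The chance
#' level is the null mean; the p-value uses the add-one convention
#' p = (1 + #\{null >= observed\}) / (n_perm + 1).
#'
#' @inheritParams holdout_classification
#' @param n_perm number of label permutations (>= 99).
#' @return a \code{"classification_report"} with \code{chance_percent},
#'   \code{p_value} and the \code{null_accuracy} vector filled in.
#' @export
permutation_significance <- function(x, y, n_perm = 1000, seed = 1,
                                     ridge = 0,
                                     prior = c("proportions", "uniform")) {
  if (n_perm < 99) stop("use at least 99 permutations")
  prior <- match.arg(prior)
  x <- as.matrix(x)
  y <- as.factor(y)
  g <- nlevels(y)
  yi <- as.integer(y)
  pp <- prior == "proportions"
  report <- holdout_classification(x, y, seed = seed, ridge = ridge,
                                   prior = prior)
  null_acc <- with_seed(seed + 1L, vapply(seq_len(n_perm), function(b) {
    holdout_core(x, sample(yi), g, ridge = ridge, prior_prop = pp)
  }, numeric(1)))
  report$null_accuracy <- null_acc
  report$chance_percent <- mean(null_acc)
  report$p_value <- (1 + sum(null_acc >= report$percent_correct)) /
    (n_perm + 1)
  report$n_permutations <- n_perm
  report
}

#' Permuted DFA controlling for individual identity
#'
#' When several calls come from the same animal, call-level label
#' permutation overstates significance. Here the permutation unit is the
#' subject: subject-to-class assignments are shuffled (respecting the
#' number of subjects per class), all calls of a subject inheriting its
#' permuted class. The test statistic is the cross-validated (holdout)
#' accuracy recomputed per permutation. Subjects recorded in two classes
#' must be split into subject-class pairs beforehand; this is done
#' automatically with a message.
#'
#' @inheritParams permutation_significance
#' @param subject subject (animal) id per call; each class needs >= 2
#'   subjects.
#' @return list of class \code{"pdfa_result"} with \code{statistic}
#'   (observed percent correct), \code{chance_percent}, \code{p_value},
#'   \code{n_permutations}, \code{null_accuracy}.
#' @export
pdfa <- function(x, y, subject, n_perm = 1000, seed = 1, ridge = 0,
                 prior = c("proportions", "uniform")) {
  if (n_perm < 99) stop("use at least 99 permutations")
  prior <- match.arg(prior)
  pp <- prior == "proportions"
  x <- as.matrix(x)
  y <- as.factor(y)
  g <- nlevels(y)
  yi <- as.integer(y)
  subject <- as.character(subject)
  spans <- tapply(yi, subject, function(v) length(unique(v)))
  if (any(spans > 1)) {
    message(sum(spans > 1),
            " subject(s) span several classes; using subject-class pairs ",
            "as permutation units")
    subject <- paste(subject, yi, sep = ":")
  }
  subj_levels <- unique(subject)
  subj_class <- yi[match(subj_levels, subject)]
  per_class <- table(subj_class)
  if (any(per_class < 2))
    stop("class(es) with a single subject cannot be permuted: ",
         paste(levels(y)[as.integer(names(per_class)[per_class < 2])],
               collapse = ", "))
  si <- match(subject, subj_levels)
  observed <- with_seed(seed, holdout_core(x, yi, g, ridge = ridge,
                                           prior_prop = pp))
  null_acc <- with_seed(seed + 1L, vapply(seq_len(n_perm), function(b) {
    y_perm <- sample(subj_class)[si]
    holdout_core(x, y_perm, g, ridge = ridge, prior_prop = pp)
  }, numeric(1)))
  structure(list(statistic = observed,
                 chance_percent = mean(null_acc),
                 p_value = (1 + sum(null_acc >= observed)) / (n_perm + 1),
                 n_permutations = n_perm, null_accuracy = null_acc,
                 n_subjects = length(subj_levels)),
            class = "pdfa_result")
}

#' @export
print.pdfa_result <- function(x, ...) {
  cat("pDFA (subject-level permutation,", x$n_subjects, "subjects):\n")
  cat("observed accuracy:", round(x$statistic, 1), "%, chance:",
      round(x$chance_percent, 1), "%, p =",
      format.pval(x$p_value, digits = 3), "(", x$n_permutations,
      "permutations )\n")
  invisible(x)
}

#' MANOVA with Wilks lambda
#'
#' Multivariate test of mean differences between classes, reporting Wilks
#' lambda with Rao's F approximation.
#'
#' @param x numeric response matrix.
#' @param y grouping labels.
#' @return list with \code{wilks_lambda}, \code{f_value}, \code{df1},
#'   \code{df2}, \code{p_value}.
#' @export
manova_wilks <- function(x, y) {
  x <- as.matrix(x)
  y <- as.factor(y)
  g <- nlevels(y)
  if (nrow(x) <= ncol(x) + g)
    stop("too few calls for MANOVA: need n > p + number of classes")
  fit <- stats::manova(x ~ y)
  sm <- tryCatch(summary(fit, test = "Wilks")$stats,
                 error = function(e)
                   stop("MANOVA scatter matrix is singular: ",
                        conditionMessage(e)))
  list(wilks_lambda = unname(sm[1, "Wilks"]),
       f_value = unname(sm[1, "approx F"]),
       df1 = unname(sm[1, "num Df"]), df2 = unname(sm[1, "den Df"]),
       p_value = unname(sm[1, "Pr(>F)"]))
}

#' Classification accuracy as a function of calls available
#'
#' Simulates a receiver that has 1..n calls from the same (unknown)
#' situation: per draw, \code{n} calls are sampled without replacement from
#' each situation and summarized by averaging their features (acoustic
#' mode) or by their call-type proportions (types mode); the summarized
#' samples are classified by a discriminant fitted on all remaining calls
#' (leave-sample-out). \code{inner} draws form one repetition; means and
#' 95 percent confidence intervals are taken over \code{outer} repetitions.
#' Situations with fewer than \code{max(n_range)} calls are excluded with
#' a warning.
#'
#' @param x predictor per call: a numeric feature matrix (acoustic mode) or
#'   a vector of call-type labels (types mode).
#' @param y situation (or gross-category) label per call.
#' @param n_range increasing vector of sample sizes (default 1..20).
#' @param inner draws per repetition (default 10).
#' @param outer repetitions (default 20).
#' @param seed integer seed.
#' @param mode \code{"acoustic"} or \code{"types"}.
#' @param ridge ridge for the discriminant; defaults to 1e-8 in types mode
#'   and 0 otherwise.
#' @param prior class prior for the discriminant. Defaults to
#'   \code{"uniform"}: every simulation draw classifies exactly one
#'   averaged sample per situation, so the prior over situations is
#'   uniform by construction of the leave-sample-out design (unlike
#'   single-call holdout, where training frequencies are the natural
#'   prior).
#' @return object of class \code{"accuracy_curve"}: data.frame with
#'   columns \code{n}, \code{mean}, \code{ci_lo}, \code{ci_hi} plus
#'   attributes \code{mode} and \code{n_situations}.
#' @export
multi_call_accuracy <- function(x, y, n_range = 1:20, inner = 10,
                                outer = 20, seed = 1,
                                mode = c("acoustic", "types"),
                                ridge = NULL,
                                prior = c("uniform", "proportions")) {
  mode <- match.arg(mode)
  prior <- match.arg(prior)
  if (is.unsorted(n_range, strictly = TRUE))
    stop("n_range must be strictly increasing")
  if (mode == "types") {
    x <- dummy_code_types(x)
    if (is.null(ridge)) ridge <- 1e-8
  } else {
    x <- as.matrix(x)
    if (is.null(ridge)) ridge <- 0
  }
  y <- as.factor(y)
  cnt <- table(y)
  small <- names(cnt)[cnt < max(n_range)]
  if (length(small)) {
    warning("situation(s) with fewer than ", max(n_range),
            " calls excluded: ", paste(small, collapse = ", "))
    keep <- !(y %in% small)
    x <- x[keep, , drop = FALSE]
    y <- droplevels(y[keep])
  }
  g <- nlevels(y)
  yi <- as.integer(y)
  idx_by_class <- split(seq_along(yi), yi)
  res <- with_seed(seed, {
    out <- vector("list", length(n_range))
    for (ni in seq_along(n_range)) {
      n <- n_range[ni]
      pct <- numeric(outer)
      for (o in seq_len(outer)) {
        correct <- 0L
        for (i in seq_len(inner)) {
          samp <- lapply(idx_by_class, function(ix) sample(ix, n))
          test_rows <- unlist(samp, use.names = FALSE)
          fit <- lda_core(x[-test_rows, , drop = FALSE], yi[-test_rows],
                          g, prior_prop = (prior == "proportions"),
                          ridge = ridge)
          summ <- t(vapply(samp, function(ix)
            colMeans(x[ix, , drop = FALSE]), numeric(ncol(x))))
          scores <- summ %*% fit$coef +
            matrix(fit$const, g, g, byrow = TRUE)
          pred <- max.col(scores, ties.method = "first")
          correct <- correct + sum(pred == seq_len(g))
        }
        pct[o] <- 100 * correct / (inner * g)
      }
      se <- stats::sd(pct) / sqrt(outer)
      out[[ni]] <- data.frame(n = n, mean = mean(pct),
                              ci_lo = mean(pct) - 1.96 * se,
                              ci_hi = mean(pct) + 1.96 * se)
    }
    do.call(rbind, out)
  })
  structure(res, mode = mode, n_situations = g,
            class = c("accuracy_curve", "data.frame"))
}

#' @export
print.accuracy_curve <- function(x, ...) {
  cat("Multi-call classification accuracy (", attr(x, "mode"), " mode, ",
      attr(x, "n_situations"), " classes):\n", sep = "")
  print.data.frame(transform(as.data.frame(x), mean = round(mean, 1),
                             ci_lo = round(ci_lo, 1),
                             ci_hi = round(ci_hi, 1)), row.names = FALSE)
  invisible(x)
}

#' @export
plot.accuracy_curve <- function(x, ...) {
  graphics::plot(x$n, x$mean, type = "b", pch = 15, ylim = c(0, 100),
                 xlab = "calls available", ylab = "% correct", ...)
  graphics::arrows(x$n, x$ci_lo, x$n, x$ci_hi, angle = 90, code = 3,
                   length = 0.03)
  invisible(x)
}
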