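#' Age-adjusted group comparison (ANCOVA)
#'
#' Fits the linear model \code{score ~ age + group} and tests the group term
#' by comparing against the age-only model (Type-II sum of squares for the
#' group effect; no interaction is modelled). Adjusted group means are the
#' model predictions at the grand mean age.
#'
#' @param scores numeric response per participant.
#' @param group group label per participant (>= 2 groups, each with >= 2
#'   members).
#' @param age numeric covariate per participant.
#' @return object of class \code{ancova_result}: \code{f_statistic},
#'   \code{df_between}, \code{df_residual}, \code{p_value},
#'   \code{adjusted_group_means}, and the underlying \code{model}.
#' @examples
#' set.seed(1)
#' g <- rep(c("a", "b", "c"), each = 20)
#' age <- runif(60, 20, 75)
#' y <- 70 + c(a = 0, b = -5, c = -10)[g] - 0.1 * age + rnorm(60, 0, 4)
#' ancova(y, g, age)
#' @export
ancova <- function(scores, group, age) {
  group <- factor(group)
  if (length(scores) != length(group) || length(scores) != length(age))
    stop("input error: scores, group and age must have equal length")
  if (anyNA(scores) || anyNA(group) || anyNA(age))
    stop("input error: missing values are not supported")
  if (nlevels(group) < 2L) stop("need at least two groups")
  if (any(table(group) < 2L)) stop("every group needs >= 2 members")
  dat <- data.frame(scores = scores, group = group, age = age)
  full <- stats::lm(scores ~ age + group, data = dat)
  if (any(is.na(stats::coef(full))))
    stop("design error: singular design (age collinear with group)")
  reduced <- stats::lm(scores ~ age, data = dat)
  cmp <- stats::anova(reduced, full)
  fstat <- cmp$F[2L]
  if (is.na(fstat)) fstat <- 0      # zero residual change, e.g. identical groups
  df_between <- cmp$Df[2L]
  df_residual <- full$df.residual
  pval <- stats::pf(fstat, df_between, df_residual, lower.tail = FALSE)
  nd <- data.frame(age = mean(age), group = levels(group))
  adj <- stats::predict(full, newdata = nd)
  names(adj) <- levels(group)
  structure(list(f_statistic = fstat, df_between = df_between,
                 df_residual = df_residual, p_value = pval,
                 adjusted_group_means = adj, model = full),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA (age-adjusted): F(%d,%d) = %.3f, p = %.4g\n",
              x$df_between, x$df_residual, x$f_statistic, x$p_value))
  cat("Adjusted group means at grand-mean age:\n")
  print(round(x$adjusted_group_means, 2))
  invisible(x)
}

#' Pairwise age-adjusted contrasts from a fitted ANCOVA
#'
#' Computes, for every pair of groups, the difference of adjusted means as a
#' contrast of the full-model coefficients, with a t test on the model's
#' residual degrees of freedom.
#'
#' @param fit an \code{ancova_result}.
#' @return data frame with \code{pair}, \code{estimate}, \code{se},
#'   \code{t}, \code{p_value}.
#' @export
ancova_posthoc <- function(fit) {
  model <- fit$model
  lv <- levels(model$model$group)
  cf <- stats::coef(model)
  V <- stats::vcov(model)
  pairs <- utils::combn(lv, 2L)
  out <- apply(pairs, 2L, function(pr) {
    # contrast vector on the treatment-coded group dummies
    k <- stats::setNames(numeric(length(cf)), names(cf))
    for (g in pr[1L]) if (g != lv[1L]) k[paste0("group", g)] <- 1
    for (g in pr[2L]) if (g != lv[1L]) k[paste0("group", g)] <- k[paste0("group", g)] - 1
    est <- sum(k * cf)
    se <- sqrt(drop(t(k) %*% V %*% k))
    tval <- est / se
    p <- 2 * stats::pt(abs(tval), model$df.residual, lower.tail = FALSE)
    c(estimate = est, se = se, t = tval, p_value = p)
  })
  data.frame(pair = paste(pairs[1L, ], pairs[2L, ], sep = " vs "),
             t(out), stringsAsFactors = FALSE)
}

#' Bonferroni-corrected post hoc decisions
#'
#' Applies the familywise Bonferroni threshold \code{family_alpha /
#' n_comparisons} to a set of pairwise p-values. With the conventional three
#' post hoc comparisons at family alpha 0.05 the per-comparison threshold is
#' 0.05/3 = 0.0167, conventionally reported truncated to three decimals as
#' 0.016.
#'
#' @param p_values named numeric vector (or the data frame returned by
#'   \code{\link{ancova_posthoc}}, whose \code{p_value} column is used).
#' @param n_comparisons size of the comparison family, default 3.
#' @param family_alpha familywise error rate.
#' @return data frame with \code{pair}, \code{p_value}, \code{threshold},
#'   \code{significant}; the threshold and its truncated 3-decimal label are
#'   attached as attributes \code{threshold} and \code{threshold_label}.
#' @export
bonferroni_posthoc <- function(p_values, n_comparisons = 3L,
                               family_alpha = 0.05) {
  if (n_comparisons < 1L) stop("n_comparisons must be >= 1")
  if (is.data.frame(p_values)) {
    pairs <- p_values$pair
    p <- p_values$p_value
  } else {
    p <- as.numeric(p_values)
    pairs <- if (!is.null(names(p_values))) names(p_values)
             else paste0("comparison_", seq_along(p))
  }
  thr <- family_alpha / n_comparisons
  out <- data.frame(pair = pairs, p_value = p, threshold = thr,
                    significant = p < thr, stringsAsFactors = FALSE)
  attr(out, "threshold") <- thr
  attr(out, "threshold_label") <- sprintf("%.3f", floor(thr * 1000) / 1000)
  out
}

#' Within-participant condition comparison with age adjustment
#'
#' Models the per-participant difference between two conditions (e.g.
#' intra- versus cross-dimensional questions) with a centred age covariate;
#' the F statistic tests the intercept, i.e. the condition effect at the
#' mean age.
#'
#' @param score_a,score_b per-participant scores under the two conditions
#'   (same participants, same order).
#' @param age per-participant age.
#' @return object of class \code{ancova_result} with the adjusted mean
#'   difference in \code{adjusted_group_means["difference"]}.
#' @export
paired_condition_compare <- function(score_a, score_b, age) {
  if (length(score_a) != length(score_b) || length(score_a) != length(age))
    stop("input error: lengths differ")
  d <- score_a - score_b
  ac <- age - mean(age)
  fit <- stats::lm(d ~ ac)
  sm <- summary(fit)
  tval <- sm$coefficients["(Intercept)", "t value"]
  if (is.nan(tval)) tval <- 0       # zero-variance difference
  fstat <- tval^2
  dfr <- fit$df.residual
  structure(list(f_statistic = fstat, df_between = 1L, df_residual = dfr,
                 p_value = stats::pf(fstat, 1L, dfr, lower.tail = FALSE),
                 adjusted_group_means = c(difference = unname(stats::coef(fit)[1L])),
                 model = fit),
            class = "ancova_result")
}
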