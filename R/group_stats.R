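## Emotion-specificity statistics: Fisher Z, one-way ANOVA with eta-squared
## and Bonferroni post hocs, and recognition-vs-chance t tests.

#' Fisher Z transformation
#'
#' z = atanh(r), applied to the correlation-valued features (distance
#' correlations, synchronisation) before ANOVA. |r| >= 1 is clipped just
#' inside the open interval with a warning.
#'
#' @param r correlations in [-1, 1] (NA passed through).
#' @return z values.
#' @export
fisher_z <- function(r) {
  bad <- !is.na(r) & abs(r) >= 1
  if (any(bad)) {
    warning("|r| >= 1 clipped before Fisher Z", call. = FALSE)
    r[bad] <- sign(r[bad]) * (1 - 1e-12)
  }
  atanh(r)
}

#' One-way ANOVA with effect size and Bonferroni post hoc tests
#'
#' Classical fixed-effects one-way ANOVA (F, p, eta^2 = SS_between /
#' SS_total, per-group means and SEMs) followed by all-pairs two-sample t
#' tests, Bonferroni-corrected by the number of pairs.
#'
#' @param values numeric feature values, one per scene (NA dropped with its
#'   label).
#' @param labels group labels (e.g. emotions), same length.
#' @param feature_name label carried into the result.
#' @param welch use Welch (unpooled) post hoc t tests (default FALSE =
#'   pooled-variance).
#' @return Object of class \code{anova_result}: list with
#'   \code{feature_name}, \code{F}, \code{df}, \code{p}, \code{eta_sq},
#'   \code{group_means}, \code{group_sems}, \code{posthoc} (data frame with
#'   raw and corrected p values and mean differences).
#' @export
one_way_anova <- function(values, labels, feature_name = "feature",
                          welch = FALSE) {
  keep <- !is.na(values)
  values <- values[keep]
  labels <- as.character(labels)[keep]
  groups <- unique(labels)
  k <- length(groups)
  n <- length(values)
  if (k < 2) stop_dyadkin("one_way_anova needs >= 2 groups")
  if (any(table(labels) < 2))
    stop_dyadkin("one_way_anova needs >= 2 observations per group")
  gm <- tapply(values, labels, mean)[groups]
  gn <- tapply(values, labels, length)[groups]
  gv <- tapply(values, labels, stats::var)[groups]
  grand <- mean(values)
  ss_b <- sum(gn * (gm - grand)^2)
  ss_w <- sum((gn - 1) * gv)
  ss_t <- ss_b + ss_w
  if (ss_w < 1e-300 * max(1, ss_t))
    stop_dyadkin("degenerate ANOVA: zero within-group variance")
  df <- c(between = k - 1L, within = n - k)
  f_stat <- (ss_b / df[1]) / (ss_w / df[2])
  p <- stats::pf(f_stat, df[1], df[2], lower.tail = FALSE)
  eta_sq <- if (ss_t > 0) ss_b / ss_t else 0
  pairs <- utils::combn(groups, 2)
  n_pairs <- ncol(pairs)
  posthoc <- do.call(rbind, lapply(seq_len(n_pairs), function(j) {
    a <- values[labels == pairs[1, j]]
    b <- values[labels == pairs[2, j]]
    tt <- stats::t.test(a, b, var.equal = !welch)
    data.frame(group_a = pairs[1, j], group_b = pairs[2, j],
               mean_diff = mean(a) - mean(b),
               t = unname(tt$statistic), p_raw = tt$p.value,
               p_bonferroni = min(1, n_pairs * tt$p.value),
               stringsAsFactors = FALSE)
  }))
  structure(list(feature_name = feature_name, F = unname(f_stat),
                 df = unname(df), p = unname(p), eta_sq = unname(eta_sq),
                 group_means = gm, group_sems = sqrt(gv / gn),
                 posthoc = posthoc),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("%s: F(%d,%d) = %.2f, p = %.3g, eta^2 = %.2f\n",
              x$feature_name, x$df[1], x$df[2], x$F, x$p, x$eta_sq))
  invisible(x)
}

#' ANOVA table over all features
#'
#' Runs \code{\link{one_way_anova}} per feature column; correlation-valued
#' features (DC_*, SYNC_*) are Fisher-Z transformed first.
#'
#' @param features feature table from \code{\link{extract_features}}.
#' @param feature_names columns to test (default all 20).
#' @return List of \code{anova_result}, named by feature.
#' @export
feature_anova_table <- function(features, feature_names = all_features()) {
  stats::setNames(lapply(feature_names, function(fn) {
    v <- features[[fn]]
    if (grepl("^(DC|SYNC)_", fn)) v <- fisher_z(v)
    one_way_anova(v, features$emotion, feature_name = fn)
  }), feature_names)
}

#' Recognition accuracy versus chance
#'
#' Per-rater, per-emotion recognition accuracies tested against the 4-way
#' chance level of 0.25 with one-sample t tests, Bonferroni-corrected by the
#' number of emotions.
#'
#' @param ratings a \code{rating_set} (columns rater, emotion_true,
#'   response).
#' @param chance chance accuracy (default 0.25).
#' @return Data frame with one row per emotion: mean accuracy, SEM, t, df,
#'   raw and corrected p.
#' @export
recognition_vs_chance <- function(ratings, chance = 0.25) {
  raters <- unique(ratings$rater)
  if (length(raters) < 2)
    stop_dyadkin("recognition_vs_chance needs >= 2 raters")
  emos <- intersect(EMOTIONS, unique(ratings$emotion_true))
  acc <- sapply(emos, function(e) {
    vapply(raters, function(r) {
      sub <- ratings[ratings$rater == r & ratings$emotion_true == e, ]
      mean(sub$response == sub$emotion_true)
    }, numeric(1))
  })
  acc <- matrix(acc, nrow = length(raters),
                dimnames = list(NULL, emos))
  out <- do.call(rbind, lapply(emos, function(e) {
    x <- acc[, e]
    if (stats::sd(x) < 1e-12) {
      tt <- list(statistic = if (mean(x) > chance) Inf else -Inf,
                 parameter = length(x) - 1,
                 p.value = if (mean(x) > chance) 0 else 1)
    } else {
      tt <- stats::t.test(x, mu = chance)
    }
    data.frame(emotion = e, accuracy = mean(x),
               sem = stats::sd(x) / sqrt(length(x)),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value,
               p_bonferroni = min(1, length(emos) * tt$p.value),
               stringsAsFactors = FALSE)
  }))
  attr(out, "per_rater_accuracy") <- acc
  out
}
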