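## Representational similarity analysis: model / feature / behavioural /
## combination RDMs, Kendall tau-A, permutation and signed-rank inference,
## noise ceilings, MDS.

#' Construct a representational dissimilarity matrix
#'
#' @param m n x n numeric matrix (symmetric, zero diagonal, nonnegative;
#'   validated).
#' @param labels scene ids in matrix order.
#' @param flavour one of \code{"model_emotion"}, \code{"model_valence"},
#'   \code{"feature"}, \code{"behav_emotion"}, \code{"behav_valence"},
#'   \code{"combination"}.
#' @param name display name.
#' @return Object of class \code{rdm}.
#' @export
rdm <- function(m, labels, flavour = "feature", name = flavour) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), nrow(m) == length(labels))
  if (max(abs(m - t(m))) > 1e-9) stop_dyadkin("RDM must be symmetric")
  if (max(abs(diag(m))) > 1e-9) stop_dyadkin("RDM must have a zero diagonal")
  if (min(m) < -1e-9) stop_dyadkin("RDM must be nonnegative")
  flavour <- match.arg(flavour, c("model_emotion", "model_valence", "feature",
                                  "behav_emotion", "behav_valence",
                                  "combination"))
  diag(m) <- 0
  m[m < 0] <- 0
  m <- (m + t(m)) / 2
  dimnames(m) <- list(labels, labels)
  structure(list(matrix = m, labels = as.character(labels),
                 flavour = flavour, name = name), class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm '%s'> %s, %d x %d\n", x$name, x$flavour,
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

upper_vec <- function(x) {
  m <- if (inherits(x, "rdm")) x$matrix else x
  m[upper.tri(m)]
}

check_same_labels <- function(a, b) {
  if (!identical(a$labels, b$labels))
    stop_dyadkin("RDMs must share labels and order")
}

#' Categorical model RDM
#'
#' Entry (i, j) is 0 when scenes i and j share a category and 1 otherwise.
#'
#' @param categories per-scene category labels (emotion categories or
#'   valence classes).
#' @param labels scene ids (default names or indices of \code{categories}).
#' @param flavour \code{"model_emotion"} (default) or \code{"model_valence"}.
#' @return An \code{\link{rdm}}.
#' @export
model_rdm <- function(categories, labels = NULL,
                      flavour = c("model_emotion", "model_valence")) {
  flavour <- match.arg(flavour)
  if (anyNA(categories)) stop_dyadkin("every scene must be labelled")
  labels <- labels %||% names(categories) %||% as.character(seq_along(categories))
  m <- 1 - outer(categories, categories, "==")
  storage.mode(m) <- "double"
  rdm(m, labels, flavour, name = flavour)
}

#' Per-feature RDM (absolute difference)
#'
#' @param values per-scene feature scalars.
#' @param labels scene ids.
#' @param name feature name.
#' @return An \code{\link{rdm}}; constant features give an all-zero RDM
#'   with a warning (downstream correlations are then undefined).
#' @export
feature_rdm <- function(values, labels = NULL, name = "feature") {
  labels <- labels %||% names(values) %||% as.character(seq_along(values))
  if (anyNA(values))
    stop_dyadkin("feature '%s' has missing values; impute first", name)
  if (stats::sd(values) < 1e-15)
    warning(sprintf("feature '%s' is constant: all-zero RDM", name),
            call. = FALSE)
  m <- abs(outer(values, values, "-"))
  rdm(m, labels, "feature", name = name)
}

#' Feature RDMs for a whole feature table
#'
#' Missing correlation-valued entries are imputed with the feature's median
#' before the RDM is built.
#'
#' @param features table from \code{\link{extract_features}}.
#' @param feature_names default all 20.
#' @return Named list of \code{\link{rdm}}s.
#' @export
feature_rdms <- function(features, feature_names = all_features()) {
  stats::setNames(lapply(feature_names, function(fn) {
    v <- features[[fn]]
    v[is.na(v)] <- stats::median(v, na.rm = TRUE)
    feature_rdm(v, labels = features$scene_id, name = fn)
  }), feature_names)
}

#' Behavioural RDMs from a rating set
#'
#' Per subject: a binary emotion RDM on the subject's own responses (0 if
#' identical rating, 1 otherwise) and a valence RDM of pairwise absolute
#' rating differences; plus the group-average of each.
#'
#' @param ratings a \code{rating_set}.
#' @return list(emotion = per-subject list of rdm, valence = per-subject
#'   list, group_emotion, group_valence).
#' @export
behavioural_rdms <- function(ratings) {
  ids <- unique(ratings$scene_id)
  raters <- unique(ratings$rater)
  complete <- table(ratings$rater, ratings$scene_id)
  if (any(complete != 1)) {
    miss <- which(complete != 1, arr.ind = TRUE)
    stop_dyadkin("incomplete rating matrix; first missing cell: rater %s, scene %s",
                 rownames(complete)[miss[1, 1]], colnames(complete)[miss[1, 2]])
  }
  emo <- list(); val <- list()
  for (r in raters) {
    sub <- ratings[ratings$rater == r, ]
    sub <- sub[match(ids, sub$scene_id), ]
    me <- 1 - outer(sub$response, sub$response, "==")
    storage.mode(me) <- "double"
    emo[[as.character(r)]] <- rdm(me, ids, "behav_emotion",
                                  name = sprintf("emotion_rater%s", r))
    mv <- abs(outer(sub$valence, sub$valence, "-"))
    storage.mode(mv) <- "double"
    val[[as.character(r)]] <- rdm(mv, ids, "behav_valence",
                                  name = sprintf("valence_rater%s", r))
  }
  avg <- function(lst, flavour, name) {
    m <- Reduce(`+`, lapply(lst, function(r) r$matrix)) / length(lst)
    rdm(m, ids, flavour, name = name)
  }
  list(emotion = emo, valence = val,
       group_emotion = avg(emo, "behav_emotion", "group_emotion"),
       group_valence = avg(val, "behav_valence", "group_valence"))
}

## ---- Kendall tau-A ------------------------------------------------------

# C - D via grouping on the vector with few distinct values: for value
# groups g < h of y, every cross pair contributes sign(x_j - x_i).
tau_num_grouped <- function(x, y) {
  vals <- sort(unique(y))
  groups <- lapply(vals, function(v) sort(x[y == v]))
  cd <- 0
  G <- length(groups)
  for (g in seq_len(G - 1)) {
    sxg <- groups[[g]]
    ng <- length(sxg)
    for (h in (g + 1):G) {
      xj <- groups[[h]]
      le <- findInterval(xj, sxg)                    # #(x_g <= x_j)
      lt <- findInterval(xj, sxg, left.open = TRUE)  # #(x_g <  x_j)
      cd <- cd + sum(lt - (ng - le))
    }
  }
  cd
}

#' Kendall's tau-A between two RDMs (or dissimilarity vectors)
#'
#' (concordant - discordant) / (m(m-1)/2) over all pairs of
#' upper-triangle entries; ties count in the denominator but not the
#' numerator (the tau-A convention, as opposed to tau-b).
#'
#' @param a,b \code{\link{rdm}}s (upper triangles are compared) or plain
#'   numeric vectors of equal length.
#' @return tau-A in [-1, 1]; NA with a warning if either vector is
#'   constant.
#' @export
tau_a <- function(a, b) {
  if (inherits(a, "rdm") && inherits(b, "rdm")) check_same_labels(a, b)
  x <- if (inherits(a, "rdm")) upper_vec(a) else as.numeric(a)
  y <- if (inherits(b, "rdm")) upper_vec(b) else as.numeric(b)
  if (length(x) != length(y)) stop_dyadkin("vector length mismatch")
  m <- length(x)
  n0 <- m * (m - 1) / 2
  ux <- length(unique(x)); uy <- length(unique(y))
  if (ux < 2 || uy < 2) {
    warning("tau_a undefined for a constant vector", call. = FALSE)
    return(NA_real_)
  }
  if (min(ux, uy) <= 64) {
    cd <- if (uy <= ux) tau_num_grouped(x, y) else tau_num_grouped(y, x)
    return(cd / n0)
  }
  ## general case: convert tau-b back to C - D via the tie counts
  tb <- stats::cor(x, y, method = "kendall")
  tie_term <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  cd <- tb * sqrt((n0 - tie_term(x)) * (n0 - tie_term(y)))
  cd / n0
}

#' Correlation between two RDMs
#'
#' @param a,b \code{\link{rdm}}s.
#' @param statistic \code{"tau_a"} or \code{"pearson"}.
#' @return The correlation (NA with warning when degenerate).
#' @export
rdm_cor <- function(a, b, statistic = c("tau_a", "pearson")) {
  statistic <- match.arg(statistic)
  if (statistic == "tau_a") return(tau_a(a, b))
  check_same_labels(a, b)
  x <- upper_vec(a); y <- upper_vec(b)
  if (stats::sd(x) < 1e-15 || stats::sd(y) < 1e-15) {
    warning("pearson undefined for a constant RDM", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y)
}

## ---- model vs feature RDMs ---------------------------------------------

permute_rdm <- function(r, idx) {
  m <- r$matrix[idx, idx]
  dimnames(m) <- list(r$labels, r$labels)
  r$matrix <- m
  r
}

#' Relate model RDMs to feature RDMs
#'
#' Pairwise tau-A among all supplied RDMs; model-vs-feature cells are tested
#' with a two-sided scene-label permutation test and Bonferroni-corrected by
#' the number of features. A 2-D classical MDS embedding of the
#' 1 - tau-A distances is attached.
#'
#' @param model_rdms,feature_rdms named lists of \code{\link{rdm}}s.
#' @param n_perm permutations for the label-permutation test (default
#'   10000; tests and the acceptance script pass smaller values).
#' @param seed RNG seed for the permutations.
#' @return list(tau = full pairwise tau-A matrix, comparisons = data frame
#'   (model, feature, tau, p, p_bonferroni), mds = embedding coordinates).
#' @export
relate_models_to_features <- function(model_rdms, feature_rdms,
                                      n_perm = 10000L, seed = 1L) {
  all_rdms <- c(model_rdms, feature_rdms)
  if (length(all_rdms) < 2) stop_dyadkin("need >= 2 RDMs")
  nm <- names(all_rdms) %||% paste0("rdm", seq_along(all_rdms))
  n <- length(all_rdms)
  taumat <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  diag(taumat) <- 1
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    taumat[i, j] <- taumat[j, i] <-
      suppressWarnings(tau_a(all_rdms[[i]], all_rdms[[j]]))
  }
  ns <- length(all_rdms[[1]]$labels)
  n_feat <- length(feature_rdms)
  comparisons <- with_seed(seed, {
    perm_idx <- replicate(n_perm, sample.int(ns), simplify = FALSE)
    do.call(rbind, lapply(names(model_rdms), function(mn) {
      do.call(rbind, lapply(names(feature_rdms), function(fn) {
        obs <- taumat[mn, fn]
        p <- NA_real_
        if (is.finite(obs)) {
          fr <- feature_rdms[[fn]]
          null <- vapply(perm_idx, function(ix) {
            suppressWarnings(tau_a(permute_rdm(model_rdms[[mn]], ix), fr))
          }, numeric(1))
          p <- (1 + sum(abs(null) >= abs(obs), na.rm = TRUE)) / (n_perm + 1)
        }
        data.frame(model = mn, feature = fn, tau = obs, p = p,
                   p_bonferroni = min(1, n_feat * p),
                   stringsAsFactors = FALSE)
      }))
    }))
  })
  d <- 1 - taumat
  d[!is.finite(d)] <- max(d[is.finite(d)])
  diag(d) <- 0
  mds <- if (n >= 3) stats::cmdscale(stats::as.dist(d), k = 2) else NULL
  list(tau = taumat, comparisons = comparisons, mds = mds)
}

## ---- features vs behaviour ---------------------------------------------

#' Noise ceiling of a subject RDM cohort
#'
#' Upper bound: mean correlation of each subject's RDM with the group-mean
#' RDM (subject included); lower bound: with the leave-that-subject-out
#' group mean.
#'
#' @param subject_rdms list of per-subject \code{\link{rdm}}s (>= 2).
#' @param statistic \code{"tau_a"} or \code{"pearson"}.
#' @return list(lower, upper).
#' @export
noise_ceiling <- function(subject_rdms, statistic = c("tau_a", "pearson")) {
  statistic <- match.arg(statistic)
  ns <- length(subject_rdms)
  if (ns < 2) stop_dyadkin("noise ceiling needs >= 2 subjects")
  labels <- subject_rdms[[1]]$labels
  mats <- lapply(subject_rdms, function(r) r$matrix)
  total <- Reduce(`+`, mats)
  corr <- function(sub, meanmat) {
    suppressWarnings(rdm_cor(sub, rdm(meanmat, labels, sub$flavour),
                             statistic))
  }
  upper <- mean(vapply(seq_len(ns), function(s) {
    corr(subject_rdms[[s]], total / ns)
  }, numeric(1)), na.rm = TRUE)
  lower <- mean(vapply(seq_len(ns), function(s) {
    corr(subject_rdms[[s]], (total - mats[[s]]) / (ns - 1))
  }, numeric(1)), na.rm = TRUE)
  list(lower = lower, upper = upper)
}

#' Relate feature RDMs to per-subject behavioural RDMs
#'
#' Per feature: the across-subject mean correlation with the subject RDMs,
#' a one-sided Wilcoxon signed-rank test across subjects against zero,
#' Holm-Bonferroni corrected p values and Benjamini-Hochberg FDR flags at
#' 0.05, plus the cohort noise ceiling.
#'
#' @param feature_rdms named list of feature \code{\link{rdm}}s.
#' @param subject_rdms list of per-subject behavioural RDMs.
#' @param statistic \code{"tau_a"} (emotion RDMs) or \code{"pearson"}
#'   (valence RDMs).
#' @return list(table = per-feature data frame ranked by mean correlation,
#'   per_subject = feature x subject correlation matrix, ceiling).
#' @export
relate_features_to_behaviour <- function(feature_rdms, subject_rdms,
                                         statistic = c("tau_a", "pearson")) {
  statistic <- match.arg(statistic)
  if (length(subject_rdms) < 2) stop_dyadkin("need >= 2 subjects")
  per_subject <- t(vapply(feature_rdms, function(fr) {
    vapply(subject_rdms, function(sr) {
      suppressWarnings(rdm_cor(fr, sr, statistic))
    }, numeric(1))
  }, numeric(length(subject_rdms))))
  rownames(per_subject) <- names(feature_rdms)
  means <- rowMeans(per_subject, na.rm = TRUE)
  p_raw <- apply(per_subject, 1, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2 || all(abs(v) < 1e-15)) return(1)
    suppressWarnings(stats::wilcox.test(v, alternative = "greater")$p.value)
  })
  tab <- data.frame(feature = names(feature_rdms), mean_cor = means,
                    p_raw = p_raw,
                    p_holm = stats::p.adjust(p_raw, "holm"),
                    fdr_significant = stats::p.adjust(p_raw, "BH") < 0.05,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$mean_cor), ]
  rownames(tab) <- NULL
  list(table = tab, per_subject = per_subject,
       ceiling = noise_ceiling(subject_rdms, statistic))
}

#' Pairwise feature comparisons across subjects
#'
#' Two-sided Wilcoxon signed-rank tests on the per-subject correlation
#' differences for every feature pair, with Benjamini-Hochberg FDR control
#' at 0.05.
#'
#' @param per_subject feature x subject correlation matrix (from
#'   \code{\link{relate_features_to_behaviour}}).
#' @param fdr FDR level (default 0.05).
#' @return list(p = symmetric matrix of raw p values (diagonal NA),
#'   p_fdr = BH-adjusted matrix, significant = logical matrix).
#' @export
pairwise_feature_tests <- function(per_subject, fdr = 0.05) {
  if (ncol(per_subject) < 6)
    stop_dyadkin("signed-rank comparisons need >= 6 subjects")
  nf <- nrow(per_subject)
  nm <- rownames(per_subject)
  p <- matrix(NA_real_, nf, nf, dimnames = list(nm, nm))
  for (i in seq_len(nf - 1)) for (j in (i + 1):nf) {
    d <- per_subject[i, ] - per_subject[j, ]
    d <- d[is.finite(d)]
    p[i, j] <- p[j, i] <- if (!length(d) || all(abs(d) < 1e-15)) 1 else
      suppressWarnings(stats::wilcox.test(d, alternative = "two.sided")$p.value)
  }
  pv <- p[upper.tri(p)]
  adj <- stats::p.adjust(pv, "BH")
  p_fdr <- p
  p_fdr[upper.tri(p_fdr)] <- adj
  p_fdr[lower.tri(p_fdr)] <- t(p_fdr)[lower.tri(p_fdr)]
  list(p = p, p_fdr = p_fdr, significant = p_fdr < fdr)
}

#' Average RDMs into a combination RDM
#'
#' Each input's upper triangle is normalised (min-max to [0, 1] by default,
#' z-scoring optionally) and the normalised geometries are averaged
#' entrywise. Constant inputs are excluded with a warning.
#'
#' @param rdm_list list of >= 2 \code{\link{rdm}}s with identical labels.
#' @param normalize \code{"minmax"} (default) or \code{"zscore"}.
#' @param name name of the combination RDM.
#' @return An \code{\link{rdm}} of flavour \code{"combination"}.
#' @export
combine_rdms <- function(rdm_list, normalize = c("minmax", "zscore"),
                         name = "combination") {
  normalize <- match.arg(normalize)
  stopifnot(length(rdm_list) >= 2)
  labels <- rdm_list[[1]]$labels
  for (r in rdm_list) check_same_labels(rdm_list[[1]], r)
  keep <- vapply(rdm_list, function(r) stats::sd(upper_vec(r)) > 1e-15,
                 logical(1))
  if (!all(keep)) {
    warning("constant RDM(s) excluded from combination", call. = FALSE)
    rdm_list <- rdm_list[keep]
  }
  if (length(rdm_list) < 1) stop_dyadkin("no non-constant RDMs to combine")
  n <- length(labels)
  norm_tri <- vapply(rdm_list, function(r) {
    v <- upper_vec(r)
    if (normalize == "minmax") (v - min(v)) / (max(v) - min(v))
    else as.numeric(scale(v))
  }, numeric(n * (n - 1) / 2))
  avg <- rowMeans(matrix(norm_tri, ncol = length(rdm_list)))
  if (normalize == "zscore") avg <- avg - min(avg)  # keep nonnegative
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- avg
  m <- m + t(m)
  rdm(m, labels, "combination", name = name)
}
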