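# run code under a temporary RNG state so seeded internals don't disturb
# the caller's random stream
.with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' positive is scored above a randomly chosen negative, ties counting one
#' half. Computed from mid-ranks, so it is exact under ties.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1), same length.
#' @return Score in `[0, 1]`, or `NA` with a warning when only one class is
#'   present.
#' @export
#' @examples
#' auc_roc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))  # 1
auc_roc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0L || nn == 0L) {
    warn("single-class labels: AUC-ROC undefined")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-interpolated average precision: predictions are sorted by
#' decreasing score (ties broken by input position) and the precision at
#' each positive's rank is averaged over the positives. Step interpolation
#' avoids the optimism of linear PR interpolation.
#'
#' @inheritParams auc_roc
#' @return Score in `(0, 1]`, or `NA` with a warning when there is no
#'   positive.
#' @export
#' @examples
#' auc_pr(c(0.9, 0.8, 0.7), c(0, 1, 1))  # (1/2 + 2/3) / 2
auc_pr <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  np <- sum(labels == 1)
  if (np == 0L) {
    warn("no positives: AUC-PR undefined")
    return(NA_real_)
  }
  ord <- order(-scores)
  lab <- labels[ord]
  precision_at <- cumsum(lab) / seq_along(lab)
  sum(precision_at[lab == 1]) / np
}

#' Repeated cross-validation of a drug kernel with WNN-GIP
#'
#' Partitions the drugs into `n_folds` near-equal folds (reshuffled each
#' repeat with a seed derived from `seed`), treats each fold's drugs as new
#' compounds — their adjacency rows hidden during training, their profiles
#' imputed — and scores all hidden drug-target pairs with
#' [predict_interactions()]. AUC-ROC and AUC-PR are computed over the
#' pooled hidden pairs of each fold.
#'
#' @param network An `interaction_network`.
#' @param drug_sim Chemical `similarity_matrix` over all drugs, e.g. from
#'   [pairwise_similarity()] (corpus-wide vocabulary for the TF/TF-IDF
#'   kernels).
#' @param target_sim Genomic `similarity_matrix` over all targets.
#' @param config A [gip_config()].
#' @param n_folds Folds per repeat (default 5).
#' @param n_repeats Repeats (default 5).
#' @param seed Master seed; repeat r uses `seed + r`.
#' @param method Label stored in the result (defaults to the kernel name
#'   recorded in `drug_sim`).
#' @return A `cv_result`: use [tidy()] for per-fold scores, [glance()] for
#'   the summary row.
#' @export
cross_validate <- function(network, drug_sim, target_sim,
                           config = gip_config(), n_folds = 5L,
                           n_repeats = 5L, seed = 1L,
                           method = attr(drug_sim, "method")) {
  stopifnot(inherits(network, "interaction_network"))
  n_drugs <- length(network$drug_ids)
  if (n_drugs < n_folds) {
    abort(sprintf("%d drugs cannot form %d folds", n_drugs, n_folds))
  }
  rows <- list()
  for (r in seq_len(n_repeats)) {
    assignment <- .with_local_seed(seed + r,
      sample(rep(seq_len(n_folds), length.out = n_drugs)))
    for (f in seq_len(n_folds)) {
      test_ids <- network$drug_ids[assignment == f]
      S <- predict_interactions(network, drug_sim, target_sim, config,
                                test_drugs = test_ids)
      truth <- network$adjacency[test_ids, , drop = FALSE]
      scores <- as.vector(S[test_ids, , drop = FALSE])
      labels <- as.vector(truth)
      roc <- suppressWarnings(auc_roc(scores, labels))
      pr <- suppressWarnings(auc_pr(scores, labels))
      if (is.na(roc) || is.na(pr)) {
        warn(sprintf("repeat %d fold %d has a single class; fold skipped", r, f))
        next
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        repeat_ = r, fold = f, n_test_drugs = length(test_ids),
        n_pairs = length(labels), auc_roc = roc, auc_pr = pr)
    }
  }
  structure(
    list(method = method %||% "unknown",
         folds = dplyr::bind_rows(rows),
         seed = seed, n_folds = n_folds, n_repeats = n_repeats,
         config = config),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<cv_result> %s: %d x %d-fold CV (seed %d)\n  AUC-ROC %.3f (%.3f)  AUC-PR %.3f (%.3f)\n",
    x$method, x$n_repeats, x$n_folds, x$seed,
    g$mean_auc_roc, g$sd_auc_roc, g$mean_auc_pr, g$sd_auc_pr))
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `cv_result`.
#' @param ... Unused.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$folds

#' @rdname cross_validate
#' @details `glance()` reports standard deviations both over all folds
#'   (`sd_*`) and over the per-repeat means (`sd_*_repeats`), since summary
#'   tables in the literature do not always say which convention they use.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  f <- x$folds
  by_rep <- dplyr::summarise(dplyr::group_by(f, .data$repeat_),
                             roc = mean(.data$auc_roc),
                             pr = mean(.data$auc_pr))
  tibble::tibble(
    method = x$method,
    n_folds = nrow(f),
    mean_auc_roc = mean(f$auc_roc),
    sd_auc_roc = stats::sd(f$auc_roc),
    mean_auc_pr = mean(f$auc_pr),
    sd_auc_pr = stats::sd(f$auc_pr),
    sd_auc_roc_repeats = stats::sd(by_rep$roc),
    sd_auc_pr_repeats = stats::sd(by_rep$pr),
    seed = x$seed
  )
}

#' Paired t-test between two cross-validation results
#'
#' Two-sided paired t-test on the per-fold differences of a metric. The two
#' results must come from matched partitions (same seed, fold counts). A
#' zero-variance nonzero difference is degenerate for the t-statistic and
#' is reported as significant with a warning.
#'
#' @param a,b `cv_result` objects from [cross_validate()] with the same
#'   seed and fold structure.
#' @param metric `"auc_roc"` or `"auc_pr"`.
#' @param alpha Significance level (default 0.05).
#' @return One-row tibble: `statistic`, `p_value`, `significant`,
#'   `mean_diff` (a minus b).
#' @export
paired_ttest <- function(a, b, metric = c("auc_roc", "auc_pr"), alpha = 0.05) {
  metric <- match.arg(metric)
  stopifnot(inherits(a, "cv_result"), inherits(b, "cv_result"))
  if (a$seed != b$seed || a$n_folds != b$n_folds || a$n_repeats != b$n_repeats ||
      nrow(a$folds) != nrow(b$folds)) {
    abort("cv results use different fold partitions; rerun with matched seeds")
  }
  d <- a$folds[[metric]] - b$folds[[metric]]
  if (stats::sd(d) < 1e-12) {
    if (all(abs(d) < 1e-12)) {
      return(tibble::tibble(statistic = 0, p_value = 1, significant = FALSE,
                            mean_diff = 0))
    }
    warn("constant nonzero difference across folds: p-value degenerate at 0")
    return(tibble::tibble(statistic = sign(mean(d)) * Inf, p_value = 0,
                          significant = TRUE, mean_diff = mean(d)))
  }
  tt <- t.test(a$folds[[metric]], b$folds[[metric]], paired = TRUE)
  tibble::tibble(statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 significant = tt$p.value < alpha,
                 mean_diff = mean(d))
}
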