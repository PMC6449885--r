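# Leave-one-out cross-validation with pooled rank-threshold ROC curves,
# cold-start evaluation and the alpha/beta grid sweep.

#' True- and false-positive rates from confusion counts
#'
#' `tpr = TP / (TP + FN)` and `fpr = FP / (TN + FP)`, with the convention
#' that an empty denominator yields 0.
#'
#' @param tp,fp,tn,fn nonnegative counts (vectorised).
#' @return A tibble with columns `tpr` and `fpr`.
#' @export
confusion_rates <- function(tp, fp, tn, fn) {
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be nonnegative", call. = FALSE)
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  tibble::tibble(tpr = safe_div(tp, tp + fn), fpr = safe_div(fp, tn + fp))
}

trapezoid <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Pooled rank-threshold ROC over cross-validation folds
#'
#' Each fold ranks one held-out positive among a candidate list. For every
#' rank cutoff c: a fold contributes a true positive when its held-out rank
#' is at most c; the fold's remaining `min(c, L)` top slots are false
#' positives; candidates below the cutoff split into the false negative (the
#' held-out pair, when missed) and true negatives. Rates are pooled across
#' folds and the AUC is the trapezoidal integral of TPR over FPR.
#'
#' @param folds a data frame with columns `rank` (held-out rank, 1-based)
#'   and `n_candidates` (candidate-list length of that fold).
#' @return An object of class `mda_roc` with elements `points` (per-cutoff
#'   counts and rates), `auc` and `n_folds`.
#' @export
pooled_roc <- function(folds) {
  stopifnot(is.data.frame(folds), all(c("rank", "n_candidates") %in% names(folds)))
  r <- folds$rank
  L <- folds$n_candidates
  if (length(r) == 0) stop("no folds", call. = FALSE)
  if (any(r < 1 | r > L)) stop("held-out rank out of bounds", call. = FALSE)
  cuts <- 0:max(L)
  tp <- vapply(cuts, function(c) sum(r <= c), numeric(1))
  pred_pos <- vapply(cuts, function(c) sum(pmin(c, L)), numeric(1))
  fp <- pred_pos - tp
  nf <- length(r)
  neg <- sum(L - 1)
  fn <- nf - tp
  tn <- neg - fp
  rates <- confusion_rates(tp, fp, tn, fn)
  pts <- tibble::tibble(cutoff = cuts, tp = tp, fp = fp, tn = tn, fn = fn,
                        tpr = rates$tpr, fpr = rates$fpr)
  structure(list(points = pts, auc = trapezoid(pts$fpr, pts$tpr), n_folds = nf),
            class = "mda_roc")
}

#' @export
print.mda_roc <- function(x, ...) {
  cat(sprintf("<pooled ROC over %d fold(s): AUC = %.4f>\n", x$n_folds, x$auc))
  invisible(x)
}

#' @rdname pooled_roc
#' @param x an `mda_roc` object.
#' @param ... unused.
#' @export
tidy.mda_roc <- function(x, ...) x$points

#' @rdname pooled_roc
#' @export
glance.mda_roc <- function(x, ...) tibble::tibble(auc = x$auc, n_folds = x$n_folds)

#' ROC curve plot
#'
#' @param object an `mda_roc` object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mda_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("AUC = %.4f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Tie-corrected rank concordance (Mann-Whitney AUC)
#'
#' The probability that a randomly chosen positive outranks a randomly
#' chosen negative, with ties counted half. Used as the independent
#' cross-check of the pooled rank-threshold ROC.
#'
#' @param scores numeric scores, higher = more confident.
#' @param labels logical (or 0/1) ground-truth labels.
#' @return The concordance AUC, or `NA` if either class is empty.
#' @export
concordance_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-out cross-validation of the recommender
#'
#' Each known association (i, j) is removed in turn, the score column of
#' disease j is recomputed on the modified association matrix, and the
#' held-out miRNA is ranked (descending score, ties by input order) among
#' the candidate set: all miRNAs with no verified association to j in the
#' full data, plus the held-out miRNA itself. Similarity networks depend
#' only on the interaction, family, cluster and MeSH data — never on the
#' associations — so they are computed once outside the loop without
#' leakage. Because every score component is linear in the association
#' matrix, removing one association shifts the j-th score column by exactly
#' `-beta * M[, i]` (`M` the miRNA-space weight matrix); this incremental
#' update equals naive per-fold recomputation.
#'
#' @param fit an [mda_fit()] object.
#' @param alpha,beta optional overrides of the fitted blend weights (the
#'   neighbourhoods `k1`, `k2` are taken from the fit).
#' @return An object of class `mda_cv` with elements `roc` (pooled
#'   [pooled_roc()] result), `folds` (per-fold log: held-out pair, candidate
#'   count, held-out rank), `per_disease` (per-disease pooled AUCs) and
#'   `params`.
#' @export
mda_loocv <- function(fit, alpha = NULL, beta = NULL) {
  stopifnot(inherits(fit, "mda_fit"))
  p <- fit$params
  if (!is.null(alpha)) {
    if (!(alpha > 0 && alpha <= 1)) stop("alpha must lie in (0, 1]", call. = FALSE)
    p$alpha <- alpha
  }
  if (!is.null(beta)) {
    if (!(beta > 0 && beta <= 1)) stop("beta must lie in (0, 1]", call. = FALSE)
    p$beta <- beta
  }
  AS <- fit$assoc
  if (sum(AS) < 1) stop("no known associations to cross-validate", call. = FALSE)
  M <- mirna_space_weights(fit$weights$W1, fit$weights$W2, p$alpha,
                           fit$cluster, p$cluster_fallback)
  fc <- p$beta * (M %*% AS) + (1 - p$beta) * (AS %*% fit$weights$V)
  known <- which(AS == 1, arr.ind = TRUE)
  known <- known[order(known[, 2], known[, 1]), , drop = FALSE]
  nfold <- nrow(known)
  rank_out <- integer(nfold)
  ncand <- integer(nfold)
  for (f in seq_len(nfold)) {
    i <- known[f, 1]; j <- known[f, 2]
    # rounding to 12 decimals makes the id-order tie rule robust to
    # floating-point summation order
    sc <- round(fc[, j] - p$beta * M[, i], 12)
    cand <- sort(c(which(AS[, j] == 0), i))
    ord <- cand[order(-sc[cand], cand)]
    rank_out[f] <- match(i, ord)
    ncand[f] <- length(cand)
  }
  folds <- tibble::tibble(
    mirna = rownames(AS)[known[, 1]],
    disease = colnames(AS)[known[, 2]],
    rank = rank_out,
    n_candidates = ncand
  )
  roc <- pooled_roc(folds)
  per_disease <- folds |>
    dplyr::group_by(.data$disease) |>
    dplyr::summarise(
      n_folds = dplyr::n(),
      auc = pooled_roc(dplyr::pick("rank", "n_candidates"))$auc,
      .groups = "drop"
    )
  structure(list(roc = roc, folds = folds, per_disease = per_disease, params = p),
            class = "mda_cv")
}

#' @export
print.mda_cv <- function(x, ...) {
  cat(sprintf("<LOOCV: %d fold(s), pooled AUC = %.4f, mean per-disease AUC = %.4f>\n",
              x$roc$n_folds, x$roc$auc, mean(x$per_disease$auc)))
  invisible(x)
}

#' @rdname mda_loocv
#' @param x an `mda_cv` object.
#' @param ... unused.
#' @export
tidy.mda_cv <- function(x, ...) x$folds

#' @rdname mda_loocv
#' @export
glance.mda_cv <- function(x, ...) {
  tibble::tibble(auc = x$roc$auc,
                 mean_disease_auc = mean(x$per_disease$auc),
                 n_folds = x$roc$n_folds,
                 alpha = x$params$alpha,
                 beta = x$params$beta)
}

#' @rdname mda_loocv
#' @param object an `mda_cv` object.
#' @export
autoplot.mda_cv <- function(object, ...) autoplot(object$roc)

#' Cold-start evaluation of one disease
#'
#' Removes every known association of the disease, rescored as if newly
#' described: the miRNA-space score vanishes and candidates are ranked by
#' the disease-space score alone. The AUC is the tie-corrected probability
#' that a truly associated miRNA outranks a non-associated one, judged
#' against the original association column.
#'
#' @param fit an [mda_fit()] object.
#' @param disease a disease with at least one known association.
#' @return A list with `rankings` (tibble: rank, mirna, score, known) and
#'   `auc`.
#' @export
isolated_disease_eval <- function(fit, disease) {
  stopifnot(inherits(fit, "mda_fit"))
  ds <- colnames(fit$assoc)
  if (!disease %in% ds) unknown_disease_error(disease, ds)
  j <- match(disease, ds)
  labels <- fit$assoc[, j] == 1
  if (!any(labels))
    stop("disease has no known associations to evaluate against", call. = FALSE)
  AS0 <- fit$assoc
  AS0[, j] <- 0
  p <- fit$params
  sc <- p$beta * (fit$weights$M %*% AS0)[, j] + (1 - p$beta) * (AS0 %*% fit$weights$V)[, j]
  ord <- order(-sc, seq_along(sc))
  rankings <- tibble::tibble(rank = seq_along(ord),
                             mirna = rownames(fit$assoc)[ord],
                             score = unname(sc[ord]),
                             known = unname(labels[ord]))
  list(rankings = rankings, auc = concordance_auc(sc, labels))
}

#' Cold-start evaluation of one miRNA
#'
#' Mirror image of [isolated_disease_eval()]: the miRNA's association row is
#' removed, the disease-space score vanishes, and diseases are ranked by the
#' miRNA-space score alone against the original row labels.
#'
#' @param fit an [mda_fit()] object.
#' @param mirna a miRNA with at least one known association.
#' @return A list with `rankings` (tibble: rank, disease, score, known) and
#'   `auc`.
#' @export
isolated_mirna_eval <- function(fit, mirna) {
  stopifnot(inherits(fit, "mda_fit"))
  ms <- rownames(fit$assoc)
  if (!mirna %in% ms) stop("unknown miRNA: ", mirna, call. = FALSE)
  i <- match(mirna, ms)
  labels <- fit$assoc[i, ] == 1
  if (!any(labels))
    stop("miRNA has no known associations to evaluate against", call. = FALSE)
  AS0 <- fit$assoc
  AS0[i, ] <- 0
  p <- fit$params
  sc <- p$beta * (fit$weights$M %*% AS0)[i, ] + (1 - p$beta) * (AS0 %*% fit$weights$V)[i, ]
  ord <- order(-sc, seq_along(sc))
  rankings <- tibble::tibble(rank = seq_along(ord),
                             disease = colnames(fit$assoc)[ord],
                             score = unname(sc[ord]),
                             known = unname(labels[ord]))
  list(rankings = rankings, auc = concordance_auc(sc, labels))
}

#' Shuffled-label negative control
#'
#' Permutes the disease endpoint of every known association (collapsing any
#' duplicates the permutation creates), decoupling association patterns from
#' both similarity networks while keeping the association count and the
#' miRNA degree distribution approximately intact. Cross-validating against
#' the shuffled matrix should drive the AUC to about 0.5. Note that
#' permuting whole matrix columns would *not* work as a null: the
#' miRNA-space vote is column-local, so relabelling columns merely permutes
#' the score columns with them.
#'
#' @param assoc binary association matrix.
#' @param seed integer seed for the permutation.
#' @return A binary matrix of the same shape and dimnames.
#' @export
shuffle_association_labels <- function(assoc, seed) {
  assoc <- as_assoc_matrix(assoc)
  idx <- which(assoc == 1, arr.ind = TRUE)
  withr::with_seed(as.integer(seed), {
    shuffled <- matrix(0, nrow(assoc), ncol(assoc), dimnames = dimnames(assoc))
    shuffled[cbind(idx[, 1], sample(idx[, 2]))] <- 1
    shuffled
  })
}

#' Grid sweep of the blend weights
#'
#' Runs [mda_loocv()] for every (alpha, beta) combination and reports the
#' pooled AUC; the best cell is attached as attribute `"best"`.
#'
#' @param fit an [mda_fit()] object.
#' @param alphas,betas numeric vectors of blend weights in (0, 1].
#' @return A tibble with columns `alpha`, `beta`, `auc`.
#' @export
parameter_grid <- function(fit, alphas, betas) {
  if (!length(alphas) || !length(betas)) stop("empty parameter grid", call. = FALSE)
  if (any(alphas <= 0 | alphas > 1) || any(betas <= 0 | betas > 1))
    stop("grid values must lie in (0, 1]", call. = FALSE)
  grid <- tidyr::expand_grid(alpha = alphas, beta = betas)
  grid$auc <- purrr::pmap_dbl(grid, function(alpha, beta) {
    mda_loocv(fit, alpha = alpha, beta = beta)$roc$auc
  })
  attr(grid, "best") <- grid[which.max(grid$auc), ]
  grid
}
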