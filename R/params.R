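#' Hyperparameters of the recommender
#'
#' Collects every tunable parameter of the scoring pipeline with its default.
#' The defaults are the operating point used throughout: an even blend of the
#' neighbour and cluster votes in miRNA space (`alpha = 0.5`), a 0.8 / 0.2
#' split between miRNA and disease space (`beta = 0.8`), an even blend of
#' functional and semantic disease similarity (`gamma = 0.5`), 50 miRNA and 30
#' disease neighbours, an ancestor-contribution decay of 0.5 and a 20 kb
#' genomic-cluster threshold.
#'
#' @param alpha weight of the k-nearest-neighbour score against the
#'   genomic-cluster score in miRNA space; in (0, 1].
#' @param beta weight of the miRNA-space score against the disease-space score
#'   in the final blend; in (0, 1].
#' @param gamma weight of gene-interaction functional similarity against MeSH
#'   semantic similarity when integrating disease similarity; in (0, 1).
#' @param k1 number of miRNA neighbours used by the miRNA-space vote.
#' @param k2 number of disease neighbours used by the disease-space vote.
#' @param delta per-edge decay of ancestor contributions in the semantic
#'   similarity measure; in (0, 1).
#' @param cluster_threshold_bp maximum genomic gap, in base pairs, for two
#'   miRNAs to count as members of the same cluster (strict `<`).
#' @param dd_denominator denominator of the semantic-similarity ratio: twice
#'   the smaller semantic value (`"min"`, the default) or the sum of both
#'   semantic values (`"sum"`).
#' @param cluster_fallback miRNA-space blend for miRNAs without any cluster
#'   member: apply the alpha blend to a zero cluster score (`"formula"`, the
#'   default) or fall back to the neighbour score alone (`"renormalize"`).
#'
#' @return A list of class `"mda_params"`.
#' @examples
#' mda_params(alpha = 1)  # disable the cluster vote
#' @export
mda_params <- function(alpha = 0.5, beta = 0.8, gamma = 0.5,
                       k1 = 50L, k2 = 30L, delta = 0.5,
                       cluster_threshold_bp = 20000L,
                       dd_denominator = c("min", "sum"),
                       cluster_fallback = c("formula", "renormalize")) {
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha <= 1))
    stop("alpha must lie in (0, 1]", call. = FALSE)
  if (!(is.numeric(beta) && length(beta) == 1 && beta > 0 && beta <= 1))
    stop("beta must lie in (0, 1]", call. = FALSE)
  if (!(is.numeric(gamma) && length(gamma) == 1 && gamma > 0 && gamma < 1))
    stop("gamma must lie in (0, 1)", call. = FALSE)
  if (!(is.numeric(delta) && length(delta) == 1 && delta > 0 && delta < 1))
    stop("delta must lie in (0, 1)", call. = FALSE)
  k1 <- as.integer(k1); k2 <- as.integer(k2)
  if (is.na(k1) || k1 < 1) stop("k1 must be a positive integer", call. = FALSE)
  if (is.na(k2) || k2 < 1) stop("k2 must be a positive integer", call. = FALSE)
  cluster_threshold_bp <- as.integer(cluster_threshold_bp)
  if (is.na(cluster_threshold_bp) || cluster_threshold_bp <= 0)
    stop("cluster_threshold_bp must be a positive integer", call. = FALSE)
  structure(list(
    alpha = alpha, beta = beta, gamma = gamma, k1 = k1, k2 = k2,
    delta = delta, cluster_threshold_bp = cluster_threshold_bp,
    dd_denominator = match.arg(dd_denominator),
    cluster_fallback = match.arg(cluster_fallback)
  ), class = "mda_params")
}

#' @export
print.mda_params <- function(x, ...) {
  cat("miRNA-disease recommender parameters\n")
  cat(sprintf("  alpha = %g, beta = %g, gamma = %g\n", x$alpha, x$beta, x$gamma))
  cat(sprintf("  k1 = %d miRNA neighbours, k2 = %d disease neighbours\n", x$k1, x$k2))
  cat(sprintf("  delta = %g (semantic decay), cluster threshold = %d bp\n",
              x$delta, x$cluster_threshold_bp))
  cat(sprintf("  semantic denominator = %s, empty-cluster fallback = %s\n",
              x$dd_denominator, x$cluster_fallback))
  invisible(x)
}
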