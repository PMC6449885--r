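# The neighbour-recommendation scores. All four components are weighted
# votes of 0/1 association entries, so each is linear in the association
# matrix: s1 = W1 %*% AS, s2 = W2 %*% AS, S_disease = AS %*% V, with fixed
# weight matrices derived from the similarity networks alone. This linearity
# is what makes leave-one-out recomputation of a single score column exact
# and cheap (see mda_loocv).

# Row-normalised top-k neighbour weights: W[i, k] is miRNA k's share of the
# vote for miRNA i. Self is excluded; only neighbours with positive
# similarity vote; ties in the descending similarity sort are broken by the
# stable input id order.
neighbor_weight_matrix <- function(sim, k) {
  s <- sim_values(sim)
  n <- nrow(s)
  W <- matrix(0, n, n, dimnames = dimnames(s))
  for (i in seq_len(n)) {
    row <- s[i, ]
    ord <- order(-row, seq_len(n))
    ord <- ord[ord != i]
    ord <- ord[row[ord] > 0]
    sel <- head(ord, k)
    tot <- sum(row[sel])
    if (length(sel) && tot > 0) W[i, sel] <- row[sel] / tot
  }
  W
}

# Cluster-vote weights: every cluster member votes, weighted by similarity.
cluster_weight_matrix <- function(sim, clu) {
  s <- sim_values(sim)
  if (!identical(dimnames(s), dimnames(clu)))
    stop("id order mismatch between similarity and cluster matrices", call. = FALSE)
  n <- nrow(s)
  W <- matrix(0, n, n, dimnames = dimnames(s))
  for (i in seq_len(n)) {
    members <- which(clu[i, ] == 1)
    if (!length(members)) next
    tot <- sum(s[i, members])
    if (tot > 0) W[i, members] <- s[i, members] / tot
  }
  W
}

# Disease-space weights as a column-oriented matrix: V[k, j] is disease k's
# share of the vote for disease j.
disease_weight_matrix <- function(sd, k2) {
  t(neighbor_weight_matrix(sd, k2))
}

# Blend the two miRNA-space weight matrices. Under the default "formula"
# fallback the alpha blend applies unconditionally (a miRNA with no cluster
# simply gets alpha * s1); under "renormalize", rows without any cluster
# member use the neighbour vote alone.
mirna_space_weights <- function(W1, W2, alpha, clu, cluster_fallback = "formula") {
  M <- alpha * W1 + (1 - alpha) * W2
  if (cluster_fallback == "renormalize") {
    no_cluster <- rowSums(clu) == 0
    M[no_cluster, ] <- W1[no_cluster, , drop = FALSE]
  }
  M
}

check_ids <- function(id, pool, what) {
  if (!id %in% pool) stop("unknown ", what, ": ", id, call. = FALSE)
}

#' miRNA-space neighbour score for one pair
#'
#' Weighted vote of the `k1` most similar miRNAs of `mirna` (self excluded,
#' positive similarity only, ties by input order): the sum of neighbour
#' similarities of neighbours associated with `disease`, divided by the sum
#' over all selected neighbours. A zero denominator yields 0.
#'
#' @param mirna,disease identifiers.
#' @param mirnasim miRNA similarity matrix (family-boosted), `mda_sim` or
#'   plain named matrix.
#' @param assoc binary association matrix (miRNAs x diseases).
#' @param k1 neighbourhood size.
#' @return A number in \[0, 1\].
#' @export
neighbor_score_s1 <- function(mirna, disease, mirnasim, assoc, k1 = 50) {
  if (!inherits(mirnasim, "mda_sim")) mirnasim <- new_sim(mirnasim, "miRNAsim")
  check_ids(mirna, rownames(sim_values(mirnasim)), "miRNA")
  check_ids(disease, colnames(assoc), "disease")
  W <- neighbor_weight_matrix(mirnasim, k1)
  sum(W[mirna, ] * assoc[, disease])
}

#' Genomic-cluster score for one pair
#'
#' Weighted vote of all miRNAs in the same genomic cluster as `mirna`,
#' weighted by (family-boosted) similarity. A miRNA with no cluster members,
#' or with zero total similarity to them, scores 0.
#'
#' @inheritParams neighbor_score_s1
#' @param clu binary cluster co-membership matrix from [cluster_matrix()].
#' @return A number in \[0, 1\].
#' @export
cluster_score_s2 <- function(mirna, disease, mirnasim, clu, assoc) {
  if (!inherits(mirnasim, "mda_sim")) mirnasim <- new_sim(mirnasim, "miRNAsim")
  check_ids(mirna, rownames(sim_values(mirnasim)), "miRNA")
  check_ids(disease, colnames(assoc), "disease")
  W <- cluster_weight_matrix(mirnasim, clu)
  sum(W[mirna, ] * assoc[, disease])
}

#' Blend the neighbour and cluster scores in miRNA space
#'
#' @param s1 neighbour score.
#' @param s2 cluster score.
#' @param alpha weight of `s1`, in (0, 1]. The blend is applied
#'   unconditionally; with `s2 = 0` (no cluster) the result is
#'   `alpha * s1`.
#' @return `alpha * s1 + (1 - alpha) * s2`.
#' @export
mirna_space_score <- function(s1, s2, alpha = 0.5) {
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha <= 1))
    stop("alpha must lie in (0, 1]", call. = FALSE)
  alpha * s1 + (1 - alpha) * s2
}

#' Disease-space neighbour score for one pair
#'
#' Weighted vote of the `k2` diseases most similar to `disease` (self
#' excluded, positive similarity only, ties by input order): the
#' similarity-weighted fraction of neighbour diseases already associated
#' with `mirna`. A zero denominator yields 0.
#'
#' @inheritParams neighbor_score_s1
#' @param sd integrated disease similarity matrix.
#' @param k2 neighbourhood size.
#' @return A number in \[0, 1\].
#' @export
disease_space_score <- function(mirna, disease, sd, assoc, k2 = 30) {
  if (!inherits(sd, "mda_sim")) sd <- new_sim(sd, "SD")
  check_ids(mirna, rownames(assoc), "miRNA")
  check_ids(disease, colnames(sim_values(sd)), "disease")
  V <- disease_weight_matrix(sd, k2)
  sum(assoc[mirna, ] * V[, disease])
}

score_components <- function(assoc, mirnasim, sd, clu, params = mda_params()) {
  ms <- sim_values(if (inherits(mirnasim, "mda_sim")) mirnasim else new_sim(mirnasim, "miRNAsim"))
  sdv <- sim_values(if (inherits(sd, "mda_sim")) sd else new_sim(sd, "SD"))
  if (!identical(rownames(ms), rownames(assoc)))
    stop("miRNA id order mismatch between similarity and association matrices", call. = FALSE)
  if (!identical(rownames(sdv), colnames(assoc)))
    stop("disease id order mismatch between similarity and association matrices", call. = FALSE)
  if (!identical(dimnames(ms), dimnames(clu)))
    stop("id order mismatch between similarity and cluster matrices", call. = FALSE)
  W1 <- neighbor_weight_matrix(new_sim(ms, "miRNAsim"), params$k1)
  W2 <- cluster_weight_matrix(new_sim(ms, "miRNAsim"), clu)
  V <- disease_weight_matrix(new_sim(sdv, "SD"), params$k2)
  M <- mirna_space_weights(W1, W2, params$alpha, clu, params$cluster_fallback)
  s1 <- W1 %*% assoc
  s2 <- W2 %*% assoc
  s_mirna <- M %*% assoc
  s_disease <- assoc %*% V
  fc <- params$beta * s_mirna + (1 - params$beta) * s_disease
  list(s1 = s1, s2 = s2, s_mirna = s_mirna, s_disease = s_disease, fc = fc,
       W1 = W1, W2 = W2, V = V, M = M)
}

#' Final prediction score matrix
#'
#' `beta * S_miRNA + (1 - beta) * S_disease` for every miRNA-disease pair.
#' An isolated disease (all-zero association column) receives pure
#' disease-space scores and an isolated miRNA pure miRNA-space scores; both
#' emerge from the formulas without special-casing because the missing
#' space's numerator vanishes.
#'
#' @param assoc binary association matrix (miRNAs x diseases).
#' @param mirnasim family-boosted miRNA similarity matrix.
#' @param sd integrated disease similarity matrix.
#' @param clu binary cluster co-membership matrix.
#' @param params an [mda_params()] object.
#' @return A numeric matrix of scores in \[0, 1\] with the association
#'   matrix's dimnames; attribute `"components"` holds the intermediate
#'   `s1`, `s2`, `s_mirna`, `s_disease` matrices.
#' @export
final_scores <- function(assoc, mirnasim, sd, clu, params = mda_params()) {
  comp <- score_components(assoc, mirnasim, sd, clu, params)
  structure(comp$fc,
            components = comp[c("s1", "s2", "s_mirna", "s_disease")],
            params = params)
}

#' Fit the miRNA-disease recommender
#'
#' Builds every similarity network from the raw tables and computes the full
#' prediction score matrix. Disease names in the gene-interaction and MeSH
#' tables are matched to the association table case-insensitively after
#' trimming whitespace, since the source databases differ in capitalisation.
#'
#' @param associations tibble of (mirna, disease) pairs or binary matrix.
#' @param mirna_targets tibble of (mirna, mRNA) interaction pairs.
#' @param disease_genes optional tibble of (disease, gene) interaction
#'   pairs; `NULL` disables functional disease similarity.
#' @param family optional tibble of (mirna, family) assignments.
#' @param coordinates optional tibble of genomic records from
#'   [read_coordinates()].
#' @param mesh optional tibble of (disease, tree_number) rows.
#' @param params an [mda_params()] object.
#' @return An object of class `mda_fit` with elements `assoc`, `scores`,
#'   `components`, `similarities`, `family`, `cluster`, `weights`, `params`.
#' @examples
#' toy <- toy10_bundle()
#' fit <- mda_fit(toy$assoc_matrix, toy$mirna_targets,
#'                disease_genes = toy$disease_genes, family = toy$family,
#'                coordinates = toy$coordinates, mesh = toy$mesh,
#'                params = mda_params(k1 = 3, k2 = 2))
#' glance(fit)
#' @export
mda_fit <- function(associations, mirna_targets, disease_genes = NULL,
                    family = NULL, coordinates = NULL, mesh = NULL,
                    params = mda_params()) {
  stopifnot(inherits(params, "mda_params"))
  assoc <- as_assoc_matrix(associations)
  mirnas <- rownames(assoc)
  diseases <- colnames(assoc)
  sm <- mi_similarity(mirna_targets, ids = mirnas, role = "SM")
  fam <- family_matrix(family, mirnas)
  msim <- family_boost(sm, fam)
  sdf <- if (is.null(disease_genes)) new_sim(zero_mat(diseases), "SDF") else
    mi_similarity(harmonize_disease_names(disease_genes, diseases),
                  ids = diseases, role = "SDF")
  dd <- if (is.null(mesh)) new_sim(zero_mat(diseases), "DD") else
    semantic_similarity(harmonize_disease_names(mesh, diseases),
                        ids = diseases, delta = params$delta,
                        denominator = params$dd_denominator)
  sd_ <- integrate_disease_similarity(sdf, dd, params$gamma)
  clu <- if (is.null(coordinates)) zero_mat(mirnas) else
    cluster_matrix(coordinates, mirnas, params$cluster_threshold_bp)
  comp <- score_components(assoc, msim, sd_, clu, params)
  structure(list(
    assoc = assoc,
    scores = comp$fc,
    components = comp[c("s1", "s2", "s_mirna", "s_disease")],
    weights = comp[c("W1", "W2", "V", "M")],
    similarities = list(sm = sm, mirnasim = msim, sdf = sdf, dd = dd, sd = sd_),
    family = fam,
    cluster = clu,
    params = params
  ), class = "mda_fit")
}

# Map disease spellings in an auxiliary table onto the association table's
# spellings, case-insensitively after trimming.
harmonize_disease_names <- function(df, diseases) {
  key <- tolower(trimws(as.character(df[[1]])))
  lookup <- setNames(diseases, tolower(trimws(diseases)))
  hit <- key %in% names(lookup)
  df[[1]][hit] <- unname(lookup[key[hit]])
  df
}

#' @export
print.mda_fit <- function(x, ...) {
  cat(sprintf("<miRNA-disease recommender fit: %d miRNAs x %d diseases, %d known associations>\n",
              nrow(x$assoc), ncol(x$assoc), sum(x$assoc)))
  print(x$params)
  invisible(x)
}

#' Tidy the fitted score matrix
#'
#' @param x an `mda_fit` object.
#' @param ... unused.
#' @return A long tibble with columns `mirna`, `disease`, `score`,
#'   `s_mirna`, `s_disease` and `known` (whether the pair is a verified
#'   association), ordered by disease then descending score.
#' @export
tidy.mda_fit <- function(x, ...) {
  fc <- x$scores
  out <- tibble::tibble(
    mirna = rownames(fc)[row(fc)],
    disease = colnames(fc)[col(fc)],
    score = as.vector(fc),
    s_mirna = as.vector(x$components$s_mirna),
    s_disease = as.vector(x$components$s_disease),
    known = as.vector(x$assoc) == 1
  )
  dplyr::arrange(out, .data$disease, dplyr::desc(.data$score), .data$mirna)
}

#' One-row summary of a recommender fit
#'
#' @param x an `mda_fit` object.
#' @param ... unused.
#' @return A one-row tibble with network dimensions and hyperparameters.
#' @export
glance.mda_fit <- function(x, ...) {
  tibble::tibble(
    n_mirnas = nrow(x$assoc),
    n_diseases = ncol(x$assoc),
    n_associations = as.integer(sum(x$assoc)),
    alpha = x$params$alpha, beta = x$params$beta, gamma = x$params$gamma,
    k1 = x$params$k1, k2 = x$params$k2
  )
}

#' Heatmap of prediction scores
#'
#' @param object an `mda_fit` object.
#' @param ... unused.
#' @return A ggplot object: miRNAs x diseases tile plot of the final score.
#' @export
autoplot.mda_fit <- function(object, ...) {
  fc <- object$scores
  df <- tibble::tibble(
    mirna = factor(rownames(fc)[row(fc)], levels = rev(rownames(fc))),
    disease = factor(colnames(fc)[col(fc)], levels = colnames(fc)),
    score = as.vector(fc)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$disease, .data$mirna, fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
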