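# Information-entropy similarity kernel over bipartite interaction tables.
#
# Each entity (miRNA or disease) is profiled by its set of interaction
# partners (target mRNAs or genes). A target t occurring n(t) times among the
# N unique interactions carries the weight -p(t) * log2(p(t)) with
# p(t) = n(t) / N. Note that p(.) is a global occurrence rate, not a
# normalised distribution over an entity's profile, so the per-entity sums
# are "pseudo-entropies"; the formula is applied literally, without
# renormalisation. The base of the logarithm cancels in the similarity ratio
# and is fixed at 2 so that reported entropy values are reproducible bits.

interaction_profile <- function(pairs) {
  stopifnot(is.data.frame(pairs), ncol(pairs) >= 2)
  src <- as.character(pairs[[1]])
  tgt <- as.character(pairs[[2]])
  keep <- !duplicated(paste(src, tgt, sep = "\r"))
  src <- src[keep]; tgt <- tgt[keep]
  n <- length(src)
  if (n == 0) stop("interaction table is empty", call. = FALSE)
  counts <- table(tgt)
  p <- as.numeric(counts) / n
  hterm <- setNames(-p * log2(p), names(counts))
  sets <- split(tgt, factor(src, levels = unique(src)))
  list(sets = sets, hterm = hterm, counts = counts, n = n)
}

entity_targets <- function(prof, entity) {
  s <- prof$sets[[entity]]
  if (is.null(s)) character() else s
}

#' Interaction-profile entropy of one entity
#'
#' Sums `-p(t) * log2(p(t))` over the entity's interaction partners, with
#' `p(t)` the global occurrence rate of target `t` among all unique
#' interactions. An entity with no recorded interactions has entropy 0; a
#' target present in every interaction (`p = 1`) contributes 0.
#'
#' @param pairs a two-column data frame of (source, target) interaction
#'   pairs; duplicates are ignored.
#' @param entity a source identifier.
#' @return Entropy in bits (a single number).
#' @examples
#' profile_entropy(toy10_bundle()$mirna_targets, "A")
#' @export
profile_entropy <- function(pairs, entity) {
  prof <- interaction_profile(pairs)
  s <- entity_targets(prof, entity)
  if (!length(s)) return(0)
  sum(prof$hterm[s])
}

#' Entropy of the shared interaction profile of two entities
#'
#' Applies the [profile_entropy()] sum to the intersection of the two
#' entities' target sets, with the same global occurrence rates.
#'
#' @inheritParams profile_entropy
#' @param a,b source identifiers.
#' @return Entropy in bits.
#' @export
intersection_entropy <- function(pairs, a, b) {
  prof <- interaction_profile(pairs)
  shared <- intersect(entity_targets(prof, a), entity_targets(prof, b))
  if (!length(shared)) return(0)
  sum(prof$hterm[shared])
}

#' Mutual-information similarity matrix over shared targets
#'
#' For every pair of entities the similarity is twice the entropy of the
#' shared target set divided by the sum of the two profile entropies:
#' `2 * H(Ta intersect Tb) / (H(Ta) + H(Tb))`. Because the shared-profile
#' entropy never exceeds either profile entropy, values lie in \[0, 1\]. A
#' pair with zero combined entropy scores 0, and the diagonal is 1 for
#' entities with a nonempty profile and 0 otherwise (an entity with no
#' evidence is not similar to itself for recommendation purposes).
#'
#' @inheritParams profile_entropy
#' @param ids ordered identifiers defining the matrix; may include entities
#'   absent from the table (their rows are zero). Defaults to the sources in
#'   first-appearance order.
#' @param role label of the resulting matrix: `"SM"` for miRNAs (default) or
#'   `"SDF"` for diseases.
#' @return A symmetric `mda_sim` similarity matrix.
#' @examples
#' sm <- mi_similarity(toy10_bundle()$mirna_targets)
#' sm["A", "B"]
#' @export
mi_similarity <- function(pairs, ids = NULL, role = c("SM", "SDF")) {
  role <- match.arg(role)
  prof <- interaction_profile(pairs)
  if (is.null(ids)) ids <- names(prof$sets)
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("ids contain duplicates", call. = FALSE)
  n <- length(ids)
  h <- vapply(ids, function(i) {
    s <- prof$sets[[i]]
    if (is.null(s)) 0 else sum(prof$hterm[s])
  }, numeric(1))
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n)) {
    sa <- prof$sets[[ids[a]]]
    if (is.null(sa)) next
    S[a, a] <- 1
    if (a == n) next
    for (b in seq(a + 1, n)) {
      sb <- prof$sets[[ids[b]]]
      if (is.null(sb)) next
      shared <- intersect(sa, sb)
      if (!length(shared)) next
      denom <- h[a] + h[b]
      if (denom > 0) S[a, b] <- S[b, a] <- 2 * sum(prof$hterm[shared]) / denom
    }
  }
  new_sim(S, role)
}

#' Boost miRNA similarity by family co-membership
#'
#' Rescales each entry by `1 + FAM(i, j)`, doubling the similarity of
#' same-family pairs. The result is deliberately left uncapped (range
#' \[0, 2\]): the downstream neighbour scores normalise by the same weights,
#' so final scores stay in \[0, 1\], whereas capping would silently discard
#' the family signal whenever the base similarity exceeds 0.5. The diagonal
#' is unchanged because the family matrix has zero diagonal.
#'
#' @param sm an `mda_sim` miRNA similarity matrix (role `SM`).
#' @param fam a binary family co-membership matrix over the same ids, from
#'   [family_matrix()].
#' @return An `mda_sim` matrix with role `miRNAsim`.
#' @export
family_boost <- function(sm, fam) {
  v <- sim_values(sm)
  if (!identical(dimnames(v), dimnames(fam)))
    stop("id order mismatch between similarity and family matrices", call. = FALSE)
  new_sim(v * (1 + fam), "miRNAsim")
}

#' Integrate functional and semantic disease similarity
#'
#' Elementwise convex combination `gamma * SDF + (1 - gamma) * DD`. Diseases
#' missing from the gene-interaction table contribute `SDF = 0`, and diseases
#' missing from the MeSH DAG contribute `DD = 0`; the formula is applied
#' as-is in both cases.
#'
#' @param sdf an `mda_sim` disease functional similarity matrix (role `SDF`).
#' @param dd an `mda_sim` disease semantic similarity matrix (role `DD`) over
#'   the same ids.
#' @param gamma balance factor in (0, 1).
#' @return An `mda_sim` matrix with role `SD`.
#' @export
integrate_disease_similarity <- function(sdf, dd, gamma = 0.5) {
  if (!(is.numeric(gamma) && length(gamma) == 1 && gamma > 0 && gamma < 1))
    stop("gamma must lie in (0, 1)", call. = FALSE)
  a <- sim_values(sdf); b <- sim_values(dd)
  if (!identical(dimnames(a), dimnames(b)))
    stop("id order mismatch between SDF and DD matrices", call. = FALSE)
  new_sim(gamma * a + (1 - gamma) * b, "SD")
}
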