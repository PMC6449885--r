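# Independent brute-force oracles and small fixture builders. Everything
# here works by literal set arithmetic and explicit loops, deliberately
# avoiding the package's weight-matrix implementation paths.

write_tsv_fixture <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# --- entropy / similarity oracles -----------------------------------------

oracle_targets <- function(pairs, entity) {
  src <- as.character(pairs[[1]]); tgt <- as.character(pairs[[2]])
  keep <- !duplicated(paste(src, tgt, sep = "\r"))
  unique(tgt[keep][src[keep] == entity])
}

oracle_entropy_of_set <- function(pairs, targets) {
  src <- as.character(pairs[[1]]); tgt <- as.character(pairs[[2]])
  keep <- !duplicated(paste(src, tgt, sep = "\r"))
  tgt <- tgt[keep]
  N <- length(tgt)
  if (!length(targets)) return(0)
  p <- vapply(targets, function(t) sum(tgt == t) / N, numeric(1))
  -sum(p * log2(p))
}

oracle_entropy <- function(pairs, entity) {
  oracle_entropy_of_set(pairs, oracle_targets(pairs, entity))
}

oracle_sm <- function(pairs, a, b) {
  ha <- oracle_entropy(pairs, a)
  hb <- oracle_entropy(pairs, b)
  shared <- intersect(oracle_targets(pairs, a), oracle_targets(pairs, b))
  hi <- oracle_entropy_of_set(pairs, shared)
  if (ha + hb == 0) 0 else 2 * hi / (ha + hb)
}

random_pair_table <- function(n_entities, n_targets, n_pairs) {
  df <- tibble::tibble(
    source = sample(sprintf("e%02d", seq_len(n_entities)), n_pairs, replace = TRUE),
    target = sample(sprintf("t%02d", seq_len(n_targets)), n_pairs, replace = TRUE)
  )
  df[!duplicated(df), ]
}

# --- DAG oracle: exhaustive path enumeration ------------------------------

# Parent map recomputed from the prefix rule, then every upward path is
# walked; an ancestor's contribution is the max of delta^length over paths.
oracle_contributions <- function(mesh, disease, delta) {
  d <- as.character(mesh[[1]]); tn <- as.character(mesh[[2]])
  keep <- !duplicated(paste(d, tn, sep = "\r")); d <- d[keep]; tn <- tn[keep]
  owner <- stats::setNames(d, tn)
  parent_of <- function(node) {
    out <- character()
    for (t in tn[d == node]) {
      segs <- strsplit(t, ".", fixed = TRUE)[[1]]
      if (length(segs) < 2) next
      ptn <- paste(segs[-length(segs)], collapse = ".")
      if (ptn %in% names(owner) && owner[[ptn]] != node)
        out <- union(out, unname(owner[[ptn]]))
    }
    out
  }
  best <- new.env(parent = emptyenv())
  walk <- function(node, depth) {
    w <- delta^depth
    cur <- get0(node, envir = best, ifnotfound = -Inf)
    if (w > cur) assign(node, w, envir = best)
    for (p in parent_of(node)) walk(p, depth + 1)
  }
  walk(disease, 0)
  contributions <- unlist(as.list(best))
  list(contributions = contributions, dv = sum(contributions))
}

# Random multi-path DAG expressed as a tree-number table: node i hangs under
# a random earlier node, and some nodes get a second tree number grafted
# under another earlier node (creating a second parent).
random_mesh <- function(n_nodes) {
  stopifnot(n_nodes >= 1)
  ids <- sprintf("n%02d", seq_len(n_nodes))
  tns <- list("C01")
  rows <- tibble::tibble(disease = ids[1], tree_number = "C01")
  for (i in seq_len(n_nodes)[-1]) {
    anchor <- sample(seq_len(i - 1), 1)
    tn <- paste0(sample(tns[[anchor]], 1), ".", i)
    tns[[i]] <- tn
    rows <- rbind(rows, tibble::tibble(disease = ids[i], tree_number = tn))
    if (i > 2 && stats::runif(1) < 0.4) {
      other <- sample(setdiff(seq_len(i - 1), anchor), 1)
      tn2 <- paste0(sample(tns[[other]], 1), ".x", i)
      tns[[i]] <- c(tns[[i]], tn2)
      rows <- rbind(rows, tibble::tibble(disease = ids[i], tree_number = tn2))
    }
  }
  rows
}

# --- naive score oracles (explicit loops over the formulas) ---------------

naive_s1 <- function(i, j, sim, AS, k1) {
  s <- sim[i, ]
  n <- length(s)
  ord <- order(-s, seq_len(n))
  ord <- ord[ord != i]
  ord <- ord[s[ord] > 0]
  sel <- utils::head(ord, k1)
  den <- sum(s[sel])
  if (!length(sel) || den <= 0) return(0)
  sum(s[sel] * AS[sel, j]) / den
}

naive_s2 <- function(i, j, sim, CLU, AS) {
  members <- which(CLU[i, ] == 1)
  if (!length(members)) return(0)
  den <- sum(sim[i, members])
  if (den <= 0) return(0)
  sum(sim[i, members] * AS[members, j]) / den
}

naive_sdis <- function(i, j, SD, AS, k2) {
  s <- SD[, j]
  n <- length(s)
  ord <- order(-s, seq_len(n))
  ord <- ord[ord != j]
  ord <- ord[s[ord] > 0]
  sel <- utils::head(ord, k2)
  den <- sum(s[sel])
  if (!length(sel) || den <= 0) return(0)
  sum(AS[i, sel] * s[sel]) / den
}

naive_fc_matrix <- function(AS, sim, SD, CLU, params) {
  out <- matrix(0, nrow(AS), ncol(AS), dimnames = dimnames(AS))
  for (i in seq_len(nrow(AS))) {
    for (j in seq_len(ncol(AS))) {
      s1 <- naive_s1(i, j, sim, AS, params$k1)
      s2 <- naive_s2(i, j, sim, CLU, AS)
      sm <- params$alpha * s1 + (1 - params$alpha) * s2
      sd <- naive_sdis(i, j, SD, AS, params$k2)
      out[i, j] <- params$beta * sm + (1 - params$beta) * sd
    }
  }
  out
}

# Naive LOOCV: full per-fold recomputation of the held-out disease's score
# column on the modified association matrix.
naive_loocv_ranks <- function(AS, sim, SD, CLU, params) {
  known <- which(AS == 1, arr.ind = TRUE)
  known <- known[order(known[, 2], known[, 1]), , drop = FALSE]
  out <- data.frame(rank = integer(nrow(known)), n_candidates = integer(nrow(known)))
  for (f in seq_len(nrow(known))) {
    i <- known[f, 1]; j <- known[f, 2]
    AS0 <- AS
    AS0[i, j] <- 0
    sc <- round(vapply(seq_len(nrow(AS)), function(m) {
      s1 <- naive_s1(m, j, sim, AS0, params$k1)
      s2 <- naive_s2(m, j, sim, CLU, AS0)
      sd <- naive_sdis(m, j, SD, AS0, params$k2)
      params$beta * (params$alpha * s1 + (1 - params$alpha) * s2) +
        (1 - params$beta) * sd
    }, numeric(1)), 12)
    cand <- sort(c(which(AS[, j] == 0), i))
    ord <- cand[order(-sc[cand], cand)]
    out$rank[f] <- match(i, ord)
    out$n_candidates[f] <- length(cand)
  }
  out
}

# random symmetric similarity matrix with unit diagonal and distinct
# off-diagonal entries (no ties)
random_sim <- function(ids) {
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  vals <- sample(seq_len(n * (n - 1) / 2)) / (n * (n - 1) / 2 + 1)
  m[upper.tri(m)] <- vals
  m <- m + t(m)
  diag(m) <- 1
  m
}

random_binary_symmetric <- function(ids, p) {
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[upper.tri(m)] <- as.numeric(stats::runif(n * (n - 1) / 2) < p)
  m + t(m)
}

random_assoc <- function(mirnas, diseases, p) {
  m <- matrix(as.numeric(stats::runif(length(mirnas) * length(diseases)) < p),
              length(mirnas), length(diseases),
              dimnames = list(mirnas, diseases))
  m
}

# Mann-Whitney concordance from per-fold ranks: the probability that the
# held-out positive outranks a random negative in its own fold.
fold_concordance <- function(rank, n_candidates) {
  mean((n_candidates - rank) / (n_candidates - 1))
}
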