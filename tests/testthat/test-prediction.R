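# micro-instance used by the worked examples
micro_sim <- function() {
  ids <- c("m0", "m1", "m2", "m3")
  s <- matrix(0, 4, 4, dimnames = list(ids, ids))
  diag(s) <- 1
  s["m0", c("m1", "m2", "m3")] <- c(0.8, 0.4, 0.1)
  s[c("m1", "m2", "m3"), "m0"] <- c(0.8, 0.4, 0.1)
  s
}

test_that("single-pair scores reproduce the worked micro-examples", {
  sim <- micro_sim()
  AS <- matrix(0, 4, 2, dimnames = list(rownames(sim), c("d1", "d2")))
  AS[c("m1", "m3"), "d1"] <- 1
  # top-2 neighbours have sims 0.8 (associated) and 0.4 (not)
  expect_equal(neighbor_score_s1("m0", "d1", sim, AS, k1 = 2), 0.8 / 1.2)
  # all selected neighbours associated -> 1; none associated -> 0
  AS1 <- AS; AS1[c("m1", "m2"), "d1"] <- 1
  expect_equal(neighbor_score_s1("m0", "d1", sim, AS1, k1 = 2), 1)
  expect_equal(neighbor_score_s1("m0", "d2", sim, AS, k1 = 2), 0)

  sim2 <- sim
  sim2["m0", c("m1", "m2")] <- c(0.6, 0.2)
  sim2[c("m1", "m2"), "m0"] <- c(0.6, 0.2)
  clu <- matrix(0, 4, 4, dimnames = dimnames(sim))
  clu["m0", c("m1", "m2")] <- 1; clu[c("m1", "m2"), "m0"] <- 1
  AS2 <- AS * 0; AS2["m1", "d1"] <- 1
  expect_equal(cluster_score_s2("m0", "d1", sim2, clu, AS2), 0.6 / 0.8)
  # empty cluster row -> 0; all members associated -> 1
  expect_equal(cluster_score_s2("m3", "d1", sim2, clu, AS2), 0)
  AS3 <- AS2; AS3["m2", "d1"] <- 1
  expect_equal(cluster_score_s2("m0", "d1", sim2, clu, AS3), 1)

  expect_equal(mirna_space_score(2 / 3, 0.75, 0.5), 0.7083333, tolerance = 1e-6)
  expect_equal(mirna_space_score(0.4, 0, 0.5), 0.2)
  expect_equal(mirna_space_score(0.4, 0.9, 1), 0.4)  # alpha = 1 ignores s2
  expect_error(mirna_space_score(0.4, 0.9, 0), "alpha")

  sd <- matrix(0, 3, 3, dimnames = rep(list(c("d1", "d2", "d3")), 2))
  diag(sd) <- 1
  sd["d1", c("d2", "d3")] <- c(0.9, 0.3); sd[c("d2", "d3"), "d1"] <- c(0.9, 0.3)
  ASd <- matrix(0, 1, 3, dimnames = list("mX", colnames(sd)))
  ASd["mX", "d3"] <- 1
  expect_equal(disease_space_score("mX", "d1", sd, ASd, k2 = 2), 0.3 / 1.2)
  ASd["mX", "d2"] <- 1
  expect_equal(disease_space_score("mX", "d1", sd, ASd, k2 = 2), 1)
  # isolated miRNA: all-zero association row
  expect_equal(disease_space_score("mX", "d1", sd, ASd * 0, k2 = 2), 0)

  # final blend: beta * 0.7083333 + (1 - beta) * 0.25
  expect_equal(0.8 * mirna_space_score(2 / 3, 0.75, 0.5) + 0.2 * 0.25,
               0.6166667, tolerance = 1e-6)
})

test_that("full score matrices agree with naive per-pair evaluation", {
  set.seed(303)
  params <- mda_params(k1 = 3, k2 = 2)
  for (k in 1:8) {
    mirnas <- sprintf("m%d", 1:8)
    diseases <- sprintf("d%d", 1:5)
    sim <- random_sim(mirnas)
    SD <- random_sim(diseases)
    CLU <- random_binary_symmetric(mirnas, 0.3)
    AS <- random_assoc(mirnas, diseases, 0.3)
    fc <- final_scores(AS, sim, SD, CLU, params)
    want <- naive_fc_matrix(AS, sim, SD, CLU, params)
    expect_equal(unclass(fc)[seq_along(want)], want[seq_along(want)], tolerance = 1e-12)
    comp <- attr(fc, "components")
    for (nm in names(comp)) {
      expect_true(all(comp[[nm]] >= 0 & comp[[nm]] <= 1))
    }
    expect_true(all(fc >= 0 & fc <= 1))
  }
})

test_that("scores are invariant to input permutation", {
  set.seed(404)
  mirnas <- sprintf("m%d", 1:7)
  diseases <- sprintf("d%d", 1:4)
  sim <- random_sim(mirnas)
  SD <- random_sim(diseases)
  CLU <- random_binary_symmetric(mirnas, 0.4)
  AS <- random_assoc(mirnas, diseases, 0.35)
  params <- mda_params(k1 = 3, k2 = 2)
  fc <- unclass(final_scores(AS, sim, SD, CLU, params))

  pm <- sample(length(mirnas)); pd <- sample(length(diseases))
  fc_perm <- unclass(final_scores(AS[pm, pd], sim[pm, pm], SD[pd, pd],
                                  CLU[pm, pm], params))
  expect_equal(fc_perm[rownames(fc), colnames(fc)], fc[, ], tolerance = 1e-12)
})

test_that("zero family and cluster reduce to the pure two-space recommender", {
  toy <- toy10_bundle()
  params <- mda_params(k1 = 3, k2 = 2)
  fit_full <- mda_fit(toy$assoc_matrix, toy$mirna_targets,
                      disease_genes = toy$disease_genes, family = toy$family,
                      coordinates = toy$coordinates, mesh = toy$mesh,
                      params = params)
  fit_plain <- mda_fit(toy$assoc_matrix, toy$mirna_targets,
                       disease_genes = toy$disease_genes,
                       mesh = toy$mesh, params = params)
  # without family/cluster data: s2 is identically zero and the similarity
  # is the unboosted kernel
  expect_true(all(fit_plain$components$s2 == 0))
  expect_equal(mirdap:::sim_values(fit_plain$similarities$mirnasim),
               mirdap:::sim_values(fit_plain$similarities$sm))
  sm <- fit_plain$similarities$sm
  sd <- fit_plain$similarities$sd
  want <- naive_fc_matrix(fit_plain$assoc, unclass(sm), unclass(sd),
                          fit_plain$cluster, params)
  expect_equal(unclass(fit_plain$scores)[seq_along(want)], want[seq_along(want)],
               tolerance = 1e-12)

  # with alpha = 1 the cluster channel has no effect even when present
  p1 <- mda_params(alpha = 1, k1 = 3, k2 = 2)
  fit_a1 <- mda_fit(toy$assoc_matrix, toy$mirna_targets,
                    disease_genes = toy$disease_genes, family = toy$family,
                    coordinates = toy$coordinates, mesh = toy$mesh, params = p1)
  fit_a1_nc <- mda_fit(toy$assoc_matrix, toy$mirna_targets,
                       disease_genes = toy$disease_genes, family = toy$family,
                       mesh = toy$mesh, params = p1)
  expect_equal(fit_a1$scores, fit_a1_nc$scores, tolerance = 1e-12)
})

test_that("isolated entities follow from the formulas without special-casing", {
  set.seed(505)
  mirnas <- sprintf("m%d", 1:6)
  diseases <- sprintf("d%d", 1:4)
  sim <- random_sim(mirnas)
  SD <- random_sim(diseases)
  CLU <- random_binary_symmetric(mirnas, 0.3)
  AS <- random_assoc(mirnas, diseases, 0.4)
  AS[, "d2"] <- 0       # isolated disease
  AS["m3", ] <- 0       # isolated miRNA
  params <- mda_params(k1 = 3, k2 = 2, beta = 0.8)
  fc <- final_scores(AS, sim, SD, CLU, params)
  comp <- attr(fc, "components")
  expect_true(all(comp$s_mirna[, "d2"] == 0))
  expect_equal(fc[, "d2"], 0.2 * comp$s_disease[, "d2"])
  expect_true(all(comp$s_disease["m3", ] == 0))
  expect_equal(fc["m3", ], 0.8 * comp$s_mirna["m3", ])
})

test_that("the empty-cluster fallback switch renormalises the blend", {
  set.seed(606)
  mirnas <- sprintf("m%d", 1:5)
  diseases <- sprintf("d%d", 1:3)
  sim <- random_sim(mirnas)
  SD <- random_sim(diseases)
  AS <- random_assoc(mirnas, diseases, 0.5)
  CLU <- matrix(0, 5, 5, dimnames = list(mirnas, mirnas))
  CLU["m1", "m2"] <- CLU["m2", "m1"] <- 1
  p_formula <- mda_params(alpha = 0.5, beta = 1, k1 = 3, k2 = 2)
  p_renorm <- mda_params(alpha = 0.5, beta = 1, k1 = 3, k2 = 2,
                         cluster_fallback = "renormalize")
  fc_f <- unclass(final_scores(AS, sim, SD, CLU, p_formula))
  fc_r <- unclass(final_scores(AS, sim, SD, CLU, p_renorm))
  # cluster members are blended identically; cluster-less miRNAs fall back
  # to the full neighbour score instead of alpha * s1
  expect_equal(fc_r[c("m1", "m2"), ], fc_f[c("m1", "m2"), ])
  s1_m3 <- vapply(diseases, function(j) naive_s1(3, j, sim, AS, 3), numeric(1))
  expect_equal(unname(fc_r["m3", ]), unname(s1_m3))
  expect_equal(unname(fc_f["m3", ]), unname(0.5 * s1_m3))
})

test_that("fit objects expose tidy, glance and plot methods", {
  toy <- toy10_bundle()
  fit <- fit_bundle(toy, mda_params(k1 = 3, k2 = 2))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("mirna", "disease", "score", "s_mirna", "s_disease", "known"))
  expect_equal(nrow(td), nrow(fit$assoc) * ncol(fit$assoc))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n_associations, 5L)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(fit$similarities$sm), "ggplot")
})
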