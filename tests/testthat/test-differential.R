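test_that("geometric fold-change matches closed forms and is antisymmetric", {
  x <- c(1.5, 2.5, 3.5)
  expect_equal(geometric_fold_change(x, x), 0)
  expect_equal(geometric_fold_change(rep(2, 10), rep(1, 10)), 1,
               tolerance = 1e-5)                       # log2(2) with eps ~ 0
  expect_equal(geometric_fold_change(rep(-2, 10), rep(2, 10)), 0)  # |.| based
  set.seed(1)
  a <- stats::rlnorm(50); b <- stats::rlnorm(50, 1)
  expect_equal(geometric_fold_change(a, b), -geometric_fold_change(b, a))
  # epsilon regularizes exact zeros without error
  expect_true(is.finite(geometric_fold_change(c(0, 0), c(1, 1))))
  expect_error(geometric_fold_change(numeric(), 1),
               class = "fluxpath_validation_error")
})

test_that("permutation p-values honor the add-one estimator bounds", {
  expect_equal(permutation_pvalue(rep(3, 5), rep(3, 5), n_perm = 99,
                                  seed = 1), 1)
  # perfectly separated groups reach the minimum attainable p
  p <- permutation_pvalue(rep(0, 50), rep(10, 50), n_perm = 999, seed = 2)
  expect_equal(p, 1 / 1000)
  # determinism
  set.seed(7); a <- stats::rnorm(30); b <- stats::rnorm(30, 0.5)
  expect_identical(permutation_pvalue(a, b, 200, seed = 5),
                   permutation_pvalue(a, b, 200, seed = 5))
})

test_that("permutation test is calibrated under an exchangeable null", {
  n_rep <- 400L
  alpha <- 0.05
  set.seed(11)
  rej <- vapply(seq_len(n_rep), function(i) {
    x <- stats::rnorm(30); y <- stats::rnorm(30)
    permutation_pvalue(x, y, n_perm = 199, seed = 1000L + i) < alpha
  }, logical(1))
  mc_se <- sqrt(alpha * (1 - alpha) / n_rep)
  expect_lt(mean(rej), alpha + 3 * mc_se)
  expect_gt(mean(rej), alpha - 3 * mc_se)
})

test_that("metabolite utilization totals production flux and balances consumption", {
  # chain IN -> A -(M1)-> B -(M2)-> out at flux 3: turnover of A and B is 3
  mod <- coupled_chain_model()
  pts <- matrix(3, 2, 3, dimnames = list(NULL, c("IN", "M1", "M2")))
  smp <- structure(list(points = pts, reaction_ids = colnames(pts),
                        n_steps_per_point = 1L, seed = 1L,
                        model_id = mod$id, degenerate = FALSE),
                   class = "flux_sample")
  ut <- metabolite_utilization(mod, smp)
  expect_equal(unname(ut$points[1, ]), c(3, 3))
  # additivity: two producers at 1 and 2 give turnover 3
  mod2 <- branched_model()
  pts2 <- matrix(c(3, 2, 1, 2), 1, 4,
                 dimnames = list(NULL, c("IN", "AB", "AW", "OBJ")))
  smp2 <- structure(list(points = pts2, reaction_ids = colnames(pts2),
                         n_steps_per_point = 1L, seed = 1L,
                         model_id = mod2$id, degenerate = FALSE),
                    class = "flux_sample")
  ut2 <- metabolite_utilization(mod2, smp2)
  expect_equal(unname(ut2$points[1, "A"]), 3)
  # conservation: production equals consumption at steady state
  setup <- toy_reference_setup()
  S <- stoichiometric_matrix(setup$cmod)
  V <- setup$sample$points[1:50, , drop = FALSE]
  prod <- pmax(V, 0) %*% t(pmax(S, 0)) + pmax(-V, 0) %*% t(pmax(-S, 0))
  cons <- pmax(V, 0) %*% t(pmax(-S, 0)) + pmax(-V, 0) %*% t(pmax(S, 0))
  expect_lt(max(abs(prod - cons)), 1e-6)
  expect_true(all(metabolite_utilization(setup$cmod,
                                         setup$sample)$points >= -1e-12))
})

test_that("subsystem utilization sums absolute fluxes and partitions the total", {
  mod <- branched_model()
  mod$reactions$subsystem <- c("U", "V", "V", "W")
  pts <- matrix(c(3, -2, 5, 2), 1, 4,
                dimnames = list(NULL, c("IN", "AB", "AW", "OBJ")))
  smp <- structure(list(points = pts, reaction_ids = colnames(pts),
                        n_steps_per_point = 1L, seed = 1L,
                        model_id = mod$id, degenerate = FALSE),
                   class = "flux_sample")
  ut <- subsystem_utilization(mod, smp)
  expect_equal(unname(ut$points[1, c("U", "V", "W")]), c(3, 7, 2))
  expect_equal(sum(ut$points[1, ]), sum(abs(pts)))
})

test_that("reaction-level differential drops demand reactions and excluded subsystems", {
  setup <- toy_reference_setup()
  ko <- toy_ko_setup("GND")
  recs <- differential_levels(ko$sample, setup$sample, setup$model,
                              level = "reaction", n_perm = 99, seed = 3)
  expect_false("DM_glu" %in% recs$entity_id)          # demand reaction
  expect_false("NADH16" %in% recs$entity_id)          # excluded subsystem
  expect_false("GLCpts" %in% recs$entity_id)          # transport excluded
  expect_true(all(c("GND", "EDD_EDA", "TKT1") %in% recs$entity_id))
  expect_true(all(recs$p_permuted >= 1 / 100))
  expect_equal(recs$significant,
               recs$p_permuted < 0.05 & abs(recs$gfc) > 0.001)
})

test_that("GND knockout comparison flags ED spillover and transketolase flux flips", {
  setup <- toy_reference_setup()
  ko <- toy_ko_setup("GND")
  recs <- differential_levels(ko$sample, setup$sample, setup$model,
                              level = "reaction", n_perm = 199, seed = 3)
  ed <- recs[recs$entity_id == "EDD_EDA", ]
  expect_true(ed$significant)
  expect_gt(ed$gfc, 0)                                 # KO over reference
  for (rid in c("TKT1", "TKT2", "TALA")) {
    row <- recs[recs$entity_id == rid, ]
    expect_true(row$significant, label = rid)
    expect_lt(sign(row$mean_a) * sign(row$mean_b), 0, label = rid)  # flip
  }
})

test_that("SUCDi knockout comparison shows strictly positive succinate secretion", {
  setup <- toy_reference_setup()
  ko <- toy_ko_setup("SUCDi")
  expect_gt(min(ko$sample$points[, "EX_succ"]), 0)
  recs <- differential_levels(ko$sample, setup$sample, setup$model,
                              level = "reaction", n_perm = 199, seed = 4)
  succ <- recs[recs$entity_id == "EX_succ", ]
  expect_true(succ$significant)
  expect_gt(succ$gfc, 0)
  expect_gt(succ$mean_a, 0)
})

test_that("metabolite- and subsystem-level analyses run and keep n_points consistent", {
  setup <- toy_reference_setup()
  ko <- toy_ko_setup("GND")
  met <- differential_levels(ko$sample, setup$sample, setup$model,
                             level = "metabolite", n_perm = 49, seed = 5)
  expect_setequal(met$entity_id, setup$model$metabolites$id)
  sub <- differential_levels(ko$sample, setup$sample, setup$model,
                             level = "subsystem", n_perm = 49, seed = 5)
  ed <- sub[sub$entity_id == "Entner-Doudoroff Pathway", ]
  expect_gt(ed$gfc, 0)
})

test_that("fold-change clustering is deterministic and permutation-invariant", {
  m <- rbind(g1a = c(1, 1.1, 0.9), g1b = c(1.05, 1.0, 0.95),
             g2a = c(-3, -3.1, -2.9), g2b = c(-3.05, -3.0, -2.95))
  cl <- cluster_fold_changes(m)
  top_split <- stats::cutree(cl$hclust, k = 2)
  expect_equal(unname(top_split[c("g1a", "g1b")]),
               rep(top_split[["g1a"]], 2))
  expect_false(top_split[["g1a"]] == top_split[["g2a"]])
  perm <- cluster_fold_changes(m[c(3, 1, 4, 2), ])
  expect_equal(perm$hclust$height, cl$hclust$height)
  expect_equal(perm$leaf_order, cl$leaf_order)
  # identical rows merge at height zero
  z <- cluster_fold_changes(rbind(a = c(1, 2), b = c(1, 2), c = c(5, 9)))
  expect_equal(min(z$hclust$height), 0)
  expect_error(cluster_fold_changes(m[1, , drop = FALSE]),
               class = "fluxpath_validation_error")
  m_na <- m; m_na[1, 1] <- NA
  expect_error(cluster_fold_changes(m_na),
               class = "fluxpath_validation_error")
})
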