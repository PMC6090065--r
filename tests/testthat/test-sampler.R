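test_that("warmup spans the polytope and respects constraints", {
  mod <- box_model()
  warm <- generate_warmup(mod, seed = 1)
  free <- c("R1in", "R1out", "R2in", "R2out")
  expect_gte(nrow(warm), 2L * length(free))
  for (j in free) {
    expect_equal(min(warm[, j]), 0, tolerance = 1e-9)
    expect_equal(max(warm[, j]), 1, tolerance = 1e-9)
  }
  S <- stoichiometric_matrix(mod)
  expect_lt(max(abs(S %*% t(warm))), 1e-6)
})

test_that("warmup on a fully fixed model returns identical points", {
  mod <- chain_model()
  mod$reactions$lower_bound <- c(4, 4)
  mod$reactions$upper_bound <- c(4, 4)
  warm <- generate_warmup(mod, seed = 1)
  expect_true(all(apply(warm, 2, function(x) diff(range(x)) == 0)))
})

test_that("sampled points satisfy steady state and bounds; fixed seed is bit-identical", {
  setup <- toy_reference_setup()
  smp <- setup$sample
  S <- stoichiometric_matrix(setup$cmod)
  expect_lt(max(abs(S %*% t(smp$points))), 1e-6)
  lb <- setup$cmod$reactions$lower_bound
  ub <- setup$cmod$reactions$upper_bound
  expect_true(all(t(smp$points) >= lb - 1e-9))
  expect_true(all(t(smp$points) <= ub + 1e-9))
  again <- sample_fluxes(setup$cmod, n_points = nrow(smp$points),
                         n_steps = smp$n_steps_per_point, seed = smp$seed)
  expect_identical(again$points, smp$points)
  different <- sample_fluxes(setup$cmod, n_points = nrow(smp$points),
                             n_steps = smp$n_steps_per_point, seed = 99)
  expect_false(identical(different$points, smp$points))
})

test_that("all-bounds-fixed model yields the unique point repeated with a warning", {
  mod <- chain_model()
  mod$reactions$lower_bound <- c(4, 4)
  mod$reactions$upper_bound <- c(4, 4)
  expect_warning(smp <- sample_fluxes(mod, n_points = 10, n_steps = 5,
                                      seed = 1),
                 "degenerate")
  expect_true(all(smp$points[, "EX_A"] == smp$points[1, "EX_A"]))
  expect_equal(nrow(smp$points), 10L)
})

test_that("box-polytope marginals are uniform (KS at alpha 0.01) and KS distance shrinks with n", {
  mod <- box_model()
  smp <- sample_fluxes(mod, n_points = 2000, n_steps = 100, seed = 5)
  for (j in c("R1in", "R2in")) {
    ks <- suppressWarnings(stats::ks.test(smp$points[, j], "punif", 0, 1))
    expect_gt(ks$p.value, 0.01, label = paste("marginal", j))
  }
  small <- sample_fluxes(mod, n_points = 200, n_steps = 100, seed = 5)
  d_small <- suppressWarnings(
    stats::ks.test(small$points[, "R1in"], "punif", 0, 1))$statistic
  d_big <- suppressWarnings(
    stats::ks.test(smp$points[, "R1in"], "punif", 0, 1))$statistic
  expect_lt(d_big, d_small)
})

test_that("mixed fraction is 0 for a replayed chain, ~0.5 for i.i.d. draws", {
  # second half duplicates the first half point-for-point
  half <- matrix(stats::runif(50 * 3), 50, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  smp <- structure(list(points = rbind(half, half),
                        reaction_ids = c("a", "b", "c"),
                        n_steps_per_point = 1L, seed = 1L, model_id = "x",
                        degenerate = FALSE), class = "flux_sample")
  expect_equal(mixed_fraction(smp), 0)
  # i.i.d. draws concentrate at 0.5 within the exact binomial 99% interval
  n <- 1000L
  set.seed(42)
  iid <- structure(list(points = matrix(stats::rnorm(n), n, 1,
                                        dimnames = list(NULL, "a")),
                        reaction_ids = "a", n_steps_per_point = 1L,
                        seed = 1L, model_id = "x", degenerate = FALSE),
                   class = "flux_sample")
  mf <- mixed_fraction(iid)
  band <- stats::qbinom(c(0.005, 0.995), n / 2, 0.5) / (n / 2)
  expect_gte(mf, band[1])
  expect_lte(mf, band[2])
  # all-constant sample is an error
  const <- iid
  const$points[] <- 1
  expect_error(mixed_fraction(const), class = "fluxpath_validation_error")
})

test_that("sample summaries use linear-interpolation quartiles and keep order", {
  pts <- cbind(const = rep(2, 4), var = c(1, 2, 3, 4))
  smp <- structure(list(points = pts, reaction_ids = colnames(pts),
                        n_steps_per_point = 1L, seed = 1L, model_id = "x",
                        degenerate = FALSE), class = "flux_sample")
  sm <- summarize_sample(smp)
  cv <- sm[sm$reaction_id == "const", ]
  expect_equal(unlist(cv[, c("mean", "median", "q1", "q3", "min", "max")]),
               c(mean = 2, median = 2, q1 = 2, q3 = 2, min = 2, max = 2))
  vv <- sm[sm$reaction_id == "var", ]
  expect_equal(vv$median, 2.5)
  expect_equal(vv$q1, 1.75)
  expect_equal(vv$q3, 3.25)
  real <- summarize_sample(toy_reference_setup()$sample)
  expect_true(all(real$min <= real$q1 + 1e-12 & real$q1 <= real$median + 1e-12 &
                    real$median <= real$q3 + 1e-12 & real$q3 <= real$max + 1e-12))
})

test_that("samples export as TSV with a JSON sidecar", {
  smp <- sample_fluxes(box_model(), n_points = 50, n_steps = 20, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sample(smp, path)
  tab <- utils::read.delim(path)
  expect_equal(nrow(tab), 50L)
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(side$seed, 3L)
  expect_equal(side$n_points, 50L)
})
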