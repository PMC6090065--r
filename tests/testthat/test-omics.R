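test_that("concentration QC drops blank-contaminated and high-RSD metabolites", {
  tab <- simulate_concentrations(n_metabolites = 10, missing_rate = 0,
                                 seed = 21, blank_level = c(met_4 = 0.9),
                                 qc_rsd = 5)
  out <- qc_filter_concentrations(tab)
  expect_true("met_4" %in% out$report$metabolite)
  expect_equal(out$report$reason[out$report$metabolite == "met_4"],
               "blank_fraction")
  expect_false("met_4" %in% rownames(out$table$values))
  # clean table passes unchanged
  clean <- simulate_concentrations(n_metabolites = 6, missing_rate = 0,
                                   seed = 22, blank_level = 0.01, qc_rsd = 5,
                                   cv = 0.05, factor_sd = 0.05)
  out2 <- qc_filter_concentrations(clean)
  expect_equal(nrow(out2$report), 0L)
  expect_equal(out2$table$values, clean$values)
  # idempotence
  out3 <- qc_filter_concentrations(out$table)
  expect_equal(rownames(out3$table$values), rownames(out$table$values))
  # planted high QC variability is caught
  noisy_qc <- simulate_concentrations(n_metabolites = 6, missing_rate = 0,
                                      seed = 23, qc_rsd = 80,
                                      blank_level = 0.01)
  expect_true("qc_rsd" %in% qc_filter_concentrations(noisy_qc)$report$reason)
})

test_that("bootstrap-EM imputation beats per-metabolite mean imputation on correlated data", {
  tab <- simulate_concentrations(n_metabolites = 8,
                                 groups = rep("ref", 30),
                                 missing_rate = 0, seed = 31,
                                 cv = 0.05, factor_sd = 0.6)
  bio <- which(tab$sample_roles == "biological")
  truth <- tab$values[, bio]
  # punch 10% MCAR holes
  set.seed(99)
  holes <- matrix(stats::runif(length(truth)) < 0.10, nrow(truth))
  holes[, 1] <- FALSE                        # keep one complete sample
  tab$values[, bio][holes] <- NA
  tab$missing_mask <- is.na(tab$values)
  imp <- impute_missing(tab, n_imputations = 40, seed = 5)
  expect_false(anyNA(imp$values))
  rmse <- function(est) sqrt(mean((log(est[holes]) - log(truth[holes]))^2))
  got <- rmse(imp$values[, bio])
  col_mean <- truth
  for (i in seq_len(nrow(truth)))
    col_mean[i, holes[i, ]] <- exp(mean(log(truth[i, !holes[i, ]])))
  expect_lt(got, rmse(col_mean))
  # determinism and no-op on complete tables
  imp2 <- impute_missing(tab, n_imputations = 40, seed = 5)
  expect_identical(imp$values, imp2$values)
  complete <- simulate_concentrations(n_metabolites = 4, missing_rate = 0,
                                      seed = 32)
  expect_identical(impute_missing(complete, 10, seed = 1)$values,
                   complete$values)
})

test_that("all-missing metabolites fall back to half-LLOQ over biomass", {
  vals <- matrix(c(5, 6, 5.5, NA, NA, NA), 2, 3, byrow = TRUE,
                 dimnames = list(c("ok", "gone"), c("s1", "s2", "s3")))
  tab <- concentration_table(vals, rep("biological", 3), rep("g", 3),
                             lloq = c(0.1, 0.2), biomass = c(1, 2, 4))
  imp <- impute_missing(tab, n_imputations = 5, seed = 2)
  expect_equal(unname(imp$values["gone", ]), 0.5 * 0.2 / c(1, 2, 4))
})

test_that("glog reduces to log2 at lambda 0 and inverts to 1e-9", {
  y <- c(0.01, 1, 10, 1e4)
  expect_equal(glog(y, 0), log2(y))
  for (lam in c(0, 0.5, 10)) {
    g <- glog(y, lam)
    expect_lt(max(abs(glog_inverse(g, lam) - y)), 1e-9)
    expect_true(all(diff(glog(seq(0, 5, by = 0.1), lam)) > 0)) # increasing
  }
  # asymptotic agreement with log2 for y >> sqrt(lambda)
  expect_lt(abs(glog(1e5, 1) - log2(1e5)), 1e-6)
  expect_error(glog(1, -1), class = "fluxpath_validation_error")
})

test_that("glog normalization stabilizes variance across abundance", {
  # additive + multiplicative noise: low-abundance variance inflated on the
  # raw log scale, evened out by the glog
  set.seed(13)
  base <- 2^seq(2, 12, length.out = 24)
  n <- 12
  vals <- vapply(seq_len(n), function(i)
    base * exp(stats::rnorm(24, 0, 0.15)) + stats::rnorm(24, 0, 3),
    numeric(24))
  vals[vals <= 0] <- 0.01
  rownames(vals) <- sprintf("met_%d", seq_len(24))
  tab <- concentration_table(vals, rep("biological", n), rep("g", n))
  ratio_spread <- function(m) {
    v <- apply(m, 1, stats::var)
    stats::var(log(v))
  }
  before <- ratio_spread(log2(vals + 1e-6))
  gn <- glog_normalize(tab, lambda = "auto")
  expect_gt(attr(gn, "lambda"), 0)
  expect_lt(ratio_spread(gn$values), before)
})

test_that("differential metabolite testing controls Bonferroni FWER and finds planted effects", {
  # planted 4-fold shift at low noise among nulls: exactly that hit flagged
  tab <- simulate_concentrations(n_metabolites = 21,
                                 groups = rep(c("ref", "ko"), each = 3),
                                 effect_log2 = c(met_7 = 2),
                                 missing_rate = 0, seed = 41,
                                 cv = 0.03, factor_sd = 0.03)
  gn <- glog_normalize(tab, lambda = 0)
  res <- diff_metabolites(gn, "ko", "ref", alpha = 0.01)
  expect_equal(res$metabolite[res$significant], "met_7")
  expect_gt(res$difference[res$metabolite == "met_7"], 0)
  # identical groups: nothing significant
  null_tab <- simulate_concentrations(n_metabolites = 15,
                                      groups = rep(c("a", "b"), each = 3),
                                      missing_rate = 0, seed = 42,
                                      cv = 0.05)
  nres <- diff_metabolites(glog_normalize(null_tab, lambda = 0), "a", "b")
  expect_false(any(nres$significant))
  expect_error(diff_metabolites(gn, "ko", "missing_group"),
               class = "fluxpath_validation_error")
})

test_that("Bonferroni family-wise error stays at or below alpha under the null", {
  n_sim <- 60L
  alpha <- 0.05
  fw <- vapply(seq_len(n_sim), function(i) {
    tab <- simulate_concentrations(n_metabolites = 20,
                                   groups = rep(c("a", "b"), each = 4),
                                   missing_rate = 0, seed = 5000L + i,
                                   cv = 0.1, factor_sd = 0)
    any(diff_metabolites(glog_normalize(tab, lambda = 0), "a", "b",
                         alpha = alpha)$significant)
  }, logical(1))
  mc_se <- sqrt(alpha * (1 - alpha) / n_sim)
  expect_lte(mean(fw), alpha + 3 * mc_se)
})

test_that("MID QC drops high-RSD and blank-dominated channels", {
  fr <- rbind(
    # F1: all channels replicate-stable, M2 dominated by blank signal
    data.frame(fragment = "F1", channel = "M0", replicate = 1:3,
               fraction = c(0.50, 0.52, 0.51)),
    data.frame(fragment = "F1", channel = "M1", replicate = 1:3,
               fraction = c(0.20, 0.19, 0.18)),
    data.frame(fragment = "F1", channel = "M2", replicate = 1:3,
               fraction = c(0.30, 0.29, 0.31)),
    # F2: N1 has replicate RSD ~ 66%
    data.frame(fragment = "F2", channel = "N0", replicate = 1:3,
               fraction = c(0.9, 0.5, 0.7)),
    data.frame(fragment = "F2", channel = "N1", replicate = 1:3,
               fraction = c(0.1, 0.5, 0.3)))
  bl <- data.frame(fragment = c("F1", "F1", "F1", "F2", "F2"),
                   channel = c("M0", "M1", "M2", "N0", "N1"),
                   blank_fraction = c(0.1, 0.2, 0.85, 0.1, 0.1))
  mid <- mid_table(fr, bl)
  out <- qc_filter_mids(mid)
  expect_setequal(out$report$channel, c("M2", "N1"))
  expect_equal(out$report$reason[out$report$channel == "N1"], "rsd")
  expect_equal(out$report$reason[out$report$channel == "M2"], "blank")
  expect_setequal(unique(out$mids$fractions$channel), c("M0", "M1", "N0"))
  # clean zero-RSD fragment is kept
  clean <- mid_table(data.frame(fragment = "F2", channel = "M0",
                                replicate = 1:2, fraction = c(1, 1)),
                     data.frame(fragment = "F2", channel = "M0",
                                blank_fraction = 0))
  expect_equal(nrow(qc_filter_mids(clean)$report), 0L)
  # fractions violating the sum-to-one invariant are rejected at construction
  expect_error(mid_table(data.frame(fragment = "F3", channel = c("M0", "M1"),
                                    replicate = 1, fraction = c(0.5, 0.2)),
                         bl),
               class = "fluxpath_validation_error")
})

test_that("growth rate recovers exponential slopes and validates inputs", {
  tt <- seq(0, 1.75, by = 0.25)
  od <- 0.1 * exp(0.9 * tt)
  fit <- growth_rate(tt, od)
  expect_equal(fit$mu, 0.9, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  # 2% multiplicative noise keeps the estimate within 5%
  set.seed(3)
  noisy <- od * exp(stats::rnorm(length(od), 0, 0.02))
  expect_lt(abs(growth_rate(tt, noisy)$mu - 0.9) / 0.9, 0.05)
  expect_error(growth_rate(tt[1:5], od[1:5]),
               class = "fluxpath_validation_error")  # < 8 points
  expect_equal(growth_rate(tt[1:4], od[1:4], min_points = 4)$mu, 0.9,
               tolerance = 1e-12)                    # ALE-platform mode
  bad <- od; bad[3] <- -0.1
  expect_error(growth_rate(tt, bad), class = "fluxpath_validation_error")
  expect_error(growth_rate(rev(tt), od), class = "fluxpath_validation_error")
})

test_that("fitness trajectories are monotone interpolants of isotonic-adjusted knots", {
  tt <- c(0, 5, 12, 20, 30)
  rr <- c(0.60, 0.70, 0.78, 0.83, 0.85)
  f <- fitness_trajectory(tt, rr)
  expect_equal(f(tt), rr, tolerance = 1e-12)         # interpolates knots
  grid <- seq(0, 30, by = 0.05)
  expect_true(all(diff(f(grid)) >= -1e-10))          # never decreases
  # non-monotone input: spline passes through the isotonic regression knots
  rr2 <- c(0.60, 0.75, 0.72, 0.80, 0.85)
  iso <- stats::isoreg(tt, rr2)$yf
  f2 <- fitness_trajectory(tt, rr2)
  expect_equal(f2(tt), iso, tolerance = 1e-12)
  expect_true(all(diff(f2(grid)) >= -1e-10))
  expect_error(fitness_trajectory(c(0, 10), c(1, 2)),
               class = "fluxpath_validation_error")
  expect_error(fitness_trajectory(c(0, 10, 5), c(1, 2, 3)),
               class = "fluxpath_validation_error")
})

test_that("replicate correlation QC passes duplicates and fails independent noise", {
  set.seed(8)
  m <- matrix(stats::rexp(2000), 1000, 2)
  dup <- cbind(r1 = m[, 1], r2 = m[, 1] * (1 + stats::rnorm(1000, 0, 0.001)))
  res <- replicate_correlation_qc(dup)
  expect_true(all(res$pass))
  indep <- cbind(r1 = m[, 1], r2 = m[, 2])
  res2 <- replicate_correlation_qc(indep)
  expect_false(any(res2$pass))
  expect_lt(abs(res2$r), 0.2)
  flat <- cbind(r1 = rep(1, 10), r2 = stats::runif(10))
  expect_error(replicate_correlation_qc(flat),
               class = "fluxpath_validation_error")
})
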