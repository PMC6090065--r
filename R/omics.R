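# Metabolomics QC / imputation / normalization / testing, MID QC filters,
# growth-rate and fitness-trajectory fitting, replicate-correlation QC.

#' Construct a metabolite concentration table
#'
#' Metabolite x sample matrix of concentrations (arbitrary units per gDCW)
#' with sample-role annotations. Missing values are `NA` in `values`.
#'
#' @param values numeric matrix, metabolites in rows (rownames = metabolite
#'   ids), samples in columns (colnames = sample ids); non-negative where
#'   present.
#' @param sample_roles character vector per sample: `"biological"`, `"qc"`
#'   (pooled quality-control injections) or `"blank_medium"` (processed
#'   medium blank).
#' @param groups condition label per sample; required for biological
#'   samples, `NA` allowed otherwise.
#' @param lloq per-metabolite lower limit of quantification (> 0); recycled
#'   if length 1.
#' @param biomass per-sample biomass (gDCW); recycled if length 1.
#' @return An object of class `concentration_table`.
#' @export
concentration_table <- function(values, sample_roles, groups,
                                lloq = 1e-3, biomass = 1) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("met_%d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  if (any(values < 0, na.rm = TRUE))
    stop_fluxpath("validation", "concentrations must be >= 0 where present")
  roles <- as.character(sample_roles)
  bad <- setdiff(roles, c("biological", "qc", "blank_medium"))
  if (length(bad))
    stop_fluxpath("validation",
                  paste0("unknown sample role(s): ", paste(bad, collapse = ", ")))
  if (length(roles) != ncol(values))
    stop_fluxpath("validation", "one sample role per column required")
  lloq <- rep_len(as.numeric(lloq), nrow(values))
  if (any(lloq <= 0)) stop_fluxpath("validation", "lloq must be > 0")
  biomass <- rep_len(as.numeric(biomass), ncol(values))
  groups <- rep_len(as.character(groups), ncol(values))
  if (any(roles == "biological" & is.na(groups)))
    stop_fluxpath("validation", "every biological sample needs a group label")
  structure(list(values = values, missing_mask = is.na(values),
                 lloq = stats::setNames(lloq, rownames(values)),
                 sample_roles = stats::setNames(roles, colnames(values)),
                 groups = stats::setNames(groups, colnames(values)),
                 biomass = stats::setNames(biomass, colnames(values))),
            class = "concentration_table")
}

#' @export
print.concentration_table <- function(x, ...) {
  cat("concentration_table: ", nrow(x$values), " metabolites x ",
      ncol(x$values), " samples (",
      sum(x$sample_roles == "biological"), " biological, ",
      sum(x$sample_roles == "qc"), " QC, ",
      sum(x$sample_roles == "blank_medium"), " blank); ",
      sum(x$missing_mask), " missing entries\n", sep = "")
  invisible(x)
}

rsd_pct <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  m <- mean(x)
  if (m == 0) return(if (stats::sd(x) == 0) 0 else Inf)
  100 * stats::sd(x) / m
}

#' QC-filter a concentration table
#'
#' Drops metabolites failing any of the acquisition QC rules: (1) medium
#' blank concentration greater than `blank_frac` (default 80%) of the mean
#' biological concentration; (2) RSD across QC samples at or above `qc_rsd`
#' percent (default 50); (3) any per-group biological-replicate RSD at or
#' above `component_rsd` percent (default 80). The filter is idempotent.
#'
#' @param table a `concentration_table`.
#' @param blank_frac blank-to-biological concentration ratio cutoff.
#' @param qc_rsd QC-sample RSD cutoff, percent.
#' @param component_rsd per-component biological RSD cutoff, percent.
#' @return list with `table` (filtered) and `report` (data.frame of
#'   `metabolite`, `reason`, `value`).
#' @export
qc_filter_concentrations <- function(table, blank_frac = 0.8, qc_rsd = 50,
                                     component_rsd = 80) {
  roles <- table$sample_roles
  bio <- which(roles == "biological")
  if (length(bio) == 0L)
    stop_fluxpath("validation", "no biological samples in table")
  qc <- which(roles == "qc"); blank <- which(roles == "blank_medium")
  drops <- list()
  for (i in seq_len(nrow(table$values))) {
    met <- rownames(table$values)[i]
    bio_mean <- mean(table$values[i, bio], na.rm = TRUE)
    if (length(blank) && !is.nan(bio_mean) && bio_mean > 0) {
      bl <- mean(table$values[i, blank], na.rm = TRUE)
      if (!is.nan(bl) && bl > blank_frac * bio_mean) {
        drops[[length(drops) + 1L]] <-
          data.frame(metabolite = met, reason = "blank_fraction",
                     value = bl / bio_mean)
        next
      }
    }
    if (length(qc) >= 2L) {
      r <- rsd_pct(table$values[i, qc])
      if (!is.na(r) && r >= qc_rsd) {
        drops[[length(drops) + 1L]] <-
          data.frame(metabolite = met, reason = "qc_rsd", value = r)
        next
      }
    }
    grp_rsd <- vapply(split(bio, table$groups[bio]), function(j)
      rsd_pct(table$values[i, j]), numeric(1))
    grp_rsd <- grp_rsd[!is.na(grp_rsd)]
    if (length(grp_rsd) && max(grp_rsd) >= component_rsd) {
      drops[[length(drops) + 1L]] <-
        data.frame(metabolite = met, reason = "component_rsd",
                   value = max(grp_rsd))
    }
  }
  report <- if (length(drops)) do.call(rbind, drops)
  else data.frame(metabolite = character(), reason = character(),
                  value = numeric())
  keep <- setdiff(rownames(table$values), report$metabolite)
  out <- table
  out$values <- table$values[keep, , drop = FALSE]
  out$missing_mask <- table$missing_mask[keep, , drop = FALSE]
  out$lloq <- table$lloq[keep]
  list(table = out, report = report)
}

# One EM fit of a multivariate normal to rows-with-missing data.
# X: n x p with NAs; returns list(mu, sigma). Ridge keeps sigma invertible
# when p approaches n.
em_mvnorm <- function(X, ridge = NULL, max_iter = 50, tol = 1e-6) {
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  Xi <- X
  for (j in seq_len(p)) Xi[is.na(Xi[, j]), j] <- mu[j]
  sigma <- stats::cov(Xi) * (n - 1) / n
  if (is.null(ridge)) ridge <- 1e-4 * mean(diag(sigma)) + 1e-8
  for (iter in seq_len(max_iter)) {
    sig_r <- sigma + diag(ridge, p)
    Ex <- X
    Exx_corr <- matrix(0, p, p)
    for (r in seq_len(n)) {
      m <- which(is.na(X[r, ]))
      if (!length(m)) next
      o <- setdiff(seq_len(p), m)
      if (length(o)) {
        So_inv <- solve(sig_r[o, o, drop = FALSE])
        B <- sig_r[m, o, drop = FALSE] %*% So_inv
        Ex[r, m] <- mu[m] + as.vector(B %*% (X[r, o] - mu[o]))
        Cm <- sig_r[m, m, drop = FALSE] - B %*% sig_r[o, m, drop = FALSE]
      } else {
        Ex[r, m] <- mu[m]
        Cm <- sig_r[m, m, drop = FALSE]
      }
      Exx_corr[m, m] <- Exx_corr[m, m] + Cm
    }
    mu_new <- colMeans(Ex)
    centred <- sweep(Ex, 2L, mu_new)
    sigma_new <- (crossprod(centred) + Exx_corr) / n
    delta <- max(abs(mu_new - mu), abs(sigma_new - sigma))
    mu <- mu_new; sigma <- sigma_new
    if (delta < tol) break
  }
  list(mu = mu, sigma = sigma + diag(ridge, p))
}

#' Impute missing concentrations by bootstrap EM
#'
#' Missing entries of biological samples are imputed on the log scale with a
#' bootstrap-EM multivariate-normal scheme: samples are resampled with
#' replacement `n_imputations` times, a normal model is fitted to each
#' bootstrap set by EM, the conditional expectation of each missing entry
#' given the sample's observed metabolites is computed under each fit, and
#' the imputed value is the average across fits (back-transformed). Entries
#' that remain missing (e.g. metabolites missing in every sample, or
#' missing QC/blank entries) are set to half the metabolite's lower limit of
#' quantification normalized to the sample's biomass.
#'
#' @param table a `concentration_table`.
#' @param n_imputations number of bootstrap EM fits (default 1000).
#' @param seed integer seed.
#' @return The table with `values` completed (`missing_mask` updated to all
#'   FALSE).
#' @export
impute_missing <- function(table, n_imputations = 1000L, seed) {
  if (any(table$lloq <= 0)) stop_fluxpath("validation", "lloq must be > 0")
  vals <- table$values
  if (!anyNA(vals)) return(table)
  bio <- which(table$sample_roles == "biological")
  # metabolites observed at least once in biological samples are EM-imputable
  imputable <- rowSums(!is.na(vals[, bio, drop = FALSE])) > 0L
  if (any(imputable) && anyNA(vals[imputable, bio])) {
    X <- t(log(vals[imputable, bio, drop = FALSE]))   # samples x metabolites
    n <- nrow(X)
    acc <- matrix(0, n, ncol(X)); cnt <- 0L
    with_seed(seed, {
      for (b in seq_len(n_imputations)) {
        rows <- sample.int(n, n, replace = TRUE)
        Xb <- X[rows, , drop = FALSE]
        # every variable must be observed in the bootstrap set
        if (any(colSums(!is.na(Xb)) == 0L)) next
        fit <- em_mvnorm(Xb)
        sig <- fit$sigma
        for (r in seq_len(n)) {
          m <- which(is.na(X[r, ]))
          if (!length(m)) next
          o <- setdiff(seq_len(ncol(X)), m)
          est <- if (length(o)) {
            fit$mu[m] + as.vector(
              sig[m, o, drop = FALSE] %*%
                solve(sig[o, o, drop = FALSE], X[r, o] - fit$mu[o]))
          } else fit$mu[m]
          acc[r, m] <- acc[r, m] + est
        }
        cnt <- cnt + 1L
      }
    })
    if (cnt > 0L) {
      for (r in seq_len(n)) {
        m <- which(is.na(X[r, ]))
        if (length(m)) X[r, m] <- acc[r, m] / cnt
      }
      vals[imputable, bio] <- t(exp(X))
    }
  }
  # fallback: half-LLOQ normalized to sample biomass
  still <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(still))
    vals[still] <- 0.5 * table$lloq[still[, 1]] / table$biomass[still[, 2]]
  table$values <- vals
  table$missing_mask[] <- FALSE
  table
}

#' Generalized logarithm transform
#'
#' `glog(y) = log2((y + sqrt(y^2 + lambda)) / 2)`; equals `log2(y)` exactly
#' at `lambda = 0` and is strictly increasing and invertible for
#' `lambda >= 0` on `y >= 0`.
#'
#' @param y non-negative numeric values.
#' @param lambda non-negative transform parameter.
#' @return Transformed values.
#' @seealso [glog_inverse()], [glog_normalize()]
#' @export
glog <- function(y, lambda = 0) {
  if (any(lambda < 0)) stop_fluxpath("validation", "lambda must be >= 0")
  log2((y + sqrt(y^2 + lambda)) / 2)
}

#' Inverse generalized logarithm
#'
#' @param g glog-transformed values.
#' @param lambda the lambda used in the forward transform.
#' @return Original-scale values.
#' @export
glog_inverse <- function(g, lambda = 0) {
  z <- 2^g
  z - lambda / (4 * z)
}

#' Variance-stabilizing normalization of a concentration table
#'
#' Applies the glog transform elementwise. `lambda = "auto"` selects, over a
#' data-scaled grid, the lambda minimizing the spread (standard deviation of
#' the log) of per-metabolite variances across biological samples — the
#' heuristic target of variance stabilization.
#'
#' @param table a `concentration_table` (complete; impute first).
#' @param lambda non-negative value, or `"auto"`.
#' @return The table with transformed `values` and attribute `lambda`.
#' @export
glog_normalize <- function(table, lambda = "auto") {
  vals <- table$values
  if (anyNA(vals))
    stop_fluxpath("validation", "table has missing values; impute first")
  if (identical(lambda, "auto")) {
    bio <- table$sample_roles == "biological"
    spread <- function(l) {
      v <- apply(glog(vals[, bio, drop = FALSE], l), 1L, stats::var)
      v <- v[v > 0]
      if (!length(v)) return(Inf)
      stats::sd(log(v))
    }
    grid <- stats::quantile(vals[vals > 0], 0.25)^2 * 10^seq(-4, 4, by = 0.5)
    lambda <- grid[which.min(vapply(grid, spread, numeric(1)))]
  }
  if (!is.numeric(lambda) || lambda < 0)
    stop_fluxpath("validation", "lambda must be a non-negative number or 'auto'")
  table$values <- glog(vals, lambda)
  attr(table, "lambda") <- as.numeric(lambda)
  table
}

#' Differential metabolite testing with Bonferroni control
#'
#' Two-sample Student's t-test per metabolite between two biological groups
#' of a (normalized) concentration table, Bonferroni-adjusted over the
#' tested metabolites; significance at adjusted p below `alpha`
#' (default 0.01).
#'
#' @param table a `concentration_table`, already glog- (or median-)
#'   normalized.
#' @param group_a,group_b group labels to compare.
#' @param alpha adjusted-p significance cutoff.
#' @return data.frame with `metabolite`, `mean_a`, `mean_b`, `difference`,
#'   `t`, `p_value`, `p_adjusted`, `significant`.
#' @export
diff_metabolites <- function(table, group_a, group_b, alpha = 0.01) {
  roles <- table$sample_roles
  ia <- which(roles == "biological" & table$groups == group_a)
  ib <- which(roles == "biological" & table$groups == group_b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop_fluxpath("validation", "each group needs at least 2 biological samples")
  res <- lapply(seq_len(nrow(table$values)), function(i) {
    xa <- table$values[i, ia]; xb <- table$values[i, ib]
    tt <- tryCatch(stats::t.test(xa, xb, var.equal = TRUE),
                   error = function(e) NULL)
    data.frame(metabolite = rownames(table$values)[i],
               mean_a = mean(xa), mean_b = mean(xb),
               difference = mean(xa) - mean(xb),
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p_value = if (is.null(tt)) 1 else tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "bonferroni")
  out$significant <- out$p_adjusted < alpha
  out
}

#' Construct a mass-isotopomer-distribution (MID) table
#'
#' Long-format isotopomer fractions per fragment, mass channel and
#' replicate, with the fraction of each channel's signal found in
#' unlabeled/blank samples. Per fragment and replicate the channel
#' fractions must sum to 1 within 0.01.
#'
#' @param fractions data.frame with columns `fragment`, `channel`,
#'   `replicate`, `fraction` (in `[0, 1]`).
#' @param blank_signal_fraction data.frame with columns `fragment`,
#'   `channel`, `blank_fraction`.
#' @return An object of class `mid_table`.
#' @export
mid_table <- function(fractions, blank_signal_fraction) {
  need <- c("fragment", "channel", "replicate", "fraction")
  if (!all(need %in% names(fractions)))
    stop_fluxpath("format", paste0("fractions needs columns: ",
                                   paste(need, collapse = ", ")))
  if (any(fractions$fraction < 0 | fractions$fraction > 1))
    stop_fluxpath("validation", "MID fractions must lie in [0, 1]")
  sums <- tapply(fractions$fraction,
                 interaction(fractions$fragment, fractions$replicate,
                             drop = TRUE), sum)
  if (any(abs(sums - 1) > 0.01))
    stop_fluxpath("validation",
                  "MID fractions must sum to 1 (within 0.01) per fragment and replicate")
  structure(list(fractions = fractions, blank = blank_signal_fraction),
            class = "mid_table")
}

#' QC-filter MID channels
#'
#' Drops mass channels whose fraction RSD across replicates exceeds
#' `rsd_cut` percent (default 50), and channels whose signal in unlabeled or
#' blank samples exceeds `blank_cut` (default 0.8) of the total.
#'
#' @param mids a `mid_table`.
#' @param rsd_cut replicate RSD cutoff, percent (strictly greater drops).
#' @param blank_cut blank signal fraction cutoff (strictly greater drops).
#' @return list with `mids` (filtered) and `report` (data.frame of
#'   `fragment`, `channel`, `reason`, `value`).
#' @export
qc_filter_mids <- function(mids, rsd_cut = 50, blank_cut = 0.8) {
  fr <- mids$fractions
  key <- interaction(fr$fragment, fr$channel, drop = TRUE)
  if (any(tapply(fr$replicate, key, function(r) length(unique(r))) < 2L))
    stop_fluxpath("validation", "RSD filter needs >= 2 replicates per channel")
  drops <- list()
  for (k in levels(key)) {
    rows <- which(key == k)
    frag <- fr$fragment[rows[1]]; chan <- fr$channel[rows[1]]
    r <- rsd_pct(fr$fraction[rows])
    if (!is.na(r) && r > rsd_cut) {
      drops[[length(drops) + 1L]] <-
        data.frame(fragment = frag, channel = chan, reason = "rsd", value = r)
      next
    }
    bl <- mids$blank$blank_fraction[mids$blank$fragment == frag &
                                      mids$blank$channel == chan]
    if (length(bl) && bl[1] > blank_cut)
      drops[[length(drops) + 1L]] <-
        data.frame(fragment = frag, channel = chan, reason = "blank",
                   value = bl[1])
  }
  report <- if (length(drops)) do.call(rbind, drops)
  else data.frame(fragment = character(), channel = character(),
                  reason = character(), value = numeric())
  keep <- !(paste(fr$fragment, fr$channel) %in%
              paste(report$fragment, report$channel))
  out <- mids
  out$fractions <- fr[keep, , drop = FALSE]
  list(mids = out, report = report)
}

#' Estimate exponential growth rate from an OD600 curve
#'
#' Ordinary least-squares slope of `ln(OD600)` against time over the
#' exponential phase. Batch-culture rates use at least 8 time points;
#' automated serial-passage (ALE) platforms read only 4 per flask, so
#' `min_points` can be lowered to 4 for that mode.
#'
#' @param times hours, strictly increasing.
#' @param od600 positive OD600 readings.
#' @param min_points minimum curve length (default 8).
#' @return list with `mu` (h^-1) and `r_squared`.
#' @export
growth_rate <- function(times, od600, min_points = 8L) {
  if (length(times) != length(od600))
    stop_fluxpath("validation", "times and od600 lengths differ")
  if (length(times) < min_points)
    stop_fluxpath("validation",
                  paste0("growth curve needs >= ", min_points, " points"))
  if (any(diff(times) <= 0))
    stop_fluxpath("validation", "times must be strictly increasing")
  if (any(od600 <= 0))
    stop_fluxpath("validation", "OD600 readings must be positive")
  fit <- stats::lm(log(od600) ~ times)
  list(mu = unname(stats::coef(fit)[2]),
       r_squared = suppressWarnings(summary(fit)$r.squared))
}

#' Monotone fitness trajectory through growth-rate observations
#'
#' Fits a C1 monotone cubic interpolant (monotone-preserving Hermite
#' scheme) through (cumulative time, growth rate) knots; non-monotone raw
#' rates are first replaced by their isotonic regression, so the returned
#' spline interpolates the monotone-adjusted knots and never decreases
#' between them.
#'
#' @param times cumulative process time, strictly increasing (>= 3 points).
#' @param rates growth rates at those times.
#' @return A function of time evaluating the fitted trajectory.
#' @export
fitness_trajectory <- function(times, rates) {
  if (length(times) < 3L)
    stop_fluxpath("validation", "need >= 3 knots")
  if (length(times) != length(rates))
    stop_fluxpath("validation", "times and rates lengths differ")
  if (any(diff(times) <= 0))
    stop_fluxpath("validation", "times must be strictly increasing")
  y <- stats::isoreg(times, rates)$yf
  stats::splinefun(times, y, method = "hyman")
}

#' Pairwise replicate-correlation QC
#'
#' Pearson correlation per replicate pair on log-scale values; a pair fails
#' when r falls below `min_r` (default 0.95).
#'
#' @param expression_matrix numeric features x replicates matrix.
#' @param min_r pass threshold.
#' @param log_transform apply `log2(x + 1)` first (default TRUE; set FALSE
#'   if the matrix is already on a log scale).
#' @return data.frame with `replicate_a`, `replicate_b`, `r`, `pass`.
#' @export
replicate_correlation_qc <- function(expression_matrix, min_r = 0.95,
                                     log_transform = TRUE) {
  m <- as.matrix(expression_matrix)
  if (ncol(m) < 2L) stop_fluxpath("validation", "need >= 2 replicates")
  if (is.null(colnames(m))) colnames(m) <- sprintf("rep%d", seq_len(ncol(m)))
  if (log_transform) m <- log2(m + 1)
  if (any(apply(m, 2L, stats::sd) == 0))
    stop_fluxpath("validation",
                  "zero-variance replicate: correlation undefined")
  pairs <- utils::combn(ncol(m), 2L)
  data.frame(
    replicate_a = colnames(m)[pairs[1, ]],
    replicate_b = colnames(m)[pairs[2, ]],
    r = apply(pairs, 2L, function(p) stats::cor(m[, p[1]], m[, p[2]])),
    stringsAsFactors = FALSE) -> out
  out$pass <- out$r >= min_r
  out
}
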