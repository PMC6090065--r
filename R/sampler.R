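# Uniform-style sampling of the steady-state flux polytope with an
# artificial-centering hit-and-run chain, plus chain diagnostics and
# per-reaction summaries.

free_width_tol <- 1e-9

# Split reactions into free and fixed sets; fixed reactions sit at their
# (common) bound and are eliminated from the chain.
polytope_geometry <- function(model) {
  rxn <- model$reactions
  b <- cap_bounds(rxn$lower_bound, rxn$upper_bound)
  free <- which(b$ub - b$lb > free_width_tol)
  fixed <- setdiff(seq_len(nrow(rxn)), free)
  S <- stoichiometric_matrix(model)
  list(S = S, lb = b$lb, ub = b$ub, free = free, fixed = fixed)
}

#' Generate warmup points spanning the flux polytope
#'
#' Solves, for every free reaction, the LPs minimizing and maximizing its
#' flux, plus a set of LPs with random signed objectives, yielding at least
#' `2 * n_free` feasible vertices that span the polytope. These seed the
#' hit-and-run chain of [sample_fluxes()].
#'
#' @param model a feasible `metabolic_model`.
#' @param seed integer seed for the random objective directions.
#' @param n_random number of additional random-direction vertices.
#' @return Matrix (points x reactions) of feasible flux vectors, columns
#'   named by reaction id.
#' @export
generate_warmup <- function(model, seed, n_random = 0L) {
  geo <- polytope_geometry(model)
  n <- length(geo$lb)
  dirs <- list()
  for (j in geo$free) {
    e <- numeric(n); e[j] <- 1
    dirs[[length(dirs) + 1L]] <- e
    dirs[[length(dirs) + 1L]] <- -e
  }
  if (length(dirs) == 0L) {          # fully fixed polytope: single point
    v <- geo$lb
    res <- solve_lp(geo$S, geo$lb, geo$ub, numeric(n))
    if (res$status == "infeasible")
      stop_fluxpath("infeasible", paste0("model '", model$id, "' is infeasible"))
    pts <- rbind(res$v, res$v)
    colnames(pts) <- model$reactions$id
    return(pts)
  }
  if (n_random > 0L) {
    rnd <- with_seed(seed, replicate(n_random, {
      e <- numeric(n)
      e[geo$free] <- stats::rnorm(length(geo$free))
      e
    }, simplify = FALSE))
    dirs <- c(dirs, rnd)
  }
  pts <- matrix(NA_real_, length(dirs), n,
                dimnames = list(NULL, model$reactions$id))
  for (k in seq_along(dirs)) {
    res <- solve_lp(geo$S, geo$lb, geo$ub, dirs[[k]], maximize = TRUE)
    if (res$status == "infeasible")
      stop_fluxpath("infeasible", paste0("model '", model$id, "' is infeasible"))
    if (res$status != "optimal")
      stop_fluxpath("infeasible", "warmup LP did not converge")
    pts[k, ] <- res$v
  }
  pts
}

#' Sample steady-state flux distributions by hit-and-run
#'
#' Runs a single artificial-centering hit-and-run chain in the null-space
#' parameterization of the stoichiometric matrix, so every point satisfies
#' S v = 0 by construction. One point is retained every `n_steps` steps.
#' The defaults (5,000 points from 5,000 steps each) are the settings used
#' for characterizing knockout strains of central metabolism; convergence is
#' checked with [mixed_fraction()], which is about 0.5 for a well-mixed
#' chain.
#'
#' @param model a feasible `metabolic_model`.
#' @param n_points number of points to retain (>= 2).
#' @param n_steps chain steps between retained points (>= 1).
#' @param seed integer seed; a fixed seed gives a bit-identical sample.
#' @return A `flux_sample`: list with `points` (n_points x n_reactions
#'   matrix), `reaction_ids`, `n_steps_per_point`, `seed`, `model_id`, and
#'   `degenerate` (TRUE when the polytope is a single point and that point
#'   is repeated).
#' @export
sample_fluxes <- function(model, n_points = 5000L, n_steps = 5000L, seed) {
  if (n_points < 2L) stop_fluxpath("validation", "n_points must be >= 2")
  if (n_steps < 1L) stop_fluxpath("validation", "n_steps must be >= 1")
  if (missing(seed)) stop_fluxpath("validation", "seed is required")
  geo <- polytope_geometry(model)
  warm <- generate_warmup(model, seed = seed,
                          n_random = max(0L, length(geo$free)))
  degenerate <- FALSE
  if (length(geo$free) == 0L) {
    pts <- warm[rep(1L, n_points), , drop = FALSE]
    degenerate <- TRUE
  } else {
    Sf <- geo$S[, geo$free, drop = FALSE]
    # null space of the free stoichiometry (svd-based, orthonormal)
    sv <- svd(Sf, nu = 0, nv = ncol(Sf))
    tol <- max(dim(Sf)) * max(sv$d, 0) * .Machine$double.eps
    rank <- sum(sv$d > tol)
    d <- ncol(Sf) - rank
    if (d == 0L) {
      pts <- warm[rep(1L, n_points), , drop = FALSE]
      degenerate <- TRUE
    } else {
      N <- sv$v[, seq.int(rank + 1L, ncol(Sf)), drop = FALSE]
      # particular solution: project the warmup centroid onto null(S_free)
      Wf <- warm[, geo$free, drop = FALSE]
      vbar <- colMeans(Wf)
      fixed_part <- if (length(geo$fixed))
        as.vector(geo$S[, geo$fixed, drop = FALSE] %*% geo$lb[geo$fixed])
      else numeric(nrow(geo$S))
      v0 <- vbar - qr.coef(qr(Sf), as.vector(Sf %*% vbar) + fixed_part)
      v0[is.na(v0)] <- vbar[is.na(v0)]
      alpha <- t(N) %*% (t(Wf) - v0)
      chain <- .achr_chain(N, v0, alpha, geo$lb[geo$free], geo$ub[geo$free],
                           as.integer(n_points), as.integer(n_steps),
                           as.numeric(seed))
      pts <- matrix(0, n_points, ncol(geo$S))
      colnames(pts) <- model$reactions$id
      pts[, geo$free] <- chain
      if (length(geo$fixed))
        pts[, geo$fixed] <- rep(geo$lb[geo$fixed], each = n_points)
    }
  }
  if (degenerate)
    warning("flux polytope is degenerate (single point); sample repeats it")
  structure(list(points = pts, reaction_ids = model$reactions$id,
                 n_steps_per_point = as.integer(n_steps),
                 seed = as.integer(seed), model_id = model$id,
                 degenerate = degenerate),
            class = "flux_sample")
}

#' @export
print.flux_sample <- function(x, ...) {
  cat("flux_sample: ", nrow(x$points), " points x ", ncol(x$points),
      " reactions (", x$n_steps_per_point, " steps/point, seed ", x$seed,
      ", model '", x$model_id, "')\n", sep = "")
  invisible(x)
}

#' Mixed-fraction convergence diagnostic
#'
#' Pairs point i with point i + n/2 in chain order; for each non-constant
#' reaction the fraction of pairs whose two members lie on opposite sides of
#' that reaction's sample median is computed, and the mean over non-constant
#' reactions returned. A well-mixed chain gives about 0.5; a chain whose
#' second half replays its first gives 0.
#'
#' @param sample a `flux_sample` with an even number (>= 4) of points.
#' @param const_sd reactions with sample standard deviation below this are
#'   treated as constant and excluded.
#' @return The mean fraction, in `[0, 1]`.
#' @export
mixed_fraction <- function(sample, const_sd = 1e-12) {
  pts <- sample$points
  n <- nrow(pts)
  if (n < 4L || n %% 2L != 0L)
    stop_fluxpath("validation", "mixed_fraction needs an even number of points >= 4")
  sds <- apply(pts, 2L, stats::sd)
  keep <- which(sds >= const_sd)
  if (length(keep) == 0L)
    stop_fluxpath("validation",
                  "all reactions constant: mixed fraction undefined")
  half <- n %/% 2L
  fr <- vapply(keep, function(j) {
    x <- pts[, j]
    side <- x > stats::median(x)
    mean(side[seq_len(half)] != side[half + seq_len(half)])
  }, numeric(1))
  mean(fr)
}

#' Per-reaction descriptive statistics of a flux sample
#'
#' @param sample a `flux_sample`.
#' @return data.frame (`flux_summary`) with columns `reaction_id`, `mean`,
#'   `median`, `q1`, `q3`, `min`, `max`; quartiles use linear interpolation
#'   (type 7).
#' @export
summarize_sample <- function(sample) {
  pts <- sample$points
  qs <- t(apply(pts, 2L, stats::quantile,
                probs = c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE))
  out <- data.frame(reaction_id = sample$reaction_ids,
                    mean = colMeans(pts),
                    median = qs[, 3], q1 = qs[, 2], q3 = qs[, 4],
                    min = qs[, 1], max = qs[, 5],
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("flux_summary", "data.frame")
  out
}

#' Write a flux sample as TSV plus JSON sidecar
#'
#' The TSV holds one row per retained point (columns = reaction ids); the
#' sidecar records seed, steps per point, model id and the mixed-fraction
#' diagnostic.
#'
#' @param sample a `flux_sample`.
#' @param path output TSV path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_sample <- function(sample, path) {
  df <- as.data.frame(sample$points)
  names(df) <- sample$reaction_ids
  utils::write.table(cbind(point = seq_len(nrow(df)), df), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  mf <- tryCatch(mixed_fraction(sample), error = function(e) NA_real_)
  jsonlite::write_json(
    list(model_id = sample$model_id, seed = sample$seed,
         n_steps_per_point = sample$n_steps_per_point,
         n_points = nrow(sample$points), mixed_fraction = mf),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
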