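# One-site binding isotherm fits and apparent free energies.
#
# Site occupancy y (percent) versus free-ligand concentration x (percent)
# is fitted, unconstrained, to the one-site specific-binding isotherm
#
#     y = Bmax * x / (Kd + x)
#
# giving the apparent dissociation constant Kd_app (the free-cholesterol
# concentration at half-maximal occupancy) and the plateau Bmax_app.
# Apparent free-energy differences between sites follow as
# ddG = RT * ln(Kd_A / Kd_B); units of Kd cancel.

.one_site <- function(x, kd, bmax) bmax * x / (kd + x)

#' Fit the one-site saturation isotherm
#'
#' Unconstrained nonlinear least squares of `y = Bmax*x/(Kd+x)`.
#' Initialisation: `Bmax0 = max(y)`, `Kd0 = median(x)`; Gauss-Newton
#' (`stats::nls`) with convergence tolerance 1e-8, falling back to direct
#' Nelder-Mead minimisation of the residual sum of squares when the
#' Gauss-Newton step fails (e.g. degenerate all-zero data).  Failures are
#' flagged, never raised.
#'
#' @param x free-ligand concentration, percent (or a data.frame with
#'   columns `x` and `y`).
#' @param y site occupancy, percent.
#' @return object of class `fit_result`: `kd_app`, `bmax_app`,
#'   `fit_stderrs` (asymptotic, named kd/bmax), `converged`,
#'   `residual_norm`, `n_points`.
#' @export
fit_one_site <- function(x, y = NULL) {
  if (is.data.frame(x)) { y <- x$y; x <- x$x }
  stopifnot(length(x) == length(y))
  if (length(unique(x)) < 3) stop("need >= 3 distinct x values to fit")
  start <- list(kd = stats::median(x), bmax = max(y))
  res <- tryCatch({
    fit <- stats::nls(y ~ bmax * x / (kd + x), start = start,
                      control = stats::nls.control(maxiter = 1024,
                                                   tol = 1e-8,
                                                   minFactor = 1e-12,
                                                   scaleOffset = 1,
                                                   warnOnly = FALSE))
    co <- stats::coef(fit)
    se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) c(NA, NA))
    list(kd = co[["kd"]], bmax = co[["bmax"]],
         se = c(kd = unname(se[1]), bmax = unname(se[2])),
         rss = sum(stats::resid(fit)^2), converged = TRUE)
  }, error = function(e) NULL)
  if (is.null(res)) {
    sse <- function(p) sum((y - .one_site(x, exp(p[1]), p[2]))^2)
    op <- stats::optim(c(log(max(start$kd, 1e-6)), start$bmax), sse,
                       control = list(maxit = 1e4, reltol = 1e-12))
    res <- list(kd = exp(op$par[1]), bmax = op$par[2],
                se = c(kd = NA_real_, bmax = NA_real_),
                rss = op$value, converged = op$convergence == 0L)
  }
  if (!is.finite(res$kd) || res$kd <= 0 || !is.finite(res$bmax) ||
      res$bmax <= 0) {
    res$converged <- FALSE
  }
  structure(list(kd_app = res$kd, bmax_app = res$bmax,
                 fit_stderrs = res$se, converged = res$converged,
                 residual_norm = sqrt(res$rss), n_points = length(x)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("one-site fit: Kd_app = %.4g%%, Bmax_app = %.4g%% (%s, n = %d, |r| = %.3g)\n",
              x$kd_app, x$bmax_app,
              if (x$converged) "converged" else "NOT converged",
              x$n_points, x$residual_norm))
  invisible(x)
}

#' Predicted occupancy from a fit
#' @param object a `fit_result`
#' @param newdata data.frame with column `x`, or numeric x
#' @param ... unused
#' @export
predict.fit_result <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$x else newdata
  .one_site(x, object$kd_app, object$bmax_app)
}

#' Standard error of the mean across replicate estimates
#'
#' Sample standard deviation divided by sqrt(count); the headline error on
#' Kd_app is this SEM over independent replicate fits.
#'
#' @param values per-replicate estimates (>= 2).
#' @return SEM.
#' @export
replicate_sem <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need >= 2 replicate values for a SEM")
  stats::sd(values) / sqrt(length(values))
}

#' Apparent binding free energy from Kd_app
#'
#' dG_app = RT ln(Kd), with Kd expressed as a mole fraction
#' (percent / 100): stronger binding (smaller Kd) gives a more negative
#' dG, and dG_A - dG_B equals [delta_delta_g()].  The absolute value
#' depends on the mole-fraction reference state; only differences between
#' sites (ddG) are reference-free.
#'
#' @param kd_percent Kd_app in percent free cholesterol (> 0).
#' @param temperature kelvin.
#' @return kJ/mol.
#' @export
delta_g_app <- function(kd_percent, temperature = 310) {
  if (any(kd_percent <= 0)) stop("Kd must be positive")
  rt_kj(temperature) * log(kd_percent / 100)
}

#' Apparent free-energy difference between two sites
#'
#' ddG = dG_A - dG_B = RT * ln(Kd_A / Kd_B).  Units of Kd cancel, so the
#' inputs may be in percent directly.  Antisymmetric under site swap;
#' negative when A binds more strongly (smaller Kd).
#'
#' @param kd_a,kd_b Kd_app of the two sites, same units, > 0.
#' @param temperature kelvin.
#' @return kJ/mol.
#' @export
delta_delta_g <- function(kd_a, kd_b, temperature = 310) {
  if (any(c(kd_a, kd_b) <= 0)) stop("Kd must be positive")
  rt_kj(temperature) * log(kd_a / kd_b)
}

#' Fit a saturation dataset: pooled fit plus per-replicate fits with SEM
#'
#' The pooled fit uses every (x, y) point; per-replicate fits give the
#' replicate scatter, summarised as the SEM of Kd_app (the protocol's
#' headline error).
#'
#' @param points data.frame with columns `x`, `y`, `replicate`.
#' @return list: `pooled` (a [fit_one_site()] result), `per_replicate`
#'   (list of fit_results), `kd_app` (pooled estimate), `kd_sem`,
#'   `bmax_sem` (NA when < 2 converged replicate fits).
#' @export
fit_saturation <- function(points) {
  stopifnot(all(c("x", "y", "replicate") %in% names(points)))
  pooled <- fit_one_site(points$x, points$y)
  reps <- sort(unique(points$replicate))
  per <- lapply(reps, function(r) {
    p <- points[points$replicate == r, ]
    tryCatch(fit_one_site(p$x, p$y), error = function(e) NULL)
  })
  names(per) <- as.character(reps)
  kds <- vapply(per, function(f) {
    if (is.null(f) || !f$converged) NA_real_ else f$kd_app
  }, numeric(1))
  bmaxs <- vapply(per, function(f) {
    if (is.null(f) || !f$converged) NA_real_ else f$bmax_app
  }, numeric(1))
  ok <- is.finite(kds)
  list(pooled = pooled,
       per_replicate = per,
       kd_app = pooled$kd_app,
       bmax_app = pooled$bmax_app,
       kd_per_replicate = kds,
       kd_sem = if (sum(ok) >= 2) replicate_sem(kds[ok]) else NA_real_,
       bmax_sem = if (sum(ok) >= 2) replicate_sem(bmaxs[ok]) else NA_real_)
}

#' Convergence scan: re-fit on replicate subsets and truncated trajectories
#'
#' Mirrors the convergence protocol: the isotherm is re-fitted with fewer
#' replicates and/or shorter trajectories and the drift of Kd_app relative
#' to the full fit is reported.  Trajectory truncation requires the dataset
#' to carry its per-frame contact series (see
#' [generate_saturation_dataset()] with `keep_series = TRUE`).
#'
#' @param dataset a saturation dataset: list with `points` (data.frame
#'   x, y, replicate, condition) and optionally `series` + `sites` for
#'   truncation support.
#' @param replicate_subsets list of integer vectors of replicate ids
#'   (default: the full set only).
#' @param frame_truncations integer vector of frame counts to truncate each
#'   replicate series to (requires stored series); `NULL` for none.
#' @return data.frame: one row per scan entry with `subset`, `frames`,
#'   `kd_app`, `bmax_app`, `kd_drift_rel` (|Kd - Kd_full| / Kd_full).
#' @export
convergence_scan <- function(dataset, replicate_subsets = NULL,
                             frame_truncations = NULL) {
  pts <- dataset$points
  reps <- sort(unique(pts$replicate))
  if (length(reps) < 2) stop("convergence scan needs >= 2 replicates")
  if (is.null(replicate_subsets)) replicate_subsets <- list(reps)
  if (!length(replicate_subsets)) stop("empty subset request")
  full <- fit_one_site(pts$x, pts$y)
  rows <- list()
  add_row <- function(subset, frames, fit) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subset = paste(subset, collapse = "+"),
      frames = frames,
      kd_app = fit$kd_app, bmax_app = fit$bmax_app,
      converged = fit$converged,
      kd_drift_rel = abs(fit$kd_app - full$kd_app) / full$kd_app,
      stringsAsFactors = FALSE)
  }
  for (sub in replicate_subsets) {
    p <- pts[pts$replicate %in% sub, ]
    add_row(sub, NA_integer_, fit_one_site(p$x, p$y))
    for (tr in frame_truncations) {
      if (is.null(dataset$series)) {
        stop("frame truncation requires a dataset with stored contact series")
      }
      p2 <- .truncated_points(dataset, sub, tr)
      add_row(sub, tr, fit_one_site(p2$x, p2$y))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "full_fit") <- full
  out
}

# Recompute (x, y) points from stored series truncated to `frames` frames.
.truncated_points <- function(dataset, replicates, frames) {
  pts <- dataset$points
  keep <- pts$replicate %in% replicates
  out <- pts[keep, ]
  for (i in which(keep)) {
    ser <- dataset$series[[i]]
    nf <- ncol(ser$residue_states)
    f <- min(frames, nf)
    sub <- ser
    sub$residue_states <- ser$residue_states[, seq_len(f), drop = FALSE]
    sub$pair_states <- ser$pair_states[, , seq_len(f), drop = FALSE]
    out$y[out$replicate == pts$replicate[i] &
            out$condition == pts$condition[i]] <-
      site_occupancy(sub, dataset$site)
  }
  out
}
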