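# 2D Gaussian pRF estimation: forward model (overlap + HRF convolution),
# coarse grid search maximising the Pearson correlation between predicted
# and observed BOLD, Nelder-Mead refinement, then amplitude/baseline
# regression.

#' Coarse search grid over pRF parameters
#'
#' Polar positions (eccentricity x angle, positions deduplicated at the
#' origin) crossed with log-spaced sigmas. Eccentricities extend 10%
#' beyond the aperture radius so border pRFs have a starting basin.
#'
#' @param n_ecc,n_angle,n_sigma grid dimensions.
#' @param max_ecc largest candidate eccentricity, deg.
#' @param sigma_range range of candidate SDs, deg (log-spaced).
#' @return data frame with columns `x0`, `y0`, `sigma`.
#' @export
prf_search_grid <- function(n_ecc = 12, n_angle = 24, n_sigma = 16,
                            max_ecc = 1.1 * 7.5, sigma_range = c(0.1, 4)) {
  stopifnot(n_ecc >= 1, n_angle >= 1, n_sigma >= 1,
            all(sigma_range > 0), max_ecc > 0)
  eccs <- seq(0, max_ecc, length.out = n_ecc)
  angles <- seq(0, 360, length.out = n_angle + 1)[seq_len(n_angle)]
  pos <- unique(do.call(rbind, lapply(eccs, function(e) {
    if (e == 0) data.frame(x0 = 0, y0 = 0)
    else data.frame(x0 = round(e * cos(angles * pi / 180), 10),
                    y0 = round(e * sin(angles * pi / 180), 10))
  })))
  sigmas <- exp(seq(log(sigma_range[1]), log(sigma_range[2]),
                    length.out = n_sigma))
  out <- merge(pos, data.frame(sigma = sigmas))
  # deterministic candidate order: sigma within position, positions as built
  out[order(match(paste(out$x0, out$y0), paste(pos$x0, pos$y0)), out$sigma), ,
      drop = FALSE]
}

#' Precompute the linear forward operator of the pRF model
#'
#' The mapping-volume BOLD prediction of any pixel weight field `g` is
#' `CF %*% g` (up to the positive normalisation that correlation ignores),
#' where `CF` combines the causal HRF convolution over the full run with
#' the restriction to mapping volumes; HRF spill-over across blank/baseline
#' boundaries is therefore modelled.
#'
#' @param apertures a [build_run_apertures()] sequence.
#' @param kernel HRF kernel, default canonical at the design TR.
#' @return object of class `prf_model`.
#' @export
prf_model <- function(apertures, kernel = NULL) {
  stopifnot(inherits(apertures, "aperture_sequence"))
  if (is.null(kernel)) kernel <- hrf_kernel(tr = apertures$design$tr)
  n_time <- ncol(apertures$frames)
  K <- convolution_operator(kernel, n_time, apertures$mapping_idx)
  structure(list(
    CF = K %*% t(apertures$frames),
    x = apertures$grid$x, y = apertures$grid$y,
    mapping_idx = apertures$mapping_idx,
    n_time = n_time, kernel = kernel, grid = apertures$grid
  ), class = "prf_model")
}

#' Predicted neural response of a Gaussian pRF
#'
#' Normalised overlap of the pRF profile with each aperture frame:
#' 0 for an empty frame, 1 for a full-field frame.
#'
#' @param params list/vector with `x0`, `y0`, `sigma` (sigma > 0).
#' @param apertures aperture sequence.
#' @return series in `[0, 1]` of length `ncol(apertures$frames)`.
#' @export
predict_neural <- function(params, apertures) {
  p <- as.numeric(unlist(params)[c("x0", "y0", "sigma")])
  if (!is.finite(p[3]) || p[3] <= 0) stop("sigma must be positive")
  g <- cpp_gauss_field(apertures$grid$x, apertures$grid$y, p[1], p[2], p[3])
  as.numeric(crossprod(apertures$frames, g)) / sum(g)
}

#' Predicted BOLD response of a Gaussian pRF
#'
#' @param params list/vector with `x0`, `y0`, `sigma`.
#' @param apertures aperture sequence.
#' @param kernel HRF kernel.
#' @param mapping_only restrict to the mapping volumes used for fitting.
#' @return predicted series.
#' @export
predict_bold <- function(params, apertures, kernel = NULL,
                         mapping_only = FALSE) {
  if (is.null(kernel)) kernel <- hrf_kernel(tr = apertures$design$tr)
  y <- convolve_hrf(predict_neural(params, apertures), kernel)
  if (mapping_only) y[apertures$mapping_idx] else y
}

#' Standardised grid predictions for the coarse stage
#'
#' @param model a [prf_model()].
#' @param grid_df a [prf_search_grid()].
#' @return object of class `prf_grid_predictions` holding the candidate
#'   table and the column-standardised mapping-volume predictions
#'   (zero-variance candidates are flagged invalid and never win).
#' @export
grid_predictions <- function(model, grid_df = prf_search_grid()) {
  stopifnot(inherits(model, "prf_model"), nrow(grid_df) > 0)
  m <- nrow(model$CF)
  P <- matrix(0, m, nrow(grid_df))
  for (j in seq_len(nrow(grid_df))) {
    g <- cpp_gauss_field(model$x, model$y,
                         grid_df$x0[j], grid_df$y0[j], grid_df$sigma[j])
    P[, j] <- model$CF %*% g
  }
  mu <- colMeans(P)
  P <- sweep(P, 2, mu)
  ss <- sqrt(colSums(P^2))
  valid <- ss > 1e-10
  P[, valid] <- sweep(P[, valid, drop = FALSE], 2, ss[valid], "/")
  structure(list(grid = grid_df, P = P, valid = valid),
            class = "prf_grid_predictions")
}

#' Coarse grid stage
#'
#' @param observed observed series over the mapping volumes (nonconstant).
#' @param gridpred a [grid_predictions()].
#' @param n_starts number of top candidates (at distinct positions) to
#'   report as refinement starts; the correlation surface can hold
#'   small-sigma local maxima away from the global one, so refining from
#'   more than one basin guards against collapse.
#' @return list with `params` (x0, y0, sigma) of the winner
#'   (first-encountered maximum in deterministic grid order), `cor`,
#'   `index`, and `starts`: a data frame of the top `n_starts` candidates
#'   at distinct positions with their correlations.
#' @export
grid_stage <- function(observed, gridpred, n_starts = 2) {
  stopifnot(inherits(gridpred, "prf_grid_predictions"))
  if (length(observed) != nrow(gridpred$P))
    stop("observed length must match the mapping volumes")
  o <- observed - mean(observed)
  n <- sqrt(sum(o^2))
  if (n < 1e-12) stop("observed series is constant")
  r <- as.numeric(crossprod(gridpred$P, o / n))
  r[!gridpred$valid] <- -Inf
  best <- which.max(r)
  ord <- order(r, decreasing = TRUE)
  pos <- paste(gridpred$grid$x0[ord], gridpred$grid$y0[ord])
  top <- ord[!duplicated(pos)][seq_len(min(n_starts, nrow(gridpred$grid)))]
  list(params = c(x0 = gridpred$grid$x0[best], y0 = gridpred$grid$y0[best],
                  sigma = gridpred$grid$sigma[best]),
       cor = r[best], index = best,
       starts = data.frame(x0 = gridpred$grid$x0[top],
                           y0 = gridpred$grid$y0[top],
                           sigma = gridpred$grid$sigma[top], cor = r[top]))
}

#' Nelder-Mead refinement stage
#'
#' Local maximisation of the Pearson correlation over (x0, y0, sigma),
#' started from the grid-stage winner. Sigma is unconstrained apart from a
#' degeneracy guard; implausible fits are caught by the downstream vertex
#' filter. If the simplex fails to improve on the grid result the grid
#' parameters are returned with a flag.
#'
#' @param observed observed mapping-volume series.
#' @param model a [prf_model()].
#' @param init initial parameters (named x0, y0, sigma).
#' @param options list: `maxit`, `reltol`, `restarts` (extra restarted
#'   simplex runs guarding against premature collapse).
#' @return list with `params`, `cor`, `flag` (`"ok"` or `"refine_failed"`).
#' @export
refine_stage <- function(observed, model, init,
                         options = list(maxit = 500, reltol = 1e-8,
                                        restarts = 1)) {
  stopifnot(inherits(model, "prf_model"))
  o <- observed - mean(observed)
  onorm <- sqrt(sum(o^2))
  if (onorm < 1e-12) stop("observed series is constant")
  obj <- function(p)
    -cpp_prf_cor(model$CF, model$x, model$y, o, onorm, p[1], p[2], p[3])
  init <- as.numeric(unlist(init)[c("x0", "y0", "sigma")])
  init_cor <- -obj(init)
  fit <- tryCatch({
    f <- optim(init, obj, method = "Nelder-Mead",
               control = list(maxit = options$maxit %||% 500,
                              reltol = options$reltol %||% 1e-8))
    for (i in seq_len(options$restarts %||% 1))
      f <- optim(f$par, obj, method = "Nelder-Mead",
                 control = list(maxit = options$maxit %||% 500,
                                reltol = options$reltol %||% 1e-8))
    f
  }, error = function(e) NULL)
  if (is.null(fit) || -fit$value < init_cor - 1e-6)
    return(list(params = c(x0 = init[1], y0 = init[2], sigma = init[3]),
                cor = init_cor, flag = "refine_failed"))
  list(params = c(x0 = fit$par[1], y0 = fit$par[2], sigma = fit$par[3]),
       cor = -fit$value, flag = "ok")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Amplitude and baseline by ordinary least squares
#'
#' @param observed,predicted equal-length series; `predicted` nonconstant.
#' @return list with `beta`, `baseline`, `r2` (squared Pearson
#'   correlation).
#' @export
fit_amplitude_baseline <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  vp <- var(predicted)
  if (!is.finite(vp) || vp < 1e-20) stop("predicted series is constant")
  beta <- cov(observed, predicted) / vp
  baseline <- mean(observed) - beta * mean(predicted)
  r <- cor(observed, predicted)
  list(beta = beta, baseline = baseline, r2 = r^2)
}

#' Fit one vertex: grid stage, refinement, amplitude regression
#'
#' The observed series is the run-averaged, detrended, z-scored time
#' course; it may be the full run (cropped internally to the mapping
#' volumes) or already mapping-restricted. For the amplitude regression
#' the refined prediction is z-scored first, so `beta` is the response
#' amplitude per unit-variance prediction (equal to the fit correlation
#' for z-scored data), the scale on which the 0.01--3 plausibility filter
#' operates.
#'
#' @param series observed series (full run or mapping volumes).
#' @param model a [prf_model()].
#' @param gridpred a [grid_predictions()].
#' @param options see [refine_stage()].
#' @return one-row data frame: `x0`, `y0`, `sigma`, `beta`, `baseline`,
#'   `r2`, `ecc`, `polar`, `flag`. Failures are reported with `r2 = 0`
#'   and a flag rather than an error.
#' @export
fit_vertex <- function(series, model, gridpred,
                       options = list(maxit = 500, reltol = 1e-8,
                                      restarts = 1)) {
  obs <- if (length(series) == model$n_time) series[model$mapping_idx]
         else if (length(series) == nrow(model$CF)) series
         else stop("series length matches neither the run nor the mapping volumes")
  empty <- data.frame(x0 = 0, y0 = 0, sigma = 0, beta = 0, baseline = 0,
                      r2 = 0, ecc = 0, polar = 0, flag = "fit_failed",
                      stringsAsFactors = FALSE)
  out <- tryCatch({
    coarse <- grid_stage(obs, gridpred, n_starts = options$n_starts %||% 2)
    opt0 <- options; opt0$restarts <- 0
    fine <- NULL
    for (s in seq_len(nrow(coarse$starts))) {
      cand <- refine_stage(obs, model, coarse$starts[s, c("x0", "y0", "sigma")],
                           opt0)
      if (is.null(fine) || cand$cor > fine$cor) fine <- cand
    }
    # polish only the winning basin
    if ((options$restarts %||% 1) > 0)
      fine <- refine_stage(obs, model, fine$params, options)
    p <- fine$params
    g <- cpp_gauss_field(model$x, model$y, p[1], p[2], abs(p[3]))
    pred <- as.numeric(model$CF %*% g)
    pz <- (pred - mean(pred)) / sd(pred)
    ab <- fit_amplitude_baseline(obs, pz)
    data.frame(x0 = p[1], y0 = p[2], sigma = p[3], beta = ab$beta,
               baseline = ab$baseline, r2 = ab$r2,
               ecc = sqrt(p[1]^2 + p[2]^2), polar = atan2(p[2], p[1]),
               flag = fine$flag, stringsAsFactors = FALSE)
  }, error = function(e) empty)
  out
}

#' Fit every vertex and condition of a simulated dataset
#'
#' Runs the full conditioning + estimation chain per vertex and condition:
#' per-run linear detrend and z-scoring, odd/even split-half reliability,
#' Spearman-Brown noise ceiling, run averaging, coarse-to-fine pRF fit,
#' and the normalised goodness of fit nR^2.
#'
#' @param dataset a [simulate_fmri_dataset()].
#' @param grid_df search grid, default [prf_search_grid()].
#' @param options optimiser options, see [refine_stage()].
#' @param progress print a line per participant.
#' @return data frame with one row per vertex x condition: identifiers,
#'   truth sigma, fitted parameters, `split_half_r`, `ceiling`, `r2`,
#'   `nr2`, `flag`.
#' @export
fit_dataset <- function(dataset, grid_df = prf_search_grid(),
                        options = list(maxit = 500, reltol = 1e-8,
                                       restarts = 1),
                        progress = FALSE) {
  stopifnot(inherits(dataset, "prf_dataset"))
  model <- prf_model(dataset$apertures, dataset$hrf_kernel)
  gridpred <- grid_predictions(model, grid_df)
  conds <- names(dataset$cfg$adaptation$adapter_sf)
  verts <- dataset$vertices
  out <- vector("list", nrow(verts) * length(conds))
  k <- 0
  for (i in seq_len(nrow(verts))) {
    if (progress && verts$vertex_id[i] %% dataset$cfg$n_vertices == 1)
      message(sprintf("participant %d", verts$participant[i]))
    for (cond in conds) {
      k <- k + 1
      runs <- dataset$bold[[i]][[cond]]
      pre <- tryCatch(apply(runs, 2, detrend_zscore), error = function(e) NULL)
      if (is.null(pre)) {
        fit <- data.frame(x0 = 0, y0 = 0, sigma = 0, beta = 0, baseline = 0,
                          r2 = 0, ecc = 0, polar = 0, flag = "constant_run",
                          stringsAsFactors = FALSE)
        shr <- NA_real_; ceil <- 0
      } else {
        shr <- if (ncol(pre) >= 2) split_half_reliability(pre) else NA_real_
        ceil <- if (is.na(shr)) 1 else spearman_brown(shr)
        fit <- fit_vertex(average_runs(pre), model, gridpred, options)
      }
      truth <- switch(cond,
                      high_adapted = verts$truth_sigma_high[i],
                      low_adapted = verts$truth_sigma_low[i], NA_real_)
      out[[k]] <- cbind(
        verts[i, c("participant", "vertex_id", "roi", "hemifield")],
        data.frame(condition = cond, truth_sigma = truth,
                   split_half_r = shr, ceiling = ceil,
                   stringsAsFactors = FALSE),
        fit)
    }
  }
  res <- do.call(rbind, out)
  res$nr2 <- normalized_r2(res$r2, res$ceiling)
  rownames(res) <- NULL
  res
}
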