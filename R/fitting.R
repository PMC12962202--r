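#' @keywords internal
new_fit_result <- function(pdff, r2star, psi, water, fat, residual, valid,
                           method, params) {
  structure(
    list(pdff = pdff, r2star_s = r2star, psi_hz = psi, water = water,
         fat = fat, residual = residual, valid = valid, method = method,
         params = params),
    class = "fam_fit"
  )
}

#' @export
print.fam_fit <- function(x, ...) {
  d <- dim(x$pdff)
  cat("<fam_fit> ", x$method, " fit, ", d[1], "x", d[2], ", ",
      sum(x$valid), " valid voxels\n", sep = "")
  invisible(x)
}

# shared input checks; returns magnitude stack [n_echo x n_vox] and dims
series_stack <- function(series) {
  stopifnot(inherits(series, "fam_echoes"))
  d <- dim(series$images[[1]])
  s <- do.call(cbind, lapply(series$images, as.vector))   # n_vox x n_echo
  list(S = t(s), dims = d)   # n_echo x n_vox
}

# single-voxel magnitude NLS from one initialization
fit_voxel_mag_once <- function(m, cn, te_s, start, cap) {
  resid_fn <- function(p) {
    Mod(p[1] + p[2] * cn) * exp(-p[3] * te_s) - m
  }
  jac_fn <- function(p) {
    z <- p[1] + p[2] * cn
    az <- Mod(z)
    az[az == 0] <- .Machine$double.eps
    dec <- exp(-p[3] * te_s)
    cbind(Re(z) / az * dec, Re(z * Conj(cn)) / az * dec, -te_s * az * dec)
  }
  fit <- minpack.lm::nls.lm(
    par = start, lower = c(0, 0, 0), upper = c(Inf, Inf, cap),
    fn = resid_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(maxiter = 100, ftol = 1e-12,
                                         ptol = 1e-12)
  )
  list(par = fit$par, rss = sum(fit$fvec^2))
}

# initial R2* guess from the magnitude envelope
init_r2star <- function(m, te_s, cap) {
  m1 <- max(m[1], .Machine$double.eps)
  mn <- max(m[length(m)], .Machine$double.eps)
  min(cap, max(0, log(m1 / mn) / (te_s[length(te_s)] - te_s[1])))
}

#' Magnitude-based confounder-corrected PDFF fitting
#'
#' Per-voxel bounded nonlinear least squares of the magnitude model
#' `|W + F c(TE)| exp(-R2* TE)` to the echo magnitudes, over
#' `(W, F, R2*)` with `W, F >= 0` and `R2*` capped. Magnitude fitting is
#' insensitive to any voxelwise phase but carries the classic dominance
#' ambiguity around PDFF 50%; both a water-dominant and a fat-dominant
#' initialization are therefore tried and the lower-residual solution kept
#' (ties go to the water-dominant solution).
#'
#' @param series A [echo_series()] with at least 4 echoes.
#' @param spectrum A [fat_spectrum()].
#' @param b0_t Field strength; defaults to the series' protocol value.
#' @param r2star_cap Upper bound on R2* (1/s).
#' @param mask Optional logical matrix restricting the fit; defaults to
#'   voxels whose mean magnitude exceeds `1e-9` times the image maximum
#'   (all-zero voxels are flagged invalid, not errors).
#' @return A `fam_fit` with maps `pdff` (percent), `r2star_s`, `water`,
#'   `fat`, `residual` (sum of squared residuals), and a `valid` mask. The
#'   field map is `NA` (magnitude fitting does not estimate it).
#' @export
magnitude_fit <- function(series, spectrum, b0_t = series$params$b0_t,
                          r2star_cap = 1000, mask = NULL) {
  st <- series_stack(series)
  if (nrow(st$S) < 4L) stop("magnitude fitting needs at least 4 echoes", call. = FALSE)
  M <- Mod(st$S)
  te_s <- series$tes_ms / 1000
  cn <- fat_phasor(spectrum, series$tes_ms, b0_t)
  nv <- ncol(M)
  if (is.null(mask)) {
    mask <- colMeans(M) > 1e-9 * max(M)
  } else {
    mask <- as.logical(as.vector(mask))
  }
  W <- Fm <- R2 <- RSS <- rep(NA_real_, nv)
  for (v in which(mask)) {
    m <- M[, v]
    a1 <- m[1]
    r20 <- init_r2star(m, te_s, r2star_cap)
    fw <- fit_voxel_mag_once(m, cn, te_s, c(a1, 0.05 * a1, r20), r2star_cap)
    ff <- fit_voxel_mag_once(m, cn, te_s, c(0.05 * a1, a1, r20), r2star_cap)
    best <- if (ff$rss < fw$rss - 1e-12) ff else fw
    W[v] <- best$par[1]; Fm[v] <- best$par[2]; R2[v] <- best$par[3]
    RSS[v] <- best$rss
  }
  finish_fit(W, Fm, R2, psi = rep(NA_real_, nv), RSS, mask, st$dims,
             "magnitude", series$params)
}

# assemble maps from per-voxel vectors
finish_fit <- function(W, Fm, R2, psi, RSS, valid, dims, method, params) {
  tot <- W + Fm
  pdff <- ifelse(valid & tot > 0, 100 * Fm / tot, NA_real_)
  shape <- function(x) array(x, dims)
  new_fit_result(shape(pdff), shape(R2), shape(psi), shape(W), shape(Fm),
                 shape(RSS), shape(as.logical(valid)), method, params)
}

# complex 2-species least squares at fixed R2* for demodulated data
complex_coefs <- function(d, cn, te_s, r2) {
  a <- exp(-r2 * te_s)
  A <- cbind(a + 0i, cn * a)
  Ah <- Conj(t(A))
  B <- solve(Ah %*% A, Ah %*% d)
  res <- d - A %*% B
  list(coefs = drop(B), rss = sum(Mod(res)^2))
}

fit_voxel_complex <- function(d, cn, te_s, cap) {
  obj <- function(r2) complex_coefs(d, cn, te_s, r2)$rss
  # coarse bracket then local refinement (objective can dip sharply)
  grid <- seq(0, cap, length.out = 21)
  vals <- vapply(grid, obj, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(obj, c(lo, hi), tol = 1e-10)
  cc <- complex_coefs(d, cn, te_s, opt$minimum)
  list(w = cc$coefs[1], f = cc$coefs[2], r2 = opt$minimum, rss = cc$rss)
}

#' Complex CSE fitting given a field map
#'
#' Demodulates the supplied field map from the complex data, then solves a
#' complex linear least-squares problem for the water and fat amplitudes at
#' each candidate R2* (1-D bracketed search). Magnitudes of the complex
#' amplitudes populate the maps. If the field map is wrong by exactly the
#' fat-water ambiguity frequency, water and fat swap — the classic failure
#' mode this fit inherits from its field-map input.
#'
#' @inheritParams magnitude_fit
#' @param psi_map Field map (Hz), matrix matching the image shape.
#' @return A `fam_fit` (method `"complex"`); `psi_hz` carries `psi_map`.
#' @export
complex_fit <- function(series, psi_map, spectrum, b0_t = series$params$b0_t,
                        r2star_cap = 1000, mask = NULL) {
  st <- series_stack(series)
  te_s <- series$tes_ms / 1000
  cn <- fat_phasor(spectrum, series$tes_ms, b0_t)
  psi <- as.vector(psi_map)
  nv <- ncol(st$S)
  if (is.null(mask)) {
    mask <- colMeans(Mod(st$S)) > 1e-9 * max(Mod(st$S))
  } else mask <- as.logical(as.vector(mask))
  W <- Fm <- R2 <- RSS <- PH <- rep(NA_real_, nv)
  for (v in which(mask)) {
    d <- st$S[, v] * exp(-1i * 2 * pi * psi[v] * te_s)
    fit <- fit_voxel_complex(d, cn, te_s, r2star_cap)
    W[v] <- Mod(fit$w); Fm[v] <- Mod(fit$f); R2[v] <- fit$r2; RSS[v] <- fit$rss
    PH[v] <- Arg(fit$w + fit$f)
  }
  out <- finish_fit(W, Fm, R2, psi, RSS, mask, st$dims, "complex", series$params)
  attr(out, "phase0") <- array(PH, st$dims)
  out
}

#' Regularized field-map estimation
#'
#' Estimates the B0 off-resonance map by minimizing
#' \deqn{\sum_v D_v(\psi_v) + \lambda \sum_{(v,u)} |\psi_v - \psi_u|}
#' over a discretized \eqn{\psi} grid spanning the full fat-water ambiguity
#' period \eqn{\pm 1/(2\Delta TE)}. The data term \eqn{D_v} is the
#' variable-projection residual of the complex two-species model over a joint
#' (\eqn{\psi}, R2*) grid, normalized by the mean voxel power. The discrete
#' optimizer is iterated conditional modes with checkerboard sweeps over the
#' 4-neighborhood, whose total energy is non-increasing by construction; the
#' energy trace is returned as an attribute.
#'
#' @inheritParams magnitude_fit
#' @param lambda_smooth Smoothness weight (per Hz of neighbor difference,
#'   against the power-normalized data term). 0 disables regularization.
#' @param n_psi Number of grid points across the ambiguity period; the grid
#'   step must not exceed `max_step_frac` of the period.
#' @param r2_grid R2* values (1/s) marginalized in the data term.
#' @param max_step_frac Maximum allowed grid step as a fraction of the
#'   ambiguity period `1/dTE`.
#' @param max_sweeps Maximum ICM sweeps.
#' @return Field map matrix (Hz) with attributes `psi_grid` and
#'   `energy_trace`.
#' @export
estimate_field_map <- function(series, spectrum, b0_t = series$params$b0_t,
                               lambda_smooth = 0.01, n_psi = 81L,
                               r2_grid = seq(0, 200, by = 25),
                               max_step_frac = 0.05, max_sweeps = 100L) {
  st <- series_stack(series)
  te_s <- series$tes_ms / 1000
  dte_s <- series$params$dte_ms / 1000
  period <- 1 / dte_s
  psi_grid <- seq(-period / 2, period / 2, length.out = n_psi)
  step <- psi_grid[2] - psi_grid[1]
  if (step > max_step_frac * period) {
    stop("field-map grid too coarse: step exceeds ", max_step_frac,
         " of the ambiguity period", call. = FALSE)
  }
  cn <- fat_phasor(spectrum, series$tes_ms, b0_t)
  S <- st$S
  nv <- ncol(S)
  power <- colSums(Mod(S)^2)
  norm <- mean(power[power > 0])
  if (!is.finite(norm) || norm <= 0) norm <- 1
  # data term D: nv x n_psi
  D <- matrix(0, nv, n_psi)
  for (g in seq_len(n_psi)) {
    demod <- exp(-1i * 2 * pi * psi_grid[g] * te_s)
    Sg <- S * demod            # recycles demod down each column
    best <- rep(Inf, nv)
    for (r2 in r2_grid) {
      a <- exp(-r2 * te_s)
      A <- cbind(a + 0i, cn * a)
      Ah <- Conj(t(A))
      B <- solve(Ah %*% A, Ah %*% Sg)
      R <- Sg - A %*% B
      best <- pmin(best, colSums(Mod(R)^2))
    }
    D[, g] <- best / norm
  }
  labels <- max.col(-D, ties.method = "first")
  dims <- st$dims
  if (lambda_smooth > 0) {
    energy <- function(lab) {
      psi <- array(psi_grid[lab], dims)
      sum(D[cbind(seq_len(nv), lab)]) + lambda_smooth *
        (sum(abs(psi[-1, ] - psi[-dims[1], ])) +
           sum(abs(psi[, -1] - psi[, -dims[2]])))
    }
    rowi <- rep(seq_len(dims[1]), dims[2])
    coli <- rep(seq_len(dims[2]), each = dims[1])
    colors <- (rowi + coli) %% 2L
    trace <- energy(labels)
    for (sweep in seq_len(max_sweeps)) {
      changed <- FALSE
      for (col in 0:1) {
        psi <- array(psi_grid[labels], dims)
        pen <- matrix(0, nv, n_psi)
        shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
        for (sh in shifts) {
          nb <- shift_map(psi, sh)
          ok <- !is.na(as.vector(nb))
          pen[ok, ] <- pen[ok, ] +
            abs(outer(as.vector(nb)[ok], psi_grid, "-"))
        }
        cost <- D + lambda_smooth * pen
        new_lab <- max.col(-cost, ties.method = "first")
        sel <- colors == col
        if (any(new_lab[sel] != labels[sel])) changed <- TRUE
        labels[sel] <- new_lab[sel]
      }
      trace <- c(trace, energy(labels))
      if (!changed) break
    }
    # global constant-relabel move: ICM's local sweeps cannot cross the flat
    # plateaus of the L1 penalty (any monotone ramp costs the same as a step),
    # so also offer the best constant map and accept it when it lowers energy
    const_costs <- colSums(D)
    best_const <- which.min(const_costs)
    if (const_costs[best_const] < energy(labels)) {
      labels <- rep(best_const, nv)
      trace <- c(trace, energy(labels))
    }
  } else {
    trace <- sum(D[cbind(seq_len(nv), labels)])
  }
  out <- array(psi_grid[labels], dims)
  attr(out, "psi_grid") <- psi_grid
  attr(out, "energy_trace") <- trace
  out
}

# shift a matrix by (dr, dc), padding with NA
shift_map <- function(m, sh) {
  d <- dim(m)
  out <- array(NA_real_, d)
  r <- seq_len(d[1]); c <- seq_len(d[2])
  rs <- r - sh[1]; cs <- c - sh[2]
  okr <- rs >= 1 & rs <= d[1]; okc <- cs >= 1 & cs <= d[2]
  out[r[okr], c[okc]] <- m[rs[okr], cs[okc]]
  out
}

#' Hybrid magnitude/complex CSE fitting
#'
#' Minimizes the per-voxel convex combination
#' `weight_w * ||complex residual||^2 + (1 - weight_w) * ||magnitude
#' residual||^2` over `(W, F, R2*, phi0)` after demodulating the field map,
#' initialized from [complex_fit()]. `weight_w = 1` reduces to the complex
#' fit, `weight_w = 0` to the magnitude fit.
#'
#' @inheritParams magnitude_fit
#' @param weight_w Complex-fit weight in `[0, 1]` (default 0.5).
#' @param psi_map Optional field map (Hz); estimated with
#'   [estimate_field_map()] when missing.
#' @param ... Passed to [estimate_field_map()] when `psi_map` is `NULL`.
#' @return A `fam_fit` (method `"hybrid"`).
#' @export
hybrid_fit <- function(series, spectrum, b0_t = series$params$b0_t,
                       weight_w = 0.5, psi_map = NULL, r2star_cap = 1000,
                       mask = NULL, ...) {
  if (weight_w < 0 || weight_w > 1) stop("weight_w must lie in [0, 1]", call. = FALSE)
  if (weight_w == 0) {
    out <- magnitude_fit(series, spectrum, b0_t, r2star_cap, mask)
    out$method <- "hybrid"
    return(out)
  }
  if (is.null(psi_map)) {
    psi_map <- estimate_field_map(series, spectrum, b0_t, ...)
  }
  init <- complex_fit(series, psi_map, spectrum, b0_t, r2star_cap, mask)
  if (weight_w == 1) {
    init$method <- "hybrid"
    return(init)
  }
  st <- series_stack(series)
  te_s <- series$tes_ms / 1000
  cn <- fat_phasor(spectrum, series$tes_ms, b0_t)
  psi <- as.vector(psi_map)
  ph0 <- as.vector(attr(init, "phase0"))
  nv <- ncol(st$S)
  valid <- as.vector(init$valid)
  W <- Fm <- R2 <- RSS <- rep(NA_real_, nv)
  sw <- sqrt(weight_w); sm <- sqrt(1 - weight_w)
  for (v in which(valid)) {
    d <- st$S[, v] * exp(-1i * 2 * pi * psi[v] * te_s)
    md <- Mod(d)
    resid_fn <- function(p) {
      z <- (p[1] + p[2] * cn) * exp(-p[3] * te_s)
      zc <- z * exp(1i * p[4])
      c(sw * Re(zc - d), sw * Im(zc - d), sm * (Mod(z) - md))
    }
    start <- c(init$water[v], init$fat[v], init$r2star_s[v], ph0[v])
    fit <- minpack.lm::nls.lm(
      par = start, lower = c(0, 0, 0, -Inf), upper = c(Inf, Inf, r2star_cap, Inf),
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 100, ftol = 1e-12,
                                           ptol = 1e-12)
    )
    W[v] <- fit$par[1]; Fm[v] <- fit$par[2]; R2[v] <- fit$par[3]
    RSS[v] <- sum(fit$fvec^2)
  }
  finish_fit(W, Fm, R2, psi, RSS, valid, st$dims, "hybrid", series$params)
}

#' Undo steady-state T1 weighting in a fit
#'
#' For constant-flip steady-state acquisitions the fitted amplitudes are the
#' T1-saturated species signals. When the acquisition flip angle, TR and the
#' species T1s are known (as in a matched-model phantom experiment), dividing
#' each amplitude by its [spgr_steady_state()] factor recovers the unbiased
#' proton densities and hence the true PDFF.
#'
#' @param fit A `fam_fit` from a constant-flip steady-state acquisition.
#' @param alpha_deg,tr_ms Acquisition flip angle (deg) and TR (ms).
#' @param t1_water_ms,t1_fat_ms Species T1s: scalars or maps matching the fit.
#' @return A `fam_fit` with corrected `water`, `fat` and `pdff` maps.
#' @export
correct_steady_state_t1 <- function(fit, alpha_deg, tr_ms, t1_water_ms,
                                    t1_fat_ms) {
  stopifnot(inherits(fit, "fam_fit"))
  gw <- spgr_steady_state(alpha_deg, tr_ms, t1_water_ms)
  gf <- spgr_steady_state(alpha_deg, tr_ms, t1_fat_ms)
  fit$water <- fit$water / gw
  fit$fat <- fit$fat / gf
  tot <- fit$water + fit$fat
  fit$pdff <- ifelse(fit$valid & tot > 0, 100 * fit$fat / tot, NA_real_)
  dim(fit$pdff) <- dim(fit$water)
  fit$method <- paste0(fit$method, "+t1corr")
  fit
}
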