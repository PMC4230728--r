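#' Fraction of native contacts (Q)
#'
#' Per-contact formation is scored with the smooth rational switching
#' function s(r) = 1 / (1 + (r / (r0_scale * sigma))^6), clamped to 1 for
#' r <= sigma, and Q is the (optionally strength-weighted) mean of the
#' scores. Because every native distance scores 1 and the all-broken limit
#' scores 0, Q is rescaled so the native configuration maps to 1 and a
#' fully extended chain to 0.
#'
#' @param x an `sbm_trajectory` or a single `n_beads` x 3 coordinate matrix.
#' @param contacts contact subset: a [contact_map] or data.frame with
#'   columns i, j, sigma (and epsilon when `strength_scaled`).
#' @param strength_scaled logical; weight each contact by its epsilon
#'   (the Q* coordinate) instead of 1.
#' @param r0_scale switching midpoint as a multiple of sigma (default 1.2).
#' @param subset label recorded on the result.
#' @return a `q_series`: per-frame Q values in \[0, 1\].
#' @export
compute_q <- function(x, contacts, strength_scaled = FALSE, r0_scale = 1.2,
                      subset = "all") {
  if (nrow(contacts) == 0) stop("contact subset is empty")
  if (inherits(x, "sbm_trajectory")) {
    r <- pair_distance_series_cpp(x$frames, as.integer(contacts$i) - 1L,
                                  as.integer(contacts$j) - 1L)
  } else {
    xyz <- as.matrix(x)
    r <- matrix(sqrt(rowSums((xyz[contacts$i, , drop = FALSE] -
                                xyz[contacts$j, , drop = FALSE])^2)), nrow = 1)
  }
  sig <- matrix(contacts$sigma, nrow(r), ncol(r), byrow = TRUE)
  s <- 1 / (1 + (r / (r0_scale * sig))^6)
  s[r <= sig * (1 + 1e-9)] <- 1
  w <- if (strength_scaled) contacts$epsilon else rep(1, nrow(contacts))
  q_series(as.vector(s %*% w) / sum(w), subset = subset,
           strength_scaled = strength_scaled)
}

#' @rdname compute_q
#' @param values per-frame Q values.
#' @export
q_series <- function(values, subset = "all", strength_scaled = FALSE) {
  stopifnot(all(is.finite(values)))
  structure(list(values = values, subset = subset,
                 strength_scaled = strength_scaled),
            class = "q_series")
}

#' @export
print.q_series <- function(x, ...) {
  cat(sprintf("q_series (%s%s): %d frames, mean Q = %.3f\n", x$subset,
              if (x$strength_scaled) ", strength-scaled" else "",
              length(x$values), mean(x$values)))
  invisible(x)
}

#' Centre-of-mass distance between two residue groups
#'
#' Euclidean distance between the unweighted bead centroids of two disjoint
#' residue sets (uniform masses).
#'
#' @param coords `n` x 3 coordinate matrix, or an `sbm_trajectory` (then a
#'   per-frame vector is returned).
#' @param group_a,group_b residue index sets (non-empty, disjoint).
#' @export
com_distance <- function(coords, group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) stop("groups must be non-empty")
  if (length(intersect(group_a, group_b)) > 0) stop("groups must be disjoint")
  if (inherits(coords, "sbm_trajectory")) {
    fr <- coords$frames
    ca <- apply(fr[group_a, , , drop = FALSE], c(2, 3), mean)
    cb <- apply(fr[group_b, , , drop = FALSE], c(2, 3), mean)
    return(sqrt(colSums((ca - cb)^2)))
  }
  xyz <- as.matrix(coords)
  ca <- colMeans(xyz[group_a, , drop = FALSE])
  cb <- colMeans(xyz[group_b, , drop = FALSE])
  sqrt(sum((ca - cb)^2))
}

#' Bundle one simulation run for WHAM
#'
#' @param T run temperature (reduced).
#' @param energy per-frame potential energies.
#' @param rc per-frame reaction coordinate: a vector, a `q_series`, or a
#'   two-column matrix for 2-D surfaces.
#' @export
wham_run <- function(T, energy, rc = NULL) {
  if (inherits(rc, "q_series")) rc <- rc$values
  stopifnot(T > 0, all(is.finite(energy)))
  structure(list(T = T, energy = energy, rc = rc), class = "wham_run")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Self-consistent multi-histogram (WHAM/MBAR-style) state of the pooled
# samples: per-sample log-denominators logD_n (which are independent of any
# target temperature) plus bookkeeping. Free energies f_k are found by
# maximizing the convex WHAM likelihood with BFGS. `drop_block` deletes one
# contiguous block (of n_blocks) from every run, for jackknife.
wham_state <- function(runs, drop_block = 0L, n_blocks = 10L) {
  keep_idx <- lapply(runs, function(r) {
    n <- length(r$energy)
    if (drop_block == 0L) return(seq_len(n))
    bounds <- floor(seq(0, n, length.out = n_blocks + 1))
    setdiff(seq_len(n), (bounds[drop_block] + 1):bounds[drop_block + 1])
  })
  E <- unlist(mapply(function(r, idx) r$energy[idx], runs, keep_idx,
                     SIMPLIFY = FALSE))
  N_k <- vapply(keep_idx, length, 0L)
  beta_k <- 1 / vapply(runs, function(r) r$T, 0)
  K <- length(runs)

  if (K == 1L) {
    logD <- log(N_k[1]) - beta_k[1] * E
  } else {
    # A_kn = log N_k + f_k - beta_k E_n ; logD_n = logsumexp_k A_kn
    colLSE <- function(f) {
      a1 <- log(N_k[1]) + f[1] - beta_k[1] * E
      m <- a1
      rows <- vector("list", K); rows[[1]] <- a1
      for (k in 2:K) {
        rows[[k]] <- log(N_k[k]) + f[k] - beta_k[k] * E
        m <- pmax(m, rows[[k]])
      }
      s <- exp(rows[[1]] - m)
      for (k in 2:K) s <- s + exp(rows[[k]] - m)
      list(logD = m + log(s), rows = rows)
    }
    negll <- function(fr) {
      f <- c(0, fr)
      sum(N_k * f) * -1 + sum(colLSE(f)$logD)
    }
    grad <- function(fr) {
      f <- c(0, fr)
      cl <- colLSE(f)
      g <- vapply(2:K, function(k) sum(exp(cl$rows[[k]] - cl$logD)) - N_k[k], 0)
      g
    }
    fr0 <- rep(0, K - 1)
    opt <- stats::optim(fr0, negll, grad, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    logD <- colLSE(c(0, opt$par))$logD
  }
  list(logD = logD, energy = E, keep_idx = keep_idx)
}

# normalized log-weights of the pooled samples at target_T
wham_weights_at <- function(state, target_T) {
  logw <- -state$energy / target_T - state$logD
  logw - logsumexp(logw)
}

wham_log_weights <- function(runs, target_T, drop_block = 0L, n_blocks = 10L) {
  st <- wham_state(runs, drop_block = drop_block, n_blocks = n_blocks)
  list(logw = wham_weights_at(st, target_T), energy = st$energy,
       keep_idx = st$keep_idx)
}

pooled_rc <- function(runs, keep_idx) {
  rcs <- mapply(function(r, idx) {
    if (is.null(r$rc)) stop("every run must supply reaction-coordinate values")
    if (is.matrix(r$rc)) r$rc[idx, , drop = FALSE] else r$rc[idx]
  }, runs, keep_idx, SIMPLIFY = FALSE)
  if (is.matrix(rcs[[1]])) do.call(rbind, rcs) else unlist(rcs)
}

profile_from_weights <- function(rc, logw, breaks) {
  bin <- findInterval(rc, breaks, rightmost.closed = TRUE)
  nb <- length(breaks) - 1
  dG <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    sel <- bin == b
    if (any(sel)) dG[b] <- -logsumexp(logw[sel])
  }
  dG - min(dG, na.rm = TRUE)
}

#' WHAM free-energy profile along a reaction coordinate
#'
#' Self-consistent multi-histogram reweighting of one or more constant-
#' temperature runs to `target_T`. The degenerate single-run case at its
#' own temperature reduces exactly to -ln(histogram). Errors are delete-one
#' -block jackknife variances (contiguous blocks per run); downstream error
#' bars are conventionally 2*sqrt(variance). Free energies are in units of
#' k_B * target_T and zeroed at the populated minimum.
#'
#' @param runs list of [wham_run()] objects (each must carry `rc`).
#' @param target_T temperature at which the profile is evaluated.
#' @param n_bins number of histogram bins.
#' @param rc_range range of the reaction coordinate (default c(0, 1)).
#' @param n_blocks jackknife blocks (>= 2 for error bars, 0 to skip).
#' @param rc_name coordinate label.
#' @return a `free_energy_profile`: `rc_grid` (bin centres), `dG`,
#'   `variance`, `rc_name`, `T_ref`.
#' @export
wham_reweight <- function(runs, target_T, n_bins = 50L, rc_range = c(0, 1),
                          n_blocks = 10L, rc_name = "Q") {
  if (inherits(runs, "wham_run")) runs <- list(runs)
  check_energy_overlap(runs)
  breaks <- seq(rc_range[1], rc_range[2], length.out = n_bins + 1)
  full <- wham_log_weights(runs, target_T)
  rc <- pooled_rc(runs, full$keep_idx)
  if (is.matrix(rc)) return(wham_fes2d(runs, target_T, n_bins, rc_name))
  dG <- profile_from_weights(rc, full$logw, breaks)
  variance <- rep(NA_real_, n_bins)
  if (n_blocks >= 2) {
    reps <- matrix(NA_real_, n_blocks, n_bins)
    for (b in seq_len(n_blocks)) {
      wb <- wham_log_weights(runs, target_T, drop_block = b, n_blocks = n_blocks)
      reps[b, ] <- profile_from_weights(pooled_rc(runs, wb$keep_idx), wb$logw, breaks)
    }
    mbar <- colMeans(reps)
    variance <- (n_blocks - 1) / n_blocks * colSums(sweep(reps, 2, mbar)^2)
    variance[is.na(dG)] <- NA_real_
  }
  structure(list(rc_grid = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 dG = dG, variance = variance, rc_name = rc_name,
                 T_ref = target_T),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  pop <- !is.na(x$dG)
  cat(sprintf("free_energy_profile over %s at T = %g: %d/%d populated bins, max dG = %.2f kT\n",
              x$rc_name, x$T_ref, sum(pop), length(x$dG), max(x$dG[pop])))
  invisible(x)
}

#' Two-dimensional free-energy surface
#'
#' As [wham_reweight()] but over two reaction coordinates; each run's `rc`
#' must be a two-column matrix. Unpopulated cells are `NA`.
#'
#' @inheritParams wham_reweight
#' @param rc_names labels of the two coordinates.
#' @param rc_ranges 2x2 matrix of ranges (rows = coordinates).
#' @return a `fes2d`: `x_grid`, `y_grid`, `dG` matrix (k_B T units).
#' @export
wham_fes2d <- function(runs, target_T, n_bins = 50L, rc_names = c("Q1", "Q2"),
                       rc_ranges = rbind(c(0, 1), c(0, 1))) {
  if (inherits(runs, "wham_run")) runs <- list(runs)
  full <- wham_log_weights(runs, target_T)
  rc <- pooled_rc(runs, full$keep_idx)
  stopifnot(is.matrix(rc), ncol(rc) == 2)
  bx <- seq(rc_ranges[1, 1], rc_ranges[1, 2], length.out = n_bins + 1)
  by <- seq(rc_ranges[2, 1], rc_ranges[2, 2], length.out = n_bins + 1)
  ix <- findInterval(rc[, 1], bx, rightmost.closed = TRUE)
  iy <- findInterval(rc[, 2], by, rightmost.closed = TRUE)
  dG <- matrix(NA_real_, n_bins, n_bins)
  valid <- ix >= 1 & ix <= n_bins & iy >= 1 & iy <= n_bins
  cell <- (ix - 1) * n_bins + iy
  for (cl in unique(cell[valid])) {
    sel <- valid & cell == cl
    dG[(cl - 1) %% n_bins + 1, (cl - 1) %/% n_bins + 1] <- -logsumexp(full$logw[sel])
  }
  dG <- dG - min(dG, na.rm = TRUE)
  structure(list(x_grid = (bx[-1] + bx[-length(bx)]) / 2,
                 y_grid = (by[-1] + by[-length(by)]) / 2,
                 dG = t(dG), rc_names = rc_names, T_ref = target_T),
            class = "fes2d")
}

check_energy_overlap <- function(runs) {
  if (length(runs) < 2) return(invisible(TRUE))
  rngs <- lapply(runs, function(r) range(r$energy))
  o <- order(vapply(runs, function(r) r$T, 0))
  for (k in seq_len(length(runs) - 1)) {
    a <- rngs[[o[k]]]; b <- rngs[[o[k + 1]]]
    if (a[2] < b[1] || b[2] < a[1])
      warning(sprintf("energy distributions of runs at T = %g and T = %g do not overlap; reweighting between them is unreliable",
                      runs[[o[k]]]$T, runs[[o[k + 1]]]$T))
  }
  invisible(TRUE)
}

#' Heat-capacity curve by WHAM extrapolation
#'
#' Cv(T) = (<E^2>_T - <E>_T^2) / (k_B T^2) with expectations reweighted from
#' the supplied runs; the folding temperature T_f is the argmax of Cv. A
#' warning is raised when the T grid extends far beyond the simulated
#' temperature bracket (where reweighting is unreliable).
#'
#' @param runs list of [wham_run()] objects (rc not required).
#' @param T_grid temperatures at which to evaluate Cv.
#' @param n_blocks jackknife blocks for replicate curves (0 to skip).
#' @return a `heat_capacity_curve`: `T_grid`, `Cv`, `T_f`, `no_transition`
#'   flag (no interior peak), and jackknife `block_curves`.
#' @export
heat_capacity <- function(runs, T_grid, n_blocks = 10L) {
  if (inherits(runs, "wham_run")) runs <- list(runs)
  Ts <- vapply(runs, function(r) r$T, 0)
  margin <- 0.25 * diff(range(c(Ts, Ts[1] * 1.001)))
  if (min(T_grid) < min(Ts) - max(margin, 0.25 * min(Ts)) ||
      max(T_grid) > max(Ts) + max(margin, 0.25 * min(Ts)))
    warning("T grid extends well beyond the simulated temperatures; reweighted Cv may be unreliable there")
  cv_curve <- function(drop_block) {
    st <- wham_state(runs, drop_block = drop_block, n_blocks = n_blocks)
    vapply(T_grid, function(Tt) {
      p <- exp(wham_weights_at(st, Tt))
      m1 <- sum(p * st$energy); m2 <- sum(p * st$energy^2)
      (m2 - m1^2) / Tt^2
    }, 0)
  }
  Cv <- cv_curve(0L)
  block_curves <- NULL
  if (n_blocks >= 2) {
    block_curves <- t(vapply(seq_len(n_blocks), function(b) cv_curve(b), T_grid))
  }
  heat_capacity_curve(T_grid, Cv, block_curves = block_curves)
}

#' @rdname heat_capacity
#' @param Cv heat-capacity values matching `T_grid` (for analytically
#'   constructed curves).
#' @param block_curves optional jackknife replicate matrix
#'   (n_blocks x length(T_grid)).
#' @export
heat_capacity_curve <- function(T_grid, Cv, block_curves = NULL) {
  stopifnot(length(T_grid) == length(Cv), all(Cv >= -1e-9))
  # the outermost grid points are excluded from the peak search: reweighted
  # curves are least reliable at the edges of the simulated bracket, and a
  # peak there is not a resolved transition anyway
  interior <- 2:(length(Cv) - 1L)
  peak <- interior[which.max(Cv[interior])]
  structure(list(T_grid = T_grid, Cv = Cv, T_f = T_grid[peak],
                 no_transition = peak == interior[1] ||
                   peak == interior[length(interior)] ||
                   max(Cv[interior]) < 1.05 * stats::median(Cv),
                 block_curves = block_curves),
            class = "heat_capacity_curve")
}

#' @export
print.heat_capacity_curve <- function(x, ...) {
  cat(sprintf("heat_capacity_curve: T_f = %g (peak Cv = %.3g)%s\n",
              x$T_f, max(x$Cv), if (x$no_transition) " [no clear transition]" else ""))
  invisible(x)
}

#' Folding cooperativity: van't Hoff / calorimetric enthalpy ratio
#'
#' From a heat-capacity curve with a detected peak at T_f:
#' dH_vH = 2 T_f sqrt(k_B Cv(T_f)) and dH_cal = integral of Cv over the
#' window between the Cv minima flanking the peak (grid edges when no
#' interior minimum exists). Both use the transition's *excess* heat
#' capacity: the linear baseline joining the window endpoints (the
#' non-transitional background, e.g. the harmonic vibrations of the folded
#' and unfolded chains) is subtracted before the peak height is read and
#' before integrating. A ratio of 1 indicates all-or-nothing (two-state)
#' folding; uncoupled sub-transitions push the ratio below 1. The jackknife
#' variance of the ratio is computed from the curve's block replicates when
#' available.
#'
#' @param curve a `heat_capacity_curve`.
#' @param baseline `"subtract"` (default) or `"none"` to use the raw curve.
#' @return a `cooperativity_report`: `dH_vH`, `dH_cal`, `ratio`, `variance`.
#' @export
cooperativity_ratio <- function(curve, baseline = c("subtract", "none")) {
  baseline <- match.arg(baseline)
  if (curve$no_transition) stop("heat-capacity curve has no detected peak")
  one <- function(Tg, Cv) {
    interior <- 2:(length(Cv) - 1L)
    p <- interior[which.max(Cv[interior])]
    lo <- which.min(Cv[1:p])
    hi <- p - 1 + which.min(Cv[p:length(Cv)])
    Tf <- Tg[p]
    win <- lo:hi
    base <- if (baseline == "subtract") {
      Cv[lo] + (Cv[hi] - Cv[lo]) * (Tg[win] - Tg[lo]) / (Tg[hi] - Tg[lo])
    } else 0
    excess_peak <- max(Cv[p] - (if (baseline == "subtract")
      Cv[lo] + (Cv[hi] - Cv[lo]) * (Tg[p] - Tg[lo]) / (Tg[hi] - Tg[lo]) else 0), 0)
    dH_vH <- 2 * Tf * sqrt(excess_peak)
    integrand <- pmax(Cv[win] - base, 0)
    dH_cal <- sum(diff(Tg[win]) * (integrand[-1] + integrand[-length(integrand)]) / 2)
    c(dH_vH = dH_vH, dH_cal = dH_cal, ratio = dH_vH / dH_cal)
  }
  full <- one(curve$T_grid, curve$Cv)
  variance <- NA_real_
  if (!is.null(curve$block_curves)) {
    B <- nrow(curve$block_curves)
    reps <- vapply(seq_len(B), function(b) one(curve$T_grid, curve$block_curves[b, ])["ratio"], 0)
    variance <- (B - 1) / B * sum((reps - mean(reps))^2)
  }
  structure(list(dH_vH = unname(full["dH_vH"]), dH_cal = unname(full["dH_cal"]),
                 ratio = unname(full["ratio"]), variance = variance),
            class = "cooperativity_report")
}

#' @export
print.cooperativity_report <- function(x, ...) {
  cat(sprintf("cooperativity: dH_vH = %.3g, dH_cal = %.3g, ratio = %.3f%s\n",
              x$dH_vH, x$dH_cal, x$ratio,
              if (is.finite(x$variance)) sprintf(" (2*sqrt(var) = %.3f)", 2 * sqrt(x$variance)) else ""))
  invisible(x)
}

#' Foldedness of a mutant relative to wild type
#'
#' The ratio of the mutant's population at the reaction-coordinate value
#' where the wild type is folded (q_ref, the WT folded-basin minimum) to
#' the wild type's population there. With both profiles zeroed at their
#' folded-basin minima this is exp(-dG_mut(q_ref)) / exp(-dG_wt(q_ref)),
#' in k_B T_f units; a value of 1 means the mutant's native ensemble is as
#' folded as the wild type's, values below 1 indicate incomplete folding.
#'
#' @param fep_mut,fep_wt `free_energy_profile`s of mutant and wild type.
#' @param q_ref reaction-coordinate value where WT is folded; default the
#'   WT folded-basin minimum (populated bin of lowest dG with rc >=
#'   `folded_region`).
#' @param folded_region lower edge of the folded basin on the RC.
#' @return a `foldedness_result`: `value`, `uncertainty` (propagated from
#'   the profiles' jackknife variances), `q_ref`.
#' @export
foldedness <- function(fep_mut, fep_wt, q_ref = NULL, folded_region = 0.5) {
  basin_zero <- function(fep) {
    sel <- which(!is.na(fep$dG) & fep$rc_grid >= folded_region)
    if (length(sel) == 0) stop("profile has no populated bins in the folded region")
    sel[which.min(fep$dG[sel])]
  }
  wt0 <- basin_zero(fep_wt)
  if (is.null(q_ref)) q_ref <- fep_wt$rc_grid[wt0]
  value_at <- function(fep, zero_bin) {
    pop <- !is.na(fep$dG)
    if (q_ref < min(fep$rc_grid[pop]) || q_ref > max(fep$rc_grid[pop]))
      stop(sprintf("q_ref = %.3f lies outside the populated range of the profile", q_ref))
    g <- stats::approx(fep$rc_grid[pop], fep$dG[pop], xout = q_ref)$y
    v <- if (all(is.na(fep$variance))) 0 else {
      vb <- stats::approx(fep$rc_grid[pop], fep$variance[pop], xout = q_ref)$y
      vb + fep$variance[zero_bin]
    }
    list(dG = g - fep$dG[zero_bin], var = v)
  }
  mut <- value_at(fep_mut, basin_zero(fep_mut))
  wt <- value_at(fep_wt, wt0)
  value <- exp(-mut$dG) / exp(-wt$dG)
  unc <- value * sqrt(mut$var + wt$var)
  structure(list(value = value, uncertainty = unc, q_ref = q_ref),
            class = "foldedness_result")
}

#' @export
print.foldedness_result <- function(x, ...) {
  cat(sprintf("foldedness = %.3f +/- %.3f at q_ref = %.3f\n",
              x$value, x$uncertainty, x$q_ref))
  invisible(x)
}

#' Detect folding/unfolding transitions in a Q time series
#'
#' A frame is in the folded basin when Q > `folded_threshold` and in the
#' unfolded basin when Q < `unfolded_threshold`. Transition segments are
#' maximal frame intervals starting at the last exit from one basin and
#' ending at the first entry into the other, labelled by direction.
#'
#' @param q a `q_series` or numeric vector.
#' @param folded_threshold,unfolded_threshold basin thresholds in \[0, 1\].
#' @return data.frame with columns `start`, `end` (frame indices) and
#'   `direction` (`"folding"` or `"unfolding"`).
#' @export
detect_transitions <- function(q, folded_threshold = 0.7, unfolded_threshold = 0.3) {
  if (inherits(q, "q_series")) q <- q$values
  if (folded_threshold < 0 || folded_threshold > 1 ||
      unfolded_threshold < 0 || unfolded_threshold > 1)
    stop("thresholds must lie in [0, 1]")
  if (unfolded_threshold >= folded_threshold)
    stop("unfolded_threshold must be below folded_threshold")
  st <- ifelse(q > folded_threshold, "F", ifelse(q < unfolded_threshold, "U", NA))
  idx <- which(!is.na(st))
  out <- data.frame(start = integer(0), end = integer(0), direction = character(0))
  if (length(idx) < 2) return(out)
  lab <- st[idx]
  change <- which(lab[-1] != lab[-length(lab)])
  for (c0 in change) {
    out <- rbind(out, data.frame(
      start = idx[c0], end = idx[c0 + 1],
      direction = if (lab[c0] == "U") "folding" else "unfolding"))
  }
  out
}

#' Delete-one-block jackknife variance
#'
#' Splits a per-frame stream into `n_blocks` contiguous blocks and computes
#' the jackknife variance of `statistic` over the delete-one-block
#' estimates. Error bars downstream are reported as 2*sqrt(variance).
#'
#' @param x numeric vector (per-frame statistic stream).
#' @param statistic function of a numeric vector returning a scalar (or a
#'   fixed-length vector, in which case a variance per component is
#'   returned).
#' @param n_blocks number of contiguous blocks (>= 2).
#' @export
jackknife_variance <- function(x, statistic = mean, n_blocks = 10L) {
  n <- length(x)
  if (n_blocks < 2) stop("n_blocks must be at least 2")
  if (n < n_blocks) stop("fewer frames than blocks")
  bounds <- floor(seq(0, n, length.out = n_blocks + 1))
  reps <- vapply(seq_len(n_blocks), function(b) {
    statistic(x[-((bounds[b] + 1):bounds[b + 1])])
  }, statistic(x))
  if (is.matrix(reps)) {
    m <- rowMeans(reps)
    (n_blocks - 1) / n_blocks * rowSums((reps - m)^2)
  } else {
    (n_blocks - 1) / n_blocks * sum((reps - mean(reps))^2)
  }
}

#' @export
print.fes2d <- function(x, ...) {
  pop <- sum(!is.na(x$dG))
  cat(sprintf("fes2d over (%s, %s) at T = %g: %d populated cells, max dG = %.2f kT\n",
              x$rc_names[1], x$rc_names[2], x$T_ref, pop,
              max(x$dG, na.rm = TRUE)))
  invisible(x)
}
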