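## Well-tempered metadynamics: group-distance collective variables, bias
## bookkeeping, the Langevin engine wrapper, free-energy reconstruction,
## profile averaging and Boltzmann projection.
##
## Conventions: the well-tempered hill height is w = w0 exp(-V(s)/kB dT)
## with dT = (gamma - 1) T, and the free energy is recovered from the
## converged bias as F(s) = -(gamma/(gamma - 1)) V(s), gauge-fixed so the
## minimum over the grid is exactly zero.

#' Group-distance collective variable
#'
#' The CV value is the Euclidean distance between the mean positions of two
#' disjoint, non-empty atom groups (e.g. the methyl protons of Met120 vs the
#' H12/H13 aromatic protons of the ligand A ring).
#'
#' @param name label (e.g. "CV1").
#' @param group_a,group_b atom index vectors.
#' @return object of class `CollectiveVariable`.
#' @export
collective_variable <- function(name, group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("CV groups must be non-empty")
  if (length(intersect(group_a, group_b)) > 0L)
    stop("CV groups must be disjoint")
  structure(list(name = name, group_a = as.integer(group_a),
                 group_b = as.integer(group_b)),
            class = "CollectiveVariable")
}

#' Evaluate a collective variable on a frame
#'
#' @param frame a `Frame` or n x 3 coordinate matrix.
#' @param cv a [collective_variable()].
#' @return distance between the two group centroids, Angstrom.
#' @export
cv_value <- function(frame, cv) {
  pos <- if (inherits(frame, "Frame")) frame$positions else as.matrix(frame)
  a <- colMeans(pos[cv$group_a, , drop = FALSE])
  b <- colMeans(pos[cv$group_b, , drop = FALSE])
  sqrt(sum((a - b)^2))
}

#' Well-tempered bias parameters
#'
#' Defaults follow common practice for a small-ligand landscape: initial
#' hill height 0.1 kcal/mol, width 0.2 Angstrom, one deposition per ps,
#' bias factor 10 at 300 K.
#'
#' @param w0 initial Gaussian height, kcal/mol.
#' @param sigma Gaussian width, Angstrom.
#' @param pace deposition interval, ps.
#' @param bias_factor well-tempered gamma (> 1).
#' @param temperature K.
#' @return object of class `BiasParameters`.
#' @export
bias_parameters <- function(w0 = 0.1, sigma = 0.2, pace = 1,
                            bias_factor = 10, temperature = 300) {
  stopifnot(w0 > 0, sigma > 0, pace > 0, bias_factor > 1, temperature > 0)
  structure(list(w0 = w0, sigma = sigma, pace = pace,
                 bias_factor = bias_factor, temperature = temperature),
            class = "BiasParameters")
}

#' One-sided harmonic wall
#'
#' Zero at or below `limit`; `kappa * (s - limit)^exponent` above, summed
#' over CVs. The harmonic form (exponent 2) is the conventional default for
#' restraining sampled distances.
#'
#' @param limit wall position, Angstrom.
#' @param kappa wall magnitude, kcal/mol.
#' @param exponent wall exponent.
#' @return object of class `WallParameters`.
#' @export
wall_parameters <- function(limit = 12, kappa = 100, exponent = 2) {
  stopifnot(kappa >= 0, exponent > 0)
  structure(list(limit = limit, kappa = kappa, exponent = exponent),
            class = "WallParameters")
}

#' Wall energy at a CV point
#' @param s CV vector, Angstrom.
#' @param wall a [wall_parameters()].
#' @return kcal/mol.
#' @export
wall_energy <- function(s, wall = wall_parameters()) {
  over <- pmax(s - wall$limit, 0)
  sum(wall$kappa * over^wall$exponent)
}

#' Create an empty bias state
#' @param params a [bias_parameters()].
#' @param dims CV dimensionality.
#' @return object of class `BiasState` holding a `hills` table and params.
#' @export
bias_state <- function(params = bias_parameters(), dims = 1L) {
  structure(list(hills = new_hills(numeric(0),
                                   matrix(numeric(0), 0, dims),
                                   matrix(numeric(0), 0, dims),
                                   numeric(0), numeric(0)),
                 params = params, dims = as.integer(dims)),
            class = "BiasState")
}

#' Deposited bias potential at a CV point
#'
#' Exact sum over hills of `height * exp(-sum_i (s_i - c_i)^2 / (2 sigma_i^2))`.
#'
#' @param state a `BiasState` or a `hills` table.
#' @param s CV vector (length = CV dimensionality).
#' @return kcal/mol.
#' @export
bias_potential <- function(state, s) {
  hills <- if (inherits(state, "BiasState")) state$hills else state
  k <- hills_dim(hills)
  if (length(s) != k)
    stop("CV point has length ", length(s), ", hills have ", k, " CVs")
  if (nrow(hills) == 0L) return(0)
  C <- hills_centers(hills); S <- hills_sigmas(hills)
  z <- sweep(C, 2, as.numeric(s))
  sum(hills$height * exp(-rowSums(z^2 / (2 * S^2))))
}

#' Deposit a well-tempered hill
#'
#' Appends a Gaussian at `s` with height `w0 * exp(-V(s) / (kB dT))`,
#' `dT = (gamma - 1) T`. Heights never exceed `w0` and strictly decrease
#' under repeated deposition at a fixed point; in the `gamma -> Inf` limit
#' the height stays `w0` (standard metadynamics).
#'
#' @param state a `BiasState`.
#' @param s CV vector.
#' @param time deposit time stamp, ps (defaults to continuing the pace).
#' @return the updated `BiasState`.
#' @export
deposit <- function(state, s, time = NULL) {
  stopifnot(inherits(state, "BiasState"))
  p <- state$params
  V <- bias_potential(state, s)
  w <- if (is.finite(p$bias_factor))
    p$w0 * exp(-V / (KB_KCAL * (p$bias_factor - 1) * p$temperature))
  else p$w0
  if (is.null(time))
    time <- if (nrow(state$hills) == 0L) p$pace else
      state$hills$time[nrow(state$hills)] + p$pace
  k <- state$dims
  nh <- new_hills(c(state$hills$time, time),
                  rbind(hills_centers(state$hills), as.numeric(s)),
                  rbind(hills_sigmas(state$hills),
                        rep(p$sigma, k)),
                  c(state$hills$height, w),
                  c(state$hills$biasf, p$bias_factor))
  state$hills <- nh
  state
}

#' Run (well-tempered metadynamics) Langevin dynamics on a toy potential
#'
#' Overdamped Euler-Maruyama dynamics at `temperature` on
#' `U + V_bias + wall`, with hills deposited every `params$pace` ps when
#' `biased = TRUE`. The CV space is the potential's own coordinate space.
#' Seed-deterministic; the hills conform to the HILLS dialect of
#' [write_hills()].
#'
#' @param potential a [make_toy_potential()].
#' @param params a [bias_parameters()].
#' @param wall a [wall_parameters()].
#' @param n_steps number of integration steps.
#' @param dt time step, ps.
#' @param seed RNG seed.
#' @param x0 start point (default: the potential's first minimum).
#' @param diffusion diffusion constant, Angstrom^2/ps.
#' @param stride trajectory output stride, steps.
#' @param biased deposit hills?
#' @param hills_path optional path to write the HILLS file to.
#' @return list with `times`, `positions` (matrix, one column per CV),
#'   `state` (a `BiasState`; empty when unbiased) and `hills`.
#' @export
run_wt_metad <- function(potential, params = bias_parameters(),
                         wall = wall_parameters(), n_steps = 1e5, dt = 0.02,
                         seed = 1, x0 = NULL, diffusion = 0.05, stride = 10,
                         biased = TRUE, hills_path = NULL) {
  stopifnot(inherits(potential, "ToyPotential"))
  d <- potential$dims
  if (is.null(x0)) {
    first_min <- function(ref) ref$minima[1]
    x0 <- if (d == 1L) first_min(potential$reference)
    else vapply(potential$reference, first_min, numeric(1))
  }
  forms <- match(potential$axis_forms, c("double_well", "harmonic")) - 1L
  ap <- matrix(0, d, 3)
  for (k in seq_len(d)) {
    pk <- potential$axis_params[[k]]
    ap[k, seq_along(pk)] <- pk
  }
  lo <- potential$domain[, 1] - 2
  hi <- pmin(potential$domain[, 2], wall$limit) + 2
  pace_steps <- max(1L, as.integer(round(params$pace / dt)))
  set.seed(seed)
  res <- .cpp_run_langevin(forms, ap, as.numeric(x0),
                           as.integer(n_steps), dt,
                           params$temperature, diffusion,
                           wall$limit, wall$kappa,
                           biased, params$w0, params$sigma,
                           pace_steps, params$bias_factor,
                           lo, hi, params$sigma / 5, as.integer(stride))
  st <- bias_state(params, dims = d)
  if (biased && res$n_hills > 0) {
    st$hills <- new_hills(res$hill_time,
                          res$hill_center,
                          matrix(params$sigma, res$n_hills, d),
                          res$hill_height, params$bias_factor)
  }
  if (!is.null(hills_path)) write_hills(st$hills, hills_path)
  list(times = res$times, positions = res$positions, state = st,
       hills = st$hills, params = params, wall = wall, dt = dt,
       potential = potential)
}

## ---- free-energy surfaces -------------------------------------------------

new_fes <- function(grid, values, bias_factor = NA_real_) {
  if (!is.list(grid)) grid <- list(grid)
  values <- if (length(grid) == 1L) as.numeric(values) else
    array(values, dim = vapply(grid, length, integer(1)))
  structure(list(grid = grid, values = values, bias_factor = bias_factor),
            class = "fes")
}

#' @export
print.fes <- function(x, ...) {
  cat("<fes> ", length(x$grid), "-D grid (",
      paste(vapply(x$grid, length, integer(1)), collapse = " x "),
      "), range 0 .. ", sprintf("%.3f", max(x$values)), " kcal/mol\n",
      sep = "")
  invisible(x)
}

# bias potential accumulated on a grid; per-hill vectorised (1D) or
# separable outer products (2D/3D)
sum_hills_grid <- function(hills, grid) {
  if (!is.list(grid)) grid <- list(grid)
  k <- hills_dim(hills)
  if (length(grid) != k) stop("grid dimensionality does not match hills")
  dims <- vapply(grid, length, integer(1))
  V <- array(0, dim = dims)
  if (nrow(hills) == 0L) return(V)
  C <- hills_centers(hills); S <- hills_sigmas(hills); h <- hills$height
  for (i in seq_len(nrow(hills))) {
    gs <- lapply(seq_len(k), function(j)
      exp(-(grid[[j]] - C[i, j])^2 / (2 * S[i, j]^2)))
    contrib <- Reduce(function(a, b) outer(a, b), gs)
    V <- V + h[i] * contrib
  }
  V
}

#' Reconstruct the free-energy surface from a bias state
#'
#' `F(s) = -(gamma / (gamma - 1)) V(s)` on the grid, shifted so the minimum
#' over the grid is exactly 0 (the "free energy zero at the absolute
#' minimum" convention). A state with no hills gives a flat zero surface.
#'
#' @param state a `BiasState` or `hills` table.
#' @param grid numeric vector (1 CV) or list of per-axis vectors.
#' @param n_hills use only the first `n_hills` hills (default all).
#' @return a `fes` object.
#' @export
reconstruct_fes <- function(state, grid, n_hills = NULL) {
  if (is.null(state)) stop("empty bias state")
  hills <- if (inherits(state, "BiasState")) state$hills else state
  gamma <- if (inherits(state, "BiasState")) state$params$bias_factor
  else if (nrow(hills) > 0) hills$biasf[1] else NA_real_
  if (!is.null(n_hills)) hills <- hills[seq_len(n_hills), , drop = FALSE]
  V <- sum_hills_grid(hills, grid)
  scale <- if (is.na(gamma) || !is.finite(gamma)) 1
  else gamma / (gamma - 1)
  f <- -scale * V
  new_fes(grid, f - min(f), bias_factor = gamma)
}

#' Free-energy profiles at successive deposition checkpoints
#'
#' Reconstructs the FES after each of `n_profiles` hill counts evenly spaced
#' over the `fraction` last part of the run (profile averaging smooths the
#' oscillation of the instantaneous well-tempered estimate).
#'
#' @param state a `BiasState`.
#' @param grid per-axis grid (as in [reconstruct_fes()]).
#' @param n_profiles number of checkpoints.
#' @param fraction final fraction of the deposition history to span.
#' @return list of `fes` objects.
#' @export
reconstruct_profiles <- function(state, grid, n_profiles = 100,
                                 fraction = 0.5) {
  hills <- if (inherits(state, "BiasState")) state$hills else state
  nh <- nrow(hills)
  if (nh < n_profiles) stop("need at least ", n_profiles, " hills")
  gamma <- if (inherits(state, "BiasState")) state$params$bias_factor
  else hills$biasf[1]
  checkpoints <- unique(round(seq(nh - fraction * nh + 1, nh,
                                  length.out = n_profiles)))
  if (!is.list(grid)) grid <- list(grid)
  dims <- vapply(grid, length, integer(1))
  V <- array(0, dim = dims)
  C <- hills_centers(hills); S <- hills_sigmas(hills); h <- hills$height
  k <- length(grid)
  out <- vector("list", length(checkpoints)); oi <- 1L
  for (i in seq_len(nh)) {
    gs <- lapply(seq_len(k), function(j)
      exp(-(grid[[j]] - C[i, j])^2 / (2 * S[i, j]^2)))
    V <- V + h[i] * Reduce(function(a, b) outer(a, b), gs)
    if (oi <= length(checkpoints) && i == checkpoints[oi]) {
      f <- -(gamma / (gamma - 1)) * V
      out[[oi]] <- new_fes(grid, f - min(f), bias_factor = gamma)
      oi <- oi + 1L
    }
  }
  out
}

#' Average free-energy profiles
#'
#' Bin-wise mean over profiles on a common grid, re-zeroed at the minimum of
#' the mean; the bin-wise standard deviation is attached.
#'
#' @param profiles list of `fes` objects on identical grids.
#' @return a `fes` with attribute `"sd"` (per-bin sd array).
#' @export
average_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  g0 <- profiles[[1]]$grid
  for (p in profiles) {
    if (length(p$grid) != length(g0) ||
        !all(vapply(seq_along(g0), function(j)
          isTRUE(all.equal(p$grid[[j]], g0[[j]])), logical(1))))
      stop("profiles are not on a common grid")
  }
  vals <- vapply(profiles, function(p) as.numeric(p$values),
                 numeric(length(as.numeric(profiles[[1]]$values))))
  m <- rowMeans(vals)
  s <- apply(vals, 1, stats::sd)
  out <- new_fes(g0, m - min(m), bias_factor = profiles[[1]]$bias_factor)
  attr(out, "sd") <- if (length(g0) == 1L) s else array(s, dim = dim(out$values))
  out
}

#' Boltzmann projection of a 3-CV free-energy surface onto 2 CVs
#'
#' `F2(a, b) = -kB T log( sum_c exp(-F3(a, b, c) / kB T) dc )`, computed
#' with a log-sum-exp guard (finite whenever any `F3` along the dropped axis
#' is finite) and re-zeroed at the minimum. Projecting a separable surface
#' `F3 = f(a, b) + g(c)` returns exactly `f - min f`.
#'
#' @param fes3 a 3-D `fes`.
#' @param drop_axis axis to integrate out (1, 2 or 3).
#' @param temperature K.
#' @return a 2-D `fes`.
#' @export
project_fes <- function(fes3, drop_axis = 3L, temperature = 300) {
  stopifnot(inherits(fes3, "fes"), length(fes3$grid) == 3L,
            drop_axis %in% 1:3)
  kBT <- KB_KCAL * temperature
  keep <- setdiff(1:3, drop_axis)
  g <- fes3$grid[[drop_axis]]
  dc <- if (length(g) > 1) g[2] - g[1] else 1
  lse <- function(v) {            # log sum exp of -v/kBT
    v <- v[is.finite(v)]
    if (length(v) == 0L) return(-Inf)
    m <- min(v)
    -m / kBT + log(sum(exp(-(v - m) / kBT)))
  }
  f2 <- apply(fes3$values, keep, lse)
  f2 <- -kBT * (f2 + log(dc))
  f2 <- f2 - min(f2[is.finite(f2)])
  new_fes(fes3$grid[keep], f2, bias_factor = fes3$bias_factor)
}

#' Barrier height of a 1-D free-energy profile between two wells
#'
#' The maximum of the profile on the interval between the two given minima,
#' minus the profile minimum (0 by gauge).
#'
#' @param fes a 1-D `fes`.
#' @param minima the two well positions, Angstrom.
#' @return kcal/mol.
#' @export
fes_barrier_1d <- function(fes, minima) {
  stopifnot(inherits(fes, "fes"), length(fes$grid) == 1L)
  g <- fes$grid[[1]]
  inner <- g >= min(minima) & g <= max(minima)
  max(fes$values[inner]) - min(fes$values)
}

#' Write a free-energy surface as dense TSV
#'
#' Header lines record the CV names, grid spacing and the zero convention.
#'
#' @param fes a `fes`.
#' @param path output path.
#' @param cv_names CV labels.
#' @return `path`, invisibly.
#' @export
write_fes_tsv <- function(fes, path, cv_names = NULL) {
  k <- length(fes$grid)
  if (is.null(cv_names)) cv_names <- paste0("CV", seq_len(k))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste("# cvs:", paste(cv_names, collapse = " ")),
               paste("# spacing:", paste(sprintf("%.6g",
                 vapply(fes$grid, function(g)
                   if (length(g) > 1) g[2] - g[1] else NA_real_, numeric(1))),
                 collapse = " ")),
               "# zero: absolute minimum of the surface"), con)
  pts <- as.matrix(expand.grid(fes$grid))
  colnames(pts) <- cv_names
  df <- data.frame(pts, free_energy = as.numeric(fes$values))
  utils::write.table(format(df, digits = 8), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
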