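## Analytic toy potentials for the metadynamics engine. These stand in for
## a real binding free-energy landscape: small, differentiable, with named
## analytic minima and barrier heights so reconstructions can be checked
## exactly.

#' Build an analytic toy potential
#'
#' Forms:
#' \describe{
#'   \item{`double_well_1d`}{`U(s) = barrier * ((s - c)^2 - a^2)^2 / a^4`
#'     with minima at `c - a` and `c + a` (U = 0) and a barrier of height
#'     `barrier` kcal/mol at `c`.}
#'   \item{`separable_3d`}{a sum of three independent per-axis terms
#'     (`double_well` or `harmonic`), so `U(x, y, z) = f(x, y) + g(z)`
#'     holds exactly by construction.}
#' }
#'
#' @param form `"double_well_1d"` or `"separable_3d"`.
#' @param barrier barrier height, kcal/mol (double well).
#' @param minima the two well positions, Angstrom (double well).
#' @param axes for `separable_3d`: list of 3 per-axis specs, each
#'   `list(form = "double_well", barrier =, minima =)` or
#'   `list(form = "harmonic", k =, center =)` (k in kcal/mol/A^2).
#' @param domain length-2 bounds per axis, Angstrom.
#' @return object of class `ToyPotential`: list with `energy(x)`,
#'   `gradient(x)` (both vectorised over rows for matrix input), `dims`,
#'   `domain` and `reference` (analytic minima/barrier bookkeeping).
#' @export
make_toy_potential <- function(form = c("double_well_1d", "separable_3d"),
                               barrier = 3, minima = c(-1, 1),
                               axes = NULL, domain = NULL) {
  form <- match.arg(form)
  dw1 <- function(barrier, minima) {
    cc <- mean(minima); a <- abs(diff(minima)) / 2
    stopifnot(barrier > 0, a > 0)
    list(
      u = function(s) barrier * ((s - cc)^2 - a^2)^2 / a^4,
      g = function(s) 4 * barrier * ((s - cc)^2 - a^2) * (s - cc) / a^4,
      ref = list(minima = sort(minima), barrier_at = cc,
                 barrier = barrier))
  }
  harm <- function(k, center) {
    stopifnot(k > 0)
    list(u = function(s) 0.5 * k * (s - center)^2,
         g = function(s) k * (s - center),
         ref = list(minima = center, barrier = NA_real_))
  }
  if (form == "double_well_1d") {
    t1 <- dw1(barrier, minima)
    if (is.null(domain))
      domain <- range(minima) + c(-1, 1) * 2 * abs(diff(minima))
    pot <- list(
      form = form, dims = 1L, domain = matrix(domain, 1, 2),
      energy = function(x) t1$u(as.numeric(x)),
      gradient = function(x) t1$g(as.numeric(x)),
      reference = t1$ref,
      axis_forms = "double_well", axis_params = list(
        c(barrier = barrier, center = mean(minima),
          halfsep = abs(diff(minima)) / 2)))
  } else {
    if (is.null(axes))
      axes <- list(list(form = "double_well", barrier = 3, minima = c(-1, 1)),
                   list(form = "double_well", barrier = 2, minima = c(-1, 1)),
                   list(form = "harmonic", k = 2, center = 0))
    stopifnot(length(axes) == 3L)
    terms <- lapply(axes, function(ax) {
      switch(ax$form,
             double_well = dw1(ax$barrier, ax$minima),
             harmonic = harm(ax$k, ax$center),
             stop("unknown axis form '", ax$form, "'"))
    })
    if (is.null(domain)) domain <- c(-4, 4)
    dom <- matrix(rep(domain, each = 3), 3, 2)
    pot <- list(
      form = form, dims = 3L, domain = dom,
      energy = function(x) {
        x <- if (is.matrix(x)) x else matrix(x, ncol = 3)
        terms[[1]]$u(x[, 1]) + terms[[2]]$u(x[, 2]) + terms[[3]]$u(x[, 3])
      },
      gradient = function(x) {
        x <- if (is.matrix(x)) x else matrix(x, ncol = 3)
        cbind(terms[[1]]$g(x[, 1]), terms[[2]]$g(x[, 2]), terms[[3]]$g(x[, 3]))
      },
      reference = lapply(terms, `[[`, "ref"),
      axis_forms = vapply(axes, `[[`, character(1), "form"),
      axis_params = lapply(axes, function(ax)
        if (ax$form == "double_well")
          c(barrier = ax$barrier, center = mean(ax$minima),
            halfsep = abs(diff(ax$minima)) / 2)
        else c(k = ax$k, center = ax$center)))
  }
  structure(pot, class = "ToyPotential")
}

#' Finite-difference consistency check of a toy potential's gradient
#'
#' @param potential a `ToyPotential`.
#' @param points matrix of evaluation points (rows), defaults to a small
#'   deterministic grid inside the domain.
#' @param h step size.
#' @return maximum relative error (scalar).
#' @export
check_gradient <- function(potential, points = NULL, h = 1e-6) {
  d <- potential$dims
  if (is.null(points)) {
    ax <- lapply(seq_len(d), function(k)
      seq(potential$domain[k, 1] + 0.1, potential$domain[k, 2] - 0.1,
          length.out = 5))
    points <- as.matrix(expand.grid(ax))
  }
  points <- if (is.matrix(points)) points else matrix(points, ncol = d)
  worst <- 0
  for (i in seq_len(nrow(points))) {
    x <- points[i, , drop = FALSE]
    g <- as.numeric(potential$gradient(x))
    fd <- vapply(seq_len(d), function(k) {
      xp <- x; xm <- x; xp[k] <- xp[k] + h; xm[k] <- xm[k] - h
      (potential$energy(xp) - potential$energy(xm)) / (2 * h)
    }, numeric(1))
    scale <- pmax(abs(g), 1)
    worst <- max(worst, max(abs(g - fd) / scale))
  }
  worst
}
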