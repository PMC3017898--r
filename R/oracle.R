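#' Finite-difference reference solution on a uniform grid
#'
#' Independent second-order reference discretisation of the same PDE
#' systems, used to validate the spectral scheme. Nodes are cell centres
#' of a vertex-centred finite volume: interior cells of width `h`,
#' half-width wall cells. The total tumour flux `dn n_x - gamma n f_x`
#' (and the diffusive `m`/`u` fluxes) is evaluated at cell faces with
#' arithmetic-mean densities and centred gradients, and is set to zero at
#' the walls for flux boundary conditions; for the `basic` variant the
#' right-wall values `n = m = 0` are pinned instead. The semidiscrete
#' system is advanced with the same adaptive stiff integrator contract as
#' the spectral solver (banded Jacobian).
#'
#' This solver shares no discretisation code with the spectral modules.
#'
#' @param variant Model variant.
#' @param params An `invasion_params`.
#' @param M Number of uniform grid points (`M >= 51`), spacing
#'   `h = 1/(M-1)`.
#' @param snapshot_times Ascending non-negative times (0 prepended if
#'   absent).
#' @param settings An [integrator_settings()].
#' @param initial Optional list with vectors `n`, `f`, `m` (and `u`) of
#'   length `M` on the uniform grid, overriding the canonical initial
#'   profile (used for closed-form limit checks).
#' @return An object of class `fd_result`: `times`, `x`, `fields`
#'   (per-field `times` by `M` matrices), `metadata`.
#' @export
fd_reference_solve <- function(variant, params, M,
                               snapshot_times = c(0, 1, 2, 10, 20),
                               settings = integrator_settings(),
                               initial = NULL) {
  variant <- invasion_variant(variant)
  stopifnot(inherits(params, "invasion_params"),
            inherits(settings, "integrator_settings"))
  .check_params_variant(params, variant)
  if (!is.numeric(M) || length(M) != 1L || M < 51 || M != round(M)) {
    stop("`M` must be a single integer >= 51", call. = FALSE)
  }
  M <- as.integer(M)
  times <- sort(unique(as.numeric(snapshot_times)))
  if (any(times < 0)) stop("snapshot times must be non-negative",
                           call. = FALSE)
  if (length(times) == 0L || times[1L] > 0) times <- c(0, times)

  h <- 1 / (M - 1)
  x <- seq(0, 1, length.out = M)
  nf <- if (variant == "inhibitor") 4L else 3L
  dirichlet <- variant == "basic"

  if (is.null(initial)) {
    n0 <- exp(-x^2 / params$epsilon)
    f0 <- 1 - 0.5 * n0
    m0 <- 0.5 * n0
    u0 <- rep(0, M)
  } else {
    stopifnot(all(c("n", "f", "m") %in% names(initial)),
              all(lengths(initial) == M))
    n0 <- initial$n; f0 <- initial$f; m0 <- initial$m
    u0 <- if (is.null(initial$u)) rep(0, M) else initial$u
  }
  if (dirichlet) { n0[M] <- 0; m0[M] <- 0 }
  y0 <- rbind(n0, f0, m0)
  if (nf == 4L) y0 <- rbind(y0, u0)
  # interleave fields per node so the Jacobian is banded
  y0 <- as.vector(y0)

  dn <- params$dn; dm <- params$dm; duu <- params$du; gamma <- params$gamma
  eta <- params$eta; alpha <- params$alpha; beta <- params$beta
  mu1 <- params$mu1; mu2 <- params$mu2
  theta <- params$theta; xi <- params$xi; rho <- params$rho
  wcell <- c(h / 2, rep(h, M - 2L), h / 2)   # finite-volume cell widths

  deriv <- function(t, y, parms) {
    if (any(!is.finite(y)) || max(abs(y)) > .blowup_limit) {
      stop(sprintf("reference solution blow-up at t = %.6g", t),
           call. = FALSE)
    }
    Y <- matrix(y, nrow = nf)
    n <- Y[1L, ]; f <- Y[2L, ]; m <- Y[3L, ]
    if (nf == 4L) u <- Y[4L, ]

    i <- seq_len(M - 1L)                    # faces between nodes i, i+1
    dfdx <- (f[i + 1L] - f[i]) / h
    Fn <- dn * (n[i + 1L] - n[i]) / h -
      gamma * 0.5 * (n[i] + n[i + 1L]) * dfdx
    Fm <- dm * (m[i + 1L] - m[i]) / h
    FnL <- 0; FnR <- 0; FmL <- 0; FmR <- 0   # wall fluxes (zero-flux)
    divn <- (c(Fn, FnR) - c(FnL, Fn)) / wcell
    divm <- (c(Fm, FmR) - c(FmL, Fm)) / wcell

    dndt <- divn + mu1 * n * (1 - n - f)
    dfdt <- -eta * m * f + mu2 * f * (1 - n - f)
    prod <- if (variant == "saturating") alpha * n * (1 - n) else alpha * n
    dmdt <- divm + prod - beta * m
    if (dirichlet) { dndt[M] <- 0; dmdt[M] <- 0 }

    out <- rbind(dndt, dfdt, dmdt)
    if (nf == 4L) {
      Fu <- duu * (u[i + 1L] - u[i]) / h
      divu <- (c(Fu, 0) - c(0, Fu)) / wcell
      dmdt2 <- dmdt - theta * u * m
      dudt <- divu + xi * f - theta * u * m - rho * u
      out <- rbind(dndt, dfdt, dmdt2, dudt)
    }
    list(as.vector(out))
  }

  extra <- list(y = y0, times = times, func = deriv, parms = NULL,
                method = settings$method,
                rtol = settings$rel_tol, atol = settings$abs_tol,
                jactype = "bandint", bandup = 2L * nf, banddown = 2L * nf)
  if (!is.null(settings$max_step)) extra$hmax <- settings$max_step
  out <- do.call(deSolve::ode, extra)
  if (any(!is.finite(out[, -1]))) {
    stop("reference integration produced non-finite values", call. = FALSE)
  }

  sel <- function(k) out[, 1L + seq(k, by = nf, length.out = M),
                         drop = FALSE]
  fields <- list(n = unname(sel(1L)), f = unname(sel(2L)),
                 m = unname(sel(3L)))
  if (nf == 4L) fields$u <- unname(sel(4L))
  structure(
    list(times = times, x = x, M = M, fields = fields,
         metadata = list(variant = variant, params = params, M = M,
                         settings = settings)),
    class = "fd_result"
  )
}

#' @export
print.fd_result <- function(x, ...) {
  cat("finite-difference reference solution (", x$metadata$variant,
      " variant ), M =", x$M, "uniform points\n")
  invisible(x)
}

#' Barycentric interpolation from a CGL grid
#'
#' Evaluates the degree-`N + 1` polynomial interpolant of nodal values at
#' arbitrary query points in `[0, 1]`, using the closed-form barycentric
#' weights of the Chebyshev-Gauss-Lobatto family (alternating signs,
#' halved at the endpoints); numerically stable for any `N` used here.
#'
#' @param grid A `cgl_grid`.
#' @param values Nodal values (length `N + 2`).
#' @param query Positions in `[0, 1]`.
#' @return Interpolated values at `query`.
#' @export
barycentric_interpolate <- function(grid, values, query) {
  stopifnot(inherits(grid, "cgl_grid"))
  P <- grid$N + 2L
  if (length(values) != P) stop("`values` must have length N + 2",
                                call. = FALSE)
  query <- as.numeric(query)
  if (any(query < -1e-12 | query > 1 + 1e-12)) {
    stop("query positions must lie within [0, 1]", call. = FALSE)
  }
  bw <- (-1)^(0:(P - 1L))
  bw[1L] <- bw[1L] / 2
  bw[P] <- bw[P] / 2
  vapply(query, function(q) {
    d <- q - grid$nodes
    hit <- which(abs(d) < 1e-14)
    if (length(hit) > 0L) return(values[hit[1L]])
    r <- bw / d
    sum(r * values) / sum(r)
  }, numeric(1))
}

#' Total mass by Clenshaw-Curtis quadrature
#'
#' Integral of the nodal field over `[0, 1]` using quadrature weights
#' matched to the CGL nodes; exact for polynomials of degree `N + 1`.
#'
#' @param grid A `cgl_grid`.
#' @param values Full-length nodal vector.
#' @return Scalar integral.
#' @export
total_mass <- function(grid, values) {
  stopifnot(inherits(grid, "cgl_grid"))
  if (length(values) != grid$N + 2L) {
    stop("`values` must have length N + 2", call. = FALSE)
  }
  sum(clenshaw_curtis_weights(grid) * values)
}

#' Count tumour-cell clusters in a density profile
#'
#' Operationalises the visual notion of "distinct clusters" (a
#' leading-edge peak separated from the main tumour body by a pronounced
#' dip): local maxima, boundary points compared one-sidedly, are peaks if
#' they reach at least `height_frac` of the global maximum; two retained
#' peaks count as distinct clusters only if the minimum between them
#' falls below `(1 - dip_frac)` times the lower of the two peak heights,
#' otherwise they are merged (the taller survives).
#'
#' @param profile Finite numeric vector on a uniform evaluation grid.
#' @param height_frac Minimum relative peak height, in (0, 1).
#' @param dip_frac Required relative dip between distinct peaks, in
#'   (0, 1).
#' @return Integer cluster count (0 for a non-positive profile).
#' @export
count_clusters <- function(profile, height_frac = 0.1, dip_frac = 0.1) {
  profile <- as.numeric(profile)
  if (length(profile) == 0L) stop("empty profile", call. = FALSE)
  if (any(!is.finite(profile))) stop("profile must be finite",
                                     call. = FALSE)
  if (height_frac <= 0 || height_frac >= 1 || dip_frac <= 0 ||
        dip_frac >= 1) {
    stop("`height_frac` and `dip_frac` must lie in (0, 1)", call. = FALSE)
  }
  gmax <- max(profile)
  if (gmax <= 0) return(0L)
  L <- length(profile)
  is_peak <- vapply(seq_len(L), function(i) {
    left  <- if (i > 1L) profile[i] > profile[i - 1L] else TRUE
    right <- if (i < L) profile[i] >= profile[i + 1L] else TRUE
    left && right
  }, logical(1))
  peaks <- which(is_peak & profile >= height_frac * gmax)
  if (length(peaks) == 0L) return(0L)
  kept <- peaks[1L]
  for (p in peaks[-1L]) {
    last <- kept[length(kept)]
    valley <- min(profile[last:p])
    if (valley < (1 - dip_frac) * min(profile[last], profile[p])) {
      kept <- c(kept, p)
    } else if (profile[p] > profile[last]) {
      kept[length(kept)] <- p
    }
  }
  length(kept)
}

#' Evaluate a spectral snapshot on a uniform grid
#'
#' Convenience wrapper: barycentric interpolation of one field of an
#' `invasion_result` onto `n_points` equally spaced positions, e.g. for
#' cluster counting or plotting.
#'
#' @param result An `invasion_result`.
#' @param field,time Field name and snapshot time.
#' @param n_points Number of uniform evaluation points, default 1001.
#' @return Numeric vector of length `n_points`.
#' @export
profile_on_uniform_grid <- function(result, field, time, n_points = 1001L) {
  vals <- snapshot(result, field, time)
  grid <- cgl_grid(result$metadata$N)
  barycentric_interpolate(grid, vals, seq(0, 1, length.out = n_points))
}

#' Max-abs discrepancy between spectral and reference solutions
#'
#' Interpolates the spectral snapshot to the reference solver's uniform
#' grid and returns the maximum absolute difference.
#'
#' @param spectral An `invasion_result`.
#' @param reference An `fd_result`.
#' @param field,time Field name and snapshot time (must be present in
#'   both results).
#' @return Scalar maximum absolute discrepancy.
#' @export
compare_solutions <- function(spectral, reference, field, time) {
  stopifnot(inherits(spectral, "invasion_result"),
            inherits(reference, "fd_result"))
  sv <- snapshot(spectral, field, time)
  i <- which(abs(reference$times - time) <= 1e-9 * max(1, abs(time)))
  if (length(i) != 1L || !field %in% names(reference$fields)) {
    stop("field/time not present in the reference result", call. = FALSE)
  }
  rv <- reference$fields[[field]][i, ]
  grid <- cgl_grid(spectral$metadata$N)
  si <- barycentric_interpolate(grid, sv, reference$x)
  max(abs(si - rv))
}
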