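# canonical variant names; aliases accepted on input
.variants <- c("basic", "proliferation", "saturating", "inhibitor")

#' Normalise a model-variant name
#'
#' The four model variants are: `"basic"` (no proliferation, Dirichlet
#' right boundary), `"proliferation"` (logistic tumour growth and ECM
#' renewal, zero-flux at both walls), `"saturating"` (as proliferation but
#' MDE production saturating in the cell density), and `"inhibitor"`
#' (four-field model with endogenous inhibitors).
#'
#' @param variant Character; one of the canonical names above or the
#'   aliases `"basic_dirichlet"`, `"saturating_mde"`.
#' @return The canonical variant string.
#' @export
invasion_variant <- function(variant) {
  v <- tolower(as.character(variant)[1])
  v <- switch(v,
    basic_dirichlet = "basic",
    saturating_mde  = "saturating",
    v
  )
  if (!v %in% .variants) {
    stop("unknown model variant: ", variant,
         " (expected one of ", paste(.variants, collapse = ", "), ")",
         call. = FALSE)
  }
  v
}

#' Model parameters for the invasion systems
#'
#' All coefficients of the dimensionless invasion models on the scaled
#' tissue domain `[0, 1]`:
#' \describe{
#'   \item{dn}{tumour-cell random motility coefficient (must be > 0).}
#'   \item{dm}{MDE diffusion coefficient (must be > 0).}
#'   \item{du}{inhibitor diffusion coefficient (> 0 for the inhibitor
#'     variant).}
#'   \item{gamma}{haptotaxis coefficient.}
#'   \item{eta}{ECM degradation rate by MDEs.}
#'   \item{alpha}{MDE production rate by tumour cells.}
#'   \item{beta}{MDE decay rate.}
#'   \item{mu1}{tumour proliferation rate (logistic in `n + f`).}
#'   \item{mu2}{ECM renewal rate.}
#'   \item{theta}{MDE-inhibitor neutralisation rate.}
#'   \item{xi}{inhibitor production rate by the ECM.}
#'   \item{rho}{inhibitor decay rate.}
#'   \item{epsilon}{width of the initial tumour profile
#'     `n(x, 0) = exp(-x^2 / epsilon)`.}
#' }
#' Defaults are the shared base values used throughout the simulation
#' study (`dn = dm = 0.001`, `alpha = 0.1`, `epsilon = 0.01`, all other
#' rates 0).
#'
#' @param dn,dm,du,gamma,eta,alpha,beta,mu1,mu2,theta,xi,rho,epsilon
#'   Non-negative scalars, see above.
#' @return An object of class `invasion_params`.
#' @export
invasion_params <- function(dn = 0.001, dm = 0.001, du = 0,
                            gamma = 0, eta = 0, alpha = 0.1, beta = 0,
                            mu1 = 0, mu2 = 0,
                            theta = 0, xi = 0, rho = 0,
                            epsilon = 0.01) {
  p <- list(dn = dn, dm = dm, du = du, gamma = gamma, eta = eta,
            alpha = alpha, beta = beta, mu1 = mu1, mu2 = mu2,
            theta = theta, xi = xi, rho = rho, epsilon = epsilon)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop("parameter `", nm, "` must be a single non-negative number",
           call. = FALSE)
    }
  }
  if (p$dn <= 0) stop("`dn` must be positive", call. = FALSE)
  if (p$dm <= 0) stop("`dm` must be positive", call. = FALSE)
  if (p$epsilon <= 0) stop("`epsilon` must be positive", call. = FALSE)
  structure(p, class = "invasion_params")
}

#' @export
print.invasion_params <- function(x, ...) {
  cat("invasion model parameters:\n")
  print(unlist(unclass(x)))
  invisible(x)
}

.check_params_variant <- function(params, variant) {
  if (variant == "inhibitor" && params$du <= 0) {
    stop("`du` must be positive for the inhibitor variant", call. = FALSE)
  }
  invisible(TRUE)
}

#' Initial state of the invasion system
#'
#' Closed-form initial conditions: a tumour centred at the left wall,
#' `n(x, 0) = exp(-x^2 / epsilon)`; ECM already partially degraded,
#' `f(x, 0) = 1 - 0.5 n(x, 0)`; MDE proportional to the tumour with
#' constant 1/2, `m(x, 0) = 0.5 n(x, 0)`; and (inhibitor variant) no
#' inhibitor, `u(x, 0) = 0`.
#'
#' For the `basic` variant the Dirichlet values `n = m = 0` at the right
#' wall remove that node from the unknowns; `n`, `f`, `m` then span nodes
#' `0..N` and the (time-constant) ECM value at the right wall is stored
#' as `f_right`. For the zero-flux variants all fields span all `N + 2`
#' nodes.
#'
#' @param grid A `cgl_grid`.
#' @param params An `invasion_params`.
#' @param variant Model variant, see [invasion_variant()].
#' @return An object of class `invasion_state` with fields `n`, `f`, `m`,
#'   optionally `u`, plus `variant`, `N`, and `f_right` for `basic`.
#' @export
initial_state <- function(grid, params, variant) {
  stopifnot(inherits(grid, "cgl_grid"), inherits(params, "invasion_params"))
  variant <- invasion_variant(variant)
  .check_params_variant(params, variant)
  x <- grid$nodes
  n0 <- exp(-x^2 / params$epsilon)
  f0 <- 1 - 0.5 * n0
  m0 <- 0.5 * n0
  P <- length(x)
  if (variant == "basic") {
    st <- list(n = n0[-P], f = f0[-P], m = m0[-P],
               f_right = f0[P], variant = variant, N = grid$N)
  } else {
    st <- list(n = n0, f = f0, m = m0, variant = variant, N = grid$N)
    if (variant == "inhibitor") st$u <- rep(0, P)
  }
  structure(st, class = "invasion_state")
}

#' MDE production term
#'
#' Linear production `alpha * n` for the basic, proliferation, and
#' inhibitor variants; saturating production `alpha * n * (1 - n)`
#' (polarised expression at the invading edge, vanishing where cells are
#' at carrying capacity) for the saturating variant.
#'
#' @param n Nodal tumour-cell densities.
#' @param variant Model variant.
#' @param alpha Production rate.
#' @return Nodal production vector.
#' @export
mde_production <- function(n, variant, alpha) {
  variant <- invasion_variant(variant)
  if (variant == "saturating") alpha * n * (1 - n) else alpha * n
}

#' Discrete haptotaxis divergence
#'
#' The unmodified spectral discretisation of the haptotactic term
#' `d/dx (n df/dx)`: differentiate `f` with the full matrix, multiply by
#' `n` component-wise, differentiate again. Used by the zero-flux scheme,
#' where `f` obeys no flux condition of its own.
#'
#' @param n,f Full-length nodal vectors.
#' @param ops A `boundary_ops` (carries the full differentiation matrix).
#' @return Nodal vector of the same length.
#' @export
haptotaxis_divergence <- function(n, f, ops) {
  stopifnot(inherits(ops, "boundary_ops"))
  D <- ops$D
  if (length(n) != length(f) || length(n) != nrow(D)) {
    stop("`n`, `f`, and `D` dimensions must agree", call. = FALSE)
  }
  fx <- D %*% f
  as.vector(D %*% (n * as.vector(fx)))
}

#' Semidiscrete right-hand side, basic model with Dirichlet right wall
#'
#' Assembles the method-of-lines right-hand side of the three-field
#' invasion model with a zero-flux wall at `x = 0` and `n = m = 0` pinned
#' at `x = 1`. The left-wall flux condition
#' `dn n_x = gamma n f_x` is embedded by replacing the first component of
#' the spectral derivative of `n` with the boundary value it implies; the
#' known right-boundary values enter through the last column of the
#' differentiation matrix.
#'
#' Since `m(1, t) = 0`, the ECM at the right wall never degrades and its
#' value stays at `f_right = f(1, 0)`; it enters the assembly as a known
#' constant.
#'
#' @param state An `invasion_state` with `variant == "basic"`.
#' @param grid A `cgl_grid`.
#' @param ops Matching `boundary_ops`.
#' @param params An `invasion_params`.
#' @return A list with components `n`, `f`, `m`: the time derivatives.
#' @export
rhs_basic <- function(state, grid, ops, params) {
  if (!identical(state$variant, "basic")) {
    stop("`rhs_basic` requires the basic (Dirichlet) variant", call. = FALSE)
  }
  n <- state$n; f <- state$f; m <- state$m
  P <- grid$N + 2L
  if (length(n) != P - 1L || length(f) != P - 1L || length(m) != P - 1L) {
    stop("state layout does not match the grid", call. = FALSE)
  }
  dn <- params$dn; gamma <- params$gamma
  f_full <- c(f, state$f_right)
  n_full <- c(n, 0)
  m_full <- c(m, 0)
  s0f  <- boundary_sum(ops$row0,    f_full)
  sN1n <- boundary_sum(ops$rowLast, n_full)
  sN1f <- boundary_sum(ops$rowLast, f_full)
  sN1m <- boundary_sum(ops$rowLast, m_full)

  # n_x with left-flux substitution; f_x and f_xx with known right value
  nx  <- as.vector(ops$D0 %*% n) + (gamma / dn) * n[1L] * s0f * ops$e1
  fx  <- as.vector(ops$D1 %*% f) + state$f_right * ops$w
  fxx <- as.vector(ops$D1 %*% fx) + sN1f * ops$w

  dndt <- dn * (as.vector(ops$D1 %*% nx) + sN1n * ops$w) -
    gamma * (nx * fx + n * fxx)
  dfdt <- -params$eta * (m * f)
  dmdt <- params$dm * (as.vector(ops$D1 %*% as.vector(ops$D0 %*% m)) +
                         sN1m * ops$w) +
    params$alpha * n - params$beta * m
  list(n = dndt, f = dfdt, m = dmdt)
}

#' Semidiscrete right-hand side, zero-flux variants
#'
#' Assembles the right-hand sides of the proliferation, saturating-MDE,
#' and inhibitor models with flux conditions at both walls. The boundary
#' rows of the derivative of `n` are replaced by the values the flux
#' conditions imply (`n_x = (gamma/dn) n f_x` at each wall), giving a
#' discrete total flux `dn n_x - gamma n f_x` that vanishes identically
#' at the walls; `m` (and `u`) get homogeneous Neumann rows.
#'
#' @param state An `invasion_state` for a zero-flux variant.
#' @param grid A `cgl_grid`.
#' @param ops Matching `boundary_ops`.
#' @param params An `invasion_params`.
#' @return List of time derivatives `n`, `f`, `m` (and `u`).
#' @export
rhs_zero_flux <- function(state, grid, ops, params) {
  variant <- invasion_variant(state$variant)
  if (variant == "basic") {
    stop("`rhs_zero_flux` requires a zero-flux variant", call. = FALSE)
  }
  n <- state$n; f <- state$f; m <- state$m
  P <- grid$N + 2L
  if (length(n) != P || length(f) != P || length(m) != P) {
    stop("state layout does not match the grid", call. = FALSE)
  }
  dn <- params$dn; gamma <- params$gamma
  D <- grid$D

  fx <- as.vector(D %*% f)
  wvec <- numeric(P)
  wvec[1L] <- fx[1L] * n[1L]      # s0f * n(x0)
  wvec[P]  <- fx[P] * n[P]        # sN1f * n(xN+1)
  nx_flux <- as.vector(ops$D00 %*% n) + (gamma / dn) * wvec

  flux <- dn * nx_flux - gamma * (n * fx)
  dndt <- as.vector(D %*% flux) +
    params$mu1 * n * (1 - n - f)
  dfdt <- -params$eta * (m * f) + params$mu2 * f * (1 - n - f)
  # m_xx: zero the boundary derivative rows (m_x = 0 at both walls), then
  # differentiate again -- same composition as for n
  dmdt <- params$dm * as.vector(D %*% (ops$D00 %*% m)) +
    mde_production(n, variant, params$alpha) - params$beta * m

  out <- list(n = dndt, f = dfdt, m = dmdt)
  if (variant == "inhibitor") {
    u <- state$u
    if (length(u) != P) stop("state layout does not match the grid",
                             call. = FALSE)
    out$m <- out$m - params$theta * u * m
    out$u <- params$du * as.vector(D %*% (ops$D00 %*% u)) +
      params$xi * f - params$theta * u * m - params$rho * u
  }
  out
}
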