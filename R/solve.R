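#' Integrator settings
#'
#' Settings for the adaptive, stiffness-capable implicit time stepping of
#' the semidiscrete systems. The ECM kinetics (`-eta * m * f` with `eta`
#' up to 20) make the systems moderately stiff, so the default method is
#' `lsoda`, which switches automatically between Adams and BDF.
#'
#' @param rel_tol Relative tolerance (> 0), default `1e-8`.
#' @param abs_tol Absolute tolerance (> 0), default `1e-10`.
#' @param max_step Optional cap on the internal step size (`NULL` = none).
#' @param method deSolve integration method; must be stiffness-capable
#'   (`"lsoda"`, `"bdf"`, `"vode"`, `"lsode"`, `"radau"`).
#' @return An object of class `integrator_settings`.
#' @export
integrator_settings <- function(rel_tol = 1e-8, abs_tol = 1e-10,
                                max_step = NULL, method = "lsoda") {
  if (!is.numeric(rel_tol) || rel_tol <= 0) stop("`rel_tol` must be > 0",
                                                 call. = FALSE)
  if (!is.numeric(abs_tol) || abs_tol <= 0) stop("`abs_tol` must be > 0",
                                                 call. = FALSE)
  method <- match.arg(method, c("lsoda", "bdf", "vode", "lsode", "radau"))
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol,
                 max_step = max_step, method = method),
            class = "integrator_settings")
}

# magnitude beyond which integration is aborted as a blow-up
.blowup_limit <- 1e6

.pack_state <- function(state) {
  if (state$variant == "inhibitor") c(state$n, state$f, state$m, state$u)
  else c(state$n, state$f, state$m)
}

.unpack_state <- function(y, template) {
  len <- length(template$n)
  nf <- if (template$variant == "inhibitor") 4L else 3L
  st <- template
  st$n <- y[seq_len(len)]
  st$f <- y[len + seq_len(len)]
  st$m <- y[2L * len + seq_len(len)]
  if (nf == 4L) st$u <- y[3L * len + seq_len(len)]
  st
}

#' Integrate an invasion model in time
#'
#' Advances the semidiscrete system from `t = 0` and returns snapshots at
#' the requested times. Arbitrary initial states (not only the canonical
#' tumour profile) are accepted, which permits closed-form limit checks.
#'
#' @param variant Model variant, see [invasion_variant()].
#' @param params An `invasion_params`.
#' @param grid A `cgl_grid`.
#' @param initial An `invasion_state`, or `NULL` for [initial_state()].
#' @param snapshot_times Ascending non-negative times; `0` is prepended
#'   if absent.
#' @param settings An [integrator_settings()].
#' @return An object of class `invasion_result`: `times`, `x` (the full
#'   node vector), per-field snapshot matrices (`times` by nodes) in
#'   `fields`, and `metadata`. For the `basic` variant the pinned
#'   boundary values (`n = m = 0`, constant `f`) are included, so every
#'   snapshot covers all `N + 2` grid points.
#' @export
solve_invasion <- function(variant, params, grid, initial = NULL,
                           snapshot_times = c(0, 1, 2, 10, 20),
                           settings = integrator_settings()) {
  variant <- invasion_variant(variant)
  stopifnot(inherits(params, "invasion_params"), inherits(grid, "cgl_grid"),
            inherits(settings, "integrator_settings"))
  .check_params_variant(params, variant)
  times <- sort(unique(as.numeric(snapshot_times)))
  if (any(times < 0)) stop("snapshot times must be non-negative",
                           call. = FALSE)
  if (length(times) == 0L || times[1L] > 0) times <- c(0, times)

  if (is.null(initial)) initial <- initial_state(grid, params, variant)
  if (!identical(invasion_variant(initial$variant), variant)) {
    stop("initial state variant does not match `variant`", call. = FALSE)
  }
  ops <- boundary_operators(grid)
  y0 <- .pack_state(initial)

  if (length(times) == 1L) {
    # only t = 0 requested: the snapshot is the initial state itself
    out <- matrix(c(0, y0), nrow = 1L)
    attr(out, "istate") <- c(2L, 0L, 0L)
  } else {
    deriv <- function(t, y, parms) {
      if (any(!is.finite(y)) || max(abs(y)) > .blowup_limit) {
        stop(sprintf("solution blow-up detected at t = %.6g", t),
             call. = FALSE)
      }
      st <- .unpack_state(y, initial)
      d <- if (variant == "basic") rhs_basic(st, grid, ops, params)
           else rhs_zero_flux(st, grid, ops, params)
      list(unlist(d, use.names = FALSE))
    }

    extra <- list(y = y0, times = times, func = deriv, parms = NULL,
                  method = settings$method,
                  rtol = settings$rel_tol, atol = settings$abs_tol)
    if (!is.null(settings$max_step)) extra$hmax <- settings$max_step
    out <- do.call(deSolve::ode, extra)
    if (any(!is.finite(out[, -1]))) {
      stop("integration produced non-finite values", call. = FALSE)
    }
  }

  len <- length(initial$n)
  P <- grid$N + 2L
  nt <- length(times)
  take <- function(block) out[, 1L + (block - 1L) * len + seq_len(len),
                              drop = FALSE]
  n <- take(1L); f <- take(2L); m <- take(3L)
  if (variant == "basic") {
    # append the known right-wall values so snapshots span the full grid
    n <- cbind(n, rep(0, nt))
    f <- cbind(f, rep(initial$f_right, nt))
    m <- cbind(m, rep(0, nt))
  }
  fields <- list(n = unname(n), f = unname(f), m = unname(m))
  if (variant == "inhibitor") fields$u <- unname(take(4L))

  structure(
    list(
      times = times, x = grid$nodes, fields = fields,
      metadata = list(variant = variant, params = params, N = grid$N,
                      settings = settings,
                      istate = attr(out, "istate"),
                      n_steps = unname(attr(out, "istate")[3L]))
    ),
    class = "invasion_result"
  )
}

#' @export
print.invasion_result <- function(x, ...) {
  cat("invasion model simulation (", x$metadata$variant, " variant )\n",
      sep = "")
  cat("  N =", x$metadata$N, "(", length(x$x), "grid points ),",
      length(x$times), "snapshots at t =",
      paste(signif(x$times, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Extract one snapshot field
#'
#' @param result An `invasion_result`.
#' @param field One of `"n"`, `"f"`, `"m"`, `"u"`.
#' @param time A snapshot time present in `result$times`.
#' @return Numeric vector of nodal values.
#' @export
snapshot <- function(result, field, time) {
  stopifnot(inherits(result, "invasion_result"))
  if (!field %in% names(result$fields)) {
    stop("field `", field, "` not present in this result", call. = FALSE)
  }
  i <- which(abs(result$times - time) <= 1e-9 * max(1, abs(time)))
  if (length(i) != 1L) stop("time ", time, " is not a snapshot time",
                            call. = FALSE)
  result$fields[[field]][i, ]
}
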