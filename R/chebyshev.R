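#' Chebyshev-Gauss-Lobatto collocation points on [0, 1]
#'
#' Returns the `N + 2` cosine-spaced collocation nodes
#' \eqn{x_i = 1/2 - (1/2)\cos(i\pi/(N+1))}, \eqn{i = 0, \dots, N+1},
#' in ascending order. The nodes cluster near both domain ends, which is
#' what gives polynomial interpolation on them spectral accuracy for
#' smooth functions.
#'
#' @param N Integer spectral order, `N >= 1`. The grid has `N + 2` points.
#' @return Numeric vector of `N + 2` node positions, `0` and `1` included.
#' @examples
#' cgl_points(5)
#' length(cgl_points(30))  # 32 grid points
#' @export
cgl_points <- function(N) {
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 1 || N != round(N)) {
    stop("`N` must be a single integer >= 1", call. = FALSE)
  }
  i <- 0:(N + 1)
  0.5 - 0.5 * cos(i * pi / (N + 1))
}

#' First-order spectral differentiation matrix
#'
#' Builds the dense matrix `D` that maps nodal values of a function to the
#' nodal values of the derivative of its polynomial interpolant. For
#' `P` pairwise-distinct nodes the matrix is exact on polynomials of
#' degree `P - 1`.
#'
#' Off-diagonal entries use the barycentric formula
#' \eqn{d_{ij} = (w_j / w_i) / (x_i - x_j)}; each diagonal entry is the
#' negated sum of its row's off-diagonal entries ("negative-sum trick"),
#' so constants differentiate to exactly zero and every row sums to zero
#' in floating point.
#'
#' @param nodes Numeric vector of pairwise-distinct node positions.
#' @return A `length(nodes) x length(nodes)` numeric matrix.
#' @examples
#' x <- cgl_points(8)
#' D <- differentiation_matrix(x)
#' max(abs(D %*% x^2 - 2 * x))  # ~ machine precision
#' @export
differentiation_matrix <- function(nodes) {
  x <- as.numeric(nodes)
  P <- length(x)
  if (P < 2L) stop("need at least two nodes", call. = FALSE)
  if (anyDuplicated(x)) stop("nodes must be pairwise distinct", call. = FALSE)

  # barycentric weights, rescaled each step to avoid under/overflow
  w <- rep(1, P)
  for (j in seq_len(P)) {
    w[j] <- 1 / prod(x[j] - x[-j])
  }
  w <- w / max(abs(w))

  diffx <- outer(x, x, "-")
  diag(diffx) <- 1
  D <- outer(1 / w, w, "*") / diffx
  diag(D) <- 0
  diag(D) <- -rowSums(D)
  D
}

#' Collocation grid constructor
#'
#' Bundles the spectral order, the Chebyshev-Gauss-Lobatto nodes on
#' `[0, 1]`, and the full first-order differentiation matrix on those
#' nodes.
#'
#' @param N Integer spectral order, `N >= 4` recommended for the invasion
#'   models (`N >= 1` accepted).
#' @return An object of class `cgl_grid` with fields `N`, `nodes`
#'   (length `N + 2`), and `D` (`(N+2) x (N+2)`).
#' @examples
#' g <- cgl_grid(30)
#' g$N; length(g$nodes)
#' @export
cgl_grid <- function(N) {
  nodes <- cgl_points(N)
  structure(
    list(N = as.integer(N), nodes = nodes, D = differentiation_matrix(nodes)),
    class = "cgl_grid"
  )
}

#' @export
print.cgl_grid <- function(x, ...) {
  cat("Chebyshev-Gauss-Lobatto collocation grid on [0, 1]\n")
  cat("  spectral order N =", x$N, " (", x$N + 2, "grid points )\n")
  invisible(x)
}

#' Boundary-modified differentiation operators
#'
#' Derives from the full differentiation matrix the sub-blocks and vectors
#' used to embed flux boundary conditions into the semidiscrete invasion
#' systems:
#' \describe{
#'   \item{D1}{rows and columns `0..N` of `D` (indices 1..N+1 in R).}
#'   \item{D0}{`D1` with its first row zeroed (the derivative at the left
#'     wall is supplied by the boundary condition instead).}
#'   \item{D00}{the full `(N+2) x (N+2)` matrix with first and last rows
#'     zeroed, used when flux conditions hold at both walls.}
#'   \item{w}{last column of `D`, rows `0..N` (couples the interior to the
#'     known right-boundary value).}
#'   \item{e1}{unit vector with 1 in the first position, length `N + 1`.}
#'   \item{row0, rowLast}{the first and last rows of `D`, used to form the
#'     boundary derivative sums.}
#' }
#'
#' @param grid A `cgl_grid`.
#' @return An object of class `boundary_ops`.
#' @export
boundary_operators <- function(grid) {
  stopifnot(inherits(grid, "cgl_grid"))
  D <- grid$D
  P <- nrow(D)                      # N + 2
  idx <- seq_len(P - 1L)            # nodes 0..N
  D1 <- D[idx, idx, drop = FALSE]
  D0 <- D1
  D0[1L, ] <- 0
  D00 <- D
  D00[1L, ] <- 0
  D00[P, ] <- 0
  e1 <- c(1, rep(0, P - 2L))
  structure(
    list(
      N = grid$N, D = D, D1 = D1, D0 = D0, D00 = D00,
      w = D[idx, P], e1 = e1,
      row0 = D[1L, ], rowLast = D[P, ]
    ),
    class = "boundary_ops"
  )
}

#' Boundary derivative sum
#'
#' Dot product of a boundary row of the differentiation matrix with a
#' full-length nodal vector: the spectral approximation of the field's
#' derivative at that wall.
#'
#' @param row A boundary row of `D` (length `N + 2`).
#' @param values Full-length nodal vector (length `N + 2`).
#' @return Scalar derivative estimate.
#' @export
boundary_sum <- function(row, values) {
  if (length(row) != length(values)) {
    stop("`row` and `values` must have equal length", call. = FALSE)
  }
  sum(row * values)
}

#' Clenshaw-Curtis quadrature weights for a CGL grid
#'
#' Weights `q` such that `sum(q * v)` approximates the integral of the
#' interpolating polynomial of the nodal values `v` over `[0, 1]`; exact
#' for polynomials of degree up to `N + 1`.
#'
#' The weights solve the moment system in the Chebyshev polynomial basis
#' (a well-conditioned cosine-structured system), with exact Chebyshev
#' moments \eqn{\int_{-1}^{1} T_j = 2/(1-j^2)} for even `j`, 0 for odd.
#'
#' @param grid A `cgl_grid`.
#' @return Numeric weight vector of length `N + 2`, summing to 1.
#' @export
clenshaw_curtis_weights <- function(grid) {
  stopifnot(inherits(grid, "cgl_grid"))
  P <- grid$N + 2L
  xi <- 2 * grid$nodes - 1          # map to [-1, 1]
  # Vandermonde in Chebyshev basis: V[j+1, i] = T_j(xi_i)
  V <- matrix(0, P, P)
  V[1L, ] <- 1
  V[2L, ] <- xi
  if (P > 2L) {
    for (j in 3:P) V[j, ] <- 2 * xi * V[j - 1L, ] - V[j - 2L, ]
  }
  j <- 0:(P - 1L)
  mom <- ifelse(j %% 2L == 0L, 2 / (1 - j^2), 0)
  q <- solve(V, mom)
  q / 2                              # [-1,1] -> [0,1] scaling
}
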