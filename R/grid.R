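# Uniform 2-D grid, discrete operators and the elliptic/parabolic solvers
# shared by every field equation (oxygen, TAF, pressure, drug).

.nv_cache <- new.env(parent = emptyenv())

#' Uniform square grid specification
#'
#' All continuum fields live on a uniform n x n grid of square cells covering
#' a square domain. Lengths are in millimetres; `length_scale` records the
#' nondimensionalization length used when reporting nondimensional quantities.
#'
#' @param n_cells Number of cells per axis (>= 8).
#' @param domain_mm Physical side length of the domain in mm (default 2).
#' @param length_scale_mm Reference length for nondimensional reporting (mm).
#' @return An object of class `grid_spec` with fields `n`, `L`, `h`
#'   (cell width, mm) and `length_scale`.
#' @examples
#' g <- grid_spec(64)
#' g$h  # 2/64 mm
#' @export
grid_spec <- function(n_cells, domain_mm = 2, length_scale_mm = 0.1) {
  n_cells <- as.integer(n_cells)
  if (n_cells < 8L) stop("n_cells must be >= 8")
  if (domain_mm <= 0) stop("domain_mm must be > 0")
  structure(list(n = n_cells, L = domain_mm, h = domain_mm / n_cells,
                 length_scale = length_scale_mm),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells over %.3g x %.3g mm (h = %.4g mm)\n",
              x$n, x$n, x$L, x$L, x$h))
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return Numeric vector of length `n` with the coordinate of each cell
#'   centre along one axis (both axes are identical).
#' @export
cell_centers <- function(grid) (seq_len(grid$n) - 0.5) * grid$h

#' Scalar field on a grid
#'
#' Thin wrapper pairing an n x n matrix of values with its grid and a
#' boundary-condition tag. All discrete operators honour zero-Neumann
#' boundaries (ghost cells mirror the interior); this is the only boundary
#' condition used by the model.
#'
#' @param grid A [grid_spec()].
#' @param values Matrix of values (n x n) or a single number to fill.
#' @param bc Boundary condition tag; only `"neumann0"` is supported.
#' @return Object of class `scalar_field` (list: `grid`, `values`, `bc`).
#' @export
scalar_field <- function(grid, values = 0, bc = "neumann0") {
  stopifnot(inherits(grid, "grid_spec"))
  if (!identical(bc, "neumann0")) stop("only bc = 'neumann0' is supported")
  if (length(values) == 1L) values <- matrix(values, grid$n, grid$n)
  if (!is.matrix(values) || any(dim(values) != grid$n))
    stop("values must be a ", grid$n, " x ", grid$n, " matrix")
  if (any(!is.finite(values))) stop("field values must be finite")
  structure(list(grid = grid, values = values, bc = bc), class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("<scalar_field> %d x %d, range [%.4g, %.4g]\n",
              x$grid$n, x$grid$n, min(x$values), max(x$values)))
  invisible(x)
}

# Accept either a scalar_field or a bare matrix/scalar; return a matrix.
field_values <- function(x, grid) {
  if (inherits(x, "scalar_field")) return(x$values)
  if (length(x) == 1L) return(matrix(x, grid$n, grid$n))
  if (is.matrix(x) && all(dim(x) == grid$n)) return(x)
  stop("expected a scalar_field, a matrix or a single number")
}

#' Sparse 5-point Laplacian with zero-Neumann boundaries
#'
#' Returns the N^2 x N^2 sparse matrix of the standard 5-point Laplacian
#' (1/h^2 scaling included) under mirrored (zero-flux) boundaries, in the
#' column-major vectorization order of R matrices. Row sums are exactly zero,
#' which is the discrete divergence theorem for this operator.
#'
#' @param grid A [grid_spec()].
#' @return A `dgCMatrix`.
#' @export
grid_laplacian <- function(grid) {
  key <- sprintf("lap_%d_%.12g", grid$n, grid$h)
  if (!is.null(.nv_cache[[key]])) return(.nv_cache[[key]])
  n <- grid$n
  id <- matrix(seq_len(n * n), n, n)
  ii <- jj <- xx <- list()
  add <- function(from, to) {
    ii[[length(ii) + 1L]] <<- from; jj[[length(jj) + 1L]] <<- to
    xx[[length(xx) + 1L]] <<- rep(1, length(from))
    ii[[length(ii) + 1L]] <<- from; jj[[length(jj) + 1L]] <<- from
    xx[[length(xx) + 1L]] <<- rep(-1, length(from))
  }
  add(as.vector(id[-n, ]), as.vector(id[-1, ]))   # +x neighbour
  add(as.vector(id[-1, ]), as.vector(id[-n, ]))   # -x
  add(as.vector(id[, -n]), as.vector(id[, -1]))   # +y
  add(as.vector(id[, -1]), as.vector(id[, -n]))   # -y
  L <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n * n, n * n))
  L <- L / grid$h^2
  .nv_cache[[key]] <- L
  L
}

#' Steady reaction--diffusion solve
#'
#' Solves `0 = D * Lap(u) + source(u) - sink_rate * u` on the grid under
#' zero-Neumann boundaries. `source` may be a field (linear problem, one
#' sparse solve) or a function of the unknown (Picard iteration with a
#' sparse factorization reused across iterations).
#'
#' @param grid A [grid_spec()].
#' @param D Diffusivity (> 0), in mm^2 per time unit.
#' @param source Scalar field / matrix / scalar, or `function(u_matrix)`
#'   returning the source matrix.
#' @param sink_rate Non-negative scalar field / matrix / scalar of linear
#'   sink rates. Must not be identically zero (the pure-Neumann operator is
#'   singular otherwise).
#' @param tol Picard convergence tolerance on max|delta u|.
#' @param max_iter Maximum Picard iterations.
#' @return A `scalar_field` with the steady solution.
#' @export
solve_steady_rd <- function(grid, D, source, sink_rate, tol = 1e-10,
                            max_iter = 100) {
  if (D <= 0) stop("D must be > 0")
  sink <- field_values(sink_rate, grid)
  if (any(sink < 0)) stop("sink_rate must be >= 0 everywhere")
  if (max(sink) == 0) stop("sink_rate must be positive somewhere (singular operator)")
  A <- -D * grid_laplacian(grid) + Matrix::Diagonal(x = as.vector(sink))
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  solve1 <- function(rhs)
    matrix(as.vector(Matrix::solve(fac, as.vector(rhs))), grid$n, grid$n)
  if (!is.function(source)) return(scalar_field(grid, solve1(field_values(source, grid))))
  # damped Picard with adaptive relaxation: plain iteration oscillates or
  # diverges when the source responds strongly to the unknown
  u <- matrix(0, grid$n, grid$n)
  omega <- 1
  delta_prev <- Inf
  for (k in seq_len(max_iter)) {
    v <- solve1(source(u))
    delta <- max(abs(v - u))
    if (delta < tol) return(scalar_field(grid, v))
    if (delta > 0.9 * delta_prev) omega <- omega / 2
    u <- u + omega * (v - u)
    delta_prev <- delta
  }
  stop(sprintf("steady reaction-diffusion solve did not converge: residual %.3g after %d iterations",
               delta, max_iter))
}

#' One implicit diffusion--decay time step
#'
#' Backward-Euler step of `du/dt = D * Lap(u) + source - decay * u` under
#' zero-Neumann boundaries. Unconditionally stable; the discrete mass
#' balance `sum(u') - sum(u) = dt * (sum(source) - sum(decay * u'))` holds
#' to solver precision because the Neumann Laplacian has zero column sums.
#'
#' @param field `scalar_field` (or matrix) at time t.
#' @param D Diffusivity (>= 0).
#' @param source Source field/matrix/scalar.
#' @param decay Non-negative decay rate (scalar or field).
#' @param dt Time step (> 0).
#' @param grid Required when `field` is a bare matrix.
#' @return `scalar_field` at time t + dt.
#' @seealso [make_diffusion_stepper()] for repeated steps with a cached
#'   factorization.
#' @export
step_diffusion_decay <- function(field, D, source, decay, dt, grid = NULL) {
  if (inherits(field, "scalar_field")) grid <- field$grid
  if (is.null(grid)) stop("grid must be supplied when field is a matrix")
  stepper <- make_diffusion_stepper(grid, D, decay, dt)
  scalar_field(grid, stepper(field_values(field, grid),
                             field_values(source, grid)))
}

#' Factory for repeated implicit diffusion--decay steps
#'
#' Factorizes the backward-Euler operator `I/dt - D*Lap + diag(decay)` once
#' and returns `function(u, source)` performing one step by triangular
#' solves. Used in the inner drug/TAF loops where the operator is constant.
#'
#' @inheritParams step_diffusion_decay
#' @param grid A [grid_spec()].
#' @return A function `(u_matrix, source_matrix) -> u_matrix`.
#' @export
make_diffusion_stepper <- function(grid, D, decay, dt) {
  if (dt <= 0) stop("dt must be > 0")
  if (D < 0) stop("D must be >= 0")
  dec <- field_values(decay, grid)
  if (any(dec < 0)) stop("decay must be >= 0")
  A <- Matrix::Diagonal(grid$n^2, 1 / dt) + Matrix::Diagonal(x = as.vector(dec))
  if (D > 0) A <- A - D * grid_laplacian(grid)
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  n <- grid$n
  function(u, source) {
    rhs <- as.vector(u) / dt + as.vector(source)
    matrix(as.vector(Matrix::solve(fac, rhs)), n, n)
  }
}

# --- shift helpers (zero-Neumann: edge values replicate) -------------------
shift_xm <- function(M) M[c(1L, seq_len(nrow(M) - 1L)), , drop = FALSE] # value at i-1
shift_xp <- function(M) M[c(seq_len(nrow(M))[-1L], nrow(M)), , drop = FALSE]
shift_ym <- function(M) M[, c(1L, seq_len(ncol(M) - 1L)), drop = FALSE]
shift_yp <- function(M) M[, c(seq_len(ncol(M))[-1L], ncol(M)), drop = FALSE]

# Central-difference gradient under mirrored boundaries; returns list(gx, gy).
grad_centered <- function(M, h) {
  list(gx = (shift_xp(M) - shift_xm(M)) / (2 * h),
       gy = (shift_yp(M) - shift_ym(M)) / (2 * h))
}
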