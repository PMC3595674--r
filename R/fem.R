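#' Assemble the P1 stiffness system
#'
#' Standard piecewise-linear finite element stiffness matrix for
#' `-div(coef grad u)` on a triangle mesh, with element-wise constant
#' coefficient. The unconstrained matrix is symmetric positive semidefinite
#' with constants in its kernel (zero row sums); Dirichlet constraints are
#' applied at solve time by symmetric elimination.
#'
#' @param mesh a `triangle_mesh`.
#' @param coefficient scalar or per-element positive coefficient (for the
#'   forward problem, conductivity sampled at element centroids).
#' @return object of class `fem_system`: `mesh`, sparse `stiffness`, zero
#'   `load`, empty constraint set.
#' @export
assemble_p1 <- function(mesh, coefficient = 1) {
  m <- nrow(mesh$triangles)
  coef <- rep_len(coefficient, m)
  if (any(!is.finite(coef)) || any(coef <= 0))
    stop_validation("element coefficients must be positive and finite")
  v <- mesh$vertices; t <- mesh$triangles
  x1 <- v[t[, 1], 1]; y1 <- v[t[, 1], 2]
  x2 <- v[t[, 2], 1]; y2 <- v[t[, 2], 2]
  x3 <- v[t[, 3], 1]; y3 <- v[t[, 3], 2]
  # gradient coefficients: grad(phi_i) = (b_i, c_i) / (2A)
  b1 <- y2 - y3; b2 <- y3 - y1; b3 <- y1 - y2
  c1 <- x3 - x2; c2 <- x1 - x3; c3 <- x2 - x1
  area2 <- x2 * y3 - x3 * y2 - x1 * y3 + x3 * y1 + x1 * y2 - x2 * y1  # 2A signed
  if (any(area2 <= 0)) stop_solver("mesh contains non-positively oriented or degenerate elements")
  w <- coef / (2 * area2)
  b <- cbind(b1, b2, b3); cc <- cbind(c1, c2, c3)
  ii <- jj <- xx <- vector("list", 9)
  p <- 0
  for (i in 1:3) for (j in 1:3) {
    p <- p + 1
    ii[[p]] <- t[, i]; jj[[p]] <- t[, j]
    xx[[p]] <- w * (b[, i] * b[, j] + cc[, i] * cc[, j])
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = rep(nrow(v), 2))
  structure(list(mesh = mesh, stiffness = K,
                 load = numeric(nrow(v)),
                 dirichlet = list(index = integer(0), value = numeric(0))),
            class = "fem_system")
}

#' @export
print.fem_system <- function(x, ...) {
  cat(sprintf("<fem_system> %d dof, %d nonzeros, %d Dirichlet constraints\n",
              length(x$load), Matrix::nnzero(x$stiffness), length(x$dirichlet$index)))
  invisible(x)
}

# Attach Dirichlet constraints (vertex indices, values) to a system.
set_dirichlet <- function(system, index, value) {
  value <- rep_len(value, length(index))
  keep <- !duplicated(index)
  system$dirichlet <- list(index = as.integer(index[keep]), value = value[keep])
  system
}

#' Solve a constrained FEM system by conjugate gradients
#'
#' Eliminates the Dirichlet constraints symmetrically and solves the reduced
#' positive-definite system with Jacobi-preconditioned conjugate gradients.
#'
#' @param system a `fem_system` with at least one Dirichlet constraint (the
#'   unconstrained stiffness is singular).
#' @param tol relative residual tolerance.
#' @param maxit iteration cap; default `10 * n` unknowns.
#' @return list with `u` (full vertex vector, constraints exact), `iterations`,
#'   `relres`.
#' @export
solve_cg <- function(system, tol = 1e-8, maxit = NULL) {
  K <- system$stiffness
  n <- length(system$load)
  di <- system$dirichlet$index
  if (length(di) == 0)
    stop_solver("system has no Dirichlet constraints; the stiffness matrix is singular")
  dv <- system$dirichlet$value
  free <- setdiff(seq_len(n), di)
  if (is.null(maxit)) maxit <- 10L * max(length(free), 1L)
  u <- numeric(n); u[di] <- dv
  if (length(free) == 0) return(list(u = u, iterations = 0L, relres = 0))
  b <- system$load[free] - as.numeric(K[free, di, drop = FALSE] %*% dv)
  A <- K[free, free]
  x <- cg_core(A, b, tol = tol, maxit = maxit)
  u[free] <- x$x
  list(u = u, iterations = x$iterations, relres = x$relres)
}

# Jacobi-preconditioned CG on a sparse SPD matrix.
cg_core <- function(A, b, tol = 1e-8, maxit = 1000L, x0 = NULL) {
  n <- length(b)
  x <- if (is.null(x0)) numeric(n) else x0
  d <- Matrix::diag(A)
  d[d <= 0] <- 1
  r <- b - as.numeric(A %*% x)
  nb <- sqrt(sum(b^2))
  if (nb == 0) return(list(x = x, iterations = 0L, relres = 0))
  z <- r / d
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(maxit)) {
    relres <- sqrt(sum(r^2)) / nb
    if (relres <= tol) return(list(x = x, iterations = it - 1L, relres = relres))
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  relres <- sqrt(sum(r^2)) / nb
  if (relres > tol)
    stop_solver("conjugate gradients did not converge in %d iterations (relative residual %.3g, tolerance %.3g)",
                maxit, relres, tol)
  list(x = x, iterations = maxit, relres = relres)
}
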