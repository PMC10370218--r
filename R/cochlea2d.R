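## --- 2D box-model solver ----------------------------------------------------
## Incompressible fluid in a rectangular scala [0,L] x [0,H] above the
## cochlear partition (single-scala representation; by the antisymmetry of the
## two scalae the pressure difference is twice the single-scala pressure).
## Laplace's equation holds in the fluid; the partition couples the normal
## pressure gradient to partition acceleration through the admittance Y
## derived from the same wavenumber model as the 1D solver, so the 2D model
## reduces to the transmission line in the long-wave limit. Boundary
## conditions: stapes piston drive (or wave reflectance R_st for point-source
## problems), rigid top wall, radiating apex.

## solve A z = b for complex sparse A given as triplet vectors
solve_complex_sparse <- function(ii, jj, vv, b, n) {
  iR <- c(ii, ii + n, ii, ii + n)
  jR <- c(jj, jj + n, jj + n, jj)
  vR <- c(Re(vv), Re(vv), -Im(vv), Im(vv))
  keep <- vR != 0
  A <- Matrix::sparseMatrix(i = iR[keep], j = jR[keep], x = vR[keep],
                            dims = c(2L * n, 2L * n))
  nrhs <- if (is.matrix(b)) ncol(b) else 1L
  bR <- rbind(matrix(Re(b), ncol = nrhs), matrix(Im(b), ncol = nrhs))
  z <- tryCatch(as.matrix(Matrix::solve(A, bR)), error = function(e) e)
  if (inherits(z, "error"))
    stop("2D finite-difference system is (near-)singular: ",
         conditionMessage(z))
  out <- z[seq_len(n), , drop = FALSE] + 1i * z[n + seq_len(n), , drop = FALSE]
  if (nrhs == 1L) out[, 1] else out
}

## assemble the 2D system; returns triplets and grid metadata
fd2d_system <- function(model, frequency, activity, nx, ny,
                        base_bc = c("piston", "reflectance"),
                        stapes_reflectance = 0) {
  base_bc <- match.arg(base_bc)
  L <- model$length; H <- model$height
  dx <- L / (nx - 1)
  # extended x grid past the apex, as in the 1D solver: the tonotopic map
  # continues and the natural cut-off absorbs outgoing waves
  nx_tot <- nx + ceiling(0.18 * (nx - 1))
  x <- seq(0, by = dx, length.out = nx_tot)
  y <- seq(0, H, length.out = ny)
  dy <- y[2] - y[1]
  k1 <- wavenumber_ext(model, x, frequency, activity)
  k2sp <- k1^2
  kL <- k1[nx_tot]
  nx <- nx_tot
  # scala width taper b(x) propto A(x): x-operator is (1/b) d/dx (b dp/dx)
  Aw <- area_raw(model, x)
  Awm <- area_raw(model, x - dx / 2)
  Awp <- area_raw(model, x + dx / 2)
  id <- function(i, j) (j - 1L) * nx + i
  n <- nx * ny
  ii <- integer(0); jj <- integer(0); vv <- complex(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); vv <<- c(vv, v)
  }
  # build per-row stencils vectorised over i for each j-band
  for (j in seq_len(ny)) {
    i <- seq_len(nx)
    here <- id(i, j)
    diagv <- -(Awm + Awp) / (Aw * dx^2) - 2 / dy^2 + 0i
    # x-neighbours, width-weighted
    west <- Awm / (Aw * dx^2) + 0i
    east <- Awp / (Aw * dx^2) + 0i
    # stapes end i = 1: ghost elimination
    east[1] <- (Awm[1] + Awp[1]) / (Aw[1] * dx^2)
    west[1] <- 0
    if (base_bc == "reflectance") {
      beta <- (1 - stapes_reflectance) / (1 + stapes_reflectance)
      diagv[1] <- diagv[1] - 2i * k1[1] * beta * Awm[1] / (Aw[1] * dx)
    }
    # apex i = nx: radiation ghost
    west[nx] <- (Awm[nx] + Awp[nx]) / (Aw[nx] * dx^2)
    east[nx] <- 0
    diagv[nx] <- diagv[nx] - 2i * kL * Awp[nx] / (Aw[nx] * dx)
    # y-neighbours
    if (j == 1L) {
      # partition: p_y(x, 0) = -H k^2 p  (ghost eliminated)
      up <- rep(2 / dy^2 + 0i, nx); down <- rep(0 + 0i, nx)
      diagv <- diagv + 2 * H * k2sp / dy
    } else if (j == ny) {
      up <- rep(0 + 0i, nx); down <- rep(2 / dy^2 + 0i, nx)
    } else {
      up <- rep(1 / dy^2 + 0i, nx); down <- rep(1 / dy^2 + 0i, nx)
    }
    add(here, here, diagv)
    add(here[-1], id(i[-1] - 1L, j), west[-1])
    add(here[-nx], id(i[-nx] + 1L, j), east[-nx])
    if (j > 1L) add(here, id(i, j - 1L), down)
    if (j < ny) add(here, id(i, j + 1L), up)
  }
  list(ii = ii, jj = jj, vv = vv, n = n, nx = nx, ny = ny, x = x, y = y,
       dx = dx, dy = dy, k1 = k1, id = id)
}

#' 2D box-model solution of the cochlea
#'
#' Solves Laplace's equation for the fluid pressure in a rectangular scala
#' above the cochlear partition, with the partition admittance boundary
#' condition `V_CP = Y * P0`, a stapes piston drive (uniform velocity
#' `stapes_velocity`) or a unit point source on the partition, a rigid top
#' wall and a radiating apex. One sparse complex solve per frequency.
#'
#' @param model a [cochlear_model()]; supplies geometry, tonotopy and the
#'   partition admittance.
#' @param frequency frequency in Hz.
#' @param activity `"on"` or `"off"`.
#' @param drive `"stapes"` (piston) or `"point"` (volume-velocity source on
#'   the partition at `source_position`, with a radiating/reflective basal
#'   boundary).
#' @param source_position point-source position (m) for `drive = "point"`.
#' @param stapes_reflectance basal wave reflectance `R_st` for point-source
#'   problems (default 0, reflectionless).
#' @param nx,ny grid resolution (defaults: the model grid in x, 17 rows in y).
#' @param stapes_velocity piston velocity amplitude (m/s).
#' @return An object of class `"bm_response"`: list with `x`, `y`,
#'   `pressure` (nx x ny complex fluid pressure, single scala),
#'   `pressure_at_partition` (`P0`, the pressure difference `2 p(x, 0)`),
#'   `bm_velocity` (`V_CP = Y P0`), `admittance`, `frequency`, `activity`.
#' @export
solve_2d <- function(model, frequency, activity = c("on", "off"),
                     drive = c("stapes", "point"), source_position = NULL,
                     stapes_reflectance = 0,
                     nx = model$grid, ny = 17L, stapes_velocity = 1e-3) {
  activity <- match.arg(activity)
  drive <- match.arg(drive)
  omega <- 2 * pi * frequency
  rho <- model$fluid_density
  base_bc <- if (drive == "stapes") "piston" else "reflectance"
  sys <- fd2d_system(model, frequency, activity, nx, ny, base_bc,
                     stapes_reflectance)
  b <- rep(0 + 0i, sys$n)
  if (drive == "stapes") {
    # piston: p_x(0, y) = -i omega rho U_st, ghost-eliminated RHS
    g <- -1i * omega * rho * stapes_velocity
    b[sys$id(1L, seq_len(ny))] <- 2 * g / sys$dx
  } else {
    if (is.null(source_position))
      stop("'source_position' is required for a point-source drive")
    isrc <- which.min(abs(sys$x - source_position))
    isrc <- min(max(isrc, 2L), nx - 1L)
    # unit point source on the partition, normalised so the long-wave limit
    # matches the 1D Green's function (source strength -H in the partition BC)
    b[sys$id(isrc, 1L)] <- -2 * model$height / (sys$dy * sys$dx)
  }
  p <- solve_complex_sparse(sys$ii, sys$jj, sys$vv, b, sys$n)
  P <- matrix(p, sys$nx, sys$ny)[seq_len(nx), , drop = FALSE]  # physical duct
  xphys <- sys$x[seq_len(nx)]
  Y <- partition_admittance(model, xphys, frequency, activity)
  P0 <- 2 * P[, 1]
  structure(list(
    x = xphys, y = sys$y, pressure = P,
    pressure_at_partition = P0,
    bm_velocity = Y * P0,
    admittance = Y,
    frequency = frequency, activity = activity, drive = drive,
    dx = sys$dx, dy = sys$dy
  ), class = "bm_response")
}

#' @exportS3Method base::print
print.bm_response <- function(x, ...) {
  pk <- which.max(Mod(x$bm_velocity))
  cat(sprintf("2D box-model response at %.2f kHz (amplifier %s, %s drive)\n",
              x$frequency / 1e3, x$activity, x$drive))
  cat(sprintf("  grid %d x %d; |V_CP| peak at x = %.2f mm\n",
              length(x$x), length(x$y), 1e3 * x$x[pk]))
  invisible(x)
}

#' Partition-pressure Green's function of the 2D model
#'
#' Single-scala partition pressure at `x` in response to a unit point source
#' at `x'` on the partition, computed in the 2D finite-difference model. With
#' a reflective basal boundary (`stapes_reflectance != 0`) the basal-side
#' response shows an interference ripple that is absent in the reflectionless
#' case.
#'
#' @param model a [cochlear_model()].
#' @param x receiver position(s) (m); default: the 2D x grid.
#' @param xp source position (m) on the partition.
#' @param frequency frequency in Hz.
#' @param activity `"on"` or `"off"`.
#' @param stapes_reflectance complex basal wave reflectance `R_st`.
#' @param nx,ny grid resolution.
#' @return complex Green's function value(s) at `x` (single-scala pressure
#'   per unit source, comparable directly with [wkb_green()]).
#' @export
greens_2d <- function(model, x = NULL, xp, frequency,
                      activity = c("on", "off"), stapes_reflectance = 0,
                      nx = model$grid, ny = 17L) {
  activity <- match.arg(activity)
  sol <- solve_2d(model, frequency, activity, drive = "point",
                  source_position = xp,
                  stapes_reflectance = stapes_reflectance, nx = nx, ny = ny)
  g <- sol$pressure[, 1]  # single-scala partition pressure
  if (is.null(x)) return(structure(g, x = sol$x))
  interp_lin(sol$x, g, x)
}

## Green's matrix on the partition for the 2D provider: one factorisation
## would be ideal; Matrix keeps the factorisation inside solve(A, B), so all
## sources are passed as one multi-RHS solve.
green_matrix_fd2d <- function(model, frequency, activity, ny = 17L,
                              stapes_reflectance = 0) {
  nx <- model$grid
  sys <- fd2d_system(model, frequency, activity, nx, ny, "reflectance",
                     stapes_reflectance)
  srcs <- 2:nx                   # sources on the physical partition
  B <- matrix(0 + 0i, sys$n, length(srcs))
  B[cbind(sys$id(srcs, 1L), seq_along(srcs))] <-
    -2 * model$height / (sys$dy * sys$dx)
  sol <- solve_complex_sparse(sys$ii, sys$jj, sys$vv, B, sys$n)
  Gp <- sol[sys$id(seq_len(nx), 1L), , drop = FALSE]  # partition rows
  G <- matrix(0 + 0i, nx, nx)
  G[, srcs] <- Gp
  G[, 1] <- G[, 2]
  G
}
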