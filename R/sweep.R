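#' Classify the remodeling outcome
#'
#' Net bone turnover after one cycle is judged by the steady-state bone
#' volume: balanced ("normal") remodeling returns it to 100\% of the
#' pre-remodeling volume, over-remodeling ends above, under-remodeling
#' (over-resorption) below.
#'
#' @param zbar steady-state bone volume (\%); vectorized.
#' @param tol tolerance (\% bone volume) around 100 counted as normal;
#'   default 0.5.
#' @return Character vector: \code{"over"}, \code{"normal"} or
#'   \code{"under"}.
#' @examples
#' classify_remodeling(c(100, 103, 96))
#' @export
classify_remodeling <- function(zbar, tol = 0.5) {
  if (any(!is.finite(zbar)))
    stop_validation("zbar must be finite")
  ifelse(zbar > 100 + tol, "over",
         ifelse(zbar < 100 - tol, "under", "normal"))
}

#' Map steady-state bone volume over a parameter grid
#'
#' Runs one remodeling event per grid point with the named parameter(s)
#' overridden, recording the steady-state bone volume and a convergence
#' flag. One- and two-parameter grids are supported. Every point is a pure,
#' independent computation, so the result does not depend on evaluation
#' order.
#'
#' @param base baseline [remodeling_params()] the grid perturbs.
#' @param param_x name of the first swept parameter.
#' @param values_x ordered numeric values for \code{param_x}.
#' @param param_y,values_y optional second swept parameter.
#' @inheritParams steady_state_bone_volume
#' @return A \code{"sweep_grid"}: list with the grid definition, a
#'   \code{zbar} matrix (\code{length(values_x)} by
#'   \code{length(values_y)}, one column for 1-D sweeps) and a matching
#'   \code{converged} flag matrix. Coerce with \code{as.data.frame} for the
#'   long format \code{(param_x, param_y, zbar, converged)}.
#' @examples
#' \donttest{
#' sw <- zbar_map(param_x = "g42", values_x = c(0.8, 1, 1.2))
#' as.data.frame(sw)
#' }
#' @export
zbar_map <- function(base = remodeling_params(),
                     param_x, values_x,
                     param_y = NULL, values_y = NULL,
                     init = initial_condition(),
                     horizon = 300, dt_out = 0.25, ...) {
  base <- as_remodeling_params(base)
  for (nm in c(param_x, param_y))
    if (!nm %in% names(.param_defaults))
      stop_validation("unknown parameter in sweep grid: %s", nm)
  if (is.null(param_y) != is.null(values_y))
    stop_validation("param_y and values_y must be given together")
  if (!is.numeric(values_x) || !all(is.finite(values_x)))
    stop_validation("values_x must be finite numerics")
  vy <- if (is.null(values_y)) NA_real_ else values_y
  zbar <- matrix(NA_real_, length(values_x), length(vy))
  conv <- matrix(NA, length(values_x), length(vy))
  for (i in seq_along(values_x)) {
    for (j in seq_along(vy)) {
      ov <- stats::setNames(list(values_x[i]), param_x)
      if (!is.null(param_y)) ov[[param_y]] <- vy[j]
      p <- do.call(remodeling_params, c(ov, list(base = base)))
      z <- suppressWarnings(
        steady_state_bone_volume(p, init, horizon, dt_out = dt_out, ...))
      zbar[i, j] <- z
      conv[i, j] <- attr(z, "converged")
    }
  }
  structure(list(param_x = param_x, values_x = values_x,
                 param_y = param_y, values_y = values_y,
                 zbar = zbar, converged = conv,
                 base = base, horizon = horizon),
            class = "sweep_grid")
}

#' @export
as.data.frame.sweep_grid <- function(x, ...) {
  grid <- expand.grid(x = x$values_x,
                      y = if (is.null(x$values_y)) NA_real_ else x$values_y)
  out <- data.frame(param_x = x$param_x, value_x = grid$x,
                    param_y = if (is.null(x$param_y)) NA_character_ else x$param_y,
                    value_y = grid$y,
                    zbar = as.vector(x$zbar),
                    converged = as.vector(x$converged))
  out
}

#' @export
print.sweep_grid <- function(x, ...) {
  cat(sprintf("Steady-state bone volume sweep over %s (%d values)%s\n",
              x$param_x, length(x$values_x),
              if (is.null(x$param_y)) ""
              else sprintf(" x %s (%d values)", x$param_y, length(x$values_y))))
  cat(sprintf("  zbar range: [%.2f, %.2f]%%; %d/%d points converged\n",
              min(x$zbar), max(x$zbar), sum(x$converged), length(x$converged)))
  invisible(x)
}

#' RANKL-effectiveness pair giving balanced remodeling
#'
#' Steady-state bone volume decreases monotonically in the pre-osteoblast
#' RANKL-effectiveness exponent \code{g42} (more RANKL, more
#' osteoclastogenesis, more resorption). For a given osteocyte
#' RANKL-effectiveness \code{g41}, this finds the \code{g42} on the
#' normal-remodeling contour -- the value returning bone volume to exactly
#' 100\% -- by safeguarded root bracketing over \code{bracket}.
#'
#' @param g41 osteocyte RANKL-effectiveness exponent to hold fixed.
#' @param base baseline parameters for everything else.
#' @param bracket search interval for \code{g42}; default \code{c(0, 2)},
#'   the physiologically explored range.
#' @param tol root tolerance on \code{g42}; default 1e-3.
#' @inheritParams steady_state_bone_volume
#' @return The balancing \code{g42}, with attribute \code{zbar} (the bone
#'   volume at the root).
#' @examples
#' \donttest{
#' find_normal_g42(1)  # ~1 at baseline
#' }
#' @seealso [normal_remodeling_contour()] for a table over several
#'   \code{g41}.
#' @export
find_normal_g42 <- function(g41, base = remodeling_params(),
                            bracket = c(0, 2), tol = 1e-3,
                            init = initial_condition(),
                            horizon = 300, dt_out = 0.25) {
  if (!is.numeric(bracket) || length(bracket) != 2L || bracket[1L] >= bracket[2L])
    stop_validation("bracket must be an increasing interval c(lo, hi)")
  fz <- function(g42) {
    p <- remodeling_params(g41 = g41, g42 = g42, base = base)
    as.numeric(suppressWarnings(
      steady_state_bone_volume(p, init, horizon, dt_out = dt_out))) - 100
  }
  f_lo <- fz(bracket[1L]); f_hi <- fz(bracket[2L])
  if (sign(f_lo) == sign(f_hi))
    stop_validation(
      "no sign change in bracket [%g, %g]: zbar - 100 = %.3f and %.3f",
      bracket[1L], bracket[2L], f_lo, f_hi)
  root <- stats::uniroot(fz, bracket, f.lower = f_lo, f.upper = f_hi,
                         tol = tol)
  structure(root$root, zbar = root$f.root + 100)
}

#' Normal-remodeling contour in the RANKL-effectiveness plane
#'
#' Tabulates, for each supplied osteocyte RANKL-effectiveness \code{g41},
#' the pre-osteoblast RANKL-effectiveness \code{g42} that yields balanced
#' remodeling, answering which cell type can compensate for the other as a
#' RANKL source.
#'
#' @param g41_values numeric vector of \code{g41} values.
#' @inheritParams find_normal_g42
#' @return \code{data.frame} with columns \code{g41}, \code{g42} and
#'   \code{zbar} (achieved bone volume, \%).
#' @export
normal_remodeling_contour <- function(g41_values, base = remodeling_params(),
                                      bracket = c(0, 2), tol = 1e-3, ...) {
  rows <- lapply(g41_values, function(a) {
    r <- find_normal_g42(a, base = base, bracket = bracket, tol = tol, ...)
    data.frame(g41 = a, g42 = as.numeric(r), zbar = attr(r, "zbar"))
  })
  do.call(rbind, rows)
}

#' Calibrate the bone-formation rate
#'
#' The cell subsystem is independent of the turnover rates \code{k1, k2},
#' so the net bone-volume change over a cycle is
#' \code{k2 * int B - k1 * int C} with the integrals fixed by the cell
#' trajectories alone. The formation rate that closes the balance -- making
#' one cycle of remodeling return bone volume exactly to 100\% -- is
#' therefore available in closed form,
#' \deqn{k_2 = k_1 \int C\,dt \; / \int B\,dt,}
#' evaluated by quadrature on one dense baseline solve. This is how the
#' baseline \code{k2 = 0.015445} is pinned down from the remaining
#' parameters.
#'
#' @param base parameters (everything except \code{k2} matters).
#' @param init an [initial_condition()]; must actually trigger remodeling.
#' @inheritParams simulate_remodeling
#' @return Calibrated \code{k2} (\% volume per day per osteoblast), with
#'   attribute \code{integrals} (the quadrature values of B and C).
#' @examples
#' \donttest{
#' calibrate_k2()  # ~0.0155 at baseline
#' }
#' @export
calibrate_k2 <- function(base = remodeling_params(),
                         init = initial_condition(),
                         horizon = 300, dt_out = 0.01,
                         rtol = 1e-8, atol = 1e-10) {
  traj <- simulate_remodeling(base, init, horizon, rtol, atol, dt_out)
  ints <- cell_integrals(traj)
  if (ints[["B"]] <= 0)
    stop_domain(
      "degenerate trajectory: int B = %g cell-days (no osteoblast activity, nothing to calibrate)",
      ints[["B"]])
  structure(unname(traj$params[["k1"]] * ints[["C"]] / ints[["B"]]),
            integrals = ints)
}
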