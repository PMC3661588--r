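# Baseline parameter values for a cycle of normal targeted remodeling.
# First-order rates are per day; K_S and epsilon are cell counts; k1, k2 are
# % bone volume per day per cell; exponents are dimensionless signaling
# effectiveness.
.param_defaults <- c(
  alpha1 = 0.5,     # osteoblast embedding rate
  alpha2 = 0.1,     # differentiation rate of pre-osteoblast precursors
  alpha3 = 0.1,     # pre-osteoblast proliferation rate
  alpha4 = 0.1,     # differentiation rate of osteoclast precursors
  beta1  = 0.1,     # differentiation rate of pre-osteoblasts
  beta2  = 0.1,     # osteoblast apoptosis rate
  beta3  = 0.1,     # osteoclast apoptosis rate
  delta  = 0.1,     # pre-osteoblast apoptosis rate
  K_S    = 200,     # critical osteocyte population (sclerostin threshold)
  k1     = 0.7,     # bone resorption rate per osteoclast
  k2     = 0.015445,# bone formation rate per osteoblast
  g31 = 1,          # osteoblast autocrine signaling (embedding)
  g21 = 2,          # osteocyte paracrine signaling of pre-osteoblasts
  g22 = 1,          # sclerostin regulation of osteoblastogenesis
  g32 = 1,          # pre-osteoblast autocrine signaling (proliferation)
  g41 = 1,          # osteocyte RANKL signaling of osteoclasts
  g42 = 1,          # pre-osteoblast RANKL signaling of osteoclasts
  g43 = -1,         # osteoblast (OPG) signaling of osteoclasts
  g44 = 1,          # sclerostin regulation of osteoclastogenesis
  f12 = 1,          # pre-osteoblast autocrine signaling (differentiation)
  f14 = 1,          # osteoclast paracrine signaling of osteoblasts
  f23 = 1,          # osteoblast autocrine signaling for apoptosis
  f34 = 1,          # osteoclast autocrine signaling for apoptosis
  epsilon = 1       # OPG-guard offset on the osteoblast base
)

.rate_names <- c("alpha1", "alpha2", "alpha3", "alpha4",
                 "beta1", "beta2", "beta3", "delta", "k1", "k2")
.exponent_names <- c("g31", "g21", "g22", "g32",
                     "g41", "g42", "g43", "g44",
                     "f12", "f14", "f23", "f34")

#' Model parameters for targeted bone remodeling
#'
#' Constructs a validated, fully populated parameter set for the remodeling
#' model. Defaults are the baseline values chosen so that a single remodeling
#' cycle completes in roughly one hundred days with bone volume returning to
#' 100%. Any subset of parameters can be overridden by name.
#'
#' Parameters fall into four groups:
#' \itemize{
#'   \item First-order rates (per day): \code{alpha1} (osteoblast embedding),
#'     \code{alpha2} (differentiation of pre-osteoblast precursors),
#'     \code{alpha3} (pre-osteoblast proliferation), \code{alpha4}
#'     (differentiation of osteoclast precursors), \code{beta1}
#'     (pre-osteoblast differentiation), \code{beta2} (osteoblast apoptosis),
#'     \code{beta3} (osteoclast apoptosis), \code{delta} (pre-osteoblast
#'     apoptosis).
#'   \item Bone turnover rates (\% volume per day per cell): \code{k1}
#'     (resorption per osteoclast), \code{k2} (formation per osteoblast).
#'   \item The sclerostin threshold \code{K_S} (cells): the critical osteocyte
#'     population below which the local drop in sclerostin releases Wnt
#'     signaling and initiates remodeling.
#'   \item Dimensionless signaling-effectiveness exponents \code{g31},
#'     \code{g21}, \code{g22}, \code{g32}, \code{g41}, \code{g42}, \code{g43},
#'     \code{g44}, \code{f12}, \code{f14}, \code{f23}, \code{f34}, and the
#'     OPG-guard offset \code{epsilon} (cells) added to the osteoblast base so
#'     the typically negative exponent \code{g43} never divides by zero.
#' }
#'
#' Validation enforces: all rates nonnegative, \code{K_S > 0},
#' \code{epsilon > 0}, and a negative exponent permitted only for \code{g43},
#' whose base \code{epsilon + B} is bounded away from zero. All other bases
#' (cell populations and the sclerostin gate) reach zero at steady state, so
#' a negative exponent there would be singular.
#'
#' @param ... named parameter overrides, e.g. \code{g42 = 1.3}.
#' @param base an existing \code{remodeling_params} object to start from
#'   (default: the baseline set).
#' @return A named numeric vector of class \code{"remodeling_params"} with
#'   all 24 parameters.
#' @examples
#' p <- remodeling_params()
#' p_hi_rankl <- remodeling_params(g42 = 1.3)
#' @seealso [initial_condition()], [remodeling_rhs()], [simulate_remodeling()]
#' @export
remodeling_params <- function(..., base = NULL) {
  values <- if (is.null(base)) .param_defaults else unclass(base)
  overrides <- c(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop_validation("all parameter overrides must be named")
    unknown <- setdiff(names(overrides), names(.param_defaults))
    if (length(unknown))
      stop_validation("unknown parameter(s): %s", paste(unknown, collapse = ", "))
    values[names(overrides)] <- as.numeric(overrides)
  }
  values <- values[names(.param_defaults)]
  validate_params(values)
  structure(values, class = "remodeling_params")
}

validate_params <- function(p) {
  if (!is.numeric(p) || length(p) != length(.param_defaults))
    stop_validation("parameter set must contain the %d model parameters",
                    length(.param_defaults))
  if (any(!is.finite(p)))
    stop_validation("non-finite parameter(s): %s",
                    paste(names(p)[!is.finite(p)], collapse = ", "))
  bad_rate <- .rate_names[p[.rate_names] < 0]
  if (length(bad_rate))
    stop_validation("rate(s) must be >= 0: %s", paste(bad_rate, collapse = ", "))
  if (p[["K_S"]] <= 0)
    stop_validation("K_S must be > 0 (critical osteocyte population)")
  if (p[["epsilon"]] <= 0)
    stop_validation("epsilon must be > 0 (OPG-guard offset)")
  unguarded <- setdiff(.exponent_names, "g43")
  neg <- unguarded[p[unguarded] < 0]
  if (length(neg))
    stop_validation(
      "negative exponent(s) on unguarded base(s): %s (only g43 acts on the epsilon-guarded base)",
      paste(neg, collapse = ", "))
  invisible(p)
}

#' @export
print.remodeling_params <- function(x, ...) {
  cat("Targeted bone remodeling parameters\n")
  v <- unclass(x)
  changed <- names(v)[v != .param_defaults]
  fmt <- function(nm) paste(sprintf("%s = %g", nm, v[nm]), collapse = ", ")
  cat("  rates (/day):   ", fmt(setdiff(.rate_names, c("k1", "k2"))), "\n")
  cat("  turnover (%/d): ", fmt(c("k1", "k2")), "\n")
  cat("  threshold:      ", fmt(c("K_S", "epsilon")), "\n")
  cat("  exponents:      ", fmt(.exponent_names), "\n")
  if (length(changed))
    cat("  (differs from baseline:", paste(changed, collapse = ", "), ")\n")
  invisible(x)
}

#' @export
as.list.remodeling_params <- function(x, ...) as.list(unclass(x))

#' Initial condition for a remodeling event
#'
#' A remodeling cycle is initiated by damage-induced osteocyte apoptosis: the
#' osteocyte population drops by \code{sigma} cells below the sclerostin
#' threshold \code{K_S}, lowering local sclerostin and opening the gate. All
#' other cell populations start at zero (no committed pre-osteoblasts or
#' active osteoclasts before remodeling begins) and bone volume at \code{z0}.
#'
#' @param sigma initial osteocyte deficit (cells, the apoptotic drop);
#'   default 20.
#' @param z0 initial bone volume (\% of pre-remodeling volume); default 100.
#' @return An object of class \code{"initial_condition"}.
#' @examples
#' init <- initial_condition()        # sigma = 20, z0 = 100
#' quiet <- initial_condition(sigma = 0)  # stays at equilibrium
#' @export
initial_condition <- function(sigma = 20, z0 = 100) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    stop_validation("sigma must be a finite number >= 0")
  if (!is.numeric(z0) || length(z0) != 1L || !is.finite(z0) || z0 < 0)
    stop_validation("z0 must be a finite number >= 0")
  structure(list(sigma = sigma, z0 = z0), class = "initial_condition")
}

#' @export
print.initial_condition <- function(x, ...) {
  cat(sprintf("Initial condition: osteocyte deficit sigma = %g cells, z0 = %g%%\n",
              x$sigma, x$z0))
  invisible(x)
}

#' Initial state vector implied by an initial condition
#'
#' The model starts at the unique remodeling-free steady state perturbed by
#' the apoptotic osteocyte deficit: \code{(K_S - sigma, 0, 0, 0, z0)}.
#'
#' @param params a [remodeling_params()] object.
#' @param init an [initial_condition()] object.
#' @return Named numeric vector \code{c(S, P, B, C, z)}.
#' @export
initial_state <- function(params = remodeling_params(),
                          init = initial_condition()) {
  params <- as_remodeling_params(params)
  if (!inherits(init, "initial_condition"))
    init <- do.call(initial_condition, as.list(init))
  if (init$sigma > params[["K_S"]])
    stop_validation("sigma (%g) may not exceed K_S (%g)", init$sigma, params[["K_S"]])
  c(S = params[["K_S"]] - init$sigma, P = 0, B = 0, C = 0, z = init$z0)
}

# Accept either a classed parameter vector or anything coercible to one.
as_remodeling_params <- function(p) {
  if (inherits(p, "remodeling_params")) {
    validate_params(unclass(p))
    return(p)
  }
  do.call(remodeling_params, as.list(p))
}
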