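#' Construct a sensor curve (parameter -> hormone)
#'
#' Log-linear response \code{H = exp(alpha + s * beta * P)}: the hormone is
#' strictly positive everywhere and strictly monotone in the parameter, with
#' slope sign \code{s} given by the direction. This is the conventional shape
#' for hormone responses measured on a log scale (e.g. the log-linear TSH-FT4
#' relationship).
#'
#' @param alpha log-scale intercept (dimensionless).
#' @param beta log-scale slope magnitude (per parameter unit), > 0.
#' @param direction \code{"stimulatory"} (hormone rises with the parameter,
#'   e.g. insulin with glucose) or \code{"suppressive"} (e.g. PTH with
#'   calcium).
#' @param domain admissible parameter range.
#' @return a [ResponseCurve-class] with role \code{"sensor"}.
#' @export
sensorCurve <- function(alpha, beta,
                        direction = c("suppressive", "stimulatory"),
                        domain = c(0, 50)) {
  direction <- match.arg(direction)
  new("ResponseCurve", role = "sensor", direction = direction,
      params = c(alpha = alpha, beta = beta), domain = domain)
}

#' Construct an effector curve (hormone -> parameter)
#'
#' Saturating hyperbolic response: \code{P = p0 + gain * H / (H + k)} when
#' stimulatory, \code{P = p0 + gain * k / (H + k)} when suppressive. Output is
#' bounded in \code{[p0, p0 + gain]}: \code{p0} is the hormone-independent
#' basal level, \code{gain} the maximal hormone-driven contribution and
#' \code{k} the half-activation hormone level.
#'
#' @param p0 basal parameter level (>= 0).
#' @param gain maximal hormone-driven output (> 0), parameter units.
#' @param k half-activation hormone level (> 0), hormone units.
#' @param direction \code{"stimulatory"} (parameter raised by the hormone,
#'   e.g. calcium by PTH) or \code{"suppressive"} (e.g. glucose by insulin).
#' @param domain admissible hormone range; hormone inputs must be > 0.
#' @return a [ResponseCurve-class] with role \code{"effector"}.
#' @export
effectorCurve <- function(p0, gain, k,
                          direction = c("stimulatory", "suppressive"),
                          domain = c(0, Inf)) {
  direction <- match.arg(direction)
  new("ResponseCurve", role = "effector", direction = direction,
      params = c(p0 = p0, gain = gain, k = k), domain = domain)
}

#' @describeIn evaluateCurve evaluate a sensor or effector curve.
setMethod("evaluateCurve", "ResponseCurve", function(curve, x) {
  if (length(x) == 0L) return(numeric())
  if (any(!is.finite(x)))
    stop("curve input must be finite", call. = FALSE)
  if (any(x < curve@domain[1] | x > curve@domain[2]))
    stop(sprintf("input outside curve domain [%g, %g]",
                 curve@domain[1], curve@domain[2]), call. = FALSE)
  p <- curve@params
  if (identical(curve@role, "sensor")) {
    s <- if (identical(curve@direction, "stimulatory")) 1 else -1
    exp(p[["alpha"]] + s * p[["beta"]] * x)
  } else {
    if (any(x <= 0))
      stop("hormone input must be strictly positive", call. = FALSE)
    if (identical(curve@direction, "stimulatory"))
      p[["p0"]] + p[["gain"]] * x / (x + p[["k"]])
    else
      p[["p0"]] + p[["gain"]] * p[["k"]] / (x + p[["k"]])
  }
})

#' Construct a negative-feedback system
#'
#' @param name identifier, e.g. \code{"calcium_pth"}.
#' @param sensor sensor [ResponseCurve-class] (parameter -> hormone).
#' @param effector effector [ResponseCurve-class] (hormone -> parameter).
#' @param parameterUnits,hormoneUnits display labels.
#' @return a [FeedbackSystem-class].
#' @export
feedbackSystem <- function(name, sensor, effector,
                           parameterUnits = "arb. units",
                           hormoneUnits = "arb. units") {
  new("FeedbackSystem", name = name, sensor = sensor, effector = effector,
      parameterUnits = parameterUnits, hormoneUnits = hormoneUnits)
}

#' Predefined endocrine feedback systems
#'
#' Templates for the three classical negative-feedback loops. Directions
#' follow the physiology: calcium suppresses PTH and PTH raises calcium;
#' glucose stimulates insulin and insulin lowers glucose; FT4 suppresses TSH
#' and TSH raises FT4. Curve magnitudes are illustrative (arbitrary units) —
#' only the directions, and hence the correlation signs derived from them,
#' are claims about the physiology.
#'
#' @param name one of \code{"calcium_pth"}, \code{"glucose_insulin"},
#'   \code{"ft4_tsh"}.
#' @return a [FeedbackSystem-class].
#' @examples
#' predefinedSystem("glucose_insulin")
#' @export
predefinedSystem <- function(name = c("calcium_pth", "glucose_insulin",
                                      "ft4_tsh")) {
  name <- match.arg(name)
  switch(name,
    calcium_pth = feedbackSystem("calcium_pth",
      sensorCurve(alpha = 1, beta = 1, direction = "suppressive"),
      effectorCurve(p0 = 0.5, gain = 2, k = 1, direction = "stimulatory"),
      parameterUnits = "calcium (arb. units)",
      hormoneUnits = "PTH (arb. units)"),
    glucose_insulin = feedbackSystem("glucose_insulin",
      sensorCurve(alpha = -1, beta = 1, direction = "stimulatory"),
      effectorCurve(p0 = 0.5, gain = 2, k = 1, direction = "suppressive"),
      parameterUnits = "glucose (arb. units)",
      hormoneUnits = "insulin (arb. units)"),
    ft4_tsh = feedbackSystem("ft4_tsh",
      sensorCurve(alpha = 1, beta = 1, direction = "suppressive"),
      effectorCurve(p0 = 0.5, gain = 2, k = 1, direction = "stimulatory"),
      parameterUnits = "FT4 (arb. units)",
      hormoneUnits = "TSH (arb. units)")
  )
}

# Vectorized bisection on phi(P) = g(f(P)) - P over the bracket [p0, p0+gain].
# Under negative feedback phi is strictly decreasing with phi(p0) > 0 and
# phi(p0 + gain) < 0, so the root is unique; called with parameter vectors it
# solves a whole cohort at once.
.solveEquilibriumCore <- function(alpha, beta, sensSign, p0, gain, k, effStim,
                                  tolerance = 1e-9, maxIterations = 200L) {
  f <- function(P) exp(alpha + sensSign * beta * P)
  g <- if (effStim) function(H) p0 + gain * H / (H + k)
       else         function(H) p0 + gain * k / (H + k)
  phi <- function(P) g(f(P)) - P
  lo <- p0
  hi <- p0 + gain
  if (any(phi(lo) <= 0) || any(phi(hi) >= 0))
    stop("no sign change of g(f(P)) - P on [p0, p0 + gain]; ",
         "system violates the negative-feedback model", call. = FALSE)
  iter <- 0L
  while (iter < maxIterations && max(hi - lo) > tolerance * 1e-3) {
    mid <- 0.5 * (lo + hi)
    up <- phi(mid) > 0
    lo <- ifelse(up, mid, lo)
    hi <- ifelse(up, hi, mid)
    iter <- iter + 1L
  }
  P <- 0.5 * (lo + hi)
  H <- f(P)
  res <- abs(g(H) - P)
  if (any(res > tolerance))
    stop("equilibrium solver did not reach the requested tolerance",
         call. = FALSE)
  list(P = P, H = H, residual = res, iterations = iter)
}

.systemCoefs <- function(system) {
  sp <- system@sensor@params
  ep <- system@effector@params
  list(alpha = sp[["alpha"]], beta = sp[["beta"]],
       sensSign = if (identical(system@sensor@direction, "stimulatory"))
         1 else -1,
       p0 = ep[["p0"]], gain = ep[["gain"]], k = ep[["k"]],
       effStim = identical(system@effector@direction, "stimulatory"))
}

#' @describeIn solveEquilibrium bisection on the bracket
#'   \code{[p0, p0 + gain]}, where the fixed point of \code{g(f(P))} is
#'   guaranteed and unique.
setMethod("solveEquilibrium", "FeedbackSystem",
  function(system, tolerance = 1e-9) {
    if (!is.finite(tolerance) || tolerance <= 0)
      stop("tolerance must be positive", call. = FALSE)
    co <- .systemCoefs(system)
    sol <- .solveEquilibriumCore(co$alpha, co$beta, co$sensSign,
                                 co$p0, co$gain, co$k, co$effStim,
                                 tolerance = tolerance)
    new("EquilibriumPoint", pStar = sol$P, hStar = sol$H,
        residual = sol$residual, iterations = sol$iterations)
  })

# -- accessors --------------------------------------------------------------

#' @rdname accessors
#' @aliases sensor,FeedbackSystem-method
setMethod("sensor", "FeedbackSystem", function(x) x@sensor)
#' @rdname accessors
#' @aliases effector,FeedbackSystem-method
setMethod("effector", "FeedbackSystem", function(x) x@effector)
#' @rdname accessors
#' @aliases systemName,FeedbackSystem-method
setMethod("systemName", "FeedbackSystem", function(x) x@name)
#' @rdname accessors
#' @aliases curveDirection,ResponseCurve-method
setMethod("curveDirection", "ResponseCurve", function(x) x@direction)
#' @rdname accessors
#' @aliases curveParams,ResponseCurve-method
setMethod("curveParams", "ResponseCurve", function(x) x@params)
#' @rdname accessors
#' @aliases pStar,EquilibriumPoint-method
setMethod("pStar", "EquilibriumPoint", function(x) x@pStar)
#' @rdname accessors
#' @aliases hStar,EquilibriumPoint-method
setMethod("hStar", "EquilibriumPoint", function(x) x@hStar)
#' @rdname accessors
#' @aliases residual,EquilibriumPoint-method
setMethod("residual", "EquilibriumPoint", function(x) x@residual)

# -- show -------------------------------------------------------------------

setMethod("show", "ResponseCurve", function(object) {
  cat(sprintf("%s ResponseCurve (%s)\n", object@role, object@direction))
  cat("  params:", paste(names(object@params), signif(object@params, 4),
                         sep = " = ", collapse = ", "), "\n")
})

setMethod("show", "FeedbackSystem", function(object) {
  cat(sprintf("FeedbackSystem '%s'\n", object@name))
  cat(sprintf("  sensor  : %s, H = exp(alpha %s beta * P)\n",
              object@sensor@direction,
              if (identical(object@sensor@direction, "stimulatory"))
                "+" else "-"))
  cat(sprintf("  effector: %s, bounded in [p0, p0 + gain]\n",
              object@effector@direction))
  cat(sprintf("  units   : P in %s, H in %s\n",
              object@parameterUnits, object@hormoneUnits))
})

setMethod("show", "EquilibriumPoint", function(object) {
  cat(sprintf("EquilibriumPoint: P* = %.6g, H* = %.6g (residual %.2e, %d iterations)\n",
              object@pStar, object@hStar, object@residual, object@iterations))
})

# -- config serialization ---------------------------------------------------

#' Serialize a feedback system to a plain list / config file
#'
#' The list form round-trips through YAML or JSON with keys
#' \code{name}, \code{sensor{direction, alpha, beta}},
#' \code{effector{direction, p0, gain, k}}.
#'
#' @param system a [FeedbackSystem-class].
#' @return \code{systemToList}: a nested plain list.
#' @export
systemToList <- function(system) {
  stopifnot(is(system, "FeedbackSystem"))
  sp <- system@sensor@params; ep <- system@effector@params
  list(
    name = system@name,
    sensor = list(direction = system@sensor@direction,
                  alpha = sp[["alpha"]], beta = sp[["beta"]]),
    effector = list(direction = system@effector@direction,
                    p0 = ep[["p0"]], gain = ep[["gain"]], k = ep[["k"]]),
    parameter_units = system@parameterUnits,
    hormone_units = system@hormoneUnits
  )
}

#' @rdname systemToList
#' @param config nested list as produced by \code{systemToList}.
#' @return \code{systemFromList}: a [FeedbackSystem-class].
#' @export
systemFromList <- function(config) {
  feedbackSystem(
    name = config$name,
    sensor = sensorCurve(config$sensor$alpha, config$sensor$beta,
                         direction = config$sensor$direction),
    effector = effectorCurve(config$effector$p0, config$effector$gain,
                             config$effector$k,
                             direction = config$effector$direction),
    parameterUnits = config$parameter_units %||% "arb. units",
    hormoneUnits = config$hormone_units %||% "arb. units"
  )
}

#' @rdname systemToList
#' @param path file path ending in \code{.yaml}/\code{.yml} or \code{.json}.
#' @export
writeSystemConfig <- function(system, path) {
  .writeConfig(systemToList(system), path)
  invisible(path)
}

#' @rdname systemToList
#' @export
readSystemConfig <- function(path) {
  systemFromList(.readConfig(path))
}
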