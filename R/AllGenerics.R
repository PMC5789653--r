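#' Evaluate one arm of a feedback loop
#'
#' @param curve a [ResponseCurve-class].
#' @param x input value(s): parameter level for a sensor, hormone level for an
#'   effector. Must be finite and lie inside the curve's domain (hormone
#'   inputs must additionally be strictly positive).
#' @return numeric vector of outputs, same length as \code{x}.
#' @examples
#' s <- sensorCurve(alpha = 1, beta = 1, direction = "suppressive")
#' evaluateCurve(s, 1)  # exp(1 - 1) = 1
#' @export
setGeneric("evaluateCurve", function(curve, x) standardGeneric("evaluateCurve"))

#' Solve the equilibrium (intersection) point of a feedback loop
#'
#' @param system a [FeedbackSystem-class].
#' @param tolerance maximum admissible fixed-point defect
#'   \code{|g(f(P*)) - P*|}, in parameter units.
#' @return an [EquilibriumPoint-class].
#' @examples
#' sys <- feedbackSystem("demo",
#'   sensorCurve(1, 1, "suppressive"),
#'   effectorCurve(0.5, 1, 1, "stimulatory"))
#' solveEquilibrium(sys)  # P* = H* = 1
#' @export
setGeneric("solveEquilibrium",
  function(system, tolerance = 1e-9) standardGeneric("solveEquilibrium"))

#' Number of active radiator elements at a given temperature
#'
#' An element is active when the temperature is strictly below its threshold
#' ("comes on when the temperature drops below" it); at exactly the threshold
#' it is off.
#'
#' @param radiator a [Radiator-class].
#' @param temp temperature(s) in degrees C.
#' @return integer vector of active-element counts.
#' @examples
#' activeElements(radiator(), c(15, 19, 30))  # 4, 2, 0
#' @export
setGeneric("activeElements",
  function(radiator, temp) standardGeneric("activeElements"))

#' Steady state of a heated house
#'
#' Radiator regime: solves the heat balance
#' \code{power * activeElements(T) = k (T - T_ext)}. If the loss line crosses
#' the heater staircase inside a constant step, that intersection is a
#' \code{fixed_point}; if it crosses at a step discontinuity the temperature
#' pins to the threshold and the element duty-cycles
#' (\code{threshold_duty_cycle}), with energy equal to the loss at that
#' temperature. Thermostat regime: temperature equals the set point and energy
#' equals demand while demand is within the power cap (\code{thermostat_held}),
#' else the house saturates at full power (\code{thermostat_saturated}).
#'
#' @param house a [House-class] with positive heat-loss coefficient.
#' @return list with components \code{temperature} (degrees C), \code{energy}
#'   (kW) and \code{mode}.
#' @examples
#' steadyState(house(k = 0.5, externalTemp = 10))  # 16 degrees, 3 kW
#' @export
setGeneric("steadyState", function(house) standardGeneric("steadyState"))

#' Accessors
#'
#' Read-only access to slots of the package's classes.
#' @param x an object of the documented classes.
#' @name accessors
#' @return the slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("sensor", function(x) standardGeneric("sensor"))
#' @rdname accessors
#' @export
setGeneric("effector", function(x) standardGeneric("effector"))
#' @rdname accessors
#' @export
setGeneric("systemName", function(x) standardGeneric("systemName"))
#' @rdname accessors
#' @export
setGeneric("curveDirection", function(x) standardGeneric("curveDirection"))
#' @rdname accessors
#' @export
setGeneric("curveParams", function(x) standardGeneric("curveParams"))
#' @rdname accessors
#' @export
setGeneric("pStar", function(x) standardGeneric("pStar"))
#' @rdname accessors
#' @export
setGeneric("hStar", function(x) standardGeneric("hStar"))
#' @rdname accessors
#' @export
setGeneric("residual", function(x) standardGeneric("residual"))
#' @rdname accessors
#' @export
setGeneric("cohortPairs", function(x) standardGeneric("cohortPairs"))
#' @rdname accessors
#' @export
setGeneric("parameterDraws", function(x) standardGeneric("parameterDraws"))
#' @rdname accessors
#' @export
setGeneric("consistencyCounts", function(x) standardGeneric("consistencyCounts"))
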