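#' @import methods
NULL

# ---------------------------------------------------------------------------
# feedback loop primitives
# ---------------------------------------------------------------------------

#' ResponseCurve: one arm of a negative-feedback loop
#'
#' A strictly monotone response in one arm of a hormonal feedback loop.
#' A \emph{sensor} curve maps the regulated parameter P to the controlling
#' hormone H (e.g. PTH suppressed by calcium, insulin stimulated by glucose)
#' as \code{H = exp(alpha + s * beta * P)} with \code{s = +1} for a
#' stimulatory and \code{s = -1} for a suppressive arm. An \emph{effector}
#' curve maps hormone back to parameter through a saturating hyperbola,
#' \code{P = p0 + gain * H / (H + k)} (stimulatory) or
#' \code{P = p0 + gain * k / (H + k)} (suppressive), so its output is bounded
#' by \code{[p0, p0 + gain]}.
#'
#' @slot role character, \code{"sensor"} or \code{"effector"}.
#' @slot direction character, \code{"stimulatory"} or \code{"suppressive"}.
#' @slot params named numeric: \code{alpha}, \code{beta} for a sensor
#'   (\code{beta > 0}); \code{p0 >= 0}, \code{gain > 0}, \code{k > 0} for an
#'   effector.
#' @slot domain numeric(2), admissible range of the input variable.
#'
#' @seealso [sensorCurve()], [effectorCurve()], [evaluateCurve()]
#' @export
setClass("ResponseCurve",
  representation(
    role      = "character",
    direction = "character",
    params    = "numeric",
    domain    = "numeric"
  )
)

setValidity("ResponseCurve", function(object) {
  msg <- character()
  if (!object@role %in% c("sensor", "effector"))
    msg <- c(msg, "role must be 'sensor' or 'effector'")
  if (!object@direction %in% c("stimulatory", "suppressive"))
    msg <- c(msg, "direction must be 'stimulatory' or 'suppressive'")
  if (length(object@domain) != 2L || anyNA(object@domain) ||
      object@domain[1] >= object@domain[2])
    msg <- c(msg, "domain must be an increasing pair")
  p <- object@params
  if (identical(object@role, "sensor")) {
    if (!all(c("alpha", "beta") %in% names(p)))
      msg <- c(msg, "sensor needs params 'alpha' and 'beta'")
    else if (!is.finite(p[["alpha"]]) || !is.finite(p[["beta"]]) ||
             p[["beta"]] <= 0)
      msg <- c(msg, "sensor requires finite alpha and beta > 0")
  }
  if (identical(object@role, "effector")) {
    if (!all(c("p0", "gain", "k") %in% names(p)))
      msg <- c(msg, "effector needs params 'p0', 'gain' and 'k'")
    else if (!all(is.finite(p[c("p0", "gain", "k")])) ||
             p[["p0"]] < 0 || p[["gain"]] <= 0 || p[["k"]] <= 0)
      msg <- c(msg, "effector requires p0 >= 0, gain > 0, k > 0")
  }
  if (length(msg)) msg else TRUE
})

#' FeedbackSystem: a negative-feedback loop between a parameter and a hormone
#'
#' Pairs a sensor curve \code{H = f(P)} with an effector curve \code{P = g(H)}.
#' Negative feedback requires the two directions to be opposite (one
#' stimulatory, one suppressive), which makes the composition
#' \code{P -> g(f(P))} strictly decreasing and its fixed point unique.
#'
#' @slot name character identifier, e.g. \code{"calcium_pth"}.
#' @slot sensor,effector [ResponseCurve-class] objects with matching roles.
#' @slot parameterUnits,hormoneUnits display labels for P and H.
#'
#' @seealso [feedbackSystem()], [predefinedSystem()], [solveEquilibrium()]
#' @export
setClass("FeedbackSystem",
  representation(
    name           = "character",
    sensor         = "ResponseCurve",
    effector       = "ResponseCurve",
    parameterUnits = "character",
    hormoneUnits   = "character"
  )
)

setValidity("FeedbackSystem", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a non-empty string")
  if (!identical(object@sensor@role, "sensor"))
    msg <- c(msg, "slot 'sensor' must hold a sensor curve")
  if (!identical(object@effector@role, "effector"))
    msg <- c(msg, "slot 'effector' must hold an effector curve")
  if (identical(object@sensor@direction, object@effector@direction))
    msg <- c(msg, paste(
      "negative feedback requires sensor and effector of opposite",
      "direction (one stimulatory, one suppressive)"))
  if (length(msg)) msg else TRUE
})

#' EquilibriumPoint: the intersection of the two feedback-loop arms
#'
#' The steady state of a [FeedbackSystem-class]: the unique pair
#' \code{(P*, H*)} where the sensor and effector curves cross, i.e.
#' \code{H* = f(P*)} and \code{P* = g(H*)}.
#'
#' @slot pStar equilibrium parameter level (parameter units).
#' @slot hStar equilibrium hormone level (hormone units).
#' @slot residual absolute fixed-point defect |g(f(P*)) - P*|.
#' @slot iterations bisection iterations used by the solver.
#' @export
setClass("EquilibriumPoint",
  representation(
    pStar      = "numeric",
    hStar      = "numeric",
    residual   = "numeric",
    iterations = "integer"
  )
)

# ---------------------------------------------------------------------------
# population simulation
# ---------------------------------------------------------------------------

#' PopulationSpec: how to draw a synthetic cohort
#'
#' Describes a cohort of individuals who share a template feedback loop but
#' differ in its component parameters. Under the \code{equilibrium} model each
#' individual's (P, H) pair is their own intersection point; under the
#' \code{setpoint} model each individual is assigned a target parameter level
#' drawn independently of their effector parameters, and the hormone level is
#' whatever attains it through their effector curve.
#'
#' Interindividual variation is controlled by per-parameter coefficients of
#' variation. \code{variation_mode = "effector_dominant"} (all sensor CVs zero)
#' encodes the physiological regime of tightly conserved hormone-response
#' physiology; \code{"sensor_dominant"} is the mirror image;
#' \code{"mixed"} allows both.
#'
#' @slot system template [FeedbackSystem-class].
#' @slot n cohort size (>= 2).
#' @slot seed integer RNG seed; recorded in provenance.
#' @slot model \code{"equilibrium"} or \code{"setpoint"}.
#' @slot variationMode \code{"effector_dominant"}, \code{"sensor_dominant"} or
#'   \code{"mixed"}.
#' @slot sensorCV named numeric CVs for \code{alpha} and \code{beta}, each in
#'   \code{[0, 1)}.
#' @slot effectorCV named numeric CVs for \code{p0}, \code{gain}, \code{k}.
#' @slot setpointMean mean target level (setpoint model); \code{NA} means
#'   "use the template system's own equilibrium".
#' @slot setpointCV CV of the target distribution.
#' @slot epsilon truncation margin: targets are confined to
#'   \code{(p0 + eps*gain, p0 + (1-eps)*gain)} so effector inversion is defined.
#' @seealso [populationSpec()], [simulateEquilibriumCohort()],
#'   [simulateSetpointCohort()]
#' @export
setClass("PopulationSpec",
  representation(
    system        = "FeedbackSystem",
    n             = "integer",
    seed          = "integer",
    model         = "character",
    variationMode = "character",
    sensorCV      = "numeric",
    effectorCV    = "numeric",
    setpointMean  = "numeric",
    setpointCV    = "numeric",
    epsilon       = "numeric"
  )
)

setValidity("PopulationSpec", function(object) {
  msg <- character()
  if (object@n < 2L) msg <- c(msg, "n must be >= 2")
  if (!object@model %in% c("equilibrium", "setpoint"))
    msg <- c(msg, "model must be 'equilibrium' or 'setpoint'")
  if (!object@variationMode %in%
        c("effector_dominant", "sensor_dominant", "mixed"))
    msg <- c(msg, "unknown variation mode")
  if (!all(c("alpha", "beta") %in% names(object@sensorCV)))
    msg <- c(msg, "sensorCV needs entries 'alpha' and 'beta'")
  if (!all(c("p0", "gain", "k") %in% names(object@effectorCV)))
    msg <- c(msg, "effectorCV needs entries 'p0', 'gain' and 'k'")
  cvs <- c(object@sensorCV, object@effectorCV, object@setpointCV)
  if (any(!is.finite(cvs)) || any(cvs < 0) || any(cvs >= 1))
    msg <- c(msg, "all CVs must lie in [0, 1)")
  if (identical(object@variationMode, "effector_dominant") &&
      any(object@sensorCV > 0))
    msg <- c(msg, "effector_dominant mode requires all sensor CVs == 0")
  if (identical(object@variationMode, "sensor_dominant") &&
      any(object@effectorCV > 0))
    msg <- c(msg, "sensor_dominant mode requires all effector CVs == 0")
  if (object@epsilon <= 0 || object@epsilon >= 0.5)
    msg <- c(msg, "epsilon must lie in (0, 0.5)")
  if (!is.na(object@setpointMean) && object@setpointMean <= 0)
    msg <- c(msg, "setpointMean must be positive (or NA for automatic)")
  if (length(msg)) msg else TRUE
})

#' CohortSample: paired (P, H) values for a simulated cohort
#'
#' @slot pairs data.frame with columns \code{id}, \code{P}, \code{H}.
#' @slot spec the generating [PopulationSpec-class] (provenance).
#' @slot draws data.frame of the per-individual curve parameters actually
#'   drawn (and, under the set-point model, the target), kept for audit.
#' @seealso [cohortPairs()], [exportCohort()]
#' @export
setClass("CohortSample",
  representation(
    pairs = "data.frame",
    spec  = "PopulationSpec",
    draws = "data.frame"
  )
)

setValidity("CohortSample", function(object) {
  msg <- character()
  if (!all(c("id", "P", "H") %in% names(object@pairs)))
    msg <- c(msg, "pairs must have columns id, P, H")
  else {
    if (nrow(object@pairs) != object@spec@n)
      msg <- c(msg, "pairs must have one row per individual")
    if (!all(is.finite(object@pairs$P)) || !all(is.finite(object@pairs$H)) ||
        any(object@pairs$P <= 0) || any(object@pairs$H <= 0))
      msg <- c(msg, "all P and H must be finite and positive")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# correlation-consistency reporting
# ---------------------------------------------------------------------------

#' ConsistencyReport: classification of cohort correlations under both models
#'
#' @slot records data.frame of correlation records with, for each regulation
#'   model, the implied sign and a classification
#'   (\code{consistent}/\code{inconsistent}/\code{indeterminate}).
#' @slot counts table of classification counts, models in rows.
#' @slot impliedSigns data.frame of implied correlation signs per system and
#'   model.
#' @seealso [evaluateTable()]
#' @export
setClass("ConsistencyReport",
  representation(
    records      = "data.frame",
    counts       = "matrix",
    impliedSigns = "data.frame"
  )
)

# ---------------------------------------------------------------------------
# heating analogy
# ---------------------------------------------------------------------------

#' Radiator: a multi-element heater with fixed activation thresholds
#'
#' Element i switches on when the temperature drops strictly below its
#' threshold; there is no hysteresis and no programmed target temperature.
#'
#' @slot thresholds strictly descending activation temperatures (degrees C).
#' @slot power output per active element (kW).
#' @seealso [radiator()], [activeElements()]
#' @export
setClass("Radiator",
  representation(thresholds = "numeric", power = "numeric")
)

setValidity("Radiator", function(object) {
  msg <- character()
  th <- object@thresholds
  if (length(th) < 1L || anyNA(th) || any(diff(th) >= 0))
    msg <- c(msg, "thresholds must be strictly descending")
  if (length(object@power) != 1L || !is.finite(object@power) ||
      object@power <= 0)
    msg <- c(msg, "power must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' House: a heated enclosure under one of two regulation regimes
#'
#' In the \code{radiator} regime heating power is a pure step function of the
#' current indoor temperature (no target anywhere in the system); in the
#' \code{thermostat} regime a comparator deploys whatever power restores the
#' set temperature, capped at the same total power as the radiator
#' (\code{length(thresholds) * power}).
#'
#' @slot lossCoefficient heat-loss coefficient k (kW per degree C); must be
#'   positive for a steady state to exist, k = 0 is admitted only in dynamic
#'   simulation.
#' @slot capacitance thermal capacitance C (kWh per degree C).
#' @slot externalTemp outdoor temperature (degrees C).
#' @slot regime \code{"radiator"} or \code{"thermostat"}.
#' @slot setpoint thermostat target (degrees C); \code{NA} in radiator regime.
#' @slot radiator the [Radiator-class] (also fixes the thermostat power cap).
#' @seealso [house()], [steadyState()], [simulateDynamics()]
#' @export
setClass("House",
  representation(
    lossCoefficient = "numeric",
    capacitance     = "numeric",
    externalTemp    = "numeric",
    regime          = "character",
    setpoint        = "numeric",
    radiator        = "Radiator"
  )
)

setValidity("House", function(object) {
  msg <- character()
  if (!is.finite(object@lossCoefficient) || object@lossCoefficient < 0)
    msg <- c(msg, "lossCoefficient must be finite and >= 0")
  if (!is.finite(object@capacitance) || object@capacitance <= 0)
    msg <- c(msg, "capacitance must be positive")
  if (!is.finite(object@externalTemp))
    msg <- c(msg, "externalTemp must be finite")
  if (!object@regime %in% c("radiator", "thermostat"))
    msg <- c(msg, "regime must be 'radiator' or 'thermostat'")
  if (identical(object@regime, "thermostat") && !is.finite(object@setpoint))
    msg <- c(msg, "thermostat regime requires a finite setpoint")
  if (length(msg)) msg else TRUE
})

#' TownSpec: a town of houses under one shared climate and heater design
#'
#' Heat-loss coefficients vary between houses (log-normal); thermostat
#' set points vary normally and are drawn independently of the heat-loss
#' coefficients — inhabitants choose their thermal comfort without regard to
#' how leaky their house is.
#'
#' @slot nHouses houses per town (>= 10).
#' @slot lossMean,lossCV mean and CV of the heat-loss coefficient (kW/degC).
#' @slot setpointMean,setpointCV mean and CV of the thermostat set point.
#' @slot radiator shared [Radiator-class] design.
#' @slot externalTemp shared outdoor temperature (degrees C).
#' @slot seed integer RNG seed.
#' @seealso [townSpec()], [twoTowns()]
#' @export
setClass("TownSpec",
  representation(
    nHouses      = "integer",
    lossMean     = "numeric",
    lossCV       = "numeric",
    setpointMean = "numeric",
    setpointCV   = "numeric",
    radiator     = "Radiator",
    externalTemp = "numeric",
    seed         = "integer"
  )
)

setValidity("TownSpec", function(object) {
  msg <- character()
  if (object@nHouses < 10L) msg <- c(msg, "need at least 10 houses per town")
  if (!is.finite(object@lossMean) || object@lossMean <= 0)
    msg <- c(msg, "lossMean must be positive")
  if (object@lossCV < 0 || object@lossCV >= 1 ||
      object@setpointCV < 0 || object@setpointCV >= 1)
    msg <- c(msg, "CVs must lie in [0, 1)")
  if (!is.finite(object@setpointMean))
    msg <- c(msg, "setpointMean must be finite")
  if (length(msg)) msg else TRUE
})
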