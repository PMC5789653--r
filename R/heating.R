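#' Construct a radiator
#'
#' Default: four elements of 1 kW switching on below 22, 20, 18 and 16
#' degrees C — a heater with graded temperature responses but no programmed
#' target anywhere in the system.
#'
#' @param thresholds strictly descending activation temperatures (degrees C).
#' @param power per-element output (kW).
#' @return a [Radiator-class].
#' @export
radiator <- function(thresholds = c(22, 20, 18, 16), power = 1) {
  new("Radiator", thresholds = as.numeric(thresholds),
      power = as.numeric(power))
}

#' Construct a house
#'
#' @param k heat-loss coefficient (kW per degree C).
#' @param capacitance thermal capacitance (kWh per degree C).
#' @param externalTemp outdoor temperature (degrees C).
#' @param regime \code{"radiator"} (no target) or \code{"thermostat"}
#'   (comparator defending a set point, power capped at the radiator total).
#' @param setpoint thermostat target (degrees C); required in thermostat
#'   regime.
#' @param rad the [Radiator-class] installed (fixes the thermostat cap too).
#' @return a [House-class].
#' @export
house <- function(k, capacitance = 2, externalTemp = 10,
                  regime = c("radiator", "thermostat"), setpoint = NA_real_,
                  rad = radiator()) {
  regime <- match.arg(regime)
  new("House", lossCoefficient = as.numeric(k),
      capacitance = as.numeric(capacitance),
      externalTemp = as.numeric(externalTemp), regime = regime,
      setpoint = as.numeric(setpoint), radiator = rad)
}

#' @describeIn activeElements strict-inequality threshold count.
setMethod("activeElements", "Radiator", function(radiator, temp) {
  if (any(!is.finite(temp))) stop("temperature must be finite", call. = FALSE)
  vapply(temp, function(tt) sum(tt < radiator@thresholds), integer(1))
})

.maxPower <- function(rad) length(rad@thresholds) * rad@power

#' @describeIn steadyState heat-balance solution by exhaustive enumeration of
#'   the heater's power steps; the loss line crosses the staircase exactly
#'   once.
setMethod("steadyState", "House", function(house) {
  k <- house@lossCoefficient
  if (k <= 0)
    stop("steady state requires a positive heat-loss coefficient ",
         "(k = 0 is admitted only in simulateDynamics)", call. = FALSE)
  rad <- house@radiator
  text <- house@externalTemp
  if (identical(house@regime, "thermostat")) {
    demand <- k * (house@setpoint - text)
    cap <- .maxPower(rad)
    if (demand <= 0)
      return(list(temperature = text, energy = 0, mode = "thermostat_held"))
    if (demand <= cap)
      return(list(temperature = house@setpoint, energy = demand,
                  mode = "thermostat_held"))
    return(list(temperature = text + cap / k, energy = cap,
                mode = "thermostat_saturated"))
  }
  # radiator regime: look for a fixed point inside a constant power step
  for (m in 0:length(rad@thresholds)) {
    tm <- text + m * rad@power / k
    if (activeElements(rad, tm) == m)
      return(list(temperature = tm, energy = m * rad@power,
                  mode = "fixed_point"))
  }
  # otherwise the loss line crosses at a step discontinuity: the element at
  # that threshold duty-cycles and the temperature pins to the threshold
  for (j in seq_along(rad@thresholds)) {
    th <- rad@thresholds[j]
    loss <- k * (th - text)
    nAbove <- activeElements(rad, th)         # element j off at exactly th
    nBelow <- nAbove + 1L
    if (loss >= nAbove * rad@power && loss <= nBelow * rad@power)
      return(list(temperature = th, energy = loss,
                  mode = "threshold_duty_cycle"))
  }
  stop("no steady state found; radiator/house configuration inconsistent",
       call. = FALSE)  # unreachable for valid houses
})

#' Explicit time integration of a heated house
#'
#' Forward-Euler integration of \code{C dT/dt = heating(T) - k (T - T_ext)}.
#' In the radiator regime the heating term is the step response
#' \code{power * activeElements(T)}; a steady state pinned to a threshold
#' appears as a small duty-cycle oscillation around it. In the thermostat
#' regime the comparator deploys the demand \code{k (S - T_ext)} plus a
#' proportional correction towards the set point, clamped to the power cap,
#' so the unsaturated stationary temperature is exactly the set point.
#'
#' @param house a [House-class]; \code{k = 0} (perfect insulation) is allowed
#'   here.
#' @param T0 initial indoor temperature (degrees C).
#' @param dt time step (hours); must satisfy the explicit-stability bound
#'   \code{dt < C / k} (thermostat regime: \code{C / (5 k)} because of the
#'   controller gain).
#' @param duration total simulated time (hours).
#' @return data.frame with columns \code{time} (h), \code{temperature}
#'   (degrees C) and \code{power} (kW).
#' @examples
#' h <- house(k = 0.5, externalTemp = 10)
#' tr <- simulateDynamics(h, T0 = 21, dt = 0.01, duration = 40)
#' mean(tail(tr$temperature, 800))  # approaches 16
#' @export
simulateDynamics <- function(house, T0, dt = 0.01, duration = 48) {
  stopifnot(is(house, "House"))
  if (!is.finite(T0)) stop("T0 must be finite", call. = FALSE)
  if (dt <= 0 || duration <= dt)
    stop("need dt > 0 and duration > dt", call. = FALSE)
  k <- house@lossCoefficient
  cc <- house@capacitance
  gain <- if (identical(house@regime, "thermostat")) 5 * k else k
  if (gain > 0 && dt >= cc / gain)
    stop(sprintf("unstable time step: dt must be < %g h for this house",
                 cc / gain), call. = FALSE)
  rad <- house@radiator
  cap <- .maxPower(rad)
  nSteps <- floor(duration / dt)
  temp <- power <- numeric(nSteps + 1L)
  temp[1] <- T0
  heatAt <- if (identical(house@regime, "radiator")) {
    function(tt) rad@power * activeElements(rad, tt)
  } else {
    demand <- k * (house@setpoint - house@externalTemp)
    function(tt) min(cap, max(0, demand + 4 * k * (house@setpoint - tt)))
  }
  for (i in seq_len(nSteps)) {
    power[i] <- heatAt(temp[i])
    temp[i + 1L] <- temp[i] +
      dt / cc * (power[i] - k * (temp[i] - house@externalTemp))
  }
  power[nSteps + 1L] <- heatAt(temp[nSteps + 1L])
  data.frame(time = seq(0, by = dt, length.out = nSteps + 1L),
             temperature = temp, power = power)
}

#' Construct a two-towns experiment specification
#'
#' @param nHouses houses per town.
#' @param lossMean,lossCV mean and CV of the log-normal heat-loss
#'   coefficient distribution (kW/degC).
#' @param setpointMean,setpointCV mean and CV of the normal set-point
#'   distribution (degrees C), drawn independently of heat loss.
#' @param rad shared [Radiator-class].
#' @param externalTemp shared outdoor temperature (degrees C).
#' @param seed integer RNG seed.
#' @return a [TownSpec-class].
#' @export
townSpec <- function(nHouses = 500, lossMean = 0.2, lossCV = 0.3,
                     setpointMean = 21, setpointCV = 0.05,
                     rad = radiator(), externalTemp = 10, seed = 1) {
  new("TownSpec", nHouses = as.integer(nHouses), lossMean = lossMean,
      lossCV = lossCV, setpointMean = setpointMean, setpointCV = setpointCV,
      radiator = rad, externalTemp = externalTemp, seed = as.integer(seed))
}

#' The two-towns experiment
#'
#' Two towns share the same climate, the same spread of house heat-loss
#' properties and the same heater hardware; one town's heaters are
#' thermostat-controlled with set points chosen by the inhabitants
#' (independently of heat loss), the other's are threshold radiators with no
#' target. Under the set-point regime houses aiming higher consume more
#' energy, giving a positive temperature-energy correlation across houses;
#' under the radiator regime leakier houses run colder yet consume more, as
#' more elements switch on, giving a negative correlation.
#'
#' @param spec a [TownSpec-class].
#' @return list with components \code{correlations} (named numeric:
#'   \code{thermostat}, \code{radiator} Pearson coefficients) and
#'   \code{houses} (per-house data.frame: \code{house_id}, \code{regime},
#'   \code{k}, \code{setpoint}, \code{T_steady}, \code{energy},
#'   \code{mode}).
#' @examples
#' tt <- twoTowns(townSpec(nHouses = 200, seed = 42))
#' tt$correlations
#' @export
twoTowns <- function(spec) {
  stopifnot(is(spec, "TownSpec"))
  n <- spec@nHouses
  sig <- sqrt(log1p(spec@lossCV^2))
  draws <- withSeed(spec@seed, {
    list(
      kTherm = stats::rlnorm(n, log(spec@lossMean) - sig^2 / 2, sig),
      kRad   = stats::rlnorm(n, log(spec@lossMean) - sig^2 / 2, sig),
      s      = stats::rnorm(n, spec@setpointMean,
                            spec@setpointCV * spec@setpointMean)
    )
  })
  runTown <- function(kk, setpoints, regime) {
    states <- lapply(seq_len(n), function(i) {
      h <- house(kk[i], externalTemp = spec@externalTemp, regime = regime,
                 setpoint = if (identical(regime, "thermostat"))
                   setpoints[i] else NA_real_,
                 rad = spec@radiator)
      steadyState(h)
    })
    data.frame(
      house_id = seq_len(n), regime = regime, k = kk,
      setpoint = if (identical(regime, "thermostat")) setpoints else NA_real_,
      T_steady = vapply(states, `[[`, numeric(1), "temperature"),
      energy = vapply(states, `[[`, numeric(1), "energy"),
      mode = vapply(states, `[[`, character(1), "mode")
    )
  }
  thermo <- runTown(draws$kTherm, draws$s, "thermostat")
  rad <- runTown(draws$kRad, NULL, "radiator")
  corOf <- function(town) {
    if (stats::sd(town$T_steady) == 0 || stats::sd(town$energy) == 0)
      stop("correlation undefined: no variance across houses in town '",
           town$regime[1], "'", call. = FALSE)
    stats::cor(town$T_steady, town$energy)
  }
  list(
    correlations = c(thermostat = corOf(thermo), radiator = corOf(rad)),
    houses = rbind(thermo, rad)
  )
}

#' Export a two-towns house table to CSV
#'
#' @param towns result of [twoTowns()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
exportTownTable <- function(towns, path) {
  utils::write.csv(towns$houses, path, row.names = FALSE)
  invisible(path)
}

setMethod("show", "Radiator", function(object) {
  cat(sprintf("Radiator: %d elements of %g kW, thresholds %s degC\n",
              length(object@thresholds), object@power,
              paste(object@thresholds, collapse = "/")))
})

setMethod("show", "House", function(object) {
  cat(sprintf("House (%s): k = %g kW/degC, C = %g kWh/degC, T_ext = %g degC",
              object@regime, object@lossCoefficient, object@capacitance,
              object@externalTemp))
  if (identical(object@regime, "thermostat"))
    cat(sprintf(", setpoint = %g degC", object@setpoint))
  cat("\n")
})

setMethod("show", "TownSpec", function(object) {
  cat(sprintf(
    "TownSpec: %d houses/town, k ~ lognormal(%g, CV %g), S ~ N(%g, CV %g), T_ext = %g (seed %d)\n",
    object@nHouses, object@lossMean, object@lossCV, object@setpointMean,
    object@setpointCV, object@externalTemp, object@seed))
})
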