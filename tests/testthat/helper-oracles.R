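# Independent oracles and small fixture builders shared across tests.

# Reference feedback system with a fixed point constructed at (P, H) = (1, 1):
# f(1) = exp(1 - 1) = 1 and g(1) = 0.5 + 1 * 1/2 = 1.
demoSystem <- function(gain = 1) {
  feedbackSystem("demo",
    sensorCurve(alpha = 1, beta = 1, direction = "suppressive"),
    effectorCurve(p0 = 0.5, gain = gain, k = 1, direction = "stimulatory"))
}

# Raw curve arithmetic, independent of evaluateCurve()
rawSensor <- function(sys, P) {
  p <- curveParams(sensor(sys))
  s <- if (curveDirection(sensor(sys)) == "stimulatory") 1 else -1
  exp(p[["alpha"]] + s * p[["beta"]] * P)
}
rawEffector <- function(sys, H) {
  p <- curveParams(effector(sys))
  if (curveDirection(effector(sys)) == "stimulatory")
    p[["p0"]] + p[["gain"]] * H / (H + p[["k"]])
  else
    p[["p0"]] + p[["gain"]] * p[["k"]] / (H + p[["k"]])
}

# Grid-scan oracle for the fixed point of P -> g(f(P)): locate sign changes
# of g(f(P)) - P on a dense grid over the bracket [p0, p0 + gain].
gridScanOracle <- function(sys, nGrid = 2001L) {
  p <- curveParams(effector(sys))
  grid <- seq(p[["p0"]], p[["p0"]] + p[["gain"]], length.out = nGrid)
  grid[1] <- grid[1] + 1e-12  # effector output is open at the ends
  v <- rawEffector(sys, rawSensor(sys, grid)) - grid
  idx <- which(diff(sign(v)) != 0)
  list(nSignChanges = length(idx),
       bracketMid = if (length(idx)) (grid[idx] + grid[idx + 1]) / 2,
       step = grid[2] - grid[1])
}

# Random valid negative-feedback system (draws from the ambient RNG stream)
randomSystem <- function() {
  flip <- runif(1) < 0.5
  feedbackSystem("random",
    sensorCurve(alpha = runif(1, -1, 1.5), beta = runif(1, 0.3, 2),
                direction = if (flip) "suppressive" else "stimulatory"),
    effectorCurve(p0 = runif(1, 0, 1), gain = runif(1, 0.5, 3),
                  k = runif(1, 0.3, 3),
                  direction = if (flip) "stimulatory" else "suppressive"))
}

# Exhaustive step-enumeration oracle for the radiator-house heat balance:
# scan the net flux power*active(T) - k(T - T_ext) on a fine temperature grid
# and return the crossing (either inside a step or at a jump across zero).
heatBalanceOracle <- function(h, nGrid = 200001L) {
  rad <- h@radiator
  text <- h@externalTemp
  k <- h@lossCoefficient
  hi <- max(max(rad@thresholds) + 1,
            text + length(rad@thresholds) * rad@power / k + 1)
  grid <- seq(min(text, min(rad@thresholds) - 1), hi, length.out = nGrid)
  counts <- rowSums(outer(grid, rad@thresholds, `<`))
  net <- rad@power * counts - k * (grid - text)
  idx <- which(net[-length(net)] > 0 & net[-1] <= 0)[1]
  if (is.na(idx)) return(list(temperature = grid[1], energy = 0,
                              step = grid[2] - grid[1]))
  tStar <- (grid[idx] + grid[idx + 1]) / 2
  list(temperature = tStar, energy = k * (tStar - text),
       step = grid[2] - grid[1])
}

# Random radiator-regime house with moderate time constant
randomHouse <- function() {
  house(k = runif(1, 0.2, 1.2), capacitance = 2,
        externalTemp = runif(1, -5, 25), regime = "radiator")
}

tailMean <- function(x, frac = 0.2) mean(utils::tail(x, ceiling(frac * length(x))))
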