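#' Specify a synthetic cohort
#'
#' Builds a [PopulationSpec-class] with field defaults chosen for the
#' physiological regime the package models: interindividual variation
#' concentrated in the effector arm (CV 0.2 on each effector parameter),
#' reflecting tightly conserved hormone-response physiology, and — for the
#' set-point model — targets drawn with CV 0.1 around the template system's
#' own equilibrium level, independent of every effector draw.
#'
#' @param system template [FeedbackSystem-class].
#' @param n cohort size.
#' @param seed integer RNG seed.
#' @param model \code{"equilibrium"} or \code{"setpoint"}.
#' @param variationMode \code{"effector_dominant"} (sensor CVs forced to 0),
#'   \code{"sensor_dominant"} (effector CVs 0) or \code{"mixed"}.
#' @param sensorCV named numeric CVs (\code{alpha}, \code{beta}); a single
#'   unnamed value is recycled to both. Defaults: 0 under
#'   \code{effector_dominant}, 0.1 otherwise.
#' @param effectorCV named numeric CVs (\code{p0}, \code{gain}, \code{k}); a
#'   single unnamed value is recycled. Defaults: 0 under
#'   \code{sensor_dominant}, 0.2 otherwise.
#' @param setpointMean mean of the target distribution (set-point model);
#'   \code{NA} (default) uses the template system's equilibrium parameter
#'   level.
#' @param setpointCV CV of the target distribution (default 0.1).
#' @param epsilon truncation margin as a fraction of \code{gain}
#'   (default 0.05): targets are confined to
#'   \code{(p0 + eps*gain, p0 + (1-eps)*gain)}.
#' @return a validated [PopulationSpec-class].
#' @examples
#' populationSpec(predefinedSystem("calcium_pth"), n = 100, seed = 1)
#' @export
populationSpec <- function(system, n, seed,
                           model = c("equilibrium", "setpoint"),
                           variationMode = c("effector_dominant",
                                             "sensor_dominant", "mixed"),
                           sensorCV = NULL, effectorCV = NULL,
                           setpointMean = NA_real_, setpointCV = 0.1,
                           epsilon = 0.05) {
  model <- match.arg(model)
  variationMode <- match.arg(variationMode)
  expand <- function(cv, nms, default) {
    if (is.null(cv)) cv <- default
    if (is.null(names(cv)) && length(cv) == 1L)
      cv <- stats::setNames(rep(cv, length(nms)), nms)
    cv[nms]
  }
  sensorCV <- expand(sensorCV, c("alpha", "beta"),
    if (identical(variationMode, "effector_dominant")) 0 else 0.1)
  effectorCV <- expand(effectorCV, c("p0", "gain", "k"),
    if (identical(variationMode, "sensor_dominant")) 0 else 0.2)
  new("PopulationSpec", system = system, n = as.integer(n),
      seed = as.integer(seed), model = model, variationMode = variationMode,
      sensorCV = sensorCV, effectorCV = effectorCV,
      setpointMean = as.numeric(setpointMean), setpointCV = setpointCV,
      epsilon = epsilon)
}

# sdlog for a lognormal with the requested coefficient of variation
.cvSigma <- function(cv) sqrt(log1p(cv^2))

# Draw per-individual curve parameters with the ambient RNG stream.
# alpha varies additively on the log-intercept (i.e. the multiplicative scale
# exp(alpha) is lognormal); strictly positive parameters are drawn
# median-preserving lognormal around the template value.
.drawParametersRaw <- function(spec) {
  n <- spec@n
  co <- .systemCoefs(spec@system)
  scv <- spec@sensorCV; ecv <- spec@effectorCV
  drawPos <- function(template, cv) {
    if (cv == 0 || template == 0) rep(template, n)
    else stats::rlnorm(n, meanlog = log(template), sdlog = .cvSigma(cv))
  }
  for (try in seq_len(100L)) {
    d <- data.frame(
      id    = seq_len(n),
      alpha = co$alpha + stats::rnorm(n, 0, .cvSigma(scv[["alpha"]])),
      beta  = drawPos(co$beta, scv[["beta"]]),
      p0    = drawPos(co$p0, ecv[["p0"]]),
      gain  = drawPos(co$gain, ecv[["gain"]]),
      k     = drawPos(co$k, ecv[["k"]])
    )
    ok <- is.finite(d$alpha) & is.finite(d$beta) & d$beta > 0 &
      is.finite(d$p0) & d$p0 >= 0 & is.finite(d$gain) & d$gain > 0 &
      is.finite(d$k) & d$k > 0
    if (all(ok)) return(d)
  }
  stop("could not draw valid curve parameters after 100 attempts",
       call. = FALSE)
}

.individualFromDraw <- function(spec, draw) {
  feedbackSystem(
    name = spec@system@name,
    sensor = sensorCurve(draw$alpha, draw$beta,
                         direction = spec@system@sensor@direction,
                         domain = spec@system@sensor@domain),
    effector = effectorCurve(draw$p0, draw$gain, draw$k,
                             direction = spec@system@effector@direction,
                             domain = spec@system@effector@domain),
    parameterUnits = spec@system@parameterUnits,
    hormoneUnits = spec@system@hormoneUnits
  )
}

#' Draw a cohort of individuals around a template feedback system
#'
#' Each individual's curve parameters are drawn independently (log-normally,
#' median-preserving) around the template with the CVs in the spec; the
#' result is fully reproducible from the seed.
#'
#' @param spec a [PopulationSpec-class].
#' @return list of \code{spec@n} [FeedbackSystem-class] objects.
#' @examples
#' spec <- populationSpec(predefinedSystem("calcium_pth"), n = 3, seed = 7)
#' length(samplePopulation(spec))
#' @export
samplePopulation <- function(spec) {
  stopifnot(is(spec, "PopulationSpec"))
  draws <- withSeed(spec@seed, .drawParametersRaw(spec))
  lapply(seq_len(nrow(draws)),
         function(i) .individualFromDraw(spec, draws[i, ]))
}

#' Simulate a cohort under the equilibrium-point model
#'
#' Every individual's (P, H) pair is the intersection point of their own
#' sensor and effector curves. In \code{effector_dominant} mode all
#' individuals share the sensor curve exactly, so every point lies on it and
#' the cohort's parameter-hormone association is a perfect monotone relation
#' with the sign of the sensor direction (Spearman rho = -1 for calcium/PTH
#' and FT4/TSH, +1 for glucose/insulin).
#'
#' @param spec a [PopulationSpec-class] with \code{model = "equilibrium"}.
#' @param tolerance equilibrium solver tolerance (parameter units).
#' @return a [CohortSample-class].
#' @examples
#' spec <- populationSpec(predefinedSystem("glucose_insulin"),
#'                        n = 50, seed = 1)
#' samp <- simulateEquilibriumCohort(spec)
#' cor(cohortPairs(samp)$P, cohortPairs(samp)$H, method = "spearman")
#' @export
simulateEquilibriumCohort <- function(spec, tolerance = 1e-9) {
  stopifnot(is(spec, "PopulationSpec"))
  if (!identical(spec@model, "equilibrium"))
    stop("spec@model must be 'equilibrium'", call. = FALSE)
  draws <- withSeed(spec@seed, .drawParametersRaw(spec))
  co <- .systemCoefs(spec@system)
  sol <- tryCatch(
    .solveEquilibriumCore(draws$alpha, draws$beta, co$sensSign,
                          draws$p0, draws$gain, draws$k, co$effStim,
                          tolerance = tolerance),
    error = function(e) stop("equilibrium solve failed for cohort: ",
                             conditionMessage(e), call. = FALSE))
  pairs <- data.frame(id = draws$id, P = sol$P, H = sol$H)
  new("CohortSample", pairs = pairs, spec = spec, draws = draws)
}

# closed-form inversion of the hyperbolic effector on (p0, p0 + gain)
.invertEffector <- function(target, p0, gain, k, stimulatory) {
  if (stimulatory) k * (target - p0) / (p0 + gain - target)
  else             k * (p0 + gain - target) / (target - p0)
}

#' Simulate a cohort under the set-point model
#'
#' Each individual is assigned a target parameter level drawn independently
#' of their effector parameters (the set-point premise: targets are chosen
#' without regard to effector sensitivity). The effector arm is then "slaved"
#' to the target: the hormone level is obtained by closed-form inversion of
#' that individual's effector curve, so \code{P = target} and
#' \code{P = g(H)} hold exactly. Targets falling outside the invertible band
#' \code{(p0 + eps*gain, p0 + (1-eps)*gain)} are redrawn (at most 100 rounds).
#'
#' @param spec a [PopulationSpec-class] with \code{model = "setpoint"}.
#' @return a [CohortSample-class]; \code{parameterDraws()} includes the drawn
#'   \code{target}.
#' @examples
#' spec <- populationSpec(predefinedSystem("calcium_pth"), n = 100, seed = 1,
#'                        model = "setpoint")
#' samp <- simulateSetpointCohort(spec)
#' cor(cohortPairs(samp)$P, cohortPairs(samp)$H)  # positive under set points
#' @export
simulateSetpointCohort <- function(spec) {
  stopifnot(is(spec, "PopulationSpec"))
  if (!identical(spec@model, "setpoint"))
    stop("spec@model must be 'setpoint'", call. = FALSE)
  co <- .systemCoefs(spec@system)
  mu <- spec@setpointMean
  if (is.na(mu)) mu <- solveEquilibrium(spec@system)@pStar
  out <- withSeed(spec@seed, {
    draws <- .drawParametersRaw(spec)
    lo <- draws$p0 + spec@epsilon * draws$gain
    hi <- draws$p0 + (1 - spec@epsilon) * draws$gain
    target <- stats::rnorm(spec@n, mu, spec@setpointCV * mu)
    for (try in seq_len(100L)) {
      bad <- which(target <= lo | target >= hi)
      if (!length(bad)) break
      target[bad] <- stats::rnorm(length(bad), mu, spec@setpointCV * mu)
    }
    if (any(target <= lo | target >= hi))
      stop("set-point targets outside the invertible effector range ",
           "after 100 redraws", call. = FALSE)
    draws$target <- target
    draws
  })
  H <- .invertEffector(out$target, out$p0, out$gain, out$k, co$effStim)
  pairs <- data.frame(id = out$id, P = out$target, H = H)
  new("CohortSample", pairs = pairs, spec = spec, draws = out)
}

# -- accessors / coercion ---------------------------------------------------

#' @rdname accessors
#' @aliases cohortPairs,CohortSample-method
setMethod("cohortPairs", "CohortSample", function(x) x@pairs)
#' @rdname accessors
#' @aliases parameterDraws,CohortSample-method
setMethod("parameterDraws", "CohortSample", function(x) x@draws)

#' @export
as.data.frame.CohortSample <- function(x, ...) x@pairs

setMethod("show", "PopulationSpec", function(object) {
  cat(sprintf("PopulationSpec: %s model, %d individuals of '%s' (seed %d)\n",
              object@model, object@n, object@system@name, object@seed))
  cat(sprintf("  variation: %s; sensor CVs (%s); effector CVs (%s)\n",
              object@variationMode,
              paste(signif(object@sensorCV, 3), collapse = ", "),
              paste(signif(object@effectorCV, 3), collapse = ", ")))
})

setMethod("show", "CohortSample", function(object) {
  cat(sprintf("CohortSample: %d individuals, %s model of '%s' (seed %d)\n",
              nrow(object@pairs), object@spec@model, object@spec@system@name,
              object@spec@seed))
  print(utils::head(object@pairs, 4))
  if (nrow(object@pairs) > 4) cat("  ...\n")
})

#' Export a cohort sample to CSV
#'
#' Writes columns \code{id, P, H, model, seed}.
#'
#' @param cohort a [CohortSample-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
exportCohort <- function(cohort, path) {
  stopifnot(is(cohort, "CohortSample"))
  out <- cohort@pairs
  out$model <- cohort@spec@model
  out$seed <- cohort@spec@seed
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a population spec to a plain list / config file
#'
#' @param spec a [PopulationSpec-class].
#' @return \code{populationSpecToList}: a nested plain list.
#' @export
populationSpecToList <- function(spec) {
  stopifnot(is(spec, "PopulationSpec"))
  list(
    system = systemToList(spec@system),
    n = spec@n, seed = spec@seed, model = spec@model,
    variation_mode = spec@variationMode,
    sensor_cv = as.list(spec@sensorCV),
    effector_cv = as.list(spec@effectorCV),
    setpoint = list(mean = spec@setpointMean, cv = spec@setpointCV,
                    epsilon = spec@epsilon)
  )
}

#' @rdname populationSpecToList
#' @param config nested list as produced by \code{populationSpecToList}.
#' @return \code{populationSpecFromList}: a [PopulationSpec-class].
#' @export
populationSpecFromList <- function(config) {
  populationSpec(
    system = systemFromList(config$system),
    n = config$n, seed = config$seed, model = config$model,
    variationMode = config$variation_mode,
    sensorCV = unlist(config$sensor_cv),
    effectorCV = unlist(config$effector_cv),
    setpointMean = config$setpoint$mean %||% NA_real_,
    setpointCV = config$setpoint$cv %||% 0.1,
    epsilon = config$setpoint$epsilon %||% 0.05
  )
}
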