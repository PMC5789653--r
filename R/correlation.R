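#' Correlation between parameter and hormone levels in a cohort
#'
#' Thin wrapper around [stats::cor.test()] that accepts a
#' [CohortSample-class] or any two-column table of (P, H) pairs and enforces
#' the preconditions under which a cohort correlation is meaningful.
#'
#' @param x a [CohortSample-class], or a data.frame/matrix with columns
#'   \code{P} and \code{H} (or exactly two numeric columns).
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return list with components \code{r} (coefficient), \code{p} (two-sided
#'   p-value; t transform with n - 2 df for Pearson, large-sample
#'   approximation for Spearman), \code{n} and \code{method}.
#' @examples
#' cohortCorrelation(data.frame(P = c(0, 1, 2), H = c(0, 1, 2)))$r  # 1
#' @export
cohortCorrelation <- function(x, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is(x, "CohortSample")) x <- x@pairs
  x <- as.data.frame(x)
  if (all(c("P", "H") %in% names(x))) {
    p <- x$P; h <- x$H
  } else if (ncol(x) == 2L) {
    p <- x[[1]]; h <- x[[2]]
  } else {
    stop("need columns P and H (or exactly two columns)", call. = FALSE)
  }
  if (length(p) < 3L)
    stop("need at least 3 pairs to compute a correlation", call. = FALSE)
  if (stats::sd(p) == 0 || stats::sd(h) == 0)
    stop("correlation undefined: zero variance in P or H", call. = FALSE)
  ct <- stats::cor.test(p, h, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(p),
       method = method)
}

.knownSystems <- c("calcium_pth", "glucose_insulin", "ft4_tsh")

.dirSign <- function(direction) {
  if (identical(direction, "stimulatory")) 1L else -1L
}

#' Correlation sign implied by a regulation model
#'
#' Under a set-point model, targets are attained by adjusting the controlling
#' hormone, so across a population the parameter-hormone correlation must run
#' in the direction of the parameter's response to the hormone — the
#' \emph{effector} direction (positive for calcium/PTH and FT4/TSH, negative
#' for glucose/insulin). Under an equilibrium-point model with
#' interindividual variation concentrated in the effector arm, all
#' individuals sit on the shared sensor curve, so the correlation runs in the
#' direction of the hormone's response to the parameter — the \emph{sensor}
#' direction (signs reversed). For every negative-feedback system the two
#' implied signs are opposite.
#'
#' @param system a [FeedbackSystem-class] or the name of a predefined system.
#' @param model \code{"setpoint"} or \code{"equilibrium"}.
#' @return \code{+1L} or \code{-1L}.
#' @examples
#' impliedSign("calcium_pth", "setpoint")      # +1
#' impliedSign("calcium_pth", "equilibrium")   # -1
#' @export
impliedSign <- function(system, model = c("setpoint", "equilibrium")) {
  model <- match.arg(model)
  if (is.character(system)) {
    if (!system %in% .knownSystems)
      stop("unknown system '", system, "'; predefined systems are: ",
           paste(.knownSystems, collapse = ", "), call. = FALSE)
    system <- predefinedSystem(system)
  }
  stopifnot(is(system, "FeedbackSystem"))
  if (identical(model, "setpoint")) .dirSign(system@effector@direction)
  else .dirSign(system@sensor@direction)
}

.classifyOne <- function(r, implied) {
  if (r == 0) "indeterminate"
  else if (sign(r) == implied) "consistent"
  else "inconsistent"
}

#' Classify cohort correlation records against a regulation model
#'
#' A record is \code{consistent} when the sign of its coefficient equals the
#' model-implied sign for its system, \code{inconsistent} when opposite, and
#' \code{indeterminate} when the coefficient is exactly zero. Significance
#' labels are carried through but never alter the classification — records
#' are judged by the point-estimate sign alone.
#'
#' @param records data.frame of correlation records with at least columns
#'   \code{system} and \code{r} (see [readCorrelationTable()] for the full
#'   schema).
#' @param model \code{"setpoint"} or \code{"equilibrium"}.
#' @return the input with columns \code{implied_sign} and
#'   \code{classification} appended.
#' @export
classifyRecords <- function(records, model = c("setpoint", "equilibrium")) {
  model <- match.arg(model)
  records <- .validateRecords(records)
  records$implied_sign <- vapply(records$system, impliedSign,
                                 integer(1), model = model)
  records$classification <- mapply(.classifyOne, records$r,
                                   records$implied_sign)
  records
}

.validateRecords <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L)
    stop("empty correlation table", call. = FALSE)
  if (!all(c("system", "r") %in% names(records)))
    stop("correlation records need columns 'system' and 'r'", call. = FALSE)
  unknown <- setdiff(unique(records$system), .knownSystems)
  if (length(unknown))
    stop("unknown system(s) in correlation table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (any(!is.finite(records$r)) || any(abs(records$r) > 1))
    stop("coefficients must be finite and lie in [-1, 1]", call. = FALSE)
  records
}

#' Evaluate a table of cohort correlations under both regulation models
#'
#' Classifies every record under the set-point and the equilibrium-point
#' model and tallies the classifications. Because the two models imply
#' opposite signs for every negative-feedback system, no record can be
#' consistent with both.
#'
#' @param records data.frame of correlation records (see
#'   [readCorrelationTable()]); defaults to the bundled table of published
#'   calcium/PTH and glucose/insulin cohort correlations.
#' @return a [ConsistencyReport-class].
#' @examples
#' rep <- evaluateTable(correlationFixture())
#' consistencyCounts(rep)
#' @export
evaluateTable <- function(records = correlationFixture()) {
  records <- .validateRecords(records)
  out <- records
  classes <- c("consistent", "inconsistent", "indeterminate")
  counts <- matrix(0L, nrow = 2, ncol = 3,
                   dimnames = list(c("setpoint", "equilibrium"), classes))
  for (model in rownames(counts)) {
    cl <- classifyRecords(records, model)
    out[[paste0(model, "_sign")]] <- cl$implied_sign
    out[[paste0(model, "_class")]] <- cl$classification
    tab <- table(factor(cl$classification, levels = classes))
    counts[model, ] <- as.integer(tab)
  }
  systems <- intersect(.knownSystems, unique(records$system))
  implied <- data.frame(
    system = systems,
    setpoint = vapply(systems, impliedSign, integer(1), model = "setpoint"),
    equilibrium = vapply(systems, impliedSign, integer(1),
                         model = "equilibrium"),
    row.names = NULL
  )
  new("ConsistencyReport", records = out, counts = counts,
      impliedSigns = implied)
}

#' @rdname accessors
#' @aliases consistencyCounts,ConsistencyReport-method
setMethod("consistencyCounts", "ConsistencyReport", function(x) x@counts)

#' @export
as.data.frame.ConsistencyReport <- function(x, ...) x@records

setMethod("show", "ConsistencyReport", function(object) {
  n <- nrow(object@records)
  cat(sprintf("ConsistencyReport over %d correlation record%s\n",
              n, if (n == 1) "" else "s"))
  for (model in rownames(object@counts)) {
    cat(sprintf("  %-11s: %d consistent, %d inconsistent, %d indeterminate\n",
                model,
                object@counts[model, "consistent"],
                object@counts[model, "inconsistent"],
                object@counts[model, "indeterminate"]))
  }
})

#' Read a table of cohort correlation records
#'
#' CSV schema: \code{system} (one of \code{calcium_pth},
#' \code{glucose_insulin}, \code{ft4_tsh}), \code{source} (study label),
#' \code{subgroup} (e.g. sex/menopausal status), \code{n} (cohort size),
#' \code{r} (coefficient in \[-1, 1\]), \code{method} (\code{pearson},
#' \code{spearman} or \code{unspecified}), \code{transform}
#' (\code{identity} or \code{log}, the hormone transform used by the source),
#' \code{significance} (free-text label such as \code{"P<0.01"} or
#' \code{"NS"}).
#'
#' @param path CSV file path.
#' @return validated data.frame of records.
#' @export
readCorrelationTable <- function(path) {
  if (!file.exists(path))
    stop("correlation table not found: ", path,
         " (expected a CSV of cohort correlation records)", call. = FALSE)
  .validateRecords(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Bundled table of published cohort correlations
#'
#' The ten cohort-level parameter/hormone correlations the package evaluates:
#' five calcium/PTH subgroups from two studies (Jorde et al., Minisola et
#' al.) and five glucose/insulin subgroups from three studies (Gibson et al.,
#' Peplies et al., Chen et al.), transcribed with cohort sizes, coefficient
#' method and hormone transform where the sources state them.
#'
#' @return data.frame of 10 correlation records.
#' @examples
#' nrow(correlationFixture())
#' @export
correlationFixture <- function() {
  readCorrelationTable(system.file("extdata", "table1_correlations.csv",
                                   package = "equipoint", mustWork = TRUE))
}
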