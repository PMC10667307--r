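#' @import methods
NULL

## Controlled vocabularies -----------------------------------------------

#' The ten modeled functional groups
#'
#' Group names, in the fixed alphabetical order used throughout the package
#' for count vectors, feature matrices and CSV output.
#'
#' @return Character vector of length 10.
#' @export
#' @examples
#' fragmentGroups()
fragmentGroups <- function() {
  c("amide", "amine", "aromatic", "bromine", "carboxylic_acid",
    "chlorine", "ester", "ether", "hydroxyl", "ketone")
}

#' The seven excluded ("unusual") functional groups
#'
#' Compounds carrying any of these groups are flagged ineligible for the
#' published fragment models: too few training examples carried them for a
#' reliable contribution to be estimated.
#'
#' @return Character vector of length 7.
#' @export
excludedGroups <- function() {
  c("boron", "cyanide", "epoxide", "fluorine", "nitro", "phosphate", "thiol")
}

.SCENARIO_VOCAB <- list(
  source  = c("abdomen", "breast", "thigh"),
  layer   = c("epidermis", "dermis", "epidermis+dermis", "stratum_corneum"),
  donor   = c("diluted", "saturated"),
  tempBin = c("20-25", "26-30", "31-35", "36-40")
)

## FragmentProfile --------------------------------------------------------

#' FragmentProfile: functional-group counts for one molecule
#'
#' Counts of the ten modeled functional groups (always all ten keys,
#' zero-filled) plus the subset of the seven excluded groups present. A
#' non-empty \code{excluded} slot marks the compound ineligible for the
#' published fragment models.
#'
#' @slot counts Named integer vector over exactly \code{fragmentGroups()}.
#' @slot excluded Character vector, subset of \code{excludedGroups()}.
#'
#' @export
setClass("FragmentProfile",
  representation(counts = "integer", excluded = "character"),
  prototype(
    counts = structure(integer(10), names = c("amide", "amine", "aromatic",
      "bromine", "carboxylic_acid", "chlorine", "ester", "ether",
      "hydroxyl", "ketone")),
    excluded = character(0)
  )
)

setValidity("FragmentProfile", function(object) {
  msgs <- character(0)
  if (!identical(sort(names(object@counts)), fragmentGroups()))
    msgs <- c(msgs, "counts must be named over exactly the ten modeled groups")
  if (anyNA(object@counts) || any(object@counts < 0L))
    msgs <- c(msgs, "counts must be non-negative integers")
  if (!all(object@excluded %in% excludedGroups()))
    msgs <- c(msgs, "excluded must be a subset of the seven excluded groups")
  if (anyDuplicated(object@excluded))
    msgs <- c(msgs, "excluded group names must be unique")
  if (length(msgs)) msgs else TRUE
})

## ScenarioKey ------------------------------------------------------------

#' ScenarioKey: one of the 96 experimental scenarios
#'
#' Identifies a combination of skin source (3) x skin layer (4) x donor
#' concentration class (2) x donor temperature bin (4) = 96 scenarios under
#' which permeability was measured; 27 carried enough data (n > 1) to fit a
#' scenario model.
#'
#' @slot source One of abdomen, breast, thigh.
#' @slot layer One of epidermis, dermis, epidermis+dermis, stratum_corneum.
#' @slot donor One of diluted, saturated.
#' @slot tempBin One of 20-25, 26-30, 31-35, 36-40 (degrees C, closed bins).
#'
#' @export
setClass("ScenarioKey",
  representation(source = "character", layer = "character",
                 donor = "character", tempBin = "character"))

setValidity("ScenarioKey", function(object) {
  msgs <- character(0)
  for (f in names(.SCENARIO_VOCAB)) {
    v <- slot(object, f)
    if (length(v) != 1L || is.na(v) || !(v %in% .SCENARIO_VOCAB[[f]]))
      msgs <- c(msgs, sprintf("%s must be one of: %s", f,
                              paste(.SCENARIO_VOCAB[[f]], collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

setClassUnion("ScenarioKeyOrNULL", c("ScenarioKey", "NULL"))

## FragmentModel ----------------------------------------------------------

#' FragmentModel: a group-contribution equation for logKp
#'
#' An intercept (the predicted logKp when no modeled group is present) plus
#' one additive contribution per occurrence of each functional group, on the
#' log10 cm/s scale. Groups absent from \code{coefficients} contribute zero.
#'
#' @slot name Model identifier.
#' @slot intercept Numeric scalar, log10 cm/s.
#' @slot coefficients Named numeric vector; names a subset of
#'   \code{fragmentGroups()}.
#' @slot provenance Free-text provenance (table row, n, R-squared as printed).
#' @slot scenario Optional \linkS4class{ScenarioKey}.
#'
#' @export
setClass("FragmentModel",
  representation(name = "character", intercept = "numeric",
                 coefficients = "numeric", provenance = "character",
                 scenario = "ScenarioKeyOrNULL"),
  prototype(name = "unnamed", intercept = NA_real_,
            coefficients = structure(numeric(0), names = character(0)),
            provenance = "", scenario = NULL))

setValidity("FragmentModel", function(object) {
  msgs <- character(0)
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msgs <- c(msgs, "intercept must be a finite numeric scalar")
  cf <- object@coefficients
  if (length(cf) && (is.null(names(cf)) || !all(names(cf) %in% fragmentGroups())))
    msgs <- c(msgs, "coefficient names must be among the ten modeled groups")
  if (anyNA(cf))
    msgs <- c(msgs, "coefficients must not contain NA")
  if (length(msgs)) msgs else TRUE
})

## ComparatorModel --------------------------------------------------------

#' ComparatorModel: a logKow/MW permeability equation
#'
#' Linear comparator of the form
#' \code{logKp = intercept + logKowCoeff * logKow + mwCoeff * MW}, on the
#' log10 cm/h scale used by the regulatory screening equations (DERMWIN,
#' Potts & Guy). Convert with \code{\link{convertLogKpPerHourToPerSecond}}
#' before comparing against fragment-model output.
#'
#' @slot name Model identifier.
#' @slot intercept,logKowCoeff,mwCoeff Numeric scalars (log10 cm/h scale).
#'
#' @export
setClass("ComparatorModel",
  representation(name = "character", intercept = "numeric",
                 logKowCoeff = "numeric", mwCoeff = "numeric"))

setValidity("ComparatorModel", function(object) {
  ok <- vapply(c(object@intercept, object@logKowCoeff, object@mwCoeff),
               function(v) length(v) == 1L && is.finite(v), logical(1))
  if (all(ok)) TRUE else "intercept, logKowCoeff, mwCoeff must be finite scalars"
})

## FitResult --------------------------------------------------------------

#' FitResult: one ordinary-least-squares fit
#'
#' Output of \code{\link{fitOLS}}: the coefficient vector solving the normal
#' equations, the maximum-likelihood residual standard deviation, the
#' diagonal of (X'X)^-1 needed by the significance criterion, fit statistics
#' and per-coefficient significance flags.
#'
#' @slot coefficients Named numeric, intercept first.
#' @slot labels Fragment-group names of the non-intercept columns.
#' @slot sigmaHat MLE residual sd: sqrt(SSE / m).
#' @slot sigmaHatUnbiased sqrt(SSE / (m - k - 1)).
#' @slot cjj Diagonal of (X'X)^-1, length k + 1.
#' @slot sse Residual sum of squares (the minimised objective).
#' @slot rSquared 1 - SSE/SST on the training data.
#' @slot rmse sqrt(SSE / m).
#' @slot fStat,fPvalue Overall-regression ANOVA F and its upper-tail p.
#' @slot df Degrees of freedom used by the t criterion.
#' @slot thresholds Per-coefficient significance thresholds.
#' @slot significant Logical flags: |coefficient| at or above its threshold.
#' @slot m,k Number of observations and of fragment terms.
#' @slot alpha Significance level used for the flags.
#'
#' @export
setClass("FitResult",
  representation(coefficients = "numeric", labels = "character",
                 sigmaHat = "numeric", sigmaHatUnbiased = "numeric",
                 cjj = "numeric", sse = "numeric", rSquared = "numeric",
                 rmse = "numeric", fStat = "numeric", fPvalue = "numeric",
                 df = "numeric", thresholds = "numeric",
                 significant = "logical", m = "integer", k = "integer",
                 alpha = "numeric"))

setValidity("FitResult", function(object) {
  msgs <- character(0)
  if (length(object@coefficients) != object@k + 1L)
    msgs <- c(msgs, "coefficients must have length k + 1")
  if (length(object@cjj) != object@k + 1L)
    msgs <- c(msgs, "cjj must have length k + 1")
  if (is.finite(object@sse) && object@sse < -1e-8)
    msgs <- c(msgs, "sse must be non-negative")
  if (length(msgs)) msgs else TRUE
})

## EliminationTrace -------------------------------------------------------

#' EliminationTrace: record of one top-down elimination run
#'
#' @slot steps data.frame with one row per removed term: term, coefficient,
#'   tRatio (|coefficient| / threshold at removal) and modelSizeAfter.
#' @slot finalFit \linkS4class{FitResult} of the surviving model.
#' @slot finalLabels Fragment groups retained in the final model.
#'
#' @export
setClass("EliminationTrace",
  representation(steps = "data.frame", finalFit = "FitResult",
                 finalLabels = "character"))

## show methods -----------------------------------------------------------

setMethod("show", "FragmentProfile", function(object) {
  nz <- object@counts[object@counts > 0L]
  cat("FragmentProfile:",
      if (length(nz)) paste(names(nz), nz, sep = "=", collapse = ", ")
      else "no modeled groups", "\n")
  if (length(object@excluded))
    cat("  excluded groups present:",
        paste(object@excluded, collapse = ", "), "\n")
})

setMethod("show", "ScenarioKey", function(object) {
  cat(sprintf("ScenarioKey: %s / %s / %s / %s degC\n",
              object@source, object@layer, object@donor, object@tempBin))
})

setMethod("show", "FragmentModel", function(object) {
  cat(sprintf("FragmentModel '%s': logKp = %.3f", object@name,
              object@intercept))
  cf <- object@coefficients
  if (length(cf))
    cat("", paste(sprintf("%+.3f (%s)", cf, names(cf)), collapse = " "))
  cat("\n")
  if (!is.null(object@scenario)) show(object@scenario)
  if (nzchar(object@provenance)) cat("  ", object@provenance, "\n", sep = "")
})

setMethod("show", "ComparatorModel", function(object) {
  cat(sprintf("ComparatorModel '%s': logKp (cm/h) = %.4g %+.4g logKow %+.4g MW\n",
              object@name, object@intercept, object@logKowCoeff,
              object@mwCoeff))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: m = %d, k = %d\n", object@m, object@k))
  tab <- data.frame(coefficient = round(object@coefficients, 4),
                    threshold = round(object@thresholds, 4),
                    significant = object@significant)
  print(tab)
  cat(sprintf("sigma-hat %.4g | R2 %.4f | RMSE %.4g | F %.4g (p %.3g)\n",
              object@sigmaHat, object@rSquared, object@rmse, object@fStat,
              object@fPvalue))
})

setMethod("show", "EliminationTrace", function(object) {
  cat(sprintf("EliminationTrace: %d term(s) removed\n", nrow(object@steps)))
  if (nrow(object@steps)) print(object@steps)
  cat("final terms:",
      if (length(object@finalLabels)) paste(object@finalLabels, collapse = ", ")
      else "(intercept only)", "\n")
})

## Constructors and accessors ---------------------------------------------

#' Construct a FragmentProfile from counts
#'
#' @param counts Named numeric/integer vector; missing groups are zero-filled.
#' @param excluded Character vector of excluded-group names present.
#' @return A \linkS4class{FragmentProfile}.
#' @export
#' @examples
#' FragmentProfile(c(aromatic = 1, hydroxyl = 1))  # phenol
FragmentProfile <- function(counts = integer(0), excluded = character(0)) {
  full <- structure(integer(10), names = fragmentGroups())
  if (length(counts)) {
    bad <- setdiff(names(counts), fragmentGroups())
    if (length(bad))
      stop("unknown fragment group(s): ", paste(bad, collapse = ", "))
    full[names(counts)] <- as.integer(counts)
  }
  new("FragmentProfile", counts = full, excluded = as.character(excluded))
}

#' @describeIn FragmentProfile-class Named integer count vector (all ten groups).
#' @param object A FragmentProfile.
#' @export
setGeneric("fragmentCounts", function(object) standardGeneric("fragmentCounts"))

#' @rdname FragmentProfile-class
#' @export
setMethod("fragmentCounts", "FragmentProfile", function(object) object@counts)

#' @describeIn FragmentProfile-class Excluded groups detected in the molecule.
#' @export
setGeneric("excludedIn", function(object) standardGeneric("excludedIn"))

#' @rdname FragmentProfile-class
#' @export
setMethod("excludedIn", "FragmentProfile", function(object) object@excluded)

#' @describeIn FragmentProfile-class TRUE if no excluded group is present, so
#'   the published fragment models apply.
#' @export
setGeneric("isEligible", function(object) standardGeneric("isEligible"))

#' @rdname FragmentProfile-class
#' @export
setMethod("isEligible", "FragmentProfile",
          function(object) length(object@excluded) == 0L)

#' Construct a ScenarioKey
#'
#' @param source Skin source: abdomen, breast or thigh.
#' @param layer Skin layer: epidermis, dermis, epidermis+dermis or
#'   stratum_corneum.
#' @param donor Donor concentration class: diluted or saturated.
#' @param tempBin Temperature bin: one of "20-25", "26-30", "31-35", "36-40".
#' @return A \linkS4class{ScenarioKey}.
#' @export
#' @examples
#' ScenarioKey("abdomen", "epidermis", "diluted", "31-35")
ScenarioKey <- function(source, layer, donor, tempBin) {
  new("ScenarioKey", source = source, layer = layer, donor = donor,
      tempBin = tempBin)
}

#' Construct a FragmentModel
#'
#' @param name Identifier.
#' @param intercept Numeric scalar, log10 cm/s.
#' @param coefficients Named numeric vector of per-group contributions.
#' @param provenance Free-text provenance string.
#' @param scenario Optional \linkS4class{ScenarioKey}.
#' @return A \linkS4class{FragmentModel}.
#' @export
#' @examples
#' FragmentModel("toy", -6, c(hydroxyl = -0.5))
FragmentModel <- function(name, intercept, coefficients = numeric(0),
                          provenance = "", scenario = NULL) {
  new("FragmentModel", name = name, intercept = as.numeric(intercept),
      coefficients = coefficients, provenance = provenance,
      scenario = scenario)
}

#' All 96 valid scenario keys as strings
#'
#' @return Character vector of length 96, "source/layer/donor/tempBin".
#' @export
allScenarioKeys <- function() {
  g <- expand.grid(tempBin = .SCENARIO_VOCAB$tempBin,
                   donor = .SCENARIO_VOCAB$donor,
                   layer = .SCENARIO_VOCAB$layer,
                   source = .SCENARIO_VOCAB$source,
                   stringsAsFactors = FALSE)
  sort(paste(g$source, g$layer, g$donor, g$tempBin, sep = "/"))
}

#' @describeIn ScenarioKey-class Canonical "source/layer/donor/tempBin" string.
#' @param key A ScenarioKey.
#' @export
scenarioString <- function(key) {
  stopifnot(is(key, "ScenarioKey"))
  paste(key@source, key@layer, key@donor, key@tempBin, sep = "/")
}
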