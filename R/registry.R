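## Registry of the published models: the global equation (eq1), the selected
## scenario equation (eq2), the 27 scenario-stratified models, and the
## DERMWIN comparator. All constants live in one plain-text DCF file
## (inst/extdata/models.dcf) so the transcription can be proofread line by
## line against the published table.

.registryEnv <- new.env(parent = emptyenv())

.parseRegistry <- function(path) {
  raw <- read.dcf(path)
  models <- list()
  for (i in seq_len(nrow(raw))) {
    rec <- raw[i, ]
    rec <- rec[!is.na(rec)]
    nm <- rec[["name"]]
    type <- rec[["type"]]
    if (type == "comparator") {
      models[[nm]] <- new("ComparatorModel", name = nm,
                          intercept = as.numeric(rec[["intercept"]]),
                          logKowCoeff = as.numeric(rec[["logkow_coeff"]]),
                          mwCoeff = as.numeric(rec[["mw_coeff"]]))
      next
    }
    scen <- NULL
    if (all(c("source", "layer", "donor", "temp_bin") %in% names(rec)))
      scen <- ScenarioKey(rec[["source"]], rec[["layer"]], rec[["donor"]],
                          rec[["temp_bin"]])
    cfNames <- intersect(names(rec), fragmentGroups())
    cf <- structure(as.numeric(rec[cfNames]), names = cfNames)
    prov <- if ("provenance" %in% names(rec)) rec[["provenance"]] else sprintf(
      "scenario model%s%s",
      if ("n" %in% names(rec)) paste0(", n=", rec[["n"]]) else "",
      if ("r_squared" %in% names(rec))
        paste0(", R2=", rec[["r_squared"]]) else ", R2 not applicable")
    if ("note" %in% names(rec)) prov <- paste0(prov, "; ", rec[["note"]])
    models[[nm]] <- FragmentModel(nm, as.numeric(rec[["intercept"]]),
                                  coefficients = cf, provenance = prov,
                                  scenario = scen)
  }
  models
}

#' The registry of published permeability models
#'
#' Parses the bundled plain-text model file once per session and caches it.
#'
#' @param path Optional path to an alternative registry file in the same DCF
#'   format.
#' @return Named list of \linkS4class{FragmentModel} /
#'   \linkS4class{ComparatorModel} objects: \code{eq1}, \code{eq2},
#'   \code{dermwin} and \code{scenario_01} .. \code{scenario_27}.
#' @export
#' @examples
#' names(modelRegistry())[1:3]
modelRegistry <- function(path = NULL) {
  if (!is.null(path)) return(.parseRegistry(path))
  if (is.null(.registryEnv$models)) {
    p <- system.file("extdata", "models.dcf", package = "fragkin")
    if (!nzchar(p)) p <- file.path("inst", "extdata", "models.dcf")
    .registryEnv$models <- .parseRegistry(p)
  }
  .registryEnv$models
}

#' Fetch one registered model by name
#'
#' @param name Registry name, e.g. \code{"eq1"}, \code{"eq2"},
#'   \code{"dermwin"}, \code{"scenario_10"}.
#' @return The registered model object.
#' @export
getModel <- function(name) {
  reg <- modelRegistry()
  if (!name %in% names(reg))
    stop("no registered model named '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  reg[[name]]
}

#' Look up the scenario model for an experimental condition
#'
#' @param key A \linkS4class{ScenarioKey} or its "source/layer/donor/tempBin"
#'   string form.
#' @return The matching \linkS4class{FragmentModel}, or \code{NULL} when none
#'   of the 27 fitted scenarios matches (not-found is a value, not an error).
#' @export
#' @examples
#' lookupScenario(ScenarioKey("abdomen", "epidermis", "diluted", "31-35"))
lookupScenario <- function(key) {
  ks <- if (is(key, "ScenarioKey")) scenarioString(key) else as.character(key)
  if (!ks %in% allScenarioKeys())
    stop("'", ks, "' is not one of the 96 valid scenario keys")
  reg <- modelRegistry()
  for (m in reg) {
    if (is(m, "FragmentModel") && !is.null(m@scenario) &&
        startsWith(m@name, "scenario_") && scenarioString(m@scenario) == ks)
      return(m)
  }
  NULL
}

## Prediction --------------------------------------------------------------

#' Predict logKp from a fragment model
#'
#' \code{intercept + sum_g coefficient(g) * count(g)}: each occurrence of a
#' group adds its contribution once (two aromatic rings add the aromatic
#' contribution twice). Groups absent from the model contribute zero.
#'
#' @param model A \linkS4class{FragmentModel}.
#' @param profile A \linkS4class{FragmentProfile}, a named count vector, or a
#'   count matrix (one row per compound, columns named by group).
#' @param warnExcluded Warn when the profile carries excluded groups (the
#'   published models were trained without such compounds). The prediction is
#'   still returned.
#' @return Numeric: predicted logKp in log10 cm/s.
#' @export
#' @examples
#' predictLogKp(getModel("eq2"), countFragments("Clc1ccccc1"))
setGeneric("predictLogKp", function(model, profile, ...)
  standardGeneric("predictLogKp"))

#' @rdname predictLogKp
#' @param ... Passed between methods.
#' @export
setMethod("predictLogKp", signature("FragmentModel", "FragmentProfile"),
  function(model, profile, warnExcluded = TRUE) {
    if (warnExcluded && !isEligible(profile))
      warning("profile carries excluded group(s) (",
              paste(profile@excluded, collapse = ", "),
              "); the published models do not cover such compounds")
    .predictCounts(model, profile@counts)
  })

#' @rdname predictLogKp
#' @export
setMethod("predictLogKp", signature("FragmentModel", "numeric"),
  function(model, profile, ...) .predictCounts(model, profile))

#' @rdname predictLogKp
#' @export
setMethod("predictLogKp", signature("FragmentModel", "matrix"),
  function(model, profile, ...) {
    apply(profile, 1L, function(r) .predictCounts(model, r))
  })

.predictCounts <- function(model, counts) {
  cf <- model@coefficients
  if (length(cf)) {
    missing <- setdiff(names(cf), names(counts))
    if (length(missing))
      stop("counts lack group(s): ", paste(missing, collapse = ", "))
    model@intercept + sum(cf * counts[names(cf)])
  } else {
    model@intercept
  }
}

#' DERMWIN comparator prediction
#'
#' logKp (cm/h) = intercept + 0.66 logKow - 0.0056 MW with the transcribed
#' screening-equation constants; override \code{model} for a user-supplied
#' comparator such as Potts & Guy (whose constants are not bundled and must
#' be supplied from the cited source).
#'
#' @param logKow Octanol-water partition coefficient (log10).
#' @param mw Molecular weight, g/mol.
#' @param model A \linkS4class{ComparatorModel}; default the bundled DERMWIN
#'   constants.
#' @return Predicted logKp on the log10 cm/h scale (note the unit).
#' @export
#' @examples
#' dermwinLogKp(1, 100)
dermwinLogKp <- function(logKow, mw, model = getModel("dermwin")) {
  stopifnot(is(model, "ComparatorModel"),
            all(is.finite(logKow)), all(is.finite(mw)))
  model@intercept + model@logKowCoeff * logKow + model@mwCoeff * mw
}

#' Build a user-supplied comparator model
#'
#' @param name Identifier.
#' @param intercept,logKowCoeff,mwCoeff Constants on the log10 cm/h scale.
#' @return A \linkS4class{ComparatorModel}.
#' @export
comparatorModel <- function(name, intercept, logKowCoeff, mwCoeff) {
  new("ComparatorModel", name = name, intercept = as.numeric(intercept),
      logKowCoeff = as.numeric(logKowCoeff), mwCoeff = as.numeric(mwCoeff))
}

#' Convert logKp between cm/h and cm/s scales
#'
#' Kp in cm/s = Kp in cm/h / 3600, so logKp shifts by -log10(3600). The
#' comparator equations print cm/h; the fragment models and the permeability
#' database use cm/s.
#'
#' @param logkp Numeric vector.
#' @return Converted values.
#' @export
#' @examples
#' convertLogKpPerHourToPerSecond(0)   # -log10(3600)
convertLogKpPerHourToPerSecond <- function(logkp) logkp - log10(3600)

#' @rdname convertLogKpPerHourToPerSecond
#' @export
convertLogKpPerSecondToPerHour <- function(logkp) logkp + log10(3600)

#' Mean-baseline model
#'
#' A constant model whose intercept is the arithmetic mean of the observed
#' logKp values and whose coefficients are all zero: the floor any fragment
#' model must beat. Its RMSE on the data it was built from equals the
#' population standard deviation of those values.
#'
#' @param logkp Numeric vector of observed logKp (length >= 1).
#' @param name Model name.
#' @return A constant \linkS4class{FragmentModel}.
#' @export
#' @examples
#' meanBaselineModel(c(-5, -7))
meanBaselineModel <- function(logkp, name = "mean_baseline") {
  logkp <- as.numeric(logkp)
  if (length(logkp) == 0L || anyNA(logkp))
    stop("need at least one finite logKp value")
  FragmentModel(name, intercept = mean(logkp),
                provenance = sprintf("mean of %d observations", length(logkp)))
}
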