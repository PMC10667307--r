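## Reader and record-selection rules for permeability tables in a documented
## HuskinDB-style CSV schema:
##   compound, smiles, logkp (or kp_cm_s), source, layer, donor,
##   temperature_c, ph, reference
## plus the selection rules used to reduce the database to one value per
## compound and to stratify records over the 96 experimental scenarios.

.SCHEMA_MANDATORY <- c("compound", "source", "layer", "donor", "temperature_c")

.normalizeSource <- function(x) {
  x <- tolower(trimws(x))
  ifelse(x %in% c("abdomen", "abdominal"), "abdomen",
  ifelse(x %in% c("breast"), "breast",
  ifelse(x %in% c("thigh", "leg"), "thigh", NA_character_)))
}

.normalizeLayer <- function(x) {
  x <- gsub("\\s+", "", tolower(trimws(x)))
  ifelse(x %in% c("epidermis"), "epidermis",
  ifelse(x %in% c("dermis"), "dermis",
  ifelse(x %in% c("epidermis+dermis", "epidermisdermis", "epidermis&dermis"),
         "epidermis+dermis",
  ifelse(x %in% c("stratumcorneum", "stratum_corneum", "sc"),
         "stratum_corneum", NA_character_))))
}

## "neat"/"concentrated" are the saturated class: the source vocabularies
## vary (neat/diluted, concentrated solute, Saturated) but describe the same
## two donor classes.
.normalizeDonor <- function(x) {
  x <- tolower(trimws(x))
  ifelse(x %in% c("diluted", "dilute"), "diluted",
  ifelse(x %in% c("saturated", "neat", "concentrated"), "saturated",
         NA_character_))
}

#' Map a donor temperature to its bin
#'
#' The printed bins (20-25, 26-30, 31-35, 36-40 degrees C) tile the integers,
#' so temperatures are rounded to the nearest integer first; values outside
#' 20-40 after rounding are unmapped (NA).
#'
#' @param temperature Numeric vector, degrees C.
#' @return Character vector of bin labels or NA.
#' @export
#' @examples
#' temperatureBin(c(32, 25.4, 19))
temperatureBin <- function(temperature) {
  t <- round(as.numeric(temperature))
  ifelse(!is.finite(t), NA_character_,
  ifelse(t >= 20 & t <= 25, "20-25",
  ifelse(t >= 26 & t <= 30, "26-30",
  ifelse(t >= 31 & t <= 35, "31-35",
  ifelse(t >= 36 & t <= 40, "36-40", NA_character_)))))
}

#' Read permeability records from CSV
#'
#' Header matching is case-insensitive. Kp may be given as \code{logkp}
#' (log10 cm/s) or as \code{kp_cm_s} (linear cm/s, log10-converted on load).
#' Rows failing validation (non-numeric or out-of-range temperature,
#' non-finite logKp, missing compound) are collected into a rejects report,
#' never silently dropped; rows whose scenario labels do not normalize are
#' kept but flagged \code{mapped = FALSE}.
#'
#' @param path CSV file path.
#' @return List: \code{records} (data.frame with normalized columns compound,
#'   smiles, logkp, source, layer, donor, temperature_c, temp_bin, ph,
#'   reference, mapped, plus any extra input columns), and \code{rejects}
#'   (data.frame: row, reason).
#' @export
readRecords <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(raw) <- tolower(trimws(names(raw)))
  missing <- setdiff(.SCHEMA_MANDATORY, names(raw))
  if (!("logkp" %in% names(raw) || "kp_cm_s" %in% names(raw)))
    missing <- c(missing, "logkp (or kp_cm_s)")
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))

  n <- nrow(raw)
  rejects <- data.frame(row = integer(0), reason = character(0),
                        stringsAsFactors = FALSE)
  addReject <- function(rows, reason) {
    if (length(rows))
      rejects <<- rbind(rejects, data.frame(row = rows, reason = reason,
                                            stringsAsFactors = FALSE))
  }

  logkp <- if ("logkp" %in% names(raw))
    suppressWarnings(as.numeric(raw$logkp)) else rep(NA_real_, n)
  if ("kp_cm_s" %in% names(raw)) {
    kp <- suppressWarnings(as.numeric(raw$kp_cm_s))
    use <- is.na(logkp) & !is.na(kp) & kp > 0
    logkp[use] <- log10(kp[use])
  }
  temp <- suppressWarnings(as.numeric(raw$temperature_c))
  ph <- if ("ph" %in% names(raw))
    suppressWarnings(as.numeric(raw$ph)) else rep(NA_real_, n)

  bad <- !is.finite(logkp)
  addReject(which(bad), "logkp missing or not finite")
  badT <- !is.finite(temp) | temp < 0 | temp > 50
  addReject(which(badT & !bad), "temperature missing, non-numeric or outside 0-50")
  badC <- is.na(raw$compound) | !nzchar(trimws(as.character(raw$compound)))
  addReject(which(badC & !bad & !badT), "missing compound identifier")
  keep <- !(bad | badT | badC)

  rec <- data.frame(
    compound = as.character(raw$compound),
    smiles = if ("smiles" %in% names(raw)) as.character(raw$smiles)
             else NA_character_,
    logkp = logkp,
    source = .normalizeSource(raw$source),
    layer = .normalizeLayer(raw$layer),
    donor = .normalizeDonor(raw$donor),
    temperature_c = temp,
    ph = ph,
    reference = if ("reference" %in% names(raw)) as.character(raw$reference)
                else NA_character_,
    stringsAsFactors = FALSE)
  rec$temp_bin <- temperatureBin(rec$temperature_c)
  rec$mapped <- !is.na(rec$source) & !is.na(rec$layer) & !is.na(rec$donor) &
    !is.na(rec$temp_bin)
  extra <- setdiff(names(raw), c(names(rec), "kp_cm_s"))
  for (col in extra) rec[[col]] <- raw[[col]]
  list(records = rec[keep, , drop = FALSE], rejects = rejects)
}

#' Filter records by donor pH window
#'
#' Keeps records whose donor pH lies inside the closed interval. Records with
#' missing pH are kept by default (the published selection maximised dataset
#' size); set \code{keepMissing = FALSE} for the strict mode.
#'
#' @param records Records data.frame from \code{\link{readRecords}}.
#' @param window Length-2 numeric, closed interval (default c(7, 7.5)).
#' @param keepMissing Keep records with missing pH.
#' @return Filtered data.frame.
#' @export
filterPh <- function(records, window = c(7, 7.5), keepMissing = TRUE) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  inside <- !is.na(records$ph) & records$ph >= window[1] &
    records$ph <= window[2]
  if (keepMissing) inside <- inside | is.na(records$ph)
  records[inside, , drop = FALSE]
}

#' Default record-selection preferences
#'
#' Ordered preference lists reflecting the published choice of conditions
#' closest to in vivo use: abdomen source, epidermis+dermis layer, saturated
#' ("concentrated") donor, 31-35 degrees C.
#'
#' @return List of ordered character vectors: source, layer, donor, tempBin.
#' @export
selectionConfig <- function() {
  list(source = c("abdomen", "breast", "thigh"),
       layer = c("epidermis+dermis", "epidermis", "dermis", "stratum_corneum"),
       donor = c("saturated", "diluted"),
       tempBin = c("31-35", "26-30", "36-40", "20-25"))
}

#' Reduce to one record per compound
#'
#' Applies the preference lists lexicographically — best available source,
#' then layer, then donor, then temperature bin. Records still tied after all
#' four keys are merged into one record at their mean logKp and the tie is
#' logged.
#'
#' @param records Records data.frame.
#' @param config Preference lists as from \code{\link{selectionConfig}}.
#' @return List: \code{records} (one row per compound), \code{ties}
#'   (data.frame: compound, n_merged, mean_logkp).
#' @export
selectOnePerCompound <- function(records, config = selectionConfig()) {
  prefRank <- function(values, pref)
    match(values, pref, nomatch = length(pref) + 1L)
  keys <- list(prefRank(records$source, config$source),
               prefRank(records$layer, config$layer),
               prefRank(records$donor, config$donor),
               prefRank(records$temp_bin, config$tempBin))
  ties <- data.frame(compound = character(0), n_merged = integer(0),
                     mean_logkp = numeric(0), stringsAsFactors = FALSE)
  out <- lapply(split(seq_len(nrow(records)), records$compound), function(idx) {
    for (kk in keys) {
      best <- min(kk[idx])
      idx <- idx[kk[idx] == best]
    }
    row <- records[idx[1L], , drop = FALSE]
    if (length(idx) > 1L) {
      row$logkp <- mean(records$logkp[idx])
      ties <<- rbind(ties, data.frame(compound = row$compound,
                                      n_merged = length(idx),
                                      mean_logkp = row$logkp,
                                      stringsAsFactors = FALSE))
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  list(records = res[order(res$compound), , drop = FALSE], ties = ties)
}

#' Drop compounds carrying excluded functional groups
#'
#' Profiles are computed from the record SMILES unless supplied. Compounds
#' with any of the seven excluded groups are dropped; compounds lacking both
#' a SMILES and a supplied profile are rejected with a message.
#'
#' @param records Records data.frame.
#' @param profiles Optional named list of \linkS4class{FragmentProfile},
#'   keyed by compound.
#' @return List: \code{records} (survivors), \code{excluded} (data.frame:
#'   compound, groups), \code{rejects} (compounds with no structure).
#' @export
excludeUnusualCompounds <- function(records, profiles = NULL) {
  compounds <- unique(records$compound)
  exc <- character(0); rejects <- character(0)
  excluded <- data.frame(compound = character(0), groups = character(0),
                         stringsAsFactors = FALSE)
  for (cp in compounds) {
    prof <- profiles[[cp]]
    if (is.null(prof)) {
      smi <- records$smiles[records$compound == cp]
      smi <- smi[!is.na(smi) & nzchar(smi)]
      if (!length(smi)) { rejects <- c(rejects, cp); next }
      prof <- countFragments(smi[1L])
    }
    if (!isEligible(prof)) {
      exc <- c(exc, cp)
      excluded <- rbind(excluded, data.frame(
        compound = cp, groups = paste(excludedIn(prof), collapse = ";"),
        stringsAsFactors = FALSE))
    }
  }
  if (length(rejects))
    message("rejected (no SMILES and no profile): ",
            paste(rejects, collapse = ", "))
  list(records = records[!(records$compound %in% c(exc, rejects)), ,
                         drop = FALSE],
       excluded = excluded, rejects = rejects)
}

#' Stratify records over the 96 experimental scenarios
#'
#' Partitions mapped records by their ScenarioKey. A compound appears in
#' several strata when it has records under several conditions. Scenarios
#' with more than one record are fit-eligible (the n > 1 rule under which 27
#' of the 96 scenarios carried a model).
#'
#' @param records Records data.frame.
#' @return List: \code{strata} (named list of data.frames, names are
#'   "source/layer/donor/tempBin"), \code{eligible} (stratum names with
#'   n > 1), \code{unmapped} (records whose labels did not normalize).
#' @export
stratifyScenarios <- function(records) {
  mapped <- records[records$mapped %in% TRUE, , drop = FALSE]
  unmapped <- records[!(records$mapped %in% TRUE), , drop = FALSE]
  if (nrow(mapped) == 0L)
    return(list(strata = list(), eligible = character(0),
                unmapped = unmapped))
  key <- paste(mapped$source, mapped$layer, mapped$donor, mapped$temp_bin,
               sep = "/")
  strata <- split(mapped, key)
  eligible <- names(strata)[vapply(strata, nrow, integer(1)) > 1L]
  list(strata = strata, eligible = eligible, unmapped = unmapped)
}

#' Remove extreme outliers within scenario strata
#'
#' Default \code{rule = "none"} (identity): the published removals are
#' unstated, so any removal here is opt-in and logged. With
#' \code{rule = "z"}, records more than \code{tau} standard deviations from
#' their stratum mean are dropped; strata with fewer than 3 records, or zero
#' spread, pass through untouched (flagged).
#'
#' @param records Records data.frame.
#' @param rule \code{"none"} or \code{"z"}.
#' @param tau Z-score threshold for \code{rule = "z"}.
#' @return List: \code{records}, \code{removed} (data.frame: compound,
#'   logkp, z), \code{skippedStrata} (too small or zero-sd strata).
#' @export
removeOutliers <- function(records, rule = c("none", "z"), tau = 3) {
  rule <- match.arg(rule)
  if (rule == "none")
    return(list(records = records,
                removed = data.frame(compound = character(0),
                                     logkp = numeric(0), z = numeric(0),
                                     stringsAsFactors = FALSE),
                skippedStrata = character(0)))
  strat <- stratifyScenarios(records)
  removed <- data.frame(compound = character(0), logkp = numeric(0),
                        z = numeric(0), stringsAsFactors = FALSE)
  skipped <- character(0)
  kept <- list()
  for (nm in names(strat$strata)) {
    s <- strat$strata[[nm]]
    sdv <- stats::sd(s$logkp)
    if (nrow(s) < 3L || !is.finite(sdv) || sdv == 0) {
      skipped <- c(skipped, nm)
      kept[[nm]] <- s
      next
    }
    z <- (s$logkp - mean(s$logkp)) / sdv
    out <- abs(z) > tau
    if (any(out))
      removed <- rbind(removed, data.frame(compound = s$compound[out],
                                           logkp = s$logkp[out], z = z[out],
                                           stringsAsFactors = FALSE))
    kept[[nm]] <- s[!out, , drop = FALSE]
  }
  res <- do.call(rbind, c(kept, list(strat$unmapped)))
  rownames(res) <- NULL
  list(records = res, removed = removed, skippedStrata = skipped)
}
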