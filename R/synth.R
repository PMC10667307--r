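## Synthetic fragment-count datasets: counts drawn per group (independent
## Poisson by default, or a deterministic full-rank grid), logKp generated
## from a FragmentModel plus Gaussian noise. This emulates the statistical
## structure y = a0 + sum_j a_j x_j + eps assumed by the regression; it does
## not generate chemical structures.

#' Default per-group Poisson rates
#'
#' Calibrated so most synthetic molecules carry one to three groups, as small
#' drug-like molecules do, while keeping the design matrix full-rank.
#'
#' @return Named numeric vector over the ten groups (rates 0.3-0.8).
#' @export
defaultCountRates <- function() {
  c(amide = 0.3, amine = 0.4, aromatic = 0.8, bromine = 0.3,
    carboxylic_acid = 0.3, chlorine = 0.3, ester = 0.4, ether = 0.5,
    hydroxyl = 0.6, ketone = 0.4)
}

#' Draw synthetic fragment-count profiles
#'
#' Counts are independent Poisson per group. Reproducible given \code{seed}.
#'
#' @param n Number of compounds (>= 1).
#' @param rates Named Poisson rates; defaults to \code{defaultCountRates()}.
#'   Groups omitted from \code{rates} get count zero.
#' @param seed Integer seed.
#' @return Integer matrix n x 10, columns \code{fragmentGroups()}.
#' @export
#' @examples
#' head(generateProfiles(5, seed = 1))
generateProfiles <- function(n, rates = defaultCountRates(), seed = 1) {
  stopifnot(n >= 1, all(rates >= 0))
  bad <- setdiff(names(rates), fragmentGroups())
  if (length(bad))
    stop("unknown fragment group(s) in rates: ", paste(bad, collapse = ", "))
  set.seed(as.integer(seed))
  full <- structure(numeric(10), names = fragmentGroups())
  full[names(rates)] <- rates
  counts <- vapply(fragmentGroups(),
                   function(g) stats::rpois(n, full[[g]]), numeric(n))
  if (n == 1L)
    counts <- matrix(counts, nrow = 1L,
                     dimnames = list(NULL, fragmentGroups()))
  storage.mode(counts) <- "integer"
  rownames(counts) <- sprintf("synth-%04d", seq_len(n))
  counts
}

#' Deterministic full-rank grid of fragment counts
#'
#' A fixed design for exact-recovery checks: the zero row, each unit and
#' doubled unit vector, and adjacent-pair rows, giving 3k + 1 full-rank rows
#' with counts in 0..maxCount.
#'
#' @param groups Group names (columns); default all ten.
#' @param maxCount Maximum count level (>= 2).
#' @return Integer matrix with 3 * length(groups) + 1 rows.
#' @export
#' @examples
#' dim(gridProfiles())  # 31 x 10
gridProfiles <- function(groups = fragmentGroups(), maxCount = 2) {
  stopifnot(maxCount >= 2)
  k <- length(groups)
  rows <- list(rep(0L, k))
  for (j in seq_len(k)) {
    e <- rep(0L, k); e[j] <- 1L; rows[[length(rows) + 1L]] <- e
    e[j] <- as.integer(maxCount); rows[[length(rows) + 1L]] <- e
  }
  for (j in seq_len(k)) {
    e <- rep(0L, k); e[j] <- 1L; e[j %% k + 1L] <- 1L
    rows[[length(rows) + 1L]] <- e
  }
  m <- do.call(rbind, rows)
  colnames(m) <- groups
  rownames(m) <- sprintf("grid-%04d", seq_len(nrow(m)))
  m
}

#' Generate a synthetic permeability dataset
#'
#' logKp_i = predictLogKp(model, profile_i) + eps_i with eps ~ N(0, noiseSd^2).
#'
#' @param model Generating \linkS4class{FragmentModel} (e.g.
#'   \code{getModel("eq2")}).
#' @param n Number of compounds (ignored when \code{profiles} is supplied).
#' @param noiseSd Gaussian noise standard deviation on logKp (>= 0).
#' @param seed Integer seed (drives both counts and noise).
#' @param rates Poisson rates for \code{\link{generateProfiles}}.
#' @param profiles Optional count matrix to use instead of Poisson draws.
#' @return List: \code{profiles} (count matrix), \code{logkp} (numeric),
#'   \code{model}, \code{noiseSd}, \code{seed}.
#' @export
#' @examples
#' d <- generateDataset(getModel("eq2"), n = 10, noiseSd = 0, seed = 1)
generateDataset <- function(model, n = 100, noiseSd = 0.3, seed = 1,
                            rates = defaultCountRates(), profiles = NULL) {
  stopifnot(is(model, "FragmentModel"), noiseSd >= 0)
  if (is.null(profiles)) {
    profiles <- generateProfiles(n, rates = rates, seed = seed)
  } else {
    profiles <- as.matrix(profiles)
    set.seed(as.integer(seed))
  }
  mu <- predictLogKp(model, profiles)
  eps <- if (noiseSd > 0) stats::rnorm(nrow(profiles), 0, noiseSd) else 0
  list(profiles = profiles, logkp = as.numeric(mu + eps), model = model,
       noiseSd = noiseSd, seed = as.integer(seed))
}

#' Export a synthetic dataset as a permeability CSV
#'
#' Writes the HuskinDB-style schema consumed by \code{\link{readRecords}}
#' (scenario fields filled with constants; fragment-count columns appended so
#' the table is self-contained) and round-trips losslessly.
#'
#' @param profiles Count matrix.
#' @param logkp Numeric vector, one value per row of \code{profiles}.
#' @param path Output CSV path.
#' @param scenario \linkS4class{ScenarioKey} used to fill the condition
#'   columns; default abdomen/epidermis/diluted/31-35.
#' @param temperature Numeric donor temperature written to temperature_c
#'   (must fall in the scenario's bin).
#' @param ph Donor pH constant.
#' @return The path, invisibly.
#' @export
exportDataset <- function(profiles, logkp, path,
                          scenario = ScenarioKey("abdomen", "epidermis",
                                                 "diluted", "31-35"),
                          temperature = 33, ph = 7.2) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) == 0L) stop("empty dataset: nothing to export")
  if (nrow(profiles) != length(logkp))
    stop("profiles and logkp lengths differ")
  ids <- rownames(profiles)
  if (is.null(ids)) ids <- sprintf("synth-%04d", seq_len(nrow(profiles)))
  df <- data.frame(compound = ids, smiles = "", logkp = logkp,
                   source = scenario@source, layer = scenario@layer,
                   donor = scenario@donor, temperature_c = temperature,
                   ph = ph, reference = "synthetic",
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(profiles))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
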