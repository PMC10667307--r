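## Ordinary least squares exactly as the group-contribution method defines
## it: solve the normal equations a = (X'X)^-1 X'Y, estimate sigma by maximum
## likelihood (divide by m, not m-k-1), flag a coefficient as significant
## when |a_j| >= t_df * sigma_hat * sqrt(m |c_jj| / df), and eliminate terms
## top-down until everything left passes. Implemented here from first
## principles; stats::lm serves only as an independent cross-check in tests.

#' Build a design matrix from fragment counts
#'
#' Prepends the intercept column of ones to a count matrix.
#'
#' @param counts Numeric matrix, one row per compound, one column per group.
#' @return Matrix with first column \code{"(Intercept)"} identically 1.
#' @export
designMatrix <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) > 0L && is.null(colnames(counts)))
    colnames(counts) <- paste0("x", seq_len(ncol(counts)))
  cbind("(Intercept)" = rep(1, nrow(counts)), counts)
}

#' Fit a group-contribution model by the normal equations
#'
#' Minimises q = sum_i (y_i - a0 - sum_j a_j x_ij)^2. Coefficients are
#' obtained from a QR solve for numerical stability; the c_jj diagonal is
#' taken from the explicitly formed (X'X)^-1 because the significance
#' criterion is defined on it.
#'
#' @param counts Numeric matrix of fragment counts (no intercept column).
#' @param y Numeric vector of observed logKp (log10 cm/s), length nrow(counts).
#' @param alpha Significance level for the per-coefficient flags.
#' @param dfMode Degrees of freedom for the t criterion: \code{"params"}
#'   (default) uses m - (k + 1), the number of fitted parameters including
#'   the intercept; \code{"terms"} uses m - k.
#' @param conditionLimit Reciprocal-condition threshold; an X'X with
#'   \code{kappa} above 1/conditionLimit raises a typed error
#'   (\code{fragkin_singular_error}) suggesting removal of collinear or
#'   constant columns.
#' @return A \linkS4class{FitResult}.
#' @export
#' @examples
#' X <- cbind(hydroxyl = c(0, 1, 2))
#' fitOLS(X, c(1, 2, 3))
fitOLS <- function(counts, y, alpha = 0.05,
                   dfMode = c("params", "terms"),
                   conditionLimit = 1e-12) {
  dfMode <- match.arg(dfMode)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  y <- as.numeric(y)
  m <- nrow(counts); k <- ncol(counts)
  if (length(y) != m) stop("length(y) must equal nrow(counts)")
  if (!all(is.finite(y)) || !all(is.finite(counts)))
    stop("counts and y must be finite")
  if (m <= k + 1L)
    stop(sprintf("need m > k + 1 observations to fit (m = %d, k = %d)", m, k))
  X <- designMatrix(counts)
  XtX <- crossprod(X)
  if (rcond(XtX) < conditionLimit)
    stop(structure(class = c("fragkin_singular_error", "error", "condition"),
      list(message = paste("X'X is singular or near-singular;",
             "remove collinear or constant fragment columns"), call = NULL)))
  a <- qr.solve(X, y)
  names(a) <- colnames(X)
  cjj <- diag(solve(XtX))
  fitted <- drop(X %*% a)
  resid <- y - fitted
  sse <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  sigmaHat <- sqrt(sse / m)
  dfResid <- m - (k + 1L)
  sigmaHatUnb <- sqrt(sse / dfResid)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  ## overall-regression ANOVA: all slopes zero
  ssr <- sst - sse
  if (k > 0L && sse > .Machine$double.eps * sst) {
    fStat <- (ssr / k) / (sse / dfResid)
    fP <- stats::pf(fStat, k, dfResid, lower.tail = FALSE)
  } else if (k > 0L) {
    fStat <- Inf; fP <- 0
  } else {
    fStat <- NA_real_; fP <- NA_real_
  }
  df <- if (dfMode == "params") m - (k + 1L) else m - k
  if (df <= 0L) stop("non-positive degrees of freedom for the t criterion")
  thr <- .sigThresholds(a, sigmaHat, cjj, m, df, alpha)
  new("FitResult", coefficients = a, labels = colnames(counts) %||% character(0),
      sigmaHat = sigmaHat, sigmaHatUnbiased = sigmaHatUnb, cjj = cjj,
      sse = sse, rSquared = r2, rmse = sqrt(sse / m), fStat = fStat,
      fPvalue = fP, df = as.numeric(df),
      thresholds = thr$threshold, significant = thr$significant,
      m = as.integer(m), k = as.integer(k), alpha = alpha)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.sigThresholds <- function(a, sigmaHat, cjj, m, df, alpha) {
  tcrit <- stats::qt(1 - alpha / 2, df = df)
  threshold <- tcrit * sigmaHat * sqrt(m * abs(cjj) / df)
  ## the criterion reads "not significant if |a_j| < threshold"; when a
  ## perfect fit collapses the threshold to zero, an exactly-zero coefficient
  ## must still count as not significant
  significant <- ifelse(threshold > 0, abs(a) >= threshold, abs(a) > 0)
  list(threshold = threshold, significant = as.logical(significant))
}

#' Maximum-likelihood residual standard deviation
#'
#' sigma-hat = sqrt((Y'Y - a'X'Y) / m): divides by m as the method defines
#' (the MLE), not by the residual degrees of freedom. Set
#' \code{unbiased = TRUE} for the m - k - 1 denominator.
#'
#' @param counts,y Design counts and response as in \code{\link{fitOLS}}.
#' @param a Coefficient vector (intercept first) from a fit on the same data.
#' @param unbiased Use the m - k - 1 denominator instead of m.
#' @return Non-negative scalar.
#' @export
sigmaHat <- function(counts, y, a, unbiased = FALSE) {
  X <- designMatrix(as.matrix(counts))
  y <- as.numeric(y)
  m <- nrow(X)
  q <- max(0, sum(y * y) - sum(a * drop(crossprod(X, y))))
  denom <- if (unbiased) m - ncol(X) else m
  sqrt(q / denom)
}

#' Per-coefficient significance flags
#'
#' Recomputes the flags of a \linkS4class{FitResult} at a new level:
#' a coefficient is not significantly different from zero when
#' |a_j| < t_df . sigma-hat . sqrt(m |c_jj| / df).
#'
#' @param fit A \linkS4class{FitResult}.
#' @param alpha Significance level in (0, 1].
#' @return Named logical vector (intercept first).
#' @export
coefficientSignificance <- function(fit, alpha = fit@alpha) {
  stopifnot(is(fit, "FitResult"))
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (fit@df <= 0) stop("non-positive degrees of freedom")
  thr <- .sigThresholds(fit@coefficients, fit@sigmaHat, fit@cjj, fit@m,
                        fit@df, alpha)
  structure(thr$significant, names = names(fit@coefficients))
}

#' Overall-regression ANOVA F
#'
#' Tests the hypothesis that all fragment contributions are zero:
#' F = (SSR / k) / (SSE / (m - k - 1)) with its upper-tail probability.
#' A perfect fit reports F = Inf, p = 0.
#'
#' @param fit A \linkS4class{FitResult}.
#' @return Named numeric vector c(F, p).
#' @export
anovaF <- function(fit) {
  stopifnot(is(fit, "FitResult"))
  c(F = fit@fStat, p = fit@fPvalue)
}

#' Top-down elimination of non-significant fragment terms
#'
#' Fits the full model, then repeatedly removes the single least significant
#' non-significant term — smallest ratio |a_j| / threshold_j; ties broken by
#' smaller |a_j|, then alphabetically — and refits, until every remaining
#' term is significant at \code{alpha}. The intercept is never removed.
#'
#' @inheritParams fitOLS
#' @return An \linkS4class{EliminationTrace}.
#' @export
topDownEliminate <- function(counts, y, alpha = 0.05,
                             dfMode = c("params", "terms")) {
  dfMode <- match.arg(dfMode)
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("x", seq_len(ncol(counts)))
  steps <- data.frame(term = character(0), coefficient = numeric(0),
                      tRatio = numeric(0), modelSizeAfter = integer(0),
                      stringsAsFactors = FALSE)
  live <- colnames(counts)
  repeat {
    fit <- fitOLS(counts[, live, drop = FALSE], y, alpha = alpha,
                  dfMode = dfMode)
    sig <- fit@significant[-1L]
    if (all(sig) || length(live) == 0L) break
    a <- fit@coefficients[-1L]
    thr <- fit@thresholds[-1L]
    ratio <- ifelse(thr > 0, abs(a) / thr, ifelse(abs(a) > 0, Inf, 0))
    cand <- which(!sig)
    ## least significant first; deterministic tie-breaks
    ord <- order(ratio[cand], abs(a[cand]), names(a)[cand])
    drop1 <- cand[ord[1L]]
    steps <- rbind(steps, data.frame(
      term = names(a)[drop1], coefficient = unname(a[drop1]),
      tRatio = unname(ratio[drop1]),
      modelSizeAfter = length(live) - 1L, stringsAsFactors = FALSE))
    live <- setdiff(live, names(a)[drop1])
    if (length(live) == 0L) {
      fit <- fitOLS(matrix(numeric(0), nrow = nrow(counts), ncol = 0,
                           dimnames = list(NULL, character(0))),
                    y, alpha = alpha, dfMode = dfMode)
      break
    }
  }
  new("EliminationTrace", steps = steps, finalFit = fit, finalLabels = live)
}

#' Coefficient of determination
#'
#' Two conventions: \code{"sst"} (default for training fits) is
#' 1 - SSE/SST; \code{"pearson"} is the squared Pearson correlation between
#' predictions and observations (the convention for evaluating a fixed model
#' on held-out data). They agree for a least-squares fit evaluated on its own
#' training data and can diverge badly otherwise.
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 2).
#' @param convention \code{"sst"} or \code{"pearson"}.
#' @return Scalar; \code{"sst"} may be negative for a poor fixed model.
#' @export
rSquared <- function(observed, predicted, convention = c("sst", "pearson")) {
  convention <- match.arg(convention)
  stopifnot(length(observed) == length(predicted), length(observed) >= 2L)
  if (convention == "sst") {
    sst <- sum((observed - mean(observed))^2)
    if (sst == 0) stop("observed values have zero variance")
    1 - sum((observed - predicted)^2) / sst
  } else {
    if (stats::var(observed) == 0)
      stop("observed values have zero variance")
    if (stats::var(predicted) == 0)
      stop("predictions have zero variance; pearson convention undefined")
    stats::cor(observed, predicted)^2
  }
}

#' Root mean square error
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return sqrt(mean((observed - predicted)^2)).
#' @export
rmse <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  sqrt(mean((observed - predicted)^2))
}

#' Serialize a fit as a coefficient table
#'
#' @param fit A \linkS4class{FitResult}.
#' @return data.frame: term, coefficient, threshold, significant.
#' @export
coefficientTable <- function(fit) {
  stopifnot(is(fit, "FitResult"))
  data.frame(term = names(fit@coefficients),
             coefficient = unname(fit@coefficients),
             threshold = unname(fit@thresholds),
             significant = unname(fit@significant),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Turn a FitResult into a FragmentModel
#'
#' @param fit A \linkS4class{FitResult} whose non-intercept columns are
#'   fragment-group names.
#' @param name Model name.
#' @param provenance Provenance text.
#' @param scenario Optional \linkS4class{ScenarioKey}.
#' @return A \linkS4class{FragmentModel}.
#' @export
asFragmentModel <- function(fit, name = "fitted", provenance = "",
                            scenario = NULL) {
  stopifnot(is(fit, "FitResult"))
  cf <- fit@coefficients[-1L]
  FragmentModel(name, intercept = unname(fit@coefficients[1L]),
                coefficients = cf, provenance = provenance,
                scenario = scenario)
}
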