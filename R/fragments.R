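## SMARTS definitions -----------------------------------------------------
## The source equations never define the groups structurally, so the patterns
## below fix one definition per group. Precedence (an atom feeds at most one
## group) is encoded in the patterns themselves via recursive-SMARTS
## exclusions rather than post-hoc bookkeeping:
##   * a carbonyl carbon is acid, ester, amide or ketone, never two of them
##     (the ketone pattern requires two carbon neighbours, which excludes the
##     other three; amide keys on the N);
##   * a divalent oxygen is acid-OH, ester bridge, ether or hydroxyl, never
##     two (ether/hydroxyl exclude oxygens attached to a carbonyl carbon);
##   * amine excludes amide nitrogens and nitro; aromatic ring nitrogens are
##     excluded because [N] is the aliphatic-nitrogen primitive.
## Phenols count as hydroxyl; anilines as amine; heteroaromatic rings count
## toward "aromatic"; aldehydes match none of the ten groups (documented).

.FRAGMENT_SMARTS <- c(
  amide           = "[NX3][CX3]=[OX1]",
  amine           = "[NX3;!$([NX3]=[OX1]);!$([NX3][CX3]=[OX1])]",
  bromine         = "[Br]",
  carboxylic_acid = "[CX3](=[OX1])[OX2H1]",
  chlorine        = "[Cl]",
  ester           = "[CX3](=[OX1])[OX2H0][#6]",
  ether           = "[OD2H0;!$([OX2][CX3]=[OX1])]([#6])[#6]",
  hydroxyl        = "[OX2H][#6;!$([CX3]=[OX1])]",
  ketone          = "[#6][CX3](=[OX1])[#6]"
)

## Eligibility filter only, so breadth over precision.
.EXCLUDED_SMARTS <- c(
  boron     = "[#5]",
  cyanide   = "[CX2]#[NX1]",
  epoxide   = "[CX4]1[OX2][CX4]1",
  fluorine  = "[F]",
  nitro     = "[$([NX3](=O)=O),$([NX3+](=[OX1])[O-])]",
  phosphate = "[PX4]=[OX1]",
  thiol     = "[SX2H]"
)

#' SMARTS patterns behind the fragment counter
#'
#' The structural definition used for each of the ten modeled groups and the
#' seven excluded groups. Fixed; exposed so the definitions can be audited.
#'
#' @return Named list with elements \code{modeled} (9 SMARTS; the tenth group,
#'   \code{aromatic}, is counted as aromatic rings in the smallest set of
#'   smallest rings, not by SMARTS) and \code{excluded} (7 SMARTS).
#' @export
fragmentSmarts <- function() {
  list(modeled = .FRAGMENT_SMARTS, excluded = .EXCLUDED_SMARTS)
}

## Parsing ----------------------------------------------------------------

#' Parse SMILES into molecule handles
#'
#' Wraps \code{ChemmineR::smiles2sdf} (OpenBabel): aromaticity is perceived
#' and the result is independent of the SMILES spelling. Invalid SMILES raise
#' a typed error (\code{fragkin_parse_error}) naming the offending input.
#'
#' @param smiles Character vector of SMILES strings.
#' @param ids Optional identifiers (defaults to the SMILES themselves).
#' @return An \code{SDFset} with one molecule per input.
#' @export
#' @examples
#' mol <- parseMolecule("c1ccccc1")
parseMolecule <- function(smiles, ids = NULL) {
  if (!is.character(smiles) || length(smiles) == 0L)
    stop("smiles must be a non-empty character vector")
  if (any(is.na(smiles) | !nzchar(smiles)))
    stop(.parseError("<empty>"))
  if (is.null(ids)) ids <- smiles
  names(smiles) <- make.unique(as.character(ids))
  ## parse one-by-one so a bad record names itself rather than failing the
  ## whole batch opaquely inside OpenBabel
  sdfs <- lapply(seq_along(smiles), function(i) {
    out <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles[i])),
                    error = function(e) NULL)
    if (is.null(out) || length(out) != 1L ||
        nrow(ChemmineR::atomblock(out[[1]])) == 0L)
      stop(.parseError(smiles[i]))
    out
  })
  out <- if (length(sdfs) == 1L) sdfs[[1L]]
         else suppressWarnings(Reduce(c, sdfs))
  ChemmineR::cid(out) <- names(smiles)
  out
}

.parseError <- function(input) {
  structure(
    class = c("fragkin_parse_error", "error", "condition"),
    list(message = sprintf("cannot parse SMILES: '%s'", input),
         call = NULL, input = input))
}

## Counting ---------------------------------------------------------------

.countMatrix <- function(sdf) {
  n <- length(sdf)
  pat <- vapply(.FRAGMENT_SMARTS, function(p)
    as.numeric(ChemmineR::smartsSearchOB(sdf, p, uniqueMatches = TRUE)),
    numeric(n))
  if (n == 1L) pat <- matrix(pat, nrow = 1L,
                             dimnames = list(NULL, names(.FRAGMENT_SMARTS)))
  ## aromatic = aromatic rings in the SSSR (naphthalene counts 2, matching
  ## the published "x 2" multiplicity convention for fused systems)
  ar <- ChemmineR::rings(sdf, type = "count", arom = TRUE, inner = TRUE)
  nArom <- if (is.matrix(ar)) as.numeric(ar[, "AROMATIC"])
           else as.numeric(ar[["AROMATIC"]])
  cnt <- cbind(pat, aromatic = nArom)
  cnt <- cnt[, fragmentGroups(), drop = FALSE]
  storage.mode(cnt) <- "integer"
  rownames(cnt) <- ChemmineR::sdfid(sdf)
  cnt
}

.excludedMatrix <- function(sdf) {
  n <- length(sdf)
  m <- vapply(.EXCLUDED_SMARTS, function(p)
    as.numeric(ChemmineR::smartsSearchOB(sdf, p, uniqueMatches = TRUE)),
    numeric(n))
  if (n == 1L) m <- matrix(m, nrow = 1L,
                           dimnames = list(NULL, names(.EXCLUDED_SMARTS)))
  m > 0
}

#' Count the ten modeled functional groups
#'
#' Counts occurrences of each modeled group (deduplicated by matched atom
#' set, so symmetric matches are not double-counted) and detects the seven
#' excluded groups. Counts are invariant to SMILES spelling and to explicit
#' hydrogens.
#'
#' @param x SMILES character vector or an \code{SDFset} from
#'   \code{\link{parseMolecule}}.
#' @return A \linkS4class{FragmentProfile} for a single molecule, or a list
#'   of them for several.
#' @export
#' @examples
#' countFragments("CC(=O)Oc1ccccc1C(=O)O")  # aspirin
countFragments <- function(x) {
  sdf <- if (is(x, "SDFset")) x else parseMolecule(x)
  cnt <- .countMatrix(sdf)
  exc <- .excludedMatrix(sdf)
  profs <- lapply(seq_len(nrow(cnt)), function(i)
    new("FragmentProfile", counts = cnt[i, ],
        excluded = colnames(exc)[exc[i, ]]))
  if (length(profs) == 1L) profs[[1]] else profs
}

#' Detect the seven excluded functional groups
#'
#' @param x SMILES string or \code{SDFset} (single molecule).
#' @return Character vector: the subset of \code{excludedGroups()} present.
#' @export
#' @examples
#' flagExcludedGroups("Fc1ccccc1")
flagExcludedGroups <- function(x) {
  sdf <- if (is(x, "SDFset")) x else parseMolecule(x)
  exc <- .excludedMatrix(sdf)
  if (nrow(exc) != 1L)
    return(lapply(seq_len(nrow(exc)), function(i) colnames(exc)[exc[i, ]]))
  colnames(exc)[exc[1L, ]]
}

#' Flatten a FragmentProfile to a feature vector
#'
#' @param profile A \linkS4class{FragmentProfile}.
#' @param groupOrder Ordered group names (a permutation or subset of the ten).
#' @return Integer vector of counts in the requested order.
#' @export
#' @examples
#' profileToFeatureVector(countFragments("Oc1ccccc1"),
#'                        c("aromatic", "hydroxyl"))
profileToFeatureVector <- function(profile, groupOrder = fragmentGroups()) {
  stopifnot(is(profile, "FragmentProfile"))
  bad <- setdiff(groupOrder, fragmentGroups())
  if (length(bad))
    stop("unknown fragment group(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(groupOrder))
    stop("groupOrder contains duplicates")
  profile@counts[groupOrder]
}

#' Fragment counts for many molecules as a table
#'
#' @param smiles Character vector of SMILES.
#' @param ids Optional compound identifiers.
#' @return data.frame: compound, one integer column per group (fixed order
#'   \code{fragmentGroups()}), and \code{excluded_groups}
#'   (semicolon-separated, empty when none).
#' @export
fragmentTable <- function(smiles, ids = NULL) {
  sdf <- parseMolecule(smiles, ids = ids)
  cnt <- .countMatrix(sdf)
  exc <- .excludedMatrix(sdf)
  data.frame(compound = rownames(cnt), as.data.frame(cnt),
             excluded_groups = vapply(seq_len(nrow(exc)), function(i)
               paste(colnames(exc)[exc[i, ]], collapse = ";"), character(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
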