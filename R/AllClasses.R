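#' @import methods
NULL

.uniqueNonEmpty <- function(x) {
  length(x) > 0 && !anyNA(x) && all(nzchar(x)) && !anyDuplicated(x)
}

#' IndexMatrix: the objects-by-criteria evaluation table
#'
#' The input of InterCriteria analysis is a two-dimensional index matrix
#' \eqn{[O, C, e_{O_i,C_k}]}: a set of objects \eqn{O_1 \ldots O_m} (rows),
#' a set of criteria \eqn{C_1 \ldots C_n} (columns), and a real evaluation
#' of every object against every criterion. In the docking use case the
#' objects are protein--ligand complexes and the criteria are scoring
#' functions (plus, optionally, an experimental affinity column); the cell
#' units are whatever the criterion measures (score, RMSD in Angstroms,
#' -logK), which is immaterial because ICrA only compares orderings.
#'
#' Validity requires at least two objects and two criteria, fully finite
#' evaluations (missing data have no defined semantics in ICrA), and unique
#' non-empty labels on each axis.
#'
#' @slot evaluations numeric matrix, m objects x n criteria, with dimnames
#'   carrying the object and criteria labels.
#'
#' @seealso [IndexMatrix()], [readIndexMatrix()], [runICrA()]
#' @export
setClass("IndexMatrix", representation(evaluations = "matrix"))

setValidity("IndexMatrix", function(object) {
  ev <- object@evaluations
  if (!is.numeric(ev))
    return("evaluations must be numeric")
  if (nrow(ev) < 2L)
    return("at least two objects are required for pairwise comparison")
  if (ncol(ev) < 2L)
    return("at least two criteria are required")
  if (!all(is.finite(ev)))
    return("evaluations must be finite; missing values are not supported")
  if (is.null(rownames(ev)) || !.uniqueNonEmpty(rownames(ev)))
    return("object labels must be unique and non-empty")
  if (is.null(colnames(ev)) || !.uniqueNonEmpty(colnames(ev)))
    return("criteria labels must be unique and non-empty")
  TRUE
})

#' IFPairs: parallel vectors of intuitionistic fuzzy pairs
#'
#' An intuitionistic fuzzy pair \eqn{\langle\mu, \nu\rangle} carries a degree
#' of agreement (membership) \eqn{\mu \in [0,1]} and a degree of disagreement
#' (non-membership) \eqn{\nu \in [0,1]} subject to the intuitionistic fuzzy
#' condition \eqn{0 \le \mu + \nu \le 1}. The residual
#' \eqn{\pi = 1 - \mu - \nu} is the degree of uncertainty. This class holds a
#' vector of such pairs (optionally named), so whole tables of criteria pairs
#' can be classified at once.
#'
#' @slot mu numeric vector of agreement degrees.
#' @slot nu numeric vector of disagreement degrees, parallel to `mu`.
#'
#' @seealso [ifPairs()], [classifyPairs()], [triangleCoordinates()]
#' @export
setClass("IFPairs", representation(mu = "numeric", nu = "numeric"))

setValidity("IFPairs", function(object) {
  mu <- object@mu
  nu <- object@nu
  if (length(mu) != length(nu))
    return("mu and nu must have equal length")
  if (anyNA(mu) || anyNA(nu))
    return("mu and nu must not contain NA")
  tol <- 1e-12
  if (any(mu < -tol | mu > 1 + tol))
    return("mu must lie in [0, 1]")
  if (any(nu < -tol | nu > 1 + tol))
    return("nu must lie in [0, 1]")
  if (any(mu + nu > 1 + tol))
    return("the intuitionistic fuzzy condition mu + nu <= 1 is violated")
  if (!is.null(names(mu)) && !is.null(names(nu)) &&
      !identical(names(mu), names(nu)))
    return("names of mu and nu disagree")
  TRUE
})

#' ICrAResult: intuitionistic fuzzy relations between all criteria pairs
#'
#' The output of InterCriteria analysis is itself an index matrix: a
#' symmetric criteria-by-criteria table whose (k, l) entry is the
#' intuitionistic fuzzy pair \eqn{\langle\mu_{C_k,C_l}, \nu_{C_k,C_l}\rangle}
#' relating criteria k and l, with \eqn{\langle 1, 0\rangle} on the diagonal
#' (every criterion fully agrees with itself). The raw comparison counters
#' are retained so results can be audited: for each pair,
#' `sMu + sNu + sTie = m(m-1)/2`.
#'
#' @slot mu,nu symmetric n x n numeric matrices of agreement/disagreement
#'   degrees, dimnames = criteria labels.
#' @slot sMu,sNu,sTie symmetric n x n matrices of concordant, discordant and
#'   tie-absorbed comparison counts.
#' @slot m integer, number of objects the degrees were computed over.
#' @slot tieMode character, `"unbiased"` or `"mu_biased"`.
#' @slot epsilon numeric, tie tolerance used on evaluation differences.
#'
#' @seealso [runICrA()], [agreement()], [disagreement()], [uncertainty()]
#' @export
setClass("ICrAResult",
  representation(mu = "matrix", nu = "matrix",
                 sMu = "matrix", sNu = "matrix", sTie = "matrix",
                 m = "integer", tieMode = "character", epsilon = "numeric"))

setValidity("ICrAResult", function(object) {
  n <- ncol(object@mu)
  tol <- 1e-9
  for (s in c("mu", "nu", "sMu", "sNu", "sTie")) {
    mat <- slot(object, s)
    if (!identical(dim(mat), c(n, n)))
      return(sprintf("slot %s has wrong dimensions", s))
    if (max(abs(mat - t(mat))) > tol)
      return(sprintf("slot %s is not symmetric", s))
  }
  if (any(abs(diag(object@mu) - 1) > tol) || any(abs(diag(object@nu)) > tol))
    return("diagonal must be the pair <1, 0>")
  if (any(object@mu + object@nu > 1 + tol))
    return("mu + nu exceeds 1 for some pair")
  np <- object@m * (object@m - 1) / 2
  off <- upper.tri(object@sMu)
  if (any(abs((object@sMu + object@sNu + object@sTie)[off] - np) > tol))
    return("counters do not sum to m(m-1)/2")
  if (!object@tieMode %in% c("unbiased", "mu_biased"))
    return("tieMode must be 'unbiased' or 'mu_biased'")
  TRUE
})

#' ThresholdScheme: consonance/dissonance classification thresholds
#'
#' A pair of thresholds \eqn{\alpha > \beta} plus a scale and a boundary
#' convention. Under the classical *quarters* scale (default
#' \eqn{\alpha = 0.75, \beta = 0.25}) a criteria pair is in positive
#' consonance when \eqn{\mu \ge \alpha} and \eqn{\nu \le \beta} (inclusive
#' boundary; strict uses \eqn{\mu > \alpha} and \eqn{\nu < \beta}), in
#' negative consonance when \eqn{\mu \le \beta} and \eqn{\nu \ge \alpha},
#' and in dissonance otherwise.
#' The *thirds* scale (\eqn{\alpha = 0.67 \approx 2/3},
#' \eqn{\beta = 0.33 \approx 1/3}) adds a fourth class, *uncertainty*, for
#' pairs with \eqn{\mu < \alpha}, \eqn{\nu < \alpha} and
#' \eqn{\mu + \nu < \alpha} -- the region near the uncertainty vertex of the
#' intuitionistic triangle.
#'
#' @slot alpha numeric in (0, 1].
#' @slot beta numeric in [0, 1), with `alpha > beta`.
#' @slot scale `"quarters"` or `"thirds"`.
#' @slot boundary `"inclusive"` (mu = alpha qualifies; default) or
#'   `"strict"`.
#'
#' @seealso [thresholdScheme()], [classifyPairs()]
#' @export
setClass("ThresholdScheme",
  representation(alpha = "numeric", beta = "numeric",
                 scale = "character", boundary = "character"))

setValidity("ThresholdScheme", function(object) {
  a <- object@alpha; b <- object@beta
  if (length(a) != 1L || length(b) != 1L || is.na(a) || is.na(b))
    return("alpha and beta must be single numbers")
  if (a <= 0 || a > 1) return("alpha must lie in (0, 1]")
  if (b < 0 || b >= 1) return("beta must lie in [0, 1)")
  if (a <= b) return("alpha must exceed beta")
  if (!object@scale %in% c("quarters", "thirds"))
    return("scale must be 'quarters' or 'thirds'")
  if (!object@boundary %in% c("inclusive", "strict"))
    return("boundary must be 'inclusive' or 'strict'")
  TRUE
})

#' SweepSummary: positive-consonance counts over a threshold grid
#'
#' Result of sweeping classification thresholds \eqn{(\alpha, \beta)} with
#' \eqn{\alpha + \beta = 1} over a table of agreement degrees (criteria
#' pairs x evaluation blocks). Two complementary summaries are kept: per
#' block, how many pairs are in positive consonance at each threshold
#' setting (a sensitivity profile of the block), and per pair, in how many
#' blocks it is positive at each setting (a comparability profile of the
#' pair).
#'
#' @slot perBlock numeric matrix, threshold settings x blocks.
#' @slot perPair numeric matrix, pairs x threshold settings.
#' @slot alphas numeric vector of alpha values swept (beta = 1 - alpha).
#' @slot scheme the [ThresholdScheme-class] template (scale/boundary) used.
#'
#' @seealso [thresholdSweep()]
#' @export
setClass("SweepSummary",
  representation(perBlock = "matrix", perPair = "matrix",
                 alphas = "numeric", scheme = "ThresholdScheme"))

setValidity("SweepSummary", function(object) {
  if (nrow(object@perBlock) != length(object@alphas))
    return("perBlock must have one row per alpha")
  if (ncol(object@perPair) != length(object@alphas))
    return("perPair must have one column per alpha")
  if (any(object@perBlock < 0) || any(object@perPair < 0))
    return("counts must be non-negative")
  TRUE
})
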