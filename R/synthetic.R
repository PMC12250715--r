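## Gaussian-copula generator of docking-output-like evaluation matrices.
## Rank concordance of a bivariate Gaussian has a closed form (the arcsine
## law: tau = (2/pi) asin(rho)), so the achieved degree of agreement
## mu = (1 + tau)/2 is analytically known for tie-free marginals -- the
## generator can be calibrated to a target mu exactly in expectation.

.defaultCriteria <- c("London dG", "ASE", "Affinity dG", "Alpha HB",
                      "GBVI/WSA dG", "-logKd/Ki")
.blockKinds <- c("best_ds", "best_rmsd", "rmsd_best_ds", "ds_best_rmsd")

#' Specification of a synthetic docking-output block
#'
#' Bundles the parameters of the synthetic generator: number of objects
#' (protein--ligand complexes; default 195, the size of the CASF-2013
#' benchmark), criteria labels (default: the five MOE scoring functions
#' plus an experimental -logK column), a symmetric positive semi-definite
#' latent correlation matrix controlling pairwise concordance, the kind of
#' docking output the block emulates (it decides the marginal transforms:
#' negative score-like values for score blocks, non-negative Angstrom-like
#' values for RMSD blocks), and a seed.
#'
#' @slot m integer, number of objects.
#' @slot criteriaLabels character vector, length >= 2.
#' @slot targetRho numeric correlation matrix, unit diagonal, PSD.
#' @slot blockKind one of `"best_ds"`, `"best_rmsd"`, `"rmsd_best_ds"`,
#'   `"ds_best_rmsd"`.
#' @slot seed integer RNG seed.
#' @seealso [syntheticSpec()], [generateBlock()]
#' @export
setClass("SyntheticSpec",
  representation(m = "integer", criteriaLabels = "character",
                 targetRho = "matrix", blockKind = "character",
                 seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  if (object@m < 2L) return("m must be at least 2")
  n <- length(object@criteriaLabels)
  if (n < 2L) return("at least two criteria are required")
  rho <- object@targetRho
  if (!identical(dim(rho), c(n, n)))
    return("targetRho must be square with one row per criterion")
  if (max(abs(rho - t(rho))) > 1e-12) return("targetRho must be symmetric")
  if (max(abs(diag(rho) - 1)) > 1e-12)
    return("targetRho must have unit diagonal")
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    return(sprintf("targetRho is not positive semi-definite (eigenvalue %.3g)",
                   min(ev)))
  if (!object@blockKind %in% .blockKinds)
    return(sprintf("blockKind must be one of %s",
                   paste(.blockKinds, collapse = ", ")))
  TRUE
})

#' Construct a SyntheticSpec
#'
#' @param m number of objects (default 195).
#' @param criteriaLabels criteria names; default the five MOE scoring
#'   functions plus the experimental affinity column.
#' @param targetRho latent Gaussian correlation matrix (default identity:
#'   independent criteria, expected mu = 0.5 for every pair).
#' @param blockKind which docking output to emulate; decides marginal
#'   transforms only, never the concordance structure.
#' @param seed RNG seed.
#' @return a validated [SyntheticSpec-class].
#' @export
syntheticSpec <- function(m = 195L, criteriaLabels = .defaultCriteria,
                          targetRho = diag(length(criteriaLabels)),
                          blockKind = "best_ds", seed = 1L) {
  new("SyntheticSpec", m = as.integer(m),
      criteriaLabels = criteriaLabels,
      targetRho = as.matrix(targetRho),
      blockKind = blockKind, seed = as.integer(seed))
}

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: %d objects x %d criteria, block '%s', seed %d\n",
              object@m, length(object@criteriaLabels), object@blockKind,
              object@seed))
  invisible(NULL)
})

#' Generate a synthetic docking-output block
#'
#' Draws m latent vectors from a zero-mean Gaussian with correlation
#' `targetRho`, then maps each criterion's column through a strictly
#' increasing, block-appropriate transform: score blocks get shifted
#' negative values (lower = better binding, as docking scores are
#' reported), RMSD blocks get non-negative lognormal values on an
#' Angstrom-like scale, and an experimental column (any label containing
#' "logK") gets affinity-like values around 6 pK units. Strict
#' monotonicity guarantees the transforms never alter pairwise
#' concordance, so the achieved degree of agreement for a pair with latent
#' correlation rho is (1 + (2/pi) asin(rho))/2 in expectation. Pairs with
#' `targetRho` exactly +/-1 are constructed comonotone/antitone exactly
#' (identical or negated latent columns), so their mu is exactly 1 or 0.
#'
#' @param spec a [SyntheticSpec-class].
#' @return an [IndexMatrix-class], m objects x length(criteriaLabels)
#'   criteria, reproducible under the spec's seed.
#' @examples
#' im <- generateBlock(syntheticSpec(m = 50, seed = 7))
#' dim(im)
#' @export
generateBlock <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  set.seed(spec@seed)
  n <- length(spec@criteriaLabels)
  z <- MASS::mvrnorm(spec@m, mu = rep(0, n), Sigma = spec@targetRho,
                     tol = 1e-6)
  ## enforce exact co/antimonotonicity where requested, immune to the
  ## floating-point noise of the eigendecomposition sampler
  for (k in seq_len(n - 1L)) for (l in seq.int(k + 1L, n)) {
    if (spec@targetRho[k, l] == 1) z[, l] <- z[, k]
    if (spec@targetRho[k, l] == -1) z[, l] <- -z[, k]
  }
  isExp <- grepl("logK", spec@criteriaLabels, ignore.case = TRUE)
  isRmsd <- spec@blockKind %in% c("best_rmsd", "rmsd_best_ds")
  ev <- sapply(seq_len(n), function(j) {
    if (isExp[j]) 6 + 1.9 * z[, j]                # -logK, pK units
    else if (isRmsd) 1.5 * exp(0.55 * z[, j])     # RMSD, Angstroms, > 0
    else -12 + 2.5 * z[, j]                       # docking score, kcal/mol
  })
  IndexMatrix(ev,
              objectLabels = sprintf("L%03d", seq_len(spec@m)),
              criteriaLabels = spec@criteriaLabels)
}

#' Latent correlation achieving a target degree of agreement
#'
#' Inverts the Gaussian-copula concordance identity
#' mu = 1/2 + asin(rho)/pi, giving the latent correlation whose generated
#' blocks recover `muTarget` in expectation (tie-free marginals).
#'
#' @param muTarget degree of agreement in the open interval (0, 1); for the
#'   boundary values use the exact comonotone construction (`targetRho`
#'   entries of +/-1) instead.
#' @return latent correlation rho = sin(pi (muTarget - 1/2)).
#' @examples
#' rhoForTargetMu(0.5)    # 0: independent criteria
#' rhoForTargetMu(0.84)   # sin(0.34 * pi)
#' @export
rhoForTargetMu <- function(muTarget) {
  if (any(muTarget <= 0) || any(muTarget >= 1))
    stop("muTarget must lie strictly inside (0, 1); ",
         "use exact comonotone columns for mu = 0 or 1", call. = FALSE)
  sin(pi * (muTarget - 0.5))
}

#' @describeIn rhoForTargetMu the forward map: expected mu for a latent
#'   correlation rho.
#' @param rho latent Gaussian correlation in \[-1, 1\].
#' @export
muForRho <- function(rho) 0.5 + asin(rho) / pi

#' Assemble a full latent correlation matrix from pairwise mu targets
#'
#' Builds the criteria x criteria latent correlation matrix whose (k, l)
#' entry is [rhoForTargetMu()] of the requested agreement for that pair.
#' Joint calibration from 15 independent pairwise targets need not be
#' positive semi-definite; when it is not, the matrix is projected to the
#' nearest correlation matrix (`Matrix::nearPD`) and the achieved expected
#' mu values are reported next to the requested ones.
#'
#' @param muTargets named numeric vector of target agreement degrees; names
#'   are `"<criterion1>-<criterion2>"` pair labels.
#' @param labels character vector of criteria labels covering every name
#'   in `muTargets`.
#' @return list with `rho` (the PSD matrix), `adjusted` (logical: was a
#'   projection needed), and `achieved` (data.frame of requested vs
#'   expected mu after projection).
#' @export
calibrateRho <- function(muTargets, labels) {
  n <- length(labels)
  rho <- diag(n)
  dimnames(rho) <- list(labels, labels)
  parts <- lapply(names(muTargets), .splitPairLabel, labels = labels)
  for (i in seq_along(muTargets)) {
    p <- parts[[i]]
    rho[p[1L], p[2L]] <- rho[p[2L], p[1L]] <- rhoForTargetMu(muTargets[[i]])
  }
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  adjusted <- min(ev) < -1e-10
  if (adjusted)
    rho <- as.matrix(Matrix::nearPD(rho, corr = TRUE)$mat)
  achieved <- data.frame(
    pair = names(muTargets),
    requested = unname(muTargets),
    achieved = vapply(seq_along(muTargets), function(i) {
      p <- parts[[i]]
      muForRho(rho[p[1L], p[2L]])
    }, numeric(1)))
  list(rho = rho, adjusted = adjusted, achieved = achieved)
}

## Split "A-B" into known criteria labels A and B. Criterion names may
## themselves contain hyphens (e.g. "-logKd/Ki"), so every split point is
## tried against the label set rather than splitting on the first "-".
.splitPairLabel <- function(pairLabel, labels) {
  seps <- gregexpr("-", pairLabel, fixed = TRUE)[[1L]]
  for (at in seps) {
    left <- substr(pairLabel, 1L, at - 1L)
    right <- substr(pairLabel, at + 1L, nchar(pairLabel))
    if (left %in% labels && right %in% labels) return(c(left, right))
  }
  stop(sprintf("pair label '%s' does not name two known criteria", pairLabel),
       call. = FALSE)
}
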