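## Published reference values for the docking scoring-function comparison:
## degrees of agreement mu for all 15 criteria pairs (10 scoring-function
## pairs + 5 pairs against the experimental -logKd/-logKi column) in each
## of the four docking outputs, and the matching Pearson correlation
## coefficients. The raw docking evaluations behind these numbers are not
## public, so the tables are shipped as given inputs for the threshold
## analysis and display tests, not recomputed.

.blockLabels <- c("BestDS", "BestRMSD", "RMSD_BestDS", "DS_BestRMSD")

.pairLabels <- c(
  "Affinity dG-Alpha HB", "Affinity dG-ASE", "Affinity dG-GBVI/WSA dG",
  "Affinity dG-London dG", "Alpha HB-ASE", "Alpha HB-GBVI/WSA dG",
  "Alpha HB-London dG", "ASE-GBVI/WSA dG", "ASE-London dG",
  "GBVI/WSA dG-London dG", "Affinity dG--logKd/Ki", "Alpha HB--logKd/Ki",
  "ASE--logKd/Ki", "GBVI/WSA dG--logKd/Ki", "London dG--logKd/Ki")

.table1mu <- matrix(c(
  0.60, 0.81, 0.67, 0.59,
  0.62, 0.77, 0.68, 0.57,
  0.55, 0.83, 0.67, 0.61,
  0.56, 0.78, 0.63, 0.56,
  0.66, 0.79, 0.64, 0.62,
  0.47, 0.76, 0.69, 0.45,
  0.72, 0.84, 0.68, 0.70,
  0.44, 0.73, 0.66, 0.36,
  0.62, 0.77, 0.65, 0.60,
  0.48, 0.73, 0.64, 0.46,
  0.45, 0.57, 0.50, 0.53,
  0.40, 0.53, 0.44, 0.49,
  0.35, 0.56, 0.37, 0.57,
  0.58, 0.56, 0.60, 0.55,
  0.45, 0.53, 0.45, 0.48), nrow = 15L, byrow = TRUE)

.table4r <- matrix(c(
   0.20, 0.74, 0.55,  0.19,
   0.23, 0.68, 0.53,  0.03,
   0.12, 0.81, 0.55,  0.22,
   0.14, 0.66, 0.35,  0.06,
   0.54, 0.77, 0.45,  0.42,
  -0.10, 0.63, 0.53, -0.05,
   0.55, 0.79, 0.52,  0.47,
  -0.19, 0.57, 0.48, -0.16,
   0.29, 0.68, 0.42,  0.24,
  -0.16, 0.57, 0.36, -0.06,
  -0.08, 0.21, 0.19,  0.06,
  -0.29, 0.10, 0.03, -0.18,
  -0.42, 0.12, 0.24, -0.37,
   0.13, 0.23, 0.19,  0.09,
  -0.13, 0.06, -0.02, -0.11), nrow = 15L, byrow = TRUE)

#' Published agreement degrees for the docking scoring-function study
#'
#' The degrees of agreement mu between the five MOE scoring functions
#' (and the experimental -logKd/-logKi column) over 195 protein--ligand
#' complexes, one column per docking output: best docking score (BestDS),
#' lowest pose RMSD (BestRMSD), RMSD of the best-scored pose
#' (RMSD_BestDS), and score of the lowest-RMSD pose (DS_BestRMSD). Values
#' are as printed, at two decimals. This is the standing input of the
#' threshold-sweep analysis.
#'
#' @return 15 x 4 numeric matrix, rownames = criteria-pair labels,
#'   colnames = docking-output blocks, all values in \[0, 1\].
#' @examples
#' table1Fixture()["Alpha HB-London dG", ]
#' @export
table1Fixture <- function() {
  mu <- .table1mu
  dimnames(mu) <- list(.pairLabels, .blockLabels)
  mu
}

#' Published Pearson correlations for the same criteria pairs
#'
#' The correlation coefficients reported next to the agreement degrees of
#' [table1Fixture()], for juxtaposition displays. Like the mu values, they
#' derive from unpublished raw docking outputs and are shipped as
#' constants.
#'
#' @return 15 x 4 numeric matrix shaped like [table1Fixture()].
#' @export
table4Fixture <- function() {
  r <- .table4r
  dimnames(r) <- list(.pairLabels, .blockLabels)
  r
}

#' @rdname table1Fixture
#' @export
dockingBlockLabels <- function() .blockLabels

#' @rdname table1Fixture
#' @export
scoringPairLabels <- function() .pairLabels
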