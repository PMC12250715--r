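#' Sweep classification thresholds over a table of agreement degrees
#'
#' Varies the gap between alpha and beta while keeping alpha + beta = 1,
#' and summarizes positive-consonance membership from both directions:
#' pairs per block (how sensitive each evaluation block is to the
#' thresholds) and blocks per pair (how consistently comparable each pair
#' of criteria is). The default grid alpha in {0.75, 0.70, 0.67, 0.65,
#' 0.60} spans the conventional quarters setting down to a gap of 0.2.
#'
#' Since beta = 1 - alpha and nu is completed as 1 - mu, classification
#' reduces to the one-dimensional rule mu >= alpha (inclusive boundary),
#' so per-block counts are necessarily non-increasing in alpha.
#'
#' @inheritParams countPositivePerBlock
#' @param alphas numeric vector of alpha values, each in (0.5, 1]; beta is
#'   1 - alpha.
#' @param scale,boundary passed to [thresholdScheme()].
#' @return a [SweepSummary-class].
#' @examples
#' sw <- thresholdSweep(table1Fixture())
#' perBlockCounts(sw)
#' @export
thresholdSweep <- function(muTable,
                           alphas = c(0.75, 0.70, 0.67, 0.65, 0.60),
                           scale = "quarters", boundary = "inclusive",
                           nuTable = NULL) {
  if (any(alphas <= 0.5) || any(alphas > 1))
    stop("alphas must lie in (0.5, 1] so that alpha > beta = 1 - alpha",
         call. = FALSE)
  schemes <- lapply(alphas, function(a)
    thresholdScheme(a, 1 - a, scale = scale, boundary = boundary))
  mu <- .asMuMatrix(muTable)
  perBlock <- do.call(rbind, lapply(schemes, function(sch)
    countPositivePerBlock(mu, sch, nuTable)))
  rownames(perBlock) <- vapply(schemes, .schemeLabel, character(1))
  perPair <- countPositivePerPair(mu, schemes, nuTable)
  new("SweepSummary", perBlock = perBlock, perPair = perPair,
      alphas = alphas, scheme = schemes[[1L]])
}

#' @describeIn SweepSummary threshold-settings x blocks count matrix.
#' @param x a SweepSummary.
#' @export
perBlockCounts <- function(x) {
  stopifnot(is(x, "SweepSummary"))
  x@perBlock
}

#' @describeIn SweepSummary pairs x threshold-settings count matrix.
#' @export
perPairCounts <- function(x) {
  stopifnot(is(x, "SweepSummary"))
  x@perPair
}

setMethod("show", "SweepSummary", function(object) {
  cat(sprintf("SweepSummary over alpha = {%s} (%s scale, %s boundary)\n",
              paste(object@alphas, collapse = ", "),
              object@scheme@scale, object@scheme@boundary))
  cat("pairs in positive consonance per block:\n")
  print(object@perBlock)
  invisible(NULL)
})

#' Write sweep summaries as CSV
#'
#' @param sweep a [SweepSummary-class].
#' @param dir output directory (created if needed).
#' @return paths written (`per_block.csv`, `per_pair.csv`), invisibly.
#' @export
writeSweepSummary <- function(sweep, dir) {
  stopifnot(is(sweep, "SweepSummary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("per_block.csv", "per_pair.csv"))
  pb <- data.frame("alpha/beta" = rownames(sweep@perBlock), sweep@perBlock,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(pb, paths[1L], row.names = FALSE, quote = FALSE)
  pp <- data.frame(pair = rownames(sweep@perPair), sweep@perPair,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(pp, paths[2L], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
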