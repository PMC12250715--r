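#' Pearson correlation between two criteria columns
#'
#' A checked wrapper around the product-moment coefficient, with the
#' preconditions a pairwise criteria comparison needs: equal lengths of at
#' least 3 and non-constant columns (a constant column has undefined
#' correlation and is treated as an error rather than returned as NA).
#'
#' @param xs,ys numeric vectors of equal length >= 3.
#' @return the correlation coefficient in \[-1, 1\].
#' @examples
#' pearson(1:4, c(1, 3, 2, 4))  # 0.8
#' @export
pearson <- function(xs, ys) {
  if (length(xs) != length(ys))
    stop("xs and ys must have the same length", call. = FALSE)
  if (length(xs) < 3L)
    stop("at least three observations are required", call. = FALSE)
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stop("correlation is undefined for a constant column", call. = FALSE)
  stats::cor(xs, ys, method = "pearson")
}

#' Juxtapose ICrA agreement degrees with Pearson correlations
#'
#' For every criteria pair in every evaluation block, reports the ICrA
#' degree of agreement mu next to the Pearson correlation r computed from
#' the same evaluations. The two measures answer related but different
#' questions: mu counts order concordance (invariant under any strictly
#' increasing transform of a column), while r measures linear association
#' (invariant only under positive affine transforms). Comparing them
#' side by side shows where rank agreement exists without linearity.
#'
#' @param icraResults named list of [ICrAResult-class], one per block.
#' @param matrices named list of [IndexMatrix-class] with the same names
#'   and the same criteria labels as the corresponding results.
#' @return data.frame with columns `pair`, `block`, `mu`, `nu`, `r`,
#'   sorted by pair then block.
#' @examples
#' im <- IndexMatrix(cbind(A = c(1, 2, 3, 4), B = c(2, 4, 6, 9)))
#' juxtapose(list(demo = runICrA(im)), list(demo = im))
#' @export
juxtapose <- function(icraResults, matrices) {
  if (!identical(names(icraResults), names(matrices)))
    stop("block names of results and matrices must match", call. = FALSE)
  if (is.null(names(icraResults)))
    stop("blocks must be named", call. = FALSE)
  rows <- lapply(names(icraResults), function(blk) {
    res <- icraResults[[blk]]
    im <- matrices[[blk]]
    if (!identical(criteriaLabels(res), criteriaLabels(im)))
      stop(sprintf("criteria labels disagree in block '%s'", blk),
           call. = FALSE)
    ev <- evaluations(im)
    long <- icraPairs(res)
    long$block <- blk
    long$r <- mapply(function(c1, c2) pearson(ev[, c1], ev[, c2]),
                     long$c1, long$c2)
    long[, c("pair", "block", "mu", "nu", "r")]
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$pair, out$block), ]
  rownames(out) <- NULL
  out
}
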