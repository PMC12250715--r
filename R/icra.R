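## Core of InterCriteria analysis: relation counting over all object pairs
## and the normalized intuitionistic fuzzy degrees.

## Sign of every upper-triangle pairwise difference of x, with differences
## within eps of zero flagged as ties (0). Length m(m-1)/2, ordered by
## column-major upper triangle, i.e. pairs (1,2), (1,3), (2,3), (1,4), ...
.pairSigns <- function(x, eps) {
  m <- length(x)
  d <- outer(x, x, "-")[upper.tri(matrix(0, m, m))]
  s <- sign(d)
  s[abs(d) <= eps] <- 0
  s
}

.countFromSigns <- function(sk, sl, tieMode) {
  tied <- sk == 0L | sl == 0L
  sMu <- sum(!tied & sk == sl)
  sNu <- sum(!tied & sk != sl)
  if (tieMode == "mu_biased") {
    bothTied <- sk == 0L & sl == 0L
    sMu <- sMu + sum(bothTied)
    sTie <- sum(tied) - sum(bothTied)
  } else {
    sTie <- sum(tied)
  }
  c(sMu = sMu, sNu = sNu, sTie = sTie)
}

#' Intuitionistic fuzzy counters for one pair of criteria
#'
#' Compares two criteria over the same m objects by walking all
#' m(m-1)/2 unordered object pairs. For each object pair the relation
#' R = "greater than" either holds or its dual holds in each criterion:
#' the pair is *concordant* (increments `sMu`) when R holds in both
#' criteria or the dual holds in both, and *discordant* (increments `sNu`)
#' when R holds in one and the dual in the other. Object pairs where either
#' criterion's two evaluations are equal within `epsilon` carry no order
#' information; under the default `"unbiased"` tie mode they are absorbed
#' into `sTie` (and so into the uncertainty degree pi), while `"mu_biased"`
#' credits pairs tied in *both* criteria to `sMu` (agreement by shared
#' indifference).
#'
#' The counts always satisfy the conservation identity
#' `sMu + sNu + sTie = m(m-1)/2`.
#'
#' @param xs,ys numeric vectors of evaluations of the two criteria over the
#'   same objects; equal length m >= 2, all finite.
#' @param tieMode `"unbiased"` (default) or `"mu_biased"`.
#' @param epsilon non-negative tie tolerance on evaluation differences
#'   (default 0: exact equality is a tie).
#' @return named integer vector `c(sMu, sNu, sTie)`.
#' @examples
#' pairwiseCounters(c(1, 2, 3), c(1, 2, 3))   # 3 concordant pairs
#' pairwiseCounters(c(1, 2, 3), c(3, 2, 1))   # 3 discordant pairs
#' pairwiseCounters(c(1, 2, 2, 3), c(2, 1, 3, 3))
#' @export
pairwiseCounters <- function(xs, ys, tieMode = c("unbiased", "mu_biased"),
                             epsilon = 0) {
  tieMode <- match.arg(tieMode)
  if (length(xs) != length(ys))
    stop("xs and ys must have the same length", call. = FALSE)
  if (length(xs) < 2L)
    stop("at least two objects are required", call. = FALSE)
  if (!all(is.finite(xs)) || !all(is.finite(ys)))
    stop("evaluations must be finite", call. = FALSE)
  if (epsilon < 0)
    stop("epsilon must be non-negative", call. = FALSE)
  .countFromSigns(.pairSigns(xs, epsilon), .pairSigns(ys, epsilon), tieMode)
}

#' Degrees of agreement and disagreement from counters
#'
#' Normalizes the concordance counters by the total number of object pairs:
#' \deqn{\mu_{C_k,C_l} = 2 S^\mu_{k,l} / (m(m-1)), \quad
#'       \nu_{C_k,C_l} = 2 S^\nu_{k,l} / (m(m-1)),}
#' with the uncertainty degree \eqn{\pi = 1 - \mu - \nu} absorbing
#' tie-dropped comparisons.
#'
#' @param counters named vector as returned by [pairwiseCounters()] (only
#'   `sMu` and `sNu` are used).
#' @param m number of objects (>= 2).
#' @return an [IFPairs-class] of length 1.
#' @examples
#' degrees(c(sMu = 3, sNu = 1, sTie = 2), m = 4)  # <0.5, 1/6>
#' @export
degrees <- function(counters, m) {
  if (m < 2L) stop("m must be at least 2", call. = FALSE)
  np <- m * (m - 1) / 2
  ifPairs(mu = unname(counters["sMu"]) / np,
          nu = unname(counters["sNu"]) / np)
}

#' Construct intuitionistic fuzzy pairs
#'
#' @param mu,nu numeric vectors of equal length with `mu + nu <= 1`
#'   elementwise. When `nu` is omitted it defaults to `1 - mu`, the
#'   tie-free (pi = 0) completion used when only agreement degrees are
#'   reported.
#' @return a validated [IFPairs-class].
#' @export
ifPairs <- function(mu, nu = 1 - mu) {
  new("IFPairs", mu = as.numeric(mu), nu = as.numeric(nu))
}

#' @describeIn IFPairs agreement degrees.
#' @export
setMethod("agreement", "IFPairs", function(x) x@mu)

#' @describeIn IFPairs disagreement degrees.
#' @export
setMethod("disagreement", "IFPairs", function(x) x@nu)

#' @describeIn IFPairs uncertainty degrees pi = 1 - mu - nu.
#' @export
setMethod("uncertainty", "IFPairs", function(x) 1 - x@mu - x@nu)

#' @rdname IFPairs
#' @export
setMethod("length", "IFPairs", function(x) length(x@mu))

setMethod("show", "IFPairs", function(object) {
  cat(sprintf("IFPairs of length %d\n", length(object)))
  df <- data.frame(mu = object@mu, nu = object@nu,
                   pi = uncertainty(object))
  if (!is.null(names(object@mu))) rownames(df) <- names(object@mu)
  print(utils::head(df, 10L))
  if (length(object) > 10L)
    cat(sprintf("... and %d more\n", length(object) - 10L))
  invisible(NULL)
})

#' Run InterCriteria analysis on an index matrix
#'
#' Evaluates every one of the n(n-1)/2 unordered pairs of criteria with
#' [pairwiseCounters()] and [degrees()], assembling the symmetric output
#' index matrix of intuitionistic fuzzy pairs with \eqn{\langle 1, 0\rangle}
#' on the diagonal.
#'
#' Because only the order of evaluations within each criterion matters, the
#' result is invariant under any strictly increasing transform of a
#' criterion's column, and under any permutation of the objects. This is
#' what makes ICrA applicable across criteria measured on entirely
#' different scales (docking scores, RMSDs, affinities).
#'
#' @param im an [IndexMatrix-class] (objects x criteria).
#' @inheritParams pairwiseCounters
#' @return an [ICrAResult-class].
#' @examples
#' im <- IndexMatrix(cbind(A = c(1, 2, 3, 4), B = c(1, 3, 2, 4),
#'                         C = c(4, 3, 2, 1)))
#' res <- runICrA(im)
#' agreement(res)
#' @export
runICrA <- function(im, tieMode = c("unbiased", "mu_biased"), epsilon = 0) {
  stopifnot(is(im, "IndexMatrix"))
  tieMode <- match.arg(tieMode)
  ev <- evaluations(im)
  m <- nrow(ev)
  n <- ncol(ev)
  np <- m * (m - 1) / 2
  signs <- lapply(seq_len(n), function(k) .pairSigns(ev[, k], epsilon))

  lab <- criteriaLabels(im)
  mu <- nu <- sMu <- sNu <- sTie <- matrix(0, n, n)
  for (k in seq_len(n - 1L)) {
    for (l in seq.int(k + 1L, n)) {
      cnt <- .countFromSigns(signs[[k]], signs[[l]], tieMode)
      mu[k, l] <- mu[l, k] <- cnt[["sMu"]] / np
      nu[k, l] <- nu[l, k] <- cnt[["sNu"]] / np
      sMu[k, l] <- sMu[l, k] <- cnt[["sMu"]]
      sNu[k, l] <- sNu[l, k] <- cnt[["sNu"]]
      sTie[k, l] <- sTie[l, k] <- cnt[["sTie"]]
    }
  }
  diag(mu) <- 1
  diag(sMu) <- np
  dimnames(mu) <- dimnames(nu) <- dimnames(sMu) <- dimnames(sNu) <-
    dimnames(sTie) <- list(lab, lab)
  new("ICrAResult", mu = mu, nu = nu, sMu = sMu, sNu = sNu, sTie = sTie,
      m = as.integer(m), tieMode = tieMode, epsilon = epsilon)
}

#' @describeIn ICrAResult the symmetric matrix of agreement degrees mu.
#' @export
setMethod("agreement", "ICrAResult", function(x) x@mu)

#' @describeIn ICrAResult the symmetric matrix of disagreement degrees nu.
#' @export
setMethod("disagreement", "ICrAResult", function(x) x@nu)

#' @describeIn ICrAResult the matrix of uncertainty degrees pi.
#' @export
setMethod("uncertainty", "ICrAResult", function(x) 1 - x@mu - x@nu)

#' @describeIn ICrAResult list of raw counter matrices (sMu, sNu, sTie).
#' @export
setMethod("counters", "ICrAResult",
          function(x) list(sMu = x@sMu, sNu = x@sNu, sTie = x@sTie))

#' @rdname ICrAResult
#' @export
setMethod("criteriaLabels", "ICrAResult", function(x) colnames(x@mu))

setMethod("show", "ICrAResult", function(object) {
  n <- ncol(object@mu)
  cat(sprintf(
    "ICrAResult: %d criteria over %d objects (%s ties, epsilon = %g)\n",
    n, object@m, object@tieMode, object@epsilon))
  cat("agreement degrees mu:\n")
  print(round(object@mu, 3L))
  invisible(NULL)
})

#' Long-format view of an ICrA result
#'
#' One row per unordered criteria pair, with the agreement, disagreement
#' and uncertainty degrees.
#'
#' @param res an [ICrAResult-class].
#' @return data.frame with columns `pair`, `c1`, `c2`, `mu`, `nu`, `pi`.
#' @export
icraPairs <- function(res) {
  stopifnot(is(res, "ICrAResult"))
  lab <- criteriaLabels(res)
  n <- length(lab)
  idx <- which(upper.tri(res@mu), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  data.frame(
    pair = paste(lab[idx[, "row"]], lab[idx[, "col"]], sep = "-"),
    c1 = lab[idx[, "row"]], c2 = lab[idx[, "col"]],
    mu = res@mu[idx], nu = res@nu[idx],
    pi = 1 - res@mu[idx] - res@nu[idx],
    stringsAsFactors = FALSE)
}

#' Write an ICrA result as CSV tables
#'
#' Writes the twin square matrices of agreement (`mu.csv`) and disagreement
#' (`nu.csv`) degrees, mirroring ICrAData's two-table display, plus the
#' long-format pair table (`pairs.csv`).
#'
#' @param res an [ICrAResult-class].
#' @param dir output directory (created if needed).
#' @return character vector of the three paths written, invisibly.
#' @export
writeICrAResult <- function(res, dir) {
  stopifnot(is(res, "ICrAResult"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("mu.csv", "nu.csv", "pairs.csv"))
  .writeSquare(res@mu, paths[1L])
  .writeSquare(res@nu, paths[2L])
  utils::write.csv(icraPairs(res), paths[3L], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

.writeSquare <- function(mat, path) {
  df <- data.frame(criterion = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}
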