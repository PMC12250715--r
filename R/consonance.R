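#' Construct a ThresholdScheme
#'
#' @param alpha upper threshold in (0, 1]; default 0.75, the conventional
#'   default of ICrA software.
#' @param beta lower threshold in [0, 1) with `beta < alpha`; default 0.25.
#' @param scale `"quarters"` (three classes) or `"thirds"` (adds an
#'   uncertainty class; conventionally alpha = 0.67, beta = 0.33).
#' @param boundary `"inclusive"` (default; mu = alpha qualifies as positive
#'   consonance) or `"strict"`. The inclusive convention is the one that
#'   reproduces published counts from agreement degrees printed at two
#'   decimals.
#' @return a validated [ThresholdScheme-class].
#' @examples
#' thresholdScheme(0.67, 0.33, scale = "thirds")
#' @export
thresholdScheme <- function(alpha = 0.75, beta = 0.25,
                            scale = c("quarters", "thirds"),
                            boundary = c("inclusive", "strict")) {
  new("ThresholdScheme", alpha = alpha, beta = beta,
      scale = match.arg(scale), boundary = match.arg(boundary))
}

setMethod("show", "ThresholdScheme", function(object) {
  cat(sprintf("ThresholdScheme: alpha = %g, beta = %g (%s scale, %s boundary)\n",
              object@alpha, object@beta, object@scale, object@boundary))
  invisible(NULL)
})

.relationLevels <- c("positive_consonance", "negative_consonance",
                     "dissonance", "uncertainty")

#' Classify intuitionistic fuzzy pairs into consonance/dissonance
#'
#' Under the quarters scale a pair is in *positive consonance* when mu
#' exceeds alpha and nu falls below beta; in *negative consonance* when mu
#' falls below beta and nu exceeds alpha; and in *dissonance* otherwise.
#' The inclusive boundary (default) lets boundary values qualify on both
#' conditions (mu >= alpha, nu <= beta), which is what makes the rule
#' collapse to the one-dimensional test mu >= alpha when beta = 1 - alpha
#' and nu = 1 - mu; the strict boundary uses mu > alpha, nu < beta. The thirds scale refines dissonance by
#' carving out an *uncertainty* class for pairs where mu, nu and mu + nu
#' all fall below alpha -- the region dominated by the uncertainty degree
#' pi rather than by genuine opposition. Classes are tested in the order
#' positive, negative, uncertainty, so the classification is exhaustive
#' and mutually exclusive.
#'
#' @param pairs an [IFPairs-class], or a numeric vector of mu values (nu
#'   then defaults to 1 - mu).
#' @param scheme a [ThresholdScheme-class].
#' @return factor with levels positive_consonance, negative_consonance,
#'   dissonance, uncertainty (the last only reachable under the thirds
#'   scale), named like `pairs` when it carries names.
#' @examples
#' q <- thresholdScheme(0.75, 0.25)
#' classifyPairs(ifPairs(c(0.84, 0.60), c(0.16, 0.40)), q)
#' classifyPairs(ifPairs(0.2, 0.2), thresholdScheme(0.67, 0.33, "thirds"))
#' @export
classifyPairs <- function(pairs, scheme = thresholdScheme()) {
  stopifnot(is(scheme, "ThresholdScheme"))
  if (!is(pairs, "IFPairs")) pairs <- ifPairs(pairs)
  mu <- pairs@mu
  nu <- pairs@nu
  a <- scheme@alpha
  b <- scheme@beta
  ## threshold comparisons carry a tiny tolerance so that degrees derived
  ## by complementation (nu = 1 - mu) cannot miss a boundary by one ulp
  tol <- 1e-9
  inclusive <- scheme@boundary == "inclusive"
  atLeast <- if (inclusive) function(x, t) x >= t - tol else
    function(x, t) x > t + tol
  below <- if (inclusive) function(x, t) x <= t + tol else
    function(x, t) x < t - tol

  out <- rep("dissonance", length(mu))
  pos <- atLeast(mu, a) & below(nu, b)
  neg <- below(mu, b) & atLeast(nu, a)
  out[neg] <- "negative_consonance"
  out[pos] <- "positive_consonance"
  if (scheme@scale == "thirds") {
    unc <- !pos & !neg & mu < a & nu < a & (mu + nu) < a
    out[unc] <- "uncertainty"
  }
  factor(out, levels = .relationLevels) |>
    stats::setNames(names(mu))
}

#' Count pairs in positive consonance within each block
#'
#' Given a table of agreement degrees (criteria pairs x evaluation blocks,
#' e.g. the four docking outputs) classify every cell and count, per block,
#' the pairs in positive consonance. When only mu is available, nu is taken
#' as `1 - mu` -- exact whenever alpha + beta = 1, and the worst case
#' consistent with the intuitionistic fuzzy condition otherwise.
#'
#' @param muTable numeric matrix (rownames = pair labels, colnames = block
#'   labels), or a named list of identically-named numeric vectors, one per
#'   block.
#' @param scheme a [ThresholdScheme-class].
#' @param nuTable optional matrix of nu values, same shape as `muTable`;
#'   default `1 - muTable`.
#' @return named integer vector, one count per block.
#' @examples
#' countPositivePerBlock(table1Fixture(), thresholdScheme(0.75, 0.25))
#' @export
countPositivePerBlock <- function(muTable, scheme = thresholdScheme(),
                                  nuTable = NULL) {
  mu <- .asMuMatrix(muTable)
  nu <- if (is.null(nuTable)) 1 - mu else .asMuMatrix(nuTable)
  if (!identical(dim(mu), dim(nu)))
    stop("mu and nu tables must have the same shape", call. = FALSE)
  vapply(seq_len(ncol(mu)), function(j) {
    lab <- classifyPairs(ifPairs(mu[, j], nu[, j]), scheme)
    sum(lab == "positive_consonance")
  }, integer(1)) |> stats::setNames(colnames(mu))
}

#' Count blocks in positive consonance for each pair
#'
#' The transposed summary of [countPositivePerBlock()]: for every criteria
#' pair and every threshold scheme, in how many blocks is the pair in
#' positive consonance. A pair positive in many blocks indicates criteria
#' with consistently similar performance.
#'
#' @inheritParams countPositivePerBlock
#' @param schemes a [ThresholdScheme-class] or list of them.
#' @return integer matrix, pairs x schemes (columns named "alpha/beta").
#' @examples
#' countPositivePerPair(table1Fixture(),
#'                      list(thresholdScheme(0.67, 0.33, "thirds"),
#'                           thresholdScheme(0.70, 0.30)))
#' @export
countPositivePerPair <- function(muTable, schemes = thresholdScheme(),
                                 nuTable = NULL) {
  mu <- .asMuMatrix(muTable)
  nu <- if (is.null(nuTable)) 1 - mu else .asMuMatrix(nuTable)
  if (is(schemes, "ThresholdScheme")) schemes <- list(schemes)
  counts <- vapply(schemes, function(sch) {
    vapply(seq_len(nrow(mu)), function(i) {
      lab <- classifyPairs(ifPairs(mu[i, ], nu[i, ]), sch)
      sum(lab == "positive_consonance")
    }, integer(1))
  }, integer(nrow(mu)))
  counts <- matrix(counts, nrow = nrow(mu))
  dimnames(counts) <- list(rownames(mu),
                           vapply(schemes, .schemeLabel, character(1)))
  counts
}

.schemeLabel <- function(sch) sprintf("%.2f/%.2f", sch@alpha, sch@beta)

.asMuMatrix <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    if (is.null(names(x))) stop("blocks must be named", call. = FALSE)
    pairNames <- names(x[[1L]])
    if (is.null(pairNames))
      stop("each block must be a named vector of pair values", call. = FALSE)
    ok <- vapply(x, function(v) identical(sort(names(v)), sort(pairNames)),
                 logical(1))
    if (!all(ok))
      stop("all blocks must share the same pair-label set", call. = FALSE)
    x <- vapply(x, function(v) v[pairNames], numeric(length(pairNames)))
    rownames(x) <- pairNames
  }
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x))
    stop("mu table must be numeric with no missing values", call. = FALSE)
  x
}

#' Coordinates in the interpretative intuitionistic triangle
#'
#' Each pair \eqn{\langle\mu, \nu\rangle} is a point (x = mu, y = nu) in the
#' triangle with vertices (0,0) (full uncertainty), (1,0) (full agreement)
#' and (0,1) (full disagreement); the hypotenuse mu + nu = 1 holds the
#' pairs with no uncertainty. Useful for plotting results the way ICrA
#' software displays them.
#'
#' @param pairs an [IFPairs-class] (or numeric mu vector, nu = 1 - mu).
#' @return data.frame with columns `x`, `y` (and rownames from pair names).
#' @examples
#' triangleCoordinates(ifPairs(c(1, 0, 0.5), c(0, 1, 0.5)))
#' @export
triangleCoordinates <- function(pairs) {
  if (!is(pairs, "IFPairs")) pairs <- ifPairs(pairs)
  df <- data.frame(x = pairs@mu, y = pairs@nu)
  if (!is.null(names(pairs@mu))) rownames(df) <- names(pairs@mu)
  df
}

#' Display colors for relation labels
#'
#' The color semantics used by ICrA software: green for positive
#' consonance, red for negative consonance, magenta for dissonance. The
#' thirds-scale uncertainty class, which that display does not have, is
#' rendered grey.
#'
#' @param labels factor/character of relation labels from [classifyPairs()].
#' @return character vector of color names.
#' @export
relationColors <- function(labels) {
  map <- c(positive_consonance = "green", negative_consonance = "red",
           dissonance = "magenta", uncertainty = "grey")
  unname(map[as.character(labels)])
}
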