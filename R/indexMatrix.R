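#' Construct an IndexMatrix
#'
#' @param evaluations numeric matrix (objects in rows, criteria in columns)
#'   or an object coercible to one.
#' @param objectLabels optional character vector of row labels; defaults to
#'   existing rownames, or `O1..Om`.
#' @param criteriaLabels optional character vector of column labels; defaults
#'   to existing colnames, or `C1..Cn`.
#' @return a validated [IndexMatrix-class].
#' @examples
#' im <- IndexMatrix(cbind(a = c(1, 2, 3), b = c(2, 1, 3)))
#' dim(im)
#' @export
IndexMatrix <- function(evaluations, objectLabels = NULL,
                        criteriaLabels = NULL) {
  ev <- as.matrix(evaluations)
  storage.mode(ev) <- "double"
  if (is.null(objectLabels))
    objectLabels <- rownames(ev) %||% paste0("O", seq_len(nrow(ev)))
  if (is.null(criteriaLabels))
    criteriaLabels <- colnames(ev) %||% paste0("C", seq_len(ncol(ev)))
  dimnames(ev) <- list(as.character(objectLabels),
                       as.character(criteriaLabels))
  new("IndexMatrix", evaluations = ev)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname IndexMatrix
#' @export
setMethod("evaluations", "IndexMatrix", function(x) x@evaluations)

#' @rdname IndexMatrix
#' @export
setMethod("objectLabels", "IndexMatrix", function(x) rownames(x@evaluations))

#' @rdname IndexMatrix
#' @export
setMethod("criteriaLabels", "IndexMatrix", function(x) colnames(x@evaluations))

#' @rdname IndexMatrix
#' @export
setMethod("dim", "IndexMatrix", function(x) dim(x@evaluations))

#' @describeIn IndexMatrix swap the object and criteria axes. Transposition
#'   is an involution: `t(t(im))` equals `im`.
#' @export
setMethod("t", "IndexMatrix", function(x)
  new("IndexMatrix", evaluations = t(x@evaluations)))

setMethod("show", "IndexMatrix", function(object) {
  d <- dim(object)
  cat(sprintf("IndexMatrix: %d objects x %d criteria\n", d[1L], d[2L]))
  cat("criteria:", paste(criteriaLabels(object), collapse = ", "), "\n")
  ev <- evaluations(object)
  print(utils::head(ev, 4L))
  if (d[1L] > 4L) cat(sprintf("... and %d more objects\n", d[1L] - 4L))
  invisible(NULL)
})

.detectDelimiter <- function(lines) {
  probe <- utils::head(lines, 5L)
  cands <- c(",", ";", "\t")
  counts <- vapply(cands, function(d)
    sum(nchar(probe) - nchar(gsub(d, "", probe, fixed = TRUE))), numeric(1))
  if (all(counts == 0))
    stop("could not detect a delimiter (none of ',', ';', tab present)",
         call. = FALSE)
  cands[which.max(counts)]
}

#' Read an IndexMatrix from delimited text
#'
#' Reads a CSV/TSV table with one header row of labels and one label column
#' into an [IndexMatrix-class]. The delimiter is auto-detected among comma,
#' semicolon and tab unless given. When the file stores criteria in rows
#' (`orientation = "criteria_as_rows"`), the result is transposed so that
#' objects are always rows. Decimal commas (e.g. `"0,5"`) are rejected
#' rather than silently misparsed; any other non-numeric cell raises an
#' error naming its row and column.
#'
#' @param source path to a file, or a character vector of lines / a single
#'   string containing the delimited text.
#' @param orientation `"objects_as_rows"` (default) or `"criteria_as_rows"`.
#' @param delimiter single character, or `NULL` to auto-detect.
#' @return a validated [IndexMatrix-class] with objects as rows.
#' @examples
#' txt <- "id,scoreA,scoreB\nL1,1.5,2.0\nL2,0.5,1.0\nL3,2.5,0.1"
#' im <- readIndexMatrix(txt)
#' criteriaLabels(im)
#' @export
readIndexMatrix <- function(source,
                            orientation = c("objects_as_rows",
                                            "criteria_as_rows"),
                            delimiter = NULL) {
  orientation <- match.arg(orientation)
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("input must contain a header row and at least one data row",
         call. = FALSE)
  sep <- delimiter %||% .detectDelimiter(lines)

  fields <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L)
    stop(sprintf(
      "ragged input: rows have %s fields; all rows must match the header",
      paste(unique(widths), collapse = "/")), call. = FALSE)

  header <- trimws(fields[[1L]])[-1L]
  body <- fields[-1L]
  rowLabels <- trimws(vapply(body, `[`, character(1), 1L))
  cells <- lapply(body, function(f) trimws(f[-1L]))

  parsed <- matrix(NA_real_, nrow = length(body), ncol = length(header))
  for (i in seq_along(cells)) {
    suppressWarnings(vals <- as.numeric(cells[[i]]))
    bad <- which(!is.finite(vals))
    if (length(bad)) {
      cell <- cells[[i]][bad[1L]]
      hint <- if (grepl("^-?[0-9]+,[0-9]+$", cell))
        " (decimal commas are not accepted; use '.')" else ""
      stop(sprintf("non-numeric cell '%s' at object '%s', column '%s'%s",
                   cell, rowLabels[i], header[bad[1L]], hint), call. = FALSE)
    }
    parsed[i, ] <- vals
  }
  dimnames(parsed) <- list(rowLabels, header)
  if (orientation == "criteria_as_rows") parsed <- t(parsed)
  IndexMatrix(parsed)
}

#' Write an IndexMatrix as delimited text
#'
#' @param im an [IndexMatrix-class].
#' @param path output file path.
#' @param delimiter field separator (default comma).
#' @return `path`, invisibly.
#' @export
writeIndexMatrix <- function(im, path, delimiter = ",") {
  stopifnot(is(im, "IndexMatrix"))
  ev <- evaluations(im)
  df <- data.frame(object = rownames(ev), ev, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
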