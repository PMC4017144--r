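# Delimited-text readers/writers. Series files are T rows x N columns with
# a header row of region names; connectivity files are square matrices with
# region names on both axes (rows = target, columns = source). Values are
# written with 17 significant digits so write/read round trips are exact.

#' Read a multivariate time series from delimited text
#'
#' Expects T rows x N columns of numbers with a header row of region names.
#'
#' @param path Input file path.
#' @param sep Field separator (default tab).
#' @return T x N numeric matrix with region names as column names.
#' @export
read_timeseries <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 1 || nrow(df) < 1) stop("empty series file: ", path)
  m <- matrix(NA_real_, nrow(df), ncol(df),
              dimnames = list(NULL, names(df)))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v))
    if (length(bad) > 0)
      stop(sprintf(
        "non-numeric or missing value at row %d, column '%s' of %s",
        bad[1], names(df)[j], path))
    m[, j] <- v
  }
  m
}

#' Write a multivariate time series as delimited text
#'
#' @param y T x N matrix; unnamed columns are labelled `R1..RN`.
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @export
write_timeseries <- function(y, path, sep = "\t") {
  y <- as.matrix(y)
  if (is.null(colnames(y))) colnames(y) <- paste0("R", seq_len(ncol(y)))
  body <- apply(y, 2, function(v) sprintf("%.17g", v))
  if (!is.matrix(body)) body <- matrix(body, nrow = nrow(y))
  utils::write.table(rbind(colnames(y), body), path, sep = sep,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a connectivity matrix as delimited text
#'
#' Square matrix with a region-name header row and column; cell (i, j) is
#' the strength of the influence of region j (column) on region i (row).
#'
#' @param C Square numeric matrix.
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @export
write_connectivity <- function(C, path, sep = "\t") {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C)) stop("'C' must be square")
  nm <- if (is.null(rownames(C))) paste0("R", seq_len(nrow(C)))
        else rownames(C)
  body <- cbind(nm, apply(C, 2, function(v) sprintf("%.17g", v)))
  utils::write.table(rbind(c("", nm), body), path, sep = sep,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a connectivity matrix written by [write_connectivity()]
#'
#' @param path Input file path.
#' @param sep Field separator (default tab).
#' @return Square numeric matrix with region names on both axes.
#' @export
read_connectivity <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("connectivity file is not square: ", path)
  storage.mode(m) <- "double"
  if (any(is.na(m))) stop("missing values in connectivity file: ", path)
  m
}

#' Write a JSON run manifest
#'
#' Records the package version, a timestamp, and any named settings (seeds,
#' input digests, convergence diagnostics, ...) needed to re-execute a run.
#'
#' @param path Output file path.
#' @param ... Named settings to record.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, ...) {
  manifest <- c(list(tool = "vbconn",
                     version = as.character(utils::packageVersion("vbconn")),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                list(...))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
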