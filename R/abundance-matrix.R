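#' Construct an AbundanceMatrix
#'
#' @param values numeric matrix of nonnegative abundances,
#'   observations in rows, features in columns.
#' @param featureIds unique feature identifiers; defaults to the column
#'   names, or `f1..fP` when absent.
#' @param obsIds unique observation identifiers; defaults to the row names,
#'   or `s1..sN` when absent.
#' @param coords optional integer matrix of pixel coordinates
#'   (`n_obs` rows, 2 or 3 columns).
#'
#' @return an [AbundanceMatrix-class].
#' @examples
#' m <- AbundanceMatrix(matrix(1:6, nrow = 3, ncol = 2))
#' dim(m)
#' featureIds(m)
#' @export
AbundanceMatrix <- function(values, featureIds = NULL, obsIds = NULL,
                            coords = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(featureIds)) {
    featureIds <- colnames(values)
    if (is.null(featureIds)) featureIds <- paste0("f", seq_len(ncol(values)))
  }
  if (is.null(obsIds)) {
    obsIds <- rownames(values)
    if (is.null(obsIds)) obsIds <- paste0("s", seq_len(nrow(values)))
  }
  dimnames(values) <- NULL
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    storage.mode(coords) <- "integer"
  }
  new("AbundanceMatrix", values = values,
      featureIds = as.character(featureIds), obsIds = as.character(obsIds),
      coords = coords)
}

#' @rdname AbundanceMatrix-class
#' @export
setMethod("abundances", "AbundanceMatrix", function(x) x@values)

#' @rdname AbundanceMatrix-class
#' @export
setMethod("featureIds", "AbundanceMatrix", function(x) x@featureIds)

#' @rdname AbundanceMatrix-class
#' @export
setMethod("obsIds", "AbundanceMatrix", function(x) x@obsIds)

#' @rdname AbundanceMatrix-class
#' @export
setMethod("coords", "AbundanceMatrix", function(x) x@coords)

#' @rdname AbundanceMatrix-class
#' @export
setMethod("dim", "AbundanceMatrix", function(x) dim(x@values))

#' @rdname AbundanceMatrix-class
#' @param i,j row (observation) and column (feature) indices.
#' @param ... ignored.
#' @param drop ignored; subsetting always returns an `AbundanceMatrix`.
#' @export
setMethod("[", "AbundanceMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@values))
  if (missing(j)) j <- seq_len(ncol(x@values))
  new("AbundanceMatrix",
      values = x@values[i, j, drop = FALSE],
      featureIds = x@featureIds[j],
      obsIds = x@obsIds[i],
      coords = if (is.null(x@coords)) NULL else x@coords[i, , drop = FALSE])
})

setMethod("show", "AbundanceMatrix", function(object) {
  cat("AbundanceMatrix:", nrow(object@values), "observations x",
      ncol(object@values), "features\n")
  if (!is.null(object@coords)) {
    cat("  with", ncol(object@coords), "D pixel coordinates\n")
  }
  cat("  abundance range: [",
      format(min(object@values), digits = 4), ", ",
      format(max(object@values), digits = 4), "]\n", sep = "")
})

.formatFromPath <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = "csv",
    tsv = "tsv",
    txt = "tsv",
    bin = "binary",
    stop("cannot infer matrix format from extension '.", ext,
         "'; pass 'format' explicitly", call. = FALSE)
  )
}

#' Read an abundance matrix from disk
#'
#' Delimited text (`csv`/`tsv`: header row of feature identifiers, first
#' column of observation identifiers) or a raw little-endian double binary
#' container with a JSON sidecar (`<path>.json`) declaring shape and
#' identifiers.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"binary"`.
#' @return an [AbundanceMatrix-class]; negative abundances are rejected.
#' @seealso [writeMatrix()]
#' @export
readMatrix <- function(path, format = c("auto", "csv", "tsv", "binary")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- .formatFromPath(path)
  if (format == "binary") {
    side <- paste0(path, ".json")
    if (!file.exists(side)) {
      stop("binary container requires a sidecar at ", side, call. = FALSE)
    }
    meta <- jsonlite::fromJSON(side)
    needed <- c("n_obs", "n_feat", "obs_ids", "feature_ids")
    if (!all(needed %in% names(meta))) {
      stop("malformed binary sidecar: missing ",
           paste(setdiff(needed, names(meta)), collapse = ", "),
           call. = FALSE)
    }
    n <- as.integer(meta$n_obs)
    p <- as.integer(meta$n_feat)
    raw <- readBin(path, what = "double", n = n * p, size = 8,
                   endian = "little")
    if (length(raw) != n * p) stop("binary payload shorter than declared shape",
                                   call. = FALSE)
    values <- matrix(raw, nrow = n, ncol = p)
    return(AbundanceMatrix(values, featureIds = meta$feature_ids,
                           obsIds = meta$obs_ids))
  }
  sep <- if (format == "csv") "," else "\t"
  dt <- data.table::fread(path, sep = sep, header = TRUE, fill = FALSE,
                          data.table = FALSE)
  if (ncol(dt) < 2L) stop("malformed header: need an id column plus features",
                          call. = FALSE)
  obs <- as.character(dt[[1L]])
  values <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(values)) stop("non-numeric abundance entries", call. = FALSE)
  AbundanceMatrix(values, featureIds = colnames(dt)[-1L], obsIds = obs)
}

#' Write an abundance matrix to disk
#'
#' @param m an [AbundanceMatrix-class].
#' @param path output file.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"binary"`.
#'   The binary container stores little-endian doubles plus a JSON sidecar
#'   and round-trips bitwise through [readMatrix()].
#' @export
writeMatrix <- function(m, path, format = c("auto", "csv", "tsv", "binary")) {
  stopifnot(is(m, "AbundanceMatrix"))
  format <- match.arg(format)
  if (format == "auto") format <- .formatFromPath(path)
  if (format == "binary") {
    writeBin(as.vector(m@values), path, size = 8, endian = "little")
    jsonlite::write_json(
      list(n_obs = nrow(m@values), n_feat = ncol(m@values),
           obs_ids = m@obsIds, feature_ids = m@featureIds),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  df <- data.frame(obs_id = m@obsIds, m@values, check.names = FALSE)
  colnames(df) <- c("obs_id", m@featureIds)
  data.table::fwrite(df, path, sep = if (format == "csv") "," else "\t")
  invisible(path)
}

#' Read / write per-observation label and annotation tables
#'
#' Two-column TSV files: `obs_id` plus either an integer cluster label
#' (`readLabels`) or a region-of-interest name (`readRoi`).
#'
#' @param path input or output file.
#' @return `readLabels`: named integer vector; `readRoi`: named character
#'   vector.  Names are observation identifiers.
#' @export
readLabels <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  out <- as.integer(dt[[2L]])
  names(out) <- as.character(dt[[1L]])
  out
}

#' @rdname readLabels
#' @param labels integer labels, named by observation id (or unnamed).
#' @export
writeLabels <- function(labels, path) {
  ids <- names(labels)
  if (is.null(ids)) ids <- paste0("s", seq_along(labels))
  data.table::fwrite(data.frame(obs_id = ids, label = as.integer(labels)),
                     path, sep = "\t")
  invisible(path)
}

#' @rdname readLabels
#' @export
readRoi <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  out <- as.character(dt[[2L]])
  names(out) <- as.character(dt[[1L]])
  out
}
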