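#' Construct a ModelingDataset from matrices
#'
#' @param x a named list of numeric descriptor matrices (one per descriptor
#'   set) or a single matrix (wrapped as set \code{"descriptors"}).
#' @param y numeric response vector; binary responses are coded 0/1.
#' @param ids optional character identifiers (default \code{"1"..."n"}).
#' @param responseType \code{"auto"} (default; binary iff the response takes
#'   only the values 0 and 1), \code{"binary"} or \code{"continuous"}.
#' @return a validated \linkS4class{ModelingDataset}.
#' @examples
#' d <- makeModelingDataset(matrix(rnorm(20), 10), y = rep(c(0, 1), 5))
#' responseType(d)
#' @export
makeModelingDataset <- function(x, y, ids = NULL,
                                responseType = c("auto", "binary", "continuous")) {
  responseType <- match.arg(responseType)
  if (is.matrix(x)) x <- list(descriptors = x)
  if (!is.list(x)) stop("'x' must be a matrix or a named list of matrices")
  x <- lapply(x, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  y <- as.numeric(y)
  if (is.null(ids)) ids <- as.character(seq_along(y))
  if (responseType == "auto")
    responseType <- if (all(y %in% c(0, 1)) && !anyNA(y)) "binary" else "continuous"
  new("ModelingDataset", ids = as.character(ids), response = y,
      descriptorSets = x, responseType = responseType)
}

#' Describe a descriptor set inside a wider table
#'
#' A descriptor-set specification names a set and gives either its width
#' (\code{length}, consumed left-to-right from the descriptor columns in
#' declared order) or an explicit vector of column names/1-based positions.
#'
#' @param name descriptor-set name.
#' @param length number of contiguous descriptor columns in this set.
#' @param columns explicit column names or 1-based indices into the full table.
#' @return a \code{DescriptorSetSpec} list.
#' @export
descriptorSetSpec <- function(name, length = NULL, columns = NULL) {
  if (is.null(length) == is.null(columns))
    stop("give exactly one of 'length' or 'columns'")
  if (!nzchar(name)) stop("descriptor-set name must be non-empty")
  structure(list(name = name, length = length, columns = columns),
            class = "DescriptorSetSpec")
}

validateNumericCells <- function(df, cols, path) {
  for (cl in cols) {
    v <- df[[cl]]
    if (is.character(v) || is.factor(v)) {
      v2 <- suppressWarnings(as.numeric(as.character(v)))
      bad <- which(is.na(v2) & !is.na(v))
      if (length(bad))
        stop("non-numeric value in column '", cl, "', row ", bad[1],
             " of ", path)
      v <- v2
    }
    na <- which(is.na(v))
    if (length(na))
      stop("missing value in column '", cl, "', row ", na[1], " of ", path)
    df[[cl]] <- as.numeric(v)
  }
  df
}

#' Load a ModelingDataset from a delimited file
#'
#' Reads a comma-separated table with a header row holding an optional ID
#' column, one response column, and descriptor columns, and partitions the
#' descriptor columns into named descriptor sets.
#'
#' @param path CSV file path.
#' @param responseColumn name of the response column.
#' @param idColumn optional name of the ID column.
#' @param setSpecs optional list of \code{\link{descriptorSetSpec}}s.  When
#'   omitted, all non-ID, non-response columns form one set named
#'   \code{"descriptors"}.  Specs given as widths are consumed left-to-right
#'   in declared order.
#' @param responseType see \code{\link{makeModelingDataset}}.
#' @return a validated \linkS4class{ModelingDataset}.
#' @export
loadDataset <- function(path, responseColumn, idColumn = NULL, setSpecs = NULL,
                        responseType = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!responseColumn %in% names(df))
    stop("response column '", responseColumn, "' not found in ", path)
  if (!is.null(idColumn) && !idColumn %in% names(df))
    stop("id column '", idColumn, "' not found in ", path)
  descCols <- setdiff(names(df), c(responseColumn, idColumn))

  pickColumns <- function(spec) {
    if (!is.null(spec$columns)) {
      cols <- spec$columns
      if (is.numeric(cols)) {
        if (any(cols < 1 | cols > ncol(df)))
          stop("column index out of range in set '", spec$name, "'")
        cols <- names(df)[cols]
      }
      missing <- setdiff(cols, names(df))
      if (length(missing))
        stop("columns not found for set '", spec$name, "': ",
             paste(missing, collapse = ", "))
      if (any(cols %in% c(responseColumn, idColumn)))
        stop("set '", spec$name, "' overlaps the response/ID columns")
      cols
    } else {
      spec$length
    }
  }

  if (is.null(setSpecs)) {
    if (!length(descCols)) stop("no descriptor columns found")
    setCols <- list(descriptors = descCols)
  } else {
    setCols <- list()
    cursor <- 0L
    for (spec in setSpecs) {
      got <- pickColumns(spec)
      if (is.numeric(got) && length(got) == 1L && is.null(spec$columns)) {
        idx <- cursor + seq_len(got)
        if (max(idx) > length(descCols))
          stop("descriptor-set widths exceed the ", length(descCols),
               " available descriptor columns")
        setCols[[spec$name]] <- descCols[idx]
        cursor <- cursor + got
      } else {
        setCols[[spec$name]] <- got
      }
    }
    if (anyDuplicated(unlist(setCols)))
      stop("descriptor sets must not overlap")
  }

  used <- unique(unlist(setCols))
  df <- validateNumericCells(df, c(responseColumn, used), path)

  ids <- if (is.null(idColumn)) as.character(seq_len(nrow(df)))
         else as.character(df[[idColumn]])
  sets <- lapply(setCols, function(cols) {
    m <- as.matrix(df[, cols, drop = FALSE])
    storage.mode(m) <- "double"
    m
  })
  makeModelingDataset(sets, df[[responseColumn]], ids = ids,
                      responseType = responseType)
}

#' Write out-of-fold predictions to a long-format CSV
#'
#' One row per (split, descriptor set, method, observation) with the observed
#' response and the predicted score; round-trips through
#' \code{\link{readPredictions}}.
#'
#' @param store a non-empty \linkS4class{PredictionStore}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writePredictions <- function(store, path) {
  stopifnot(is(store, "PredictionStore"))
  if (!length(store@entries)) stop("the prediction store is empty")
  keys <- names(store@entries)
  parts <- strsplit(keys, "|", fixed = TRUE)
  n <- length(store@observed)
  rows <- lapply(seq_along(keys), function(i) {
    data.frame(
      split = as.integer(parts[[i]][1]),
      descriptor_set = parts[[i]][2],
      method = parts[[i]][3],
      id = store@ids,
      observed = store@observed,
      predicted = store@entries[[i]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a predictions CSV back into a PredictionStore
#'
#' @param path a CSV written by \code{\link{writePredictions}}.
#' @param responseType response type of the original data; \code{"auto"}
#'   infers binary iff observed values are all 0/1.
#' @return a \linkS4class{PredictionStore}.
#' @export
readPredictions <- function(path, responseType = "auto") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"))
  need <- c("split", "descriptor_set", "method", "id", "observed", "predicted")
  if (!all(need %in% names(df)))
    stop("predictions file must have columns: ", paste(need, collapse = ", "))
  first <- df[df$split == df$split[1] & df$descriptor_set == df$descriptor_set[1] &
              df$method == df$method[1], ]
  ids <- first$id
  observed <- first$observed
  if (responseType == "auto")
    responseType <- if (all(observed %in% c(0, 1))) "binary" else "continuous"
  keydf <- unique(df[, c("split", "descriptor_set", "method")])
  entries <- list()
  for (r in seq_len(nrow(keydf))) {
    sel <- df$split == keydf$split[r] &
      df$descriptor_set == keydf$descriptor_set[r] &
      df$method == keydf$method[r]
    block <- df[sel, ]
    block <- block[match(ids, block$id), ]
    entries[[storeKey(keydf$split[r], keydf$descriptor_set[r], keydf$method[r])]] <-
      block$predicted
  }
  new("PredictionStore", entries = entries,
      splits = sort(unique(as.integer(df$split))),
      setNames = unique(df$descriptor_set),
      methodNames = unique(df$method),
      ids = ids, observed = observed, responseType = responseType,
      failures = character())
}
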