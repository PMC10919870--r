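# Plain-text interchange: TSV matrices with a stimulus_id column, BIDS-style
# events tables, PNG images, and optional NIfTI export of time series.

#' Write a matrix as TSV with an id column
#'
#' Values are written at full double precision (17 significant digits) so the
#' round trip is lossless.
#'
#' @param m Numeric matrix; rownames become the id column (row index
#'   otherwise).
#' @param path Output file.
#' @param idName Name of the id column.
#' @export
writeMatrixTsv <- function(m, path, idName = "stimulus_id") {
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  cols <- colnames(m)
  if (is.null(cols)) cols <- sprintf("v%d", seq_len(ncol(m)))
  df <- data.frame(id = ids, format(as.data.frame(m), digits = 17, trim = TRUE,
                                    scientific = TRUE),
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c(idName, cols)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV matrix written by [writeMatrixTsv()]
#'
#' @param path Input file.
#' @return Numeric matrix with the id column as rownames.
#' @export
readMatrixTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Write an events table (BIDS events.tsv dialect)
#'
#' @param events data.frame with onset, duration, stimulus_id (and run).
#' @param path Output file.
#' @export
writeEventsTsv <- function(events, path) {
  stopifnot(all(c("onset", "duration", "stimulus_id") %in% names(events)))
  utils::write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an image matrix as PNG
#'
#' @param image side x side matrix in [0, 1].
#' @param path Output file.
#' @export
writeImagePng <- function(image, path) {
  png::writePNG(clamp(image, 0, 1), path)
  invisible(path)
}

#' Export a simulated session as NIfTI
#'
#' Voxels are laid out along one spatial axis; requires the RNifti package.
#'
#' @param session A \linkS4class{SimulatedSession}.
#' @param path Output .nii.gz path.
#' @export
writeNiftiTimeseries <- function(session, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("NIfTI export requires the RNifti package")
  }
  y <- session@series
  arr <- array(t(y), dim = c(ncol(y), 1L, 1L, nrow(y)))
  img <- RNifti::asNifti(arr)
  RNifti::writeNifti(img, path)
  invisible(path)
}
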