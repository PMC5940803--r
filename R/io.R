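# Shared readers and writers: TIFF images (8/16/32-bit, single or
# multi-page) and CSV tables with schema checks.

#' Read a TIFF image or stack
#'
#' @param path Path to a TIFF file. If a range sidecar (`<path>.range.json`,
#'   written by [write_image()] with `rescale = TRUE`) is present, intensities
#'   are mapped back to their original range.
#'
#' @return A matrix for single-page files, otherwise a list of matrices.
#'   Multi-channel pages are returned as arrays.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path, call. = FALSE)
  frames <- tryCatch(tiff::readTIFF(path, all = TRUE),
                     error = function(e) stop("cannot read TIFF '", path,
                                              "': ", conditionMessage(e),
                                              call. = FALSE))
  sidecar <- paste0(path, ".range.json")
  if (file.exists(sidecar)) {
    rg <- jsonlite::fromJSON(sidecar)
    frames <- lapply(frames, function(f) f * (rg$max - rg$min) + rg$min)
  }
  if (length(frames) == 1L) frames[[1]] else frames
}

#' Write a TIFF image or stack
#'
#' Writes 32-bit float TIFF by default (16- or 8-bit integer on request).
#' The TIFF float path stores values in `[0, 1]`; data outside that range
#' are linearly rescaled when `rescale = TRUE` and the original range is
#' recorded in a `<path>.range.json` sidecar that [read_image()] uses to
#' restore the values (to 32-bit float precision).
#'
#' @param image Matrix, or list of matrices for a multi-page stack.
#' @param path Output path.
#' @param bits.per.sample 8, 16, or 32.
#' @param rescale Rescale out-of-range data and write the range sidecar.
#'
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits.per.sample = 32L, rescale = FALSE) {
  if (!bits.per.sample %in% c(8L, 16L, 32L)) {
    stop("unsupported bit depth: ", bits.per.sample, call. = FALSE)
  }
  frames <- if (is.list(image)) image else list(image)
  vals <- range(unlist(lapply(frames, range)))
  sidecar <- paste0(path, ".range.json")
  if (rescale && (vals[1] < 0 || vals[2] > 1)) {
    span <- max(vals[2] - vals[1], .Machine$double.eps)
    frames <- lapply(frames, function(f) (f - vals[1]) / span)
    jsonlite::write_json(list(min = vals[1], max = vals[1] + span), sidecar,
                         auto_unbox = TRUE, digits = NA)
  } else {
    if (vals[1] < 0 || vals[2] > 1) {
      stop("image values outside [0, 1]; use `rescale = TRUE`", call. = FALSE)
    }
    if (file.exists(sidecar)) file.remove(sidecar)
  }
  tiff::writeTIFF(if (length(frames) == 1L) frames[[1]] else frames, path,
                  bits.per.sample = bits.per.sample)
  invisible(path)
}

#' Read a CSV table with schema check
#'
#' @param path CSV file with a header row.
#' @param required Character vector of required column names; a missing
#'   column raises an error naming it.
#'
#' @return data.frame.
#' @export
read_table <- function(path, required = NULL) {
  if (!file.exists(path)) stop("no such table file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("table '", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write a CSV table
#'
#' Deterministic CSV output (no row names, fixed 15-significant-digit
#' formatting) so identical inputs produce byte-identical files.
#'
#' @param records data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  df <- as.data.frame(records)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) {
    ifelse(x == round(x) & abs(x) < 1e15, format(x, scientific = FALSE, trim = TRUE),
           formatC(x, digits = 15, format = "g"))
  })
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Displacement/traction fields to and from long tables -----------------------

#' Convert a displacement or traction field to a long table
#'
#' @param field A [displacement_field()] or [traction_field()].
#' @return data.frame with grid indices `row`, `col` and components
#'   (`ux`, `uy` or `tx`, `ty`).
#' @export
field_as_table <- function(field) {
  if (inherits(field, "displacement_field")) {
    comp <- list(ux = field$ux, uy = field$uy)
  } else if (inherits(field, "traction_field")) {
    comp <- list(tx = field$tx, ty = field$ty)
  } else stop("unsupported field type", call. = FALSE)
  nr <- nrow(comp[[1]]); nc <- ncol(comp[[1]])
  out <- data.frame(row = rep(seq_len(nr), nc),
                    col = rep(seq_len(nc), each = nr))
  for (nm in names(comp)) out[[nm]] <- as.vector(comp[[nm]])
  out
}
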