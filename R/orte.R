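## Orte matrices: tables of localized blink events, the pipeline's
## central currency.  Columns: amplitude (a.u.), x_nm, y_nm, loc_error_nm
## and optionally frame.  Coordinates are absolute nm in the image frame,
## origin at the top-left corner, y increasing downward.

.ORTE_COLS <- c("amplitude", "x_nm", "y_nm", "loc_error_nm")

#' Construct an orte matrix
#'
#' @param amplitude signal amplitudes (> 0, arbitrary units)
#' @param x,y coordinates in nm
#' @param loc_error per-event localization error in nm (>= 0)
#' @param frame optional integer frame indices
#' @param channel channel label (e.g. `"ch1"`, `"gH2AX"`)
#' @param source free-text source identifier
#' @return a `data.frame` of class `orte_matrix`
#' @export
orte_matrix <- function(amplitude, x, y, loc_error, frame = NULL,
                        channel = "ch1", source = "memory") {
  n <- length(x)
  if (length(y) != n || length(amplitude) != n || length(loc_error) != n)
    stopf("amplitude, x, y, loc_error must have equal length")
  if (n > 0) {
    if (any(!is.finite(x)) || any(!is.finite(y)))
      stopf("orte coordinates must be finite")
    if (any(!is.finite(amplitude)) || any(amplitude <= 0))
      stopf("orte amplitudes must be positive")
    if (any(!is.finite(loc_error)) || any(loc_error < 0))
      stopf("orte localization errors must be >= 0")
  }
  df <- data.frame(amplitude = as.numeric(amplitude),
                   x_nm = as.numeric(x), y_nm = as.numeric(y),
                   loc_error_nm = as.numeric(loc_error))
  if (!is.null(frame)) {
    if (length(frame) != n) stopf("frame must match length of x")
    df$frame <- as.integer(frame)
  }
  structure(df, class = c("orte_matrix", "data.frame"),
            channel = channel, source = source)
}

#' @export
print.orte_matrix <- function(x, ...) {
  cat(sprintf("orte matrix: %d events, channel '%s' (source: %s)\n",
              nrow(x), attr(x, "channel"), attr(x, "source")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' @noRd
as_orte <- function(df, channel = "ch1", source = "memory") {
  orte_matrix(df$amplitude, df$x_nm, df$y_nm, df$loc_error_nm,
              frame = df$frame, channel = channel, source = source)
}

#' @noRd
detect_delimiter <- function(header_line) {
  counts <- vapply(c(",", "\t", ";"),
                   function(d) lengths(regmatches(header_line,
                     gregexpr(d, header_line, fixed = TRUE))),
                   integer(1))
  if (all(counts == 0L)) stopf("cannot detect delimiter (comma/tab/semicolon)")
  names(counts)[which.max(counts)]
}

#' Read an orte matrix from delimited text
#'
#' The header must name at least `amplitude`, `x_nm`, `y_nm`,
#' `loc_error_nm` (a `frame` column is kept when present).  Delimiter is
#' auto-detected among comma, tab and semicolon unless given.
#'
#' @param path file path
#' @param delimiter `NULL` (auto) or one of `","`, `"\t"`, `";"`
#' @param channel channel label recorded on the result
#' @return an [orte_matrix()]
#' @export
read_orte <- function(path, delimiter = NULL, channel = "ch1") {
  if (!file.exists(path)) stopf("orte file not found: %s", path)
  header <- readLines(path, n = 1L)
  if (!length(header)) stopf("empty orte file: %s", path)
  if (is.null(delimiter)) delimiter <- detect_delimiter(header)
  cols <- trimws(strsplit(header, delimiter, fixed = TRUE)[[1L]])
  missing_cols <- setdiff(.ORTE_COLS, cols)
  if (length(missing_cols))
    stopf("orte file %s missing mandatory column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  num <- list()
  for (cn in c(.ORTE_COLS, if ("frame" %in% cols) "frame")) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]) | is.na(df[[cn]]))
    if (length(bad))
      stopf("non-numeric value in column '%s' of %s at data row %d",
            cn, path, bad[1L])
    num[[cn]] <- v
  }
  orte_matrix(num$amplitude, num$x_nm, num$y_nm, num$loc_error_nm,
              frame = num$frame, channel = channel, source = path)
}

#' Write an orte matrix as CSV
#'
#' @param orte an [orte_matrix()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_orte <- function(orte, path) {
  df <- as.data.frame(orte)
  utils::write.table(format(df, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
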