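#' Ground-truth annotations as axis-aligned boxes in millimetres
#'
#' Annotations carry the gold-standard cluster locations used by the
#' true-positive criterion (any shared volume with a detection counts).
#' They are stored as a data frame with one box per row.
#'
#' @param label character labels.
#' @param xmin_mm,xmax_mm,ymin_mm,ymax_mm,zmin_mm,zmax_mm box bounds (mm).
#' @param provenance free-text source note.
#' @return a data frame of class `mcc_annotations`.
#' @export
annotations <- function(label = character(), xmin_mm = numeric(),
                        xmax_mm = numeric(), ymin_mm = numeric(),
                        ymax_mm = numeric(), zmin_mm = numeric(),
                        zmax_mm = numeric(), provenance = "") {
  df <- data.frame(label = as.character(label),
                   xmin_mm = as.numeric(xmin_mm), xmax_mm = as.numeric(xmax_mm),
                   ymin_mm = as.numeric(ymin_mm), ymax_mm = as.numeric(ymax_mm),
                   zmin_mm = as.numeric(zmin_mm), zmax_mm = as.numeric(zmax_mm),
                   stringsAsFactors = FALSE)
  validate_annotations(df)
  attr(df, "provenance") <- provenance
  class(df) <- c("mcc_annotations", "data.frame")
  df
}

validate_annotations <- function(df) {
  need <- c("label", "xmin_mm", "xmax_mm", "ymin_mm", "ymax_mm",
            "zmin_mm", "zmax_mm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("annotation table lacks columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  bad <- which(df$xmin_mm > df$xmax_mm | df$ymin_mm > df$ymax_mm |
               df$zmin_mm > df$zmax_mm)
  if (length(bad))
    stop(sprintf("annotation row %d has min > max", bad[1]), call. = FALSE)
  invisible(df)
}

#' Read / write annotation boxes as delimited text
#'
#' CSV with header `label, xmin_mm, xmax_mm, ymin_mm, ymax_mm, zmin_mm,
#' zmax_mm`; round-trip stable.
#'
#' @param path CSV file.
#' @return [read_annotations()] returns an `mcc_annotations` data frame.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) <= 1L)
    return(annotations())
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop(sprintf(
                   "cannot parse annotation file %s: %s", path,
                   conditionMessage(e)), call. = FALSE))
  num_cols <- c("xmin_mm", "xmax_mm", "ymin_mm", "ymax_mm", "zmin_mm", "zmax_mm")
  for (cc in intersect(num_cols, names(df))) {
    vals <- suppressWarnings(as.numeric(df[[cc]]))
    if (any(is.na(vals) & !is.na(df[[cc]])))
      stop(sprintf("malformed annotation row %d: non-numeric %s",
                   which(is.na(vals))[1], cc), call. = FALSE)
    df[[cc]] <- vals
  }
  validate_annotations(df)
  annotations(df$label, df$xmin_mm, df$xmax_mm, df$ymin_mm, df$ymax_mm,
              df$zmin_mm, df$zmax_mm)
}

#' @rdname read_annotations
#' @param annots an `mcc_annotations` data frame (or compatible data frame).
#' @export
write_annotations <- function(annots, path) {
  validate_annotations(annots)
  write.csv(as.data.frame(annots)[, c("label", "xmin_mm", "xmax_mm",
                                      "ymin_mm", "ymax_mm", "zmin_mm",
                                      "zmax_mm")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
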