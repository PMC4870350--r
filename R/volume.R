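#' 3D grey-level volume with physical voxel spacing
#'
#' The basic carrier for every image field in the pipeline (reconstructed
#' volume, objectness, SNR, MOR).  Data are stored as a 3D array with the
#' slice (depth) axis last; `spacing` and `origin` give the physical frame in
#' millimetres.  Voxel indices are 1-based in R; the physical position of
#' voxel `(i, j, k)` is its *center*, `origin + (c(i, j, k) - 1) * spacing`
#' (the origin sits at the first voxel center).
#'
#' @param data numeric 3D array of grey levels (arbitrary units).
#' @param spacing numeric length-3, voxel pitch `(dx, dy, dz)` in mm; the
#'   reference DBT geometry is `c(0.1, 0.1, 1.0)` (fine in-plane pitch,
#'   coarse 1 mm slice interval).
#' @param origin numeric length-3, physical position (mm) of the first voxel
#'   center.
#' @return An object of class `dbt_volume`.
#' @export
dbt_volume <- function(data, spacing = c(0.1, 0.1, 1.0), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite values (mm)", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "dbt_volume")
}

#' @export
print.dbt_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dbt_volume> %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3],
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  grey levels in [%g, %g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.dbt_volume <- function(x) dim(x$data)

#' Physical volume of one voxel in cubic millimetres
#' @param v a [dbt_volume()].
#' @return scalar, `dx * dy * dz` in mm^3.
#' @export
voxel_volume_mm3 <- function(v) prod(v$spacing)

# physical coordinates (mm) of voxel centers given 1-based index matrix
voxel_centers_mm <- function(idx, spacing, origin) {
  sweep(sweep(idx - 1, 2, spacing, `*`), 2, origin, `+`)
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a$data), dim(b$data)) ||
      max(abs(a$spacing - b$spacing)) > 1e-9 ||
      max(abs(a$origin - b$origin)) > 1e-9)
    stop(sprintf("%s must share grid shape, spacing and origin", what),
         call. = FALSE)
  invisible(TRUE)
}

#' Read a 3D volume with spacing metadata
#'
#' Supports NIfTI (`.nii`, `.nii.gz`), MetaImage (`.mhd`, `.mha`) and a raw
#' binary + JSON sidecar pair used for fixtures (`<stem>.raw` together with
#' `<stem>.json` holding `dim`, `dtype`, `spacing`, `origin`).  When a file
#' carries no usable spacing, the configured default is applied with a
#' warning.
#'
#' @param path file to read.
#' @param format optional explicit format, one of `"nifti"`, `"metaimage"`,
#'   `"raw"`; guessed from the extension when `NULL`.
#' @param default_spacing spacing (mm) used when the header has none.
#' @return a [dbt_volume()].
#' @export
read_volume <- function(path, format = NULL,
                        default_spacing = c(0.1, 0.1, 1.0)) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  fmt <- format %||% guess_format(path)
  v <- switch(fmt,
    nifti = read_volume_nifti(path, default_spacing),
    metaimage = read_volume_mhd(path, default_spacing),
    raw = read_volume_raw(path, default_spacing),
    stop(sprintf("unsupported volume format: %s", fmt), call. = FALSE))
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

guess_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  if (grepl("\\.mhd$|\\.mha$", low)) return("metaimage")
  if (grepl("\\.raw$|\\.json$", low)) return("raw")
  stop(sprintf("cannot guess volume format from extension of %s", path),
       call. = FALSE)
}

read_volume_nifti <- function(path, default_spacing) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a rank-3 NIfTI volume", call. = FALSE)
  pix <- RNifti::pixdim(img)
  if (length(pix) < 3 || any(!is.finite(pix[1:3])) || any(pix[1:3] <= 0)) {
    warning("NIfTI header carries no usable spacing; applying default")
    pix <- default_spacing
  }
  dbt_volume(unclass(arr)[, , , drop = FALSE], spacing = pix[1:3])
}

read_volume_mhd <- function(path, default_spacing) {
  # header is "Key = Value" per line; .mha embeds data after the header
  kv <- list()
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  repeat {
    ln <- readLines(con, n = 1L, warn = FALSE)
    if (length(ln) == 0) break
    m <- regmatches(ln, regexec("^([A-Za-z]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- trimws(m[3])
    if (!is.null(kv$ElementDataFile)) break
  }
  dims <- as.integer(strsplit(kv$DimSize %||% "", "\\s+")[[1]])
  if (length(dims) != 3L) stop("MetaImage header must give 3D DimSize", call. = FALSE)
  spacing <- as.numeric(strsplit(kv$ElementSpacing %||% kv$ElementSize %||% "",
                                 "\\s+")[[1]])
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    warning("MetaImage header carries no usable spacing; applying default")
    spacing <- default_spacing
  }
  origin <- as.numeric(strsplit(kv$Offset %||% "0 0 0", "\\s+")[[1]])
  if (length(origin) != 3L) origin <- c(0, 0, 0)
  etype <- kv$ElementType %||% "MET_DOUBLE"
  n <- prod(dims)
  datafile <- kv$ElementDataFile
  if (identical(datafile, "LOCAL")) {
    vals <- read_met_values(con, etype, n)
  } else {
    dpath <- file.path(dirname(path), datafile)
    dcon <- file(dpath, "rb")
    on.exit(close(dcon), add = TRUE)
    vals <- read_met_values(dcon, etype, n)
  }
  if (length(vals) != n) stop("MetaImage pixel payload truncated", call. = FALSE)
  dbt_volume(array(vals, dim = dims), spacing = spacing, origin = origin)
}

read_met_values <- function(con, etype, n) {
  switch(etype,
    MET_DOUBLE = readBin(con, "double", n = n, size = 8, endian = "little"),
    MET_FLOAT = readBin(con, "double", n = n, size = 4, endian = "little"),
    MET_SHORT = readBin(con, "integer", n = n, size = 2, endian = "little"),
    MET_USHORT = readBin(con, "integer", n = n, size = 2, signed = FALSE,
                         endian = "little"),
    MET_UCHAR = as.numeric(readBin(con, "integer", n = n, size = 1,
                                   signed = FALSE, endian = "little")),
    stop(sprintf("unsupported MetaImage ElementType: %s", etype), call. = FALSE))
}

read_volume_raw <- function(path, default_spacing) {
  stem <- sub("\\.(raw|json)$", "", path)
  raw_path <- paste0(stem, ".raw")
  side_path <- paste0(stem, ".json")
  if (!file.exists(raw_path)) stop(sprintf("raw payload missing: %s", raw_path),
                                   call. = FALSE)
  meta <- if (file.exists(side_path)) jsonlite::read_json(side_path,
                                                          simplifyVector = TRUE)
          else list()
  dims <- as.integer(meta$dim %||% integer())
  if (length(dims) != 3L)
    stop("raw sidecar must define a 3-element `dim`", call. = FALSE)
  spacing <- as.numeric(meta$spacing %||% numeric())
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    warning("raw sidecar carries no usable spacing; applying default")
    spacing <- default_spacing
  }
  origin <- as.numeric(meta$origin %||% c(0, 0, 0))
  vals <- readBin(raw_path, "double", n = prod(dims), size = 8,
                  endian = "little")
  if (length(vals) != prod(dims)) stop("raw payload truncated", call. = FALSE)
  dbt_volume(array(vals, dim = dims), spacing = spacing, origin = origin)
}

#' Write a 3D volume with spacing metadata
#'
#' Counterpart of [read_volume()]; the format is chosen from the extension.
#' Volumes containing non-finite voxels are rejected.
#'
#' @param v a [dbt_volume()].
#' @param path output file (`.nii`/`.nii.gz`, `.mhd`, `.mha`, or `.raw`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "dbt_volume"))
  if (any(!is.finite(v$data)))
    stop("volume contains non-finite voxels; refusing to write", call. = FALSE)
  fmt <- guess_format(path)
  switch(fmt,
    nifti = {
      img <- RNifti::asNifti(v$data)
      RNifti::pixdim(img) <- v$spacing
      RNifti::writeNifti(img, path)
    },
    metaimage = write_volume_mhd(v, path),
    raw = write_volume_raw(v, path))
  invisible(path)
}

write_volume_mhd <- function(v, path) {
  dims <- dim(v$data)
  is_mha <- grepl("\\.mha$", tolower(path))
  datafile <- if (is_mha) "LOCAL" else paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(dims, collapse = " ")),
           paste("ElementSpacing =", paste(format(v$spacing, digits = 17), collapse = " ")),
           paste("Offset =", paste(format(v$origin, digits = 17), collapse = " ")),
           "ElementType = MET_DOUBLE",
           paste("ElementDataFile =", datafile))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (is_mha) {
    writeBin(as.vector(v$data), con, size = 8, endian = "little")
  } else {
    rcon <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(as.vector(v$data), rcon, size = 8, endian = "little")
  }
  invisible(path)
}

write_volume_raw <- function(v, path) {
  stem <- sub("\\.raw$", "", path)
  writeBin(as.vector(v$data), paste0(stem, ".raw"), size = 8,
           endian = "little")
  jsonlite::write_json(
    list(dim = dim(v$data), dtype = "float64", spacing = v$spacing,
         origin = v$origin),
    paste0(stem, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' In-plane subsampling by block maximum (max-pooling)
#'
#' Prescreening reduction: each slice is divided into non-overlapping
#' `factor x factor` windows and each window is replaced by its maximum grey
#' value; the slice axis is untouched.  Edge windows smaller than
#' `factor x factor` are reduced over the voxels available.  Output spacing
#' is `(dx * factor, dy * factor, dz)`; the origin shifts to the center of
#' the first window footprint so voxel centers stay physically registered.
#'
#' @param v a [dbt_volume()].
#' @param factor positive integer reduction factor (reference pipeline: 10,
#'   taking the 0.1 mm in-plane pitch to 1 mm).
#' @return a [dbt_volume()] on the coarse grid.
#' @export
subsample_xy <- function(v, factor) {
  stopifnot(inherits(v, "dbt_volume"))
  factor <- as.integer(factor)
  if (length(factor) != 1L || is.na(factor) || factor < 1L)
    stop("`factor` must be a positive integer", call. = FALSE)
  if (factor == 1L) return(v)
  d <- dim(v$data)
  nxo <- ceiling(d[1] / factor)
  nyo <- ceiling(d[2] / factor)
  # pad to a multiple of factor with -Inf, then fold blocks with pmax
  out <- array(-Inf, dim = c(nxo, nyo, d[3]))
  for (di in seq_len(factor)) {
    ix <- seq.int(di, d[1], by = factor)
    for (dj in seq_len(factor)) {
      jy <- seq.int(dj, d[2], by = factor)
      sub <- v$data[ix, jy, , drop = FALSE]
      blk_i <- seq_along(ix)
      blk_j <- seq_along(jy)
      out[blk_i, blk_j, ] <- pmax(out[blk_i, blk_j, , drop = FALSE], sub)
    }
  }
  new_spacing <- c(v$spacing[1] * factor, v$spacing[2] * factor, v$spacing[3])
  # first output voxel center = center of the first factor x factor window
  new_origin <- c(v$origin[1] + (factor - 1) / 2 * v$spacing[1],
                  v$origin[2] + (factor - 1) / 2 * v$spacing[2],
                  v$origin[3])
  dbt_volume(out, spacing = new_spacing, origin = new_origin)
}
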