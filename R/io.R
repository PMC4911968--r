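# Volume I/O. No NIfTI reader exists in the supported R stack, so volumes are
# stored in the MetaImage (.mha, local raw) format, which every major medical
# imaging toolkit (ITK/SimpleITK, 3D Slicer) reads. Little-endian only.

metaimage_types <- c(MET_DOUBLE = "double", MET_FLOAT = "double",
                     MET_SHORT = "integer", MET_USHORT = "integer",
                     MET_INT = "integer", MET_UCHAR = "integer")
metaimage_sizes <- c(MET_DOUBLE = 8L, MET_FLOAT = 4L, MET_SHORT = 2L,
                     MET_USHORT = 2L, MET_INT = 4L, MET_UCHAR = 1L)

#' Read a voxel volume from disk
#'
#' Supports MetaImage (.mha with local, uncompressed, little-endian raw data).
#'
#' @param path file path.
#' @return A `voxel_grid`.
#' @export
read_volume <- function(path) {
  if (!grepl("\\.mha$", path, ignore.case = TRUE))
    stop("unsupported volume format (expected .mha)")
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, 1L, warn = FALSE)
    if (!length(line)) stop("truncated MetaImage header")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed MetaImage header line: ", line)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr$ElementDataFile, "LOCAL"))
    stop("only LOCAL ElementDataFile is supported")
  if (identical(hdr$CompressedData, "True")) stop("compressed data not supported")
  if (identical(hdr$BinaryDataByteOrderMSB, "True"))
    stop("big-endian data not supported")
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  if (length(dims) != 3L) stop("expected a 3D volume")
  spacing <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  et <- hdr$ElementType
  if (!et %in% names(metaimage_types)) stop("unsupported ElementType: ", et)
  n <- prod(dims)
  raw <- readBin(con, metaimage_types[[et]], n = n, size = metaimage_sizes[[et]],
                 endian = "little",
                 signed = !et %in% c("MET_UCHAR", "MET_USHORT"))
  if (length(raw) != n) stop("truncated MetaImage data")
  voxel_grid(array(as.numeric(raw), dims), spacing)
}

#' Write a voxel volume to disk
#'
#' @param grid a `voxel_grid` (or `mask3d`, written as 0/1).
#' @param path output path ending in .mha.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  if (inherits(grid, "mask3d"))
    grid <- voxel_grid(array(as.numeric(grid$voxels), dim(grid$voxels)),
                       grid$spacing)
  stopifnot(inherits(grid, "voxel_grid"))
  if (!grepl("\\.mha$", path, ignore.case = TRUE))
    stop("unsupported volume format (expected .mha)")
  d <- dim(grid$data)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("ObjectType = Image", "NDims = 3", "BinaryData = True",
               "BinaryDataByteOrderMSB = False", "CompressedData = False",
               paste("DimSize =", paste(d, collapse = " ")),
               paste("ElementSpacing =",
                     paste(format(grid$spacing, digits = 15), collapse = " ")),
               "ElementType = MET_DOUBLE", "ElementDataFile = LOCAL"), con)
  writeBin(as.numeric(grid$data), con, size = 8L, endian = "little")
  invisible(path)
}

#' Write / read a planar image as a CSV grid
#'
#' Plain numeric grid (rows = x, columns = z) preceded by comment lines
#' recording pixel spacing and view.
#'
#' @param img a `planar_image`.
#' @param path output path ending in .csv.
#' @return `path` invisibly (write) or a `planar_image` (read).
#' @export
write_planar_csv <- function(img, path) {
  stopifnot(inherits(img, "planar_image"))
  hdr <- c(sprintf("# view: %s", img$view),
           sprintf("# pixel_spacing_mm: %s",
                   paste(format(img$pixel_spacing, digits = 15), collapse = " ")))
  writeLines(hdr, path)
  utils::write.table(img$counts, path, append = TRUE, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_planar_csv
#' @export
read_planar_csv <- function(path) {
  hdr <- readLines(path, 2L)
  view <- sub("^# view: ", "", hdr[1])
  spacing <- as.numeric(strsplit(sub("^# pixel_spacing_mm: ", "", hdr[2]),
                                 "\\s+")[[1]])
  m <- as.matrix(utils::read.csv(path, header = FALSE, comment.char = "#"))
  dimnames(m) <- NULL
  planar_image(m, spacing, view)
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take the [pipeline_config()]
#' defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}
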