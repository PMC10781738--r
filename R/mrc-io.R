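## MRC2014 binary map format. Header words honoured: nx/ny/nz, mode,
## nxstart/nystart/nzstart, mx/my/mz, cella, mapc/mapr/maps, dmin/dmax/dmean,
## origin, MAP stamp, machst, rms. Data are read for modes 0 (int8),
## 1 (int16) and 2 (float32) and always written as mode 2.

#' Read a density map from an MRC2014 file
#'
#' Axis order is normalised at read time: whatever the file's
#' `mapc/mapr/maps` permutation, the returned array is canonical x-fastest
#' `values[ix, iy, iz]`. The real-space origin is taken from the `origin`
#' header record when non-zero, otherwise from the
#' `nxstart/nystart/nzstart` records times the voxel size.
#'
#' @param path path to an MRC2014 file.
#' @param resolution optional global resolution (angstrom) to attach to the
#'   returned map (MRC files do not carry one).
#' @return A [density_map()].
#' @export
read_density_map <- function(path, resolution = NULL) {
  if (!file.exists(path)) stop_cf("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_dbl <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  nxyz <- hdr_int[1:3]
  mode <- hdr_int[4]
  nstart <- hdr_int[5:7]
  mxyz <- hdr_int[8:10]
  cella <- hdr_dbl[11:13]
  mapcrs <- hdr_int[17:19]
  orig <- hdr_dbl[50:52]

  if (any(nxyz < 1) || any(nxyz > 1e5))
    stop_cf("malformed MRC header: nx/ny/nz = ",
            paste(nxyz, collapse = ","))
  if (!mode %in% c(0L, 1L, 2L))
    stop_cf("malformed MRC header: unsupported mode ", mode,
            " (modes 0, 1, 2 readable)")
  if (!setequal(mapcrs, 1:3))
    stop_cf("malformed MRC header: mapc/mapr/maps = ",
            paste(mapcrs, collapse = ","), " is not a permutation of 1,2,3")
  if (any(mxyz < 1))
    stop_cf("malformed MRC header: mx/my/mz = ", paste(mxyz, collapse = ","))
  if (any(!is.finite(cella)) || any(cella <= 0))
    stop_cf("malformed MRC header: cella = ", paste(cella, collapse = ","))

  seek(con, 1024 + hdr_int[24])
  nvox <- prod(nxyz)
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = nvox, size = 1,
                             signed = TRUE, endian = "little")),
    "1" = as.numeric(readBin(con, "integer", n = nvox, size = 2,
                             signed = TRUE, endian = "little")),
    "2" = readBin(con, "numeric", n = nvox, size = 4, endian = "little"))
  if (length(data) != nvox)
    stop_cf("malformed MRC file: expected ", nvox, " voxels, read ",
            length(data))
  if (any(!is.finite(data)))
    stop_cf("MRC data contain non-finite values")

  arr <- array(data, nxyz)                  # stored order: col, row, section
  perm <- match(1:3, mapcrs)                # result dim k <- stored dim
  arr <- aperm(arr, perm)

  voxel <- cella / mxyz                     # cell axes are x, y, z directly
  nstart_xyz <- numeric(3)
  nstart_xyz[mapcrs] <- nstart              # nstart records follow col/row/sec
  origin <- if (any(orig != 0)) orig else nstart_xyz * voxel
  density_map(arr, voxel, origin, resolution)
}

#' Write a density map as MRC2014 (mode 2)
#'
#' Writes canonical axis order (`mapc/mapr/maps = 1,2,3`), float32 data,
#' the voxel size via `cella = dim * voxel_size`, the origin record, and
#' recomputed min/max/mean/rms statistics.
#'
#' @param map a [density_map()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_density_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  n <- grid_dim(map)
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop_cf("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))

  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")

  vals <- as.vector(map$values)
  wi(n)                                     # nx ny nz
  wi(2L)                                    # mode 2 = float32
  wi(c(0L, 0L, 0L))                         # nxstart
  wi(n)                                     # mx my mz
  wf(n * map$voxel_size)                    # cella
  wf(c(90, 90, 90))                         # cellb
  wi(1:3)                                   # mapc mapr maps
  wf(c(min(vals), max(vals), mean(vals)))   # dmin dmax dmean
  wi(1L)                                    # ispg: 3-D volume
  wi(0L)                                    # nsymbt
  wi(integer(2))                            # extra words 25-26
  writeChar("MRCO", con, nchars = 4, eos = NULL)  # exttyp
  wi(20140L)                                # nversion
  wi(integer(21))                           # remaining extra words
  wf(map$origin)                            # origin record
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst: little-endian
  wf(stats::sd(vals) * sqrt((length(vals) - 1) / length(vals)))  # rms
  wi(0L)                                    # nlabl
  writeBin(raw(800), con)                   # labels
  wf(vals)                                  # float32 data, x fastest
  invisible(path)
}
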