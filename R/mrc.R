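# MRC/CCP4 2014 density map I/O. The in-memory representation is a
# `density_map`: an (nx, ny, nz) R array in canonical x,y,z axis order with
# the physical frame taken from the header (voxel size in Angstrom, origin
# = physical position of grid point [1,1,1]).

#' Construct a density map
#' @param data 3D numeric array (x, y, z order)
#' @param voxel voxel size in Angstrom (isotropic)
#' @param origin physical position (Angstrom) of the first grid point
#' @return object of class `density_map`
#' @export
density_map <- function(data, voxel, origin = c(0, 0, 0)) {
  stopifnot(length(dim(data)) == 3, voxel > 0)
  structure(list(data = data, voxel = voxel, origin = origin),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat("density_map:", paste(dim(x$data), collapse = " x "), "voxels,",
      x$voxel, "A/voxel, origin", paste(round(x$origin, 2), collapse = " "),
      "\n")
  invisible(x)
}

#' Physical center of a map box (rotation center for projections)
#' @param map a `density_map`
#' @return length-3 position in Angstrom
#' @export
map_center <- function(map) {
  map$origin + (dim(map$data) %/% 2) * map$voxel
}

#' Read an MRC/CCP4 map
#'
#' Honors voxel size, origin (ORIGIN record plus NXSTART offsets) and the
#' MAPC/MAPR/MAPS axis permutation; the returned grid is always in x,y,z
#' order. Only cubic boxes with isotropic voxels are supported.
#'
#' @param path MRC file
#' @return a [density_map()]
#' @export
read_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_i <- readBin(con, "integer", 10, size = 4, endian = "little")
  nx <- hdr_i[1]; ny <- hdr_i[2]; nz <- hdr_i[3]; mode <- hdr_i[4]
  nstart <- hdr_i[5:7]; mgrid <- hdr_i[8:10]
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  readBin(con, "numeric", 3, size = 4, endian = "little")  # cellb
  mapcrs <- readBin(con, "integer", 3, size = 4, endian = "little")
  readBin(con, "numeric", 3, size = 4, endian = "little")  # dmin dmax dmean
  readBin(con, "integer", 2, size = 4, endian = "little")  # ispg nsymbt
  readBin(con, "integer", 25, size = 4, endian = "little") # extra
  origin <- readBin(con, "numeric", 3, size = 4, endian = "little")
  readChar(con, 4, useBytes = TRUE)                        # "MAP "
  readBin(con, "integer", 1, size = 4, endian = "little")  # machst
  readBin(con, "numeric", 1, size = 4, endian = "little")  # rms
  readBin(con, "integer", 1, size = 4, endian = "little")  # nlabl
  readChar(con, 800, useBytes = TRUE)
  if (mode != 2) stop("unsupported MRC mode ", mode, " (expect float32)")
  vox <- cella / mgrid
  if (max(vox) - min(vox) > 1e-4)
    stop("unsupported input: anisotropic voxels (", paste(round(vox, 4),
         collapse = ", "), ")")
  n <- c(nx, ny, nz)
  dat <- readBin(con, "numeric", prod(n), size = 4, endian = "little")
  arr <- array(dat, dim = n)  # stored order: column, row, section
  # permute so that axis k of the array is physical axis k (x,y,z)
  perm <- order(mapcrs)       # perm[k] = which stored axis is physical k
  if (!all(perm == 1:3)) {
    arr <- aperm(arr, perm)
    nstart <- nstart[perm]
  }
  nxyz <- dim(arr)
  if (length(unique(nxyz)) != 1)
    stop("unsupported input: non-cubic box (", paste(nxyz, collapse = "x"), ")")
  density_map(arr, vox[1], origin + nstart * vox[1])
}

#' Write an MRC 2014 map
#' @param map a `density_map`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_map <- function(map, path) {
  n <- dim(map$data)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(n, 2L, 0L, 0L, 0L, n)), con, size = 4,
           endian = "little")
  writeBin(as.numeric(c(n * map$voxel, 90, 90, 90)), con, size = 4,
           endian = "little")
  writeBin(1:3, con, size = 4, endian = "little")
  d <- as.numeric(map$data)
  writeBin(as.numeric(c(min(d), max(d), mean(d))), con, size = 4,
           endian = "little")
  writeBin(c(1L, 0L), con, size = 4, endian = "little")
  writeBin(integer(25), con, size = 4, endian = "little")
  writeBin(as.numeric(map$origin), con, size = 4, endian = "little")
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(17476L, con, size = 4, endian = "little")  # little-endian stamp
  writeBin(stats::sd(d), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeChar(paste(rep(" ", 800), collapse = ""), con, nchars = 800, eos = NULL)
  writeBin(d, con, size = 4, endian = "little")
  invisible(path)
}
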