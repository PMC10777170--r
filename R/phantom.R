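# Coordinate convention: u = beam axis (depth, mm), t = horizontal, v =
# vertical transverse coordinates (mm). The front scorer sits at u = 0.

#' Water tank phantom with staggered bone cube inserts
#'
#' Solid-geometry description of a 20 x 20 x 20 cm^3 water tank (RSP 1)
#' containing five 1 cm bone cubes (RSP 1.27). The cubes are staggered
#' laterally by 20 mm in both transverse directions and placed so that their
#' proximal faces sit at radiological depths of 10, 50, 100, 150 and 190 mm
#' (all-water upstream, so geometric and radiological depth coincide). Each
#' cube is tilted about the beam axis (about its own centre) so that its
#' lateral edges are slanted with respect to the image pixel grid.
#'
#' @param tilt_deg rotation of each cube about the beam axis, degrees
#' @param rsp_cube relative stopping power of the cube material
#' @return an object of class `cube_phantom` with fields `size` (mm),
#'   `cube_edge` (mm), `cube_rsp`, `tilt_deg` and `cubes` (data.frame with
#'   columns `u0`, `tc`, `vc`: proximal depth and transverse centre of each
#'   cube, mm)
#' @export
cube_phantom <- function(tilt_deg = 2.5, rsp_cube = 1.27) {
  depths <- c(10, 50, 100, 150, 190)
  lat <- seq(-40, 40, by = 20)
  structure(list(
    size = c(200, 200, 200),
    cube_edge = 10,
    cube_rsp = rsp_cube,
    tilt_deg = tilt_deg,
    cubes = data.frame(u0 = depths, tc = lat, vc = lat)
  ), class = "cube_phantom")
}

#' @export
print.cube_phantom <- function(x, ...) {
  cat(sprintf("cube_phantom: %g x %g x %g mm water tank, %d cubes (RSP %g, %g deg tilt)\n",
              x$size[1], x$size[2], x$size[3], nrow(x$cubes), x$cube_rsp, x$tilt_deg))
  print(x$cubes)
  invisible(x)
}

#' Voxelized relative-stopping-power volume
#'
#' @param rsp_grid 3D numeric array of dimensionless RSP values, indexed
#'   `[u, t, v]` (u = beam axis)
#' @param spacing voxel spacing in mm along (u, t, v)
#' @param origin position (mm) of the corner of the volume: voxel `[1,1,1]`
#'   spans `origin` to `origin + spacing`
#' @return an `rsp_volume` object
#' @export
rsp_volume <- function(rsp_grid, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(rsp_grid), length(dim(rsp_grid)) == 3,
            all(dim(rsp_grid) >= 1),
            length(spacing) %in% c(1, 3), all(spacing > 0),
            length(origin) == 3, all(is.finite(rsp_grid)),
            all(rsp_grid >= 0))
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  structure(list(rsp_grid = rsp_grid, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "rsp_volume")
}

#' @export
print.rsp_volume <- function(x, ...) {
  d <- dim(x$rsp_grid)
  cat(sprintf("rsp_volume: %d x %d x %d voxels, spacing (%g, %g, %g) mm, RSP in [%g, %g]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$rsp_grid), max(x$rsp_grid)))
  invisible(x)
}

#' Voxelize a cube phantom onto a regular RSP grid
#'
#' Samples the solid geometry at voxel centres (nearest-material assignment,
#' no partial-volume averaging).
#'
#' @param phantom a [cube_phantom()]
#' @param spacing voxel spacing, mm (scalar or length 3); default 0.5
#' @return an [rsp_volume()] with origin at `(0, -100, -100)`
#' @export
build_cube_phantom <- function(phantom = cube_phantom(), spacing = 0.5) {
  stopifnot(inherits(phantom, "cube_phantom"), all(spacing > 0))
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  sz <- phantom$size
  dims <- as.integer(round(sz / spacing))
  origin <- c(0, -sz[2] / 2, -sz[3] / 2)
  grid <- array(1.0, dim = dims)
  half <- phantom$cube_edge / 2
  th <- phantom$tilt_deg * pi / 180
  uc <- origin[1] + (seq_len(dims[1]) - 0.5) * spacing[1]
  tc <- origin[2] + (seq_len(dims[2]) - 0.5) * spacing[2]
  vc <- origin[3] + (seq_len(dims[3]) - 0.5) * spacing[3]
  for (k in seq_len(nrow(phantom$cubes))) {
    cb <- phantom$cubes[k, ]
    iu <- which(uc >= cb$u0 & uc < cb$u0 + phantom$cube_edge)
    # bounding box in t, v enlarged to cover the rotated square
    r <- half * (abs(cos(th)) + abs(sin(th)))
    it <- which(abs(tc - cb$tc) <= r)
    iv <- which(abs(vc - cb$vc) <= r)
    if (!length(iu) || !length(it) || !length(iv)) next
    dt <- tc[it] - cb$tc
    dv <- vc[iv] - cb$vc
    # rotate voxel centres into the cube frame
    tp <- outer(dt, dv, function(a, b)  cos(th) * a + sin(th) * b)
    vp <- outer(dt, dv, function(a, b) -sin(th) * a + cos(th) * b)
    inside <- abs(tp) <= half & abs(vp) <= half  # length(it) x length(iv)
    sub <- grid[iu, it, iv, drop = FALSE]
    mask <- aperm(array(inside, dim = c(length(it), length(iv), length(iu))),
                  c(3, 1, 2))
    sub[mask] <- phantom$cube_rsp
    grid[iu, it, iv] <- sub
  }
  rsp_volume(grid, spacing, origin)
}

#' RSP of a cube phantom at arbitrary points (exact geometry)
#'
#' @param phantom a [cube_phantom()]
#' @param u,t,v coordinates in mm (vectorized)
#' @return RSP values; 0 outside the tank
#' @export
rsp_at <- function(phantom, u, t, v) {
  stopifnot(inherits(phantom, "cube_phantom"))
  sz <- phantom$size
  out <- ifelse(u >= 0 & u <= sz[1] & abs(t) <= sz[2] / 2 & abs(v) <= sz[3] / 2,
                1.0, 0.0)
  th <- phantom$tilt_deg * pi / 180
  half <- phantom$cube_edge / 2
  for (k in seq_len(nrow(phantom$cubes))) {
    cb <- phantom$cubes[k, ]
    dt <- t - cb$tc; dv <- v - cb$vc
    tp <- cos(th) * dt + sin(th) * dv
    vp <- -sin(th) * dt + cos(th) * dv
    ins <- u >= cb$u0 & u < cb$u0 + phantom$cube_edge &
      abs(tp) <= half & abs(vp) <= half
    out[ins] <- phantom$cube_rsp
  }
  out
}

# ---- MetaImage (MHD/RAW) I/O ------------------------------------------------
# Minimal local-file MetaImage support: plain-text .mhd header plus
# little-endian .raw payload, MET_FLOAT or MET_DOUBLE, no compression.

#' Write a 2D/3D array as a MetaImage file
#'
#' A `.mhd` path produces a header/raw pair; a `.mha` path produces a single
#' file with the payload appended after the header (`ElementDataFile = LOCAL`).
#'
#' @param x numeric array (2D or 3D), an [rsp_volume()], or matrix
#' @param path output path ending in `.mhd` or `.mha`
#' @param spacing,origin physical metadata (taken from `x` when it is an
#'   `rsp_volume`)
#' @param type element type, `"float"` or `"double"`
#' @return `path`, invisibly
#' @export
write_mhd <- function(x, path, spacing = 1, origin = 0, type = "float") {
  if (inherits(x, "rsp_volume")) {
    spacing <- x$spacing; origin <- x$origin; x <- x$rsp_grid
  }
  stopifnot(is.numeric(x), length(dim(x)) %in% c(2, 3),
            grepl("\\.(mhd|mha)$", path))
  local <- grepl("\\.mha$", path)
  nd <- length(dim(x))
  if (length(spacing) == 1) spacing <- rep(spacing, nd)
  if (length(origin) == 1) origin <- rep(origin, nd)
  et <- switch(match.arg(type, c("float", "double")),
               float = "MET_FLOAT", double = "MET_DOUBLE")
  rawfile <- if (local) "LOCAL" else sub("\\.mhd$", ".raw", basename(path))
  hdr <- c(
    "ObjectType = Image",
    sprintf("NDims = %d", nd),
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("DimSize = %s", paste(dim(x), collapse = " ")),
    sprintf("ElementSpacing = %s", paste(format(spacing, trim = TRUE), collapse = " ")),
    sprintf("Offset = %s", paste(format(origin, trim = TRUE), collapse = " ")),
    sprintf("ElementType = %s", et),
    sprintf("ElementDataFile = %s", rawfile)
  )
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (!local) {
    close(con); on.exit()
    con <- file(file.path(dirname(path), rawfile), "wb")
    on.exit(close(con))
  }
  writeBin(as.vector(x), con,
           size = if (et == "MET_FLOAT") 4L else 8L, endian = "little")
  invisible(path)
}

#' Read a MetaImage file (`.mhd`/`.raw` pair or single-file `.mha`)
#'
#' @param path path to a `.mhd` or `.mha` file
#' @return a list with `data` (array), `spacing`, `origin`
#' @export
read_mhd <- function(path) {
  stopifnot(file.exists(path))
  # parse the ASCII header byte-wise: everything up to (and including) the
  # ElementDataFile line; for .mha the binary payload follows immediately
  head_raw <- readBin(path, "raw", n = min(file.size(path), 8192))
  nl <- which(head_raw == as.raw(10L))
  lines <- character()
  start <- 1L
  offset <- NA_integer_
  for (p in nl) {
    ln <- rawToChar(head_raw[seq.int(start, p - 1L)])
    lines <- c(lines, ln)
    if (startsWith(ln, "ElementDataFile")) { offset <- p; break }
    start <- p + 1L
  }
  if (is.na(offset)) stop("not a MetaImage header: ", path)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  val <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) NULL else kv[[i]][2]
  }
  dims <- as.integer(strsplit(val("DimSize"), "\\s+")[[1]])
  et <- val("ElementType")
  if (!et %in% c("MET_FLOAT", "MET_DOUBLE"))
    stop("unsupported ElementType: ", et)
  if (identical(val("CompressedData"), "True"))
    stop("compressed MetaImage not supported")
  spacing <- as.numeric(strsplit(val("ElementSpacing") %||% "1", "\\s+")[[1]])
  origin <- as.numeric(strsplit(val("Offset") %||% "0", "\\s+")[[1]])
  n <- prod(dims)
  sz <- if (et == "MET_FLOAT") 4L else 8L
  df <- val("ElementDataFile")
  if (identical(df, "LOCAL")) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = offset)  # skip the header
    dat <- readBin(con, "numeric", n = n, size = sz, endian = "little")
  } else {
    con <- file(file.path(dirname(path), df), "rb")
    on.exit(close(con))
    dat <- readBin(con, "numeric", n = n, size = sz, endian = "little")
  }
  list(data = array(dat, dim = dims), spacing = spacing, origin = origin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
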