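#' Read a colored point cloud from file
#'
#' Supported formats: PLY (ascii or binary little-endian, vertex properties
#' x/y/z plus red/green/blue), uncompressed LAS 1.2 point format 2 (RGB), and
#' whitespace-separated XYZ text (`x y z r g b`, `#` comments allowed). Point
#' order is preserved from the file; colors are coerced to 8-bit integers.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"ply"`, `"las"` or `"xyz"`.
#' @return A point-cloud tibble (see [point_cloud()]) with stage `"raw"`.
#' @seealso [write_point_cloud()]
#' @export
read_point_cloud <- function(path, format = c("auto", "ply", "las", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- guess_pc_format(path)
  switch(format,
         ply = read_ply(path),
         las = read_las(path),
         xyz = read_xyz(path))
}

#' Write a colored point cloud to file
#'
#' PLY is written with double-precision coordinates (lossless round trip);
#' LAS 1.2 point format 2 stores coordinates as scaled integers at 1 mm
#' resolution with the offset at the cloud minimum, so the round trip is exact
#' to 0.5 mm; XYZ text is plain decimal (lossless at 17 significant digits).
#'
#' @param cloud A point-cloud tibble.
#' @param path Output path.
#' @param format `"auto"` (by extension), `"ply"`, `"las"` or `"xyz"`.
#' @param binary For PLY: write `binary_little_endian` (default) or ascii.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path,
                              format = c("auto", "ply", "las", "xyz"),
                              binary = TRUE) {
  cloud <- as_point_cloud(cloud)
  format <- match.arg(format)
  if (format == "auto") format <- guess_pc_format(path)
  switch(format,
         ply = write_ply(cloud, path, binary = binary),
         las = write_las(cloud, path),
         xyz = write_xyz(cloud, path))
  invisible(path)
}

guess_pc_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = "ply",
         las = "las",
         xyz = , txt = "xyz",
         laz = stop("compressed LAZ is not supported; decompress to LAS first",
                    call. = FALSE),
         stop("cannot infer point-cloud format from extension '.", ext,
              "'; pass `format`", call. = FALSE))
}

## ---- XYZ text ---------------------------------------------------------------

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- grepl("\\S", lines)
  lines <- lines[keep]
  if (length(lines) == 0) return(point_cloud())
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  bad <- which(nf != 6L)
  if (length(bad) > 0)
    stop("xyz parse error at record ", bad[1], ": expected 6 fields, got ",
         nf[bad[1]], call. = FALSE)
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 6, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(m, 1, anyNA))[1]
    stop("xyz parse error at record ", bad, ": non-numeric field",
         call. = FALSE)
  }
  point_cloud(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5], m[, 6])
}

write_xyz <- function(cloud, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# x y z r g b", con)
  if (nrow(cloud) > 0) {
    out <- sprintf("%.17g %.17g %.17g %d %d %d",
                   cloud$x, cloud$y, cloud$z, cloud$r, cloud$g, cloud$b)
    writeLines(out, con)
  }
  invisible(path)
}

## ---- PLY --------------------------------------------------------------------

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    ln <- readBin(con, "raw", n = 0)  # no-op to keep con binary
    line <- read_bin_line(con)
    header <- c(header, line)
    if (identical(line, "end_header")) break
    if (length(header) > 500) stop("ply: header not terminated", call. = FALSE)
  }
  if (!identical(header[1], "ply")) stop("not a PLY file: ", path, call. = FALSE)
  fmt_line <- grep("^format ", header, value = TRUE)
  fmt <- strsplit(fmt_line, "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("ply: unsupported format '", fmt, "'", call. = FALSE)

  # parse the vertex element's property list
  el_lines <- grep("^element ", header)
  vert_at <- grep("^element vertex ", header)
  if (length(vert_at) != 1) stop("ply: no vertex element", call. = FALSE)
  n_vert <- as.integer(strsplit(header[vert_at], "\\s+")[[1]][3])
  next_el <- el_lines[el_lines > vert_at]
  end_at <- if (length(next_el)) min(next_el) else length(header)
  props <- header[(vert_at + 1):end_at]
  props <- grep("^property ", props, value = TRUE)
  if (any(grepl("^property list", props)))
    stop("ply: list properties on vertices are not supported", call. = FALSE)
  pp <- strsplit(props, "\\s+")
  ptypes <- vapply(pp, `[`, "", 2)
  pnames <- vapply(pp, `[`, "", 3)
  cmap <- c(x = "x", y = "y", z = "z",
            red = "r", green = "g", blue = "b",
            r = "r", g = "g", b = "b",
            diffuse_red = "r", diffuse_green = "g", diffuse_blue = "b")
  have <- cmap[pnames]
  if (!all(c("x", "y", "z") %in% have))
    stop("ply: vertex element lacks x/y/z", call. = FALSE)
  if (!all(c("r", "g", "b") %in% have))
    stop("no radiometry: PLY vertex element has no red/green/blue properties",
         call. = FALSE)
  if (n_vert == 0) return(point_cloud())

  if (fmt == "ascii") {
    lines <- character(n_vert)
    for (i in seq_len(n_vert)) lines[i] <- read_bin_line(con)
    fields <- strsplit(trimws(lines), "\\s+")
    nf <- lengths(fields)
    if (any(nf < length(pnames)))
      stop("ply parse error at vertex ", which(nf < length(pnames))[1],
           call. = FALSE)
    m <- matrix(as.numeric(unlist(lapply(fields, `[`, seq_along(pnames)))),
                ncol = length(pnames), byrow = TRUE)
    cols <- stats::setNames(seq_along(pnames), have)
  } else {
    sizes <- ply_type_size[ptypes]
    if (anyNA(sizes)) stop("ply: unknown property type", call. = FALSE)
    stride <- sum(sizes)
    raw <- readBin(con, "raw", n = n_vert * stride)
    if (length(raw) < n_vert * stride)
      stop("ply: truncated binary payload", call. = FALSE)
    offs <- cumsum(c(0L, sizes))[seq_along(sizes)]
    m <- matrix(0, nrow = n_vert, ncol = length(pnames))
    base <- (seq_len(n_vert) - 1L) * stride
    for (j in seq_along(pnames)) {
      idx <- rep(base, each = sizes[j]) + offs[j] + seq_len(sizes[j])
      bytes <- raw[idx]
      m[, j] <- decode_ply_col(bytes, ptypes[j], n_vert)
    }
    cols <- stats::setNames(seq_along(pnames), have)
  }
  point_cloud(m[, cols[["x"]]], m[, cols[["y"]]], m[, cols[["z"]]],
              m[, cols[["r"]]], m[, cols[["g"]]], m[, cols[["b"]]])
}

decode_ply_col <- function(bytes, type, n) {
  switch(type,
    float = , float32 = readBin(bytes, "double", n = n, size = 4,
                                endian = "little"),
    double = , float64 = readBin(bytes, "double", n = n, size = 8,
                                 endian = "little"),
    uchar = , uint8 = as.numeric(readBin(bytes, "integer", n = n, size = 1,
                                         signed = FALSE, endian = "little")),
    char = , int8 = as.numeric(readBin(bytes, "integer", n = n, size = 1,
                                       signed = TRUE, endian = "little")),
    ushort = , uint16 = as.numeric(readBin(bytes, "integer", n = n, size = 2,
                                           signed = FALSE, endian = "little")),
    short = , int16 = as.numeric(readBin(bytes, "integer", n = n, size = 2,
                                         signed = TRUE, endian = "little")),
    int = , int32 = , uint = , uint32 =
      as.numeric(readBin(bytes, "integer", n = n, size = 4,
                         endian = "little")),
    stop("ply: unsupported type ", type, call. = FALSE))
}

read_bin_line <- function(con) {
  out <- raw()
  repeat {
    b <- readBin(con, "raw", n = 1)
    if (length(b) == 0) break
    if (b == as.raw(10L)) break
    out <- c(out, b)
  }
  sub("\r$", "", rawToChar(out))
}

write_ply <- function(cloud, path, binary = TRUE) {
  n <- nrow(cloud)
  fmt <- if (binary) "binary_little_endian 1.0" else "ascii 1.0"
  header <- c("ply",
              paste("format", fmt),
              "comment written by canopyr",
              paste("element vertex", n),
              "property double x", "property double y", "property double z",
              "property uchar red", "property uchar green",
              "property uchar blue",
              "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
  if (n > 0) {
    if (binary) {
      stride <- 27L
      raw <- raw(n * stride)
      base <- (seq_len(n) - 1L) * stride
      put <- function(off, bytes, size) {
        idx <- rep(base, each = size) + off + seq_len(size)
        raw[idx] <<- bytes
      }
      put(0L, writeBin(cloud$x, raw(), size = 8, endian = "little"), 8L)
      put(8L, writeBin(cloud$y, raw(), size = 8, endian = "little"), 8L)
      put(16L, writeBin(cloud$z, raw(), size = 8, endian = "little"), 8L)
      put(24L, as.raw(cloud$r), 1L)
      put(25L, as.raw(cloud$g), 1L)
      put(26L, as.raw(cloud$b), 1L)
      writeBin(raw, con)
    } else {
      lines <- sprintf("%.17g %.17g %.17g %d %d %d",
                       cloud$x, cloud$y, cloud$z, cloud$r, cloud$g, cloud$b)
      writeBin(charToRaw(paste0(paste(lines, collapse = "\n"), "\n")), con)
    }
  }
  invisible(path)
}

## ---- LAS 1.2, point format 2 ------------------------------------------------

LAS_SCALE <- 0.001  # 1 mm coordinate resolution

write_las <- function(cloud, path) {
  n <- nrow(cloud)
  off <- if (n > 0) c(min(cloud$x), min(cloud$y), min(cloud$z)) else c(0, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  header_size <- 227L
  rec_len <- 26L
  writeBin(charToRaw("LASF"), con)
  writeBin(integer(2), con, size = 2, endian = "little")  # source id, encoding
  writeBin(integer(2), con, size = 4, endian = "little")  # project GUID 1-2
  writeBin(raw(8), con)                                    # project GUID 3-4
  writeBin(as.raw(c(1L, 2L)), con)                         # version 1.2
  sysid <- charToRaw("canopyr"); length(sysid) <- 32
  software <- charToRaw("canopyr"); length(software) <- 32
  writeBin(sysid, con)
  writeBin(software, con)
  writeBin(c(1L, 2020L), con, size = 2, endian = "little") # day, year
  writeBin(header_size, con, size = 2, endian = "little")
  writeBin(header_size, con, size = 4, endian = "little")  # offset to points
  writeBin(0L, con, size = 4, endian = "little")           # no VLRs
  writeBin(as.raw(2L), con)                                # point format 2
  writeBin(rec_len, con, size = 2, endian = "little")
  writeBin(n, con, size = 4, endian = "little")
  writeBin(integer(5), con, size = 4, endian = "little")   # points by return
  writeBin(rep(LAS_SCALE, 3), con, size = 8, endian = "little")
  writeBin(off, con, size = 8, endian = "little")
  if (n > 0) {
    ranges <- c(max(cloud$x), min(cloud$x), max(cloud$y), min(cloud$y),
                max(cloud$z), min(cloud$z))
  } else ranges <- numeric(6)
  writeBin(ranges, con, size = 8, endian = "little")

  if (n > 0) {
    xi <- as.integer(round((cloud$x - off[1]) / LAS_SCALE))
    yi <- as.integer(round((cloud$y - off[2]) / LAS_SCALE))
    zi <- as.integer(round((cloud$z - off[3]) / LAS_SCALE))
    raw <- raw(n * rec_len)
    base <- (seq_len(n) - 1L) * rec_len
    put <- function(off_b, bytes, size) {
      idx <- rep(base, each = size) + off_b + seq_len(size)
      raw[idx] <<- bytes
    }
    put(0L, writeBin(xi, raw(), size = 4, endian = "little"), 4L)
    put(4L, writeBin(yi, raw(), size = 4, endian = "little"), 4L)
    put(8L, writeBin(zi, raw(), size = 4, endian = "little"), 4L)
    # intensity(2), return byte, classification, scan angle, user data,
    # point source id(2) all zero; RGB as 16-bit (8-bit value * 257)
    put(20L, writeBin(as.integer(cloud$r) * 257L, raw(), size = 2,
                      endian = "little"), 2L)
    put(22L, writeBin(as.integer(cloud$g) * 257L, raw(), size = 2,
                      endian = "little"), 2L)
    put(24L, writeBin(as.integer(cloud$b) * 257L, raw(), size = 2,
                      endian = "little"), 2L)
    writeBin(raw, con)
  }
  invisible(path)
}

read_las <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- rawToChar(readBin(con, "raw", n = 4))
  if (!identical(sig, "LASF")) stop("not a LAS file: ", path, call. = FALSE)
  seek(con, 24)
  ver <- as.integer(readBin(con, "raw", n = 2))
  seek(con, 96)
  offset_to_points <- readBin(con, "integer", size = 4, endian = "little")
  seek(con, 104)
  pdf_raw <- as.integer(readBin(con, "raw", n = 1))
  pdf <- pdf_raw %% 128L  # mask LAZ compression bit
  rec_len <- readBin(con, "integer", size = 2, signed = FALSE,
                     endian = "little")
  n <- readBin(con, "integer", size = 4, endian = "little")
  seek(con, 131)
  scale <- readBin(con, "double", n = 3, size = 8, endian = "little")
  off <- readBin(con, "double", n = 3, size = 8, endian = "little")
  if (!pdf %in% c(2L, 3L))
    stop("no radiometry: LAS point format ", pdf,
         " carries no RGB (need format 2 or 3)", call. = FALSE)
  rgb_at <- if (pdf == 2L) 20L else 28L
  if (n == 0) return(point_cloud())
  seek(con, offset_to_points)
  raw <- readBin(con, "raw", n = n * rec_len)
  if (length(raw) < n * rec_len)
    stop("las: truncated point payload", call. = FALSE)
  base <- (seq_len(n) - 1L) * rec_len
  take <- function(off_b, size) raw[rep(base, each = size) + off_b +
                                       seq_len(size)]
  xi <- readBin(take(0L, 4L), "integer", n = n, size = 4, endian = "little")
  yi <- readBin(take(4L, 4L), "integer", n = n, size = 4, endian = "little")
  zi <- readBin(take(8L, 4L), "integer", n = n, size = 4, endian = "little")
  r16 <- readBin(take(rgb_at, 2L), "integer", n = n, size = 2,
                 signed = FALSE, endian = "little")
  g16 <- readBin(take(rgb_at + 2L, 2L), "integer", n = n, size = 2,
                 signed = FALSE, endian = "little")
  b16 <- readBin(take(rgb_at + 4L, 2L), "integer", n = n, size = 2,
                 signed = FALSE, endian = "little")
  point_cloud(xi * scale[1] + off[1], yi * scale[2] + off[2],
              zi * scale[3] + off[3],
              round(r16 / 257), round(g16 / 257), round(b16 / 257))
}

## ---- plot maps --------------------------------------------------------------

#' Read a plot map from CSV or GeoJSON
#'
#' CSV columns: `plot_id, genotype, vertex_index, x, y` (one row per ring
#' vertex). GeoJSON: a `FeatureCollection` of `Polygon` features whose
#' properties carry `plot_id` and `genotype`; only the outer ring is used.
#'
#' @param path Path to a `.csv`, `.json` or `.geojson` file.
#' @return A plot-map tibble (see [as_plot_map()]).
#' @export
read_plot_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("json", "geojson")) {
    fc <- jsonlite::read_json(path)
    feats <- fc$features
    if (is.null(feats)) stop("geojson: no features", call. = FALSE)
    rows <- purrr::map_dfr(feats, function(f) {
      ring <- f$geometry$coordinates[[1]]
      xy <- matrix(unlist(ring), ncol = 2, byrow = TRUE)
      # GeoJSON rings repeat the first vertex; drop the closure
      if (nrow(xy) > 3 && all(xy[1, ] == xy[nrow(xy), ]))
        xy <- xy[-nrow(xy), , drop = FALSE]
      tibble::tibble(plot_id = as.character(f$properties$plot_id),
                     genotype = as.character(f$properties$genotype %||% NA),
                     vertex_index = seq_len(nrow(xy)),
                     x = xy[, 1], y = xy[, 2])
    })
    as_plot_map(rows)
  } else {
    as_plot_map(readr::read_csv(path, show_col_types = FALSE))
  }
}

#' Write a plot map to CSV
#'
#' @param plot_map A plot-map tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plot_map <- function(plot_map, path) {
  readr::write_csv(as_plot_map(plot_map), path)
  invisible(path)
}

## ---- clipping ---------------------------------------------------------------

#' Clip a point cloud by a 2D polygon
#'
#' Keeps exactly the points whose (x, y) fall inside or on the boundary of the
#' polygon (closed-polygon convention, matching common clipping tools such as
#' lasclip). z and color are untouched and point order is preserved.
#'
#' @param cloud A point-cloud tibble.
#' @param polygon Either a two-column matrix/data frame of ring vertices
#'   (x, y), or a plot-map tibble together with `plot_id`.
#' @param plot_id When `polygon` is a plot map: which plot's ring to use.
#' @return The clipped point-cloud tibble, stage `"plot"`.
#' @export
clip_by_polygon <- function(cloud, polygon, plot_id = NULL) {
  cloud <- as_point_cloud(cloud)
  ring <- resolve_ring(polygon, plot_id)
  keep <- points_in_ring(cloud$x, cloud$y, ring)
  set_stage(cloud[keep, , drop = FALSE], "plot")
}

#' Assign points to plots
#'
#' Adds a `plot_id` column: the id of the (first) plot polygon containing each
#' point, `NA` for points outside every plot.
#'
#' @param cloud A point-cloud tibble.
#' @param plot_map A plot-map tibble.
#' @return `cloud` with an additional `plot_id` column.
#' @export
assign_plots <- function(cloud, plot_map) {
  cloud <- as_point_cloud(cloud)
  plot_map <- as_plot_map(plot_map)
  pid <- rep(NA_character_, nrow(cloud))
  for (id in unique(plot_map$plot_id)) {
    ring <- plot_ring(plot_map, id)
    unset <- is.na(pid)
    if (!any(unset)) break
    inside <- points_in_ring(cloud$x[unset], cloud$y[unset], ring)
    pid[which(unset)[inside]] <- id
  }
  cloud$plot_id <- pid
  cloud
}

resolve_ring <- function(polygon, plot_id = NULL) {
  if (is.data.frame(polygon) && all(c("plot_id", "vertex_index") %in%
                                    names(polygon))) {
    if (is.null(plot_id)) {
      ids <- unique(polygon$plot_id)
      if (length(ids) != 1)
        stop("plot map has several plots; pass `plot_id`", call. = FALSE)
      plot_id <- ids
    }
    ring <- plot_ring(polygon, plot_id)
  } else {
    ring <- as.matrix(polygon)[, 1:2, drop = FALSE]
    n <- nrow(ring)
    if (n > 3 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  }
  if (nrow(unique(ring)) < 3)
    stop("degenerate polygon: fewer than 3 distinct vertices", call. = FALSE)
  if (abs(pracma::polyarea(ring[, 1], ring[, 2])) <= 0)
    stop("degenerate polygon: zero area", call. = FALSE)
  ring
}

# boundary-inclusive point-in-polygon
points_in_ring <- function(x, y, ring) {
  if (length(x) == 0) return(logical(0))
  pracma::inpolygon(x, y, ring[, 1], ring[, 2], boundary = TRUE)
}
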