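# File formats: binary map container, trace CSV with commented header,
# float TIFF images with JSON sidecar, YAML/JSON configs.

.MAP_MAGIC <- charToRaw("FSMP")
.MAP_VERSION <- 1L

# uint32 <-> signed int32 for writeBin/readBin
.u32_to_i32 <- function(x) {
  x <- as.numeric(x)
  as.integer(ifelse(x >= 2^31, x - 2^32, x))
}
.i32_to_u32 <- function(x) {
  x <- as.numeric(x)
  ifelse(x < 0, x + 2^32, x)
}

#' Read and write contour maps
#'
#' The map file is a little-endian binary container: a 4-byte magic
#' (`FSMP`), version, level counts, region, placeholder word, the two level
#' arrays as doubles, a JSON metadata blob, then the raw 32-bit entry array.
#' Round-trips are bit-identical on the entries. `write_map_json` exports a
#' human-readable debug copy.
#'
#' @param map A `contour_map`.
#' @param path File path.
#' @return `read_map` returns the `contour_map`; the writers return `path`
#'   invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "contour_map"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.MAP_MAGIC, con)
  writeBin(as.integer(c(.MAP_VERSION, map$h_levels$n_levels,
                        map$v_levels$n_levels)), con, size = 4L,
           endian = "little")
  writeBin(as.numeric(map$region), con, size = 8L, endian = "little")
  writeBin(.u32_to_i32(PLACEHOLDER), con, size = 4L, endian = "little")
  writeBin(as.numeric(map$h_levels$levels), con, size = 8L, endian = "little")
  writeBin(as.numeric(map$v_levels$levels), con, size = 8L, endian = "little")
  meta <- charToRaw(jsonlite::toJSON(map$build_metadata, auto_unbox = TRUE,
                                     digits = NA))
  writeBin(length(meta), con, size = 4L, endian = "little")
  writeBin(meta, con)
  writeBin(.u32_to_i32(map$entries), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (!identical(magic, .MAP_MAGIC)) stop("not a map file: bad magic")
  hdr <- readBin(con, "integer", 3L, size = 4L, endian = "little")
  if (hdr[1] != .MAP_VERSION) stop("unsupported map file version")
  nh <- hdr[2]; nv <- hdr[3]
  if (nh < 2 || nv < 2) stop("corrupt map header: bad level counts")
  region <- readBin(con, "numeric", 4L, size = 8L, endian = "little")
  ph <- .i32_to_u32(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  if (ph != PLACEHOLDER) stop("corrupt map header: unexpected placeholder")
  h_lv <- readBin(con, "numeric", nh, size = 8L, endian = "little")
  v_lv <- readBin(con, "numeric", nv, size = 8L, endian = "little")
  mlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (length(mlen) != 1L || mlen < 0) stop("corrupt map header: metadata length")
  meta <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", mlen)))
  entries <- readBin(con, "integer", nh * nv + 1L, size = 4L,
                     endian = "little")
  if (length(entries) != nh * nv)
    stop(sprintf("map entry array has %d entries, expected %d x %d = %d",
                 length(entries), nh, nv, nh * nv))
  mk_levels <- function(lv) structure(
    list(levels = lv, n_levels = length(lv),
         spacing = (lv[length(lv)] - lv[1]) / (length(lv) - 1)),
    class = "contour_levels")
  structure(list(entries = .i32_to_u32(entries), h_levels = mk_levels(h_lv),
                 v_levels = mk_levels(v_lv), region = region,
                 build_metadata = meta,
                 cache = new.env(parent = emptyenv())),
            class = "contour_map")
}

#' @rdname write_map
#' @export
write_map_json <- function(map, path) {
  stopifnot(inherits(map, "contour_map"))
  jsonlite::write_json(
    list(n_h_levels = map$h_levels$n_levels,
         n_v_levels = map$v_levels$n_levels,
         region = map$region, placeholder = PLACEHOLDER,
         h_levels = map$h_levels$levels, v_levels = map$v_levels$levels,
         build_metadata = map$build_metadata, entries = map$entries),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write tracked-trace CSV files
#'
#' Column layout: `t`, `x_nm`, `y_nm`. Header comment lines (`# key: value`)
#' record the nominal rate, block size, miss/clamp counts and the map file
#' checksum when given.
#'
#' @param trace A `tracked_trace` (or data.frame with `t`, `x`, `y`).
#' @param path File path.
#' @param map_file Optional path of the map used; its MD5 goes in the header.
#' @return `read_trace` returns a `tracked_trace` with header attributes.
#' @export
write_trace <- function(trace, path, map_file = NULL) {
  hdr <- c(
    sprintf("# nominal_rate: %.10g", attr(trace, "nominal_rate") %||% NA),
    sprintf("# block_size: %d", as.integer(attr(trace, "block_size") %||% NA)),
    sprintf("# misses: %d", as.integer(attr(trace, "misses") %||% 0L)),
    sprintf("# clamped: %d", as.integer(attr(trace, "clamped") %||% 0L)))
  if (!is.null(map_file))
    hdr <- c(hdr, sprintf("# map_md5: %s", unname(tools::md5sum(map_file))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("t,x_nm,y_nm", con)
  utils::write.table(
    data.frame(t = trace$t, x_nm = trace$x, y_nm = trace$y),
    con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  d <- utils::read.csv(text = lines[!grepl("^#", lines)])
  trace <- data.frame(t = d$t, x = d$x_nm, y = d$y_nm)
  kv <- sub("^# *", "", hdr)
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  for (i in seq_along(keys)) {
    v <- suppressWarnings(as.numeric(vals[i]))
    attr(trace, keys[i]) <- if (is.na(v)) vals[i] else v
  }
  class(trace) <- c("tracked_trace", "data.frame")
  trace
}

#' Read and write raster images as TIFF with a JSON sidecar
#'
#' Images are stored as 32-bit float TIFF, normalized to the unit peak; the
#' sidecar (`<path>.json`) records the scale factor, region, pixel size and
#' dwell so reading restores counts and metadata.
#'
#' @param image A `raster_image`.
#' @param path TIFF path (sidecar written next to it).
#' @return `read_image` returns the restored `raster_image`.
#' @export
write_image <- function(image, path) {
  m <- unclass(image)
  attributes(m) <- list(dim = dim(m))
  scale <- max(m, 1e-300)
  tiff::writeTIFF(m / scale, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(scale = scale, region = attr(image, "region"),
         pixel = attr(image, "pixel"), dwell = attr(image, "dwell")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  m <- tiff::readTIFF(path)
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  structure(m * side$scale, region = as.numeric(side$region),
            pixel = side$pixel, dwell = side$dwell,
            class = c("raster_image", "matrix", "array"))
}

#' Read and write experiment configuration files
#'
#' Configurations are plain nested lists serialized as YAML (`.yml`/`.yaml`)
#' or JSON (`.json`), chosen by extension.
#'
#' @param config A named list.
#' @param path File path ending in `.yaml`, `.yml`, or `.json`.
#' @return `read_config` returns the list.
#' @export
write_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(config, path)
  else if (ext == "json")
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  else stop("config path must end in .yaml, .yml, or .json")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
  else stop("config path must end in .yaml, .yml, or .json")
}
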