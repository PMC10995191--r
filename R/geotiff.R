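# Minimal GeoTIFF writer/reader.
#
# The package's map products are uncompressed little-endian GeoTIFFs with one
# page per layer (float32 or int16 samples, single strip), carrying
# ModelPixelScale/ModelTiepoint, a minimal GeoKeyDirectory (projected CRS,
# PixelIsArea) and a GDAL_NODATA tag, with layer names stored as PageName.
# Only this profile is read back; compressed or tiled TIFFs are out of scope.

.tiff_types <- c(ASCII = 2L, SHORT = 3L, LONG = 4L, DOUBLE = 12L)
.tiff_type_size <- c(`2` = 1L, `3` = 2L, `4` = 4L, `12` = 8L)

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
.f64 <- function(x) writeBin(as.double(x), raw(), size = 8, endian = "little")

# one 12-byte IFD entry; val is a raw vector already padded to 4 bytes
.ifd_entry <- function(tag, type, count, val4) {
  c(.u16(tag), .u16(type), .u32(count), val4)
}

.pad4 <- function(r) {
  if (length(r) < 4L) c(r, raw(4L - length(r))) else r[1:4]
}

.epsg_code <- function(crs) {
  m <- regmatches(crs, regexpr("[0-9]+$", crs))
  if (length(m) && nzchar(m)) as.integer(m) else 32767L
}

#' Write raster layers to a GeoTIFF file
#'
#' @param path output file path.
#' @param layers named list of numeric matrices sharing dimensions; row 1 is
#'   the northernmost row.
#' @param formats per-layer sample format, \code{"float32"} or \code{"int16"}.
#' @param xmin,ymax projected coordinates of the upper-left corner (m).
#' @param res cell size (m).
#' @param crs CRS tag; a trailing number is exported as the EPSG geokey.
#' @param nodata per-layer no-data value substituted for \code{NA}.
#' @return \code{path}, invisibly.
#' @seealso [read_geotiff()]
#' @export
write_geotiff <- function(path, layers, formats = "float32",
                          xmin = 0, ymax = NULL, res = 1,
                          crs = "EPSG:32643", nodata = -9999) {
  stopifnot(is.list(layers), length(layers) >= 1L, !is.null(names(layers)))
  n <- length(layers)
  dims <- lapply(layers, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    stop("all layers must share dimensions", call. = FALSE)
  }
  formats <- rep_len(formats, n)
  nodata <- rep_len(nodata, n)
  nr <- nrow(layers[[1L]]); nc <- ncol(layers[[1L]])
  if (is.null(ymax)) ymax <- nr * res

  px_bytes <- ifelse(formats == "float32", 4L, 2L)
  strip_len <- as.integer(nr * nc * px_bytes)

  # ---- data strips ------------------------------------------------------
  strips <- vector("list", n)
  for (i in seq_len(n)) {
    v <- layers[[i]]
    v[is.na(v)] <- nodata[i]
    vec <- as.vector(t(v))                       # TIFF row-major, top row first
    strips[[i]] <- if (formats[i] == "float32") {
      writeBin(as.double(vec), raw(), size = 4, endian = "little")
    } else {
      writeBin(as.integer(round(vec)), raw(), size = 2, endian = "little")
    }
  }
  strip_off <- 8L + c(0L, cumsum(strip_len))[seq_len(n)]
  after_data <- 8L + sum(strip_len)

  # ---- per-IFD out-of-line blocks and entries ---------------------------
  geo_scale <- .f64(c(res, res, 0))
  geo_tie <- .f64(c(0, 0, 0, xmin, ymax, 0))
  gk <- c(1L, 1L, 0L, 3L,
          1024L, 0L, 1L, 1L,
          1025L, 0L, 1L, 1L,
          3072L, 0L, 1L, .epsg_code(crs))
  geo_keys <- .u16(gk)

  offset <- after_data
  ifds <- vector("list", n)
  for (i in seq_len(n)) {
    name_raw <- c(charToRaw(names(layers)[i]), as.raw(0L))
    nod_raw <- c(charToRaw(format(nodata[i], scientific = FALSE)), as.raw(0L))
    aux <- raw(0)
    aux_off <- function() offset + length(aux)

    val_or_off <- function(bytes) {
      if (length(bytes) <= 4L) {
        .pad4(bytes)
      } else {
        o <- .u32(aux_off()); aux <<- c(aux, bytes); o
      }
    }
    sf <- if (formats[i] == "float32") 3L else 2L
    bps <- if (formats[i] == "float32") 32L else 16L
    entries <- list(
      .ifd_entry(256L, 4L, 1L, .u32(nc)),
      .ifd_entry(257L, 4L, 1L, .u32(nr)),
      .ifd_entry(258L, 3L, 1L, .pad4(.u16(bps))),
      .ifd_entry(259L, 3L, 1L, .pad4(.u16(1L))),
      .ifd_entry(262L, 3L, 1L, .pad4(.u16(1L))),
      .ifd_entry(273L, 4L, 1L, .u32(strip_off[i])),
      .ifd_entry(277L, 3L, 1L, .pad4(.u16(1L))),
      .ifd_entry(278L, 4L, 1L, .u32(nr)),
      .ifd_entry(279L, 4L, 1L, .u32(strip_len[i])),
      .ifd_entry(285L, 2L, length(name_raw), val_or_off(name_raw)),
      .ifd_entry(297L, 3L, 2L, c(.u16(i - 1L), .u16(n))),
      .ifd_entry(339L, 3L, 1L, .pad4(.u16(sf)))
    )
    if (i == 1L) {
      entries <- c(entries, list(
        .ifd_entry(33550L, 12L, 3L, val_or_off(geo_scale)),
        .ifd_entry(33922L, 12L, 6L, val_or_off(geo_tie)),
        .ifd_entry(34735L, 3L, length(gk), val_or_off(geo_keys))
      ))
    }
    entries <- c(entries, list(
      .ifd_entry(42113L, 2L, length(nod_raw), val_or_off(nod_raw))
    ))
    ifd_body_len <- 2L + 12L * length(entries) + 4L
    ifds[[i]] <- list(aux = aux, entries = entries,
                      aux_offset = offset, ifd_offset = offset + length(aux))
    offset <- offset + length(aux) + ifd_body_len
  }

  # ---- assemble ---------------------------------------------------------
  out <- c(charToRaw("II"), .u16(42L), .u32(ifds[[1L]]$ifd_offset))
  out <- c(out, do.call(c, strips))
  for (i in seq_len(n)) {
    nxt <- if (i < n) ifds[[i + 1L]]$ifd_offset else 0L
    body <- c(.u16(length(ifds[[i]]$entries)),
              do.call(c, ifds[[i]]$entries), .u32(nxt))
    out <- c(out, ifds[[i]]$aux, body)
  }
  writeBin(out, path)
  invisible(path)
}

.read_tag_values <- function(raw, entry_off, type, count) {
  size <- .tiff_type_size[[as.character(type)]]
  total <- size * count
  src_off <- if (total <= 4L) {
    entry_off + 8L
  } else {
    readBin(raw[(entry_off + 9L):(entry_off + 12L)], "integer",
            size = 4, endian = "little")
  }
  bytes <- raw[(src_off + 1L):(src_off + total)]
  switch(as.character(type),
    `2` = rawToChar(bytes[bytes != as.raw(0L)]),
    `3` = readBin(bytes, "integer", n = count, size = 2, signed = FALSE,
                  endian = "little"),
    `4` = readBin(bytes, "integer", n = count, size = 4, endian = "little"),
    `12` = readBin(bytes, "double", n = count, size = 8, endian = "little")
  )
}

#' Read a GeoTIFF written by \code{write_geotiff}
#'
#' @param path file path.
#' @return a list with \code{layers} (named list of matrices, no-data as
#'   \code{NA}), \code{xmin}, \code{ymax}, \code{res}, \code{epsg},
#'   \code{nodata}, \code{formats}.
#' @export
read_geotiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (rawToChar(raw[1:2]) != "II" ||
      readBin(raw[3:4], "integer", size = 2, endian = "little") != 42L) {
    stop("not a little-endian TIFF file", call. = FALSE)
  }
  ifd_off <- readBin(raw[5:8], "integer", size = 4, endian = "little")
  layers <- list(); nodata <- c(); formats <- c()
  xmin <- 0; ymax <- NULL; res <- 1; epsg <- NA_integer_
  page <- 0L
  while (ifd_off != 0L) {
    page <- page + 1L
    n_ent <- readBin(raw[(ifd_off + 1L):(ifd_off + 2L)], "integer",
                     size = 2, signed = FALSE, endian = "little")
    tags <- list()
    for (k in seq_len(n_ent)) {
      e_off <- ifd_off + 2L + 12L * (k - 1L)
      tag <- readBin(raw[(e_off + 1L):(e_off + 2L)], "integer",
                     size = 2, signed = FALSE, endian = "little")
      type <- readBin(raw[(e_off + 3L):(e_off + 4L)], "integer",
                      size = 2, signed = FALSE, endian = "little")
      count <- readBin(raw[(e_off + 5L):(e_off + 8L)], "integer",
                       size = 4, endian = "little")
      tags[[as.character(tag)]] <- .read_tag_values(raw, e_off, type, count)
    }
    nc <- tags[["256"]]; nr <- tags[["257"]]
    bps <- tags[["258"]]; sf <- tags[["339"]] %||% 1L
    comp <- tags[["259"]] %||% 1L
    if (comp != 1L) stop("compressed TIFF not supported", call. = FALSE)
    offs <- tags[["273"]]; cnts <- tags[["279"]]
    bytes <- do.call(c, lapply(seq_along(offs), function(s) {
      raw[(offs[s] + 1L):(offs[s] + cnts[s])]
    }))
    vec <- if (sf == 3L && bps == 32L) {
      readBin(bytes, "double", n = nr * nc, size = 4, endian = "little")
    } else if (bps == 16L) {
      readBin(bytes, "integer", n = nr * nc, size = 2, signed = TRUE,
              endian = "little")
    } else {
      stop("unsupported sample layout (bits=", bps, ", format=", sf, ")",
           call. = FALSE)
    }
    m <- matrix(vec, nrow = nr, ncol = nc, byrow = TRUE)
    nod <- suppressWarnings(as.numeric(tags[["42113"]] %||% NA))
    if (!is.na(nod)) m[m == nod] <- NA
    nm <- tags[["285"]] %||% paste0("layer", page)
    layers[[nm]] <- m
    nodata <- c(nodata, nod)
    formats <- c(formats, if (sf == 3L) "float32" else "int16")
    if (!is.null(tags[["33550"]])) res <- tags[["33550"]][1L]
    if (!is.null(tags[["33922"]])) {
      xmin <- tags[["33922"]][4L]; ymax <- tags[["33922"]][5L]
    }
    if (!is.null(tags[["34735"]])) {
      gk <- matrix(tags[["34735"]], ncol = 4L, byrow = TRUE)
      hit <- which(gk[, 1L] == 3072L)
      if (length(hit)) epsg <- gk[hit[1L], 4L]
    }
    ifd_off <- readBin(raw[(ifd_off + 2L + 12L * n_ent + 1L):
                           (ifd_off + 2L + 12L * n_ent + 4L)],
                       "integer", size = 4, endian = "little")
  }
  list(layers = layers, xmin = xmin, ymax = ymax, res = res, epsg = epsg,
       nodata = nodata, formats = formats)
}
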