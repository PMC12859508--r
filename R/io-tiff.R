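# Minimal baseline TIFF codec: uncompressed, single-channel, 8/16-bit,
# multi-page, little-endian on write, either byte order on read. No
# pre-installed R package reads TIFF in this environment, and the subset
# needed here (grayscale strips + an OME-XML ImageDescription) is small
# and fully specified, so it is implemented directly.

tiff_types <- c(BYTE = 1L, ASCII = 2L, SHORT = 3L, LONG = 4L, RATIONAL = 5L)

ome_description <- function(stack) {
  d <- dim(stack$frames[[1]])
  type <- if (stack$bit_depth == 16) "uint16" else "uint8"
  ps <- stack$pixel_size
  ps_attr <- if (!is.na(ps)) {
    sprintf(' PhysicalSizeX="%.10g" PhysicalSizeY="%.10g" PhysicalSizeXUnit="µm" PhysicalSizeYUnit="µm"', ps, ps)
  } else ""
  paste0('<?xml version="1.0" encoding="UTF-8"?>',
         '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
         sprintf('<Image ID="Image:0" Name="%s"><Pixels ID="Pixels:0" ',
                 stack$name),
         sprintf('DimensionOrder="XYCZT" Type="%s" SizeX="%d" SizeY="%d" ',
                 type, d[2], d[1]),
         sprintf('SizeC="1" SizeZ="1" SizeT="%d"%s/>', length(stack$frames),
                 ps_attr),
         '</Image></OME>')
}

#' Write a frame stack as a multi-page (OME-)TIFF
#'
#' Writes an uncompressed grayscale baseline TIFF, one page per frame,
#' with the pixel size embedded as OME-XML in the first page's
#' ImageDescription (so it round-trips through [read_frame_stack()]).
#'
#' @param stack a [frame_stack()].
#' @param path output path.
#' @param ome embed OME-XML metadata (default TRUE).
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path, ome = TRUE) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames[[1]])
  h <- d[1]; w <- d[2]
  bps <- if (stack$bit_depth == 16) 16L else 8L
  bytes_pp <- bps / 8L
  desc <- if (ome) ome_description(stack) else ""
  desc_raw <- c(charToRaw(enc2utf8(desc)), as.raw(0))
  if (length(desc_raw) %% 2 == 1) desc_raw <- c(desc_raw, as.raw(0))
  n <- length(stack$frames)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  # layout: header(8) [desc] [page data x n] [IFD x n]
  desc_off <- 8L
  data_off <- desc_off + if (ome) length(desc_raw) else 0L
  strip_size <- w * h * bytes_pp
  strip_offs <- data_off + (seq_len(n) - 1L) * strip_size
  n_entries <- function(i) if (i == 1 && ome) 10L else 9L
  ifd_sizes <- 2L + 12L * vapply(seq_len(n), n_entries, integer(1)) + 4L
  ifd_offs <- data_off + n * strip_size + c(0L, cumsum(ifd_sizes))[seq_len(n)]
  writeBin(as.integer(ifd_offs[1]), con, size = 4, endian = "little")
  if (ome) writeBin(desc_raw, con)
  for (f in stack$frames) {
    v <- as.integer(round(t(f)))       # TIFF stores rows sequentially
    if (bps == 8) {
      writeBin(as.raw(pmin(pmax(v, 0L), 255L)), con)
    } else {
      writeBin(pmin(pmax(v, 0L), 65535L), con, size = 2, endian = "little")
    }
  }
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == tiff_types["SHORT"] && count == 1) {
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (i in seq_len(n)) {
    writeBin(n_entries(i), con, size = 2, endian = "little")
    entry(256, tiff_types["LONG"], 1, w)
    entry(257, tiff_types["LONG"], 1, h)
    entry(258, tiff_types["SHORT"], 1, bps)
    entry(259, tiff_types["SHORT"], 1, 1)        # no compression
    entry(262, tiff_types["SHORT"], 1, 1)        # BlackIsZero
    if (i == 1 && ome) {
      entry(270, tiff_types["ASCII"], length(desc_raw), desc_off)
    }
    entry(273, tiff_types["LONG"], 1, strip_offs[i])
    entry(277, tiff_types["SHORT"], 1, 1)
    entry(278, tiff_types["LONG"], 1, h)
    entry(279, tiff_types["LONG"], 1, strip_size)
    nxt <- if (i < n) ifd_offs[i + 1] else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

read_uint <- function(raw, off, size, endian) {
  b <- as.integer(raw[off + seq_len(size)])
  if (endian == "little") b <- rev(b)
  Reduce(function(a, x) a * 256 + x, b, 0)
}

#' Read a (OME-)TIFF time series
#'
#' Parses a multi-page uncompressed grayscale TIFF (8- or 16-bit, either
#' byte order, strip layout). The pixel size is taken from OME-XML
#' metadata in the ImageDescription when present, otherwise from
#' `pixel_size_override`; a plain TIFF with neither is an error, because
#' the physical mode amplitudes cannot be interpreted without it.
#'
#' @param path TIFF file.
#' @param pixel_size_override um/px used when the file has no OME pixel
#'   size.
#' @param name experiment/video name (default: file name).
#' @return a [frame_stack()].
#' @export
read_frame_stack <- function(path, pixel_size_override = NA_real_,
                             name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8) stop("truncated TIFF: ", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  if (read_uint(raw, 2, 2, endian) != 42) stop("not a TIFF file: ", path)
  ifd_off <- read_uint(raw, 4, 4, endian)
  frames <- list()
  desc <- NULL
  while (ifd_off != 0) {
    if (ifd_off + 2 > length(raw)) stop("truncated TIFF: ", path)
    n_ent <- read_uint(raw, ifd_off, 2, endian)
    tags <- list()
    for (k in seq_len(n_ent)) {
      e <- ifd_off + 2 + (k - 1) * 12
      tag <- read_uint(raw, e, 2, endian)
      type <- read_uint(raw, e + 2, 2, endian)
      count <- read_uint(raw, e + 4, 4, endian)
      tsize <- c(1, 1, 2, 4, 8)[type]
      if (is.na(tsize)) next
      total <- tsize * count
      voff <- if (total <= 4) e + 8 else read_uint(raw, e + 8, 4, endian)
      vals <- if (type == 2) {
        b <- raw[voff + seq_len(count)]
        rawToChar(b[b != as.raw(0)])
      } else {
        vapply(seq_len(count) - 1,
               function(j) read_uint(raw, voff + j * tsize, tsize, endian),
               numeric(1))
      }
      tags[[as.character(tag)]] <- vals
    }
    need <- function(t) {
      v <- tags[[as.character(t)]]
      if (is.null(v)) stop("TIFF missing required tag ", t)
      v
    }
    w <- need(256); h <- need(257)
    bps <- if (is.null(tags[["258"]])) 8 else tags[["258"]][1]
    comp <- if (is.null(tags[["259"]])) 1 else tags[["259"]][1]
    if (comp != 1) stop("compressed TIFF not supported (compression ", comp, ")")
    if (!bps %in% c(8, 16)) stop("unsupported bit depth: ", bps)
    if (!is.null(tags[["270"]]) && is.null(desc)) desc <- tags[["270"]]
    offs <- need(273); cnts <- need(279)
    buf <- unlist(lapply(seq_along(offs), function(j) {
      raw[offs[j] + seq_len(cnts[j])]
    }))
    if (bps == 8) {
      v <- as.numeric(buf)
    } else {
      m <- matrix(as.integer(buf), nrow = 2)
      v <- if (endian == "little") m[1, ] + 256 * m[2, ]
           else m[2, ] + 256 * m[1, ]
    }
    # frames are double matrices: everything downstream is arithmetic
    frames[[length(frames) + 1]] <- matrix(as.numeric(v), nrow = h,
                                           ncol = w, byrow = TRUE)
    ifd_off <- read_uint(raw, ifd_off + 2 + n_ent * 12, 4, endian)
  }
  if (!length(frames)) stop("TIFF contains no images: ", path)
  pixel_size <- NA_real_
  bit_depth <- if (max(frames[[1]]) > 255 || bps == 16) 16L else 8L
  if (!is.null(desc) && grepl("<OME", desc, fixed = TRUE)) {
    px <- tryCatch({
      doc <- xml2::read_xml(desc)
      node <- xml2::xml_find_first(doc, "//*[local-name() = 'Pixels']")
      as.numeric(xml2::xml_attr(node, "PhysicalSizeX"))
    }, error = function(e) NA_real_)
    if (!is.na(px)) pixel_size <- px
  }
  if (is.na(pixel_size)) pixel_size <- pixel_size_override
  if (is.na(pixel_size)) {
    stop("pixel size missing: '", basename(path), "' carries no OME ",
         "PhysicalSizeX metadata and no pixel_size_override was given; ",
         "plain .tif files must have the pixel size supplied explicitly")
  }
  frame_stack(frames, pixel_size = pixel_size, bit_depth = bit_depth,
              source = path,
              name = if (is.null(name)) basename(path) else name)
}
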