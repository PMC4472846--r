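# Minimal baseline TIFF codec. No TIFF reader is available in the
# environment this package targets, so the subset of the format the assay
# needs is implemented here: uncompressed, chunky-planar, 8- or 16-bit
# unsigned, grayscale (1 sample) or RGB (3 samples), multi-page, with
# resolution tags and an ImageJ-style hyperstack ImageDescription.
# Anything else (compression, tiles, planar RGB) is rejected loudly.

.TAG <- list(
  width = 256L, length = 257L, bits = 258L, compression = 259L,
  photometric = 262L, description = 270L, strip_offsets = 273L,
  samples = 277L, rows_per_strip = 278L, strip_bytes = 279L,
  xres = 282L, yres = 283L, planar = 284L, resunit = 296L
)

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) {
  # values can exceed .Machine$integer.max only for files > 2 GB, out of scope
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

# One 12-byte IFD entry. `value` is either inline (<= 4 bytes once encoded)
# or an offset into the out-of-line data block prepared by the caller.
.ifd_entry <- function(tag, type, count, value_raw4) {
  c(.u16(tag), .u16(type), .u32(count), value_raw4)
}

.pad4 <- function(x) if (length(x) %% 2 == 1) c(x, as.raw(0)) else x

#' Write a multi-page TIFF
#'
#' @param path output file.
#' @param pages list of `y x x` integer matrices (grayscale) or
#'   `y x x x 3` arrays (RGB).
#' @param bits bits per sample, 8 or 16.
#' @param pixel_size physical pixel size in micrometres per pixel, written as
#'   resolution tags (pixels per centimetre); `NULL` omits the tags.
#' @param description ImageDescription string attached to the first page.
#' @return `path`, invisibly.
#' @keywords internal
write_tiff <- function(path, pages, bits = 16L, pixel_size = NULL,
                       description = NULL) {
  stopifnot(is.list(pages), length(pages) >= 1, bits %in% c(8L, 16L))
  con <- file(path, "wb")
  on.exit(close(con))

  encode_page <- function(pg) {
    if (length(dim(pg)) == 3) {
      v <- as.vector(aperm(pg, c(3L, 2L, 1L)))  # sample, x, y -> interleaved
      spp <- 3L
    } else {
      v <- as.vector(t(pg))  # row-major
      spp <- 1L
    }
    v <- as.integer(round(v))
    maxv <- if (bits == 8L) 255L else 65535L
    v[v < 0L] <- 0L
    v[v > maxv] <- maxv
    dat <- if (bits == 8L) as.raw(v) else
      writeBin(v, raw(), size = 2, endian = "little")
    list(data = dat, spp = spp,
         h = dim(pg)[1], w = dim(pg)[2])
  }

  enc <- lapply(pages, encode_page)
  header <- c(charToRaw("II"), .u16(42L))
  # layout: header(8) | page data blocks | aux data | IFD chain
  offset <- 8L
  data_off <- integer(length(enc))
  for (i in seq_along(enc)) {
    data_off[i] <- offset
    offset <- offset + length(enc[[i]]$data) + (length(enc[[i]]$data) %% 2)
  }
  aux <- raw(0)
  aux_base <- offset
  put_aux <- function(r) {
    off <- aux_base + length(aux)
    aux <<- c(aux, .pad4(r))
    off
  }

  rational <- function(num, den) c(.u32(num), .u32(den))
  res_raw <- NULL
  if (!is.null(pixel_size)) {
    # pixels per centimetre as a rational with 1e3 denominator
    ppcm <- 10000 / pixel_size
    res_raw <- rational(round(ppcm * 1000), 1000L)
  }

  ifds <- vector("list", length(enc))
  desc_raw <- if (!is.null(description)) c(charToRaw(description), as.raw(0L)) else NULL

  # first pass cannot know IFD offsets yet; sizes are fixed so compute them
  n_entries <- function(i) {
    n <- 10L  # width,length,bits,compression,photometric,strips,samples,rows,bytes,planar
    if (!is.null(res_raw)) n <- n + 3L  # xres, yres, resunit
    if (i == 1L && !is.null(desc_raw)) n <- n + 1L
    n
  }

  # aux data: description, resolution rationals, RGB BitsPerSample triple
  desc_off <- if (!is.null(desc_raw) && length(desc_raw) > 4) put_aux(desc_raw) else NULL
  xres_off <- yres_off <- NULL
  if (!is.null(res_raw)) {
    xres_off <- put_aux(res_raw)
    yres_off <- put_aux(res_raw)
  }
  bits3_off <- if (any(vapply(enc, function(e) e$spp, 1L) == 3L)) {
    put_aux(c(.u16(bits), .u16(bits), .u16(bits)))
  } else NULL
  ifd_base <- aux_base + length(aux)
  ifd_off <- integer(length(enc))
  off <- ifd_base
  for (i in seq_along(enc)) {
    ifd_off[i] <- off
    off <- off + 2L + 12L * n_entries(i) + 4L
  }

  inline16 <- function(x) c(.u16(x), .u16(0L))
  for (i in seq_along(enc)) {
    e <- enc[[i]]
    photometric <- if (e$spp == 3L) 2L else 1L
    entries <- list(
      .ifd_entry(.TAG$width, 4L, 1L, .u32(e$w)),
      .ifd_entry(.TAG$length, 4L, 1L, .u32(e$h)),
      if (e$spp == 1L) {
        .ifd_entry(.TAG$bits, 3L, 1L, inline16(bits))
      } else {
        .ifd_entry(.TAG$bits, 3L, 3L, .u32(bits3_off))
      },
      .ifd_entry(.TAG$compression, 3L, 1L, inline16(1L)),
      .ifd_entry(.TAG$photometric, 3L, 1L, inline16(photometric)),
      if (i == 1L && !is.null(desc_raw)) {
        if (length(desc_raw) <= 4) {
          .ifd_entry(.TAG$description, 2L, length(desc_raw),
                     c(desc_raw, raw(4 - length(desc_raw))))
        } else {
          .ifd_entry(.TAG$description, 2L, length(desc_raw), .u32(desc_off))
        }
      },
      .ifd_entry(.TAG$strip_offsets, 4L, 1L, .u32(data_off[i])),
      .ifd_entry(.TAG$samples, 3L, 1L, inline16(e$spp)),
      .ifd_entry(.TAG$rows_per_strip, 4L, 1L, .u32(e$h)),
      .ifd_entry(.TAG$strip_bytes, 4L, 1L, .u32(length(e$data))),
      if (!is.null(res_raw)) .ifd_entry(.TAG$xres, 5L, 1L, .u32(xres_off)),
      if (!is.null(res_raw)) .ifd_entry(.TAG$yres, 5L, 1L, .u32(yres_off)),
      .ifd_entry(.TAG$planar, 3L, 1L, inline16(1L)),
      if (!is.null(res_raw)) .ifd_entry(.TAG$resunit, 3L, 1L, inline16(3L))
    )
    entries <- Filter(Negate(is.null), entries)
    stopifnot(length(entries) == n_entries(i))
    # entries must be sorted by tag id
    tags <- vapply(entries, function(r) {
      as.integer(r[1]) + 256L * as.integer(r[2])
    }, integer(1))
    entries <- entries[order(tags)]
    next_off <- if (i < length(enc)) ifd_off[i + 1] else 0L
    ifds[[i]] <- c(.u16(length(entries)), do.call(c, entries), .u32(next_off))
  }

  writeBin(c(header, .u32(ifd_off[1])), con)
  for (i in seq_along(enc)) {
    d <- enc[[i]]$data
    if (length(d) %% 2 == 1) d <- c(d, as.raw(0))
    writeBin(d, con)
  }
  if (length(aux)) writeBin(aux, con)
  writeBin(do.call(c, ifds), con)
  invisible(path)
}

#' Read a baseline TIFF
#'
#' Supports the subset written by [write_tiff()] plus common grayscale/RGB
#' uncompressed files from other writers (both byte orders, multiple strips).
#'
#' @param path TIFF file.
#' @return list with `pages` (matrices or `y x x x 3` arrays), `description`,
#'   `pixel_size` (um/px from resolution tags, `NA` if absent), `bits`.
#' @keywords internal
read_tiff <- function(path) {
  if (!file.exists(path)) stop_input("cannot read TIFF: file not found: ", path)
  raw_all <- readBin(path, "raw", file.size(path))
  if (length(raw_all) < 8) stop_input("truncated TIFF: ", path)
  endian <- if (raw_all[1] == charToRaw("I")[1]) "little" else "big"
  magic <- readBin(raw_all[3:4], "integer", size = 2, endian = endian, signed = FALSE)
  if (magic != 42) stop_input("not a TIFF file: ", path)

  rd <- function(off, n, size, signed = FALSE) {
    if (off + n * size - 1 > length(raw_all)) stop_input("truncated TIFF: ", path)
    readBin(raw_all[(off + 1):(off + n * size)], "integer",
            n = n, size = size, endian = endian, signed = signed)
  }
  rd32 <- function(off, n = 1) rd(off, n, 4, signed = TRUE)

  ifd_off <- rd32(4)
  pages <- list()
  description <- NULL
  pixel_size <- NA_real_
  bits_out <- NA_integer_

  type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)

  while (ifd_off != 0) {
    n_ent <- rd(ifd_off, 1, 2)
    tags <- list()
    for (k in seq_len(n_ent)) {
      e <- ifd_off + 2 + (k - 1) * 12
      tag <- rd(e, 1, 2)
      typ <- rd(e + 2, 1, 2)
      cnt <- rd32(e + 4)
      tsz <- type_size[as.character(typ)]
      if (is.na(tsz)) next
      total <- tsz * cnt
      voff <- if (total <= 4) e + 8 else rd32(e + 8)
      val <- switch(as.character(typ),
        `1` = as.integer(raw_all[(voff + 1):(voff + cnt)]),
        `2` = {
          chars <- raw_all[(voff + 1):(voff + cnt)]
          rawToChar(chars[chars != as.raw(0)])
        },
        `3` = rd(voff, cnt, 2),
        `4` = rd32(voff, cnt),
        `5` = {
          nums <- rd32(voff, 2 * cnt)
          nums[seq(1, 2 * cnt, 2)] / nums[seq(2, 2 * cnt, 2)]
        }
      )
      tags[[as.character(tag)]] <- val
    }
    g <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    w <- g(.TAG$width); h <- g(.TAG$length)
    if (is.null(w) || is.null(h)) stop_input("TIFF page missing dimensions: ", path)
    comp <- g(.TAG$compression, 1L)
    if (comp != 1L) stop_input("unsupported TIFF compression (", comp, "): ", path)
    spp <- g(.TAG$samples, 1L)
    bits <- g(.TAG$bits, 8L)[1]
    if (!bits %in% c(8L, 16L)) stop_input("unsupported bit depth (", bits, "): ", path)
    if (!spp %in% c(1L, 3L)) stop_input("unsupported samples per pixel (", spp, "): ", path)
    if (g(.TAG$planar, 1L) != 1L) stop_input("planar TIFF not supported: ", path)
    bits_out <- bits
    if (is.null(description)) description <- g(.TAG$description)
    xres <- g(.TAG$xres)
    if (!is.null(xres) && is.na(pixel_size) && xres > 0) {
      unit <- g(.TAG$resunit, 2L)
      unit_um <- if (unit == 3L) 10000 else if (unit == 2L) 25400 else NA_real_
      if (!is.na(unit_um)) pixel_size <- unit_um / xres
    }

    offs <- g(.TAG$strip_offsets)
    cnts <- g(.TAG$strip_bytes)
    if (is.null(offs) || is.null(cnts)) stop_input("TIFF page missing strip data: ", path)
    data <- do.call(c, lapply(seq_along(offs), function(i) {
      raw_all[(offs[i] + 1):(offs[i] + cnts[i])]
    }))
    nval <- w * h * spp
    v <- if (bits == 8L) as.integer(data[seq_len(nval)]) else
      readBin(data, "integer", n = nval, size = 2, endian = endian, signed = FALSE)
    pg <- if (spp == 1L) {
      t(matrix(v, nrow = w, ncol = h))
    } else {
      aperm(array(v, dim = c(3L, w, h)), c(3L, 2L, 1L))
    }
    pages[[length(pages) + 1L]] <- pg
    ifd_off <- rd32(ifd_off + 2 + 12 * n_ent)
  }
  if (!length(pages)) stop_input("TIFF contains no pages: ", path)
  list(pages = pages, description = description,
       pixel_size = pixel_size, bits = bits_out)
}
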