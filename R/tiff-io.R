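# Minimal baseline TIFF codec (little-endian, uncompressed, grayscale,
# multi-page). The scientific R stack installed here has no TIFF package,
# and image I/O is plumbing, not method: this writes exactly the subset it
# reads back (8/16/32-bit unsigned, one sample per pixel), stores channel
# or plane identity in ImageDescription, and the physical pixel size in
# the resolution tags (ResolutionUnit = cm).

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)

wb2 <- function(con, x) writeBin(as.integer(x), con, size = 2L,
                                 endian = "little")
wb4 <- function(con, x) writeBin(as.integer(x), con, size = 4L,
                                 endian = "little")

tiff_entry <- function(tag, type, count, value_or_offset) {
  list(tag = tag, type = type, count = count, value = value_or_offset)
}

write_tiff <- function(path, pages, bits, descriptions, px_per_um) {
  stopifnot(length(pages) >= 1L, bits %in% c(8L, 16L, 32L))
  nr <- nrow(pages[[1]]); nc <- ncol(pages[[1]])
  bpp <- bits / 8L
  data_sizes <- vapply(pages, function(p) nrow(p) * ncol(p) * bpp,
                       numeric(1))
  data_offsets <- 8 + cumsum(c(0, data_sizes[-length(data_sizes)]))
  # per-page auxiliary block: description (NUL-terminated, even-padded)
  # + two 8-byte rationals (x/y resolution)
  desc_bytes <- lapply(descriptions, function(d) {
    b <- c(charToRaw(d), as.raw(0))
    if (length(b) %% 2L) b <- c(b, as.raw(0))
    b
  })
  aux_sizes <- vapply(desc_bytes, length, integer(1)) + 16L
  n_entries <- 14L
  ifd_size <- 2L + n_entries * 12L + 4L
  aux_offsets <- 8 + sum(data_sizes) +
    cumsum(c(0, (aux_sizes + ifd_size)[-length(pages)]))
  ifd_offsets <- aux_offsets + aux_sizes
  res_num <- if (is.na(px_per_um)) 0 else round(px_per_um * 1e7)  # px/cm x 1000
  res_den <- 1000

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  wb2(con, 42L)
  wb4(con, ifd_offsets[1])
  for (i in seq_along(pages)) {
    v <- as.vector(t(pages[[i]]))  # row-major
    writeBin(as.integer(v), con, size = bpp, endian = "little")
  }
  for (i in seq_along(pages)) {
    db <- desc_bytes[[i]]
    writeBin(db, con)
    wb4(con, c(res_num, res_den, res_num, res_den))
    desc_off <- aux_offsets[i]
    xres_off <- aux_offsets[i] + length(db)
    yres_off <- xres_off + 8
    entries <- list(
      tiff_entry(256L, 4L, 1L, nc),
      tiff_entry(257L, 4L, 1L, nr),
      tiff_entry(258L, 3L, 1L, bits),
      tiff_entry(259L, 3L, 1L, 1L),
      tiff_entry(262L, 3L, 1L, 1L),
      tiff_entry(270L, 2L, length(db), desc_off),
      tiff_entry(273L, 4L, 1L, data_offsets[i]),
      tiff_entry(277L, 3L, 1L, 1L),
      tiff_entry(278L, 4L, 1L, nr),
      tiff_entry(279L, 4L, 1L, data_sizes[i]),
      tiff_entry(282L, 5L, 1L, xres_off),
      tiff_entry(283L, 5L, 1L, yres_off),
      tiff_entry(296L, 3L, 1L, 3L),
      tiff_entry(339L, 3L, 1L, 1L))
    wb2(con, n_entries)
    for (e in entries) {
      wb2(con, e$tag)
      wb2(con, e$type)
      wb4(con, e$count)
      if (e$type == 3L && e$count == 1L) {
        wb2(con, e$value); wb2(con, 0L)
      } else if (e$type == 2L && e$count <= 4L) {
        b <- c(desc_bytes[[i]], raw(4))[1:4]
        writeBin(b, con)
      } else {
        wb4(con, e$value)
      }
    }
    wb4(con, if (i < length(pages)) ifd_offsets[i + 1] else 0L)
  }
  invisible(path)
}

read_tiff <- function(path) {
  abort_if(!file.exists(path), "file not found: ", path)
  raw_all <- readBin(path, "raw", file.info(path)$size)
  abort_if(length(raw_all) < 8L, "not a TIFF file: ", path)
  order_tag <- rawToChar(raw_all[1:2])
  abort_if(order_tag != "II",
           "only little-endian TIFF is supported (got '", order_tag, "')")
  rd_int <- function(off, size, signed = TRUE)
    readBin(raw_all[(off + 1):(off + size)], "integer", size = size,
            endian = "little", signed = signed)
  rd_ints <- function(off, size, n)
    readBin(raw_all[(off + 1):(off + n * size)], "integer", n = n,
            size = size, endian = "little",
            signed = size >= 4L)
  abort_if(rd_int(2, 2, signed = FALSE) != 42L, "bad TIFF magic in ", path)
  ifd_off <- rd_int(4, 4)
  pages <- list(); descriptions <- character(0); px_per_um <- NA_real_
  while (ifd_off != 0L) {
    n <- rd_int(ifd_off, 2, signed = FALSE)
    tags <- list()
    for (i in seq_len(n)) {
      e0 <- ifd_off + 2 + (i - 1) * 12
      tag <- rd_int(e0, 2, signed = FALSE)
      type <- rd_int(e0 + 2, 2, signed = FALSE)
      count <- rd_int(e0 + 4, 4)
      tsz <- TIFF_TYPE_SIZE[as.character(type)]
      inline <- !is.na(tsz) && tsz * count <= 4
      val_off <- if (inline) e0 + 8 else rd_int(e0 + 8, 4)
      tags[[as.character(tag)]] <- list(type = type, count = count,
                                        off = val_off, inline = inline)
    }
    getv <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) return(default)
      if (t$type == 2L) {
        b <- raw_all[(t$off + 1):(t$off + t$count)]
        return(rawToChar(b[b != as.raw(0)]))
      }
      if (t$type == 5L) {
        v <- rd_ints(t$off, 4L, 2L * t$count)
        return(v[seq(1, length(v), 2)] / v[seq(2, length(v), 2)])
      }
      tsz <- TIFF_TYPE_SIZE[as.character(t$type)]
      rd_ints(t$off, tsz, t$count)
    }
    abort_if(!identical(getv(259L, 1L), 1L),
             "compressed TIFF not supported: ", path)
    nc <- getv(256L); nr <- getv(257L)
    bits <- getv(258L, 8L)
    abort_if(!bits %in% c(8L, 16L, 32L),
             "unsupported BitsPerSample ", bits, " in ", path)
    abort_if(!identical(getv(277L, 1L), 1L),
             "only one sample per pixel is supported: ", path)
    offs <- getv(273L); cnts <- getv(279L)
    vals <- integer(0)
    for (s in seq_along(offs))
      vals <- c(vals, rd_ints(offs[s], bits / 8L, cnts[s] / (bits / 8L)))
    abort_if(length(vals) != nr * nc, "corrupt strip data in ", path)
    if (bits == 16L) vals <- ifelse(vals < 0L, vals + 65536L, vals)
    m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
    pages[[length(pages) + 1L]] <- m
    descriptions <- c(descriptions, getv(270L, ""))
    xres <- getv(282L)
    if (!is.null(xres) && xres > 0 && identical(getv(296L, 2L), 3L))
      px_per_um <- xres / 1e4
    ifd_off <- rd_int(ifd_off + 2 + n * 12, 4)
  }
  list(pages = pages, descriptions = descriptions, px_per_um = px_per_um)
}

pick_bits <- function(maxv) if (maxv > 65535) 32L else 16L

#' Write / read a field image as multi-page TIFF
#'
#' One grayscale page per channel, channel names recorded in
#' ImageDescription, physical pixel size in the resolution tags. Pixel
#' values must be non-negative integers (raw detector units); write raw
#' fields, not normalized ones.
#'
#' @param field a [field_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "field_image"))
  for (nm in names(field$channels)) {
    ch <- field$channels[[nm]]
    abort_if(any(ch < 0) || any(ch != floor(ch)),
             "channel '", nm, "' is not non-negative integer-valued; ",
             "write raw detector images, not normalized ones")
  }
  bits <- pick_bits(max(vapply(field$channels, max, numeric(1)), 0))
  write_tiff(path, field$channels, bits,
             paste0("channel:", names(field$channels)), field$px_per_um)
  invisible(path)
}

#' @rdname write_field
#' @param px_per_um fallback resolution if the file carries none.
#' @export
read_field <- function(path, px_per_um = NULL) {
  tf <- read_tiff(path)
  abort_if(!all(startsWith(tf$descriptions, "channel:")),
           path, " is not a field TIFF (use read_stack for z-stacks)")
  chans <- tf$pages
  names(chans) <- sub("^channel:", "", tf$descriptions)
  res <- if (!is.na(tf$px_per_um)) tf$px_per_um else px_per_um
  abort_if(is.null(res), "no resolution stored in ", path,
           " and no px_per_um given")
  field_image(chans, res, provenance = list(source = path))
}

#' Write / read a label mask TIFF
#'
#' Single-page integer TIFF; 16-bit when the largest label fits, widened
#' to 32-bit otherwise, so label identities are never truncated.
#'
#' @param mask a [label_mask()].
#' @param path file path.
#' @return `path` / a [label_mask()].
#' @export
write_labels <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  bits <- pick_bits(max(mask$labels, 0L))
  write_tiff(path, list(mask$labels), bits,
             paste0("labels:", mask$channel_of_origin), NA_real_)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  tf <- read_tiff(path)
  abort_if(length(tf$pages) != 1L ||
             !startsWith(tf$descriptions[1], "labels:"),
           path, " is not a label-mask TIFF")
  label_mask(tf$pages[[1]], sub("^labels:", "", tf$descriptions[1]))
}

#' Write / read a single-channel z-stack TIFF
#'
#' One page per plane, recorded as `plane:<i>`. `read_stack` returns the
#' 3-D array; passing `plane_range` applies [max_project()] on the fly and
#' equals projecting after a full read.
#'
#' @param stack 3-D non-negative integer array (rows x cols x planes).
#' @param path file path.
#' @param px_per_um physical resolution to store.
#' @return `path` / 3-D array or 2-D projection.
#' @export
write_stack <- function(stack, path, px_per_um = 16) {
  abort_if(!is.array(stack) || length(dim(stack)) != 3L,
           "stack must be a 3-D array")
  abort_if(any(stack < 0) || any(stack != floor(stack)),
           "stack must be non-negative integer-valued")
  pages <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  write_tiff(path, pages, pick_bits(max(stack)),
             paste0("plane:", seq_along(pages)), px_per_um)
  invisible(path)
}

#' @rdname write_stack
#' @param plane_range optional inclusive plane pair for on-the-fly MIP.
#' @export
read_stack <- function(path, plane_range = NULL) {
  tf <- read_tiff(path)
  abort_if(!all(startsWith(tf$descriptions, "plane:")),
           path, " is not a z-stack TIFF")
  arr <- array(0L, dim = c(nrow(tf$pages[[1]]), ncol(tf$pages[[1]]),
                           length(tf$pages)))
  for (i in seq_along(tf$pages)) arr[, , i] <- tf$pages[[i]]
  if (is.null(plane_range)) arr else max_project(arr, plane_range)
}
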