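#' Minimal FITS image I/O
#'
#' Self-contained writer/reader for the subset of FITS used by this
#' package: 64-bit float image HDUs (primary plus any number of IMAGE
#' extensions) with scalar header cards. Arrays round-trip exactly;
#' `NAXIS1` corresponds to the first R array dimension. Not a
#' general-purpose FITS library.
#'
#' @param hdus list of HDUs, each a list with elements `data` (numeric
#'   array or `NULL`) and `header` (named list of scalar values).
#' @param file path.
#' @return `write_fits`: the path, invisibly. `read_fits`: a list of HDUs
#'   in the same shape.
#' @name fits_io
NULL

fits_card <- function(key, value) {
  key <- toupper(substr(key, 1, 8))
  val <- if (is.logical(value)) {
    sprintf("%20s", if (value) "T" else "F")
  } else if (is.character(value)) {
    sprintf("%-20s", paste0("'", substr(value, 1, 66), "'"))
  } else if (is.na(value)) {
    sprintf("%20s", "")
  } else if (is.numeric(value) && value == round(value) &&
             abs(value) < 2^52) {
    sprintf("%20s", format(value, scientific = FALSE))
  } else {
    sprintf("%20s", format(value, digits = 16))
  }
  card <- sprintf("%-8s= %s", key, val)
  substr(sprintf("%-80s", card), 1, 80)
}

pad_block <- function(n, fill = c("space", "zero")) {
  fill <- match.arg(fill)
  rem <- n %% 2880
  if (rem == 0) return(NULL)
  if (fill == "space") charToRaw(strrep(" ", 2880 - rem)) else raw(2880 - rem)
}

write_hdu <- function(con, data, header, primary) {
  cards <- character(0)
  if (primary) {
    cards <- c(cards, fits_card("SIMPLE", TRUE))
  } else {
    cards <- c(cards, fits_card("XTENSION", "IMAGE"))
  }
  dims <- if (is.null(data)) integer(0) else dim(data) %||% length(data)
  cards <- c(cards, fits_card("BITPIX", -64),
             fits_card("NAXIS", length(dims)))
  for (i in seq_along(dims))
    cards <- c(cards, fits_card(paste0("NAXIS", i), dims[i]))
  if (!primary)
    cards <- c(cards, fits_card("PCOUNT", 0), fits_card("GCOUNT", 1))
  for (k in names(header)) {
    if (toupper(k) %in% c("SIMPLE", "BITPIX", "NAXIS", "XTENSION")) next
    v <- header[[k]]
    if (is.null(v) || length(v) != 1) next
    cards <- c(cards, fits_card(k, v))
  }
  cards <- c(cards, substr(sprintf("%-80s", "END"), 1, 80))
  htxt <- paste(cards, collapse = "")
  writeChar(htxt, con, eos = NULL)
  pad <- pad_block(nchar(htxt), "space")
  if (!is.null(pad)) writeBin(pad, con)
  if (length(dims) > 0) {
    writeBin(as.double(as.vector(data)), con, size = 8, endian = "big")
    pad <- pad_block(prod(dims) * 8, "zero")
    if (!is.null(pad)) writeBin(pad, con)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname fits_io
#' @export
write_fits <- function(hdus, file) {
  con <- file(file, "wb")
  on.exit(close(con))
  for (i in seq_along(hdus))
    write_hdu(con, hdus[[i]]$data, hdus[[i]]$header %||% list(), i == 1)
  invisible(file)
}

parse_card_value <- function(v) {
  v <- trimws(v)
  if (v == "") return(NA)
  if (startsWith(v, "'")) {
    return(trimws(gsub("'", "", v)))
  }
  if (v == "T") return(TRUE)
  if (v == "F") return(FALSE)
  suppressWarnings(num <- as.numeric(v))
  if (!is.na(num)) num else v
}

read_hdu <- function(con) {
  header <- list()
  repeat {
    block <- readChar(con, 2880, useBytes = TRUE)
    if (length(block) == 0 || nchar(block) < 2880) return(NULL)
    done <- FALSE
    for (k in seq_len(36)) {
      card <- substr(block, (k - 1) * 80 + 1, k * 80)
      key <- trimws(substr(card, 1, 8))
      if (key == "END") { done <- TRUE; break }
      if (key == "" || substr(card, 9, 10) != "= ") next
      header[[key]] <- parse_card_value(substr(card, 11, 80))
    }
    if (done) break
  }
  naxis <- as.integer(header$NAXIS %||% 0)
  data <- NULL
  if (naxis > 0) {
    dims <- vapply(seq_len(naxis),
                   function(i) as.integer(header[[paste0("NAXIS", i)]]),
                   integer(1))
    n <- prod(dims)
    vals <- readBin(con, "double", n, size = 8, endian = "big")
    skip <- (8 * n) %% 2880
    if (skip > 0) readBin(con, "raw", 2880 - skip)
    data <- if (naxis == 1) vals else array(vals, dim = dims)
  }
  list(data = data, header = header)
}

#' @rdname fits_io
#' @export
read_fits <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  hdus <- list()
  repeat {
    h <- tryCatch(read_hdu(con), error = function(e) NULL)
    if (is.null(h)) break
    hdus[[length(hdus) + 1L]] <- h
  }
  if (length(hdus) == 0) fc_abort("not a FITS file (no HDUs)",
                                  "fibercube_io_error")
  hdus
}

#' Frame, RSS, cube and map FITS carriers
#'
#' Standard-format serialization of the pipeline products: frames carry
#' `FRAMTYPE`, `EXPTIME` and `SEED` keys; row-stacked spectra store the
#' intensity image plus extensions for dispersion coefficients, throughput
#' factors and dead flags; cubes store the 3D image with a linear spectral
#' WCS (`CRVAL3`/`CDELT3`, cm^-1) and the dead-spaxel mask as an extension.
#'
#' @param frame,rss,cube,map the object to write.
#' @param file path.
#' @param extra extra header cards (named list).
#' @return writers return the path invisibly; readers the reconstructed
#'   object.
#' @name fits_carriers
NULL

#' @rdname fits_carriers
#' @export
write_frame_fits <- function(frame, file, extra = list()) {
  hdr <- c(list(FRAMTYPE = toupper(frame$type), EXPTIME = frame$exptime),
           frame$header, extra)
  write_fits(list(list(data = frame$data, header = hdr)), file)
}

#' @rdname fits_carriers
#' @export
read_frame_fits <- function(file) {
  h <- read_fits(file)[[1]]
  type <- tolower(h$header$FRAMTYPE %||% "science")
  if (type == "master-bias" || type == "masterbia") type <- "master-bias"
  new_frame(h$data, type, h$header$EXPTIME %||% 0, header = h$header)
}

#' @rdname fits_carriers
#' @export
write_rss_fits <- function(rss, file, extra = list()) {
  hdus <- list(list(data = rss$intensity,
                    header = c(list(PRODUCT = "RSS"), extra)))
  if (!is.null(rss$dispersion))
    hdus <- c(hdus, list(list(
      data = rss$dispersion$coef,
      header = list(EXTNAME = "DISP",
                    EXCITWL = rss$dispersion$excitation_nm))))
  if (!is.null(rss$throughput))
    hdus <- c(hdus, list(list(data = ifelse(is.na(rss$throughput), -1,
                                            rss$throughput),
                              header = list(EXTNAME = "THRUPUT"))))
  hdus <- c(hdus, list(list(data = as.numeric(rss$dead),
                            header = list(EXTNAME = "DEAD"))))
  write_fits(hdus, file)
}

#' @rdname fits_carriers
#' @export
read_rss_fits <- function(file) {
  hdus <- read_fits(file)
  extname <- vapply(hdus, function(h) as.character(h$header$EXTNAME %||% ""),
                    character(1))
  disp <- NULL
  if ("DISP" %in% extname) {
    h <- hdus[[which(extname == "DISP")[1]]]
    disp <- dispersion_model(h$data, h$header$EXCITWL %||% 785)
  }
  thr <- NULL
  if ("THRUPUT" %in% extname) {
    thr <- hdus[[which(extname == "THRUPUT")[1]]]$data
    thr[thr < 0] <- NA_real_
  }
  dead <- if ("DEAD" %in% extname)
    as.logical(hdus[[which(extname == "DEAD")[1]]]$data)
  else rep(FALSE, nrow(hdus[[1]]$data))
  new_rss(hdus[[1]]$data, dead = dead, throughput = thr, dispersion = disp)
}

#' @rdname fits_carriers
#' @export
write_cube_fits <- function(cube, file, extra = list()) {
  hdr <- c(list(PRODUCT = "CUBE", CRVAL3 = cube$axis[1],
                CDELT3 = cube$axis[2] - cube$axis[1], CUNIT3 = "cm-1"),
           cube$meta[vapply(cube$meta, length, integer(1)) == 1], extra)
  write_fits(list(
    list(data = cube$data, header = hdr),
    list(data = matrix(as.numeric(cube$mask), nrow(cube$mask)),
         header = list(EXTNAME = "MASK"))), file)
}

#' @rdname fits_carriers
#' @export
read_cube_fits <- function(file) {
  hdus <- read_fits(file)
  h <- hdus[[1]]
  n3 <- dim(h$data)[3]
  axis <- h$header$CRVAL3 + (seq_len(n3) - 1) * h$header$CDELT3
  mask <- NULL
  for (x in hdus[-1])
    if (identical(x$header$EXTNAME, "MASK"))
      mask <- matrix(as.logical(x$data), nrow(x$data))
  raman_cube(h$data, axis, mask, meta = h$header)
}

#' @rdname fits_carriers
#' @export
write_map_fits <- function(map, file, extra = list()) {
  v <- map$values
  v[is.na(v)] <- -1
  write_fits(list(list(
    data = v,
    header = c(list(PRODUCT = "CHEMMAP", SUBSTNC = map$substance,
                    RAMANSHF = map$shift), extra))), file)
}
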