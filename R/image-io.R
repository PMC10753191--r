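#' Multi-channel section image
#'
#' Container for a 4-channel immunofluorescence section: integer matrices on
#' the 0-255 (8-bit) scale, named by staining role: `slow_350` (slow MHC,
#' Alexa Fluor 350), `regen_488` (embryonic MHC, AF488), `fast_594` (fast MHC,
#' AF594) and `collagen_647` (collagen VI outline, AF647).
#'
#' @param channels Named list of 4 numeric matrices of identical shape.
#' @return A `multichannel_image` object.
#' @export
multichannel_image <- function(channels) {
  if (!setequal(names(channels), channel_roles())) {
    abort(paste0("channels must be named ", paste(channel_roles(), collapse = ", ")))
  }
  channels <- channels[channel_roles()]
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1) abort("all channels must share one shape")
  structure(list(channels = channels, dim = dims[[1]]), class = "multichannel_image")
}

#' Channel role names, in acquisition order (350/488/594/647)
#' @return Character vector of the 4 channel roles.
#' @export
channel_roles <- function() c("slow_350", "regen_488", "fast_594", "collagen_647")

#' @export
print.multichannel_image <- function(x, ...) {
  cat(sprintf("<multichannel_image %d x %d, channels: %s>\n",
              x$dim[1], x$dim[2], paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Read a multi-channel section TIFF
#'
#' Expects a 4-plane TIFF. Planes are mapped to channel roles positionally in
#' acquisition order (350, 488, 594, 647) unless `mapping` gives the plane
#' index for each role. Inputs deeper than 8 bits are rescaled to 0-255 by
#' their maximum (with a message).
#'
#' @param path Path to a multi-plane TIFF.
#' @param mapping Optional named integer vector role -> plane index.
#' @return A [multichannel_image()].
#' @export
read_image <- function(path, mapping = NULL) {
  if (!file.exists(path)) abort(paste0("image file not found: ", path))
  planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  planes <- lapply(planes, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    storage.mode(p) <- "numeric"
    p
  })
  if (length(planes) != 4 && is.null(mapping)) {
    abort(paste0("expected a 4-plane TIFF (roles ", paste(channel_roles(), collapse = ", "),
                 "); got ", length(planes), " plane(s) and no explicit mapping"))
  }
  idx <- if (is.null(mapping)) setNames(1:4, channel_roles()) else mapping
  if (!setequal(names(idx), channel_roles())) {
    abort(paste0("mapping must name planes for ", paste(channel_roles(), collapse = ", ")))
  }
  ch <- lapply(channel_roles(), function(r) planes[[idx[[r]]]])
  names(ch) <- channel_roles()
  mx <- max(vapply(ch, max, numeric(1)), 1)
  if (mx > 255) {
    message(sprintf("read_image: rescaling %s-level input to 8-bit by max", format(mx)))
    ch <- lapply(ch, function(p) round(p / mx * 255))
  }
  multichannel_image(ch)
}

#' Write a multi-channel section TIFF
#'
#' Writes the 4 channel planes as an 8-bit multi-plane TIFF in acquisition
#' order; [read_image()] inverse (pixel-exact).
#'
#' @param image A [multichannel_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  planes <- lapply(image$channels, function(p) {
    p <- pmin(pmax(round(p), 0), 255)
    p / 255
  })
  tiff::writeTIFF(planes, path, bits.per.sample = 8)
  invisible(path)
}

#' Read / write an integer label mask TIFF
#'
#' Label masks (0 = background/boundary) are stored as 16-bit TIFFs, exact for
#' label values up to 65535.
#'
#' @param path TIFF path.
#' @return Integer matrix of labels.
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_label_mask
#' @param labels Integer matrix of labels (max 65535).
#' @return `path`, invisibly (for `write_label_mask`).
#' @export
write_label_mask <- function(labels, path) {
  if (max(labels) > 65535) abort("label mask exceeds 16-bit range")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a Cq table CSV
#'
#' Validates a long qPCR table with columns `sample_id`, `genotype`, `gene`,
#' `Cq`, `replicate`. Replicates are kept as-is (collapse is a separate step,
#' see [collapse_replicates()]).
#'
#' @param path CSV path.
#' @return Tibble with the five columns.
#' @export
read_qpcr <- function(path) {
  if (!file.exists(path)) abort(paste0("qPCR file not found: ", path))
  dat <- tibble::as_tibble(utils::read.csv(path))
  validate_qpcr(dat)
}

validate_qpcr <- function(dat) {
  need <- c("sample_id", "genotype", "gene", "Cq", "replicate")
  missing_cols <- setdiff(need, names(dat))
  if (length(missing_cols)) {
    abort(paste0("qPCR table missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "musclephys_format_error")
  }
  if (any(!is.finite(dat$Cq)) || any(dat$Cq <= 0 | dat$Cq > 45)) {
    abort("Cq values must lie in (0, 45]", class = "musclephys_validation_error")
  }
  if (anyDuplicated(dat[c("sample_id", "gene", "replicate")])) {
    abort("duplicate (sample_id, gene, replicate) rows", class = "musclephys_validation_error")
  }
  n_rep <- dplyr::count(dat, .data$sample_id, .data$gene)
  if (any(n_rep$n > 3)) {
    abort("more than 3 replicates for a (sample, gene) pair", class = "musclephys_validation_error")
  }
  tibble::as_tibble(dat[need])
}
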