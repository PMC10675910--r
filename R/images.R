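#' Read an 8-bit RGB image from disk
#'
#' Supports PNG. Grayscale images are expanded to three identical channels;
#' an alpha channel, if present, is dropped.
#'
#' @param path PNG file path.
#' @return `H x W x 3` integer-valued array in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext != "png")
    stop("unsupported image format '", ext, "' (", path,
         "); images must be 8-bit PNG")
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  round(px * 255)
}

#' Write an RGB array as PNG
#' @param pixels `H x W x 3` array in `[0, 255]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(pixels, path) {
  png::writePNG(pmin(pmax(pixels, 0), 255) / 255, path)
  invisible(path)
}

#' Luminance channel of an RGB image
#'
#' ITU-R BT.601 weighting `0.299 R + 0.587 G + 0.114 B`, the convention used
#' throughout the cleaning pipeline (quality scoring, margin detection).
#'
#' @param pixels `H x W x 3` array in `[0, 255]`, or an [image_record()].
#' @return `H x W` numeric matrix in `[0, 255]`.
#' @export
luminance <- function(pixels) {
  if (inherits(pixels, "image_record")) pixels <- pixels$pixels
  out <- 0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] +
    0.114 * pixels[, , 3]
  matrix(out, dim(pixels)[1], dim(pixels)[2])
}

# Bilinear resize of an H x W x 3 array in [0,255] to out_h x out_w,
# via EBImage (width-major layout, hence the aperm round trip).
resize_rgb <- function(pixels, out_h, out_w) {
  d <- dim(pixels)
  if (d[1] == out_h && d[2] == out_w) return(pixels)
  im <- EBImage::Image(aperm(pixels / 255, c(2, 1, 3)), colormode = "Color")
  r <- EBImage::resize(im, w = out_w, h = out_h)
  out <- aperm(EBImage::imageData(r), c(2, 1, 3))
  pmin(pmax(round(out * 255), 0), 255)
}

# Gaussian blur on an H x W x 3 array in [0,255]; sigma in pixels.
blur_rgb <- function(pixels, sigma) {
  im <- EBImage::Image(aperm(pixels / 255, c(2, 1, 3)), colormode = "Color")
  b <- EBImage::gblur(im, sigma = sigma)
  out <- aperm(EBImage::imageData(b), c(2, 1, 3))
  pmin(pmax(round(out * 255), 0), 255)
}
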