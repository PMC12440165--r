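# Grayscale image I/O and resampling helpers (EBImage-backed).

#' Load grayscale images
#'
#' Reads PNG/JPEG files into an `(H, W, N)` array in `[0, 1]`. Color images
#' are averaged to one channel; an optional resize to a square side length is
#' applied per image.
#'
#' @param paths Character vector of image files.
#' @param size Optional target side length in pixels.
#' @return Numeric array `(H, W, N)`.
#' @export
load_images <- function(paths, size = NULL) {
  imgs <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("image file not readable: ", p)
    if (grepl("\\.png$", p, ignore.case = TRUE)) {
      img <- png::readPNG(p)
      if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
    } else {
      img <- EBImage::imageData(EBImage::readImage(p))
      if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
      img <- t(img)   # EBImage stores (x, y); package arrays are (row, col)
    }
    if (!is.null(size)) img <- resize_image(img, size)
    img
  })
  d <- dim(imgs[[1]])
  array(unlist(imgs, use.names = FALSE), dim = c(d[1], d[2], length(imgs)))
}

#' Bilinear resize of one grayscale image
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param size Target side length.
#' @return `size x size` matrix.
#' @export
resize_image <- function(img, size) {
  resize_bilinear(img, as.integer(size), as.integer(size))
}

#' Write one grayscale image as PNG
#'
#' Written via the png bit-level writer, which embeds no timestamps: the
#' same pixel data always yields byte-identical files.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param path Output `.png` file.
#' @export
save_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

# Gaussian smoothing of a plain matrix (separable kernel, replicated edges)
blur_image <- function(img, sigma) {
  if (sigma <= 0) return(img)
  gauss_blur_cpp(img, sigma)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)
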