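#' Read an RGB image
#'
#' Reads PNG/TIFF/JPEG via EBImage and returns the package's native
#' representation: an `H x W x 3` array in `[0, 1]`, `[row, col, channel]`.
#' Gray images are replicated to 3 channels; an alpha channel is dropped.
#'
#' @param path image file path.
#' @return RGB array.
#' @export
read_rgb <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  # EBImage stores (x = col, y = row); transpose to (row, col)
  out <- array(0, c(dim(a)[2], dim(a)[1], 3))
  for (ch in 1:3) out[, , ch] <- t(a[, , ch])
  pmin(pmax(out, 0), 1)
}

#' Write an RGB image or a mask to PNG/TIFF/JPEG
#'
#' @param img RGB array in `[0, 1]`, or a matrix (masks/label images are
#'   scaled to the maximum label).
#' @param path output path; format from the extension.
#' @export
write_image <- function(img, path) {
  if (is.matrix(img)) {
    mx <- max(img)
    img <- if (mx > 0) img / mx else img * 0
    EBImage::writeImage(EBImage::Image(t(img)), path)
  } else {
    a <- array(0, c(dim(img)[2], dim(img)[1], 3))
    for (ch in 1:3) a[, , ch] <- t(img[, , ch])
    EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path)
  }
  invisible(path)
}

#' Serialize a stain matrix to JSON
#'
#' @param M 3 x 2 stain matrix.
#' @param path output path.
#' @export
write_stain_matrix <- function(M, path) {
  jsonlite::write_json(list(hematoxylin = M[, 1], eosin = M[, 2]), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a stain matrix from JSON
#'
#' @param path JSON path written by [write_stain_matrix()].
#' @return 3 x 2 stain matrix.
#' @export
read_stain_matrix <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cbind(H = x$hematoxylin, E = x$eosin)
}

#' Write detections to JSON
#'
#' @param detections data frame from [run_pipeline()] (`row`, `col`,
#'   `score`, `size`).
#' @param path output path.
#' @export
write_detections <- function(detections, path) {
  jsonlite::write_json(detections, path, dataframe = "rows", digits = NA,
                       na = "null")
  invisible(path)
}

#' Write a scene's ground truth to JSON
#'
#' @param scene a `synthetic_scene`.
#' @param path output path.
#' @export
write_ground_truth <- function(scene, path) {
  jsonlite::write_json(
    list(image_size = scene$image_size, nuclei = scene$nuclei,
         seed = scene$seed),
    path, dataframe = "rows", digits = NA
  )
  invisible(path)
}
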