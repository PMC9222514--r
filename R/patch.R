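#' Image patch
#'
#' Light container for a single 2-D histology patch: a numeric pixel grid in
#' \[0, 1\] (grayscale matrix, or height x width x 3 array for RGB) plus an
#' optional class label (`"VT"` viable tumor, `"NVT"` non-viable tumor,
#' `"NT"` non-tumor).
#'
#' @param pixels numeric matrix (h x w) or array (h x w x 3) with finite
#'   values; rescaled into \[0, 1\] when `normalize = TRUE` and values fall
#'   outside that range.
#' @param label optional class label, or `NA`.
#' @param id optional sample identifier.
#' @param normalize divide by 255 when the input looks like 8-bit data, then
#'   clip into \[0, 1\].
#' @return an object of class `image_patch`.
#' @export
image_patch <- function(pixels, label = NA_character_, id = NULL,
                        normalize = TRUE) {
  if (is.null(dim(pixels)) || length(dim(pixels)) > 3)
    stop("pixels must be a 2-D matrix or h x w x channels array")
  if (length(pixels) == 0) stop("empty image")
  if (!all(is.finite(pixels))) stop("pixels must be finite")
  pixels <- unclass(pixels)  # drop e.g. EBImage classes
  if (normalize) {
    if (max(pixels) > 1.5) pixels <- pixels / 255
    pixels <- clip01(pixels)
  }
  structure(list(pixels = pixels, label = as.character(label), id = id),
            class = "image_patch")
}

#' @export
print.image_patch <- function(x, ...) {
  d <- dim(x$pixels)
  ch <- if (length(d) == 3) d[3] else 1L
  cat(sprintf("<image_patch %dx%d, %d channel(s), label=%s>\n",
              d[1], d[2], ch, x$label))
  invisible(x)
}

#' @export
dim.image_patch <- function(x) dim(x$pixels)

# Coerce to a grayscale matrix (channel mean for RGB).
patch_gray <- function(x) {
  px <- if (inherits(x, "image_patch")) x$pixels else x
  if (length(dim(px)) == 3) px <- apply(px, c(1, 2), mean)
  px
}

# Accept image_patch / matrix / array, run f on the pixel data, return the
# same type. Multi-channel inputs are filtered per channel.
map_pixels <- function(img, f, per_channel = TRUE) {
  is_patch <- inherits(img, "image_patch")
  px <- if (is_patch) img$pixels else img
  if (length(px) == 0) stop("empty image")
  if (length(dim(px)) == 3 && per_channel) {
    out <- px
    for (ch in seq_len(dim(px)[3])) out[, , ch] <- f(px[, , ch])
  } else {
    out <- f(px)
  }
  if (is_patch) {
    img$pixels <- out
    img
  } else out
}

#' Read image patches from a directory or manifest
#'
#' Reads PNG/TIFF/JPEG patches. Labels come either from a manifest CSV with
#' columns `path,label` (paths relative to its directory) or from the name of
#' each file's parent directory.
#'
#' @param source a directory containing one sub-directory per class, or a
#'   manifest CSV file.
#' @return list of [image_patch()] objects.
#' @export
read_patches <- function(source) {
  if (length(source) != 1 || !file.exists(source))
    stop("source not found: ", source)
  if (dir.exists(source)) {
    files <- list.files(source, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                        recursive = TRUE, full.names = TRUE,
                        ignore.case = TRUE)
    if (length(files) == 0) stop("no image files under ", source)
    labels <- basename(dirname(files))
  } else {
    man <- utils::read.csv(source, stringsAsFactors = FALSE)
    if (!all(c("path", "label") %in% names(man)))
      stop("manifest must have columns path,label")
    files <- ifelse(file.exists(man$path), man$path,
                    file.path(dirname(source), man$path))
    labels <- man$label
  }
  Map(function(f, lab) {
    px <- EBImage::imageData(EBImage::readImage(f))
    # EBImage stores x,y(,c); transpose the spatial plane to row=y convention
    px <- if (length(dim(px)) == 3) aperm(px, c(2, 1, 3)) else t(px)
    if (length(dim(px)) == 3 && dim(px)[3] > 3) px <- px[, , 1:3]
    image_patch(px, label = lab, id = sub("\\.[^.]+$", "", basename(f)))
  }, files, labels)
}

#' Write image patches as PNG files with a manifest
#'
#' Writes one PNG per patch under `dir/<label>/<id>.png`, a `manifest.csv`
#' (columns `path,label`) and a `normalization.json` sidecar recording the
#' value range convention.
#'
#' @param patches list of [image_patch()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data frame.
#' @export
write_patches <- function(patches, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(patches), function(i) {
    p <- patches[[i]]
    lab <- if (is.na(p$label)) "unlabeled" else p$label
    id <- if (is.null(p$id)) sprintf("patch_%04d", i) else p$id
    sub <- file.path(dir, lab)
    dir.create(sub, showWarnings = FALSE)
    px <- p$pixels
    px <- if (length(dim(px)) == 3) aperm(px, c(2, 1, 3)) else t(px)
    EBImage::writeImage(EBImage::Image(clip01(px),
      colormode = if (length(dim(px)) == 3) "Color" else "Grayscale"),
      file.path(sub, paste0(id, ".png")))
    data.frame(path = file.path(lab, paste0(id, ".png")), label = lab)
  })
  man <- do.call(rbind, rows)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(list(range = c(0, 1), encoding = "png-8bit"),
                       file.path(dir, "normalization.json"),
                       auto_unbox = TRUE)
  invisible(man)
}
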