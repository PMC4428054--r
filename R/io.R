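#' Read and write colony images as 16-bit grayscale TIFF
#'
#' \code{writeColonyTiff} stores the intensity raster as a single-page
#' 16-bit grayscale TIFF (values rounded to integers).
#' \code{readColonyTiff} reads it back as a [ColonyImage-class]; the pixel
#' size is not stored in the TIFF and must be supplied (or comes from the
#' plate map when reading a whole plate).
#'
#' @param image a [ColonyImage-class].
#' @param path TIFF file path.
#' @param pixelSize um per px of the stored image.
#' @return \code{writeColonyTiff}: \code{path}, invisibly;
#'   \code{readColonyTiff}: a [ColonyImage-class] (without ground truth).
#' @export
writeColonyTiff <- function(image, path) {
  stopifnot(is(image, "ColonyImage"))
  tiff::writeTIFF(round(image@intensity) / 65535, path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeColonyTiff
#' @export
readColonyTiff <- function(path, pixelSize) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3) m <- m[, , 1]  # tolerate multi-channel files
  new("ColonyImage", intensity = m * 1.0, pixelSize = pixelSize,
      metadata = list(source = path), truth = list())
}

#' Write a colony set as TIFFs plus a plate-map CSV
#'
#' One single-page 16-bit TIFF per colony under \code{dir}, and a plate map
#' \code{plate_map.csv} with columns image, compound, dose, group,
#' replicate, pixel_size_um. \code{readPlateMap} reconstructs the
#' [ColonySet-class] from such a directory.
#'
#' @param colonies a [ColonySet-class].
#' @param dir output directory (created if needed).
#' @param design optional [doseDesign()] supplying per-group doses for the
#'   plate map (dose column is NA without it).
#' @return invisible path of the plate-map CSV.
#' @export
writeColonySet <- function(colonies, dir, design = NULL) {
  stopifnot(is(colonies, "ColonySet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  info <- colonies@info
  files <- sprintf("colony_%s_%s_%02d.tif", info$compound, info$group,
                   info$replicate)
  for (i in seq_len(length(colonies)))
    writeColonyTiff(colonies[[i]], file.path(dir, files[i]))
  dose <- if (is.null(design)) NA_real_
          else unname(design$concentrations[info$group])
  pm <- data.frame(image = files, compound = info$compound, dose = dose,
                   group = info$group, replicate = info$replicate,
                   pixel_size_um = vapply(colonies@images, pixelSize,
                                          numeric(1)))
  path <- file.path(dir, "plate_map.csv")
  utils::write.csv(pm, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeColonySet
#' @param plateMap path of a plate-map CSV; image paths are resolved
#'   relative to its directory.
#' @export
readPlateMap <- function(plateMap) {
  pm <- utils::read.csv(plateMap)
  need <- c("image", "compound", "group", "replicate", "pixel_size_um")
  if (!all(need %in% names(pm)))
    stop("plate map must have columns ", paste(need, collapse = ", "))
  base <- dirname(plateMap)
  images <- lapply(seq_len(nrow(pm)), function(i)
    readColonyTiff(file.path(base, pm$image[i]), pm$pixel_size_um[i]))
  new("ColonySet", images = images,
      info = pm[, c("compound", "group", "replicate",
                    intersect("dose", names(pm)))])
}

#' Write / read a multi-page TIFF time-lapse stack
#'
#' @param stack numeric array (height x width x frames), 16-bit intensity
#'   scale.
#' @param path TIFF file path.
#' @return \code{writeStackTiff}: path invisibly; \code{readStackTiff}:
#'   the array.
#' @export
writeStackTiff <- function(stack, path) {
  stopifnot(length(dim(stack)) == 3)
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(f) round(stack[, , f]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeStackTiff
#' @export
readStackTiff <- function(path) {
  pages <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages))) * 1.0
}

#' Write / read a viability CSV
#'
#' Columns cell_line, concentration, replicate, viability.
#'
#' @param viability a viability data.frame (see [generateViabilityData()]).
#' @param path CSV path.
#' @return \code{writeViabilityCsv}: path invisibly;
#'   \code{readViabilityCsv}: the data.frame.
#' @export
writeViabilityCsv <- function(viability, path) {
  utils::write.csv(viability, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeViabilityCsv
#' @export
readViabilityCsv <- function(path) {
  v <- utils::read.csv(path)
  need <- c("cell_line", "concentration", "replicate", "viability")
  if (!all(need %in% names(v)))
    stop("viability table must have columns ", paste(need, collapse = ", "))
  v
}
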