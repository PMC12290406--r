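# Standard-format I/O: 8-bit PNG for images and masks, NIfTI slice extraction,
# and a seeded fixture corpus writer.

#' Read / write 8-bit PNG images
#'
#' Intensities are [0,1] internally; 8-bit I/O scales by 255. RGB files are
#' returned channel-last (H x W x 3); grayscale files as a matrix.
#'
#' @param path file path.
#' @return `readImagePNG`: matrix or H x W x 3 array in [0,1].
#' @export
readImagePNG <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) {
    if (dim(x)[3L] >= 3L) return(x[, , 1:3, drop = FALSE])
    x <- x[, , 1L]
  }
  x
}

#' @rdname readImagePNG
#' @param image matrix or H x W x 3 array in [0,1].
#' @export
writeImagePNG <- function(image, path) {
  png::writePNG(clip01(image), path)
  invisible(path)
}

#' Read / write binary masks as PNG (255 = observed, 0 = missing)
#'
#' @param path file path.
#' @return `readMaskPNG`: H x W matrix in {0,1}.
#' @export
readMaskPNG <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  m <- round(x)
  checkMask(m)
  m
}

#' @rdname readMaskPNG
#' @param mask H x W binary matrix.
#' @export
writeMaskPNG <- function(mask, path) {
  checkMask(mask)
  png::writePNG(mask, path)
  invisible(path)
}

#' Extract one axial slice from a NIfTI volume
#'
#' Reads a .nii/.nii.gz volume, extracts axial slice `slice` (third index;
#' defaults to the middle slice) and min-max normalizes it to [0,1].
#'
#' @param path NIfTI file path.
#' @param slice slice index, or `NULL` for the middle slice.
#' @return matrix in [0,1].
#' @export
readNiftiSlice <- function(path, slice = NULL) {
  vol <- RNifti::readNifti(path)
  arr <- as.array(vol)
  if (length(dim(arr)) < 3L) {
    sl <- if (length(dim(arr)) == 2L) arr else stop("volume is not 2-D or 3-D")
  } else {
    nz <- dim(arr)[3L]
    if (is.null(slice)) slice <- (nz + 1L) %/% 2L
    if (slice < 1L || slice > nz) stop("slice index out of range")
    sl <- arr[, , slice]
  }
  sl <- matrix(as.numeric(sl), nrow(sl), ncol(sl))
  rng <- range(sl)
  if (rng[2] > rng[1]) sl <- (sl - rng[1]) / (rng[2] - rng[1]) else sl[] <- 0
  sl
}

#' Write a seeded fixture corpus
#'
#' Generates `n` phantoms, one mask per image (cycling the given families),
#' corrupts each, writes clean/mask/corrupted PNGs plus a CSV manifest, and
#' returns the manifest invisibly.
#'
#' @param outDir output directory (created if needed).
#' @param n number of images.
#' @param height,width image size.
#' @param families mask family names to cycle over.
#' @param noise a [NoiseParams-class].
#' @param seed integer base seed.
#' @return data.frame manifest (invisibly written to `manifest.csv`).
#' @export
makeFixtureCorpus <- function(outDir, n = 10L, height = 32L, width = 32L,
                              families = c("chin", "square", "vrect", "bottom"),
                              noise = NoiseParams(), seed = 1L) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    fam <- families[((i - 1L) %% length(families)) + 1L]
    clean <- generatePhantom(height, width, complexity = 3L, seed = seed + i)
    mask <- generateMask(MaskSpec(fam, seed = seed + 1000L + i), height, width)
    obs <- corruptImage(clean, mask, noise, seed = seed + 2000L + i)
    cleanPath <- file.path(outDir, sprintf("clean_%03d.png", i))
    maskPath <- file.path(outDir, sprintf("mask_%03d.png", i))
    corruptPath <- file.path(outDir, sprintf("corrupt_%03d.png", i))
    writeImagePNG(clean, cleanPath)
    writeMaskPNG(mask, maskPath)
    writeImagePNG(obs@observed, corruptPath)
    rows[[i]] <- data.frame(index = i, family = fam,
                            coverage = maskCoverage(mask),
                            clean = basename(cleanPath),
                            mask = basename(maskPath),
                            corrupt = basename(corruptPath),
                            seed = seed + i)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
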