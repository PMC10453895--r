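#' @include AllClasses.R utils.R
NULL

#' Construct a MultiModalVolume
#'
#' @param voxels 4-D numeric array, dim = c(4, nSlices, nRows, nCols),
#'   modalities in (T1, T1c, T2, FLAIR) order.
#' @param voxelSpacing numeric(3), mm per axis.
#' @return a [MultiModalVolume-class].
#' @export
MultiModalVolume <- function(voxels, voxelSpacing = c(1, 1, 1)) {
  new("MultiModalVolume", voxels = voxels,
      modalityOrder = c("T1", "T1c", "T2", "FLAIR"),
      voxelSpacing = as.numeric(voxelSpacing))
}

#' Construct a MultiModalSlice
#'
#' @param pixels 3-D numeric array, dim = c(4, height, width).
#' @param sourceIndex slice number within the source volume.
#' @return a [MultiModalSlice-class].
#' @export
MultiModalSlice <- function(pixels, sourceIndex = NA_integer_) {
  new("MultiModalSlice", pixels = pixels,
      sourceIndex = as.integer(sourceIndex))
}

#' Construct a SegmentationMask
#'
#' @param labels integer matrix (slice mask) or 3-D array (volume mask,
#'   dim = c(nSlices, nRows, nCols)) with values in {0,1,2,3}.
#' @return a [SegmentationMask-class].
#' @export
SegmentationMask <- function(labels) {
  storage.mode(labels) <- "integer"
  new("SegmentationMask", labels = labels)
}

.MODALITIES <- c("t1", "t1c", "t2", "flair")

#' Read a multi-modal MRI volume from NIfTI files
#'
#' Accepts either four single-modality NIfTI paths (in T1, T1c, T2, FLAIR
#' order, or named `t1`, `t1c`, `t2`, `flair`) or one path to a 4-channel
#' NIfTI whose fourth dimension holds the modalities in that order. Raw
#' intensities are returned untouched; use [normalizeIntensity()] before
#' slicing.
#'
#' In-plane dimensions of the files become (row, col); the third NIfTI
#' dimension indexes axial slices. The returned voxel array is channel-major:
#' dim = c(4, nSlices, nRows, nCols).
#'
#' @param path character vector of 1 or 4 file paths.
#' @return a [MultiModalVolume-class].
#' @export
readVolume <- function(path) {
  if (length(path) == 1L) {
    img <- RNifti::readNifti(path[[1]])
    arr <- unclass(img)
    if (length(dim(arr)) != 4L || dim(arr)[4] != 4L)
      stop("incomplete case: single file must be 4-channel NIfTI")
    pix <- RNifti::pixdim(img)
    vox <- aperm(arr, c(4L, 3L, 1L, 2L))
    return(MultiModalVolume(vox, voxelSpacing = pix[seq_len(3)]))
  }
  if (length(path) != 4L)
    stop("incomplete case: expected 4 modality files (T1, T1c, T2, FLAIR)")
  if (!is.null(names(path))) {
    nm <- tolower(names(path))
    if (!all(.MODALITIES %in% nm))
      stop("incomplete case: need modalities t1, t1c, t2, flair")
    path <- path[match(.MODALITIES, nm)]
  }
  missing <- !file.exists(unlist(path))
  if (any(missing))
    stop("incomplete case: missing file(s) ",
         paste(unlist(path)[missing], collapse = ", "))
  imgs <- lapply(path, function(p) {
    arr <- unclass(RNifti::readNifti(p))
    # single-slice volumes lose their trailing singleton dimension on read
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    arr
  })
  dims <- lapply(imgs, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("unaligned modalities: shapes differ across files")
  d <- dims[[1]]
  if (length(d) != 3L) stop("unaligned modalities: each file must be 3-D")
  vox <- array(0, dim = c(4L, d[3], d[1], d[2]))
  for (m in 1:4) vox[m, , , ] <- aperm(imgs[[m]], c(3L, 1L, 2L))
  spacing <- RNifti::niftiHeader(path[[1]])$pixdim[2:4]
  MultiModalVolume(vox, voxelSpacing = spacing)
}

#' Write a multi-modal volume to one 4-channel NIfTI file
#'
#' @param volume a [MultiModalVolume-class].
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path) {
  arr <- aperm(pixelData(volume), c(3L, 4L, 2L, 1L))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Read / write a segmentation mask (NIfTI, unsigned 8-bit labels)
#'
#' A 3-D file is interpreted as (row, col, slice) and returned with labels
#' dim = c(nSlices, nRows, nCols); a 2-D file as a single slice mask.
#'
#' @param path NIfTI file path.
#' @return [SegmentationMask-class] for `readMask`; `path` invisibly for
#'   `writeMask`.
#' @export
readMask <- function(path) {
  raw <- unclass(RNifti::readNifti(path))
  arr <- array(as.integer(round(raw)), dim = dim(raw))
  if (length(dim(arr)) == 3L) arr <- aperm(arr, c(3L, 1L, 2L))
  SegmentationMask(arr)
}

#' @rdname readMask
#' @param mask a [SegmentationMask-class].
#' @export
writeMask <- function(mask, path) {
  lab <- maskLabels(mask)
  if (length(dim(lab)) == 3L) lab <- aperm(lab, c(2L, 3L, 1L))
  RNifti::writeNifti(RNifti::asNifti(lab, datatype = "uint8"), path)
  invisible(path)
}

#' Min-max intensity normalization to [0, 1]
#'
#' Normalizes each modality independently to the standard range \[0, 1\] by a
#' min-max map computed over brain voxels. The brain mask is taken as voxels
#' that are nonzero in at least one modality (the skull-stripped background is
#' exactly zero in BraTS-style input); background voxels stay 0. A
#' constant-valued modality maps to all zeros (divide-by-zero guard). With
#' `lowerQuantile`/`upperQuantile` set, intensities are first clipped to those
#' robust percentiles of the brain voxels (off by default).
#'
#' The map is idempotent: renormalizing a normalized volume is the identity
#' (the brain-voxel minimum is 0 and maximum 1 after the first pass).
#'
#' @param volume a [MultiModalVolume-class] (or [MultiModalSlice-class]).
#' @param lowerQuantile,upperQuantile optional robust clipping percentiles in
#'   \[0, 1\]; `NULL` disables clipping.
#' @return the normalized object, same class as the input.
#' @export
normalizeIntensity <- function(volume, lowerQuantile = NULL,
                               upperQuantile = NULL) {
  if (is(volume, "MultiModalSlice")) {
    pix <- pixelData(volume)
    vox <- array(pix, dim = c(4L, 1L, dim(pix)[2], dim(pix)[3]))
    out <- normalizeIntensity(MultiModalVolume(vox), lowerQuantile,
                              upperQuantile)
    return(MultiModalSlice(array(pixelData(out), dim = dim(pix)),
                           sourceIndex = volume@sourceIndex))
  }
  vox <- pixelData(volume)
  if (!all(is.finite(vox))) stop("invalid intensities: non-finite values")
  brain <- apply(vox != 0, c(2, 3, 4), any)
  for (m in 1:4) {
    ch <- vox[m, , , ]
    vals <- ch[brain]
    if (length(vals) == 0L || max(vals) == min(vals)) {
      vox[m, , , ] <- 0
      next
    }
    if (!is.null(lowerQuantile) || !is.null(upperQuantile)) {
      lo <- if (is.null(lowerQuantile)) 0 else lowerQuantile
      hi <- if (is.null(upperQuantile)) 1 else upperQuantile
      qs <- stats::quantile(vals, c(lo, hi), names = FALSE)
      ch <- pmin(pmax(ch, qs[1]), qs[2])
      vals <- ch[brain]
      if (max(vals) == min(vals)) { vox[m, , , ] <- 0; next }
    }
    lo <- min(vals); hi <- max(vals)
    ch <- (ch - lo) / (hi - lo)
    ch[!brain] <- 0
    vox[m, , , ] <- pmin(pmax(ch, 0), 1)
  }
  MultiModalVolume(vox, voxelSpacing = volume@voxelSpacing)
}

# symmetric zero-pad of a matrix to target x target (extra pixel on the
# bottom/right when the difference is odd)
.padMatrix <- function(m, target, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  if (target < h || target < w) stop("cannot pad down")
  out <- matrix(fill, target, target)
  r0 <- (target - h) %/% 2L
  c0 <- (target - w) %/% 2L
  out[r0 + seq_len(h), c0 + seq_len(w)] <- m
  out
}

#' Cut a volume into padded per-slice training examples
#'
#' Each axial slice is zero-padded symmetrically to `targetSize` (default 256;
#' the 240-pixel BraTS plane gets 8 pixels on each side) and paired with its
#' mask slice, padded with label 0. Slices whose mask is entirely background
#' are dropped unless `keepEmpty = TRUE` (keep them for inference).
#'
#' @param volume a normalized [MultiModalVolume-class].
#' @param mask the congruent volume [SegmentationMask-class]
#'   (dim = c(nSlices, nRows, nCols)).
#' @param targetSize network input size in pixels.
#' @param keepEmpty keep slices without any tumor label.
#' @return list of `list(slice = MultiModalSlice, mask = SegmentationMask)`.
#' @export
sliceDataset <- function(volume, mask, targetSize = 256L, keepEmpty = FALSE) {
  vox <- pixelData(volume)
  lab <- maskLabels(mask)
  if (length(dim(lab)) != 3L || !all(dim(lab) == dim(vox)[2:4]))
    stop("unaligned modalities: mask not congruent with volume")
  d <- dim(vox)
  if (targetSize < d[3] || targetSize < d[4]) stop("cannot pad down")
  out <- vector("list", d[2])
  n <- 0L
  for (s in seq_len(d[2])) {
    ms <- lab[s, , ]
    if (!keepEmpty && all(ms == 0L)) next
    pix <- array(0, dim = c(4L, targetSize, targetSize))
    for (m in 1:4) pix[m, , ] <- .padMatrix(vox[m, s, , ], targetSize)
    n <- n + 1L
    out[[n]] <- list(slice = MultiModalSlice(pix, sourceIndex = s),
                     mask = SegmentationMask(.padMatrix(ms, targetSize)))
  }
  out[seq_len(n)]
}

#' Read / write a dataset manifest
#'
#' The manifest is a CSV with columns `case_id`, `t1`, `t1c`, `t2`, `flair`,
#' `mask`; relative paths are resolved against the manifest's directory.
#'
#' @param path CSV file path.
#' @return data.frame for `readManifest`; `path` invisibly for
#'   `writeManifest`.
#' @export
readManifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", .MODALITIES, "mask")
  if (!all(need %in% names(df)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  base <- dirname(normalizePath(path))
  for (col in c(.MODALITIES, "mask")) {
    rel <- !grepl("^(/|[A-Za-z]:)", df[[col]])
    df[[col]][rel] <- file.path(base, df[[col]][rel])
  }
  df
}

#' @rdname readManifest
#' @param manifest data.frame with the manifest columns.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
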