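#' @include AllClasses.R utils.R io_preprocess.R
NULL

# nested sub-region geometry constants: the edema annulus reaches
# EDEMA_FACTOR x the (deformed) tumor radius, and the angular deformation
# modulates the radius by at most DEFORM_AMP
.EDEMA_FACTOR <- 1.4
.DEFORM_AMP <- 0.15

# default per-modality additive contrast offsets, rows (T1, T1c, T2, FLAIR),
# cols (edema, core, enhancing): FLAIR-bright edema, T1c-bright enhancing
# rim, T2-bright core, mildly hypointense T1 -- the qualitative glioma
# appearance on normalized intensities
.defaultContrasts <- function() {
  matrix(c(-0.05, -0.10, -0.05,
            0.00, -0.05,  0.45,
            0.25,  0.35,  0.15,
            0.40,  0.30,  0.20),
         nrow = 4, byrow = TRUE,
         dimnames = list(c("T1", "T1c", "T2", "FLAIR"),
                         c("edema", "core", "enhancing")))
}

#' Construct a PhantomSpec
#'
#' Settings for the multi-modal phantom generator; see
#' [PhantomSpec-class] for slot meanings. Defaults scale with
#' `imageSize` (tumor radius 1/8 to 1/4 of the image side, capped so the
#' deformed edema annulus always fits inside the image).
#'
#' @param imageSize image side, pixels.
#' @param tumorRadiusRange min/max tumor radius, pixels.
#' @param ringThickness enhancing-rim thickness, pixels.
#' @param modalityContrasts 4 x 3 offsets matrix; see
#'   [PhantomSpec-class].
#' @param noiseSd Gaussian noise sd, intensity units.
#' @param backgroundTextureScale texture smoothing length, pixels.
#' @param seed base seed.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(imageSize = 64L,
                        tumorRadiusRange = c(imageSize / 8,
                                             min(imageSize / 4,
                                                 (imageSize / 2 - 2.1) / 1.65)),
                        ringThickness = max(2, imageSize / 32),
                        modalityContrasts = .defaultContrasts(),
                        noiseSd = 0.05,
                        backgroundTextureScale = imageSize / 16,
                        seed = 1L) {
  new("PhantomSpec", imageSize = as.integer(imageSize),
      tumorRadiusRange = as.numeric(tumorRadiusRange),
      ringThickness = as.numeric(ringThickness),
      modalityContrasts = modalityContrasts, noiseSd = as.numeric(noiseSd),
      backgroundTextureScale = as.numeric(backgroundTextureScale),
      seed = as.integer(seed))
}

#' Generate one multi-modal phantom slice with nested tumor labels
#'
#' The phantom is a smooth-textured elliptical "brain" on an exactly-zero
#' background (emulating skull-stripped input) carrying a randomly placed,
#' angularly deformed disc tumor with three nested sub-regions: label 3 is
#' the enhancing rim, label 2 the core interior, label 1 the surrounding
#' edema annulus. The nesting ET (3) inside TC (2,3) inside WT (1,2,3) holds
#' by construction. Each modality receives its configured contrast offsets
#' plus Gaussian noise and is clipped to \[0, 1\]. Fully deterministic given
#' `seed`.
#'
#' @param spec a [PhantomSpec-class].
#' @param seed integer seed for this draw.
#' @return `list(slice = MultiModalSlice, mask = SegmentationMask)`.
#' @examples
#' pair <- generatePhantomSlice(phantomSpec(imageSize = 48), seed = 7)
#' pair$mask
#' table(maskLabels(pair$mask))
#' @export
generatePhantomSlice <- function(spec, seed = spec@seed) {
  validObject(spec)
  n <- spec@imageSize
  .withSeed(seed, {
    ## brain ellipse
    cx <- n / 2 + runif(1, -n / 32, n / 32)
    cy <- n / 2 + runif(1, -n / 32, n / 32)
    ax <- n * runif(1, 0.40, 0.46)   # semi-axes
    ay <- n * runif(1, 0.34, 0.40)
    xg <- matrix(rep(seq_len(n), each = n), n, n)   # col coordinate
    yg <- matrix(rep(seq_len(n), times = n), n, n)  # row coordinate
    brain <- ((xg - cx) / ax)^2 + ((yg - cy) / ay)^2 <= 1

    ## background texture: Gaussian-filtered white noise, rescaled
    tex <- .gaussianBlur(matrix(rnorm(n * n), n, n),
                         spec@backgroundTextureScale)
    tex <- 0.08 * tex / max(stats::sd(as.vector(tex)), 1e-12)

    ## tumor: deformed disc placed to keep the edema annulus inside the brain
    r0 <- runif(1, spec@tumorRadiusRange[1], spec@tumorRadiusRange[2])
    reach <- r0 * .EDEMA_FACTOR * (1 + .DEFORM_AMP) + 1
    tx <- cx + runif(1, -1, 1) * max(ax - reach - 1, 0) * 0.8
    ty <- cy + runif(1, -1, 1) * max(ay - reach - 1, 0) * 0.8
    amp <- runif(2, 0, .DEFORM_AMP / 2)
    phase <- runif(2, 0, 2 * pi)
    dx <- xg - tx; dy <- yg - ty
    rho <- sqrt(dx^2 + dy^2)
    phi <- atan2(dy, dx)
    rphi <- r0 * (1 + amp[1] * cos(2 * phi + phase[1]) +
                      amp[2] * cos(3 * phi + phase[2]))
    labels <- matrix(0L, n, n)
    labels[rho < rphi * .EDEMA_FACTOR] <- 1L              # edema annulus
    labels[rho < rphi] <- 3L                              # enhancing rim
    labels[rho < pmax(rphi - spec@ringThickness, 0)] <- 2L  # core interior
    labels[!brain] <- 0L

    ## intensities
    pix <- array(0, dim = c(4L, n, n))
    base <- 0.35
    for (m in 1:4) {
      ch <- matrix(0, n, n)
      ch[brain] <- base + tex[brain]
      off <- spec@modalityContrasts[m, ]
      ch[labels == 1L] <- ch[labels == 1L] + off[1]
      ch[labels == 2L] <- ch[labels == 2L] + off[2]
      ch[labels == 3L] <- ch[labels == 3L] + off[3]
      if (spec@noiseSd > 0) {
        noise <- matrix(rnorm(n * n, sd = spec@noiseSd), n, n)
        ch[brain] <- ch[brain] + noise[brain]
      } else {
        rnorm(n * n)   # keep the draw sequence identical across noise levels
      }
      pix[m, , ] <- pmin(pmax(ch, 0), 1)
    }
    list(slice = MultiModalSlice(pix), mask = SegmentationMask(labels))
  })
}

#' Generate a phantom dataset
#'
#' Draws `n` independent phantom slices. Per-item seeds are derived
#' deterministically by hashing `(seed, index)`, so the dataset does not
#' depend on generation order.
#'
#' @param spec a [PhantomSpec-class].
#' @param n number of slices (>= 1).
#' @param seed base seed.
#' @return list of `n` `list(slice=, mask=)` pairs.
#' @export
generatePhantomDataset <- function(spec, n, seed = spec@seed) {
  if (n < 1) stop("empty dataset request")
  lapply(seq_len(n), function(i)
    generatePhantomSlice(spec, seed = .deriveSeed(seed, i)))
}

#' Write a phantom dataset as NIfTI cases plus a manifest
#'
#' Each case gets four single-modality files and a mask file (single-slice
#' volumes), and one manifest CSV row.
#'
#' @param spec a [PhantomSpec-class].
#' @param n number of cases.
#' @param seed base seed.
#' @param dir output directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
writePhantomDataset <- function(spec, n, seed, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- generatePhantomDataset(spec, n, seed)
  rows <- lapply(seq_along(ds), function(i) {
    id <- sprintf("case%03d", i)
    pix <- pixelData(ds[[i]]$slice)
    files <- character(4)
    for (m in 1:4) {
      files[m] <- sprintf("%s_%s.nii.gz", id, .MODALITIES[m])
      arr <- array(pix[m, , ], dim = c(dim(pix)[2], dim(pix)[3], 1L))
      RNifti::writeNifti(RNifti::asNifti(arr), file.path(dir, files[m]))
    }
    maskFile <- sprintf("%s_mask.nii.gz", id)
    lab <- maskLabels(ds[[i]]$mask)
    writeMask(SegmentationMask(array(lab, dim = c(1L, dim(lab)))),
              file.path(dir, maskFile))
    data.frame(case_id = id, t1 = files[1], t1c = files[2], t2 = files[3],
               flair = files[4], mask = maskFile)
  })
  manifest <- do.call(rbind, rows)
  writeManifest(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}
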