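## Stack rendering: per-cell fluorophore amounts -> two-channel 3D
## lateral-view stacks (Z = ML depth, Y = DV, X = AP) with Gaussian
## optics, Poisson shot noise and Gaussian read noise; transverse
## reslicing; TIFF + JSON-sidecar I/O.

## Column-normalized banded Gaussian convolution matrix; columns sum to 1
## so convolution preserves total intensity away from the array edges.
.axisBlurMatrix <- function(n, sigmaVox) {
  if (sigmaVox <= 0) return(NULL)
  idx <- seq_len(n)
  K <- exp(-outer(idx, idx, "-")^2 / (2 * sigmaVox^2))
  K[abs(outer(idx, idx, "-")) > ceiling(4 * sigmaVox)] <- 0
  sweep(K, 2, colSums(K), "/")
}

.blur3d <- function(arr, sigmaVox) {
  d <- dim(arr)
  Kz <- .axisBlurMatrix(d[1], sigmaVox[1])
  Ky <- .axisBlurMatrix(d[2], sigmaVox[2])
  Kx <- .axisBlurMatrix(d[3], sigmaVox[3])
  if (!is.null(Kz)) arr <- array(Kz %*% matrix(arr, d[1]), d)
  if (!is.null(Ky)) {
    arr <- aperm(arr, c(2, 1, 3))
    arr <- array(Ky %*% matrix(arr, d[2]), c(d[2], d[1], d[3]))
    arr <- aperm(arr, c(2, 1, 3))
  }
  if (!is.null(Kx))
    arr <- array(matrix(arr, d[1] * d[2]) %*% t(Kx), d)
  arr
}

#' Render per-cell states into a two-channel image stack
#'
#' Each cell deposits its channel amounts at the voxel containing its
#' position; the deposited field is convolved with a sum-preserving
#' Gaussian whose width combines the optical point-spread function with
#' the cell's own spatial extent (`cellSigma`, default a quarter of the
#' cell diameter -- cells are extended fluorophore-filled objects, not
#' points), scaled by the photon gain on top of the constant background
#' offset, and optionally degraded with Poisson shot noise followed by
#' additive Gaussian read noise (clamped at 0). Rendering is
#' deterministic given `noise@seed`.
#'
#' @param states per-cell channel amounts: the `data.frame` returned by
#'   [simulateReporter()] (columns `green`, `red`) or a numeric matrix
#'   with one column per channel, row-aligned with `cells`.
#' @param cells population from [buildEmbryo()].
#' @param geometry a [SpinalCordGeometry-class].
#' @param optics an [OpticsModel-class].
#' @param noise a [NoiseModel-class]; use [noiseOff()] for a noiseless
#'   render.
#' @param layout tissue layout from [embryoLayout()].
#' @param channels channel names (default green/red).
#' @param convertedApWindow `[start, end]` um of the photoconverted AP
#'   span, recorded in the stack metadata (empty if none).
#' @param cellSigma Gaussian sigma of the cell's own fluorophore
#'   distribution, um (0 renders cells as points).
#' @return a [KaedeStack-class].
#' @examples
#' geom <- SpinalCordGeometry()
#' cells <- buildEmbryo(geom, cellSpacing = 5, seed = 1)
#' st <- simulateReporter(cells, activityField("hh"),
#'   ConversionEvent(24, c(50, 200)), tImage = 30)
#' stack <- renderStack(st, cells, geom, noise = noiseOff())
#' @export
renderStack <- function(states, cells, geometry, optics = OpticsModel(),
                        noise = NoiseModel(),
                        layout = embryoLayout(geometry),
                        channels = NULL,
                        convertedApWindow = numeric(0),
                        cellSigma = geometry@cellDiameter / 4) {
  cells <- .asCells(cells)
  stopifnot(is(geometry, "SpinalCordGeometry"), is(optics, "OpticsModel"),
            is(noise, "NoiseModel"))
  if (is.data.frame(states)) {
    cn <- intersect(c("green", "red"), names(states))
    if (length(cn) == 0) stop("'states' has no channel columns")
    amounts <- as.matrix(states[, cn, drop = FALSE])
  } else {
    amounts <- as.matrix(states)
    cn <- colnames(amounts)
    if (is.null(cn)) cn <- paste0("ch", seq_len(ncol(amounts)))
  }
  if (is.null(channels)) channels <- cn
  if (nrow(amounts) != nrow(cells))
    stop("'states' and 'cells' must be index-aligned")
  if (any(amounts < 0)) stop("channel amounts must be >= 0")

  vs <- optics@voxelSize                      # (ML, DV, AP) um per voxel
  dims <- c(ceiling(layout$sizeMl / vs[1]),
            ceiling(layout$sizeDv / vs[2]),
            ceiling(layout$sizeAp / vs[3]))
  iz <- pmin(pmax(floor(cells$ml_um / vs[1]) + 1, 1), dims[1])
  iy <- pmin(pmax(floor(cells$dv_um / vs[2]) + 1, 1), dims[2])
  ix <- pmin(pmax(floor(cells$ap_um / vs[3]) + 1, 1), dims[3])
  lin <- (ix - 1) * dims[1] * dims[2] + (iy - 1) * dims[1] + iz
  sigmaVox <- sqrt(optics@psfSigma^2 + cellSigma^2) / vs

  nC <- ncol(amounts)
  data <- array(0, c(dims, nC))
  for (ch in seq_len(nC)) {
    field <- numeric(prod(dims))
    agg <- rowsum(amounts[, ch], lin)
    field[as.integer(rownames(agg))] <- agg[, 1]
    field <- .blur3d(array(field, dims), sigmaVox)
    counts <- optics@backgroundOffset + noise@photonGain * field
    data[, , , ch] <- counts
  }
  if (noise@shotNoise || noise@readNoiseSigma > 0) {
    data <- .withSeed(noise@seed, {
      v <- as.numeric(data)
      if (noise@shotNoise) v <- rpois(length(v), v)
      if (noise@readNoiseSigma > 0)
        v <- v + rnorm(length(v), 0, noise@readNoiseSigma)
      array(pmax(v, 0), dim(data))
    })
  }
  KaedeStack(data = data, voxelSize = vs,
             convertedApWindow = convertedApWindow, channels = channels,
             meta = list(geometry = geometry, layout = layout))
}

#' Reslice a lateral stack into transverse sections
#'
#' Swaps the first two axes, turning the lateral-view stack
#' `[Z = ML, Y = DV, X = AP]` into an ordered pile of transverse
#' sections `[Y = DV, Z = ML]` indexed by AP position. The operation is
#' a pure permutation of voxels (no interpolation) and is its own
#' inverse on plain arrays.
#'
#' @param x a [KaedeStack-class], or a 3D/4D array with axes
#'   `[Z, Y, X(, C)]`.
#' @return an array `[Y, Z, X(, C)]`; section `i` is `result[, , i, ]`.
#' @examples
#' a <- array(seq_len(24), c(2, 3, 4))
#' identical(resliceTransverse(resliceTransverse(a)), a)
#' @export
setGeneric("resliceTransverse", function(x) standardGeneric("resliceTransverse"))

#' @rdname resliceTransverse
#' @export
setMethod("resliceTransverse", "array", function(x) {
  nd <- length(dim(x))
  if (nd == 3) aperm(x, c(2, 1, 3))
  else if (nd == 4) aperm(x, c(2, 1, 3, 4))
  else stop("expected a 3D [Z, Y, X] or 4D [Z, Y, X, C] array")
})

#' @rdname resliceTransverse
#' @export
setMethod("resliceTransverse", "KaedeStack", function(x) {
  out <- aperm(x@data, c(2, 1, 3, 4))
  attr(out, "voxelSize") <- x@voxelSize
  attr(out, "channels") <- x@channels
  out
})

#' Extract one transverse section
#'
#' @param stack a [KaedeStack-class].
#' @param apIndex AP voxel index of the section.
#' @param channel channel name or index.
#' @return a `[Y = DV, Z = ML]` matrix.
#' @export
transverseSection <- function(stack, apIndex, channel = "green") {
  stopifnot(is(stack, "KaedeStack"))
  d <- dim(stack@data)
  if (apIndex < 1 || apIndex > d[3]) stop("'apIndex' outside the stack")
  if (is.character(channel)) channel <- match(channel, stack@channels)
  if (is.na(channel)) stop("unknown channel")
  t(stack@data[, , apIndex, channel])
}

#' Spinal-cord mask for transverse sections
#'
#' Logical `[Y = DV, Z = ML]` matrix marking voxels inside the
#' spinal-cord cross-section, derived from the stack's recorded geometry
#' and tissue layout.
#'
#' @param stack a [KaedeStack-class] rendered by [renderStack()] (or any
#'   stack whose `meta` carries `geometry` and `layout`).
#' @return logical matrix with the dimensions of a transverse section.
#' @export
cordSectionMask <- function(stack) {
  stopifnot(is(stack, "KaedeStack"))
  geometry <- stack@meta$geometry
  layout <- stack@meta$layout
  if (is.null(geometry) || is.null(layout))
    stop("stack metadata lacks geometry/layout")
  d <- dim(stack@data)
  yc <- (seq_len(d[2]) - 0.5) * stack@voxelSize[2]
  zc <- (seq_len(d[1]) - 0.5) * stack@voxelSize[1]
  inY <- yc >= layout$cordDv0 & yc <= layout$cordDv0 + geometry@dvHeight
  inZ <- zc >= layout$cordMl0 & zc <= layout$cordMl0 + geometry@mlWidth
  outer(inY, inZ, "&")
}

#' Canal position in a transverse section
#'
#' @param stack a [KaedeStack-class] with geometry metadata.
#' @return `c(y, z)` voxel indices of the central canal.
#' @export
canalPosition <- function(stack) {
  stopifnot(is(stack, "KaedeStack"))
  geometry <- stack@meta$geometry
  layout <- stack@meta$layout
  if (is.null(geometry) || is.null(layout))
    stop("stack metadata lacks geometry/layout")
  y <- layout$cordDv0 + geometry@canalDvFrac * geometry@dvHeight
  z <- layout$cordMl0 + geometry@canalMlFrac * geometry@mlWidth
  c(y = floor(y / stack@voxelSize[2]) + 1,
    z = floor(z / stack@voxelSize[1]) + 1)
}

#' Write / read a stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered channel-first (all Z planes of channel 1, then
#' channel 2, ...), each page a `[Y, X]` plane. Counts are stored scaled
#' into [0, 1]; the scale factor, voxel size, axis convention, channel
#' names, converted AP window and the geometry/layout needed to rebuild
#' cord masks travel in the JSON sidecar.
#'
#' @param stack a [KaedeStack-class].
#' @param path TIFF output path.
#' @param sidecar JSON sidecar path (default `<path>.json`).
#' @return `writeKaedeStack`: the TIFF path, invisibly;
#'   `readKaedeStack`: the reconstructed [KaedeStack-class].
#' @export
writeKaedeStack <- function(stack, path,
                            sidecar = paste0(path, ".json")) {
  stopifnot(is(stack, "KaedeStack"))
  d <- dim(stack@data)
  scale <- max(stack@data, 1)
  pages <- vector("list", d[1] * d[4])
  k <- 1
  for (ch in seq_len(d[4])) for (z in seq_len(d[1])) {
    pages[[k]] <- stack@data[z, , , ch] / scale
    k <- k + 1
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  geometry <- stack@meta$geometry
  side <- list(
    axes = "ZYX", dims = as.integer(d[1:3]),
    channels = stack@channels,
    voxel_size_um = stack@voxelSize,
    scale_max = scale,
    converted_ap_window_um = stack@convertedApWindow)
  if (!is.null(geometry))
    side$geometry <- list(
      dv_height = geometry@dvHeight, ml_width = geometry@mlWidth,
      ap_length = geometry@apLength, canal_dv_frac = geometry@canalDvFrac,
      canal_ml_frac = geometry@canalMlFrac,
      somite_length = geometry@somiteLength,
      cell_diameter = geometry@cellDiameter)
  if (!is.null(stack@meta$layout))
    side$layout <- stack@meta$layout
  if (!is.null(stack@meta$t0)) side$t0_hpf <- stack@meta$t0
  if (!is.null(stack@meta$tImage)) side$t_image_hpf <- stack@meta$tImage
  jsonlite::write_json(side, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeKaedeStack
#' @export
readKaedeStack <- function(path, sidecar = paste0(path, ".json")) {
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(side$dims)
  nC <- length(side$channels)
  data <- array(0, c(d, nC))
  k <- 1
  for (ch in seq_len(nC)) for (z in seq_len(d[1])) {
    data[z, , , ch] <- pages[[k]] * side$scale_max
    k <- k + 1
  }
  meta <- list()
  if (!is.null(side$geometry)) {
    g <- side$geometry
    meta$geometry <- SpinalCordGeometry(
      dvHeight = g$dv_height, mlWidth = g$ml_width, apLength = g$ap_length,
      canalDvFrac = g$canal_dv_frac, canalMlFrac = g$canal_ml_frac,
      somiteLength = g$somite_length, cellDiameter = g$cell_diameter)
  }
  if (!is.null(side$layout)) meta$layout <- side$layout
  if (!is.null(side$t0_hpf)) meta$t0 <- side$t0_hpf
  if (!is.null(side$t_image_hpf)) meta$tImage <- side$t_image_hpf
  KaedeStack(data = data, voxelSize = as.numeric(side$voxel_size_um),
             convertedApWindow = as.numeric(side$converted_ap_window_um),
             channels = side$channels, meta = meta)
}
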