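#' Construct a CT volume
#'
#' A `ggn_volume` is a 3D numeric array of Hounsfield units together with its
#' voxel spacing and origin. The internal axis convention is fixed to
#' `(z, y, x)` — the first array index runs along the scanner axis (slices) —
#' and spacing/origin vectors follow the same order. File readers convert from
#' the on-disk axis order into this convention so that downstream code never
#' has to reason about transpositions.
#'
#' @param values 3D numeric array of intensities in HU, indexed `[z, y, x]`.
#' @param spacing_mm positive numeric triple, voxel spacing in mm `(z, y, x)`.
#' @param origin_mm numeric triple, physical position of voxel `[1,1,1]`.
#' @return An object of class `ggn_volume`.
#' @export
new_volume <- function(values, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (length(dim(values)) != 3L)
    stop("volume values must be a 3D array, got ", length(dim(values)), "D")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("spacing_mm must be three positive finite numbers")
  if (any(!is.finite(values))) stop("volume contains non-finite intensities")
  structure(
    list(values = values, spacing_mm = spacing_mm,
         origin_mm = as.numeric(origin_mm)),
    class = "ggn_volume"
  )
}

#' @export
print.ggn_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ggn_volume> %d x %d x %d voxels (z,y,x), spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.ggn_volume <- function(x) dim(x$values)

#' Read or write a volume (NIfTI or NRRD)
#'
#' Formats are chosen by extension: `.nii` / `.nii.gz` (via RNifti) or
#' `.nrrd`. On-disk axis order for both formats is fastest-first `(x, y, z)`;
#' values and spacing are reordered into the internal `(z, y, x)` convention.
#' A write followed by a read round-trips values and spacing to float
#' precision.
#'
#' @param path file path ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @return `read_volume()` returns a [new_volume()] object; `write_volume()`
#'   returns `path` invisibly.
#' @export
read_volume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    if (length(dim(img)) != 3L)
      stop("expected 3D image, got ", length(dim(img)), "D: ", path)
    sp <- RNifti::pixdim(img)
    if (length(sp) < 3L || any(sp[1:3] <= 0))
      stop("missing or invalid spacing metadata in ", path)
    new_volume(aperm(unclass(img)[, , , drop = FALSE], c(3, 2, 1)),
               spacing_mm = rev(sp[1:3]))
  } else if (grepl("\\.nrrd$", path)) {
    nrrd_read(path)
  } else {
    stop("unsupported volume format: ", path)
  }
}

#' @rdname read_volume
#' @param volume a `ggn_volume`.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ggn_volume"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    arr <- aperm(volume$values, c(3, 2, 1)) # back to (x, y, z)
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- rev(volume$spacing_mm)
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.nrrd$", path)) {
    nrrd_write(volume, path)
  } else {
    stop("unsupported volume format: ", path)
  }
  invisible(path)
}

#' Resample a volume to isotropic 1 mm voxels
#'
#' Trilinear interpolation onto a 1 mm grid anchored at the input origin, with
#' voxel centres aligned to the input's first voxel centre. Intensities stay
#' on the Hounsfield scale. Interpolation clamps at the edges (no
#' extrapolation), so resampled values always lie within the input value
#' range, and a volume that is already isotropic at the target spacing passes
#' through unchanged.
#'
#' @param volume a [new_volume()] object.
#' @param new_spacing_mm target isotropic spacing, default 1 mm.
#' @return A resampled `ggn_volume` with spacing `(1, 1, 1)` mm.
#' @export
resample_isotropic <- function(volume, new_spacing_mm = 1) {
  stopifnot(inherits(volume, "ggn_volume"))
  d <- dim(volume$values)
  sp <- volume$spacing_mm
  extent <- (d - 1) * sp
  nd <- pmax(1L, as.integer(ceiling(extent / new_spacing_mm - 1e-9)) + 1L)

  # continuous input index (1-based) of each output grid centre, per axis
  fidx <- lapply(1:3, function(a) {
    pos <- (seq_len(nd[a]) - 1) * new_spacing_mm
    clamp(pos / sp[a] + 1, 1, d[a])
  })
  i0 <- lapply(1:3, function(a) clamp(floor(fidx[[a]]), 1, max(d[a] - 1L, 1L)))
  fr <- lapply(1:3, function(a) fidx[[a]] - i0[[a]])

  nz <- nd[1]; ny <- nd[2]; nx <- nd[3]
  Z0 <- rep.int(i0[[1]], ny * nx)
  Y0 <- rep.int(rep(i0[[2]], each = nz), nx)
  X0 <- rep(i0[[3]], each = nz * ny)
  FZ <- rep.int(fr[[1]], ny * nx)
  FY <- rep.int(rep(fr[[2]], each = nz), nx)
  FX <- rep(fr[[3]], each = nz * ny)

  v <- volume$values
  gather <- function(dz, dy, dx) {
    z <- clamp(Z0 + dz, 1L, d[1]); y <- clamp(Y0 + dy, 1L, d[2])
    x <- clamp(X0 + dx, 1L, d[3])
    v[z + (y - 1L) * d[1] + (x - 1L) * d[1] * d[2]]
  }
  out <- gather(0, 0, 0) * (1 - FZ) * (1 - FY) * (1 - FX) +
    gather(1, 0, 0) * FZ * (1 - FY) * (1 - FX) +
    gather(0, 1, 0) * (1 - FZ) * FY * (1 - FX) +
    gather(1, 1, 0) * FZ * FY * (1 - FX) +
    gather(0, 0, 1) * (1 - FZ) * (1 - FY) * FX +
    gather(1, 0, 1) * FZ * (1 - FY) * FX +
    gather(0, 1, 1) * (1 - FZ) * FY * FX +
    gather(1, 1, 1) * FZ * FY * FX

  new_volume(array(out, nd), spacing_mm = rep(new_spacing_mm, 3),
             origin_mm = volume$origin_mm)
}

#' Extract the 64-cube volume of interest around a seed voxel
#'
#' Crops a `size`^3 patch centred on the seed voxel of a 1 mm isotropic
#' volume; regions falling outside the volume are padded with air
#' (-1000 HU). The seed lands at output index `size/2` on each axis.
#'
#' @param volume isotropic (1 mm) `ggn_volume`.
#' @param seed integer triple `(z, y, x)`, 1-based voxel index of the lesion
#'   centre in the resampled volume.
#' @param size cube edge length in voxels (default 64).
#' @param pad_hu fill value for out-of-volume voxels (default -1000, air).
#' @return A `ggn_volume` of shape `size`^3 carrying attribute
#'   `source_offset` — the 0-based index of the patch origin in the source
#'   volume (possibly negative when padding occurred).
#' @export
extract_voi <- function(volume, seed, size = 64L, pad_hu = -1000) {
  stopifnot(inherits(volume, "ggn_volume"))
  if (max(abs(volume$spacing_mm - volume$spacing_mm[1])) > 1e-6)
    stop("extract_voi expects an isotropic volume; run resample_isotropic() first")
  d <- dim(volume$values)
  seed <- as.integer(seed)
  if (length(seed) != 3L || any(seed < 1L) || any(seed > d))
    stop("seed voxel ", paste(seed, collapse = ","), " is outside the volume")
  half <- size %/% 2L
  start <- seed - half + 1L           # seed maps to output index `half`
  out <- array(pad_hu, rep(size, 3))
  src_lo <- pmax(start, 1L)
  src_hi <- pmin(start + size - 1L, d)
  if (all(src_lo <= src_hi)) {
    dst_lo <- src_lo - start + 1L
    dst_hi <- src_hi - start + 1L
    out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
      volume$values[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  }
  voi <- new_volume(out, spacing_mm = volume$spacing_mm,
                    origin_mm = volume$origin_mm + (start - 1L) * volume$spacing_mm)
  attr(voi, "source_offset") <- start - 1L
  voi
}
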