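## internal helpers shared across modules

dim3 <- function(grid) grid@shape

## voxel-centre coordinate vectors (cm) along each axis
axisCoords <- function(grid) {
  lapply(1:3, function(a)
    grid@origin[a] + (seq_len(grid@shape[a]) - 0.5) * grid@spacing[a])
}

## Splittable per-patient seed: a fixed multiplicative mix of the master
## seed and the 1-based patient index, reduced mod 2^31 - 1. Extending a
## cohort never reshuffles earlier patients.
patientSeed <- function(masterSeed, index) {
  (masterSeed * 48271 + index * 2654435761) %% 2147483647
}

## Evaluate fn with a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  fn()
}

## Order-independent provenance hash of a character vector (djb2-style,
## folded to hex). Used to tie NormConstants and models to the cohort that
## produced them, not for cryptographic purposes.
provenanceHash <- function(ids) {
  ids <- sort(as.character(ids))
  h <- 5381
  for (ch in utf8ToInt(paste(ids, collapse = "|"))) {
    h <- (h * 33 + ch) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

## anisotropic Euclidean distance (cm) to the nearest TRUE voxel
distanceToMask <- function(mask, grid) {
  stopifnot(any(mask))
  d <- cpp_edt3d(as.logical(mask), dim3(grid), grid@spacing)
  array(d, dim = dim3(grid))
}

## signed distance to the surface of `mask`: negative inside, positive outside
signedDistance <- function(mask, grid) {
  dOut <- distanceToMask(mask, grid)
  dIn <- if (all(mask)) array(0, dim3(grid)) else distanceToMask(!mask, grid)
  d <- dOut
  d[mask] <- -dIn[mask]
  d
}

## Gaussian blur with sigma in cm, converted per axis to voxels
blurGaussian <- function(values, grid, sigmaCm) {
  sig <- sigmaCm / grid@spacing
  array(cpp_blur3d(as.numeric(values), dim3(grid), sig), dim = dim3(grid))
}
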