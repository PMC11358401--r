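# Grid sampling helpers. `ijk0` holds continuous 0-based voxel indices
# (m x 3); samples outside the grid return `fill`.

interp_nearest <- function(arr, ijk0, fill = 0) {
  dm <- dim(arr)
  i <- round(ijk0[, 1]); j <- round(ijk0[, 2]); k <- round(ijk0[, 3])
  ok <- i >= 0 & i <= dm[1] - 1 & j >= 0 & j <= dm[2] - 1 &
        k >= 0 & k <= dm[3] - 1
  out <- rep(fill, nrow(ijk0))
  lin <- 1 + i[ok] + dm[1] * (j[ok] + dm[2] * k[ok])
  out[ok] <- arr[lin]
  if (is.integer(arr)) storage.mode(out) <- "integer"
  out
}

interp_trilinear <- function(arr, ijk0, fill = 0) {
  dm <- dim(arr)
  i0 <- floor(ijk0[, 1]); j0 <- floor(ijk0[, 2]); k0 <- floor(ijk0[, 3])
  fi <- ijk0[, 1] - i0; fj <- ijk0[, 2] - j0; fk <- ijk0[, 3] - k0
  out <- rep(as.numeric(fill), nrow(ijk0))
  ok <- ijk0[, 1] >= 0 & ijk0[, 1] <= dm[1] - 1 &
        ijk0[, 2] >= 0 & ijk0[, 2] <= dm[2] - 1 &
        ijk0[, 3] >= 0 & ijk0[, 3] <= dm[3] - 1
  if (!any(ok)) return(out)
  i0 <- i0[ok]; j0 <- j0[ok]; k0 <- k0[ok]
  fi <- fi[ok]; fj <- fj[ok]; fk <- fk[ok]
  # clamp the upper corner for points exactly on the last plane
  i1 <- pmin(i0 + 1, dm[1] - 1); j1 <- pmin(j0 + 1, dm[2] - 1)
  k1 <- pmin(k0 + 1, dm[3] - 1)
  at <- function(i, j, k) arr[1 + i + dm[1] * (j + dm[2] * k)]
  acc <- at(i0, j0, k0) * (1 - fi) * (1 - fj) * (1 - fk) +
         at(i1, j0, k0) * fi       * (1 - fj) * (1 - fk) +
         at(i0, j1, k0) * (1 - fi) * fj       * (1 - fk) +
         at(i1, j1, k0) * fi       * fj       * (1 - fk) +
         at(i0, j0, k1) * (1 - fi) * (1 - fj) * fk +
         at(i1, j0, k1) * fi       * (1 - fj) * fk +
         at(i0, j1, k1) * (1 - fi) * fj       * fk +
         at(i1, j1, k1) * fi       * fj       * fk
  out[ok] <- acc
  out
}
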