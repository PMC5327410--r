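# Independent brute-force flood fill (pure R, queue-based), the oracle for
# the package's connected-component labeling on small volumes.
flood_fill_labels <- function(mask, connectivity = 6) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) {
    offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  }
  cur <- 0L
  for (i in which(mask)) {
    if (lab[i]) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      ai <- arrayInd(j, d)
      for (o in seq_len(nrow(offs))) {
        p <- ai + offs[o, ]
        if (any(p < 1) || any(p > d)) next
        k <- p[1] + d[1] * ((p[2] - 1) + d[2] * (p[3] - 1))
        if (mask[k] && !lab[k]) {
          lab[k] <- cur
          queue <- c(queue, k)
        }
      }
    }
  }
  lab
}

# Two labelings describe the same partition of the foreground iff the
# label pairs are in bijection.
same_partition <- function(a, b) {
  fg <- a > 0
  if (!identical(fg, b > 0)) return(FALSE)
  tab <- table(a[fg], b[fg])
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# Solid ellipsoid volume with the given semi-axes in voxels, centred in a
# grid with a background margin.
make_ellipsoid_volume <- function(semi_vox, margin = 3, value = 1,
                                  voxel_um = 10) {
  dims <- as.integer(ceiling(2 * semi_vox) + 2 * margin + 1)
  centre <- (dims - 1) / 2
  dz2 <- ((seq_len(dims[1]) - 1 - centre[1]) / semi_vox[1])^2
  dy2 <- ((seq_len(dims[2]) - 1 - centre[2]) / semi_vox[2])^2
  dx2 <- ((seq_len(dims[3]) - 1 - centre[3]) / semi_vox[3])^2
  v <- array(0, dims)
  v[outer(outer(dz2, dy2, `+`), dx2, `+`) <= 1] <- value
  attr(v, "voxel_size_um") <- voxel_um
  attr(v, "centre") <- centre
  v
}

# Carve an axis-aligned ellipsoidal void at `centre_vox` (1-based voxel
# coordinates) with semi-axes in voxels.
carve_void <- function(v, centre_vox, semi_vox) {
  d <- dim(v)
  dz2 <- ((seq_len(d[1]) - centre_vox[1]) / semi_vox[1])^2
  dy2 <- ((seq_len(d[2]) - centre_vox[2]) / semi_vox[2])^2
  dx2 <- ((seq_len(d[3]) - centre_vox[3]) / semi_vox[3])^2
  v[outer(outer(dz2, dy2, `+`), dx2, `+`) <= 1] <- 0
  v
}

ellipsoid_voxels <- function(semi_vox) 4 / 3 * pi * prod(semi_vox)

# Centred disk slice phantom for reconstruction checks.
make_disk_volume <- function(n = 96, radius = 30, mu = 0.4, voxel_um = 50) {
  cc <- (n - 1) / 2
  r2 <- outer(((1:n) - 1 - cc)^2, ((1:n) - 1 - cc)^2, `+`)
  vol <- array(0, c(1, n, n))
  vol[1, , ][r2 <= radius^2] <- mu
  attr(vol, "voxel_size_um") <- voxel_um
  vol
}
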