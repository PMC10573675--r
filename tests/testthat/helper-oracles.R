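# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's compiled code paths.

# per-voxel triple-loop threshold oracle
oracle_threshold <- function(voxels, lo, hi) {
  d <- dim(voxels)
  out <- array(0L, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    if (voxels[i, j, k] >= lo && voxels[i, j, k] <= hi) out[i, j, k] <- 1L
  out
}

# BFS flood-fill connected-component oracle in plain R
oracle_flood_fill <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  nz <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- offs[nz > 0 & ((connectivity == 26) |
                           (connectivity == 18 & nz <= 2) |
                           (connectivity == 6 & nz == 1)), ]
  labels <- array(0L, d)
  lab <- 0L
  for (start in which(mask != 0)) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(v, d)
      for (o in seq_len(nrow(offs))) {
        p <- ijk + c(offs$dx[o], offs$dy[o], offs$dz[o])
        if (any(p < 1) || any(p > d)) next
        lin <- p[1] + d[1] * ((p[2] - 1) + d[2] * (p[3] - 1))
        if (mask[lin] != 0 && labels[lin] == 0L) {
          labels[lin] <- lab
          queue <- c(queue, lin)
        }
      }
    }
  }
  labels
}

# do two labelmaps define the same partition of the foreground?
same_partition <- function(a, b) {
  fg <- which(a != 0)
  if (!identical(fg, which(b != 0))) return(FALSE)
  key <- paste(a[fg], b[fg])
  # bijection between label sets
  length(unique(key)) == length(unique(a[fg])) &&
    length(unique(key)) == length(unique(b[fg]))
}

# brute-force max pairwise distance over all component voxels
oracle_max_diameter <- function(labels, label, spacing) {
  idx <- which(labels == label)
  coords <- sweep(arrayInd(idx, dim(labels)) - 1, 2, spacing, `*`)
  if (nrow(coords) < 2) return(0)
  max(dist(coords))
}

# small centered digitized-sphere phantom (no blur, no noise)
sphere_phantom <- function(r_mm, h_mm, hu_stone = 1200, hu_bg = 0,
                           margin_mm = 2) {
  ext <- 2 * r_mm + 2 * margin_mm
  n <- ceiling(ext / h_mm)
  ax <- (seq_len(n) - 0.5) * h_mm
  ctr <- n * h_mm / 2
  g <- expand.grid(x = ax, y = ax, z = ax)
  inside <- (g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= r_mm^2
  hu_volume(array(ifelse(inside, hu_stone, hu_bg), c(n, n, n)),
            spacing = rep(h_mm, 3))
}

# tiny repeated-measurement table with exactly reproducing observers
perfect_trio_table <- function(n_cases = 8, n_reps = 3) {
  vols <- 100 * seq_len(n_cases)
  expand.grid(case_id = seq_len(n_cases),
              observer_id = c("A", "B", "C"),
              replicate = seq_len(n_reps), KEEP.OUT.ATTRS = FALSE) |>
    (\(d) {d$volume_mm3 <- vols[d$case_id]; d})()
}
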