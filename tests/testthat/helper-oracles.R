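# Independent flood-fill oracle: 26-connected component of `mask` containing
# `seed_idx`, grown by repeated masked dilation (array shifts) to a fixpoint.
# Deliberately a different algorithm from the package's BFS.
flood26_oracle <- function(mask, seed_idx) {
  d <- dim(mask)
  shift_arr <- function(x, s) {
    out <- array(FALSE, d)
    src <- dst <- lapply(d, seq_len)
    for (ax in 1:3) {
      n <- d[ax]
      if (s[ax] > 0) { dst[[ax]] <- (1 + s[ax]):n; src[[ax]] <- 1:(n - s[ax]) }
      else if (s[ax] < 0) { dst[[ax]] <- 1:(n + s[ax]); src[[ax]] <- (1 - s[ax]):n }
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
    out
  }
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  comp <- array(FALSE, d)
  comp[seed_idx] <- TRUE
  repeat {
    grown <- comp
    for (r in seq_len(nrow(offs))) grown <- grown | shift_arr(comp, offs[r, ])
    grown <- grown & mask
    if (identical(grown, comp)) break
    comp <- grown
  }
  comp
}

# brute-force voxel-centre count inside a sphere
sphere_count_oracle <- function(grid, center_mm, radius_mm) {
  ctr <- voxel_centers(grid)
  sum(rowSums(sweep(ctr, 2, center_mm)^2) <= radius_mm^2)
}
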