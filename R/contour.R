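# Connected-component extraction on pixel/voxel grids.
#
# 8-connectivity in 2D (26 in 3D), grown from a seed by a vectorised
# frontier expansion. Used by the autocontouring step and by the 3D
# segmentation front-end.

# mask: logical matrix; start: linear index with mask[start] TRUE
flood_fill2d <- function(mask, start) {
  nr <- nrow(mask); nc <- ncol(mask)
  reached <- array(FALSE, dim(mask))
  reached[start] <- TRUE
  frontier <- start
  off <- expand.grid(dr = -1:1, dc = -1:1)
  off <- off[!(off$dr == 0 & off$dc == 0), ]
  while (length(frontier)) {
    r <- (frontier - 1L) %% nr + 1L
    c <- (frontier - 1L) %/% nr + 1L
    nxt <- integer(0)
    for (k in seq_len(nrow(off))) {
      rr <- r + off$dr[k]; cc <- c + off$dc[k]
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      if (!any(ok)) next
      idx <- (cc[ok] - 1L) * nr + rr[ok]
      idx <- idx[mask[idx] & !reached[idx]]
      if (length(idx)) {
        reached[idx] <- TRUE
        nxt <- c(nxt, idx)
      }
    }
    frontier <- unique(nxt)
  }
  reached
}

# mask: logical 3D array; start: linear index
flood_fill3d <- function(mask, start) {
  d <- dim(mask)
  reached <- array(FALSE, d)
  reached[start] <- TRUE
  frontier <- start
  off <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  off <- off[!(off$di == 0 & off$dj == 0 & off$dk == 0), ]
  n12 <- d[1] * d[2]
  while (length(frontier)) {
    i0 <- frontier - 1L
    i <- i0 %% d[1] + 1L
    j <- (i0 %/% d[1]) %% d[2] + 1L
    k <- i0 %/% n12 + 1L
    nxt <- integer(0)
    for (m in seq_len(nrow(off))) {
      ii <- i + off$di[m]; jj <- j + off$dj[m]; kk <- k + off$dk[m]
      ok <- ii >= 1L & ii <= d[1] & jj >= 1L & jj <= d[2] &
        kk >= 1L & kk <= d[3]
      if (!any(ok)) next
      idx <- (kk[ok] - 1L) * n12 + (jj[ok] - 1L) * d[1] + ii[ok]
      idx <- idx[mask[idx] & !reached[idx]]
      if (length(idx)) {
        reached[idx] <- TRUE
        nxt <- c(nxt, idx)
      }
    }
    frontier <- unique(nxt)
  }
  reached
}
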