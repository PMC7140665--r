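# Independent brute-force oracles, kept free of the package's own code
# paths so the dual-route checks stay meaningful.

# flood-fill connected components of a 0/1 array in (y, x, t);
# returns an integer label array (0 = background)
oracle_flood_fill <- function(b, connectivity = 26L) {
  d <- dim(b)
  offs <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dt = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  lab <- array(0L, d)
  cur <- 0L
  for (start in which(b == 1)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      pos <- arrayInd(v, d)
      for (o in seq_len(nrow(offs))) {
        ny <- pos[1] + offs[o, 1]; nx <- pos[2] + offs[o, 2]
        nt <- pos[3] + offs[o, 3]
        if (ny < 1 || ny > d[1] || nx < 1 || nx > d[2] ||
            nt < 1 || nt > d[3]) next
        li <- ny + (nx - 1L) * d[1] + (nt - 1L) * d[1] * d[2]
        if (b[li] == 1 && lab[li] == 0L) {
          lab[li] <- cur
          queue <- c(queue, li)
        }
      }
    }
  }
  lab
}

# partition of positive voxels as a canonical string set, from a label array
oracle_partition <- function(lab) {
  pos <- which(lab != 0)
  unname(sort(vapply(split(pos, lab[pos]), function(ix)
    paste(sort(ix), collapse = ","), character(1)), method = "radix"))
}

# partition from an epifish cluster set (linear indices in the same array)
cluster_partition <- function(clusters, d) {
  unname(sort(vapply(clusters, function(cl) {
    li <- cl$voxels[, "y"] + (cl$voxels[, "x"] - 1L) * d[1] +
      (cl$voxels[, "t"] - 1L) * d[1] * d[2]
    paste(sort(li), collapse = ",")
  }, character(1)), method = "radix"))
}

# naive, independently-coded version of the iterative trim decomposition
# (plain vector ops, no sorting/cumsum tricks); same definition:
# fit -> check |mean - median| < tol*sd -> drop > mean + k*sd -> repeat
oracle_trim_modes <- function(lp, k = 2, tol = 0.01, max_iter = 100) {
  keep <- lp
  for (i in seq_len(max_iter + 1L)) {
    mu <- mean(keep); s <- sd(keep)
    if (abs(mu - median(keep)) < tol * s) break
    nk <- keep[keep <= mu + k * s]
    if (length(nk) == length(keep) || length(nk) < 3) break
    keep <- nk
  }
  mu <- mean(keep); s <- sd(keep)
  sm <- lp[lp > mu + k * s]
  list(mm_mean = mu, mm_sd = s,
       delta = if (length(sm) > 0) mean(sm) - mu else 0,
       n_sm = length(sm))
}
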