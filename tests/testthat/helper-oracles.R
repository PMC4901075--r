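# Independent oracles used across the suite. These are deliberately naive
# implementations (brute force, closed forms) kept free of the package's
# own code paths.

# Frontier-based (breadth-first) flood fill on a logical 3-D array; returns
# integer labels. Voxel coordinates are precomputed once so each frontier
# expansion is a handful of vectorised comparisons.
flood_fill_labels <- function(mask, connectivity = 26) {
  d <- dim(mask)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  m <- rowSums(abs(off))
  off <- off[m > 0 & m <= switch(as.character(connectivity),
                                 `6` = 1, `18` = 2, `26` = 3), , drop = FALSE]
  shift <- off[, 1] + d[1] * off[, 2] + d[1] * d[2] * off[, 3]
  ix <- arrayInd(seq_len(prod(d)), d)
  labels <- array(0L, d)
  nextlab <- 0L
  todo <- which(mask)
  while (length(todo)) {
    seed <- todo[1]
    nextlab <- nextlab + 1L
    frontier <- seed
    labels[seed] <- nextlab
    while (length(frontier)) {
      cand <- integer(0)
      for (o in seq_len(nrow(off))) {
        ok <- ix[frontier, 1] + off[o, 1] >= 1 &
          ix[frontier, 1] + off[o, 1] <= d[1] &
          ix[frontier, 2] + off[o, 2] >= 1 &
          ix[frontier, 2] + off[o, 2] <= d[2] &
          ix[frontier, 3] + off[o, 3] >= 1 &
          ix[frontier, 3] + off[o, 3] <= d[3]
        cand <- c(cand, frontier[ok] + shift[o])
      }
      cand <- unique(cand)
      cand <- cand[mask[cand] & labels[cand] == 0L]
      labels[cand] <- nextlab
      frontier <- cand
    }
    todo <- todo[labels[todo] == 0L]
  }
  labels
}

# Two labelings are equivalent iff they induce the same partition.
same_partition <- function(a, b) {
  fa <- as.integer(a[a > 0 | b > 0])
  fb <- as.integer(b[a > 0 | b > 0])
  if (any((fa == 0) != (fb == 0))) return(FALSE)
  key <- paste(fa, fb)
  length(unique(key)) == length(unique(fa)) &&
    length(unique(key)) == length(unique(fb))
}

# Textbook Pearson correlation from covariance/SD sums.
pearson_oracle <- function(a, b) {
  n <- length(a)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  num / den
}

# Paired t from difference scores.
paired_t_oracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  tval <- mean(d) / (sd(d) / sqrt(n))
  list(t = tval, df = n - 1,
       p = 2 * pt(-abs(tval), n - 1))
}

# One-way between-cells ANOVA by explicit sums of squares.
anova_ss_oracle <- function(y, g) {
  g <- factor(g)
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(unlist(tapply(y, g, function(v) (v - mean(v))^2)))
  dfb <- nlevels(g) - 1
  dfw <- length(y) - nlevels(g)
  F <- (ssb / dfb) / (ssw / dfw)
  list(F = F, df_between = dfb, df_error = dfw,
       p = pf(F, dfb, dfw, lower.tail = FALSE))
}

# Tukey HSD adjusted p for one pair via the studentized range distribution.
tukey_pair_oracle <- function(y, g, a, b) {
  g <- factor(g)
  k <- nlevels(g)
  nper <- tabulate(g)
  mse <- sum(unlist(tapply(y, g, function(v) (v - mean(v))^2))) /
    (length(y) - k)
  means <- tapply(y, g, mean)
  se <- sqrt(mse / 2 * (1 / nper[levels(g) == a] + 1 / nper[levels(g) == b]))
  q <- abs(means[[a]] - means[[b]]) / se
  ptukey(q, k, length(y) - k, lower.tail = FALSE)
}

# Voxel count of a sphere by explicit lattice enumeration.
sphere_count_oracle <- function(center_mm, radius_mm, grid) {
  count <- 0L
  for (k in 0:(grid$dims[3] - 1))
    for (j in 0:(grid$dims[2] - 1))
      for (i in 0:(grid$dims[1] - 1)) {
        w <- voxel_to_world(grid, c(i, j, k))
        if (sum((w - center_mm)^2) <= radius_mm^2) count <- count + 1L
      }
  count
}

# Small helpers -------------------------------------------------------------

tiny_grid <- function(dims = c(8, 8, 6), voxel = c(3.4375, 3.4375, 4))
  acq_grid(dims, voxel_size = voxel)

rand_volume <- function(grid, seed = 1) {
  set.seed(seed)
  fmri_volume(array(rnorm(prod(grid$dims)), grid$dims), grid)
}

rand_stat_maps <- function(grid, df = 19, seed = 1, scale = 2) {
  set.seed(seed)
  maps <- lapply(c(Value = 1, Mathematical = 2, Emotion = 3), function(i)
    stat_map(fmri_volume(array(rnorm(prod(grid$dims), sd = scale),
                               grid$dims), grid), df = df))
  maps
}
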