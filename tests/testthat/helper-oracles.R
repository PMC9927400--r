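# Independent brute-force oracles for the texture features, written against
# the definitions directly (exhaustive pair / run / neighbour enumeration).
# Deliberately slow and simple; never reuse package internals.

ALL_DIRS_26 <- {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d[!(d[, 1] == 0 & d[, 2] == 0 & d[, 3] == 0), , drop = FALSE]
}

HALF_DIRS_13 <- {
  d <- ALL_DIRS_26
  keep <- d[, 3] > 0 | (d[, 3] == 0 & d[, 2] > 0) |
    (d[, 3] == 0 & d[, 2] == 0 & d[, 1] > 0)
  d[keep, , drop = FALSE]
}

in_grid <- function(p, dims) all(p >= 1) && all(p <= dims)

# symmetric normalized GLCM by enumerating every voxel and every offset
oracle_glcm <- function(labels, ng, distance = 1, directions = HALF_DIRS_13) {
  dims <- dim(labels)
  counts <- matrix(0, ng, ng)
  for (di in seq_len(nrow(directions))) {
    off <- directions[di, ] * distance
    for (z in 1:dims[3]) for (y in 1:dims[2]) for (x in 1:dims[1]) {
      a <- labels[x, y, z]
      if (a == 0) next
      q <- c(x, y, z) + off
      if (!in_grid(q, dims)) next
      b <- labels[q[1], q[2], q[3]]
      if (b == 0) next
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  if (sum(counts) == 0) {
    counts <- matrix(0, ng, ng)
    counts[1, 1] <- 1
    return(counts)
  }
  counts / sum(counts)
}

# run-length counts by walking each maximal run
oracle_glrlm <- function(labels, ng, directions = HALF_DIRS_13) {
  dims <- dim(labels)
  counts <- matrix(0, ng, max(dims))
  for (di in seq_len(nrow(directions))) {
    off <- directions[di, ]
    for (z in 1:dims[3]) for (y in 1:dims[2]) for (x in 1:dims[1]) {
      a <- labels[x, y, z]
      if (a == 0) next
      prev <- c(x, y, z) - off
      if (in_grid(prev, dims) && labels[prev[1], prev[2], prev[3]] == a) next
      len <- 1
      cur <- c(x, y, z) + off
      while (in_grid(cur, dims) && labels[cur[1], cur[2], cur[3]] == a) {
        len <- len + 1
        cur <- cur + off
      }
      counts[a, len] <- counts[a, len] + 1
    }
  }
  counts
}

# (level, dependence) counts by exhaustive 26-neighbourhood checks
oracle_gldm <- function(labels, ng, alpha = 0) {
  dims <- dim(labels)
  counts <- matrix(0, ng, 27)
  for (z in 1:dims[3]) for (y in 1:dims[2]) for (x in 1:dims[1]) {
    a <- labels[x, y, z]
    if (a == 0) next
    dep <- 1
    for (di in seq_len(nrow(ALL_DIRS_26))) {
      q <- c(x, y, z) + ALL_DIRS_26[di, ]
      if (!in_grid(q, dims)) next
      b <- labels[q[1], q[2], q[3]]
      if (b == 0) next
      if (abs(a - b) <= alpha) dep <- dep + 1
    }
    counts[a, dep] <- counts[a, dep] + 1
  }
  counts
}

# random small discretized volume with holes in the mask
random_dv <- function(seed, dims = c(4, 4, 4), ng = 4, p_mask = 0.8) {
  withr::with_seed(seed, {
    labels <- array(sample(1:ng, prod(dims), replace = TRUE), dims)
    mask <- array(runif(prod(dims)) < p_mask, dims)
    labels[!mask] <- 0L
    if (!any(mask)) {
      mask[1] <- TRUE
      labels[1] <- 1L
    }
    structure(list(labels = labels, ng = as.integer(ng), mask = mask,
                   spacing = c(1, 1, 1)),
              class = "discretized_volume")
  })
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  sc <- function(x) sum(choose(x, 2))
  si <- sc(tab)
  sa <- sc(rowSums(tab))
  sb <- sc(colSums(tab))
  st <- choose(sum(tab), 2)
  e <- sa * sb / st
  (si - e) / ((sa + sb) / 2 - e)
}

# small 1-mm phantom cohort used by several tests
small_cohort <- function(n, seed, preset = "strong", effect_scale = 1,
                         images = TRUE) {
  cfg <- generator_config(n_lesions = n, seed = seed, image_shape = 48,
                          spacing_mm = c(1, 1, 1), texture_signal = preset,
                          effect_scale = effect_scale)
  generate_cohort(cfg, images = images)
}
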