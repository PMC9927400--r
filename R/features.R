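# Native radiomics features on discretized unit cubes: first-order, shape,
# GLCM, GLRLM, GLDM, GLSZM and NGTDM families. Definitions follow the IBSI
# conventions; all entropies are log base 2; co-occurrence and run counts are
# aggregated by summing over the 13 unique 3D directions before
# normalization (merged strategy).

#' Discretize in-mask intensities into equal-width bins
#'
#' @param cube a [volume3d()] (values typically in `[0, 1]`).
#' @param mask binary [volume3d()] with the same dims.
#' @param n_bins number of grey levels.
#' @return a `discretized_volume`: integer array `labels` (0 outside mask,
#'   `1..ng` inside), level count `ng`, and the logical `mask`.
#' @export
discretize <- function(cube, mask, n_bins = 32) {
  stopifnot(inherits(cube, "volume3d"), inherits(mask, "volume3d"))
  if (!identical(dim(cube$data), dim(mask$data))) stopf("cube/mask dims differ")
  inmask <- mask$data > 0.5
  if (!any(inmask)) stopf("empty mask: cannot discretize")
  v <- cube$data[inmask]
  r <- range(v)
  labels <- array(0L, dim(cube$data))
  if (diff(r) == 0) {
    labels[inmask] <- 1L
    ng <- 1L
  } else {
    lv <- pmin(as.integer(floor((v - r[1]) / diff(r) * n_bins)) + 1L, as.integer(n_bins))
    labels[inmask] <- lv
    ng <- as.integer(n_bins)
  }
  structure(list(labels = labels, ng = ng, mask = inmask,
                 spacing = cube$spacing),
            class = "discretized_volume")
}

#' Grey-level co-occurrence matrix
#'
#' Symmetric, normalized co-occurrence probabilities aggregated over the
#' supplied direction set (the 13 unique 3D directions by default); only
#' in-mask voxel pairs are counted.
#'
#' @param dv a [discretize()]d volume.
#' @param distance voxel offset distance.
#' @param directions integer matrix of direction offsets (columns dx, dy, dz).
#' @return `ng x ng` matrix summing to 1 (single-cell `p(1,1)=1` when `ng=1`
#'   and/or no valid pairs exist).
#' @export
glcm_matrix <- function(dv, distance = 1, directions = directions_13()) {
  stopifnot(inherits(dv, "discretized_volume"))
  counts <- .glcm_counts_cpp(as.integer(dv$labels), dim(dv$labels),
                             directions, dv$ng, as.integer(distance))
  tot <- sum(counts)
  if (tot == 0) {
    p <- matrix(0, dv$ng, dv$ng)
    p[1, 1] <- 1
    return(p)
  }
  counts / tot
}

#' GLCM features
#'
#' Computes `Idmn`, `Idn`, `Idm`, `InverseVariance`, `Imc1`, `Imc2`,
#' `ClusterShade`, `ClusterProminence`, `Contrast`, `Correlation`,
#' `JointEnergy` and `JointEntropy` from a normalized symmetric GLCM.
#' Degenerate marginal entropies give `Imc1 = Imc2 = 0`; zero variance gives
#' `Correlation = 1`.
#'
#' @param p normalized symmetric co-occurrence matrix.
#' @return named numeric vector.
#' @export
glcm_features <- function(p) {
  ng <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sdx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sdy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  nz <- p > 0
  hxy <- -sum(p[nz] * log2(p[nz]))
  pxy <- outer(px, py)
  nzm <- pxy > 0
  hxy1 <- -sum(p[nzm] * log2(pxy[nzm]))
  hxy2 <- -sum(pxy[nzm] * log2(pxy[nzm]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  imc1 <- if (max(hx, hy) == 0) 0 else (hxy - hxy1) / max(hx, hy)
  imc2 <- if (max(hx, hy) == 0) 0 else sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  corr <- if (sdx * sdy == 0) 1 else
    sum((i - mux) * (j - muy) * p) / (sdx * sdy)
  off <- i != j
  c(
    Idmn = sum(p / (1 + (i - j)^2 / ng^2)),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    Idm = sum(p / (1 + (i - j)^2)),
    InverseVariance = sum(p[off] / (i[off] - j[off])^2),
    Imc1 = imc1,
    Imc2 = imc2,
    ClusterShade = sum((i + j - mux - muy)^3 * p),
    ClusterProminence = sum((i + j - mux - muy)^4 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    JointEnergy = sum(p^2),
    JointEntropy = hxy
  )
}

#' Grey-level run-length matrix
#'
#' Run counts per (level, run length), aggregated by summing over the
#' supplied directions.
#'
#' @inheritParams glcm_matrix
#' @return numeric matrix `ng x max_run_length` of counts (not normalized).
#' @export
glrlm_matrix <- function(dv, directions = directions_13()) {
  stopifnot(inherits(dv, "discretized_volume"))
  .glrlm_counts_cpp(as.integer(dv$labels), dim(dv$labels), directions, dv$ng)
}

#' GLRLM features
#'
#' @param R run-count matrix from [glrlm_matrix()].
#' @param n_voxels number of in-mask voxels.
#' @param n_directions number of directions aggregated (for RunPercentage).
#' @return named numeric vector incl. `RunEntropy` (log2).
#' @export
glrlm_features <- function(R, n_voxels, n_directions = 13) {
  nr <- sum(R)
  if (nr == 0) return(c(ShortRunEmphasis = 0, LongRunEmphasis = 0,
                        GrayLevelNonUniformity = 0, RunLengthNonUniformity = 0,
                        RunPercentage = 0, GrayLevelVariance = 0,
                        RunVariance = 0, RunEntropy = 0))
  q <- R / nr
  l <- col(R); g <- row(R)
  mug <- sum(g * q); mul <- sum(l * q)
  nzq <- q > 0
  c(
    ShortRunEmphasis = sum(R / col(R)^2) / nr,
    LongRunEmphasis = sum(R * col(R)^2) / nr,
    GrayLevelNonUniformity = sum(rowSums(R)^2) / nr,
    RunLengthNonUniformity = sum(colSums(R)^2) / nr,
    RunPercentage = nr / (n_voxels * n_directions),
    GrayLevelVariance = sum((g - mug)^2 * q),
    RunVariance = sum((l - mul)^2 * q),
    RunEntropy = -sum(q[nzq] * log2(q[nzq]))
  )
}

#' Grey-level dependence matrix
#'
#' For each in-mask voxel, dependence = 1 + number of in-mask 26-neighbours
#' whose level differs by at most `alpha`.
#'
#' @inheritParams glcm_matrix
#' @param alpha level-difference tolerance.
#' @return numeric matrix `ng x 27` of counts.
#' @export
gldm_matrix <- function(dv, alpha = 0) {
  stopifnot(inherits(dv, "discretized_volume"))
  .gldm_counts_cpp(as.integer(dv$labels), dim(dv$labels), dv$ng, as.integer(alpha))
}

#' GLDM features
#'
#' @param P dependence-count matrix from [gldm_matrix()].
#' @return named numeric vector incl. `DependenceEntropy` (log2).
#' @export
gldm_features <- function(P) {
  nz <- sum(P)
  q <- P / nz
  d <- col(P); g <- row(P)
  mud <- sum(d * q)
  nzq <- q > 0
  c(
    SmallDependenceEmphasis = sum(P / col(P)^2) / nz,
    LargeDependenceEmphasis = sum(P * col(P)^2) / nz,
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nz,
    DependenceNonUniformity = sum(colSums(P)^2) / nz,
    DependenceVariance = sum((d - mud)^2 * q),
    DependenceEntropy = -sum(q[nzq] * log2(q[nzq]))
  )
}

#' GLSZM features
#'
#' Zones are 26-connected components of equal level inside the mask.
#'
#' @inheritParams glcm_matrix
#' @return named numeric vector.
#' @export
glszm_features <- function(dv) {
  stopifnot(inherits(dv, "discretized_volume"))
  Z <- .glszm_counts_cpp(as.integer(dv$labels), dim(dv$labels), dv$ng)
  nz <- sum(Z)
  q <- Z / nz
  nzq <- q > 0
  np <- sum(dv$mask)
  c(
    SmallAreaEmphasis = sum(Z / col(Z)^2) / nz,
    LargeAreaEmphasis = sum(Z * col(Z)^2) / nz,
    GrayLevelNonUniformity = sum(rowSums(Z)^2) / nz,
    SizeZoneNonUniformity = sum(colSums(Z)^2) / nz,
    ZonePercentage = nz / np,
    ZoneEntropy = -sum(q[nzq] * log2(q[nzq]))
  )
}

#' NGTDM features
#'
#' @inheritParams glcm_matrix
#' @return named numeric vector (Coarseness, Contrast, Busyness, Complexity,
#'   Strength).
#' @export
ngtdm_features <- function(dv) {
  stopifnot(inherits(dv, "discretized_volume"))
  cn <- .ngtdm_counts_cpp(as.integer(dv$labels), dim(dv$labels), dv$ng)
  s <- cn$s; n <- cn$n
  nv <- sum(n)
  p <- n / nv
  act <- p > 0
  ngp <- sum(act)
  iv <- seq_along(p)
  coarse <- sum(p * s)
  contrast <- if (ngp > 1) {
    (sum(outer(p[act], p[act]) * outer(iv[act], iv[act], "-")^2) /
       (ngp * (ngp - 1))) * (sum(s) / nv)
  } else 0
  busy_den <- sum(abs(outer(iv[act] * p[act], iv[act] * p[act], "-")))
  busyness <- if (busy_den == 0) 0 else sum(p * s) / busy_den
  cmplx <- if (nv > 0 && ngp > 1) {
    pi_ <- p[act]; ii <- iv[act]; si <- s[act]
    sum(abs(outer(ii, ii, "-")) *
          (outer(pi_ * si, pi_ * si, "+") / outer(pi_, pi_, "+"))) / nv
  } else 0
  strength <- if (sum(s) == 0) 0 else {
    pi_ <- p[act]; ii <- iv[act]
    sum(outer(pi_, pi_, "+") * outer(ii, ii, "-")^2) / sum(s)
  }
  c(Coarseness = if (coarse == 0) 1e6 else 1 / coarse,
    Contrast = contrast, Busyness = busyness,
    Complexity = cmplx, Strength = strength)
}

#' First-order intensity statistics
#'
#' Population-variance convention; entropy and uniformity use the discretized
#' histogram (equal-width bins over the in-mask range, log2).
#'
#' @param cube a [volume3d()].
#' @param mask binary [volume3d()].
#' @param n_bins histogram bins for entropy/uniformity.
#' @return named numeric vector of 13 statistics.
#' @export
firstorder_features <- function(cube, mask, n_bins = 32) {
  stopifnot(inherits(cube, "volume3d"), inherits(mask, "volume3d"))
  v <- cube$data[mask$data > 0.5]
  if (length(v) == 0L) stopf("empty mask")
  m <- mean(v)
  va <- mean((v - m)^2)
  s <- sqrt(va)
  dv <- discretize(cube, mask, n_bins)
  q <- tabulate(dv$labels[dv$mask], dv$ng)
  q <- q[q > 0] / length(v)
  c(
    Mean = m, Variance = va,
    Skewness = if (s == 0) 0 else mean((v - m)^3) / s^3,
    Kurtosis = if (s == 0) 0 else mean((v - m)^4) / s^4,
    Entropy = -sum(q * log2(q)),
    Uniformity = sum(q^2),
    Energy = sum(v^2),
    Minimum = min(v), Maximum = max(v), Median = median(v),
    Range = diff(range(v)),
    MeanAbsoluteDeviation = mean(abs(v - m)),
    RootMeanSquared = sqrt(mean(v^2))
  )
}

#' Shape features from a binary mask
#'
#' Eigen-decomposition of the physical-coordinate covariance of in-mask voxel
#' centres gives the principal axis lengths; `Elongation = sqrt(l2/l1)` and
#' `Flatness = sqrt(l3/l1)` with eigenvalues `l1 >= l2 >= l3`. A single-voxel
#' mask returns Elongation = Flatness = 1 by convention. Surface area is the
#' summed area of exposed voxel faces (voxel-surface approximation).
#'
#' @param mask binary [volume3d()].
#' @param spacing optional spacing override (mm).
#' @return named numeric vector.
#' @export
shape_features <- function(mask, spacing = NULL) {
  stopifnot(inherits(mask, "volume3d"))
  sp <- spacing %||% mask$spacing
  w <- which(mask$data > 0.5, arr.ind = TRUE)
  if (nrow(w) == 0L) stopf("empty mask")
  nvox <- nrow(w)
  vol <- nvox * prod(sp)
  # exposed voxel faces
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  faces <- .surface_faces_cpp(as.integer(mask$data > 0.5), dim(mask$data))
  sa <- sum(faces * face_area)
  if (nvox == 1L) {
    ax <- rep(min(sp), 3)
    ev <- c(1, 1, 1) * 0
    elo <- flat <- 1
  } else {
    phys <- sweep(w - 1, 2, sp, "*")
    cv <- cov(phys) * (nvox - 1) / nvox
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
    elo <- if (ev[1] == 0) 1 else sqrt(ev[2] / ev[1])
    flat <- if (ev[1] == 0) 1 else sqrt(ev[3] / ev[1])
    ax <- 4 * sqrt(ev)
  }
  c(
    VoxelVolume = vol,
    SurfaceArea = sa,
    Sphericity = (pi^(1 / 3) * (6 * vol)^(2 / 3)) / sa,
    MajorAxisLength = ax[1], MinorAxisLength = ax[2], LeastAxisLength = ax[3],
    Elongation = elo, Flatness = flat
  )
}

#' Compute the full feature vector for one cube/mask pair
#'
#' @param cube normalized [volume3d()] from [preprocess_pair()].
#' @param mask cropped binary [volume3d()] on the same grid.
#' @param n_bins discretization levels.
#' @param distance GLCM offset distance.
#' @param alpha GLDM dependence tolerance.
#' @return named numeric vector with family-prefixed names.
#' @export
feature_vector <- function(cube, mask, n_bins = 32, distance = 1, alpha = 0) {
  dv <- discretize(cube, mask, n_bins)
  fo <- firstorder_features(cube, mask, n_bins)
  sh <- shape_features(mask)
  gl <- glcm_features(glcm_matrix(dv, distance))
  rl <- glrlm_features(glrlm_matrix(dv), n_voxels = sum(dv$mask))
  dm <- gldm_features(gldm_matrix(dv, alpha))
  sz <- glszm_features(dv)
  nt <- ngtdm_features(dv)
  out <- c(setNames(fo, paste0("firstorder_", names(fo))),
           setNames(sh, paste0("shape_", names(sh))),
           setNames(gl, paste0("GLCM_", names(gl))),
           setNames(rl, paste0("GLRLM_", names(rl))),
           setNames(dm, paste0("GLDM_", names(dm))),
           setNames(sz, paste0("GLSZM_", names(sz))),
           setNames(nt, paste0("NGTDM_", names(nt))))
  out
}

#' The core selected feature set
#'
#' The nine phase-prefixed radiomics features the fusion model is built
#' around: six pre-ablation nodule features and three post-ablation
#' ablation-zone features.
#'
#' @return character vector of nine feature names.
#' @export
core_selected_features <- function() {
  c("pre_shape_Elongation", "pre_GLCM_Idmn", "pre_GLCM_Imc1",
    "pre_GLCM_InverseVariance", "pre_GLCM_ClusterShade",
    "pre_GLDM_DependenceEntropy",
    "post_GLCM_Idmn", "post_GLRLM_RunEntropy", "post_GLCM_Imc2")
}

#' Extract the lesion-by-feature table for a cohort
#'
#' One row per lesion: `pre_` features from the preprocessed pre-ablation
#' nodule cube/mask and `post_` features from the ablation-zone cube/mask.
#'
#' @param cohort an `rfa_cohort` with images, or a list of `lesion_case`.
#' @param size_mm preprocessing cube edge (mm).
#' @param n_bins,distance,alpha extraction settings (see [feature_vector()]).
#' @return data.frame keyed by `lesion_id` with phase-prefixed feature
#'   columns; errors if any feature is non-finite, naming lesion and feature.
#' @export
extract_feature_table <- function(cohort, size_mm = 40, n_bins = 32,
                                  distance = 1, alpha = 0) {
  cases <- if (inherits(cohort, "rfa_cohort")) cohort$cases else cohort
  if (is.null(cases)) stopf("cohort has no image cases (images = FALSE?)")
  rows <- lapply(cases, function(case) {
    pp <- preprocess_case(case, size_mm)
    pre <- feature_vector(pp$pre$cube, pp$pre$mask, n_bins, distance, alpha)
    post <- feature_vector(pp$post$cube, pp$post$mask, n_bins, distance, alpha)
    v <- c(setNames(pre, paste0("pre_", names(pre))),
           setNames(post, paste0("post_", names(post))))
    bad <- !is.finite(v)
    if (any(bad))
      stopf("non-finite feature(s) for lesion %s: %s", case$lesion_id,
            paste(names(v)[bad], collapse = ", "))
    v
  })
  tab <- as.data.frame(do.call(rbind, rows))
  tab <- cbind(lesion_id = vapply(cases, `[[`, "", "lesion_id"), tab)
  rownames(tab) <- NULL
  attr(tab, "settings") <- list(size_mm = size_mm, n_bins = n_bins,
                                distance = distance, alpha = alpha,
                                n_directions = 13)
  tab
}
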