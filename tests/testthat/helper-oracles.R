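# Independent oracles and small fixtures shared across the test files.
# Everything here is deliberately written the slow, obvious way so that the
# package implementations are checked against a second, independent route.

# small isotropic volume centred however the caller likes
tiny_vol <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     unit = "HU") {
  image_volume(array(values, dim = dim(values) %||% length(values)),
               spacing, origin, unit = unit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# R trilinear interpolation with out-of-field fill, 0-based fractional
# voxel index convention (matches standard image interpolation);
# vectorized over the rows of pts
interp_r <- function(vol, pts, fill = 0) {
  d <- dim(vol$values)
  fx <- (pts[, 1] - vol$origin[1]) / vol$spacing[1]
  fy <- (pts[, 2] - vol$origin[2]) / vol$spacing[2]
  fz <- (pts[, 3] - vol$origin[3]) / vol$spacing[3]
  inside <- fx >= 0 & fx <= d[1] - 1 & fy >= 0 & fy <= d[2] - 1 &
    fz >= 0 & fz <= d[3] - 1
  out <- rep(fill, nrow(pts))
  if (!any(inside)) return(out)
  fx <- fx[inside]; fy <- fy[inside]; fz <- fz[inside]
  i0 <- pmin(floor(fx), d[1] - 2); wx <- fx - i0
  j0 <- pmin(floor(fy), d[2] - 2); wy <- fy - j0
  k0 <- pmin(floor(fz), d[3] - 2); wz <- fz - k0
  v <- vol$values
  at <- function(dx, dy, dz)
    v[cbind(i0 + dx + 1, j0 + dy + 1, k0 + dz + 1)]
  acc <- (1 - wx) * (1 - wy) * (1 - wz) * at(0, 0, 0) +
    wx * (1 - wy) * (1 - wz) * at(1, 0, 0) +
    (1 - wx) * wy * (1 - wz) * at(0, 1, 0) +
    wx * wy * (1 - wz) * at(1, 1, 0) +
    (1 - wx) * (1 - wy) * wz * at(0, 0, 1) +
    wx * (1 - wy) * wz * at(1, 0, 1) +
    (1 - wx) * wy * wz * at(0, 1, 1) +
    wx * wy * wz * at(1, 1, 1)
  out[inside] <- acc
  out
}

# integer-shifted copy of an array, NA outside
shift_arr <- function(A, v) {
  d <- dim(A)
  out <- array(NA_real_, d)
  src1 <- pmax(1, 1 + v); src2 <- pmin(d, d + v)
  if (any(src1 > src2)) return(out)
  dst1 <- src1 - v; dst2 <- src2 - v
  out[dst1[1]:dst2[1], dst1[2]:dst2[2], dst1[3]:dst2[3]] <-
    A[src1[1]:src2[1], src1[2]:src2[2], src1[3]:src2[3]]
  out
}

# exhaustive gamma: full subgrid enumeration, no sorting, no early exit.
# With the subgrid step dta/10 equal to spacing/10 (the configuration the
# oracle tests use), every evaluation position "voxel centre + offset"
# lies on one fine lattice of pitch step; that lattice is interpolated
# once with the independent R interpolation above, and each offset then
# reduces to a single indexed lookup across all voxels. Positions outside
# the evaluation grid are NA and excluded from the minimum, matching the
# convention that out-of-field evaluation positions are skipped.
gamma_brute <- function(ref, evl, dose_tol, dta, cutoff = 15,
                        prescription) {
  stopifnot(all(abs(ref$spacing - dta) < 1e-12))
  dd_abs <- dose_tol / 100 * prescription
  step <- dta / 10
  m <- 30L   # offsets of -30..30 steps cover the 3 x dta search radius
  d <- dim(ref$values)
  axf <- lapply(1:3, function(a)
    ref$origin[a] + ((-m):((d[a] - 1) * 10 + m)) * step)
  nf <- vapply(axf, length, integer(1))
  ptsf <- as.matrix(expand.grid(x = axf[[1]], y = axf[[2]], z = axf[[3]]))
  finev <- interp_r(evl, ptsf, fill = NA_real_)
  # linear fine-lattice index of each voxel centre
  bx <- (0:(d[1] - 1)) * 10 + m + 1
  by <- (0:(d[2] - 1)) * 10 + m + 1
  bz <- (0:(d[3] - 1)) * 10 + m + 1
  B <- outer(outer(bx, (by - 1) * nf[1], "+"),
             (bz - 1) * nf[1] * nf[2], "+")
  s <- -m:m
  offi <- as.matrix(expand.grid(dx = s, dy = s, dz = s))
  d2 <- rowSums((offi * step)^2)
  keep <- d2 <= (3 * dta)^2
  offi <- offi[keep, , drop = FALSE]
  d2n <- d2[keep] / dta^2
  best <- array(Inf, d)
  refv <- ref$values
  for (o in seq_len(nrow(offi))) {
    ev <- finev[B + offi[o, 1] + offi[o, 2] * nf[1] +
                  offi[o, 3] * nf[1] * nf[2]]
    gam2 <- ((ev - refv) / dd_abs)^2 + d2n[o]
    gam2[is.na(gam2)] <- Inf
    best <- pmin(best, gam2)
  }
  g <- sqrt(best)
  emask <- ref$values >= cutoff / 100 * prescription
  g[!emask] <- NA_real_
  list(gamma = g, eval_mask = emask,
       pass_rate = 100 * sum(g[emask] <= 1) / sum(emask))
}

# exact two-sided rank-sum p by complete enumeration (no ties assumed),
# matching the standard exact convention: double the smaller tail, cap at 1
rank_sum_enum <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r_obs <- sum(rank(pooled)[seq_len(n1)])
  u_obs <- r_obs - n1 * (n1 + 1) / 2
  cmb <- utils::combn(length(pooled), n1)
  rk <- rank(pooled)
  us <- apply(cmb, 2, function(ix) sum(rk[ix]) - n1 * (n1 + 1) / 2)
  pl <- mean(us <= u_obs); pu <- mean(us >= u_obs)
  list(u = u_obs, p = min(1, 2 * min(pl, pu)))
}

# one shared default phantom (a few tests only need any realistic head)
shared_phantom <- local({
  ph <- NULL
  function() {
    if (is.null(ph)) ph <<- generate_head_phantom(phantom_spec())
    ph
  }
})
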