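#' 3D image stacks
#'
#' A minimal container for a single-channel 3D intensity stack: a numeric
#' array with a voxel size in um per axis. Distances derived from stacks are
#' always converted to um with the (possibly anisotropic) voxel size.
#'
#' @param voxels Non-negative numeric 3D array (x, y, z order).
#' @param voxel_size Length-3 positive numeric, um per voxel along each axis.
#' @param channel Channel name (free text).
#' @return An object of class `"stack"`.
#' @export
new_stack <- function(voxels, voxel_size = c(1, 1, 1), channel = "") {
  if (length(dim(voxels)) != 3) abort("`voxels` must be a 3D array.")
  if (any(voxels < 0)) abort("Intensities must be non-negative.")
  if (length(voxel_size) != 3 || any(voxel_size <= 0)) {
    abort("`voxel_size` must be three positive numbers (um).")
  }
  structure(list(voxels = voxels, voxel_size = as.numeric(voxel_size),
                 channel = channel), class = "stack")
}

#' @export
print.stack <- function(x, ...) {
  cat(sprintf("<stack '%s'> %s voxels @ %s um, range [%.3g, %.3g]\n",
              x$channel, paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Binary nuclear mask of a DAPI stack
#'
#' Thresholds the DAPI channel into a 0/1 mask used to suppress non-nuclear
#' signal (e.g. EdU saturation from the endoderm lumen). The Otsu threshold
#' is computed on the nonzero voxels; a constant image cannot be thresholded
#' automatically and raises an error suggesting `method = "fixed"`.
#'
#' @param dapi A [new_stack()] (DAPI channel).
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param level Threshold intensity for `method = "fixed"`.
#' @return A 0/1 `stack` named `"mask"`.
#' @export
binary_mask <- function(dapi, method = c("otsu", "fixed"), level = NULL) {
  method <- match.arg(method)
  v <- dapi$voxels
  if (length(v) == 0) abort("Empty stack.")
  if (method == "otsu") {
    nz <- v[v > 0]
    if (length(nz) == 0 || diff(range(nz)) == 0) {
      abort("Constant image: Otsu threshold undefined; use method = \"fixed\".")
    }
    level <- otsu_threshold(nz)
  } else if (is.null(level) || !is.numeric(level)) {
    abort("`level` is required for method = \"fixed\".")
  }
  new_stack((v >= level) * 1, dapi$voxel_size, "mask")
}

# Otsu threshold on raw intensities; EBImage's implementation when present
# (it is a Suggests dependency), otherwise the classical between-class
# variance maximiser on a 256-level histogram.
otsu_threshold <- function(x, levels = 256) {
  r <- range(x)
  u <- (x - r[1]) / diff(r)
  th <- if (requireNamespace("EBImage", quietly = TRUE)) {
    EBImage::otsu(matrix(u, ncol = 1), range = c(0, 1), levels = levels)
  } else {
    h <- tabulate(pmin(floor(u * levels), levels - 1) + 1, nbins = levels)
    p <- h / sum(h)
    omega <- cumsum(p)
    mu <- cumsum(p * seq_len(levels))
    mu_t <- mu[levels]
    sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
    sb[!is.finite(sb)] <- 0
    (which.max(sb) - 0.5) / levels
  }
  r[1] + th * diff(r)
}

#' Apply a binary mask to a channel
#'
#' Voxelwise product; intensities outside the mask become exactly 0.
#'
#' @param channel,mask `stack`s of identical dimensions.
#' @return The masked `stack`.
#' @export
mask_channel <- function(channel, mask) {
  if (!identical(dim(channel$voxels), dim(mask$voxels))) {
    abort("Channel and mask dimensions differ.")
  }
  new_stack(channel$voxels * mask$voxels, channel$voxel_size, channel$channel)
}

#' Detect nuclei in a masked stack
#'
#' Threshold, 26-connected component labelling, volume filter and
#' intensity-weighted centroids (um). Optional marker stacks give per-
#' detection marker calls by mean intensity within the component.
#'
#' @param masked A masked intensity `stack`.
#' @param min_volume Minimum component volume in voxels (default 5).
#' @param marker_stacks Named list of `stack`s (e.g. `list(edu = ..., phh3
#'   = ...)`).
#' @param threshold Detection threshold; `"otsu"` (default) or a number.
#' @param marker_threshold Mean intensity needed for a positive marker call;
#'   `"otsu"` (computed per marker channel) or a number.
#' @return Tibble: `id`, `x_um`, `y_um`, `z_um`, `volume`, `mean_intensity`,
#'   plus one logical column per marker stack. Zero rows if nothing detected.
#' @export
detect_nuclei <- function(masked, min_volume = 5, marker_stacks = list(),
                          threshold = "otsu", marker_threshold = "otsu") {
  v <- masked$voxels
  if (length(v) == 0) abort("Empty stack.")
  if (identical(threshold, "otsu")) {
    nz <- v[v > 0]
    if (length(nz) == 0 || diff(range(nz)) == 0) {
      return(empty_detections(marker_stacks))
    }
    threshold <- otsu_threshold(nz)
  }
  fg <- v >= threshold & v > 0
  if (!any(fg)) return(empty_detections(marker_stacks))
  lab <- label_components_3d(fg)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_volume)
  if (length(keep) == 0) return(empty_detections(marker_stacks))
  dims <- dim(v)
  vs <- masked$voxel_size
  rows <- lapply(seq_along(keep), function(j) {
    idx <- which(lab == keep[j])
    co <- arrayInd(idx, dims)
    w <- v[idx]
    ctr <- colSums(co * w) / sum(w)
    out <- tibble(id = j,
                  x_um = (ctr[1] - 0.5) * vs[1],
                  y_um = (ctr[2] - 0.5) * vs[2],
                  z_um = (ctr[3] - 0.5) * vs[3],
                  volume = length(idx),
                  mean_intensity = mean(w))
    for (mk in names(marker_stacks)) {
      out[[paste0("mean_", mk)]] <- mean(marker_stacks[[mk]]$voxels[idx])
    }
    out
  })
  det <- list_rbind(rows)
  for (mk in names(marker_stacks)) {
    mth <- marker_threshold
    if (identical(mth, "otsu")) {
      mv <- marker_stacks[[mk]]$voxels
      mnz <- mv[mv > 0]
      mth <- if (length(mnz) == 0 || diff(range(mnz)) == 0) Inf else
        otsu_threshold(mnz)
    }
    det[[mk]] <- det[[paste0("mean_", mk)]] >= mth
  }
  det
}

empty_detections <- function(marker_stacks) {
  out <- tibble(id = integer(), x_um = numeric(), y_um = numeric(),
                z_um = numeric(), volume = integer(), mean_intensity = numeric())
  for (mk in names(marker_stacks)) {
    out[[paste0("mean_", mk)]] <- numeric()
    out[[mk]] <- logical()
  }
  out
}

# 26-connectivity component labelling of a logical 3D array, breadth-first
# over foreground voxels. No installed package labels components in 3D, so
# this is done directly on linear indices.
label_components_3d <- function(fg) {
  dims <- dim(fg)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(off != 0) > 0, , drop = FALSE]
  lin_off <- off[, 1] + off[, 2] * nx + off[, 3] * nx * ny
  lab <- array(0L, dims)
  seeds <- which(fg)
  current <- 0L
  for (s in seeds) {
    if (lab[s] != 0L) next
    current <- current + 1L
    lab[s] <- current
    frontier <- s
    while (length(frontier) > 0) {
      co <- arrayInd(frontier, dims)
      cand <- rep(frontier, each = nrow(off)) + rep(lin_off, length(frontier))
      ci <- co[rep(seq_along(frontier), each = nrow(off)), , drop = FALSE] +
        off[rep(seq_len(nrow(off)), length(frontier)), , drop = FALSE]
      ok <- ci[, 1] >= 1 & ci[, 1] <= nx & ci[, 2] >= 1 & ci[, 2] <= ny &
        ci[, 3] >= 1 & ci[, 3] <= nz
      cand <- unique(cand[ok])
      cand <- cand[fg[cand] & lab[cand] == 0L]
      lab[cand] <- current
      frontier <- cand
    }
  }
  lab
}

#' Render a simulated embryo as synthetic 3D stacks
#'
#' Draws Gaussian nuclear blobs at the exported nucleus positions in a DAPI
#' channel, with EdU and PhH3 blobs only at flagged nuclei, then adds
#' Poisson shot noise and Gaussian read noise. Deterministic per seed. Used
#' for round-trip testing of the masking/detection stage.
#'
#' @param nuclei Nucleus table (needs `x_um`, `y_um`, `z_um`, `edu`, `phh3`).
#' @param nucleus_radius Gaussian sigma of a nucleus, um.
#' @param snr Peak signal over background noise standard deviation.
#' @param seed Integer seed.
#' @param voxel_size um per voxel (length 3).
#' @param field Optional list `list(origin = c(x,y,z), dim = c(nx,ny,nz))`;
#'   by default the field is fitted around the nuclei with a margin. Nuclei
#'   outside a requested field raise an error.
#' @return Named list of `stack`s: `dapi`, `edu`, `phh3`.
#' @export
render_embryo <- function(nuclei, nucleus_radius = 2, snr = 5, seed = 1L,
                          voxel_size = c(1, 1, 1), field = NULL) {
  if (nucleus_radius <= 0 || snr <= 0) abort("`nucleus_radius` and `snr` must be > 0.")
  margin <- 4 * nucleus_radius
  pos <- as.matrix(nuclei[, c("x_um", "y_um", "z_um")])
  if (is.null(field)) {
    origin <- if (nrow(pos) > 0) apply(pos, 2, min) - margin else c(0, 0, 0)
    extent <- if (nrow(pos) > 0) apply(pos, 2, max) + margin - origin else
      rep(20, 3)
    dims <- pmax(4L, ceiling(extent / voxel_size))
  } else {
    origin <- field$origin
    dims <- field$dim
    upper <- origin + dims * voxel_size
    if (nrow(pos) > 0 &&
        (any(t(pos) < origin + 1e-9) || any(t(pos) > upper - 1e-9))) {
      abort("Nuclei fall outside the requested field.")
    }
  }
  background <- 10
  sigma_bg <- sqrt(background + 1) # Poisson at background + read noise sd 1
  amp <- snr * sigma_bg
  blob <- function(flags) {
    a <- array(0, dims)
    sel <- which(flags)
    for (i in sel) {
      ctr <- (pos[i, ] - origin) / voxel_size + 0.5 # voxel coords of centre
      rng <- lapply(1:3, function(ax) {
        r <- 3 * nucleus_radius / voxel_size[ax]
        max(1, floor(ctr[ax] - r)):min(dims[ax], ceiling(ctr[ax] + r))
      })
      gx <- exp(-((rng[[1]] - ctr[1]) * voxel_size[1])^2 / (2 * nucleus_radius^2))
      gy <- exp(-((rng[[2]] - ctr[2]) * voxel_size[2])^2 / (2 * nucleus_radius^2))
      gz <- exp(-((rng[[3]] - ctr[3]) * voxel_size[3])^2 / (2 * nucleus_radius^2))
      a[rng[[1]], rng[[2]], rng[[3]]] <-
        a[rng[[1]], rng[[2]], rng[[3]]] + amp * outer(outer(gx, gy), gz)
    }
    a
  }
  with_seed(seed, {
    chans <- list(dapi = blob(rep(TRUE, nrow(pos))),
                  edu = blob(nuclei$edu),
                  phh3 = blob(nuclei$phh3))
    out <- lapply(names(chans), function(ch) {
      noisy <- rpois(length(chans[[ch]]), chans[[ch]] + background) +
        rnorm(length(chans[[ch]]), 0, 1)
      new_stack(array(pmax(noisy - background, 0), dims), voxel_size, ch)
    })
    setNames(out, names(chans))
  })
}

#' Read and write multi-page TIFF stacks
#'
#' One file per channel; pages are z slices. Intensities are stored as
#' 32-bit floats after scaling to `[0, 1]` by `scale` (kept in the stack on
#' read via the `scale` argument).
#'
#' @param x A `stack`.
#' @param path File path.
#' @param voxel_size Voxel size to attach on read (um).
#' @param scale Intensity scale: values are divided by it on write and
#'   multiplied back on read.
#' @param channel Channel name to attach on read.
#' @return `write_stack()` returns `path` invisibly; `read_stack()` returns
#'   a `stack`.
#' @export
write_stack <- function(x, path, scale = max(x$voxels, 1)) {
  if (max(x$voxels) > scale * (1 + 1e-9)) {
    abort("`scale` must be >= the maximum intensity (TIFF pages store [0, 1]).")
  }
  pages <- lapply(seq_len(dim(x$voxels)[3]), function(k) {
    t(x$voxels[, , k]) / scale # TIFF pages are row-major (y rows)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, voxel_size = c(1, 1, 1), channel = "",
                       scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- simplify2array(lapply(pages, t))
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1)
  new_stack(arr * scale, voxel_size, channel)
}
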