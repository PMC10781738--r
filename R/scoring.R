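#' Cross-correlation coefficient between two maps
#'
#' Zero-mean Pearson correlation of voxel intensities over a support voxel
#' set (default: all voxels). Both maps must share a grid.
#'
#' @param map_a,map_b [density_map()]s on identical grids.
#' @param support optional logical array (grid dimensions) or integer vector
#'   of linear voxel indices restricting the correlation.
#' @return Correlation in `[-1, 1]`; `NA` with a warning if either map has
#'   zero variance on the support.
#' @export
ccc <- function(map_a, map_b, support = NULL) {
  if (!identical(dim(map_a$values), dim(map_b$values)))
    stop_cf("maps must share a grid")
  a <- map_a$values
  b <- map_b$values
  if (!is.null(support)) {
    a <- a[support]
    b <- b[support]
  }
  if (length(a) < 2 || stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("CCC undefined: zero variance on the support", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(as.vector(a), as.vector(b))
}

## pad an array to a cube of edge m with zeros (corner-anchored)
.pad_cube <- function(v, m) {
  out <- array(0, c(m, m, m))
  d <- dim(v)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- v
  out
}

#' Fourier shell correlation
#'
#' Shell-wise normalised cross-correlation of the two maps' Fourier
#' transforms, with shells one reciprocal voxel wide. Non-cubic grids are
#' zero-padded to a cube; voxels must be isotropic.
#'
#' @param map_a,map_b [density_map()]s on identical grids with isotropic
#'   voxels.
#' @return Data frame with columns `shell` (integer radius in reciprocal
#'   voxels), `freq` (spatial frequency, 1/angstrom), `fsc` and `nvox`
#'   (voxels in the shell). Empty shells are skipped.
#' @export
fsc <- function(map_a, map_b) {
  if (!identical(dim(map_a$values), dim(map_b$values)))
    stop_cf("maps must share a grid")
  vs <- map_a$voxel_size
  if (max(vs) - min(vs) > 1e-9 * max(vs))
    stop_cf("fsc requires isotropic voxels")
  m <- max(dim(map_a$values))
  fa <- stats::fft(.pad_cube(map_a$values, m))
  fb <- stats::fft(.pad_cube(map_b$values, m))
  k <- c(0:(m %/% 2), -((m - m %/% 2 - 1):1))  # signed frequency indices
  k2 <- k^2
  r <- sqrt(outer(outer(k2, k2, "+"), k2, "+"))
  shell <- as.integer(round(r))
  num <- Re(fa * Conj(fb))
  pa <- Mod(fa)^2
  pb <- Mod(fb)^2
  smax <- m %/% 2
  keep <- shell <= smax & shell >= 1
  sn <- tapply(num[keep], shell[keep], sum)
  sa <- tapply(pa[keep], shell[keep], sum)
  sb <- tapply(pb[keep], shell[keep], sum)
  nv <- tapply(rep(1, sum(keep)), shell[keep], sum)
  s <- as.integer(names(sn))
  denom <- sqrt(sa * sb)
  ok <- is.finite(denom) & denom > 0
  data.frame(shell = s[ok], freq = s[ok] / (m * vs[1]),
             fsc = as.numeric(sn[ok] / denom[ok]),
             nvox = as.numeric(nv[ok]))
}

## soft-edged spherical mask values: 1 inside radius, raised-cosine falloff
## over `falloff` angstrom, 0 beyond
.soft_sphere <- function(r, radius, falloff) {
  w <- numeric(length(r))
  w[r <= radius] <- 1
  ramp <- r > radius & r < radius + falloff
  w[ramp] <- 0.5 * (1 + cos(pi * (r[ramp] - radius) / falloff))
  w
}

## first low-to-high-frequency crossing of `thr`, linearly interpolated in
## frequency; NA if the curve never drops below thr
.fsc_crossing <- function(curve, thr = 0.5) {
  f <- curve$fsc
  for (s in seq_along(f)[-1]) {
    if (f[s] < thr && f[s - 1] >= thr) {
      t <- (f[s - 1] - thr) / (f[s - 1] - f[s])
      return(curve$freq[s - 1] + t * (curve$freq[s] - curve$freq[s - 1]))
    }
  }
  if (f[1] < thr) return(curve$freq[1])
  NA_real_
}

## anchor atom per residue: CA for amino acids, C1' for nucleotides
.residue_anchors <- function(model) {
  a <- model$atoms
  sel <- a[a$atom_name %in% c("CA", "C1'"), , drop = FALSE]
  sel[!duplicated(paste(sel$chain_id, sel$residue_index)), , drop = FALSE]
}

#' Per-residue local-FSC fit score (LoQFit)
#'
#' For each residue, a soft-edged spherical mask of diameter five times the
#' global resolution, centred on the residue's C-alpha (C1' for
#' nucleotides), is applied to both the experimental map and a map simulated
#' from the full model; the score is the resolution (angstrom) at which the
#' masked FSC first crosses 0.5, linearly interpolated between shells.
#' Lower is better. Residues whose FSC never drops below 0.5 are censored
#' at the Nyquist resolution `2 * max(voxel_size)` (the best attainable
#' value).
#'
#' @param model an [atomic_model()] with C-alpha (or C1') atoms.
#' @param exp_map experimental [density_map()] with isotropic voxels.
#' @param global_resolution map resolution, angstrom; defaults to
#'   `exp_map$resolution`.
#' @param mask_falloff raised-cosine mask edge width, voxels (default 3).
#' @return A `local_score_track` data frame with columns `chain_id`,
#'   `residue_index`, `value` (angstrom) and `censored`.
#' @export
loqfit <- function(model, exp_map, global_resolution = exp_map$resolution,
                   mask_falloff = 3) {
  if (is.null(global_resolution))
    stop_cf("a global map resolution is required")
  vs <- exp_map$voxel_size
  if (max(vs) - min(vs) > 1e-9 * max(vs))
    stop_cf("loqfit requires isotropic voxels")
  vx <- vs[1]
  sim <- simulate_map(gmm_state(model), exp_map)
  nyq <- 2 * max(vs)
  radius <- 2.5 * global_resolution            # mask diameter = 5 x resolution
  fall <- mask_falloff * vx
  half <- ceiling((radius + fall) / vx) + 1
  n <- grid_dim(exp_map)
  anchors <- .residue_anchors(model)
  if (nrow(anchors) == 0)
    stop_cf("model has no CA/C1' anchor atoms")
  res <- lapply(seq_len(nrow(anchors)), function(k) {
    ctr <- c(anchors$x[k], anchors$y[k], anchors$z[k])
    ci <- round((ctr - exp_map$origin) / vs)
    lo <- pmax(ci - half, 0)
    hi <- pmin(ci + half, n - 1)
    sl <- lapply(1:3, function(a) (lo[a]:hi[a]) + 1)
    sub_e <- exp_map$values[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
    sub_s <- sim$values[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
    ax <- lapply(1:3, function(a) (lo[a]:hi[a]) * vs[a] +
                   exp_map$origin[a] - ctr[a])
    r <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+"))
    w <- array(.soft_sphere(r, radius, fall), dim(r))
    me <- density_map(sub_e * w, vs)
    ms <- density_map(sub_s * w, vs)
    if (all(me$values == 0) || all(ms$values == 0))
      return(data.frame(chain_id = anchors$chain_id[k],
                        residue_index = anchors$residue_index[k],
                        value = nyq, censored = TRUE))
    curve <- fsc(ms, me)
    fcross <- .fsc_crossing(curve, 0.5)
    if (is.na(fcross))
      data.frame(chain_id = anchors$chain_id[k],
                 residue_index = anchors$residue_index[k],
                 value = nyq, censored = TRUE)
    else
      data.frame(chain_id = anchors$chain_id[k],
                 residue_index = anchors$residue_index[k],
                 value = max(1 / fcross, nyq), censored = FALSE)
  })
  out <- do.call(rbind, res)
  structure(out, score_name = "LoQFit", class = c("local_score_track",
                                                  class(out)))
}

#' Per-residue windowed Manders overlap (SMOCf)
#'
#' For each residue, takes the contiguous window of `window_residues`
#' residues centred on it along its chain (truncated at the termini),
#' collects the voxels within `cutoff_sigma * bwidth` of the window's atoms,
#' and computes the Manders overlap coefficient
#' \eqn{\sum ab / \sqrt{\sum a^2 \sum b^2}} between the simulated and
#' experimental maps over that region.
#'
#' @param model an [atomic_model()].
#' @param exp_map experimental [density_map()].
#' @param window_residues odd window length in residues (default 9).
#' @return A `local_score_track` data frame with columns `chain_id`,
#'   `residue_index`, `value`.
#' @export
smocf <- function(model, exp_map, window_residues = 9) {
  if (window_residues %% 2 != 1)
    stop_cf("window_residues must be odd")
  state <- gmm_state(model)
  sim <- simulate_map(state, exp_map)
  a <- model$atoms
  half <- (window_residues - 1) %/% 2
  ## per-atom voxel blocks, reused across windows
  blocks <- lapply(seq_len(nrow(a)), function(i)
    .atom_block(exp_map, c(a$x[i], a$y[i], a$z[i]), a$bwidth[i],
                state$cutoff_sigma)$idx)
  out <- list()
  for (ch in unique(a$chain_id)) {
    resi <- sort(unique(a$residue_index[a$chain_id == ch]))
    for (j in seq_along(resi)) {
      win <- resi[max(1, j - half):min(length(resi), j + half)]
      rows <- which(a$chain_id == ch & a$residue_index %in% win)
      idx <- unique(unlist(blocks[rows]))
      va <- sim$values[idx]
      vb <- exp_map$values[idx]
      denom <- sqrt(sum(va^2) * sum(vb^2))
      out[[length(out) + 1L]] <- data.frame(
        chain_id = ch, residue_index = resi[j],
        value = if (denom > 0) sum(va * vb) / denom else 0)
    }
  }
  out <- do.call(rbind, out)
  structure(out, score_name = "SMOCf", class = c("local_score_track",
                                                 class(out)))
}

#' Write a per-residue score track as CSV
#'
#' @param track a `local_score_track` from [loqfit()] or [smocf()].
#' @param path output CSV path (columns chain, resi, score).
#' @return Invisibly, `path`.
#' @export
write_score_track <- function(track, path) {
  utils::write.csv(data.frame(chain = track$chain_id,
                              resi = track$residue_index,
                              score = track$value),
                   path, row.names = FALSE)
  invisible(path)
}
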