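## Shared fixtures and independent oracles for the test suite. The oracles
## deliberately re-implement the quantities with plain scalar loops (or raw
## byte-level I/O) so they share no code path with the package internals
## they check.

## small memoised toy systems -------------------------------------------------
.fx_cache <- new.env(parent = emptyenv())

fx_toy <- function(n_residues = 6, seed = 2, ...) {
  key <- paste0("toy_", n_residues, "_", seed, "_",
                paste(unlist(list(...)), collapse = "_"))
  if (is.null(.fx_cache[[key]]))
    .fx_cache[[key]] <- make_toy_model(toy_spec(n_residues = n_residues,
                                                seed = seed, ...))
  .fx_cache[[key]]
}

## a single-atom model at an arbitrary off-lattice position
fx_atom <- function(x = 0.3, y = -0.2, z = 0.15, b = 1.2, zn = 6,
                    name = "CA") {
  atomic_model(data.frame(
    element = "C", atomic_number = zn, chain_id = "A", residue_index = 1L,
    residue_name = "ALA", atom_name = name, x = x, y = y, z = z,
    bwidth = b))
}

## n-atom model from explicit positions/widths
fx_model <- function(xyz, b, zn = NULL, chain = "A") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  zn <- zn %||% rep(6, n)
  atomic_model(data.frame(
    element = c("C", "N", "O")[(seq_len(n) - 1) %% 3 + 1],
    atomic_number = zn, chain_id = chain,
    residue_index = seq_len(n), residue_name = "ALA",
    atom_name = rep("CA", n), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    bwidth = rep_len(b, n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## brute-force M-step oracle --------------------------------------------------
## dense scalar loops over every voxel, no cutoff (callers use states whose
## cutoff covers the whole grid so the implementation sees the same voxels)
oracle_mstep <- function(state, exp_map) {
  a <- state$model$atoms
  n <- dim(exp_map$values)
  E <- state$background
  norm <- if (is.null(state$normalise)) TRUE else isTRUE(state$normalise)
  npos <- matrix(0, nrow(a), 3)
  nb <- numeric(nrow(a))
  ## per-voxel coordinates
  ms_at <- function(px, py, pz) {
    s <- E
    for (i in seq_len(nrow(a))) {
      d2 <- (px - a$x[i])^2 + (py - a$y[i])^2 + (pz - a$z[i])^2
      amp <- if (norm) a$atomic_number[i] / (pi^1.5 * a$bwidth[i]^3)
             else a$atomic_number[i]
      s <- s + amp * exp(-d2 / a$bwidth[i]^2)
    }
    s
  }
  sw <- numeric(nrow(a))
  sx <- matrix(0, nrow(a), 3)
  sv <- numeric(nrow(a))
  werr_sum <- 0
  nvox <- 0
  for (iz in 0:(n[3] - 1)) for (iy in 0:(n[2] - 1)) for (ix in 0:(n[1] - 1)) {
    px <- ix * exp_map$voxel_size[1] + exp_map$origin[1]
    py <- iy * exp_map$voxel_size[2] + exp_map$origin[2]
    pz <- iz * exp_map$voxel_size[3] + exp_map$origin[3]
    ms <- ms_at(px, py, pz)
    me <- exp_map$values[ix + 1, iy + 1, iz + 1]
    nvox <- nvox + 1
    werr_sum <- werr_sum + me * E / ms
    for (i in seq_len(nrow(a))) {
      d2 <- (px - a$x[i])^2 + (py - a$y[i])^2 + (pz - a$z[i])^2
      amp <- if (norm) a$atomic_number[i] / (pi^1.5 * a$bwidth[i]^3)
             else a$atomic_number[i]
      g <- amp * exp(-d2 / a$bwidth[i]^2) / ms
      w <- me * g
      sw[i] <- sw[i] + w
      sx[i, ] <- sx[i, ] + w * c(px, py, pz)
      sv[i] <- sv[i] + w * d2
    }
  }
  for (i in seq_len(nrow(a))) {
    npos[i, ] <- sx[i, ] / sw[i]
    nb[i] <- sqrt(2 / 3 * sv[i] / sw[i])
  }
  list(positions = npos, bwidths = nb, background = werr_sum / nvox)
}

## independent raw-byte MRC reader (fixed canonical axis order assumed)
oracle_read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ints <- readBin(con, "integer", 256, size = 4, endian = "little")
  seek(con, 0)
  dbls <- readBin(con, "numeric", 256, size = 4, endian = "little")
  n <- ints[1:3]
  seek(con, 1024 + ints[24])
  vals <- readBin(con, "numeric", prod(n), size = 4, endian = "little")
  list(dim = n, mode = ints[4], mapcrs = ints[17:19],
       cella = dbls[11:13], origin = dbls[50:52],
       dmin = dbls[20], dmax = dbls[21], dmean = dbls[22],
       values = array(vals, n))
}

## independent raw-byte MRC writer, with arbitrary axis permutation:
## `mapcrs[d]` is the crystallographic axis stored along file dimension d
oracle_write_mrc <- function(values_xyz, voxel, origin, path,
                             mapcrs = c(1, 2, 3)) {
  stored <- aperm(values_xyz, mapcrs)   # stored dim d runs along axis mapcrs[d]
  nxyz_store <- dim(stored)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(nxyz_store); wi(2L); wi(c(0L, 0L, 0L))
  wi(dim(values_xyz))                       # mx,my,mz follow x,y,z
  wf(dim(values_xyz) * voxel); wf(c(90, 90, 90))
  wi(mapcrs)
  wf(c(min(values_xyz), max(values_xyz), mean(values_xyz)))
  wi(1L); wi(0L); wi(integer(25))
  wf(origin)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  wf(0); wi(0L)
  writeBin(raw(800), con)
  wf(as.vector(stored))
}

## central finite-difference gradient of f: R^(n*3) -> R at x (n x 3)
fd_gradient <- function(f, x, h = 1e-5) {
  g <- matrix(0, nrow(x), 3)
  for (i in seq_len(nrow(x))) for (j in 1:3) {
    xp <- x; xp[i, j] <- xp[i, j] + h
    xm <- x; xm[i, j] <- xm[i, j] - h
    g[i, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

## total responsibility per supported voxel (for conservation checks)
resp_total <- function(rf) {
  tot <- numeric(prod(rf$dim))
  tot[rf$support] <- rf$gamma_err
  for (i in seq_along(rf$atom_idx))
    tot[rf$atom_idx[[i]]] <- tot[rf$atom_idx[[i]]] + rf$atom_gamma[[i]]
  tot[rf$support]
}
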