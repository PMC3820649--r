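#' Hounsfield-unit mixture parameters for the lung phantom
#'
#' The phantom renders lung parenchyma as a two-component Gaussian mixture:
#' aerated parenchyma (air-filled alveoli, low density) and consolidated
#' tissue (alveoli replaced by cells and collagen, soft-tissue density).
#' Defaults place aerated lung at -500 HU and consolidation at +100 HU with
#' equal 80-HU spread, so that at a 50/50 mix the two components are
#' symmetric about -200 HU and the lung median sits on the conventional
#' fibrosis threshold.
#'
#' @param mu_aerated,sigma_aerated mean and SD (HU) of aerated parenchyma.
#' @param mu_consolidated,sigma_consolidated mean and SD (HU) of
#'   consolidated tissue; must satisfy `mu_consolidated > mu_aerated`.
#' @return A `mixture_params` list.
#' @export
mixture_params <- function(mu_aerated = -500, sigma_aerated = 80,
                           mu_consolidated = 100, sigma_consolidated = 80) {
  if (sigma_aerated <= 0 || sigma_consolidated <= 0)
    stop("mixture standard deviations must be positive", call. = FALSE)
  if (mu_consolidated <= mu_aerated)
    stop("consolidated tissue must be denser than aerated lung", call. = FALSE)
  structure(list(mu_aerated = mu_aerated, sigma_aerated = sigma_aerated,
                 mu_consolidated = mu_consolidated,
                 sigma_consolidated = sigma_consolidated),
            class = "mixture_params")
}

#' Fibrosis stage of the phantom
#'
#' A stage is a timepoint (weeks post-irradiation) plus the fraction of the
#' irradiated lung rendered as consolidated tissue and the number of seed
#' points the patchy consolidation is grown from.
#'
#' @param week integer timepoint, conventionally in `{0, 8, 12, 16, 20}`.
#' @param consolidation_fraction fraction in `[0, 1]` of lung voxels
#'   rendered from the consolidated mixture component.
#' @param n_patch_seeds number of region-growing seeds (>= 1).
#' @export
stage_params <- function(week, consolidation_fraction, n_patch_seeds = 5L) {
  if (consolidation_fraction < 0 || consolidation_fraction > 1)
    stop("consolidation_fraction must lie in [0, 1]", call. = FALSE)
  if (n_patch_seeds < 1) stop("n_patch_seeds must be >= 1", call. = FALSE)
  structure(list(week = as.integer(week),
                 consolidation_fraction = consolidation_fraction,
                 n_patch_seeds = as.integer(n_patch_seeds)),
            class = "stage_params")
}

#' Default stage table for the 0-20 week fibrosis trajectory
#'
#' Consolidation fractions by week, calibrated so the default mixture
#' reproduces the canonical densitometric landmarks: an unirradiated lung
#' with median HU near -500 and V_-200 well under 5%, V_-200 still under
#' 10% at 12 weeks, a half-consolidated lung at 16 weeks (median HU -200,
#' V_-200 50%), and near-total opacification at 20 weeks.
#'
#' @return data.frame with columns `week` and `consolidation_fraction`.
#' @export
default_stage_table <- function() {
  data.frame(week = c(0L, 8L, 12L, 16L, 20L),
             consolidation_fraction = c(0.00, 0.03, 0.08, 0.50, 0.95))
}

#' Stage parameters for a given week of the default trajectory
#' @param week one of the weeks in [default_stage_table()].
#' @param n_patch_seeds passed to [stage_params()].
#' @export
default_stage <- function(week, n_patch_seeds = 5L) {
  tab <- default_stage_table()
  i <- match(as.integer(week), tab$week)
  if (is.na(i))
    stop(sprintf("no default stage for week %s; available: %s",
                 week, paste(tab$week, collapse = ", ")), call. = FALSE)
  stage_params(tab$week[i], tab$consolidation_fraction[i], n_patch_seeds)
}

#' Phantom configuration
#'
#' Describes one synthetic thoracic CT acquisition: grid, voxel spacing,
#' HU mixture, fibrosis stage, which lung was irradiated, and the RNG seed.
#'
#' @param grid_shape 3 positive integers (voxels); every axis must be at
#'   least 32 so the two lung ellipsoids fit.
#' @param spacing_mm 3 positive voxel edge lengths in mm (mouse-scale
#'   default 0.25 mm isotropic).
#' @param mixture a [mixture_params()] object.
#' @param stage a [stage_params()] object.
#' @param irradiated_side `"right"`, `"left"` or `"both"`.
#' @param rng_seed integer seed, or `NULL` to draw from the current RNG
#'   stream (used when a cohort generator manages one stream for many
#'   phantoms).
#' @export
phantom_config <- function(grid_shape = c(128L, 128L, 96L),
                           spacing_mm = c(0.25, 0.25, 0.25),
                           mixture = mixture_params(),
                           stage = stage_params(0L, 0),
                           irradiated_side = c("right", "left", "both"),
                           rng_seed = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 32L))
    stop("grid too small: each axis must be >= 32 voxels to fit two lungs",
         call. = FALSE)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive reals", call. = FALSE)
  irradiated_side <- match.arg(irradiated_side)
  stopifnot(inherits(mixture, "mixture_params"), inherits(stage, "stage_params"))
  structure(list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
                 mixture = mixture, stage = stage,
                 irradiated_side = irradiated_side,
                 rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)),
            class = "phantom_config")
}

# mask labels targeted by an irradiated_side setting
side_labels <- function(side) {
  switch(side, right = 1L, left = 2L, both = c(1L, 2L))
}

#' Generate the thoracic geometry: body, two lungs, labels
#'
#' Builds the deterministic anatomy underlying a phantom: air background at
#' -1000 HU, a soft-tissue body cylinder at +40 HU, and two ellipsoidal
#' lung fields (labels 1 = right, 2 = left) filled with the aerated-lung
#' mean as a noise-free baseline. Lung size scales with the grid, giving
#' roughly 1e5 voxels per lung at the default 128 x 128 x 96 grid.
#'
#' @param config a [phantom_config()].
#' @return list with elements `volume` (a [voxel_volume()]) and `mask`
#'   (a [lung_mask()]).
#' @export
generate_lung_geometry <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  d <- config$grid_shape
  nx <- d[1]; ny <- d[2]; nz <- d[3]

  # body: elliptical cylinder along z
  xs <- seq_len(nx); ys <- seq_len(ny); zs <- seq_len(nz)
  cxb <- (nx + 1) / 2; cyb <- (ny + 1) / 2
  bx2 <- ((xs - cxb) / (0.44 * nx))^2
  by2 <- ((ys - cyb) / (0.345 * ny))^2
  body2d <- outer(bx2, by2, "+") <= 1

  # lungs: two ellipsoids inside the body
  ax <- 0.17 * nx; ay <- 0.235 * ny; az <- 0.40 * nz
  cz <- (nz + 1) / 2
  lung_field <- function(cx) {
    dx2 <- ((xs - cx) / ax)^2
    dy2 <- ((ys - cyb) / ay)^2
    dz2 <- ((zs - cz) / az)^2
    outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
  }
  right <- lung_field(0.28 * nx)   # subject right = image left, label 1
  left  <- lung_field(0.72 * nx)

  mask <- array(0L, dim = d)
  mask[right] <- 1L
  mask[left]  <- 2L

  if (sum(right) < 100L || sum(left) < 100L)
    stop("grid too small to fit lung geometry", call. = FALSE)

  vol <- array(-1000, dim = d)
  body3d <- array(rep(body2d, nz), dim = d)
  vol[body3d] <- 40
  vol[mask > 0L] <- config$mixture$mu_aerated

  list(volume = voxel_volume(vol, config$spacing_mm),
       mask = lung_mask(mask, config$spacing_mm))
}

#' Grow a patchy consolidation map inside one lung
#'
#' Flags exactly `ceiling(f * N)` voxels of the target lung (N = its voxel
#' count) as consolidated, by stochastic region growing: `n_seeds` seed
#' voxels are drawn uniformly from the lung, then voxels are accreted one
#' at a time from a shared frontier (6-connectivity), with the next voxel
#' chosen uniformly at random among frontier candidates. The flagged set is
#' therefore a union of connected patches contained in the target lung,
#' with an exactly prescribed voxel count. Should the frontier empty before
#' the count is reached (possible only for disconnected masks), growth
#' restarts from a fresh uniformly drawn unflagged lung voxel.
#'
#' Uses the current RNG stream; seed it (or use [generate_phantom()]) for
#' reproducibility.
#'
#' @param mask a [lung_mask()].
#' @param side lung label to consolidate (1 = right, 2 = left).
#' @param f fraction in `[0, 1]` of the lung to consolidate.
#' @param n_seeds number of seed points (>= 1).
#' @return logical 3D array, `TRUE` at consolidated voxels.
#' @export
grow_consolidation <- function(mask, side, f, n_seeds = 5L) {
  if (f < 0 || f > 1) stop("f must lie in [0, 1]", call. = FALSE)
  if (n_seeds < 1) stop("n_seeds must be >= 1", call. = FALSE)
  d <- dim(mask)
  target <- which(mask == as.integer(side))
  if (length(target) == 0L)
    stop(sprintf("mask contains no voxels with label %s", side), call. = FALSE)

  N <- length(target)
  k <- ceiling(f * N)
  flagged <- array(FALSE, dim = d)
  if (k == 0L) return(flagged)
  if (k == N) { flagged[target] <- TRUE; return(flagged) }

  nx <- d[1]; nxy <- d[1] * d[2]
  in_target <- logical(prod(d)); in_target[target] <- TRUE
  done <- logical(prod(d))

  frontier <- target[sample.int(N, min(n_seeds, N))]
  fl <- length(frontier)
  length(frontier) <- max(4096L, fl)
  count <- 0L
  ny <- d[2]; nz <- d[3]

  while (count < k) {
    if (fl == 0L) {
      remaining <- target[!done[target]]
      frontier[1L] <- remaining[sample.int(length(remaining), 1L)]
      fl <- 1L
    }
    j <- sample.int(fl, 1L)
    v <- frontier[j]; frontier[j] <- frontier[fl]; fl <- fl - 1L
    if (done[v]) next
    done[v] <- TRUE
    count <- count + 1L

    i0 <- v - 1L
    x <- i0 %% nx
    y <- (i0 %/% nx) %% ny
    z <- i0 %/% nxy
    nb <- c(if (x > 0L) v - 1L, if (x < nx - 1L) v + 1L,
            if (y > 0L) v - nx, if (y < ny - 1L) v + nx,
            if (z > 0L) v - nxy, if (z < nz - 1L) v + nxy)
    nb <- nb[in_target[nb] & !done[nb]]
    nn <- length(nb)
    if (nn > 0L) {
      if (fl + nn > length(frontier))
        length(frontier) <- 2L * (fl + nn)
      frontier[(fl + 1L):(fl + nn)] <- nb
      fl <- fl + nn
    }
  }
  flagged[which(done)] <- TRUE
  flagged
}

#' Render Hounsfield units over a geometry
#'
#' Replaces lung voxels of the baseline geometry with draws from the HU
#' mixture: aerated voxels iid Normal(mu_aerated, sigma_aerated),
#' consolidated voxels iid Normal(mu_consolidated, sigma_consolidated).
#' Non-lung voxels are untouched, and all values are clamped to the 12-bit
#' CT range [-1024, 3071]. Uses the current RNG stream.
#'
#' @param geometry baseline [voxel_volume()] from [generate_lung_geometry()].
#' @param mask matching [lung_mask()].
#' @param consolidation logical array flagging consolidated lung voxels.
#' @param mixture a [mixture_params()].
#' @return a [voxel_volume()] of rendered HU.
#' @export
render_hu <- function(geometry, mask, consolidation, mixture = mixture_params()) {
  check_same_grid(geometry, mask)
  if (!identical(dim(consolidation), dim(mask)))
    stop("consolidation map does not match the mask grid", call. = FALSE)
  lung <- mask > 0L
  if (any(consolidation & !lung))
    stop("consolidation map leaks outside the lung mask", call. = FALSE)
  aer <- which(lung & !consolidation)
  con <- which(consolidation)
  out <- unclass(geometry)
  out[aer] <- stats::rnorm(length(aer), mixture$mu_aerated, mixture$sigma_aerated)
  out[con] <- stats::rnorm(length(con), mixture$mu_consolidated,
                           mixture$sigma_consolidated)
  out <- pmin(pmax(out, -1024), 3071)
  voxel_volume(out, spacing(geometry))
}

#' Generate a complete phantom in one call
#'
#' Builds the geometry, grows the stage's consolidation in the irradiated
#' lung(s), and renders HU noise. With a fixed `rng_seed` in the config the
#' output is bit-reproducible.
#'
#' @param config a [phantom_config()].
#' @return list of class `ct_phantom` with `volume`, `mask`,
#'   `consolidation`, and the `config`.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  geom <- generate_lung_geometry(config)
  cons <- array(FALSE, dim = config$grid_shape)
  for (lab in side_labels(config$irradiated_side)) {
    cons <- cons | grow_consolidation(geom$mask, lab,
                                      config$stage$consolidation_fraction,
                                      config$stage$n_patch_seeds)
  }
  vol <- render_hu(geom$volume, geom$mask, cons, config$mixture)
  structure(list(volume = vol, mask = geom$mask, consolidation = cons,
                 config = config),
            class = "ct_phantom")
}

#' @export
print.ct_phantom <- function(x, ...) {
  cat(sprintf("<ct_phantom> week %d, f = %.2f, irradiated side: %s\n",
              x$config$stage$week, x$config$stage$consolidation_fraction,
              x$config$irradiated_side))
  print(x$volume)
  invisible(x)
}
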