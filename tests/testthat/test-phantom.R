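test_that("lung geometry has the promised anatomy", {
  cfg <- tiny_config()
  g <- generate_lung_geometry(cfg)

  expect_setequal(unique(as.vector(g$mask)), c(0L, 1L, 2L))
  expect_gt(sum(g$mask == 1L), 0)
  expect_gt(sum(g$mask == 2L), 0)
  expect_identical(dim(g$volume), dim(g$mask))
  expect_equal(spacing(g$volume), spacing(g$mask))
  # background is air, body is soft tissue
  expect_equal(min(g$volume), -1000)
  expect_true(any(g$volume == 40))
})

test_that("default-grid lungs are large enough for densitometry", {
  g <- cached_phantom(0L)
  expect_gte(sum(g$mask == 1L), 10000)
  expect_gte(sum(g$mask == 2L), 10000)
})

test_that("every lung voxel lies inside the body cylinder", {
  cfg <- tiny_config()
  g <- generate_lung_geometry(cfg)
  d <- dim(g$mask)
  # brute-force containment scan against the analytic cylinder
  idx <- which(g$mask > 0L, arr.ind = TRUE)
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  r2 <- ((idx[, 1] - cx) / (0.44 * d[1]))^2 + ((idx[, 2] - cy) / (0.345 * d[2]))^2
  expect_true(all(r2 <= 1))
  # equivalently, lung voxels never sit on background air
  base <- generate_lung_geometry(cfg)$volume
  expect_true(all(base[g$mask > 0L] != -1000))
})

test_that("a too-small grid raises a geometry error", {
  expect_error(phantom_config(grid_shape = c(16L, 16L, 16L)), "grid too small")
})

test_that("phantom generation is bit-reproducible under a fixed seed", {
  cfg <- tiny_config(week = 16L, seed = 123L)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(as.vector(a$volume), as.vector(b$volume))
  expect_identical(a$consolidation, b$consolidation)
})

test_that("consolidation growth flags exactly ceiling(f * N) voxels", {
  cfg <- tiny_config()
  g <- generate_lung_geometry(cfg)
  N <- sum(g$mask == 1L)
  set.seed(5)
  for (f in c(0, 0.001, 0.1, 0.25, 0.5, 0.999, 1)) {
    cons <- grow_consolidation(g$mask, 1L, f, 3L)
    expect_identical(sum(cons), as.integer(ceiling(f * N)))
    expect_true(all(g$mask[cons] == 1L))  # flagged subset of target lung
  }
})

test_that("flagged regions are 6-connected components reachable from within", {
  cfg <- tiny_config()
  g <- generate_lung_geometry(cfg)
  set.seed(9)
  cons <- grow_consolidation(g$mask, 1L, 0.25, 3L)
  # flood-fill oracle: every flagged voxel must be reachable from some
  # flagged voxel through 6-connected flagged neighbours, in <= n_seeds
  # components
  d <- dim(cons)
  flagged <- which(cons)
  comp <- rep(0L, length(cons))
  n_comp <- 0L
  nx <- d[1]; ny <- d[2]; nxy <- d[1] * d[2]; nz <- d[3]
  neighbours <- function(v) {
    i0 <- v - 1L
    x <- i0 %% nx; y <- (i0 %/% nx) %% ny; z <- i0 %/% nxy
    c(if (x > 0L) v - 1L, if (x < nx - 1L) v + 1L,
      if (y > 0L) v - nx, if (y < ny - 1L) v + nx,
      if (z > 0L) v - nxy, if (z < nz - 1L) v + nxy)
  }
  for (s in flagged) {
    if (comp[s] > 0L) next
    n_comp <- n_comp + 1L
    queue <- s; comp[s] <- n_comp
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- neighbours(v)
      nb <- nb[cons[nb] & comp[nb] == 0L]
      comp[nb] <- n_comp
      queue <- c(queue, nb)
    }
  }
  expect_lte(n_comp, 3L)  # grown from 3 seeds; patches may merge
  expect_identical(sort(which(comp > 0L)), sort(flagged))
})

test_that("growth rejects invalid fractions and absent labels", {
  cfg <- tiny_config()
  g <- generate_lung_geometry(cfg)
  expect_error(grow_consolidation(g$mask, 1L, -0.1), "\\[0, 1\\]")
  expect_error(grow_consolidation(g$mask, 1L, 1.1), "\\[0, 1\\]")
  expect_error(grow_consolidation(g$mask, 7L, 0.5), "label 7")
})

test_that("HU rendering touches only lung voxels and clamps to CT range", {
  cfg <- tiny_config()
  g <- generate_lung_geometry(cfg)
  set.seed(3)
  cons <- grow_consolidation(g$mask, 1L, 0.5, 3L)
  v <- render_hu(g$volume, g$mask, cons, mixture_params())
  outside <- g$mask == 0L
  expect_identical(as.vector(v)[outside], as.vector(g$volume)[outside])
  expect_gte(min(v), -1024)
  expect_lte(max(v), 3071)
  # extreme mixture values are clamped
  set.seed(3)
  v2 <- render_hu(g$volume, g$mask, cons,
                  mixture_params(mu_aerated = -5000, sigma_aerated = 1,
                                 mu_consolidated = 9000, sigma_consolidated = 1))
  expect_identical(min(v2), -1024)
  expect_identical(max(v2), 3071)
})

test_that("rendered aerated lung matches its mean in the small-noise limit", {
  cfg <- tiny_config()
  g <- generate_lung_geometry(cfg)
  cons <- array(FALSE, dim = dim(g$mask))
  set.seed(2)
  v <- render_hu(g$volume, g$mask, cons,
                 mixture_params(sigma_aerated = 1e-6))
  expect_equal(unique(round(v[g$mask > 0L], 3)), -500)
})

test_that("rendered lung mean obeys the law of large numbers", {
  ph <- cached_phantom(0L)  # f = 0: all aerated, >= 1e5 lung voxels
  hu <- ph$volume[ph$mask == 1L]
  expect_gte(length(hu), 1e5)
  expect_lt(abs(mean(hu) - (-500)), 3)  # 3 HU ~ 12 * sigma / sqrt(n)
})

test_that("a half-consolidated lung is bimodal near the component means", {
  ph <- cached_phantom(16L)
  hu <- ph$volume[ph$mask == 1L]
  dens <- density(hu, bw = 30, n = 1024)
  y <- dens$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  # keep prominent modes only
  peaks <- peaks[y[peaks] > 0.25 * max(y)]
  modes <- dens$x[peaks]
  expect_length(modes, 2L)
  expect_lt(abs(modes[1] - (-500)), 40)
  expect_lt(abs(modes[2] - 100), 40)
})

test_that("lung HU tails follow the analytic mixture law", {
  ph <- cached_phantom(16L)
  hu <- ph$volume[ph$mask == 1L]
  n <- length(hu)
  expect_gte(n, 1e5)
  f_actual <- sum(ph$consolidation[ph$mask == 1L]) / n
  for (T in c(-400, -300, -200, -100, 0)) {
    p <- mixture_tail(T, f_actual)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(hu >= T) - p), 3 * se + 1e-12)
  }
})

test_that("mixture and stage parameter invariants are enforced", {
  expect_error(mixture_params(sigma_aerated = 0), "positive")
  expect_error(mixture_params(mu_consolidated = -600), "denser")
  expect_error(stage_params(0L, 1.2), "\\[0, 1\\]")
  expect_error(default_stage(5L), "no default stage")
  tab <- default_stage_table()
  expect_true(all(diff(tab$consolidation_fraction) >= 0))  # f non-decreasing
})
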