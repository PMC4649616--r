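test_that("initialization respects the box and conserves volume", {
  cfg <- sim_config(n_particles = 1000, seed = 5)
  set.seed(cfg$seed)
  st <- init_state(cfg)
  r <- radius_from_volume(st$volumes)
  expect_true(all(st$positions >= r - 1e-9))
  expect_true(all(st$positions <= cfg$box_side - r + 1e-9))
  expect_lte(nrow(st$positions), 1000)
  # volume conserved through initial overlap resolution
  set.seed(cfg$seed)
  v0 <- sum(sample_powerlaw_volumes(1000, cfg$exponent, cfg$v_min, cfg$v_max))
  expect_equal(sum(st$volumes), v0, tolerance = 1e-9)
  # single particle anywhere in the box
  st1 <- init_state(sim_config(n_particles = 1, seed = 3))
  expect_equal(nrow(st1$positions), 1L)
  # position marginal roughly uniform per axis (chi-square, 10 bins)
  cfg_nf <- sim_config(n_particles = 2000, fusion = FALSE, v_min = 0.5,
                       v_max = 0.6, seed = 8)
  set.seed(8)
  stu <- init_state(cfg_nf)
  for (j in 1:2) {
    cnt <- table(cut(stu$positions[, j], seq(1, 399, length.out = 11)))
    expect_gt(stats::chisq.test(cnt)$p.value, 1e-4)
  }
})

test_that("fusion conserves volume and merges chains", {
  # two touching equal spheres merge at the midpoint with volume 2V
  V <- volume_from_radius(2)
  st <- gravicreep:::.sim_state(rbind(c(100, 100), c(103.9, 100)), c(V, V), 0)
  out <- resolve_fusions(st, 400)
  expect_equal(nrow(out$positions), 1L)
  expect_equal(out$volumes, 2 * V)
  expect_equal(unname(out$positions[1, ]), c(101.95, 100))
  # chain of three mutually overlapping bodies collapses to one
  st3 <- gravicreep:::.sim_state(rbind(c(100, 100), c(103, 100), c(106, 100)),
                                 rep(V, 3), 0)
  out3 <- resolve_fusions(st3, 400)
  expect_equal(nrow(out3$positions), 1L)
  expect_equal(out3$volumes, 3 * V, tolerance = 1e-12)
  # no overlaps: identity
  far <- gravicreep:::.sim_state(rbind(c(50, 50), c(300, 300)), c(V, V), 0)
  expect_equal(resolve_fusions(far, 400), far)
  # no overlapping pair persists after resolution on a crowded instance
  set.seed(4)
  pos <- cbind(runif(200, 10, 390), runif(200, 10, 390))
  stc <- gravicreep:::.sim_state(pos, rep(volume_from_radius(8), 200), 0)
  res <- resolve_fusions(stc, 400)
  rr <- radius_from_volume(res$volumes)
  if (nrow(res$positions) > 1) {
    d <- as.matrix(dist(res$positions))
    gap <- d - outer(rr, rr, `+`)
    diag(gap) <- Inf
    expect_true(all(gap >= -1e-9))
  }
  expect_equal(sum(res$volumes), sum(stc$volumes), tolerance = 1e-9)
})

test_that("deterministic drift matches the Stokes velocity at T = 0", {
  V <- volume_from_radius(3)
  cfg <- sim_config(n_particles = 1, temperature = 0, g_multiple = 100,
                    v_min = V * 0.999, v_max = V * 1.001, fusion = FALSE,
                    dt = 1, t_end = 10, seed = 1)
  st <- gravicreep:::.sim_state(rbind(c(200, 300)), V, 0)
  v_expect <- stokes_velocity(stokes_context(3, cfg$delta_rho,
                                             100, cfg$eta1))
  st1 <- sim_step(st, cfg)
  expect_equal(st$positions[1, 2] - st1$positions[1, 2], v_expect,
               tolerance = 1e-12)
  expect_equal(st1$positions[1, 1], 200)
  # T = 0, g = 0: state unchanged
  cfg0 <- sim_config(n_particles = 1, temperature = 0, g_multiple = 0,
                     fusion = FALSE, dt = 1, seed = 1)
  expect_equal(sim_step(st, cfg0)$positions, st$positions)
})

test_that("ensemble MSD matches 4 D t at g = 0", {
  V <- volume_from_radius(1)
  cfg <- sim_config(n_particles = 2500, g_multiple = 0, fusion = FALSE,
                    v_min = V * 0.9999, v_max = V * 1.0001, eta1 = 0.01,
                    box_side = 4000, dt = 5, t_end = 20, seed = 6)
  set.seed(6)
  st <- init_state(cfg)
  # keep particles far from walls so reflections do not truncate the MSD
  st$positions[] <- 2000
  pos0 <- st$positions
  n_steps <- 4
  for (i in seq_len(n_steps)) st <- sim_step(st, cfg)
  disp2 <- rowSums((st$positions - pos0)^2)
  D <- thermal_energy(cfg$temperature) / stokes_drag(1, cfg$eta1)
  expect_equal(mean(disp2), 4 * D * (n_steps * cfg$dt), tolerance = 0.05)
})

test_that("recommended timestep bounds per-step displacement", {
  cfg <- sim_config(g_multiple = 1, seed = 1)
  dt <- recommended_timestep(cfg)
  expect_gt(dt, 0)
  for (V in c(cfg$v_min, cfg$v_max)) {
    R <- radius_from_volume(V)
    drift <- gravitational_force(V, cfg$delta_rho, cfg$g_multiple) /
      stokes_drag(R, cfg$eta1) * dt
    brown <- 3 * sqrt(2 * thermal_energy(cfg$temperature) /
                        stokes_drag(R, cfg$eta1) * dt)
    expect_lt(drift + brown, 2 * R)
  }
  # direct check: simulate the fastest particle at T = 0 for one step
  cfg_hi <- sim_config(g_multiple = 1000, temperature = 0, fusion = FALSE,
                       seed = 1)
  dt_hi <- recommended_timestep(cfg_hi)
  Rmax <- radius_from_volume(cfg_hi$v_max)
  st <- gravicreep:::.sim_state(rbind(c(200, 300)), cfg_hi$v_max, 0)
  st1 <- sim_step(st, cfg_hi, dt_hi)
  expect_lt(abs(st$positions[1, 2] - st1$positions[1, 2]), 2 * Rmax)
  # doubling g at least halves dt in the drift-dominated regime
  cfg_2g <- sim_config(g_multiple = 2000, temperature = 0, seed = 1)
  expect_lte(recommended_timestep(cfg_2g), dt_hi / 2 + 1e-12)
  # no motion at all: dt capped at t_end
  cfg_still <- sim_config(g_multiple = 0, temperature = 0, t_end = 100,
                          seed = 1)
  expect_equal(recommended_timestep(cfg_still), 100)
})

test_that("runs are seed-deterministic with monotone coarsening", {
  cfg <- sim_config(g_multiple = 1000, n_particles = 200, t_end = 400,
                    seed = 31)
  a <- run_sedimentation(cfg, n_samples = 10, keep_snapshots = TRUE)
  b <- run_sedimentation(cfg, n_samples = 10)
  expect_identical(a$series, b$series)
  expect_true(all(diff(a$series$count) <= 0))
  # total volume conserved across the whole run (fusion only redistributes)
  vols <- vapply(a$snapshots, function(s) sum(s$volumes), numeric(1))
  expect_equal(max(abs(vols - vols[1])), 0, tolerance = 1e-9)
  # T = 0, g = 0: nothing moves
  cfg0 <- sim_config(g_multiple = 0, temperature = 0, n_particles = 100,
                     t_end = 100, dt = 10, seed = 2)
  r0 <- run_sedimentation(cfg0, n_samples = 5)
  expect_true(all(r0$series$delta_z_um == 0))
  expect_true(all(r0$series$count == r0$series$count[1]))
})

test_that("monodisperse T = 0 run creeps at the exact Stokes velocity", {
  V <- volume_from_radius(2)
  cfg <- sim_config(n_particles = 50, temperature = 0, g_multiple = 100,
                    v_min = V * (1 - 1e-9), v_max = V * (1 + 1e-9),
                    fusion = FALSE, dt = 2, t_end = 200, seed = 44)
  v <- stokes_velocity(stokes_context(radius_from_volume(V), cfg$delta_rho,
                                      100, cfg$eta1))
  # keep the window short of the first wall contact: the linear law holds
  # only until the lowest particle reaches the floor
  set.seed(cfg$seed)
  z_low <- min(init_state(cfg)$positions[, 2])
  cfg$t_end <- 2 * floor((z_low - radius_from_volume(V)) / v / 2 * 0.9)
  run <- run_sedimentation(cfg, n_samples = 10)
  expect_equal(run$series$delta_z_um, v * run$series$time_s,
               tolerance = 1e-6)
  # tau-star by interpolation on an exact line
  expect_equal(time_to_displacement(run, v * cfg$t_end / 2), cfg$t_end / 2,
               tolerance = 1e-6)
  expect_true(is.na(time_to_displacement(run, 1e6)))
})

test_that("early-time sedimentation is linear at source-model density", {
  # At the source model's number density (1,000 bodies in a 1,600-um box,
  # here 300 in 800 um) drift dominates the fusion survivor bias and the
  # first quartile of the run is linear in time. In the crowded 400-um
  # default box the early-time mean is additionally shaped by big sinking
  # bodies absorbing low-lying small ones.
  r2 <- vapply(1:5, function(i) {
    cfg <- sim_config(g_multiple = 1000, n_particles = 300, box_side = 800,
                      t_end = 9600, seed = 100 + i)
    run <- run_sedimentation(cfg, n_samples = 96)
    s <- run$series[run$series$time_s <= 2400, ]
    summary(stats::lm(delta_z_um ~ time_s, data = s))$r.squared
  }, numeric(1))
  expect_gt(mean(r2), 0.98)
})

test_that("sedimentation and coarsening are coupled over a long run", {
  # as the emulsion sediments, floor coalescence raises the median size;
  # displacement and median radius rise together
  cfg <- sim_config(g_multiple = 1000, n_particles = 300, t_end = 20000,
                    seed = 101)
  run <- run_sedimentation(cfg, n_samples = 25)
  s <- run$series
  expect_gt(cor(s$delta_z_um, s$r_median_um), 0.5)
  expect_gt(s$r_median_um[nrow(s)], 1.5 * s$r_median_um[1])
  expect_gt(s$delta_z_um[nrow(s)], 150)
})
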