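test_that("tip dilation closed form: single atom peak height", {
  m <- atomic_model(data.frame(chain = "A", resno = 1, resid = "GLY",
                               elety = "CA", x = 0, y = 0, z = 5))
  # zero tip: grounded atom center sits at atom_radius, envelope peak at
  # z_a + atom_radius = 0.4 nm
  t0 <- simulate_topograph(m, pixel_size = 0.1, tip_radius = 0,
                           atom_radius = 0.2, pad = 0.5)
  expect_equal(max_height(t0), 0.4, tolerance = 1e-12)
  # finite tip leaves the on-axis peak unchanged (sqrt(R^2) - r_tip):
  t1 <- simulate_topograph(m, pixel_size = 0.1, tip_radius = 1,
                           atom_radius = 0.2, pad = 0.5)
  expect_equal(max_height(t1), 0.4, tolerance = 1e-12)
  expect_error(simulate_topograph(m, pixel_size = 0), "pixel_size")
})

test_that("tip dilation is monotone in tip radius, pixel by pixel", {
  m <- toy_model(1, 10, "beads", seed = 2)
  grid <- c(24L, 40L)
  t_sharp <- simulate_topograph(m, 0.5, tip_radius = 0.5, atom_radius = 0.2,
                                grid_dim = grid)
  t_blunt <- simulate_topograph(m, 0.5, tip_radius = 2, atom_radius = 0.2,
                                grid_dim = grid)
  expect_true(all(t_blunt$heights >= t_sharp$heights - 1e-12))
})

test_that("max_height reports the whole-field maximum", {
  h <- matrix(0, 4, 4)
  expect_equal(max_height(topograph(h + 0, 1)), 0)
  h[2, 3] <- 5.9
  expect_equal(max_height(topograph(h, 1)), 5.9)
})

test_that("topograph text round trip preserves grid and metadata", {
  m <- toy_model(1, 8, seed = 1)
  topo <- simulate_topograph(m, 0.5, 1, 0.2)
  f <- tempfile(fileext = ".txt")
  write_topograph(topo, f)
  back <- read_topograph(f)
  expect_equal(back$heights, topo$heights, tolerance = 1e-12)
  expect_equal(back$pixel_size, topo$pixel_size)
  expect_equal(back$origin, topo$origin)
})

test_that("docking a model into its own noise-free topograph recovers the
           generating placement", {
  m <- toy_model(1, 12, "beads", seed = 3)
  topo <- simulate_topograph(m, pixel_size = 0.5, tip_radius = 1,
                             atom_radius = 0.2, pad = 3)
  res <- dock(m, topo, rotation_step = 90, layer_thickness = 1)
  best <- res$poses[1, ]
  expect_equal(best$rot_deg, 0)              # within one rotation step
  expect_lte(abs(best$dx_px), 1)             # xy offset within 1 pixel
  expect_lte(abs(best$dy_px), 1)
  expect_lte(res$xy_offset_best, topo$pixel_size)
  # energy equals minus the favorable-atom count for the best pose
  expect_equal(best$energy, -best$n_favorable)
})

test_that("ranked energies match a brute-force enumeration on a small grid", {
  set.seed(8)
  at <- data.frame(chain = "A", resno = 1:5, resid = "GLY", elety = "CA",
                   x = c(0, 4, 8, 4, 4), y = c(0, 0, 0, 4, -3),
                   z = c(0, 3, 1, 2, 5))
  m <- atomic_model(at)
  topo <- simulate_topograph(m, pixel_size = 1, tip_radius = 0.5,
                             atom_radius = 0.2, grid_dim = c(8L, 8L))
  res <- dock(m, topo, rotation_step = 360, layer_thickness = 1)
  expect_equal(sort(res$poses$energy),
               brute_dock_energies(m, topo, layer_thickness = 1))
})

test_that("pose statistics are internally consistent", {
  m <- toy_model(1, 10, "beads", seed = 5)
  topo <- simulate_topograph(m, 0.5, 1, 0.2, pad = 3)
  res <- dock(m, topo, rotation_step = 60, layer_thickness = 1)
  expect_equal(res$min_energy, res$poses$energy[1])
  expect_gte(res$mean_energy_top10, res$min_energy)
  expect_false(is.unsorted(res$poses$energy))
  # energies are recomputable: every pose energy is -(favorable count)
  expect_equal(res$poses$energy, -res$poses$n_favorable)
  # keep truncates the ranked list
  res2 <- dock(m, topo, rotation_step = 60, layer_thickness = 1, keep = 5)
  expect_equal(nrow(res2$poses), 5L)
  expect_equal(res2$poses$energy, res$poses$energy[1:5])
  # degenerate top-3 (a single retained pose) has zero RMSD
  res1 <- dock(m, topo, rotation_step = 60, layer_thickness = 1, keep = 1)
  expect_equal(res1$rmsd_top3, 0)
})

test_that("whole-pixel co-translation of model and topograph content leaves
           energies unchanged", {
  m <- toy_model(1, 8, "beads", seed = 4)
  topo <- simulate_topograph(m, 0.5, 1, 0.2, pad = 4)
  shift <- rigid_transform(diag(3), c(2 * topo$pixel_size * 10, 0, 0)) # A
  m_sh <- apply_transform(m, shift)
  topo_sh <- topograph(topo$heights, topo$pixel_size,
                       topo$origin + c(2 * topo$pixel_size, 0))
  e1 <- sort(dock(m, topo, 360, 1)$poses$energy)
  e2 <- sort(dock(m_sh, topo_sh, 360, 1)$poses$energy)
  expect_equal(e1, e2)
})

test_that("model generated from the topograph beats a rival model", {
  mx <- toy_model(1, 14, "beads", seed = 10)       # generator of the map
  rival <- toy_model(1, 14, "helix", seed = 10)    # same size, wrong shape
  topo <- simulate_topograph(mx, 0.5, 1, 0.2, pad = 3)
  # hard clash rejection: the generating model fits, the rival does not
  ex_hard <- dock(mx, topo, rotation_step = 90, layer_thickness = 1)
  er_hard <- dock(rival, topo, rotation_step = 90, layer_thickness = 1)
  expect_gt(nrow(ex_hard$poses), 0)
  expect_equal(nrow(er_hard$poses), 0)
  # soft-penalty mode scores both; the generating model still wins
  ex <- dock(mx, topo, rotation_step = 90, layer_thickness = 1,
             soft_penalty = TRUE)$min_energy
  er <- dock(rival, topo, rotation_step = 90, layer_thickness = 1,
             soft_penalty = TRUE)$min_energy
  expect_lt(ex, er)
})

test_that("an impossible fit returns an empty result with a diagnostic", {
  # tall thin model versus a flat zero-height map: every pose protrudes
  at <- data.frame(chain = "A", resno = 1:4, resid = "GLY", elety = "CA",
                   x = 0, y = 0, z = c(0, 20, 40, 60))
  m <- atomic_model(at)
  topo <- topograph(matrix(0, 6, 6), 1)
  res <- dock(m, topo, rotation_step = 360, layer_thickness = 0.5,
              clash_tolerance = 0.1)
  expect_equal(nrow(res$poses), 0L)
  expect_match(res$diagnostic, "no valid placement")
})
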