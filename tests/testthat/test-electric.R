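# Conduction solver against closed forms and conservation/shielding
# properties.

test_that("homogeneous strip reproduces the 1D closed form exactly", {
  fx <- toy_fixtures()$strip
  m <- fx$mesh
  phi <- solve_linear_potential(m, 1, dirichlet_set(m, 1000))
  gf <- gradient_field(m, phi)
  y_mm <- m$nodes[, 2] * 1e3
  expect_equal(phi, fx$reference$phi_at(y_mm), tolerance = 1e-12)
  expect_equal(gf$E_mag, rep(fx$reference$E_mag, nrow(m$tri)),
               tolerance = 1e-12)
  sol <- list(phi = phi, sigma_elem = rep(1, nrow(m$tri)))
  expect_equal(boundary_current(m, sol, "electrode_surface"),
               fx$reference$current_per_width, tolerance = 1e-10)
  expect_equal(boundary_current(m, sol, "electrode_surface"),
               -boundary_current(m, sol, "dispersive_pad"),
               tolerance = 1e-10)
  expect_lt(boundary_current(m, sol, "lateral"), 1e-9)
})

test_that("two-layer slab matches the series-conductance closed form", {
  fx <- toy_fixtures()$two_layer
  m <- fx$mesh
  sig <- ifelse(m$region == "layer_a", fx$params$sigma_a, fx$params$sigma_b)
  phi <- solve_linear_potential(m, sig, dirichlet_set(m, 1000))
  iface <- which(abs(m$nodes[, 2] - 0.005) < 1e-12)
  expect_equal(phi[iface], rep(fx$reference$phi_interface, length(iface)),
               tolerance = 1e-12)
  gf <- gradient_field(m, phi)
  a <- m$region == "layer_a"
  expect_equal(gf$E_mag[a], rep(fx$reference$E_a, sum(a)), tolerance = 1e-11)
  expect_equal(gf$E_mag[!a], rep(fx$reference$E_b, sum(!a)), tolerance = 1e-11)
})

test_that("gradient of linear and constant potentials is exact", {
  m <- structured_rect_mesh(0, 7, 0, 4, 7, 5)
  phi_lin <- 1e5 * m$nodes[, 2]          # phi = 1e5 y -> |E| = 1e5 V/m
  gf <- gradient_field(m, phi_lin)
  expect_equal(gf$E_mag, rep(1e5, nrow(m$tri)), tolerance = 1e-10)
  expect_equal(gf$Ex, rep(0, nrow(m$tri)), tolerance = 1e-6)
  gf0 <- gradient_field(m, rep(42, nrow(m$nodes)))
  expect_equal(gf0$E_mag, rep(0, nrow(m$tri)), tolerance = 1e-12)
})

test_that("conducting annulus shields its core like the analytic solution", {
  fx <- toy_fixtures()$shield
  m <- fx$mesh
  sig <- ifelse(m$region == "shell", fx$params$sig_s, fx$params$sig_m)
  outer <- unique(c(m$edges$n1[m$edges$tag == "outer"],
                    m$edges$n2[m$edges$tag == "outer"]))
  bc <- list(nodes = outer, values = -fx$params$E0 * m$nodes[outer, 1])
  phi <- solve_linear_potential(m, sig, bc)
  gf <- gradient_field(m, phi)
  core <- m$region == "core"
  ratio <- mean(gf$E_mag[core]) / fx$params$E0
  expect_lt(ratio, 1e-4)                       # shielding property
  expect_equal(ratio, fx$reference$ratio, tolerance = 0.05)
  # interior field is uniform in the analytic solution
  expect_lt(stats::sd(gf$E_mag[core]) / mean(gf$E_mag[core]), 0.5)
})

test_that("maximum principle and charge conservation hold on study meshes", {
  for (cfg in list(list(artery = FALSE, stent = FALSE),
                   list(artery = TRUE, stent = TRUE))) {
    f <- coarse_field(cfg$artery, cfg$stent, gap = 1)
    expect_gte(min(f$sol$phi), 0)
    expect_lte(max(f$sol$phi), 1000)
    Iin <- boundary_current(f$mesh, f$sol, "electrode_surface")
    Iout <- boundary_current(f$mesh, f$sol, "dispersive_pad")
    expect_equal(abs(Iin), abs(Iout), tolerance = 1e-3)   # 0.1 %
  }
})

test_that("fixed point is immediate without field dependence", {
  tb <- material_table()
  for (nm in names(tb)) { tb[[nm]]$sigma1 <- tb[[nm]]$sigma0
                          tb[[nm]]$electroporation_dependent <- FALSE }
  g <- build_geometry(geometry_config())
  m <- generate_mesh(g, mesh_sizing("coarse", h_edge = 0.2, h_fine = 0.4,
                                    h_fat = 0.6))
  f <- solve_selfconsistent(m, table = tb, amplitude = 1000)
  expect_equal(f$iterations, 1L)
  # and the result equals the plain linear solution
  sig <- vapply(m$region, function(tag) tb[[tag]]$sigma0, 1)
  phi_lin <- solve_linear_potential(m, sig, dirichlet_set(m, 1000))
  expect_equal(f$phi, phi_lin, tolerance = 1e-12)
})

test_that("self-consistent conductivity lands inside the sigmoid bounds", {
  f <- coarse_field(artery = TRUE, stent = FALSE, gap = 1)
  m <- f$mesh
  fat <- m$region == "fat"
  expect_true(all(f$sol$sigma_elem[fat] >= 0.0377 - 1e-9))
  expect_true(all(f$sol$sigma_elem[fat] <= 0.0438 + 1e-9))
  # artery shields: lumen mean below the surrounding fat field
  ls <- lumen_stats(m, f$sol)
  expect_lt(ls$mean_Vcm, 400)
  expect_gt(ls$mean_Vcm, 50)
})

test_that("solver rejects degenerate inputs", {
  m <- structured_rect_mesh(0, 2, 0, 2, 2, 2)
  expect_error(solve_linear_potential(m, -1, dirichlet_set(m, 10)),
               "positive")
  expect_error(solve_linear_potential(m, 1, list(nodes = integer(0),
                                                 values = numeric(0))),
               "singular|Dirichlet")
  expect_error(boundary_current(m, list(phi = rep(0, nrow(m$nodes)),
                                        sigma_elem = 1), "nope"),
               "unknown")
})
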