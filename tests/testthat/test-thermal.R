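# Bioheat stepping against equilibrium, adiabatic-heating and transient
# Robin-slab closed forms; energy balance.

all_domain <- function(mesh, robin = list()) {
  list(elements = seq_len(nrow(mesh$tri)),
       nodes = seq_len(nrow(mesh$nodes)), robin = robin)
}

test_that("equilibrium at 37 C is exact for any step size", {
  m <- structured_rect_mesh(0, 6, 0, 6, 6, 6)
  dom <- all_domain(m, list(robin_condition("electrode_surface", 500, 37),
                            robin_condition("dispersive_pad", 20, 37)))
  Tn <- rep(37, nrow(m$nodes))
  for (dt in c(1e-5, 1e-3, 0.5)) {
    Tn2 <- advance(m, dom, Tn, dt, Q_elem = 0)
    expect_equal(Tn2, Tn, tolerance = 1e-12)
  }
})

test_that("insulated block under uniform power heats as Q t / (rho c)", {
  fx <- toy_fixtures()$heated_block
  m <- fx$mesh
  dom <- all_domain(m)
  sys <- thermal_system(m, dom, dt = 1e-4)
  Tn <- rep(37, nrow(m$nodes))
  for (i in 1:10) Tn <- advance_state(sys, Tn, fx$params$Q)
  # exact for the discrete system: spatially uniform at every step
  expect_equal(Tn, rep(37 + fx$reference$dT, length(Tn)), tolerance = 1e-9)
})

test_that("transient Robin slab approaches the analytic series solution", {
  # 1D slab 0..L insulated at y = 0, Robin (h, T_inf) at y = L, uniform
  # initial offset; series T(y,t) with eigenvalues beta_n tan(beta_n) = Bi
  fat <- material_for("fat")
  L <- 2e-3; h <- 500; T0 <- 37; Tinf <- 47
  Bi <- h * L / fat$k
  beta <- vapply(1:8, function(n) {
    stats::uniroot(function(b) b * tan(b) - Bi,
                   c((n - 1) * pi + 1e-9, (n - 0.5) * pi - 1e-9),
                   tol = 1e-13)$root
  }, 1)
  Cn <- 4 * sin(beta) / (2 * beta + sin(2 * beta))
  slab_T <- function(y, t_s) {
    alpha <- fat$k / (fat$rho * fat$c)
    theta <- vapply(y, function(yy) {
      sum(Cn * exp(-beta^2 * alpha * t_s / L^2) * cos(beta * yy / L))
    }, 1)
    Tinf + (T0 - Tinf) * theta
  }
  m <- structured_rect_mesh(0, 1, 0, 2, nx = 2, ny = 40)
  # Robin face is the bottom edge (y = L); lateral and top stay natural
  dom <- all_domain(m, list(robin_condition("dispersive_pad", h, Tinf)))
  sys <- thermal_system(m, dom, dt = 2e-3)
  Tn <- rep(T0, nrow(m$nodes))
  t_end <- 0.4
  for (i in seq_len(t_end / 2e-3)) Tn <- advance_state(sys, Tn, 0)
  ref <- slab_T(m$nodes[, 2], t_end)
  expect_lt(max(abs(Tn - ref)) / (Tinf - T0), 0.01)     # 1 % of the step
})

test_that("per-step energy balance closes", {
  fat <- material_for("fat")
  m <- structured_rect_mesh(0, 5, 0, 5, 10, 10)
  h <- 200; Tinf <- 37
  dom <- all_domain(m, list(robin_condition("dispersive_pad", h, Tinf)))
  sys <- thermal_system(m, dom, dt = 5e-3)
  Tn <- rep(37, nrow(m$nodes))
  Qv <- 5e7
  for (i in 1:20) {
    Tp <- Tn
    Tn <- advance_state(sys, Tn, Qv)
    # stored-energy change vs source minus boundary loss over the step
    dE <- sum(sys$M %*% (Tn - Tp))
    src <- Qv * sum(m$areas) * sys$dt
    e <- m$edges[m$edges$tag == "dispersive_pad", ]
    len <- sqrt(rowSums((m$nodes[e$n1, ] - m$nodes[e$n2, ])^2))
    Tedge <- (Tn[e$n1] + Tn[e$n2]) / 2
    loss <- sum(h * (Tedge - Tinf) * len) * sys$dt
    expect_equal(dE, src - loss, tolerance = 5e-3)      # 0.5 %
  }
})

test_that("thermal domain excludes the flowing pools and picks Robin walls", {
  mk <- function(...) generate_mesh(build_geometry(geometry_config(...)),
                                    mesh_sizing("coarse"))
  m0 <- mk()
  d0 <- thermal_domain(m0)
  expect_false(any(m0$region[d0$elements] %in%
                     c("blood_chamber", "saline")))
  tags0 <- vapply(d0$robin, function(r) r$tag, "")
  expect_setequal(tags0, c("air_top", "endocardial_wall"))
  hs <- vapply(d0$robin, function(r) r$h, 1)
  expect_equal(sort(hs), c(20, 1417))

  m1 <- mk(artery_present = TRUE)
  d1 <- thermal_domain(m1)
  expect_false(any(m1$region[d1$elements] == "artery_lumen"))
  r1 <- d1$robin[[which(vapply(d1$robin, function(r) r$tag, "") == "artery_wall")]]
  expect_equal(r1$h, 63.19)
  expect_equal(r1$T_inf, 37)

  m2 <- mk(artery_present = TRUE, stent_present = TRUE)
  d2 <- thermal_domain(m2)
  expect_true("stent" %in% m2$region[d2$elements])
  tags2 <- vapply(d2$robin, function(r) r$tag, "")
  expect_true("stent_inner_wall" %in% tags2)
  expect_false("artery_wall" %in% tags2)
  d2b <- thermal_domain(m2, lumen_robin = FALSE)
  expect_false("stent_inner_wall" %in%
                 vapply(d2b$robin, function(r) r$tag, ""))
  # static-saline variant keeps the film in the solve
  d0s <- thermal_domain(m0, saline_flowing = FALSE)
  expect_true("saline" %in% m0$region[d0s$elements])
})

test_that("joule source arithmetic", {
  expect_equal(joule_source(0.0438, 1e5), 4.38e8)
  expect_equal(joule_source(c(1, 2), 0), c(0, 0))
  # fat vs blood heating ratio at saturation field
  expect_equal(joule_source(0.0438, 1e5) / joule_source(0.748, 1e5),
               0.0438 / 0.748)
})
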