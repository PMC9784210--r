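# Nodal recovery, isoline extraction and lesion metrics.

test_that("nodal recovery is the area-weighted neighbour average", {
  m <- structured_rect_mesh(0, 4, 0, 4, 4, 4)
  # uniform element field -> same value at every node
  En <- nodal_field(m, 7)
  expect_equal(En, rep(7, nrow(m$nodes)))
  # equal-area triangles sharing a node average (a + b)/2 when split evenly
  v <- ifelse(seq_len(nrow(m$tri)) %% 2 == 0, 2, 4)
  En2 <- nodal_field(m, v)
  expect_true(all(En2 >= 2 - 1e-12 & En2 <= 4 + 1e-12))
  # exact two-element check
  nodes2 <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)) * 1e-3
  mesh2 <- structure(list(nodes = nodes2,
                          tri = rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)),
                          region = c("fat", "fat")), class = "pef_mesh")
  mesh2$areas <- rep(0.5e-6, 2)
  En3 <- nodal_field(mesh2, c(10, 20))
  expect_equal(En3[c(1, 3)], c(15, 15))   # nodes shared by both
  expect_equal(En3[c(2, 4)], c(10, 20))
})

test_that("isolines of a linear field are exact straight lines", {
  m <- structured_rect_mesh(0, 10, 0, 10, 10, 10)
  f <- m$nodes[, 2] * 1e3          # f = y in mm
  iso <- extract_isolines(m, f, 4.5)
  expect_equal(length(iso), 1)
  expect_equal(unname(iso[[1]][, "y"]), rep(4.5, nrow(iso[[1]])),
               tolerance = 1e-9)
  expect_equal(range(iso[[1]][, "x"]), c(0, 10), tolerance = 1e-9)
  expect_equal(extract_isolines(m, f, 99), list())   # never crossed
})

test_that("isoline radius matches a radial field crossing", {
  m <- disc_annulus_mesh(R = 8, r1 = 2, r2 = 2.5, N = 64)
  r <- sqrt(rowSums(m$nodes^2)) * 1e3
  iso <- extract_isolines(m, r, 5)
  expect_gte(length(iso), 1)
  pts <- do.call(rbind, iso)
  rr <- sqrt(pts[, "x"]^2 + pts[, "y"]^2)
  h <- 2 * pi * 5 / 64
  expect_lt(max(abs(rr - 5)), h)                     # within mesh size
  # closed contour: endpoints coincide
  expect_equal(iso[[1]][1, ], iso[[1]][nrow(iso[[1]]), ], tolerance = 1e-9)
})

test_that("zone metrics summarise super-threshold tissue", {
  f <- coarse_field(artery = FALSE)
  z <- pef_zone_metrics(f$mesh, f$sol$E_mag)
  expect_gt(z$width_mm, 4)
  expect_lt(z$width_mm, 20)
  expect_true(z$confined_to_fat)
  expect_lte(z$depth_mm, f$mesh$geom$config$fat_thickness + 1e-6)
  # zero field -> empty metrics
  z0 <- pef_zone_metrics(f$mesh, rep(0, nrow(f$mesh$tri)))
  expect_equal(z0$width_mm, 0)
  expect_equal(z0$depth_mm, 0)
  expect_true(z0$confined_to_fat)
  expect_equal(z0$polylines, list())
})

test_that("zone metrics are mirror symmetric for symmetric scenarios", {
  f <- coarse_field(artery = TRUE, stent = TRUE, gap = 1)
  z <- pef_zone_metrics(f$mesh, f$sol$E_mag)
  xs <- unlist(lapply(z$polylines, function(p) p[, "x"]))
  expect_lt(abs(max(xs) + min(xs)) / z$width_mm, 0.01)
})

test_that("lumen statistics detect shielding and the homogeneous limit", {
  f1 <- coarse_field(artery = TRUE, stent = FALSE, gap = 1)
  f2 <- coarse_field(artery = TRUE, stent = TRUE, gap = 1)
  l1 <- lumen_stats(f1$mesh, f1$sol)
  l2 <- lumen_stats(f2$mesh, f2$sol)
  expect_gt(l1$mean_Vcm / max(l2$mean_Vcm, 1e-12), 1e3)  # Faraday cage
  expect_lt(l2$mean_Vcm, 0.01)
  expect_equal(l1$area_mm2, pi * 1.15^2, tolerance = 0.01)
  f0 <- coarse_field(artery = FALSE)
  expect_error(lumen_stats(f0$mesh, f0$sol), "no artery")
  # homogeneity limit: lumen given fat conductivity shows no field
  # distortion, so the lumen mean matches the no-artery solution averaged
  # over the same disc
  tb <- material_table()
  tb$artery_lumen <- tb$fat
  g <- build_geometry(geometry_config(artery_present = TRUE))
  m <- generate_mesh(g, mesh_sizing("coarse"))
  fh <- solve_selfconsistent(m, table = tb, amplitude = 1000)
  lh <- lumen_stats(m, fh)
  ctr <- c(f0$mesh$geom$artery, list(cx = 0, cy = 2.15))   # f0 has no artery
  cx <- (f0$mesh$nodes[f0$mesh$tri[, 1], 1] +
         f0$mesh$nodes[f0$mesh$tri[, 2], 1] +
         f0$mesh$nodes[f0$mesh$tri[, 3], 1]) / 3 * 1e3
  cy <- (f0$mesh$nodes[f0$mesh$tri[, 1], 2] +
         f0$mesh$nodes[f0$mesh$tri[, 2], 2] +
         f0$mesh$nodes[f0$mesh$tri[, 3], 2]) / 3 * 1e3
  disc <- (cx - 0)^2 + (cy - 2.15)^2 <= 1.15^2
  ref <- sum((f0$sol$E_mag * f0$mesh$areas)[disc]) /
    sum(f0$mesh$areas[disc]) / 100
  expect_equal(lh$mean_Vcm, ref, tolerance = 0.05)
})
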