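# Mesh generation contracts: conformity, tiling, feature resolution,
# refinement scaling, point location.

coarse_mesh <- function(...) {
  generate_mesh(build_geometry(geometry_config(...)), mesh_sizing("coarse"))
}

test_that("mesh tiles the domain and matches analytic region areas", {
  for (cfg in list(list(), list(artery_present = TRUE),
                   list(artery_present = TRUE, stent_present = TRUE,
                        electrode_artery_gap = 0.25))) {
    m <- do.call(coarse_mesh, cfg)
    a <- region_areas(m)
    expect_equal(sum(a), 80 * 40, tolerance = 1e-3)     # 0.1 % tiling
    ref <- geometry_areas(m$geom)
    for (reg in names(ref))
      expect_equal(unname(a[reg]), unname(ref[reg]), tolerance = 0.01,
                   info = paste(reg, length(cfg)))
    expect_true(all(m$areas > 0))
    # no duplicate nodes
    key <- paste(round(m$nodes[, 1] * 1e9), round(m$nodes[, 2] * 1e9))
    expect_equal(anyDuplicated(key), 0L)
  }
})

test_that("artery lumen area matches the disc area within 1 %", {
  m <- coarse_mesh(artery_present = TRUE)
  expect_equal(unname(region_areas(m)["artery_lumen"]), pi * 1.15^2,
               tolerance = 0.01)
  ms <- coarse_mesh(artery_present = TRUE, stent_present = TRUE)
  expect_equal(unname(region_areas(ms)["artery_lumen"]), pi * 1.05^2,
               tolerance = 0.01)
  expect_equal(unname(region_areas(ms)["stent"]), pi * (1.15^2 - 1.05^2),
               tolerance = 0.01)
})

test_that("stent wall is resolved by at least two element layers", {
  m <- coarse_mesh(artery_present = TRUE, stent_present = TRUE)
  ar <- m$geom$artery
  idx <- which(m$region == "stent")
  # radial span of each stent triangle must be at most half the wall
  ctr <- c(ar$cx, ar$cy) * 1e-3
  for (k in idx) {
    r <- sqrt((m$nodes[m$tri[k, ], 1] - ctr[1])^2 +
              (m$nodes[m$tri[k, ], 2] - ctr[2])^2)
    expect_lte(max(r) - min(r), 0.5 * (ar$r_out - ar$r_in) * 1e-3 + 1e-9)
  }
})

test_that("uniform refinement quadruples the node count approximately", {
  g <- build_geometry(geometry_config(artery_present = TRUE))
  n1 <- nrow(generate_mesh(g, mesh_sizing("coarse"))$nodes)
  n2 <- nrow(generate_mesh(g, mesh_sizing("coarse", refine = 2))$nodes)
  expect_gt(n2 / n1, 2.8)
  expect_lt(n2 / n1, 5.2)
})

test_that("structured rectangle mesh honours the sizing contract", {
  m <- structured_rect_mesh(0, 10, 0, 5, nx = 10, ny = 5)
  # uniform 1 mm cells split in two: every edge within [0.5 h, 2 h]
  el <- rbind(m$tri[, 1:2], m$tri[, 2:3], m$tri[, c(3, 1)])
  len <- sqrt(rowSums((m$nodes[el[, 1], ] - m$nodes[el[, 2], ])^2)) * 1e3
  expect_true(all(len >= 0.5 & len <= 2))
  expect_equal(sum(m$areas) * 1e6, 50)
})

test_that("geometric quantities are mirror symmetric", {
  m <- coarse_mesh(artery_present = TRUE, stent_present = TRUE)
  a <- region_areas(m)
  mm <- m
  mm$nodes[, 1] <- -mm$nodes[, 1]
  am <- region_areas(mm)   # same triangles, mirrored coordinates
  expect_equal(a, am[names(a)], tolerance = 5e-3)
  # boundary chains exist and have sane lengths
  expect_equal(boundary_length(m, "dispersive_pad"), 80, tolerance = 1e-6)
  expect_equal(boundary_length(m, "artery_wall"), 2 * pi * 1.15,
               tolerance = 0.01)
  expect_equal(boundary_length(m, "stent_inner_wall"), 2 * pi * 1.05,
               tolerance = 0.01)
})

test_that("tagged boundary edges form connected chains", {
  m <- coarse_mesh(artery_present = TRUE)
  n_components <- function(e) {
    # union-find over the chain graph
    parent <- new.env(hash = TRUE)
    find <- function(x) {
      p <- get0(x, envir = parent, ifnotfound = x)
      if (p != x) { p <- find(p); assign(x, p, envir = parent) }
      p
    }
    for (i in seq_len(nrow(e)))
      assign(find(as.character(e$n1[i])), find(as.character(e$n2[i])),
             envir = parent)
    length(unique(vapply(as.character(unique(c(e$n1, e$n2))), find, "")))
  }
  # the two metal segments and the two domain sides give two chains each;
  # every other tag is a single connected chain
  expected <- c(electrode_surface = 2, lateral = 2, air_top = 1,
                dispersive_pad = 1, endocardial_wall = 1, artery_wall = 1)
  for (tag in unique(m$edges$tag)) {
    e <- m$edges[m$edges$tag == tag, ]
    expect_equal(n_components(e), unname(expected[tag]), info = tag)
  }
})

test_that("locate_region finds the right region with deterministic ties", {
  m <- coarse_mesh(artery_present = TRUE, stent_present = TRUE,
                   electrode_artery_gap = 1)
  expect_equal(locate_region(m, c(0, 2.15)), "artery_lumen") # artery centre
  expect_equal(locate_region(m, c(0, 39)), "blood_chamber")
  expect_equal(locate_region(m, c(0, 4.8)), "fat")
  expect_equal(locate_region(m, c(30, 6)), "myocardium")
  expect_error(locate_region(m, c(0, 45)), "outside")
  # a point on a shared vertical edge: both candidates agree deterministically
  expect_type(locate_region(m, c(0, 6)), "character")
})
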