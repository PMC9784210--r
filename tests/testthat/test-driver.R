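# Coupled-run orchestration on the fast (coarse) profile.

test_that("zero-amplitude run stays at body temperature with empty zone", {
  r <- cached_run(amplitude = 0)
  # no heating anywhere; tissue holds 37 C exactly (the domain top may cool
  # marginally toward the 21 C ambient air, which only lowers temperatures)
  expect_true(all(r$T_final <= 37 + 1e-9))
  tissue <- unique(as.vector(r$mesh$tri[r$mesh$region %in%
                                          c("fat", "myocardium"), ]))
  expect_equal(r$T_final[tissue], rep(37, length(tissue)), tolerance = 1e-9)
  expect_equal(r$metrics$zone$width_mm, 0)
  expect_equal(r$metrics$probe$T_max_global, 37, tolerance = 1e-9)
  expect_equal(r$metrics$probe$t_peak, 0)      # earliest tie wins
})

test_that("temperature peaks at the end of the last pulse in every config", {
  for (args in list(list(artery = FALSE),
                    list(artery = TRUE, gap = 1),
                    list(artery = TRUE, stent = TRUE, gap = 0.25))) {
    r <- do.call(cached_run, args)
    p <- r$metrics$probe
    expect_true(p$latency_flag, info = r$label)
    expect_equal(p$t_peak, r$t_end_train_s, tolerance = 0.02,
                 info = r$label)
    # non-increasing trace over the latency window
    lat <- r$trace[r$trace$t_s > r$t_end_train_s + 1e-9, ]
    expect_true(all(diff(lat$Tmax_C) <= 1e-9), info = r$label)
  }
})

test_that("runs are deterministic: identical metrics on re-run", {
  sc <- scenario(geometry_config(artery_present = TRUE,
                                 electrode_artery_gap = 1),
                 pulse_train(), label = "det")
  p <- solver_profile("coarse")
  a <- run_scenario(sc, p)
  b <- run_scenario(sc, p)
  expect_identical(metrics_summary(a), metrics_summary(b))
  expect_identical(a$trace, b$trace)
})

test_that("halving the amplitude quarters the heating with linear sigma", {
  tb <- material_table()
  for (nm in names(tb)) { tb[[nm]]$sigma1 <- tb[[nm]]$sigma0
                          tb[[nm]]$electroporation_dependent <- FALSE
                          tb[[nm]]$temp_coeff <- 1 }
  p <- solver_profile("coarse")
  mk <- function(amp) {
    sc <- scenario(geometry_config(), pulse_train(amplitude = amp),
                   label = paste0("lin", amp), materials = tb)
    run_scenario(sc, p)$metrics$probe$T_max_global - 37
  }
  dT_full <- mk(1000)
  dT_half <- mk(500)
  expect_equal(dT_full / dT_half, 4, tolerance = 1e-3)
})

test_that("artery changes the zone width by less than half a millimetre", {
  w0 <- cached_run(artery = FALSE)$metrics$zone$width_mm
  w1 <- cached_run(artery = TRUE, gap = 1)$metrics$zone$width_mm
  expect_lt(abs(w0 - w1), 0.5)
})

test_that("stent raises the hot-spot temperatures; closer gap runs hotter", {
  t_a1 <- cached_run(artery = TRUE, gap = 1)$metrics$probe
  t_s1 <- cached_run(artery = TRUE, stent = TRUE, gap = 1)$metrics$probe
  t_a025 <- cached_run(artery = TRUE, gap = 0.25)$metrics$probe
  t_s025 <- cached_run(artery = TRUE, stent = TRUE, gap = 0.25)$metrics$probe
  expect_gte(t_s1$T_max_global, t_a1$T_max_global - 0.1)
  expect_gte(t_s025$T_max_global, t_a025$T_max_global - 0.1)
  expect_gt(t_a025$front_hotspot_T, t_a1$front_hotspot_T)
  expect_gt(t_s025$front_hotspot_T, t_s1$front_hotspot_T)
  # front hot spot dominates the rear one
  expect_gt(t_s025$front_hotspot_T, t_s025$rear_hotspot_T)
})

test_that("compare_protocols reruns identical geometry per interval", {
  sc <- scenario(geometry_config(artery_present = TRUE, stent_present = TRUE,
                                 electrode_artery_gap = 0.25),
                 pulse_train(), label = "cmp")
  p <- solver_profile("coarse")
  tab <- compare_protocols(sc, c(100, 10), p)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$dTmax_C[1], 0)
  expect_lt(abs(tab$dTmax_C[2]), 0.5)
  one <- compare_protocols(sc, 100, p)
  expect_equal(nrow(one), 1)
  expect_equal(one$dTmax_C, 0)
  dup <- compare_protocols(sc, c(100, 100), p)
  expect_equal(dup$Tmax_C[1], dup$Tmax_C[2])   # reproducibility
})

test_that("field re-solves happen at pulse onsets and on temperature drift", {
  r <- cached_run(artery = TRUE, stent = TRUE, gap = 0.25)
  reasons <- vapply(r$convergence, function(cv) cv$reason, "")
  expect_equal(sum(grepl("pulse onset", reasons)), 10)
  its <- vapply(r$convergence, function(cv) cv$iterations, 1L)
  expect_true(all(its >= 1))
  # warm starts keep later solves cheap
  expect_lt(mean(its[-1]), its[1])
})
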