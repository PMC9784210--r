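# Shared fixtures and cached scenario runs. Tests use the coarse profile
# unless a check is explicitly about production resolution; runs are cached
# per (label, profile) so several test files can share them.

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(artery = FALSE, stent = FALSE, gap = 1,
                       interval = 100, profile = "coarse", refine = 1,
                       amplitude = 1000) {
  key <- sprintf("a%d_s%d_g%g_i%g_%s_r%g_V%g", artery, stent, gap, interval,
                 profile, refine, amplitude)
  r <- get0(key, envir = .run_cache)
  if (is.null(r)) {
    sc <- scenario(geometry_config(artery_present = artery,
                                   stent_present = stent,
                                   electrode_artery_gap = gap),
                   pulse_train(amplitude = amplitude, interval = interval),
                   label = key)
    r <- run_scenario(sc, solver_profile(profile, refine = refine))
    assign(key, r, envir = .run_cache)
  }
  r
}

coarse_field <- function(artery = FALSE, stent = FALSE, gap = 1, T_nodal = 37) {
  key <- sprintf("field_a%d_s%d_g%g_T%g", artery, stent, gap, T_nodal[1])
  f <- get0(key, envir = .run_cache)
  if (is.null(f)) {
    g <- build_geometry(geometry_config(artery_present = artery,
                                        stent_present = stent,
                                        electrode_artery_gap = gap))
    m <- generate_mesh(g, mesh_sizing("coarse"))
    f <- list(mesh = m,
              sol = solve_selfconsistent(m, T_nodal = T_nodal,
                                         amplitude = 1000))
    assign(key, f, envir = .run_cache)
  }
  f
}
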