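test_that("mass-conservation scaling recovers trivial factors", {
  inlet <- pulse_flow(8e-5)
  # outlets already summing to the inlet peak: factor 1, unchanged
  halves <- list(pulse_flow(4e-5, "innominate"),
                 pulse_flow(4e-5, "descending_aorta"))
  r <- conserve_mass_scale(inlet, halves)
  expect_equal(r$factor, 1, tolerance = 1e-9)
  expect_equal(r$outlets[[1]]$flow, halves[[1]]$flow, tolerance = 1e-9)
  # single outlet at twice the inlet: factor 0.5
  r2 <- conserve_mass_scale(inlet, list(pulse_flow(16e-5, "descending_aorta")))
  expect_equal(r2$factor, 0.5, tolerance = 1e-9)
  expect_error(conserve_mass_scale(inlet, list()), "at least one outlet")
  z <- mk_flow(rep(0, 11), "lcca")
  expect_error(conserve_mass_scale(inlet, list(z)), "zero peak")
})

test_that("a known uniform factor applied inversely is recovered", {
  f0 <- 0.8243
  inlet <- pulse_flow(7.84e-5)
  shares <- c(innominate = 0.45, lcca = 0.15, lsca = 0.15,
              descending_aorta = 0.25)
  consistent <- lapply(names(shares), function(p)
    pulse_flow(shares[[p]] * 7.84e-5, p))
  raw <- lapply(consistent, function(w)
    flow_waveform(w$patch, w$time, w$flow / f0))
  r <- conserve_mass_scale(inlet, raw)
  expect_equal(r$factor, f0, tolerance = 1e-6)
  # post-condition: peak of the scaled sum equals the inlet peak to 1e-9
  total <- Reduce(`+`, lapply(r$outlets, `[[`, "flow"))
  expect_equal(max(total), max(inlet$flow), tolerance = 1e-9)
})

test_that("optional phase alignment moves branch peaks onto the inlet peak", {
  inlet <- pulse_flow(8e-5)
  lag <- gen_waveform(waveform_params(1.0, phase_lag = 0.08,
                                      n_samples = 1000), "innominate")
  q_lag <- velocity_to_flow(lag, 1e-4)
  dao <- pulse_flow(3e-5, "descending_aorta")
  r <- conserve_mass_scale(inlet, list(q_lag, dao), align_phases = TRUE)
  t_in <- peak_of(inlet)$t_peak
  expect_equal(peak_of(r$outlets[[1]])$t_peak, t_in, tolerance = 1e-2)
  # the descending aorta is exempt from alignment
  expect_equal(peak_of(r$outlets[[2]])$t_peak, t_in)
  # default behavior leaves the lag untouched
  r0 <- conserve_mass_scale(inlet, list(q_lag, dao))
  expect_equal(peak_of(r0$outlets[[1]])$t_peak, peak_of(q_lag)$t_peak)
})

test_that("branch ratios are peak-to-peak relative to the innominate", {
  inn <- pulse_flow(3.72e-5, "innominate")
  lcca <- pulse_flow(1.09e-5, "lcca")
  lsca <- pulse_flow(1.09e-5, "lsca")
  r <- branch_ratios_from(list(inn, lcca, lsca))
  expect_equal(round(r[["lcca"]], 4), 0.2930)
  expect_equal(unname(r["lsca"]), unname(r["lcca"]))
  # identical waveforms give ratio 1; halving halves the ratio
  expect_equal(branch_ratios_from(list(inn, pulse_flow(3.72e-5, "lcca")))[["lcca"]], 1)
  half <- flow_waveform("lcca", lcca$time, lcca$flow / 2)
  expect_equal(branch_ratios_from(list(inn, half))[["lcca"]],
               r[["lcca"]] / 2)
  expect_error(branch_ratios_from(list(lcca, lsca)), "innominate")
  z <- mk_flow(rep(0, 11), "innominate")
  expect_error(branch_ratios_from(list(z, lcca)), "zero")
})

test_that("partial post-repair imputation solves the descending scaling", {
  f1 <- split_factors(outlet_scale = 0.8243,
                      branch_ratios = c(lcca = 0.293, lsca = 0.293))
  inlet2 <- pulse_flow(7.92e-5)
  # branch waveforms identically zero: the descending carries the whole inlet
  tiny <- flow_waveform("innominate", inlet2$time, rep(0, length(inlet2$time)))
  r0 <- derive_case2_outlets(f1, inlet2, tiny)
  expect_equal(r0$factors$descending_inlet_scale, 1, tolerance = 1e-8)
  # constructed so the solved factor is 0.5101: with aligned same-shape
  # envelopes, peak(branches) = (1 - s) * peak(inlet)
  s0 <- 0.5101
  b_peak <- (1 - s0) * 7.92e-5 / (0.8243 * (1 + 0.293 + 0.293))
  inn2 <- pulse_flow(b_peak, "innominate")
  r <- derive_case2_outlets(f1, inlet2, inn2)
  expect_equal(r$factors$descending_inlet_scale, s0, tolerance = 1e-4)
  expect_equal(vapply(r$outlets, `[[`, "", "patch"),
               c("innominate", "lcca", "lsca", "descending_aorta"))
  # steady descending BC with the factor fixed externally: 0.5101 * 7.92e-5
  rf <- derive_case2_outlets(f1, inlet2, inn2, descending_scale = 0.5101)
  spec <- extract_steady_bcs(inlet2, rf$outlets)
  expect_equal(round(spec$outlet_flows[["descending_aorta"]] * 1e5, 2), 4.04)
  # missing ratios is a configuration error
  expect_error(derive_case2_outlets(split_factors(outlet_scale = 0.8),
                                    inlet2, inn2), "branch_ratios")
})

test_that("healthy split routes a fixed fraction distally and conserves mass pointwise", {
  inlet <- pulse_flow(7.92e-5)
  areas <- c(innominate = 5.2e-5, lcca = 1.4e-5, lsca = 2.0e-5)
  outs <- derive_case3_outlets(inlet, areas, fraction = 0.70)
  dao <- outs[[4]]
  expect_equal(dao$patch, "descending_aorta")
  expect_equal(max(dao$flow), 0.70 * 7.92e-5)
  total <- Reduce(`+`, lapply(outs, `[[`, "flow"))
  expect_equal(total, inlet$flow, tolerance = 1e-12)
  # equal areas: each branch carries (1 - f)/3 = 10% of the inlet
  eq <- derive_case3_outlets(inlet, c(innominate = 1, lcca = 1, lsca = 1), 0.70)
  expect_equal(max(eq[[1]]$flow), 0.10 * 7.92e-5, tolerance = 1e-12)
  # invariant under uniform rescaling of the areas
  outs2 <- derive_case3_outlets(inlet, areas * 1e3, fraction = 0.70)
  for (i in 1:4) expect_equal(outs2[[i]]$flow, outs[[i]]$flow)
  expect_error(derive_case3_outlets(inlet, areas[-1]), "patch_areas")
  expect_error(derive_case3_outlets(inlet, areas, fraction = 1),
               "strictly in")
})

test_that("steady BCs are read at the first inlet-peak instant and summed", {
  inlet <- pulse_flow(7.92e-5)
  # outlets proportional to the inlet: steady values are their own peaks
  outs <- derive_case3_outlets(inlet, c(innominate = 2, lcca = 1, lsca = 1))
  spec <- extract_steady_bcs(inlet, outs)
  expect_s3_class(spec, "boundary_spec")
  expect_equal(spec$inlet_flow, 7.92e-5, tolerance = 1e-9)
  expect_equal(spec$inlet_flow, sum(spec$outlet_flows))
  # a phase-lagged outlet reads strictly below its own peak
  lagged <- gen_waveform(waveform_params(1.0, phase_lag = 0.06), "lsca")
  ql <- velocity_to_flow(lagged, 1e-4)
  spec2 <- extract_steady_bcs(inlet, list(outs[[4]], ql))
  expect_lt(spec2$outlet_flows[["lsca"]], peak_of(ql)$q_max)
  expect_error(extract_steady_bcs(inlet, list()), "at least one outlet")
})

test_that("boundary specs enforce the conservation contract", {
  q <- c(innominate = 3.72e-5, lcca = 1.09e-5, lsca = 1.09e-5,
         descending_aorta = 1.94e-5)
  spec <- boundary_spec(q)
  expect_equal(spec$inlet_flow, 7.84e-5)
  expect_error(boundary_spec(q, inlet_flow = 7.92e-5), "sum of outlet")
  expect_error(boundary_spec(unname(q)), "named")
  expect_error(split_factors(outlet_scale = 2.5), "\\(0, 2\\]")
  expect_error(split_factors(descending_fraction = 1), "strictly in")
})

test_that("flow reports serialize factors and per-patch values", {
  spec <- boundary_spec(c(innominate = 3.72e-5, lcca = 1.09e-5,
                          lsca = 1.09e-5, descending_aorta = 1.94e-5))
  fac <- split_factors(outlet_scale = 0.8243,
                       branch_ratios = c(lcca = 0.293, lsca = 0.293))
  fy <- tempfile(fileext = ".yaml")
  write_flow_report(spec, fac, fy)
  y <- yaml::read_yaml(fy)
  expect_equal(y$outlets$innominate$display, 3.72)
  expect_equal(y$factors$outlet_scale, 0.8243)
  fj <- tempfile(fileext = ".json")
  write_flow_report(spec, fac, fj)
  j <- jsonlite::read_json(fj)
  expect_equal(j$inlet$si, 7.84e-5)
})
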