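cfg <- analysis_config()   # gamma 0.0067, window 10, min flux 1 au/s

test_that("steady-state flux is gamma times profile height", {
  prof <- flat_profile(300, 100)
  expect_equal(rnap_flux_at(prof, 50, cfg), 2.01)
  expect_equal(rnap_flux_at(flat_profile(0, 100), 50, cfg), 0)
  expect_error(rnap_flux_at(prof, 101, cfg), "out of bounds")
})

test_that("promoter activity is the windowed rise in flux", {
  vals <- c(rep(100, 50), rep(400, 50))
  prof <- transcription_profile(vals, "p", "sense")
  # part occupies [41, 60]: upstream window [31,40] at 100, downstream
  # [61,70] at 400
  expect_equal(promoter_activity(prof, 41, 60, cfg), 0.0067 * 300)
  expect_equal(promoter_activity(flat_profile(100, 100), 41, 60, cfg), 0)
  expect_error(promoter_activity(prof, 5, 60, cfg), "out of profile")
  # linearity in the profile
  prof2 <- scale_profile(prof, 3)
  expect_equal(promoter_activity(prof2, 41, 60, cfg),
               3 * promoter_activity(prof, 41, 60, cfg))
})

test_that("terminator strength is the upstream/downstream fold drop", {
  vals <- c(rep(500, 60), rep(2.5, 60))
  prof <- transcription_profile(vals, "p", "sense")
  part <- list(start = 55, end = 62)
  ts <- terminator_strength(prof, part, cfg)
  expect_equal(ts$Ts, 200)
  expect_false(ts$filtered)
  # scale invariance
  expect_equal(terminator_strength(scale_profile(prof, 10), part, cfg)$Ts, 200)
  # no drop
  expect_equal(terminator_strength(flat_profile(500, 120), part, cfg)$Ts, 1)
  # low incoming flux (< 1 au/s) is filtered: 0.5 au/s = 74.6 au
  low <- transcription_profile(c(rep(0.5 / 0.0067, 60), rep(1, 60)), "p", "sense")
  tl <- terminator_strength(low, part, cfg)
  expect_true(tl$filtered)
  expect_match(tl$reason, "low input flux")
  # zero downstream window reports +Inf with a flag
  z <- transcription_profile(c(rep(500, 60), rep(0, 60)), "p", "sense")
  tz <- terminator_strength(z, part, cfg)
  expect_equal(tz$Ts, Inf)
  expect_true(tz$filtered)
})

test_that("ribozyme cleavage efficiency from net fluxes around the cut", {
  gamma <- cfg$gamma
  # background 0; level 10/gamma au before the cut, 100/gamma after
  vals <- c(rep(0, 100), rep(10 / gamma, 100), rep(100 / gamma, 300))
  prof <- transcription_profile(vals, "p", "sense")
  rz <- list(start = 150, end = 260, cut_site = 200)
  r <- ribozyme_cleavage_efficiency(prof, rz, cfg, background_boundary = 101)
  expect_equal(r$p_c, 0.9)
  expect_false(r$filtered)
  # complete cleavage: zero upstream of the cut
  vals2 <- c(rep(0, 200), rep(100 / gamma, 300))
  r2 <- ribozyme_cleavage_efficiency(
    transcription_profile(vals2, "p", "sense"), rz, cfg, 101)
  expect_equal(r2$p_c, 1)
  # low flux leaving the ribozyme is filtered
  vals3 <- c(rep(0, 200), rep(0.5 / gamma, 300))
  r3 <- ribozyme_cleavage_efficiency(
    transcription_profile(vals3, "p", "sense"), rz, cfg, 101)
  expect_true(r3$filtered)
  expect_error(
    ribozyme_cleavage_efficiency(prof, list(start = 1, end = 10,
                                            cut_site = NA), cfg),
    "cut_site")
})

test_that("antisense activity is gamma times the regional mean", {
  anti <- flat_profile(150, 400, strand = "antisense")
  expect_equal(antisense_activity(anti, list(start = 100, end = 200), cfg),
               1.005)
  expect_equal(antisense_activity(flat_profile(0, 400, strand = "antisense"),
                                  list(start = 100, end = 200), cfg), 0)
  expect_error(antisense_activity(anti, list(start = 350, end = 450), cfg),
               "bounds")
})

test_that("measuring the recovery circuit's expected profile returns truth", {
  ann <- recovery_circuit()
  truth <- recovery_truth()
  prof <- simulate_expected_profile(ann, truth, "s1")
  m <- measure_parts(prof$sense, ann, cfg, "s1", prof$antisense)
  expect_equal(m$value[m$part == "Pdemo" & m$metric == "delta_J"], 2.01)
  expect_equal(m$value[m$part == "Tdemo" & m$metric == "Ts"], 20)
  expect_equal(m$value[m$part == "RzDemo" & m$metric == "p_c"], 0.9)
  expect_false(any(m$filtered[m$metric %in% c("delta_J", "Ts", "p_c")]))
})

test_that("tandem promoters are measured as one combined part", {
  ann <- example_circuit_annotation()
  truth <- example_circuit_truth()
  prof <- simulate_expected_profile(ann, truth, "+/+/-")
  m <- measure_parts(prof$sense, ann, analysis_config(), "+/+/-")
  expect_true("P_Tac-P_Tet1" %in% m$part)
  expect_false("P_Tac" %in% m$part)
  # combined activity equals the sum of the tandem pair's true activities
  a <- truth$promoter_activities[["+/+/-"]]
  expect_equal(m$value[m$part == "P_Tac-P_Tet1"],
               unname(a["P_Tac"] + a["P_Tet1"]), tolerance = 1e-6)
})
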