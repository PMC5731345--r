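test_that("expected profiles follow the steady-state tracing rules", {
  parts <- data.frame(
    name = c("P1", "gene", "Term"),
    part_type = c("promoter", "cds", "terminator"),
    start = c(101L, 201L, 1201L), end = c(150L, 1100L, 1260L),
    strand = "+", cut_site = NA_real_, tss = c(150, NA, NA),
    stringsAsFactors = FALSE)
  ann <- circuit_annotation(parts, "p", 2000L)
  truth <- ground_truth(
    promoter_activities = list(s = c(P1 = 2.01)),
    terminator_Ts = c(Term = 100), gamma = 0.0067)
  prof <- simulate_expected_profile(ann, truth, "s")
  expect_equal(prof$sense$values[600], 300)     # M = deltaJ / gamma
  expect_equal(prof$sense$values[1500], 3)      # past Ts = 100
  expect_equal(prof$sense$values[50], 0)
  expect_equal(sum(prof$antisense$values), 0)
})

test_that("antisense promoters produce minus-strand plateaus upstream", {
  parts <- data.frame(
    name = c("P1", "gene", "Term"),
    part_type = c("promoter", "cds", "terminator"),
    start = c(101L, 201L, 1201L), end = c(150L, 1100L, 1260L),
    strand = "+", cut_site = NA_real_, tss = c(150, NA, NA),
    stringsAsFactors = FALSE)
  ann <- circuit_annotation(parts, "p", 2000L)
  truth <- ground_truth(
    promoter_activities = list(s = c(P1 = 2.01)),
    terminator_Ts = c(Term = 100),
    antisense_promoters = data.frame(name = "Prev", position = 800,
                                     activity = 0.67),
    gamma = 0.0067)
  prof <- simulate_expected_profile(ann, truth, "s")
  expect_equal(prof$antisense$values[400], 100)  # 0.67/0.0067, toward 5'
  expect_equal(prof$antisense$values[801], 0)    # nothing downstream of TSS
})

test_that("fragment sampling conserves mass, is seeded, honors bounds", {
  prof <- flat_profile(50, 2000)
  fr <- sample_fragments(prof, demo_fld(), depth = 5000, seed = 4)
  expect_equal(nrow(fr), 5000)
  cov <- build_strand_profiles(fr, 2000, reference_id = "demo")$sense
  expect_equal(sum(cov$values), sum(fr$end - fr$start + 1))
  expect_true(all(fr$start >= 1 & fr$end <= 2000))
  fr2 <- sample_fragments(prof, demo_fld(), depth = 5000, seed = 4)
  expect_identical(fr, fr2)
  expect_error(sample_fragments(prof, demo_fld(), depth = 0), ">= 1")
  expect_error(sample_fragments(flat_profile(50, 60), fld(100L, 1), 10),
               "exceeds every")
})

test_that("sampled end coverage matches the analytic curve", {
  prof <- flat_profile(10, 2000)
  fr <- sample_fragments(prof, fld(100L, 1), depth = 2e5, seed = 13)
  cov <- build_strand_profiles(fr, 2000, reference_id = "demo")$sense
  x <- 1:500
  oracle <- analytic_end_coverage(x, 100, 2000)
  dev <- cov$values[x] / max(cov$values[x]) - oracle / max(oracle)
  expect_lt(max(abs(dev)), 0.04)
})

test_that("multi-state experiments are complete and reproducible", {
  ann <- example_circuit_annotation()
  truth <- example_circuit_truth()
  states <- names(truth$promoter_activities)
  expect_length(states, 8)
  exp1 <- simulate_experiment(ann, truth, states, demo_fld(),
                              depth = 2000, seed = 17)
  expect_length(exp1$fragments, 8)
  expect_length(exp1$profiles, 8)
  exp2 <- simulate_experiment(ann, truth, states, demo_fld(),
                              depth = 2000, seed = 17)
  expect_identical(exp1$fragments, exp2$fragments)
  # sigma = 0: expected profiles regenerate exactly from the truth
  st <- states[3]
  direct <- simulate_expected_profile(ann, truth, st)
  expect_identical(exp1$profiles[[st]]$sense$values, direct$sense$values)
  expect_error(simulate_experiment(ann, truth, character(), demo_fld(),
                                   10, 1),
               "empty")
  expect_error(simulate_experiment(ann, truth, "no-such-state", demo_fld(),
                                   10, 1), "no activities")
})

test_that("the pipeline recovers part parameters from sampled fragments", {
  ann <- recovery_circuit()
  truth <- recovery_truth()
  exp_ <- simulate_experiment(ann, truth, "s1", demo_fld(),
                              depth = 2e5, seed = 31)
  rec <- recover_parameters(exp_, "s1", reference_gene = "gene1",
                            draws = 2e5)
  m <- rec$measurements
  dj <- m$value[m$part == "Pdemo" & m$metric == "delta_J"]
  ts <- m$value[m$part == "Tdemo" & m$metric == "Ts"]
  pc <- m$value[m$part == "RzDemo" & m$metric == "p_c"]
  expect_equal(dj, 2.01, tolerance = 0.10)
  expect_equal(ts, 20, tolerance = 0.15)
  expect_lt(abs(pc - 0.9), 0.05)
})
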