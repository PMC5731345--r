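test_that("RPU conversion is a zero-intercept proportional fit", {
  rpu <- c(0.1, 0.5, 1, 2, 3)
  conv <- fit_rpu_conversion(rpu, 2895 * rpu)
  expect_equal(conv$slope, 2895)
  expect_equal(conv$r_squared, 1)
  conv2 <- fit_rpu_conversion(rpu, 42 * rpu)
  expect_equal(conv2$slope, 42)
  expect_error(fit_rpu_conversion(1, 2895), ">= 2 states")
})

test_that("predicted profiles follow the tracing rules", {
  ann <- recovery_circuit()
  pred <- design_prediction(
    promoter_strengths = list(on = c(Pdemo = 100)),
    terminator_Ts = c(Tdemo = 50),
    ribozyme_pc = c(RzDemo = 0.9),
    units = "au")
  prof <- predict_profile(ann, pred, state = "on")
  expect_equal(prof$values[100], 0)           # upstream of the promoter
  expect_equal(prof$values[200], 10)          # pre-cut: 100 x (1 - 0.9)
  expect_equal(prof$values[500], 100)         # post-cut plateau
  expect_equal(prof$values[2000], 2)          # past terminator: 100 / 50
  # piecewise constant: change points only at TSS, cut site, terminator end
  changes <- which(diff(prof$values) != 0)
  expect_setequal(changes, c(134, 285, 1680))
  # linear in promoter strength
  pred2 <- pred
  pred2$promoter_strengths$on["Pdemo"] <- 300
  expect_equal(predict_profile(ann, pred2, state = "on")$values,
               3 * prof$values)
})

test_that("tandem promoters combine additively at the ribozyme", {
  parts <- data.frame(
    name = c("P1", "P2", "Rz", "gene", "Term"),
    part_type = c("promoter", "promoter", "ribozyme", "cds", "terminator"),
    start = c(101L, 151L, 201L, 401L, 1201L),
    end = c(150L, 200L, 280L, 1100L, 1260L),
    strand = "+",
    cut_site = c(NA, NA, 250, NA, NA),
    tss = c(150, 200, NA, NA, NA), stringsAsFactors = FALSE)
  ann <- circuit_annotation(parts, "p", 1500L)
  pred <- design_prediction(
    promoter_strengths = list(s = c(P1 = 30, P2 = 70)),
    terminator_Ts = c(Term = 10), ribozyme_pc = c(Rz = 0.9), units = "au")
  prof <- predict_profile(ann, pred, state = "s")
  expect_equal(prof$values[700], 100)           # 30 + 70 after the cut
  expect_equal(prof$values[175], 3)             # P1 only, x (1 - p_c)
  expect_equal(prof$values[230], 10)            # both, x (1 - p_c)
  expect_equal(prof$values[1400], 10)           # read-through 100/10
})

test_that("RPU predictions require a conversion factor and scale by it", {
  ann <- recovery_circuit()
  pred <- design_prediction(
    promoter_strengths = list(on = c(Pdemo = 2)),
    terminator_Ts = c(Tdemo = 50), ribozyme_pc = c(RzDemo = 1),
    units = "RPU")
  expect_error(predict_profile(ann, pred, state = "on"), "conversion")
  conv <- fit_rpu_conversion(c(1, 2), c(2895, 5790))
  prof <- predict_profile(ann, pred, conv, state = "on")
  expect_equal(prof$values[500], 2 * 2895)
})

test_that("predicted/observed comparison summarises per-gene agreement", {
  ann <- recovery_circuit()
  genes <- annotation_genes(ann)
  pred <- design_prediction(
    promoter_strengths = list(s1 = c(Pdemo = 300)),
    terminator_Ts = c(Tdemo = 20), ribozyme_pc = c(RzDemo = 0.9),
    units = "au")
  p1 <- predict_profile(ann, pred, state = "s1")
  same <- compare_predicted_observed(list(s1 = p1), list(s1 = p1), genes)
  expect_equal(same$summary$slope, 1)
  expect_equal(same$summary$r_squared, 1)
  doubled <- p1; doubled$values <- 2 * doubled$values
  two <- compare_predicted_observed(list(s1 = p1), list(s1 = doubled), genes)
  expect_equal(two$summary$slope, 2)
  other <- p1; other$reference_id <- "elsewhere"
  expect_error(compare_predicted_observed(list(s1 = p1), list(s1 = other),
                                          genes),
               "different references")
  expect_error(compare_predicted_observed(list(s1 = p1), list(s1 = p1),
                                          genes[0, ]), "empty gene list")
})
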