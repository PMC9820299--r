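specs <- default_parameter_specs()

test_that("normalization clamps at the curve ends and hits breakpoints", {
  tn <- specs$TN
  expect_equal(normalize_parameter(0, tn), 100)
  expect_equal(normalize_parameter(-0.5, tn), 100)   # better than ideal
  expect_equal(normalize_parameter(10, tn), 0)       # beyond worst
  # interior breakpoints return exactly their tabulated sub-index
  for (k in seq_along(tn$curve$conc))
    expect_equal(normalize_parameter(tn$curve$conc[k], tn), tn$curve$ci[k])
  expect_error(normalize_parameter(Inf, tn), "non-finite")

  stepped <- parameter_spec("X", curve = list(conc = c(0, 1, 2),
                                              ci = c(100, 60, 20),
                                              interpolation = "step"))
  expect_equal(normalize_parameter(1.5, stepped), 60)
  expect_equal(normalize_parameter(c(0.2, 1), stepped), c(100, 60))
})

test_that("WQI is the weighted mean of sub-indices", {
  two <- structure(list(
    parameter_spec("A", weight = 1,
                   curve = list(conc = c(0, 100), ci = c(100, 0))),
    parameter_spec("B", weight = 3,
                   curve = list(conc = c(0, 100), ci = c(100, 0)))),
    names = c("A", "B"), class = "wq_spec_set")
  # concentrations 20 and 40 map linearly to Ci = 80 and 60
  res <- compute_wqi(c(A = 20, B = 40), two)
  expect_equal(res$value, (80 * 1 + 60 * 3) / 4)
  expect_equal(res$value, 65)

  perfect <- compute_wqi(c(A = 0, B = 0), two)
  expect_equal(perfect$value, 100)

  # invariance under common rescaling of all weights
  scaled <- two
  for (nm in names(scaled)) scaled[[nm]]$weight <- scaled[[nm]]$weight * 7
  expect_equal(compute_wqi(c(A = 20, B = 40), scaled)$value, res$value)

  # missing parameters drop out of both sums
  expect_equal(compute_wqi(c(A = 20, B = NA), two)$value, 80)
  expect_error(compute_wqi(c(A = NA_real_), two), "no measured")
})

test_that("grading follows the five published bands", {
  expect_equal(classify_wqi(72.1), "Good")
  expect_equal(classify_wqi(68.31), "Moderate")
  expect_equal(classify_wqi(100), "Excellent")
  expect_equal(classify_wqi(0), "Very poor")
  expect_equal(classify_wqi(c(91, 90.5, 71, 70.5, 51, 50.5, 26, 25.5)),
               c("Excellent", "Good", "Good", "Moderate", "Moderate",
                 "Poor", "Poor", "Very poor"))
  expect_error(classify_wqi(101), "0, 100")
})

test_that("WQI bounds and monotonicity hold on random records", {
  set.seed(1)
  params <- wq_parameters()
  for (rep in 1:200) {
    rec <- setNames(runif(14, 0, 5), params)
    rec["F_coli"] <- runif(1, 0, 5e4)
    rec["pH"] <- runif(1, 5, 10)
    drop <- sample(14, sample(0:10, 1))
    if (length(drop) && length(drop) < 14) rec[drop] <- NA
    if (all(is.na(rec))) next
    res <- compute_wqi(rec, specs)
    ci <- res$sub_indices[!is.na(res$sub_indices)]
    expect_gte(res$value, min(ci) - 1e-12)
    expect_lte(res$value, max(ci) + 1e-12)

    # worsening one pollutant never raises the index
    worse <- rec
    worse["TN"] <- if (is.na(rec["TN"])) 3 else rec[["TN"]] + 1
    expect_lte(compute_wqi(worse, specs)$value, res$value + 1e-12)
  }
})

test_that("descriptive statistics match brute-force counting", {
  model <- generate_source_model(5, seed = 31)
  ds <- simulate_monitoring(model, 3, 30, seed = 32)
  st <- descriptive_stats(ds, specs)

  # constant series has zero CV
  const <- ds
  const$values[, "TN"] <- 1.2
  st_const <- descriptive_stats(const, specs)
  expect_equal(st_const$cv_pct[st_const$parameter == "TN" &
                                 st_const$station == "ALL"], 0)

  # worked exceedance example: [0.5, 1.2, 2.1] against threshold 1.0
  toy <- ds
  toy$values <- toy$values[1:3, , drop = FALSE]
  toy$censored <- toy$censored[1:3, , drop = FALSE]
  toy$station <- factor(rep("S1", 3))
  toy$date <- toy$date[1:3]
  toy$values[, "TN"] <- c(0.5, 1.2, 2.1)
  row <- descriptive_stats(toy, specs)
  expect_equal(row$exceed_III[row$parameter == "TN" & row$station == "ALL"],
               2 / 3, tolerance = 1e-12)

  # brute-force exceedance scan for every parameter with class standards
  all_rows <- st[st$station == "ALL", ]
  for (nm in c("TN", "CODMn", "Fe", "Mn")) {
    thr <- specs[[nm]]$class_standards[["III"]]
    expect_equal(all_rows$exceed_III[all_rows$parameter == nm],
                 mean(ds$values[, nm] > thr))
  }
  # DO exceeds in the downward direction
  do_thr <- specs$DO$class_standards[["III"]]
  expect_equal(all_rows$exceed_III[all_rows$parameter == "DO"],
               mean(ds$values[, "DO"] < do_thr))
})
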