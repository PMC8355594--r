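write_toy_csv <- function(traces, path) {
  d <- tibble::as_tibble(traces)
  names(d) <- c("well", "group", "experiment", "measurement", "time_min",
                "OCR", "ECAR")
  readr::write_csv(d, path)
  path
}

test_that("read_flux_table conserves rows and is order-insensitive", {
  tr <- toy_traces(list(c(100, 40, 150, 20), c(90, 35, 140, 18)))
  f <- write_toy_csv(tr, withr::local_tempfile(fileext = ".csv"))
  got <- read_flux_table(f)
  expect_equal(nrow(got), 24)

  shuffled <- readr::read_csv(f, show_col_types = FALSE)
  set.seed(1)
  shuffled <- shuffled[sample(nrow(shuffled)), ]
  f2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(shuffled, f2)
  got2 <- read_flux_table(f2)
  expect_equal(tibble::as_tibble(got2), tibble::as_tibble(got))
})

test_that("read_flux_table names the missing column and the broken well", {
  tr <- toy_traces(c(100, 40, 150, 20))
  f <- withr::local_tempfile(fileext = ".csv")
  d <- tibble::as_tibble(tr)
  names(d) <- c("well", "group", "experiment", "measurement", "time_min",
                "OCR", "ECAR")
  readr::write_csv(dplyr::select(d, -"ECAR"), f)
  expect_error(read_flux_table(f), "ECAR")

  d2 <- d[d$measurement != 5, ] # gap in well W01
  readr::write_csv(d2, f)
  expect_error(read_flux_table(f), "W01")
})

test_that("normalization divides by cells per unit and refuses reuse", {
  tr <- toy_traces(list(c(200, 80, 300, 40), c(200, 80, 300, 40)))
  counts <- tibble::tibble(well = c("W01", "W02"), cells = c(2000, 1000))
  norm <- normalize_per_well(tr, counts)
  expect_equal(norm$ocr[norm$well == "W01" & norm$measurement == 1], 100)
  expect_equal(
    norm$ocr[norm$well == "W02"], 2 * norm$ocr[norm$well == "W01"]
  )
  expect_error(normalize_per_well(norm, counts), "already normalized")
  expect_error(normalize_per_well(tr, counts[1, ]), "W02")
  expect_error(
    normalize_per_well(tr, tibble::tibble(well = c("W01", "W02"),
                                          cells = c(0, 1000))),
    "positive"
  )
})

test_that("OCR/ECAR ratio is invariant to per-well normalization", {
  set.seed(42)
  phases <- replicate(6, runif(4, 10, 200), simplify = FALSE)
  ecar <- replicate(6, runif(4, 5, 60), simplify = FALSE)
  tr <- toy_traces(phases, ecar)
  counts <- tibble::tibble(well = sprintf("W%02d", 1:6),
                           cells = sample(2e4:2e5, 6))
  before <- compute_well_metrics(tr)
  after <- compute_well_metrics(normalize_per_well(tr, counts))
  expect_equal(after$ocr_ecar_ratio, before$ocr_ecar_ratio,
               tolerance = 1e-12)
})

test_that("phase assignment partitions measurements and checks bounds", {
  tr <- toy_traces(c(100, 40, 150, 20)) # 12 measurements, schedule 1/4/7/10
  ph <- assign_phases(tr)
  expect_equal(as.integer(table(ph$phase)), c(3, 3, 3, 3))
  expect_equal(as.character(ph$phase[ph$measurement %in% 7:9]),
               rep("FCCP", 3))
  bad <- injection_schedule(1L, 4L, 7L, 13L)
  expect_error(assign_phases(tr, bad), "exceeds the last measurement")
})

test_that("schedule construction enforces ordering invariants", {
  expect_error(injection_schedule(2L, 4L, 7L, 10L), "measurement 1")
  expect_error(injection_schedule(1L, 7L, 4L, 10L), "strictly increasing")
})

test_that("well metrics follow the subtraction formulas", {
  m <- compute_well_metrics(toy_traces(c(100, 40, 150, 20),
                                       c(30, 45, 45, 24)))
  expect_equal(m$basal_ocr, 80)
  expect_equal(m$maximal_ocr, 130)
  expect_equal(m$src, 50)
  expect_equal(m$basal_ecar, 30)
  expect_equal(m$ocr_ecar_ratio, 80 / 30)
  expect_equal(m$flags, "")

  flat <- compute_well_metrics(toy_traces(c(70, 70, 70, 70)))
  expect_equal(flat$basal_ocr, 0)
  expect_equal(flat$maximal_ocr, 0)
  expect_equal(flat$src, 0)
})

test_that("well metrics use the phase mean / FCCP maximum aggregators", {
  sched <- injection_schedule(1L, 4L, 7L, 10L)
  rec <- tibble::tibble(
    well = "W1", group = "G", experiment = "toy", measurement = 1:12,
    time_min = (0:11) * 6.5,
    ocr = c(98, 102, 100, 41, 39, 40, 140, 151, 148, 19, 21, 20),
    ecar = c(29, 31, 30, rep(45, 6), rep(24, 3))
  )
  m <- compute_well_metrics(flux_traces(rec, schedule = sched))
  expect_equal(m$basal_ocr, 80)     # mean(98,102,100) - mean(19,21,20)
  expect_equal(m$maximal_ocr, 131)  # max(140,151,148) - 20
  expect_equal(m$src, 51)
  expect_equal(m$basal_ecar, 30)

  last <- compute_well_metrics(flux_traces(rec, schedule = sched),
                               baseline_mode = "last")
  expect_equal(last$basal_ocr, 100 - 20)
  expect_equal(last$basal_ecar, 30)

  excl <- compute_well_metrics(flux_traces(rec, schedule = sched),
                               exclude_first_post_injection = TRUE)
  expect_equal(excl$basal_ocr, 100 - mean(c(21, 20)))
  expect_equal(excl$maximal_ocr, max(151, 148) - mean(c(21, 20)))
})

test_that("an emptied phase is an error naming the phase", {
  tr <- toy_traces(c(100, 40, 150, 20), mpp = 1)
  expect_error(
    compute_well_metrics(tr, exclude_first_post_injection = TRUE),
    "oligomycin|FCCP|rot_aa"
  )
})

test_that("negative derived metrics are flagged, not clipped", {
  m <- compute_well_metrics(toy_traces(c(10, 8, 12, 50)))
  expect_lt(m$basal_ocr, 0)
  expect_match(m$flags, "negative_basal_ocr")
  expect_match(m$flags, "negative_maximal_ocr")
})

test_that("SRC identity and scale equivariance hold exactly", {
  set.seed(7)
  for (i in 1:25) {
    ocr <- runif(4, 5, 300)
    ecar <- runif(4, 2, 80)
    m <- compute_well_metrics(toy_traces(ocr, ecar))
    expect_identical(m$src, m$maximal_ocr - m$basal_ocr)
    k <- runif(1, 0.2, 8)
    mk <- compute_well_metrics(toy_traces(k * ocr, ecar))
    expect_equal(mk$basal_ocr, k * m$basal_ocr, tolerance = 1e-12)
    expect_equal(mk$maximal_ocr, k * m$maximal_ocr, tolerance = 1e-12)
    expect_equal(mk$src, k * m$src, tolerance = 1e-12)
    expect_equal(mk$ocr_ecar_ratio, k * m$ocr_ecar_ratio,
                 tolerance = 1e-12)
  }
})

test_that("raising a post-FCCP measurement never decreases maximal OCR", {
  set.seed(9)
  for (i in 1:20) {
    ocr <- runif(4, 10, 200)
    tr <- toy_traces(ocr)
    base <- compute_well_metrics(tr)$maximal_ocr
    j <- sample(7:9, 1) # an FCCP-phase measurement
    tr$ocr[tr$measurement == j] <- tr$ocr[tr$measurement == j] + runif(1, 0, 100)
    expect_gte(compute_well_metrics(tr)$maximal_ocr, base)
  }
})

test_that("group summaries use n-1 sd and mark single wells undefined", {
  tr <- toy_traces(
    list(c(90, 40, 150, 20), c(110, 40, 170, 20), c(80, 30, 120, 15)),
    groups = c("A", "A", "B")
  )
  s <- summarize_groups(compute_well_metrics(tr))
  a <- dplyr::filter(s, group == "A", metric == "basal_ocr")
  expect_equal(a$mean, 80)
  expect_equal(a$sd, sd(c(70, 90)))
  expect_equal(a$sd, 14.142, tolerance = 1e-4)
  b <- dplyr::filter(s, group == "B", metric == "basal_ocr")
  expect_true(is.na(b$sd))
  expect_equal(b$n, 1L)

  same <- toy_traces(list(c(100, 40, 150, 20), c(100, 40, 150, 20)))
  s2 <- summarize_groups(compute_well_metrics(same))
  expect_true(all(s2$sd == 0))
})

test_that("group comparisons run Welch t with one BH family per call", {
  tr <- toy_traces(
    list(c(100, 40, 150, 20), c(100, 40, 150, 20),
         c(100, 40, 150, 20), c(100, 40, 150, 20)),
    groups = c("A", "A", "B", "B")
  )
  cmp <- compare_groups(compute_well_metrics(tr),
                        metric_names = "basal_ocr")
  expect_equal(cmp$t, 0)
  expect_equal(cmp$p, 1)
  expect_equal(cmp$p_adj, cmp$p) # family of one comparison

  shifted <- toy_traces(
    list(c(101, 40, 150, 20), c(102, 40, 150, 20), c(103, 40, 150, 20),
         c(111, 40, 150, 20), c(112, 40, 150, 20), c(113, 40, 150, 20)),
    groups = c("A", "A", "A", "B", "B", "B")
  )
  mets <- compute_well_metrics(shifted)
  cmp2 <- compare_groups(mets, metric_names = "basal_ocr")
  want <- welch_oracle(c(81, 82, 83), c(91, 92, 93))
  expect_equal(abs(cmp2$t), abs(want$t), tolerance = 1e-9)

  one <- toy_traces(list(c(100, 40, 150, 20), c(90, 35, 140, 18)),
                    groups = c("A", "B"))
  expect_error(compare_groups(compute_well_metrics(one)),
               "fewer than 2")
})
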