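parallel_traces <- function(width = 20, n = 41, length = 200) {
  list(pre = membrane_trace(cbind(seq(0, length, length.out = n), 0), 1, "presynaptic"),
       post = membrane_trace(cbind(seq(0, length, length.out = n), width), 1, "postsynaptic"))
}

test_that("parallel membranes measure a uniform cleft", {
  tr <- parallel_traces(20)
  pr <- measure_cleft_width(tr$pre, tr$post, step_nm = 2)
  expect_equal(pr$mean_nm, 20, tolerance = 1e-12)
  expect_equal(pr$cv, 0, tolerance = 1e-12)
  expect_identical(pr$n_dropped, 0L)
  expect_true(all(pr$widths_nm > 0))
})

test_that("concentric arcs measure the analytic width to 1e-6 nm", {
  th <- seq(0, pi / 2, length.out = 8001)
  pre <- membrane_trace(cbind(200 * cos(th), 200 * sin(th)), 1, "presynaptic")
  post <- membrane_trace(cbind(220 * cos(th), 220 * sin(th)), 1, "postsynaptic")
  pr <- measure_cleft_width(pre, post, step_nm = 2)
  expect_lt(max(abs(pr$widths_nm - 20)), 1e-6)
})

test_that("intersecting or disjoint traces are rejected", {
  cross_a <- membrane_trace(cbind(c(0, 10), c(0, 10)), 1, "presynaptic")
  cross_b <- membrane_trace(cbind(c(0, 10), c(10, 0)), 1, "postsynaptic")
  expect_error(measure_cleft_width(cross_a, cross_b), "intersect")
  away <- membrane_trace(cbind(c(100, 110), c(200, 200)), 1, "postsynaptic")
  side <- membrane_trace(cbind(c(0, 0.001), c(0, 10)), 1, "presynaptic")
  expect_error(measure_cleft_width(side, away), "no normal")
})

test_that("phantom width statistics are recovered under jitter", {
  set.seed(401)
  means <- sds <- numeric(30)
  for (i in 1:30) {
    ph <- generate_synapse_phantom(i, width_nm = 20, width_jitter_sd = 2,
                                   n_vesicles = 0)
    pr <- measure_cleft_width(ph$annotation$membranes[[1]],
                              ph$annotation$membranes[[2]], 2)
    means[i] <- pr$mean_nm; sds[i] <- pr$sd_nm
  }
  expect_lt(abs(mean(means) - 20), 0.5)
  expect_lt(abs(mean(sds) - 2) / 2, 0.3)
})

test_that("cleft width is symmetric under swapping the traces", {
  ph <- generate_synapse_phantom(11, n_vesicles = 0)
  a <- measure_cleft_width(ph$annotation$membranes[[1]], ph$annotation$membranes[[2]], 2)
  b <- measure_cleft_width(ph$annotation$membranes[[2]], ph$annotation$membranes[[1]], 2)
  expect_lt(abs(a$mean_nm - b$mean_nm), 2)  # <= step_nm
})

test_that("vesicle states partition by gap with annotation-flag overrides", {
  tr <- parallel_traces(20, length = 400)
  th <- morphometry_thresholds()
  mk <- function(gap, r = 20, ...) vesicle(c(200, -(r + gap)), r, ...)
  expect_identical(classify_vesicle_state(mk(0), tr$pre, th), "docked_or_primed")
  expect_identical(classify_vesicle_state(mk(8), tr$pre, th), "tethered_candidate")
  expect_identical(classify_vesicle_state(mk(100), tr$pre, th), "free")
  expect_identical(classify_vesicle_state(mk(2.01), tr$pre, th), "tethered_candidate")
  expect_identical(classify_vesicle_state(mk(0, fusing = TRUE), tr$pre, th), "fusing")
  expect_identical(classify_vesicle_state(mk(0, fused = TRUE), tr$pre, th), "fully_fused")
  # center more than one radius beyond the membrane: inconsistent annotation
  beyond <- vesicle(c(200, 25), 20)
  expect_error(classify_vesicle_state(beyond, tr$pre, th), "inconsistent")
  # total partition over random gaps
  set.seed(402)
  for (i in 1:50) {
    g <- stats::runif(1, -5, 200)
    st <- classify_vesicle_state(mk(g), tr$pre, th)
    expect_true(st %in% c("docked_or_primed", "tethered_candidate", "free"))
  }
})

test_that("phantom state mixes are classified in full agreement with truth", {
  set.seed(403)
  for (i in 1:10) {
    ph <- generate_synapse_phantom(i, state_mix = c(docked = 2, tethered = 3,
                                                    fusing = 1, fused = 1),
                                   n_vesicles = 20)
    pre <- ph$annotation$membranes[[1]]
    states <- vapply(ph$annotation$vesicles, classify_vesicle_state, "",
                     pre = pre, pixel_size_nm = ph$annotation$pixel_size_nm)
    expect_identical(unname(states), ph$truth$states)
  }
  expect_error(generate_synapse_phantom(1, n_vesicles = 2,
                                        state_mix = c(docked = 5)), "state mix")
})

test_that("the canonical phantom passes all three identification criteria", {
  ph <- generate_synapse_phantom(7)
  prof <- measure_cleft_width(ph$annotation$membranes[[1]],
                              ph$annotation$membranes[[2]], 2)
  rep <- evaluate_synapse_criteria(ph$annotation, prof, cleft_density = TRUE)
  expect_true(rep$c1); expect_true(rep$c2); expect_true(rep$c3)
  expect_identical(rep$evidence$vesicles_postsynaptic, 0)
})

test_that("degenerate annotations fail the intended criterion", {
  # single membrane, no vesicles
  lone <- synapse_annotation(
    membranes = list(membrane_trace(cbind(0:10, 0), 1, "presynaptic")))
  rep1 <- evaluate_synapse_criteria(lone, profile = NULL, cleft_density = TRUE)
  expect_false(rep1$c1); expect_false(rep1$c2); expect_false(rep1$c3)
  # 40 nm cleft: C3 fails, C1/C2 intact
  ph <- generate_synapse_phantom(8, width_nm = 40)
  prof <- measure_cleft_width(ph$annotation$membranes[[1]],
                              ph$annotation$membranes[[2]], 2)
  rep2 <- evaluate_synapse_criteria(ph$annotation, prof)
  expect_true(rep2$c1); expect_true(rep2$c2); expect_false(rep2$c3)
  # no membranes at all
  expect_error(evaluate_synapse_criteria(synapse_annotation(), NULL), "no membranes")
  # missing density evidence sinks C3 even at the right width
  ph2 <- generate_synapse_phantom(9)
  prof2 <- measure_cleft_width(ph2$annotation$membranes[[1]],
                               ph2$annotation$membranes[[2]], 2)
  expect_false(evaluate_synapse_criteria(ph2$annotation, prof2,
                                         cleft_density = FALSE)$c3)
})

test_that("vesicle population statistics summarize sizes, states and connectors", {
  empty <- vesicle_population_stats(synapse_annotation())
  expect_identical(empty$n_vesicles, 0L)
  expect_true(all(empty$state_histogram == 0))
  tr <- parallel_traces(20, length = 800)
  ves <- lapply(seq(50, 750, length.out = 10),
                function(x) vesicle(c(x, -100), radius_nm = 20))
  ann <- synapse_annotation(list(tr$pre), ves)
  st <- vesicle_population_stats(ann)
  expect_equal(st$diameter_mean_nm, 40)
  expect_equal(st$diameter_sd_nm, 0)
  expect_identical(unname(st$state_histogram["free"]), 10L)
  # known connector graph from the phantom generator
  ph <- generate_synapse_phantom(12, n_vesicles = 12, n_connectors = 6)
  stats_ph <- vesicle_population_stats(ph$annotation)
  truth_deg <- tabulate(ph$truth$connector_pairs, nbins = 12)
  expect_identical(stats_ph$connector_degree, truth_deg)
})

test_that("measurements are invariant to the annotation pixel size", {
  a <- generate_synapse_phantom(5, pixel_size_nm = 1)
  b <- generate_synapse_phantom(5, pixel_size_nm = 2)
  pa <- measure_cleft_width(a$annotation$membranes[[1]], a$annotation$membranes[[2]], 2)
  pb <- measure_cleft_width(b$annotation$membranes[[1]], b$annotation$membranes[[2]], 2)
  expect_lt(abs(pa$mean_nm - pb$mean_nm), 1e-6)
  sa <- vesicle_population_stats(a$annotation)
  sb <- vesicle_population_stats(b$annotation)
  expect_equal(sa$diameter_mean_nm, sb$diameter_mean_nm, tolerance = 1e-9)
  expect_identical(as.integer(sa$state_histogram), as.integer(sb$state_histogram))
})

test_that("annotations round-trip through JSON", {
  ph <- generate_synapse_phantom(6, n_vesicles = 8, n_connectors = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_annotation(ph$annotation, f)
  back <- read_annotation(f)
  expect_equal(back$membranes[[1]]$polyline, ph$annotation$membranes[[1]]$polyline,
               tolerance = 1e-12)
  expect_identical(back$membranes[[2]]$label, "postsynaptic")
  expect_equal(back$vesicles[[3]]$center, ph$annotation$vesicles[[3]]$center,
               tolerance = 1e-12)
  expect_equal(back$connectors, ph$annotation$connectors, tolerance = 1e-12)
})

test_that("malformed membrane traces are rejected", {
  expect_error(membrane_trace(cbind(1, 2), 1, "presynaptic"), ">= 2")
  expect_error(membrane_trace(rbind(c(0, 0), c(0, 0), c(1, 1)), 1, "other"),
               "distinct")
})
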