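test_that("traffic efficiency is the per-image median ratio with cell-count QC", {
  cells <- data.frame(image_id = "img1",
                      surface_signal = rep(2, 21), total_signal = rep(4, 21))
  te <- traffic_efficiency(cells)
  expect_equal(te$te, 0.5)
  expect_true(te$qc_pass)

  few <- data.frame(image_id = "img2",
                    surface_signal = rep(2, 19), total_signal = rep(4, 19))
  expect_false(traffic_efficiency(few)$qc_pass)

  ladder <- data.frame(image_id = "img3",
                       surface_signal = 0.1 * (1:25), total_signal = 1)
  expect_equal(traffic_efficiency(ladder)$te, 1.3)

  bad <- data.frame(image_id = "img4", surface_signal = 1,
                    total_signal = c(rep(1, 5), 0))
  expect_error(traffic_efficiency(bad), "total signal")
})

test_that("deviation scores follow the 2xSEM normalisation and are scale-free", {
  expect_equal(deviation_score(0.6, 0.6, 0.05), 0)
  expect_equal(deviation_score(0.6 + 2 * 0.05, 0.6, 0.05), 1)
  expect_equal(deviation_score(0.8, 0.6, 0.05), 2)
  expect_error(deviation_score(0.8, 0.6, 0), "positive")
  # affine equivariance: scaling every TE and SEM by c > 0 leaves DS fixed
  c0 <- 3.7
  expect_equal(deviation_score(c0 * 0.8, c0 * 0.6, c0 * 0.05), 2)
})

test_that("well summaries average only QC-passing images and controls give a SEM", {
  set.seed(2)
  cells <- do.call(rbind, lapply(1:4, function(w) {
    do.call(rbind, lapply(1:3, function(i) {
      n <- if (w == 1 && i == 3) 10 else 25   # one failing image
      data.frame(image_id = sprintf("w%d_i%d", w, i),
                 well_id = sprintf("w%d", w),
                 condition = if (w <= 2) "EGFP" else "siX",
                 surface_signal = rnorm(n, 2, 0.1),
                 total_signal = 4)
    }))
  }))
  wells <- well_traffic_efficiency(cells)
  expect_equal(wells$n_images_passed[wells$well_id == "w1"], 2)
  cs <- control_stats(wells, "EGFP")
  expect_equal(cs$n_wells, 2)
  expect_gt(cs$sem, 0)
})

test_that("the siRNA global effect reproduces the published worked rows", {
  rows <- list(NF2_1 = c(-0.701, 0.319, -0.761),
               IQGAP1_1 = c(0.536, 0.264, 0.044))
  types <- c("wt", "F508del", "F508del_VX809")
  ds <- do.call(rbind, lapply(names(rows), function(s) {
    data.frame(sirna = s, cftr_type = rep(types, each = 3),
               replicate = rep(1:3, 3), ds = rep(rows[[s]], each = 3))
  }))
  expect_equal(sirna_effect(ds, "NF2_1")$effect, 1.781, tolerance = 1e-12)
  expect_equal(sirna_effect(ds, "IQGAP1_1")$effect, 0.844, tolerance = 1e-12)
  expect_equal(unname(sirna_effect(ds, "NF2_1")$type_means),
               rows$NF2_1)

  zero <- ds; zero$ds <- 0
  expect_equal(sirna_effect(zero, "NF2_1")$effect, 0)
  expect_error(sirna_effect(ds[ds$cftr_type != "wt" | ds$sirna != "NF2_1", ],
                            "NF2_1"), "lacks scores")
})

test_that("the effect dominates each single type mean", {
  scr <- generate_screen(n_sirnas = 6, seed = 41)
  for (s in unique(scr$sirna)) {
    eff <- sirna_effect(scr, s)
    expect_gte(eff$effect, max(abs(eff$type_means)) - 1e-12)
  }
})

test_that("a constant matrix gives permutation p = 1 everywhere", {
  ds <- expand.grid(sirna = sprintf("s%d", 1:5),
                    cftr_type = c("wt", "F508del", "F508del_VX809"),
                    replicate = 1:3, stringsAsFactors = FALSE)
  ds$ds <- 0.7
  res <- suppressWarnings(permutation_test(ds, n_perm = 99, seed = 3))
  expect_true(all(res$p == 1))
})

test_that("permutation p is invariant to siRNA relabelling", {
  scr <- generate_screen(n_sirnas = 8, planted = list(siRNA_03 = c(2, 2, 2)),
                         seed = 19)
  r1 <- permutation_test(scr, n_perm = 500, seed = 7)
  relabel <- scr
  relabel$sirna <- paste0("z_", relabel$sirna)
  r2 <- permutation_test(relabel, n_perm = 500, seed = 7)
  expect_equal(r1$p[r1$sirna == "siRNA_03"],
               r2$p[r2$sirna == "z_siRNA_03"])
})

test_that("a strongly planted siRNA is detected", {
  hits <- 0
  for (seed in 1:10) {
    scr <- generate_screen(planted = list(siRNA_01 = c(3, 3, 3)),
                           seed = seed)
    res <- permutation_test(scr, n_perm = 1000, seed = seed + 1000)
    hits <- hits + (res$p[res$sirna == "siRNA_01"] < 0.05)
  }
  expect_gte(hits, 9)
})

test_that("decay fitting recovers noiseless model parameters exactly", {
  tt <- seq(0, 70, by = 0.5)
  tr <- data.frame(t = tt,
                   F = ifelse(tt <= 10, 1, 0.1 + 0.9 * exp(-0.08 * (tt - 10))))
  fit <- fit_decay(tr, baseline_end = 10)
  expect_equal(fit$rate, 0.08, tolerance = 1e-8)
  expect_equal(fit$amplitude, 0.9, tolerance = 1e-8)
  expect_equal(fit$initial_slope, -0.072, tolerance = 1e-8)

  flat <- data.frame(t = tt, F = 5)
  ffit <- fit_decay(flat, baseline_end = 10)
  expect_equal(ffit$amplitude, 0)
  expect_equal(ffit$initial_slope, 0)

  expect_error(fit_decay(tr[tr$t <= 12, ], 10), "at least 10")
})

test_that("decay slope is recovered within 5% under realistic noise", {
  set.seed(77)
  for (rep in 1:10) {
    tt <- seq(0, 70, by = 0.5)
    clean <- ifelse(tt <= 10, 1, 0.1 + 0.9 * exp(-0.08 * (tt - 10)))
    tr <- data.frame(t = tt, F = clean + rnorm(length(tt), 0, 0.01))
    fit <- fit_decay(tr, baseline_end = 10)
    expect_lt(abs(fit$initial_slope - (-0.072)) / 0.072, 0.05)
  }
})

test_that("surface retention normalises to the reference condition", {
  expect_equal(surface_retention(0.4, 0.4), 100)
  expect_equal(surface_retention(0.46 * 0.4, 0.4), 46)
  expect_equal(surface_retention(0, 0.4), 0)
  expect_error(surface_retention(0.2, 0), "positive")
})
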