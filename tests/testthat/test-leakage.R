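noise_free <- function(...) {
  section_spec(..., noise_gain = 0, read_noise_sd = 0)
}

test_that("a leak-free section scores at the noise floor", {
  sec <- generate_section(noise_free(leak_fraction = 0, seed = 2,
                                     intravascular_hb = 0))
  px <- 2.5
  v <- detect_vessels(sec$image$channels$lectin, sec$truth$regions,
                      pixel_size_um = px)
  gm <- gm_hb_score(sec$image$channels$hemoglobin, v, sec$truth$regions,
                    pixel_size_um = px)
  wm <- wm_hb_score(sec$image$channels$hemoglobin, sec$truth$regions,
                    pixel_size_um = px)
  expect_equal(gm, 0)
  expect_equal(wm, 0)
})

test_that("a single halo is recovered within 5 percent of its rendered
           integral", {
  # one leaked vessel, no intravascular signal, ample gray matter
  sec <- generate_section(noise_free(n_vessels = 1, leak_fraction = 1,
                                     intravascular_hb = 0,
                                     n_neurons_per_horn = 0,
                                     n_inclusions = 0, seed = 8))
  px <- 2.5
  reg <- sec$truth$regions
  v <- detect_vessels(sec$image$channels$lectin, reg, pixel_size_um = px)
  truth <- sec$truth$hb_extravascular
  comp <- sec$truth$vessels$leaked[1] # placed wherever the generator put it
  expect_true(comp)
  gm <- gm_hb_score(sec$image$channels$hemoglobin, v, reg,
                    pixel_size_um = px)
  wm <- wm_hb_score(sec$image$channels$hemoglobin, reg, pixel_size_um = px)
  ga <- mask_area_mm2(region_mask(reg, "gray"), px)
  wa <- mask_area_mm2(region_mask(reg, "white"), px)
  recovered <- gm * ga + wm * wa
  expect_lt(abs(recovered - truth$total) / truth$total, 0.05)
})

test_that("the proximity condition separates gray- from white-style
           scoring", {
  # hemoglobin blob far from the only vessel
  nr <- 120
  hb <- matrix(20, nr, nr)
  hb[disk_mask(nr, nr, 100, 100, 6)] <- 150
  lectin <- matrix(0, nr, nr)
  lectin[disk_mask(nr, nr, 20, 20, 4)] <- 200
  reg <- flat_regions(nr, nr, "gray")
  v <- detect_vessels(lectin, reg, vessel_criteria(10, 1000, 3), 1)
  crit <- hb_criteria(proximity_radius_um = 25)
  expect_equal(gm_hb_score(hb, v, reg, crit, 1), 0) # blob 113 um away

  regw <- flat_regions(nr, nr, "white")
  expect_gt(wm_hb_score(hb, regw, crit, 1), 0) # counted without proximity

  # with the blob moved next to the vessel, the gray score counts it
  hb2 <- matrix(20, nr, nr)
  hb2[disk_mask(nr, nr, 30, 20, 6)] <- 150
  expect_gt(gm_hb_score(hb2, v, reg, crit, 1), 0)
})

test_that("gray scoring with an infinite radius equals unconditioned
           scoring, and disjoint halos superpose", {
  withr::with_seed(17, {
    hb <- matrix(rnorm(90 * 90, 25, 2), 90, 90)
    hb[disk_mask(90, 90, 25, 25, 5)] <- 160
    hb[disk_mask(90, 90, 70, 70, 5)] <- 160
    lectin <- matrix(0, 90, 90)
    lectin[disk_mask(90, 90, 25, 35, 3)] <- 200
  })
  reg <- flat_regions(90, 90, "gray")
  v <- detect_vessels(lectin, reg, vessel_criteria(10, 1000, 3), 1)
  crit_inf <- hb_criteria(proximity_radius_um = 1e9)
  gm <- gm_hb_score(hb, v, reg, crit_inf, 1)
  unconditioned <- oracle_hb_score(hb, region_mask(reg, "tissue"), crit_inf,
                                   1)
  expect_equal(gm, unconditioned, tolerance = 1e-12)

  # superposition of disjoint objects (noise-free background)
  base <- matrix(20, 90, 90)
  h1 <- base; h1[disk_mask(90, 90, 25, 25, 5)] <- 160
  h2 <- base; h2[disk_mask(90, 90, 70, 70, 5)] <- 160
  h12 <- base
  h12[disk_mask(90, 90, 25, 25, 5) | disk_mask(90, 90, 70, 70, 5)] <- 160
  regw <- flat_regions(90, 90, "white")
  s1 <- wm_hb_score(h1, regw, pixel_size_um = 1)
  s2 <- wm_hb_score(h2, regw, pixel_size_um = 1)
  s12 <- wm_hb_score(h12, regw, pixel_size_um = 1)
  expect_lt(abs(s12 - (s1 + s2)) / (s1 + s2), 0.01)
})

test_that("hemoglobin scores match the per-pixel oracle on small fixtures", {
  withr::with_seed(23, {
    hb <- matrix(rnorm(64 * 64, 30, 3), 64, 64)
    hb[disk_mask(64, 64, 20, 20, 5)] <- hb[disk_mask(64, 64, 20, 20, 5)] + 120
    hb[disk_mask(64, 64, 48, 48, 4)] <- hb[disk_mask(64, 64, 48, 48, 4)] + 120
    lectin <- matrix(0, 64, 64)
    lectin[disk_mask(64, 64, 26, 20, 3)] <- 200
  })
  reg <- flat_regions(64, 64, "gray")
  regw <- flat_regions(64, 64, "white")
  crit <- hb_criteria(min_area_um2 = 10, max_area_um2 = 5000,
                      proximity_radius_um = 15)
  v <- detect_vessels(lectin, reg, vessel_criteria(5, 500, 3), 2)
  gm <- gm_hb_score(hb, v, reg, crit, 2)
  gm_oracle <- oracle_hb_score(hb, region_mask(reg, "tissue"), crit, 2,
                               vessel_mask = v$mask,
                               proximity_radius_um = 15)
  expect_equal(gm, gm_oracle, tolerance = 1e-12)
  wm <- wm_hb_score(hb, regw, crit, 2)
  wm_oracle <- oracle_hb_score(hb, region_mask(regw, "tissue"), crit, 2)
  expect_equal(wm, wm_oracle, tolerance = 1e-12)
})

test_that("scores without vessels warn and return zero", {
  hb <- matrix(20, 50, 50)
  hb[disk_mask(50, 50, 25, 25, 5)] <- 150
  reg <- flat_regions(50, 50, "gray")
  novessels <- list(records = data.frame(), mask = matrix(FALSE, 50, 50),
                    labels = matrix(0L, 50, 50))
  expect_warning(s <- gm_hb_score(hb, novessels, reg, pixel_size_um = 1),
                 "no vessels")
  expect_equal(s, 0)
})

test_that("leak classification obeys the degenerate masks and conserves
           counts", {
  sec <- generate_section(noise_free(seed = 5))
  px <- 2.5
  v <- detect_vessels(sec$image$channels$lectin, sec$truth$regions,
                      pixel_size_um = px)
  n <- nrow(v$records)
  all_false <- classify_vessel_leakage(v, matrix(FALSE, 192, 192))
  expect_equal(sum(all_false$records$leaked), 0)
  all_true <- classify_vessel_leakage(v, matrix(TRUE, 192, 192))
  expect_equal(sum(all_true$records$leaked), n)

  lmask <- leakage_mask(sec$image$channels$hemoglobin, sec$truth$regions, px)
  cls <- classify_vessel_leakage(v, lmask)
  expect_equal(sum(cls$records$leaked) + sum(!cls$records$leaked), n)

  # overlap rule also labels every vessel
  ov <- classify_vessel_leakage(v, lmask, rule = "overlap",
                                overlap_frac = 0.5)
  expect_false(any(is.na(ov$records$leaked)))
})

test_that("increasing leak amplitude strictly increases recovered scores", {
  scores <- vapply(c(60, 150, 300), function(amp) {
    sec <- generate_section(noise_free(seed = 12, leak_amplitude = amp))
    wm_hb_score(sec$image$channels$hemoglobin, sec$truth$regions,
                pixel_size_um = 2.5)
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("NVU group means are order-invariant and recover an injected
           white-matter deficit", {
  records <- data.frame(
    compartment = rep(c("gray", "white"), each = 4),
    leaked = rep(c(TRUE, FALSE), 4),
    marker_mean = 42
  )
  gm <- nvu_group_means(records)
  expect_true(all(gm$mean_intensity == 42))
  gm_perm <- nvu_group_means(records[sample(nrow(records)), ])
  expect_equal(gm[order(gm$compartment, gm$leaked), ],
               gm_perm[order(gm_perm$compartment, gm_perm$leaked), ],
               ignore_attr = TRUE)

  # injected 7.4 percent decrease around leaked vessels, noise-free
  difs <- vapply(1:3, function(s) {
    sec <- generate_section(noise_free(seed = s, nvu_intensity = 100,
                                       nvu_leak_factor = 0.926,
                                       n_neurons_per_horn = 0,
                                       n_inclusions = 0))
    g <- nvu_section_means(sec$image, sec$truth$regions,
                           intensity_window = c(50, Inf))
    w <- g[g$compartment == "white", ]
    100 * (w$mean_intensity[!w$leaked] - w$mean_intensity[w$leaked]) /
      w$mean_intensity[!w$leaked]
  }, numeric(1))
  expect_lt(abs(mean(difs) - 7.4), 2)
})
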