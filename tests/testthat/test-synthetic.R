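noise_free <- function(...) {
  section_spec(..., noise_gain = 0, read_noise_sd = 0)
}

test_that("generation is deterministic and honours the empty case", {
  s <- section_spec(seed = 7)
  a <- generate_section(s)
  b <- generate_section(s)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth$vessels, b$truth$vessels)

  empty <- generate_section(noise_free(n_vessels = 0, n_neurons_per_horn = 0,
                                       n_inclusions = 0, seed = 1))
  expect_equal(nrow(empty$truth$vessels), 0)
  tissue <- region_mask(empty$truth$regions, "tissue")
  hb <- empty$image$channels$hemoglobin
  expect_true(all(hb[tissue] == empty$image$channels$hemoglobin[tissue][1]))
  expect_true(all(hb[!tissue] == 0))
})

test_that("the leaked-vessel count equals round(leak_fraction * n)", {
  sec <- generate_section(section_spec(n_vessels = 50, leak_fraction = 0.2,
                                       min_vessel_separation_um = 20,
                                       seed = 1))
  expect_identical(sum(sec$truth$vessels$leaked), 10L)
  for (s in 2:4) {
    tr <- generate_section(section_spec(seed = s))$truth$vessels
    expect_lte(abs(mean(tr$leaked) - 0.3), 1 / nrow(tr))
  }
})

test_that("non-physical specs are rejected with a message", {
  expect_error(section_spec(leak_fraction = 1.4), "leak_fraction")
  expect_error(section_spec(vessel_radius_range_um = c(8, 3)), "maxima")
  expect_error(section_spec(leak_halo_decay_um = -1), "positive")
  expect_error(section_spec(width_px = 40, height_px = 40,
                            vessel_radius_range_um = c(3, 30)),
               "non-physical")
})

test_that("region geometry nests correctly", {
  reg <- generate_section(noise_free(seed = 2))$truth$regions
  horns <- region_mask(reg, "anterior_horn")
  gray <- region_mask(reg, "gray")
  white <- region_mask(reg, "white")
  expect_true(all(gray[horns]))          # horns inside gray
  expect_false(any(gray & white))        # gray and white disjoint
  expect_true(all(region_mask(reg, "tissue")[gray | white]))
})

test_that("noise-free halos integrate to the recorded ground truth and decay
           monotonically", {
  sec <- generate_section(noise_free(seed = 4))
  hb <- sec$image$channels$hemoglobin
  lum <- sec$truth$lumen_mask
  tissue <- region_mask(sec$truth$regions, "tissue")
  bg <- 20 # halos extend past the tissue ellipse, where no background is laid
  rendered <- sum(hb[!lum]) - bg * sum(tissue & !lum)
  expect_lt(abs(rendered - sec$truth$hb_extravascular$total) /
              max(sec$truth$hb_extravascular$total, 1), 1e-3)

  # radial profile from a single leaked vessel rim out to 3 decay lengths
  single <- generate_section(noise_free(seed = 4, n_vessels = 1,
                                        leak_fraction = 1))
  v1 <- single$truth$vessels
  px <- 2.5
  dirn <- if (v1$row < 96) 1 else -1 # sample toward the frame centre
  d_um <- seq(px, 3 * 15, by = px)
  prof <- vapply(d_um, function(d) {
    r_px <- (v1$radius_um + d) / px
    single$image$channels$hemoglobin[round(v1$row + dirn * r_px),
                                     round(v1$col)]
  }, numeric(1))
  expect_true(all(diff(prof) < 0))
})

test_that("inclusion ground truth stays within the requested diameter
           range", {
  tr <- generate_section(noise_free(seed = 6))$truth$inclusions
  expect_true(all(tr$diameter_um >= 4 & tr$diameter_um <= 12))
  expect_true(all(tr$compartment == "anterior_horn"))
})

test_that("cohort generation lays out case/level/section with a manifest", {
  design <- expand.grid(case = c("a", "b"),
                        level = c("cervical", "thoracic", "lumbar"),
                        section = 1:3, stringsAsFactors = FALSE)
  design$group <- "ALS"
  tiny <- section_spec(width_px = 96, height_px = 96, n_vessels = 6,
                       n_neurons_per_horn = 0, n_inclusions = 0,
                       min_vessel_separation_um = 25)
  dir <- file.path(tempdir(), "cohort_test")
  coh <- generate_cohort(design, base_spec = tiny, base_seed = 9, dir = dir)
  expect_equal(length(coh$sections), 18)
  expect_equal(nrow(coh$manifest), 18)
  expect_equal(sum(file.exists(coh$manifest$path)), 18)
  reread <- read.csv(file.path(dir, "manifest.csv"),
                     stringsAsFactors = FALSE)
  expect_equal(reread$case, coh$manifest$case)
  expect_equal(reread$seed, coh$manifest$seed)

  dup <- rbind(design, design[1, ])
  expect_error(generate_cohort(dup, base_spec = tiny), "duplicate")
})

test_that("CSF cohorts have the study arm sizes, censoring, and respond to a
           location shift", {
  csf <- generate_csf_cohort(87, 236, seed = 42)
  expect_identical(as.vector(table(csf$group)[c("control", "ALS")]),
                   c(87L, 236L))
  expect_true(all(csf$hb_ng_ml >= 6.25))
  expect_true(all(csf$censored == (csf$hb_ng_ml == 6.25) |
                    !csf$censored))

  shifted <- generate_csf_cohort(
    200, 200, seed = 3,
    control_params = list(hb_meanlog = log(40), hb_sdlog = 1,
                          protein_meanlog = log(741), protein_sdlog = 0.3),
    als_params = list(hb_meanlog = log(40) + 1, hb_sdlog = 1,
                      protein_meanlog = log(741), protein_sdlog = 0.3)
  )
  med <- tapply(shifted$hb_ng_ml, shifted$group, median)
  expect_gt(med[["ALS"]], med[["control"]])

  expect_error(generate_csf_cohort(
    5, 5, control_params = list(hb_meanlog = 1, hb_sdlog = 0,
                                protein_meanlog = 1, protein_sdlog = 0.3)),
    "positive")
})

test_that("identical arms are non-significant in most seeds (null
           calibration)", {
  p_vals <- vapply(1:60, function(s) {
    eq <- generate_csf_cohort(
      60, 60, seed = s,
      control_params = list(hb_meanlog = log(40), hb_sdlog = 1.5,
                            protein_meanlog = log(741), protein_sdlog = 0.3),
      als_params = list(hb_meanlog = log(40), hb_sdlog = 1.5,
                        protein_meanlog = log(741), protein_sdlog = 0.3)
    )
    mann_whitney(eq$hb_ng_ml[eq$group == "control"],
                 eq$hb_ng_ml[eq$group == "ALS"])$p
  }, numeric(1))
  expect_gte(mean(p_vals >= 0.05), 0.9)
})
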