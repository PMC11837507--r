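test_that("fraction window selection keeps the closed interval", {
  samples <- toy_samples(n_plots = 1, sites = "Valley")[1, , drop = FALSE]
  fr <- as_qsip_fractions(
    toy_fractions(samples, densities = c(1.60, 1.67, 1.70, 1.74, 1.78)))
  out <- select_fractions(fr)
  expect_equal(out$density, c(1.67, 1.70, 1.74))

  inside <- as_qsip_fractions(
    toy_fractions(samples, densities = c(1.68, 1.70, 1.72)))
  expect_equal(as.data.frame(select_fractions(inside)),
               as.data.frame(inside), ignore_attr = TRUE)

  sparse <- as_qsip_fractions(
    toy_fractions(samples, densities = c(1.62, 1.64, 1.70, 1.72)))
  expect_warning(out2 <- select_fractions(sparse), "unusable")
  expect_equal(attr(out2, "unusable_tubes"), unique(sparse$tube_id))
})

test_that("taxon copies and weighted average density follow the arithmetic", {
  expect_equal(taxon_fraction_copies(c(0.5, 0.5), c(100, 300)), c(50, 150))
  expect_equal(taxon_fraction_copies(c(0, 1), c(100, 300)), c(0, 300))
  expect_equal(taxon_fraction_copies(c(0.2, 0.3, 0.5), rep(10, 3)), c(2, 3, 5))
  expect_error(taxon_fraction_copies(c(0.5, 0.5), 100), "length")
  expect_error(taxon_fraction_copies(c(-0.1, 1.1), c(1, 1)), "\\[0, 1\\]")

  expect_equal(weighted_average_density(c(0, 10, 0), c(1.68, 1.70, 1.72)),
               1.70)
  # hand arithmetic: 0.125*1.68 + 0.25*1.70 + 0.625*1.72
  expect_equal(weighted_average_density(c(1, 2, 5), c(1.68, 1.70, 1.72)),
               0.125 * 1.68 + 0.25 * 1.70 + 0.625 * 1.72)
  expect_equal(weighted_average_density(c(1, 1), c(1.69, 1.71)), 1.70)
  expect_true(is.na(weighted_average_density(c(0, 0), c(1.69, 1.71))))
})

test_that("WAD is translation-equivariant and bounded by fraction densities", {
  set.seed(401)
  for (i in 1:25) {
    n <- sample(3:10, 1)
    copies <- runif(n, 0, 100)
    dens <- sort(runif(n, 1.66, 1.75))
    w <- weighted_average_density(copies, dens)
    expect_gte(w, min(dens))
    expect_lte(w, max(dens))
    delta <- runif(1, -0.01, 0.01)
    expect_equal(weighted_average_density(copies, dens + delta), w + delta,
                 tolerance = 1e-12)
  }
})

test_that("light WAD averages over unlabeled tubes and flags absences", {
  samples <- toy_samples(n_plots = 2, sites = "Valley")
  design <- validate_design(samples)
  wads <- data.frame(
    genus = rep(c("g1", "g2"), each = 6),
    tube_id = rep(paste0("T_", samples$sample_id), 2),
    sample_id = rep(samples$sample_id, 2),
    wad = c(1.700, NA, NA, 1.702, NA, NA,     # g1 in both controls
            NA, 1.71, 1.71, NA, 1.71, 1.71),  # g2 labeled only
    copies_recovered = 1, n_fractions_detected = 1, rel_abund = 0.5,
    stringsAsFactors = FALSE)
  lw <- light_wad(wads, design)
  expect_equal(lw$w_light_mean[lw$genus == "g1"], 1.701)
  expect_equal(lw$n_tubes[lw$genus == "g1"], 2)
  expect_true(is.na(lw$w_light_mean[lw$genus == "g2"]))
  expect_equal(lw$n_tubes[lw$genus == "g2"], 0)
})

test_that("tube correction recovers an injected constant offset", {
  # unenriched community, no noise: one tube's WADs shifted by +0.002
  set.seed(77)
  cfg <- sim_config(n_taxa = 60, eaf_pi0 = 1, map_intercept = 0,
                    map_noise_sd = 0, qpcr_cv = 0, tube_offset_sd = 0,
                    seq_depth = Inf, n_plots = 2, seed = 901)
  sim <- simulate_study(cfg)
  fr <- select_fractions(sim$fractions)
  g <- aggregate_to_genus(sim$counts)
  wads <- wad_table(g, fr)
  target <- unique(wads$tube_id[grepl("field", wads$tube_id)])[1]
  wads$wad[wads$tube_id == target] <- wads$wad[wads$tube_id == target] + 0.002
  shifts <- tube_correction(wad_shifts(wads, sim$design), n_ref = 20)
  off <- attr(shifts, "tube_offsets")
  expect_equal(unname(off[target]), 0.002, tolerance = 1e-4)
  corr <- shifts$corrected_dwad[shifts$tube_id == target]
  expect_lt(mean(abs(corr), na.rm = TRUE), 2e-4)

  # all raw shifts zero -> offsets zero, table unchanged
  zero <- wad_shifts(wads, sim$design)
  zero$raw_dwad[] <- 0
  z <- tube_correction(zero, n_ref = 20)
  expect_true(all(z$tube_offset == 0))
  expect_true(all(z$corrected_dwad == 0))

  # n_ref exceeding the genus count falls back to all genera with a warning
  expect_warning(tube_correction(wad_shifts(wads, sim$design), n_ref = 1000),
                 "using all")
})

test_that("tube correction is invariant to genus and tube ordering", {
  set.seed(78)
  sh <- expand.grid(genus = paste0("g", 1:30), tube_id = paste0("t", 1:6),
                    stringsAsFactors = FALSE)
  sh$raw_dwad <- rnorm(nrow(sh), 0, 1e-3) +
    rep(rnorm(6, 0, 2e-3), each = 30)[order(rep(1:6, each = 30))]
  a <- tube_correction(sh, n_ref = 10)
  perm <- sh[sample.int(nrow(sh)), ]
  b <- tube_correction(perm, n_ref = 10)
  key <- function(d) paste(d$genus, d$tube_id)
  expect_equal(b$corrected_dwad[match(key(a), key(b))], a$corrected_dwad)
})

test_that("corrected shifts vanish as measurement noise vanishes", {
  cfg <- sim_config(n_taxa = 80, eaf_pi0 = 1, map_intercept = 0,
                    map_noise_sd = 0, qpcr_cv = 1e-3, seq_depth = 1e6,
                    tube_offset_sd = 0.002, n_plots = 3, seed = 902)
  sim <- simulate_study(cfg)
  fr <- select_fractions(sim$fractions)
  wads <- wad_table(aggregate_to_genus(sim$counts), fr)
  shifts <- tube_correction(wad_shifts(wads, sim$design), n_ref = 30)
  expect_lt(mean(abs(shifts$corrected_dwad), na.rm = TRUE), 2e-4)
  expect_lt(mean(abs(shifts$corrected_dwad), na.rm = TRUE),
            0.2 * mean(abs(shifts$raw_dwad), na.rm = TRUE))
})
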