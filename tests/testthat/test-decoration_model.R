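test_that("profile and gate constructors validate their inputs", {
  expect_error(serum_profile(titer = -1), "titer")
  expect_error(serum_profile(p_opposite_lc = 2), "p_opposite_lc")
  expect_error(gate_set(kappa_pos = 0), "positive")
  expect_error(gate_set(detection_efficiency = 1.5), "detection_efficiency")
  expect_equal(healthy_serum()$titer, 0)
  expect_equal(sleh_serum()$susceptibility[["BND"]], 0)
})

test_that("without serum, apparent kl equals the detected true rate", {
  rep <- generate_repertoire(generator_config(n_cells = 20000, seed = 21))
  ev <- stain(rep$truth, healthy_serum(), gate_set(), seed = 22)
  app <- apparent_frequencies(ev)
  tk <- true_kl_summary(ev)
  # decoration off: the double-positive gate contains exactly the true
  # kappa/lambda cells whose secondary chain stained above the gate
  expect_equal(app$kl_apparent_pct, tk$detected_true_kl_pct)
  expect_false(any(ev$decorated))
  # detection efficiency thins the true rate as designed
  n_true <- sum(ev$true_lc_class == "kappa_lambda")
  expect_lt(abs(tk$detected_true_kl_pct - 0.35 * tk$true_kl_pct),
            300 * sqrt(0.35 * 0.65 * n_true) / nrow(ev))
})

test_that("forced saturation drives every gated cell double positive", {
  cfg <- generator_config(n_cells = 4000, p_kl = 0, p_kk = 0, p_ll = 0,
                          seed = 31)
  rep <- generate_repertoire(cfg)
  serum <- serum_profile(titer = 1, p_decorate_base = 1, p_opposite_lc = 1,
                         susceptibility = c(naive = 1, aNAV = 1, MZlike = 1,
                                            BND = 1, DN = 1,
                                            switched_memory = 1))
  ev <- stain(rep$truth, serum, gate_set(detection_efficiency = 1), seed = 32)
  app <- apparent_frequencies(ev)
  expect_equal(app$kl_apparent_pct, 100)
  expect_equal(app$g4_pct, 100)
})

test_that("apparent kl matches its closed-form expectation at n = 1e5", {
  cfg <- generator_config(n_cells = 1e5, seed = 41)
  rep <- generate_repertoire(cfg)
  d <- 0.4
  serum <- serum_profile(titer = 1, p_decorate_base = d, p_opposite_lc = 0.5,
                         susceptibility = c(naive = 1, aNAV = 1, MZlike = 1,
                                            BND = 1, DN = 1,
                                            switched_memory = 1))
  ev <- stain(rep$truth, serum, gate_set(detection_efficiency = 1), seed = 42)
  app <- apparent_frequencies(ev)
  kl_true <- mean(rep$truth$true_lc_class == "kappa_lambda")
  expected <- kl_true + (1 - kl_true) * d * 0.5
  expect_lt(abs(app$kl_apparent_pct / 100 - expected),
            3 * sqrt(expected * (1 - expected) / cfg$n_cells))
})

test_that("apparent kl and 9G4 are non-decreasing in titer", {
  rep <- generate_repertoire(generator_config(n_cells = 8000, seed = 51))
  titers <- c(0, 0.5, 1, 2, 4, 8, 16, 32)
  # common random numbers: the same stain seed across the titer grid
  res <- purrr::map_dfr(titers, function(t) {
    ev <- stain(rep$truth, serum_profile(titer = t), gate_set(), seed = 52)
    apparent_frequencies(ev)
  })
  expect_false(is.unsorted(res$kl_apparent_pct))
  expect_false(is.unsorted(res$g4_pct))
})

test_that("decoration creates kl events only among 9G4-positive cells", {
  rep <- generate_repertoire(generator_config(n_cells = 10000, seed = 61))
  for (t in c(0, 2, 16)) {
    ev <- stain(rep$truth, serum_profile(titer = t), gate_set(), seed = 62)
    app <- apparent_frequencies(ev)
    det <- true_kl_summary(ev)$detected_true_kl_pct
    expect_gte(app$g4_pct, app$kl_apparent_pct - det)
  }
})

test_that("gate membership cross-tabulates exactly with the truth links", {
  rep <- generate_repertoire(generator_config(n_cells = 10000, seed = 71))
  gates <- gate_set()
  ev <- stain(rep$truth, sleh_serum(), gates, seed = 72)
  in_gate <- ev$kappa_intensity > gates$kappa_pos &
    ev$lambda_intensity > gates$lambda_pos
  # reconstruct each channel from the truth links alone
  kpos <- rep(FALSE, nrow(ev))
  lpos <- rep(FALSE, nrow(ev))
  lc1k <- rep$truth$lc1_locus == "IGK"
  kpos[lc1k] <- TRUE
  lpos[!lc1k] <- TRUE
  kpos[ev$lc2_detected & rep$truth$lc2_locus == "IGK"] <- TRUE
  lpos[ev$lc2_detected & rep$truth$lc2_locus == "IGL"] <- TRUE
  kpos[!is.na(ev$decorating_lc) & ev$decorating_lc == "IGK"] <- TRUE
  lpos[!is.na(ev$decorating_lc) & ev$decorating_lc == "IGL"] <- TRUE
  expect_equal(in_gate, kpos & lpos)
})

test_that("BND cells are spared at any titer", {
  rep <- generate_repertoire(generator_config(n_cells = 20000, seed = 81))
  for (t in c(0, 16, 64)) {
    ev <- stain(rep$truth, serum_profile(titer = t), gate_set(), seed = 82)
    by_sub <- apparent_frequencies(ev, by = "subset")
    bnd_events <- ev[ev$subset == "BND", ]
    det_bnd <- 100 * mean(bnd_events$true_lc_class == "kappa_lambda" &
                            bnd_events$lc2_detected)
    expect_equal(by_sub$kl_apparent_pct[by_sub$subset == "BND"], det_bnd)
  }
})

test_that("counting events in the double-positive gate is plain arithmetic", {
  gates <- gate_set()
  ev <- tibble::tibble(
    barcode = paste0("E", 1:10),
    kappa_intensity = c(rep(3, 3), rep(3, 4), rep(1, 3)),
    lambda_intensity = c(rep(3, 3), rep(1, 4), rep(1, 3)),
    g4_intensity = c(rep(3, 5), rep(1, 5)),
    subset = "naive", true_lc_class = "single_kappa", vh4_34 = FALSE,
    isotype_class = "IgMD", lc2_detected = FALSE, decorated = FALSE,
    decorating_lc = NA_character_)
  app <- apparent_frequencies(ev, gates)
  expect_equal(app$kl_apparent_pct, 30)
  expect_equal(app$g4_pct, 50)
  empty <- apparent_frequencies(ev[0, ], gates)
  expect_equal(empty$n_events, 0L)
  expect_true(is.na(empty$kl_apparent_pct))
})

test_that("serum transfer at attenuation 1 reproduces a full stain", {
  rep <- generate_repertoire(generator_config(n_cells = 3000, seed = 91))
  direct <- apparent_frequencies(stain(rep$truth, sleh_serum(), gate_set(),
                                       seed = 92))
  transfer <- simulate_serum_transfer(rep$truth, list(sle = sleh_serum()),
                                      gate_set(), attenuation = 1, seed = 92)
  expect_equal(transfer$kl_apparent_pct, direct$kl_apparent_pct)
  expect_equal(transfer$g4_pct, direct$g4_pct)
})

test_that("patient sera, not control sera, inflate the transfer readout", {
  rep <- generate_repertoire(generator_config(n_cells = 15000, seed = 101))
  res <- simulate_serum_transfer(
    rep$truth,
    list(autologous = healthy_serum(), hc = serum_profile(titer = 1),
         sleh = sleh_serum()),
    gate_set(), attenuation = 0.5, seed = 102)
  base <- res$kl_apparent_pct[res$serum_id == "autologous"]
  hc <- res$kl_apparent_pct[res$serum_id == "hc"]
  sleh <- res$kl_apparent_pct[res$serum_id == "sleh"]
  # healthy serum at titer ~1 moves the readout by well under a percent
  expect_lt(abs(hc - base), 1)
  expect_gt(sleh, base + 3)
  expect_gt(res$g4_pct[res$serum_id == "sleh"], res$g4_pct[res$serum_id == "hc"])
})

test_that("cohort simulation separates true and apparent dual rates", {
  cohort <- simulate_cohort(n_controls = 8, n_patients = 8,
                            config = generator_config(n_cells = 3000),
                            patient_titers = c(1, 1, 1, 1, 16, 16, 24, 32),
                            seed = 111)
  sub <- cohort$subjects
  # flow-apparent values span far more than the sequencing-true band
  expect_lt(diff(range(sub$true_kl_pct)), 3)
  expect_gt(max(sub$kl_apparent_pct), 10)
  high <- sub$group == "patient" & sub$titer >= 16
  expect_true(all(sub$hl_call[high] == "H"))
  expect_true(all(sub$hl_call[sub$group == "control"] == "L"))
  expect_gt(cohort$regression$effect, 0)
  expect_lt(cohort$regression$p_value, 0.05)
  gl <- glance(cohort)
  expect_equal(gl$n_H, sum(sub$hl_call == "H"))
})

test_that("with all titers at zero essentially nobody is called high", {
  cohort <- simulate_cohort(n_controls = 10, n_patients = 10,
                            config = generator_config(n_cells = 3000),
                            control_titers = rep(0, 10),
                            patient_titers = rep(0, 10), seed = 121)
  expect_lte(sum(cohort$subjects$hl_call == "H"), 1)
})
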