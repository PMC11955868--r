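test_that("cross-section generation is deterministic given (seed, animal)", {
  cfg <- synthetic_config(seed = 7)
  n1 <- generate_cross_section(cfg, 3)
  n2 <- generate_cross_section(cfg, 3)
  expect_identical(n1$fascicles, n2$fascicles)
  expect_identical(attr(n1, "ground_truth"), attr(n2, "ground_truth"))
  n3 <- generate_cross_section(cfg, 4)
  expect_false(identical(n1$fascicles, n3$fascicles))
})

test_that("zero count SD yields exactly one cardiac fascicle, always efferent", {
  cfg <- synthetic_config(
    count_sd = c(cardiac = 0, laryngeal = 0, pulmonary = 0,
                 cardiopulmonary = 0, laryngopulmonary = 0),
    seed = 5
  )
  for (a in 1:10) {
    n <- generate_cross_section(cfg, a)
    card <- n$fascicles[n$fascicles$organ_label == "cardiac", ]
    expect_equal(nrow(card), 1L)
    expect_identical(card$fibre_label, "efferent")
    cp <- n$fascicles[n$fascicles$organ_label == "cardiopulmonary", ]
    expect_true(all(cp$fibre_label == "afferent"))
  }
})

test_that("generated fascicle discs are contained and pairwise disjoint", {
  cfg <- synthetic_config(seed = 13)
  for (a in 1:5) {
    n <- generate_cross_section(cfg, a)
    f <- n$fascicles
    r <- sqrt(f$area / pi)
    expect_true(all(sqrt(f$cx^2 + f$cy^2) + r <= n$nerve_radius + 1e-9))
    if (nrow(f) > 1) {
      dd <- as.matrix(dist(cbind(f$cx, f$cy)))
      lim <- outer(r, r, "+")
      diag(dd) <- Inf
      expect_true(all(dd >= lim - 1e-9))
    }
  }
})

test_that("afferent and efferent lobes recover the configured separation", {
  cfg <- synthetic_config(afferent_efferent_separation = 180, seed = 97)
  diffs <- vapply(1:200, function(a) {
    n <- generate_cross_section(cfg, a)
    gt <- attr(n, "ground_truth")
    f <- n$fascicles
    aff <- f[f$fibre_label == "afferent", ]
    eff <- f[f$fibre_label == "efferent", ]
    am <- circular_mean(cart2pol(aff$cx, aff$cy)$angle)
    em <- circular_mean(cart2pol(eff$cx, eff$cy)$angle)
    (am - em) %% 360
  }, numeric(1))
  expect_lt(angular_distance(circular_mean(diffs), 180), 5)
})

test_that("sub-threshold stimulation leaves the trace at pure baseline", {
  cfg <- synthetic_config(seed = 3)
  nerve <- generate_cross_section(cfg, 1, technique = "svns")
  cuff <- electrode_cuff()
  model <- activation_model(noise_sd = c(hr = 0, etco2 = 0, emg_rms = 0))
  protocol <- stimulation_protocol("cardiac_efferent", amplitude = 0.001)
  tr <- simulate_session(nerve, cuff, protocol, model, seed = 1)[[1]]
  expect_true(all(tr$value == model$baseline[["hr"]]))
})

test_that("activated effect magnitudes are monotone in amplitude", {
  cfg <- synthetic_config(seed = 19)
  nerve <- generate_cross_section(cfg, 2, technique = "svns")
  cuff <- electrode_cuff()
  model <- activation_model(noise_sd = c(hr = 0, etco2 = 0, emg_rms = 0))
  gts <- lapply(c(0.05, 0.9, 2, 5), function(amp) {
    pr <- stimulation_protocol("cardiac_efferent", amplitude = amp)
    attr(simulate_session(nerve, cuff, pr, model, seed = 1)[[1]],
         "ground_truth")$total
  })
  for (k in 2:length(gts)) {
    expect_true(all(abs(gts[[k]]) >= abs(gts[[k - 1]]) - 1e-12))
  }
})

test_that("vagotomy state gates the cardiac pathways as in the study design", {
  cfg <- synthetic_config(seed = 23)
  nerve <- generate_cross_section(cfg, 1, technique = "svns")
  cuff <- electrode_cuff()
  quiet <- c(hr = 0, etco2 = 0, emg_rms = 0)
  protocol <- stimulation_protocol("cardiac_afferent")

  # intact nerve, efferent protocol: decreases only
  m0 <- activation_model(noise_sd = quiet, vagotomy_state = "intact")
  pr_eff <- stimulation_protocol("cardiac_efferent")
  gt0 <- attr(simulate_session(nerve, cuff, pr_eff, m0, seed = 1)[[1]],
              "ground_truth")$total
  expect_true(all(gt0 <= 0))
  expect_lt(min(gt0), 0)

  # right distal vagotomy: reflex with the animal's polarity
  m_brady <- activation_model(noise_sd = quiet, vagotomy_state = "right_distal",
                              afferent_polarity = "bradycardia")
  gt_b <- attr(simulate_session(nerve, cuff, protocol, m_brady, seed = 1)[[1]],
               "ground_truth")$total
  expect_true(all(gt_b <= 0))
  expect_lt(min(gt_b), 0)

  m_tachy <- activation_model(noise_sd = quiet, vagotomy_state = "right_distal",
                              afferent_polarity = "tachycardia")
  gt_t <- attr(simulate_session(nerve, cuff, protocol, m_tachy, seed = 1)[[1]],
               "ground_truth")$total
  expect_true(all(gt_t >= 0))
  expect_gt(max(gt_t), 0)

  # bilateral vagotomy abolishes reflex bradycardia but not tachycardia
  m_bil_b <- activation_model(noise_sd = quiet, vagotomy_state = "right_and_left",
                              afferent_polarity = "bradycardia")
  tr <- simulate_session(nerve, cuff, protocol, m_bil_b, seed = 1)[[1]]
  expect_true(all(tr$value == m_bil_b$baseline[["hr"]]))

  m_bil_t <- activation_model(noise_sd = quiet, vagotomy_state = "right_and_left",
                              afferent_polarity = "tachycardia")
  gt_bt <- attr(simulate_session(nerve, cuff, protocol, m_bil_t, seed = 1)[[1]],
                "ground_truth")$total
  expect_equal(gt_bt, gt_t)
})

test_that("simulated traces are reproducible and annotated consistently", {
  cfg <- synthetic_config(seed = 29)
  nerve <- generate_cross_section(cfg, 1, technique = "svns")
  cuff <- electrode_cuff()
  model <- activation_model()
  protocol <- stimulation_protocol("cardiac_efferent")
  t1 <- simulate_session(nerve, cuff, protocol, model, seed = 42)[[1]]
  t2 <- simulate_session(nerve, cuff, protocol, model, seed = 42)[[1]]
  expect_identical(t1$value, t2$value)
  expect_equal(nrow(t1$schedule), cuff$n_pairs)
  expect_true(all(diff(t1$time) > 0))
  # epochs lie within the trace and do not overlap
  expect_true(all(t1$schedule$t_on >= t1$time[1]))
  expect_true(all(t1$schedule$t_off <= max(t1$time) + 1e-9))
  expect_true(all(diff(t1$schedule$t_on) >=
                    protocol$on_duration + protocol$off_duration - 1e-9))
})
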