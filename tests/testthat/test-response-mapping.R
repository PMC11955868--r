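make_step_trace <- function(base = 100, during = 90, on = 15, off = 15,
                            pairs = 1:3, fs = 10, modality = "hr") {
  pct <- rep(NA_real_, max(pairs))
  pct[pairs] <- 100 * (during - base) / base
  synthesize_trace(pct, pairs = pairs, on_s = on, off_s = off,
                   modality = modality, baseline = base, fs = fs)
}

test_that("extract_pair_response recovers step changes and flat traces", {
  tr <- make_step_trace(base = 100, during = 90)
  expect_equal(extract_pair_response(tr, 1, baseline_window = 15,
                                     response_window = 15), -10,
               tolerance = 1e-9)

  flat <- synthesize_trace(rep(0, 3), pairs = 1:3, on_s = 10, off_s = 10,
                           baseline = 100)
  expect_equal(extract_pair_response(flat, 2, 10, 10), 0)

  # unstimulated pair -> missing
  expect_true(is.na(extract_pair_response(tr, 9, 15, 15)))
})

test_that("extraction rejects non-positive physiological baselines", {
  n <- 400
  time <- (seq_len(n) - 1) / 10
  sched <- data.frame(pair = 1, t_on = 15, t_off = 30)
  tr <- physio_trace("hr", time, rep(0, n), sched)
  expect_error(extract_pair_response(tr, 1, 15, 15), "invalid physiology")
})

test_that("noisy injected responses are recovered to within the noise scale", {
  # ~ -7.8% HR effect on two pairs, 0.5 b.p.m. additive noise
  pct <- rep(0, 14)
  pct[c(4, 5)] <- -7.8
  tr <- synthesize_trace(pct, pairs = 1:14, on_s = 15, off_s = 15,
                         baseline = 80, fs = 10, noise_sd = 0.5, seed = 77)
  got4 <- extract_pair_response(tr, 4, 15, 15)
  got5 <- extract_pair_response(tr, 5, 15, 15)
  expect_lt(abs(got4 - (-7.8)), 0.5)
  expect_lt(abs(got5 - (-7.8)), 0.5)
})

test_that("effective pair count implements the 75%-of-max rule", {
  expect_equal(effective_pair_count(c(-8, -6.2, -1, 0, rep(0, 10))), 2)
  expect_equal(effective_pair_count(rep(-3, 14)), 14)
  expect_error(effective_pair_count(rep(NA_real_, 14)), "missing")

  set.seed(61)
  for (rep in 1:500) {
    v <- rnorm(14, 0, 5)
    v[sample(14, sample(0:10, 1))] <- NA
    if (all(is.na(v))) next
    got <- effective_pair_count(v)
    vv <- v[!is.na(v)]
    expect_identical(got, sum(abs(vv) >= 0.75 * max(abs(vv))))
  }
})

test_that("backprojection paints angular Voronoi sectors", {
  cuff <- electrode_cuff()
  W <- 256

  # one-hot response: exactly one sector nonzero, value 1
  v <- rep(0, 14); v[6] <- -5
  m <- backproject(v, cuff, W)
  g <- grid_coords(W)
  theta <- (atan2(g$x, g$y) * 180 / pi) %% 360
  sector6 <- angular_distance(theta, cuff$pair_angles[6])
  others <- sapply(cuff$pair_angles[-6], function(a) angular_distance(theta, a))
  in6 <- sector6 < apply(others, 1, min) & g$x^2 + g$y^2 <= 1
  expect_true(all(m$values[in6] == 1))
  expect_true(all(m$values[!in6 & (g$x^2 + g$y^2 <= 1) &
                             sector6 > apply(others, 1, min)] == 0))

  # all equal -> uniform 1 within the mask
  mu <- backproject(rep(4, 14), cuff, W)
  expect_true(all(mu$values[g$x^2 + g$y^2 <= 1] == 1))
  expect_true(all(mu$values[g$x^2 + g$y^2 > 1] == 0))

  # sector pixel counts equal across pairs within 2%
  sec <- backproject(seq_len(14), cuff, W)  # distinct values per sector
  counts <- vapply(seq_len(14), function(k) {
    sum(abs(sec$values - k / 14) < 1e-12)
  }, numeric(1))
  expect_lt((max(counts) - min(counts)) / mean(counts), 0.02)

  # missing pairs map to zero
  vna <- rep(NA_real_, 14); vna[2] <- 10
  mna <- backproject(vna, cuff, W)
  expect_equal(sort(unique(as.vector(mna$values))), c(0, 1))
})

test_that("backprojection is approximately equivariant to pair rotation", {
  cuff <- electrode_cuff()
  W <- 256
  set.seed(67)
  v <- rnorm(14)
  m1 <- backproject(v, cuff, W)
  v_shift <- v[c(14, 1:13)]              # pair k takes pair k-1's value
  m2 <- backproject(v_shift, cuff, W)
  m1_rot <- rotate_map(m1, 360 / 14)
  g <- grid_coords(W)
  inmask <- g$x^2 + g$y^2 <= 1
  agree <- mean(abs(m1_rot$values[inmask] - m2$values[inmask]) < 1e-9)
  expect_gt(agree, 0.98)
})

test_that("simulated sessions invert through response extraction", {
  cfg <- synthetic_config(seed = 71)
  nerve <- generate_cross_section(cfg, 1, technique = "svns")
  cuff <- electrode_cuff()
  model <- activation_model(noise_sd = c(hr = 0, etco2 = 0, emg_rms = 0),
                            response_delay = c(efferent = 0, afferent = 0))
  for (target in c("cardiac_efferent", "laryngeal", "pulmonary")) {
    protocol <- stimulation_protocol(target)
    tr <- simulate_session(nerve, cuff, protocol, model, seed = 1)[[1]]
    gt <- attr(tr, "ground_truth")$total
    prs <- pair_responses(tr, cuff, baseline_window = protocol$off_duration,
                          response_window = protocol$on_duration,
                          animal_id = "a1", condition = "pre_vagotomy")
    expect_equal(prs$values[protocol$pairs_stimulated],
                 gt[protocol$pairs_stimulated], tolerance = 1e-6)
  }
})

test_that("delayed reflex responses are still recovered", {
  cfg <- synthetic_config(seed = 73)
  nerve <- generate_cross_section(cfg, 2, technique = "svns")
  cuff <- electrode_cuff()
  model <- activation_model(noise_sd = c(hr = 0, etco2 = 0, emg_rms = 0),
                            vagotomy_state = "right_distal",
                            afferent_polarity = "bradycardia")
  protocol <- stimulation_protocol("cardiac_afferent")
  tr <- simulate_session(nerve, cuff, protocol, model, seed = 1)[[1]]
  gt <- attr(tr, "ground_truth")$total
  # baseline window excludes the previous epoch's delayed-response tail
  # (the reflex returns to baseline delay + on_duration after onset)
  prs <- pair_responses(tr, cuff, baseline_window = 40,
                        response_window = protocol$on_duration +
                          protocol$off_duration / 2)
  expect_equal(prs$values[protocol$pairs_stimulated],
               gt[protocol$pairs_stimulated], tolerance = 1e-6)
  expect_true(all(is.na(prs$values[-protocol$pairs_stimulated])))
})

test_that("response atlases are max-normalized means of per-animal maps", {
  cuff <- electrode_cuff()
  v1 <- c(1, 0.5, rep(0, 12))
  v2 <- c(0.5, 1, rep(0, 12))
  m1 <- rotate_map(backproject(v1, cuff, 128, group = "cardiac_efferent"), 0)
  m2 <- rotate_map(backproject(v2, cuff, 128, group = "cardiac_efferent"), 0)

  # one animal: atlas equals its normalized map
  a1 <- build_atlas(list(m1), renormalize = TRUE)
  expect_equal(a1$values, m1$values)

  # identical maps: atlas max is 1
  a2 <- build_atlas(list(m1, m1), renormalize = TRUE)
  expect_equal(max(a2$values), 1)
  expect_equal(a2$values, m1$values)

  # differing maps: values stay in [0, 1] and max is 1
  a3 <- build_atlas(list(m1, m2), renormalize = TRUE)
  expect_true(all(a3$values >= 0 & a3$values <= 1))
  expect_equal(max(a3$values), 1)
})
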