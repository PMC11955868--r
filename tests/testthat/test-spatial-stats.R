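test_that("centre of mass matches a direct-summation oracle", {
  # point mass: single positive pixel at known polar position
  m <- disc_map(90, 0.5, 0.001, W = 256)  # sub-pixel disc -> up to a few px
  if (sum(m$values) == 0) {
    # ensure at least the nearest pixel is set
    W <- 256
    ctr <- pol2cart(90, 0.5)
    j <- floor((ctr[1, "x"] + 1) * W / 2) + 1
    i <- floor((1 - ctr[1, "y"]) * W / 2) + 1
    vals <- matrix(0, W, W); vals[i, j] <- 1
    m <- pixel_map(vals, group = "laryngeal")
  }
  cm <- center_of_mass(m)
  expect_lt(angular_distance(cm$angle, 90), 1)
  expect_lt(abs(cm$radius - 0.5), 2 / 256 + 1e-9)

  # uniform disc: degenerate, radius ~ 0
  g <- grid_coords(64)
  unif <- pixel_map((g$x^2 + g$y^2 <= 1) * 1, group = "laryngeal")
  cmu <- center_of_mass(unif)
  expect_true(cmu$degenerate)
  expect_equal(cmu$angle, 0)
  expect_lt(cmu$radius, 2 / 64)

  # empty map errors
  expect_error(center_of_mass(pixel_map(matrix(0, 16, 16))), "no positive")

  # random 7x7 maps against the explicit sum(w x)/sum(w) oracle
  set.seed(83)
  gc <- grid_coords(7)
  mask <- gc$x^2 + gc$y^2 <= 1
  for (rep in 1:500) {
    vals <- matrix(runif(49), 7, 7) * mask
    if (sum(vals) == 0) next
    m <- pixel_map(vals, group = "laryngeal")
    cm <- center_of_mass(m)
    xb <- sum(vals * gc$x) / sum(vals)
    yb <- sum(vals * gc$y) / sum(vals)
    expect_equal(cm$radius, sqrt(xb^2 + yb^2), tolerance = 1e-12)
    if (!cm$degenerate) {
      expect_equal(cm$angle, (atan2(xb, yb) * 180 / pi) %% 360,
                   tolerance = 1e-12)
    }
  }
})

test_that("overlap matrices match exhaustive pixel-set intersections", {
  # identical maps: off-diagonal equals diagonal
  m <- disc_map(0, 0.4, 0.3, W = 64, group = "laryngeal", frame = "rotated")
  m2 <- m; m2$group <- "pulmonary"
  om <- overlap_matrix(list(laryngeal = m, pulmonary = m2), tau = 0.5)
  expect_equal(om["laryngeal", "pulmonary"], om["laryngeal", "laryngeal"])

  # disjoint maps: zero off-diagonal
  d1 <- disc_map(0, 0.6, 0.15, W = 64, group = "laryngeal", frame = "rotated")
  d2 <- disc_map(180, 0.6, 0.15, W = 64, group = "pulmonary", frame = "rotated")
  om2 <- overlap_matrix(list(laryngeal = d1, pulmonary = d2), tau = 0.5)
  expect_equal(om2["laryngeal", "pulmonary"], 0)

  # random maps vs set-operation oracle; invariants hold
  set.seed(89)
  g <- grid_coords(32)
  mask <- g$x^2 + g$y^2 <= 1
  total <- sum(mask)
  for (rep in 1:200) {
    a <- random_binary_map(32, runif(1, 0.05, 0.6), "laryngeal")
    b <- random_binary_map(32, runif(1, 0.05, 0.6), "pulmonary")
    om <- overlap_matrix(list(laryngeal = a, pulmonary = b), tau = 0.5)
    pa <- a$values == 1 & mask
    pb <- b$values == 1 & mask
    expect_equal(om["laryngeal", "laryngeal"], sum(pa) / total)
    expect_equal(om["pulmonary", "pulmonary"], sum(pb) / total)
    expect_equal(om["laryngeal", "pulmonary"], sum(pa & pb) / total)
    expect_equal(om["laryngeal", "pulmonary"], om["pulmonary", "laryngeal"])
    expect_lte(om["laryngeal", "pulmonary"],
               min(om["laryngeal", "laryngeal"], om["pulmonary", "pulmonary"]) + 1e-12)
    expect_true(all(om >= 0 & om <= 1))
  }
})

test_that("relative overlap reproduces the published worked examples", {
  ref <- reference_overlap_matrices()
  expect_equal(relative_overlap(ref$microct, "pulmonary", "cardiac_afferent"), 48)
  expect_equal(relative_overlap(ref$microct, "cardiac_afferent", "cardiac_efferent"), 0)
  expect_equal(relative_overlap(ref$microct, "cardiac_efferent", "pulmonary"), 30)
  expect_equal(relative_overlap(ref$svns, "pulmonary", "cardiac_efferent"), 52)
  # self-ratio is always 100%
  expect_equal(relative_overlap(ref$microct, "laryngeal", "laryngeal"), 100)
  # undefined for a zero-area group
  gr <- functional_groups()
  z <- matrix(0.0, 4, 4, dimnames = list(gr, gr)); diag(z) <- c(0.5, 0.5, 0.5, 0)
  zm <- as_overlap_matrix(z)
  expect_error(relative_overlap(zm, "cardiac_afferent", "laryngeal"),
               "zero area")
})

test_that("relative overlaps satisfy the symmetry identity up to rounding", {
  set.seed(97)
  for (rep in 1:50) {
    a <- random_binary_map(32, runif(1, 0.1, 0.5), "laryngeal")
    b <- random_binary_map(32, runif(1, 0.1, 0.5), "pulmonary")
    om <- overlap_matrix(list(laryngeal = a, pulmonary = b), tau = 0.5)
    if (om["laryngeal", "laryngeal"] == 0 || om["pulmonary", "pulmonary"] == 0) next
    rab <- relative_overlap(om, "laryngeal", "pulmonary")
    rba <- relative_overlap(om, "pulmonary", "laryngeal")
    lhs <- rab * om["laryngeal", "laryngeal"]
    rhs <- rba * om["pulmonary", "pulmonary"]
    # both equal 100*offdiag up to the integer rounding of each factor
    expect_lt(abs(lhs - rhs),
              0.5 * (om["laryngeal", "laryngeal"] + om["pulmonary", "pulmonary"]) + 1e-9)
  }
})

test_that("cross-technique overlap equals the set-intersection oracle", {
  m <- disc_map(0, 0.4, 0.3, W = 64, frame = "rotated")
  expect_equal(cross_technique_overlap(m, m, tau = 0.5),
               sum(m$values >= 0.5) / sum(grid_coords(64)$x^2 +
                                            grid_coords(64)$y^2 <= 1))
  d1 <- disc_map(0, 0.6, 0.15, W = 64, frame = "rotated")
  d2 <- disc_map(180, 0.6, 0.15, W = 64, frame = "rotated")
  expect_equal(cross_technique_overlap(d1, d2, 0.5), 0)

  set.seed(101)
  g <- grid_coords(32); mask <- g$x^2 + g$y^2 <= 1
  for (rep in 1:100) {
    a <- random_binary_map(32, runif(1, 0.05, 0.6))
    b <- random_binary_map(32, runif(1, 0.05, 0.6))
    expect_equal(cross_technique_overlap(a, b, 0.5),
                 sum(a$values == 1 & b$values == 1 & mask) / sum(mask))
  }
})

test_that("angular group comparison detects separated groups, not identical ones", {
  # identical angle sets -> F = 0, p = 1
  coms <- data.frame(angle = rep(c(10, 20, 30), 2),
                     group = rep(c("a", "b"), each = 3))
  res <- angular_group_comparison(coms)
  expect_equal(attr(res, "F_overall"), 0, tolerance = 1e-12)
  expect_equal(res$p_adjusted, 1, tolerance = 1e-9)

  # groups at 0 and 180, SD 5, n = 5 -> adjusted p << 0.001
  set.seed(103)
  coms2 <- data.frame(
    angle = c(rnorm(5, 0, 5) %% 360, rnorm(5, 180, 5)),
    group = rep(c("cardiac_efferent", "cardiac_afferent"), each = 5)
  )
  res2 <- angular_group_comparison(coms2)
  expect_lt(res2$p_adjusted, 0.001)

  # a group straddling the 0/360 wrap must not inflate its variance
  set.seed(104)
  coms3 <- data.frame(
    angle = c((rnorm(6, 0, 8)) %% 360, (rnorm(6, 180, 8)) %% 360),
    group = rep(c("ce", "ca"), each = 6)
  )
  res3 <- angular_group_comparison(coms3)
  expect_lt(res3$p_adjusted, 1e-6)

  # undersized groups are excluded with a warning
  coms4 <- rbind(coms2, data.frame(angle = 90, group = "laryngeal"))
  expect_warning(res4 <- angular_group_comparison(coms4), "fewer than 2")
  expect_equal(nrow(res4), 1L)
})

test_that("ANOVA p-values agree with a permutation oracle", {
  set.seed(107)
  angle <- c(rnorm(6, 20, 30), rnorm(6, 60, 30), rnorm(6, 90, 30)) %% 360
  group <- rep(c("a", "b", "c"), each = 6)
  res <- angular_group_comparison(data.frame(angle = angle, group = group))
  p_anova <- attr(res, "p_overall")

  # permutation distribution of the between/within F on the unwrapped angles
  x <- vagusmap:::unwrap_by_group(angle, group)
  f_of <- function(x, g) {
    gm <- tapply(x, g, mean); n <- tapply(x, g, length)
    ssb <- sum(n * (gm - mean(x))^2)
    ssw <- sum((x - ave(x, g))^2)
    (ssb / (length(unique(g)) - 1)) / (ssw / (length(x) - length(unique(g))))
  }
  f_obs <- f_of(x, group)
  perm <- replicate(10000, f_of(x, sample(group)))
  p_perm <- mean(perm >= f_obs)
  expect_lt(abs(p_anova - p_perm), 0.02)
})

test_that("the circular Watson-Williams variant agrees on clear separations", {
  set.seed(109)
  coms <- data.frame(
    angle = c(rnorm(8, 0, 10) %% 360, rnorm(8, 180, 10)),
    group = rep(c("ce", "ca"), each = 8)
  )
  res <- angular_group_comparison(coms, circular = TRUE)
  expect_identical(res$method, "watson-williams")
  expect_lt(res$p_adjusted, 0.001)

  null <- data.frame(angle = rep(c(40, 50, 60, 70), 2),
                     group = rep(c("a", "b"), each = 4))
  res0 <- angular_group_comparison(null, circular = TRUE)
  expect_gt(res0$p_value, 0.9)
})

test_that("angular separation summaries are unbiased at 180 degrees", {
  a <- data.frame(animal_id = 1:5, angle = rep(10, 5))
  s0 <- angular_separation_summary(a, a)
  expect_equal(s0$mean, 0)
  expect_equal(s0$sd, 0)

  b <- data.frame(animal_id = 1:5, angle = (a$angle + 180) %% 360)
  s180 <- angular_separation_summary(a, b)
  expect_equal(s180$mean, 180)
  expect_equal(s180$sd, 0)

  # separations straddling the fold at 180 keep their mean there
  set.seed(113)
  ca <- data.frame(animal_id = 1:200,
                   angle = (180 + rnorm(200, 0, 40)) %% 360)
  ce <- data.frame(animal_id = 1:200, angle = rep(0, 200))
  s <- angular_separation_summary(ca, ce)
  expect_lt(abs(s$mean - 180), 10)
  expect_gt(s$sd, 25)
})
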