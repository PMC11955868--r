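# Shared fixtures built in code.

# A nerve with hand-placed fascicles: cardiac efferent near the top (0 deg),
# cardiopulmonary near the bottom (180 deg), laryngeal/pulmonary off-axis.
toy_nerve <- function(radius = 1) {
  fas <- rbind(
    fascicle("ce", 0.00, 0.60 * radius, 0.02, "cardiac", "efferent"),
    fascicle("ca", 0.00, -0.60 * radius, 0.02, "cardiopulmonary", "afferent"),
    fascicle("la", 0.40 * radius, 0.40 * radius, 0.03, "laryngeal", "efferent"),
    fascicle("pu", -0.40 * radius, -0.40 * radius, 0.03, "pulmonary", "afferent")
  )
  nerve_cross_section("toy", radius, fas, technique = "microct")
}

# Pixel map holding a single disc at polar (angle, radius) with disc radius r.
disc_map <- function(angle, radius, r, W = 256, group = "cardiac_efferent",
                     frame = "raw") {
  ctr <- pol2cart(angle, radius)
  cx <- (seq_len(W) - 0.5) * 2 / W - 1
  x <- matrix(cx, W, W, byrow = TRUE)
  y <- matrix(rev(cx), W, W)
  vals <- ((x - ctr[1, "x"])^2 + (y - ctr[1, "y"])^2 <= r^2) * 1
  pixel_map(vals, group = group, frame = frame)
}

# Random binary map: each in-mask pixel on with probability p.
random_binary_map <- function(W = 32, p = 0.3, group = "laryngeal",
                              frame = "rotated") {
  vals <- matrix(as.numeric(stats::runif(W * W) < p), W, W)
  pixel_map(vals, group = group, frame = frame)
}

# Template pixel-centre coordinates, duplicated from first principles so map
# oracles do not depend on the package internals.
grid_coords <- function(W) {
  cx <- (seq_len(W) - 0.5) * 2 / W - 1
  list(x = matrix(cx, W, W, byrow = TRUE), y = matrix(rev(cx), W, W))
}
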