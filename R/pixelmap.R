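## Raster template ---------------------------------------------------------
## The template is the unit disc sampled on a W x W grid. Pixel (i, j) (row i
## from the top, column j from the left) has centre
##   x = (j - 0.5) * 2/W - 1,  y = 1 - (i - 0.5) * 2/W,
## so row 1 is the top of the displayed cross-section, consistent with the
## 0-degrees-at-top, clockwise angle convention.

template_grid_env <- new.env(parent = emptyenv())

template_grid <- function(W) {
  key <- as.character(W)
  if (!is.null(template_grid_env[[key]])) return(template_grid_env[[key]])
  cx <- (seq_len(W) - 0.5) * 2 / W - 1
  x <- matrix(cx, nrow = W, ncol = W, byrow = TRUE)
  y <- matrix(rev(cx), nrow = W, ncol = W)
  g <- list(x = x, y = y, mask = x^2 + y^2 <= 1)
  template_grid_env[[key]] <- g
  g
}

#' Construct a pixel map on the circular template
#'
#' A W x W raster over the unit-disc template. Values outside the disc mask
#' are always 0; fascicle maps are binary (\{0, 1\}), response and atlas maps
#' take values in \[0, 1\].
#'
#' @param values W x W numeric matrix (row 1 = top of the cross-section).
#' @param group Functional group of the map (see [functional_groups()]), or
#'   `NA` for generic maps.
#' @param frame `"raw"` (as acquired) or `"rotated"` (cardiac-efferent
#'   centre of mass aligned to 0 degrees).
#' @param animal_id Optional animal identifier carried as metadata.
#' @param technique Optional technique tag (`"microct"` or `"svns"`).
#' @return An object of class `pixel_map`.
#' @export
pixel_map <- function(values, group = NA_character_, frame = c("raw", "rotated"),
                      animal_id = NA_character_, technique = NA_character_) {
  frame <- match.arg(frame)
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    stop("values must be a square matrix")
  }
  W <- nrow(values)
  g <- template_grid(W)
  values[!g$mask] <- 0
  if (any(values < 0 | values > 1)) stop("pixel map values must lie in [0, 1]")
  structure(
    list(values = values, W = W, group = group, frame = frame,
         animal_id = animal_id, technique = technique),
    class = "pixel_map"
  )
}

#' @export
print.pixel_map <- function(x, ...) {
  cat(sprintf("<%s> %dx%d, group %s, frame %s, %d positive pixels\n",
              class(x)[1], x$W, x$W, x$group, x$frame, sum(x$values > 0)))
  invisible(x)
}

#' Display a pixel map
#'
#' Draws the map with the package's orientation convention (0 degrees at the
#' top, angles increasing clockwise) and marks the electrode pair positions
#' if a cuff is supplied.
#'
#' @param x A [pixel_map()].
#' @param cuff Optional [electrode_cuff()] whose pair positions are marked.
#' @param ... Passed to [graphics::image()].
#' @export
plot.pixel_map <- function(x, cuff = NULL, ...) {
  W <- x$W
  cx <- (seq_len(W) - 0.5) * 2 / W - 1
  ## image() expects z[i, j] at x = cx[i], y = cx[j]; our row 1 is the top
  z <- t(x$values)[, W:1, drop = FALSE]
  graphics::image(cx, cx, z, asp = 1, xlab = "x", ylab = "y",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  main = sprintf("%s (%s)", x$group, x$frame), ...)
  th <- seq(0, 2 * pi, length.out = 256)
  graphics::lines(cos(th), sin(th))
  if (!is.null(cuff)) {
    ep <- electrode_positions(cuff, 1.03)
    graphics::points(ep[, "x"], ep[, "y"], pch = 19)
    graphics::text(ep[, "x"] * 1.12, ep[, "y"] * 1.12, seq_len(cuff$n_pairs),
                   cex = 0.7)
  }
  invisible(x)
}

## Group membership --------------------------------------------------------

#' Functional group(s) of a fascicle
#'
#' Maps organ labels to the functional map groups. Purely cardiac fascicles
#' are cardiac efferent (in the porcine cervical vagus they were found to be
#' exclusively efferent); cardiopulmonary fascicles carry afferent fibres of
#' both cardiac and pulmonary origin and contribute to the cardiac afferent
#' and pulmonary maps; laryngopulmonary fascicles contribute to both the
#' laryngeal and pulmonary maps.
#'
#' @param organ_label A single organ label.
#' @return Character vector of functional groups.
#' @export
group_of <- function(organ_label) {
  switch(organ_label,
    cardiac = "cardiac_efferent",
    cardiopulmonary = c("cardiac_afferent", "pulmonary"),
    pulmonary = "pulmonary",
    laryngeal = "laryngeal",
    laryngopulmonary = c("laryngeal", "pulmonary"),
    stop("unknown organ_label '", organ_label, "'")
  )
}

#' Rasterize the fascicles of one functional group
#'
#' Projects the nerve's fascicles onto the template and paints each fascicle
#' of the requested group as a filled disc of equivalent radius
#' `sqrt(area/pi)` (template units). A pixel is 1 iff its centre lies inside
#' any such disc and inside the nerve mask.
#'
#' @param nerve A [nerve_cross_section()].
#' @param cuff An [electrode_cuff()].
#' @param group A functional group (see [functional_groups()]).
#' @param W Raster width in pixels (default 256).
#' @return A binary [pixel_map()] in the raw frame.
#' @export
rasterize_group <- function(nerve, cuff, group, W = 256) {
  group <- match.arg(group, functional_groups())
  proj <- project_to_template(nerve$fascicles, nerve, cuff)
  sel <- vapply(proj$organ_label, function(o) group %in% group_of(o), logical(1))
  g <- template_grid(W)
  vals <- matrix(0, W, W)
  if (any(sel)) {
    ctr <- pol2cart(proj$angle[sel], proj$radius[sel])
    rr <- sqrt(proj$area[sel] / pi)
    for (k in seq_len(nrow(ctr))) {
      inside <- (g$x - ctr[k, "x"])^2 + (g$y - ctr[k, "y"])^2 <= rr[k]^2
      vals[inside] <- 1
    }
  }
  pixel_map(vals, group = group, frame = "raw",
            animal_id = nerve$animal_id, technique = nerve$technique)
}

#' Alignment angle of a cardiac-efferent map
#'
#' The rotation reference for each animal: the centre-of-mass angle of its
#' cardiac-efferent map. Rotating every map of that animal by the negation of
#' this angle places the cardiac-efferent centre of mass at 0 degrees (top).
#' When several cardiac-efferent fascicles are present the area-weighted
#' centre of mass of the whole group map is used.
#'
#' @param map A non-empty cardiac-efferent [pixel_map()].
#' @return Angle in degrees.
#' @export
alignment_angle <- function(map) {
  stopifnot(inherits(map, "pixel_map"))
  if (sum(map$values) <= 0) {
    stop("cannot align: cardiac-efferent map is empty")
  }
  center_of_mass(map)$angle
}

#' Rotate a pixel map about the template centre
#'
#' Nearest-neighbour resampling under rotation by `angle` degrees (content at
#' angle theta moves to theta + angle, i.e. clockwise for positive angles).
#' Nearest-neighbour interpolation preserves binarity, which the atlas
#' semantics require. The nerve mask is invariant.
#'
#' @param map A [pixel_map()].
#' @param angle Rotation in degrees.
#' @return A [pixel_map()] in the rotated frame.
#' @export
rotate_map <- function(map, angle) {
  stopifnot(inherits(map, "pixel_map"))
  W <- map$W
  g <- template_grid(W)
  a <- deg2rad(angle)
  ## inverse mapping: output pixel at angle psi samples input at psi - angle
  xs <- g$x * cos(a) - g$y * sin(a)
  ys <- g$x * sin(a) + g$y * cos(a)
  j <- pmin(pmax(floor((xs + 1) * W / 2) + 1L, 1L), W)
  i <- pmin(pmax(floor((1 - ys) * W / 2) + 1L, 1L), W)
  vals <- matrix(map$values[cbind(as.vector(i), as.vector(j))], W, W)
  vals[!g$mask] <- 0
  out <- pixel_map(vals, group = map$group, frame = "rotated",
                   animal_id = map$animal_id, technique = map$technique)
  out
}

#' Average rotation-aligned maps into a cross-animal atlas
#'
#' Pixel-wise arithmetic mean of per-animal maps of the same group in the
#' rotated frame. For binary fascicle maps the mean is already the normalized
#' atlas: 0 means no animal had the group at that location, 1 means every
#' animal did. For response maps (per-animal values already max-normalized to
#' \[0, 1\]) set `renormalize = TRUE` to divide the averaged atlas by its own
#' maximum so the atlas maximum is 1.
#'
#' @param maps List of [pixel_map()]s, same `W`, same group, rotated frame.
#' @param renormalize Divide the mean map by its maximum (response atlases).
#' @return An `atlas_map` (subclass of `pixel_map`) with field `n_animals`.
#' @export
build_atlas <- function(maps, renormalize = FALSE) {
  stopifnot(length(maps) >= 1, all(vapply(maps, inherits, logical(1), "pixel_map")))
  W <- maps[[1]]$W
  grp <- maps[[1]]$group
  if (!all(vapply(maps, function(m) m$W == W, logical(1)))) {
    stop("all maps must share the same raster width")
  }
  if (!all(vapply(maps, function(m) identical(m$group, grp), logical(1)))) {
    stop("all maps must belong to the same group")
  }
  if (!all(vapply(maps, function(m) m$frame == "rotated", logical(1)))) {
    stop("atlas inputs must be in the rotated frame")
  }
  mean_vals <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
  if (renormalize && max(mean_vals) > 0) mean_vals <- mean_vals / max(mean_vals)
  out <- pixel_map(mean_vals, group = grp, frame = "rotated",
                   technique = maps[[1]]$technique)
  out$n_animals <- length(maps)
  class(out) <- c("atlas_map", class(out))
  out
}
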