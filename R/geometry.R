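#' @keywords internal
"_PACKAGE"

## Shared label sets -------------------------------------------------------

#' Organ, fibre and functional-group label sets
#'
#' Labels used throughout the package. Organ labels follow the branch origin
#' of each fascicle traced in microCT; fibre labels follow whether a fascicle
#' originates from the nodose ganglion (afferent) or bypasses it (efferent).
#' Functional groups are the four map/atlas categories: laryngeal, pulmonary,
#' cardiac efferent and cardiac afferent.
#'
#' @name labels
#' @keywords internal
NULL

organ_labels <- function() {
  c("laryngeal", "pulmonary", "cardiac", "cardiopulmonary", "laryngopulmonary")
}

fibre_labels <- function() c("afferent", "efferent", "mixed")

#' Functional group labels
#'
#' The four functional groups mapped by the pipeline, in canonical order:
#' laryngeal (L), pulmonary (P), cardiac efferent (CE), cardiac afferent (CA).
#'
#' @return Character vector of length 4.
#' @export
functional_groups <- function() {
  c("laryngeal", "pulmonary", "cardiac_efferent", "cardiac_afferent")
}

## Angle conventions -------------------------------------------------------
## Angles are in degrees, 0 at the top (12 o'clock) of the displayed
## cross-section, increasing clockwise. All modules share this convention.

deg2rad <- function(d) d * pi / 180

#' Convert polar template coordinates to Cartesian
#'
#' Angles are degrees clockwise from the top of the cross-section; the
#' returned Cartesian frame has x to the right and y upward.
#'
#' @param angle Angle in degrees (0 = top, clockwise positive).
#' @param radius Radial coordinate (same units as the output).
#' @return A two-column matrix with columns `x`, `y`.
#' @export
pol2cart <- function(angle, radius) {
  a <- deg2rad(angle)
  cbind(x = radius * sin(a), y = radius * cos(a))
}

#' Convert Cartesian coordinates to the polar template convention
#'
#' @param x,y Cartesian coordinates (x right, y up).
#' @return A list with `angle` (degrees in \[0, 360), clockwise from top) and
#'   `radius`.
#' @export
cart2pol <- function(x, y) {
  list(angle = (atan2(x, y) * 180 / pi) %% 360,
       radius = sqrt(x^2 + y^2))
}

#' Wrapped absolute angular separation
#'
#' Absolute separation between two angles on the circle, wrapped to
#' \[0, 180\] degrees. Vectorised over both arguments.
#'
#' @param a,b Angles in degrees.
#' @return Separation in degrees, in \[0, 180\].
#' @examples
#' angular_distance(350, 10) # 20
#' @export
angular_distance <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Circular mean of angles
#'
#' @param angles Angles in degrees.
#' @param w Optional non-negative weights.
#' @return Circular mean in degrees, in \[0, 360).
#' @export
circular_mean <- function(angles, w = NULL) {
  if (is.null(w)) w <- rep(1, length(angles))
  a <- deg2rad(angles)
  (atan2(sum(w * sin(a)), sum(w * cos(a))) * 180 / pi) %% 360
}

## wrap a signed angular difference to (-180, 180]
wrap180 <- function(d) {
  out <- -((-d + 180) %% 360 - 180)
  out
}

## Cuff geometry -----------------------------------------------------------

#' Multi-electrode cuff geometry
#'
#' Describes a circumferential nerve cuff with `n_pairs` electrode pairs.
#' Each pair occupies one angular position (the two longitudinal rings of the
#' physical cuff share angular coordinates, so they collapse to a single
#' angle for mapping purposes). The default is the 14-pair array used for
#' spatially selective vagus nerve stimulation: two rings of 14 pads
#' (3.00 x 0.35 mm) on a 2.7 mm inner-diameter tube, pairs equally spaced
#' around the circumference.
#'
#' @param n_pairs Number of electrode pairs (>= 2).
#' @param pair_angles Angular positions of the pairs in degrees, strictly
#'   increasing, all in \[0, 360). Default: equally spaced, starting at 0.
#' @param inner_diameter Cuff inner diameter in mm.
#' @param pad_width,pad_length Pad dimensions in mm (metadata only; pads are
#'   modelled as points for mapping).
#' @return An object of class `electrode_cuff`.
#' @export
electrode_cuff <- function(n_pairs = 14, pair_angles = NULL,
                           inner_diameter = 2.7,
                           pad_width = 0.35, pad_length = 3.00) {
  if (!is.numeric(n_pairs) || length(n_pairs) != 1 || n_pairs < 2) {
    stop("n_pairs must be a single number >= 2")
  }
  n_pairs <- as.integer(n_pairs)
  if (is.null(pair_angles)) {
    pair_angles <- (seq_len(n_pairs) - 1) * 360 / n_pairs
  }
  if (length(pair_angles) != n_pairs) {
    stop("pair_angles must have length n_pairs")
  }
  if (any(pair_angles < 0 | pair_angles >= 360)) {
    stop("pair_angles must lie in [0, 360)")
  }
  if (any(diff(pair_angles) <= 0)) {
    stop("pair_angles must be strictly increasing")
  }
  structure(
    list(n_pairs = n_pairs, pair_angles = pair_angles,
         inner_diameter = inner_diameter,
         pad_width = pad_width, pad_length = pad_length),
    class = "electrode_cuff"
  )
}

#' Electrode positions on a circle
#'
#' Cartesian positions of the electrode pairs placed on a circle of the given
#' radius (the nerve boundary, or the unit circle of the template).
#'
#' @param cuff An [electrode_cuff()].
#' @param radius Circle radius (default 1, the template).
#' @return Matrix with columns `x`, `y`, one row per pair.
#' @export
electrode_positions <- function(cuff, radius = 1) {
  stopifnot(inherits(cuff, "electrode_cuff"))
  pol2cart(cuff$pair_angles, radius)
}

## Fascicles and cross-sections --------------------------------------------

#' Construct a fascicle record
#'
#' One segmented fascicle cross-section: centroid in nerve-local mm
#' coordinates, cross-sectional area, and its organ / fibre-type labels.
#'
#' @param id Fascicle identifier (character).
#' @param cx,cy Centroid coordinates in mm (nerve-local, x right, y up).
#' @param area Cross-sectional area in mm^2 (> 0).
#' @param organ_label One of `"laryngeal"`, `"pulmonary"`, `"cardiac"`,
#'   `"cardiopulmonary"`, `"laryngopulmonary"`.
#' @param fibre_label One of `"afferent"`, `"efferent"`, `"mixed"`.
#' @return A one-row data frame.
#' @export
fascicle <- function(id, cx, cy, area, organ_label, fibre_label) {
  df <- data.frame(id = as.character(id), cx = cx, cy = cy, area = area,
                   organ_label = organ_label, fibre_label = fibre_label,
                   stringsAsFactors = FALSE)
  validate_fascicles(df)
  df
}

validate_fascicles <- function(df, nerve_radius = NULL) {
  req <- c("id", "cx", "cy", "area", "organ_label", "fibre_label")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("fascicle table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  bad <- which(!(df$organ_label %in% organ_labels()))
  if (length(bad)) {
    stop(sprintf("row %d: unknown organ_label '%s'", bad[1], df$organ_label[bad[1]]))
  }
  bad <- which(!(df$fibre_label %in% fibre_labels()))
  if (length(bad)) {
    stop(sprintf("row %d: unknown fibre_label '%s'", bad[1], df$fibre_label[bad[1]]))
  }
  bad <- which(!is.finite(df$area) | df$area <= 0)
  if (length(bad)) {
    stop(sprintf("row %d: non-positive fascicle area", bad[1]))
  }
  if (!is.null(nerve_radius)) {
    ## reject centroids strictly outside the boundary (invalid segmentation);
    ## points on the boundary itself are tolerated
    r <- sqrt(df$cx^2 + df$cy^2)
    bad <- which(r > nerve_radius * (1 + 1e-12))
    if (length(bad)) {
      stop(sprintf("row %d: fascicle centroid outside the nerve boundary", bad[1]))
    }
  }
  invisible(df)
}

#' Construct a nerve cross-section
#'
#' A nerve's mid-cuff cross-section: a circular boundary of radius
#' `nerve_radius` (mm) and a table of labelled fascicles. All fascicle
#' centroids must lie strictly inside the boundary.
#'
#' @param animal_id Animal identifier.
#' @param nerve_radius Nerve boundary radius in mm (> 0).
#' @param fascicles Data frame of fascicles (see [fascicle()]).
#' @param technique `"microct"` (traced anatomy) or `"svns"` (stimulation
#'   session geometry).
#' @return An object of class `nerve_cross_section`.
#' @export
nerve_cross_section <- function(animal_id, nerve_radius, fascicles,
                                technique = c("microct", "svns")) {
  technique <- match.arg(technique)
  if (!is.numeric(nerve_radius) || nerve_radius <= 0) {
    stop("nerve_radius must be > 0")
  }
  validate_fascicles(fascicles, nerve_radius = nerve_radius)
  structure(
    list(animal_id = as.character(animal_id), nerve_radius = nerve_radius,
         fascicles = fascicles, technique = technique),
    class = "nerve_cross_section"
  )
}

#' @export
print.nerve_cross_section <- function(x, ...) {
  cat(sprintf("<nerve_cross_section> animal %s (%s): radius %.3f mm, %d fascicles\n",
              x$animal_id, x$technique, x$nerve_radius, nrow(x$fascicles)))
  tab <- table(x$fascicles$organ_label)
  cat("  ", paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Nearest electrode pair to a fascicle centroid
#'
#' Electrodes are modelled as points on the nerve boundary circle at the cuff
#' pair angles. Returns, for each fascicle, the pair index minimising the
#' Euclidean centroid-to-electrode distance (ties broken by lowest index) and
#' that distance in mm. Pair indices are 1-based.
#'
#' @param fascicles A fascicle data frame (one or more rows).
#' @param nerve A [nerve_cross_section()].
#' @param cuff An [electrode_cuff()].
#' @return Data frame with columns `pair` and `distance` (mm).
#' @export
nearest_electrode <- function(fascicles, nerve, cuff) {
  stopifnot(inherits(nerve, "nerve_cross_section"),
            inherits(cuff, "electrode_cuff"))
  validate_fascicles(fascicles, nerve_radius = nerve$nerve_radius)
  el <- electrode_positions(cuff, radius = nerve$nerve_radius)
  dx <- outer(fascicles$cx, el[, "x"], "-")
  dy <- outer(fascicles$cy, el[, "y"], "-")
  d <- sqrt(dx^2 + dy^2)
  pair <- max.col(-d, ties.method = "first")
  data.frame(pair = pair, distance = d[cbind(seq_len(nrow(d)), pair)])
}

#' Project fascicles onto the unit-disc template
#'
#' Co-registers fascicles from nerve-local mm coordinates onto the common
#' circular template so that the radial distance to the nearest electrode is
#' maintained. Each fascicle keeps its polar angle about the nerve centre;
#' with electrodes modelled as points on the circular nerve boundary,
#' dividing the centroid radius by `nerve_radius` preserves the normalized
#' centroid-to-nearest-electrode distance exactly. Areas are rescaled by
#' `1/nerve_radius^2`; the template radius is clipped to \[0, 1\].
#'
#' @inheritParams nearest_electrode
#' @return Data frame with columns `id`, `angle` (degrees), `radius`
#'   (template units), `area` (template units), `organ_label`, `fibre_label`,
#'   `pair` (nearest electrode), `distance` (normalized).
#' @export
project_to_template <- function(fascicles, nerve, cuff) {
  ne <- nearest_electrode(fascicles, nerve, cuff)
  pol <- cart2pol(fascicles$cx, fascicles$cy)
  data.frame(
    id = fascicles$id,
    angle = pol$angle,
    radius = pmin(pol$radius / nerve$nerve_radius, 1),
    area = fascicles$area / nerve$nerve_radius^2,
    organ_label = fascicles$organ_label,
    fibre_label = fascicles$fibre_label,
    pair = ne$pair,
    distance = ne$distance / nerve$nerve_radius,
    stringsAsFactors = FALSE
  )
}
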