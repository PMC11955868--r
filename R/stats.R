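#' Centre of mass of a pixel map
#'
#' Value-weighted mean of the pixel-centre coordinates, reported in polar
#' template coordinates. For maps that are symmetric about the centre the
#' radius is ~0 and the angle is undefined; such results carry
#' `degenerate = TRUE` (angle reported as 0).
#'
#' @param map A non-empty [pixel_map()].
#' @return A list of class `com` with `angle` (degrees in \[0, 360)),
#'   `radius` (template units), `degenerate`, plus the map's `group`,
#'   `animal_id` and `technique`.
#' @export
center_of_mass <- function(map) {
  stopifnot(inherits(map, "pixel_map"))
  w <- map$values
  tot <- sum(w)
  if (tot <= 0) stop("centre of mass undefined: map has no positive values")
  g <- template_grid(map$W)
  xb <- sum(w * g$x) / tot
  yb <- sum(w * g$y) / tot
  pol <- cart2pol(xb, yb)
  degenerate <- pol$radius < 2 / map$W
  structure(
    list(angle = if (degenerate) 0 else pol$angle,
         radius = pol$radius, degenerate = degenerate,
         group = map$group, animal_id = map$animal_id,
         technique = map$technique),
    class = "com"
  )
}

#' @export
print.com <- function(x, ...) {
  cat(sprintf("<com> %s: angle %.1f deg, radius %.3f%s\n",
              x$group, x$angle, x$radius,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Collect centres of mass into a table
#'
#' @param coms List of `com` objects.
#' @return Data frame with columns `group`, `animal_id`, `technique`,
#'   `angle`, `radius`, `degenerate`.
#' @export
com_table <- function(coms) {
  do.call(rbind, lapply(coms, function(cm) {
    data.frame(group = cm$group, animal_id = cm$animal_id,
               technique = cm$technique, angle = cm$angle,
               radius = cm$radius, degenerate = cm$degenerate,
               stringsAsFactors = FALSE)
  }))
}

## Overlap matrices ---------------------------------------------------------

#' Area and overlap-fraction matrix of group maps
#'
#' Binarizes each group map at threshold `tau` and computes, as fractions of
#' the total nerve (disc) area: the per-group area fraction (diagonal) and
#' the pairwise shared-area fraction (off-diagonal). For binary per-animal
#' maps any `tau` in (0, 1] selects exactly the painted pixels; for atlases
#' `tau = 0.5` means "present in at least half the animals".
#'
#' @param maps Named list of [pixel_map()]s, one per group, sharing `W`.
#' @param tau Binarization threshold (pixels with value >= `tau` count).
#' @param technique Optional technique tag stored on the result.
#' @return An `overlap_matrix`: a symmetric numeric matrix with group
#'   dimnames and attributes `technique` and `tau`.
#' @export
overlap_matrix <- function(maps, tau = 0.5, technique = NULL) {
  stopifnot(length(maps) >= 2, all(vapply(maps, inherits, logical(1), "pixel_map")))
  if (is.null(names(maps))) names(maps) <- vapply(maps, `[[`, character(1), "group")
  W <- maps[[1]]$W
  if (!all(vapply(maps, function(m) m$W == W, logical(1)))) {
    stop("all maps must share the same raster width")
  }
  g <- template_grid(W)
  total <- sum(g$mask)
  bin <- lapply(maps, function(m) m$values >= tau & g$mask)
  k <- length(bin)
  out <- matrix(0, k, k, dimnames = list(names(maps), names(maps)))
  for (i in seq_len(k)) {
    for (j in i:k) {
      out[i, j] <- out[j, i] <- sum(bin[[i]] & bin[[j]]) / total
    }
  }
  if (is.null(technique)) technique <- maps[[1]]$technique
  structure(out, class = c("overlap_matrix", "matrix"),
            technique = technique, tau = tau)
}

#' Validate a printed/previously computed overlap matrix
#'
#' Wraps a plain numeric matrix (e.g. published area/overlap fractions) as an
#' `overlap_matrix` after checking symmetry, the \[0, 1\] range, and that no
#' shared fraction exceeds either group's area fraction (a small tolerance
#' accommodates values rounded for publication).
#'
#' @param m Square numeric matrix with group dimnames; diagonal = area
#'   fractions, off-diagonal = shared-area fractions.
#' @param technique Technique tag (`"microct"`, `"svns"`, ...).
#' @param tol Tolerance for the consistency checks (default 0.005, half a
#'   printed rounding unit).
#' @return An `overlap_matrix`.
#' @export
as_overlap_matrix <- function(m, technique = NA_character_, tol = 0.005) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), !is.null(rownames(m)))
  if (any(m < -tol | m > 1 + tol)) stop("entries must lie in [0, 1]")
  if (max(abs(m - t(m))) > tol) stop("overlap matrix must be symmetric")
  d <- diag(m)
  lim <- outer(d, d, pmin)
  if (any(m > lim + tol)) {
    stop("shared fractions cannot exceed either group's area fraction")
  }
  structure(m, class = c("overlap_matrix", "matrix"),
            technique = technique, tau = NA_real_)
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("<overlap_matrix> technique %s (fractions of total nerve area)\n",
              attr(x, "technique")))
  print(round(unclass(x), 2))
  invisible(x)
}

round_half_up <- function(x) floor(x + 0.5)

#' Relative overlap of one group's region with another
#'
#' The shared-area fraction of groups `a` and `b` expressed as a percentage
#' of group `a`'s own area fraction: `100 * offdiag(a, b) / diag(a)`,
#' rounded half-up to the nearest integer percent (the convention used for
#' reporting). Note the asymmetry: the overlap of `a` with `b` differs from
#' the overlap of `b` with `a` unless the areas are equal.
#'
#' @param m An `overlap_matrix`.
#' @param a,b Group names (rows/columns of `m`).
#' @return Integer percent.
#' @export
relative_overlap <- function(m, a, b) {
  stopifnot(inherits(m, "overlap_matrix"))
  if (!all(c(a, b) %in% rownames(m))) stop("unknown group name")
  if (m[a, a] <= 0) stop("relative overlap undefined: group '", a,
                         "' has zero area fraction")
  round_half_up(100 * m[a, b] / m[a, a])
}

#' Shared-area fraction between techniques for one group
#'
#' Binarizes the same group's atlas from each technique at `tau` and returns
#' the fraction of the total nerve area covered by both.
#'
#' @param map_a,map_b [pixel_map()]s on the same template (e.g. the microCT
#'   and sVNS atlases of one group).
#' @param tau Binarization threshold.
#' @return Fraction in \[0, 1\].
#' @export
cross_technique_overlap <- function(map_a, map_b, tau = 0.5) {
  stopifnot(inherits(map_a, "pixel_map"), inherits(map_b, "pixel_map"),
            map_a$W == map_b$W)
  g <- template_grid(map_a$W)
  sum(map_a$values >= tau & map_b$values >= tau & g$mask) / sum(g$mask)
}

## Angular group comparisons ------------------------------------------------

## Unwrap each group's angles to a linear scale: observations are expressed
## as (group circular mean, mapped to (-180, 180]) + signed deviation. This
## keeps within-group spread linear without splitting groups whose mean sits
## near the +/-180 wrap point.
unwrap_by_group <- function(angle, group) {
  out <- numeric(length(angle))
  for (g in unique(group)) {
    idx <- group == g
    mu <- circular_mean(angle[idx])
    mu_lin <- wrap180(mu)
    out[idx] <- mu_lin + wrap180(angle[idx] - mu)
  }
  out
}

#' Compare angular locations across functional groups
#'
#' One-way ANOVA on the rotation-aligned centre-of-mass angles of the groups,
#' followed by all pairwise comparisons with multiple-comparison adjustment
#' (Tukey HSD by default, Bonferroni optionally). Angles are unwrapped to a
#' linear scale about each group's circular mean before the ANOVA; a circular
#' alternative (Watson-Williams high-concentration F test) is available with
#' `circular = TRUE`.
#'
#' @param coms Data frame with columns `angle` (degrees) and `group` (see
#'   [com_table()]), or a list of `com` objects.
#' @param method Multiple-comparison adjustment: `"tukey"` or `"bonferroni"`.
#' @param circular Use the Watson-Williams test instead of linear ANOVA.
#' @return Data frame of class `angular_comparison` with columns `group1`,
#'   `group2`, `statistic` (pairwise F), `p_value` (raw), `p_adjusted`,
#'   `method`; the overall ANOVA F and p are attached as attributes
#'   `F_overall` and `p_overall`.
#' @export
angular_group_comparison <- function(coms, method = c("tukey", "bonferroni"),
                                     circular = FALSE) {
  method <- match.arg(method)
  if (!is.data.frame(coms)) coms <- com_table(coms)
  stopifnot(all(c("angle", "group") %in% names(coms)))
  cnt <- table(coms$group)
  drop <- names(cnt)[cnt < 2]
  if (length(drop)) {
    warning("excluding group(s) with fewer than 2 observations: ",
            paste(drop, collapse = ", "))
    coms <- coms[!(coms$group %in% drop), , drop = FALSE]
  }
  if (length(unique(coms$group)) < 2) {
    stop("need at least two groups with >= 2 observations each")
  }
  if (circular) {
    return(watson_williams_comparison(coms$angle, coms$group, method))
  }
  x <- unwrap_by_group(coms$angle, coms$group)
  grp <- factor(coms$group)
  fit <- stats::aov(x ~ grp)
  an <- summary(fit)[[1]]
  F_overall <- an[["F value"]][1]
  p_overall <- an[["Pr(>F)"]][1]
  mse <- an[["Mean Sq"]][2]
  dfres <- an[["Df"]][2]
  means <- tapply(x, grp, mean)
  ns <- tapply(x, grp, length)
  levs <- levels(grp)
  pairs <- utils::combn(levs, 2)
  tukey <- stats::TukeyHSD(fit)$grp
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    se <- sqrt(mse * (1 / ns[[g1]] + 1 / ns[[g2]]))
    tval <- (means[[g2]] - means[[g1]]) / se
    p_raw <- 2 * stats::pt(-abs(tval), dfres)
    key <- paste0(g2, "-", g1)
    key2 <- paste0(g1, "-", g2)
    p_adj <- if (method == "tukey") {
      if (key %in% rownames(tukey)) tukey[key, "p adj"] else tukey[key2, "p adj"]
    } else {
      min(1, p_raw * ncol(pairs))
    }
    data.frame(group1 = g1, group2 = g2, statistic = tval^2,
               p_value = p_raw, p_adjusted = p_adj,
               method = if (method == "tukey") "anova+tukey" else "anova+bonferroni",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "F_overall") <- F_overall
  attr(out, "p_overall") <- p_overall
  class(out) <- c("angular_comparison", class(out))
  out
}

## A(kappa) inverse by the usual piecewise approximation (Fisher 1993)
est_kappa <- function(rbar) {
  if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
}

watson_williams_F <- function(angle, group) {
  grp <- factor(group)
  N <- length(angle)
  k <- nlevels(grp)
  a <- deg2rad(angle)
  Ri <- tapply(seq_along(a), grp, function(idx) {
    sqrt(sum(cos(a[idx]))^2 + sum(sin(a[idx]))^2)
  })
  R <- sqrt(sum(cos(a))^2 + sum(sin(a))^2)
  sumRi <- sum(Ri)
  rbar <- sumRi / N
  kap <- est_kappa(rbar)
  K <- 1 + 3 / (8 * kap)
  Fstat <- K * ((N - k) * (sumRi - R)) / ((k - 1) * (N - sumRi))
  p <- stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  list(F = Fstat, p = p, df1 = k - 1, df2 = N - k)
}

watson_williams_comparison <- function(angle, group, method) {
  levs <- sort(unique(group))
  pairs <- utils::combn(levs, 2)
  overall <- watson_williams_F(angle, group)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    idx <- group %in% pairs[, k]
    ww <- watson_williams_F(angle[idx], group[idx])
    data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
               statistic = ww$F, p_value = ww$p, p_adjusted = NA_real_,
               method = "watson-williams", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  ## Tukey is undefined for the circular test; fall back to Bonferroni
  out$p_adjusted <- pmin(1, out$p_value * nrow(out))
  attr(out, "F_overall") <- overall$F
  attr(out, "p_overall") <- overall$p
  class(out) <- c("angular_comparison", class(out))
  out
}

#' Mean +/- SD angular separation between paired centres of mass
#'
#' For two sets of centres of mass paired by animal (e.g. cardiac afferent
#' vs. cardiac efferent), computes the per-animal angular separation and
#' returns its arithmetic mean and SD. Separations are measured on a linear
#' scale obtained by unwrapping the per-animal circular differences about
#' their cohort circular mean: folding each difference into \[0, 180\] would
#' bias the mean separation of diametrically opposed groups downward (folded
#' values cannot exceed 180 degrees), whereas the unwrapped scale estimates a
#' true 180-degree separation without bias and admits an SD larger than the
#' distance to the fold point.
#'
#' @param coms_a,coms_b Data frames with columns `animal_id` and `angle`
#'   (or lists of `com` objects); paired on `animal_id`.
#' @return List with `mean`, `sd`, `n` and the per-animal `separations`.
#' @export
angular_separation_summary <- function(coms_a, coms_b) {
  if (!is.data.frame(coms_a)) coms_a <- com_table(coms_a)
  if (!is.data.frame(coms_b)) coms_b <- com_table(coms_b)
  m <- merge(coms_a[, c("animal_id", "angle")],
             coms_b[, c("animal_id", "angle")],
             by = "animal_id", suffixes = c("_a", "_b"))
  if (nrow(m) == 0) stop("no common animal_id between the two sets")
  d <- (m$angle_a - m$angle_b) %% 360
  mu <- circular_mean(d)
  sep <- (mu %% 360) + wrap180(d - mu)
  ## report the separation magnitude: mirror when the mean difference points
  ## the "short way" past 180 (a - b vs b - a is arbitrary)
  if (mu > 180) sep <- 360 - sep
  list(mean = mean(sep), sd = stats::sd(sep), n = nrow(m),
       separations = stats::setNames(sep, m$animal_id))
}
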