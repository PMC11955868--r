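## Response extraction and sector back-projection ---------------------------

## centred moving average with shrinking windows at the edges (no NAs)
moving_average <- function(x, k) {
  n <- length(x)
  if (k <= 1 || n == 0) return(x)
  half <- floor(k / 2)
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Extract the percent response of one electrode pair from a trace
#'
#' For each stimulation epoch of the pair: the baseline is the mean signal
#' over the `baseline_window` seconds immediately preceding stimulation
#' onset; the response is the extremum (signed value of the largest absolute
#' deviation from baseline) of the moving-average-smoothed signal within
#' `[t_on, t_on + response_window]`; the percent change is
#' `100 * (response - baseline) / baseline`. Epochs are averaged. The
#' extremum (rather than the window mean) accommodates delayed afferent
#' reflex responses without modality-specific handling.
#'
#' @param trace A [physio_trace()].
#' @param pair 1-based electrode pair index.
#' @param baseline_window Baseline duration, s (typically the preceding off
#'   period).
#' @param response_window Search window after onset, s (extend beyond the on
#'   duration for delayed reflex responses).
#' @param smooth_s Moving-average window, s (default 2).
#' @return Percent change (signed), or `NA` if the pair has no epochs.
#' @export
extract_pair_response <- function(trace, pair, baseline_window,
                                  response_window, smooth_s = 2) {
  stopifnot(inherits(trace, "physio_trace"))
  sched <- trace$schedule[trace$schedule$pair == pair, , drop = FALSE]
  if (nrow(sched) == 0) return(NA_real_)
  fs <- 1 / stats::median(diff(trace$time))
  k <- max(1L, round(smooth_s * fs))
  if (k %% 2 == 0) k <- k + 1L
  sm <- moving_average(trace$value, k)
  pct <- vapply(seq_len(nrow(sched)), function(e) {
    t_on <- sched$t_on[e]
    bidx <- trace$time >= t_on - baseline_window & trace$time < t_on
    if (!any(bidx)) stop("no baseline samples before epoch at t=", t_on)
    baseline <- mean(trace$value[bidx])
    if (trace$modality %in% c("hr", "etco2") && baseline <= 0) {
      stop("invalid physiology: non-positive ", trace$modality, " baseline")
    }
    ridx <- trace$time >= t_on & trace$time <= t_on + response_window
    dev <- sm[ridx] - baseline
    resp <- dev[which.max(abs(dev))]
    100 * resp / baseline
  }, numeric(1))
  mean(pct)
}

#' Per-pair response set for one modality
#'
#' Applies [extract_pair_response()] to every cuff pair. Pairs without
#' stimulation epochs get `NA`.
#'
#' @inheritParams extract_pair_response
#' @param cuff An [electrode_cuff()].
#' @param animal_id,condition Metadata carried on the result; `condition` is
#'   one of `"pre_vagotomy"`, `"post_right_vagotomy"`,
#'   `"post_bilateral_vagotomy"`.
#' @return An object of class `pair_response_set`: list with `modality`,
#'   `values` (length `n_pairs`, percent change, `NA` where unstimulated),
#'   `animal_id`, `condition`.
#' @export
pair_responses <- function(trace, cuff, baseline_window, response_window,
                           smooth_s = 2, animal_id = NA_character_,
                           condition = NA_character_) {
  values <- vapply(seq_len(cuff$n_pairs), function(p) {
    extract_pair_response(trace, p, baseline_window, response_window, smooth_s)
  }, numeric(1))
  structure(
    list(modality = trace$modality, values = values,
         animal_id = animal_id, condition = condition),
    class = "pair_response_set"
  )
}

#' @export
print.pair_response_set <- function(x, ...) {
  cat(sprintf("<pair_response_set> %s (%s): %d/%d pairs measured\n",
              x$modality, x$condition, sum(!is.na(x$values)), length(x$values)))
  print(round(x$values, 2))
  invisible(x)
}

#' Count the most effective electrode pairs
#'
#' Pairs whose absolute response reaches at least `fraction` of the maximal
#' absolute response across pairs (the "at least 75% of maximal response"
#' definition).
#'
#' @param responses A `pair_response_set` or numeric vector of percent
#'   changes (`NA` = unstimulated).
#' @param fraction Threshold fraction of the maximal absolute response.
#' @return Integer count.
#' @export
effective_pair_count <- function(responses, fraction = 0.75) {
  v <- if (inherits(responses, "pair_response_set")) responses$values else responses
  v <- v[!is.na(v)]
  if (!length(v)) stop("all responses missing")
  sum(abs(v) >= fraction * max(abs(v)))
}

#' Back-project per-pair responses onto the circular template
#'
#' Subdivides the disc into `n_pairs` angular sectors (each pixel belongs to
#' the pair whose angle is nearest; ties go to the lower index) and paints
#' every pixel of sector k with the pair's absolute response, normalized by
#' the maximal absolute response so values lie in \[0, 1\]. Missing pairs map
#' to 0. Polarity is retained in the `pair_response_set`, not in the map.
#'
#' @param responses A `pair_response_set` or numeric vector (length
#'   `n_pairs`).
#' @param cuff An [electrode_cuff()].
#' @param W Raster width (default 256).
#' @param group Functional group tag for the resulting map.
#' @return A [pixel_map()] in the raw frame.
#' @export
backproject <- function(responses, cuff, W = 256, group = NA_character_) {
  if (inherits(responses, "pair_response_set")) {
    v <- responses$values
    animal_id <- responses$animal_id
  } else {
    v <- responses
    animal_id <- NA_character_
  }
  stopifnot(length(v) == cuff$n_pairs)
  v[is.na(v)] <- 0
  m <- max(abs(v))
  norm <- if (m > 0) abs(v) / m else rep(0, length(v))
  g <- template_grid(W)
  theta <- cart2pol(g$x, g$y)$angle
  d <- vapply(cuff$pair_angles, function(a) angular_distance(theta, a),
              numeric(length(theta)))
  sector <- max.col(-d, ties.method = "first")
  vals <- matrix(norm[sector], W, W)
  vals[!g$mask] <- 0
  pixel_map(vals, group = group, frame = "raw", animal_id = animal_id,
            technique = "svns")
}
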