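## Synthetic cohorts --------------------------------------------------------
## The generator emulates the composition and organization reported for the
## porcine mid-cervical vagus: ~29 fascicles per nerve across five organ
## classes, purely cardiac fascicles exclusively efferent, cardiopulmonary
## fascicles afferent, and a bimodal angular organization in which
## efferent-type fascicles cluster around one axis and afferent-type
## fascicles around the opposite one.

## deterministic per-animal stream derived from (seed, k); kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((abs(as.double(seed)) * 2654435.0 + as.double(k) * 97561.0) %%
               2147483647)
}

#' Configuration for the synthetic nerve generator
#'
#' Defaults reproduce the reported composition of the porcine mid-cervical
#' vagus: mean fascicle counts per organ class 1.2 cardiac, 10.2 recurrent
#' laryngeal, 10.4 pulmonary, 1.4 cardiopulmonary and 6 laryngopulmonary
#' (with their reported SDs), a nerve cross-sectional area of 2.68 mm^2, and
#' afferent and efferent fascicle populations concentrated on opposite sides
#' of the nerve (separation 180 degrees).
#'
#' @param n_animals Number of animals in the cohort.
#' @param mean_counts Named mean fascicle counts per organ class.
#' @param count_sd Named SDs of the counts.
#' @param nerve_area Nerve cross-sectional area in mm^2; the boundary radius
#'   is `sqrt(nerve_area / pi)`.
#' @param efferent_axis Ground-truth cardiac-efferent direction in degrees.
#'   `NULL` (default) draws one uniformly per animal; a scalar fixes it for
#'   all animals; a vector gives one per animal.
#' @param afferent_efferent_separation Angular separation between the
#'   afferent and efferent population axes, degrees in \[0, 360).
#' @param angular_spread SD of the wrapped-normal angular placement about
#'   each population axis, degrees.
#' @param fascicle_radius_range Range (mm) of fascicle equivalent radii.
#' @param fibre_mix Named list of per-organ-class fibre-type proportions
#'   (afferent, efferent, mixed). Defaults follow the reported proportions;
#'   purely cardiac fascicles are always efferent and cardiopulmonary
#'   fascicles always afferent.
#' @param seed Integer seed; each animal uses a stream derived from
#'   `(seed, animal_index)`.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_animals = 5,
    mean_counts = c(cardiac = 1.2, laryngeal = 10.2, pulmonary = 10.4,
                    cardiopulmonary = 1.4, laryngopulmonary = 6.0),
    count_sd = c(cardiac = 0.5, laryngeal = 1.8, pulmonary = 1.9,
                 cardiopulmonary = 0.6, laryngopulmonary = 2.0),
    nerve_area = 2.68,
    efferent_axis = NULL,
    afferent_efferent_separation = 180,
    angular_spread = 25,
    fascicle_radius_range = c(0.04, 0.09),
    fibre_mix = list(
      laryngeal = c(afferent = 0, efferent = 0.824, mixed = 0.176),
      pulmonary = c(afferent = 0.885, efferent = 0, mixed = 0.115),
      laryngopulmonary = c(afferent = 0.567, efferent = 0.133, mixed = 0.300)
    ),
    seed = 1L) {
  stopifnot(n_animals >= 1, all(mean_counts >= 0),
            afferent_efferent_separation >= 0,
            afferent_efferent_separation < 360,
            nerve_area > 0, angular_spread > 0,
            length(fascicle_radius_range) == 2,
            all(fascicle_radius_range > 0),
            diff(fascicle_radius_range) >= 0)
  cls <- c("cardiac", "laryngeal", "pulmonary", "cardiopulmonary",
           "laryngopulmonary")
  if (!all(cls %in% names(mean_counts)) || !all(cls %in% names(count_sd))) {
    stop("mean_counts and count_sd must name all five organ classes")
  }
  structure(
    list(n_animals = as.integer(n_animals),
         mean_counts = mean_counts[cls], count_sd = count_sd[cls],
         nerve_area = nerve_area,
         nerve_radius = sqrt(nerve_area / pi),
         efferent_axis = efferent_axis,
         afferent_efferent_separation = afferent_efferent_separation,
         angular_spread = angular_spread,
         fascicle_radius_range = fascicle_radius_range,
         fibre_mix = fibre_mix,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

draw_fibre_label <- function(organ, fibre_mix) {
  switch(organ,
    cardiac = "efferent",          # purely cardiac fascicles: efferent only
    cardiopulmonary = "afferent",  # cardiac afferent group by definition
    {
      p <- fibre_mix[[organ]]
      sample(names(p), 1, prob = p)
    }
  )
}

#' Generate one synthetic nerve cross-section
#'
#' Draws fascicle counts per organ class (rounded normal; floor 0, with at
#' least one cardiac fascicle), assigns fibre-type labels (purely cardiac
#' fascicles efferent, cardiopulmonary afferent, others by the configured
#' proportions), and places fascicles as non-overlapping discs inside the
#' nerve boundary by rejection sampling. Efferent-type fascicles are placed
#' with angular mean at the animal's efferent axis, afferent-type fascicles
#' at the axis plus the configured separation, mixed fascicles on either side
#' with equal probability; all with the configured angular spread.
#'
#' Fully deterministic given `(config$seed, animal_index)`.
#'
#' @param config A [synthetic_config()].
#' @param animal_index Animal index (1-based) within the cohort.
#' @param technique Technique tag for the cross-section.
#' @return A [nerve_cross_section()] with attribute `ground_truth`: a list
#'   with the animal's `efferent_axis` and `afferent_axis` (degrees).
#' @export
generate_cross_section <- function(config, animal_index,
                                   technique = c("microct", "svns")) {
  stopifnot(inherits(config, "synthetic_config"))
  technique <- match.arg(technique)
  set.seed(derive_seed(config$seed, animal_index))
  R <- config$nerve_radius

  axis <- if (is.null(config$efferent_axis)) {
    stats::runif(1, 0, 360)
  } else if (length(config$efferent_axis) >= animal_index) {
    config$efferent_axis[animal_index]
  } else {
    config$efferent_axis[1]
  }
  aff_axis <- (axis + config$afferent_efferent_separation) %% 360

  counts <- mapply(function(m, s) max(0L, as.integer(round(stats::rnorm(1, m, s)))),
                   config$mean_counts, config$count_sd)
  counts["cardiac"] <- max(1L, counts["cardiac"])

  organ <- rep(names(counts), counts)
  fibre <- vapply(organ, draw_fibre_label, character(1),
                  fibre_mix = config$fibre_mix)
  n <- length(organ)
  rf <- stats::runif(n, config$fascicle_radius_range[1],
                     config$fascicle_radius_range[2])
  ## place large fascicles first: packing succeeds more often
  ord <- order(rf, decreasing = TRUE)
  organ <- organ[ord]; fibre <- fibre[ord]; rf <- rf[ord]

  lobe <- ifelse(fibre == "efferent", axis,
                 ifelse(fibre == "afferent", aff_axis,
                        ifelse(stats::runif(n) < 0.5, axis, aff_axis)))

  margin <- 0.005
  cx <- numeric(n); cy <- numeric(n)
  for (k in seq_len(n)) {
    placed <- FALSE
    cmax <- R - rf[k] - margin
    for (try in seq_len(4000L)) {
      ang <- (stats::rnorm(1, lobe[k], config$angular_spread)) %% 360
      cc <- sqrt(stats::runif(1)) * cmax
      pt <- pol2cart(ang, cc)
      if (k > 1) {
        dd <- sqrt((cx[seq_len(k - 1)] - pt[1, "x"])^2 +
                     (cy[seq_len(k - 1)] - pt[1, "y"])^2)
        if (any(dd < rf[seq_len(k - 1)] + rf[k] + margin)) next
      }
      cx[k] <- pt[1, "x"]; cy[k] <- pt[1, "y"]
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("fascicle placement failed after bounded retries; ",
           "reduce fascicle counts or enlarge the nerve")
    }
  }

  fas <- data.frame(
    id = sprintf("A%d_f%02d", animal_index, seq_len(n)),
    cx = cx, cy = cy, area = pi * rf^2,
    organ_label = organ, fibre_label = fibre,
    stringsAsFactors = FALSE
  )
  nerve <- nerve_cross_section(sprintf("animal_%02d", animal_index), R, fas,
                               technique = technique)
  attr(nerve, "ground_truth") <- list(efferent_axis = axis,
                                      afferent_axis = aff_axis)
  nerve
}

## Stimulation protocols -----------------------------------------------------

#' Stimulation protocol for one target function
#'
#' Defaults follow the reported starting parameters per target: pulmonary
#' (all pairs, 0.8 mA, 50 us, 20 Hz, 15 s on/off), laryngeal (all pairs,
#' 0.2 mA, 50 us, 20 Hz, 5 s on/off), cardiac efferent pre-vagotomy (all
#' pairs, 1 mA, 1 ms, 10 Hz, 15 s on/off) and cardiac afferent post-vagotomy
#' (every 2nd pair, 5 mA, 2 ms, 10 Hz, 15 s on / 60 s off).
#'
#' @param target One of `"laryngeal"`, `"pulmonary"`, `"cardiac_efferent"`,
#'   `"cardiac_afferent"`.
#' @param amplitude Pulse amplitude, mA.
#' @param pulse_width Pulse width, ms.
#' @param frequency Pulse repetition frequency, Hz.
#' @param on_duration,off_duration Stimulation epoch on/off durations, s.
#' @param pairs_stimulated 1-based electrode pair indices, in stimulation
#'   order.
#' @param n_pairs Number of cuff pairs (used for the defaults).
#' @return An object of class `stimulation_protocol`.
#' @export
stimulation_protocol <- function(target = c("laryngeal", "pulmonary",
                                            "cardiac_efferent",
                                            "cardiac_afferent"),
                                 amplitude = NULL, pulse_width = NULL,
                                 frequency = NULL, on_duration = NULL,
                                 off_duration = NULL, pairs_stimulated = NULL,
                                 n_pairs = 14) {
  target <- match.arg(target)
  def <- switch(target,
    pulmonary        = list(1:n_pairs, 0.8, 0.05, 20, 15, 15),
    laryngeal        = list(1:n_pairs, 0.2, 0.05, 20, 5, 5),
    cardiac_efferent = list(1:n_pairs, 1.0, 1.0, 10, 15, 15),
    cardiac_afferent = list(seq(1, n_pairs, by = 2), 5.0, 2.0, 10, 15, 60)
  )
  p <- list(
    target = target,
    pairs_stimulated = if (is.null(pairs_stimulated)) def[[1]] else pairs_stimulated,
    amplitude = if (is.null(amplitude)) def[[2]] else amplitude,
    pulse_width = if (is.null(pulse_width)) def[[3]] else pulse_width,
    frequency = if (is.null(frequency)) def[[4]] else frequency,
    on_duration = if (is.null(on_duration)) def[[5]] else on_duration,
    off_duration = if (is.null(off_duration)) def[[6]] else off_duration
  )
  stopifnot(p$amplitude > 0, p$pulse_width > 0, p$frequency > 0,
            p$on_duration > 0, p$off_duration > 0,
            all(p$pairs_stimulated >= 1))
  class(p) <- "stimulation_protocol"
  p
}

#' Deterministic-threshold activation model
#'
#' The minimal model that reproduces amplitude-dependent selectivity: a
#' fascicle of the responsive group is activated iff the pulse amplitude
#' reaches that group's threshold, and its contribution to the response of a
#' stimulated pair is its normalized area weighted by a Gaussian in angular
#' separation, `exp(-d^2 / (2 * angular_sigma^2))`. Thresholds keep the
#' reported ~100x ratio between cardiac and laryngeal fibres, with each
#' protocol's starting amplitude just above its target's threshold.
#'
#' @param thresholds Named activation thresholds per functional group, mA.
#' @param angular_sigma Spatial selectivity of a pair, degrees.
#' @param gain Named gain per modality: percent change of the baseline per
#'   unit of activated (weighted, normalized) fascicle area.
#' @param response_delay Named response latency, s: 0 for the direct efferent
#'   pathway, tens of seconds for the afferent reflex (brainstem loop).
#' @param afferent_polarity Reflex HR polarity of the animal
#'   (`"tachycardia"` or `"bradycardia"`); fixed per animal.
#' @param vagotomy_state `"intact"`, `"right_distal"` (efferent HR pathway
#'   removed, reflex preserved) or `"right_and_left"` (reflex bradycardia
#'   also removed; reflex tachycardia via the sympathetic chain persists).
#' @param noise_sd Named additive Gaussian noise SD per modality (signal
#'   units).
#' @param baseline Named baseline level per modality: HR b.p.m., ETCO2 mmHg,
#'   EMG RMS a.u.
#' @param fs Trace sampling rate, samples/s.
#' @return An object of class `activation_model`.
#' @export
activation_model <- function(
    thresholds = c(laryngeal = 0.008, pulmonary = 0.5,
                   cardiac_efferent = 0.8, cardiac_afferent = 4.0),
    angular_sigma = 20,
    gain = c(hr = 300, etco2 = 300, emg_rms = 400),
    response_delay = c(efferent = 0, afferent = 10),
    afferent_polarity = c("tachycardia", "bradycardia"),
    vagotomy_state = c("intact", "right_distal", "right_and_left"),
    noise_sd = c(hr = 0.5, etco2 = 0.3, emg_rms = 0.02),
    baseline = c(hr = 80, etco2 = 40, emg_rms = 1),
    fs = 10) {
  afferent_polarity <- match.arg(afferent_polarity)
  vagotomy_state <- match.arg(vagotomy_state)
  stopifnot(all(thresholds > 0), angular_sigma > 0, fs > 0,
            all(baseline > 0))
  structure(
    list(thresholds = thresholds, angular_sigma = angular_sigma, gain = gain,
         response_delay = response_delay,
         afferent_polarity = afferent_polarity,
         vagotomy_state = vagotomy_state, noise_sd = noise_sd,
         baseline = baseline, fs = fs),
    class = "activation_model"
  )
}

target_modality <- function(target) {
  switch(target,
    laryngeal = "emg_rms",
    pulmonary = "etco2",
    cardiac_efferent = ,
    cardiac_afferent = "hr",
    stop("unknown target")
  )
}

## Per-pair percent-change effect size for one group/pathway.
group_pair_effects <- function(nerve, cuff, group, amplitude, model, sign) {
  proj <- project_to_template(nerve$fascicles, nerve, cuff)
  sel <- vapply(proj$organ_label, function(o) group %in% group_of(o), logical(1))
  out <- numeric(cuff$n_pairs)
  if (!any(sel) || amplitude < model$thresholds[[group]]) return(out)
  ang <- proj$angle[sel]
  ar <- proj$area[sel]
  modality <- switch(group, laryngeal = "emg_rms", pulmonary = "etco2", "hr")
  for (p in seq_len(cuff$n_pairs)) {
    d <- angular_distance(ang, cuff$pair_angles[p])
    w <- exp(-d^2 / (2 * model$angular_sigma^2))
    out[p] <- sign * model$gain[[modality]] * sum(w * ar)
  }
  out
}

## Pathway-gated response components for a protocol: list of
## list(pct = per-pair percent change, delay = seconds).
response_components <- function(nerve, cuff, protocol, model) {
  comps <- list()
  tg <- protocol$target
  if (tg == "laryngeal") {
    comps[[1]] <- list(pct = group_pair_effects(nerve, cuff, "laryngeal",
                                                protocol$amplitude, model, +1),
                       delay = 0)
  } else if (tg == "pulmonary") {
    comps[[1]] <- list(pct = group_pair_effects(nerve, cuff, "pulmonary",
                                                protocol$amplitude, model, -1),
                       delay = 0)
  } else {
    ## HR target: direct efferent pathway requires an intact right vagus
    if (model$vagotomy_state == "intact") {
      comps[[length(comps) + 1]] <- list(
        pct = group_pair_effects(nerve, cuff, "cardiac_efferent",
                                 protocol$amplitude, model, -1),
        delay = model$response_delay[["efferent"]])
    }
    ## afferent reflex: abolished only when bilateral vagotomy removes the
    ## parasympathetic (bradycardia) loop; reflex tachycardia persists
    reflex_alive <- !(model$vagotomy_state == "right_and_left" &&
                        model$afferent_polarity == "bradycardia")
    if (reflex_alive) {
      sgn <- if (model$afferent_polarity == "tachycardia") +1 else -1
      comps[[length(comps) + 1]] <- list(
        pct = group_pair_effects(nerve, cuff, "cardiac_afferent",
                                 protocol$amplitude, model, sgn),
        delay = model$response_delay[["afferent"]])
    }
    if (!length(comps)) comps[[1]] <- list(pct = numeric(cuff$n_pairs), delay = 0)
  }
  comps
}

#' Construct a physiological trace
#'
#' @param modality `"hr"`, `"etco2"` or `"emg_rms"`.
#' @param time Sample times, s (strictly increasing, uniform).
#' @param value Signal values.
#' @param schedule Data frame with columns `pair`, `t_on`, `t_off` (s).
#' @return An object of class `physio_trace`.
#' @export
physio_trace <- function(modality = c("hr", "etco2", "emg_rms"), time, value,
                         schedule) {
  modality <- match.arg(modality)
  stopifnot(length(time) == length(value), all(diff(time) > 0),
            all(c("pair", "t_on", "t_off") %in% names(schedule)))
  if (any(schedule$t_on < time[1] | schedule$t_off > time[length(time)] + 1e-9)) {
    stop("schedule windows must lie within the trace extent")
  }
  structure(list(modality = modality, time = time, value = value,
                 schedule = schedule),
            class = "physio_trace")
}

#' @export
print.physio_trace <- function(x, ...) {
  cat(sprintf("<physio_trace> %s: %d samples over %.1f s, %d stimulation epochs\n",
              x$modality, length(x$time), diff(range(x$time)), nrow(x$schedule)))
  invisible(x)
}

#' Synthesize a stimulation-annotated trace from per-pair effect sizes
#'
#' Builds a baseline trace with one stimulation epoch per entry of `pairs`
#' (sequential, preceded by one off period) and injects each response
#' component as a percent change of the baseline over
#' `[t_on + delay, t_off + delay)`, plus optional additive Gaussian noise.
#' Used by [simulate_session()] and directly in round-trip checks.
#'
#' @param components List of components, each `list(pct = <per-pair percent
#'   change, indexed by pair>, delay = <s>)`. A single numeric vector is
#'   promoted to one zero-delay component.
#' @param pairs 1-based pair indices in stimulation order.
#' @param on_s,off_s Epoch on/off durations, s.
#' @param modality Trace modality.
#' @param baseline Baseline signal level.
#' @param fs Sampling rate, samples/s.
#' @param noise_sd Additive Gaussian noise SD (0 = noise-free).
#' @param seed Optional seed for the noise.
#' @return A [physio_trace()].
#' @export
synthesize_trace <- function(components, pairs, on_s, off_s,
                             modality = "hr", baseline = 80, fs = 10,
                             noise_sd = 0, seed = NULL) {
  if (is.numeric(components)) components <- list(list(pct = components, delay = 0))
  n_epochs <- length(pairs)
  total <- off_s + n_epochs * (on_s + off_s)
  n <- ceiling(total * fs)
  time <- (seq_len(n) - 1) / fs
  value <- rep(baseline, n)
  sched <- data.frame(pair = integer(n_epochs), t_on = numeric(n_epochs),
                      t_off = numeric(n_epochs))
  t0 <- off_s
  for (e in seq_len(n_epochs)) {
    p <- pairs[e]
    t_on <- t0; t_off <- t0 + on_s
    for (comp in components) {
      pct <- comp$pct[p]
      if (!is.na(pct) && pct != 0) {
        idx <- time >= t_on + comp$delay & time < t_off + comp$delay
        value[idx] <- value[idx] + baseline * pct / 100
      }
    }
    sched$pair[e] <- p; sched$t_on[e] <- t_on; sched$t_off[e] <- t_off
    t0 <- t_off + off_s
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    value <- value + stats::rnorm(n, 0, noise_sd)
  }
  physio_trace(modality, time, value, sched)
}

#' Simulate a spatially selective stimulation session
#'
#' Applies the protocol's stimulation sequentially to its electrode pairs on
#' the synthetic nerve and produces the physiological trace of the target's
#' modality under the activation model (threshold activation, Gaussian
#' angular weighting, pathway gating by vagotomy state, response latency per
#' pathway, additive noise). Deterministic given `seed`.
#'
#' @param nerve A [nerve_cross_section()].
#' @param cuff An [electrode_cuff()].
#' @param protocol A [stimulation_protocol()].
#' @param model An [activation_model()].
#' @param seed Seed for the trace noise.
#' @return A list with one [physio_trace()], carrying attribute
#'   `ground_truth`: the per-pair injected percent changes summed over
#'   pathway components (named `total`, plus one entry per component).
#' @export
simulate_session <- function(nerve, cuff, protocol, model, seed = 1L) {
  stopifnot(inherits(protocol, "stimulation_protocol"),
            inherits(model, "activation_model"))
  if (any(protocol$pairs_stimulated > cuff$n_pairs)) {
    stop("protocol stimulates pairs beyond the cuff's n_pairs")
  }
  modality <- target_modality(protocol$target)
  comps <- response_components(nerve, cuff, protocol, model)
  trace <- synthesize_trace(
    comps, pairs = protocol$pairs_stimulated,
    on_s = protocol$on_duration, off_s = protocol$off_duration,
    modality = modality, baseline = model$baseline[[modality]],
    fs = model$fs, noise_sd = model$noise_sd[[modality]], seed = seed
  )
  gt <- list(total = Reduce(`+`, lapply(comps, `[[`, "pct")),
             components = comps)
  attr(trace, "ground_truth") <- gt
  list(trace)
}
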