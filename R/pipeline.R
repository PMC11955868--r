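## End-to-end pipeline --------------------------------------------------------

map_condition <- function(vagotomy_state) {
  switch(vagotomy_state,
    intact = "pre_vagotomy",
    right_distal = "post_right_vagotomy",
    right_and_left = "post_bilateral_vagotomy"
  )
}

## Rotation-aligned binary group maps + CoMs for one traced nerve.
map_nerve <- function(nerve, cuff, W = 256) {
  raw <- lapply(functional_groups(), function(g) rasterize_group(nerve, cuff, g, W))
  names(raw) <- functional_groups()
  if (sum(raw$cardiac_efferent$values) <= 0) {
    stop("nerve ", nerve$animal_id, " has an empty cardiac-efferent map; cannot align")
  }
  align <- alignment_angle(raw$cardiac_efferent)
  rot <- lapply(raw, rotate_map, angle = -align)
  coms <- lapply(rot[vapply(rot, function(m) sum(m$values) > 0, logical(1))],
                 center_of_mass)
  list(raw = raw, rotated = rot, alignment = align, coms = unname(coms))
}

## Rotation-aligned response maps + CoMs for one animal's sVNS sessions.
## `session` is a list with animal_id and, per target, a list(trace, protocol,
## condition).
map_session <- function(session, cuff, W = 256, smooth_s = 2) {
  prs <- list(); raw <- list()
  for (tg in names(session$targets)) {
    s <- session$targets[[tg]]
    ## baseline: second half of the preceding off period, so a delayed reflex
    ## tail from the previous epoch cannot contaminate it
    bw <- s$protocol$off_duration / 2
    rw <- s$protocol$on_duration + s$protocol$off_duration / 2
    prs[[tg]] <- pair_responses(s$trace, cuff, baseline_window = bw,
                                response_window = rw, smooth_s = smooth_s,
                                animal_id = session$animal_id,
                                condition = s$condition)
    raw[[tg]] <- backproject(prs[[tg]], cuff, W = W, group = tg)
  }
  if (sum(raw$cardiac_efferent$values) <= 0) {
    stop("animal ", session$animal_id,
         ": pre-vagotomy cardiac response map is empty; cannot align")
  }
  align <- alignment_angle(raw$cardiac_efferent)
  rot <- lapply(raw, rotate_map, angle = -align)
  coms <- lapply(rot[vapply(rot, function(m) sum(m$values) > 0, logical(1))],
                 center_of_mass)
  list(responses = prs, raw = raw, rotated = rot, alignment = align,
       coms = unname(coms))
}

## Simulate the four per-animal stimulation sessions of the study design.
simulate_animal_sessions <- function(nerve, cuff, base_model, polarity, seed) {
  mk <- function(target, state, k) {
    protocol <- stimulation_protocol(target, n_pairs = cuff$n_pairs)
    model <- base_model
    model$vagotomy_state <- state
    model$afferent_polarity <- polarity
    trace <- simulate_session(nerve, cuff, protocol, model,
                              seed = derive_seed(seed, k))[[1]]
    list(trace = trace, protocol = protocol, condition = map_condition(state))
  }
  list(
    animal_id = nerve$animal_id,
    polarity = polarity,
    targets = list(
      laryngeal = mk("laryngeal", "intact", 1L),
      pulmonary = mk("pulmonary", "intact", 2L),
      cardiac_efferent = mk("cardiac_efferent", "intact", 3L),
      cardiac_afferent = mk("cardiac_afferent", "right_distal", 4L)
    )
  )
}

#' Build the cross-animal spatial atlas of vagal functional groups
#'
#' The package's end-to-end analysis. The microCT arm rasterizes each traced
#' nerve's fascicles into binary group maps on the circular template, rotates
#' each animal so its cardiac-efferent centre of mass sits at 0 degrees, and
#' averages across animals into four atlases. The sVNS arm extracts per-pair
#' percent responses from stimulation sessions, back-projects them onto 14
#' angular sectors, aligns on the pre-vagotomy cardiac response map, and
#' averages likewise. Both arms feed centre-of-mass angular comparisons
#' (ANOVA + multiple-comparison adjustment), the cardiac afferent-efferent
#' angular separation summary, and area/overlap matrices.
#'
#' With `nerves`/`sessions` omitted, a synthetic cohort is generated: the
#' sVNS arm simulates `n_svns` animals (laryngeal, pulmonary, pre-vagotomy
#' cardiac and post-right-vagotomy cardiac sessions each; reflex polarity
#' drawn 6:4 tachycardia:bradycardia), and the microCT arm traces the last
#' `n_microct` animals of the same cohort, mirroring the study design in
#' which the imaged nerves came from the stimulated animals.
#'
#' @param n_microct Number of traced nerves (synthetic mode).
#' @param n_svns Number of stimulation-session animals (synthetic mode).
#' @param seed Integer seed governing all randomness.
#' @param config A [synthetic_config()]; default uses the package defaults
#'   with `seed`.
#' @param model An [activation_model()] (vagotomy state and polarity are set
#'   per session).
#' @param cuff An [electrode_cuff()].
#' @param W Raster width.
#' @param tau Atlas binarization threshold for overlap matrices.
#' @param adjust Multiple-comparison method (`"tukey"` or `"bonferroni"`).
#' @param circular Use the Watson-Williams test instead of linear ANOVA.
#' @param nerves Optional list of [nerve_cross_section()]s (data mode,
#'   microCT arm).
#' @param sessions Optional list of per-animal session lists (data mode, sVNS
#'   arm); each has `animal_id` and `targets`, a named list (per functional
#'   group) of `list(trace, protocol, condition)`.
#' @return An object of class `vagus_atlas`; see [print.vagus_atlas()].
#' @export
vagus_atlas <- function(n_microct = 5, n_svns = 10, seed = 1L,
                        config = NULL, model = activation_model(),
                        cuff = electrode_cuff(), W = 256, tau = 0.5,
                        adjust = c("tukey", "bonferroni"), circular = FALSE,
                        nerves = NULL, sessions = NULL) {
  adjust <- match.arg(adjust)
  if (is.null(config)) config <- synthetic_config(n_animals = max(n_svns, n_microct),
                                                  seed = seed)

  ## --- sVNS arm ------------------------------------------------------------
  if (is.null(sessions)) {
    sessions <- lapply(seq_len(n_svns), function(a) {
      nerve <- generate_cross_section(config, a, technique = "svns")
      set.seed(derive_seed(config$seed, 100000L + a))
      polarity <- sample(c("tachycardia", "bradycardia"), 1, prob = c(0.6, 0.4))
      simulate_animal_sessions(nerve, cuff, model, polarity,
                               seed = derive_seed(config$seed, 200000L + a))
    })
  }
  svns_mapped <- lapply(sessions, map_session, cuff = cuff, W = W)
  svns_coms <- com_table(unlist(lapply(svns_mapped, `[[`, "coms"),
                                recursive = FALSE))
  svns_atlases <- lapply(functional_groups(), function(g) {
    build_atlas(lapply(svns_mapped, function(m) m$rotated[[g]]),
                renormalize = TRUE)
  })
  names(svns_atlases) <- functional_groups()
  svns_overlap <- overlap_matrix(svns_atlases, tau = tau, technique = "svns")
  eff_pairs <- vapply(svns_mapped, function(m) {
    effective_pair_count(m$responses$cardiac_efferent)
  }, numeric(1))

  ## --- microCT arm -----------------------------------------------------------
  if (is.null(nerves)) {
    idx <- seq.int(max(1L, n_svns - n_microct + 1L), length.out = n_microct)
    nerves <- lapply(idx, function(a) {
      generate_cross_section(config, a, technique = "microct")
    })
  }
  ct_mapped <- lapply(nerves, map_nerve, cuff = cuff, W = W)
  ct_coms <- com_table(unlist(lapply(ct_mapped, `[[`, "coms"),
                              recursive = FALSE))
  ct_atlases <- lapply(functional_groups(), function(g) {
    build_atlas(lapply(ct_mapped, function(m) m$rotated[[g]]))
  })
  names(ct_atlases) <- functional_groups()
  ct_overlap <- overlap_matrix(ct_atlases, tau = tau, technique = "microct")
  ct_overlap_animals <- lapply(ct_mapped, function(m) {
    overlap_matrix(m$rotated, tau = 0.5, technique = "microct")
  })
  ## per-animal cardiac afferent-with-efferent relative overlap (animals with
  ## a cardiac-afferent fascicle present)
  rel_ca_ce <- vapply(
    Filter(function(m) m["cardiac_afferent", "cardiac_afferent"] > 0,
           ct_overlap_animals),
    relative_overlap, numeric(1),
    a = "cardiac_afferent", b = "cardiac_efferent"
  )

  ## --- statistics ------------------------------------------------------------
  comparisons <- list(
    microct = angular_group_comparison(ct_coms, method = adjust,
                                       circular = circular),
    svns = angular_group_comparison(svns_coms, method = adjust,
                                    circular = circular)
  )
  sep_of <- function(coms) {
    ca <- coms[coms$group == "cardiac_afferent", , drop = FALSE]
    ce <- coms[coms$group == "cardiac_efferent", , drop = FALSE]
    angular_separation_summary(ca, ce)
  }
  separation <- list(microct = sep_of(ct_coms), svns = sep_of(svns_coms))
  cross_tech <- vapply(functional_groups(), function(g) {
    cross_technique_overlap(ct_atlases[[g]], svns_atlases[[g]], tau = tau)
  }, numeric(1))

  structure(
    list(
      microct = list(nerves = nerves, mapped = ct_mapped, atlases = ct_atlases,
                     coms = ct_coms, overlap = ct_overlap,
                     overlap_per_animal = ct_overlap_animals,
                     rel_overlap_ca_ce = rel_ca_ce),
      svns = list(sessions = sessions, mapped = svns_mapped,
                  atlases = svns_atlases, coms = svns_coms,
                  overlap = svns_overlap, effective_pairs = eff_pairs),
      comparisons = comparisons,
      separation = separation,
      cross_technique = cross_tech,
      cuff = cuff, W = W, tau = tau, seed = seed, config = config
    ),
    class = "vagus_atlas"
  )
}

adj_p <- function(comp, g1, g2) {
  hit <- (comp$group1 == g1 & comp$group2 == g2) |
    (comp$group1 == g2 & comp$group2 == g1)
  if (!any(hit)) return(NA_real_)
  comp$p_adjusted[hit][1]
}

#' @export
print.vagus_atlas <- function(x, ...) {
  cat("<vagus_atlas>\n")
  cat(sprintf("  microCT arm: %d nerves;  sVNS arm: %d animals;  template %dx%d\n",
              length(x$microct$nerves), length(x$svns$sessions), x$W, x$W))
  cat(sprintf("  cardiac afferent-efferent CoM separation: %.0f +/- %.0f deg (microCT), %.0f +/- %.0f deg (sVNS)\n",
              x$separation$microct$mean, x$separation$microct$sd,
              x$separation$svns$mean, x$separation$svns$sd))
  cat(sprintf("  CE-CA adjusted p: %.2g (microCT), %.2g (sVNS)\n",
              adj_p(x$comparisons$microct, "cardiac_efferent", "cardiac_afferent"),
              adj_p(x$comparisons$svns, "cardiac_efferent", "cardiac_afferent")))
  cat(sprintf("  effective pairs (HR decrease, pre-vagotomy): %.1f +/- %.1f of %d\n",
              mean(x$svns$effective_pairs), stats::sd(x$svns$effective_pairs),
              x$cuff$n_pairs))
  cat(sprintf("  relative overlap CA with CE (per-animal microCT maps): %.0f%%\n",
              mean(x$microct$rel_overlap_ca_ce)))
  invisible(x)
}

#' Summarise a fitted vagus atlas
#'
#' @param object A `vagus_atlas`.
#' @param ... Unused.
#' @return A list with the CoM table, angular comparisons, separation
#'   summaries, overlap matrices, cross-technique overlaps and effective pair
#'   counts.
#' @export
summary.vagus_atlas <- function(object, ...) {
  out <- list(
    coms = rbind(object$microct$coms, object$svns$coms),
    comparisons = object$comparisons,
    separation = object$separation,
    overlap = list(microct = object$microct$overlap,
                   svns = object$svns$overlap),
    cross_technique = object$cross_technique,
    effective_pairs = object$svns$effective_pairs,
    seed = object$seed
  )
  class(out) <- "summary.vagus_atlas"
  out
}

#' @export
print.summary.vagus_atlas <- function(x, ...) {
  cat("Angular comparisons (microCT):\n")
  print(as.data.frame(x$comparisons$microct), digits = 3)
  cat("\nAngular comparisons (sVNS):\n")
  print(as.data.frame(x$comparisons$svns), digits = 3)
  cat("\nOverlap matrix, microCT atlases:\n"); print(x$overlap$microct)
  cat("\nOverlap matrix, sVNS atlases:\n"); print(x$overlap$svns)
  cat("\nBetween-technique shared-area fractions:\n")
  print(round(x$cross_technique, 2))
  invisible(x)
}

#' Plot the eight cross-animal atlases
#'
#' @param x A `vagus_atlas`.
#' @param ... Passed to [plot.pixel_map()].
#' @export
plot.vagus_atlas <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 4), mar = c(2, 2, 3, 1))
  on.exit(graphics::par(op))
  for (g in functional_groups()) plot(x$microct$atlases[[g]], cuff = x$cuff, ...)
  for (g in functional_groups()) plot(x$svns$atlases[[g]], cuff = x$cuff, ...)
  invisible(x)
}

## Reference matrices ---------------------------------------------------------

#' Published porcine area/overlap matrices (worked example)
#'
#' The area- and shared-area-fraction matrices reported for the porcine
#' mid-cervical vagus (fractions of the total nerve cross-section; diagonal =
#' per-group area fraction, off-diagonal = pairwise shared fraction), one per
#' technique, plus the between-technique shared fractions. These are bundled
#' so the relative-overlap worked examples can be reproduced without any
#' animal data; they are the printed, rounded values.
#'
#' @return A list with `microct` and `svns` (each an `overlap_matrix` with
#'   groups in [functional_groups()] order) and `between_techniques` (named
#'   numeric vector).
#' @export
reference_overlap_matrices <- function() {
  gr <- functional_groups()
  mct <- matrix(c(
    0.74, 0.42, 0.23, 0.24,
    0.42, 0.65, 0.07, 0.31,
    0.23, 0.07, 0.23, 0.00,
    0.24, 0.31, 0.00, 0.34
  ), 4, 4, byrow = TRUE, dimnames = list(gr, gr))
  sv <- matrix(c(
    0.43, 0.40, 0.32, 0.40,
    0.40, 0.61, 0.32, 0.59,
    0.32, 0.32, 0.40, 0.33,
    0.40, 0.59, 0.33, 0.75
  ), 4, 4, byrow = TRUE, dimnames = list(gr, gr))
  list(
    microct = as_overlap_matrix(mct, technique = "microct"),
    svns = as_overlap_matrix(sv, technique = "svns"),
    between_techniques = stats::setNames(c(0.40, 0.50, 0.22, 0.33), gr)
  )
}

## Pipeline runner -------------------------------------------------------------

#' Run the full pipeline from a configuration and write results
#'
#' Synthetic mode generates the cohort; data mode reads fascicle tables
#' (CSV + JSON sidecars) for the microCT arm. Writes per-group atlases
#' (TIFF + JSON), the CoM table, angular comparisons, overlap matrices and a
#' machine-readable `summary.json` carrying the seed and a config hash.
#' Deterministic given the seed.
#'
#' @param config A `run_config` (see [read_run_config()]) or a YAML path.
#' @param out_dir Output directory (created if needed); overrides
#'   `config$out_dir`.
#' @return The fitted [vagus_atlas()], invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("an output directory is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cuff <- electrode_cuff(n_pairs = config$cuff$n_pairs,
                         pair_angles = config$cuff$pair_angles,
                         inner_diameter = config$cuff$inner_diameter)
  nerves <- NULL
  if (config$mode == "data") {
    if (is.null(config$paths$fascicle_tables)) {
      stop("data mode requires paths$fascicle_tables")
    }
    files <- Sys.glob(file.path(config$paths$fascicle_tables, "*.csv"))
    if (!length(files)) stop("no fascicle tables found in ",
                             config$paths$fascicle_tables)
    nerves <- lapply(files, read_fascicle_table)
  }
  syn <- synthetic_config(
    n_animals = max(config$synthetic$n_svns, config$synthetic$n_microct),
    nerve_area = config$synthetic$nerve_area,
    afferent_efferent_separation = config$synthetic$afferent_efferent_separation,
    angular_spread = config$synthetic$angular_spread,
    seed = config$seed
  )
  fit <- vagus_atlas(
    n_microct = config$synthetic$n_microct,
    n_svns = config$synthetic$n_svns,
    seed = config$seed, config = syn, cuff = cuff,
    W = config$mapping$W, tau = config$mapping$tau,
    adjust = config$stats$adjust, circular = config$stats$circular,
    nerves = nerves
  )

  hash <- config_hash(unclass(config))
  for (tech in c("microct", "svns")) {
    for (g in functional_groups()) {
      write_pixel_map(fit[[tech]]$atlases[[g]],
                      file.path(out_dir, sprintf("atlas_%s_%s.tif", tech, g)))
    }
    write_overlap_matrix(fit[[tech]]$overlap,
                         file.path(out_dir, sprintf("overlap_%s.csv", tech)))
    utils::write.csv(as.data.frame(fit$comparisons[[tech]]),
                     file.path(out_dir, sprintf("comparisons_%s.csv", tech)),
                     row.names = FALSE)
  }
  utils::write.csv(rbind(fit$microct$coms, fit$svns$coms),
                   file.path(out_dir, "coms.csv"), row.names = FALSE)
  summary_json <- list(
    seed = config$seed,
    config_hash = hash,
    n_microct = length(fit$microct$nerves),
    n_svns = length(fit$svns$sessions),
    separation_microct_deg = fit$separation$microct$mean,
    separation_microct_sd = fit$separation$microct$sd,
    separation_svns_deg = fit$separation$svns$mean,
    separation_svns_sd = fit$separation$svns$sd,
    p_adj_ce_ca_microct = adj_p(fit$comparisons$microct, "cardiac_efferent",
                                "cardiac_afferent"),
    p_adj_ce_ca_svns = adj_p(fit$comparisons$svns, "cardiac_efferent",
                             "cardiac_afferent"),
    effective_pairs_mean = mean(fit$svns$effective_pairs),
    effective_pairs_sd = stats::sd(fit$svns$effective_pairs),
    relative_overlap_ca_ce_microct = mean(fit$microct$rel_overlap_ca_ce),
    cross_technique = as.list(fit$cross_technique)
  )
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(fit)
}
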