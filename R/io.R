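## File formats --------------------------------------------------------------
## Fascicle tables: CSV with header id,cx_mm,cy_mm,area_mm2,organ_label,
## fibre_label plus a JSON sidecar (animal_id, nerve_radius_mm, technique).
## Traces: CSV with time_s,value,pair_index (-1 when off),stim_on plus a JSON
## sidecar (modality). Maps: 32-bit float TIFF plus a JSON sidecar.

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' Write a nerve cross-section as a fascicle table
#'
#' Writes `<path>` (CSV: `id,cx_mm,cy_mm,area_mm2,organ_label,fibre_label`)
#' and a JSON sidecar `<path base>.json` with `animal_id`, `nerve_radius_mm`
#' and `technique`.
#'
#' @param nerve A [nerve_cross_section()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fascicle_table <- function(nerve, path) {
  stopifnot(inherits(nerve, "nerve_cross_section"))
  df <- data.frame(id = nerve$fascicles$id,
                   cx_mm = nerve$fascicles$cx,
                   cy_mm = nerve$fascicles$cy,
                   area_mm2 = nerve$fascicles$area,
                   organ_label = nerve$fascicles$organ_label,
                   fibre_label = nerve$fascicles$fibre_label)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(animal_id = nerve$animal_id,
         nerve_radius_mm = nerve$nerve_radius,
         technique = nerve$technique),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a fascicle table into a nerve cross-section
#'
#' Validates labels, areas and centroid containment, reporting the offending
#' row number on failure. Row order is preserved.
#'
#' @param path CSV path (see [write_fascicle_table()] for the format).
#' @param sidecar JSON sidecar path; defaults to `<path base>.json`.
#' @return A [nerve_cross_section()].
#' @export
read_fascicle_table <- function(path, sidecar = sidecar_path(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("id", "cx_mm", "cy_mm", "area_mm2", "organ_label", "fibre_label")
  if (!all(req %in% names(df))) {
    stop("fascicle CSV must have header ", paste(req, collapse = ","))
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  fas <- data.frame(id = as.character(df$id), cx = df$cx_mm, cy = df$cy_mm,
                    area = df$area_mm2, organ_label = df$organ_label,
                    fibre_label = df$fibre_label, stringsAsFactors = FALSE)
  nerve_cross_section(meta$animal_id, meta$nerve_radius_mm, fas,
                      technique = meta$technique)
}

#' Write a physiological trace as annotated CSV
#'
#' Columns: `time_s`, `value`, `pair_index` (the stimulated pair during an
#' epoch, -1 otherwise) and `stim_on` (0/1). Modality goes to the JSON
#' sidecar.
#'
#' @param trace A [physio_trace()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "physio_trace"))
  pair_index <- rep(-1L, length(trace$time))
  stim_on <- rep(0L, length(trace$time))
  for (e in seq_len(nrow(trace$schedule))) {
    idx <- trace$time >= trace$schedule$t_on[e] &
      trace$time < trace$schedule$t_off[e]
    pair_index[idx] <- trace$schedule$pair[e]
    stim_on[idx] <- 1L
  }
  df <- data.frame(time_s = trace$time, value = trace$value,
                   pair_index = pair_index, stim_on = stim_on)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(modality = trace$modality)
  gt <- attr(trace, "ground_truth")
  if (!is.null(gt)) meta$ground_truth_pct <- gt$total
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an annotated trace CSV
#'
#' Reconstructs the stimulation schedule from the `pair_index`/`stim_on`
#' columns (contiguous runs of `stim_on == 1`).
#'
#' @param path CSV path (see [write_trace_csv()]).
#' @param sidecar JSON sidecar path.
#' @return A [physio_trace()].
#' @export
read_trace_csv <- function(path, sidecar = sidecar_path(path)) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dt <- stats::median(diff(df$time_s))
  r <- rle(df$stim_on == 1)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  on_runs <- which(r$values)
  sched <- data.frame(
    pair = df$pair_index[starts[on_runs]],
    t_on = df$time_s[starts[on_runs]],
    t_off = df$time_s[ends[on_runs]] + dt
  )
  physio_trace(meta$modality, df$time_s, df$value, sched)
}

#' Write a pixel map as TIFF plus JSON metadata
#'
#' Single-channel 32-bit float TIFF with values in \[0, 1\]; group, frame,
#' raster width, animal id and (optionally) the alignment angle go to the
#' JSON sidecar.
#'
#' @param map A [pixel_map()].
#' @param path Output TIFF path.
#' @param alignment_angle Optional alignment angle (degrees) recorded in the
#'   metadata.
#' @return `path`, invisibly.
#' @export
write_pixel_map <- function(map, path, alignment_angle = NULL) {
  stopifnot(inherits(map, "pixel_map"))
  tiff::writeTIFF(map$values, path, bits.per.sample = 32L)
  meta <- list(group = map$group, frame = map$frame, W = map$W,
               animal_id = map$animal_id, technique = map$technique)
  if (!is.null(alignment_angle)) meta$alignment_angle <- alignment_angle
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pixel map written by [write_pixel_map()]
#'
#' @param path TIFF path.
#' @param sidecar JSON sidecar path.
#' @return A [pixel_map()].
#' @export
read_pixel_map <- function(path, sidecar = sidecar_path(path)) {
  vals <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pixel_map(vals, group = meta$group, frame = meta$frame,
            animal_id = if (is.null(meta$animal_id)) NA_character_ else meta$animal_id,
            technique = if (is.null(meta$technique)) NA_character_ else meta$technique)
}

#' Write an overlap matrix as CSV
#'
#' Rows and columns in group order; the first column holds the row group
#' names, mirroring the published layout.
#'
#' @param m An `overlap_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_overlap_matrix <- function(m, path) {
  stopifnot(inherits(m, "overlap_matrix"))
  df <- data.frame(group = rownames(m), unclass(m), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an overlap matrix CSV
#'
#' @param path CSV path (see [write_overlap_matrix()]).
#' @param technique Technique tag for the result.
#' @return An `overlap_matrix`.
#' @export
read_overlap_matrix <- function(path, technique = NA_character_) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$group
  as_overlap_matrix(m, technique = technique)
}

## Run configuration ---------------------------------------------------------

run_config_defaults <- function() {
  list(
    mode = "synthetic",
    seed = 1L,
    out_dir = NULL,
    cuff = list(n_pairs = 14L, pair_angles = NULL, inner_diameter = 2.7),
    synthetic = list(n_microct = 5L, n_svns = 10L,
                     afferent_efferent_separation = 180,
                     angular_spread = 25, nerve_area = 2.68),
    mapping = list(W = 256L, tau = 0.5, smooth_s = 2),
    stats = list(adjust = "tukey", circular = FALSE),
    paths = list(fascicle_tables = NULL, traces = NULL)
  )
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys (at the top level or within a block) are rejected; missing
#' keys take the package defaults.
#'
#' @param path YAML file path.
#' @return A validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- run_config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (blk in c("cuff", "synthetic", "mapping", "stats", "paths")) {
    if (!is.null(cfg[[blk]])) {
      bad <- setdiff(names(cfg[[blk]]), names(defaults[[blk]]))
      if (length(bad)) {
        stop("unknown key(s) in '", blk, "': ", paste(bad, collapse = ", "))
      }
      defaults[[blk]][names(cfg[[blk]])] <- cfg[[blk]]
    }
  }
  for (k in setdiff(names(cfg), c("cuff", "synthetic", "mapping", "stats", "paths"))) {
    defaults[[k]] <- cfg[[k]]
  }
  if (!defaults$mode %in% c("synthetic", "data")) {
    stop("mode must be 'synthetic' or 'data'")
  }
  class(defaults) <- "run_config"
  defaults
}

## tiny FNV-1a over the deparsed config, for output provenance
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
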