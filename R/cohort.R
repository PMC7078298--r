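#' Default qualitative time-course profile of the synthetic cohort
#'
#' Generator parameters encoding, as configuration, the qualitative
#' activation profile reported for unilateral laser-induced ocular
#' hypertension: in lasered (OHT) eyes the plexiform-layer cell count and
#' the NFL-GCL area fraction peak at days 3-5, soma size is maximal at
#' day 1, arbors are retracted most at days 3-5, vertical processes
#' increase progressively to day 15, and P2RY12 intensity shows a trough
#' at days 3-5; contralateral eyes show milder activation with soma
#' maximal at day 3, elevated but flat vertical processes, unchanged
#' plexiform counts and unchanged P2RY12. Naive baselines for P2RY12
#' intensity are set so the recovered percentages sit near the reported
#' naive means (OPL 18.47%, IPL 32.21%, NFL-GCL 14.35% of 255).
#'
#' All numbers here are configuration of the simulator, not measurements;
#' the module never injects effects beyond what this profile states.
#'
#' @return A list with elements `baseline` (per-layer [field_spec()]
#'   parameters), `effects` (tibble of per-group, per-day multipliers and
#'   vertical-process counts) and `animal_cv` (between-animal coefficients
#'   of variation).
#' @export
default_cohort_profile <- function() {
  baseline <- list(
    OS = list(n_cells = 4, soma_radius_um = c(4.2, 0.4),
              arbor_radius_um = c(8, 1), n_processes = c(2, 4),
              min_spacing_um = 30, intensity_mean = NA_real_),
    OPL = list(n_cells = 16, soma_radius_um = c(4, 0.4),
               arbor_radius_um = c(17, 1.5), n_processes = c(4, 6),
               min_spacing_um = 45, intensity_mean = 47.0985),
    IPL = list(n_cells = 18, soma_radius_um = c(4, 0.4),
               arbor_radius_um = c(16, 1.5), n_processes = c(4, 6),
               min_spacing_um = 45, intensity_mean = 82.1355),
    NFL_GCL = list(n_cells = 45, soma_radius_um = c(4.8, 0.4),
                   arbor_radius_um = c(14, 1.5), n_processes = c(5, 7),
                   min_spacing_um = 18, allow_overlap = TRUE,
                   intensity_mean = 36.5925),
    OPL_OS = list(n_puncta = 8))
  days <- c(1, 3, 5, 8, 15)
  effects <- dplyr::bind_rows(
    tibble(group = "naive", day = NA_real_, count_mult = 1,
           os_count_mult = 1, nfl_count_mult = 1, soma_mult = 1,
           arbor_mult = 1, intensity_mult = 1, vp_count = 8),
    tibble(group = "OHT", day = days,
           count_mult = c(1.25, 1.8, 2.1, 1.6, 1.3),
           os_count_mult = c(1.8, 2.8, 3.6, 2.5, 2.0),
           nfl_count_mult = c(1.3, 1.6, 1.8, 1.5, 1.2),
           soma_mult = c(1.5, 1.4, 1.3, 1.2, 1.15),
           arbor_mult = c(0.8, 0.68, 0.62, 0.7, 0.75),
           intensity_mult = c(0.9, 0.45, 0.5, 0.7, 0.85),
           vp_count = c(10, 14, 17, 20, 24)),
    tibble(group = "contralateral", day = days,
           count_mult = 1,
           os_count_mult = c(1.4, 2.4, 2.1, 1.8, 1.2),
           nfl_count_mult = c(1.15, 1.3, 1.35, 1.25, 1.1),
           soma_mult = c(1.15, 1.3, 1.25, 1.12, 1.05),
           arbor_mult = c(0.92, 0.78, 0.78, 0.8, 0.85),
           intensity_mult = 1,
           vp_count = c(14, 15, 15, 15, 14)))
  list(baseline = baseline, effects = effects,
       animal_cv = c(count = 0.06, soma = 0.04, arbor = 0.04,
                     intensity = 0.15, vp = 0.06))
}

#' Specification of a synthetic study cohort
#'
#' Describes a full synthetic study: one naive group plus one lasered
#' group per survival day, each of `n_animals` animals; lasered animals
#' contribute an OHT and a contralateral eye, naive animals one eye. For
#' every eye, every retinal layer (and the OPL-OS interface plane) gets
#' `fields_per_animal` fields, with zones cycling through superior /
#' inferior / nasal / temporal. Per-field seeds derive deterministically
#' from `master_seed`.
#'
#' @param n_animals Animals per group (default 8).
#' @param days Survival days of the lasered groups.
#' @param layers Retinal layers to simulate.
#' @param fields_per_animal Fields per eye per layer.
#' @param field_px Raster size of each field.
#' @param n_z z planes per stack.
#' @param noise_sd Gaussian noise SD (8-bit units).
#' @param profile Parameter curves; see [default_cohort_profile()].
#' @param master_seed Master RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_animals = 8, days = c(1, 3, 5, 8, 15),
                        layers = c("OS", "OPL", "IPL", "NFL_GCL", "OPL_OS"),
                        fields_per_animal = 4, field_px = 512, n_z = 4,
                        noise_sd = 5,
                        profile = default_cohort_profile(),
                        master_seed = 1) {
  stopifnot(n_animals >= 2, fields_per_animal >= 1, field_px >= 16)
  layers <- match.arg(layers, several.ok = TRUE,
                      choices = c("OS", "OPL", "IPL", "NFL_GCL", "OPL_OS"))
  missing_days <- setdiff(days, profile$effects$day)
  if (length(missing_days)) {
    abort(sprintf("profile lacks effect rows for day(s) %s",
                  paste(missing_days, collapse = ", ")))
  }
  structure(
    list(n_animals = as.integer(n_animals), days = days, layers = layers,
         fields_per_animal = as.integer(fields_per_animal),
         field_px = as.integer(field_px), n_z = as.integer(n_z),
         noise_sd = noise_sd, profile = profile,
         master_seed = as.integer(master_seed)),
    class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d animals/group, days %s, layers %s, %d field(s)/eye/layer, %d px, seed %d\n",
    x$n_animals, paste(x$days, collapse = "/"),
    paste(x$layers, collapse = "/"), x$fields_per_animal, x$field_px,
    x$master_seed))
  invisible(x)
}

ZONES <- c("superior", "inferior", "nasal", "temporal")

# Deterministic per-index seed below 2^31.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master %% 10007L) * 104729 + index) %% 2147483647)
}

# Between-animal multipliers, one draw per animal per metric class.
animal_multipliers <- function(spec) {
  cvs <- spec$profile$animal_cv
  rows <- list()
  idx <- 0L
  emit <- function(group, day, animal) {
    idx <<- idx + 1L
    set.seed(derive_seed(spec$master_seed, 900000L + idx))
    m <- exp(rnorm(length(cvs), 0, cvs))
    tibble(group = group, day = day, animal = animal,
           m_count = m[1], m_soma = m[2], m_arbor = m[3],
           m_intensity = m[4], m_vp = m[5])
  }
  for (a in seq_len(spec$n_animals)) {
    rows[[length(rows) + 1L]] <- emit("naive", NA_real_, sprintf("N%02d", a))
  }
  for (d in spec$days) {
    for (a in seq_len(spec$n_animals)) {
      rows[[length(rows) + 1L]] <-
        emit("laser", d, sprintf("D%02d-%02d", d, a))
    }
  }
  dplyr::bind_rows(rows)
}

# Resolve the field_spec for one (group, day, layer) cell given the
# animal's multipliers.
resolve_field_spec <- function(spec, group, day, layer, am, seed) {
  prof <- spec$profile
  base <- prof$baseline[[layer]]
  eff <- if (group == "naive") {
    prof$effects[prof$effects$group == "naive", ]
  } else {
    prof$effects[prof$effects$group == group & prof$effects$day == day, ]
  }
  if (layer == "OPL_OS") {
    return(field_spec(
      layer = "OPL_OS", n_cells = 0,
      n_puncta = max(0L, round(eff$vp_count * am$m_vp)),
      background_level = 8, noise_sd = spec$noise_sd,
      field_px = spec$field_px, n_z = 1, seed = seed))
  }
  cmult <- switch(layer,
                  OS = eff$os_count_mult,
                  NFL_GCL = eff$nfl_count_mult,
                  eff$count_mult)
  # Arbor retraction is a plexiform-layer phenomenon; in the NFL-GCL the
  # area fraction is driven by cell accumulation (and soma growth), so
  # the retraction multiplier is not applied there.
  amult <- if (layer == "NFL_GCL") 1 else eff$arbor_mult
  field_spec(
    layer = layer,
    n_cells = max(0L, round(base$n_cells * cmult * am$m_count)),
    soma_radius_um = c(base$soma_radius_um[1] * eff$soma_mult * am$m_soma,
                       base$soma_radius_um[2]),
    arbor_radius_um = c(base$arbor_radius_um[1] * amult * am$m_arbor,
                        base$arbor_radius_um[2]),
    n_processes = base$n_processes,
    min_spacing_um = base$min_spacing_um,
    allow_overlap = isTRUE(base$allow_overlap),
    intensity_mean = if (is.na(base$intensity_mean)) NA_real_ else
      min(255, base$intensity_mean * eff$intensity_mult * am$m_intensity),
    background_level = 8, noise_sd = spec$noise_sd,
    field_px = spec$field_px, n_z = spec$n_z, seed = seed)
}

#' Generate a synthetic cohort
#'
#' Builds the manifest of every field of the cohort — animal, eye group,
#' day, layer, zone, per-field seed — and the fully resolved
#' [field_spec()] for each row. Images are rendered lazily by the
#' quantification pipeline (deterministically, from the per-field seeds);
#' with `dir` set, all stacks are also written to disk as TIFFs together
#' with per-field ground-truth JSON, a manifest CSV and the cohort
#' parameters as YAML.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional output directory for TIFF/JSON/CSV/YAML export.
#' @return A `glia_cohort`: list with `manifest` (tibble) and
#'   `field_specs` (list parallel to manifest rows), plus the spec.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  am <- animal_multipliers(spec)
  rows <- list()
  specs <- list()
  ri <- 0L
  add_eye <- function(animal, group, day, amrow, zone_offset) {
    for (layer in spec$layers) {
      for (f in seq_len(spec$fields_per_animal)) {
        ri <<- ri + 1L
        seed <- derive_seed(spec$master_seed, ri)
        rows[[ri]] <<- tibble(
          animal = animal, group = group, day = day, layer = layer,
          zone = ZONES[(f - 1L + zone_offset) %% 4L + 1L], field = f,
          seed = seed,
          file = sprintf("%s_%s_d%s_%s_f%d.tif", animal, group,
                         ifelse(is.na(day), "NA", day), layer, f))
        specs[[ri]] <<- resolve_field_spec(spec, group, day, layer,
                                           amrow, seed)
      }
    }
  }
  for (a in seq_len(spec$n_animals)) {
    amrow <- am[am$group == "naive" &
                  am$animal == sprintf("N%02d", a), ]
    add_eye(sprintf("N%02d", a), "naive", NA_real_, amrow, a)
  }
  for (d in spec$days) {
    for (a in seq_len(spec$n_animals)) {
      id <- sprintf("D%02d-%02d", d, a)
      amrow <- am[am$group == "laser" & am$animal == id, ]
      add_eye(id, "OHT", d, amrow, a + d)
      add_eye(id, "contralateral", d, amrow, a + d + 1L)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  cohort <- structure(list(spec = spec, manifest = manifest,
                           field_specs = specs),
                      class = "glia_cohort")
  if (!is.null(dir)) export_cohort(cohort, dir)
  cohort
}

#' @export
print.glia_cohort <- function(x, ...) {
  cat(sprintf("<glia_cohort> %d fields (%d animals/group, days %s)\n",
              nrow(x$manifest), x$spec$n_animals,
              paste(x$spec$days, collapse = "/")))
  invisible(x)
}

#' @rdname generate_cohort
#' @param x A `glia_cohort`.
#' @param ... Unused.
#' @return `tidy()` returns the manifest tibble.
#' @export
tidy.glia_cohort <- function(x, ...) x$manifest

# Render a single manifest row (stack or puncta plane).
render_cohort_field <- function(cohort, i) {
  fs <- cohort$field_specs[[i]]
  if (fs$layer == "OPL_OS") render_puncta_plane(fs) else render_field(fs)
}

export_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  for (i in seq_len(nrow(man))) {
    r <- render_cohort_field(cohort, i)
    path <- file.path(dir, man$file[i])
    if (inherits(r$stack %||% NULL, "image_stack")) {
      write_stack(r$stack, path)
    } else {
      tiff::writeTIFF(r$image$pixels / 255, path, bits.per.sample = 8)
    }
    truth <- r$truth
    jsonlite::write_json(
      list(cells = truth$cells, tips = truth$tips, puncta = truth$puncta,
           area_fraction = truth$area_fraction,
           intensity_percent = truth$intensity_percent),
      sub("\\.tif$", ".json", path), dataframe = "columns",
      auto_unbox = TRUE, digits = NA)
  }
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  sp <- cohort$spec
  yaml::write_yaml(
    list(n_animals = sp$n_animals, days = sp$days, layers = sp$layers,
         fields_per_animal = sp$fields_per_animal, field_px = sp$field_px,
         n_z = sp$n_z, noise_sd = sp$noise_sd,
         master_seed = sp$master_seed),
    file.path(dir, "cohort.yaml"))
  invisible(dir)
}
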