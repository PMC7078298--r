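#' Pipeline configuration
#'
#' Bundles a cohort (or an existing manifest-backed `glia_cohort`) with
#' the per-layer detection parameters and analysis options of a full
#' quantification run.
#'
#' @param cohort A [cohort_spec()] or a generated `glia_cohort`.
#' @param params Named list of [detection_params()] per layer; missing
#'   layers get sensible defaults (plexiform defaults; smaller segments
#'   and tighter merge radii for OS spots and interface puncta).
#' @param unit Unit of statistical analysis: `"animal"` (per-animal mean
#'   across fields; avoids pseudo-replication and is the default) or
#'   `"field"`.
#' @param soma_core_frac Fraction of per-image max defining soma cores
#'   for automated cell-body areas.
#' @param max_cells_morpho Per-field cap on cells measured for arbor
#'   areas. Morphometry protocols measure tens of cells per retina; the
#'   default of 16 per field keeps the per-field arbor mean stable.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(), params = list(),
                       unit = c("animal", "field"),
                       soma_core_frac = 0.55, max_cells_morpho = 16) {
  unit <- match.arg(unit)
  defaults <- list(
    OS = detection_params(min_distance_um = 15, min_segment_px = 3),
    OPL = detection_params(),
    IPL = detection_params(),
    NFL_GCL = detection_params(),
    OPL_OS = detection_params(min_distance_um = 8, min_segment_px = 2))
  for (nm in names(params)) defaults[[nm]] <- params[[nm]]
  structure(list(cohort = cohort, params = defaults, unit = unit,
                 soma_core_frac = soma_core_frac,
                 max_cells_morpho = max_cells_morpho),
            class = "run_config")
}

measure_field <- function(config, fs, rendered) {
  layer <- fs$layer
  p <- config$params[[layer]]
  out <- list()
  if (layer == "OPL_OS") {
    vp <- count_vertical_processes(rendered$image, p)
    out$vertical_processes <- as.numeric(vp)
    return(out)
  }
  img <- max_project(rendered$stack, "iba1")
  if (layer == "OS") {
    out$cell_count <- cell_density(count_spots(img, p))
  } else if (layer %in% c("OPL", "IPL")) {
    out$cell_count <- cell_density(count_cells(img, p))
    somas <- soma_areas_field(img, core_frac = config$soma_core_frac)
    if (length(somas)) out$soma_area <- mean(somas)
    arbors <- arbor_areas_field(img, p, max_cells = config$max_cells_morpho)
    if (length(arbors)) out$arbor_area <- mean(arbors)
  } else if (layer == "NFL_GCL") {
    out$iba1_ra <- as.numeric(area_fraction(img, p))
    somas <- soma_areas_field(img, core_frac = config$soma_core_frac)
    if (length(somas)) out$soma_area <- mean(somas)
  }
  if ("p2ry12" %in% names(rendered$stack$channels)) {
    green <- max_project(rendered$stack, "p2ry12")
    out$p2ry12_intensity <- as.numeric(mean_intensity_percent(green))
  }
  out
}

#' Run the full quantification pipeline on a cohort
#'
#' Renders (or re-renders, deterministically from the per-field seeds)
#' every field of the cohort, measures it with the layer-appropriate
#' operations — cell counts in OS/OPL/IPL, Iba-1 area fraction in
#' NFL-GCL, automated soma and arbor areas, vertical-process counts in
#' the interface plane, P2RY12 mean intensity — and assembles tidy
#' per-field and per-animal tables plus the full statistical comparison
#' table (Mann-Whitney vs naive, paired Wilcoxon OHT vs contralateral,
#' ANOVA with Bonferroni correction across days, and the retinal-zone
#' homogeneity ANOVA).
#'
#' Per-field failures are recorded and skipped; an empty manifest is an
#' error. Reruns with the same configuration are byte-identical.
#'
#' @param config A [run_config()].
#' @return A `glia_run`: list with `per_field`, `per_animal`,
#'   `comparisons`, `zone_tables`, `failures`, `manifest`, `config`.
#' @export
run_quantification <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- config$cohort
  if (inherits(cohort, "cohort_spec")) cohort <- generate_cohort(cohort)
  man <- cohort$manifest
  if (nrow(man) == 0) abort("empty cohort manifest")
  rows <- vector("list", nrow(man))
  failures <- character(0)
  for (i in seq_len(nrow(man))) {
    res <- tryCatch({
      fs <- cohort$field_specs[[i]]
      rendered <- render_cohort_field(cohort, i)
      vals <- measure_field(config, fs, rendered)
      tibble(animal = man$animal[i], group = man$group[i],
             day = man$day[i], layer = man$layer[i], zone = man$zone[i],
             field = man$field[i], metric = names(vals),
             value = unlist(vals, use.names = FALSE))
    }, error = function(e) {
      failures <<- c(failures,
                     sprintf("row %d (%s): %s", i, man$file[i],
                             conditionMessage(e)))
      NULL
    })
    rows[[i]] <- res
  }
  per_field <- dplyr::bind_rows(rows)
  if (nrow(per_field) == 0) abort("all fields failed quantification")
  per_animal <- per_field |>
    dplyr::group_by(.data$animal, .data$group, .data$day, .data$layer,
                    .data$metric) |>
    dplyr::summarise(value = mean(.data$value), n_fields = dplyr::n(),
                     .groups = "drop")
  unit_tbl <- if (config$unit == "animal") per_animal else
    dplyr::rename(per_field, n_fields = field)
  comparisons <- build_comparisons(unit_tbl)
  zone_tables <- build_zone_tables(per_field)
  structure(list(per_field = per_field, per_animal = per_animal,
                 comparisons = comparisons, zone_tables = zone_tables,
                 failures = failures, manifest = man, config = config),
            class = "glia_run")
}

# Group contrasts per metric x layer x day, plus across-day ANOVA.
build_comparisons <- function(tbl) {
  out <- list()
  combos <- dplyr::distinct(tbl, .data$layer, .data$metric)
  days <- sort(unique(tbl$day[!is.na(tbl$day)]))
  for (i in seq_len(nrow(combos))) {
    ly <- combos$layer[i]; mt <- combos$metric[i]
    sub <- tbl[tbl$layer == ly & tbl$metric == mt, ]
    naive <- sub$value[sub$group == "naive"]
    for (d in days) {
      oht <- sub[sub$group == "OHT" & sub$day == d, ]
      ctr <- sub[sub$group == "contralateral" & sub$day == d, ]
      if (length(naive) && nrow(oht)) {
        out[[length(out) + 1L]] <- comparison_row(
          mt, ly, d, "OHT vs naive", compare_unpaired(oht$value, naive))
      }
      if (length(naive) && nrow(ctr)) {
        out[[length(out) + 1L]] <- comparison_row(
          mt, ly, d, "contralateral vs naive",
          compare_unpaired(ctr$value, naive))
      }
      if (nrow(oht) && nrow(ctr)) {
        m <- dplyr::inner_join(oht, ctr,
                               by = intersect(c("animal", "field"),
                                              names(oht)),
                               suffix = c("_oht", "_ctr"))
        if (nrow(m) >= 2) {
          out[[length(out) + 1L]] <- comparison_row(
            mt, ly, d, "OHT vs contralateral (paired)",
            compare_paired(m$value_oht, m$value_ctr))
        }
      }
    }
    for (grp in c("OHT", "contralateral")) {
      g <- sub[sub$group == grp & !is.na(sub$day), ]
      if (length(unique(g$day)) >= 2 && all(table(g$day) >= 2)) {
        av <- anova_bonferroni(g$value, factor(g$day))
        out[[length(out) + 1L]] <- tidy(av) |>
          dplyr::transmute(
            metric = mt, layer = ly, day = NA_real_,
            contrast = sprintf("%s day %s vs day %s", grp,
                               .data$group1, .data$group2),
            method = "anova_bonferroni",
            statistic = glance(av)$f_statistic,
            p_raw = .data$p_raw, p_adjusted = .data$p_adjusted,
            n1 = NA_integer_, n2 = NA_integer_,
            significant = .data$significant)
      }
    }
  }
  dplyr::bind_rows(out)
}

comparison_row <- function(metric, layer, day, contrast, test) {
  td <- tidy(test)
  tibble(metric = metric, layer = layer, day = day, contrast = contrast,
         method = td$method, statistic = td$statistic,
         p_raw = td$p_value, p_adjusted = td$p_value,
         n1 = as.integer(td$n1), n2 = as.integer(td$n2),
         significant = td$p_value < 0.05)
}

# Zone homogeneity of OHT eyes: per-field counts / area fraction by zone.
build_zone_tables <- function(per_field) {
  targets <- tibble(metric = c("cell_count", "cell_count", "cell_count",
                               "iba1_ra"),
                    layer = c("OS", "OPL", "IPL", "NFL_GCL"))
  out <- list()
  for (i in seq_len(nrow(targets))) {
    sub <- per_field[per_field$group == "OHT" &
                       per_field$metric == targets$metric[i] &
                       per_field$layer == targets$layer[i], ]
    if (nrow(sub) == 0) next
    recs <- tibble(zone = sub$zone, value = sub$value)
    if (length(unique(recs$zone)) < 2 || any(table(recs$zone) < 2)) next
    av <- zone_analysis(recs)
    out[[paste(targets$metric[i], targets$layer[i], sep = ".")]] <-
      list(metric = targets$metric[i], layer = targets$layer[i],
           anova = glance(av), pairwise = tidy(av))
  }
  out
}

#' @export
print.glia_run <- function(x, ...) {
  cat(sprintf(
    "<glia_run> %d per-field measurements, %d comparison rows, %d failure(s)\n",
    nrow(x$per_field), nrow(x$comparisons), length(x$failures)))
  invisible(x)
}

#' Tidy and glance methods for pipeline runs
#'
#' `tidy()` returns the per-unit (per-animal by default) long measurement
#' table; `glance()` a one-row summary of the run.
#'
#' @param x A `glia_run`.
#' @param ... Unused.
#' @export
tidy.glia_run <- function(x, ...) x$per_animal

#' @rdname tidy.glia_run
#' @export
glance.glia_run <- function(x, ...) {
  tibble(n_fields = nrow(x$manifest),
         n_measurements = nrow(x$per_field),
         n_comparisons = nrow(x$comparisons),
         n_significant = sum(x$comparisons$significant, na.rm = TRUE),
         n_failures = length(x$failures))
}

#' Group-mean time course of one metric
#'
#' Mean and SD per group and day of one metric in one layer, from the
#' per-animal table of a run.
#'
#' @param run A `glia_run`.
#' @param metric,layer Metric and layer names as they appear in
#'   `tidy(run)`.
#' @return Tibble with `group`, `day`, `mean`, `sd`, `n`.
#' @export
time_course <- function(run, metric, layer) {
  stopifnot(inherits(run, "glia_run"))
  run$per_animal |>
    dplyr::filter(.data$metric == !!metric, .data$layer == !!layer) |>
    dplyr::group_by(.data$group, .data$day) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) sd(.data$value) else 0,
                     n = dplyr::n(), .groups = "drop")
}

#' Plot the time course of one metric
#'
#' Histogram-style group means with SD error bars at each day for OHT and
#' contralateral eyes, with the naive mean as a dotted reference line —
#' the conventional layout of activation time-course figures.
#'
#' @inheritParams time_course
#' @return A ggplot object.
#' @export
plot_time_course <- function(run, metric, layer) {
  tc <- time_course(run, metric, layer)
  exp_groups <- tc[!is.na(tc$day), ]
  naive_mean <- tc$mean[tc$group == "naive"]
  p <- ggplot2::ggplot(exp_groups,
                       ggplot2::aes(x = factor(.data$day), y = .data$mean,
                                    fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9),
                      width = 0.8) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(0.9), width = 0.25) +
    ggplot2::labs(x = "days after laser", y = metric,
                  title = sprintf("%s, %s", metric, layer)) +
    ggplot2::theme_minimal()
  if (length(naive_mean)) {
    p <- p + ggplot2::geom_hline(yintercept = naive_mean[1],
                                 linetype = "dotted")
  }
  p
}

#' @rdname plot_time_course
#' @param object A `glia_run`.
#' @param ... Passed through (`metric`, `layer`).
#' @export
autoplot.glia_run <- function(object, metric, layer, ...) {
  plot_time_course(object, metric, layer)
}

#' Render a report of a quantification run
#'
#' Writes a markdown summary (group tables, comparison table, zone
#' analysis) and one time-course figure per metric x layer to `dir`.
#' Regeneration over an existing directory overwrites the same files, so
#' the operation is idempotent.
#'
#' @param run A `glia_run`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(run, dir) {
  stopifnot(inherits(run, "glia_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  combos <- dplyr::distinct(run$per_animal, .data$layer, .data$metric)
  for (i in seq_len(nrow(combos))) {
    f <- file.path(dir, sprintf("timecourse_%s_%s.png",
                                combos$metric[i], combos$layer[i]))
    tc <- time_course(run, combos$metric[i], combos$layer[i])
    if (all(is.na(tc$day))) next
    png(f, width = 900, height = 600)
    print(plot_time_course(run, combos$metric[i], combos$layer[i]))
    dev.off()
    paths <- c(paths, f)
  }
  md <- file.path(dir, "report.md")
  con <- file(md, "w")
  on.exit(close(con))
  writeLines("# Quantification report", con)
  writeLines("", con)
  writeLines(sprintf("Fields quantified: %d; failures: %d",
                     nrow(run$manifest), length(run$failures)), con)
  writeLines("", con)
  writeLines("## Comparisons", con)
  if (nrow(run$comparisons)) {
    writeLines(knit_table(run$comparisons), con)
  } else {
    writeLines("_No statistical comparisons available._", con)
  }
  writeLines("", con)
  writeLines("## Zone homogeneity (OHT eyes)", con)
  if (length(run$zone_tables)) {
    for (nm in names(run$zone_tables)) {
      zt <- run$zone_tables[[nm]]
      writeLines(sprintf("### %s (%s)", zt$metric, zt$layer), con)
      writeLines(knit_table(zt$pairwise), con)
      writeLines("", con)
    }
  } else {
    writeLines("_No zone analysis available._", con)
  }
  paths <- c(paths, md)
  invisible(paths)
}

# Minimal markdown table writer (keeps the report dependency-free).
knit_table <- function(df) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], 4)
  }
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r) {
    paste0("| ", paste(r, collapse = " | "), " |")
  })
  c(header, sep, body)
}
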