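# Run configuration, result tables and hierarchical aggregation.
#
# Results travel as a long-format table (group, animal, tissue, field,
# metric, value, units). Aggregation is hierarchical -- fields are averaged
# within a tissue, tissues within an animal, animals within a group --
# matching how replicate micrographs are conventionally summarized, rather
# than pooling all pixels or fields across levels.

RESULT_COLS <- c("group", "animal", "tissue", "field", "metric", "value", "units")

#' Construct a long-format result table
#'
#' @param group,animal,tissue,field Identifier vectors (recycled).
#' @param metric,value,units Metric name, numeric value and unit string.
#' @return A `result_table` data frame with one row per
#'   (group, animal, tissue, field, metric).
#' @export
result_table <- function(metric, value, units = "", group = NA, animal = NA,
                         tissue = NA, field = NA) {
  df <- data.frame(group = group, animal = animal, tissue = tissue,
                   field = field, metric = metric, value = as.numeric(value),
                   units = units, stringsAsFactors = FALSE)
  key <- do.call(paste, c(df[c("group", "animal", "tissue", "field", "metric")],
                          sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (group, animal, tissue, field, metric) rows", call. = FALSE)
  df$units[!nzchar(df$units)] <- "dimensionless"
  structure(df, class = c("result_table", "data.frame"))
}

#' Aggregate a result table one level up
#'
#' Arithmetic means within each group of the next level: fields to a tissue
#' mean, tissues to an animal mean, or animals to a group mean. Rows with
#' missing values are excluded and the exclusion count is reported in the
#' `n_missing` column alongside `n` (values averaged).
#'
#' @param table A [result_table()].
#' @param level One of `"field_to_tissue"`, `"tissue_to_animal"`,
#'   `"animal_to_group"`.
#' @return A `result_table` with the averaged-over column set to `NA` and
#'   extra columns `n`, `n_missing`.
#' @export
aggregate_results <- function(table,
                              level = c("field_to_tissue", "tissue_to_animal",
                                        "animal_to_group")) {
  level <- match.arg(level)
  drop_col <- switch(level, field_to_tissue = "field",
                     tissue_to_animal = "tissue", animal_to_group = "animal")
  keys <- switch(level,
                 field_to_tissue = c("group", "animal", "tissue", "metric", "units"),
                 tissue_to_animal = c("group", "animal", "metric", "units"),
                 animal_to_group = c("group", "metric", "units"))
  dt <- data.table::as.data.table(table)
  if (nrow(dt) == 0L) stop("empty result table", call. = FALSE)
  agg <- dt[, list(value = mean(value[!is.na(value)]),
                   n = sum(!is.na(value)),
                   n_missing = sum(is.na(value))), by = keys]
  if (any(agg$n == 0L)) stop("empty group after removing missing values", call. = FALSE)
  out <- as.data.frame(agg)
  for (col in setdiff(RESULT_COLS, names(out))) out[[col]] <- NA
  out <- out[, c(RESULT_COLS, "n", "n_missing")]
  o <- do.call(order, out[c("group", "animal", "tissue", "metric")])
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("result_table", "data.frame"))
}

#' Run an analysis or simulate-analyze pipeline from a configuration
#'
#' The configuration is a named list (or path to a JSON file) with a `task`
#' plus task-specific parameters. Simulation tasks (`psr_sim`, `depot_sim`,
#' `ienf_sim`) generate scenes with the synthetic generators and push them
#' through the matching analysis chain; table tasks (`vonfrey`, `myograph`,
#' `nmj`) read a CSV (or take a data frame in `config$table`) and summarize
#' it. All numeric parameters are validated before any pixel is touched, and
#' the run is deterministic given the configuration (seeds included), so a
#' rerun yields a byte-identical table.
#'
#' @param config Named list or JSON path. Common fields: `task`, `seed`,
#'   `out_dir` (optional; results written as CSV + JSON when present).
#' @return A [result_table()] with provenance attributes `provenance`
#'   (package version, config JSON, seed).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config) || is.null(config$task))
    stop("config must be a list (or JSON file) with a `task` field", call. = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  task <- config$task
  tab <- switch(task,
    psr_sim = {
      spec <- do.call(psr_scene_spec, config$scene %||% list())
      n_fields <- config$n_fields %||% 5L
      pairs <- lapply(seq_len(n_fields), function(k)
        gen_psr_pair(spec, seed = seed + k - 1L))
      hue_spec <- if (is.null(config$hue_bins)) hue_bin_spec() else {
        hb <- config$hue_bins
        args <- lapply(hb[setdiff(names(hb), "brightness")], as_intervals_cfg)
        if (!is.null(hb$brightness)) args$brightness <- as.numeric(unlist(hb$brightness))
        do.call(hue_bin_spec, args)
      }
      res <- analyze_psr_tissue(lapply(pairs, function(p)
        list(brightfield = p$brightfield, polarized = p$polarized)), spec = hue_spec)
      tm <- res$tissue_means
      result_table(
        metric = c("total_collagen_ratio", "thin_fraction", "thick_fraction",
                   paste0("fraction_", names(tm$class_fractions))),
        value = c(tm$total_collagen_ratio, tm$thin_fraction, tm$thick_fraction,
                  unname(tm$class_fractions)),
        units = "dimensionless", tissue = config$tissue %||% "sim")
    },
    depot_sim = {
      spec <- do.call(depot_scene_spec, config$scene %||% list())
      n_fields <- config$n_fields %||% 5L
      chain <- do.call(filter_chain_spec, config$filter_chain %||% list())
      scenes <- lapply(seq_len(n_fields), function(k)
        gen_depot_scene(spec, seed = seed + k - 1L))
      ov <- overlap_tissue(lapply(scenes, function(s)
        list(nerve = s$nerve, vessel = s$vessel)), spec = chain)
      result_table(metric = c("manders_m1", "manders_m2", "manders_moc"),
                   value = c(ov$m1, ov$m2, ov$moc),
                   units = "dimensionless", tissue = config$tissue %||% "sim")
    },
    ienf_sim = {
      f <- config$fiber_fraction %||% 0.05
      n_sections <- config$n_sections %||% 3L
      secs <- lapply(seq_len(n_sections), function(k)
        gen_ienf_section(f, noise_sd = config$noise_sd %||% 10, seed = seed + k - 1L))
      res <- ienf_tissue(lapply(secs, function(s) list(image = s$image, roi = s$roi)))
      result_table(metric = "ienf_density", value = res$density,
                   units = "area fraction", tissue = config$tissue %||% "sim")
    },
    vonfrey = {
      tab <- pipeline_table(config)
      validate_vonfrey_table(tab, config$trials_expected %||% 5L)
      rows <- lapply(unique(tab$animal), function(a) {
        cur <- response_curve(tab[tab$animal == a, , drop = FALSE],
                              trials_expected = config$trials_expected %||% 5L)
        rbind(
          result_table(metric = paste0("fraction_", cur$filament_g, "g"),
                       value = cur$fraction, units = "fraction", animal = a),
          result_table(metric = "auc", value = vonfrey_auc(cur),
                       units = "g*fraction", animal = a))
      })
      structure(do.call(rbind, rows), class = c("result_table", "data.frame"))
    },
    myograph = {
      tab <- pipeline_table(config)
      if (!all(c("dose_M", "response") %in% names(tab)))
        stop("myograph table needs columns dose_M, response", call. = FALSE)
      fit <- fit_ec50(dose_response(tab$dose_M, tab$response))
      result_table(metric = c("ec50", "bottom", "top", "hill_slope", "rss"),
                   value = c(fit$ec50, fit$bottom, fit$top, fit$hill_slope, fit$rss),
                   units = c("M", "%", "%", "dimensionless", "squared %"))
    },
    nmj = {
      tab <- pipeline_table(config)
      s <- nmj_summary(tab, expected_n = config$expected_n %||% 50L)
      rows <- lapply(seq_len(nrow(s)), function(i)
        result_table(metric = c("fraction_occupied", "mean_tsc_per_nmj",
                                "n_junctions"),
                     value = c(s$fraction_occupied[i], s$mean_tsc_per_nmj[i],
                               s$n_junctions[i]),
                     units = c("fraction", "count", "count"),
                     tissue = s$tissue[i]))
      structure(do.call(rbind, rows), class = c("result_table", "data.frame"))
    },
    stop(sprintf("unknown task '%s'", task), call. = FALSE)
  )
  attr(tab, "provenance") <- list(
    package_version = as.character(utils::packageVersion("adiposcope")),
    seed = seed,
    config = jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(as.data.frame(tab), file.path(config$out_dir, "results.csv"))
    jsonlite::write_json(
      list(provenance = attr(tab, "provenance"),
           results = as.data.frame(tab)),
      file.path(config$out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  tab
}

pipeline_table <- function(config) {
  if (!is.null(config$table)) as.data.frame(config$table)
  else if (!is.null(config$input)) {
    if (!file.exists(config$input))
      stop(sprintf("input file not found: %s", config$input), call. = FALSE)
    as.data.frame(data.table::fread(config$input))
  } else stop("config needs `table` or `input`", call. = FALSE)
}

as_intervals_cfg <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(unlist(x)), ncol = 2L, byrow = TRUE)
  else as.matrix(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
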