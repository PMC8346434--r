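# End-to-end orchestration: measure -> curves -> typology -> stats, with
# figures and a provenance log. All randomness derives from one master
# seed recorded in the provenance.

#' Run the full analysis pipeline
#'
#' Executes the stages measure (frames + ROI XML + filter -> area tables),
#' curves (standardize, truncate, flag, join metadata), typology (SOTA +
#' K-means + letters) and stats (multinomial models, AIC choice,
#' probabilities, Wald contrasts), writing all tables, JSON summaries,
#' figures and a provenance log under `config$out_dir`. Any stage error
#' aborts with the stage name.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   `frames_dir` (or `areas_prefix` for precomputed tables), `rois`
#'   (ROI XML path), `metadata` (CSV path), `batch`, `out_dir`, and
#'   optional `filter` (list: mode, threshold, refs, metric),
#'   `subsample_step`, `smooth_n`, `tmax`, `n_clusters`, `n_groups`,
#'   `predictor_check` (fit both treatment and plate models), `reference`
#'   (`"auto"` or a letter), `seed`.
#' @return Invisibly, a list with every stage result.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  out_dir <- cfg$out_dir %||% "larvafeed_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed %||% 1L
  tmax <- cfg$tmax %||% 2500

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # -- measure ---------------------------------------------------------
  series <- stage("measure", {
    if (!is.null(cfg$areas_prefix)) {
      read_area_table(cfg$areas_prefix, smooth_n = cfg$smooth_n %||% 10L)
    } else {
      rois <- load_rois(cfg$rois)
      fl <- cfg$filter %||% list(mode = "diff_2G", threshold = 35)
      filt <- if (identical(fl$mode, "ref_colors"))
        color_filter("ref_colors", fl$threshold,
                     ref_colors = matrix(unlist(fl$refs), ncol = 3, byrow = TRUE),
                     metric = fl$metric %||% "L2")
      else color_filter(fl$mode, fl$threshold)
      frames <- sort(list.files(cfg$frames_dir, pattern = "\\.(png|jpe?g)$",
                                full.names = TRUE, ignore.case = TRUE))
      s <- measure_stack(frames, rois, filt,
                         subsample_step = cfg$subsample_step %||% 1,
                         smooth_n = cfg$smooth_n %||% 10,
                         cadence_min = cfg$cadence_min %||% 1)
      export_area_table(s, file.path(out_dir, "areas"))
      s
    }
  })

  # -- curves ----------------------------------------------------------
  curves <- stage("curves", {
    cl <- standardize(series, batch = cfg$batch %||% NA_character_,
                      plate = cfg$plate)
    cl <- lapply(cl, function(cv) {
      cv <- truncate_curve(cv, tmax)
      flag_anomalies(cv, jump_tol = cfg$jump_tol %||% 0.15,
                     rise_tol = cfg$rise_tol %||% 0.10)
    })
    if (!is.null(cfg$metadata)) {
      meta <- utils::read.csv(cfg$metadata)
      cl <- join_metadata(cl, meta)
    }
    write_curves(cl, file.path(out_dir, "curves.csv"))
    cl
  })

  # -- typology --------------------------------------------------------
  typ <- stage("typology", {
    cm <- curve_matrix(curves, grid = seq(0, tmax - 10, by = 10))
    fx <- features_table(curves[vapply(curves, function(cv) cv$flag != "excluded",
                                       logical(1))], tmax = tmax)
    ty <- build_typology(cm, fx, n_clusters = cfg$n_clusters %||% 14,
                         n_groups = cfg$n_groups %||% 6, seed = seed)
    jsonlite::write_json(list(
      cluster_medians = ty$cluster_medians,
      group = ty$group, letters = ty$letters,
      curve_letters = as.list(ty$curve_letters)),
      file.path(out_dir, "typology.json"), auto_unbox = TRUE, digits = NA)
    ty
  })

  # -- stats -----------------------------------------------------------
  st <- stage("stats", {
    kept <- curves[vapply(curves, function(cv) cv$flag != "excluded", logical(1))]
    df <- data.frame(
      letter = unname(typ$curve_letters),
      treatment = vapply(kept, function(cv) as.character(cv$meta$treatment %||% NA), character(1)),
      plate = vapply(kept, function(cv) as.character(cv$meta$plate %||% NA), character(1)))
    if (anyNA(df$treatment)) return(NULL)  # unlabelled run: no stats stage
    ref <- cfg$reference %||% "auto"
    if (identical(ref, "auto")) ref <- choose_reference(df)
    fit_t <- fit_multinomial(df, "treatment", reference = ref,
                             ridge = cfg$ridge %||% 0)
    res <- list(reference = ref, fit = fit_t,
                probabilities = estimate_probabilities(fit_t),
                contrasts = all_contrasts(fit_t, adjust = cfg$adjust %||% "none"))
    if (isTRUE(cfg$predictor_check) && length(unique(df$plate)) > 1) {
      fit_p <- fit_multinomial(df, "plate", reference = ref,
                               ridge = cfg$ridge %||% 0)
      res$aic <- data.frame(model = c("treatment", "plate"),
                            aic = c(fit_t$aic, fit_p$aic))
      res$chosen <- attr(compare_models(fit_t, fit_p), "chosen")
    }
    jsonlite::write_json(list(
      reference = res$reference,
      coefficients = as.data.frame(res$fit$coefficients),
      aic = res$aic, chosen = res$chosen,
      probabilities = as.data.frame(res$probabilities),
      contrasts = res$contrasts),
      file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA)
    res
  })

  # -- figures ---------------------------------------------------------
  stage("figures", {
    plot_curve_grid(series, path = file.path(out_dir, "curves_grid.pdf"),
                    curves = curves)
    if (!is.null(st))
      plot_type_distribution(st$probabilities,
                             path = file.path(out_dir, "type_distribution.pdf"))
  })

  prov <- list(package = "larvafeed",
               version = as.character(utils::packageVersion("larvafeed")),
               r_version = R.version.string,
               seed = seed, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
               config = cfg)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(series = series, curves = curves, typology = typ, stats = st))
}

#' Plot per-cage consumption curves in plate layout
#'
#' One panel per cage, arranged as on the plate; the raw pixel counts are
#' drawn in black with the median-smoothed series overlaid in red. Flagged
#' cages carry an orange marker in the panel corner.
#'
#' @param series An `area_series`.
#' @param path Output PDF path.
#' @param layout `c(rows, cols)` panel layout; by default inferred from
#'   the ROI names (`"RxxCyy"`).
#' @param curves Optional list of flagged `consumption_curve`s (for the
#'   markers), named by ROI.
#' @return `path`, invisibly.
#' @export
plot_curve_grid <- function(series, path, layout = NULL, curves = NULL) {
  stopifnot(inherits(series, "area_series"))
  nms <- colnames(series$raw)
  if (length(nms) == 0) stop("no curves to plot")
  if (is.null(layout)) {
    rr <- suppressWarnings(as.integer(sub("^R(\\d+)C\\d+$", "\\1", nms)))
    cc <- suppressWarnings(as.integer(sub("^R\\d+C(\\d+)$", "\\1", nms)))
    layout <- if (anyNA(rr) || anyNA(cc)) grDevices::n2mfrow(length(nms))
              else c(max(rr), max(cc))
  }
  grDevices::pdf(path, width = 2 * layout[2], height = 1.6 * layout[1])
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = layout, mar = c(1.2, 1.2, 1, 0.3),
                      mgp = c(1, 0.3, 0), tcl = -0.2, cex.axis = 0.5)
  on.exit(graphics::par(op), add = TRUE)
  for (nm in nms) {
    graphics::plot(series$time, series$raw[, nm], type = "l", col = "black",
                   xlab = "", ylab = "", main = nm, cex.main = 0.6)
    graphics::lines(series$time, series$med[, nm], col = "red")
    if (!is.null(curves) && !is.null(curves[[nm]]) &&
        curves[[nm]]$flag != "ok")
      graphics::points(graphics::par("usr")[2], graphics::par("usr")[4],
                       pch = 17, col = "orange", xpd = NA)
  }
  invisible(path)
}

#' Plot the behavioural-type distribution per treatment as pies
#'
#' One pie per treatment; types A-F use a fixed red-to-blue palette
#' (appetitive to aversive). Rows must sum to 1.
#'
#' @param prob_table Matrix or data frame: one row per treatment, one
#'   column per type, each row summing to 1.
#' @param path Output PDF path.
#' @return The plotted table, invisibly.
#' @export
plot_type_distribution <- function(prob_table, path) {
  m <- as.matrix(prob_table)
  if (any(m < -1e-9) || any(abs(rowSums(m) - 1) > 1e-6))
    stop("each row of the probability table must be non-negative and sum to 1")
  pal <- grDevices::colorRampPalette(c("#d73027", "#4575b4"))(ncol(m))
  grDevices::pdf(path, width = 3 * nrow(m), height = 3.4)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(1, nrow(m)), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op), add = TRUE)
  for (i in seq_len(nrow(m))) {
    sel <- m[i, ] > 0
    graphics::pie(m[i, sel], labels = colnames(m)[sel], col = pal[sel],
                  main = rownames(m)[i] %||% paste("treatment", i))
  }
  invisible(m)
}
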