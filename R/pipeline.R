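## End-to-end orchestration: generate or ingest nuclei, mask, cluster,
## compute distance statistics, co-localization, topology and group
## comparisons, and emit a reproducible report.  A single master seed is
## fanned out to per-stage child seeds (see [derive_seed()]) so toggling
## stages never changes the random stream of the others.

#' Build and validate a pipeline run configuration
#'
#' Exactly one input mode must be used.  In `"synthetic"` mode, `groups`
#' names the cohorts; each entry is a list of [scene_params()] overrides
#' (e.g. `control = list(coloc_fraction = 0, n_foci = 0)`).  In the file
#' modes, `inputs` is a list of per-nucleus entries with paths (`orte_ch1`,
#' `orte_ch2` or `stack_ch1`, `stack_ch2` plus `pixel_size_nm`,
#' `nucleus_mask`, `foci_mask`, optional `group`, optional logical
#' `include` modelling the intact-nucleus selection).
#'
#' @param mode `"synthetic"`, `"orte-files"` or `"frame-stacks"`
#' @param seed master seed
#' @param n_nuclei nuclei per group (synthetic mode; acquisition regime
#'   default 25)
#' @param scene base [scene_params()] overrides (list)
#' @param groups named list of per-group scene overrides
#' @param detection a [detection_params()]
#' @param clustering a [cluster_params()]
#' @param coloc_thresholds_nm co-localization distance limits
#' @param distance list: `bin_width_nm`, `max_distance_nm`,
#'   `smoothing_window`, `min_prominence`, `pooling`
#' @param topology list: `alpha_max_nm`, `max_points` (subsample cap per
#'   barcode), `region` in `{"foci", "nucleus", "clusters"}`
#' @param stats list: `method`, `measure` (per-nucleus value compared
#'   between groups; currently `"coloc_fraction"`), `threshold_nm`
#' @param inputs per-nucleus input entries (file modes)
#' @return a validated `run_config`
#' @export
run_config <- function(mode = c("synthetic", "orte-files",
                                "frame-stacks"),
                       seed = 1L,
                       n_nuclei = 25L,
                       scene = list(),
                       groups = list(irradiated = list(),
                                     control = list(coloc_fraction = 0,
                                                    n_foci = 0L)),
                       detection = detection_params(),
                       clustering = cluster_params(),
                       coloc_thresholds_nm = c(95, 50, 20),
                       distance = list(),
                       topology = list(),
                       stats = list(),
                       inputs = NULL) {
  if (length(mode) > 1L) mode <- mode[1L]
  mode <- match.arg(mode, c("synthetic", "orte-files", "frame-stacks"))
  check_num(seed, "seed", lower = 0)
  check_num(n_nuclei, "n_nuclei", lower = 1)
  if (mode == "synthetic" && !is.null(inputs))
    stopf("synthetic mode does not take file inputs; choose one mode")
  if (mode != "synthetic" && is.null(inputs))
    stopf("mode '%s' requires 'inputs'", mode)
  # validate every parameter block before any computation
  base_scene <- do.call(scene_params, c(scene, list(seed = 1L)))
  for (g in names(groups))
    do.call(scene_params,
            c(utils::modifyList(scene, groups[[g]]), list(seed = 1L)))
  stopifnot(inherits(detection, "detection_params"),
            inherits(clustering, "cluster_params"))
  if (!length(coloc_thresholds_nm) || any(coloc_thresholds_nm <= 0))
    stopf("coloc_thresholds_nm must be positive")
  distance <- utils::modifyList(list(bin_width_nm = 10,
                                     max_distance_nm = 1000,
                                     smoothing_window = 3L,
                                     min_prominence = 0.05,
                                     pooling = "pairs"), distance)
  topology <- utils::modifyList(list(alpha_max_nm = 500,
                                     max_points = 400L,
                                     region = "foci"), topology)
  if (!topology$region %in% c("foci", "nucleus", "clusters"))
    stopf("topology$region must be foci, nucleus or clusters")
  stats <- utils::modifyList(list(method = "ranksum",
                                  measure = "coloc_fraction",
                                  threshold_nm = 95), stats)
  structure(list(mode = mode, seed = as.integer(seed),
                 n_nuclei = as.integer(n_nuclei), scene = scene,
                 groups = groups, detection = detection,
                 clustering = clustering,
                 coloc_thresholds_nm = sort(coloc_thresholds_nm,
                                            decreasing = TRUE),
                 distance = distance, topology = topology,
                 stats = stats, inputs = inputs,
                 base_scene = base_scene),
            class = "run_config")
}

#' @noRd
collect_synthetic_nuclei <- function(config) {
  nuclei <- list()
  gi <- 0L
  for (g in names(config$groups)) {
    gi <- gi + 1L
    overrides <- utils::modifyList(config$scene, config$groups[[g]])
    for (i in seq_len(config$n_nuclei)) {
      sp <- do.call(scene_params,
                    c(overrides,
                      list(seed = derive_seed(config$seed, "nucleus",
                                              gi * 100000L + i))))
      scene <- generate_scene(sp)
      nuclei[[length(nuclei) + 1L]] <- list(
        id = sprintf("%s_%02d", g, i), group = g, scene = scene,
        orte_ch1 = sample_localizations(scene, 1L),
        orte_ch2 = sample_localizations(scene, 2L),
        nucleus_mask = scene$nucleus_mask,
        foci_mask = scene$foci_mask)
    }
  }
  nuclei
}

#' @noRd
collect_file_nuclei <- function(config) {
  nuclei <- list()
  for (i in seq_along(config$inputs)) {
    entry <- config$inputs[[i]]
    if (isFALSE(entry$include)) next      # intact-nucleus selection flag
    nucleus_mask <- read_mask(entry$nucleus_mask)
    foci_mask <- read_mask(entry$foci_mask)
    if (config$mode == "orte-files") {
      o1 <- read_orte(entry$orte_ch1, channel = "ch1")
      o2 <- read_orte(entry$orte_ch2, channel = "ch2")
    } else {
      s1 <- read_frame_stack(entry$stack_ch1, entry$pixel_size_nm)
      s2 <- read_frame_stack(entry$stack_ch2, entry$pixel_size_nm)
      o1 <- localize_stack(s1, config$detection)
      o2 <- localize_stack(s2, config$detection)
    }
    nuclei[[length(nuclei) + 1L]] <- list(
      id = if (!is.null(entry$id)) entry$id else sprintf("nucleus_%02d", i),
      group = if (!is.null(entry$group)) entry$group else "all",
      scene = NULL, orte_ch1 = o1, orte_ch2 = o2,
      nucleus_mask = nucleus_mask, foci_mask = foci_mask)
  }
  nuclei
}

#' Run the full evaluation pipeline
#'
#' Stages: generate/ingest (localizing frame stacks if needed) -> mask
#' -> DBSCAN morphometrics -> distance statistics -> co-localization ->
#' topology -> group statistics.  A nucleus failing one stage is
#' excluded from that stage's aggregate with a logged reason, not from
#' the others.
#'
#' @param config a [run_config()]
#' @return a `run_report`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  nuclei <- if (config$mode == "synthetic")
    collect_synthetic_nuclei(config) else collect_file_nuclei(config)
  if (!length(nuclei)) stopf("no nuclei to analyze")
  failures <- list()
  note_failure <- function(id, stage, err)
    failures[[length(failures) + 1L]] <<-
      data.frame(nucleus = id, stage = stage,
                 reason = conditionMessage(err))

  summaries <- list(); coloc_rows <- list(); overlap_rows <- list()
  hists <- list(ch1 = list(), ch2 = list())
  barcodes <- list(ch1 = list(), ch2 = list())
  clusters_by_nucleus <- list()

  for (k in seq_along(nuclei)) {
    nuc <- nuclei[[k]]
    o1 <- apply_mask(nuc$orte_ch1, nuc$nucleus_mask)
    o2 <- apply_mask(nuc$orte_ch2, nuc$nucleus_mask)

    ## --- cluster morphometrics (both masks, both labels)
    tryCatch({
      s <- summarize_nucleus(list(ch1 = nuc$orte_ch1,
                                  ch2 = nuc$orte_ch2),
                             nuc$nucleus_mask, nuc$foci_mask,
                             config$clustering)
      s$nucleus <- nuc$id; s$group <- nuc$group
      summaries[[nuc$id]] <- s
    }, error = function(e) note_failure(nuc$id, "clustering", e))

    cl1 <- tryCatch(cluster_orte(o1, config$clustering),
                    error = function(e) {
                      note_failure(nuc$id, "clustering", e); NULL })
    cl2 <- tryCatch(cluster_orte(o2, config$clustering),
                    error = function(e) {
                      note_failure(nuc$id, "clustering", e); NULL })
    clusters_by_nucleus[[nuc$id]] <- list(ch1 = cl1, ch2 = cl2)

    ## --- distance histograms
    for (ch in c("ch1", "ch2")) {
      o <- if (ch == "ch1") o1 else o2
      tryCatch({
        h <- pairwise_distance_histogram(
          o$x_nm, o$y_nm, config$distance$bin_width_nm,
          config$distance$max_distance_nm)
        hists[[ch]][[nuc$id]] <- h
      }, error = function(e) note_failure(nuc$id,
                                          paste0("distance_", ch), e))
    }

    ## --- co-localization at every threshold (both directions)
    tryCatch({
      for (thr in config$coloc_thresholds_nm) {
        cr <- colocalize_points(o1, o2, coloc_params(thr))
        in_cl1 <- if (!is.null(cl1) && length(cl1$clusters)) {
          ins <- rep(FALSE, nrow(o1))
          for (cl in cl1$clusters)
            if (nrow(cl$hull) >= 3L)
              ins <- ins | points_in_convex_polygon(o1$x_nm, o1$y_nm,
                                                    cl$hull)
          sum(cr$a_to_b$flags & ins)
        } else NA_integer_
        coloc_rows[[length(coloc_rows) + 1L]] <- data.frame(
          nucleus = nuc$id, group = nuc$group, threshold_nm = thr,
          direction = c("a_to_b", "b_to_a"),
          n = c(cr$a_to_b$n, cr$b_to_a$n),
          n_coloc = c(cr$a_to_b$n_coloc, cr$b_to_a$n_coloc),
          fraction_pct = c(cr$a_to_b$fraction_pct,
                           cr$b_to_a$fraction_pct),
          n_coloc_in_clustersA = c(in_cl1, NA_integer_))
      }
    }, error = function(e) note_failure(nuc$id, "colocalization", e))

    ## --- cluster overlap and cross-channel density
    tryCatch({
      if (!is.null(cl1) && !is.null(cl2)) {
        ov <- cluster_overlap(cl2$clusters, cl1$clusters)
        dc <- density_in_clusters(o2, cl1$clusters)
        overlap_rows[[length(overlap_rows) + 1L]] <- data.frame(
          nucleus = nuc$id, group = nuc$group,
          overlap_pct_ch2_on_ch1 = ov,
          ch2_density_in_ch1_clusters_per_um2 = dc$density_per_um2,
          ch1_cluster_union_area_um2 = dc$union_area_um2)
      }
    }, error = function(e) note_failure(nuc$id, "overlap", e))

    ## --- topology barcodes
    for (ch in c("ch1", "ch2")) {
      o <- if (ch == "ch1") o1 else o2
      tryCatch({
        pts <- switch(config$topology$region,
          nucleus = cbind(o$x_nm, o$y_nm),
          foci = {
            of <- apply_mask(o, nuc$foci_mask)
            cbind(of$x_nm, of$y_nm)
          },
          clusters = {
            cl <- if (ch == "ch1") cl1 else cl2
            idx <- if (!is.null(cl)) which(cl$labels != 0L) else integer(0)
            cbind(o$x_nm[idx], o$y_nm[idx])
          })
        if (nrow(pts) < 3L) stopf("too few points for topology (%d)",
                                  nrow(pts))
        if (nrow(pts) > config$topology$max_points) {
          set.seed(derive_seed(config$seed, paste0("topo_", ch), k))
          pts <- pts[sort(sample.int(nrow(pts),
                                     config$topology$max_points)), ]
        }
        barcodes[[ch]][[nuc$id]] <-
          alpha_persistence(pts, alpha_max_nm =
                              config$topology$alpha_max_nm)
      }, error = function(e) note_failure(nuc$id,
                                          paste0("topology_", ch), e))
    }
  }

  ## --- aggregates
  summary_table <- if (length(summaries)) do.call(rbind, summaries)
  if (!is.null(summary_table)) rownames(summary_table) <- NULL
  coloc_table <- if (length(coloc_rows)) do.call(rbind, coloc_rows)
  overlap_table <- if (length(overlap_rows)) do.call(rbind, overlap_rows)

  pooled <- list(); peaks <- list()
  for (ch in c("ch1", "ch2")) {
    if (length(hists[[ch]])) {
      pooled[[ch]] <- pool_distance_histograms(
        hists[[ch]], weight = config$distance$pooling)
      peaks[[ch]] <- detect_peaks(pooled[[ch]],
                                  config$distance$smoothing_window,
                                  config$distance$min_prominence)
    }
  }

  heatmaps <- list()
  if (length(barcodes$ch1) >= 2L && length(barcodes$ch2) >= 2L) {
    for (dm in c(0L, 1L)) {
      nm <- if (dm == 0L) "components" else "holes"
      heatmaps[[nm]] <- similarity_heatmaps(
        list(ch1 = barcodes$ch1, ch2 = barcodes$ch2), dimension = dm)
    }
  }

  comparisons <- list()
  groups_present <- unique(vapply(nuclei, `[[`, character(1), "group"))
  if (!is.null(coloc_table) && length(groups_present) >= 2L) {
    thr <- config$stats$threshold_nm
    for (thr_i in config$coloc_thresholds_nm) {
      sub <- coloc_table[coloc_table$direction == "a_to_b" &
                           coloc_table$threshold_nm == thr_i, ]
      va <- sub$fraction_pct[sub$group == groups_present[1L]]
      vb <- sub$fraction_pct[sub$group == groups_present[2L]]
      comparisons[[paste0("coloc_", thr_i, "nm")]] <- tryCatch(
        compare_groups(va, vb, method = config$stats$method,
                       labels = groups_present[1:2]),
        error = function(e) {
          note_failure("(cohort)", "group_stats", e); NULL })
    }
  }

  provenance <- list(
    config_hash = config_hash(config[setdiff(names(config),
                                             "base_scene")]),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("nanofoci")),
    r_version = R.version.string)

  structure(list(nuclei = nuclei,
                 nucleus_summaries = summary_table,
                 clusters = clusters_by_nucleus,
                 distance_histograms = hists,
                 pooled_histograms = pooled, peaks = peaks,
                 coloc = coloc_table, overlap = overlap_table,
                 barcodes = barcodes, heatmaps = heatmaps,
                 comparisons = comparisons,
                 failures = if (length(failures))
                   do.call(rbind, failures) else NULL,
                 provenance = provenance),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("nanofoci run report: %d nuclei, config %s (seed %d)\n",
              length(x$nuclei), substr(x$provenance$config_hash, 1, 8),
              x$provenance$seed))
  if (!is.null(x$failures))
    cat(sprintf("  %d stage failure(s) logged\n", nrow(x$failures)))
  invisible(x)
}

#' @noRd
backup_if_exists <- function(path) {
  if (file.exists(path)) file.rename(path, paste0(path, ".bak"))
  path
}

#' @noRd
write_csv_prov <- function(df, path, prov) {
  backup_if_exists(path)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nanofoci config_hash=%s seed=%d",
                     prov$config_hash, prov$seed), con)
  utils::write.table(df, con, sep = ",", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Emit a run report to disk
#'
#' Writes the per-nucleus summary, per-cluster tables, distance
#' histograms and peaks, co-localization tables, barcodes, heatmap
#' matrices, group comparisons and a human-readable summary.  All CSV
#' files carry the configuration hash in a leading comment; existing
#' files are backed up with a `.bak` suffix.
#'
#' @param report a `run_report`
#' @param outdir output directory (created if needed)
#' @param figures also write simple PNG figures (default FALSE)
#' @return character vector of files written, invisibly
#' @export
emit_report <- function(report, outdir, figures = FALSE) {
  stopifnot(inherits(report, "run_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(outdir, 2L) != 0L)
    stopf("output directory not writable: %s", outdir)
  prov <- report$provenance
  files <- character(0)
  put <- function(f) { files <<- c(files, f); f }

  if (!is.null(report$nucleus_summaries))
    put(write_csv_prov(report$nucleus_summaries,
                       file.path(outdir, "nucleus_summary.csv"), prov))

  cl_rows <- list()
  for (id in names(report$clusters)) for (ch in c("ch1", "ch2")) {
    cl <- report$clusters[[id]][[ch]]
    if (is.null(cl)) next
    for (i in seq_along(cl$clusters)) {
      p <- cl$clusters[[i]]
      cl_rows[[length(cl_rows) + 1L]] <- data.frame(
        nucleus = id, channel = ch, cluster = i, n = p$n,
        area_um2 = p$area_um2, density_per_um2 = p$density_per_um2,
        hull_wkt = paste0("POLYGON((",
                          paste(sprintf("%.2f %.2f", p$hull[, 1L],
                                        p$hull[, 2L]), collapse = ","),
                          "))"))
    }
  }
  if (length(cl_rows))
    put(write_csv_prov(do.call(rbind, cl_rows),
                       file.path(outdir, "clusters.csv"), prov))

  for (ch in names(report$pooled_histograms)) {
    h <- report$pooled_histograms[[ch]]
    nb <- length(h$rel_freq)
    put(write_csv_prov(
      data.frame(bin_left_nm = h$breaks_nm[-(nb + 1L)],
                 bin_right_nm = h$breaks_nm[-1L],
                 rel_freq = h$rel_freq),
      file.path(outdir, sprintf("distance_histogram_%s.csv", ch)),
      prov))
  }
  if (length(report$peaks)) {
    pk <- lapply(report$peaks, function(p)
      list(position_nm = p$position_nm, height = p$height,
           fwhm_nm = p$fwhm_nm,
           spacing_nm = attr(p, "spacing_nm")))
    f <- file.path(outdir, "peaks.json")
    backup_if_exists(f)
    jsonlite::write_json(c(pk, list(`_provenance` = prov)), f,
                         auto_unbox = TRUE, digits = NA, na = "null")
    put(f)
  }

  if (!is.null(report$coloc))
    put(write_csv_prov(report$coloc, file.path(outdir, "coloc.csv"),
                       prov))
  if (!is.null(report$overlap)) {
    f <- file.path(outdir, "overlap_density.json")
    backup_if_exists(f)
    jsonlite::write_json(list(rows = report$overlap,
                              `_provenance` = prov), f,
                         auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows")
    put(f)
  }

  for (ch in c("ch1", "ch2")) {
    for (id in names(report$barcodes[[ch]]))
      put(write_barcode(report$barcodes[[ch]][[id]],
                        backup_if_exists(file.path(outdir,
                          sprintf("barcode_%s_%s.csv", ch, id)))))
  }
  for (nm in names(report$heatmaps)) {
    hm <- report$heatmaps[[nm]]
    put(write_csv_prov(as.data.frame(hm$gen2$values),
                       file.path(outdir,
                                 sprintf("heatmap_gen2_%s.csv", nm)),
                       prov))
    for (key in names(hm$gen1))
      put(write_csv_prov(as.data.frame(hm$gen1[[key]]),
                         file.path(outdir,
                                   sprintf("heatmap_gen1_%s_%s.csv", nm,
                                           gsub("[^A-Za-z0-9]", "_",
                                                key))),
                         prov))
  }

  if (length(report$comparisons)) {
    f <- file.path(outdir, "comparisons.json")
    backup_if_exists(f)
    jsonlite::write_json(
      c(lapply(report$comparisons, unclass),
        list(`_provenance` = prov)),
      f, auto_unbox = TRUE, digits = NA, na = "null")
    put(f)
  }

  ## human-readable summary
  f <- file.path(outdir, "summary.txt")
  backup_if_exists(f)
  lines <- c(sprintf("nanofoci run summary (config %s, seed %d)",
                     prov$config_hash, prov$seed),
             sprintf("nuclei analyzed: %d", length(report$nuclei)))
  if (!is.null(report$nucleus_summaries)) {
    agg <- report$nucleus_summaries
    for (lab in unique(agg$label)) for (mk in unique(agg$mask)) {
      sub <- agg[agg$label == lab & agg$mask == mk, ]
      lines <- c(lines, sprintf(
        "  %s / %s: %.0f events, %.1f clusters, mean area %.3f um^2",
        lab, mk, mean(sub$n_events), mean(sub$n_clusters),
        mean(sub$mean_cluster_area_um2, na.rm = TRUE)))
    }
  }
  for (nm in names(report$comparisons)) {
    cmp <- report$comparisons[[nm]]
    if (!is.null(cmp))
      lines <- c(lines, sprintf("  %s: p = %.4g (%s)", nm, cmp$p_value,
                                cmp$annotation))
  }
  if (!is.null(report$failures))
    lines <- c(lines, sprintf("  failures: %d (see failures in report)",
                              nrow(report$failures)))
  writeLines(lines, f)
  put(f)

  if (figures) {
    for (ch in names(report$pooled_histograms)) {
      h <- report$pooled_histograms[[ch]]
      f <- file.path(outdir, sprintf("distance_histogram_%s.png", ch))
      backup_if_exists(f)
      grDevices::png(f, width = 800, height = 500)
      mids <- (h$breaks_nm[-1L] +
                 h$breaks_nm[-length(h$breaks_nm)]) / 2
      graphics::plot(mids, h$rel_freq, type = "h", xlab = "distance (nm)",
                     ylab = "relative frequency",
                     main = sprintf("pairwise distances (%s)", ch))
      grDevices::dev.off()
      put(f)
    }
    for (nm in names(report$heatmaps)) {
      hm <- report$heatmaps[[nm]]$gen2$values
      f <- file.path(outdir, sprintf("heatmap_gen2_%s.png", nm))
      backup_if_exists(f)
      grDevices::png(f, width = 500, height = 500)
      graphics::image(seq_len(nrow(hm)), seq_len(ncol(hm)),
                      t(hm[rev(seq_len(nrow(hm))), , drop = FALSE]),
                      axes = FALSE, xlab = "", ylab = "",
                      main = sprintf("2nd-generation similarity (%s)",
                                     nm))
      grDevices::dev.off()
      put(f)
    }
  }
  invisible(files)
}
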