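#' Run the full response-to-loading analysis on a cohort
#'
#' For every sample and loading state: excludes boundary pixels from the
#' mask, partitions the eroded mask into apex/intermediate/base thirds,
#' fits the requested relaxation maps voxelwise, and summarizes each map
#' over the four ROIs. Per-sample relative changes Delta1/Delta2 are then
#' computed from the ROI medians, the stress-strain curves are fitted to
#' the exponential model, and the Pauli scores are tabulated.
#'
#' @param cohort a `meniscus_cohort` from [generate_cohort]
#' @param contrasts contrasts to analyse (subset of those simulated)
#' @param keep_maps keep the fitted `parameter_map`s in the result
#'   (memory-heavy; off by default)
#' @return object of class `cohort_analysis`: list with long-format
#'   data.frames `roi_summary` (sample, group, load, contrast, roi,
#'   median, q1, q3, iqr, pixel_count), `deltas` (sample, group,
#'   contrast, roi, delta, value), `pixel_counts` (sample, load, count,
#'   from the eroded analysis masks), `biomech` (sample, group, b, c,
#'   EM_20, EM_80, true_b, true_c), `pauli`, and optionally `maps`
#' @export
run_cohort_analysis <- function(cohort, contrasts = cohort$spec$contrasts,
                                keep_maps = FALSE) {
  stopifnot(inherits(cohort, "meniscus_cohort"))
  contrasts <- match.arg(contrasts, c("T1", "T1rho", "T2"), several.ok = TRUE)
  fitters <- list(T1 = fit_t1_map, T1rho = fit_t1rho_map, T2 = fit_t2_map)

  summaries <- list(); counts <- list(); maps <- list()
  biomech <- list(); pauli <- list()

  for (s in cohort$samples) {
    for (load in names(s$loads)) {
      st <- s$loads[[load]]
      eroded <- exclude_boundary(st$mask, id = paste(s$id, load))
      part <- partition_thirds(eroded, cohort$spec$apex_side)
      counts[[length(counts) + 1L]] <-
        data.frame(sample = s$id, load = load, count = sum(eroded))
      for (ct in contrasts) {
        if (is.null(st$stacks[[ct]]))
          stop(sprintf("stage fit-maps failed: sample %s, load %s: no %s stack",
                       s$id, load, ct))
        map <- fitters[[ct]](st$stacks[[ct]], mask = eroded)
        if (keep_maps) maps[[paste(s$id, load, ct, sep = ".")]] <- map
        for (roi in c("entire", "I", "II", "III")) {
          row <- summarize_roi(map, part, roi)
          summaries[[length(summaries) + 1L]] <-
            cbind(data.frame(sample = s$id, group = s$group, load = load,
                             contrast = ct), row)
        }
      }
    }
    fit <- fit_exponential(s$stress_strain$strain, s$stress_strain$stress)
    biomech[[length(biomech) + 1L]] <-
      data.frame(sample = s$id, group = s$group, b = fit$b, c = fit$c,
                 EM_20 = fit$EM_20, EM_80 = fit$EM_80,
                 true_b = s$b, true_c = s$c)
    pauli[[length(pauli) + 1L]] <-
      cbind(data.frame(sample = s$id, group = s$group),
            s$pauli[, c("surface", "cellularity", "collagen", "staining",
                        "sum", "grade")])
  }

  roi_summary <- do.call(rbind, summaries)
  out <- list(roi_summary = roi_summary,
              deltas = compute_deltas(roi_summary),
              pixel_counts = do.call(rbind, counts),
              biomech = do.call(rbind, biomech),
              pauli = do.call(rbind, pauli),
              spec = cohort$spec)
  if (keep_maps) out$maps <- maps
  structure(out, class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("cohort analysis: %d samples, %d ROI summary rows\n",
              length(unique(x$roi_summary$sample)), nrow(x$roi_summary)))
  invisible(x)
}

#' Per-sample Delta statistics from a long ROI summary table
#'
#' `Delta_k = ((median(delta_k) / median(delta0)) - 1) * 100` per sample,
#' contrast and ROI.
#'
#' @param roi_summary the `roi_summary` data.frame of a `cohort_analysis`
#' @return long data.frame: sample, group, contrast, roi, delta
#'   (`"delta1"`/`"delta2"`), value (percent)
#' @export
compute_deltas <- function(roi_summary) {
  loads <- setdiff(unique(roi_summary$load), "delta0")
  ref <- roi_summary[roi_summary$load == "delta0", ]
  out <- list()
  for (ld in loads) {
    cur <- roi_summary[roi_summary$load == ld, ]
    key <- c("sample", "contrast", "roi")
    m <- merge(cur, ref[, c(key, "median")], by = key,
               suffixes = c("", "_ref"))
    out[[ld]] <- data.frame(sample = m$sample, group = m$group,
                            contrast = m$contrast, roi = m$roi,
                            delta = sub("^delta", "Delta", ld),
                            value = relative_change(m$median, m$median_ref))
  }
  do.call(rbind, out)
}

#' Absolute-value report across loading states (Table-1 shape)
#'
#' For each subgroup (including "all"), ROI and contrast: the cohort
#' median and quartiles of the per-sample ROI medians at each loading
#' state (per-sample-first summarization), the Friedman test across
#' loading states with Dunn's post-hoc flags in the order delta0 vs
#' delta1, delta0 vs delta2, delta1 vs delta2, and the grade-wise
#' Kruskal-Wallis p-value at each loading state.
#'
#' @param analysis a `cohort_analysis`
#' @param alpha significance level (default 0.005)
#' @return list with `values` (long data.frame), `friedman` and
#'   `kruskal` (data.frames of test results)
#' @export
table1_report <- function(analysis, alpha = 0.005) {
  rs <- analysis$roi_summary
  groups <- c("all", levels(factor(rs$group)))
  values <- list(); fried <- list(); kw <- list()
  for (g in groups) {
    sub <- if (g == "all") rs else rs[rs$group == g, ]
    for (ct in unique(sub$contrast)) for (roi in unique(sub$roi)) {
      cell <- sub[sub$contrast == ct & sub$roi == roi, ]
      wide <- stats::reshape(cell[, c("sample", "load", "median")],
                             idvar = "sample", timevar = "load",
                             direction = "wide")
      y <- as.matrix(wide[, -1, drop = FALSE])
      colnames(y) <- sub("^median\\.", "", colnames(y))
      for (ld in colnames(y)) {
        v <- y[, ld]
        q <- roi_quartiles(v[!is.na(v)])
        values[[length(values) + 1L]] <-
          data.frame(group = g, contrast = ct, roi = roi, load = ld,
                     median = stats::median(v, na.rm = TRUE),
                     q1 = q[1], q3 = q[2], n = sum(!is.na(v)))
      }
      tr <- compare_loading(y, alpha = alpha)
      fried[[length(fried) + 1L]] <-
        data.frame(group = g, contrast = ct, roi = roi,
                   statistic = tr$statistic, p = tr$p_value,
                   flags = posthoc_flags(tr))
    }
    if (g == "all") {
      for (ct in unique(rs$contrast)) for (roi in unique(rs$roi))
        for (ld in unique(rs$load)) {
          cell <- rs[rs$contrast == ct & rs$roi == roi & rs$load == ld, ]
          tr <- compare_grades(cell$median, cell$group, alpha = alpha)
          kw[[length(kw) + 1L]] <-
            data.frame(contrast = ct, roi = roi, load = ld,
                       statistic = tr$statistic, p = tr$p_value,
                       flags = posthoc_flags(tr))
        }
    }
  }
  list(values = do.call(rbind, values), friedman = do.call(rbind, fried),
       kruskal = do.call(rbind, kw))
}

#' Relative-change report (Table-2 shape)
#'
#' Mean +/- SD of the per-sample Delta1 and Delta2 values per subgroup,
#' ROI and contrast; unpaired t-test Delta1 vs Delta2; one-way ANOVA of
#' each Delta across the degeneration subgroups.
#'
#' @inheritParams table1_report
#' @return list with `values` and `tests` data.frames
#' @export
table2_report <- function(analysis, alpha = 0.005) {
  dl <- analysis$deltas
  groups <- c("all", levels(factor(dl$group)))
  values <- list(); tests <- list()
  for (g in groups) {
    sub <- if (g == "all") dl else dl[dl$group == g, ]
    for (ct in unique(sub$contrast)) for (roi in unique(sub$roi)) {
      cell <- sub[sub$contrast == ct & sub$roi == roi, ]
      d1 <- cell$value[cell$delta == "Delta1"]
      d2 <- cell$value[cell$delta == "Delta2"]
      cmp <- compare_deltas(d1, d2,
                            group = if (g == "all")
                              cell$group[cell$delta == "Delta1"] else NULL,
                            alpha = alpha)
      values[[length(values) + 1L]] <-
        data.frame(group = g, contrast = ct, roi = roi,
                   delta1_mean = mean(d1, na.rm = TRUE),
                   delta1_sd = stats::sd(d1[!is.na(d1)]),
                   delta2_mean = mean(d2, na.rm = TRUE),
                   delta2_sd = stats::sd(d2[!is.na(d2)]))
      tests[[length(tests) + 1L]] <-
        data.frame(group = g, contrast = ct, roi = roi,
                   t_p = cmp$t_test$p_value,
                   anova1_p = if (is.null(cmp$anova_delta1)) NA_real_
                              else cmp$anova_delta1$p_value,
                   anova2_p = if (is.null(cmp$anova_delta2)) NA_real_
                              else cmp$anova_delta2$p_value)
    }
  }
  list(values = do.call(rbind, values), tests = do.call(rbind, tests))
}

#' qMRI-biomechanics correlation report
#'
#' Spearman correlations between each contrast's unloaded entire-sample
#' ROI median and the Elastic Modulus at 20% and 80% strain.
#'
#' @inheritParams table1_report
#' @return data.frame: contrast, strain, rho, p, n
#' @export
correlation_report <- function(analysis) {
  rs <- analysis$roi_summary
  bm <- analysis$biomech
  out <- list()
  for (ct in unique(rs$contrast)) {
    cell <- rs[rs$contrast == ct & rs$roi == "entire" & rs$load == "delta0", ]
    m <- merge(cell[, c("sample", "median")], bm, by = "sample")
    for (em in c("EM_20", "EM_80")) {
      r <- tryCatch(correlate_qmri_biomech(m$median, m[[em]]),
                    error = function(e) {
                      message("correlation skipped: ", conditionMessage(e))
                      list(rho = NA_real_, p.value = NA_real_, n = nrow(m))
                    })
      out[[length(out) + 1L]] <-
        data.frame(contrast = ct, strain = ifelse(em == "EM_20", 0.2, 0.8),
                   rho = r$rho, p = r$p.value, n = r$n)
    }
  }
  do.call(rbind, out)
}

posthoc_flags <- function(tr) {
  if (is.null(tr$posthoc)) return(NA_character_)
  paste(ifelse(tr$posthoc$significant, "*", "ns"), collapse = ", ")
}

#' Write an analysis run to disk with a provenance record
#'
#' Writes the long-format tables of a `cohort_analysis` plus the Table-1-
#' and Table-2-shaped reports as CSV under `dir`, and a `provenance.json`
#' with the md5 hash of every written file, the spec seed and the run
#' timestamp. Deterministic stages rerun with the same config reproduce
#' the same hashes.
#'
#' @param analysis a `cohort_analysis`
#' @param dir output directory (created if needed)
#' @param alpha significance level for the reports
#' @return invisibly, the provenance list
#' @export
write_run <- function(analysis, dir, alpha = 0.005) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  t1 <- table1_report(analysis, alpha)
  t2 <- table2_report(analysis, alpha)
  files <- list(roi_summary = analysis$roi_summary,
                deltas = analysis$deltas,
                pixel_counts = analysis$pixel_counts,
                biomech = analysis$biomech,
                pauli = analysis$pauli,
                table1_values = t1$values, table1_friedman = t1$friedman,
                table1_kruskal = t1$kruskal,
                table2_values = t2$values, table2_tests = t2$tests,
                correlations = correlation_report(analysis))
  paths <- character()
  for (nm in names(files)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(files[[nm]], p, row.names = FALSE)
    paths[nm] <- p
  }
  prov <- list(seed = analysis$spec$seed, alpha = alpha,
               files = as.list(unname(tools::md5sum(paths))),
               names = as.list(names(paths)),
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(prov)
}
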