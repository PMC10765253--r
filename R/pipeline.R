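#' Study configuration
#'
#' Settings for a full study run: the simulation config (synthetic mode)
#' or input paths (real mode), the analysis roster -- the three ANCOVAs of
#' the design: a small-sample analysis in the broad 0--0.1164 Hz band, the
#' large-scale analysis in the same band, and the large-scale analysis in
#' the narrow 0.01--0.08 Hz band -- and the family-wise error control.
#'
#' @param mode `"synthetic"` or `"real"`.
#' @param sim A [simulation_config()] (synthetic mode).
#' @param paths Real mode: list with `bold_dir` (one NIfTI per participant,
#'   `<id>.nii` or `.nii.gz`), `labels` (NIfTI label volume), `roi_sidecar`
#'   (JSON label map), `participants` (TSV).
#' @param small_n_per_group Per-group size of the seeded small-sample
#'   subset (141 in the study design).
#' @param family_alpha Family-wise significance level (0.05).
#' @param seed Master seed; all randomness derives from it.
#' @param out_dir Optional directory: artifacts (TSV tables, JSON manifest,
#'   text report) are written there.
#' @return An object of class `study_config`.
#' @export
study_config <- function(mode = c("synthetic", "real"),
                         sim = simulation_config(),
                         paths = NULL,
                         small_n_per_group = 141L,
                         family_alpha = 0.05,
                         seed = 1L,
                         out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "real") {
    need <- c("bold_dir", "labels", "roi_sidecar", "participants")
    if (is.null(paths) || !all(need %in% names(paths))) {
      stop("real mode needs paths: ", paste(need, collapse = ", "))
    }
    missing <- !vapply(paths[need], file.exists, logical(1))
    if (any(missing)) {
      stop("path(s) do not exist: ",
           paste(unlist(paths[need][missing]), collapse = ", "))
    }
  }
  roster <- list(
    small_broad = list(band = band_broad(), subset = TRUE,
                       label = "small sample, 0-0.1164 Hz"),
    large_broad = list(band = band_broad(), subset = FALSE,
                       label = "largescale, 0-0.1164 Hz"),
    large_narrow = list(band = band_narrow(), subset = FALSE,
                        label = "largescale, 0.01-0.08 Hz")
  )
  structure(
    list(mode = mode, sim = sim, paths = paths,
         small_n_per_group = as.integer(small_n_per_group),
         family_alpha = family_alpha, roster = roster,
         m_tests = length(roster), seed = as.integer(seed),
         out_dir = out_dir),
    class = "study_config"
  )
}

#' Join a regional table with participant covariates
#'
#' @param regional A [regional_means()]-style table (rows of participant
#'   x region).
#' @param participants Participant table with `id`, `group`, `age`, `bmi`,
#'   `sex`.
#' @return Merged data.frame ready for [fit_ancova()].
#' @export
join_regional <- function(regional, participants) {
  out <- merge(regional, participants[, c("id", "group", "age", "bmi", "sex")],
               by.x = "participant_id", by.y = "id", sort = FALSE)
  out
}

#' Per-region summary statistics by group
#'
#' Mean, standard deviation and standard error (`sd / sqrt(n)`) of the
#' regional mean z-scores in each group x region cell -- the summary the
#' study reports alongside the ANCOVAs.
#'
#' @inheritParams join_regional
#' @return Data.frame with `group`, `region`, `n`, `mean`, `sd`, `se`
#'   (`sd`/`se` are `NA` when `n < 2`).
#' @export
render_regional_summary <- function(regional, participants) {
  dat <- join_regional(regional, participants)
  if (nrow(dat) == 0L) stop("no rows to summarise")
  key <- interaction(dat$group, dat$region, drop = TRUE)
  rows <- lapply(split(dat, key), function(d) {
    n <- sum(!is.na(d$mean_z))
    v <- d$mean_z[!is.na(d$mean_z)]
    s <- if (n >= 2) stats::sd(v) else NA_real_
    data.frame(group = d$group[1], region = d$region[1], n = n,
               mean = if (n > 0) mean(v) else NA_real_,
               sd = s, se = if (n >= 2) s / sqrt(n) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$region, out$group), , drop = FALSE]
}

# per-participant spectral chain: detrend -> periodogram -> fALFF per band
# -> z-score vs reference -> regional means. Returns one table per band.
analyze_participant <- function(ts, rois, bands, participant_id) {
  ps <- periodogram(detrend_linear(ts))
  lapply(bands, function(b) {
    z <- zscore_against_reference(falff(ps, b), rois)
    regional_means(z, rois, participant_id)
  })
}

load_real_inputs <- function(cfg) {
  participants <- read_participants_tsv(cfg$paths$participants)
  rois <- read_roi_nifti(cfg$paths$labels, cfg$paths$roi_sidecar)
  list(participants = participants, rois = rois)
}

real_participant_ts <- function(cfg, id) {
  for (ext in c(".nii.gz", ".nii")) {
    p <- file.path(cfg$paths$bold_dir, paste0(id, ext))
    if (file.exists(p)) return(read_bold_nifti(p))
  }
  stop("no BOLD file for participant ", id, " in ", cfg$paths$bold_dir)
}

#' Run the full fALFF study pipeline
#'
#' Executes the stages in fixed order: obtain the cohort (simulate or read),
#' fit propensity scores and match 1:1, compute each matched participant's
#' fALFF z-score maps and regional means in the broad and narrow bands,
#' fit the three ANCOVAs of the roster (small-sample broad, large-scale
#' broad, large-scale narrow), apply the Bonferroni-corrected threshold
#' `family_alpha / m_tests` to the group and interaction terms, and
#' assemble the balance table and per-region group summaries. All
#' randomness derives from `cfg$seed`, so a rerun with the same config
#' reproduces the report exactly.
#'
#' @param cfg A [study_config()].
#' @return An object of class `study_report`.
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  sim <- cfg$sim
  if (cfg$mode == "synthetic") {
    cohort <- simulate_cohort(sim, seed = cfg$seed)
    participants <- cohort$participants
    rois <- synthetic_rois(sim)
  } else {
    inputs <- load_real_inputs(cfg)
    participants <- inputs$participants
    rois <- inputs$rois
  }

  participants <- match_cohort(fit_propensity(participants))
  balance <- balance_table(participants)
  matched <- participants[participants$matched, , drop = FALSE]
  if (nrow(matched) == 0L) stop("stage 'match' produced no matched participants")

  bands <- list(broad = band_broad(), narrow = band_narrow())
  if (cfg$mode == "synthetic") {
    regional <- simulate_regional_dataset(sim, matched, bands,
                                          seed = cfg$seed + 10000L)
  } else {
    per_band <- list(broad = vector("list", nrow(matched)),
                     narrow = vector("list", nrow(matched)))
    for (i in seq_len(nrow(matched))) {
      id <- matched$id[i]
      tabs <- analyze_participant(real_participant_ts(cfg, id), rois, bands, id)
      per_band$broad[[i]] <- tabs$broad
      per_band$narrow[[i]] <- tabs$narrow
    }
    regional <- lapply(per_band, function(x) do.call(rbind, x))
  }

  keep_regions <- if (cfg$mode == "synthetic") {
    analysis_regions(sim)
  } else {
    setdiff(unname(rois$names),
            c(rois$names[as.character(rois$reference_label)], "csf"))
  }
  ancova_data <- lapply(regional, function(tab) {
    join_regional(tab[tab$region %in% keep_regions, , drop = FALSE], matched)
  })

  # seeded draw of the small-sample subset, per group
  set.seed(cfg$seed + 1L)
  small_ids <- unlist(lapply(split(matched$id, matched$group), function(ids) {
    sample(ids, min(cfg$small_n_per_group, length(ids)))
  }), use.names = FALSE)

  alpha_corr <- bonferroni_alpha(cfg$family_alpha, cfg$m_tests)
  ancovas <- list()
  verdicts <- list()
  for (nm in names(cfg$roster)) {
    spec <- cfg$roster[[nm]]
    band_name <- if (spec$band$f_high > 0.1) "broad" else "narrow"
    dat <- ancova_data[[band_name]]
    if (spec$subset) dat <- dat[dat$participant_id %in% small_ids, , drop = FALSE]
    fit <- fit_ancova(dat)
    ancovas[[nm]] <- fit
    for (term in c("group", "group:region", "region")) {
      p <- fit$table$p[fit$table$term == term]
      verdicts[[length(verdicts) + 1L]] <- data.frame(
        analysis = nm, term = term, p = p,
        significant = p < alpha_corr, stringsAsFactors = FALSE)
    }
  }
  verdicts <- do.call(rbind, verdicts)

  report <- structure(
    list(
      balance = balance,
      participants = participants,
      regional = regional,
      ancovas = ancovas,
      verdicts = verdicts,
      alpha_corrected = alpha_corr,
      regional_summary = render_regional_summary(
        regional$broad[regional$broad$region %in% keep_regions, , drop = FALSE],
        matched),
      config = cfg
    ),
    class = "study_report"
  )
  if (!is.null(cfg$out_dir)) write_study_artifacts(report, cfg$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("==== fALFF study report ====\n")
  print(x$balance)
  cat(sprintf("\nBonferroni-corrected threshold: %.4f (%d tests)\n",
              x$alpha_corrected, x$config$m_tests))
  for (nm in names(x$ancovas)) {
    cat(sprintf("\n-- %s --\n", x$config$roster[[nm]]$label))
    print(x$ancovas[[nm]])
  }
  cat("\nVerdicts at the corrected threshold:\n")
  for (i in seq_len(nrow(x$verdicts))) {
    v <- x$verdicts[i, ]
    cat(sprintf("  %-12s %-14s p = %-10.3g %s\n", v$analysis, v$term, v$p,
                if (v$significant) "significant" else "not significant"))
  }
  invisible(x)
}

#' @export
plot.study_report <- function(x, ...) {
  s <- x$regional_summary
  regions <- unique(s$region)
  xi <- match(s$region, regions) + ifelse(s$group == "hypertensive", -0.12, 0.12)
  col <- ifelse(s$group == "hypertensive", "firebrick", "steelblue")
  graphics::plot(xi, s$mean, pch = 19, col = col, xaxt = "n",
                 xlab = "", ylab = "regional fALFF z-score (mean ± se)",
                 ylim = range(c(s$mean - s$se, s$mean + s$se), na.rm = TRUE), ...)
  graphics::arrows(xi, s$mean - s$se, xi, s$mean + s$se,
                   angle = 90, code = 3, length = 0.02, col = col)
  graphics::axis(1, at = seq_along(regions), labels = regions, las = 2,
                 cex.axis = 0.7)
  graphics::legend("topleft", legend = c("hypertensive", "normotensive"),
                   col = c("firebrick", "steelblue"), pch = 19, bty = "n")
  invisible(x)
}

# write TSV/JSON artifacts and a plain-text report
write_study_artifacts <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_participants_tsv(report$participants,
                         file.path(out_dir, "participants.tsv"))
  for (b in names(report$regional)) {
    utils::write.table(report$regional[[b]],
                       file.path(out_dir, sprintf("regional_%s.tsv", b)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(as.data.frame(report$balance),
                     file.path(out_dir, "balance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$verdicts, file.path(out_dir, "verdicts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(report$ancovas)) {
    utils::write.table(report$ancovas[[nm]]$table,
                       file.path(out_dir, sprintf("ancova_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(report$regional_summary,
                     file.path(out_dir, "regional_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    seed = report$config$seed,
    mode = report$config$mode,
    m_tests = report$config$m_tests,
    family_alpha = report$config$family_alpha,
    alpha_corrected = report$alpha_corrected,
    n_matched = sum(report$participants$matched),
    package_version = as.character(utils::packageVersion("falff")),
    created = "run_study"
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}
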