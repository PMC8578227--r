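# Cohort-level evaluation: the fraction-classified-normal metric, summary
# tables (mean / sd / 2.5% / 97.5% per feature), and the QT/RR association.

#' Fraction of records classified Normal
#'
#' The cohort metric used to rank generator checkpoints: the proportion of
#' records a normality screener labels `normal`.
#'
#' @param verdicts a factor/character vector of labels, or a data frame
#'   with a `label` column (as returned by [screen_normality()]).
#' @return a proportion in `[0, 1]`.
#' @examples
#' fraction_normal(c("normal", "bradycardia", "normal", "tachycardia"))
#' @export
fraction_normal <- function(verdicts) {
  if (is.data.frame(verdicts)) verdicts <- verdicts$label
  if (length(verdicts) == 0) {
    stop("cannot compute the fraction normal of an empty cohort",
         call. = FALSE)
  }
  mean(as.character(verdicts) == "normal")
}

TABLE_FEATURES <- c("heart_rate", "p_duration", "qt_interval",
                    "qrs_duration", "pr_interval", "stj_amplitude_v5",
                    "r_amplitude_v5", "t_amplitude_v5")

#' Summarise a cohort's features
#'
#' Per-feature mean, standard deviation (n-1 denominator) and 2.5% / 97.5%
#' percentiles (linear interpolation between order statistics), the
#' fraction classified normal, and the squared Pearson correlation between
#' per-record QT and RR.
#'
#' @param features tibble from [extract_features()] (or any data frame with
#'   the interval/amplitude columns; a cohort's ground-truth parameter
#'   table also works once columns are named accordingly).
#' @param verdicts optional output of [screen_normality()]; when omitted
#'   and `features` carries a `label` column that is used instead.
#' @param feature_cols columns to tabulate (defaults to the eight standard
#'   interval/amplitude features present in `features`).
#' @return a `cohort_summary`: list with `stats` (tibble: feature, mean,
#'   sd, pct_2_5, pct_97_5, n_missing, flagged), `n`, `fraction_normal`
#'   (or `NA` without verdicts) and `qt_rr_r2`.
#' @export
summarize_cohort <- function(features, verdicts = NULL,
                             feature_cols = NULL) {
  stopifnot(is.data.frame(features), nrow(features) >= 2)
  if (is.null(feature_cols)) {
    feature_cols <- intersect(TABLE_FEATURES, names(features))
  }
  stats_tbl <- dplyr::bind_rows(lapply(feature_cols, function(nm) {
    v <- features[[nm]]
    ok <- v[!is.na(v)]
    flagged <- length(ok) == 0
    if (flagged) {
      tibble::tibble(feature = nm, mean = NA_real_, sd = NA_real_,
                     pct_2_5 = NA_real_, pct_97_5 = NA_real_,
                     n_missing = sum(is.na(v)), flagged = TRUE)
    } else {
      q <- stats::quantile(ok, c(0.025, 0.975), names = FALSE, type = 7)
      tibble::tibble(feature = nm, mean = mean(ok), sd = stats::sd(ok),
                     pct_2_5 = q[1], pct_97_5 = q[2],
                     n_missing = sum(is.na(v)), flagged = FALSE)
    }
  }))
  frac <- if (!is.null(verdicts)) {
    fraction_normal(verdicts)
  } else if ("label" %in% names(features)) {
    fraction_normal(features)
  } else {
    NA_real_
  }
  qt <- features[["qt_interval"]]
  rr <- features[["rr_mean"]] %||% features[["rr_interval"]]
  r2 <- if (!is.null(qt) && !is.null(rr)) {
    cc <- stats::complete.cases(qt, rr)
    if (sum(cc) >= 3 && stats::sd(qt[cc]) > 0 && stats::sd(rr[cc]) > 0) {
      stats::cor(qt[cc], rr[cc])^2
    } else {
      NA_real_
    }
  } else {
    NA_real_
  }
  structure(list(stats = stats_tbl, n = nrow(features),
                 fraction_normal = frac, qt_rr_r2 = r2),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> n = ", x$n, sep = "")
  if (!is.na(x$fraction_normal)) {
    cat(" | fraction normal = ", sprintf("%.3f", x$fraction_normal), sep = "")
  }
  if (!is.na(x$qt_rr_r2)) {
    cat(" | QT/RR r^2 = ", sprintf("%.3f", x$qt_rr_r2), sep = "")
  }
  cat("\n")
  print(x$stats)
  invisible(x)
}

#' Write a cohort summary report
#'
#' A CSV of the per-feature statistics and (optionally) a Markdown table
#' mirroring the conventional cohort-table layout (rows = features,
#' columns = mean / std / 2.5% / 97.5%).
#'
#' @param summary a `cohort_summary`.
#' @param csv_path CSV output path.
#' @param md_path optional Markdown output path.
#' @return the summary, invisibly.
#' @export
write_cohort_report <- function(summary, csv_path, md_path = NULL) {
  stopifnot(inherits(summary, "cohort_summary"))
  utils::write.csv(summary$stats, csv_path, row.names = FALSE)
  if (!is.null(md_path)) {
    s <- summary$stats
    lines <- c(
      sprintf("# Cohort summary (n = %d)", summary$n),
      if (!is.na(summary$fraction_normal))
        sprintf("Fraction classified normal: %.3f", summary$fraction_normal),
      if (!is.na(summary$qt_rr_r2))
        sprintf("QT/RR r^2: %.3f", summary$qt_rr_r2),
      "",
      "| Feature | Mean | Std | 2.5% | 97.5% |",
      "|---|---|---|---|---|",
      sprintf("| %s | %.1f | %.1f | %.1f | %.1f |", s$feature, s$mean,
              s$sd, s$pct_2_5, s$pct_97_5))
    writeLines(lines, md_path)
  }
  invisible(summary)
}

#' Compare generator checkpoints by fraction classified normal
#'
#' For each checkpoint: load the generator, generate `eval_batch_size`
#' records, extract features, screen them, and tabulate the fraction
#' classified normal. The checkpoint with the highest fraction is marked
#' best. An unloadable checkpoint is kept as a failed row and the
#' comparison continues.
#'
#' @param checkpoints a named list whose elements are checkpoint directory
#'   paths (see [save_checkpoint()]), `ecg_generator` objects, or functions
#'   `n -> list of ecg8` (the latter admits replay controls); a character
#'   vector of paths also works.
#' @param eval_batch_size records generated per checkpoint.
#' @param rules screening rules.
#' @return a tibble, one row per checkpoint: `checkpoint`, `status`,
#'   `fraction_normal`, `n_evaluated`, `rank` and `best`, ordered as given.
#' @export
checkpoint_compare <- function(checkpoints, eval_batch_size = 100,
                               rules = normality_rules()) {
  if (!is.list(checkpoints)) checkpoints <- as.list(checkpoints)
  if (length(checkpoints) == 0) {
    stop("need at least one checkpoint", call. = FALSE)
  }
  nms <- names(checkpoints)
  if (is.null(nms)) nms <- rep("", length(checkpoints))
  rows <- lapply(seq_along(checkpoints), function(i) {
    ck <- checkpoints[[i]]
    nm <- if (nzchar(nms[i])) nms[i] else
      if (is.character(ck)) basename(ck) else sprintf("checkpoint_%d", i)
    res <- tryCatch({
      ecgs <- if (is.function(ck)) {
        ck(eval_batch_size)
      } else {
        gen <- if (is.character(ck)) {
          suppressWarnings(load_checkpoint(ck)$generator)
        } else {
          ck
        }
        stopifnot(inherits(gen, "ecg_generator"))
        generate_ecg(gen, eval_batch_size)
      }
      feats <- extract_features(ecgs)
      verd <- screen_normality(feats, rules)
      tibble::tibble(checkpoint = nm, status = "ok",
                     fraction_normal = fraction_normal(verd),
                     n_evaluated = nrow(verd))
    }, error = function(e) {
      tibble::tibble(checkpoint = nm, status = paste0("failed: ",
                                                      conditionMessage(e)),
                     fraction_normal = NA_real_, n_evaluated = 0L)
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  out$rank <- dplyr::min_rank(dplyr::desc(out$fraction_normal))
  out$best <- !is.na(out$fraction_normal) &
    out$fraction_normal == max(out$fraction_normal, na.rm = TRUE)
  out
}
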