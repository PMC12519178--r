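# Pipeline: CSV measurement tables in and structured agreement reports out.
# Two wide CSV schemas are recognized (unit-suffixed column names prevent
# unit drift):
#   raw       pre_max_x1_mm pre_max_x2_mm pre_min_x1_mm pre_min_x2_mm
#             post_max_x1_mm post_max_x2_mm post_min_x1_mm post_min_x2_mm
#   averaged  dmax_mm dmin_mm post_dmax_mm post_dmin_mm
# plus subject_id and an optional group column in either schema.

RAW_COLS <- c("pre_max_x1_mm", "pre_max_x2_mm", "pre_min_x1_mm",
              "pre_min_x2_mm", "post_max_x1_mm", "post_max_x2_mm",
              "post_min_x1_mm", "post_min_x2_mm")
AVG_COLS <- c("dmax_mm", "dmin_mm", "post_dmax_mm", "post_dmin_mm")
REPORT_SCHEMA <- "ivcfit-report/1"

#' Read a diameter measurement table
#'
#' Detects the schema (raw edge pairs or already-averaged diameters) from
#' the header, collapses raw edge pairs with [mean_edge_diameter()],
#' drops rows with missing values (complete-case, counted in a warning),
#' and validates `d_max >= d_min` per stage.
#'
#' @param path Path to a CSV file (UTF-8, header required, "." decimal).
#' @param auto_sort Tolerate rows with `d_max < d_min` by swapping them
#'   (warning) instead of failing.
#' @return A data frame of class `ivc_cohort` with averaged diameter
#'   columns, `subject_id`, and `group` if present. The detected schema is
#'   attached as attribute `"schema"`.
#' @export
read_measurement_table <- function(path, auto_sort = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  schema <- if (all(RAW_COLS %in% names(raw))) "raw"
            else if (all(AVG_COLS %in% names(raw))) "averaged"
            else stop("unrecognized header in ", path, "; expected either the raw ",
                      "schema (", paste(RAW_COLS, collapse = ", "), ") or the ",
                      "averaged schema (", paste(AVG_COLS, collapse = ", "), ")",
                      call. = FALSE)
  if (!"subject_id" %in% names(raw)) {
    raw$subject_id <- sprintf("S%03d", seq_len(nrow(raw)))
  }
  if (anyDuplicated(raw$subject_id)) {
    stop("duplicate subject_id values: ",
         paste(unique(raw$subject_id[duplicated(raw$subject_id)]), collapse = ", "),
         call. = FALSE)
  }
  num_cols <- if (schema == "raw") RAW_COLS else AVG_COLS
  for (cl in num_cols) {
    if (!is.numeric(raw[[cl]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(raw[[cl]]))) &
                   !is.na(raw[[cl]]))[1L]
      stop("non-numeric value in column '", cl, "', row ", bad,
           " ('", raw[[cl]][bad], "')", call. = FALSE)
    }
  }
  complete <- stats::complete.cases(raw[num_cols])
  if (any(!complete)) {
    warning(sum(!complete), " row(s) dropped for missing values (subjects: ",
            paste(raw$subject_id[!complete], collapse = ", "), ")",
            call. = FALSE)
    raw <- raw[complete, , drop = FALSE]
  }
  if (nrow(raw) == 0L) stop("no complete rows left after filtering", call. = FALSE)

  if (schema == "raw") {
    tab <- data.frame(
      subject_id = raw$subject_id,
      dmax_mm = mean_edge_diameter(raw$pre_max_x1_mm, raw$pre_max_x2_mm),
      dmin_mm = mean_edge_diameter(raw$pre_min_x1_mm, raw$pre_min_x2_mm),
      post_dmax_mm = mean_edge_diameter(raw$post_max_x1_mm, raw$post_max_x2_mm),
      post_dmin_mm = mean_edge_diameter(raw$post_min_x1_mm, raw$post_min_x2_mm),
      stringsAsFactors = FALSE
    )
  } else {
    tab <- raw[c("subject_id", AVG_COLS)]
    lapply(AVG_COLS, function(cl) check_positive_finite(tab[[cl]], cl))
  }
  if ("group" %in% names(raw)) tab$group <- raw$group

  for (stage in list(c("dmax_mm", "dmin_mm"), c("post_dmax_mm", "post_dmin_mm"))) {
    swapped <- tab[[stage[1L]]] < tab[[stage[2L]]]
    if (any(swapped)) {
      if (!auto_sort) {
        stop(stage[1L], " < ", stage[2L], " for subject(s) ",
             paste(tab$subject_id[swapped], collapse = ", "),
             "; fix the input or set auto_sort = TRUE", call. = FALSE)
      }
      warning(sum(swapped), " row(s) had ", stage[1L], " < ", stage[2L],
              " and were swapped", call. = FALSE)
      tmp <- tab[[stage[1L]]][swapped]
      tab[[stage[1L]]][swapped] <- tab[[stage[2L]]][swapped]
      tab[[stage[2L]]][swapped] <- tmp
    }
  }
  attr(tab, "schema") <- schema
  class(tab) <- c("ivc_cohort", "data.frame")
  tab
}

#' Write a measurement table as CSV
#'
#' @param table A cohort data frame (e.g. from [simulate_cohort()]).
#' @param path Output CSV path.
#' @param schema `"raw"` writes the eight edge columns, `"averaged"` the
#'   four averaged diameter columns; both include `subject_id` (and
#'   `group` if present).
#' @return `path`, invisibly.
#' @export
write_measurement_table <- function(table, path,
                                    schema = c("averaged", "raw")) {
  schema <- match.arg(schema)
  cols <- c("subject_id", if (schema == "raw") RAW_COLS else AVG_COLS)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols) > 0L) {
    stop("table lacks column(s) required by the '", schema, "' schema: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if ("group" %in% names(table)) cols <- c(cols, "group")
  utils::write.csv(table[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full agreement analysis on a measurement table
#'
#' Computes per-subject equivalent diameters, the cohort summary, the
#' seven-pair agreement matrix (each pre-placement predictor and the
#' predicted equivalent diameter against each post-placement diameter,
#' plus post-max vs post-min), the five dependent-CCC comparisons, and
#' paired t tests of the predicted diameter against each post-placement
#' diameter.
#'
#' @param table Measurement table (class `ivc_cohort` or a data frame with
#'   the averaged columns).
#' @param seed Integer seed for the bootstrap comparisons.
#' @param n_boot Bootstrap resamples per comparison.
#' @param level Confidence level for all intervals.
#' @return An object of class `ivc_report` (a nested list): `subjects`,
#'   `summary`, `agreement`, `comparisons`, `t_tests`, `metadata`.
#'   Degenerate statistics (e.g. a CCC of exactly 1, whose interval is
#'   undefined) appear as entries with a `note` field, never silently
#'   dropped.
#' @export
run_analysis <- function(table, seed = 1L, n_boot = 2000, level = 0.95) {
  if (!is.data.frame(table)) stop("'table' must be a data frame", call. = FALSE)
  missing_cols <- setdiff(AVG_COLS, names(table))
  if (length(missing_cols) > 0L) {
    stop("table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(table)
  if (n < 3L) stop("need at least 3 subjects, got ", n, call. = FALSE)
  if (!"subject_id" %in% names(table)) {
    table$subject_id <- sprintf("S%03d", seq_len(n))
  }

  pred <- predict_equivalent_diameter(table$dmax_mm, table$dmin_mm)
  subjects <- data.frame(
    subject_id = table$subject_id,
    dmax_mm = table$dmax_mm, dmin_mm = table$dmin_mm,
    deq_mm = pred$d_eq,
    post_dmax_mm = table$post_dmax_mm, post_dmin_mm = table$post_dmin_mm,
    stringsAsFactors = FALSE
  )
  if ("group" %in% names(table)) subjects$group <- table$group

  vars <- list(dmax = subjects$dmax_mm, dmin = subjects$dmin_mm,
               deq = subjects$deq_mm, post_dmax = subjects$post_dmax_mm,
               post_dmin = subjects$post_dmin_mm)
  pairs <- list(
    c("dmax", "post_dmax"), c("dmax", "post_dmin"),
    c("dmin", "post_dmax"), c("dmin", "post_dmin"),
    c("deq", "post_dmax"), c("deq", "post_dmin"),
    c("post_dmax", "post_dmin")
  )
  agreement <- lapply(pairs, function(p) {
    entry <- list(x = p[1L], y = p[2L])
    res <- tryCatch(
      ccc_confidence_interval(vars[[p[1L]]], vars[[p[2L]]], level = level),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      ccc_pt <- tryCatch(lin_ccc(vars[[p[1L]]], vars[[p[2L]]]),
                         error = function(e) NA_real_)
      warning("agreement pair ", p[1L], " vs ", p[2L], " is degenerate: ",
              conditionMessage(res), call. = FALSE)
      c(entry, list(ccc = ccc_pt, ci_low = NA_real_, ci_high = NA_real_,
                    pearson = NA_real_, n = n,
                    agreement_class = if (is.na(ccc_pt)) NA_character_
                                      else classify_agreement(ccc_pt),
                    note = conditionMessage(res)))
    } else {
      c(entry, unclass(res)[c("ccc", "ci_low", "ci_high", "pearson", "n",
                              "agreement_class")])
    }
  })

  comps <- list(
    list(common = "post_dmax", a = "deq", b = "dmax"),
    list(common = "post_dmax", a = "deq", b = "dmin"),
    list(common = "post_dmin", a = "deq", b = "dmax"),
    list(common = "post_dmin", a = "deq", b = "dmin"),
    list(common = "deq", a = "post_dmax", b = "post_dmin")
  )
  comparisons <- lapply(seq_along(comps), function(i) {
    cp <- comps[[i]]
    res <- tryCatch(
      compare_dependent_ccc(vars[[cp$common]], vars[[cp$a]], vars[[cp$b]],
                            n_boot = n_boot, seed = seed + i, level = level),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      warning("CCC comparison ", cp$a, " vs ", cp$b, " (common ", cp$common,
              ") is degenerate: ", conditionMessage(res), call. = FALSE)
      c(cp, list(note = conditionMessage(res)))
    } else {
      c(cp, unclass(res)[c("ccc_a", "ccc_b", "delta", "ci_low", "ci_high",
                           "p_value", "n", "n_boot", "seed")],
        list(fisher_z_statistic = res$fisher_z$statistic,
             fisher_z_p_value = res$fisher_z$p_value))
    }
  })

  tpairs <- list(c("deq", "post_dmax"), c("deq", "post_dmin"),
                 c("post_dmax", "post_dmin"))
  t_tests <- lapply(tpairs, function(p) {
    res <- tryCatch(mean_diff_test(vars[[p[1L]]], vars[[p[2L]]], paired = TRUE),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("t test ", p[1L], " vs ", p[2L], " is degenerate: ",
              conditionMessage(res), call. = FALSE)
      list(x = p[1L], y = p[2L], note = conditionMessage(res))
    } else {
      c(list(x = p[1L], y = p[2L]), unclass(res))
    }
  })

  grp <- if ("group" %in% names(subjects)) subjects$group else NULL
  summary_tab <- summarize_cohort(subjects, group = grp)

  report <- list(
    schema = REPORT_SCHEMA,
    subjects = subjects,
    summary = summary_tab,
    agreement = agreement,
    comparisons = comparisons,
    t_tests = t_tests,
    metadata = list(n = n, seed = seed, n_boot = n_boot, level = level,
                    version = as.character(utils::packageVersion("ivcfit")))
  )
  class(report) <- "ivc_report"
  report
}

#' Flatten the agreement matrix of a report into a data frame
#'
#' @param report An `ivc_report`.
#' @return One row per agreement pair: `x`, `y`, `ccc`, `ci_low`,
#'   `ci_high`, `pearson`, `n`, `agreement_class`, `note`.
#' @export
agreement_table <- function(report) {
  stopifnot(inherits(report, "ivc_report"))
  do.call(rbind, lapply(report$agreement, function(a) {
    data.frame(x = a$x, y = a$y,
               ccc = a$ccc %||% NA_real_,
               ci_low = a$ci_low %||% NA_real_,
               ci_high = a$ci_high %||% NA_real_,
               pearson = a$pearson %||% NA_real_,
               n = a$n,
               agreement_class = a$agreement_class %||% NA_character_,
               note = a$note %||% "",
               stringsAsFactors = FALSE)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render an analysis report
#'
#' JSON is the canonical, lossless format; CSV renders the agreement
#' matrix (one row per pair); text is a human-readable summary with the
#' agreement classes spelled out. Output is deterministic for a given
#' report; a timestamp is added only with `stable = FALSE`.
#'
#' @param report An `ivc_report`.
#' @param format `"json"`, `"csv"`, or `"text"`.
#' @param path Output file; if `NULL` the rendering is returned as a
#'   character string.
#' @param stable Omit the timestamp so identical reports render to
#'   byte-identical files (default `TRUE`).
#' @return The rendered string (invisibly when written to `path`).
#' @export
render_report <- function(report, format = c("json", "csv", "text"),
                          path = NULL, stable = TRUE) {
  stopifnot(inherits(report, "ivc_report"))
  format <- match.arg(format)
  out <- switch(format,
    json = {
      obj <- unclass(report)
      if (!stable) obj$metadata$timestamp <- format(Sys.time(), tz = "UTC")
      jsonlite::toJSON(obj, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE, null = "null")
    },
    csv = {
      tc <- textConnection("csv_out", "w", local = TRUE)
      utils::write.csv(agreement_table(report), tc, row.names = FALSE)
      close(tc)
      paste0(paste(csv_out, collapse = "\n"), "\n")
    },
    text = render_text_report(report)
  )
  out <- as.character(out)
  if (!is.null(path)) {
    ok <- tryCatch({ writeLines(out, path, sep = ""); TRUE },
                   error = function(e) {
                     stop("cannot write report to '", path, "': ",
                          conditionMessage(e), call. = FALSE)
                   })
    return(invisible(out))
  }
  out
}

render_text_report <- function(report) {
  fmt <- function(v) sprintf("%.2f", v)
  lines <- c(
    "IVC equivalent-diameter analysis",
    sprintf("subjects: %d   seed: %d   bootstrap resamples: %d",
            report$metadata$n, report$metadata$seed, report$metadata$n_boot),
    "",
    "Cohort summary (mm, mean +/- SD):"
  )
  s <- report$summary
  lines <- c(lines, sprintf("  %-13s %s +/- %s", s$variable, fmt(s$mean), fmt(s$sd)))
  lines <- c(lines, "", sprintf(
    "Agreement (Lin's CCC, %d%% CI; poor <=0.40 < fair to good <=0.75 < excellent):",
    round(100 * report$metadata$level)))
  for (a in report$agreement) {
    if (!is.null(a$note)) {
      lines <- c(lines, sprintf("  %-10s vs %-10s CCC = %s  [%s]", a$x, a$y,
                                if (is.na(a$ccc)) "undefined" else fmt(a$ccc),
                                a$note))
    } else {
      lines <- c(lines, sprintf("  %-10s vs %-10s CCC = %.3f (%.3f-%.3f)  %s",
                                a$x, a$y, a$ccc, a$ci_low, a$ci_high,
                                a$agreement_class))
    }
  }
  lines <- c(lines, "", "CCC comparisons (delta = CCC(a,common) - CCC(b,common)):")
  for (cp in report$comparisons) {
    if (!is.null(cp$note)) {
      lines <- c(lines, sprintf("  %s vs %s on %s: degenerate [%s]",
                                cp$a, cp$b, cp$common, cp$note))
    } else {
      lines <- c(lines, sprintf(
        "  %s vs %s on %s: delta = %.3f (%.3f-%.3f), p = %.4g",
        cp$a, cp$b, cp$common, cp$delta, cp$ci_low, cp$ci_high, cp$p_value))
    }
  }
  lines <- c(lines, "", "Paired t tests:")
  for (tt in report$t_tests) {
    if (!is.null(tt$note)) {
      lines <- c(lines, sprintf("  %s vs %s: degenerate [%s]", tt$x, tt$y, tt$note))
    } else {
      lines <- c(lines, sprintf("  %s vs %s: t = %.3f, df = %g, p = %.4g",
                                tt$x, tt$y, tt$t_statistic, tt$df, tt$p_value))
    }
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @export
print.ivc_report <- function(x, ...) {
  cat(render_text_report(x))
  invisible(x)
}

#' Load a JSON report back into an `ivc_report`
#'
#' @param path Path to a JSON file written by [render_report()].
#' @return The deserialized `ivc_report`.
#' @export
load_report <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyVector = TRUE)
  if (!identical(obj$schema, REPORT_SCHEMA)) {
    stop("not an ivcfit report (schema tag '", obj$schema %||% "missing",
         "', expected '", REPORT_SCHEMA, "')", call. = FALSE)
  }
  obj$subjects <- as.data.frame(obj$subjects, stringsAsFactors = FALSE)
  obj$summary <- as.data.frame(obj$summary, stringsAsFactors = FALSE)
  class(obj) <- "ivc_report"
  obj
}

#' Paired pre/post diameter plot
#'
#' Distribution-plus-points view of the predicted equivalent diameter
#' against the measured post-placement diameters, in the spirit of a
#' raincloud plot. Requires ggplot2; plotting is optional and never
#' affects the analysis.
#'
#' @param report An `ivc_report`.
#' @return A ggplot object.
#' @export
plot_paired_diameters <- function(report) {
  stopifnot(inherits(report, "ivc_report"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the 'ggplot2' package", call. = FALSE)
  }
  s <- report$subjects
  long <- data.frame(
    variable = rep(c("D_eq (predicted)", "post D_max", "post D_min"),
                   each = nrow(s)),
    diameter_mm = c(s$deq_mm, s$post_dmax_mm, s$post_dmin_mm)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$variable, y = .data$diameter_mm)) +
    ggplot2::geom_violin(fill = "grey85", colour = NA) +
    ggplot2::geom_boxplot(width = 0.15, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL, y = "Diameter (mm)") +
    ggplot2::theme_minimal()
}
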