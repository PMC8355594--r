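#' Injection schedule for a mito stress test
#'
#' Defines which kinetic measurement indices belong to which assay phase.
#' The canonical protocol measures a baseline, then injects oligomycin
#' (ATP-synthase inhibitor), FCCP (uncoupler; the two sequential FCCP
#' injections form a single phase), and finally rotenone/antimycin A,
#' which abolishes mitochondrial respiration and leaves the
#' non-mitochondrial OCR floor.
#'
#' @param baseline,oligomycin,fccp,rot_aa First measurement index of each
#'   phase. Baseline must start at measurement 1 and indices must be
#'   strictly increasing.
#' @param concentrations Optional named character vector of compound
#'   concentrations (e.g. `c(oligomycin = "2 uM")`), carried as metadata.
#' @return An `injection_schedule` object (a tibble with columns `phase`
#'   and `first_index`).
#' @examples
#' injection_schedule() # default 3 measurements per phase
#' @export
injection_schedule <- function(baseline = 1L, oligomycin = 4L, fccp = 7L,
                               rot_aa = 10L, concentrations = NULL) {
  idx <- c(baseline = baseline, oligomycin = oligomycin,
           fccp = fccp, rot_aa = rot_aa)
  if (any(idx != round(idx)) || any(idx < 1)) {
    stop("Schedule indices must be positive integers.", call. = FALSE)
  }
  if (idx[["baseline"]] != 1L) {
    stop("The baseline phase must start at measurement 1.", call. = FALSE)
  }
  if (any(diff(idx) <= 0)) {
    stop("Phase start indices must be strictly increasing in the order ",
         "baseline < oligomycin < FCCP < rot_aa.", call. = FALSE)
  }
  out <- tibble::tibble(
    phase = factor(flux_phases(), levels = flux_phases()),
    first_index = as.integer(idx)
  )
  attr(out, "concentrations") <- concentrations
  class(out) <- c("injection_schedule", class(out))
  out
}

flux_phases <- function() c("baseline", "oligomycin", "FCCP", "rot_aa")

#' Read an injection schedule from a YAML run config
#'
#' Expects a top-level `schedule` mapping of phase label to first
#' measurement index, e.g. `schedule: {baseline: 1, oligomycin: 4, fccp: 7,
#' rot_aa: 10}`, with an optional `concentrations` mapping.
#'
#' @param path Path to a YAML file.
#' @return An [injection_schedule()].
#' @export
read_schedule <- function(path) {
  cfg <- yaml::read_yaml(path)
  sched <- cfg$schedule %||% cfg
  need <- c("baseline", "oligomycin", "fccp", "rot_aa")
  missing <- setdiff(need, tolower(names(sched)))
  if (length(missing) > 0) {
    stop("Schedule config missing phase(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  names(sched) <- tolower(names(sched))
  conc <- cfg$concentrations
  injection_schedule(
    baseline = sched$baseline, oligomycin = sched$oligomycin,
    fccp = sched$fccp, rot_aa = sched$rot_aa,
    concentrations = if (is.null(conc)) NULL else unlist(conc)
  )
}

new_flux_traces <- function(records, cell_counts = NULL, normalized = FALSE,
                            schedule = NULL) {
  out <- dplyr::arrange(records, .data$well, .data$measurement)
  attr(out, "cell_counts") <- cell_counts
  attr(out, "normalized") <- normalized
  attr(out, "schedule") <- schedule
  class(out) <- c("flux_traces", setdiff(class(out), "flux_traces"))
  out
}

validate_flux_records <- function(records) {
  split_wells <- split(records, records$well)
  for (w in names(split_wells)) {
    d <- split_wells[[w]]
    m <- sort(d$measurement)
    if (!identical(as.integer(m), seq_len(nrow(d)))) {
      stop("Well ", w, ": measurement indices are not contiguous from 1.",
           call. = FALSE)
    }
    tt <- d$time_min[order(d$measurement)]
    if (any(diff(tt) <= 0)) {
      stop("Well ", w, ": time_min must be strictly increasing.",
           call. = FALSE)
    }
    if (dplyr::n_distinct(d$group) != 1) {
      stop("Well ", w, ": multiple group labels for one well.", call. = FALSE)
    }
  }
  invisible(records)
}

#' Read a long-format extracellular-flux trace table
#'
#' Parses the delimited export dialect used throughout this package:
#' one row per (well, measurement) with columns `well`, `group`,
#' `experiment`, `measurement`, `time_min`, `OCR`, `ECAR`. Row order in the
#' file is irrelevant; traces are canonically sorted by well and
#' measurement index.
#'
#' @param path Path to a CSV file.
#' @param schedule An [injection_schedule()] attached to the result (phases
#'   are assigned later by [assign_phases()]).
#' @param cell_counts Optional path to a CSV with columns `well`, `cells`,
#'   or a data frame of the same shape.
#' @return A `flux_traces` tibble.
#' @export
read_flux_table <- function(path, schedule = injection_schedule(),
                            cell_counts = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("well", "group", "experiment", "measurement", "time_min",
            "OCR", "ECAR")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("Flux table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  records <- tibble::tibble(
    well = as.character(raw$well),
    group = as.character(raw$group),
    experiment = as.character(raw$experiment),
    measurement = as.integer(raw$measurement),
    time_min = as.numeric(raw$time_min),
    ocr = as.numeric(raw$OCR),
    ecar = as.numeric(raw$ECAR)
  )
  validate_flux_records(records)
  counts <- NULL
  if (!is.null(cell_counts)) {
    counts <- if (is.character(cell_counts)) {
      readr::read_csv(cell_counts, show_col_types = FALSE, progress = FALSE)
    } else {
      tibble::as_tibble(cell_counts)
    }
    if (!all(c("well", "cells") %in% names(counts))) {
      stop("Cell-count table needs columns `well` and `cells`.", call. = FALSE)
    }
    counts <- dplyr::select(counts, "well", "cells")
    counts$well <- as.character(counts$well)
  }
  new_flux_traces(records, cell_counts = counts, schedule = schedule)
}

#' Build a flux trace set from in-memory records
#'
#' @param records Data frame with columns `well`, `group`, `experiment`,
#'   `measurement`, `time_min`, `ocr`, `ecar`.
#' @param cell_counts Optional data frame with columns `well`, `cells`.
#' @param schedule An [injection_schedule()].
#' @param normalized Whether the rates are already per-cell normalized.
#' @return A `flux_traces` tibble.
#' @export
flux_traces <- function(records, cell_counts = NULL,
                        schedule = injection_schedule(), normalized = FALSE) {
  records <- tibble::as_tibble(records)
  need <- c("well", "group", "experiment", "measurement", "time_min",
            "ocr", "ecar")
  missing <- setdiff(need, names(records))
  if (length(missing) > 0) {
    stop("Records are missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  records$well <- as.character(records$well)
  records$measurement <- as.integer(records$measurement)
  validate_flux_records(records)
  if (!is.null(cell_counts)) {
    cell_counts <- tibble::as_tibble(cell_counts)
    cell_counts$well <- as.character(cell_counts$well)
  }
  new_flux_traces(records, cell_counts = cell_counts, schedule = schedule,
                  normalized = normalized)
}

#' Normalize flux rates to cell number per well
#'
#' Divides OCR and ECAR in every well by `cells / unit_cells`, so rates are
#' expressed per `unit_cells` cells (per 1000 by default). Normalizing an
#' already-normalized trace set is refused rather than silently repeated.
#'
#' @param traces A `flux_traces` object.
#' @param cell_counts Data frame with columns `well`, `cells`; defaults to
#'   the counts attached to `traces`.
#' @param unit_cells Reference cell number for the output scale.
#' @return A normalized `flux_traces` tibble.
#' @export
normalize_per_well <- function(traces, cell_counts = NULL, unit_cells = 1000) {
  stopifnot(inherits(traces, "flux_traces"))
  if (isTRUE(attr(traces, "normalized"))) {
    stop("Traces are already normalized; refusing to normalize twice.",
         call. = FALSE)
  }
  counts <- cell_counts %||% attr(traces, "cell_counts")
  if (is.null(counts)) {
    stop("No cell counts supplied or attached to the trace set.",
         call. = FALSE)
  }
  counts <- tibble::as_tibble(counts)
  counts$well <- as.character(counts$well)
  wells <- unique(traces$well)
  missing <- setdiff(wells, counts$well)
  if (length(missing) > 0) {
    stop("Missing cell count for well(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(counts$cells <= 0)) {
    stop("Cell counts must be positive.", call. = FALSE)
  }
  scaled <- traces |>
    dplyr::left_join(dplyr::select(counts, "well", "cells"), by = "well") |>
    dplyr::mutate(
      ocr = .data$ocr / (.data$cells / unit_cells),
      ecar = .data$ecar / (.data$cells / unit_cells)
    ) |>
    dplyr::select(-"cells")
  out <- new_flux_traces(scaled, cell_counts = counts, normalized = TRUE,
                         schedule = attr(traces, "schedule"))
  attr(out, "unit_cells") <- unit_cells
  out
}

#' Assign injection phases to every measurement
#'
#' Labels each record `baseline`, `oligomycin`, `FCCP` or `rot_aa` from the
#' schedule's first-measurement indices. Both FCCP injections fall into the
#' single FCCP phase.
#'
#' @param traces A `flux_traces` object.
#' @param schedule An [injection_schedule()]; defaults to the one attached
#'   to `traces`.
#' @return `traces` with an added `phase` factor column.
#' @export
assign_phases <- function(traces, schedule = NULL) {
  stopifnot(inherits(traces, "flux_traces"))
  schedule <- schedule %||% attr(traces, "schedule")
  if (is.null(schedule)) stop("No injection schedule available.", call. = FALSE)
  max_meas <- max(traces$measurement)
  if (max(schedule$first_index) > max_meas) {
    stop("Schedule index ", max(schedule$first_index),
         " exceeds the last measurement (", max_meas, ").", call. = FALSE)
  }
  breaks <- c(schedule$first_index, max_meas + 1L)
  phase <- cut(traces$measurement, breaks = breaks, right = FALSE,
               labels = flux_phases())
  out <- traces
  out$phase <- phase
  attr(out, "schedule") <- schedule
  out
}

#' Derived bioenergetic metrics per well
#'
#' For each well: baseline OCR/ECAR are aggregated over the baseline phase
#' (mean by default, or the last pre-injection measurement), the rotenone/
#' antimycin (non-mitochondrial) OCR floor is the mean over the rot_aa
#' phase, and the maximum OCR is the single largest post-FCCP measurement.
#' The derived metrics are
#' basal ECAR = baseline ECAR; basal OCR = baseline OCR minus the Rot/AA
#' floor; maximal OCR = maximum OCR minus the Rot/AA floor; spare
#' respiratory capacity (SRC) = maximal minus basal OCR; OCR/ECAR ratio =
#' basal OCR over basal ECAR. Negative basal or maximal OCR values are
#' returned with a quality flag rather than clipped, because silent
#' clipping would bias group means.
#'
#' @param traces A `flux_traces` object with phases assigned (or a schedule
#'   available so phases can be assigned here).
#' @param baseline_mode `"mean"` of all baseline measurements (default) or
#'   `"last"` pre-injection measurement.
#' @param exclude_first_post_injection Drop the first measurement of every
#'   post-injection phase to discard mixing transients (default `FALSE`).
#' @return A `flux_metrics` tibble: one row per well with columns `well`,
#'   `group`, `experiment`, `basal_ecar`, `basal_ocr`, `maximal_ocr`,
#'   `src`, `ocr_ecar_ratio`, `flags`.
#' @export
compute_well_metrics <- function(traces,
                                 baseline_mode = c("mean", "last"),
                                 exclude_first_post_injection = FALSE) {
  stopifnot(inherits(traces, "flux_traces"))
  baseline_mode <- match.arg(baseline_mode)
  if (!"phase" %in% names(traces)) traces <- assign_phases(traces)
  schedule <- attr(traces, "schedule")

  usable <- traces
  if (exclude_first_post_injection) {
    firsts <- schedule$first_index[schedule$phase != "baseline"]
    usable <- dplyr::filter(usable, !(.data$measurement %in% firsts))
  }

  per_well <- function(d) {
    w <- d$well[1]
    vals <- split(d, d$phase)
    for (ph in flux_phases()) {
      if (is.null(vals[[ph]]) || nrow(vals[[ph]]) == 0) {
        stop("Well ", w, ": no usable measurements in phase ", ph, ".",
             call. = FALSE)
      }
    }
    base <- vals[["baseline"]]
    baseline_ocr <- switch(baseline_mode,
      mean = mean(base$ocr),
      last = base$ocr[which.max(base$measurement)]
    )
    baseline_ecar <- switch(baseline_mode,
      mean = mean(base$ecar),
      last = base$ecar[which.max(base$measurement)]
    )
    rotaa_ocr <- mean(vals[["rot_aa"]]$ocr)
    max_ocr <- max(vals[["FCCP"]]$ocr)

    basal_ocr <- baseline_ocr - rotaa_ocr
    maximal_ocr <- max_ocr - rotaa_ocr
    src <- maximal_ocr - basal_ocr
    ratio <- if (baseline_ecar != 0) basal_ocr / baseline_ecar else NA_real_

    flags <- character(0)
    if (basal_ocr < 0) flags <- c(flags, "negative_basal_ocr")
    if (maximal_ocr < 0) flags <- c(flags, "negative_maximal_ocr")
    if (baseline_ecar == 0) flags <- c(flags, "zero_basal_ecar")

    tibble::tibble(
      well = w, group = d$group[1], experiment = d$experiment[1],
      basal_ecar = baseline_ecar, basal_ocr = basal_ocr,
      maximal_ocr = maximal_ocr, src = src, ocr_ecar_ratio = ratio,
      flags = paste(flags, collapse = ";")
    )
  }

  out <- usable |>
    dplyr::group_split(.data$well) |>
    purrr::map(per_well) |>
    purrr::list_rbind()
  attr(out, "normalized") <- isTRUE(attr(traces, "normalized"))
  attr(out, "baseline_mode") <- baseline_mode
  class(out) <- c("flux_metrics", class(out))
  out
}

#' Per-group mean and standard deviation of each metric
#'
#' Sample standard deviation uses the n - 1 denominator; groups with a
#' single well report `sd = NA` (undefined), not zero.
#'
#' @param metrics A `flux_metrics` tibble from [compute_well_metrics()].
#' @return A long tibble with columns `group`, `metric`, `mean`, `sd`, `n`.
#' @export
summarize_groups <- function(metrics) {
  stopifnot(is.data.frame(metrics))
  value_cols <- intersect(
    c("basal_ecar", "basal_ocr", "maximal_ocr", "src", "ocr_ecar_ratio"),
    names(metrics)
  )
  metrics |>
    tidyr::pivot_longer(dplyr::all_of(value_cols),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$group, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) stats::sd(.data$value) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Pairwise group comparisons of flux metrics
#'
#' Two-tailed unpaired t test per metric and group pair (Welch by default),
#' with Benjamini-Hochberg adjustment across the whole family of
#' comparisons submitted in this one call. The caller controls family
#' scope by what it passes in together.
#'
#' @param metrics A `flux_metrics` tibble from [compute_well_metrics()].
#' @param pairs List of length-2 character vectors of group labels; default
#'   all unordered group pairs.
#' @param metric_names Metrics to compare; default all present.
#' @param variant `"welch"` or `"student"`, passed to [two_sample_t()].
#' @return A tibble with one row per (metric, pair): group means, sds, ns,
#'   `t`, `df`, `p`, `p_adj`.
#' @export
compare_groups <- function(metrics, pairs = NULL, metric_names = NULL,
                           variant = c("welch", "student")) {
  variant <- match.arg(variant)
  metric_names <- metric_names %||% intersect(
    c("basal_ecar", "basal_ocr", "maximal_ocr", "src", "ocr_ecar_ratio"),
    names(metrics)
  )
  groups <- unique(metrics$group)
  if (is.null(pairs)) {
    pairs <- utils::combn(groups, 2, simplify = FALSE)
  }
  rows <- list()
  for (m in metric_names) {
    for (pr in pairs) {
      a <- metrics[[m]][metrics$group == pr[1]]
      b <- metrics[[m]][metrics$group == pr[2]]
      if (length(a) < 2 || length(b) < 2) {
        stop("Group ", pr[which(c(length(a), length(b)) < 2)[1]],
             " has fewer than 2 observations for metric ", m, ".",
             call. = FALSE)
      }
      tt <- two_sample_t(a, b, variant = variant)
      rows[[length(rows) + 1]] <- tibble::tibble(
        metric = m, group_a = pr[1], group_b = pr[2],
        mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
        mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
        t = tt$t, df = tt$df, p = tt$p
      )
    }
  }
  out <- purrr::list_rbind(rows)
  out$p_adj <- bh_adjust(out$p)
  class(out) <- c("flux_comparison", class(out))
  out
}
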