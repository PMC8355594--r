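#' Configuration for the flux-plate simulator
#'
#' Each group (population) is defined by the phase levels of an idealized
#' mito stress test on the per-1000-cell scale: a baseline OCR level, a
#' non-mitochondrial OCR floor (the rotenone/antimycin residual), the
#' fraction of mitochondrial OCR remaining under oligomycin, the fold by
#' which FCCP raises mitochondrial OCR above baseline, a basal ECAR level
#' and the ECAR fold after oligomycin. With `fccp_fold >= 1` the true
#' spare respiratory capacity is guaranteed nonnegative.
#'
#' @param groups Tibble with columns `group`, `ocr_baseline`,
#'   `ocr_nonmito`, `oligo_fraction`, `fccp_fold`, `ecar_basal`,
#'   `ecar_oligo_fold`.
#' @param wells_per_group Technical replicate wells per group (default 4).
#' @param meas_per_phase Measurements per injection phase (default 3).
#' @param noise_sd Additive Gaussian noise per measurement; a single
#'   absolute value, or a fraction of the group's baseline level if
#'   `noise_relative = TRUE`.
#' @param noise_relative Interpret `noise_sd` as a fraction of
#'   `ocr_baseline` (ECAR noise scales with `ecar_basal`).
#' @param transient_magnitude Fractional overshoot applied to the first
#'   measurement after each injection (mixing transient); default 0 (off).
#' @param cell_count_mean,cell_count_sd Per-well cell counts drawn
#'   Normal(mean, sd), rounded, floored at 1000.
#' @return A `flux_sim_config` list.
#' @export
flux_sim_config <- function(groups,
                            wells_per_group = 4,
                            meas_per_phase = 3,
                            noise_sd = 0,
                            noise_relative = FALSE,
                            transient_magnitude = 0,
                            cell_count_mean = 60000,
                            cell_count_sd = 5000) {
  groups <- tibble::as_tibble(groups)
  need <- c("group", "ocr_baseline", "ocr_nonmito", "oligo_fraction",
            "fccp_fold", "ecar_basal", "ecar_oligo_fold")
  missing <- setdiff(need, names(groups))
  if (length(missing) > 0) {
    stop("`groups` missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(groups$ocr_baseline <= 0)) stop("ocr_baseline must be > 0.", call. = FALSE)
  if (any(groups$ocr_nonmito <= 0)) stop("ocr_nonmito must be > 0.", call. = FALSE)
  if (any(groups$ocr_nonmito >= groups$ocr_baseline)) {
    stop("ocr_nonmito must be below ocr_baseline.", call. = FALSE)
  }
  if (any(groups$oligo_fraction <= 0 | groups$oligo_fraction >= 1)) {
    stop("oligo_fraction must lie in (0, 1).", call. = FALSE)
  }
  if (any(groups$fccp_fold < 1)) stop("fccp_fold must be >= 1.", call. = FALSE)
  if (any(groups$ecar_basal <= 0)) stop("ecar_basal must be > 0.", call. = FALSE)
  if (wells_per_group < 1) stop("wells_per_group must be >= 1.", call. = FALSE)
  if (meas_per_phase < 1) stop("meas_per_phase must be >= 1.", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0.", call. = FALSE)
  if (cell_count_mean <= 0) stop("cell_count_mean must be > 0.", call. = FALSE)
  structure(
    list(groups = groups, wells_per_group = wells_per_group,
         meas_per_phase = meas_per_phase, noise_sd = noise_sd,
         noise_relative = noise_relative,
         transient_magnitude = transient_magnitude,
         cell_count_mean = cell_count_mean, cell_count_sd = cell_count_sd),
    class = "flux_sim_config"
  )
}

#' A default thymocyte-like flux configuration
#'
#' Qualitative stage profile used throughout the examples and tests:
#' metabolic activity highest in the DN and ISP populations, minimal at
#' DP early, partially recovered in the SP populations.
#'
#' @param populations Which populations to include (default the thymus
#'   correlation set).
#' @param ... Passed on to [flux_sim_config()].
#' @return A `flux_sim_config`.
#' @export
flux_sim_config_thymus <- function(populations = c("DN", "ISP8", "DP early",
                                                   "SP8", "SP4"), ...) {
  profile <- tibble::tibble(
    group = c("DN", "ISP8", "DP early", "DP late", "SP8", "SP4"),
    ocr_baseline = c(100, 90, 22, 30, 60, 45),
    ocr_nonmito = c(10, 10, 8, 8, 9, 9),
    oligo_fraction = c(0.25, 0.25, 0.3, 0.3, 0.25, 0.25),
    fccp_fold = c(2.4, 1.7, 1.05, 1.15, 1.6, 1.5),
    ecar_basal = c(28, 26, 7, 9, 18, 13),
    ecar_oligo_fold = c(1.5, 1.5, 1.3, 1.3, 1.4, 1.4)
  )
  missing <- setdiff(populations, profile$group)
  if (length(missing) > 0) {
    stop("No default profile for population(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  groups <- profile[match(populations, profile$group), ]
  flux_sim_config(groups, ...)
}

sim_truth_metrics <- function(groups) {
  tibble::tibble(
    group = groups$group,
    basal_ecar = groups$ecar_basal,
    basal_ocr = groups$ocr_baseline - groups$ocr_nonmito,
    maximal_ocr = groups$fccp_fold *
      (groups$ocr_baseline - groups$ocr_nonmito),
    src = (groups$fccp_fold - 1) *
      (groups$ocr_baseline - groups$ocr_nonmito),
    ocr_ecar_ratio = (groups$ocr_baseline - groups$ocr_nonmito) /
      groups$ecar_basal
  )
}

#' Simulate a mito-stress-test plate with known ground truth
#'
#' Builds per-well OCR/ECAR kinetic traces on the per-1000-cell scale
#' (phase level + optional first-measurement mixing transient + i.i.d.
#' Gaussian noise), then multiplies each well's rates by its drawn cell
#' count over 1000 so that [normalize_per_well()] is exercised on the way
#' back. Ground-truth metrics are returned on the normalized scale.
#' Identical seeds give identical output.
#'
#' @param config A [flux_sim_config()].
#' @param seed Integer seed.
#' @return List with `traces` (an unnormalized `flux_traces` with attached
#'   cell counts and schedule) and `truth` (per-group `FluxMetrics`
#'   ground-truth tibble).
#' @export
simulate_flux_plate <- function(config, seed = 1L) {
  stopifnot(inherits(config, "flux_sim_config"))
  set.seed(seed)
  g <- config$groups
  mpp <- config$meas_per_phase
  n_meas <- 4 * mpp
  sched <- injection_schedule(
    baseline = 1L, oligomycin = mpp + 1L, fccp = 2L * mpp + 1L,
    rot_aa = 3L * mpp + 1L
  )
  phase_of <- rep(flux_phases(), each = mpp)
  time_min <- (seq_len(n_meas) - 1) * 6.5

  rows <- list()
  counts <- list()
  well_no <- 0L
  for (i in seq_len(nrow(g))) {
    mito <- g$ocr_baseline[i] - g$ocr_nonmito[i]
    ocr_level <- c(
      baseline = g$ocr_baseline[i],
      oligomycin = g$ocr_nonmito[i] + g$oligo_fraction[i] * mito,
      FCCP = g$ocr_nonmito[i] + g$fccp_fold[i] * mito,
      rot_aa = g$ocr_nonmito[i]
    )
    ecar_level <- c(
      baseline = g$ecar_basal[i],
      oligomycin = g$ecar_basal[i] * g$ecar_oligo_fold[i],
      FCCP = g$ecar_basal[i] * g$ecar_oligo_fold[i],
      rot_aa = g$ecar_basal[i] * 0.8
    )
    sd_ocr <- if (config$noise_relative) {
      config$noise_sd * g$ocr_baseline[i]
    } else {
      config$noise_sd
    }
    sd_ecar <- if (config$noise_relative) {
      config$noise_sd * g$ecar_basal[i]
    } else {
      config$noise_sd
    }
    for (w in seq_len(config$wells_per_group)) {
      well_no <- well_no + 1L
      well_id <- sprintf("W%02d", well_no)
      cells <- max(1000, round(stats::rnorm(1, config$cell_count_mean,
                                            config$cell_count_sd)))
      ocr <- ocr_level[phase_of] + stats::rnorm(n_meas, 0, sd_ocr)
      ecar <- ecar_level[phase_of] + stats::rnorm(n_meas, 0, sd_ecar)
      if (config$transient_magnitude > 0) {
        firsts <- sched$first_index[-1]
        ocr[firsts] <- ocr[firsts] * (1 + config$transient_magnitude)
        ecar[firsts] <- ecar[firsts] * (1 + config$transient_magnitude)
      }
      scale <- cells / 1000
      rows[[well_no]] <- tibble::tibble(
        well = well_id, group = g$group[i], experiment = "sim",
        measurement = seq_len(n_meas), time_min = time_min,
        ocr = ocr * scale, ecar = ecar * scale
      )
      counts[[well_no]] <- tibble::tibble(well = well_id, cells = cells)
    }
  }
  traces <- flux_traces(
    purrr::list_rbind(rows),
    cell_counts = purrr::list_rbind(counts),
    schedule = sched, normalized = FALSE
  )
  list(traces = traces, truth = sim_truth_metrics(g))
}

#' Configuration for the expression simulator
#'
#' Each pathway gets a smooth trajectory template over the scheme's
#' composited populations, built from Gaussian bumps so the programmed
#' peak and nadir stages are the template's argmax and argmin. Genes are
#' the template plus a gene-specific offset plus Gaussian noise; linked
#' genes instead track a designated flux profile (standardized) with the
#' given slope, so their correlation with that metric is known by
#' construction; isoform-switch pairs receive mirrored (negated)
#' templates.
#'
#' @param populations Ordered population labels (post-compositing, e.g.
#'   `c("DN", "ISP8", "DP early", "SP8", "SP4")`).
#' @param pathways Tibble with columns `pathway`, `n_genes`, `peak`,
#'   `nadir`, `amplitude`.
#' @param noise_sd Per-gene, per-population Gaussian noise sd.
#' @param linked Optional tibble with columns `pathway`, `n_genes`,
#'   `slope`: that many genes of the pathway are linked to the flux
#'   profile instead of following the template.
#' @param flux_profile Named numeric vector (one value per population) the
#'   linked genes track; required when `linked` is given.
#' @param n_isoform_pairs Number of anticorrelated gene pairs appended as
#'   pathway `"isoform_switch"`.
#' @return An `expr_sim_config` list.
#' @export
expr_sim_config <- function(populations, pathways, noise_sd = 0.25,
                            linked = NULL, flux_profile = NULL,
                            n_isoform_pairs = 0) {
  pathways <- tibble::as_tibble(pathways)
  need <- c("pathway", "n_genes", "peak", "nadir", "amplitude")
  missing <- setdiff(need, names(pathways))
  if (length(missing) > 0) {
    stop("`pathways` missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(c(pathways$peak, pathways$nadir), populations)
  if (length(bad) > 0) {
    stop("Peak/nadir stage(s) not in `populations`: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  if (any(pathways$amplitude < 0)) {
    stop("Amplitudes must be >= 0.", call. = FALSE)
  }
  if (!is.null(linked)) {
    linked <- tibble::as_tibble(linked)
    if (is.null(flux_profile)) {
      stop("`flux_profile` is required when `linked` is given.",
           call. = FALSE)
    }
    if (!setequal(names(flux_profile), populations)) {
      stop("`flux_profile` must be named by the populations.", call. = FALSE)
    }
    extra <- setdiff(linked$pathway, pathways$pathway)
    if (length(extra) > 0) {
      stop("Linked pathway(s) not defined: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    over <- linked$n_genes >
      pathways$n_genes[match(linked$pathway, pathways$pathway)]
    if (any(over)) {
      stop("More linked genes than pathway genes for: ",
           paste(linked$pathway[over], collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(populations = populations, pathways = pathways,
         noise_sd = noise_sd, linked = linked,
         flux_profile = flux_profile, n_isoform_pairs = n_isoform_pairs),
    class = "expr_sim_config"
  )
}

template_curve <- function(populations, peak, nadir, amplitude,
                           width = 0.5) {
  # narrow bumps keep the argmax/argmin pinned to the programmed stages
  # even when peak and nadir are adjacent
  i <- seq_along(populations)
  pk <- match(peak, populations)
  nd <- match(nadir, populations)
  amplitude * (exp(-(i - pk)^2 / (2 * width^2)) -
                 exp(-(i - nd)^2 / (2 * width^2)))
}

#' Simulate stage-structured expression with known gene-flux links
#'
#' @param config An [expr_sim_config()].
#' @param seed Integer seed.
#' @return List with `expression` (a `gene_id` + population tibble on the
#'   "normalized expression" scale), `links` (tibble `gene_id`, `pathway`,
#'   `linked`, `slope`), and `panel` (a [gene_panel()] over the simulated
#'   pathways).
#' @export
simulate_expression <- function(config, seed = 1L) {
  stopifnot(inherits(config, "expr_sim_config"))
  set.seed(seed)
  pops <- config$populations
  n_pop <- length(pops)
  std_flux <- NULL
  if (!is.null(config$flux_profile)) {
    f <- config$flux_profile[pops]
    std_flux <- (f - mean(f)) / stats::sd(f)
  }

  rows <- list()
  links <- list()
  panel_list <- list()
  for (i in seq_len(nrow(config$pathways))) {
    pw <- config$pathways$pathway[i]
    n_genes <- config$pathways$n_genes[i]
    base <- template_curve(pops, config$pathways$peak[i],
                           config$pathways$nadir[i],
                           config$pathways$amplitude[i])
    n_linked <- 0L
    slope <- 0
    if (!is.null(config$linked) && pw %in% config$linked$pathway) {
      j <- match(pw, config$linked$pathway)
      n_linked <- config$linked$n_genes[j]
      slope <- config$linked$slope[j]
    }
    ids <- sprintf("%s_g%03d", gsub("[^A-Za-z0-9]", "", pw),
                   seq_len(n_genes))
    panel_list[[pw]] <- ids
    for (k in seq_len(n_genes)) {
      is_linked <- k <= n_linked
      offset <- stats::rnorm(1, 0, 0.5)
      mu <- if (is_linked) slope * std_flux + offset else base + offset
      vals <- mu + stats::rnorm(n_pop, 0, config$noise_sd)
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene_id = ids[k], !!!stats::setNames(as.list(vals), pops)
      )
      links[[length(links) + 1]] <- tibble::tibble(
        gene_id = ids[k], pathway = pw, linked = is_linked,
        slope = if (is_linked) slope else 0
      )
    }
  }
  if (config$n_isoform_pairs > 0) {
    base <- template_curve(pops, pops[1], pops[n_pop], 1.5)
    iso_ids <- character(0)
    for (p in seq_len(config$n_isoform_pairs)) {
      ida <- sprintf("iso%02da", p)
      idb <- sprintf("iso%02db", p)
      iso_ids <- c(iso_ids, ida, idb)
      va <- base + stats::rnorm(n_pop, 0, config$noise_sd)
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene_id = ida, !!!stats::setNames(as.list(va), pops)
      )
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene_id = idb, !!!stats::setNames(as.list(
          if (config$noise_sd == 0) -base else
            -base + stats::rnorm(n_pop, 0, config$noise_sd)
        ), pops)
      )
      links[[length(links) + 1]] <- tibble::tibble(
        gene_id = c(ida, idb), pathway = "isoform_switch",
        linked = FALSE, slope = 0
      )
    }
    panel_list[["isoform_switch"]] <- iso_ids
  }
  list(
    expression = purrr::list_rbind(rows),
    links = purrr::list_rbind(links),
    panel = gene_panel(panel_list)
  )
}

#' Simulate a differential-expression statistics table with a known pass set
#'
#' Draws each gene to pass or fail the variable-gene filter with
#' probability `pass_fraction`. Passing genes satisfy every predicate;
#' failing genes violate at least one, chosen at random. The expected pass
#' set returned alongside is computed by brute-force evaluation of the
#' filter definition on the generated table, independent of
#' [filter_variable_genes()].
#'
#' @param n_genes Number of genes.
#' @param pass_fraction Probability a gene is drawn to pass.
#' @param seed Integer seed.
#' @param n_contrasts Pairwise contrasts per gene (default 3).
#' @param fc_min,adj_p_max,fpkm_min,cpm_floor,mappability_min_bp Filter
#'   thresholds the generator targets (defaults match the filter).
#' @return List with `de_table` and `expected` (character vector of genes
#'   that pass by brute force).
#' @export
simulate_de_table <- function(n_genes, pass_fraction, seed = 1L,
                              n_contrasts = 3, fc_min = 2, adj_p_max = 0.01,
                              fpkm_min = 5, cpm_floor = 0.5,
                              mappability_min_bp = 50) {
  if (pass_fraction < 0 || pass_fraction > 1) {
    stop("`pass_fraction` must lie in [0, 1].", call. = FALSE)
  }
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  should_pass <- stats::runif(n_genes) < pass_fraction

  per_gene <- list()
  per_contrast <- list()
  for (i in seq_len(n_genes)) {
    # start from an all-pass draw, then break predicates for failing genes
    fc <- exp(stats::runif(n_contrasts, log(1 / fc_min), log(fc_min)))
    hot <- sample(n_contrasts, 1)
    fc[hot] <- if (stats::runif(1) < 0.5) {
      fc_min * stats::runif(1, 1.1, 4)
    } else {
      1 / (fc_min * stats::runif(1, 1.1, 4))
    }
    adj_p <- stats::runif(n_contrasts, adj_p_max, 1)
    adj_p[hot] <- stats::runif(1, 0, adj_p_max * 0.9)
    fpkm <- stats::runif(1, fpkm_min, 100)
    cpm <- stats::runif(1, cpm_floor, 50)
    mapp <- round(stats::runif(1, mappability_min_bp, 500))
    outlier <- FALSE

    if (!should_pass[i]) {
      k <- sample(5, 1)
      if (k == 1) {           # no contrast both strong and significant
        fc <- exp(stats::runif(n_contrasts, log(1 / fc_min) * 0.9,
                               log(fc_min) * 0.9))
      } else if (k == 2) {
        adj_p <- stats::runif(n_contrasts, adj_p_max, 1)
      } else if (k == 3) {
        fpkm <- stats::runif(1, 0, fpkm_min * 0.9)
      } else if (k == 4) {
        cpm <- stats::runif(1, 0, cpm_floor * 0.9)
      } else {
        if (stats::runif(1) < 0.5) {
          mapp <- round(stats::runif(1, 10, mappability_min_bp - 1))
        } else {
          outlier <- TRUE
        }
      }
    }
    per_gene[[i]] <- tibble::tibble(
      gene_id = genes[i], max_fpkm = fpkm, max_cpm = cpm,
      mappable_bp = mapp, outlier = outlier
    )
    per_contrast[[i]] <- tibble::tibble(
      gene_id = genes[i], contrast = sprintf("c%d", seq_len(n_contrasts)),
      fold_change = fc, adj_p = adj_p
    )
  }
  gene_tbl <- purrr::list_rbind(per_gene)
  de_table <- purrr::list_rbind(per_contrast) |>
    dplyr::left_join(gene_tbl, by = "gene_id")

  # brute-force expected set straight from the filter's definition
  expected <- character(0)
  for (i in seq_len(n_genes)) {
    d <- de_table[de_table$gene_id == genes[i], ]
    de_ok <- FALSE
    for (j in seq_len(nrow(d))) {
      if ((d$fold_change[j] > fc_min || d$fold_change[j] < 1 / fc_min) &&
          d$adj_p[j] < adj_p_max) {
        de_ok <- TRUE
      }
    }
    if (de_ok && d$max_fpkm[1] >= fpkm_min && d$max_cpm[1] >= cpm_floor &&
        d$mappable_bp[1] >= mappability_min_bp && !d$outlier[1]) {
      expected <- c(expected, genes[i])
    }
  }
  list(de_table = de_table, expected = expected)
}
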