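#' Inverse-hyperbolic-sine transform with a cofactor
#'
#' `x -> asinh(x / cofactor)`: log-like for large values, near-linear
#' around zero, defined for negative inputs. Applied to extracellular-flux
#' values (cofactor 5 by default) before correlation against gene
#' z-scores; never applied to the z-scores themselves.
#'
#' @param x Numeric vector.
#' @param cofactor Positive scale divisor (default 5).
#' @return Transformed numeric vector.
#' @examples
#' asinh_cofactor(5) # asinh(1) = log(1 + sqrt(2))
#' @export
asinh_cofactor <- function(x, cofactor = 5) {
  if (!is.numeric(cofactor) || length(cofactor) != 1 || cofactor <= 0) {
    stop("`cofactor` must be a single positive number.", call. = FALSE)
  }
  asinh(x / cofactor)
}

#' Correlate gene z-score trajectories against one flux metric
#'
#' Pearson correlation per gene between its z-score row and the (already
#' asinh-transformed) flux vector across matched populations. Two-sided
#' p-values use the t reference distribution with n - 2 degrees of freedom
#' when n >= 4; with n = 3 the p-value is undefined (`NA`) and the gene is
#' excluded from the BH family with reason `"n_too_small"`. Genes whose
#' z row has zero variance get an undefined r with reason
#' `"zero_variance"`. Sign classes follow the |r| threshold: `positive`
#' when `r > r_threshold`, `negative` when `r < -r_threshold`, else
#' `weak`.
#'
#' @param z A z-scored `expression_matrix` whose value columns are the
#'   populations of `flux`, or a tibble of the same shape.
#' @param flux Named numeric vector: one transformed flux value per
#'   population. Names must match the matrix columns (order-free).
#' @param r_threshold Absolute-r threshold for sign classification
#'   (default 0.5).
#' @param alpha Significance level recorded in the result metadata
#'   (default 0.05).
#' @return A `correlation_result` tibble: `gene_id`, `r`, `p`, `p_adj`,
#'   `sign_class`, `n_populations`, `excluded_reason`.
#' @export
correlate_genes <- function(z, flux, r_threshold = 0.5, alpha = 0.05) {
  pops <- names(flux)
  if (is.null(pops)) stop("`flux` must be named by population.", call. = FALSE)
  cols <- expr_value_cols(z)
  if (!setequal(cols, pops)) {
    stop("Populations differ between expression (",
         paste(cols, collapse = ", "), ") and flux (",
         paste(pops, collapse = ", "), ").", call. = FALSE)
  }
  n <- length(pops)
  if (n < 3) stop("Need at least 3 populations.", call. = FALSE)
  if (stats::sd(flux) == 0) {
    stop("Flux vector has zero variance; correlations undefined.",
         call. = FALSE)
  }
  m <- as.matrix(z[cols])[, pops, drop = FALSE]  # align by label

  r <- rep(NA_real_, nrow(m))
  p <- rep(NA_real_, nrow(m))
  reason <- rep(NA_character_, nrow(m))
  for (i in seq_len(nrow(m))) {
    g <- m[i, ]
    if (stats::sd(g) == 0) {
      reason[i] <- "zero_variance"
      next
    }
    pc <- pearson_cor(g, flux)
    r[i] <- pc$r
    p[i] <- pc$p
    if (n < 4) reason[i] <- "n_too_small"
  }
  p_adj <- rep(NA_real_, length(p))
  in_family <- !is.na(p)
  if (any(in_family)) p_adj[in_family] <- bh_adjust(p[in_family])

  sign_class <- dplyr::case_when(
    is.na(r) ~ NA_character_,
    r > r_threshold ~ "positive",
    r < -r_threshold ~ "negative",
    TRUE ~ "weak"
  )
  out <- tibble::tibble(
    gene_id = z$gene_id, r = r, p = p, p_adj = p_adj,
    sign_class = sign_class, n_populations = n, excluded_reason = reason
  )
  attr(out, "r_threshold") <- r_threshold
  attr(out, "alpha") <- alpha
  class(out) <- c("correlation_result", class(out))
  out
}

#' Integrate flux metrics with panel expression
#'
#' The full correlation pipeline: composite the DN compartment of the
#' expression matrix with the scheme's weights, restrict both data types
#' to their shared populations, z-score gene rows across those
#' populations, asinh-transform the per-population flux values (the mean
#' of well-level metrics per population, computed before the transform),
#' and correlate every panel gene against the transformed flux, pathway by
#' pathway, with BH adjustment within each pathway (or pooled across
#' pathways with `family = "all-pathways"`).
#'
#' @param flux_summary Output of [summarize_groups()] (long tibble with
#'   `group`, `metric`, `mean`), or a named numeric vector of
#'   per-population means for `metric`.
#' @param expression An `expression_matrix` on the normalized expression
#'   scale (not yet z-scored or composited).
#' @param panel A [gene_panel()].
#' @param scheme A [population_scheme()] providing the DN weights.
#' @param metric Which flux metric to correlate (default `"basal_ocr"`).
#' @param populations Optional character vector restricting the
#'   populations entering the correlation; default: all shared ones.
#' @param cofactor asinh cofactor for the flux values (default 5).
#' @param r_threshold,alpha Passed to [correlate_genes()].
#' @param family `"per-pathway"` (default) adjusts p-values within each
#'   pathway; `"all-pathways"` pools one BH family across all pathways.
#' @return An `integration_result`: list of per-pathway
#'   `correlation_result` tibbles plus a `manifest` recording every
#'   parameter and the population set used.
#' @export
run_integration <- function(flux_summary, expression, panel, scheme,
                            metric = "basal_ocr", populations = NULL,
                            cofactor = 5, r_threshold = 0.5, alpha = 0.05,
                            family = c("per-pathway", "all-pathways")) {
  family <- match.arg(family)
  stopifnot(inherits(panel, "gene_panel"))

  if (is.data.frame(flux_summary)) {
    sub <- dplyr::filter(flux_summary, .data$metric == !!metric)
    if (nrow(sub) == 0) {
      stop("Metric ", metric, " not present in the flux summary.",
           call. = FALSE)
    }
    flux <- stats::setNames(sub$mean, sub$group)
  } else {
    flux <- flux_summary
    if (is.null(names(flux))) {
      stop("A flux vector must be named by population.", call. = FALSE)
    }
  }

  composited <- composite_dn(expression, scheme)
  shared <- intersect(expr_value_cols(composited), names(flux))
  if (!is.null(populations)) shared <- intersect(shared, populations)
  if (length(shared) < 3) {
    stop("Fewer than 3 shared populations (matched: ",
         paste(shared, collapse = ", "), ").", call. = FALSE)
  }
  restricted <- composited[c("gene_id", shared)]
  z <- zscore_rows(restricted)
  flux_t <- asinh_cofactor(flux[shared], cofactor = cofactor)

  results <- list()
  for (pw in names(panel)) {
    hit <- match_panel_genes(panel[[pw]], z$gene_id)
    if (length(hit$found) == 0) {
      stop("No panel genes found in the matrix for pathway ", pw, ".",
           call. = FALSE)
    }
    zsub <- z[z$gene_id %in% hit$found, , drop = FALSE]
    res <- correlate_genes(zsub, flux_t, r_threshold = r_threshold,
                           alpha = alpha)
    res$pathway <- pw
    results[[pw]] <- res
  }
  if (family == "all-pathways") {
    pooled <- purrr::list_rbind(results)
    ok <- !is.na(pooled$p)
    pooled$p_adj[ok] <- bh_adjust(pooled$p[ok])
    results <- split(pooled, pooled$pathway)[names(results)]
    results <- lapply(results, function(d) {
      class(d) <- c("correlation_result", class(d)); d
    })
  }
  manifest <- list(
    metric = metric, populations = shared, cofactor = cofactor,
    r_threshold = r_threshold, alpha = alpha, family = family,
    system = scheme$system, dn_weights = as.list(scheme$dn_weights),
    n_genes = stats::setNames(
      lapply(results, nrow), names(results)
    )
  )
  structure(list(results = results, manifest = manifest),
            class = "integration_result")
}

#' Write integration results and their manifest
#'
#' One TSV per pathway (`<pathway>.tsv`) plus `manifest.yaml`.
#'
#' @param x An `integration_result`.
#' @param dir Output directory (created if absent).
#' @export
write_integration <- function(x, dir) {
  stopifnot(inherits(x, "integration_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (pw in names(x$results)) {
    fn <- file.path(dir, paste0(gsub("[^A-Za-z0-9_-]", "_", pw), ".tsv"))
    readr::write_tsv(tibble::as_tibble(x$results[[pw]]), fn)
  }
  yaml::write_yaml(x$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @method tidy integration_result
#' @export
tidy.integration_result <- function(x, ...) {
  out <- purrr::list_rbind(lapply(x$results, tibble::as_tibble))
  dplyr::relocate(out, "pathway")
}

#' @method glance integration_result
#' @export
glance.integration_result <- function(x, ...) {
  tidy(x) |>
    dplyr::group_by(.data$pathway) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_positive = sum(.data$sign_class == "positive", na.rm = TRUE),
      n_negative = sum(.data$sign_class == "negative", na.rm = TRUE),
      n_weak = sum(.data$sign_class == "weak", na.rm = TRUE),
      n_significant = sum(.data$p_adj < x$manifest$alpha, na.rm = TRUE),
      .groups = "drop"
    )
}
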