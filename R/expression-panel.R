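#' Read a gene x population expression table
#'
#' Expects a TSV with a `gene_id` column and one numeric column per sample;
#' every sample column must be a stage of the supplied scheme.
#'
#' @param path Path to a tab-delimited file.
#' @param scheme A [population_scheme()] the columns must belong to.
#' @return An `expression_matrix` tibble (`gene_id` plus one column per
#'   stage, ordered as in the scheme).
#' @export
read_expression <- function(path, scheme) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"gene_id" %in% names(raw)) {
    stop("Expression table needs a `gene_id` column.", call. = FALSE)
  }
  sample_cols <- setdiff(names(raw), "gene_id")
  unknown <- setdiff(sample_cols, scheme$stages)
  if (length(unknown) > 0) {
    stop("Column(s) not in the population scheme: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  dup <- raw$gene_id[duplicated(raw$gene_id)]
  if (length(dup) > 0) {
    stop("Duplicate gene id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  for (cl in sample_cols) {
    if (!is.numeric(raw[[cl]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(raw[[cl]]))))[1]
      stop("Non-numeric value in column ", cl, ", row ", bad, ".",
           call. = FALSE)
    }
  }
  expression_matrix(raw[c("gene_id", intersect(scheme$stages, sample_cols))],
                    scheme)
}

#' Construct an expression matrix tibble
#'
#' @param data Data frame with `gene_id` plus one numeric column per stage.
#' @param scheme The [population_scheme()] the columns belong to.
#' @return An `expression_matrix` tibble.
#' @export
expression_matrix <- function(data, scheme) {
  out <- tibble::as_tibble(data)
  if (anyDuplicated(out$gene_id)) {
    stop("Duplicate gene rows are not allowed.", call. = FALSE)
  }
  attr(out, "scheme") <- scheme
  class(out) <- c("expression_matrix", setdiff(class(out),
                                               "expression_matrix"))
  out
}

#' Write an expression matrix to TSV
#'
#' @param x An `expression_matrix` tibble.
#' @param path Output path.
#' @export
write_expression <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}

expr_value_cols <- function(x) setdiff(names(x), "gene_id")

#' Row-wise z-scoring of an expression matrix
#'
#' Standardizes every gene to mean 0 and sample standard deviation 1
#' (n - 1 denominator) across its columns. Constant rows are mapped to
#' all-zero rather than NaN, so downstream pathway means stay defined; the
#' affected gene ids are recorded in the `constant_genes` attribute.
#'
#' @param x An `expression_matrix` (or any `gene_id` + value-column tibble).
#' @return A z-scored tibble of the same shape, with attribute
#'   `constant_genes`.
#' @export
zscore_rows <- function(x) {
  cols <- expr_value_cols(x)
  if (length(cols) < 2) stop("Need at least 2 sample columns.", call. = FALSE)
  m <- as.matrix(x[cols])
  mu <- rowMeans(m)
  s <- apply(m, 1, stats::sd)
  constant <- s == 0
  s[constant] <- 1
  z <- (m - mu) / s
  z[constant, ] <- 0
  out <- x
  out[cols] <- as.data.frame(z)
  attr(out, "constant_genes") <- x$gene_id[constant]
  attr(out, "scheme") <- attr(x, "scheme")
  out
}

#' Composite the DN compartment as a weighted average
#'
#' Replaces the scheme's DN member columns by one "DN" column whose value
#' per gene is the convex combination of member expression with the
#' scheme's (or supplied) population proportions. Compositing operates on
#' the input expression scale; z-score afterwards if standardized values
#' are needed, since a convex combination of separately standardized
#' columns would not correspond to any population's expression.
#'
#' @param x An `expression_matrix` containing all DN member columns.
#' @param scheme A [population_scheme()]; defaults to the one attached.
#' @param weights Named numeric vector over the DN members summing to 1;
#'   defaults to `scheme$dn_weights`.
#' @return The matrix with members replaced by a leading `DN` column;
#'   non-member columns unchanged and in their original order.
#' @export
composite_dn <- function(x, scheme = NULL, weights = NULL) {
  scheme <- scheme %||% attr(x, "scheme")
  if (is.null(scheme)) stop("No population scheme available.", call. = FALSE)
  weights <- weights %||% scheme$dn_weights
  members <- scheme$dn_members
  if (!setequal(names(weights), members)) {
    stop("Weights must cover exactly the DN members: ",
         paste(members, collapse = ", "), call. = FALSE)
  }
  weights <- weights[members]
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("Weights must sum to 1 (got ", sum(weights), ").", call. = FALSE)
  }
  missing <- setdiff(members, names(x))
  if (length(missing) > 0) {
    stop("Missing DN member column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dn <- as.matrix(x[members]) %*% weights
  rest <- setdiff(expr_value_cols(x), members)
  out <- tibble::tibble(gene_id = x$gene_id, DN = as.numeric(dn))
  out <- dplyr::bind_cols(out, x[rest])
  attr(out, "scheme") <- scheme
  class(out) <- c("expression_matrix", setdiff(class(out),
                                               "expression_matrix"))
  out
}

match_panel_genes <- function(panel_genes, matrix_genes) {
  # case-insensitive symbol matching bridges mouse title-case vs human
  # upper-case conventions
  idx <- match(toupper(panel_genes), toupper(matrix_genes))
  list(found = matrix_genes[idx[!is.na(idx)]],
       missing = panel_genes[is.na(idx)])
}

#' Per-pathway mean z-score trajectories
#'
#' For each pathway in the panel, the unweighted mean of member-gene
#' z-scores per population — the line-plot summary drawn under pathway
#' heatmaps. Gene symbols are matched case-insensitively so mouse
#' (title-case) and human (upper-case) panels work against either system.
#' Panel genes absent from the matrix are reported in the `missing_genes`
#' attribute, never silently dropped; a pathway with zero matched genes is
#' an error.
#'
#' @param z An already z-scored `expression_matrix`.
#' @param panel A [gene_panel()].
#' @return A long tibble with columns `pathway`, `population`, `mean_z`,
#'   `n_genes`; attribute `missing_genes` maps pathway to unmatched ids.
#' @export
pathway_trajectory <- function(z, panel) {
  stopifnot(inherits(panel, "gene_panel"))
  cols <- expr_value_cols(z)
  missing_by_pathway <- list()
  rows <- list()
  for (pw in names(panel)) {
    hit <- match_panel_genes(panel[[pw]], z$gene_id)
    if (length(hit$found) == 0) {
      stop("No panel genes found in the matrix for pathway ", pw, ".",
           call. = FALSE)
    }
    missing_by_pathway[[pw]] <- hit$missing
    sub <- as.matrix(z[z$gene_id %in% hit$found, cols])
    rows[[pw]] <- tibble::tibble(
      pathway = pw,
      population = factor(cols, levels = cols),
      mean_z = unname(colMeans(sub)),
      n_genes = nrow(sub)
    )
  }
  out <- purrr::list_rbind(rows)
  attr(out, "missing_genes") <- missing_by_pathway
  class(out) <- c("pathway_trajectory", class(out))
  out
}

#' Variable-gene filter over a differential-expression statistics table
#'
#' A gene passes when, in at least one pairwise contrast, its fold change
#' exceeds `fc_min` in either direction (i.e. `fc > fc_min` or
#' `fc < 1/fc_min`) with BH-adjusted Wald p below `adj_p_max`, and its
#' maximum expression reaches `fpkm_min` FPKM in at least one sample; genes
#' below `cpm_floor` counts per million in every sample, flagged count
#' outliers, and genes with mappable length below `mappability_min_bp` are
#' excluded.
#'
#' @param de_table Tibble with columns `gene_id`, `contrast`,
#'   `fold_change`, `adj_p` (one row per gene x contrast) and per-gene
#'   columns `max_fpkm`, `max_cpm`, `mappable_bp`, `outlier`.
#' @param fc_min Linear fold-change threshold (default 2).
#' @param adj_p_max Adjusted-p threshold (default 0.01).
#' @param fpkm_min Minimum FPKM in at least one sample (default 5).
#' @param cpm_floor Minimum CPM reached in at least one sample (default 0.5).
#' @param mappability_min_bp Minimum mappable length (default 50).
#' @return A tibble with one row per gene: the per-predicate outcomes
#'   (`pass_de`, `pass_fpkm`, `pass_cpm`, `pass_mappability`,
#'   `pass_outlier`) and the conjunction `pass`. The passing gene set is
#'   `result$gene_id[result$pass]`.
#' @export
filter_variable_genes <- function(de_table, fc_min = 2, adj_p_max = 0.01,
                                  fpkm_min = 5, cpm_floor = 0.5,
                                  mappability_min_bp = 50) {
  need <- c("gene_id", "contrast", "fold_change", "adj_p", "max_fpkm",
            "max_cpm", "mappable_bp", "outlier")
  missing <- setdiff(need, names(de_table))
  if (length(missing) > 0) {
    stop("DE table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(de_table) == 0) {
    return(tibble::tibble(
      gene_id = character(0), pass_de = logical(0), pass_fpkm = logical(0),
      pass_cpm = logical(0), pass_mappability = logical(0),
      pass_outlier = logical(0), pass = logical(0)
    ))
  }
  if (any(de_table$fold_change <= 0)) {
    stop("Fold changes must be positive (linear scale).", call. = FALSE)
  }
  de_table |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      pass_de = any((.data$fold_change > fc_min |
                       .data$fold_change < 1 / fc_min) &
                      .data$adj_p < adj_p_max),
      pass_fpkm = .data$max_fpkm[1] >= fpkm_min,
      pass_cpm = .data$max_cpm[1] >= cpm_floor,
      pass_mappability = .data$mappable_bp[1] >= mappability_min_bp,
      pass_outlier = !.data$outlier[1],
      .groups = "drop"
    ) |>
    dplyr::mutate(pass = .data$pass_de & .data$pass_fpkm & .data$pass_cpm &
                    .data$pass_mappability & .data$pass_outlier)
}

#' PCA of standardized expression
#'
#' Standardizes every gene (feature) to mean 0, sd 1, then decomposes with
#' `prcomp`. Samples are the observations (matrix columns), genes the
#' features. Constant genes carry no information after standardization and
#' are dropped with a warning. Component signs follow a deterministic
#' convention: the largest-magnitude loading of each component is positive.
#'
#' @param x An `expression_matrix` (genes in rows, samples in columns).
#' @return A `flux_pca` object: list with `scores` (tibble sample x PC),
#'   `loadings`, `var_explained` (fractions summing to 1), `sdev`.
#' @export
pca_standardized <- function(x) {
  cols <- expr_value_cols(x)
  if (length(cols) < 2) stop("Need at least 2 samples.", call. = FALSE)
  if (nrow(x) < 2) stop("Need at least 2 genes.", call. = FALSE)
  m <- t(as.matrix(x[cols]))            # samples x genes
  colnames(m) <- x$gene_id
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("Dropping ", sum(sds == 0), " constant gene(s) before PCA: ",
            paste(utils::head(colnames(m)[sds == 0], 5), collapse = ", "),
            call. = FALSE)
    m <- m[, sds > 0, drop = FALSE]
  }
  fit <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  # sign convention: largest-|loading| positive per component
  for (j in seq_len(ncol(fit$rotation))) {
    k <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[k, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- tibble::as_tibble(fit$x)
  scores <- dplyr::bind_cols(tibble::tibble(sample = cols), scores)
  structure(
    list(scores = scores, loadings = fit$rotation,
         var_explained = ve, sdev = fit$sdev),
    class = "flux_pca"
  )
}

#' @method tidy flux_pca
#' @export
tidy.flux_pca <- function(x, ...) {
  tidyr::pivot_longer(x$scores, -"sample", names_to = "component",
                      values_to = "score")
}

#' @method glance flux_pca
#' @export
glance.flux_pca <- function(x, ...) {
  tibble::tibble(
    component = paste0("PC", seq_along(x$var_explained)),
    var_explained = x$var_explained,
    sdev = x$sdev
  )
}
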