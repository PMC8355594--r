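# Shared fixtures and independent oracles.

# One-or-more-well trace set with piecewise-constant phase levels.
# ocr_phases / ecar_phases: length-4 vectors (baseline, oligomycin, FCCP,
# rot_aa) or a list of such vectors, one per well.
toy_traces <- function(ocr_phases, ecar_phases = c(30, 45, 45, 24),
                       mpp = 3, groups = NULL) {
  if (!is.list(ocr_phases)) ocr_phases <- list(ocr_phases)
  if (!is.list(ecar_phases)) {
    ecar_phases <- rep(list(ecar_phases), length(ocr_phases))
  }
  n_wells <- length(ocr_phases)
  groups <- groups %||% rep("G", n_wells)
  sched <- injection_schedule(1L, mpp + 1L, 2L * mpp + 1L, 3L * mpp + 1L)
  rows <- lapply(seq_len(n_wells), function(w) {
    tibble::tibble(
      well = sprintf("W%02d", w), group = groups[w], experiment = "toy",
      measurement = seq_len(4L * mpp),
      time_min = (seq_len(4L * mpp) - 1) * 6.5,
      ocr = rep(ocr_phases[[w]], each = mpp),
      ecar = rep(ecar_phases[[w]], each = mpp)
    )
  })
  flux_traces(dplyr::bind_rows(rows), schedule = sched)
}

# O(m^2) brute-force step-up BH oracle: adj_i = min_{j >= i} p_(j) * m / j.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(sorted[i:m] * m / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# Hand product-moment Pearson r.
pearson_oracle <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Closed-form Welch statistic and Welch-Satterthwaite df.
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Duplicate a composited compartment column into identical member columns
# so compositing machinery can run on simulator output.
expand_dn_members <- function(expr, scheme, from = "DN") {
  members <- scheme$dn_members
  out <- tibble::tibble(gene_id = expr$gene_id)
  for (m in members) out[[m]] <- expr[[from]]
  rest <- setdiff(names(expr), c("gene_id", from))
  out <- dplyr::bind_cols(out, expr[rest])
  expression_matrix(out, scheme)
}
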