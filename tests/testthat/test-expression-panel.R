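toy_matrix <- function(scheme = scheme_mouse_thymus()) {
  set.seed(5)
  stages <- scheme$stages
  expression_matrix(
    dplyr::bind_cols(
      tibble::tibble(gene_id = sprintf("g%02d", 1:10)),
      tibble::as_tibble(stats::setNames(
        as.data.frame(matrix(rnorm(10 * length(stages), 5, 2),
                             nrow = 10)),
        stages
      ))
    ),
    scheme
  )
}

test_that("expression TSV reading validates and round-trips", {
  scheme <- scheme_mouse_thymus()
  em <- toy_matrix(scheme)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression(em, f)
  back <- read_expression(f, scheme)
  expect_equal(nrow(back), 10)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(em))

  d <- tibble::as_tibble(em)
  names(d)[2] <- "SP9"
  f2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(d, f2)
  expect_error(read_expression(f2, scheme), "SP9")

  d2 <- tibble::as_tibble(em)
  d2$gene_id[2] <- d2$gene_id[1]
  readr::write_tsv(d2, f2)
  expect_error(read_expression(f2, scheme), "Duplicate gene")
})

test_that("row z-scoring standardizes and flags constant genes", {
  em <- expression_matrix(
    tibble::tibble(gene_id = c("a", "b"), S1 = c(1, 5), S2 = c(2, 5),
                   S3 = c(3, 5)),
    population_scheme("toy", c("S1", "S2", "S3"), "S1", c(S1 = 1))
  )
  z <- zscore_rows(em)
  expect_equal(unlist(z[1, c("S1", "S2", "S3")], use.names = FALSE),
               c(-1, 0, 1))
  expect_equal(unlist(z[2, c("S1", "S2", "S3")], use.names = FALSE),
               c(0, 0, 0))
  expect_equal(attr(z, "constant_genes"), "b")

  set.seed(3)
  big <- toy_matrix()
  zb <- zscore_rows(big)
  vals <- as.matrix(zb[setdiff(names(zb), "gene_id")])
  expect_true(all(abs(rowMeans(vals)) < 1e-12))
  expect_true(all(abs(apply(vals, 1, sd) - 1) < 1e-12))
  # idempotence on already z-scored rows
  z2 <- zscore_rows(zb)
  expect_equal(as.matrix(z2[setdiff(names(z2), "gene_id")]), vals,
               tolerance = 1e-9)
})

test_that("DN compositing forms the stated convex combination", {
  scheme <- scheme_mouse_thymus()
  em <- expression_matrix(
    tibble::tibble(
      gene_id = c("g1", "g2", "g3"),
      DN1 = c(1, 10, 2), DN2 = c(2, 20, 2), DN3 = c(3, 30, 2),
      ISP8 = 0, `DP early` = 0, `DP late` = 0, SP8 = 0, SP4 = 0
    ),
    scheme
  )
  out <- composite_dn(em, scheme)
  expect_equal(names(out)[2], "DN")
  expect_equal(out$DN,
               0.04 * c(1, 10, 2) + 0.03 * c(2, 20, 2) + 0.93 * c(3, 30, 2))

  deg <- composite_dn(em, scheme, weights = c(DN1 = 0, DN2 = 0, DN3 = 1))
  expect_equal(deg$DN, em$DN3)

  w <- c(DN1 = 0.2, DN2 = 0.3, DN3 = 0.5)
  expect_equal(composite_dn(em, scheme, weights = w)$DN[1], 2.3)

  expect_error(
    composite_dn(em, scheme, weights = c(DN1 = 0.5, DN2 = 0.6, DN3 = 0.1)),
    "sum to 1"
  )
  expect_error(
    composite_dn(em, scheme, weights = c(DN1 = 0.5, DN2 = 0.5)),
    "exactly the DN members"
  )
})

test_that("DN compositing is linear in the expression matrix", {
  scheme <- scheme_mouse_thymus()
  set.seed(13)
  a <- toy_matrix(scheme)
  b <- toy_matrix(scheme)
  cols <- scheme$stages
  b[cols] <- as.data.frame(matrix(rnorm(10 * length(cols)), nrow = 10))
  ab <- a
  ab[cols] <- as.data.frame(as.matrix(a[cols]) + as.matrix(b[cols]))
  sum_then <- composite_dn(expression_matrix(ab, scheme), scheme)
  then_sum <- composite_dn(a, scheme)$DN + composite_dn(b, scheme)$DN
  expect_equal(sum_then$DN, then_sum, tolerance = 1e-12)
})

test_that("pathway trajectories average member z-rows per population", {
  em <- expression_matrix(
    tibble::tibble(gene_id = c("g1", "g2", "g3", "g4", "g5"),
                   S1 = c(1, 2, 0, 4, 3), S2 = c(2, 4, 0, 2, 1),
                   S3 = c(3, 6, 0, 0, 2)),
    population_scheme("toy", c("S1", "S2", "S3"), "S1", c(S1 = 1))
  )
  z <- zscore_rows(em)
  panel <- gene_panel(list(
    solo = "g1",
    five = c("g1", "g2", "g3", "g4", "g5")
  ))
  tj <- pathway_trajectory(z, panel)
  solo <- dplyr::filter(tj, pathway == "solo")
  expect_equal(solo$mean_z,
               unlist(z[1, c("S1", "S2", "S3")], use.names = FALSE))
  five <- dplyr::filter(tj, pathway == "five")
  hand <- colMeans(as.matrix(z[, c("S1", "S2", "S3")]))
  expect_equal(five$mean_z, unname(hand))
  expect_equal(five$n_genes, rep(5L, 3))

  # two mirrored z-rows cancel
  panel2 <- gene_panel(list(pair = c("g1", "g4"))) # g4 is g1 reversed
  tj2 <- pathway_trajectory(z, panel2)
  expect_equal(tj2$mean_z, rep(0, 3), tolerance = 1e-12)

  # permutation of panel genes does not change the trajectory
  tj3 <- pathway_trajectory(z, gene_panel(list(five = c("g3", "g5", "g1",
                                                        "g4", "g2"))))
  expect_equal(tj3$mean_z, five$mean_z)

  expect_error(pathway_trajectory(z, gene_panel(list(none = "zz"))),
               "none")
  # case-insensitive matching, absentees reported
  tj4 <- pathway_trajectory(z, gene_panel(list(mix = c("G1", "missing"))))
  expect_equal(attr(tj4, "missing_genes")$mix, "missing")
})

test_that("variable-gene filter applies every predicate conjunctively", {
  expect_equal(nrow(filter_variable_genes(tibble::tibble(
    gene_id = character(0), contrast = character(0),
    fold_change = numeric(0), adj_p = numeric(0), max_fpkm = numeric(0),
    max_cpm = numeric(0), mappable_bp = numeric(0), outlier = logical(0)
  ))), 0)

  one <- tibble::tibble(
    gene_id = "g", contrast = "c1", fold_change = 3, adj_p = 0.005,
    max_fpkm = 10, max_cpm = 2, mappable_bp = 100, outlier = FALSE
  )
  expect_true(filter_variable_genes(one)$pass)

  # six genes engineered so exactly g1 (up) and g2 (down) pass
  toy <- tibble::tibble(
    gene_id = rep(c("g1", "g2", "g3", "g4", "g5", "g6"), each = 2),
    contrast = rep(c("c1", "c2"), 6),
    fold_change = c(3, 1.2, 0.3, 1.1, 1.5, 1.8, 5, 1, 4, 1, 3, 1),
    adj_p = c(0.001, 0.5, 0.004, 0.7, 0.001, 0.001, 0.5, 0.9,
              0.002, 0.5, 0.003, 0.5),
    max_fpkm = rep(c(20, 15, 30, 25, 3, 40), each = 2),
    max_cpm = rep(c(5, 4, 6, 7, 5, 3), each = 2),
    mappable_bp = rep(c(200, 150, 300, 250, 200, 40), each = 2),
    outlier = rep(FALSE, 12)
  )
  got <- filter_variable_genes(toy)
  expect_setequal(got$gene_id[got$pass], c("g1", "g2"))
  # predicate-by-predicate reason trace
  expect_false(got$pass_de[got$gene_id == "g3"])    # |fc| weak
  expect_false(got$pass_de[got$gene_id == "g4"])    # strong fc not significant
  expect_false(got$pass_fpkm[got$gene_id == "g5"])
  expect_false(got$pass_mappability[got$gene_id == "g6"])
})

test_that("relaxing any filter threshold never shrinks the pass set", {
  sim <- simulate_de_table(60, 0.4, seed = 17)
  strict <- filter_variable_genes(sim$de_table)
  strict_set <- strict$gene_id[strict$pass]
  relaxations <- list(
    list(fc_min = 1.5), list(adj_p_max = 0.05), list(fpkm_min = 1),
    list(cpm_floor = 0.1), list(mappability_min_bp = 10)
  )
  for (rel in relaxations) {
    loose <- do.call(filter_variable_genes, c(list(sim$de_table), rel))
    expect_true(all(strict_set %in% loose$gene_id[loose$pass]))
  }
})

test_that("standardized PCA matches an eigen-decomposition oracle", {
  set.seed(31)
  em <- expression_matrix(
    tibble::tibble(gene_id = c("a", "b", "c", "d"),
                   S1 = rnorm(4), S2 = rnorm(4), S3 = rnorm(4)),
    population_scheme("toy", c("S1", "S2", "S3"), "S1", c(S1 = 1))
  )
  fit <- pca_standardized(em)
  expect_equal(sum(fit$var_explained), 1, tolerance = 1e-9)
  expect_true(all(diff(fit$var_explained) < 1e-12))

  m <- scale(t(as.matrix(em[c("S1", "S2", "S3")])))
  eg <- eigen(cov(m))
  expect_equal(sort(fit$sdev^2, decreasing = TRUE)[1:2],
               sort(pmax(eg$values, 0), decreasing = TRUE)[1:2],
               tolerance = 1e-9)
  # scores match up to the fixed sign convention
  scores <- as.matrix(fit$scores[, -1])
  oracle <- m %*% eg$vectors
  for (j in 1:2) {
    expect_equal(abs(unname(scores[, j])), abs(unname(oracle[, j])),
                 tolerance = 1e-8)
  }
})

test_that("PCA sign convention is deterministic and rank-1 data loads PC1", {
  line <- expression_matrix(
    tibble::tibble(gene_id = c("a", "b", "c"),
                   S1 = c(1, 2, 3), S2 = c(2, 4, 6), S3 = c(3, 6, 9),
                   S4 = c(0, 0, 0) + c(4, 8, 12)),
    population_scheme("toy", c("S1", "S2", "S3", "S4"), "S1", c(S1 = 1))
  )
  fit <- pca_standardized(line)
  expect_equal(fit$var_explained[1], 1, tolerance = 1e-9)
  # largest-|loading| positive
  for (j in seq_len(ncol(fit$loadings))) {
    k <- which.max(abs(fit$loadings[, j]))
    expect_gte(fit$loadings[k, j], 0)
  }

  cst <- expression_matrix(
    tibble::tibble(gene_id = c("a", "b", "c"),
                   S1 = c(1, 5, 2), S2 = c(2, 5, 4), S3 = c(3, 5, 8)),
    population_scheme("toy", c("S1", "S2", "S3"), "S1", c(S1 = 1))
  )
  expect_warning(pca_standardized(cst), "constant")
})
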