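test_that("expression generation is deterministic with consistent shapes", {
  s <- expression_spec(n_genes = 200, seed = 7L)
  a <- simulate_expression(s)
  b <- simulate_expression(s)
  expect_identical(a$values, b$values)
  expect_identical(dim(a$values), dim(a$detection_p))
  expect_equal(nrow(a$values), 200)
  expect_equal(ncol(a$values), sum(s$groups))
  expect_error(expression_spec(cre_background_ratios = c(0.5, 0.5, 0.5)),
               "cre_background_ratios")
})

test_that("de_fraction = 0 plants an empty truth set", {
  es <- simulate_expression(n_genes = 150, de_fraction = 0)
  expect_false(any(sim_truth(es)$genes$is_de))
})

test_that("huge effects with tiny dispersion separate groups exactly", {
  es <- simulate_expression(n_genes = 200, de_fraction = 0.1,
                            effect_size_log2 = 4, dispersion = 1e-4)
  de <- differential_expression(normalize_expression(es, "log2"),
                                "CT12_VIP", "CT12_Veh")
  tt <- tidy(de)
  expect_true(all(tt$q[es$genes$is_de] < 0.05))
  expect_equal(mean(abs(tt$lfc[es$genes$is_de])), 4, tolerance = 0.05)
})

test_that("detection filtering drops only never-detected genes", {
  es <- simulate_expression(n_genes = 1000, detection_fail_fraction = 0.2,
                            seed = 3L)
  ef <- filter_detection(es)
  log <- attr(ef, "filter_log")
  expect_equal(log$dropped, 200)
  expect_true(all(ef$genes$detected))
  # all-zero detection p: nothing dropped
  es2 <- es
  es2$detection_p[] <- 0
  expect_equal(attr(filter_detection(es2), "filter_log")$dropped, 0)
  # one gene undetected everywhere: dropped
  es3 <- es
  es3$detection_p[] <- 0
  es3$detection_p[5, ] <- 0.5
  ef3 <- filter_detection(es3)
  expect_equal(attr(ef3, "filter_log")$dropped, 1)
  expect_false("gene_00005" %in% ef3$genes$gene)
})

test_that("quantile normalisation matches a brute-force oracle", {
  set.seed(9)
  m <- matrix(rexp(500, 1 / 50), 100, 5)
  brute <- m
  ranks <- apply(m, 2, rank, ties.method = "first")
  means <- rowMeans(apply(m, 2, sort))
  for (j in 1:5) brute[, j] <- means[ranks[, j]]
  expect_equal(unname(quantile_normalize(m)), unname(brute),
               tolerance = 1e-12)
})

test_that("quantile normalisation is idempotent and absorbs array gain", {
  set.seed(10)
  m <- matrix(rexp(600), 120, 5)
  q1 <- quantile_normalize(m)
  expect_equal(quantile_normalize(q1), q1, tolerance = 1e-12)
  # a gain difference on one array, applied before the log transform,
  # shifts the shared target by a constant and nothing else: every
  # between-sample contrast is unchanged
  lm1 <- quantile_normalize(log2(m))
  m2 <- m
  m2[, 3] <- m2[, 3] * 10
  lm2 <- quantile_normalize(log2(m2))
  shift <- lm2 - lm1
  expect_lt(diff(range(shift)), 1e-9)
  expect_equal(unique(round(as.vector(shift), 9)), log2(10) / 5,
               tolerance = 1e-6)
  # identical columns pass through the full transform unchanged
  mc <- matrix(rep(rexp(100), 4), 100, 4)
  es <- simulate_expression(n_genes = 100, dispersion = 0)
  es$values <- mc
  en <- normalize_expression(es)
  expect_equal(en$values, log2(mc + 1), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("post-normalisation columns share identical sorted values", {
  es <- simulate_expression(n_genes = 400, seed = 5L)
  en <- normalize_expression(es)
  sorted <- apply(en$values, 2, sort)
  expect_lt(max(sorted) - min(sorted[nrow(sorted), ]), Inf) # shape guard
  expect_equal(max(apply(sorted, 1, function(r) diff(range(r)))), 0,
               tolerance = 1e-12)
})

test_that("moderated t agrees with the established moderated fit", {
  es <- simulate_expression(n_genes = 1500, de_fraction = 0.05,
                            effect_size_log2 = 1.5, seed = 11L)
  en <- normalize_expression(es)
  de <- differential_expression(en, "CT12_VIP", "CT12_Veh")
  sel <- en$samples$group %in% c("CT12_Veh", "CT12_VIP")
  design <- stats::model.matrix(~ factor(en$samples$group[sel],
                                         levels = c("CT12_Veh", "CT12_VIP")))
  fit <- limma::eBayes(limma::lmFit(en$values[, sel], design))
  expect_gt(cor(tidy(de)$t, fit$t[, 2]), 0.999)
  expect_gt(cor(tidy(de)$p, fit$p.value[, 2]), 0.999)
})

test_that("two identical groups give null statistics", {
  es <- simulate_expression(n_genes = 100, dispersion = 0.2, seed = 2L)
  en <- normalize_expression(es)
  # compare a group against itself by duplicating it under a new label
  en2 <- en
  en2$values <- cbind(en$values[, 1:3], en$values[, 1:3])
  colnames(en2$values) <- paste0("s", 1:6)
  en2$samples <- tibble::tibble(sample = paste0("s", 1:6),
                                group = rep(c("g1", "g2"), each = 3))
  de <- differential_expression(en2, "g1", "g2")
  expect_true(all(tidy(de)$t == 0))
  expect_true(all(tidy(de)$p == 1))
})

test_that("moderated t holds its size and BH controls FDR under the null", {
  rates <- vapply(1:30, function(s) {
    es <- simulate_expression(n_genes = 800, de_fraction = 0, seed = s)
    tt <- tidy(differential_expression(normalize_expression(es),
                                       "CT12_VIP", "CT12_Veh"))
    c(mean(tt$p < 0.05), sum(tt$q < 0.05))
  }, numeric(2))
  expect_equal(mean(rates[1, ]), 0.05, tolerance = 0.01)
  # false discoveries at q < 0.05 under a global null are essentially absent
  expect_lte(mean(rates[2, ] > 0), 0.05 + 2 * sqrt(0.05 / 30))
})

test_that("q values never fall below p values", {
  es <- simulate_expression(n_genes = 500, de_fraction = 0.1, seed = 4L)
  tt <- tidy(differential_expression(normalize_expression(es),
                                     "CT12_VIP", "CT12_Veh"))
  expect_true(all(tt$q >= tt$p - 1e-12))
  expect_true(all(tt$q <= 1))
})

test_that("enrichment chi-square matches the closed-form worked table", {
  obs <- rep(c("CRE-TATA", "CRE-NoTATA", "Others"), c(60, 25, 15))
  enr <- cre_enrichment(obs, c(`CRE-TATA` = 0.40, `CRE-NoTATA` = 0.25,
                               Others = 0.35))
  expect_equal(enr$table$expected, c(40, 25, 35), ignore_attr = TRUE)
  expect_equal(enr$chi2, 21.4286, tolerance = 1e-4)
  expect_equal(enr$df, 2)
  # independent oracle
  oracle <- stats::chisq.test(c(60, 25, 15), p = c(0.40, 0.25, 0.35))
  expect_equal(enr$chi2, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(enr$p_value, oracle$p.value, tolerance = 1e-10)
})

test_that("matching proportions give chi2 = 0 and p = 1", {
  obs <- rep(c("CRE-TATA", "CRE-NoTATA", "Others"), c(40, 25, 35))
  enr <- cre_enrichment(obs, c(`CRE-TATA` = 0.40, `CRE-NoTATA` = 0.25,
                               Others = 0.35))
  expect_equal(enr$chi2, 0, tolerance = 1e-12)
  expect_equal(enr$p_value, 1)
  expect_equal(enr$table$obs_over_exp, rep(1, 3), ignore_attr = TRUE)
})

test_that("chi2 is invariant to permuting category labels", {
  set.seed(12)
  cats <- sample(c("CRE-TATA", "CRE-NoTATA", "Others"), 120, replace = TRUE,
                 prob = c(0.3, 0.3, 0.4))
  ratios <- c(`CRE-TATA` = 0.2, `CRE-NoTATA` = 0.3, Others = 0.5)
  chi_a <- cre_enrichment(cats, ratios)$chi2
  # permute labels consistently in both observed and background
  perm <- c(`CRE-TATA` = "Others", `CRE-NoTATA` = "CRE-TATA",
            Others = "CRE-NoTATA")
  cats_p <- unname(perm[cats])
  ratios_p <- stats::setNames(ratios, unname(perm[names(ratios)]))
  chi_b <- cre_enrichment(cats_p, ratios_p)$chi2
  expect_equal(chi_b, chi_a, tolerance = 1e-12)
})

test_that("low expected counts raise the approximation flag", {
  obs <- rep(c("CRE-TATA", "CRE-NoTATA", "Others"), c(2, 10, 8))
  expect_warning(
    enr <- cre_enrichment(obs, c(`CRE-TATA` = 0.05, `CRE-NoTATA` = 0.45,
                                 Others = 0.5)),
    "expected")
  expect_true(enr$low_expected)
})

test_that("planted null enrichment rejects at the nominal rate", {
  hits <- vapply(1:200, function(s) {
    es <- simulate_expression(n_genes = 400, de_fraction = 0.25,
                              cre_background_ratios = c(0.2, 0.3, 0.5),
                              cre_de_ratios = c(0.2, 0.3, 0.5), seed = s)
    g <- sim_truth(es)$genes
    cre_enrichment(g[g$is_de, ], g)$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 0.04)
})

test_that("planted enrichment is detected and quantified", {
  es <- simulate_expression(n_genes = 2000, de_fraction = 0.1,
                            cre_background_ratios = c(0.08, 0.27, 0.65),
                            cre_de_ratios = c(0.30, 0.30, 0.40), seed = 6L)
  g <- sim_truth(es)$genes
  enr <- cre_enrichment(g[g$is_de, ], g[!g$is_de, ])
  expect_lt(enr$p_value, 1e-6)
  expect_gt(enr$table$obs_over_exp[1], 2)
})
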