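# Expression analysis chain: detection filtering, normalisation, moderated-t
# differential expression with FDR, and promoter-category enrichment.

#' Filter undetected genes
#'
#' Drops genes whose detection p-value exceeds `alpha` in every sample of
#' the groups under comparison, i.e. genes never significantly above the
#' negative-control background. A gene detected in at least one relevant
#' sample is kept.
#'
#' @param exprset An `rk_expression` (see [simulate_expression()]).
#' @param alpha Detection p-value cutoff (default 0.01).
#' @param groups Character vector restricting the detection test to the
#'   samples of these groups (default: all samples).
#'
#' @return The filtered `rk_expression`, with a `filter_log` attribute
#'   recording genes kept and dropped.
#' @export
filter_detection <- function(exprset, alpha = 0.01, groups = NULL) {
  check_that(inherits(exprset, "rk_expression"), "exprset",
             "must be an `rk_expression`")
  sel_samples <- if (is.null(groups)) {
    rep(TRUE, ncol(exprset$values))
  } else {
    exprset$samples$group %in% groups
  }
  check_that(any(sel_samples), "groups", "no samples match")
  undetected <- rowSums(exprset$detection_p[, sel_samples, drop = FALSE] <= alpha) == 0
  keep <- !undetected
  out <- exprset
  out$values <- exprset$values[keep, , drop = FALSE]
  out$detection_p <- exprset$detection_p[keep, , drop = FALSE]
  out$genes <- exprset$genes[keep, ]
  attr(out, "filter_log") <- list(kept = sum(keep), dropped = sum(!keep),
                                  alpha = alpha)
  out
}

#' Variance-stabilising transform and quantile normalisation
#'
#' Transforms intensities with `log2(x + offset)` (a simple variance
#' stabiliser for intensity data whose noise grows with the mean) and then
#' quantile-normalises across arrays, replacing each column's order
#' statistics by the mean order statistics so every sample shares one
#' intensity distribution. Quantile normalisation is idempotent, and a
#' technical gain difference on one array (a multiplicative rescaling)
#' shifts only the shared target distribution by a constant on the log
#' scale, leaving all between-group contrasts unchanged.
#'
#' @inheritParams filter_detection
#' @param method `"vst"` (log2 with offset, then quantile) or `"log2"`
#'   (plain `log2(x + offset)` without quantile normalisation).
#' @param offset Additive offset before the log (default 1).
#'
#' @return The `rk_expression` with `values` replaced by normalised
#'   log2-scale values and a `normalisation` attribute.
#' @export
normalize_expression <- function(exprset, method = c("vst", "log2"),
                                 offset = 1) {
  check_that(inherits(exprset, "rk_expression"), "exprset",
             "must be an `rk_expression`")
  method <- match.arg(method)
  lv <- log2(exprset$values + offset)
  if (method == "vst") lv <- quantile_normalize(lv)
  out <- exprset
  out$values <- lv
  attr(out, "normalisation") <- list(method = method, offset = offset,
                                     scale = "log2")
  out
}

#' Quantile-normalise a matrix across columns
#'
#' Thin wrapper over the standard implementation
#' ([limma::normalizeQuantiles()]): each column's sorted values are replaced
#' by the row means of the sorted matrix, ties sharing their average.
#'
#' @param x Numeric matrix (features x samples).
#' @return The normalised matrix, same dimensions and dimnames.
#' @export
quantile_normalize <- function(x) {
  out <- limma::normalizeQuantiles(x)
  dimnames(out) <- dimnames(x)
  out
}

#' Moderated-t differential expression
#'
#' Per-gene two-group comparison on normalised log2 values, with the gene
#' variance shrunk towards a common prior estimated by method of moments on
#' the log sample variances. Writing `s_g^2` for the pooled per-gene
#' variance on `d` df and `z_g = log(s_g^2)`, the excess of `var(z)` over
#' `trigamma(d/2)` estimates `trigamma(d0/2)` and hence the prior df `d0`
#' (infinite when the observed spread is no larger than sampling noise),
#' while `mean(z)` locates the prior variance `s0^2`. The posterior variance
#' `(d0 s0^2 + d s_g^2) / (d0 + d)` gives a t statistic on `d0 + d` df.
#' P-values are adjusted by Benjamini-Hochberg FDR.
#'
#' @inheritParams filter_detection
#' @param group_a,group_b Group labels to compare; the log2 fold change is
#'   `mean(A) - mean(B)`.
#'
#' @return An object of class `rk_de`: per-gene table (via [tidy()]) with
#'   `gene`, `lfc`, `t`, `df`, `p`, `q`, `direction`, plus moderation
#'   parameters via [glance()] (`d0`, `s0_sq`, `n_genes`).
#' @export
#'
#' @examples
#' es <- simulate_expression(n_genes = 300, de_fraction = 0.1,
#'                           effect_size_log2 = 2)
#' de <- differential_expression(normalize_expression(es),
#'                               "CT12_VIP", "CT12_Veh")
#' head(tidy(de))
differential_expression <- function(exprset, group_a, group_b) {
  check_that(inherits(exprset, "rk_expression"), "exprset",
             "must be an `rk_expression`")
  norm <- attr(exprset, "normalisation")
  if (is.null(norm)) {
    warn("exprset has no normalisation attribute; values assumed log2 scale")
  }
  ga <- exprset$samples$sample[exprset$samples$group == group_a]
  gb <- exprset$samples$sample[exprset$samples$group == group_b]
  check_that(length(ga) >= 2 && length(gb) >= 2, "group_a/group_b",
             "need >= 2 samples per group")
  A <- exprset$values[, ga, drop = FALSE]
  B <- exprset$values[, gb, drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  d <- nA + nB - 2
  ss <- (rowSums((A - mA)^2) + rowSums((B - mB)^2))
  s2 <- ss / d

  mod <- moderate_variances(s2, d)
  se <- sqrt(mod$s2_post * (1 / nA + 1 / nB))
  lfc <- mA - mB
  tstat <- ifelse(se > 0, lfc / se, 0)
  df_tot <- d + mod$d0
  p <- 2 * pt(-abs(tstat), df = df_tot)
  q <- p.adjust(p, method = "BH")

  table <- tibble(gene = rownames(exprset$values), lfc = lfc, t = tstat,
                  df = df_tot, p = p, q = q,
                  direction = ifelse(lfc >= 0, "up", "down"))
  structure(list(table = table, d0 = mod$d0, s0_sq = mod$s0_sq,
                 group_a = group_a, group_b = group_b,
                 n_a = nA, n_b = nB),
            class = "rk_de")
}

# Method-of-moments moderation of per-gene variances (log-variance moments).
moderate_variances <- function(s2, d) {
  s2 <- pmax(s2, 1e-12)
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  excess <- var(e) - trigamma(d / 2)
  if (!is.finite(excess) || excess <= 0) {
    d0 <- Inf
    s0_sq <- exp(mean(e))
    s2_post <- rep(s0_sq, length(s2))
  } else {
    # invert trigamma(d0/2) = excess
    f <- function(x) trigamma(x) - excess
    half_d0 <- stats::uniroot(f, c(1e-6, 1e8))$root
    d0 <- 2 * half_d0
    s0_sq <- exp(mean(e) + digamma(half_d0) - log(half_d0))
    s2_post <- (d0 * s0_sq + d * s2) / (d0 + d)
  }
  list(d0 = d0, s0_sq = s0_sq, s2_post = s2_post)
}

#' @method print rk_de
#' @export
print.rk_de <- function(x, ...) {
  cat(sprintf("<rk_de> %s vs %s: %d genes, %d at q < 0.05 (prior df %.1f)\n",
              x$group_a, x$group_b, nrow(x$table), sum(x$table$q < 0.05),
              x$d0))
  invisible(x)
}

#' @method tidy rk_de
#' @export
tidy.rk_de <- function(x, ...) x$table

#' @method glance rk_de
#' @export
glance.rk_de <- function(x, ...) {
  tibble(n_genes = nrow(x$table), n_q05 = sum(x$table$q < 0.05),
         d0 = x$d0, s0_sq = x$s0_sq, group_a = x$group_a,
         group_b = x$group_b)
}

#' @method autoplot rk_de
#' @export
autoplot.rk_de <- function(object, alpha = 0.05, ...) {
  df <- mutate(object$table, sig = .data$q < alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lfc, y = -log10(.data$p),
                                   colour = .data$sig)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "red3"),
                                 name = sprintf("q < %.2g", alpha)) +
    ggplot2::labs(x = expression(log[2] ~ "fold change"),
                  y = expression(-log[10] ~ p),
                  title = sprintf("%s vs %s", object$group_a, object$group_b))
}

#' Promoter-category enrichment chi-square
#'
#' Tests whether differentially expressed genes are enriched for promoter
#' CRE categories relative to the background of all detected genes in the
#' comparison. Expected counts are the background category ratios scaled to
#' the number of DE genes; the statistic is Pearson's
#' `chi2 = sum (obs - exp)^2 / exp` on `categories - 1` df, and
#' observed/expected ratios are reported per category.
#'
#' @param de_genes Data frame of DE genes with a `cre_category` column (or
#'   a factor/character vector of categories).
#' @param background Data frame of all detected genes with `cre_category`
#'   (or a named ratio vector summing to 1).
#'
#' @return An object of class `rk_enrichment` with per-category `observed`,
#'   `expected` and `obs_over_exp`, plus `chi2`, `df`, `p_value` and
#'   `low_expected` (TRUE when any expected count < 5, where the
#'   chi-squared approximation weakens). [tidy()] returns the category
#'   table, [glance()] the test summary.
#' @export
#'
#' @examples
#' obs <- rep(c("CRE-TATA", "CRE-NoTATA", "Others"), c(60, 25, 15))
#' cre_enrichment(obs, c(`CRE-TATA` = 0.40, `CRE-NoTATA` = 0.25,
#'                       Others = 0.35))
cre_enrichment <- function(de_genes, background) {
  cats <- if (is.data.frame(de_genes)) de_genes$cre_category else de_genes
  check_that(!is.null(cats) && length(cats) > 0, "de_genes",
             "must carry CRE categories")
  cats <- factor(as.character(cats), levels = cre_levels)
  check_that(!anyNA(cats), "de_genes",
             "contains categories outside {CRE-TATA, CRE-NoTATA, Others}")

  ratios <- if (is.data.frame(background)) {
    bg <- factor(as.character(background$cre_category), levels = cre_levels)
    as.numeric(table(bg)) / length(bg)
  } else {
    check_that(abs(sum(background) - 1) < 1e-6, "background",
               "ratios must sum to 1")
    background[cre_levels]
  }
  observed <- as.numeric(table(cats))
  expected <- unname(ratios) * length(cats)
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(cre_levels) - 1
  p <- pchisq(chi2, df, lower.tail = FALSE)
  low <- any(expected < 5)
  if (low) warn("some expected counts are below 5; chi-square approximate")
  structure(list(
    table = tibble(cre_category = cre_levels, observed = observed,
                   expected = expected,
                   obs_over_exp = observed / expected),
    chi2 = chi2, df = df, p_value = p, n_de = length(cats),
    low_expected = low),
    class = "rk_enrichment")
}

#' @method print rk_enrichment
#' @export
print.rk_enrichment <- function(x, ...) {
  cat(sprintf("<rk_enrichment> chi2 = %.2f, df = %d, p = %.3g (n = %d)\n",
              x$chi2, x$df, x$p_value, x$n_de))
  print(x$table)
  invisible(x)
}

#' @method tidy rk_enrichment
#' @export
tidy.rk_enrichment <- function(x, ...) x$table

#' @method glance rk_enrichment
#' @export
glance.rk_enrichment <- function(x, ...) {
  tibble(chi2 = x$chi2, df = x$df, p_value = x$p_value, n_de = x$n_de,
         low_expected = x$low_expected)
}

#' @method autoplot rk_enrichment
#' @export
autoplot.rk_enrichment <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$cre_category,
                               y = .data$obs_over_exp)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Observed / expected",
                  title = sprintf("CRE enrichment (chi2 = %.1f, p = %.2g)",
                                  object$chi2, object$p_value))
}
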