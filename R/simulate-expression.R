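# Synthetic expression matrices emulating a four-group treated-slice
# microarray design with planted differential expression and promoter-element
# (CRE category) enrichment.

#' Specification of a synthetic expression experiment
#'
#' Log-normal intensities for `n_genes` genes across the sample groups of a
#' treatment time-course (defaults: an untreated baseline, a vehicle group
#' and two treated groups, 3 slices each). A fraction `de_fraction` of genes
#' is differentially expressed in `de_group`, shifted by
#' `effect_size_log2` log2 units (a fraction `up_fraction` upwards, the rest
#' down). Detection p-values are near zero for expressed genes while a
#' fraction `detection_fail_fraction` of genes fails detection (p > 0.01) in
#' every sample. Each gene carries a promoter category in
#' `{CRE-TATA, CRE-NoTATA, Others}`: null genes are sampled from
#' `cre_background_ratios`, planted DE genes from `cre_de_ratios`, so
#' category enrichment among DE calls is controlled exactly.
#'
#' @param n_genes Number of genes.
#' @param groups Named integer vector: samples per group.
#' @param de_group Group carrying the planted effect.
#' @param de_fraction Fraction of genes differentially expressed in
#'   `de_group`.
#' @param effect_size_log2 Planted |log2 fold change|.
#' @param up_fraction Fraction of DE genes shifted upwards.
#' @param dispersion SD of the per-sample log2 noise.
#' @param detection_fail_fraction Fraction of genes undetected everywhere.
#' @param cre_background_ratios,cre_de_ratios Length-3 probability vectors
#'   over `c("CRE-TATA", "CRE-NoTATA", "Others")`, each summing to 1.
#' @param seed Integer seed.
#'
#' @return A validated list of class `expression_spec`.
#' @export
expression_spec <- function(n_genes = 5000,
                            groups = c(CT10 = 3, CT12_Veh = 3,
                                       CT12_VIP = 3, CT16_VIP = 3),
                            de_group = "CT12_VIP", de_fraction = 0.05,
                            effect_size_log2 = 1, up_fraction = 0.65,
                            dispersion = 0.25,
                            detection_fail_fraction = 0.1,
                            cre_background_ratios = c(0.08, 0.27, 0.65),
                            cre_de_ratios = c(0.08, 0.27, 0.65),
                            seed = 1L) {
  check_that(n_genes >= 10, "n_genes", "must be >= 10")
  check_that(!is.null(names(groups)) && all(groups >= 2), "groups",
             "must be a named vector with >= 2 samples per group")
  check_that(de_group %in% names(groups), "de_group",
             "must name one of the groups")
  check_that(de_fraction >= 0 && de_fraction <= 1, "de_fraction",
             "must lie in [0, 1]")
  check_that(detection_fail_fraction >= 0 && detection_fail_fraction <= 1,
             "detection_fail_fraction", "must lie in [0, 1]")
  check_that(up_fraction >= 0 && up_fraction <= 1, "up_fraction",
             "must lie in [0, 1]")
  check_that(length(cre_background_ratios) == 3 &&
               abs(sum(cre_background_ratios) - 1) < 1e-9,
             "cre_background_ratios", "must be 3 ratios summing to 1")
  check_that(length(cre_de_ratios) == 3 && abs(sum(cre_de_ratios) - 1) < 1e-9,
             "cre_de_ratios", "must be 3 ratios summing to 1")
  check_that(dispersion >= 0, "dispersion", "must be >= 0")
  structure(list(n_genes = as.integer(n_genes), groups = groups,
                 de_group = de_group, de_fraction = de_fraction,
                 effect_size_log2 = effect_size_log2,
                 up_fraction = up_fraction, dispersion = dispersion,
                 detection_fail_fraction = detection_fail_fraction,
                 cre_background_ratios = cre_background_ratios,
                 cre_de_ratios = cre_de_ratios, seed = as.integer(seed)),
            class = "expression_spec")
}

cre_levels <- c("CRE-TATA", "CRE-NoTATA", "Others")

#' Simulate an expression experiment
#'
#' @param spec An [expression_spec()], or arguments forwarded to it.
#' @param ... Passed to [expression_spec()] when `spec` is missing.
#'
#' @return An object of class `rk_expression`: a list with `values`
#'   (genes x samples intensity matrix, linear scale), `detection_p`
#'   (same shape), `samples` (tibble: `sample`, `group`) and `genes`
#'   (tibble: `gene`, `cre_category`, `is_de`, `true_lfc`, `detected`).
#'   [sim_truth()] returns the spec and the planted gene table.
#' @export
#'
#' @examples
#' es <- simulate_expression(n_genes = 200)
#' dim(es$values)
simulate_expression <- function(spec = NULL, ...) {
  if (is.null(spec)) spec <- expression_spec(...)
  check_that(inherits(spec, "expression_spec"), "spec",
             "must be an `expression_spec`")
  s <- spec
  n_s <- sum(s$groups)
  group <- rep(names(s$groups), s$groups)
  sample_id <- paste0(group, "_", unlist(lapply(s$groups, seq_len)))
  gene_id <- sprintf("gene_%05d", seq_len(s$n_genes))

  out <- with_seed(s$seed, {
    mu <- rnorm(s$n_genes, 8, 1)
    n_de <- round(s$de_fraction * s$n_genes)
    is_de <- c(rep(TRUE, n_de), rep(FALSE, s$n_genes - n_de))
    sign_up <- runif(s$n_genes) < s$up_fraction
    true_lfc <- ifelse(is_de, ifelse(sign_up, 1, -1) * s$effect_size_log2, 0)

    log2v <- matrix(rnorm(s$n_genes * n_s, 0, s$dispersion), s$n_genes, n_s)
    log2v <- log2v + mu
    in_de_group <- group == s$de_group
    log2v[, in_de_group] <- log2v[, in_de_group] + true_lfc

    n_fail <- round(s$detection_fail_fraction * s$n_genes)
    fail <- sample.int(s$n_genes, n_fail)
    detp <- matrix(runif(s$n_genes * n_s, 0, 0.009), s$n_genes, n_s)
    detp[fail, ] <- runif(n_fail * n_s, 0.02, 1)

    cre <- character(s$n_genes)
    cre[is_de] <- sample(cre_levels, n_de, replace = TRUE,
                         prob = s$cre_de_ratios)
    cre[!is_de] <- sample(cre_levels, s$n_genes - n_de, replace = TRUE,
                          prob = s$cre_background_ratios)

    list(values = 2^log2v, detp = detp, is_de = is_de, true_lfc = true_lfc,
         cre = cre, fail = fail)
  })

  values <- out$values
  dimnames(values) <- list(gene_id, sample_id)
  detp <- out$detp
  dimnames(detp) <- dimnames(values)
  detected <- !(seq_len(s$n_genes) %in% out$fail)

  structure(list(
    values = values, detection_p = detp,
    samples = tibble(sample = sample_id, group = group),
    genes = tibble(gene = gene_id,
                   cre_category = factor(out$cre, levels = cre_levels),
                   is_de = out$is_de, true_lfc = out$true_lfc,
                   detected = detected),
    truth = list(spec = s,
                 genes = tibble(gene = gene_id, is_de = out$is_de,
                                true_lfc = out$true_lfc,
                                cre_category = factor(out$cre,
                                                      levels = cre_levels)))),
    class = "rk_expression")
}

#' @method print rk_expression
#' @export
print.rk_expression <- function(x, ...) {
  cat(sprintf("<rk_expression> %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$samples$group), collapse = ", ")))
  invisible(x)
}
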