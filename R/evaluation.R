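# Segmentation metrics, biological-accuracy comparison of component counts,
# caliper-style linear validation, and broad-sense heritability from clonal
# replicates.

#' Jaccard index of two binary masks
#'
#' Intersection over union; two empty masks score 1.
#'
#' @param pred,truth logical matrices of equal shape.
#' @return Scalar in `[0, 1]`.
#' @export
jaccard <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) abort("shape mismatch")
  un <- sum(pred | truth)
  if (un == 0) return(1)
  sum(pred & truth) / un
}

#' Recall (sensitivity) of a segmentation
#'
#' Probability of detecting a foreground pixel: `TP / (TP + FN)`.
#'
#' @param pred,truth logical matrices of equal shape; `truth` non-empty.
#' @return Scalar in `[0, 1]`.
#' @export
recall <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) abort("shape mismatch")
  if (!any(truth)) abort("recall undefined for empty truth")
  sum(pred & truth) / sum(truth)
}

#' Segmentation score summary
#'
#' @param pred,truth logical masks.
#' @param connectivity component connectivity (default 8).
#' @return One-row tibble: `jaccard`, `recall`, `n_components_pred`,
#'   `n_components_truth`.
#' @export
seg_score <- function(pred, truth, connectivity = 8) {
  tibble(jaccard = jaccard(pred, truth),
         recall = recall(pred, truth),
         n_components_pred = connected_components(pred, connectivity)$count,
         n_components_truth = connected_components(truth, connectivity)$count)
}

#' Compare connected-component counts across models
#'
#' One-way ANOVA over per-image component counts followed by Tukey's honest
#' significant difference test at `alpha = 0.05`; models sharing a group
#' letter do not differ significantly.
#'
#' @param counts_by_model named list of numeric vectors (component counts per
#'   image, equal lengths not required but >= 2 per model).
#' @return A `component_comparison`: list with `summary` (tibble: model,
#'   mean, ci_lo, ci_hi, n, group) and the underlying `aov` fit.
#' @export
component_count_comparison <- function(counts_by_model) {
  if (length(counts_by_model) < 2) abort("need at least 2 models")
  if (any(vapply(counts_by_model, length, integer(1)) < 2)) {
    abort("need at least 2 observations per model")
  }
  df <- dplyr::bind_rows(lapply(names(counts_by_model), function(m) {
    tibble(model = m, count = as.numeric(counts_by_model[[m]]))
  }))
  df$model <- factor(df$model)
  fit <- aov(count ~ model, data = df)
  letters <- tryCatch({
    glht <- multcomp::glht(fit, linfct = multcomp::mcp(model = "Tukey"))
    multcomp::cld(glht)$mcletters$Letters
  }, error = function(e) setNames(rep("a", nlevels(df$model)), levels(df$model)))
  summ <- df |>
    dplyr::group_by(model) |>
    dplyr::summarise(mean = mean(count), sd = sd(count), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(
      se = .data$sd / sqrt(.data$n),
      ci_lo = .data$mean - stats::qt(0.975, .data$n - 1) * .data$se,
      ci_hi = .data$mean + stats::qt(0.975, .data$n - 1) * .data$se,
      group = unname(letters[as.character(.data$model)]))
  structure(list(summary = summ, fit = fit, data = df),
            class = "component_comparison")
}

#' @export
print.component_comparison <- function(x, ...) {
  cat("Connected-component comparison (Tukey HSD, alpha = 0.05)\n")
  print(x$summary)
  invisible(x)
}

#' Linear validation of digital against manual measurements
#'
#' Ordinary least squares of the manual measurement on the image-derived
#' prediction, as used to validate petiole length/width against calipers.
#'
#' @param pred numeric vector of image-derived values.
#' @param manual numeric vector of reference measurements.
#' @return A `linear_validation` object with `r_squared`, `slope`,
#'   `intercept` and the `lm` fit.
#' @export
linear_validation <- function(pred, manual) {
  if (length(pred) != length(manual)) abort("lengths differ")
  if (length(pred) < 3) abort("need at least 3 paired values")
  if (stats::var(pred) == 0) abort("zero variance in predictions")
  fit <- lm(manual ~ pred, data = data.frame(pred = pred, manual = manual))
  # coefficient of determination computed directly; a constant reference has
  # no variance to explain, so R^2 is 0 by convention (summary.lm is
  # numerically unreliable in that case)
  sst <- sum((manual - mean(manual))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 0
  structure(list(r_squared = r2,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 fit = fit,
                 data = tibble(pred = pred, manual = manual)),
            class = "linear_validation")
}

#' @export
print.linear_validation <- function(x, ...) {
  cat(sprintf("Linear validation: R^2 = %.4f, slope = %.4f, intercept = %.4f (n = %d)\n",
              x$r_squared, x$slope, x$intercept, nrow(x$data)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.linear_validation <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @export
glance.linear_validation <- function(x, ...) {
  tibble(r_squared = x$r_squared, slope = x$slope, intercept = x$intercept,
         n = nrow(x$data))
}

#' Broad-sense heritability from clonal replicates
#'
#' One-way random-effects variance decomposition over genotypes:
#' `sigma2_E` is the within-genotype mean square, `sigma2_G` is
#' `max(0, (MS_between - MS_within) / k_bar)` with
#' `k_bar = (sum(k) - sum(k^2)/sum(k)) / (g - 1)` the effective clone number
#' for unbalanced designs, and `H2 = sigma2_G / (sigma2_G + sigma2_E)`.
#'
#' @param values numeric trait values, one per sample.
#' @param genotype_ids genotype identifier per sample.
#' @param mad_filter optional robust outlier cutoff: samples further than
#'   `mad_filter` median absolute deviations from the median are dropped
#'   before estimation (the field workflow uses 6).
#' @return A `heritability_est`: `H2`, `sigma2_G`, `sigma2_E`,
#'   `n_genotypes`, `mean_clones`, `k_bar`, `n_used`.
#' @export
heritability <- function(values, genotype_ids, mad_filter = NULL) {
  if (length(values) != length(genotype_ids)) abort("lengths differ")
  keep <- !is.na(values)
  if (!is.null(mad_filter)) {
    md <- median(values[keep])
    s <- mad(values[keep])
    if (s > 0) keep <- keep & (abs(values - md) / s <= mad_filter)
  }
  v <- values[keep]
  g <- factor(genotype_ids[keep])
  k <- table(g)
  if (nlevels(g) < 2) abort("need at least 2 genotypes")
  if (all(k < 2)) abort("all genotypes are singletons; within-genotype variance undefined")
  n <- length(v)
  gn <- nlevels(g)
  fit <- aov(v ~ g)
  # only the mean squares are used; the F-test warning on perfect fits is
  # irrelevant here
  tab <- suppressWarnings(anova(fit))
  ms_between <- tab$`Mean Sq`[1]
  ms_within <- tab$`Mean Sq`[2]
  k_bar <- (n - sum(k^2) / n) / (gn - 1)
  sigma2_G <- max(0, (ms_between - ms_within) / k_bar)
  sigma2_E <- ms_within
  H2 <- if (sigma2_G + sigma2_E > 0) sigma2_G / (sigma2_G + sigma2_E) else 0
  structure(list(H2 = H2, sigma2_G = sigma2_G, sigma2_E = sigma2_E,
                 n_genotypes = gn, mean_clones = mean(k), k_bar = k_bar,
                 n_used = n),
            class = "heritability_est")
}

#' @export
print.heritability_est <- function(x, ...) {
  cat(sprintf(
    "Broad-sense heritability: H2 = %.3f (sigma2_G = %.4g, sigma2_E = %.4g; %d genotypes, %.1f clones each)\n",
    x$H2, x$sigma2_G, x$sigma2_E, x$n_genotypes, x$mean_clones))
  invisible(x)
}

#' @export
tidy.heritability_est <- function(x, ...) {
  tibble(component = c("genotypic", "environmental"),
         variance = c(x$sigma2_G, x$sigma2_E),
         proportion = c(x$H2, 1 - x$H2))
}

#' @export
glance.heritability_est <- function(x, ...) {
  tibble(H2 = x$H2, sigma2_G = x$sigma2_G, sigma2_E = x$sigma2_E,
         n_genotypes = x$n_genotypes, mean_clones = x$mean_clones,
         n_used = x$n_used)
}
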