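#' Benjamini-Hochberg adjustment with rejection flags
#'
#' Step-up false discovery rate control: with sorted p-values `p_(1) <=
#' ... <= p_(m)`, reject all hypotheses up to the largest `i` with
#' `p_(i) <= (i/m) * fdr`. Adjusted p-values use the standard monotone
#' cumulative-minimum construction, so `reject == (adjusted <= fdr)`.
#'
#' @param p Vector of p-values in `[0, 1]` (NA allowed; never rejected).
#' @param fdr Target false discovery rate in (0, 1) (default 0.20).
#' @return A tibble with columns `p`, `adjusted`, `reject`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.5), fdr = 0.2)
#' @export
bh_adjust <- function(p, fdr = 0.20) {
  if (fdr <= 0 || fdr >= 1) abort("`fdr` must lie in (0, 1).")
  if (length(p) == 0) {
    return(tibble(p = numeric(), adjusted = numeric(),
                  reject = logical()))
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  adj <- p.adjust(p, method = "BH")
  tibble(p = p, adjusted = adj,
         reject = !is.na(adj) & adj <= fdr)
}

#' Screen every taxon of a composition table as a mediator
#'
#' Fits the marginal zero-inflated mediation model taxon by taxon, computes
#' delta-method inference for the abundance (`NIE1`) and presence (`NIE2`)
#' components of the natural indirect effect, and controls the false
#' discovery rate by Benjamini-Hochberg separately within each component.
#' Taxa that are absent everywhere, have fewer than `min_positive` positive
#' observations, or whose fit fails are flagged and excluded from the
#' adjustment family. Taxa with no observed zeros are testable for `NIE1`
#' but have a structurally zero `NIE2` (p = 1); such untestable hypotheses
#' are excluded from the `NIE2` family size. Confidence intervals are
#' reported unadjusted; only the significance flags use the FDR rule.
#'
#' @param composition Numeric matrix or data frame of relative abundances,
#'   samples in rows, taxa in columns (column names identify taxa).
#' @param y Outcome vector.
#' @param x Exposure vector.
#' @param lib_size Library-size vector.
#' @param spec An [effect_spec()] object.
#' @param fdr Target false discovery rate (default 0.20).
#' @param min_positive Minimum positive observations to attempt a fit
#'   (default 5).
#' @param quad A [quad_spec()] object.
#' @param interactions Interaction configuration, see [initial_params()].
#' @return A tibble of class `marzic_screen`, one row per taxon, with the
#'   effect estimates, standard errors, confidence limits, raw and adjusted
#'   p-values, significance flags and fit diagnostics.
#' @export
screen_taxa <- function(composition, y, x, lib_size,
                        spec = effect_spec(), fdr = 0.20,
                        min_positive = 5L, quad = quad_spec(),
                        interactions = "both") {
  composition <- as.matrix(composition)
  storage.mode(composition) <- "double"
  n <- nrow(composition)
  if (length(y) != n || length(x) != n || length(lib_size) != n) {
    abort("`composition`, `y`, `x` and `lib_size` must be aligned.")
  }
  taxa <- colnames(composition) %||% paste0("taxon", seq_len(ncol(composition)))

  one <- function(j) {
    m <- composition[, j]
    base <- tibble(
      taxon = taxa[j],
      nie1 = NA_real_, nie1_se = NA_real_, nie1_low = NA_real_,
      nie1_high = NA_real_, nie1_p = NA_real_,
      nie2 = NA_real_, nie2_se = NA_real_, nie2_low = NA_real_,
      nie2_high = NA_real_, nie2_p = NA_real_,
      nie = NA_real_, nde = NA_real_, cde = NA_real_,
      converged = FALSE, n_zero_obs = sum(m == 0),
      skipped = NA_character_
    )
    if (all(m == 0)) { base$skipped <- "all zero"; return(base) }
    if (sum(m > 0) < min_positive) {
      base$skipped <- "too few positive"; return(base)
    }
    fit <- tryCatch(
      suppressWarnings(fit_mle(mediation_data(y, m, lib_size, x),
                               quad = quad, interactions = interactions)),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged || is.null(fit$vcov)) {
      base$skipped <- "fit failed"; return(base)
    }
    eff <- tryCatch(effects_ci(fit, spec), error = function(e) NULL)
    if (is.null(eff)) { base$skipped <- "inference failed"; return(base) }
    g <- function(name, col) eff[[col]][eff$effect == name]
    tibble(
      taxon = taxa[j],
      nie1 = g("NIE1", "estimate"), nie1_se = g("NIE1", "std.error"),
      nie1_low = g("NIE1", "conf.low"), nie1_high = g("NIE1", "conf.high"),
      nie1_p = g("NIE1", "p.value"),
      nie2 = g("NIE2", "estimate"), nie2_se = g("NIE2", "std.error"),
      nie2_low = g("NIE2", "conf.low"), nie2_high = g("NIE2", "conf.high"),
      nie2_p = g("NIE2", "p.value"),
      nie = g("NIE", "estimate"), nde = g("NDE", "estimate"),
      cde = g("CDE", "estimate"),
      converged = TRUE, n_zero_obs = fit$n_zero_obs,
      skipped = NA_character_
    )
  }

  res <- purrr::map_dfr(seq_along(taxa), one)
  if (all(!is.na(res$skipped))) abort("All taxa were skipped.")

  # separate BH families; structurally-zero NIE2 (se = 0) is untestable
  fam1 <- is.na(res$skipped)
  fam2 <- fam1 & res$nie2_se > 0
  res$nie1_padj <- NA_real_
  res$nie1_sig <- FALSE
  res$nie2_padj <- NA_real_
  res$nie2_sig <- FALSE
  if (any(fam1)) {
    a1 <- bh_adjust(res$nie1_p[fam1], fdr)
    res$nie1_padj[fam1] <- a1$adjusted
    res$nie1_sig[fam1] <- a1$reject
  }
  if (any(fam2)) {
    a2 <- bh_adjust(res$nie2_p[fam2], fdr)
    res$nie2_padj[fam2] <- a2$adjusted
    res$nie2_sig[fam2] <- a2$reject
  }
  res <- dplyr::relocate(res, "nie1_padj", "nie1_sig",
                         .after = "nie1_p")
  res <- dplyr::relocate(res, "nie2_padj", "nie2_sig",
                         .after = "nie2_p")
  attr(res, "fdr") <- fdr
  attr(res, "spec") <- spec
  attr(res, "presence") <- composition > 0
  class(res) <- c("marzic_screen", class(res))
  res
}

#' Confusion metrics of a screening run against known truth
#'
#' Compares the significance flags with per-taxon truth labels for each
#' effect component. Recall is `TP / (TP + FN)` (statistical power);
#' precision is `TP / (TP + FP)` and is defined as 1 when there are no
#' false positives (precision is one minus the realised false discovery
#' proportion); F1 is the harmonic mean of the two. Skipped taxa count as
#' not rejected.
#'
#' @param results A `marzic_screen` tibble.
#' @param truth A data frame with columns `taxon`, `nie1_true`,
#'   `nie2_true` (logical), aligned by taxon name.
#' @return A tibble with one row per effect component: `effect`, `tp`,
#'   `fp`, `tn`, `fn`, `recall`, `precision`, `f1`.
#' @export
evaluate_screen <- function(results, truth) {
  stopifnot(all(c("taxon", "nie1_true", "nie2_true") %in% names(truth)))
  ix <- match(results$taxon, truth$taxon)
  if (any(is.na(ix))) abort("Truth labels missing for some taxa.")
  one <- function(flag, lab) {
    flag[is.na(flag)] <- FALSE
    tp <- sum(flag & lab); fp <- sum(flag & !lab)
    fn <- sum(!flag & lab); tn <- sum(!flag & !lab)
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    precision <- if (fp == 0) 1 else tp / (tp + fp)
    f1 <- if (!is.na(recall) && (recall + precision) > 0) {
      2 * recall * precision / (recall + precision)
    } else NA_real_
    tibble(tp = tp, fp = fp, tn = tn, fn = fn,
           recall = recall, precision = precision, f1 = f1)
  }
  dplyr::bind_rows(
    dplyr::mutate(one(results$nie1_sig, truth$nie1_true[ix]),
                  effect = "NIE1", .before = 1),
    dplyr::mutate(one(results$nie2_sig, truth$nie2_true[ix]),
                  effect = "NIE2", .before = 1)
  )
}

#' Signed mediation-strength matrix for heatmap rendering
#'
#' Per taxon, mediation strength is `1 - p` (raw, unadjusted p-value of the
#' abundance component) carrying the sign of the abundance-component
#' estimate. With the presence pattern stored by [screen_taxa()], the
#' strength is expanded to a taxa-by-samples matrix with `NA` where a taxon
#' is absent from a sample, ready for heatmap rendering.
#'
#' @param results A `marzic_screen` tibble.
#' @param per_sample Expand to a taxa x samples matrix using the presence
#'   pattern (default `TRUE` when available).
#' @return A numeric matrix (taxa x samples), or a single-column matrix of
#'   per-taxon strengths when no presence pattern is available.
#' @export
heatmap_table <- function(results, per_sample = TRUE) {
  strength <- ifelse(is.na(results$nie1_p), NA_real_,
                     sign(results$nie1) * (1 - results$nie1_p))
  pres <- attr(results, "presence")
  if (!per_sample || is.null(pres)) {
    return(matrix(strength, ncol = 1,
                  dimnames = list(results$taxon, "strength")))
  }
  out <- matrix(rep(strength, each = nrow(pres)), nrow = ncol(pres),
                byrow = TRUE,
                dimnames = list(results$taxon,
                                rownames(pres) %||%
                                  paste0("s", seq_len(nrow(pres)))))
  out[t(!pres)] <- NA_real_
  out
}

#' Heatmap of per-taxon mediation strength
#'
#' @param object A `marzic_screen` tibble.
#' @param ... Unused.
#' @return A ggplot object: taxa by samples, fill is signed strength
#'   `sign(NIE1) * (1 - p)`; absent taxa are blank.
#' @method autoplot marzic_screen
#' @export
autoplot.marzic_screen <- function(object, ...) {
  ht <- heatmap_table(object)
  df <- as_tibble(as.table(ht), .name_repair = "minimal")
  names(df) <- c("taxon", "sample", "strength")
  ggplot(df, aes(x = .data$sample, y = .data$taxon,
                 fill = .data$strength)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         na.value = "grey92", limits = c(-1, 1)) +
    labs(x = "Sample", y = "Taxon", fill = "Mediation\nstrength") +
    theme_minimal()
}

#' Tidy a screening result
#'
#' @param x A `marzic_screen` tibble.
#' @param ... Unused.
#' @return The underlying tibble without the class attribute.
#' @method tidy marzic_screen
#' @export
tidy.marzic_screen <- function(x, ...) {
  out <- x
  attr(out, "presence") <- NULL
  class(out) <- setdiff(class(out), "marzic_screen")
  as_tibble(out)
}
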