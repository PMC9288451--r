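#' Library-normalised log2 counts per million
#'
#' `log2(count / library_size * 1e6 + prior)` with a prior count of 0.5 by
#' default, so a zero count maps to `log2(0.5) = -1` and the transform is
#' defined everywhere.
#'
#' @param counts [expression_matrix()] with `scale = "counts"`.
#' @param prior pseudo-CPM added before the log (default 0.5).
#' @return [expression_matrix()] with `scale = "log_cpm"`.
#' @export
normalize_log_cpm <- function(counts, prior = 0.5) {
  stopifnot(inherits(counts, "fc_expression_matrix"))
  if (counts$scale != "counts") {
    fc_stop("fc_wrong_scale", "normalize_log_cpm expects raw counts")
  }
  lib <- colSums(counts$values)
  if (any(lib <= 0)) {
    fc_stop("fc_zero_library", "sample(s) with zero library size: %s",
            paste(colnames(counts$values)[lib <= 0], collapse = ", "))
  }
  cpm <- sweep(counts$values, 2L, lib, "/") * 1e6
  expression_matrix(log2(cpm + prior), kind = counts$kind, scale = "log_cpm")
}

#' Remove lowly expressed features
#'
#' Keeps features with CPM >= `min_cpm` in at least `min_samples` samples
#' (boundary inclusive). By default `min_samples` is the size of the
#' smallest (model, arm, day) group in the design, so a feature expressed in
#' just one full experimental group survives.
#'
#' @param counts [expression_matrix()] with `scale = "counts"`.
#' @param design `fc_sample_design`; only used for the `min_samples` default.
#' @param min_cpm CPM threshold (default 1).
#' @param min_samples minimum number of samples at or above `min_cpm`.
#' @return filtered counts matrix.
#' @export
filter_low_expression <- function(counts, design, min_cpm = 1,
                                  min_samples = NULL) {
  stopifnot(inherits(counts, "fc_expression_matrix"))
  if (counts$scale != "counts") {
    fc_stop("fc_wrong_scale", "filter_low_expression expects raw counts")
  }
  if (is.null(min_samples)) {
    grp <- table(paste(design$model, design$arm, design$day))
    min_samples <- min(grp)
  }
  lib <- colSums(counts$values)
  cpm <- sweep(counts$values, 2L, lib, "/") * 1e6
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  em_subset(counts, features = feature_ids(counts)[keep])
}

# Vectorised Welch two-sample t-test across matrix rows; returns two-sided p.
welch_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1L)
  vb <- rowSums((b - mb)^2) / (nb - 1L)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  # identical groups: zero difference and zero variance -> no evidence
  p[se2 == 0 & ma == mb] <- 1
  list(diff = ma - mb, p = p)
}

#' Differential expression for one model x day contrast
#'
#' Treated vs same-day same-model control on log-CPM values: the effect is
#' the difference of group means (log2 fold change), tested per feature with
#' a two-sided Welch t-test, and Benjamini-Hochberg adjusted across all
#' features of this single contrast. A feature is flagged differentially
#' expressed when `|log2fc| >= lfc_threshold` and `adj_p <= alpha`.
#'
#' @param log_cpm [expression_matrix()] with `scale = "log_cpm"`.
#' @param design `fc_sample_design` covering the matrix samples.
#' @param model `"bleomycin"` or `"aav_tgfb1"`.
#' @param day time point (days post-administration).
#' @param lfc_threshold absolute log2 fold-change cut (default 0.6).
#' @param alpha adjusted-p cut (default 0.05).
#' @return data frame of class `fc_contrasts` with columns `feature_id`,
#'   `model`, `day`, `log2fc`, `p_value`, `adj_p`, `mean_log_cpm`, `de_flag`.
#' @export
run_contrast <- function(log_cpm, design, model, day, lfc_threshold = 0.6,
                         alpha = 0.05) {
  stopifnot(inherits(log_cpm, "fc_expression_matrix"))
  if (log_cpm$scale != "log_cpm") {
    fc_stop("fc_wrong_scale", "run_contrast expects log-CPM values")
  }
  model <- match.arg(model, MODELS)
  trt <- design_samples(design, model, "treated", day)
  ctl <- design_samples(design, model, "control", day)
  if (length(trt) < 2L || length(ctl) < 2L) {
    fc_stop("fc_small_group", "%s day %d: need >=2 samples per arm", model, day)
  }
  a <- log_cpm$values[, trt, drop = FALSE]
  b <- log_cpm$values[, ctl, drop = FALSE]
  w <- welch_rows(a, b)
  adj <- p.adjust(w$p, method = "BH")
  df <- data.frame(
    feature_id = feature_ids(log_cpm), model = model, day = as.integer(day),
    log2fc = unname(w$diff), p_value = unname(w$p), adj_p = unname(adj),
    mean_log_cpm = unname(rowMeans(cbind(a, b))),
    de_flag = unname(abs(w$diff) >= lfc_threshold & adj <= alpha),
    stringsAsFactors = FALSE)
  class(df) <- c("fc_contrasts", "data.frame")
  df
}

#' All model x day contrasts of a design
#'
#' @inheritParams run_contrast
#' @param models models to test (default both).
#' @param days days to test (default: all treated days in the design).
#' @return row-bound `fc_contrasts` across contrasts.
#' @export
run_all_contrasts <- function(log_cpm, design, models = MODELS, days = NULL,
                              lfc_threshold = 0.6, alpha = 0.05) {
  if (is.null(days)) days <- sort(unique(design$day[design$arm == "treated"]))
  out <- list()
  for (m in models) for (d in days) {
    out[[paste(m, d)]] <- run_contrast(log_cpm, design, m, d,
                                       lfc_threshold = lfc_threshold,
                                       alpha = alpha)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("fc_contrasts", "data.frame")
  res
}

#' Count differentially expressed features per model and day
#'
#' @param results `fc_contrasts` (possibly spanning many contrasts).
#' @return data frame with columns `model`, `day`, `n_de`.
#' @export
count_de_over_time <- function(results) {
  agg <- aggregate(de_flag ~ model + day, data = results, FUN = sum)
  names(agg)[names(agg) == "de_flag"] <- "n_de"
  agg <- agg[order(agg$model, agg$day), ]
  rownames(agg) <- NULL
  agg
}

# Wide per-feature log2fc profiles: list by model of features x days matrices.
log2fc_profiles <- function(results, models = MODELS) {
  days <- sort(unique(results$day))
  out <- lapply(models, function(m) {
    sub <- results[results$model == m, ]
    feats <- unique(sub$feature_id)
    mat <- matrix(NA_real_, length(feats), length(days),
                  dimnames = list(feats, as.character(days)))
    mat[cbind(match(sub$feature_id, feats), match(sub$day, days))] <- sub$log2fc
    mat
  })
  names(out) <- models
  out
}
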