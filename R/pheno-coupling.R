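#' Pearson product-moment correlation with explicit undefined handling
#'
#' Returns `NA_real_` (the explicit "undefined correlation" signal) when
#' either input has zero variance instead of propagating a silent zero.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`, or `NA_real_` if undefined.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    fc_stop("fc_bad_input", "pearson_r needs equal lengths >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  cor(x, y, method = "pearson")
}

#' Spearman rank correlation with average ranks for ties
#'
#' Pearson correlation of average-ranked values; all-tied input yields the
#' explicit `NA_real_` undefined signal.
#'
#' @inheritParams pearson_r
#' @return rank correlation in `[-1, 1]`, or `NA_real_` if undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    fc_stop("fc_bad_input", "spearman_rho needs equal lengths >= 3")
  }
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  cor(rx, ry, method = "pearson")
}

#' Validate a lung-compliance trajectory
#'
#' @param model `"bleomycin"` or `"aav_tgfb1"`.
#' @param days strictly increasing integer days.
#' @param compliance positive treated-arm group-mean compliance (mL/cmH2O),
#'   one value per day.
#' @return data frame of class `fc_phenotype`.
#' @export
phenotype_trajectory <- function(model, days, compliance) {
  model <- match.arg(model, MODELS)
  if (length(days) != length(compliance) || is.unsorted(days, strictly = TRUE)) {
    fc_stop("fc_bad_input", "days must be strictly increasing and match compliance")
  }
  if (any(!is.finite(compliance)) || any(compliance <= 0)) {
    fc_stop("fc_bad_input", "compliance values must be finite and > 0")
  }
  df <- data.frame(model = model, day = as.integer(days),
                   compliance = as.numeric(compliance))
  class(df) <- c("fc_phenotype", "data.frame")
  df
}

#' Correlate log2 fold-change trajectories with lung-function decline
#'
#' For every feature, the per-day log2 fold-change trajectory in each model
#' is Pearson-correlated with that model's compliance trajectory over the
#' same days; `mean_r` averages the two models. Features whose trajectory is
#' constant in a model get an explicit missing correlation and are flagged
#' `undefined`.
#'
#' @param profiles named list (per model) of features x days log2fc matrices,
#'   as produced by contrast results (see [run_all_contrasts()]); column
#'   names are days.
#' @param trajectories list of two [phenotype_trajectory()] objects, or one
#'   row-bound data frame, covering both models on the same day grid as the
#'   profiles.
#' @return data frame of class `fc_lungfun_corr` with `feature_id`,
#'   `r_bleomycin`, `r_aav`, `mean_r`, `n_points`, `undefined`.
#' @export
correlate_with_lung_function <- function(profiles, trajectories) {
  if (is.data.frame(trajectories)) {
    trajectories <- split(trajectories, trajectories$model)
  }
  trajectories <- setNames(trajectories,
                           vapply(trajectories, function(t) t$model[1], ""))
  feats <- rownames(profiles[[1]])
  rs <- lapply(MODELS, function(m) {
    prof <- profiles[[m]]
    traj <- trajectories[[m]]
    if (is.null(prof) || is.null(traj)) {
      fc_stop("fc_bad_input", "missing profile or trajectory for model %s", m)
    }
    if (!identical(as.integer(colnames(prof)), traj$day)) {
      fc_stop("fc_day_mismatch", "profile days do not match trajectory days for %s", m)
    }
    apply(prof[feats, , drop = FALSE], 1L, function(v) {
      if (anyNA(v) || stats::sd(v) == 0) NA_real_ else pearson_r(v, traj$compliance)
    })
  })
  names(rs) <- MODELS
  df <- data.frame(
    feature_id = feats,
    r_bleomycin = unname(rs$bleomycin),
    r_aav = unname(rs$aav_tgfb1),
    mean_r = unname((rs$bleomycin + rs$aav_tgfb1) / 2),
    n_points = ncol(profiles[[1]]),
    undefined = unname(is.na(rs$bleomycin) | is.na(rs$aav_tgfb1)),
    stringsAsFactors = FALSE)
  class(df) <- c("fc_lungfun_corr", "data.frame")
  df
}

#' Select and rank phenotype-coupled genes
#'
#' Upregulated selection keeps features whose expression trajectory
#' anti-correlates with the compliance decline (`mean_r <= -r_threshold`; in
#' `strict` mode the threshold must hold in each model separately), that are
#' significantly altered at day 21 in both models (`adj_p <= alpha`), and
#' whose day-21 log2 fold change is `>= 0` in both models; ranked by mean
#' day-21 log2fc, descending. `direction = "down"` mirrors every sign and
#' ranks ascending.
#'
#' @param corr `fc_lungfun_corr` from [correlate_with_lung_function()].
#' @param de_day21 `fc_contrasts` restricted to (or containing) day-21 rows
#'   of both models.
#' @param direction `"up"` or `"down"`.
#' @param r_threshold absolute correlation threshold (default 0.85).
#' @param alpha adjusted-p threshold at day 21 (default 0.05).
#' @param top_n number of top features to return (default `Inf` = all
#'   passing).
#' @param strict require the r threshold in each model separately instead of
#'   on `mean_r`.
#' @return data frame with `feature_id`, `mean_r`, `log2fc_day21_bleomycin`,
#'   `log2fc_day21_aav`, `rank_key` (mean day-21 log2fc), ordered by rank.
#' @export
select_phenotype_coupled_genes <- function(corr, de_day21, direction = c("up", "down"),
                                           r_threshold = 0.85, alpha = 0.05,
                                           top_n = Inf, strict = FALSE) {
  direction <- match.arg(direction)
  sgn <- if (direction == "up") 1 else -1
  d21 <- de_day21[de_day21$day == 21L, ]
  wide <- merge(
    d21[d21$model == "bleomycin", c("feature_id", "log2fc", "adj_p")],
    d21[d21$model == "aav_tgfb1", c("feature_id", "log2fc", "adj_p")],
    by = "feature_id", suffixes = c("_b", "_a"))
  tab <- merge(corr, wide, by = "feature_id")
  r_ok <- if (strict) {
    !tab$undefined & sgn * tab$r_bleomycin <= -r_threshold &
      sgn * tab$r_aav <= -r_threshold
  } else {
    !tab$undefined & sgn * tab$mean_r <= -r_threshold
  }
  keep <- r_ok & tab$adj_p_b <= alpha & tab$adj_p_a <= alpha &
    sgn * tab$log2fc_b >= 0 & sgn * tab$log2fc_a >= 0
  sel <- tab[keep, ]
  rank_key <- (sel$log2fc_b + sel$log2fc_a) / 2
  ord <- order(sgn * rank_key, decreasing = TRUE)
  sel <- sel[ord, ]
  out <- data.frame(feature_id = sel$feature_id, mean_r = sel$mean_r,
                    log2fc_day21_bleomycin = sel$log2fc_b,
                    log2fc_day21_aav = sel$log2fc_a,
                    rank_key = rank_key[ord], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  head(out, n = if (is.finite(top_n)) top_n else nrow(out))
}

#' Rank features by correlation to a pre-defined temporal pattern
#'
#' @param profiles per-model list of features x days log2fc matrices.
#' @param pattern numeric vector over the same days, non-constant.
#' @param model which model's profiles to rank.
#' @return data frame `feature_id`, `r`, ordered by `r` descending with
#'   undefined correlations last.
#' @export
pattern_rank <- function(profiles, pattern, model = MODELS) {
  model <- match.arg(model, MODELS)
  prof <- profiles[[model]]
  if (length(pattern) != ncol(prof)) {
    fc_stop("fc_bad_input", "pattern length must equal the number of days")
  }
  if (stats::sd(pattern) == 0) {
    fc_stop("fc_bad_input", "constant pattern has no ranking power")
  }
  r <- apply(prof, 1L, function(v) {
    if (anyNA(v) || stats::sd(v) == 0) NA_real_ else pearson_r(v, pattern)
  })
  ord <- order(r, decreasing = TRUE, na.last = TRUE)
  data.frame(feature_id = rownames(prof)[ord], r = unname(r[ord]),
             stringsAsFactors = FALSE)
}

#' Partition features by model specificity of differential expression
#'
#' At one day, features are split by the magnitude-only cutoff into
#' exclusively bleomycin-altered, exclusively AAV-altered, and commonly
#' altered sets; per set the squared Pearson correlation of the two models'
#' log2fc values is reported (undefined for sets smaller than 3).
#'
#' @param log2fc_day data frame with `feature_id`, `log2fc_bleomycin`,
#'   `log2fc_aav` for one day.
#' @param day the day label.
#' @param cutoff absolute log2fc cutoff (default 0.6).
#' @return list of class `fc_specificity` with the three id sets, the
#'   `neither` remainder, and `r_squared` per set.
#' @export
partition_model_specificity <- function(log2fc_day, day, cutoff = 0.6) {
  b <- abs(log2fc_day$log2fc_bleomycin) >= cutoff
  a <- abs(log2fc_day$log2fc_aav) >= cutoff
  sets <- list(
    exclusive_bleomycin = log2fc_day$feature_id[b & !a],
    exclusive_aav = log2fc_day$feature_id[!b & a],
    common = log2fc_day$feature_id[b & a],
    neither = log2fc_day$feature_id[!b & !a])
  r2 <- vapply(sets[1:3], function(ids) {
    if (length(ids) < 3L) return(NA_real_)
    sub <- log2fc_day[log2fc_day$feature_id %in% ids, ]
    r <- pearson_r(sub$log2fc_bleomycin, sub$log2fc_aav)
    r^2
  }, numeric(1))
  structure(list(day = as.integer(day), sets = sets, r_squared = r2),
            class = "fc_specificity")
}
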