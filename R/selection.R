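#' Configuration of the staged miRNA selection cascade
#'
#' Houses every numeric threshold of the pipeline so a run log can record
#' them all in one place. Defaults reuse the thresholds applied throughout
#' the analysis: `|r| >= 0.85` for lung-function coupling, `|log2FC| >= 0.6`
#' with BH-adjusted `p <= 0.05` for differential expression, Spearman
#' `rho <= -0.6` with `>= 2` of 5 prediction tools for high-confidence
#' target pairs, and a mature-similarity alignment score of 20.
#'
#' @param r_threshold absolute lung-function correlation threshold.
#' @param lfc_threshold absolute log2 fold-change threshold.
#' @param alpha adjusted-p threshold.
#' @param min_de_timepoints minimum significant time points required.
#' @param de_both_models require the DE criterion in each model (`TRUE`) or
#'   in at least one (`FALSE`).
#' @param require_direction_consistency drop candidates whose day-21 log2fc
#'   signs conflict between models or with the correlation direction.
#' @param exclude_up_nonconserved drop upregulated candidates without
#'   perfect mouse-human seed conservation (they cannot be targeted in
#'   humans).
#' @param rho_max,min_tools high-confidence pair thresholds.
#' @param mature_threshold,inclusive mature-similarity settings, passed to
#'   conservation classification.
#' @return list of class `fc_selection_config`.
#' @export
selection_config <- function(r_threshold = 0.85, lfc_threshold = 0.6,
                             alpha = 0.05, min_de_timepoints = 1L,
                             de_both_models = TRUE,
                             require_direction_consistency = TRUE,
                             exclude_up_nonconserved = TRUE,
                             rho_max = -0.6, min_tools = 2L,
                             mature_threshold = 20, inclusive = TRUE) {
  cfg <- as.list(environment())
  stopifnot(r_threshold >= 0, r_threshold <= 1, alpha > 0, alpha <= 1,
            lfc_threshold >= 0, rho_max <= 0, min_tools >= 1)
  class(cfg) <- "fc_selection_config"
  cfg
}

#' Staged selection of miRNA hit candidates
#'
#' Applies the ordered filter cascade: (1) strong lung-function coupling
#' (`|mean_r| >= r_threshold`; anti-correlated candidates are called UP,
#' correlated ones DOWN); (2) differential expression (`|log2fc| >=
#' lfc_threshold` and `adj_p <= alpha`) at `min_de_timepoints` or more time
#' points in each model; (3) cross-model consistency of the day-21 log2
#' fold-change sign, which must also agree with the correlation direction;
#' (4) exclusion of upregulated candidates without perfect seed
#' conservation; (5) attachment of high-confidence targets for reporting.
#' An audit table records every stage-1 candidate's fate.
#'
#' @param contrasts `fc_contrasts` for the miRNA universe (all models/days).
#' @param corr `fc_lungfun_corr` for the same universe.
#' @param conservation `fc_conservation_call` rows (mouse-centric); miRNAs
#'   without a row are treated as unpaired, i.e. non-conserved.
#' @param pairs high-confidence pair list from
#'   [intersect_high_confidence()], used for target annotation only.
#' @param config [selection_config()].
#' @param mirnas optional `fc_mirna_records` used to attach mature
#'   sequences to the hit list.
#' @return data frame of class `fc_hit_list` (`mirna`, `direction`,
#'   `mature_seq`, `mean_r`, `conservation`, `n_targets`) with the full
#'   audit table in `attr(, "audit")`.
#' @export
run_staged_selection <- function(contrasts, corr, conservation, pairs = NULL,
                                 config = selection_config(), mirnas = NULL) {
  universe <- sort(unique(corr$feature_id))
  if (!setequal(universe, unique(contrasts$feature_id))) {
    fc_stop("fc_universe_mismatch",
            "contrast and correlation inputs cover different miRNA universes")
  }
  cons_cat <- setNames(rep("unpaired", length(universe)), universe)
  hit <- conservation$mouse_name %in% universe
  cons_cat[conservation$mouse_name[hit]] <- conservation$category[hit]

  ## stage 1: lung-function coupling
  c1 <- corr[!corr$undefined & abs(corr$mean_r) >= config$r_threshold, ]
  direction <- ifelse(c1$mean_r < 0, "UP", "DOWN")
  audit <- data.frame(mirna = c1$feature_id, direction = direction,
                      mean_r = c1$mean_r, stage1_coupling = TRUE,
                      stringsAsFactors = FALSE)

  ## stage 2: differential expression per model
  de <- contrasts[abs(contrasts$log2fc) >= config$lfc_threshold &
                    contrasts$adj_p <= config$alpha, ]
  n_tp <- function(f, m) sum(de$feature_id == f & de$model == m)
  s2 <- vapply(audit$mirna, function(f) {
    counts <- vapply(MODELS, function(m) n_tp(f, m), integer(1))
    if (config$de_both_models) all(counts >= config$min_de_timepoints)
    else any(counts >= config$min_de_timepoints)
  }, logical(1))
  audit$stage2_de <- unname(s2)

  ## stage 3: cross-model direction consistency at day 21
  d21 <- contrasts[contrasts$day == 21L, ]
  lfc21 <- lapply(MODELS, function(m) {
    setNames(d21$log2fc[d21$model == m], d21$feature_id[d21$model == m])
  })
  names(lfc21) <- MODELS
  s3 <- if (config$require_direction_consistency) {
    vapply(seq_len(nrow(audit)), function(i) {
      f <- audit$mirna[i]
      sgn <- if (audit$direction[i] == "UP") 1 else -1
      all(vapply(MODELS, function(m) sgn * lfc21[[m]][f] > 0, logical(1)))
    }, logical(1))
  } else rep(TRUE, nrow(audit))
  audit$stage3_consistency <- s3

  ## stage 4: conservation of upregulated candidates
  s4 <- if (config$exclude_up_nonconserved) {
    !(audit$direction == "UP" & cons_cat[audit$mirna] != "conserved")
  } else rep(TRUE, nrow(audit))
  audit$stage4_conservation <- unname(s4)

  audit$selected <- audit$stage2_de & audit$stage3_consistency &
    audit$stage4_conservation
  audit$fate <- ifelse(!audit$stage2_de, "stage2_de",
                ifelse(!audit$stage3_consistency, "stage3_consistency",
                ifelse(!audit$stage4_conservation, "stage4_conservation",
                       "selected")))

  sel <- audit[audit$selected, ]
  n_targets <- if (!is.null(pairs) && nrow(sel)) {
    vapply(sel$mirna, function(f) sum(pairs$mirna == f), integer(1))
  } else rep(0L, nrow(sel))
  seqs <- if (!is.null(mirnas)) {
    mirnas$mature_seq[match(sel$mirna, mirnas$name)]
  } else rep(NA_character_, nrow(sel))
  hits <- data.frame(mirna = sel$mirna, direction = sel$direction,
                     mature_seq = seqs, mean_r = sel$mean_r,
                     conservation = unname(cons_cat[sel$mirna]),
                     n_targets = unname(n_targets), stringsAsFactors = FALSE)
  hits <- hits[order(hits$direction, -abs(hits$mean_r)), ]
  rownames(hits) <- NULL
  rownames(audit) <- NULL
  attr(hits, "audit") <- audit
  class(hits) <- c("fc_hit_list", "data.frame")
  hits
}

#' @export
print.fc_hit_list <- function(x, ...) {
  cat(sprintf("<fc_hit_list> %d miRNA hits (%d UP, %d DOWN)\n",
              nrow(x), sum(x$direction == "UP"), sum(x$direction == "DOWN")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read a published-style miRNA hit list
#'
#' TSV with columns `mirna`, `de` (UP/DOWN) and `mature_seq`; comment lines
#' starting with `#` are ignored. Sequences are normalised to uppercase RNA
#' and validated; the 6-nt seed is derived.
#'
#' @param path TSV path.
#' @return data frame of class `fc_hit_list` with `mirna`, `direction`,
#'   `mature_seq`, `seed`.
#' @export
read_hit_list <- function(path) {
  fc_assert_file(path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("mirna", "de", "mature_seq")
  if (!all(need %in% names(df))) {
    fc_stop("fc_bad_table", "hit list misses columns: %s",
            paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (anyDuplicated(df$mirna)) {
    fc_stop("fc_duplicate_id", "duplicate miRNA in hit list")
  }
  if (!all(df$de %in% c("UP", "DOWN"))) {
    fc_stop("fc_unknown_token", "DE direction must be UP or DOWN")
  }
  rec <- mirna_records(df$mirna, df$mature_seq, species = "mouse")
  out <- data.frame(mirna = rec$name, direction = df$de,
                    mature_seq = rec$mature_seq, seed = rec$seed,
                    stringsAsFactors = FALSE)
  class(out) <- c("fc_hit_list", "data.frame")
  out
}
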