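#' Spearman correlation of every miRNA against every mRNA
#'
#' Rank correlation is computed across all samples of both models and all
#' time points on log-CPM values, after low-expression filtering. Pairs with
#' an undefined correlation (a constant profile) are flagged.
#'
#' @param mirna_log_cpm,mrna_log_cpm [expression_matrix()] objects with
#'   `scale = "log_cpm"` over the identical sample set.
#' @return data frame of class `fc_pair_corr` with `mirna`, `mrna`, `rho`,
#'   `n_samples`, `undefined`.
#' @export
correlate_all_pairs <- function(mirna_log_cpm, mrna_log_cpm) {
  stopifnot(inherits(mirna_log_cpm, "fc_expression_matrix"),
            inherits(mrna_log_cpm, "fc_expression_matrix"))
  smp <- sample_ids(mirna_log_cpm)
  if (!setequal(smp, sample_ids(mrna_log_cpm)) ||
      length(smp) != length(sample_ids(mrna_log_cpm))) {
    fc_stop("fc_sample_mismatch", "miRNA and mRNA matrices cover different samples")
  }
  a <- mirna_log_cpm$values[, smp, drop = FALSE]
  b <- mrna_log_cpm$values[, smp, drop = FALSE]
  ra <- t(apply(a, 1L, rank))
  rb <- t(apply(b, 1L, rank))
  rho <- suppressWarnings(cor(t(ra), t(rb), method = "pearson"))
  const_a <- apply(ra, 1L, function(v) stats::sd(v) == 0)
  const_b <- apply(rb, 1L, function(v) stats::sd(v) == 0)
  rho[const_a, ] <- NA_real_
  rho[, const_b] <- NA_real_
  df <- data.frame(
    mirna = rep(rownames(a), times = nrow(b)),
    mrna = rep(rownames(b), each = nrow(a)),
    rho = as.vector(rho), n_samples = length(smp),
    stringsAsFactors = FALSE)
  df$undefined <- is.na(df$rho)
  class(df) <- c("fc_pair_corr", "data.frame")
  df
}

#' Intersect anticorrelated pairs with sequence-based predictions
#'
#' The high-confidence set keeps (miRNA, mRNA) pairs that are both strongly
#' anticorrelated in expression (`rho <= rho_max`, default -0.6) and
#' predicted by at least `min_tools` prediction algorithms (default 2 of 5).
#' Both comparisons are inclusive.
#'
#' @param corr `fc_pair_corr` from [correlate_all_pairs()].
#' @param preds `fc_prediction_table`.
#' @param rho_max correlation ceiling (default -0.6).
#' @param min_tools minimum number of distinct predicting tools (default 2).
#' @return data frame with `mirna`, `mrna`, `rho`, `n_tools`.
#' @export
intersect_high_confidence <- function(corr, preds, rho_max = -0.6, min_tools = 2L) {
  if (length(unique(preds$tool)) < min_tools) {
    fc_stop("fc_bad_input", "tool vocabulary smaller than min_tools")
  }
  nt <- aggregate(tool ~ mirna + target, data = preds,
                  FUN = function(t) length(unique(t)))
  names(nt) <- c("mirna", "mrna", "n_tools")
  hit <- corr[!corr$undefined & corr$rho <= rho_max, c("mirna", "mrna", "rho")]
  out <- merge(hit, nt, by = c("mirna", "mrna"))
  out <- out[out$n_tools >= min_tools, ]
  out <- out[order(out$mirna, out$mrna), ]
  rownames(out) <- NULL
  out
}

#' Seed-match target prediction
#'
#' A self-contained stand-in predictor: a miRNA is predicted to target a
#' transcript when the reverse complement of its 6-nt seed occurs at least
#' once in the transcript sequence. Occurrence counts are retained. Rows
#' carry `tool = "seedmatch"`.
#'
#' @param mirnas `fc_mirna_records`.
#' @param target_seqs named character vector of transcript (3'UTR-like)
#'   sequences, RNA or DNA (T normalised to U).
#' @return `fc_prediction_table` with an extra `n_sites` column.
#' @export
predict_targets_seed_match <- function(mirnas, target_seqs) {
  seqs <- chartr("acgut", "ACGUT", target_seqs)
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  if (any(grepl("[^ACGU]", seqs))) {
    fc_stop("fc_invalid_alphabet", "invalid characters in target sequences")
  }
  rows <- list()
  for (i in seq_len(nrow(mirnas))) {
    site <- reverse_complement_rna(mirnas$seed[i])
    n <- vapply(seqs, function(s) count_occurrences(s, site), integer(1))
    hit <- which(n >= 1L)
    if (length(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        mirna = mirnas$name[i], target = names(seqs)[hit], tool = "seedmatch",
        n_sites = unname(n[hit]), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna = character(), target = character(), tool = character(),
               n_sites = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("fc_prediction_table", "data.frame")
  out
}

reverse_complement_rna <- function(s) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1]]), collapse = "")
}

# Overlapping occurrence count of `pat` in `s`.
count_occurrences <- function(s, pat) {
  n <- 0L; from <- 1L
  repeat {
    hit <- regexpr(pat, substr(s, from, nchar(s)), fixed = TRUE)
    if (hit == -1L) break
    n <- n + 1L
    from <- from + hit  # advance one past the match start: count overlaps
  }
  n
}

new_network <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "fc_network")
}

#' @export
print.fc_network <- function(x, ...) {
  cat(sprintf("<fc_network> %d nodes (%d miRNA, %d mRNA), %d edges (%d repression, %d coexpression)\n",
              nrow(x$nodes), sum(x$nodes$kind == "mirna"),
              sum(x$nodes$kind == "mrna"), nrow(x$edges),
              sum(x$edges$kind == "mirna_mrna"), sum(x$edges$kind == "mrna_mrna")))
  invisible(x)
}

#' Assemble the annotated miRNA-mRNA regulatory network
#'
#' Nodes are the selected miRNAs plus their first-neighbour mRNAs from the
#' high-confidence pair list; miRNA -> mRNA repression edges carry the pair's
#' Spearman rho, and mRNA - mRNA coexpression edges are added between
#' included mRNAs whose pairwise correlation is `>= mrna_mrna_min_r`
#' (inclusive). Every node must be annotated with its day-21 AAV log2 fold
#' change, its number of significant contrasts, and its lung-function
#' correlation.
#'
#' @param pairs high-confidence pair list from [intersect_high_confidence()].
#' @param mrna_log_cpm [expression_matrix()] used for mRNA - mRNA
#'   correlation (same correlation kind as the pairing: Spearman by default).
#' @param annotations data frame with `id`, `log2fc_day21_aav`,
#'   `n_significant_contrasts`, `lung_function_r` covering every emitted node.
#' @param mrna_mrna_min_r coexpression threshold (default 0.75).
#' @param method correlation kind for mRNA - mRNA edges (`"spearman"` or
#'   `"pearson"`).
#' @return `fc_network` with `nodes` and `edges` data frames.
#' @export
build_network <- function(pairs, mrna_log_cpm, annotations,
                          mrna_mrna_min_r = 0.75,
                          method = c("spearman", "pearson")) {
  method <- match.arg(method)
  mirnas <- unique(pairs$mirna)
  mrnas <- unique(pairs$mrna)
  ids <- c(mirnas, mrnas)
  missing <- setdiff(ids, annotations$id)
  if (length(missing)) {
    fc_stop("fc_missing_annotation", "no annotation for node(s): %s",
            paste(missing, collapse = ", "))
  }
  ann <- annotations[match(ids, annotations$id), ]
  nodes <- data.frame(
    id = ids, kind = rep(c("mirna", "mrna"), c(length(mirnas), length(mrnas))),
    log2fc_day21_aav = ann$log2fc_day21_aav,
    n_significant_contrasts = ann$n_significant_contrasts,
    lung_function_r = ann$lung_function_r,
    stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  edges <- data.frame(source = pairs$mirna, target = pairs$mrna,
                      kind = "mirna_mrna", weight = pairs$rho,
                      stringsAsFactors = FALSE)
  if (length(mrnas) >= 2L) {
    v <- mrna_log_cpm$values[mrnas, , drop = FALSE]
    cm <- suppressWarnings(cor(t(v), method = method))
    for (i in seq_len(length(mrnas) - 1L)) {
      for (j in seq((i + 1L), length(mrnas))) {
        r <- cm[i, j]
        if (!is.na(r) && r >= mrna_mrna_min_r) {
          edges <- rbind(edges, data.frame(
            source = mrnas[i], target = mrnas[j], kind = "mrna_mrna",
            weight = r, stringsAsFactors = FALSE))
        }
      }
    }
  }
  rownames(edges) <- NULL
  key <- paste(edges$source, edges$target)
  if (anyDuplicated(key) || any(edges$source == edges$target)) {
    fc_stop("fc_bad_input", "network would contain duplicate or self edges")
  }
  new_network(nodes, edges)
}
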