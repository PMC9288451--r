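#' Extract the seed region of a mature miRNA
#'
#' The seed is nucleotides 2-7 (1-based, inclusive) of the mature sequence,
#' the primary determinant of target recognition.
#'
#' @param mature_seq RNA string of length >= 7.
#' @return 6-nt RNA string.
#' @export
extract_seed <- function(mature_seq) {
  if (nchar(mature_seq) < 7L) {
    fc_stop("fc_short_sequence", "sequence too short for seed extraction")
  }
  substr(mature_seq, 2L, 7L)
}

#' Needleman-Wunsch global alignment score
#'
#' Optimal global alignment score under a simple RNA scheme: `match` for
#' identical bases, `mismatch` otherwise, and a linear `gap` penalty per
#' gapped symbol. With the default match = 1 / mismatch = 0 and equal-length
#' inputs, the optimum is gapless and equals the number of matching
#' positions, so a 6-nt seed pair scores 6 iff the seeds are identical.
#'
#' @param a,b non-empty RNA strings (A/C/G/U).
#' @param match,mismatch,gap scoring parameters; `gap` must be negative.
#' @return numeric alignment score.
#' @export
nw_global_score <- function(a, b, match = 1, mismatch = 0, gap = -2) {
  for (s in c(a, b)) {
    if (!is.character(s) || length(s) != 1L || !nzchar(s)) {
      fc_stop("fc_invalid_alphabet", "alignment requires non-empty strings")
    }
    if (grepl("[^ACGU]", s)) {
      fc_stop("fc_invalid_alphabet", "non-RNA character in '%s'", s)
    }
  }
  stopifnot(gap < 0)
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  prev <- gap * (0:m)
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    cur[1] <- gap * i
    for (j in seq_len(m)) {
      diag <- prev[j] + if (x[i] == y[j]) match else mismatch
      cur[j + 1L] <- max(diag, prev[j + 1L] + gap, cur[j] + gap)
    }
    prev <- cur
  }
  prev[m + 1L]
}

# Strip species prefixes like "mmu-"/"hsa-" for cross-species name matching.
base_mirna_name <- function(name) {
  tolower(sub("^(mmu|hsa|mur|hum)-", "", name, ignore.case = TRUE))
}

#' Classify mouse-human conservation of one miRNA pair
#'
#' Both the 6-nt seed regions and the full mature sequences are globally
#' aligned with [nw_global_score()] (match 1, mismatch 0). A pair is
#' `conserved` iff the seed score is 6 (perfect seed identity), otherwise
#' `non_conserved`. Independently, pairs whose mature-sequence score passes
#' the mature threshold are flagged `mature_high_similarity`; the threshold
#' comparison is `>=` when `inclusive = TRUE` (default) and `>` otherwise.
#'
#' @param mouse,human single-row `fc_mirna_records` (or lists with `name`,
#'   `species`, `mature_seq`, `seed`) of the two species; base names (after
#'   stripping the species prefix, case-insensitively) must match, including
#'   the -5p/-3p arm.
#' @param mature_threshold mature-similarity score threshold (default 20).
#' @param inclusive logical; `>=` vs `>` at the mature threshold.
#' @param gap linear gap penalty for both alignments.
#' @return one-row data frame of class `fc_conservation_call` with columns
#'   `mouse_name`, `human_name`, `seed_score`, `mature_score`, `category`,
#'   `mature_high_similarity`.
#' @export
classify_conservation <- function(mouse, human, mature_threshold = 20,
                                  inclusive = TRUE, gap = -2) {
  mouse <- as.list(as.data.frame(mouse)[1, ])
  human <- as.list(as.data.frame(human)[1, ])
  if (identical(mouse$species, human$species)) {
    fc_stop("fc_same_species", "conservation needs one mouse and one human record")
  }
  if (base_mirna_name(mouse$name) != base_mirna_name(human$name)) {
    fc_stop("fc_name_mismatch", "names do not match: %s vs %s",
            mouse$name, human$name)
  }
  seed_score <- nw_global_score(mouse$seed, human$seed, gap = gap)
  mature_score <- nw_global_score(mouse$mature_seq, human$mature_seq, gap = gap)
  flag <- if (inclusive) mature_score >= mature_threshold else mature_score > mature_threshold
  df <- data.frame(
    mouse_name = mouse$name, human_name = human$name,
    seed_score = seed_score, mature_score = mature_score,
    category = if (seed_score == 6) "conserved" else "non_conserved",
    mature_high_similarity = flag, stringsAsFactors = FALSE)
  class(df) <- c("fc_conservation_call", "data.frame")
  df
}

#' Conservation calls for all name-matched mouse-human pairs
#'
#' Pairs records across species by base name (species prefix stripped,
#' case-insensitive; the -5p/-3p arm is part of the name and must match).
#' Mouse records without a human partner are returned with category
#' `"unpaired"`; downstream conservation-dependent filters treat them as
#' non-conserved.
#'
#' @param mouse,human `fc_mirna_records` collections.
#' @inheritParams classify_conservation
#' @return data frame of class `fc_conservation_call`, one row per mouse
#'   miRNA.
#' @export
classify_all_conservation <- function(mouse, human, mature_threshold = 20,
                                      inclusive = TRUE, gap = -2) {
  hb <- setNames(seq_len(nrow(human)), base_mirna_name(human$name))
  rows <- lapply(seq_len(nrow(mouse)), function(i) {
    j <- hb[base_mirna_name(mouse$name[i])]
    if (is.na(j)) {
      df <- data.frame(mouse_name = mouse$name[i], human_name = NA_character_,
                       seed_score = NA_integer_, mature_score = NA_real_,
                       category = "unpaired", mature_high_similarity = FALSE,
                       stringsAsFactors = FALSE)
      return(df)
    }
    classify_conservation(mouse[i, ], human[j, ],
                          mature_threshold = mature_threshold,
                          inclusive = inclusive, gap = gap)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fc_conservation_call", "data.frame")
  out
}
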