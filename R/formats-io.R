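#' Read a count matrix from TSV or MatrixMarket
#'
#' The TSV dialect is tab-separated UTF-8 with sample ids in the header row
#' (the first header cell is ignored) and feature ids in the first column.
#' Alternatively a MatrixMarket `.mtx` file may be given, with sidecar files
#' `<stem>.features.txt` and `<stem>.samples.txt` holding one id per line.
#'
#' @param path path to a `.tsv`/`.txt` table or a `.mtx` MatrixMarket file.
#' @param kind `"mrna"` or `"mirna"`.
#' @return An [expression_matrix()] with `scale = "counts"`.
#' @export
read_counts <- function(path, kind = c("mrna", "mirna")) {
  kind <- match.arg(kind)
  fc_assert_file(path)
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    fpath <- paste0(stem, ".features.txt")
    spath <- paste0(stem, ".samples.txt")
    fc_assert_file(fpath)
    fc_assert_file(spath)
    rownames(m) <- readLines(fpath)
    colnames(m) <- readLines(spath)
  } else {
    raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      colClasses = "character", fileEncoding = "UTF-8")
    if (ncol(raw) < 2L) fc_stop("fc_bad_table", "counts TSV needs at least one sample column")
    ids <- raw[[1]]
    body <- as.matrix(raw[, -1, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                   dimnames = list(ids, colnames(raw)[-1])))
    if (any(is.na(num) & !is.na(body))) {
      bad <- body[is.na(num) & !is.na(body)][1]
      fc_stop("fc_non_numeric", "non-numeric cell in counts table: '%s'", bad)
    }
    if (anyNA(num)) fc_stop("fc_non_numeric", "missing cell in counts table")
    m <- num
  }
  if (anyDuplicated(rownames(m))) {
    fc_stop("fc_duplicate_id", "duplicate feature id in %s", path)
  }
  if (any(m < 0)) fc_stop("fc_negative_count", "negative count in %s", path)
  expression_matrix(m, kind = kind, scale = "counts")
}

#' Write a count matrix as TSV
#'
#' Inverse of [read_counts()]; the first header cell is `feature_id`.
#'
#' @param x an [expression_matrix()] with `scale = "counts"`.
#' @param path output path.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "fc_expression_matrix"))
  df <- data.frame(feature_id = feature_ids(x), x$values,
                   check.names = FALSE, row.names = NULL)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a longitudinal sample sheet
#'
#' CSV with columns `sample_id`, `model`, `arm`, `day`, `animal_id`. Models
#' are `bleomycin` (controls: NaCl) and `aav_tgfb1` (controls: stuffer
#' vector); arms are `treated`/`control`. Contrasts always pair a treated
#' group with the same-model same-day control group, so every treated
#' (model, day) cell must have a non-empty control cell.
#'
#' @param path CSV path.
#' @param days permitted day set (strictly positive integers).
#' @return A `data.frame` of class `fc_sample_design`.
#' @export
read_sample_sheet <- function(path, days = DEFAULT_DAYS) {
  fc_assert_file(path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  sample_design(df, days = days)
}

#' Validate a sample design data frame
#'
#' @param df data frame with columns `sample_id`, `model`, `arm`, `day`,
#'   `animal_id`.
#' @param days permitted day set.
#' @return the validated design, classed `fc_sample_design`.
#' @export
sample_design <- function(df, days = DEFAULT_DAYS) {
  need <- c("sample_id", "model", "arm", "day", "animal_id")
  if (!all(need %in% names(df))) {
    fc_stop("fc_bad_table", "sample sheet misses columns: %s",
            paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (any(!is.finite(days)) || any(days <= 0)) {
    fc_stop("fc_bad_day", "day set must be strictly positive")
  }
  df <- df[, need]
  df$day <- as.integer(df$day)
  if (anyDuplicated(df$sample_id)) {
    fc_stop("fc_duplicate_id", "duplicate sample_id: %s",
            df$sample_id[duplicated(df$sample_id)][1])
  }
  if (!all(df$model %in% MODELS)) {
    fc_stop("fc_unknown_token", "unknown model token: %s",
            setdiff(df$model, MODELS)[1])
  }
  if (!all(df$arm %in% ARMS)) {
    fc_stop("fc_unknown_token", "unknown arm token: %s", setdiff(df$arm, ARMS)[1])
  }
  if (!all(df$day %in% days)) {
    fc_stop("fc_bad_day", "day %s outside permitted set {%s}",
            setdiff(df$day, days)[1], paste(days, collapse = ","))
  }
  trt <- unique(df[df$arm == "treated", c("model", "day")])
  for (i in seq_len(nrow(trt))) {
    has_ctrl <- any(df$arm == "control" & df$model == trt$model[i] &
                      df$day == trt$day[i])
    if (!has_ctrl) {
      fc_stop("fc_unmatched_contrast",
              "treated group %s day %d has no same-day control",
              trt$model[i], trt$day[i])
    }
  }
  class(df) <- c("fc_sample_design", "data.frame")
  df
}

design_samples <- function(design, model, arm, day) {
  design$sample_id[design$model == model & design$arm == arm & design$day == day]
}

#' Read mature miRNA sequences from a miRBase-style FASTA
#'
#' The first whitespace-delimited token of each header is the miRNA name.
#' Sequences are uppercased and DNA thymine is normalised to uracil; the
#' 6-nt seed (mature positions 2-7) is derived on read.
#'
#' @param path FASTA path.
#' @param species `"mouse"` or `"human"`.
#' @return A `data.frame` of class `fc_mirna_records` with columns `name`,
#'   `species`, `mature_seq`, `seed`.
#' @export
read_mirna_fasta <- function(path, species = c("mouse", "human")) {
  species <- match.arg(species)
  fc_assert_file(path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!length(lines) || !hdr[1]) fc_stop("fc_bad_table", "not a FASTA file: %s", path)
  idx <- cumsum(hdr)
  names_full <- sub("^>", "", lines[hdr])
  nm <- vapply(strsplit(names_full, "\\s+"), `[[`, "", 1L)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste0, "", collapse = "")
  seqs <- unname(seqs[as.character(seq_along(nm))])
  seqs[is.na(seqs)] <- ""
  mirna_records(nm, seqs, species)
}

#' Build validated miRNA records from names and sequences
#'
#' @param name character vector of miRNA names.
#' @param mature_seq RNA or DNA sequences (T is normalised to U).
#' @param species `"mouse"` or `"human"`.
#' @return `fc_mirna_records` data frame.
#' @export
mirna_records <- function(name, mature_seq, species = c("mouse", "human")) {
  species <- match.arg(species)
  if (anyDuplicated(name)) {
    fc_stop("fc_duplicate_id", "duplicate miRNA name: %s", name[duplicated(name)][1])
  }
  seqs <- chartr("acgut", "ACGUT", mature_seq)
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) {
    fc_stop("fc_invalid_alphabet", "invalid characters in sequence of %s", name[bad][1])
  }
  if (any(nchar(seqs) < 8L)) {
    fc_stop("fc_short_sequence", "mature sequence of %s shorter than 8 nt",
            name[nchar(seqs) < 8L][1])
  }
  df <- data.frame(name = name, species = species, mature_seq = seqs,
                   seed = vapply(seqs, extract_seed, ""),
                   stringsAsFactors = FALSE, row.names = NULL)
  class(df) <- c("fc_mirna_records", "data.frame")
  df
}

#' Read a miRNA target-prediction table
#'
#' TSV with columns `mirna`, `target`, `tool`; one row per predicted pair per
#' tool. Duplicate (mirna, target, tool) triples are rejected.
#'
#' @param path TSV path.
#' @param tools permitted tool vocabulary (default: the five most cited
#'   prediction algorithms plus the built-in `seedmatch` predictor).
#' @return data frame of class `fc_prediction_table`.
#' @export
read_predictions <- function(path, tools = c(PREDICTION_TOOLS, "seedmatch")) {
  fc_assert_file(path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  prediction_table(df, tools = tools)
}

#' Validate a prediction table
#' @param df data frame with columns `mirna`, `target`, `tool`.
#' @param tools permitted tool vocabulary.
#' @return classed data frame.
#' @export
prediction_table <- function(df, tools = c(PREDICTION_TOOLS, "seedmatch")) {
  need <- c("mirna", "target", "tool")
  if (!all(need %in% names(df))) {
    fc_stop("fc_bad_table", "prediction table misses columns: %s",
            paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (!all(df$tool %in% tools)) {
    fc_stop("fc_unknown_token", "unknown prediction tool: %s",
            setdiff(df$tool, tools)[1])
  }
  key <- paste(df$mirna, df$target, df$tool, sep = "\r")
  if (anyDuplicated(key)) {
    fc_stop("fc_duplicate_id", "duplicate (mirna, target, tool) row")
  }
  df <- df[, need]
  class(df) <- c("fc_prediction_table", "data.frame")
  df
}

#' Write a contrast result table as TSV
#' @param contrasts `fc_contrasts` data frame from [run_contrast()].
#' @param path output TSV.
#' @export
write_contrasts <- function(contrasts, path) {
  write.table(contrasts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a contrast result table written by [write_contrasts()]
#' @param path TSV path.
#' @return `fc_contrasts` data frame.
#' @export
read_contrasts <- function(path) {
  fc_assert_file(path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$de_flag <- as.logical(df$de_flag)
  class(df) <- c("fc_contrasts", "data.frame")
  df
}

#' Export a regulatory network for Cytoscape
#'
#' SIF uses the relation tokens `represses` (miRNA -> mRNA) and `coexpr`
#' (mRNA - mRNA). GraphML carries all node and edge annotations as
#' attributes and can be re-imported with [read_network_graphml()].
#'
#' @param net `fc_network` from [build_network()].
#' @param path output file.
#' @param format `"sif"` or `"graphml"`.
#' @export
write_network <- function(net, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "fc_network"))
  if (format == "sif") {
    rel <- ifelse(net$edges$kind == "mirna_mrna", "represses", "coexpr")
    lines <- if (nrow(net$edges)) {
      paste(net$edges$source, rel, net$edges$target, sep = "\t")
    } else character()
    ok <- tryCatch({ writeLines(lines, path); TRUE },
                   error = function(e) FALSE)
    if (!ok) fc_stop("fc_unwritable", "cannot write %s", path)
  } else {
    g <- network_to_igraph(net)
    ok <- tryCatch({ igraph::write_graph(g, path, format = "graphml"); TRUE },
                   error = function(e) FALSE)
    if (!ok) fc_stop("fc_unwritable", "cannot write %s", path)
  }
  invisible(path)
}

network_to_igraph <- function(net) {
  nodes <- net$nodes
  edges <- net$edges
  g <- igraph::graph_from_data_frame(
    d = if (nrow(edges)) edges[, c("source", "target", "kind", "weight")]
        else data.frame(source = character(), target = character(),
                        kind = character(), weight = numeric()),
    directed = TRUE, vertices = nodes)
  g
}

#' Re-import a GraphML network written by [write_network()]
#' @param path GraphML path.
#' @return `fc_network` list with `nodes` and `edges` data frames.
#' @export
read_network_graphml <- function(path) {
  fc_assert_file(path)
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- as.data.frame(igraph::vertex_attr(g), stringsAsFactors = FALSE)
  names(nodes)[names(nodes) == "name"] <- "id"
  el <- igraph::as_edgelist(g)
  edges <- if (nrow(el)) {
    data.frame(source = el[, 1], target = el[, 2],
               kind = igraph::edge_attr(g, "kind"),
               weight = igraph::edge_attr(g, "weight"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(source = character(), target = character(),
               kind = character(), weight = numeric())
  }
  new_network(nodes, edges)
}
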