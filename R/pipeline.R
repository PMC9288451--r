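# MD5 of the canonical YAML serialisation of a config list; identifies a run.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

write_table_with_hash <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s", hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full transcriptome-phenotype coupling pipeline
#'
#' Orchestrates every stage on either a synthetic study (config entry
#' `simulation`) or on-file inputs (`paths` with `mrna_counts`,
#' `mirna_counts`, `sample_sheet`, `phenotype`, `mouse_fasta`,
#' `human_fasta`, and optionally `predictions`): low-expression filtering,
#' log-CPM normalisation, all model x day contrasts for mRNA and miRNA,
#' lung-function correlation, up/down gene selection, mouse-human
#' conservation calls, miRNA-mRNA pairing, the staged miRNA selection, and
#' the regulatory network around the selected miRNAs. Deterministic given
#' the seed: identical config + seed gives identical outputs.
#'
#' @param config a named list, or path to a YAML file, with optional blocks
#'   `simulation` (arguments of [simulation_config()]), `selection`
#'   (arguments of [selection_config()]), `de` (`min_cpm`, `lfc_threshold`,
#'   `alpha`), `genes` (`top_n_up`, `top_n_down`), `network`
#'   (`mrna_mrna_min_r`, `direction`), and `paths` for real inputs.
#' @param out_dir optional directory; when given, all artifact tables, the
#'   network (SIF + GraphML), the hit list, the audit table and a run log
#'   are written there, each table stamped with the config hash.
#' @return list of class `fc_run` with all intermediate and final artifacts.
#' @export
run_full_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    fc_assert_file(config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  log <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    message("[fibrocouple] ", msg)
  }
  sel_cfg <- do.call(selection_config, config$selection %||% list())
  de_cfg <- modifyList(list(min_cpm = 1, lfc_threshold = sel_cfg$lfc_threshold,
                            alpha = sel_cfg$alpha), config$de %||% list())
  gene_cfg <- modifyList(list(top_n_up = Inf, top_n_down = Inf),
                         config$genes %||% list())
  net_cfg <- modifyList(list(mrna_mrna_min_r = 0.75, direction = "down"),
                        config$network %||% list())
  hash <- config_hash(config)
  say("config hash %s", hash)

  ## ---- inputs ---------------------------------------------------------
  if (!is.null(config$simulation)) {
    sim <- do.call(simulation_config, config$simulation)
    study <- generate_study(sim)
    say("simulated study: %d genes, %d miRNAs, %d samples (seed %d)",
        nrow(study$mrna$values), nrow(study$mirna$values),
        nrow(study$design), sim$rng_seed)
  } else {
    p <- config$paths
    need <- c("mrna_counts", "mirna_counts", "sample_sheet", "phenotype",
              "mouse_fasta", "human_fasta")
    missing <- setdiff(need, names(p))
    if (length(missing)) {
      fc_stop("fc_config_error", "config misses input path(s): %s",
              paste(missing, collapse = ", "))
    }
    for (f in unlist(p)) fc_assert_file(f)
    pheno <- read.csv(p$phenotype, stringsAsFactors = FALSE)
    study <- list(
      mrna = read_counts(p$mrna_counts, kind = "mrna"),
      mirna = read_counts(p$mirna_counts, kind = "mirna"),
      design = read_sample_sheet(p$sample_sheet),
      trajectories = lapply(split(pheno, pheno$model), function(d) {
        phenotype_trajectory(d$model[1], d$day, d$compliance)
      }),
      mouse_mirnas = read_mirna_fasta(p$mouse_fasta, "mouse"),
      human_mirnas = read_mirna_fasta(p$human_fasta, "human"),
      predictions = if (!is.null(p$predictions)) read_predictions(p$predictions),
      truth = NULL)
    say("loaded study inputs from %d files", length(unlist(p)))
  }

  ## ---- expression processing -----------------------------------------
  mrna_f <- filter_low_expression(study$mrna, study$design,
                                  min_cpm = de_cfg$min_cpm)
  mirna_f <- filter_low_expression(study$mirna, study$design,
                                   min_cpm = de_cfg$min_cpm)
  say("low-expression filter kept %d/%d genes, %d/%d miRNAs",
      nrow(mrna_f$values), nrow(study$mrna$values),
      nrow(mirna_f$values), nrow(study$mirna$values))
  mrna_log <- normalize_log_cpm(mrna_f)
  mirna_log <- normalize_log_cpm(mirna_f)

  mrna_con <- run_all_contrasts(mrna_log, study$design,
                                lfc_threshold = de_cfg$lfc_threshold,
                                alpha = de_cfg$alpha)
  mirna_con <- run_all_contrasts(mirna_log, study$design,
                                 lfc_threshold = de_cfg$lfc_threshold,
                                 alpha = de_cfg$alpha)
  de_counts <- count_de_over_time(mrna_con)
  say("DE genes per contrast: %s",
      paste(sprintf("%s d%d: %d", de_counts$model, de_counts$day,
                    de_counts$n_de), collapse = "; "))

  ## ---- phenotype coupling --------------------------------------------
  gene_prof <- log2fc_profiles(mrna_con)
  mir_prof <- log2fc_profiles(mirna_con)
  gene_corr <- correlate_with_lung_function(gene_prof, study$trajectories)
  mir_corr <- correlate_with_lung_function(mir_prof, study$trajectories)
  genes_up <- select_phenotype_coupled_genes(
    gene_corr, mrna_con, "up", r_threshold = sel_cfg$r_threshold,
    alpha = sel_cfg$alpha, top_n = gene_cfg$top_n_up)
  genes_down <- select_phenotype_coupled_genes(
    gene_corr, mrna_con, "down", r_threshold = sel_cfg$r_threshold,
    alpha = sel_cfg$alpha, top_n = gene_cfg$top_n_down)
  say("phenotype-coupled genes: %d up, %d down",
      nrow(genes_up), nrow(genes_down))

  ## ---- conservation ---------------------------------------------------
  conservation <- classify_all_conservation(
    study$mouse_mirnas, study$human_mirnas,
    mature_threshold = sel_cfg$mature_threshold,
    inclusive = sel_cfg$inclusive)
  say("conservation: %d conserved, %d non-conserved, %d unpaired",
      sum(conservation$category == "conserved"),
      sum(conservation$category == "non_conserved"),
      sum(conservation$category == "unpaired"))

  ## ---- target pairing -------------------------------------------------
  pair_corr <- correlate_all_pairs(mirna_log, mrna_log)
  preds <- study$predictions
  if (is.null(preds)) {
    fc_stop("fc_config_error",
            "no prediction table available; supply paths$predictions")
  }
  hc_pairs <- intersect_high_confidence(pair_corr, preds,
                                        rho_max = sel_cfg$rho_max,
                                        min_tools = sel_cfg$min_tools)
  say("high-confidence miRNA-mRNA pairs: %d (rho <= %.2f, >= %d tools)",
      nrow(hc_pairs), sel_cfg$rho_max, sel_cfg$min_tools)

  ## ---- staged miRNA selection ----------------------------------------
  hits <- run_staged_selection(mirna_con, mir_corr, conservation,
                               pairs = hc_pairs, config = sel_cfg,
                               mirnas = study$mouse_mirnas)
  audit <- attr(hits, "audit")
  say("staged selection: %d candidates -> %d hits (%d UP, %d DOWN)",
      nrow(audit), nrow(hits), sum(hits$direction == "UP"),
      sum(hits$direction == "DOWN"))

  ## ---- regulatory network around selected miRNAs ---------------------
  net_mirs <- if (identical(net_cfg$direction, "down")) {
    hits$mirna[hits$direction == "DOWN"]
  } else hits$mirna
  net_pairs <- hc_pairs[hc_pairs$mirna %in% net_mirs, ]
  network <- if (nrow(net_pairs)) {
    ids <- unique(c(net_pairs$mirna, net_pairs$mrna))
    all_con <- rbind(mrna_con, mirna_con)
    d21a <- all_con[all_con$day == 21L & all_con$model == "aav_tgfb1", ]
    nsig <- aggregate(de_flag ~ feature_id, data = all_con, FUN = sum)
    all_corr <- rbind(gene_corr, mir_corr)
    ann <- data.frame(
      id = ids,
      log2fc_day21_aav = d21a$log2fc[match(ids, d21a$feature_id)],
      n_significant_contrasts = nsig$de_flag[match(ids, nsig$feature_id)],
      lung_function_r = all_corr$mean_r[match(ids, all_corr$feature_id)],
      stringsAsFactors = FALSE)
    build_network(net_pairs, mrna_log, ann,
                  mrna_mrna_min_r = net_cfg$mrna_mrna_min_r)
  } else {
    new_network(
      data.frame(id = character(), kind = character(),
                 log2fc_day21_aav = numeric(),
                 n_significant_contrasts = integer(),
                 lung_function_r = numeric(), stringsAsFactors = FALSE),
      data.frame(source = character(), target = character(),
                 kind = character(), weight = numeric()))
  }
  say("network: %d nodes, %d edges", nrow(network$nodes), nrow(network$edges))

  run <- structure(list(
    study = study, design = study$design,
    mrna_contrasts = mrna_con, mirna_contrasts = mirna_con,
    de_counts = de_counts, gene_corr = gene_corr, mirna_corr = mir_corr,
    genes_up = genes_up, genes_down = genes_down,
    conservation = conservation, pair_corr = pair_corr,
    hc_pairs = hc_pairs, hits = hits, audit = audit, network = network,
    config = config, config_hash = hash, log = log), class = "fc_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(out_dir, f)
    write_table_with_hash(mrna_con, out("mrna_contrasts.tsv"), hash)
    write_table_with_hash(mirna_con, out("mirna_contrasts.tsv"), hash)
    write_table_with_hash(gene_corr, out("gene_lungfun_corr.tsv"), hash)
    write_table_with_hash(mir_corr, out("mirna_lungfun_corr.tsv"), hash)
    write_table_with_hash(genes_up, out("genes_up.tsv"), hash)
    write_table_with_hash(genes_down, out("genes_down.tsv"), hash)
    write_table_with_hash(conservation, out("conservation_calls.tsv"), hash)
    write_table_with_hash(hc_pairs, out("high_confidence_pairs.tsv"), hash)
    write_table_with_hash(as.data.frame(hits), out("hit_list.tsv"), hash)
    write_table_with_hash(audit, out("selection_audit.tsv"), hash)
    write_network(network, out("network.sif"), "sif")
    write_network(network, out("network.graphml"), "graphml")
    writeLines(c(sprintf("# config_hash=%s", hash),
                 yaml::as.yaml(list(thresholds = unclass(sel_cfg))), log),
               out("run_log.txt"))
    say("wrote artifacts to %s", out_dir)
  }
  run
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fc_run <- function(x, ...) {
  cat(sprintf(paste0(
    "<fc_run> transcriptome-phenotype coupling run (config %s)\n",
    "  contrasts: %d mRNA rows, %d miRNA rows\n",
    "  phenotype-coupled genes: %d up, %d down\n",
    "  high-confidence pairs: %d; miRNA hits: %d (%d UP, %d DOWN)\n",
    "  network: %d nodes, %d edges\n"),
    substr(x$config_hash, 1, 8), nrow(x$mrna_contrasts),
    nrow(x$mirna_contrasts), nrow(x$genes_up), nrow(x$genes_down),
    nrow(x$hc_pairs), nrow(x$hits), sum(x$hits$direction == "UP"),
    sum(x$hits$direction == "DOWN"), nrow(x$network$nodes),
    nrow(x$network$edges)))
  invisible(x)
}

#' @export
summary.fc_run <- function(object, ...) {
  print(object)
  cat("\nDE features per model and day:\n")
  print(object$de_counts, row.names = FALSE)
  cat("\nSelection audit (candidate fates):\n")
  print(table(object$audit$fate))
  invisible(object)
}
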