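# Run an expression with a locally seeded RNG, restoring the caller's state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

#' Configuration of a synthetic two-model longitudinal study
#'
#' Defaults reproduce the study design of the emulated experiment: five
#' sampling days (3, 7, 14, 21, 28 post-administration), AAV-TGFb1 treated
#' n = 5 vs stuffer-vector controls n = 5, bleomycin treated n = 8 vs NaCl
#' controls n = 6, all per day. Counts follow a gamma-Poisson (negative
#' binomial) model with log-normally distributed baseline abundances.
#' Planted "tracking" features change proportionally to the compliance
#' deficit, reaching `effect_size_log2fc_day21` at day 21; planted
#' miRNA->target pairs repress (or, for downregulated miRNAs, de-repress)
#' their targets with strength `repression_strength`.
#'
#' @param n_genes,n_mirnas feature-space sizes.
#' @param group_sizes named list per model of `c(treated =, control =)`
#'   animals per day.
#' @param days sampling days.
#' @param library_size_mean named mean library sizes (`mrna`, `mirna`).
#' @param library_size_cv coefficient of variation of library sizes.
#' @param dispersion negative-binomial dispersion (1/size), > 0.
#' @param baseline_sdlog sd of the log-normal baseline abundance draw.
#' @param n_planted_genes_up,n_planted_genes_down planted tracking genes.
#' @param n_planted_mirnas_up,n_planted_mirnas_down planted tracking miRNAs
#'   per direction.
#' @param n_nonconserved_up,n_nonconserved_down how many of the planted
#'   miRNAs per direction get a human ortholog with a mutated seed.
#' @param targets_per_mirna planted repression targets per planted miRNA.
#' @param effect_size_log2fc_day21 planted log2 fold change at day 21 (> 0).
#' @param onset_delay_days delay of the AAV-TGFb1 compliance decline
#'   relative to bleomycin.
#' @param repression_strength in `[0, 1]`; fraction of target expression
#'   removed at full miRNA induction.
#' @param compliance_baseline baseline lung compliance (mL/cmH2O).
#' @param compliance_drop fractional compliance loss at day 21.
#' @param compliance_noise_cv multiplicative noise on the trajectory.
#' @param n_decoy_predictions single-tool decoy rows in the prediction
#'   table, so the >= 2-tool filter has something to reject.
#' @param rng_seed integer seed; required, all randomness derives from it.
#' @return list of class `fc_sim_config`.
#' @export
simulation_config <- function(n_genes = 500L, n_mirnas = 300L,
                              group_sizes = list(
                                bleomycin = c(treated = 8L, control = 6L),
                                aav_tgfb1 = c(treated = 5L, control = 5L)),
                              days = DEFAULT_DAYS,
                              library_size_mean = c(mrna = 2e5, mirna = 6e4),
                              library_size_cv = 0.1,
                              dispersion = 0.05,
                              baseline_sdlog = 1.2,
                              n_planted_genes_up = 30L,
                              n_planted_genes_down = 20L,
                              n_planted_mirnas_up = 8L,
                              n_planted_mirnas_down = 8L,
                              n_nonconserved_up = 3L,
                              n_nonconserved_down = 3L,
                              targets_per_mirna = 3L,
                              effect_size_log2fc_day21 = 2,
                              onset_delay_days = 7,
                              repression_strength = 0.8,
                              compliance_baseline = 0.06,
                              compliance_drop = 0.4,
                              compliance_noise_cv = 0.01,
                              n_decoy_predictions = 200L,
                              rng_seed) {
  if (missing(rng_seed)) fc_stop("fc_config_error", "rng_seed is required")
  cfg <- as.list(environment())
  if (cfg$dispersion <= 0) fc_stop("fc_config_error", "dispersion must be > 0")
  if (cfg$effect_size_log2fc_day21 <= 0) {
    fc_stop("fc_config_error", "effect size must be > 0")
  }
  if (cfg$repression_strength < 0 || cfg$repression_strength > 1) {
    fc_stop("fc_config_error", "repression_strength must be in [0, 1]")
  }
  n_planted_mirnas <- cfg$n_planted_mirnas_up + cfg$n_planted_mirnas_down
  if (cfg$n_planted_genes_up + cfg$n_planted_genes_down +
      n_planted_mirnas * cfg$targets_per_mirna > cfg$n_genes) {
    fc_stop("fc_config_error", "planted gene structure exceeds n_genes")
  }
  if (n_planted_mirnas > cfg$n_mirnas) {
    fc_stop("fc_config_error", "planted miRNAs exceed n_mirnas")
  }
  if (cfg$n_nonconserved_up > cfg$n_planted_mirnas_up ||
      cfg$n_nonconserved_down > cfg$n_planted_mirnas_down) {
    fc_stop("fc_config_error", "non-conserved counts exceed planted counts")
  }
  class(cfg) <- "fc_sim_config"
  cfg
}

# Normalised compliance deficit: 0 at day 0, 1 at day 21, via a logistic
# ramp (midpoint shifted by the AAV onset delay) so trajectories are smooth.
compliance_deficit <- function(model, days, onset_delay = 7, midpoint = 6,
                               tau = 4) {
  t0 <- if (model == "aav_tgfb1") midpoint + onset_delay else midpoint
  ramp <- function(d) stats::plogis((d - t0) / tau)
  (ramp(days) - ramp(0)) / (ramp(21) - ramp(0))
}

#' Generate a lung-compliance trajectory
#'
#' Bleomycin compliance declines from the first sampling day; the AAV-TGFb1
#' trajectory stays near baseline until the onset delay has passed and then
#' declines, both models reaching the same minimum (a `drop` fraction below
#' baseline) at day 21.
#'
#' @param model `"bleomycin"` or `"aav_tgfb1"`.
#' @param days sampling days (>= 2).
#' @param seed integer seed.
#' @param baseline baseline compliance (mL/cmH2O).
#' @param drop fractional loss at day 21.
#' @param onset_delay AAV onset delay in days.
#' @param noise_cv multiplicative trajectory noise.
#' @return [phenotype_trajectory()] data frame.
#' @export
generate_compliance <- function(model, days = DEFAULT_DAYS, seed,
                                baseline = 0.06, drop = 0.4, onset_delay = 7,
                                noise_cv = 0.01) {
  model <- match.arg(model, MODELS)
  stopifnot(length(days) >= 2L)
  deficit <- compliance_deficit(model, days, onset_delay = onset_delay)
  mean_traj <- baseline * (1 - drop * deficit)
  noisy <- with_seed(seed, mean_traj * exp(rnorm(length(days), 0, noise_cv)))
  phenotype_trajectory(model, days, noisy)
}

random_rna <- function(n, len = 22L) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, "")
}

# Mutate `k` distinct positions of an RNA string to different bases.
mutate_rna <- function(s, positions) {
  v <- strsplit(s, "")[[1]]
  for (p in positions) {
    v[p] <- sample(setdiff(c("A", "C", "G", "U"), v[p]), 1L)
  }
  paste(v, collapse = "")
}

#' Generate a complete synthetic study with planted ground truth
#'
#' Emits everything the pipeline consumes: mRNA and miRNA count matrices over
#' the full two-model longitudinal design, the sample sheet, per-model
#' compliance trajectories, mouse and human mature miRNA records, a
#' prediction table (planted pairs under >= 2 tools, decoys under 1), and a
#' ground-truth record of every planted structure.
#'
#' Planted tracking features have treated-arm log2 mean shifts proportional
#' to the model's compliance deficit (positive for UP, negative for DOWN),
#' reaching the configured effect size at day 21. Planted miRNA targets are
#' repressed log-linearly: the target's log2 mean moves by
#' `-repression_strength` times its regulator's log2 shift, so induced
#' miRNAs repress and depleted miRNAs de-repress their targets
#' symmetrically. Human orthologs of "conserved" planted miRNAs share the
#' seed exactly; "non-conserved" ones differ in at least one seed position.
#'
#' @param config an [simulation_config()] object.
#' @return list of class `fc_study` with elements `mrna`, `mirna` (count
#'   matrices), `design`, `trajectories`, `mouse_mirnas`, `human_mirnas`,
#'   `predictions`, `truth`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "fc_sim_config"))
  cfg <- config
  base_seed <- cfg$rng_seed %% 2147483000
  traj <- list(
    bleomycin = generate_compliance("bleomycin", cfg$days, seed = base_seed + 1,
                                    baseline = cfg$compliance_baseline,
                                    drop = cfg$compliance_drop,
                                    onset_delay = cfg$onset_delay_days,
                                    noise_cv = cfg$compliance_noise_cv),
    aav_tgfb1 = generate_compliance("aav_tgfb1", cfg$days, seed = base_seed + 2,
                                    baseline = cfg$compliance_baseline,
                                    drop = cfg$compliance_drop,
                                    onset_delay = cfg$onset_delay_days,
                                    noise_cv = cfg$compliance_noise_cv))
  # normalised deficit actually realised in the emitted trajectories
  deficit <- lapply(traj, function(t) {
    (cfg$compliance_baseline - t$compliance) /
      (cfg$compliance_baseline * cfg$compliance_drop)
  })

  with_seed(base_seed + 3, {
    ## ---- design -------------------------------------------------------
    rows <- list()
    for (m in MODELS) for (arm in ARMS) for (d in cfg$days) {
      n <- cfg$group_sizes[[m]][[arm]]
      tag <- sprintf("%s_%s_d%02d", sub("_tgfb1", "", m), substr(arm, 1, 3), d)
      rows[[tag]] <- data.frame(
        sample_id = sprintf("%s_%d", tag, seq_len(n)),
        model = m, arm = arm, day = d,
        animal_id = sprintf("%s_%d", tag, seq_len(n)),
        stringsAsFactors = FALSE)
    }
    design <- sample_design(do.call(rbind, rows), days = cfg$days)
    rownames(design) <- NULL

    ## ---- feature universe and planted assignments ---------------------
    genes <- sprintf("gene_%04d", seq_len(cfg$n_genes))
    mirs <- sprintf("mmu-sim-miR-%03d", seq_len(cfg$n_mirnas))
    g_up <- genes[seq_len(cfg$n_planted_genes_up)]
    g_down <- genes[cfg$n_planted_genes_up + seq_len(cfg$n_planted_genes_down)]
    m_up <- mirs[seq_len(cfg$n_planted_mirnas_up)]
    m_down <- mirs[cfg$n_planted_mirnas_up + seq_len(cfg$n_planted_mirnas_down)]
    planted_mirs <- c(m_up, m_down)
    n_targets <- length(planted_mirs) * cfg$targets_per_mirna
    target_pool <- genes[cfg$n_planted_genes_up + cfg$n_planted_genes_down +
                           seq_len(n_targets)]
    pairs <- data.frame(
      mirna = rep(planted_mirs, each = cfg$targets_per_mirna),
      target = target_pool, stringsAsFactors = FALSE)

    ## ---- per-sample signal in log2 units ------------------------------
    n_smp <- nrow(design)
    day_idx <- match(design$day, cfg$days)
    u <- numeric(n_smp)  # normalised induction per sample (treated arm only)
    for (m in MODELS) {
      sel <- design$model == m & design$arm == "treated"
      u[sel] <- deficit[[m]][day_idx[sel]]
    }
    dir_gene <- setNames(numeric(cfg$n_genes), genes)
    dir_gene[g_up] <- 1; dir_gene[g_down] <- -1
    dir_mir <- setNames(numeric(cfg$n_mirnas), mirs)
    dir_mir[m_up] <- 1; dir_mir[m_down] <- -1

    # genes x samples log2 shift
    shift_g <- outer(dir_gene, u) * cfg$effect_size_log2fc_day21
    shift_m <- outer(dir_mir, u) * cfg$effect_size_log2fc_day21
    # repression is log-linear in the regulator: the target's log2 mean moves
    # by -repression_strength times the miRNA's log2 shift, so repression by
    # induced miRNAs and de-repression by depleted ones are symmetric
    for (k in seq_len(nrow(pairs))) {
      shift_g[pairs$target[k], ] <- shift_g[pairs$target[k], ] -
        cfg$repression_strength * shift_m[pairs$mirna[k], ]
    }

    ## ---- negative-binomial counts -------------------------------------
    draw_counts <- function(features, shift, lib_mean, planted) {
      w <- rlnorm(length(features), meanlog = 0, sdlog = cfg$baseline_sdlog)
      names(w) <- features
      # planted features are drawn from a mid/high abundance band so the
      # planted signal survives low-expression filtering
      w[planted] <- rlnorm(length(planted), meanlog = 0.5, sdlog = 0.5)
      w <- w / sum(w)
      lib <- rlnorm(n_smp, log(lib_mean) - 0.5 * log(1 + cfg$library_size_cv^2),
                    sqrt(log(1 + cfg$library_size_cv^2)))
      mu <- outer(w, lib) * 2^shift
      cnt <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
                    nrow = length(features),
                    dimnames = list(features, design$sample_id))
      cnt
    }
    mrna <- expression_matrix(
      draw_counts(genes, shift_g, cfg$library_size_mean[["mrna"]],
                  c(g_up, g_down, target_pool)),
      kind = "mrna", scale = "counts")
    mirna <- expression_matrix(
      draw_counts(mirs, shift_m, cfg$library_size_mean[["mirna"]],
                  planted_mirs),
      kind = "mirna", scale = "counts")

    ## ---- miRNA sequences and conservation structure -------------------
    mouse_seqs <- random_rna(cfg$n_mirnas)
    mouse_rec <- mirna_records(mirs, mouse_seqs, species = "mouse")
    nonconserved <- c(sample(m_up, cfg$n_nonconserved_up),
                      sample(m_down, cfg$n_nonconserved_down))
    conserved <- setdiff(planted_mirs, nonconserved)
    # non-planted miRNAs: ~60% get a human partner with random seed status
    others <- setdiff(mirs, planted_mirs)
    others_paired <- others[runif(length(others)) < 0.6]
    others_cons <- others_paired[runif(length(others_paired)) < 0.5]
    human_of <- function(name, seq, keep_seed) {
      # mature differs at 0-2 positions outside the seed; a broken seed
      # differs at 1-2 of its six positions
      out <- seq
      k <- sample(0:2, 1L)
      if (k > 0) out <- mutate_rna(out, sample(setdiff(seq_len(nchar(seq)), 2:7), k))
      if (!keep_seed) out <- mutate_rna(out, sample(2:7, sample(1:2, 1L)))
      out
    }
    h_names <- character(); h_seqs <- character()
    for (nm in c(planted_mirs, others_paired)) {
      keep <- nm %in% c(conserved, others_cons)
      h_names <- c(h_names, sub("^mmu-", "hsa-", nm))
      h_seqs <- c(h_seqs, human_of(nm, mouse_rec$mature_seq[mouse_rec$name == nm], keep))
    }
    human_rec <- mirna_records(h_names, h_seqs, species = "human")

    ## ---- prediction table ---------------------------------------------
    pred_rows <- list()
    for (k in seq_len(nrow(pairs))) {
      tools <- sample(PREDICTION_TOOLS, sample(2:3, 1L))
      pred_rows[[k]] <- data.frame(mirna = pairs$mirna[k],
                                   target = pairs$target[k], tool = tools,
                                   stringsAsFactors = FALSE)
    }
    planted_key <- paste(pairs$mirna, pairs$target)
    decoys <- data.frame(
      mirna = sample(mirs, cfg$n_decoy_predictions, replace = TRUE),
      target = sample(genes, cfg$n_decoy_predictions, replace = TRUE),
      tool = sample(PREDICTION_TOOLS, cfg$n_decoy_predictions, replace = TRUE),
      stringsAsFactors = FALSE)
    decoys <- decoys[!paste(decoys$mirna, decoys$target) %in% planted_key, ]
    decoys <- decoys[!duplicated(decoys[, c("mirna", "target")]), ]
    preds <- prediction_table(rbind(do.call(rbind, pred_rows), decoys))

    truth <- list(
      genes_up = g_up, genes_down = g_down,
      mirnas = data.frame(
        name = planted_mirs,
        direction = rep(c("UP", "DOWN"),
                        c(cfg$n_planted_mirnas_up, cfg$n_planted_mirnas_down)),
        conserved = planted_mirs %in% conserved, stringsAsFactors = FALSE),
      pairs = pairs,
      expected_hits = setdiff(planted_mirs,
                              intersect(m_up, nonconserved)),
      trajectories = traj, config = cfg)

    structure(list(mrna = mrna, mirna = mirna, design = design,
                   trajectories = traj, mouse_mirnas = mouse_rec,
                   human_mirnas = human_rec, predictions = preds,
                   truth = truth),
              class = "fc_study")
  })
}

#' @export
print.fc_study <- function(x, ...) {
  cat(sprintf(paste0(
    "<fc_study> synthetic two-model longitudinal study\n",
    "  mRNA: %d x %d counts; miRNA: %d x %d counts; %d samples\n",
    "  planted: %d/%d tracking genes (up/down), %d miRNAs, %d target pairs\n"),
    nrow(x$mrna$values), ncol(x$mrna$values),
    nrow(x$mirna$values), ncol(x$mirna$values), nrow(x$design),
    length(x$truth$genes_up), length(x$truth$genes_down),
    nrow(x$truth$mirnas), nrow(x$truth$pairs)))
  invisible(x)
}
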