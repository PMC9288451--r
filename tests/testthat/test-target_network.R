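make_log_cpm <- function(values, kind) {
  expression_matrix(values, kind, "log_cpm")
}

test_that("all-pairs correlation detects reflections and flags degeneracy", {
  set.seed(51)
  n <- 50
  mir <- matrix(rnorm(3 * n), 3, n,
                dimnames = list(c("mir1", "mir2", "mirflat"), paste0("s", 1:n)))
  mir["mirflat", ] <- 1
  mrna <- matrix(rnorm(2 * n), 2, n,
                 dimnames = list(c("gA", "gB"), paste0("s", 1:n)))
  mrna["gA", ] <- -mir["mir1", ]
  pc <- correlate_all_pairs(make_log_cpm(mir, "mirna"), make_log_cpm(mrna, "mrna"))
  expect_identical(nrow(pc), 6L)
  expect_equal(pc$rho[pc$mirna == "mir1" & pc$mrna == "gA"], -1)
  expect_true(all(pc$undefined[pc$mirna == "mirflat"]))
  # agreement with the scalar implementation
  expect_equal(pc$rho[pc$mirna == "mir2" & pc$mrna == "gB"],
               spearman_rho(mir["mir2", ], mrna["gB", ]), tolerance = 1e-12)
  # sample sets must match
  expect_error(correlate_all_pairs(
    make_log_cpm(mir[, 1:10], "mirna"), make_log_cpm(mrna, "mrna")),
    class = "fc_sample_mismatch")
})

test_that("independent profiles rarely reach the anticorrelation threshold", {
  set.seed(52)
  hits <- 0L
  for (i in 1:500) {
    if (abs(spearman_rho(rnorm(50), rnorm(50))) >= 0.6) hits <- hits + 1L
  }
  expect_lte(hits, 5L)  # |rho| >= 0.6 at n = 50 under the null: < 1%
})

test_that("high-confidence intersection applies both filters inclusively", {
  corr <- data.frame(
    mirna = c("m1", "m1", "m2", "m2"), mrna = c("gA", "gB", "gA", "gB"),
    rho = c(-0.7, -0.7, -0.5, -0.6), n_samples = 50L,
    undefined = FALSE, stringsAsFactors = FALSE)
  preds <- prediction_table(data.frame(
    mirna = c("m1", "m1", "m1", "m1", "m2", "m2", "m2"),
    target = c("gA", "gA", "gA", "gB", "gA", "gB", "gB"),
    tool = c("diana", "miranda", "pictar", "diana", "targetscan", "mirdb",
             "diana")))
  hc <- intersect_high_confidence(corr, preds)
  # (rho -0.7, 3 tools) kept; (rho -0.7, 1 tool) and (rho -0.5, 2) dropped;
  # boundary rho = -0.6 with 2 tools kept
  expect_identical(paste(hc$mirna, hc$mrna), c("m1 gA", "m2 gB"))
  # brute-force double-filter oracle on a random fixture
  set.seed(53)
  rcorr <- expand.grid(mirna = paste0("m", 1:8), mrna = paste0("g", 1:15),
                       stringsAsFactors = FALSE)
  rcorr$rho <- runif(nrow(rcorr), -1, 1); rcorr$undefined <- FALSE
  rpred <- unique(data.frame(
    mirna = sample(paste0("m", 1:8), 300, TRUE),
    target = sample(paste0("g", 1:15), 300, TRUE),
    tool = sample(c(fibrocouple:::PREDICTION_TOOLS), 300, TRUE)))
  rpred <- prediction_table(rpred)
  hc2 <- intersect_high_confidence(rcorr, rpred, rho_max = -0.4, min_tools = 2)
  oracle <- merge(rcorr, aggregate(tool ~ mirna + target, rpred, length),
                  by.x = c("mirna", "mrna"), by.y = c("mirna", "target"))
  oracle <- oracle[oracle$rho <= -0.4 & oracle$tool >= 2, ]
  expect_setequal(paste(hc2$mirna, hc2$mrna),
                  paste(oracle$mirna, oracle$mrna))
  # monotonicity: relaxing either threshold never shrinks the kept set
  for (i in 1:5) {
    rho1 <- runif(1, -0.9, -0.1); rho2 <- runif(1, rho1, 0)
    k_strict <- intersect_high_confidence(rcorr, rpred, rho_max = rho1)
    k_loose <- intersect_high_confidence(rcorr, rpred, rho_max = rho2)
    expect_true(all(paste(k_strict$mirna, k_strict$mrna) %in%
                      paste(k_loose$mirna, k_loose$mrna)))
  }
  k2 <- intersect_high_confidence(rcorr, rpred, min_tools = 2)
  k1 <- intersect_high_confidence(rcorr, rpred, min_tools = 1)
  expect_true(all(paste(k2$mirna, k2$mrna) %in% paste(k1$mirna, k1$mrna)))
})

test_that("seed-match prediction counts sites like a naive scan", {
  m <- mirna_records("mmu-miR-t", "AACAUUCAACGCUGUCGGUGAG", "mouse")
  site <- fibrocouple:::reverse_complement_rna(m$seed)  # seed ACAUUC
  expect_identical(site, "GAAUGU")
  targets <- c(one = paste0("CCCC", site, "CCCC"),
               none = "CCCCCCCCCCCCCCCC",
               two = paste0(site, "AAAA", site))
  pred <- predict_targets_seed_match(m, targets)
  expect_setequal(pred$target, c("one", "two"))
  expect_identical(pred$n_sites[pred$target == "two"], 2L)
  expect_true(all(pred$tool == "seedmatch"))
  # random-sequence oracle: naive substring scan
  set.seed(61)
  naive_count <- function(s, p) {
    k <- nchar(p)
    sum(vapply(seq_len(nchar(s) - k + 1),
               function(i) substr(s, i, i + k - 1) == p, logical(1)))
  }
  seqs <- setNames(vapply(1:30, function(i) random_rna_string(200), ""),
                   paste0("t", 1:30))
  pred2 <- predict_targets_seed_match(m, seqs)
  counts <- setNames(rep(0L, length(seqs)), names(seqs))
  counts[pred2$target] <- pred2$n_sites
  expect_identical(unname(counts),
                   unname(vapply(seqs, naive_count, integer(1), p = site)))
  expect_error(predict_targets_seed_match(m, c(x = "ACGTN")),
               class = "fc_invalid_alphabet")
})

test_that("network assembly counts nodes/edges and respects the boundary", {
  smp <- paste0("s", 1:20)
  set.seed(62)
  base <- matrix(rnorm(5 * 20), 5, 20,
                 dimnames = list(paste0("g", 1:5), smp))
  base[2, ] <- base[1, ] + rnorm(20, sd = 0.01)   # g2 tracks g1
  lc <- make_log_cpm(base, "mrna")
  pairs <- data.frame(mirna = c("m1", "m1", "m2", "m2"),
                      mrna = c("g1", "g3", "g4", "g5"),
                      rho = c(-0.8, -0.7, -0.9, -0.65), n_tools = 2L)
  ann <- data.frame(id = c("m1", "m2", paste0("g", 1:5)),
                    log2fc_day21_aav = rnorm(7),
                    n_significant_contrasts = 1L, lung_function_r = 0)
  # no coexpression above threshold: 6 nodes, 4 repression edges
  net <- build_network(pairs, lc, ann, mrna_mrna_min_r = 0.9999,
                       method = "pearson")
  expect_identical(nrow(net$nodes), 6L)
  expect_identical(nrow(net$edges), 4L)
  expect_true(all(net$edges$kind == "mirna_mrna"))
  # repression edges run from miRNA nodes to mRNA nodes only
  kind_of <- setNames(net$nodes$kind, net$nodes$id)
  rep_e <- net$edges[net$edges$kind == "mirna_mrna", ]
  expect_true(all(kind_of[rep_e$source] == "mirna"))
  expect_true(all(kind_of[rep_e$target] == "mrna"))
  # inclusive coexpression boundary: engineered rho exactly at threshold
  v <- matrix(0, 2, 5, dimnames = list(c("x", "y"), paste0("s", 1:5)))
  v["x", ] <- c(1, 2, 3, 4, 5); v["y", ] <- c(1, 2, 3, 5, 4)
  rho_xy <- spearman_rho(v["x", ], v["y", ])   # = 0.9
  lc2 <- make_log_cpm(v, "mrna")
  pairs2 <- data.frame(mirna = "m1", mrna = c("x", "y"),
                       rho = c(-0.8, -0.8), n_tools = 2L)
  ann2 <- data.frame(id = c("m1", "x", "y"), log2fc_day21_aav = 0,
                     n_significant_contrasts = 0L, lung_function_r = 0)
  net2 <- build_network(pairs2, lc2, ann2, mrna_mrna_min_r = rho_xy)
  expect_true(any(net2$edges$kind == "mrna_mrna"))
  net3 <- build_network(pairs2, lc2, ann2,
                        mrna_mrna_min_r = rho_xy + 1e-9)
  expect_false(any(net3$edges$kind == "mrna_mrna"))
  # missing annotation is an error
  expect_error(build_network(pairs, lc, ann[-1, ]),
               class = "fc_missing_annotation")
})

test_that("node and edge counts match a brute-force reconstruction", {
  run <- cached_run(1)
  net <- run$network
  down_mirs <- run$hits$mirna[run$hits$direction == "DOWN"]
  exp_pairs <- run$hc_pairs[run$hc_pairs$mirna %in% down_mirs, ]
  exp_nodes <- unique(c(exp_pairs$mirna, exp_pairs$mrna))
  expect_setequal(net$nodes$id, exp_nodes)
  expect_identical(sum(net$edges$kind == "mirna_mrna"), nrow(exp_pairs))
  # every repression edge exists in the high-confidence list
  expect_true(all(paste(net$edges$source[net$edges$kind == "mirna_mrna"],
                        net$edges$target[net$edges$kind == "mirna_mrna"]) %in%
                    paste(run$hc_pairs$mirna, run$hc_pairs$mrna)))
  # no orphan, annotation-less nodes
  expect_false(any(is.na(net$nodes$log2fc_day21_aav)))
  expect_false(any(is.na(net$nodes$lung_function_r)))
})
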