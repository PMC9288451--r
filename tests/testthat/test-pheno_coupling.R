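test_that("correlation primitives match brute-force formula oracles", {
  expect_equal(pearson_r(1:5, c(2, 4, 6, 8, 10)), 1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1.0)
  x <- c(3, 7, 14, 21, 28); y <- c(1, 2, 2, 3, 6)
  expect_equal(pearson_r(x, y), oracle_pearson(x, y), tolerance = 1e-12)
  set.seed(21)
  for (i in 1:50) {
    a <- rnorm(sample(3:30, 1)); b <- rnorm(length(a))
    expect_equal(pearson_r(a, b), oracle_pearson(a, b), tolerance = 1e-12)
    expect_equal(spearman_rho(a, b), oracle_pearson(rank(a), rank(b)),
                 tolerance = 1e-12)
  }
  # undefined correlations are explicit, never silent zeros
  expect_true(is.na(pearson_r(rep(1, 5), 1:5)))
  expect_true(is.na(spearman_rho(rep(2, 4), 1:4)))
  expect_error(pearson_r(1:2, 1:2), class = "fc_bad_input")
})

test_that("spearman uses average ranks and is monotone-invariant", {
  x <- c(1, 2, 3, 4); y <- c(10, 10, 5, 1)
  expect_equal(spearman_rho(x, y), oracle_pearson(c(1, 2, 3, 4), c(3.5, 3.5, 2, 1)),
               tolerance = 1e-12)
  expect_equal(spearman_rho(1:6, (1:6)^3), 1.0)
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(10); b <- rnorm(10)
    expect_equal(spearman_rho(exp(a), b), spearman_rho(a, b), tolerance = 1e-12)
  }
})

test_that("lung-function correlation handles affine and degenerate profiles", {
  days <- c(3L, 7L, 14L, 21L, 28L)
  traj <- list(
    bleomycin = phenotype_trajectory("bleomycin", days, c(55, 48, 40, 36, 36) / 1000),
    aav_tgfb1 = phenotype_trajectory("aav_tgfb1", days, c(59, 57, 47, 36, 35) / 1000))
  mk <- function(b, a) {
    list(bleomycin = matrix(b, 1, 5, dimnames = list("f", days)),
         aav_tgfb1 = matrix(a, 1, 5, dimnames = list("f", days)))
  }
  # log2fc affine in -compliance => r = -1 in each model
  prof <- mk(2 - 30 * traj$bleomycin$compliance, 1 - 20 * traj$aav_tgfb1$compliance)
  cc <- correlate_with_lung_function(prof, traj)
  expect_equal(cc$r_bleomycin, -1)
  expect_equal(cc$r_aav, -1)
  expect_equal(cc$mean_r, -1)
  # constant profile -> undefined flag
  cc2 <- correlate_with_lung_function(mk(rep(1, 5), 1:5), traj)
  expect_true(cc2$undefined)
  expect_true(is.na(cc2$r_bleomycin))
  # mismatched day grids are an error
  bad <- prof
  colnames(bad$bleomycin) <- c(3, 7, 14, 21, 29)
  expect_error(correlate_with_lung_function(bad, traj), class = "fc_day_mismatch")
})

test_that("gene selection equals an exhaustive filter-then-sort oracle", {
  set.seed(77)
  n <- 200
  corr <- data.frame(
    feature_id = sprintf("g%03d", 1:n),
    r_bleomycin = runif(n, -1, 1), r_aav = runif(n, -1, 1),
    n_points = 5L, stringsAsFactors = FALSE)
  corr$mean_r <- (corr$r_bleomycin + corr$r_aav) / 2
  corr$undefined <- FALSE
  class(corr) <- c("fc_lungfun_corr", "data.frame")
  d21 <- rbind(
    data.frame(feature_id = corr$feature_id, model = "bleomycin", day = 21L,
               log2fc = rnorm(n), adj_p = runif(n, 0, 0.2)),
    data.frame(feature_id = corr$feature_id, model = "aav_tgfb1", day = 21L,
               log2fc = rnorm(n), adj_p = runif(n, 0, 0.2)))
  for (dir in c("up", "down")) {
    sel <- select_phenotype_coupled_genes(corr, d21, dir, r_threshold = 0.5)
    sgn <- if (dir == "up") 1 else -1
    b <- d21[d21$model == "bleomycin", ]; a <- d21[d21$model == "aav_tgfb1", ]
    pass <- corr$feature_id[sgn * corr$mean_r <= -0.5 &
      b$adj_p <= 0.05 & a$adj_p <= 0.05 &
      sgn * b$log2fc >= 0 & sgn * a$log2fc >= 0]
    expect_setequal(sel$feature_id, pass)
    expect_false(is.unsorted(sgn * -sel$rank_key))   # ranked by mean day-21 lfc
  }
  # up and down selections are images under a global sign flip
  flip_corr <- corr
  flip_corr$r_bleomycin <- -corr$r_bleomycin
  flip_corr$r_aav <- -corr$r_aav
  flip_corr$mean_r <- -corr$mean_r
  flip_d21 <- d21; flip_d21$log2fc <- -d21$log2fc
  up <- select_phenotype_coupled_genes(corr, d21, "up", r_threshold = 0.5)
  down_flipped <- select_phenotype_coupled_genes(flip_corr, flip_d21, "down",
                                                 r_threshold = 0.5)
  expect_identical(up$feature_id, down_flipped$feature_id)
  expect_equal(up$rank_key, -down_flipped$rank_key)
  # direction inconsistency excludes a feature
  one_corr <- corr[1, ]; one_corr$mean_r <- -0.9; one_corr$undefined <- FALSE
  one_d21 <- d21[d21$feature_id == corr$feature_id[1], ]
  one_d21$adj_p <- 0.01; one_d21$log2fc <- c(2, -0.1)
  expect_identical(nrow(select_phenotype_coupled_genes(one_corr, one_d21, "up")), 0L)
  one_d21$log2fc <- c(2, 1)
  expect_identical(select_phenotype_coupled_genes(one_corr, one_d21, "up")$rank_key, 1.5)
})

test_that("pattern ranking sorts by correlation with the template", {
  days <- c(3, 7, 14, 21, 28)
  prof <- list(bleomycin = rbind(
    spike3 = c(5, 0, 0, 0, 0), spike28 = c(0, 0, 0, 0, 5),
    exactly = c(1, 0, 0, 0, 0), flat = c(2, 2, 2, 2, 2)),
    aav_tgfb1 = NULL)
  colnames(prof$bleomycin) <- days
  rk <- pattern_rank(prof, c(1, 0, 0, 0, 0), "bleomycin")
  expect_identical(rk$feature_id[1:2] %in% c("spike3", "exactly"), c(TRUE, TRUE))
  expect_equal(rk$r[rk$feature_id == "exactly"], 1.0)
  expect_lt(which(rk$feature_id == "spike3"), which(rk$feature_id == "spike28"))
  expect_identical(rk$feature_id[4], "flat")  # undefined r ranks last
  expect_true(is.na(rk$r[4]))
  expect_error(pattern_rank(prof, rep(1, 5), "bleomycin"), class = "fc_bad_input")
  # agreement with a brute-force sort on random profiles
  set.seed(8)
  m <- matrix(rnorm(250), 50, 5,
              dimnames = list(sprintf("f%02d", 1:50), days))
  pat <- c(0, 1, 2, 1, 0)
  rk2 <- pattern_rank(list(bleomycin = m), pat, "bleomycin")
  r_oracle <- apply(m, 1, oracle_pearson, y = pat)
  expect_identical(rk2$feature_id, names(sort(r_oracle, decreasing = TRUE)))
})

test_that("model-specificity partition is disjoint, exhaustive and scored", {
  set.seed(12)
  df <- data.frame(feature_id = sprintf("g%02d", 1:60),
                   log2fc_bleomycin = rnorm(60), log2fc_aav = rnorm(60),
                   stringsAsFactors = FALSE)
  df$log2fc_bleomycin[1] <- 1.0; df$log2fc_aav[1] <- 0.1    # exclusive bleo
  df$log2fc_bleomycin[2] <- 0.7; df$log2fc_aav[2] <- -0.8   # common (magnitudes)
  part <- partition_model_specificity(df, day = 21L, cutoff = 0.6)
  expect_true("g01" %in% part$sets$exclusive_bleomycin)
  expect_true("g02" %in% part$sets$common)
  all_ids <- unlist(part$sets)
  expect_setequal(all_ids, df$feature_id)
  expect_identical(anyDuplicated(all_ids), 0L)
  # identical fold changes give r^2 = 1
  same <- data.frame(feature_id = c("a", "b", "c"),
                     log2fc_bleomycin = c(1, 2, -3), log2fc_aav = c(1, 2, -3))
  p2 <- partition_model_specificity(same, 21L)
  expect_equal(unname(p2$r_squared["common"]), 1.0)
})
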