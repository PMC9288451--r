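# Shared fixture builders. Everything is generated in code at test time.

# Minimal balanced design: both models, both arms, n per group, all days.
tiny_design <- function(n = 3L, days = c(3L, 7L, 14L, 21L, 28L)) {
  rows <- expand.grid(rep = seq_len(n), model = c("bleomycin", "aav_tgfb1"),
                      arm = c("treated", "control"), day = days,
                      stringsAsFactors = FALSE)
  rows$sample_id <- sprintf("%s_%s_d%02d_%d", sub("_tgfb1", "", rows$model),
                            substr(rows$arm, 1, 3), rows$day, rows$rep)
  rows$animal_id <- rows$sample_id
  sample_design(rows[, c("sample_id", "model", "arm", "day", "animal_id")],
                days = days)
}

# Random count matrix over a design.
tiny_counts <- function(design, n_features = 20L, kind = "mrna", seed = 1L,
                        lambda = 50) {
  set.seed(seed)
  prefix <- if (kind == "mrna") "g" else "mir"
  m <- matrix(rpois(n_features * nrow(design), lambda), nrow = n_features,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(n_features)),
                              design$sample_id))
  expression_matrix(m, kind = kind, scale = "counts")
}

# Brute-force Pearson correlation straight from the covariance formula.
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Benjamini-Hochberg step-up written from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  # enforce monotonicity from the largest rank downwards
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Exhaustive global alignment score by recursion over all alignments
# (no DP reuse): the independent oracle for nw_global_score.
oracle_align <- function(a, b, match = 1, mismatch = 0, gap = -2) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(x) && j > length(y)) return(0)
    best <- -Inf
    if (i <= length(x) && j <= length(y)) {
      s <- if (x[i] == y[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1))
    }
    if (i <= length(x)) best <- max(best, gap + rec(i + 1, j))
    if (j <= length(y)) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

random_rna_string <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# One default synthetic study end-to-end run, cached per seed so the
# parameter-recovery suites share work across test blocks.
.run_cache <- new.env(parent = emptyenv())
cached_run <- function(seed) {
  key <- as.character(seed)
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- suppressMessages(
      run_full_pipeline(list(simulation = list(rng_seed = as.integer(seed)))))
  }
  .run_cache[[key]]
}
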