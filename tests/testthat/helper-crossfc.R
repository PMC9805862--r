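# Shared fixture builders: everything is generated in code at test time.

# bold_series from a T x V matrix laid out on a (V, 1, 1) grid
bold_from_matrix <- function(mat, tr_s = 2) {
  v <- ncol(mat)
  bold_series(array(t(mat), dim = c(v, 1, 1, nrow(mat))), tr_s = tr_s)
}

# a small simulation config scaled for test runtime
small_config <- function(...) {
  defaults <- list(grid_shape = c(10, 10, 10), n_volumes = 100,
                   n_subjects = 4,
                   seed_region = list(lo = c(5, 2, 2), hi = c(6, 3, 3)),
                   target_region = list(lo = c(2, 6, 6), hi = c(4, 8, 8)),
                   hub_spec = list(list(lo = c(2, 2, 2), hi = c(4, 4, 4),
                                        amplitude = 1)))
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# complete 2x2 crossover design for n subjects (no file paths)
null_design <- function(n, seed = 1) {
  set.seed(seed)
  subj <- sprintf("S%02d", seq_len(n))
  d <- expand.grid(drug = c("placebo", "verum"), session = c("RS0", "RS1"),
                   subject = subj, stringsAsFactors = FALSE)
  idx <- match(d$subject, subj)
  d$sequence <- ifelse(idx %% 2 == 1, "drug-first", "placebo-first")
  d$age <- sample(31:59, n, replace = TRUE)[idx]
  d[, c("subject", "sequence", "drug", "session", "age")]
}

# map-level cohort: one 3D array per design row, iid N(effect, sd);
# effect_fun(drug, session) gives the cell mean added inside effect_mask
null_maps <- function(design, grid = c(12, 12, 12), sd = 0.1,
                      effect_fun = NULL, effect_mask = NULL) {
  lapply(seq_len(nrow(design)), function(i) {
    m <- array(stats::rnorm(prod(grid), sd = sd), grid)
    if (!is.null(effect_fun)) {
      m[effect_mask] <- m[effect_mask] +
        effect_fun(design$drug[i], design$session[i])
    }
    m
  })
}

# brute-force gFCD oracle: O(V^2) double loop over stats::cor
naive_gfcd_K <- function(mat, threshold) {
  v <- ncol(mat)
  k <- integer(v)
  sds <- apply(mat, 2, stats::sd)
  for (i in seq_len(v)) {
    if (sds[i] == 0) next
    for (j in seq_len(v)) {
      if (i == j || sds[j] == 0) next
      if (stats::cor(mat[, i], mat[, j]) > threshold) k[i] <- k[i] + 1L
    }
  }
  k
}
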