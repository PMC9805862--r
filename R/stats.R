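#' Group-level inference for the crossover design
#'
#' One-sample validation maps (hubs: gFCD > 1; connectivity: zFC != 0), the
#' 2x2 within-subject time-by-drug interaction with age and sequence
#' covariates, sign-flip permutation cluster-level FWE correction, and post
#' hoc paired tests on cluster means.
#'
#' @name group-stats
NULL

#' Validate a crossover design table
#'
#' Checks that every subject has exactly the four placebo/verum x RS0/RS1
#' cells, a consistent sequence label, and a positive age.
#'
#' @param design Data frame with columns `subject`, `sequence`, `drug`,
#'   `session`, `age` (paths optional).
#' @return The design, invisibly; errors name the offending subject/cell.
#' @export
validate_design <- function(design) {
  need <- c("subject", "sequence", "drug", "session", "age")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop("design table lacks columns: ",
                         paste(miss, collapse = ", "))
  cells <- c("placebo_RS0", "placebo_RS1", "verum_RS0", "verum_RS1")
  for (s in unique(design$subject)) {
    rows <- design[design$subject == s, ]
    have <- paste(rows$drug, rows$session, sep = "_")
    missing_cells <- setdiff(cells, have)
    if (length(missing_cells) || nrow(rows) != 4) {
      stop("subject ", s, ": expected exactly one row per cell; missing: ",
           paste(missing_cells, collapse = ", "))
    }
    if (length(unique(rows$sequence)) != 1) {
      stop("subject ", s, ": inconsistent sequence labels")
    }
    if (any(rows$age <= 0)) stop("subject ", s, ": nonpositive age")
  }
  invisible(design)
}

# stack a list of 3D maps into a V x n matrix over a mask
.maps_matrix <- function(maps, mask) {
  get_arr <- function(m) {
    if (inherits(m, "fc_map")) m$z
    else if (inherits(m, "gfcd_map")) m$K_norm
    else m
  }
  vapply(maps, function(m) get_arr(m)[mask], numeric(sum(mask)))
}

#' One-sample validation map
#'
#' Voxel-wise one-sample T against a reference value (1 for normalized gFCD
#' hub maps, 0 for Fisher-z connectivity maps) with multiple-comparison
#' correction: Benjamini-Hochberg FDR or max-statistic sign-flip permutation
#' FWE, both at `alpha`.
#'
#' @param maps List of subject-level 3D arrays (or `fc_map` / `gfcd_map`).
#' @param mask Logical analysis mask.
#' @param null_value Reference value tested against.
#' @param correction `"fdr"` or `"voxel_fwe"`.
#' @param alpha Significance level (default 0.05).
#' @param n_permutations Sign flips for `"voxel_fwe"`.
#' @param rng_seed Seed for the permutation draw.
#' @return List with 3D arrays `t`, `p`, `p_adj`, `sig` (logical), plus
#'   `df` and the correction used. Zero-variance voxels are NA with warning.
#' @export
one_sample_map <- function(maps, mask, null_value = 0,
                           correction = c("fdr", "voxel_fwe"), alpha = 0.05,
                           n_permutations = 1000L, rng_seed = 1L) {
  correction <- match.arg(correction)
  n <- length(maps)
  if (n < 3) stop("need at least 3 subjects")
  y <- .maps_matrix(maps, mask) - null_value
  m <- rowMeans(y)
  sdv <- apply(y, 1, stats::sd)
  zero <- sdv == 0
  if (any(zero)) warning(sum(zero),
                         " zero-variance voxel(s) masked out of the T map")
  tval <- ifelse(zero, NA_real_, m / (sdv / sqrt(n)))
  df <- n - 1
  p <- 2 * stats::pt(-abs(tval), df)
  if (correction == "fdr") {
    p_adj <- stats::p.adjust(p, method = "BH")
  } else {
    set.seed(as.integer(rng_seed))
    obs <- abs(tval)
    count <- rep(1, length(tval))
    for (b in seq_len(n_permutations)) {
      s <- sample(c(-1, 1), n, replace = TRUE)
      ys <- sweep(y, 2, s, "*")
      ms <- rowMeans(ys)
      sds <- sqrt((rowSums(ys^2) - n * ms^2) / (n - 1))
      tp <- ifelse(sds == 0, 0, ms / (sds / sqrt(n)))
      mx <- max(abs(tp), na.rm = TRUE)
      count <- count + (mx >= obs)
    }
    p_adj <- count / (n_permutations + 1)
    p_adj[zero] <- NA_real_
  }
  to_vol <- function(v) {
    out <- array(NA_real_, dim = dim(mask)); out[mask] <- v; out
  }
  sig <- to_vol(as.numeric(!is.na(p_adj) & p_adj <= alpha)) > 0
  list(t = to_vol(tval), p = to_vol(p), p_adj = to_vol(p_adj), sig = sig,
       df = df, correction = correction)
}

# per-subject cell contrast matrices (V x n) from a design + parallel maps
.cell_contrast <- function(design, maps, mask,
                           effect = c("interaction", "time", "drug")) {
  effect <- match.arg(effect)
  validate_design(design)
  subjects <- unique(design$subject)
  v <- sum(mask)
  y <- .maps_matrix(maps, mask)
  delta <- matrix(0, v, length(subjects))
  cell <- function(s, drug, sess) {
    i <- which(design$subject == s & design$drug == drug &
                 design$session == sess)
    y[, i]
  }
  for (j in seq_along(subjects)) {
    s <- subjects[j]
    delta[, j] <- switch(effect,
      interaction = (cell(s, "verum", "RS1") - cell(s, "verum", "RS0")) -
        (cell(s, "placebo", "RS1") - cell(s, "placebo", "RS0")),
      time = ((cell(s, "verum", "RS1") + cell(s, "placebo", "RS1")) -
                (cell(s, "verum", "RS0") + cell(s, "placebo", "RS0"))) / 2,
      drug = ((cell(s, "verum", "RS0") + cell(s, "verum", "RS1")) -
                (cell(s, "placebo", "RS0") + cell(s, "placebo", "RS1"))) / 2)
  }
  meta <- design[!duplicated(design$subject),
                 c("subject", "sequence", "age")]
  meta <- meta[match(subjects, meta$subject), ]
  list(delta = delta, subjects = subjects, age = meta$age,
       sequence = meta$sequence)
}

# covariate-adjusted intercept T for a V x n contrast matrix
.contrast_t <- function(delta, x) {
  n <- ncol(delta)
  p <- ncol(x)
  qr_x <- qr(x)
  if (qr_x$rank < p) stop("covariate design is rank-deficient")
  qty <- qr.qty(qr_x, t(delta))[seq_len(p), , drop = FALSE]
  beta <- backsolve(qr.R(qr_x), qty)
  rss <- colSums(t(delta)^2) - colSums(qty^2)
  rss[rss < 0] <- 0
  xtx_inv_11 <- chol2inv(qr.R(qr_x))[1, 1]
  sigma2 <- rss / (n - p)
  se <- sqrt(sigma2 * xtx_inv_11)
  tval <- ifelse(se == 0, ifelse(beta[1, ] == 0, 0, sign(beta[1, ]) * Inf),
                 beta[1, ] / se)
  list(t = tval, beta0 = beta[1, ], df = n - p)
}

#' Crossover interaction (or main-effect) contrast
#'
#' Computes, per subject, the difference-of-differences map
#' `(verum RS1 - verum RS0) - (placebo RS1 - placebo RS0)` (or the analogous
#' time / drug main-effect contrast from cell averages) and regresses it
#' voxel-wise on an intercept plus mean-centered age and a mean-centered
#' sequence indicator. The interaction T statistic is the intercept estimate
#' over its standard error, with `df = n - 3` (or `n - 1` without
#' covariates) — the standard equivalent of the 2x2 within-subject ANOVA
#' interaction with between-subject covariates.
#'
#' @param design Crossover design table (see [validate_design()]); rows must
#'   parallel `maps`.
#' @param maps List of per-row 3D maps (or `fc_map` / `gfcd_map`).
#' @param mask Logical analysis mask.
#' @param effect `"interaction"` (default), `"time"` or `"drug"`.
#' @param covariates Include age + sequence covariates (default TRUE).
#' @return An `fc_contrast`: `t` (3D array), `delta` (V x n matrix),
#'   `x` (covariate design), `df`, `mask`, `subjects`, `effect`.
#' @export
interaction_contrast <- function(design, maps, mask,
                                 effect = c("interaction", "time", "drug"),
                                 covariates = TRUE) {
  effect <- match.arg(effect)
  cc <- .cell_contrast(design, maps, mask, effect)
  n <- length(cc$subjects)
  if (n < 4) stop("need at least 4 complete subjects, got ", n)
  x <- if (covariates) {
    seq_ind <- as.numeric(cc$sequence == "drug-first")
    cbind(intercept = 1, age = cc$age - mean(cc$age),
          sequence = seq_ind - mean(seq_ind))
  } else {
    cbind(intercept = rep(1, n))
  }
  ct <- .contrast_t(cc$delta, x)
  t_vol <- array(NA_real_, dim = dim(mask))
  t_vol[mask] <- ct$t
  structure(list(t = t_vol, delta = cc$delta, x = x, df = ct$df, mask = mask,
                 subjects = cc$subjects, effect = effect),
            class = "fc_contrast")
}

#' @export
print.fc_contrast <- function(x, ...) {
  cat(sprintf("<fc_contrast> %s effect, %d subjects, df = %d\n", x$effect,
              length(x$subjects), x$df))
  invisible(x)
}

# max cluster size over both signs of a thresholded T vector
.max_cluster_size <- function(tval, t_thr, mask, connectivity) {
  mx <- 0L
  for (sgn in c(1, -1)) {
    sel <- array(FALSE, dim = dim(mask))
    sel[mask] <- sgn * tval > t_thr
    if (any(sel)) {
      sz <- label_clusters(sel, connectivity)$sizes
      if (length(sz)) mx <- max(mx, sz[1])
    }
  }
  mx
}

#' Cluster-level FWE correction by sign-flip permutation
#'
#' Thresholds the interaction T map at the two-sided `height_p` Student-t
#' quantile, labels suprathreshold voxels (positive and negative sets
#' separately) into connected components, and compares each cluster's extent
#' against the permutation null distribution of the maximum cluster size
#' obtained by sign-flipping the subject-level contrast maps and recomputing
#' the covariate-adjusted T map for every flip:
#' `p_fwe = (1 + #\{max k_perm >= k\}) / (1 + n_permutations)`.
#'
#' @param contrast An `fc_contrast` from [interaction_contrast()].
#' @param height_p Two-sided voxel height threshold (default 0.001).
#' @param n_permutations Number of sign flips (>= 100; default 1000).
#' @param rng_seed Seed making the flips reproducible.
#' @param connectivity Cluster connectivity (default 18).
#' @param affine Optional 4x4 voxel-to-mm matrix for peak coordinates.
#' @return List with `clusters` (data.frame: cluster, sign, k, peak_t,
#'   x/y/z mm, p_fwe), `labels` (signed integer 3D array), `t_threshold`,
#'   `null_max_k`.
#' @export
cluster_fwe <- function(contrast, height_p = 0.001, n_permutations = 1000L,
                        rng_seed = 1L, connectivity = 18, affine = NULL) {
  stopifnot(height_p > 0, height_p < 1, n_permutations >= 100)
  set.seed(as.integer(rng_seed))
  mask <- contrast$mask
  delta <- contrast$delta
  x <- contrast$x
  n <- ncol(delta)
  t_thr <- stats::qt(1 - height_p / 2, contrast$df)
  tval <- contrast$t[mask]

  # permutation null of the maximum cluster extent (both signs pooled)
  null_max <- integer(n_permutations)
  signs <- matrix(sample(c(-1, 1), n * n_permutations, replace = TRUE), n)
  xtx_inv_11 <- chol2inv(qr.R(qr(x)))[1, 1]
  xtx_inv <- chol2inv(qr.R(qr(x)))
  sumsq <- colSums(t(delta)^2)          # invariant under sign flips
  p <- ncol(x)
  dt <- t(delta)                        # n x V
  for (b in seq_len(n_permutations)) {
    xs <- x * signs[, b]                # (s o X)' Y == X' (s o Y)
    xty <- crossprod(xs, dt)            # p x V
    beta <- xtx_inv %*% xty
    rss <- sumsq - colSums(beta * xty)
    rss[rss < 0] <- 0
    se <- sqrt(rss / (n - p) * xtx_inv_11)
    tp <- ifelse(se == 0, 0, beta[1, ] / se)
    null_max[b] <- .max_cluster_size(tp, t_thr, mask, connectivity)
  }

  # observed clusters, positive and negative sets labelled separately
  rows <- list()
  labels <- array(0L, dim = dim(mask))
  next_id <- 0L
  for (sgn in c(1, -1)) {
    sel <- array(FALSE, dim = dim(mask))
    sel[mask] <- !is.na(tval) & sgn * tval > t_thr
    if (!any(sel)) next
    lc <- label_clusters(sel, connectivity)
    for (cl in seq_along(lc$sizes)) {
      next_id <- next_id + 1L
      vox <- which(lc$labels == cl, arr.ind = TRUE)
      tv <- contrast$t[lc$labels == cl]
      peak <- which.max(abs(tv))
      k <- lc$sizes[cl]
      p_fwe <- (1 + sum(null_max >= k)) / (1 + n_permutations)
      mm <- if (!is.null(affine)) .voxel_to_mm(vox[peak, , drop = FALSE],
                                               affine)
            else vox[peak, , drop = FALSE]
      rows[[next_id]] <- data.frame(cluster = next_id, sign = sgn, k = k,
                                    peak_t = tv[peak], x = mm[1], y = mm[2],
                                    z = mm[3], p_fwe = p_fwe)
      labels[lc$labels == cl] <- sgn * next_id
    }
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(0), sign = integer(0), k = integer(0),
               peak_t = numeric(0), x = numeric(0), y = numeric(0),
               z = numeric(0), p_fwe = numeric(0))
  if (nrow(clusters)) clusters <- clusters[order(clusters$p_fwe,
                                                 -clusters$k), ]
  list(clusters = clusters, labels = labels, t_threshold = t_thr,
       null_max_k = null_max)
}

# paired t with explicit handling of zero-variance differences
.paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  if (n < 2) stop("need at least 2 pairs")
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0) return(list(t = 0, df = n - 1, p = 1))
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0))
  }
  tval <- mean(d) / (s / sqrt(n))
  list(t = tval, df = n - 1, p = 2 * stats::pt(-abs(tval), n - 1))
}

#' Post hoc paired tests on cluster means
#'
#' Extracts the cluster-mean map value per subject and cell, then runs the
#' four paired comparisons: verum vs placebo at RS0 and at RS1, and RS1 vs
#' RS0 within each drug. Two-sided, df = n - 1.
#'
#' @param design Crossover design table; rows parallel `maps`.
#' @param maps List of per-row 3D maps (smoothed, as entered into the
#'   cluster-defining analysis).
#' @param cluster_mask Logical mask of one significant cluster.
#' @return Data frame with `contrast`, `t`, `df`, `p`, `mean_diff` plus a
#'   `cell_means` attribute (subject x cell matrix).
#' @export
posthoc_cluster_tests <- function(design, maps, cluster_mask) {
  validate_design(design)
  if (!any(cluster_mask)) stop("empty cluster mask")
  vals <- vapply(maps, function(m) {
    arr <- if (inherits(m, "fc_map")) m$z
           else if (inherits(m, "gfcd_map")) m$K_norm else m
    mean(arr[cluster_mask])
  }, 0)
  subjects <- unique(design$subject)
  cells <- c("placebo_RS0", "placebo_RS1", "verum_RS0", "verum_RS1")
  cm <- matrix(NA_real_, length(subjects), 4,
               dimnames = list(subjects, cells))
  for (i in seq_along(vals)) {
    cm[design$subject[i], paste(design$drug[i], design$session[i],
                                sep = "_")] <- vals[i]
  }
  comparisons <- list(
    verum_vs_placebo_RS0 = c("verum_RS0", "placebo_RS0"),
    verum_vs_placebo_RS1 = c("verum_RS1", "placebo_RS1"),
    RS1_vs_RS0_placebo = c("placebo_RS1", "placebo_RS0"),
    RS1_vs_RS0_verum = c("verum_RS1", "verum_RS0"))
  out <- do.call(rbind, lapply(names(comparisons), function(nm) {
    ab <- comparisons[[nm]]
    tt <- .paired_t(cm[, ab[1]], cm[, ab[2]])
    data.frame(contrast = nm, t = tt$t, df = tt$df, p = tt$p,
               mean_diff = mean(cm[, ab[1]] - cm[, ab[2]]))
  }))
  attr(out, "cell_means") <- cm
  out
}
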