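test_that("one-sample map: null input gives nothing, BH follows the step-up rule", {
  grid <- c(4, 4, 4)
  mask <- array(TRUE, grid)
  flat <- lapply(1:5, function(i) array(1, grid))
  expect_warning(r <- one_sample_map(flat, mask, null_value = 1),
                 "zero-variance")
  expect_false(any(r$sig, na.rm = TRUE))
  # step-up oracle: p = (.001,.02,.03,.5), m = 4, q = .05 ->
  # thresholds .0125,.025,.0375,.05 -> first three rejected
  expect_equal(p.adjust(c(0.001, 0.02, 0.03, 0.5), "BH") <= 0.05,
               c(TRUE, TRUE, TRUE, FALSE))
})

test_that("one-sample map detects a planted offset with FDR and voxel FWE", {
  set.seed(40)
  grid <- c(8, 8, 8)
  mask <- array(TRUE, grid)
  region <- box_mask(grid, c(2, 2, 2), c(4, 4, 4))
  delta <- 2; sigma <- 1; n <- 20
  maps <- lapply(seq_len(n), function(i) {
    m <- array(rnorm(prod(grid), sd = sigma), grid)
    m[region] <- m[region] + delta
    m
  })
  fdr <- one_sample_map(maps, mask, null_value = 0, correction = "fdr")
  expect_gt(mean(fdr$sig[region], na.rm = TRUE), 0.8)   # sensitivity
  expect_lt(mean(fdr$sig[!region], na.rm = TRUE), 0.05) # specificity
  fwe <- one_sample_map(maps, mask, null_value = 0, correction = "voxel_fwe",
                        n_permutations = 200, rng_seed = 2)
  expect_gt(mean(fwe$sig[region], na.rm = TRUE), 0.5)
  # determinism of the permutation route
  fwe2 <- one_sample_map(maps, mask, null_value = 0,
                         correction = "voxel_fwe", n_permutations = 200,
                         rng_seed = 2)
  expect_identical(fwe$p_adj, fwe2$p_adj)
})

test_that("interaction contrast matches the classical 2x2 repeated-measures ANOVA", {
  # 6-subject numeric fixture, balanced sequences, no covariates
  cells <- c("placebo_RS0", "placebo_RS1", "verum_RS0", "verum_RS1")
  vals <- matrix(c(10.0, 10.5, 10.2, 12.0,
                   9.0,  9.8,  9.1,  9.3,
                   11.0, 10.9, 11.5, 13.0,
                   10.2, 10.0, 10.1, 11.1,
                   9.5, 10.1,  9.4, 10.9,
                   10.8, 10.4, 11.0, 11.8),
                 nrow = 6, byrow = TRUE, dimnames = list(NULL, cells))
  subj <- sprintf("S%02d", 1:6)
  design <- do.call(rbind, lapply(1:6, function(i) {
    data.frame(subject = subj[i],
               sequence = ifelse(i %% 2 == 1, "drug-first", "placebo-first"),
               drug = rep(c("placebo", "verum"), each = 2),
               session = rep(c("RS0", "RS1"), 2),
               age = 40 + i)
  }))
  maps <- lapply(seq_len(nrow(design)), function(i) {
    array(vals[match(design$subject[i], subj),
               paste(design$drug[i], design$session[i], sep = "_")],
          c(2, 2, 2))
  })
  mask <- array(TRUE, c(2, 2, 2))
  ct <- interaction_contrast(design, maps, mask, covariates = FALSE)
  expect_equal(ct$df, 5)
  # independent oracle: repeated-measures ANOVA via stats::aov
  long <- data.frame(y = as.vector(t(vals)),
                     subject = rep(subj, each = 4),
                     drug = rep(rep(c("placebo", "verum"), each = 2), 6),
                     session = rep(c("RS0", "RS1"), 12))
  fit <- summary(aov(y ~ drug * session + Error(subject / (drug * session)),
                     data = long))
  f_int <- fit[["Error: subject:drug:session"]][[1]]["drug:session",
                                                     "F value"]
  expect_equal(ct$t[1, 1, 1]^2, f_int, tolerance = 1e-8)

  # with covariates the df drops to n - 3
  ct3 <- interaction_contrast(design, maps, mask, covariates = TRUE)
  expect_equal(ct3$df, 3)
})

test_that("main-effect contrasts use the cell-average definitions", {
  design <- null_design(4, seed = 44)
  grid <- c(3, 3, 3)
  mask <- array(TRUE, grid)
  # deterministic maps: value = f(drug, session)
  val <- function(drug, session) {
    2 * (drug == "verum") + 5 * (session == "RS1") +
      3 * (drug == "verum" && session == "RS1")
  }
  maps <- lapply(seq_len(nrow(design)), function(i)
    array(val(design$drug[i], design$session[i]), grid))
  d_int <- interaction_contrast(design, maps, mask, "interaction",
                                covariates = FALSE)
  d_time <- interaction_contrast(design, maps, mask, "time",
                                 covariates = FALSE)
  d_drug <- interaction_contrast(design, maps, mask, "drug",
                                 covariates = FALSE)
  expect_equal(unique(as.vector(d_int$delta)), 3)
  expect_equal(unique(as.vector(d_time$delta)), 5 + 3 / 2)
  expect_equal(unique(as.vector(d_drug$delta)), 2 + 3 / 2)
})

test_that("cluster labeling matches hand-countable components", {
  grid <- c(8, 8, 8)
  m <- array(FALSE, grid)
  # blob A: 7 voxels, an L-shape connected through faces/edges
  m[2:4, 2, 2] <- TRUE; m[4, 3, 2] <- TRUE; m[4, 4, 2] <- TRUE
  m[5, 5, 2] <- TRUE   # edge-diagonal from (4,4,2): 18-connected
  m[3, 2, 3] <- TRUE
  # blob B: 3 voxels, far corner
  m[7:8, 8, 8] <- TRUE; m[8, 7, 8] <- TRUE
  lc <- label_clusters(m, 18)
  expect_equal(sort(lc$sizes), c(3, 7))
  # corner-diagonal voxels are NOT 18-connected but are 26-connected
  m2 <- array(FALSE, c(4, 4, 4))
  m2[1, 1, 1] <- TRUE; m2[2, 2, 2] <- TRUE
  expect_equal(label_clusters(m2, 18)$sizes, c(1, 1))
  expect_equal(label_clusters(m2, 26)$sizes, 2)
  expect_equal(label_clusters(m2, 6)$sizes, c(1, 1))
})

test_that("cluster FWE: empty map, sign equivariance, determinism", {
  set.seed(45)
  n <- 12
  design <- null_design(n, seed = 45)
  grid <- c(8, 8, 8)
  mask <- array(TRUE, grid)
  region <- box_mask(grid, c(2, 2, 2), c(4, 4, 4))
  eff <- function(drug, session) {
    if (drug == "verum" && session == "RS1") -0.25 else 0
  }
  maps <- null_maps(design, grid, sd = 0.1, effect_fun = eff,
                    effect_mask = region)
  ct <- interaction_contrast(design, maps, mask)
  cf <- cluster_fwe(ct, height_p = 0.001, n_permutations = 200, rng_seed = 7)
  expect_gt(nrow(cf$clusters), 0)
  expect_true(all(cf$clusters$p_fwe >= 1 / 201 &
                    cf$clusters$p_fwe <= 1))
  top <- cf$clusters[1, ]
  expect_equal(top$sign, -1)
  expect_true(any(abs(cf$labels) == top$cluster & region))
  # negating all input maps negates T and preserves sizes and p values
  neg_maps <- lapply(maps, function(m) -m)
  ct_neg <- interaction_contrast(design, neg_maps, mask)
  expect_equal(ct_neg$t, -ct$t, tolerance = 1e-10)
  cf_neg <- cluster_fwe(ct_neg, height_p = 0.001, n_permutations = 200,
                        rng_seed = 7)
  expect_equal(cf_neg$clusters$k, cf$clusters$k)
  expect_equal(cf_neg$clusters$p_fwe, cf$clusters$p_fwe)
  expect_equal(cf_neg$clusters$sign, -cf$clusters$sign)
  # identical seed -> identical permutation distribution
  cf2 <- cluster_fwe(ct, height_p = 0.001, n_permutations = 200,
                     rng_seed = 7)
  expect_identical(cf2$null_max_k, cf$null_max_k)
  # all-zero T map -> empty cluster table
  zero_ct <- ct
  zero_ct$t[] <- 0
  zero_ct$delta[] <- 0
  cf0 <- cluster_fwe(zero_ct, height_p = 0.001, n_permutations = 100)
  expect_equal(nrow(cf0$clusters), 0)
})

test_that("peak coordinates are reported in mm through the affine", {
  set.seed(46)
  n <- 10
  design <- null_design(n, seed = 46)
  grid <- c(6, 6, 6)
  mask <- array(TRUE, grid)
  region <- box_mask(grid, c(3, 3, 3), c(4, 4, 4))
  maps <- null_maps(design, grid, sd = 0.05,
                    effect_fun = function(d, s)
                      if (d == "verum" && s == "RS1") 0.5 else 0,
                    effect_mask = region)
  ct <- interaction_contrast(design, maps, mask)
  aff <- diag(c(3, 3, 3, 1)); aff[1:3, 4] <- c(-9, -9, -9)
  cf <- cluster_fwe(ct, n_permutations = 100, affine = aff)
  top <- cf$clusters[1, ]
  # peak must fall inside the mm bounding box of the planted region
  mm_lo <- c(3 - 1, 3 - 1, 3 - 1) * 3 - 9
  mm_hi <- c(4 - 1, 4 - 1, 4 - 1) * 3 - 9
  expect_true(all(c(top$x, top$y, top$z) >= mm_lo - 1e-9) &&
                all(c(top$x, top$y, top$z) <= mm_hi + 1e-9))
})

test_that("post hoc paired tests: identities, degeneracy, specificity", {
  design <- null_design(8, seed = 47)
  grid <- c(3, 3, 3)
  mask <- array(TRUE, grid)
  # identical cell values -> t = 0, p = 1 everywhere
  maps_eq <- lapply(seq_len(nrow(design)), function(i) array(1.3, grid))
  r_eq <- posthoc_cluster_tests(design, maps_eq, mask)
  expect_true(all(r_eq$t == 0) && all(r_eq$p == 1))
  expect_true(all(r_eq$df == 7))
  # constant positive shift in verum RS1 -> infinite t, p = 0, no crash
  maps_c <- lapply(seq_len(nrow(design)), function(i) {
    array(1 + 0.5 * (design$drug[i] == "verum" &&
                       design$session[i] == "RS1"), grid)
  })
  r_c <- posthoc_cluster_tests(design, maps_c, mask)
  row <- r_c[r_c$contrast == "verum_vs_placebo_RS1", ]
  expect_true(is.infinite(row$t) && row$t > 0 && row$p == 0)
  # planted RS1 drug difference with subject noise: RS1 test significant,
  # RS0 test at chance level over replicates
  set.seed(48)
  hits_rs1 <- 0; hits_rs0 <- 0
  n_rep <- 50
  for (b in seq_len(n_rep)) {
    maps_p <- lapply(seq_len(nrow(design)), function(i) {
      eff <- 1 * (design$drug[i] == "verum" && design$session[i] == "RS1")
      array(rnorm(prod(grid), mean = eff, sd = 0.5), grid)
    })
    r <- posthoc_cluster_tests(design, maps_p, mask)
    hits_rs1 <- hits_rs1 +
      (r$p[r$contrast == "verum_vs_placebo_RS1"] < 0.05)
    hits_rs0 <- hits_rs0 +
      (r$p[r$contrast == "verum_vs_placebo_RS0"] < 0.05)
  }
  expect_gt(hits_rs1 / n_rep, 0.8)
  expect_lt(hits_rs0 / n_rep, 0.2)
  # nondegenerate case agrees with stats::t.test (independent route)
  set.seed(49)
  maps_r <- lapply(seq_len(nrow(design)), function(i)
    array(rnorm(prod(grid)), grid))
  r <- posthoc_cluster_tests(design, maps_r, mask)
  cm <- attr(r, "cell_means")
  tt <- t.test(cm[, "verum_RS1"], cm[, "placebo_RS1"], paired = TRUE)
  row <- r[r$contrast == "verum_vs_placebo_RS1", ]
  expect_equal(row$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(row$p, tt$p.value, tolerance = 1e-12)
})
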