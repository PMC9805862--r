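#' Synthetic crossover cohort generator
#'
#' Emulates a two-treatment, two-period crossover resting-state fMRI trial:
#' each subject is scanned immediately before dosing (RS0) and about one hour
#' post-dose (RS1) under both placebo and verum, in randomized sequence
#' order. Sessions carry planted hub communities (voxels sharing a latent
#' signal), a seed and a target region with a configurable baseline coupling
#' and a planted time-by-drug interaction on that coupling, white-matter/CSF
#' nuisance signals with a small leak into gray matter, motion-locked spike
#' artifacts, and white Gaussian noise. Latent signals are band-limited to
#' 0.01-0.1 Hz so they survive the analysis band-pass.
#'
#' @name simdata
NULL

#' Simulation configuration
#'
#' Defaults reproduce the trial's stated world: 355 volumes at TR 2 s on a
#' 3 mm grid, 35 subjects split 18 verum-first / 17 placebo-first, ages
#' uniform on 31-59 years. The 12x12x12 grid and the amplitude/noise levels
#' are generator-scale choices (see the methods vignette); regions are
#' axis-aligned boxes in voxel indices.
#'
#' @param grid_shape Voxels per axis (each >= 4).
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @param tr_s Repetition time, seconds.
#' @param n_volumes Volumes per session (before any discarding downstream).
#' @param n_subjects Cohort size.
#' @param hub_spec List of `list(lo=, hi=, amplitude=)` hub regions whose
#'   voxels share one latent signal at the given amplitude.
#' @param seed_region,target_region Boxes (`list(lo=, hi=)`) for the seed and
#'   the coupled target; both must lie inside gray matter.
#' @param seed_amp,target_amp Latent-signal amplitudes in the two regions.
#' @param coupling_r Baseline seed-target latent correlation, in (-1, 1).
#' @param interaction_delta Added to `coupling_r` in the verum RS1 cell only,
#'   so that (verum RS1 - verum RS0) - (placebo RS1 - placebo RS0) equals
#'   `interaction_delta` on the latent coupling.
#' @param wm_amp,csf_amp Amplitudes of the tissue-wide nuisance signals.
#' @param leak Fraction of the tissue nuisance signals added to every
#'   gray-matter voxel (what CompCor is there to remove).
#' @param spike_rate Expected fraction of volumes carrying a motion spike.
#' @param spike_mm Translation excursion written to the motion trace at spike
#'   volumes (use > 3 to trigger subject exclusion).
#' @param spike_intensity BOLD intensity offset added at spike volumes.
#' @param noise_sd White-noise standard deviation.
#' @param rng_seed Integer seed; identical config + seed gives a
#'   bit-identical cohort.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(grid_shape = c(12L, 12L, 12L),
                       voxel_size_mm = 3,
                       tr_s = 2,
                       n_volumes = 355L,
                       n_subjects = 35L,
                       hub_spec = list(list(lo = c(2, 2, 2), hi = c(4, 4, 4),
                                            amplitude = 1)),
                       seed_region = list(lo = c(6, 2, 2), hi = c(7, 3, 3)),
                       target_region = list(lo = c(2, 6, 6), hi = c(4, 8, 8)),
                       seed_amp = 1,
                       target_amp = 1,
                       coupling_r = -0.3,
                       interaction_delta = -0.2,
                       wm_amp = 1,
                       csf_amp = 1,
                       leak = 0.15,
                       spike_rate = 0.02,
                       spike_mm = 1.5,
                       spike_intensity = 5,
                       noise_sd = 1,
                       rng_seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size_mm = voxel_size_mm, tr_s = tr_s,
              n_volumes = as.integer(n_volumes),
              n_subjects = as.integer(n_subjects),
              hub_spec = hub_spec, seed_region = seed_region,
              target_region = target_region,
              seed_amp = seed_amp, target_amp = target_amp,
              coupling_r = coupling_r, interaction_delta = interaction_delta,
              wm_amp = wm_amp, csf_amp = csf_amp, leak = leak,
              spike_rate = spike_rate, spike_mm = spike_mm,
              spike_intensity = spike_intensity, noise_sd = noise_sd,
              rng_seed = as.integer(rng_seed))
  stopifnot(length(cfg$grid_shape) == 3, all(cfg$grid_shape >= 4),
            cfg$voxel_size_mm > 0, cfg$tr_s > 0, cfg$n_volumes >= 1,
            cfg$n_subjects >= 0, abs(cfg$coupling_r) < 1,
            is.finite(cfg$interaction_delta), cfg$noise_sd >= 0,
            cfg$spike_rate >= 0, cfg$spike_rate <= 1)
  amps <- c(vapply(cfg$hub_spec, function(h) h$amplitude, 0),
            cfg$seed_amp, cfg$target_amp, cfg$wm_amp, cfg$csf_amp)
  stopifnot(all(is.finite(amps)))
  r_max <- abs(cfg$coupling_r) + abs(cfg$interaction_delta)
  if (r_max >= 1) stop("|coupling_r| + |interaction_delta| must stay below 1")
  structure(cfg, class = "sim_config")
}

#' Tissue masks for a simulated grid
#'
#' Partitions the grid along x: the last two x-slabs are white matter, the
#' slab before them CSF, everything up to that gray matter. Seed and target
#' boxes must fall inside gray matter.
#'
#' @param config A [sim_config()].
#' @return List of logical arrays `gm`, `wm`, `csf`, `seed`, `target`, plus
#'   `hubs` (list, one mask per hub), all sharing the grid.
#' @export
sim_masks <- function(config) {
  g <- config$grid_shape
  if (g[1] < 6) stop("grid x-extent must be >= 6 to hold GM/CSF/WM slabs")
  gm <- box_mask(g, c(1, 1, 1), c(g[1] - 3, g[2], g[3]))
  csf <- box_mask(g, c(g[1] - 2, 1, 1), c(g[1] - 2, g[2], g[3]))
  wm <- box_mask(g, c(g[1] - 1, 1, 1), c(g[1], g[2], g[3]))
  seed <- box_mask(g, config$seed_region$lo, config$seed_region$hi)
  target <- box_mask(g, config$target_region$lo, config$target_region$hi)
  hubs <- lapply(config$hub_spec, function(h) box_mask(g, h$lo, h$hi))
  for (m in c(list(seed, target), hubs)) {
    if (any(m & !gm)) stop("seed/target/hub regions must lie inside gray matter")
  }
  list(gm = gm, wm = wm, csf = csf, seed = seed, target = target, hubs = hubs)
}

# band-limited unit-variance latent signal: white noise -> FFT band mask
.band_limited_signal <- function(n, tr_s, f_lo = 0.01, f_hi = 0.1) {
  x <- stats::rnorm(n)
  xf <- stats::fft(x)
  f <- seq(0, n - 1) / (n * tr_s)
  f <- pmin(f, 1 / tr_s - f)  # two-sided frequency axis
  keep <- f >= f_lo & f <= f_hi
  xf[!keep] <- 0
  y <- Re(stats::fft(xf, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) stop("band too narrow for ", n, " samples at TR ", tr_s)
  (y - mean(y)) / s
}

#' Generate one synthetic session
#'
#' @param config A [sim_config()].
#' @param subject_id Subject label (informational).
#' @param drug `"placebo"` or `"verum"`.
#' @param session `"RS0"` or `"RS1"`.
#' @param rng_state Optional integer seed; if `NULL` the current RNG stream
#'   is used (as [generate_cohort()] does after seeding once).
#' @return List with `bold` ([bold_series()]), `motion` (n_volumes x 6
#'   matrix: mm translations, rad rotations), and `truth` (expected latent
#'   seed-target correlation for this cell, 1-based spike volume indices).
#' @export
generate_session <- function(config, subject_id = "S01",
                             drug = c("placebo", "verum"),
                             session = c("RS0", "RS1"),
                             rng_state = NULL) {
  drug <- match.arg(drug)
  session <- match.arg(session)
  if (!is.null(rng_state)) set.seed(as.integer(rng_state))
  masks <- sim_masks(config)
  g <- config$grid_shape
  n_t <- config$n_volumes
  n_vox <- prod(g)

  rho <- config$coupling_r +
    if (drug == "verum" && session == "RS1") config$interaction_delta else 0

  u <- .band_limited_signal(n_t, config$tr_s)           # seed latent
  w <- .band_limited_signal(n_t, config$tr_s)
  v <- rho * u + sqrt(1 - rho^2) * w                     # target latent
  n_wm <- .band_limited_signal(n_t, config$tr_s)
  n_csf <- .band_limited_signal(n_t, config$tr_s)
  hub_sig <- lapply(masks$hubs, function(m) .band_limited_signal(n_t, config$tr_s))

  flat <- matrix(0, n_vox, n_t)
  add_signal <- function(mask, sig) {
    idx <- which(mask)
    flat[idx, ] <<- flat[idx, , drop = FALSE] +
      matrix(sig, length(idx), n_t, byrow = TRUE)
  }
  for (i in seq_along(masks$hubs)) {
    add_signal(masks$hubs[[i]], config$hub_spec[[i]]$amplitude * hub_sig[[i]])
  }
  add_signal(masks$seed, config$seed_amp * u)
  add_signal(masks$target, config$target_amp * v)
  add_signal(masks$wm, config$wm_amp * n_wm)
  add_signal(masks$csf, config$csf_amp * n_csf)
  add_signal(masks$gm, config$leak * (config$wm_amp * n_wm +
                                      config$csf_amp * n_csf))
  if (config$noise_sd > 0) {
    flat <- flat + matrix(stats::rnorm(n_vox * n_t, sd = config$noise_sd),
                          n_vox, n_t)
  }

  # slow realistic drift in the motion trace plus spike excursions
  motion <- matrix(0, n_t, 6)
  tt <- seq_len(n_t) / n_t
  for (j in 1:3) motion[, j] <- 0.05 * stats::rnorm(1) * tt +
    cumsum(stats::rnorm(n_t, sd = 0.002))
  for (j in 4:6) motion[, j] <- cumsum(stats::rnorm(n_t, sd = 0.0002))

  # spikes are isolated single-volume events starting at volume 2: a
  # first-volume excursion has no framewise signature, and the interior of a
  # sustained multi-volume excursion would not be flaggable either
  n_spikes <- min(stats::rbinom(1, n_t, config$spike_rate), n_t - 1L)
  cand <- sort(sample(2:n_t, n_spikes))
  spike_vols <- integer(0)
  for (sv in cand) {
    if (!length(spike_vols) || sv > spike_vols[length(spike_vols)] + 1L) {
      spike_vols <- c(spike_vols, sv)
    }
  }
  if (n_spikes > 0) {
    motion[spike_vols, 1] <- motion[spike_vols, 1] + config$spike_mm
    flat[, spike_vols] <- flat[, spike_vols] + config$spike_intensity
  }

  flat <- flat + 100  # baseline intensity
  affine <- diag(c(rep(config$voxel_size_mm, 3), 1))
  bold <- bold_series(array(flat, dim = c(g, n_t)), affine = affine,
                      tr_s = config$tr_s)
  truth <- list(expected_r = rho, spike_volumes = spike_vols,
                drug = drug, session = session, subject = subject_id)
  list(bold = bold, motion = motion, truth = truth)
}

#' Generate and write a full crossover cohort
#'
#' Writes, per subject, four sessions (placebo/verum x RS0/RS1) as NIfTI-1
#' `.nii.gz` plus SPM-dialect motion text files, one shared mask set, and a
#' design table CSV with columns
#' `subject,sequence,drug,session,age,bold_path,motion_path`. Subjects are
#' split between the verum-first and placebo-first sequences as evenly as
#' possible (the extra subject goes verum-first); ages are drawn uniformly
#' from the integers 31-59.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if missing).
#' @param write If `FALSE`, no files are written and sessions are returned
#'   in memory (paths in the design table are empty).
#' @return List with `design` (data.frame), `masks`, `truth` (per-cell
#'   expected couplings, per-session spike volumes, ages, sequences, and the
#'   hub voxel index set), `dir`, and, when `write = FALSE`, `sessions`
#'   (named list of [generate_session()] results).
#' @export
generate_cohort <- function(config, dir = tempfile("cohort"), write = TRUE) {
  set.seed(config$rng_seed)
  masks <- sim_masks(config)
  n <- config$n_subjects
  subjects <- sprintf("S%02d", seq_len(n))
  # alternate assignment: odd-index subjects verum-first => ceil(n/2) of them
  sequence <- ifelse(seq_len(n) %% 2 == 1, "drug-first", "placebo-first")
  ages <- if (n > 0) sample(31:59, n, replace = TRUE) else integer(0)

  if (write) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    aff <- diag(c(rep(config$voxel_size_mm, 3), 1))
    for (nm in c("gm", "wm", "csf", "seed", "target")) {
      write_nifti(masks[[nm]], file.path(dir, paste0("mask_", nm, ".nii.gz")),
                  affine = aff, datatype = "uint8")
    }
  }

  rows <- list()
  spike_truth <- list()
  expected_r <- list()
  sessions <- list()
  for (i in seq_len(n)) {
    for (drug in c("placebo", "verum")) {
      for (sess in c("RS0", "RS1")) {
        s <- generate_session(config, subjects[i], drug, sess)
        key <- paste(subjects[i], drug, sess, sep = "_")
        spike_truth[[key]] <- s$truth$spike_volumes
        expected_r[[paste(drug, sess, sep = "_")]] <- s$truth$expected_r
        bold_path <- motion_path <- ""
        if (write) {
          bold_path <- file.path(dir, paste0(key, "_bold.nii.gz"))
          motion_path <- file.path(dir, paste0("rp_", key, ".txt"))
          write_nifti(s$bold$data, bold_path, affine = s$bold$affine,
                      tr_s = config$tr_s, datatype = "float32")
          write_motion(s$motion, motion_path)
        } else {
          sessions[[key]] <- s
        }
        rows[[length(rows) + 1]] <- data.frame(
          subject = subjects[i], sequence = sequence[i], drug = drug,
          session = sess, age = ages[i], bold_path = bold_path,
          motion_path = motion_path, stringsAsFactors = FALSE)
      }
    }
  }
  design <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject = character(), sequence = character(),
               drug = character(), session = character(), age = numeric(),
               bold_path = character(), motion_path = character(),
               stringsAsFactors = FALSE)
  if (write) utils::write.csv(design, file.path(dir, "design.csv"),
                              row.names = FALSE)
  truth <- list(hub_voxels = which(Reduce(`|`, masks$hubs)),
                expected_r = expected_r, spike_volumes = spike_truth,
                ages = stats::setNames(ages, subjects),
                sequence = stats::setNames(sequence, subjects))
  out <- list(design = design, masks = masks, truth = truth, dir = dir)
  if (!write) out$sessions <- sessions
  out
}
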