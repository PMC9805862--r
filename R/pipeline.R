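#' File formats and pipeline orchestration
#'
#' Motion traces use the SPM `rp_*.txt` dialect (whitespace-delimited, one
#' row per volume, six columns: three translations in mm, three rotations in
#' rad). Design tables are CSV. Every derived output gets a JSON provenance
#' sidecar with the parameters that produced it.
#'
#' @name cli-io
NULL

#' Write a motion trace
#'
#' @param motion T x 6 numeric matrix.
#' @param path Output text file.
#' @return `path`, invisibly.
#' @export
write_motion <- function(motion, path) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion trace must have 6 columns")
  utils::write.table(format(motion, scientific = TRUE, digits = 8), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a motion trace
#'
#' @param path SPM-dialect motion text file.
#' @return T x 6 numeric matrix; parse errors report the line number.
#' @export
read_motion <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]),
                                                 "[[:space:]]+")[[1]]))
    if (length(vals) != 6 || anyNA(vals)) {
      stop("motion file ", path, ", line ", i,
           ": expected 6 numeric columns, got '", lines[i], "'")
    }
    vals
  })
  do.call(rbind, rows)
}

#' Read and validate a cohort design table
#'
#' @param path CSV with header
#'   `subject,sequence,drug,session,age,bold_path,motion_path`.
#' @param base_dir Optional directory against which relative paths resolve.
#' @return Validated design data frame.
#' @export
read_design <- function(path, base_dir = dirname(path)) {
  design <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_design(design)
  for (col in c("bold_path", "motion_path")) {
    if (col %in% names(design)) {
      rel <- nzchar(design[[col]]) & !file.exists(design[[col]])
      design[[col]][rel] <- file.path(base_dir, basename(design[[col]][rel]))
    }
  }
  design
}

#' Pipeline configuration
#'
#' Defaults reproduce the published analysis settings: discard 5 volumes,
#' 5 CompCor components, 0.01-0.1 Hz band, scrub at composite motion 0.9 mm
#' / global-signal z 5, exclude above 30% flagged volumes or 3 mm motion,
#' gFCD threshold 0.6, 8 mm FWHM smoothing of derived maps, cluster height
#' p < 0.001 with cluster-level FWE alpha 0.05.
#'
#' @param cohort_dir Directory with the cohort files (design.csv, masks).
#' @param out_dir Output directory.
#' @param n_discard,compcor_k,band,scrub_motion_mm,scrub_global_z
#'   Preprocessing parameters.
#' @param max_bad_fraction,max_translation_mm Exclusion thresholds.
#' @param gfcd_threshold Edge threshold for gFCD.
#' @param fwhm_mm Smoothing kernel FWHM for derived maps.
#' @param height_p,cluster_alpha,n_permutations,rng_seed Group-level
#'   inference parameters.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort_dir, out_dir = file.path(cohort_dir, "out"),
                            n_discard = 5L, compcor_k = 5L,
                            band = c(0.01, 0.1), scrub_motion_mm = 0.9,
                            scrub_global_z = 5, max_bad_fraction = 0.30,
                            max_translation_mm = 3, gfcd_threshold = 0.6,
                            fwhm_mm = 8, height_p = 0.001,
                            cluster_alpha = 0.05, n_permutations = 1000L,
                            rng_seed = 1L) {
  structure(list(cohort_dir = cohort_dir, out_dir = out_dir,
                 n_discard = as.integer(n_discard),
                 compcor_k = as.integer(compcor_k), band = band,
                 scrub_motion_mm = scrub_motion_mm,
                 scrub_global_z = scrub_global_z,
                 max_bad_fraction = max_bad_fraction,
                 max_translation_mm = max_translation_mm,
                 gfcd_threshold = gfcd_threshold, fwhm_mm = fwhm_mm,
                 height_p = height_p, cluster_alpha = cluster_alpha,
                 n_permutations = as.integer(n_permutations),
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

.write_sidecar <- function(path, params) {
  jsonlite::write_json(params, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

.check_grid <- function(ref_dims, ref_path, img, img_path) {
  if (!all(dim(img$data)[1:3] == ref_dims)) {
    stop("grid mismatch: ", img_path, " has grid ",
         paste(dim(img$data)[1:3], collapse = "x"), " but ", ref_path,
         " has ", paste(ref_dims, collapse = "x"))
  }
}

#' Run the full pipeline on a cohort directory
#'
#' Per session: QC -> nuisance cleaning -> gFCD and seed-FC maps -> 8 mm
#' smoothing. Group level (excluded subjects dropped whole): one-sample hub
#' map (gFCD > 1, FDR), one-sample zFC map (!= 0, FDR), the time-by-drug
#' interaction with covariates, permutation cluster FWE, and post hoc paired
#' tests on the most significant cluster. Writes NIfTI maps, TSV tables, a
#' QC report and a checksummed manifest; every output has a JSON provenance
#' sidecar.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return List with `qc` (data.frame), `excluded_subjects`, `design_used`,
#'   `gfcd_onesample`, `zfc_onesample`, `interaction`, `clusters`, `posthoc`
#'   (NULL when no significant cluster), and `manifest` (data.frame).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[crossfc] ", ...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  sess_dir <- file.path(config$out_dir, "sessions")
  grp_dir <- file.path(config$out_dir, "group")
  dir.create(sess_dir, showWarnings = FALSE)
  dir.create(grp_dir, showWarnings = FALSE)

  design <- read_design(file.path(config$cohort_dir, "design.csv"))
  masks <- list()
  mask_paths <- file.path(config$cohort_dir,
                          paste0("mask_", c("gm", "wm", "csf", "seed"),
                                 ".nii.gz"))
  names(mask_paths) <- c("gm", "wm", "csf", "seed")
  first <- read_nifti(mask_paths[["gm"]])
  ref_dims <- dim(first$data)
  affine <- first$affine
  for (nm in names(mask_paths)) {
    img <- read_nifti(mask_paths[[nm]])
    .check_grid(ref_dims, mask_paths[["gm"]], img, mask_paths[[nm]])
    masks[[nm]] <- img$data > 0
  }
  voxel_mm <- sqrt(sum(affine[1:3, 1]^2))

  qc_rows <- list()
  gfcd_maps <- list()
  zfc_maps <- list()
  say(nrow(design), " sessions, ", length(unique(design$subject)),
      " subjects")
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    key <- paste(row$subject, row$drug, row$session, sep = "_")
    img <- read_nifti(row$bold_path)
    .check_grid(ref_dims, mask_paths[["gm"]], img, row$bold_path)
    bold <- bold_series(img$data, affine = img$affine,
                        tr_s = if (is.na(img$tr_s) || img$tr_s <= 0) 2
                               else img$tr_s)
    motion <- read_motion(row$motion_path)
    pre <- preprocess_session(bold, motion, masks,
                              n_discard = config$n_discard,
                              compcor_k = config$compcor_k,
                              band = config$band,
                              scrub_motion_mm = config$scrub_motion_mm,
                              scrub_global_z = config$scrub_global_z,
                              max_bad_fraction = config$max_bad_fraction,
                              max_translation_mm = config$max_translation_mm)
    qc_rows[[key]] <- data.frame(
      subject = row$subject, drug = row$drug, session = row$session,
      bad_fraction = pre$qc$bad_volume_fraction,
      max_translation_mm = pre$qc$max_abs_translation_mm,
      excluded = pre$qc$excluded, reason = pre$qc$reason)
    if (pre$qc$excluded) {
      say(key, " excluded: ", pre$qc$reason)
      next
    }
    g <- compute_gfcd(pre$cleaned, masks$gm,
                      gfcd_params(config$gfcd_threshold))
    g <- smooth_gfcd_map(g, config$fwhm_mm, voxel_mm)
    z <- seed_fc_map(pre$cleaned, masks$seed, masks$gm)
    z <- smooth_fc_map(z, config$fwhm_mm, voxel_mm)
    gfcd_maps[[key]] <- g
    zfc_maps[[key]] <- z
    gp <- file.path(sess_dir, paste0(key, "_gfcd.nii.gz"))
    zp <- file.path(sess_dir, paste0(key, "_zfc.nii.gz"))
    write_nifti(g$K_norm, gp, affine = affine, datatype = "float32")
    write_nifti(z$z, zp, affine = affine, datatype = "float32")
    prov <- list(stage = "session", key = key,
                 params = unclass(config)[c("n_discard", "compcor_k", "band",
                                            "scrub_motion_mm",
                                            "scrub_global_z",
                                            "gfcd_threshold", "fwhm_mm")],
                 n_bad = length(pre$bad))
    .write_sidecar(gp, prov)
    .write_sidecar(zp, prov)
  }

  qc <- do.call(rbind, qc_rows)
  qc_path <- file.path(config$out_dir, "qc_report.tsv")
  utils::write.table(qc, qc_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  excluded_subjects <- unique(qc$subject[qc$excluded])
  design_used <- design[!design$subject %in% excluded_subjects, ]
  say(length(excluded_subjects), " subject(s) excluded")

  result <- list(qc = qc, excluded_subjects = excluded_subjects,
                 design_used = design_used, gfcd_onesample = NULL,
                 zfc_onesample = NULL, interaction = NULL, clusters = NULL,
                 posthoc = NULL)
  n_sub <- length(unique(design_used$subject))
  if (n_sub >= 4) {
    keys <- paste(design_used$subject, design_used$drug, design_used$session,
                  sep = "_")
    g_list <- gfcd_maps[keys]
    z_list <- zfc_maps[keys]
    say("group stage on ", n_sub, " subjects")
    result$gfcd_onesample <- one_sample_map(g_list, masks$gm, null_value = 1,
                                            correction = "fdr")
    result$zfc_onesample <- one_sample_map(z_list, masks$gm, null_value = 0,
                                           correction = "fdr")
    contrast <- interaction_contrast(design_used, z_list, masks$gm)
    cf <- cluster_fwe(contrast, height_p = config$height_p,
                      n_permutations = config$n_permutations,
                      rng_seed = config$rng_seed, affine = affine)
    result$interaction <- contrast
    result$clusters <- cf
    tp <- file.path(grp_dir, "interaction_t.nii.gz")
    tmap <- contrast$t
    tmap[is.na(tmap)] <- 0
    write_nifti(tmap, tp, affine = affine, datatype = "float32")
    .write_sidecar(tp, list(stage = "group",
                            params = unclass(config)[c("height_p",
                                                       "cluster_alpha",
                                                       "n_permutations",
                                                       "rng_seed")]))
    utils::write.table(cf$clusters, file.path(grp_dir, "clusters.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    sig <- cf$clusters[cf$clusters$p_fwe <= config$cluster_alpha, ]
    if (nrow(sig) > 0) {
      cl_mask <- abs(cf$labels) == sig$cluster[1]
      result$posthoc <- posthoc_cluster_tests(design_used, z_list, cl_mask)
      utils::write.table(result$posthoc,
                         file.path(grp_dir, "posthoc.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
  } else {
    say("fewer than 4 subjects after exclusion; group stage skipped")
  }

  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(config$out_dir, "manifest.tsv"))
  manifest <- data.frame(file = sub(paste0("^", config$out_dir, "/?"), "",
                                    files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.table(manifest, file.path(config$out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  result$manifest <- manifest
  result
}
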