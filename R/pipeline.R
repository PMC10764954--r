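#' End-to-end experiment configuration
#'
#' Bundles everything an experiment needs: the phantom, the acquisition
#' geometry, the AFN training configuration, the reconstruction parameters
#' and a master seed from which all stage seeds are derived deterministically
#' (named substream per stage).
#'
#' @param phantom a [phantom_spec()].
#' @param geom a [cone_beam_geometry()].
#' @param afn an [afn_config()].
#' @param recon a [recon_params()].
#' @param samples_per_ray forward-projector sampling.
#' @param master_seed integer master seed.
#' @param outdir optional output directory; when set, stages persist their
#'   artifacts there and a manifest with md5 hashes is written.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(phantom, geom, afn, recon,
                              samples_per_ray = 256, master_seed = 1,
                              outdir = NULL) {
  phantom$seed <- derive_seed(master_seed, "phantom")
  afn$seed <- derive_seed(master_seed, "afn")
  structure(list(phantom = phantom, geom = geom, afn = afn, recon = recon,
                 samples_per_ray = samples_per_ray,
                 master_seed = master_seed, outdir = outdir),
            class = "experiment_config")
}

#' Desk-scale experiment preset
#'
#' The clinical geometry scaled for a single CPU: the detector keeps its
#' physical panel size (so every fan/cone angle, and therefore every
#' redundancy weight, is unchanged) but is binned to 128 x 96 pixels; 60
#' views over 360 degrees; a 96 x 96 x 48 voxel phantom/reconstruction grid
#' at 2 mm pitch; and an AFN sized to the scene (hash table `2^15`, 8 levels
#' up to 128 cells per axis - about the reconstruction voxel pitch - 64
#' samples per ray, batches of 1024 rays).
#'
#' The phantom emulates a large breast (17 cm chest-wall diameter, within
#' the clinical 11.8-18.3 cm range) so that the emulated one-quarter
#' detector truncation genuinely cuts into the breast shadow - the regime
#' the offset-detector geometry is designed for; a smaller object whose
#' shadow stays inside the retained columns would make the truncation
#' vacuous.
#'
#' @param master_seed master seed for all stages.
#' @param epochs AFN training epochs.
#' @param n_views number of views.
#' @return An [experiment_config()].
#' @export
desk_experiment <- function(master_seed = 1, epochs = 30, n_views = 60) {
  geom <- geom_kbct1000(scale = 8, n_views = n_views)
  spec <- phantom_spec(semi_axes = c(85, 85, 70), pitch = 2,
                       dims = c(96, 96, 48), n_glandular_blobs = 12,
                       blob_mm = c(6, 18))
  recon <- recon_params(pitch = 2, dims = c(96, 96, 48),
                        origin = c(-95, -95, -95))
  # finest encoder level sized to the reconstruction pitch: the unit cube
  # spans the 281 mm FOV, so 128 cells give ~2.2 mm, matching 2 mm voxels
  afn <- afn_config(levels = 8, features = 2, log2_table = 16,
                    base_res = 4, finest_res = 128, k = 64,
                    rays_per_batch = 1024, epochs = epochs)
  experiment_config(spec, geom, afn, recon, master_seed = master_seed)
}

# Interior evaluation mask: inside the inner (sub-skin) ellipsoid eroded by
# `erode_mm`, away from the chest-wall plane. Used for interior RMSE.
.interior_mask <- function(annotation, erode_mm = 8) {
  spec <- annotation$spec
  d <- spec$dims; p <- spec$pitch
  origin <- c(-(d[1] - 1) / 2 * p, -(d[2] - 1) / 2 * p, -(d[3] - 0.5) * p)
  xs <- origin[1] + (seq_len(d[1]) - 1) * p
  ys <- origin[2] + (seq_len(d[2]) - 1) * p
  zs <- origin[3] + (seq_len(d[3]) - 1) * p
  inn <- pmax(spec$semi_axes - spec$skin_mm - erode_mm, 1)
  q <- outer(outer((xs / inn[1])^2, (ys / inn[2])^2, "+"), (zs / inn[3])^2, "+")
  q <= 1 & rep(zs <= -erode_mm, each = d[1] * d[2])
}

#' Reference reconstruction from complete data
#'
#' Generates the phantom, forward-projects the full scan with the full
#' detector, and reconstructs with unweighted FDK. This complete-data FDK is
#' the reference all incomplete-data methods are compared to.
#'
#' @param cfg an [experiment_config()].
#' @return list: `phantom` (volume + annotation), `projections`
#'   (complete [projection_set()]), `reference` ([ct_volume()]), `interior`
#'   (logical evaluation mask), `rmse_vs_truth` (interior RMSE of the
#'   reference against the voxelized phantom).
#' @export
run_reference <- function(cfg) {
  ph <- generate_phantom(cfg$phantom)
  proj <- forward_project(ph$volume, cfg$geom, cfg$samples_per_ray)
  ref <- fdk_reconstruct(proj, NULL, cfg$recon)
  interior <- .interior_mask(ph$annotation)
  out <- list(phantom = ph, projections = proj, reference = ref,
              interior = interior,
              rmse_vs_truth = rmse(ref$values, ph$volume$values, interior))
  if (!is.null(cfg$outdir)) .persist_reference(cfg, out)
  out
}

#' AFN inpainting pipeline on emulated incomplete data
#'
#' Emulates the short-scan + offset-detector acquisition, trains an
#' attenuation field network on the incomplete data, synthesizes the full
#' sinogram, splices it with the acquired pixels, and reconstructs with FDK
#' using the offset-detector weight applied post-convolution (FDK-M).
#' If the emulation removes nothing (360 degrees, no truncation) the splice
#' is the identity and training is skipped.
#'
#' @param cfg an [experiment_config()].
#' @param arc_deg short-scan coverage, degrees.
#' @param n_trunc_cols truncated columns per view.
#' @param ref optional precomputed [run_reference()] result (reused).
#' @return list: `volume` (FDK-M of the spliced data), `field`, `spliced`,
#'   `emulated`, `metrics` (list with per-volume [metrics_report()]s and
#'   paired interior RMSEs), `ref`.
#' @export
run_afn_pipeline <- function(cfg, arc_deg = 270, n_trunc_cols = 32,
                             ref = NULL) {
  if (is.null(ref)) ref <- run_reference(cfg)
  emul <- emulate_short_scan_offset(ref$projections, arc_deg,
                                    n_trunc_cols = n_trunc_cols)
  ph <- ref$phantom
  fov_radius <- cfg$geom$d_so * sin(gamma_max(cfg$geom))
  d <- dim(ph$volume$values)
  fov_z <- c(ph$volume$origin[3] - ph$volume$pitch, 1)

  field <- NULL
  if (all(emul$mask)) {
    spliced <- emul
  } else {
    field <- train_afn(emul, cfg$afn, fov_radius = fov_radius, fov_z = fov_z)
    synth <- synthesize_projections(field, cfg$geom, subset = !emul$mask)
    spliced <- splice(emul, synth)
  }
  wm <- offset_weight_map(cfg$geom, n_trunc_cols = n_trunc_cols)
  rp <- cfg$recon; rp$stage <- "post"
  vol <- fdk_reconstruct(spliced, wm, rp)

  interior <- ref$interior
  metrics <- list(
    afn = metrics_report(vol, ph$annotation),
    reference = metrics_report(ref$reference, ph$annotation),
    rmse_vs_reference = rmse(vol$values, ref$reference$values, interior),
    rmse_vs_truth = rmse(vol$values, ph$volume$values, interior),
    reference_rmse_vs_truth = ref$rmse_vs_truth)
  list(volume = vol, field = field, spliced = spliced, emulated = emul,
       metrics = metrics, ref = ref)
}

#' Classical weighted-FDK baselines on the same incomplete data
#'
#' Zero-fills the emulated incomplete data and reconstructs with FDK using
#' (i) the modified Parker weight, (ii) the offset-detector weight, and
#' (iii) both weights multiplied, each applied pre-convolution. These are
#' the classical failure modes: each weight can compensate only one of the
#' two incompleteness dimensions, and their product corrupts both.
#'
#' @inheritParams run_afn_pipeline
#' @return named list of [ct_volume()]s: `parker`, `offset`, `both`.
#' @export
run_baselines <- function(cfg, arc_deg = 270, n_trunc_cols = 32, ref = NULL) {
  if (is.null(ref)) ref <- run_reference(cfg)
  emul <- emulate_short_scan_offset(ref$projections, arc_deg,
                                    n_trunc_cols = n_trunc_cols)
  rp <- cfg$recon; rp$stage <- "pre"
  wp <- parker_weight_map(cfg$geom, arc_deg)
  wo <- offset_weight_map(cfg$geom, n_trunc_cols = n_trunc_cols)
  wb <- combined_weight_map(wp, wo)
  list(parker = fdk_reconstruct(emul, wp, rp),
       offset = fdk_reconstruct(emul, wo, rp),
       both = fdk_reconstruct(emul, wb, rp))
}

#' Data-sufficiency sweep over arc / offset combinations
#'
#' For each (angular coverage, truncation fraction) cell, reports the
#' analytic sampling rate `(arc/360) * (1 - truncation fraction)` and the
#' empirical rate of the emulated mask; with `train = TRUE` additionally runs
#' the full AFN pipeline per cell and reports interior RMSE vs the
#' complete-data reference.
#'
#' @param cfg an [experiment_config()].
#' @param arcs_deg angular coverages, degrees.
#' @param trunc_fracs detector truncation fractions (2*offset/width).
#' @param train run AFN per cell (slow) or rates only.
#' @param ref optional precomputed reference.
#' @return data frame with one row per combination.
#' @export
run_sufficiency_sweep <- function(cfg, arcs_deg = c(204, 220, 270),
                                  trunc_fracs = c(0.375, 0.25, 0.125),
                                  train = FALSE, ref = NULL) {
  if (is.null(ref)) ref <- run_reference(cfg)
  n_u <- cfg$geom$n_u
  grid <- expand.grid(arc_deg = arcs_deg, trunc_frac = trunc_fracs)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    arc <- grid$arc_deg[i]; fr <- grid$trunc_frac[i]
    ntr <- round(fr * n_u)
    emul <- emulate_short_scan_offset(ref$projections, arc,
                                      n_trunc_cols = ntr)
    row <- data.frame(arc_deg = arc, trunc_frac = fr, n_trunc_cols = ntr,
                      rate_analytic = analytic_sampling_rate(arc, fr / 2, 1),
                      rate_empirical = undersampling_rate(emul),
                      rmse_vs_reference = NA_real_)
    if (train) {
      res <- run_afn_pipeline(cfg, arc, ntr, ref = ref)
      row$rmse_vs_reference <- res$metrics$rmse_vs_reference
    }
    row
  })
  do.call(rbind, rows)
}

# Persist reference artifacts + manifest when an output directory is set.
.persist_reference <- function(cfg, out) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  write_volume(out$phantom$volume, file.path(cfg$outdir, "phantom.nii.gz"))
  write_volume(out$reference, file.path(cfg$outdir, "reference.nii.gz"))
  write_projections(out$projections, file.path(cfg$outdir, "projections"))
  write_geometry(cfg$geom, file.path(cfg$outdir, "geometry.json"))
  files <- list.files(cfg$outdir, full.names = TRUE)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(NULL)
}
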