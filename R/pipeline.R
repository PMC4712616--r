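#' Run the full measurement pipeline on a phantom bundle
#'
#' Executes every automated stage on one synthetic patient: lesion ROI
#' growing from supplied seeds, NAWM-referenced four-class lesion
#' classification, per-class/per-lesion mask emission, ADC map generation,
#' DSC perfusion quantification (arrival detection, concentration
#' conversion, automatic AIF selection, truncated-SVD deconvolution),
#' normal-appearing tissue masks, per-region statistics and the CSV
#' report, with a provenance record per step. On phantom bundles all
#' modalities share the FLAIR grid, so inter-modality registration reduces
#' to the identity transform; [estimate_rigid()] is exercised separately.
#'
#' The lesion stage is the pipeline's semi-automatic checkpoint: seeds
#' default to the phantom's true lesion centers (standing in for operator
#' clicks), and a pre-classified `roi_file` — e.g. one revised by hand
#' after a first run — can be supplied to resume after manual review.
#'
#' @param bundle a `phantom_bundle` from [generate_phantom()].
#' @param out_dir output directory for masks, maps, CSV, provenance; NULL
#'   computes in memory only.
#' @param mf classification multiplier factor.
#' @param local_factor region-growing threshold fraction.
#' @param arrival_fraction arrival-detection range fraction.
#' @param svd_threshold SVD truncation fraction.
#' @param n_aif_voxels AIF candidates averaged.
#' @param vscale volumetric scaling factor for normalized volumes.
#' @param patient_id id stamped on every CSV row.
#' @param roi_file optional path of a (possibly hand-revised) ROI file to
#'   reload instead of segmenting and classifying.
#' @return list: `roiset`, `masks`, `adc` (mean ADC map), `perfusion`
#'   (`perfusion_result`), `tissue` (nagm/nawm masks + labels), `stats`
#'   (data.frame), `provenance`, `csv_path` (when `out_dir` given).
#' @export
run_phantom_pipeline <- function(bundle, out_dir = NULL, mf = 2,
                                 local_factor = 0.5,
                                 arrival_fraction = 0.1,
                                 svd_threshold = 0.2, n_aif_voxels = 10L,
                                 vscale = 1, patient_id = "phantom",
                                 roi_file = NULL) {
  log <- provenance_log()
  t0 <- Sys.time()

  # --- lesion segmentation + classification (or reload after revision)
  if (!is.null(roi_file)) {
    rs <- read_roiset(roi_file)
  } else {
    seeds <- lapply(bundle$spec$lesion_specs, `[[`, "center")
    rois <- mapply(function(s, i)
      grow_lesion_roi(bundle$flair, s, local_factor, id = i),
      seeds, seq_along(seeds), SIMPLIFY = FALSE)
    rs <- roi_set(rois)
    rs <- classify_lesions(rs, bundle$t1, bundle$gd_t1,
                           bundle$nawm_ref_roi, mf = mf)
  }
  log <- append_step(log, "lesions",
                     params = list(mf = mf, local_factor = local_factor),
                     start = t0)
  masks <- class_masks(rs, bundle$flair)

  # --- diffusion
  t0 <- Sys.time()
  b <- bundle$spec$b_value
  adc_x <- adc_axis_map(bundle$dwi_b0, bundle$dwi_x, b, bundle$brain_mask)
  adc_y <- adc_axis_map(bundle$dwi_b0, bundle$dwi_y, b, bundle$brain_mask)
  adc_z <- adc_axis_map(bundle$dwi_b0, bundle$dwi_z, b, bundle$brain_mask)
  adc <- mean_adc_map(adc_x, adc_y, adc_z)
  log <- append_step(log, "diffusion", params = list(b_value = b),
                     start = t0)

  # --- perfusion
  t0 <- Sys.time()
  series <- volume_mean_series(bundle$dsc, bundle$brain_mask)
  arrival <- detect_arrival(series, arrival_fraction)
  conc <- signal_to_concentration(bundle$dsc, arrival)
  aif_sel <- select_aif(conc, bundle$brain_mask, bundle$dsc$tr_s, arrival,
                        n_voxels = n_aif_voxels)
  perf <- perfusion_maps(conc, aif_sel$aif, bundle$dsc$tr_s,
                         bundle$brain_mask, svd_threshold,
                         arrival_index = arrival,
                         aif_voxels = aif_sel$voxels)
  log <- append_step(log, "perfusion",
                     params = list(arrival_fraction = arrival_fraction,
                                   svd_threshold = svd_threshold,
                                   n_aif_voxels = n_aif_voxels,
                                   arrival_index = arrival),
                     start = t0)

  # --- tissues
  t0 <- Sys.time()
  seg <- fallback_tissue_segmentation(bundle$t1, bundle$brain_mask)
  na_masks <- make_normal_appearing(label_mask(seg$labels, 2L),
                                    label_mask(seg$labels, 3L),
                                    masks$total)
  log <- append_step(log, "tissues", params = list(vscale = vscale),
                     start = t0)

  # --- region statistics
  t0 <- Sys.time()
  maps <- list(adc = adc, cbf = perf$cbf, cbv = perf$cbv, mtt = perf$mtt)
  valid <- list(adc = attr(adc, "valid_mask"), cbf = perf$valid_mask,
                cbv = NULL, mtt = perf$valid_mask)
  regions <- list(NAGM = na_masks$nagm, NAWM = na_masks$nawm,
                  lesion_total = masks$total)
  for (k in names(masks$by_class))
    regions[[paste0("lesion_", k)]] <- masks$by_class[[k]]
  for (k in names(masks$by_lesion))
    regions[[paste0("lesion_", k)]] <- masks$by_lesion[[k]]
  codes <- phantom_label_codes()
  deep <- codes[codes >= 10L]
  for (k in names(deep))
    regions[[paste0("basal_ganglia_", k)]] <-
      label_mask(bundle$truth_structure_labels, deep[[k]])

  rows <- list()
  for (rn in names(regions)) {
    rows[[length(rows) + 1L]] <-
      region_stats(NULL, regions[[rn]], patient_id, rn, "none", vscale)
    for (mn in names(maps))
      rows[[length(rows) + 1L]] <-
        region_stats(maps[[mn]], regions[[rn]], patient_id, rn, mn, vscale,
                     valid_mask = valid[[mn]])
  }
  stats_df <- do.call(rbind, rows)
  log <- append_step(log, "analysis", params = list(patient_id = patient_id),
                     start = t0)

  csv_path <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_roiset(rs, file.path(out_dir, "lesions.roi"))
    write_volume(masks$total, file.path(out_dir, "lesion_total.nii.gz"),
                 datatype = "uint8")
    write_volume(adc, file.path(out_dir, "adc_mean.nii.gz"))
    for (mn in c("cbf", "cbv", "mtt"))
      write_volume(perf[[mn]], file.path(out_dir, paste0(mn, ".nii.gz")))
    write_aif_json(perf, file.path(out_dir, "aif.json"))
    csv_path <- file.path(out_dir, "region_stats.csv")
    write_region_csv(stats_df, csv_path)
    write_provenance(log, file.path(out_dir, "provenance.jsonl"))
  }

  list(roiset = rs, masks = masks, adc = adc, perfusion = perf,
       tissue = c(na_masks, list(labels = seg$labels)), stats = stats_df,
       provenance = log, csv_path = csv_path)
}
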