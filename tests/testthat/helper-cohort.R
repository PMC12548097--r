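# build a small synthetic cohort on disk (all four modalities per
# participant); used by the pipeline and determinism checks
write_synth_cohort_files <- function(dir, n = 3) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_len(n), function(i) {
    id <- sprintf("P%02d", i)
    sm <- synth_mosaic(peak_density = 1.6e5 + 3e4 * i,
                       peak_offset_um = c(10 * i - 20, 5 * i - 10),
                       seed = 100 + i)
    cf <- file.path(dir, paste0(id, "_coords.csv"))
    write_cone_coords(sm$mosaic, cf)
    ss <- synth_segmentation(onl_peak_um = 90 + 5 * i, seed = 200 + i)
    sf <- file.path(dir, paste0(id, "_seg.csv"))
    write_segmentation(ss$seg, sf)
    tm <- synth_thickness_map(rim_radius_um = 800 + 100 * i, seed = 300 + i)
    tf <- file.path(dir, paste0(id, "_thick.csv"))
    write_thickness_map(tm$map, tf)
    vs <- synth_vessel_mask(faz_radius_um = 250 + 30 * i, seed = 400 + i)
    mf <- file.path(dir, paste0(id, "_mask.png"))
    write_vessel_mask(vs$vm, mf)
    data.frame(id = id, axial_length_mm = 24, coords_csv = cf, seg_csv = sf,
               thickness_csv = tf, mask_png = mf)
  })
  do.call(rbind, rows)
}
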