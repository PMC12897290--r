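#' Write a simulated cohort to disk
#'
#' One 4D NIfTI per subject plus tab-separated events (onset, duration,
#' condition) and motion (6 columns) files, a cohort-level subjects
#' table (id, group, clinical columns), the atlas as 3D NIfTI with a
#' name lookup table, and the simulation config as YAML.
#'
#' @param cohort an `fmri_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- cohort$config$voxel_size_mm
  for (s in cohort$subjects) {
    img <- RNifti::asNifti(s$bold$data, pixdim = c(vs, vs, vs, s$bold$tr_s))
    RNifti::writeNifti(img, file.path(dir, paste0(s$id, "_bold.nii.gz")))
    utils::write.table(s$events, file.path(dir, paste0(s$id, "_events.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(s$motion, file.path(dir, paste0(s$id, "_motion.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  clin <- do.call(rbind, lapply(cohort$subjects, function(s)
    data.frame(id = s$id, group = s$group, t(s$clinical))))
  utils::write.table(clin, file.path(dir, "subjects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  atl <- RNifti::asNifti(cohort$atlas$labels + 0L, pixdim = rep(vs, 3))
  RNifti::writeNifti(atl, file.path(dir, "atlas.nii.gz"))
  utils::write.table(data.frame(label = seq_along(cohort$atlas$names),
                                name = cohort$atlas$names),
                     file.path(dir, "atlas_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  cfg$clinical_links <- if (!is.null(cfg$clinical_links)) as.list(cfg$clinical_links)
  yaml::write_yaml(unclass(cfg), file.path(dir, "sim_config.yaml"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory.
#' @return an `fmri_cohort` (without ground truth, which is a property
#'   of the generator, not the files).
#' @export
read_cohort <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "sim_config.yaml"))
  if (!is.null(cfg$clinical_links))
    cfg$clinical_links <- as.data.frame(cfg$clinical_links)
  cfg$base_amplitude <- unlist(cfg$base_amplitude)
  cfg$effect_rois <- as.character(unlist(cfg$effect_rois))
  cfg$conditions <- as.character(unlist(cfg$conditions))
  cfg$clinical_metrics <- as.character(unlist(cfg$clinical_metrics))
  cfg$grid_shape <- as.integer(unlist(cfg$grid_shape))
  config <- do.call(sim_config, cfg)
  lab <- RNifti::readNifti(file.path(dir, "atlas.nii.gz"))
  names_tab <- utils::read.delim(file.path(dir, "atlas_labels.tsv"))
  atlas <- structure(list(labels = array(as.integer(lab), dim(lab)),
                          names = names_tab$name,
                          voxel_size_mm = config$voxel_size_mm,
                          wm_voxels = which(slice.index(array(0L, dim(lab)), 1) == 1L),
                          csf_voxels = which(slice.index(array(0L, dim(lab)), 1) == dim(lab)[1L])),
                     class = "fmri_atlas")
  subj_tab <- utils::read.delim(file.path(dir, "subjects.tsv"))
  subjects <- list()
  for (i in seq_len(nrow(subj_tab))) {
    id <- subj_tab$id[i]
    bold <- RNifti::readNifti(file.path(dir, paste0(id, "_bold.nii.gz")))
    events <- utils::read.delim(file.path(dir, paste0(id, "_events.tsv")))
    motion <- as.matrix(utils::read.delim(file.path(dir, paste0(id, "_motion.tsv"))))
    clinical <- unlist(subj_tab[i, setdiff(names(subj_tab), c("id", "group"))])
    subjects[[id]] <- structure(
      list(id = id, group = subj_tab$group[i],
           bold = volume_series(array(as.numeric(bold), dim(bold)),
                                config$voxel_size_mm, config$tr_s),
           events = events, motion = motion, clinical = clinical,
           amp_jitter = NA_real_),
      class = "subject_record")
  }
  structure(list(subjects = subjects, atlas = atlas, ground_truth = NULL,
                 config = config),
            class = "fmri_cohort")
}

#' Write a stat map as 3D NIfTI
#' @param map a [stat_map()].
#' @param path output file path.
#' @param voxel_size_mm voxel size recorded in the header.
#' @export
write_stat_map <- function(map, path, voxel_size_mm = 3) {
  img <- RNifti::asNifti(map$values, pixdim = rep(voxel_size_mm, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a QC report table for a set of subjects
#' @param reports list of `preproc_report`s.
#' @param path output TSV path.
#' @return the data.frame written, invisibly.
#' @export
write_qc_table <- function(reports, path) {
  tab <- do.call(rbind, lapply(reports, function(r)
    data.frame(id = r$id, max_fd_mm = max(r$fd_series),
               mean_fd_mm = mean(r$fd_series),
               n_scrubbed = length(r$scrubbed_volumes),
               excluded = r$excluded,
               reason = ifelse(is.na(r$reason), "", r$reason))))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
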