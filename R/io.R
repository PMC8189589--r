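# map lattice coordinates to 1-based array indices given a spacing
.coords_to_ijk <- function(coords, spacing) {
  origin <- apply(coords, 2L, min)
  ijk <- sweep(coords, 2L, origin)
  ijk <- round(ijk / spacing) + 1L
  storage.mode(ijk) <- "integer"
  ijk
}

#' Write a mask to NIfTI
#'
#' Voxels carry their 1-based mask index (0 outside), so masked vectors can
#' be reconstructed in a stable order.
#'
#' @param mask A [cm_mask()] object.
#' @param path Output `.nii`/`.nii.gz` path.
#' @return The path, invisibly.
#' @export
write_mask_nifti <- function(mask, path) {
  ijk <- .coords_to_ijk(mask$coords, mask$spacing)
  dims <- apply(ijk, 2L, max)
  arr <- array(0L, dims)
  arr[ijk] <- seq_len(nrow(ijk))
  img <- RNifti::asNifti(arr, pixdim = rep(mask$spacing, 3L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a masked map to NIfTI
#'
#' @param values Numeric vector over the mask voxels.
#' @param mask A [cm_mask()] object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_map_nifti <- function(values, mask, path) {
  stopifnot(length(values) == nrow(mask$coords))
  ijk <- .coords_to_ijk(mask$coords, mask$spacing)
  dims <- apply(ijk, 2L, max)
  arr <- array(0, dims)
  arr[ijk] <- values
  img <- RNifti::asNifti(arr, pixdim = rep(mask$spacing, 3L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a masked map from NIfTI
#'
#' @param path Map volume path.
#' @param mask_path Mask volume written by [write_mask_nifti()] (voxel
#'   values are mask indices).
#' @return Numeric vector over mask voxels, in mask-index order.
#' @export
read_map_nifti <- function(path, mask_path) {
  mask <- as.array(RNifti::readNifti(mask_path))
  img <- as.array(RNifti::readNifti(path))
  if (!all(dim(img) == dim(mask))) stop("map and mask dimensions differ")
  idx <- which(mask > 0)
  out <- numeric(length(idx))
  out[mask[idx]] <- img[idx]
  out
}

#' Write a cohort to NIfTI volumes and a CSV manifest
#'
#' @param cohort A `cm_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  roi_mask <- cm_mask(cohort$roi_coords, cohort$spacing)
  brain_mask <- cm_mask(cohort$brain_coords, cohort$spacing)
  write_mask_nifti(roi_mask, file.path(dir, "roi_mask.nii.gz"))
  write_mask_nifti(brain_mask, file.path(dir, "brain_mask.nii.gz"))
  n <- nrow(cohort$scans)
  roi_path <- file.path(dir, sprintf("%s_roi.nii.gz", cohort$scans$scan_id))
  brain_path <- file.path(dir, sprintf("%s_brain.nii.gz", cohort$scans$scan_id))
  for (i in seq_len(n)) {
    write_map_nifti(cohort$roi[i, ], roi_mask, roi_path[i])
    write_map_nifti(cohort$brain[i, ], brain_mask, brain_path[i])
  }
  manifest <- cbind(cohort$scans,
                    roi_path = basename(roi_path),
                    brain_path = basename(brain_path))
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param manifest_path Path to `manifest.csv` (maps are resolved relative
#'   to its directory).
#' @return A list with `scans`, `roi`, `brain` matrices.
#' @export
read_cohort <- function(manifest_path) {
  manifest <- validate_manifest(manifest_path)
  dir <- dirname(manifest_path)
  roi <- do.call(rbind, lapply(file.path(dir, manifest$roi_path),
                               read_map_nifti,
                               mask_path = file.path(dir, "roi_mask.nii.gz")))
  brain <- do.call(rbind, lapply(file.path(dir, manifest$brain_path),
                                 read_map_nifti,
                                 mask_path = file.path(dir, "brain_mask.nii.gz")))
  rownames(roi) <- rownames(brain) <- manifest$scan_id
  list(scans = manifest[, c("scan_id", "subject_id", "condition")],
       roi = roi, brain = brain)
}

#' Validate a scan manifest
#'
#' Checks that every (subject, condition) pair is unique, that conditions
#' are placebo/drug, and that referenced map files exist.
#'
#' @param path Manifest CSV path (columns `subject_id`, `condition`, and
#'   optionally `roi_path`, `brain_path`), or a data frame.
#' @return The parsed manifest data frame (invisibly on error-free input).
#' @export
validate_manifest <- function(path) {
  manifest <- if (is.data.frame(path)) path else read.csv(path,
                                                          stringsAsFactors = FALSE)
  required <- c("subject_id", "condition")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols))
    stop("manifest lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!all(manifest$condition %in% c("placebo", "drug")))
    stop("condition must be 'placebo' or 'drug'")
  key <- paste(manifest$subject_id, manifest$condition)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("duplicated (subject, condition) rows: ",
         paste(dup, collapse = ", "))
  }
  if (!is.data.frame(path)) {
    dir <- dirname(path)
    for (col in intersect(c("roi_path", "brain_path"), names(manifest))) {
      p <- file.path(dir, manifest[[col]])
      ok <- file.exists(p)
      if (!all(ok))
        stop("missing map file: ", p[!ok][1])
    }
  }
  manifest
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (one set per line: name, description, members).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm)
    paste(c(nm, "synthetic", gene_sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write an expression matrix as TSV
#'
#' Rows are samples with `x`, `y`, `z`, `donor` columns followed by one
#' column per gene.
#'
#' @param expression A `cm_expression` object or a list with `values`,
#'   `coords`, `donor`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_expression_tsv <- function(expression, path) {
  df <- data.frame(x = expression$coords[, 1L], y = expression$coords[, 2L],
                   z = expression$coords[, 3L], donor = expression$donor,
                   expression$values, check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an expression TSV written by [write_expression_tsv()]
#'
#' @param path Input path.
#' @return A list with `values`, `coords`, `donor`, `genes`.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  meta <- c("x", "y", "z", "donor")
  genes <- setdiff(names(df), meta)
  list(values = as.matrix(df[, genes, drop = FALSE]),
       coords = as.matrix(df[, c("x", "y", "z")]),
       donor = as.character(df$donor), genes = genes)
}

#' Write a ranked gene list for external enrichment tools
#'
#' Two-column TSV (gene, z), written in descending and ascending z order
#' (the input format of ranked-list GO enrichment services).
#'
#' @param ranking A `gene_ranking` data frame.
#' @param path_desc,path_asc Output paths.
#' @return Invisibly, both paths.
#' @export
write_ranked_list <- function(ranking, path_desc, path_asc) {
  d <- ranking[order(-ranking$z), c("gene", "z")]
  write.table(d, path_desc, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(d[rev(seq_len(nrow(d))), ], path_asc, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(c(path_desc, path_asc))
}
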