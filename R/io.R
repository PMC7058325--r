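# Cohort serialization: 8-bit grayscale PNGs for images and masks, a CSV
# manifest, and one JSON bifurcation table per image. All coordinates are
# 0-based with x = column and y = row, origin at the image's top-left;
# this convention is recorded in every JSON artifact.

#' Write an image matrix as an 8-bit grayscale PNG
#'
#' @param m intensity matrix in \[0,1\] (rows = y).
#' @param path output file.
#' @export
writeImagePNG <- function(m, path) {
  png::writePNG(round(m * 255) / 255, path)
  invisible(path)
}

#' Read a grayscale PNG as an intensity matrix
#'
#' Color PNGs are collapsed to luminance.
#'
#' @param path PNG file.
#' @return matrix in \[0,1\].
#' @export
readImagePNG <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L)
    a <- 0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3]
  a
}

#' Write a synthetic cohort to disk
#'
#' Layout: `images/<id>.png`, `masks/<id>.png`,
#' `bifurcations/<id>.json`, and `manifest.csv` with columns
#' `id`, `subject_id`, `label`, `image_path`, `mask_path`. Images are
#' quantized to 8 bits; masks are exact.
#'
#' @param cohort a cohort from [generateCohort()].
#' @param dir output directory (created if missing).
#' @return the manifest data.frame, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  for (d in file.path(dir, c("images", "masks", "bifurcations")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$image_path <- file.path("images", paste0(man$id, ".png"))
  man$mask_path <- file.path("masks", paste0(man$id, ".png"))
  for (i in seq_along(cohort$records)) {
    rec <- cohort$records[[i]]
    writeImagePNG(rec$image@pixels, file.path(dir, man$image_path[i]))
    writeImagePNG(rec$mask@pixels, file.path(dir, man$mask_path[i]))
    bf <- rec$bifurcations
    jsonlite::write_json(
      list(coordinates = "0-based, x = column, y = row, origin top-left",
           bifurcations = bf[, c("x", "y", "d_parent", "d1", "d2",
                                 "angle_deg", "asymmetry")]),
      file.path(dir, "bifurcations", paste0(man$id[i], ".json")),
      digits = NA, auto_unbox = TRUE)
  }
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir cohort directory.
#' @return list with `records` (id, subjectId, label, image
#'   ([FundusImage-class]), mask ([VesselMask-class]), bifurcations) and
#'   `manifest`.
#' @export
readCohort <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  records <- lapply(seq_len(nrow(man)), function(i) {
    img <- readImagePNG(file.path(dir, man$image_path[i]))
    msk <- (readImagePNG(file.path(dir, man$mask_path[i])) > 0.5) * 1
    bf <- jsonlite::read_json(file.path(dir, "bifurcations",
                                        paste0(man$id[i], ".json")),
                              simplifyVector = TRUE)$bifurcations
    list(id = man$id[i], subjectId = man$subject_id[i],
         label = man$label[i],
         image = new("FundusImage", pixels = img, label = man$label[i],
                     subjectId = man$subject_id[i], provenance = "raw"),
         mask = new("VesselMask", pixels = msk),
         bifurcations = as.data.frame(bf))
  })
  structure(list(records = records, manifest = man),
            class = "retinavascCohort")
}
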