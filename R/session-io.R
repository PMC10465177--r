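#' Write one evaluation session as two CSV files
#'
#' An evaluation run is stored the way the rating software stores it: a
#' randomization file holding the presentation order and the true label of
#' every image, and a decision file holding each expert's answer and
#' decision time per presented image. The presentation order is a seeded
#' permutation of the images so the session is blind but reproducible.
#'
#' Randomization columns: `presentation_index`, `image_path`, `true_label`,
#' `group`. Decision columns: `expert_id`, `timestamp`,
#' `presentation_index`, `answer`, `time_s`.
#'
#' @param records Decision tibble from [simulate_experts()] (or compatible).
#' @param randomization_path,decisions_path Output CSV paths.
#' @param seed Seed for the presentation-order shuffle.
#' @return Invisibly, a list with the two paths and the permutation used.
#' @export
write_session_csvs <- function(records, randomization_path, decisions_path,
                               seed = 1L) {
  stopifnot(is.data.frame(records))
  need <- c("expert_id", "image_id", "group", "true_label", "answer", "time_s")
  missing <- setdiff(need, names(records))
  if (length(missing) > 0)
    abort(paste0("records lack column(s): ", paste(missing, collapse = ", ")))

  imgs <- dplyr::distinct(records, .data$image_id, .data$group, .data$true_label)
  perm <- with_seed(seed, sample.int(nrow(imgs)))
  rand <- tibble(
    presentation_index = seq_len(nrow(imgs)),
    image_path = imgs$image_id[perm],
    true_label = imgs$true_label[perm],
    group = imgs$group[perm]
  )
  lookup <- setNames(rand$presentation_index, rand$image_path)
  dec <- tibble(
    expert_id = records$expert_id,
    timestamp = format(as.POSIXct("2026-01-01", tz = "UTC"), "%Y-%m-%dT%H:%M:%S"),
    presentation_index = unname(lookup[records$image_id]),
    answer = records$answer,
    time_s = records$time_s
  )
  readr::write_csv(rand, randomization_path)
  readr::write_csv(dec, decisions_path)
  invisible(list(randomization = randomization_path, decisions = decisions_path,
                 permutation = perm))
}

#' Read an evaluation session back into decision records
#'
#' Inverse of [write_session_csvs()]: joins the decision file to the
#' randomization file on `presentation_index` and returns the record tibble.
#' Malformed rows (missing fields, unknown answers, non-positive times,
#' presentation indices absent from the randomization) raise an error naming
#' the offending line number (1-based, counting the header as line 1).
#'
#' @param randomization_path,decisions_path CSV paths written by
#'   [write_session_csvs()].
#' @return A decision tibble with the same columns as [simulate_experts()].
#' @export
read_session_csvs <- function(randomization_path, decisions_path) {
  rand <- readr::read_csv(randomization_path, show_col_types = FALSE,
                          progress = FALSE)
  need_r <- c("presentation_index", "image_path", "true_label", "group")
  if (!all(need_r %in% names(rand)))
    abort("Randomization file lacks required columns.")
  bad <- which(is.na(rand$presentation_index) | is.na(rand$image_path) |
                 !rand$true_label %in% c("real", "generated"))
  if (length(bad) > 0)
    abort(sprintf("Malformed randomization row at line %d.", bad[1] + 1L))

  dec <- readr::read_csv(decisions_path, show_col_types = FALSE,
                         progress = FALSE)
  need_d <- c("expert_id", "presentation_index", "answer", "time_s")
  if (!all(need_d %in% names(dec)))
    abort("Decision file lacks required columns.")
  bad <- which(is.na(dec$expert_id) | is.na(dec$presentation_index) |
                 !dec$answer %in% c("real", "generated", "pass") |
                 is.na(dec$time_s) | dec$time_s <= 0 |
                 !dec$presentation_index %in% rand$presentation_index)
  if (length(bad) > 0)
    abort(sprintf("Malformed decision row at line %d.", bad[1] + 1L))

  dec |>
    dplyr::left_join(rand, by = "presentation_index") |>
    dplyr::transmute(
      expert_id = .data$expert_id, image_id = .data$image_path,
      group = .data$group, true_label = .data$true_label,
      answer = .data$answer, time_s = .data$time_s
    )
}

#' Write / read an image group as 8-bit grayscale PNG files
#'
#' Images are written as `<id>.png` (intensities scaled to \[0, 1\] PNG
#' gray), masks — when present — as `<id>_mask.png` with values 0/255.
#'
#' @param dataset Image tibble (`id`, `group`, `image`, optional `mask`).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written image paths.
#' @export
write_image_dir <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::map_chr(seq_len(nrow(dataset)), function(i) {
    path <- file.path(dir, paste0(dataset$id[i], ".png"))
    png::writePNG(dataset$image[[i]] / 255, path)
    if ("mask" %in% names(dataset) && !is.null(dataset$mask[[i]])) {
      png::writePNG(dataset$mask[[i]] + 0, file.path(dir, paste0(dataset$id[i], "_mask.png")))
    }
    path
  })
  invisible(paths)
}

#' Resize every image (and mask) in a dataset to a common square size
#'
#' Images are area-resampled; masks are re-binarized at 0.5. Pairwise
#' metrics and the group report require all images on a common geometry.
#'
#' @param data Image tibble (`image`, optional `mask` list-columns).
#' @param size Target square side in pixels.
#' @return The tibble with resized list-columns.
#' @export
resize_dataset <- function(data, size) {
  data$image <- purrr::map(data$image, function(im) {
    if (all(dim(im) == c(size, size))) im else clamp255(downsample(im, size, size))
  })
  if ("mask" %in% names(data)) {
    data$mask <- purrr::map(data$mask, function(m) {
      if (is.null(m) || all(dim(m) == c(size, size))) m
      else matrix(as.integer(downsample(m + 0, size, size) > 0.5), size, size)
    })
  }
  data
}

#' @rdname write_image_dir
#' @param group Group label to attach to every image read.
#' @export
read_image_dir <- function(dir, group = basename(dir)) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  files <- files[!grepl("_mask\\.png$", files)]
  if (length(files) == 0) abort(sprintf("No PNG images found in '%s'.", dir))
  imgs <- purrr::map(files, function(f) {
    x <- png::readPNG(f)
    if (length(dim(x)) == 3) x <- x[, , 1]
    x * 255
  })
  masks <- purrr::map(files, function(f) {
    mf <- sub("\\.png$", "_mask.png", f)
    if (file.exists(mf)) {
      m <- png::readPNG(mf)
      if (length(dim(m)) == 3) m <- m[, , 1]
      matrix(as.integer(m > 0.5), nrow(m), ncol(m))
    } else NULL
  })
  tibble(
    id = sub("\\.png$", "", basename(files)),
    group = group, image = imgs, mask = masks
  )
}
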