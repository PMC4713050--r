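# ROI-level feature table assembly and z-score standardization.

#' Build the ROI feature table of a gel dataset
#'
#' Extracts the full feature inventory from every ROI and assembles one row
#' per ROI in deterministic (image_id, roi_id) order. Labels are encoded
#' 1 = spot, 0 = noise.
#'
#' @param dataset A `gel_dataset` from [generate_dataset()].
#' @param inventory Feature inventory tibble (default [feature_inventory()]).
#' @param Ng,normalization Quantization settings, see [quantize()].
#' @return A tibble: image_id, roi_id, label, then one column per feature.
#' @export
build_feature_table <- function(dataset, inventory = feature_inventory(),
                                Ng = 64L, normalization = "full-range") {
  stopifnot(inherits(dataset, "gel_dataset"))
  rois <- dplyr::arrange(dataset$rois, .data$image_id, .data$roi_id)
  head_cols <- tibble::tibble(image_id = integer(), roi_id = integer(),
                              label = integer())
  if (nrow(rois) == 0) {
    empty <- as.list(stats::setNames(rep(list(numeric()), nrow(inventory)),
                                     inventory$name))
    return(dplyr::bind_cols(head_cols, tibble::as_tibble(empty)))
  }
  feats <- purrr::map(seq_len(nrow(rois)), function(k) {
    row <- rois[k, ]
    px <- roi_pixels(dataset$images[[row$image_id]], row)
    tryCatch(extract_features(px, inventory, Ng, normalization),
             error = function(e)
               stop("feature extraction failed for image ", row$image_id,
                    " roi ", row$roi_id, ": ", conditionMessage(e)))
  })
  fm <- do.call(rbind, feats)
  dplyr::bind_cols(
    tibble::tibble(image_id = rois$image_id, roi_id = rois$roi_id,
                   label = as.integer(rois$label == "spot")),
    tibble::as_tibble(fm))
}

feature_columns <- function(table) {
  setdiff(names(table)[vapply(table, is.numeric, logical(1))],
          c("image_id", "roi_id", "label", "fold"))
}

#' Z-score standardize a feature table
#'
#' Centres and scales every feature column to mean 0 and sd 1. In
#' `"global"` mode the statistics come from all rows (the dataset is
#' preprocessed as a whole); in `"per-fold"` mode they are fitted on the
#' training rows of `fold` only and applied everywhere, which avoids
#' leaking test statistics. Zero-variance columns map to 0 with a warning.
#'
#' @param table Feature table (tibble).
#' @param mode `"global"` or `"per-fold"`.
#' @param train_rows Logical/integer index of training rows (per-fold mode).
#' @return The standardized table, with the per-column `mean` and `sd`
#'   attached as attribute `"scaling"` (a tibble).
#' @export
standardize <- function(table, mode = c("global", "per-fold"),
                        train_rows = NULL) {
  mode <- match.arg(mode)
  cols <- feature_columns(table)
  ref <- if (mode == "global") table else {
    if (is.null(train_rows)) stop("per-fold mode needs `train_rows`")
    table[train_rows, , drop = FALSE]
  }
  mu <- vapply(ref[cols], mean, numeric(1))
  sd_ <- vapply(ref[cols], stats::sd, numeric(1))
  if (any(sd_ == 0))
    warning("zero-variance feature columns mapped to 0: ",
            paste(cols[sd_ == 0], collapse = ", "))
  for (i in seq_along(cols)) {
    cn <- cols[i]
    table[[cn]] <- if (sd_[i] == 0) rep(0, nrow(table)) else
      (table[[cn]] - mu[i]) / sd_[i]
  }
  attr(table, "scaling") <- tibble::tibble(feature = cols, mean = mu, sd = sd_)
  table
}

#' Write / read a feature table as CSV
#'
#' The CSV carries the Mazda-style feature names plus image_id, roi_id and
#' label; `write_feature_table` also writes a JSON sidecar recording the
#' inventory and extraction config for provenance. The reader accepts the
#' same layout (and hence the deposited real-data table: samples by named
#' features plus a binary label).
#'
#' @param table Feature table.
#' @param path CSV path.
#' @param config Optional extraction config list for the sidecar.
#' @return `path` (writer, invisibly) or the tibble (reader).
#' @export
write_feature_table <- function(table, path, config = NULL) {
  readr::write_csv(table, path)
  sidecar <- list(features = setdiff(names(table),
                                     c("image_id", "roi_id", "label")),
                  config = config)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("label" %in% names(tab)) tab$label <- as.integer(tab$label)
  for (cn in intersect(c("image_id", "roi_id"), names(tab)))
    tab[[cn]] <- as.integer(tab[[cn]])
  tab
}
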