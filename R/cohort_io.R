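# Cohort file dialect: tab-separated text with a header row; column 1 is the
# sample ID, column 2 the binary label (0 = control, 1 = case), remaining
# columns are features. A JSON sidecar (<path>.json) carries feature_meta and
# generator provenance. Doubles are written in shortest round-trippable form,
# so read(write(x)) restores features to full stored precision.

#' Write a cohort to a delimited text file
#'
#' @param cohort A `labeled_cohort`.
#' @param path Output path for the TSV; a sidecar `<path>.json` with
#'   feature metadata and provenance is written alongside.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  # features serialized at %.17g so doubles round-trip exactly
  feat_chr <- apply(cohort$features, 2L, function(col) sprintf("%.17g", col))
  df <- tibble::as_tibble(feat_chr)
  df <- tibble::add_column(df,
                           sample_id = rownames(cohort$features),
                           label = cohort$labels, .before = 1L)
  readr::write_tsv(df, path, progress = FALSE)
  sidecar <- list(cohort_tag = cohort$cohort_tag,
                  feature_meta = cohort$feature_meta,
                  provenance = cohort$provenance)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path Path to the TSV; the sidecar `<path>.json` is read when
#'   present, otherwise minimal feature metadata is reconstructed.
#' @return A `labeled_cohort`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  # columns come in as text and are converted with R's strtod so that
  # %.17g-serialized doubles round-trip bit-for-bit
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(df) < 3L || !identical(names(df)[1:2], c("sample_id", "label")))
    stop("malformed cohort header: expected columns sample_id, label, <features...>",
         call. = FALSE)
  labels <- suppressWarnings(as.numeric(df$label))
  bad <- which(!(labels %in% c(0, 1)) | is.na(labels))
  if (length(bad))
    stop(sprintf("non-binary label value at row %d (column 2): %s",
                 bad[1L], df$label[bad[1L]]), call. = FALSE)
  feats <- suppressWarnings(
    vapply(df[-(1:2)], as.numeric, numeric(nrow(df))))
  if (!is.matrix(feats)) feats <- matrix(feats, nrow = nrow(df),
                                         dimnames = list(NULL, names(df)[-(1:2)]))
  if (anyNA(feats)) {
    pos <- which(is.na(feats), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at row %d, feature column %d (%s)",
                 pos[1L], pos[2L], colnames(feats)[pos[2L]]), call. = FALSE)
  }
  rownames(feats) <- df$sample_id

  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    meta <- tibble::as_tibble(side$feature_meta)
    if (!identical(meta$name, colnames(feats)))
      stop("sidecar feature_meta does not match file feature columns", call. = FALSE)
    tag <- side$cohort_tag
    prov <- side$provenance
  } else {
    meta <- tibble::tibble(name = colnames(feats), modality = "unknown",
                           kind = "continuous")
    tag <- basename(path)
    prov <- NULL
  }
  labeled_cohort(feats, as.integer(labels), meta, cohort_tag = tag,
                 provenance = prov)
}
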