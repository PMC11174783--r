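#' Stratified train/test split
#'
#' @param manifest Manifest tibble with a `class_id` column.
#' @param ratio Training fraction (default the 8:2 split).
#' @param seed RNG seed for the assignment.
#' @return List with `train` and `test` manifests; their union is the input
#'   and their intersection empty, with the per-class training fraction within
#'   one record of `ratio`.
#' @export
split_dataset <- function(manifest, ratio = 0.8, seed = NULL) {
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie in (0, 1)", call. = FALSE)
  counts <- table(manifest$class_id)
  if (any(counts < 2)) {
    stop("every class needs at least 2 records to split", call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  # largest-remainder allocation: per-class counts floor(n_c * ratio) plus one
  # extra for the largest fractional parts, so the overall training size is
  # exactly round(n * ratio) and every class stays within one record of ratio
  target <- round(nrow(manifest) * ratio)
  n_c <- as.integer(counts)
  base <- pmin(pmax(floor(n_c * ratio), 1L), n_c - 1L)
  frac <- n_c * ratio - floor(n_c * ratio)
  short <- target - sum(base)
  if (short > 0) {
    ord <- order(frac, decreasing = TRUE)
    ord <- ord[base[ord] < n_c[ord] - 1L]
    take <- utils::head(ord, short)
    base[take] <- base[take] + 1L
  }
  is_train <- logical(nrow(manifest))
  for (k in seq_along(counts)) {
    idx <- which(manifest$class_id == as.integer(names(counts)[k]))
    is_train[sample(idx, base[k])] <- TRUE
  }
  train <- manifest[is_train, , drop = FALSE]
  test <- manifest[!is_train, , drop = FALSE]
  train$split <- "train"
  test$split <- "test"
  list(train = train, test = test)
}

#' Per-class count and proportion table
#'
#' Summarises a manifest of records into per-class counts, whole-percent
#' proportions and a total row. When the input instead carries expansion
#' metadata (columns `n_before` and `n_expanded`), the after-expansion count
#' is their sum and all three count columns are reported.
#'
#' @param manifest Either a record manifest with `class_id`/`class_name`
#'   columns, or a per-class tibble with `class_name`, `n_before`,
#'   `n_expanded`.
#' @return A tibble with one row per class plus a `Total` row.
#' @export
manifest_summary <- function(manifest) {
  if (all(c("n_before", "n_expanded") %in% names(manifest))) {
    tbl <- tibble::tibble(class_name = manifest$class_name,
                          n_before = as.integer(manifest$n_before),
                          n_expanded = as.integer(manifest$n_expanded),
                          n = as.integer(manifest$n_before + manifest$n_expanded))
  } else {
    if (nrow(manifest) == 0) stop("empty manifest", call. = FALSE)
    ord <- manifest |>
      dplyr::distinct(.data$class_id, .data$class_name) |>
      dplyr::arrange(.data$class_id)
    tbl <- dplyr::left_join(ord, dplyr::count(manifest, .data$class_id),
                            by = "class_id")
    tbl <- tibble::tibble(class_name = tbl$class_name, n = as.integer(tbl$n))
  }
  total <- sum(tbl$n)
  tbl$proportion_pct <- as.integer(round(100 * tbl$n / total))
  total_row <- tbl[1, ]
  total_row$class_name <- "Total"
  for (col in intersect(c("n_before", "n_expanded"), names(tbl))) {
    total_row[[col]] <- sum(tbl[[col]])
  }
  total_row$n <- total
  total_row$proportion_pct <- 100L
  dplyr::bind_rows(tbl, total_row)
}

#' Read / write manifests
#'
#' @param path CSV file path.
#' @return `read_manifest` returns a tibble; `write_manifest` its input,
#'   invisibly.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' @rdname read_manifest
#' @param manifest Manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(manifest)
}
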