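#' Read and write triplet samples
#'
#' Triplets are stored as 3-column delimited text with header `x,y,z`, one
#' row per sample, plus a sidecar JSON metadata record
#' (`<path>.json`) holding `{model, kind, n, seed, p_x, p_y, p_z}` where
#' known.  `read_triplet()` restores the kind (and discrete alphabet) from
#' the sidecar when present, else treats the data as continuous.
#'
#' @param data A `triplet` tibble.
#' @param path CSV (or TSV, by extension) file path.
#' @param meta Named list merged into the sidecar metadata.
#' @return `write_triplet()` returns `path` invisibly; `read_triplet()`
#'   returns a `triplet`.
#' @export
write_triplet <- function(data, path, meta = list()) {
  writer <- if (grepl("\\.tsv$", path)) readr::write_tsv else readr::write_csv
  writer(tibble::as_tibble(data[, c("x", "y", "z")]), path)
  base <- list(
    kind = triplet_kind(data), n = nrow(data),
    model = attr(data, "model")
  )
  if (triplet_kind(data) == "discrete") base$alphabet <- as.integer(triplet_alphabet(data))
  meta <- modifyList(base[!vapply(base, is.null, logical(1))], meta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_triplet
#' @export
read_triplet <- function(path) {
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  df <- reader(path, show_col_types = FALSE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::fromJSON(sidecar) else list()
  kind <- meta$kind %||% "continuous"
  out <- as_triplet(df, kind = kind, alphabet = meta$alphabet)
  if (!is.null(meta$model)) attr(out, "model") <- meta$model
  out
}
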