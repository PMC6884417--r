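#' Write a z-stack as multi-page TIFF with sidecar metadata
#'
#' Pages are written channel-major (all slices of channel 1, then channel 2,
#' ...), 16-bit. A YAML sidecar (same path with `.yml` appended) records the
#' pixel size, slice interval, channel names and stack dimensions; CSV tables
#' and TIFFs carry no self-describing voxel metadata, so the sidecar is
#' authoritative.
#'
#' @param stack a [zstack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (!inherits(stack, "zstack")) .stopf("stack must be a zstack")
  v <- stack$voxels
  if (max(v) > 65535) .stopf("voxel values exceed the 16-bit range")
  pages <- list()
  for (ch in seq_len(dim(v)[4]))
    for (z in seq_len(dim(v)[3]))
      pages[[length(pages) + 1L]] <- v[, , z, ch] / 65535
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(pixel_size_um = stack$pixel_size_um,
               slice_interval_um = stack$slice_interval_um,
               channel_names = as.list(stack$channel_names),
               n_slices = dim(v)[3],
               image_shape = as.list(dim(v)[1:2]))
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

#' Load a z-stack written by [write_stack()]
#'
#' @param path TIFF path; the sidecar `<path>.yml` must exist.
#' @return a [zstack()]. Reading back a stack written with [write_stack()]
#'   reproduces the voxels bit-identically.
#' @export
load_stack <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  meta_path <- paste0(path, ".yml")
  if (!file.exists(meta_path))
    .stopf("missing sidecar metadata file: %s", meta_path)
  meta <- yaml::read_yaml(meta_path)
  for (field in c("pixel_size_um", "slice_interval_um", "channel_names",
                  "n_slices", "image_shape"))
    if (is.null(meta[[field]]))
      .stopf("sidecar metadata is missing required field '%s'", field)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      .stopf("cannot parse TIFF '%s': %s", path,
                             conditionMessage(e)))
  channels <- unlist(meta$channel_names)
  nz <- meta$n_slices
  if (length(pages) != nz * length(channels))
    .stopf("TIFF has %d pages but metadata promises %d slices x %d channels",
           length(pages), nz, length(channels))
  if (length(channels) != 2L) {
    if (!"FISH" %in% channels)
      .stopf("input is not 2-channel and no FISH channel is identifiable")
    .warnf("expected a 2-channel (FISH, DAPI) stack; got %d channel(s), proceeding",
           length(channels))
  }
  nr <- meta$image_shape[[1]]; nc <- meta$image_shape[[2]]
  v <- array(0, dim = c(nr, nc, nz, length(channels)))
  i <- 0L
  for (ch in seq_along(channels))
    for (z in seq_len(nz)) {
      i <- i + 1L
      v[, , z, ch] <- pages[[i]]
    }
  zstack(v, channels, meta$pixel_size_um, meta$slice_interval_um)
}

#' Write / read a lineage count table as CSV
#'
#' @param table a lineage count table (`data.frame` with columns `embryo_id`,
#'   `pair_id`, `member`, `treatment`, `cdx2`, `sox17`, `nanog`).
#' @param path CSV path.
#' @return `write_counts_csv`: `path` invisibly; `read_counts_csv`: the table.
#' @export
write_counts_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_csv
#' @export
read_counts_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("embryo_id", "pair_id", "member", "cdx2", "sox17", "nanog")
  miss <- setdiff(need, names(tab))
  if (length(miss)) .stopf("count table is missing column(s): %s",
                           paste(miss, collapse = ", "))
  if (is.null(tab$total)) tab$total <- tab$cdx2 + tab$sox17 + tab$nanog
  class(tab) <- c("lineage_count_table", "data.frame")
  tab
}

#' Write / read an expression matrix as CSV
#'
#' Genes in rows, samples in columns, first row carrying the sample labels
#' (e.g. `"7a"`, `"7b"`), first column the gene ids.
#'
#' @param x numeric gene x sample matrix with dimnames.
#' @param path CSV path.
#' @return `write_expression_csv`: `path` invisibly; `read_expression_csv`:
#'   the matrix with pair labels re-derived from the sample names and
#'   attached as `attr(, "pair_labels")`.
#' @export
write_expression_csv <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_csv
#' @export
read_expression_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  attr(m, "pair_labels") <- as.integer(sub("[ab]$", "", colnames(m)))
  m
}

#' Write a run manifest
#'
#' Records every generator / analysis parameter (including seeds) of a run
#' into a YAML manifest so that any output can be regenerated.
#'
#' @param params named list (or a `*_sim_params` object) to record.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(params, path) {
  strip <- function(x) {
    if (is.list(x)) return(lapply(unclass(x), strip))
    if (is.numeric(x) || is.character(x) || is.logical(x)) {
      if (length(x) > 1L) as.list(unname(x)) else unname(x)
    } else as.character(x)
  }
  yaml::write_yaml(strip(params), path)
  invisible(path)
}
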