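# Plain-text readers and writers for the AHBA-style triplet, the atlas and
# the auxiliary tables, so that pipelines can run from files on disk.

#' Write / read an AHBA-style expression triplet
#'
#' Writes `Probes.csv` (probe_id, gene_symbol, entrez_id; empty fields for
#' unannotated probes), `SampleAnnot.csv` (sample_id, donor_id, mni_x/y/z)
#' and `MicroarrayExpression.csv` (first column probe_id, remaining
#' columns one per sample) into a directory; `read_ahba_triplet` loads
#' them back into the in-memory layout used by the pipeline.
#'
#' @param dataset List with `probes`, `samples`, `expression` (as produced
#'   by [generate_expression_dataset()]; `truth` is not written).
#' @param dir Directory (created if missing).
#' @return The directory path (write) or a list with probes, samples,
#'   expression (read).
#' @export
write_ahba_triplet <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$probes, file.path(dir, "Probes.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$samples, file.path(dir, "SampleAnnot.csv"),
                   row.names = FALSE)
  expr <- data.frame(probe_id = rownames(dataset$expression),
                     dataset$expression, check.names = FALSE)
  utils::write.csv(expr, file.path(dir, "MicroarrayExpression.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_ahba_triplet
#' @export
read_ahba_triplet <- function(dir) {
  probes <- utils::read.csv(file.path(dir, "Probes.csv"),
                            colClasses = "character")
  samples <- utils::read.csv(file.path(dir, "SampleAnnot.csv"))
  raw <- utils::read.csv(file.path(dir, "MicroarrayExpression.csv"),
                         check.names = FALSE)
  expr <- as.matrix(raw[, -1, drop = FALSE])
  rownames(expr) <- raw[[1]]
  list(probes = probes, samples = samples, expression = expr)
}

#' Write / read a cROI atlas as TSV
#'
#' The atlas is stored as two tab-separated files: `atlas.tsv` with one
#' row per region (roi_label, rank, centroid coordinates) and
#' `atlas_points.tsv` with the spatial representatives.
#'
#' @param atlas A `croi_atlas`.
#' @param dir Directory.
#' @return The directory (write) or a `croi_atlas` (read).
#' @export
write_atlas_tsv <- function(atlas, dir) {
  stopifnot(inherits(atlas, "croi_atlas"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(atlas$regions, file.path(dir, "atlas.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(atlas$points, file.path(dir, "atlas_points.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_atlas_tsv
#' @export
read_atlas_tsv <- function(dir) {
  regions <- utils::read.delim(file.path(dir, "atlas.tsv"))
  points <- utils::read.delim(file.path(dir, "atlas_points.tsv"))
  # truncation radius is recomputed from the stored geometry
  cent <- as.matrix(regions[, c("centroid_x", "centroid_y", "centroid_z")])
  offs <- as.matrix(points[, c("x", "y", "z")]) -
    cent[match(points$roi_label, regions$roi_label), , drop = FALSE]
  structure(list(regions = regions, points = points,
                 trunc_radius_mm = max(sqrt(rowSums(offs^2)))),
            class = "croi_atlas")
}
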