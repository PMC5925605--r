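#' @name io
#' @title Tab-separated and JSON artifact formats
#' @description
#' Every pipeline stage communicates through plain-text artifacts: the
#' manifest, sample sheet, DMP table and segment tables as TSV; signal and
#' beta matrices as wide TSV with a `probe_id` first column; the truth set
#' and the fitted panel model as JSON. All writers round-trip through the
#' matching readers.
NULL

#' @rdname io
#' @param x object to write (see details per function).
#' @param path file path.
#' @export
write_table_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname io
#' @export
read_table_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
}

#' @rdname io
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.table::data.table(probe_id = rownames(x), as.data.frame(x))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_matrix_tsv <- function(path) {
  df <- data.table::fread(path, sep = "\t")
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}

#' @rdname io
#' @param signal list of `meth`, `unmeth`, `detection_p` matrices.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @export
write_signal <- function(signal, dir, prefix = "signal") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("meth", "unmeth", "detection_p")) {
    write_matrix_tsv(signal[[nm]], file.path(dir, paste0(prefix, "_", nm, ".tsv")))
  }
  invisible(dir)
}

#' @rdname io
#' @export
read_signal <- function(dir, prefix = "signal") {
  setNames(lapply(c("meth", "unmeth", "detection_p"), function(nm) {
    read_matrix_tsv(file.path(dir, paste0(prefix, "_", nm, ".tsv")))
  }), c("meth", "unmeth", "detection_p"))
}

#' @rdname io
#' @param truth truth set list (`dmp`, `dmr`, `cnv`).
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname io
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(el) {
    if (is.null(el) || length(el) == 0) NULL else as.data.frame(el)
  })
}

#' @rdname io
#' @param regions region table with 1-based inclusive `start`/`end`.
#' @details [write_regions_bed()] converts to BED's 0-based half-open
#'   coordinates; [read_regions_bed()] converts back.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$start - 1L,
                    end = regions$end)
  extra <- setdiff(names(regions), c("chrom", "start", "end"))
  bed <- cbind(bed, regions[, extra, drop = FALSE])
  data.table::fwrite(bed, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_regions_bed <- function(path) {
  bed <- as.data.frame(data.table::fread(path, sep = "\t"))
  bed$start <- bed$start + 1L
  bed
}

#' @rdname io
#' @param model fitted panel model.
#' @param provenance optional list (seed, configuration hash) stamped into
#'   the file.
#' @export
write_panel <- function(model, path, provenance = NULL) {
  payload <- list(
    probe_ids = model$probe_ids,
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    lambda = model$lambda,
    standardization = model$standardization,
    threshold = model$threshold,
    provenance = provenance
  )
  jsonlite::write_json(payload, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname io
#' @export
read_panel <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    probe_ids = raw$probe_ids,
    intercept = raw$intercept,
    coefficients = setNames(unlist(raw$coefficients), names(raw$coefficients)),
    lambda = raw$lambda,
    standardization = as.data.frame(raw$standardization),
    threshold = raw$threshold,
    provenance = raw$provenance
  ), class = "panel_model")
}
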