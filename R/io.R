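# File I/O: TSV (0-based vertex indexing on disk), ASCII GIFTI, FreeSurfer
# .annot. All writers and readers are exact inverses on valid inputs; numeric
# TSV cells are printed with 17 significant digits so doubles round-trip
# bit-identically.

fmt_num <- function(x) sprintf("%.17g", x)

#' Read a vertex-by-timepoint time-series matrix
#'
#' Supported formats: `tsv` (comment header `#key<TAB>value` lines carrying
#' TR and identifiers, then a header row `vertex_index t1 ... tT` with
#' 0-based vertex indices) and ASCII `gifti` (`.func.gii`, one DataArray per
#' timepoint).
#'
#' @param path input file.
#' @param format `"tsv"` or `"gifti"`; guessed from the extension by default.
#' @return An [timeseries_matrix()] (`fc_timeseries`).
#' @export
read_timeseries <- function(path, format = guess_format(path)) {
  if (!file.exists(path)) {
    fc_abort(sprintf("cannot read time series: no such file '%s'", path),
             "fcparc_io_error")
  }
  switch(match.arg(format, c("tsv", "gifti")),
    tsv = read_timeseries_tsv(path),
    gifti = read_timeseries_gifti(path)
  )
}

guess_format <- function(path) {
  if (grepl("\\.gii$", path)) "gifti" else if (grepl("\\.annot$", path)) "annot" else "tsv"
}

#' Write a time-series matrix
#'
#' @param ts an `fc_timeseries`.
#' @param path output file.
#' @param format `"tsv"` or `"gifti"`.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path, format = guess_format(path)) {
  switch(match.arg(format, c("tsv", "gifti")),
    tsv = write_timeseries_tsv(ts, path),
    gifti = write_timeseries_gifti(ts, path)
  )
  invisible(path)
}

write_timeseries_tsv <- function(ts, path) {
  m <- ts_meta(ts)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    sprintf("#tr_seconds\t%s", fmt_num(m$tr_seconds)),
    sprintf("#subject_id\t%s", m$subject_id),
    sprintf("#session_id\t%s", m$session_id),
    sprintf("#run_id\t%s", m$run_id),
    paste(c("vertex_index", paste0("t", seq_len(ncol(ts)))), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(ts)), function(i) {
    paste(c(as.character(i - 1L), fmt_num(ts[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), con, sep = "\n")
}

read_timeseries_tsv <- function(path) {
  lines <- readLines(path)
  meta <- list(tr_seconds = 1, subject_id = NA, session_id = NA, run_id = NA)
  is_meta <- startsWith(lines, "#")
  for (l in lines[is_meta]) {
    kv <- strsplit(sub("^#", "", l), "\t", fixed = TRUE)[[1]]
    if (length(kv) == 2 && kv[1] %in% names(meta)) meta[[kv[1]]] <- kv[2]
  }
  body <- lines[!is_meta]
  if (length(body) < 2) {
    fc_abort(sprintf("'%s': no data rows", path), "fcparc_io_error")
  }
  cells <- strsplit(body[-1], "\t", fixed = TRUE)
  ncells <- lengths(cells)
  if (length(unique(ncells)) != 1L) {
    fc_abort(sprintf("'%s': ragged rows", path), "fcparc_io_error")
  }
  mat <- matrix(unlist(cells), nrow = length(cells), byrow = TRUE)
  num <- suppressWarnings(array(as.numeric(mat), dim(mat)))
  bad <- which(is.na(num) & mat != "NA", arr.ind = TRUE)
  if (nrow(bad) > 0) {
    fc_abort(
      sprintf("'%s': non-numeric cell at data row %d, column %d ('%s')",
              path, bad[1, 1], bad[1, 2], mat[bad[1, 1], bad[1, 2]]),
      "fcparc_parse_error"
    )
  }
  ord <- order(num[, 1])
  timeseries_matrix(
    num[ord, -1, drop = FALSE],
    tr_seconds = as.numeric(meta$tr_seconds),
    subject_id = meta$subject_id, session_id = meta$session_id,
    run_id = meta$run_id
  )
}

# --- minimal ASCII GIFTI ----------------------------------------------------

gifti_header <- function(n_arrays) {
  c('<?xml version="1.0" encoding="UTF-8"?>',
    '<!DOCTYPE GIFTI SYSTEM "http://www.nitrc.org/frs/download.php/115/gifti.dtd">',
    sprintf('<GIFTI Version="1.0" NumberOfDataArrays="%d">', n_arrays))
}

gifti_data_array <- function(values, intent, datatype, dims) {
  dim_attrs <- paste(
    sprintf('Dim%d="%d"', seq_along(dims) - 1L, dims),
    collapse = " "
  )
  c(sprintf(
      paste0('<DataArray Intent="%s" DataType="%s" ArrayIndexingOrder=',
             '"RowMajorOrder" Dimensionality="%d" %s Encoding="ASCII" ',
             'Endian="LittleEndian" ExternalFileName="" ExternalFileOffset="">'),
      intent, datatype, length(dims), dim_attrs),
    "<Data>",
    paste(values, collapse = " "),
    "</Data>",
    "</DataArray>")
}

write_timeseries_gifti <- function(ts, path) {
  m <- ts_meta(ts)
  lines <- c(
    gifti_header(ncol(ts)),
    "<MetaData>",
    sprintf("<MD><Name>TimeStep</Name><Value>%s</Value></MD>", fmt_num(m$tr_seconds)),
    sprintf("<MD><Name>SubjectID</Name><Value>%s</Value></MD>", m$subject_id),
    sprintf("<MD><Name>SessionID</Name><Value>%s</Value></MD>", m$session_id),
    sprintf("<MD><Name>RunID</Name><Value>%s</Value></MD>", m$run_id),
    "</MetaData>"
  )
  for (t in seq_len(ncol(ts))) {
    lines <- c(lines, gifti_data_array(
      fmt_num(ts[, t]), "NIFTI_INTENT_TIME_SERIES", "NIFTI_TYPE_FLOAT64",
      nrow(ts)
    ))
  }
  writeLines(c(lines, "</GIFTI>"), path)
}

read_timeseries_gifti <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  if (length(arrays) == 0) {
    fc_abort(sprintf("'%s': GIFTI file has no DataArray", path), "fcparc_io_error")
  }
  enc <- xml2::xml_attr(arrays, "Encoding")
  if (!all(enc == "ASCII")) {
    fc_abort(sprintf("'%s': only ASCII GIFTI encoding is supported", path),
             "fcparc_io_error")
  }
  cols <- lapply(arrays, function(a) {
    txt <- xml2::xml_text(xml2::xml_find_first(a, "./Data"))
    as.numeric(strsplit(trimws(txt), "\\s+")[[1]])
  })
  md <- gifti_metadata(doc)
  timeseries_matrix(
    do.call(cbind, cols),
    tr_seconds = as.numeric(md[["TimeStep"]] %||% 1),
    subject_id = md[["SubjectID"]] %||% NA_character_,
    session_id = md[["SessionID"]] %||% NA_character_,
    run_id = md[["RunID"]] %||% NA_character_
  )
}

gifti_metadata <- function(doc) {
  mds <- xml2::xml_find_all(doc, "./MetaData/MD")
  vals <- xml2::xml_text(xml2::xml_find_first(mds, "./Value"))
  stats::setNames(as.list(vals), xml2::xml_text(xml2::xml_find_first(mds, "./Name")))
}

#' Write / read a surface mesh as ASCII GIFTI
#'
#' Writes pointset and triangle arrays (`.surf.gii`); the ROI mask is stored
#' as a shape array so the mesh round-trips completely.
#'
#' @param mesh a [surface_mesh()].
#' @param path file path.
#' @return `write_mesh`: `path` invisibly; `read_mesh`: a `surface_mesh`.
#' @export
write_mesh <- function(mesh, path) {
  lines <- c(
    gifti_header(3L),
    gifti_data_array(fmt_num(t(mesh$coords)), "NIFTI_INTENT_POINTSET",
                     "NIFTI_TYPE_FLOAT64", c(nrow(mesh$coords), 3L)),
    gifti_data_array(as.character(t(mesh$triangles) - 1L),
                     "NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32",
                     c(nrow(mesh$triangles), 3L)),
    gifti_data_array(as.character(as.integer(mesh$roi_mask)),
                     "NIFTI_INTENT_SHAPE", "NIFTI_TYPE_INT32",
                     nrow(mesh$coords)),
    "</GIFTI>"
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  get_arr <- function(intent) {
    hit <- arrays[xml2::xml_attr(arrays, "Intent") == intent]
    if (length(hit) == 0) {
      fc_abort(sprintf("'%s': missing %s array", path, intent), "fcparc_io_error")
    }
    a <- hit[[1]]
    txt <- xml2::xml_text(xml2::xml_find_first(a, "./Data"))
    vals <- as.numeric(strsplit(trimws(txt), "\\s+")[[1]])
    d0 <- as.integer(xml2::xml_attr(a, "Dim0"))
    ncol <- length(vals) / d0
    matrix(vals, nrow = d0, ncol = ncol, byrow = TRUE)
  }
  coords <- get_arr("NIFTI_INTENT_POINTSET")
  tri <- get_arr("NIFTI_INTENT_TRIANGLE") + 1L
  roi <- as.logical(get_arr("NIFTI_INTENT_SHAPE")[, 1])
  surface_mesh(coords, tri, roi_mask = roi)
}

# --- parcellation I/O -------------------------------------------------------

#' Write / read a parcellation
#'
#' TSV dialect: two columns `vertex_index` (0-based mesh index) and `label`,
#' with a header row; only ROI vertices appear. The FreeSurfer `.annot`
#' export covers the full surface with label 0 ("unknown") outside the ROI
#' and a generated color table.
#'
#' @param parc an [parcellation()] object.
#' @param path file path.
#' @param format `"tsv"` or `"annot"`; guessed from the extension by default.
#' @param level parcellation level to stamp on read (`"group"` or
#'   `"individual"`).
#' @return `write_parcellation`: `path` invisibly; `read_parcellation`: an
#'   `fc_parcellation`.
#' @export
write_parcellation <- function(parc, path, format = guess_format(path)) {
  switch(match.arg(format, c("tsv", "annot")),
    tsv = {
      writeLines(c(
        "vertex_index\tlabel",
        sprintf("%d\t%d", parc$roi_vertices - 1L, parc$labels)
      ), path)
    },
    annot = write_annot(parc, path)
  )
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path, format = guess_format(path),
                              level = "group") {
  if (!file.exists(path)) {
    fc_abort(sprintf("cannot read parcellation: no such file '%s'", path),
             "fcparc_io_error")
  }
  switch(match.arg(format, c("tsv", "annot")),
    tsv = {
      df <- utils::read.delim(path, sep = "\t")
      if (!identical(names(df), c("vertex_index", "label"))) {
        fc_abort(sprintf("'%s': expected columns vertex_index, label", path),
                 "fcparc_parse_error")
      }
      if (any(df$label < 1L)) {
        fc_abort(sprintf("'%s': labels must be >= 1 (0 is reserved)", path),
                 "fcparc_validation_error")
      }
      parcellation(df$label, df$vertex_index + 1L, k = max(df$label),
                   level = level, provenance = sprintf("read from %s", path))
    },
    annot = read_annot(path, level = level)
  )
}

annot_color <- function(label) {
  # distinct RGB per label; code = R + G*256 + B*65536 must be unique
  cbind(r = label %% 256L, g = (label %/% 256L) %% 256L, b = label %/% 65536L)
}

write_annot <- function(parc, path) {
  nv <- parc$n_vertices_total
  full <- integer(nv)
  full[parc$roi_vertices] <- parc$labels
  cols <- annot_color(0:parc$k)
  codes <- cols[, "r"] + cols[, "g"] * 256L + cols[, "b"] * 65536L
  vert_codes <- codes[full + 1L]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(nv), con, size = 4, endian = "big")
  inter <- integer(2L * nv)
  inter[seq(1, 2 * nv, by = 2)] <- 0:(nv - 1L)
  inter[seq(2, 2 * nv, by = 2)] <- vert_codes
  writeBin(as.integer(inter), con, size = 4, endian = "big")
  writeBin(1L, con, size = 4, endian = "big")          # TAG_OLD_COLORTABLE
  writeBin(-2L, con, size = 4, endian = "big")         # ctab version 2
  writeBin(parc$k + 1L, con, size = 4, endian = "big") # max entries
  fname <- "fcparc.ctab"
  writeBin(nchar(fname) + 1L, con, size = 4, endian = "big")
  writeChar(fname, con, eos = NULL)
  writeBin(0L, con, size = 1)
  writeBin(parc$k + 1L, con, size = 4, endian = "big") # entry count
  names <- c("unknown", sprintf("network_%d", seq_len(parc$k)))
  for (i in 0:parc$k) {
    writeBin(as.integer(i), con, size = 4, endian = "big")
    nm <- names[i + 1L]
    writeBin(nchar(nm) + 1L, con, size = 4, endian = "big")
    writeChar(nm, con, eos = NULL)
    writeBin(0L, con, size = 1)
    writeBin(as.integer(c(cols[i + 1L, ], 0L)), con, size = 4, endian = "big")
  }
}

read_annot <- function(path, level = "group") {
  con <- file(path, "rb")
  on.exit(close(con))
  nv <- readBin(con, integer(), 1, size = 4, endian = "big")
  inter <- readBin(con, integer(), 2L * nv, size = 4, endian = "big")
  vert_codes <- inter[seq(2, 2 * nv, by = 2)]
  tag <- readBin(con, integer(), 1, size = 4, endian = "big")
  if (length(tag) == 0 || tag != 1L) {
    fc_abort(sprintf("'%s': missing color table", path), "fcparc_parse_error")
  }
  version <- readBin(con, integer(), 1, size = 4, endian = "big")
  if (version != -2L) {
    fc_abort(sprintf("'%s': unsupported annot color-table version", path),
             "fcparc_parse_error")
  }
  readBin(con, integer(), 1, size = 4, endian = "big") # max entries
  fn_len <- readBin(con, integer(), 1, size = 4, endian = "big")
  readBin(con, raw(), fn_len)
  n_entries <- readBin(con, integer(), 1, size = 4, endian = "big")
  entry_codes <- integer(n_entries)
  entry_struct <- integer(n_entries)
  for (i in seq_len(n_entries)) {
    entry_struct[i] <- readBin(con, integer(), 1, size = 4, endian = "big")
    nm_len <- readBin(con, integer(), 1, size = 4, endian = "big")
    readBin(con, raw(), nm_len)
    rgbt <- readBin(con, integer(), 4, size = 4, endian = "big")
    entry_codes[i] <- rgbt[1] + rgbt[2] * 256L + rgbt[3] * 65536L
  }
  lab_full <- entry_struct[match(vert_codes, entry_codes)]
  if (anyNA(lab_full)) {
    fc_abort(sprintf("'%s': vertex annotation code missing from color table", path),
             "fcparc_parse_error")
  }
  roi <- which(lab_full != 0L)
  parcellation(lab_full[roi], roi, k = max(lab_full), n_vertices_total = nv,
               level = level, provenance = sprintf("read from %s", path))
}

# --- small tabular helpers shared by the CLI --------------------------------

write_similarity_tsv <- function(sim, path) {
  lines <- c(
    paste(c("subject", sim$subject_ids), collapse = "\t"),
    vapply(seq_along(sim$subject_ids), function(i) {
      paste(c(sim$subject_ids[i], fmt_num(sim$values[i, ])), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

read_similarity_tsv <- function(path, metric_name = "similarity") {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  similarity_matrix(m, metric_name, subject_ids = df[[1]])
}
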