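# GIFTI surface-data input/output and the in-memory containers for per-vertex
# signals and label maps. Only the GIFTI subset needed for surface metrics,
# label maps and sphere meshes is supported: DataArray encodings ASCII,
# Base64Binary and GZipBase64Binary (little-endian), written as ASCII so the
# files stay plain text. Vertex ids are 0-based, matching GIFTI arrays.

#' Per-vertex multi-channel surface signal
#'
#' @param values `|V| x C` numeric matrix, one column per channel.
#' @param channel_names Character vector of length `C` (defaults to
#'   `channel1..channelC`).
#' @param mesh_order Icosphere order the signal lives on, or `"native"`.
#' @return An object of class `surface_signal`.
#' @export
surface_signal <- function(values, channel_names = NULL, mesh_order = "native") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) < 1L) stop("a surface signal needs at least one channel")
  if (any(!is.finite(values)))
    stop(sprintf("surface signal contains %d non-finite values",
                 sum(!is.finite(values))))
  if (is.null(channel_names)) channel_names <- paste0("channel", seq_len(ncol(values)))
  if (length(channel_names) != ncol(values))
    stop("`channel_names` length must equal the number of channels")
  out <- list(values = values, channel_names = as.character(channel_names),
              mesh_order = mesh_order)
  class(out) <- "surface_signal"
  out
}

#' @export
print.surface_signal <- function(x, ...) {
  cat(sprintf("surface_signal: %d vertices x %d channels (%s), mesh order %s\n",
              nrow(x$values), ncol(x$values),
              paste(x$channel_names, collapse = ", "),
              as.character(x$mesh_order)))
  invisible(x)
}

#' Per-vertex label map with a label table
#'
#' @param labels Length-`|V|` integer vector of non-negative label ids.
#' @param label_table Data frame with columns `id`, `name`, `colour` covering
#'   every id present in `labels` (ids with no vertices are allowed).
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, label_table = NULL) {
  labels <- as.integer(labels)
  if (any(is.na(labels)) || any(labels < 0))
    stop("labels must be non-negative integers")
  if (is.null(label_table)) {
    ids <- sort(unique(labels))
    label_table <- data.frame(id = ids, name = paste0("region_", ids),
                              colour = grDevices::hcl(
                                h = (ids * 137.5) %% 360, c = 60, l = 65),
                              stringsAsFactors = FALSE)
  }
  missing <- setdiff(unique(labels), label_table$id)
  if (length(missing) > 0)
    stop(sprintf("label ids not in label table: %s",
                 paste(missing, collapse = ", ")))
  out <- list(labels = labels, label_table = label_table)
  class(out) <- "label_map"
  out
}

# ---- low-level GIFTI plumbing ----------------------------------------------

# GIFTI files in the wild may or may not carry a namespace; strip it on read
.gii_read_root <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop(sprintf("cannot read GIFTI file '%s': %s", path, conditionMessage(e))))
  xml2::xml_ns_strip(doc)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "GIFTI")
    stop(sprintf("'%s' is not a GIFTI file (root element <%s>)",
                 path, xml2::xml_name(root)))
  root
}

.gii_arrays <- function(root, intent = NULL) {
  arr <- xml2::xml_find_all(root, "./DataArray")
  if (!is.null(intent)) {
    keep <- xml2::xml_attr(arr, "Intent") %in% intent
    arr <- arr[keep]
  }
  arr
}

.gii_array_name <- function(node) {
  mds <- xml2::xml_find_all(node, "./MetaData/MD")
  for (md in mds) {
    nm <- xml2::xml_text(xml2::xml_find_first(md, "./Name"))
    if (identical(nm, "Name"))
      return(xml2::xml_text(xml2::xml_find_first(md, "./Value")))
  }
  NA_character_
}

.gii_decode_array <- function(node) {
  enc <- xml2::xml_attr(node, "Encoding")
  dtype <- xml2::xml_attr(node, "DataType")
  dims <- vapply(paste0("Dim", 0:5), function(a)
    suppressWarnings(as.integer(xml2::xml_attr(node, a))), integer(1))
  dims <- dims[!is.na(dims)]
  n <- prod(dims)
  data_node <- xml2::xml_find_first(node, "./Data")
  txt <- xml2::xml_text(data_node)
  if (is.na(txt) || !nzchar(trimws(txt)))
    stop("GIFTI DataArray has no <Data> content")
  if (enc == "ASCII") {
    vals <- scan(text = txt, quiet = TRUE)
  } else if (enc %in% c("Base64Binary", "GZipBase64Binary")) {
    raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", txt))
    if (enc == "GZipBase64Binary") raw <- memDecompress(raw, type = "gzip")
    size <- switch(dtype,
                   NIFTI_TYPE_FLOAT32 = 4L, NIFTI_TYPE_FLOAT64 = 8L,
                   NIFTI_TYPE_INT32 = 4L, NIFTI_TYPE_UINT8 = 1L,
                   stop(sprintf("unsupported GIFTI data type: %s", dtype)))
    what <- if (dtype %in% c("NIFTI_TYPE_INT32", "NIFTI_TYPE_UINT8"))
      "integer" else "double"
    vals <- readBin(raw, what = what, n = n, size = size, endian = "little")
  } else stop(sprintf("unsupported GIFTI encoding: %s", enc))
  if (length(vals) != n)
    stop(sprintf("GIFTI DataArray length %d does not match declared dims (%d)",
                 length(vals), n))
  if (length(dims) == 2L) {
    ord <- xml2::xml_attr(node, "ArrayIndexingOrder")
    if (identical(ord, "ColumnMajorOrder")) matrix(vals, dims[1], dims[2])
    else matrix(vals, dims[1], dims[2], byrow = TRUE)
  } else vals
}

.gii_format_values <- function(x) {
  paste(formatC(x, format = "g", digits = 9), collapse = " ")
}

.gii_data_array_xml <- function(values, intent, dtype, name = NULL,
                                extra_attrs = "") {
  if (is.matrix(values)) {
    dim_attr <- sprintf('Dimensionality="2" Dim0="%d" Dim1="%d"',
                        nrow(values), ncol(values))
    flat <- as.vector(t(values))    # RowMajorOrder
  } else {
    dim_attr <- sprintf('Dimensionality="1" Dim0="%d"', length(values))
    flat <- values
  }
  body <- if (dtype == "NIFTI_TYPE_INT32")
    paste(format(as.integer(flat), scientific = FALSE, trim = TRUE),
          collapse = " ")
  else .gii_format_values(flat)
  meta <- if (!is.null(name))
    sprintf("<MetaData><MD><Name><![CDATA[Name]]></Name><Value><![CDATA[%s]]></Value></MD></MetaData>",
            name)
  else "<MetaData/>"
  sprintf(paste0(
    '<DataArray Intent="%s" DataType="%s" ArrayIndexingOrder="RowMajorOrder" ',
    '%s Encoding="ASCII" Endian="LittleEndian" ',
    'ExternalFileName="" ExternalFileOffset=""%s>\n%s\n<Data>%s</Data>\n</DataArray>'),
    intent, dtype, dim_attr, extra_attrs, meta, body)
}

.gii_write <- function(path, arrays_xml, label_table_xml = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<!DOCTYPE GIFTI SYSTEM "http://www.nitrc.org/frs/download.php/115/gifti.dtd">',
    sprintf('<GIFTI Version="1.0" NumberOfDataArrays="%d">', length(arrays_xml)),
    '<MetaData/>',
    label_table_xml,
    arrays_xml,
    '</GIFTI>'), con)
  invisible(path)
}

# ---- metrics ----------------------------------------------------------------

#' Read a surface metric file
#'
#' Reads a GIFTI metric file (`.shape.gii`/`.func.gii`; one DataArray per
#' channel) or, as a fallback, a delimited text file (csv/tsv, one column per
#' channel, optional header).
#'
#' @param path Input file.
#' @param expected_vertices If given, the vertex count must match.
#' @return A [surface_signal()]. The mesh order is inferred from the vertex
#'   count when it matches an icosphere (`10 * 4^k + 2`), otherwise `"native"`.
#' @export
read_metric <- function(path, expected_vertices = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read metric file '%s'", path))
  if (grepl("\\.gii$", path, ignore.case = TRUE)) {
    root <- .gii_read_root(path)
    arr <- .gii_arrays(root)
    arr <- arr[!(xml2::xml_attr(arr, "Intent") %in%
                   c("NIFTI_INTENT_POINTSET", "NIFTI_INTENT_TRIANGLE",
                     "NIFTI_INTENT_LABEL"))]
    if (length(arr) == 0) stop(sprintf("no metric data arrays in '%s'", path))
    cols <- lapply(arr, .gii_decode_array)
    if (any(vapply(cols, is.matrix, logical(1))))
      cols <- unlist(lapply(cols, function(m)
        if (is.matrix(m)) asplit(m, 2) else list(m)), recursive = FALSE)
    nv <- unique(vapply(cols, length, integer(1)))
    if (length(nv) != 1)
      stop("metric data arrays disagree on vertex count")
    values <- do.call(cbind, cols)
    nms <- vapply(arr, .gii_array_name, character(1))
    if (any(is.na(nms))) nms[is.na(nms)] <- paste0("channel", which(is.na(nms)))
  } else {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    first <- readLines(path, n = 1L)
    has_header <- suppressWarnings(any(is.na(as.numeric(
      strsplit(first, sep, fixed = TRUE)[[1]]))))
    df <- utils::read.table(path, sep = sep, header = has_header)
    values <- as.matrix(df)
    nms <- if (has_header) colnames(df) else paste0("channel", seq_len(ncol(df)))
  }
  if (!is.null(expected_vertices) && nrow(values) != expected_vertices)
    stop(sprintf("'%s' has %d vertices but %d were expected",
                 path, nrow(values), expected_vertices))
  surface_signal(values, nms, mesh_order = .infer_mesh_order(nrow(values)))
}

.infer_mesh_order <- function(n_vertices) {
  for (k in 0:8) if (n_vertices == 10 * 4^k + 2) return(k)
  "native"
}

#' Write a surface metric file (GIFTI, ASCII encoding)
#'
#' @param signal A [surface_signal()].
#' @param path Output `.shape.gii`/`.func.gii` path.
#' @return `path`, invisibly.
#' @export
write_metric <- function(signal, path) {
  stopifnot(inherits(signal, "surface_signal"))
  arrays <- vapply(seq_len(ncol(signal$values)), function(j)
    .gii_data_array_xml(signal$values[, j], "NIFTI_INTENT_SHAPE",
                        "NIFTI_TYPE_FLOAT32", name = signal$channel_names[j]),
    character(1))
  .gii_write(path, arrays)
  invisible(path)
}

# ---- labels -----------------------------------------------------------------

#' Read a GIFTI label file
#'
#' @param path A `.label.gii` file with a LabelTable.
#' @return A [label_map()].
#' @export
read_labels <- function(path) {
  root <- .gii_read_root(path)
  lt_node <- xml2::xml_find_first(root, "./LabelTable")
  if (inherits(lt_node, "xml_missing") ||
      length(xml2::xml_find_all(lt_node, "./Label")) == 0)
    stop(sprintf("'%s' has no label table", path))
  labs <- xml2::xml_find_all(lt_node, "./Label")
  label_table <- data.frame(
    id = as.integer(xml2::xml_attr(labs, "Key")),
    name = xml2::xml_text(labs),
    colour = grDevices::rgb(
      .attr_num(labs, "Red"), .attr_num(labs, "Green"), .attr_num(labs, "Blue")),
    stringsAsFactors = FALSE
  )
  arr <- .gii_arrays(root, intent = "NIFTI_INTENT_LABEL")
  if (length(arr) == 0) stop(sprintf("no label data array in '%s'", path))
  labels <- as.integer(.gii_decode_array(arr[[1]]))
  label_map(labels, label_table)
}

.attr_num <- function(nodes, name) {
  x <- suppressWarnings(as.numeric(xml2::xml_attr(nodes, name)))
  x[is.na(x)] <- 0
  pmin(pmax(x, 0), 1)
}

#' Write a GIFTI label file
#'
#' @param map A [label_map()].
#' @param path Output `.label.gii` path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(map, path) {
  stopifnot(inherits(map, "label_map"))
  lt <- map$label_table
  rgb <- grDevices::col2rgb(lt$colour) / 255
  rows <- sprintf(
    '<Label Key="%d" Red="%.6f" Green="%.6f" Blue="%.6f" Alpha="1"><![CDATA[%s]]></Label>',
    lt$id, rgb[1, ], rgb[2, ], rgb[3, ], lt$name)
  lt_xml <- paste0("<LabelTable>\n", paste(rows, collapse = "\n"),
                   "\n</LabelTable>")
  arr <- .gii_data_array_xml(map$labels, "NIFTI_INTENT_LABEL",
                             "NIFTI_TYPE_INT32")
  .gii_write(path, arr, lt_xml)
  invisible(path)
}

# ---- surfaces ---------------------------------------------------------------

#' Read a GIFTI surface geometry file
#'
#' @param path A `.surf.gii` file with POINTSET and TRIANGLE arrays.
#' @return A mesh list with `vertices` (`|V| x 3`) and `faces` (`|F| x 3`,
#'   0-based); carries class `icosphere` semantics only when counts match.
#' @export
read_surface <- function(path) {
  root <- .gii_read_root(path)
  pts <- .gii_arrays(root, "NIFTI_INTENT_POINTSET")
  tri <- .gii_arrays(root, "NIFTI_INTENT_TRIANGLE")
  if (length(pts) == 0 || length(tri) == 0)
    stop(sprintf("'%s' lacks POINTSET/TRIANGLE arrays", path))
  v <- .gii_decode_array(pts[[1]])
  f <- .gii_decode_array(tri[[1]])
  storage.mode(f) <- "integer"
  list(vertices = v, faces = f)
}

#' Write a GIFTI surface geometry file
#'
#' @param mesh A mesh list with `vertices` and 0-based `faces` (e.g. an
#'   [build_icosphere()] result).
#' @param path Output `.surf.gii` path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(mesh, path) {
  arrays <- c(
    .gii_data_array_xml(mesh$vertices, "NIFTI_INTENT_POINTSET",
                        "NIFTI_TYPE_FLOAT32"),
    .gii_data_array_xml(mesh$faces, "NIFTI_INTENT_TRIANGLE",
                        "NIFTI_TYPE_INT32"))
  .gii_write(path, arrays)
  invisible(path)
}

#' Read a dataset manifest
#'
#' A manifest is a CSV with columns `subject_id`, `metric_path`, and either
#' `target` (regression) or `label_path` (segmentation); an optional `split`
#' column with values `train`/`val` fixes the split. Relative paths are
#' resolved against the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @return A data frame with absolute paths.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "metric_path") %in% names(df)))
    stop("manifest must have columns subject_id and metric_path")
  if (!("target" %in% names(df)) && !("label_path" %in% names(df)))
    stop("manifest must have a `target` or `label_path` column")
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  df$metric_path <- fix(df$metric_path)
  if ("label_path" %in% names(df)) df$label_path <- fix(df$label_path)
  df
}
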