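# Delimited-table I/O for content tables and expression matrices.
# Content tables are long/tidy (element, tissue, daf, replicate, value, unit);
# expression matrices are wide gene x sample TSV with headers "<daf>DAF_r<rep>".

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("schema error: file not found: ", path, call. = FALSE)
  if (file.info(path)$size == 0) {
    stop("schema error: empty file: ", path, call. = FALSE)
  }
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "", quote = "\"")
}

#' Read a tidy element-content table
#'
#' Reads a long-format CSV/TSV with columns `element`, `tissue`, `daf`,
#' `replicate`, `value`, `unit` and returns one [grain_series()] per
#' (element, tissue) pair.  Sampling times must belong to the study design
#' and every element must use a single unit.
#'
#' @param path Path to a delimited table (`.csv` comma, `.tsv`/`.txt` tab).
#' @param design A [study_design()] used to validate DAF values.
#' @return Named list of `grain_series`, names `"element:tissue"`.
#' @export
read_content_table <- function(path, design) {
  stopifnot(inherits(design, "study_design"))
  tab <- read_delim_auto(path)
  need <- c("element", "tissue", "daf", "replicate", "value", "unit")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("schema error: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tab) == 0L) stop("schema error: table has no rows", call. = FALSE)
  bad_daf <- setdiff(unique(tab$daf), design$time_points)
  if (length(bad_daf)) {
    stop("validation error: DAF value(s) not in study design: ",
         paste(bad_daf, collapse = ", "), call. = FALSE)
  }
  tab$unit <- normalize_unit(tab$unit)
  key <- paste(tab$element, tab$tissue, sep = ":")
  out <- lapply(split(tab, key), function(d) {
    u <- unique(d$unit)
    if (length(u) > 1L) {
      stop("unit error: mixed units for element '", d$element[1], "': ",
           paste(u, collapse = ", "), call. = FALSE)
    }
    grain_series(d$element[1], d$tissue[1], u, d[c("daf", "replicate", "value")])
  })
  # mixed units across tissues of one element are also an error
  for (el in unique(tab$element)) {
    u <- unique(tab$unit[tab$element == el])
    if (length(u) > 1L) {
      stop("unit error: mixed units for element '", el, "': ",
           paste(u, collapse = ", "), call. = FALSE)
    }
  }
  out[order(names(out))]
}

#' Write a collection of content series as a tidy table
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces doubles exactly.
#'
#' @param series A `grain_series` or list of them.
#' @param path Output path (`.csv` comma, `.tsv` tab).
#' @export
write_content_table <- function(series, path) {
  if (inherits(series, "grain_series")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    data.frame(element = s$element, tissue = s$tissue,
               daf = s$observations$daf, replicate = s$observations$replicate,
               value = sprintf("%.17g", s$observations$value), unit = s$unit,
               stringsAsFactors = FALSE)
  }))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(rows, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

parse_sample_headers <- function(headers) {
  m <- regmatches(headers, regexec("^([0-9]+)DAF_r([0-9]+)$", headers))
  bad <- headers[vapply(m, length, integer(1)) != 3L]
  if (length(bad)) {
    stop("schema error: unparseable sample header(s): ",
         paste(bad, collapse = ", "), " (expected <daf>DAF_r<rep>)", call. = FALSE)
  }
  data.frame(sample = headers,
             daf = as.integer(vapply(m, `[`, character(1), 2L)),
             replicate = as.integer(vapply(m, `[`, character(1), 3L)),
             stringsAsFactors = FALSE)
}

#' Construct an expression matrix with replicate structure
#'
#' @param fpkm Non-negative numeric matrix, genes in rows, samples in columns
#'   named `<daf>DAF_r<rep>`.
#' @return Object of class `expression_matrix`: the FPKM matrix (columns
#'   ordered by DAF then replicate) plus parsed sample metadata.
#' @export
expression_matrix <- function(fpkm) {
  fpkm <- as.matrix(fpkm)
  if (is.null(rownames(fpkm))) stop("validation error: gene ids required", call. = FALSE)
  if (anyDuplicated(rownames(fpkm))) {
    stop("validation error: duplicate gene_id", call. = FALSE)
  }
  if (anyNA(fpkm) || any(fpkm < 0)) {
    stop("validation error: FPKM values must be non-negative", call. = FALSE)
  }
  meta <- parse_sample_headers(colnames(fpkm))
  ord <- order(meta$daf, meta$replicate)
  structure(list(fpkm = fpkm[, ord, drop = FALSE],
                 samples = meta[ord, , drop = FALSE]),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (%d DAF stages x replicates)\n",
              nrow(x$fpkm), ncol(x$fpkm), length(unique(x$samples$daf))))
  invisible(x)
}

#' Read a gene x sample FPKM matrix from TSV
#'
#' The file must have a `gene_id` column and sample columns named
#' `<daf>DAF_r<rep>`.  Duplicate gene ids and negative values are rejected.
#'
#' @param path Path to a tab-separated file.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path) {
  tab <- read_delim_auto(path)
  if (!"gene_id" %in% names(tab)) {
    stop("schema error: missing column gene_id", call. = FALSE)
  }
  genes <- as.character(tab$gene_id)
  mat <- as.matrix(tab[setdiff(names(tab), "gene_id")])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  expression_matrix(mat)
}

#' Write an expression matrix as TSV
#'
#' @param em An [expression_matrix()].
#' @param path Output path.
#' @export
write_expression_matrix <- function(em, path) {
  stopifnot(inherits(em, "expression_matrix"))
  out <- data.frame(gene_id = rownames(em$fpkm), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(em$fpkm))) {
    out[[colnames(em$fpkm)[j]]] <- sprintf("%.17g", em$fpkm[, j])
  }
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
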