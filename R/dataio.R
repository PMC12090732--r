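# Readers, writers and validation for count matrices, sample metadata and
# gene -> pathway annotation. All files are tab-separated UTF-8 text; lines
# starting with '#' are comments. Genes that are zero in every sample are
# retained through I/O; stages that must drop them do so explicitly.

ORGANISMS <- c("host", "symA", "symB")
STATUSES <- c("singleA", "singleB", "mixed")

#' Validate a gene-by-sample count matrix
#'
#' Checks uniqueness of gene and sample ids, non-negativity and integrality of
#' counts, and attaches the organism label.
#'
#' @param counts numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene ids) and colnames (sample ids)
#' @param organism one of `"host"`, `"symA"`, `"symB"`
#' @return the validated matrix (integer storage) with attribute `organism`
#' @export
count_matrix <- function(counts, organism = c("host", "symA", "symB")) {
  organism <- match.arg(organism)
  counts <- as.matrix(counts)
  if ((is.null(rownames(counts)) && nrow(counts) > 0L) ||
      is.null(colnames(counts)))
    stop("count matrix must carry gene ids (rownames) and sample ids (colnames)")
  dup_g <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_g))
    stop("duplicated gene_id: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s))
    stop("duplicated sample_id: ", paste(dup_s, collapse = ", "))
  if (anyNA(counts)) stop("count matrix contains missing values")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("negative or non-integer count at gene '", rownames(counts)[bad[1, 1]],
         "', sample '", colnames(counts)[bad[1, 2]], "'")
  }
  storage.mode(counts) <- "integer"
  attr(counts, "organism") <- organism
  counts
}

#' Read a count matrix from TSV
#'
#' Expects a header row `gene_id<TAB>sample...`; `#`-prefixed lines are
#' ignored. The sample order of the file is preserved.
#'
#' @param path file path
#' @inheritParams count_matrix
#' @return validated count matrix (see [count_matrix()])
#' @export
read_counts <- function(path, organism = c("host", "symA", "symB")) {
  organism <- match.arg(organism)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA, fileEncoding = "UTF-8")
  if (ncol(df) < 1L) stop("empty count file: ", path)
  genes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (nrow(df) == 0L) {
    m <- matrix(integer(0), 0L, ncol(df) - 1L,
                dimnames = list(NULL, colnames(df)[-1L]))
  } else {
    rownames(m) <- genes
  }
  if (!is.numeric(m)) stop("non-numeric counts in ", path)
  count_matrix(m, organism)
}

#' Write a count matrix to TSV
#' @param counts gene-by-sample matrix with dimnames
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(counts) == 0L)
    df <- stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = ncol(counts) + 1L)),
      c("gene_id", colnames(counts)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct/validate a sample metadata table
#'
#' @param df data.frame with columns `sample_id`, `culture`, `status`
#'   (one of `"singleA"`, `"singleB"`, `"mixed"`) and integer `replicate`
#' @return validated data.frame
#' @export
sample_table <- function(df) {
  req <- c("sample_id", "culture", "status", "replicate")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("sample table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(df$status), STATUSES)
  if (length(bad)) stop("unknown status value(s): ", paste(bad, collapse = ", "))
  df$replicate <- as.integer(df$replicate)
  df[req]
}

#' @rdname sample_table
#' @param path TSV file path
#' @export
read_sample_table <- function(path) {
  sample_table(utils::read.delim(path, sep = "\t", comment.char = "#",
                                 stringsAsFactors = FALSE,
                                 fileEncoding = "UTF-8"))
}

#' @rdname sample_table
#' @param meta validated sample table
#' @export
write_sample_table <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct/validate a gene annotation map
#'
#' Flat representation of gene -> KEGG ortholog -> pathway: one row per
#' (gene, pathway) assignment. Every pathway id referenced must appear in the
#' pathway-name table.
#'
#' @param df data.frame with columns `gene_id`, `ko` (ortholog id, may be NA),
#'   `pathway_id`, and `pathway_name`
#' @return validated data.frame of class `annotation_map`
#' @export
annotation_map <- function(df) {
  req <- c("gene_id", "ko", "pathway_id", "pathway_name")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("annotation lacks column(s): ", paste(miss, collapse = ", "))
  name_tab <- unique(df[!is.na(df$pathway_id), c("pathway_id", "pathway_name")])
  orphan <- unique(df$pathway_id[!is.na(df$pathway_id) &
                                   is.na(df$pathway_name)])
  if (length(orphan))
    stop("pathway id(s) without a display name: ", paste(orphan, collapse = ", "))
  if (anyDuplicated(name_tab$pathway_id))
    stop("conflicting display names for pathway id(s): ",
         paste(name_tab$pathway_id[duplicated(name_tab$pathway_id)], collapse = ", "))
  out <- df[req]
  class(out) <- c("annotation_map", class(out))
  out
}

#' @rdname annotation_map
#' @param path TSV file path
#' @export
read_annotation <- function(path) {
  annotation_map(utils::read.delim(path, sep = "\t", comment.char = "#",
                                   stringsAsFactors = FALSE,
                                   fileEncoding = "UTF-8"))
}

#' @rdname annotation_map
#' @param ann validated annotation map
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Genes annotated to a pathway
#' @param ann annotation map
#' @param pathway_id pathway identifier
#' @return character vector of gene ids
#' @export
pathway_genes <- function(ann, pathway_id) {
  unique(ann$gene_id[!is.na(ann$pathway_id) & ann$pathway_id == pathway_id])
}

#' Restrict count matrices to their shared samples, in one canonical order
#'
#' The canonical order is the metadata row order restricted to samples present
#' in every matrix; samples missing from the metadata are dropped with a
#' warning. Idempotent.
#'
#' @param matrices named list of count matrices
#' @param meta sample table (see [sample_table()])
#' @return list with elements `matrices` (aligned list) and `meta`
#'   (correspondingly restricted sample table)
#' @export
align_samples <- function(matrices, meta) {
  meta <- sample_table(meta)
  shared <- Reduce(intersect, lapply(matrices, colnames))
  extra <- setdiff(shared, meta$sample_id)
  if (length(extra))
    warning("dropping sample(s) missing from metadata: ",
            paste(extra, collapse = ", "))
  keep <- meta$sample_id[meta$sample_id %in% setdiff(shared, extra)]
  if (!length(keep))
    stop("no shared samples across matrices and metadata")
  out <- lapply(matrices, function(m) {
    org <- attr(m, "organism")
    m <- m[, keep, drop = FALSE]
    attr(m, "organism") <- org
    m
  })
  list(matrices = out, meta = meta[match(keep, meta$sample_id), , drop = FALSE])
}
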