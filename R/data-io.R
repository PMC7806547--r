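# Tabular data model and TSV readers/writers.
#
# A feature table is a base matrix of non-negative integer counts with samples
# as rows and ASVs as columns (unique dimnames on both axes). Metadata and
# phenotype tables are plain data.frames keyed by `sample_id`. These are the
# containers every downstream module consumes.

#' Validate a feature table
#'
#' Checks the count-matrix contract shared by all pipeline stages: a numeric
#' matrix of non-negative integral counts, samples as rows, ASVs as columns,
#' with unique non-empty identifiers on both axes.
#'
#' @param counts A numeric matrix (samples x ASVs).
#' @param min_dim Minimum number of samples and ASVs required (default 1;
#'   statistical operations require 2 and say so themselves).
#' @return The validated matrix, invisibly usable as-is.
#' @export
validate_feature_table <- function(counts, min_dim = 1L) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("feature table must be a numeric matrix (samples x ASVs)", call. = FALSE)
  if (nrow(counts) < min_dim || ncol(counts) < min_dim)
    stop("feature table needs at least ", min_dim, " samples and ", min_dim,
         " ASVs", call. = FALSE)
  if (anyNA(counts)) stop("feature table contains missing values", call. = FALSE)
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at sample '%s', ASV '%s'",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]),
         call. = FALSE)
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer count at sample '%s', ASV '%s'",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]),
         call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("feature table must have sample and ASV identifiers as dimnames",
         call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample identifiers in feature table", call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate ASV identifiers in feature table", call. = FALSE)
  counts
}

#' Read an ASV feature table from TSV
#'
#' Reads a tab-separated count table with one header row and one id column.
#' The QIIME2 export convention (features as rows) is the default orientation;
#' a leading `# Constructed from biom file` line and a `#OTU ID` / `#ASV ID`
#' id-column header are tolerated and stripped.
#'
#' @param path Path to a TSV file.
#' @param orientation `"asvs-as-rows"` (default, QIIME2 convention) or
#'   `"samples-as-rows"`.
#' @return A validated count matrix with samples as rows.
#' @export
read_feature_table <- function(path,
                               orientation = c("asvs-as-rows", "samples-as-rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^# Constructed from biom", lines)]
  if (!length(lines)) stop("empty feature table file: ", path, call. = FALSE)
  df <- utils::read.delim(text = lines, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("feature table must have an id column and at least ",
                          "one data column", call. = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate ids in feature table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                 ids[bad[1L]], colnames(vals)[bad[2L]], vals[bad[1L], bad[2L]]),
         call. = FALSE)
  }
  dimnames(num) <- list(ids, colnames(vals))
  if (orientation == "asvs-as-rows") num <- t(num)
  validate_feature_table(num)
  num <- round(num)
  storage.mode(num) <- "integer"
  num
}

#' Write a feature table to TSV
#'
#' @param counts A feature table (samples x ASVs).
#' @param path Output path.
#' @param orientation Row convention to write; default mirrors the reader.
#' @export
write_feature_table <- function(counts, path,
                                orientation = c("asvs-as-rows", "samples-as-rows")) {
  orientation <- match.arg(orientation)
  m <- if (orientation == "asvs-as-rows") t(counts) else counts
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1L] <- if (orientation == "asvs-as-rows") "asv_id" else "sample_id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_keyed_tsv <- function(path, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          comment.char = "", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (!"sample_id" %in% names(df))
    stop(what, " file must contain a 'sample_id' column: ", path, call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in ", what, " file: ", path, call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Read sample metadata (group / timepoint / cage) from TSV
#'
#' Requires a `sample_id` column; `group`, `timepoint` and `cage` are used when
#' present and any further columns are carried along untouched.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with character `sample_id`.
#' @export
read_metadata <- function(path) .read_keyed_tsv(path, "metadata")

#' Read per-sample phenotype measurements from TSV
#'
#' Continuous host variables (e.g. hepatic triglyceride, serum cholesterol,
#' cecal SCFAs) keyed by `sample_id`. Missing values may be written as `NA` or
#' left empty; they stay missing, never zero.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with character `sample_id` and numeric phenotype columns.
#' @export
read_phenotypes <- function(path) {
  df <- .read_keyed_tsv(path, "phenotype")
  for (nm in setdiff(names(df), "sample_id")) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- !is.na(df[[nm]]) & is.na(v)
    if (any(bad))
      stop(sprintf("non-numeric phenotype value in column '%s', sample '%s'",
                   nm, df$sample_id[which(bad)[1L]]), call. = FALSE)
    df[[nm]] <- v
  }
  df
}

#' Align a table with sample metadata
#'
#' All joins in the pipeline are by `sample_id`. By default a mismatch between
#' the two sample sets is an error; set `intersect = TRUE` to take the common
#' samples instead.
#'
#' @param counts Matrix with sample ids as rownames (counts or abundances).
#' @param metadata Metadata data.frame with a `sample_id` column.
#' @param intersect Silently intersect instead of failing (default FALSE).
#' @return List with the aligned `table` and `metadata` (same sample order).
#' @export
align_samples <- function(counts, metadata, intersect = FALSE) {
  ids <- rownames(counts)
  if (!setequal(ids, metadata$sample_id) && !intersect) {
    only_t <- setdiff(ids, metadata$sample_id)
    only_m <- setdiff(metadata$sample_id, ids)
    stop("sample sets differ between table and metadata (",
         length(only_t), " only in table, ", length(only_m),
         " only in metadata); pass intersect = TRUE to take the overlap",
         call. = FALSE)
  }
  keep <- intersect(ids, metadata$sample_id)
  if (!length(keep)) stop("no samples in common", call. = FALSE)
  list(table = counts[keep, , drop = FALSE],
       metadata = metadata[match(keep, metadata$sample_id), , drop = FALSE])
}

#' Write a cluster tree as Newick
#'
#' Serialises an `hclust`-style merge tree with merge heights as node depths:
#' each branch length is the parent's merge height minus the child's (leaves
#' sit at height 0), so a two-leaf tree merged at height h becomes
#' `(A:h,B:h);`.
#'
#' @param tree An `hclust` object (e.g. from [ward_linkage()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  stopifnot(inherits(tree, "hclust"))
  lab <- tree$labels
  if (is.null(lab)) lab <- as.character(seq_len(nrow(tree$merge) + 1L))
  node_str <- function(idx) {
    if (idx < 0) list(str = lab[-idx], h = 0) else {
      l <- node_str(tree$merge[idx, 1L])
      r <- node_str(tree$merge[idx, 2L])
      h <- tree$height[idx]
      list(str = sprintf("(%s:%s,%s:%s)",
                         l$str, format(h - l$h, digits = 12),
                         r$str, format(h - r$h, digits = 12)),
           h = h)
    }
  }
  writeLines(paste0(node_str(nrow(tree$merge))$str, ";"), path)
  invisible(path)
}
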