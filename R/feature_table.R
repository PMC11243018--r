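#' Feature table container
#'
#' An aligned LC-MS peak table: a variables x samples intensity matrix with
#' per-variable accurate mass and retention time, and per-sample group/type
#' labels. This is the object every pipeline stage consumes and returns.
#'
#' @param intensity numeric matrix, variables in rows, samples in columns.
#' @param variables data.frame with columns `variable_id`, `mz`, `rt_min`
#'   and logical `is_istd` flagging internal-standard features.
#' @param samples data.frame with columns `sample_id`, `group` (a
#'   concentration label such as "20", "50", "100", or "QC"/"blank") and
#'   `type` (`"sample"`, `"QC"` or `"blank"`).
#'
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(intensity, variables, samples) {
  intensity <- as.matrix(intensity)
  stopifnot(is.numeric(intensity))
  if (!all(c("variable_id", "mz", "rt_min") %in% names(variables)))
    stop("`variables` needs columns variable_id, mz, rt_min")
  if (is.null(variables$is_istd)) variables$is_istd <- FALSE
  if (!all(c("sample_id", "group") %in% names(samples)))
    stop("`samples` needs columns sample_id, group")
  if (is.null(samples$type))
    samples$type <- ifelse(samples$group == "QC", "QC", "sample")
  if (nrow(intensity) != nrow(variables))
    stop("row count of intensity and variables disagree")
  if (ncol(intensity) != nrow(samples))
    stop("column count of intensity and sample metadata disagree")
  if (anyDuplicated(variables$variable_id))
    stop("duplicated variable ids")
  rownames(intensity) <- variables$variable_id
  colnames(intensity) <- samples$sample_id
  structure(
    list(intensity = intensity,
         variables = as.data.frame(variables, stringsAsFactors = FALSE),
         samples = as.data.frame(samples, stringsAsFactors = FALSE)),
    class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d variables x %d samples\n",
              nrow(x$intensity), ncol(x$intensity)))
  cat("  groups:",
      paste(sprintf("%s (%d)", names(table(x$samples$group)),
                    table(x$samples$group)), collapse = ", "), "\n")
  if (any(x$variables$is_istd))
    cat("  internal standards:",
        paste(x$variables$variable_id[x$variables$is_istd], collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensity)

#' Subset a feature table by variables and/or samples
#'
#' @param x a `feature_table`.
#' @param variables,samples indices, logical masks or id character vectors.
#' @return A `feature_table`.
#' @export
ft_subset <- function(x, variables = NULL, samples = NULL) {
  vi <- if (is.null(variables)) seq_len(nrow(x$intensity)) else variables
  si <- if (is.null(samples)) seq_len(ncol(x$intensity)) else samples
  if (is.character(vi)) vi <- match(vi, x$variables$variable_id)
  if (is.character(si)) si <- match(si, x$samples$sample_id)
  feature_table(x$intensity[vi, si, drop = FALSE],
                x$variables[vi, , drop = FALSE],
                x$samples[si, , drop = FALSE])
}

#' Columns belonging to one group
#' @param x a `feature_table`.
#' @param group group label.
#' @return integer column indices.
#' @export
ft_group_cols <- function(x, group) which(x$samples$group == group)

#' Concentration (non-QC, non-blank) group labels in plate order
#' @param x a `feature_table`.
#' @return character vector of group labels, numerically sorted.
#' @export
ft_conc_groups <- function(x) {
  g <- unique(x$samples$group[x$samples$type == "sample"])
  g[order(suppressWarnings(as.numeric(g)))]
}

#' Write / read a feature table as TSV
#'
#' The matrix file holds `variable_id`, `mz`, `rt_min`, `is_istd` and one
#' intensity column per sample; a sidecar TSV holds the sample metadata.
#'
#' @param x a `feature_table`.
#' @param path matrix TSV path; the sidecar is written next to it with the
#'   suffix `.samples.tsv`.
#' @return `path`, invisibly (for the writer); a `feature_table` (reader).
#' @export
write_feature_table <- function(x, path) {
  df <- cbind(x$variables[c("variable_id", "mz", "rt_min", "is_istd")],
              as.data.frame(x$intensity, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$samples, samples_sidecar(path), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  meta_cols <- c("variable_id", "mz", "rt_min", "is_istd")
  samples <- utils::read.delim(samples_sidecar(path),
                               colClasses = c(group = "character"))
  feature_table(as.matrix(df[setdiff(names(df), meta_cols)]),
                df[meta_cols], samples)
}

samples_sidecar <- function(path) sub("(\\.tsv)?$", ".samples.tsv", path,
                                      perl = TRUE)
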