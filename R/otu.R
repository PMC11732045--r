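#' OTU count table
#'
#' A sample x OTU matrix of nonnegative integer counts with an optional
#' clustering-level label (e.g. "0.03" for species-level OTUs).
#'
#' @param counts matrix or data.frame, samples in rows, OTUs in columns
#' @param sample_ids,otu_ids optional dimension names (taken from `counts`
#'   if present)
#' @param level clustering-level label, e.g. `"0.03"`
#' @return an `otu_table`: integer matrix with a `level` attribute
#' @export
otu_table <- function(counts, sample_ids = rownames(counts),
                      otu_ids = colnames(counts), level = NA_character_) {
  m <- as.matrix(counts)
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0) ||
      any(abs(m - round(m)) > 1e-8))
    stop("counts must be nonnegative integers", call. = FALSE)
  m <- round(m)
  storage.mode(m) <- "integer"
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(m)))
  if (is.null(otu_ids)) otu_ids <- paste0("Otu", seq_len(ncol(m)))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  dimnames(m) <- list(sample_ids, otu_ids)
  if (any(rowSums(m) == 0))
    stop("every sample must have at least one positive count",
         call. = FALSE)
  structure(m, level = as.character(level), class = c("otu_table", "matrix"))
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d samples x %d OTUs (level %s), %d reads\n",
              nrow(x), ncol(x), attr(x, "level"), sum(x)))
  invisible(x)
}

#' Read a mothur shared file
#'
#' Parses the tab-delimited "shared" format (columns `label`, `Group`,
#' `numOtus`, then one column per OTU) into an [otu_table()].
#'
#' @param path file path
#' @param level optional clustering label to select when the file holds
#'   several (default: the first label found)
#' @return an [otu_table()]
#' @export
read_mothur_shared <- function(path, level = NULL) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  need <- c("label", "Group", "numOtus")
  if (!all(need %in% names(d)))
    stop("not a mothur shared file (need columns label, Group, numOtus)",
         call. = FALSE)
  if (is.null(level)) level <- d$label[1]
  d <- d[as.character(d$label) == as.character(level), , drop = FALSE]
  if (nrow(d) == 0L)
    stop("no rows at clustering level '", level, "'", call. = FALSE)
  counts <- as.matrix(d[, setdiff(names(d), need), drop = FALSE])
  rownames(counts) <- d$Group
  otu_table(counts, level = level)
}

#' Read a plain sample x OTU count matrix from CSV
#'
#' First column = sample id, remaining columns = OTU counts.
#'
#' @param path file path
#' @param level optional clustering-level label to attach
#' @return an [otu_table()]
#' @export
read_otu_csv <- function(path, level = NA_character_) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(d[, -1, drop = FALSE])
  rownames(counts) <- d[[1]]
  otu_table(counts, level = level)
}

#' Write an OTU table as mothur-shared-style TSV
#'
#' @param otu an [otu_table()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_mothur_shared <- function(otu, path) {
  lab <- attr(otu, "level")
  d <- data.frame(label = if (is.na(lab)) "user" else lab,
                  Group = rownames(otu), numOtus = ncol(otu),
                  as.data.frame(unclass(otu), check.names = FALSE),
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
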