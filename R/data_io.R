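#' Construct a taxa-by-sample count table
#'
#' The central community object: a non-negative integer count matrix with
#' taxa as rows and samples as columns, plus a kingdom label
#' (`"bacteria"` or `"fungi"`) for every taxon.
#'
#' @param counts numeric matrix, taxa x samples, with unique rownames
#'   (taxon ids) and colnames (sample ids).
#' @param kingdom either a single label recycled over all taxa or a vector
#'   with one label per taxon.
#' @return an object of class `otu_table`: a list with elements `counts`
#'   (integer matrix) and `kingdom` (named character vector).
#' @export
otu_table <- function(counts, kingdom) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have taxon rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  storage.mode(counts) <- "integer"
  if (length(kingdom) == 1L) kingdom <- rep(kingdom, nrow(counts))
  if (length(kingdom) != nrow(counts))
    stop("kingdom must have one label per taxon")
  if (!all(kingdom %in% c("bacteria", "fungi")))
    stop("kingdom labels must be 'bacteria' or 'fungi'")
  if (ncol(counts) > 0 && any(colSums(counts) == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "))
  structure(list(counts = counts,
                 kingdom = setNames(as.character(kingdom), rownames(counts))),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat("otu_table: ", nrow(x$counts), " taxa x ", ncol(x$counts),
      " samples (", paste(names(table(x$kingdom)), table(x$kingdom),
                          sep = ": ", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Per-sample relative abundances
#' @param table an [otu_table].
#' @return taxa x samples matrix with columns summing to 1.
#' @export
relative_abundance <- function(table) {
  sweep(table$counts, 2, colSums(table$counts), "/")
}

#' Read an OTU table from TSV
#'
#' Expects taxa as rows and samples as columns (the common amplicon
#' convention): first column taxon id, header row of sample ids. Use
#' `transpose = TRUE` for samples-as-rows files.
#'
#' @param path file path to a tab-separated table.
#' @param kingdom kingdom label applied to every taxon in the file.
#' @param transpose logical; transpose after reading.
#' @return an [otu_table]; row and column order preserved from the file.
#' @export
read_otu_table <- function(path, kingdom, transpose = FALSE) {
  raw <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "")
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate taxon id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m),
                                 dimnames = list(ids, colnames(m))))
  if (any(is.na(num))) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric count at taxon '", ids[bad[1L]], "', sample '",
         colnames(num)[bad[2L]], "'")
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1L, ]
    stop("negative count at taxon '", ids[bad[1L]], "', sample '",
         colnames(num)[bad[2L]], "'")
  }
  if (transpose) num <- t(num)
  otu_table(num, kingdom)
}

#' Write an OTU table to TSV
#' @param table an [otu_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  df <- data.frame(taxon_id = rownames(table$counts), table$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny from a Newick file
#'
#' Thin wrapper over [ape::read.tree] that validates what the phylogenetic
#' null models downstream require: unique tip labels and non-negative branch
#' lengths.
#'
#' @param path path to a Newick file.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("cannot parse Newick file ", path,
                                            ": ", conditionMessage(e)))
  if (is.null(tree)) stop("cannot parse Newick file ", path)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels in ", path)
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths in ", path)
  tree
}

#' Read per-sample metadata from CSV
#'
#' One row per sample. Required columns: `sample_id`, `stand_type` (levels
#' P/M), `stand_age` (20 or 31), `plot`, and the soil variables `pH`, `SWC`,
#' `SOC`, `TN`, `TP`, `AP`, `AK`, `NH4`, `NO3`.
#'
#' @param path path to a CSV file.
#' @param table optional companion [otu_table]; sample ids absent from it
#'   trigger a warning listing the set difference.
#' @return a `data.frame` with validated factor levels.
#' @export
read_metadata <- function(path, table = NULL) {
  meta <- read.table(path, header = TRUE, sep = ",", check.names = FALSE,
                     stringsAsFactors = FALSE)
  validate_metadata(meta, table)
}

soil_variables <- function() c("pH", "SWC", "SOC", "TN", "TP", "AP", "AK",
                               "NH4", "NO3")

validate_metadata <- function(meta, table = NULL) {
  need <- c("sample_id", "stand_type", "stand_age", "plot", soil_variables())
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata")
  if (!all(meta$stand_type %in% c("P", "M")))
    stop("unknown stand_type level: ",
         paste(setdiff(meta$stand_type, c("P", "M")), collapse = ", "))
  if (!all(meta$stand_age %in% c(20, 31)))
    stop("unknown stand_age level: ",
         paste(setdiff(meta$stand_age, c(20, 31)), collapse = ", "))
  for (v in soil_variables()) {
    bad <- !is.finite(as.numeric(meta[[v]]))
    if (any(bad))
      stop("non-finite ", v, " for sample(s): ",
           paste(meta$sample_id[bad], collapse = ", "))
    meta[[v]] <- as.numeric(meta[[v]])
  }
  meta$stand_type <- factor(meta$stand_type, levels = c("P", "M"))
  if (!is.null(table)) {
    extra <- setdiff(meta$sample_id, colnames(table$counts))
    if (length(extra))
      warning("metadata samples absent from OTU table: ",
              paste(extra, collapse = ", "))
  }
  meta
}

#' Align an OTU table, a phylogeny and sample metadata
#'
#' Restricts samples to the intersection of table and metadata, and records
#' which taxa are missing from the tree (those are dropped from phylogenetic
#' operations only; taxonomic analyses keep them). Idempotent.
#'
#' @param table an [otu_table].
#' @param tree an [ape::phylo] tree, or `NULL`.
#' @param meta a metadata `data.frame` as from [read_metadata].
#' @return a list of class `rhizo_study` with elements `table`, `tree`,
#'   `meta`, `taxa_phylo` (taxa usable in phylogenetic ops) and `dropped`
#'   (report of dropped samples/taxa).
#' @export
align_inputs <- function(table, tree = NULL, meta = NULL) {
  samp <- colnames(table$counts)
  dropped <- list(samples_table = character(), samples_meta = character(),
                  taxa_tree = character())
  if (!is.null(meta)) {
    keep <- intersect(samp, meta$sample_id)
    if (length(keep) == 0L)
      stop("no samples shared between OTU table and metadata")
    dropped$samples_table <- setdiff(samp, keep)
    dropped$samples_meta <- setdiff(meta$sample_id, keep)
    meta <- meta[match(keep, meta$sample_id), , drop = FALSE]
    cnt <- table$counts[, keep, drop = FALSE]
    cnt <- cnt[rowSums(cnt) >= 0, , drop = FALSE]
    table <- otu_table(cnt, table$kingdom[rownames(cnt)])
  }
  taxa_phylo <- rownames(table$counts)
  if (!is.null(tree)) {
    taxa_phylo <- intersect(taxa_phylo, tree$tip.label)
    dropped$taxa_tree <- setdiff(rownames(table$counts), taxa_phylo)
  }
  structure(list(table = table, tree = tree, meta = meta,
                 taxa_phylo = taxa_phylo, dropped = dropped),
            class = "rhizo_study")
}

#' Merge bacterial and fungal OTU tables into one cross-kingdom table
#'
#' Taxon ids are prefixed `B_` (bacteria) and `F_` (fungi), mirroring the
#' predictor naming used in cross-kingdom driver analyses. Sample sets must
#' be identical.
#'
#' @param bacteria,fungi [otu_table] objects sharing the same samples.
#' @return a merged [otu_table].
#' @export
merge_kingdoms <- function(bacteria, fungi) {
  if (!setequal(colnames(bacteria$counts), colnames(fungi$counts)))
    stop("bacterial and fungal tables must share the same samples")
  f <- fungi$counts[, colnames(bacteria$counts), drop = FALSE]
  b <- bacteria$counts
  rownames(b) <- ifelse(startsWith(rownames(b), "B_"), rownames(b),
                        paste0("B_", rownames(b)))
  rownames(f) <- ifelse(startsWith(rownames(f), "F_"), rownames(f),
                        paste0("F_", rownames(f)))
  otu_table(rbind(b, f), c(rep("bacteria", nrow(b)), rep("fungi", nrow(f))))
}
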