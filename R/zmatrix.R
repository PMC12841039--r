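#' Validate a gene-by-phenotype z-statistic table
#'
#' A z-matrix is a tibble whose first column, `gene`, holds unique gene
#' identifiers and whose remaining columns hold one finite numeric
#' z-statistic per phenotype. All zscreen analysis functions accept either
#' such a data frame or a plain numeric matrix (row names become genes,
#' column names phenotypes).
#'
#' @param x A data frame (first column `gene`, numeric phenotype columns) or
#'   a numeric matrix.
#' @return A validated tibble with a `gene` character column followed by
#'   numeric phenotype columns.
#' @examples
#' as_zmatrix(matrix(rnorm(6), 3, 2))
#' @export
as_zmatrix <- function(x) {
  if (is.matrix(x)) {
    genes <- rownames(x) %||% sprintf("g%04d", seq_len(nrow(x)))
    phen <- colnames(x) %||% sprintf("p%d", seq_len(ncol(x)))
    x <- tibble::as_tibble(as.data.frame(x), .name_repair = "minimal")
    names(x) <- phen
    x <- dplyr::bind_cols(tibble::tibble(gene = genes), x)
  }
  if (!is.data.frame(x) || ncol(x) < 2L)
    zstop("a z-matrix needs a gene column plus at least one phenotype column")
  x <- tibble::as_tibble(x)
  names(x)[1] <- "gene"
  x$gene <- as.character(x$gene)
  check_zmatrix(x)
  x
}

check_zmatrix <- function(x) {
  genes <- x$gene
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0L)
    zstop(paste0("duplicated gene identifiers: ",
                 paste(dup, collapse = ", ")))
  phen <- names(x)[-1]
  dupp <- unique(phen[duplicated(phen)])
  if (length(dupp) > 0L)
    zstop(paste0("duplicated phenotype labels: ",
                 paste(dupp, collapse = ", ")))
  for (j in phen) {
    v <- x[[j]]
    if (!is.numeric(v))
      zstop(paste0("phenotype column '", j, "' is not numeric"))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L)
      zstop(paste0("non-finite z-statistic for gene '", genes[bad[1]],
                   "', phenotype '", j, "'"))
  }
  invisible(x)
}

# internal accessors
zmat_values <- function(x) {
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$gene
  m
}
zmat_genes <- function(x) x$gene
zmat_phenotypes <- function(x) names(x)[-1]

#' Read a z-statistic matrix from a TSV file
#'
#' Expects a UTF-8 tab-separated file with a header row of phenotype labels,
#' the gene identifier in the first column (header `gene`), `.` as decimal
#' separator and no quoting. Every body cell must parse as a finite number;
#' offending cells are reported by gene and phenotype.
#'
#' @param path Path to the TSV file.
#' @param standardize If `TRUE`, treat the body as raw per-phenotype gene
#'   scores (e.g. MAGeCK-RRA log fold-changes) and pass it through
#'   [column_standardize()] so each column has mean 0 and sample standard
#'   deviation 1.
#' @return A validated z-matrix tibble (see [as_zmatrix()]).
#' @export
read_zmatrix <- function(path, standardize = FALSE) {
  if (!file.exists(path))
    zstop(paste0("input file not found: ", path), class = "zscreen_io_error")
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (ncol(x) < 2L)
    zstop(paste0("file '", path, "' has no phenotype columns"))
  names(x)[1] <- "gene"
  genes <- as.character(x$gene)
  for (j in names(x)[-1]) {
    v <- suppressWarnings(as.numeric(x[[j]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad) > 0L)
      zstop(paste0("cell is not a finite number (gene '", genes[bad[1]],
                   "', phenotype '", j, "'): ", x[[j]][bad[1]]))
    x[[j]] <- v
  }
  x$gene <- genes
  z <- as_zmatrix(x)
  if (isTRUE(standardize)) z <- column_standardize(z) else z
}

#' Write a z-matrix to a TSV file
#'
#' Values are printed with 12 significant digits so that
#' `read_zmatrix(write_zmatrix(z, path))` round-trips exactly for values
#' printable at that precision.
#'
#' @param z A z-matrix (see [as_zmatrix()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_zmatrix <- function(z, path) {
  z <- as_zmatrix(z)
  out <- z
  for (j in names(out)[-1]) out[[j]] <- sprintf("%.12g", out[[j]])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Column-standardize a raw gene score matrix into z-statistics
#'
#' Converts raw per-phenotype gene-level scores (for a CRISPR screen,
#' typically gene-level log fold-changes) into z-statistics by subtracting
#' each column's mean and dividing by its sample standard deviation
#' (n - 1 denominator).
#'
#' @param scores A score matrix in z-matrix layout (see [as_zmatrix()]).
#'   Every column must have positive standard deviation.
#' @return A z-matrix tibble; each column has mean 0 and sample standard
#'   deviation 1.
#' @examples
#' column_standardize(as_zmatrix(matrix(c(1, 2, 3, 5, 7, 12), 3, 2)))
#' @export
column_standardize <- function(scores) {
  scores <- as_zmatrix(scores)
  for (j in names(scores)[-1]) {
    v <- scores[[j]]
    s <- stats::sd(v)
    if (!is.finite(s) || s <= 0)
      zstop(paste0("phenotype '", j, "' has zero variance; cannot standardize"))
    scores[[j]] <- (v - mean(v)) / s
  }
  scores
}

#' Write a combined per-gene results table
#'
#' Joins the per-method ranking results (see [fisher_rank()], [ssz_rank()],
#' [cellmcd_rank()]) into one TSV with a row per gene, in input gene order,
#' and columns `<method>_statistic`, `<method>_criterion`, `<method>_pvalue`,
#' `<method>_rank` for each method. Numeric values are printed with 12
#' significant digits and round-trip losslessly at that precision.
#'
#' @param results A single long ranking tibble (with a `method` column) or a
#'   list of ranking tibbles. All must cover the same genes in the same
#'   order.
#' @param path Output file path.
#' @return The wide per-gene tibble, invisibly.
#' @export
write_gene_table <- function(results, path) {
  wide <- gene_table(results)
  out <- wide
  for (j in names(out)[-1]) {
    out[[j]] <- if (grepl("_rank$", j)) format(out[[j]], trim = TRUE)
                else sprintf("%.12g", out[[j]])
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(wide)
}

# combine ranking results into the wide per-gene layout
gene_table <- function(results) {
  if (is.data.frame(results)) results <- split(results, results$method)
  if (length(results) == 0L) zstop("no ranking results supplied")
  genes <- results[[1]]$gene
  for (r in results) {
    if (!identical(r$gene, genes))
      zstop("ranking results do not share the same gene list")
  }
  wide <- tibble::tibble(gene = genes)
  for (r in results) {
    meth <- r$method[1]
    for (col in c("statistic", "criterion", "pvalue", "rank"))
      wide[[paste0(meth, "_", col)]] <- r[[col]]
  }
  wide
}

#' Read a per-gene results table written by [write_gene_table()]
#'
#' @param path Path to the TSV file.
#' @return A tibble with a `gene` column and numeric result columns.
#' @export
read_gene_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
}
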