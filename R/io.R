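#' Read a feature-by-sample matrix with tumor/normal labels
#'
#' Matrices are TSV or CSV (auto-detected from the file extension, `.csv` =
#' comma, anything else = tab; `.gz` is transparent), with a header row of
#' sample ids and feature ids in the first column. Labels come from a
#' two-column companion file (see [read_labels()]) or a named vector.
#'
#' @param path path to the matrix file.
#' @param labels either a path to a labels file or a named character vector
#'   (sample id -> `"tumor"`/`"normal"`).
#' @param type declared data type, `"expression"` or `"methylation"`;
#'   methylation values are validated to lie in \[0, 1\].
#' @return An [omics_matrix()] with row/column order as in the file.
#' @seealso [write_matrix()]
#' @export
read_matrix <- function(path, labels, type = c("expression", "methylation")) {
  type <- match.arg(type)
  sep <- file_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"")
  if (ncol(df) < 2L) stop("matrix file needs a feature-id column plus >=1 sample")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate feature id: ", ids[duplicated(ids)][1L])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in matrix body of ", path)
  rownames(m) <- ids
  if (is.character(labels) && is.null(names(labels)) && length(labels) == 1L)
    labels <- read_labels(labels)
  omics_matrix(m, labels, type)
}

#' Write an omics matrix to TSV/CSV
#'
#' Inverse of [read_matrix()]; `write_matrix` then `read_matrix` reproduces
#' values and ordering exactly.
#'
#' @param x an [omics_matrix()].
#' @param path output path; `.csv` writes comma-separated, otherwise tab.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "omics_matrix"))
  sep <- file_sep(path)
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write sample labels
#'
#' Two-column TSV: sample id, then `tumor` or `normal`. No header.
#'
#' @param path file path.
#' @return `read_labels`: a named character vector.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, col.names = c("sample", "label"))
  if (anyDuplicated(df$sample))
    stop("duplicate sample id in labels: ", df$sample[duplicated(df$sample)][1L])
  stats::setNames(df$label, df$sample)
}

#' @param labels named character vector of labels.
#' @rdname read_labels
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(names(labels), unname(labels)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read gene TSS annotations
#'
#' BED-like four-column TSV without header: chromosome, TSS (1-based), gene
#' symbol, strand (`+`/`-`). Promoter windows are computed downstream from the
#' TSS, not stored here.
#'
#' @param path file path.
#' @return A data.frame with columns `gene`, `chrom`, `tss`, `strand`.
#' @export
read_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(gene = character(), chrom = character(),
                      tss = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "[ \t]+")
  bad <- which(lengths(parts) != 4L)
  if (length(bad))
    stop("malformed annotation line ", bad[1L], ": '", lines[bad[1L]], "'")
  m <- do.call(rbind, parts)
  tss <- suppressWarnings(as.integer(m[, 2L]))
  if (anyNA(tss))
    stop("malformed annotation line ", which(is.na(tss))[1L],
         ": non-integer TSS")
  ann <- data.frame(gene = m[, 3L], chrom = m[, 1L], tss = tss,
                    strand = m[, 4L], stringsAsFactors = FALSE)
  validate_annotation(ann)
}

#' @param ann annotation data.frame as returned by `read_annotation`.
#' @rdname read_annotation
#' @export
write_annotation <- function(ann, path) {
  validate_annotation(ann)
  utils::write.table(ann[, c("chrom", "tss", "gene", "strand")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

validate_annotation <- function(ann) {
  stopifnot(is.data.frame(ann),
            all(c("gene", "chrom", "tss", "strand") %in% names(ann)))
  if (nrow(ann) == 0L) return(ann)
  if (anyDuplicated(ann$gene))
    stop("duplicate gene symbol in annotation: ",
         ann$gene[duplicated(ann$gene)][1L])
  if (any(ann$tss < 1L)) stop("TSS positions must be >= 1")
  bad <- !ann$strand %in% c("+", "-")
  if (any(bad)) stop("strand must be '+' or '-'; offending gene: ",
                     ann$gene[bad][1L])
  ann
}

#' Biomarker gene panels
#'
#' Literature-reported biomarker panels for six TCGA cancer types ship with
#' the package (BRCA, PRAD, LIHC, HNSC, KIRP, THCA); custom panels are read
#' from a plain-text file with one gene symbol per line. Symbols are treated
#' as opaque case-sensitive strings.
#'
#' @param cancer one of the packaged cancer labels, or a path to a panel file.
#' @param name panel label to attach when reading from a path.
#' @return An object of class `biomarker_panel`: list with `cancer` and
#'   `genes`.
#' @examples
#' load_biomarker_panel("PRAD")$genes
#' @export
load_biomarker_panel <- function(cancer, name = cancer) {
  packaged <- c("BRCA", "PRAD", "LIHC", "HNSC", "KIRP", "THCA")
  if (cancer %in% packaged) {
    path <- system.file("extdata", "biomarkers", paste0(cancer, ".txt"),
                        package = "fuzzsig", mustWork = TRUE)
  } else if (file.exists(cancer)) {
    path <- cancer
    name <- if (identical(name, cancer)) basename(cancer) else name
  } else {
    stop("unknown cancer label '", cancer, "'; packaged panels: ",
         paste(packaged, collapse = ", "),
         " (or supply a path to a one-symbol-per-line file)")
  }
  genes <- readLines(path)
  genes <- genes[nzchar(trimws(genes))]
  biomarker_panel(name, genes)
}

#' @param genes character vector of gene symbols, unique and non-empty.
#' @rdname load_biomarker_panel
#' @export
biomarker_panel <- function(name, genes) {
  genes <- as.character(genes)
  if (!length(genes)) stop("biomarker panel must contain at least one gene")
  if (anyDuplicated(genes))
    stop("duplicate gene in panel: ", genes[duplicated(genes)][1L])
  structure(list(cancer = name, genes = genes), class = "biomarker_panel")
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat(sprintf("biomarker_panel '%s': %d genes\n  %s\n", x$cancer,
              length(x$genes), paste(x$genes, collapse = ", ")))
  invisible(x)
}

#' Published reference tables
#'
#' `dmg_count_reference()` returns the published per-cancer counts of DEGs and
#' of DMGs called from the expanded versus the original 450K methylation
#' profiles. `signature_reference()` returns a published per-cancer gene
#' signature.
#'
#' @return `dmg_count_reference`: data.frame with columns `cancer`, `n_deg`,
#'   `n_dmg_expanded`, `n_dmg_original`.
#' @export
dmg_count_reference <- function() {
  path <- system.file("extdata", "reference", "dmg_counts.tsv",
                      package = "fuzzsig", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @param cancer one of BRCA, PRAD, LIHC, HNSC, KIRP, THCA.
#' @rdname dmg_count_reference
#' @export
signature_reference <- function(cancer) {
  path <- system.file("extdata", "signatures", paste0(cancer, ".txt"),
                      package = "fuzzsig")
  if (!nzchar(path)) stop("no packaged signature for '", cancer, "'")
  readLines(path)
}

file_sep <- function(path) {
  base <- sub("\\.gz$", "", path)
  if (grepl("\\.csv$", base, ignore.case = TRUE)) "," else "\t"
}
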