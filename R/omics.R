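#' Feature-by-sample omics matrix with tumor/normal labels
#'
#' The basic data container used throughout the package: a numeric matrix with
#' features (genes or CpG loci) in rows and samples in columns, plus a
#' tumor/normal label for every sample. Methylation matrices are validated to
#' hold beta values in \[0, 1\].
#'
#' @param values numeric matrix, features x samples, with unique non-empty
#'   rownames (feature ids) and colnames (sample ids). `NA` values are
#'   rejected.
#' @param labels named character vector mapping every sample id to `"tumor"`
#'   or `"normal"`. Order need not match the columns.
#' @param type `"expression"` or `"methylation"`. Methylation values must lie
#'   in \[0, 1\].
#'
#' @return An object of class `omics_matrix`: a list with elements `values`,
#'   `labels` (aligned to `colnames(values)`) and `type`.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' om <- omics_matrix(m, c(s1 = "tumor", s2 = "normal"))
#' om
#' @export
omics_matrix <- function(values, labels, type = c("expression", "methylation")) {
  type <- match.arg(type)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stop("'values' must have rownames (features) and colnames (samples)")
  if (anyDuplicated(fid))
    stop("duplicate feature id: ", fid[duplicated(fid)][1L])
  if (anyDuplicated(sid))
    stop("duplicate sample id: ", sid[duplicated(sid)][1L])
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop("missing value at feature '", fid[idx[1L]], "', sample '",
         sid[idx[2L]], "'; NA cells are not permitted")
  }
  if (is.null(names(labels)))
    stop("'labels' must be a named vector (sample id -> tumor/normal)")
  missing_lab <- setdiff(sid, names(labels))
  if (length(missing_lab))
    stop("no label for sample(s): ", paste(missing_lab, collapse = ", "))
  labels <- as.character(labels[sid])
  names(labels) <- sid
  bad <- !labels %in% c("tumor", "normal")
  if (any(bad))
    stop("labels must be 'tumor' or 'normal'; offending sample: ",
         sid[bad][1L])
  if (type == "methylation") {
    out <- values < 0 | values > 1
    if (any(out)) {
      idx <- which(out, arr.ind = TRUE)[1L, ]
      stop("beta value ", values[idx[1L], idx[2L]], " outside [0,1] at locus '",
           fid[idx[1L]], "', sample '", sid[idx[2L]], "'")
    }
  }
  structure(list(values = values, labels = labels, type = type),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix (%s): %d features x %d samples (%d tumor, %d normal)\n",
              x$type, nrow(x$values), ncol(x$values),
              sum(x$labels == "tumor"), sum(x$labels == "normal")))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Subset an omics matrix by features and/or samples
#'
#' @param x an [omics_matrix()].
#' @param features,samples character vectors of ids (or index vectors) to
#'   keep; `NULL` keeps all.
#' @return An `omics_matrix` restricted to the requested rows/columns.
#' @export
subset_omics <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "omics_matrix"))
  v <- x$values
  if (!is.null(features)) {
    if (is.character(features)) {
      miss <- setdiff(features, rownames(v))
      if (length(miss))
        stop("unknown feature(s): ", paste(utils::head(miss, 5L), collapse = ", "))
    }
    v <- v[features, , drop = FALSE]
  }
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  omics_matrix(v, x$labels[colnames(v)], x$type)
}

# tumor/normal column indices; both classes required when strict
split_classes <- function(x, min_per_class = 1L) {
  tum <- which(x$labels == "tumor")
  nor <- which(x$labels == "normal")
  if (length(tum) < min_per_class || length(nor) < min_per_class)
    stop("need at least ", min_per_class, " samples per class; got ",
         length(tum), " tumor / ", length(nor), " normal")
  list(tumor = tum, normal = nor)
}
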