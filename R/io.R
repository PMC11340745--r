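#' Read a miRNA expression matrix from TSV
#'
#' Expects a tab-delimited file with feature ids in the first column and a
#' header row of sample ids. Feature and sample order in the file is
#' preserved. Missing or non-numeric cells are a hard error by default:
#' REO pair counting with silently missing values corrupts the 2x2 tables,
#' so imputation must be requested explicitly.
#'
#' @param path file path
#' @param scale declared scale of the stored values, `"log2"` or `"linear"`
#' @param impute if `TRUE`, missing cells are imputed with the feature
#'   (row) median instead of raising an error
#' @return a [MirnaExpressionSet-class]
#' @export
readExpression <- function(path, scale = c("log2", "linear"), impute = FALSE) {
  scale <- match.arg(scale)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("expression file needs >= 1 sample column")
  ids <- tab[[1L]]
  if (anyDuplicated(ids))
    stop("duplicated feature ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- is.na(num) & !is.na(vals) & trimws(vals) != "" &
    !toupper(trimws(vals)) %in% c("NA", "NAN")
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value '%s' at feature '%s', sample '%s'",
                 vals[w[1L], w[2L]], ids[w[1L]], colnames(vals)[w[2L]]))
  }
  if (anyNA(num)) {
    if (!impute) {
      w <- which(is.na(num), arr.ind = TRUE)[1L, ]
      stop(sprintf(paste0("missing value at feature '%s', sample '%s' ",
                          "(set impute = TRUE to impute row medians)"),
                   ids[w[1L]], colnames(vals)[w[2L]]))
    }
    for (i in which(rowSums(is.na(num)) > 0L)) {
      med <- stats::median(num[i, ], na.rm = TRUE)
      if (is.na(med)) stop("feature '", ids[i], "' is entirely missing")
      num[i, is.na(num[i, ])] <- med
    }
  }
  dimnames(num) <- list(ids, colnames(vals))
  MirnaExpressionSet(num, scale = scale)
}

#' Write a MirnaExpressionSet to TSV
#'
#' Inverse of [readExpression()] up to numeric formatting; feature and
#' sample order are preserved.
#'
#' @param x a [MirnaExpressionSet-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeExpression <- function(x, path) {
  v <- exprValues(x)
  df <- data.frame(feature_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' TSV with columns `sample_id`, `group` and optionally `dataset_id`.
#' When `expr` is supplied, every annotated sample must exist in the
#' matrix and (when `groups` is given) labels must come from that set.
#'
#' @param path file path
#' @param expr optional companion [MirnaExpressionSet-class] to validate
#'   against
#' @param groups optional character vector of allowed group labels
#' @return a `DataFrame` with columns `sample_id`, `group`, `dataset_id`
#' @export
readAnnotation <- function(path, expr = NULL, groups = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(tab)))
    stop("annotation needs columns 'sample_id' and 'group'")
  if (!"dataset_id" %in% colnames(tab)) tab$dataset_id <- NA_character_
  if (anyDuplicated(tab$sample_id))
    stop("duplicated sample_id in annotation: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]),
               collapse = ", "))
  if (!is.null(expr)) {
    missing <- setdiff(tab$sample_id, colnames(expr))
    if (length(missing))
      stop("annotated samples absent from expression matrix: ",
           paste(missing, collapse = ", "))
  }
  if (!is.null(groups)) {
    bad <- setdiff(tab$group, groups)
    if (length(bad))
      stop("group labels outside declared set: ", paste(bad, collapse = ", "))
  }
  S4Vectors::DataFrame(sample_id = tab$sample_id, group = tab$group,
                       dataset_id = tab$dataset_id)
}

#' Attach group labels from an annotation to an expression set
#'
#' @param expr a [MirnaExpressionSet-class]
#' @param ann annotation `DataFrame` as returned by [readAnnotation()]
#' @return `expr` restricted to annotated samples (file order preserved),
#'   with `group`/`dataset_id` in its `colData`
#' @export
annotateSamples <- function(expr, ann) {
  idx <- match(colnames(expr), ann$sample_id)
  keep <- !is.na(idx)
  if (!any(keep)) stop("no annotated sample found in the expression matrix")
  out <- expr[, keep]
  SummarizedExperiment::colData(out)$group <- ann$group[idx[keep]]
  SummarizedExperiment::colData(out)$dataset_id <- ann$dataset_id[idx[keep]]
  validObject(out)
  out
}

#' Read signature sets from a GMT file
#'
#' Standard GMT dialect: one set per line, `name TAB description TAB
#' feature TAB feature ...`. When a feature `universe` is supplied,
#' features outside it are dropped with a warning and sets left empty by
#' the filtering are removed (also with a warning).
#'
#' @param path file path
#' @param universe optional character vector of valid feature ids
#' @return named list of character vectors (a signature set)
#' @export
readGmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields")
    feats <- unique(f[-(1:2)])
    feats <- feats[nzchar(feats)]
    if (!length(feats)) stop("GMT line ", i, " has no features")
    if (!is.null(universe)) {
      drop <- setdiff(feats, universe)
      if (length(drop)) {
        warning("signature '", f[1L], "': dropping ", length(drop),
                " feature(s) outside the universe")
        feats <- intersect(feats, universe)
      }
    }
    if (length(feats)) sets[[f[1L]]] <- feats
    else warning("signature '", f[1L], "' empty after filtering; dropped")
  }
  if (anyDuplicated(names(sets)))
    stop("duplicated signature names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets
}

#' Write signature sets to a GMT file
#'
#' @param sets named list of character vectors
#' @param path output file path
#' @param description description field (recycled)
#' @return `path`, invisibly
#' @export
writeGmt <- function(sets, path, description = "na") {
  stopifnot(length(sets) > 0L, !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Rename features via an explicit mapping table
#'
#' Applies a user-supplied old-to-new identifier map (e.g. harmonizing
#' miRNA nomenclature versions). Unmapped features are kept unchanged and
#' their count reported; two features mapping to the same new name is an
#' error — identifiers are never silently merged.
#'
#' @param expr a [MirnaExpressionSet-class]
#' @param map data.frame-like with two columns, old and new names
#' @return the renamed [MirnaExpressionSet-class]
#' @export
applyNameMap <- function(expr, map) {
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (nrow(map) == 0L) return(expr)
  old <- as.character(map[[1L]]); new <- as.character(map[[2L]])
  if (anyDuplicated(old))
    stop("map has duplicated old names: ",
         paste(unique(old[duplicated(old)]), collapse = ", "))
  ids <- rownames(expr)
  idx <- match(ids, old)
  renamed <- ifelse(is.na(idx), ids, new[idx])
  if (anyDuplicated(renamed)) {
    coll <- renamed[duplicated(renamed) | duplicated(renamed, fromLast = TRUE)]
    clash <- unique(coll)
    detail <- vapply(clash, function(nm)
      paste0(paste(ids[renamed == nm], collapse = ","), "->", nm), "")
    stop("name map merges distinct features: ", paste(detail, collapse = "; "))
  }
  n_unmapped <- sum(is.na(idx))
  if (n_unmapped) message(n_unmapped, " feature(s) left unmapped")
  rownames(expr) <- renamed
  validObject(expr)
  expr
}

#' Read / write oriented pair sets
#'
#' TSV with columns `upper`, `lower`, optional `p_healthy`, and an
#' optional `provenance` column (constant; stored once).
#'
#' @param path file path
#' @return [readPairs()]: a [StablePairSet-class]
#' @export
readPairs <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("upper", "lower") %in% colnames(tab)))
    stop("pair file needs columns 'upper' and 'lower'")
  StablePairSet(tab$upper, tab$lower,
                p_healthy = if ("p_healthy" %in% colnames(tab)) tab$p_healthy,
                provenance = if ("provenance" %in% colnames(tab))
                  unique(tab$provenance) else character())
}

#' @rdname readPairs
#' @param x a [StablePairSet-class]
#' @return [writePairs()]: `path`, invisibly
#' @export
writePairs <- function(x, path) {
  df <- as.data.frame(x)
  if (length(provenance(x)))
    df$provenance <- paste(provenance(x), collapse = " | ")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
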