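#' Read a delimited expression matrix
#'
#' Expects delimited text (tab or comma, auto-detected from the header line)
#' with a header row of gene names and the first column holding sample
#' identifiers. Samples are in rows by default; set \code{transpose = TRUE}
#' for genes-in-rows files (first column then holds gene names, header holds
#' sample ids).
#'
#' @param path file path.
#' @param transpose logical; transpose a genes-in-rows file.
#' @return An \code{\link{ExpressionDataset}} without labels.
#' @export
readExpression <- function(path, transpose = FALSE) {
  sep <- detectSep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, colClasses = NA,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(!vapply(df, is.numeric, TRUE))[1]
    badrow <- which(is.na(suppressWarnings(as.numeric(df[[bad]]))) |
                      !nzchar(trimws(as.character(df[[bad]]))))[1]
    stop("non-numeric or blank cell in '", basename(path), "' at row '",
         rownames(df)[badrow], "', column '", colnames(df)[bad], "'")
  }
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("missing value in '", basename(path), "' at row '",
         rownames(m)[idx[1]], "', column '", colnames(m)[idx[2]], "'")
  }
  if (transpose) m <- t(m)
  if (anyDuplicated(colnames(m)))
    stop("duplicate gene names in '", basename(path), "': ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  message("read expression matrix: ", nrow(m), " samples x ", ncol(m),
          " genes")
  ExpressionDataset(m)
}

detectSep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Write an expression matrix as TSV (round-trip exact with readExpression)
#'
#' @param ds an \code{ExpressionDataset}.
#' @param path output path.
#' @export
writeExpression <- function(ds, path) {
  m <- exprMatrix(ds)
  df <- data.frame(sample = sampleIds(ds), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample label file
#'
#' Two delimited columns: sample id and label. Labels must be coded
#' \{1, -1\}; \{0, 1\} coding is accepted and remapped (0 to -1) with a
#' notice.
#'
#' @param path file path.
#' @param ds optional \code{ExpressionDataset}; labels are matched to its
#'   sample order and attached.
#' @return A named numeric vector, or an \code{ExpressionDataset} when
#'   \code{ds} is supplied.
#' @export
readLabels <- function(path, ds = NULL) {
  sep <- detectSep(path)
  df <- utils::read.table(path, header = FALSE, sep = sep,
                          stringsAsFactors = FALSE)
  if (is.character(df[[1]]) &&
      tolower(df[[1]][1]) %in% c("sample", "sample_id", "id"))
    df <- df[-1, , drop = FALSE]
  if (ncol(df) < 2) stop("label file must have two columns: sample id, label")
  y <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(y)) stop("non-numeric label at line ", which(is.na(y))[1])
  if (!all(y %in% c(-1, 0, 1)))
    stop("labels must be coded {1,-1} (or {0,1})")
  y <- remapLabels(y)
  names(y) <- as.character(df[[1]])
  if (is.null(ds)) return(y)
  miss <- setdiff(sampleIds(ds), names(y))
  if (length(miss))
    stop("labels missing for samples: ", paste(miss, collapse = ", "))
  ExpressionDataset(exprMatrix(ds), geneNames(ds), y[sampleIds(ds)],
                    sampleIds(ds))
}

#' Write labels as TSV
#' @param y named label vector or \code{ExpressionDataset} with labels.
#' @param path output path.
#' @export
writeLabels <- function(y, path) {
  if (is(y, "ExpressionDataset")) y <- stats::setNames(sampleLabels(y), sampleIds(y))
  utils::write.table(data.frame(names(y), unname(y)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated
#' (Broad dialect). Duplicate genes within a line are removed.
#'
#' @param path file path.
#' @return A \code{\link{PathwayCollection}} (unmapped).
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(PathwayCollection(character(0), list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad))
    stop("GMT line ", bad[1], " has fewer than 3 fields (name, description, ",
         "at least one gene)")
  nms <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nms))
    stop("duplicate gene-set name in GMT: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  members <- lapply(parts, function(p) unique(p[-(1:2)]))
  PathwayCollection(nms, members)
}

#' Write gene sets to a GMT file
#' @param coll a \code{PathwayCollection}.
#' @param path output path.
#' @param descriptions optional description field (recycled).
#' @export
writeGMT <- function(coll, path, descriptions = "na") {
  descriptions <- rep_len(descriptions, length(coll))
  lines <- vapply(seq_along(pathwayNames(coll)), function(i) {
    paste(c(pathwayNames(coll)[i], descriptions[i],
            pathwayMembers(coll)[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Map pathways onto an expression dataset, with size and overlap control
#'
#' Genes absent from the dataset are dropped from each set; sets outside
#' \code{[minSize, maxSize]} after mapping are removed; among any pair of
#' surviving sets whose Jaccard index exceeds \code{maxJaccard}, the smaller
#' set is removed (ties: the lexicographically later name). The default
#' \code{maxJaccard = 1} disables overlap removal. This filter is a simple,
#' explicit substitute for more elaborate database-redundancy preprocessing.
#'
#' @param coll a \code{PathwayCollection}.
#' @param ds an \code{ExpressionDataset}.
#' @param minSize,maxSize retained mapped-size range.
#' @param maxJaccard overlap threshold in (0, 1].
#' @return A mapped \code{PathwayCollection} (indexMap filled).
#' @export
mapPathways <- function(coll, ds, minSize = 5L, maxSize = 500L,
                        maxJaccard = 1.0) {
  stopifnot(minSize >= 1L)
  genes <- geneNames(ds)
  mapped <- lapply(pathwayMembers(coll), function(g) {
    idx <- match(g, genes)
    sort(idx[!is.na(idx)])
  })
  nms <- pathwayNames(coll)
  empty <- vapply(mapped, length, 1L) == 0L
  if (any(empty))
    warning(sum(empty), " pathway(s) with no genes in the dataset dropped: ",
            paste(utils::head(nms[empty], 5), collapse = ", "),
            if (sum(empty) > 5) ", ..." else "")
  keep <- !empty
  sz <- vapply(mapped, length, 1L)
  sizeDrop <- keep & (sz < minSize | sz > maxSize)
  if (any(sizeDrop))
    message(sum(sizeDrop), " pathway(s) outside size range [", minSize, ", ",
            maxSize, "] removed")
  keep <- keep & !sizeDrop
  alive <- which(keep)
  if (maxJaccard < 1 && length(alive) > 1) {
    nRemoved <- 0L
    for (a in seq_along(alive)) {
      i <- alive[a]
      if (!keep[i]) next
      for (b in seq_len(a - 1L)) {
        j <- alive[b]
        if (!keep[j]) next
        inter <- length(intersect(mapped[[i]], mapped[[j]]))
        uni <- length(union(mapped[[i]], mapped[[j]]))
        if (inter / uni > maxJaccard) {
          # remove the smaller set; tie broken against the later name
          drop <- if (sz[i] < sz[j]) i
                  else if (sz[j] < sz[i]) j
                  else if (nms[i] > nms[j]) i else j
          keep[drop] <- FALSE
          nRemoved <- nRemoved + 1L
          if (drop == i) break
        }
      }
    }
    if (nRemoved)
      message(nRemoved, " pathway(s) removed by Jaccard overlap > ",
              maxJaccard)
  }
  if (!any(keep)) stop("all pathways removed during mapping/filtering")
  PathwayCollection(nms[keep], pathwayMembers(coll)[keep], mapped[keep])
}
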