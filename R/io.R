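# Readers/writers for the external formats the pipeline touches.
# Expression: TSV, genes in rows, header = sample ids.
# PPI: 2-3 column TSV (symbol TAB symbol TAB optional score in [0,1]).
# Gene sets: GMT. Clinical: CSV with header. All outputs TSV.

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a header row of sample ids and gene symbols in the first column;
#' values are assumed to be on the log2 scale. Duplicate gene symbols are
#' resolved by keeping the row with the highest mean; rows containing any
#' missing value are dropped. Both events are recorded in attributes and
#' reported via \code{message()}.
#'
#' @param path path to a TSV file.
#' @param colData optional data.frame of sample metadata (rownames or a
#'   \code{sample_id} column matching the matrix columns), stored as
#'   \code{colData} of the result.
#' @return a \code{SummarizedExperiment} with one assay \code{"exprs"} and
#'   metadata entries \code{nDroppedMissing}, \code{nDuplicatesResolved}.
#' @export
readExpressionMatrix <- function(path, colData = NULL) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 3L)
    stop("expression TSV needs a gene column and at least 2 samples")
  genes <- as.character(raw[[1L]])
  sampleIds <- colnames(raw)[-1L]
  if (anyDuplicated(sampleIds))
    stop("malformed header: duplicate sample ids: ",
         paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    # locate the first offending cell for the error message
    for (j in seq_len(ncol(mat))) {
      v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
      bad <- which(is.na(v) & !is.na(raw[[j + 1L]]) &
                   !(trimws(as.character(raw[[j + 1L]])) %in%
                     c("NA", "", "NaN")))
      if (length(bad))
        stop(sprintf("non-numeric cell at row %d (gene %s), column %s",
                     bad[1L], genes[bad[1L]], sampleIds[j]))
    }
    mode(mat) <- "numeric"
  }
  rownames(mat) <- genes

  nMissing <- sum(!complete.cases(mat))
  if (nMissing > 0L) {
    message(nMissing, " gene row(s) dropped for missing values")
    mat <- mat[complete.cases(mat), , drop = FALSE]
  }

  nDup <- 0L
  if (anyDuplicated(rownames(mat))) {
    means <- rowMeans(mat)
    ord <- order(-means)  # best row first within each symbol
    keep <- ord[!duplicated(rownames(mat)[ord])]
    nDup <- nrow(mat) - length(keep)
    message(nDup, " duplicate gene symbol row(s) resolved (kept highest mean)")
    mat <- mat[sort(keep), , drop = FALSE]
  }
  if (nrow(mat) == 0L)
    stop("no gene rows left after validation")

  cd <- S4Vectors::DataFrame(row.names = colnames(mat))
  if (!is.null(colData)) {
    cdf <- as.data.frame(colData)
    if ("sample_id" %in% colnames(cdf)) rownames(cdf) <- cdf$sample_id
    if (!all(colnames(mat) %in% rownames(cdf)))
      stop("colData does not cover all samples")
    cd <- S4Vectors::DataFrame(cdf[colnames(mat), , drop = FALSE])
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = mat), colData = cd,
    metadata = list(nDroppedMissing = nMissing, nDuplicatesResolved = nDup))
}

#' Read an undirected PPI edge list
#'
#' Two symbol columns plus an optional confidence score column in [0, 1]
#' (HIPPIE-style). Self-loops are removed and counted; duplicate edges
#' (order-insensitive) are collapsed keeping the first score seen.
#'
#' @param path TSV path; a header is auto-detected (non-numeric third
#'   column on line 1 with the token "score"/"confidence", or two tokens
#'   equal to common header names).
#' @param header logical or NA (auto-detect).
#' @return a \code{\link{PPINetwork}}.
#' @export
readPPIEdges <- function(path, header = NA) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty PPI file: ", path)
  if (is.na(header)) {
    toks <- strsplit(first, "\t", fixed = TRUE)[[1L]]
    header <- any(tolower(toks) %in%
                  c("symbol1", "symbol2", "gene1", "gene2", "from", "to",
                    "score", "confidence"))
  }
  df <- read.delim(path, header = header, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("PPI file needs at least two columns")
  from <- as.character(df[[1L]])
  to <- as.character(df[[2L]])
  blank <- function(x) is.na(x) | !nzchar(trimws(x))
  if (any(blank(from)) || any(blank(to)))
    stop("edge referencing empty symbol")
  score <- if (ncol(df) >= 3L) as.numeric(df[[3L]]) else NULL
  if (!is.null(score) && any(score < 0 | score > 1, na.rm = TRUE))
    stop("confidence scores must lie in [0, 1]")
  makePPINetwork(from, to, score)
}

#' Construct a PPINetwork from edge endpoint vectors
#'
#' @param from,to character vectors of endpoints.
#' @param score optional numeric confidence in [0, 1].
#' @param nodes optional additional (possibly isolated) nodes.
#' @return a \code{\link{PPINetwork}}.
#' @export
makePPINetwork <- function(from, to, score = NULL, nodes = NULL) {
  loop <- from == to
  nLoop <- sum(loop)
  from <- from[!loop]; to <- to[!loop]
  if (!is.null(score)) score <- score[!loop]
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  nDup <- sum(dup)
  edges <- data.frame(from = a[!dup], to = b[!dup],
                      stringsAsFactors = FALSE)
  if (!is.null(score)) edges$score <- score[!dup]
  ord <- order(edges$from, edges$to)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  allNodes <- sort(unique(c(edges$from, edges$to, nodes)))
  new("PPINetwork", nodes = allNodes, edges = edges,
      nSelfLoopsRemoved = as.integer(nLoop),
      nDuplicatesRemoved = as.integer(nDup))
}

#' Read gene sets from a GMT file
#'
#' Each line: name TAB description TAB member [TAB member ...]. Duplicate
#' members within a set are collapsed.
#'
#' @param path GMT path.
#' @return a \code{\link{GeneSetCollection}} in file order.
#' @export
readGeneSets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 fields")
  nms <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, `[[`, character(1), 2L)
  members <- lapply(parts, function(p) unique(p[-c(1L, 2L)]))
  new("GeneSetCollection", setNames = nms, descriptions = desc,
      members = members)
}

#' Write gene sets to a GMT file
#'
#' @param gsc a \code{\link{GeneSetCollection}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneSets <- function(gsc, path) {
  lines <- mapply(function(n, d, m) paste(c(n, d, m), collapse = "\t"),
                  gsc@setNames, gsc@descriptions, gsc@members)
  writeLines(lines, path)
  invisible(path)
}

#' Declared categorical level dictionary for clinical tables
#'
#' @return named list of permitted levels per covariate column.
#' @export
clinicalLevelDictionary <- function() {
  list(
    tnm = c("I", "II-IV"),
    afp = c("<=300", ">300"),
    sex = c("female", "male"),
    age_class = c("<=50", ">50"),
    tumor_size = c("<=3cm", ">3cm")
  )
}

#' Read a clinical table from CSV
#'
#' Schema: \code{patient_id}, \code{time} (months, > 0), \code{event}
#' (0/1), the categorical covariates declared by
#' \code{\link{clinicalLevelDictionary}} (all optional), and optional
#' \code{ihc_percent} in [0, 100].
#'
#' @param path CSV path.
#' @param dictionary named list of permitted levels per covariate.
#' @return validated data.frame.
#' @export
readClinical <- function(path, dictionary = clinicalLevelDictionary()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validateClinical(df, dictionary)
}

#' Validate a clinical data.frame against the declared schema
#'
#' @param df data.frame.
#' @param dictionary named list of permitted levels per covariate.
#' @return the validated data.frame (character covariates).
#' @export
validateClinical <- function(df, dictionary = clinicalLevelDictionary()) {
  if (!all(c("time", "event") %in% colnames(df)))
    stop("clinical table must have 'time' and 'event' columns")
  badT <- which(!is.finite(df$time) | df$time <= 0)
  if (length(badT))
    stop("non-positive survival time at row ", badT[1L])
  badE <- which(!df$event %in% c(0, 1))
  if (length(badE))
    stop("event flag not in {0,1} at row ", badE[1L])
  for (cv in intersect(names(dictionary), colnames(df))) {
    lv <- unique(as.character(df[[cv]]))
    unknown <- setdiff(lv[!is.na(lv)], dictionary[[cv]])
    if (length(unknown))
      stop("unknown level(s) for '", cv, "': ",
           paste(unknown, collapse = ", "))
  }
  if ("ihc_percent" %in% colnames(df)) {
    ok <- is.na(df$ihc_percent) |
      (df$ihc_percent >= 0 & df$ihc_percent <= 100)
    if (!all(ok))
      stop("ihc_percent outside [0, 100] at row ", which(!ok)[1L])
  }
  df
}

#' Write a tabular result to TSV
#'
#' Column order is preserved as given; numbers are written at full
#' precision (15 significant digits). Optionally appends a display column
#' rounded for human reading.
#'
#' @param records data.frame (possibly zero rows).
#' @param path output path.
#' @param displayColumn optional name of a numeric column to duplicate as
#'   \code{<name>_display} rounded to \code{displayDigits} significant
#'   digits.
#' @param displayDigits significant digits for the display column.
#' @return \code{path}, invisibly.
#' @export
writeResultTable <- function(records, path, displayColumn = NULL,
                             displayDigits = 3L) {
  df <- as.data.frame(records)
  if (!is.null(displayColumn)) {
    if (!displayColumn %in% colnames(df))
      stop("no such column: ", displayColumn)
    df[[paste0(displayColumn, "_display")]] <-
      signif(df[[displayColumn]], displayDigits)
  }
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA, format(x, digits = 15, trim = TRUE,
                                scientific = NA))
  })
  con <- file(path, open = "wt")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Write an expression SummarizedExperiment back to the TSV dialect
#'
#' @param se SummarizedExperiment with assay \code{"exprs"}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(se, path) {
  mat <- SummarizedExperiment::assay(se, "exprs")
  df <- data.frame(gene = rownames(mat),
                   format(mat, digits = 15, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
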