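#' Normalize ICD-10 codes to the 3-character level
#'
#' Health outcomes are analyzed at the 3-character ICD-10 level (e.g. `K90`
#' for celiac disease, `I10` for essential hypertension). A raw code is
#' cleaned by trimming whitespace, dropping any dot suffix (`"K90.0"` ->
#' `"K90"`), uppercasing, and truncating to three characters. Normalization
#' is idempotent.
#'
#' @param raw_code character vector of raw codes.
#' @param map optional named character vector mapping normalized 3-character
#'   codes to user-defined grouped categories (applied after truncation;
#'   codes absent from the map pass through unchanged).
#' @return character vector of normalized codes.
#' @examples
#' normalizeIcd10(c("K90.0", "i10"))
#' @export
normalizeIcd10 <- function(raw_code, map = NULL) {
  if (!length(raw_code)) return(character())
  raw_code <- as.character(raw_code)
  if (any(is.na(raw_code) | !nzchar(trimws(raw_code))))
    stop("empty ICD-10 code")
  cleaned <- toupper(sub("\\..*$", "", trimws(raw_code)))
  short <- nchar(cleaned) < 3L
  if (any(short))
    stop(sprintf("ICD-10 code too short after cleaning: '%s'",
                 raw_code[short][1L]))
  out <- substr(cleaned, 1L, 3L)
  bad <- !grepl("^[A-Z][0-9]{2}$", out)
  if (any(bad))
    stop(sprintf("not a letter + two digits after normalization: '%s'",
                 raw_code[bad][1L]))
  if (!is.null(map)) {
    hit <- out %in% names(map)
    out[hit] <- unname(map[out[hit]])
  }
  out
}

.provenanceHeader <- function(what, params = list()) {
  ptxt <- if (length(params))
    paste(sprintf("%s=%s", names(params),
                  vapply(params, function(p) paste(format(p), collapse = ","),
                         "")),
          collapse = " ")
  else ""
  sprintf("# proteoseg %s | %s %s",
          as.character(utils::packageVersion("proteoseg")), what, ptxt)
}

#' Read a participants-by-proteins abundance matrix from delimited text
#'
#' The first row is the protein header, the first column the participant id.
#' Empty cells and any of the configured sentinels denote missing values.
#' Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @param delimiter field delimiter, default tab.
#' @param missing character vector of missing-value sentinels.
#' @return A [ProteinMatrix-class]; row and column order follow the file.
#' @export
readProteinMatrix <- function(path, delimiter = "\t",
                              missing = c("", "NA")) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  d <- utils::read.table(path, sep = delimiter, header = TRUE,
                         check.names = FALSE, comment.char = "#",
                         colClasses = "character", quote = "\"",
                         na.strings = character())
  if (ncol(d) < 2L) stop("matrix file needs an id column and >= 1 protein")
  ids <- d[[1L]]
  if (anyDuplicated(ids))
    stop(sprintf("duplicate participant id: %s", ids[duplicated(ids)][1L]))
  prot <- colnames(d)[-1L]
  if (anyDuplicated(prot))
    stop(sprintf("duplicate protein header: %s", prot[duplicated(prot)][1L]))
  vals <- as.matrix(d[, -1L, drop = FALSE])
  vals[vals %in% missing] <- NA_character_
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at participant '%s', protein '%s': '%s'",
                 ids[bad[1L, 1L]], prot[bad[1L, 2L]],
                 vals[bad[1L, 1L], bad[1L, 2L]]))
  dimnames(num) <- list(ids, prot)
  ProteinMatrix(num)
}

#' Write a ProteinMatrix as delimited text
#'
#' Missing entries are written as `NA`; a `#` provenance line precedes the
#' header.
#'
#' @param x a [ProteinMatrix-class].
#' @param path output path.
#' @param delimiter field delimiter.
#' @export
writeProteinMatrix <- function(x, path, delimiter = "\t") {
  m <- npx(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenanceHeader("protein_matrix",
                               list(participants = nrow(m),
                                    proteins = ncol(m))), con)
  writeLines(paste(c("participant_id", colnames(m)), collapse = delimiter),
             con)
  body <- apply(m, 1L, function(r)
    paste(c("", format(r, trim = TRUE, digits = 15L)), collapse = delimiter))
  writeLines(paste0(rownames(m), body), con)
  invisible(path)
}

#' Read a phenotype table
#'
#' Expects columns `participant_id`, `age`, `sex` and `icd10`; the `icd10`
#' column holds semicolon-separated raw codes (may be empty).
#'
#' @param path file path.
#' @param delimiter field delimiter.
#' @return A [PhenotypeTable-class].
#' @export
readPhenotypeTable <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  d <- utils::read.table(path, sep = delimiter, header = TRUE,
                         check.names = FALSE, comment.char = "#",
                         colClasses = "character", quote = "\"")
  need <- c("participant_id", "age", "sex", "icd10")
  if (!all(need %in% colnames(d)))
    stop("phenotype file needs columns participant_id, age, sex, icd10")
  codes <- strsplit(d$icd10, ";", fixed = TRUE)
  codes <- lapply(codes, function(x) x[nzchar(x)])
  PhenotypeTable(d$participant_id, as.numeric(d$age), d$sex, codes)
}

#' Write a phenotype table
#'
#' @param x a [PhenotypeTable-class].
#' @param path output path.
#' @param delimiter field delimiter.
#' @export
writePhenotypeTable <- function(x, path, delimiter = "\t") {
  d <- x@data
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenanceHeader("phenotypes", list(participants = nrow(d))),
             con)
  writeLines(paste(c("participant_id", "age", "sex", "icd10"),
                   collapse = delimiter), con)
  icd <- vapply(as.list(d$icd10), paste, "", collapse = ";")
  writeLines(paste(rownames(d), format(d$age, trim = TRUE, digits = 15L),
                   d$sex, icd, sep = delimiter), con)
  invisible(path)
}

#' Write a cluster assignment as two-column delimited text
#'
#' Rows are sorted by participant id; the noise label is written as `NA`.
#' A `#` header records the method and provenance parameters.
#'
#' @param assignment a non-empty [ClusterAssignment-class].
#' @param path output path.
#' @param delimiter field delimiter.
#' @export
writeAssignments <- function(assignment, path, delimiter = "\t") {
  labs <- clusterLabels(assignment)
  if (!length(labs)) stop("empty assignment")
  ord <- order(names(labs))
  con <- file(path, "w")
  on.exit(close(con))
  params <- assignment@provenance$params
  writeLines(.provenanceHeader(
    sprintf("assignments method=%s", clusterMethod(assignment)),
    if (is.list(params)) params else list()), con)
  writeLines(paste(c("participant_id", "cluster_label"),
                   collapse = delimiter), con)
  writeLines(paste(names(labs)[ord], ifelse(is.na(labs[ord]), "NA",
                                            labs[ord]),
                   sep = delimiter), con)
  invisible(path)
}

#' Read a cluster assignment written by [writeAssignments()]
#'
#' @param path file path.
#' @param delimiter field delimiter.
#' @param method method tag for the restored object (default taken from the
#'   provenance header when present).
#' @return A [ClusterAssignment-class].
#' @export
readAssignments <- function(path, delimiter = "\t", method = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  first <- readLines(path, n = 1L)
  if (is.null(method)) {
    method <- if (grepl("method=", first))
      sub(".*method=([^ ]+).*", "\\1", first)
    else "unknown"
  }
  d <- utils::read.table(path, sep = delimiter, header = TRUE,
                         check.names = FALSE, comment.char = "#",
                         colClasses = "character", na.strings = "NA")
  ClusterAssignment(method,
                    structure(d$cluster_label, names = d$participant_id))
}
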