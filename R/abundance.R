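
# io_profiles: abundance tables, marker normalization, prevalence filtering,
# keyword-based cas labeling.

LABEL_LEVELS <- c("POSITIVE", "NEGATIVE", "UNANNOTATED")

#' Construct a validated abundance matrix
#'
#' An abundance matrix holds non-negative real abundances of gene families
#' (rows) across samples (columns), with unique row and column identifiers.
#' It is the container every upstream reader and the synthetic generator
#' produce and every downstream stage consumes.
#'
#' @param values numeric matrix, families x samples, non-negative.
#' @param family_ids,sample_ids optional character vectors; default to the
#'   dimnames of `values`.
#' @return a numeric matrix with class `abundance_matrix` and validated
#'   dimnames.
#' @export
abundance_matrix <- function(values, family_ids = rownames(values),
                             sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_casnet("`values` must be a numeric matrix")
  }
  if (is.null(family_ids) || is.null(sample_ids)) {
    stop_casnet("family and sample identifiers are required")
  }
  family_ids <- as.character(family_ids)
  sample_ids <- as.character(sample_ids)
  if (length(family_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop_casnet("identifier lengths do not match matrix dimensions")
  }
  if (anyDuplicated(family_ids)) {
    stop_casnet("duplicate family ids: ",
                paste(unique(family_ids[duplicated(family_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop_casnet("duplicate sample ids: ",
                paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop_casnet("non-numeric or missing abundance at family '",
                family_ids[bad[1L]], "', sample '", sample_ids[bad[2L]], "'")
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop_casnet("negative abundance at family '", family_ids[bad[1L]],
                "', sample '", sample_ids[bad[2L]], "'")
  }
  dimnames(values) <- list(family_ids, sample_ids)
  class(values) <- c("abundance_matrix", class(values))
  values
}

#' Read a gene-family abundance table from TSV
#'
#' Expects a UTF-8 tab-delimited file whose header row carries sample ids and
#' whose first column carries family ids. Parsing is locale-independent
#' (`.` decimal separator enforced).
#'
#' @param path path to the TSV file.
#' @return an [abundance_matrix()].
#' @export
read_profile_table <- function(path) {
  if (!file.exists(path)) stop_casnet("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  if (nrow(tab) == 0L) stop_casnet("no data rows in ", path)
  if (ncol(tab) < 2L) stop_casnet("no sample columns in ", path)
  fam <- tab[[1L]]
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop_casnet("non-numeric abundance at family '", fam[bad[1L]],
                "', sample '", colnames(tab)[-1L][bad[2L]], "'")
  }
  abundance_matrix(num, family_ids = fam, sample_ids = colnames(tab)[-1L])
}

#' Write an abundance matrix as TSV
#'
#' @param A an [abundance_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(A, path) {
  df <- data.frame(family = rownames(A), unclass(A), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Normalize abundances by single-copy marker genes
#'
#' Divides each sample (column) by the median abundance of a curated set of
#' single-copy marker families in that sample, converting relative abundances
#' into average copy number per genome. Markers absent from the matrix are
#' reported via a message; the median is taken over the markers present.
#'
#' @param A an [abundance_matrix()].
#' @param markers character vector of marker family ids (nominally 77).
#' @return a normalized [abundance_matrix()].
#' @export
normalize_by_markers <- function(A, markers) {
  markers <- as.character(markers)
  if (length(markers) == 0L) stop_casnet("empty marker set")
  present <- intersect(markers, rownames(A))
  if (length(present) == 0L) {
    stop_casnet("none of the ", length(markers), " marker families found in matrix")
  }
  missing <- setdiff(markers, present)
  if (length(missing) > 0L) {
    message(length(missing), " marker families not found in matrix; ",
            "normalizing with the ", length(present), " present")
  }
  med <- apply(A[present, , drop = FALSE], 2L, stats::median)
  if (any(med <= 0)) {
    stop_casnet("marker median is zero in sample(s): ",
                paste(colnames(A)[med <= 0], collapse = ", "))
  }
  abundance_matrix(sweep(unclass(A), 2L, med, `/`),
                   family_ids = rownames(A), sample_ids = colnames(A))
}

#' Filter families by prevalence across samples
#'
#' Drops families detected (abundance strictly greater than zero) in fewer
#' than `min_frac` of samples; families whose presence fraction is exactly
#' `min_frac` are retained. Row order of survivors and the sample set are
#' preserved.
#'
#' @param A an [abundance_matrix()].
#' @param min_frac minimum presence fraction in (0, 1]; default 0.10.
#' @return the filtered [abundance_matrix()] (possibly with zero rows).
#' @export
filter_prevalence <- function(A, min_frac = 0.10) {
  stopifnot(is.numeric(min_frac), length(min_frac) == 1L,
            min_frac > 0, min_frac <= 1)
  frac <- rowMeans(unclass(A) > 0)
  keep <- frac >= min_frac
  abundance_matrix(unclass(A)[keep, , drop = FALSE],
                   family_ids = rownames(A)[keep], sample_ids = colnames(A))
}

#' Construct a validated label vector
#'
#' @param x named character vector or factor with values in
#'   `POSITIVE`, `NEGATIVE`, `UNANNOTATED`; names are family ids.
#' @return a named factor with those three levels and class `label_vector`.
#' @export
label_vector <- function(x) {
  if (is.null(names(x)) || anyDuplicated(names(x))) {
    stop_casnet("labels must be uniquely named by family id")
  }
  ids <- names(x)
  x <- as.character(x)
  bad <- setdiff(unique(x), LABEL_LEVELS)
  if (length(bad) > 0L) {
    stop_casnet("invalid label state(s): ", paste(bad, collapse = ", "))
  }
  out <- factor(x, levels = LABEL_LEVELS)
  names(out) <- ids
  class(out) <- c("label_vector", class(out))
  out
}

#' Label families as cas by protein-name keyword
#'
#' A family is labeled POSITIVE when any protein name attached to it contains
#' the keyword (substring match, case-sensitive by default -- "CRISPR" is an
#' uppercase acronym); otherwise NEGATIVE if the family has any preexisting
#' annotation, else UNANNOTATED.
#'
#' @param name_map named list: family id -> character vector of protein names
#'   (possibly empty).
#' @param annotated character vector of family ids with preexisting
#'   annotations.
#' @param keyword non-empty keyword; default `"CRISPR"`.
#' @param ignore_case match case-insensitively; default `FALSE`.
#' @return a [label_vector()] over the families of `name_map`.
#' @export
label_from_keyword <- function(name_map, annotated, keyword = "CRISPR",
                               ignore_case = FALSE) {
  stopifnot(is.character(keyword), length(keyword) == 1L, nzchar(keyword))
  if (is.null(names(name_map)) || anyDuplicated(names(name_map))) {
    stop_casnet("`name_map` must be uniquely named by family id")
  }
  annotated <- as.character(annotated)
  hit <- vapply(name_map, function(nms) {
    length(nms) > 0L &&
      any(grepl(keyword, nms, fixed = !ignore_case, ignore.case = ignore_case))
  }, logical(1L))
  lab <- ifelse(hit, "POSITIVE",
                ifelse(names(name_map) %in% annotated, "NEGATIVE", "UNANNOTATED"))
  names(lab) <- names(name_map)
  label_vector(lab)
}

#' Read a two-column family/label TSV as a label vector
#'
#' @param path TSV with columns `family_id` and `label`.
#' @return a [label_vector()].
#' @export
read_label_map <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  label_vector(stats::setNames(tab[[2L]], tab[[1L]]))
}

#' Read a family/protein-name TSV (one row per name) as a name map
#'
#' @param path TSV with columns `family_id` and `protein_name`.
#' @param families optional character vector of families that must appear in
#'   the map (those without any name row get an empty name set).
#' @return named list of character vectors.
#' @export
read_name_map <- function(path, families = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  nm <- split(as.character(tab[[2L]]), as.character(tab[[1L]]))
  if (!is.null(families)) {
    extra <- setdiff(as.character(families), names(nm))
    nm <- c(nm, stats::setNames(rep(list(character(0L)), length(extra)), extra))
    nm <- nm[as.character(families)]
  }
  nm
}
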