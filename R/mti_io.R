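#' Construct an MTI dataset
#'
#' An MTI (miRNA-target interaction) dataset is a deduplicated edge table for
#' one source database: one row per distinct (miRNA, gene) pair, with the
#' number of source rows collapsed into it recorded as `evidence_count`.
#'
#' @param records data.frame with columns `mirna_id`, `gene_id`,
#'   `evidence_count`, plus any preserved attribute columns.
#' @param name dataset name (e.g. the source database).
#' @return An object of class `mti_dataset`.
#' @export
mti_dataset <- function(records, name = "dataset") {
  stopifnot(is.data.frame(records))
  required <- c("mirna_id", "gene_id", "evidence_count")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("records must have columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(records) > 0L) {
    if (any(!nzchar(records$mirna_id)) || any(!nzchar(records$gene_id))) {
      stop("mirna_id and gene_id must be non-empty")
    }
    if (any(records$evidence_count < 1L)) stop("evidence_count must be >= 1")
    if (anyDuplicated(paste(records$mirna_id, records$gene_id, sep = "\r"))) {
      stop("duplicate (mirna_id, gene_id) pairs in records")
    }
  }
  rownames(records) <- NULL
  structure(list(name = name, records = records), class = "mti_dataset")
}

#' @export
print.mti_dataset <- function(x, ...) {
  s <- summarize_dataset(x)
  cat(sprintf("MTI dataset '%s': %d interactions, %d miRNAs, %d genes\n",
              x$name, s$interactions, s$mirnas, s$genes))
  invisible(x)
}

empty_records <- function(attr_cols = character()) {
  out <- data.frame(mirna_id = character(), gene_id = character(),
                    evidence_count = integer(), stringsAsFactors = FALSE)
  for (a in attr_cols) out[[a]] <- character()
  out
}

# Identifier normalization: trim whitespace on both sides; gene symbols are
# case-folded to upper case, miRNA names are kept verbatim (mature miRNA
# names are case-sensitive by convention, e.g. hsa-miR-21-5p vs hsa-mir-21).
normalize_gene_id <- function(x) toupper(trimws(x))
normalize_mirna_id <- function(x) trimws(x)

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return("\t")
  if (lengths(regmatches(first, gregexpr("\t", first))) >=
      lengths(regmatches(first, gregexpr(",", first, fixed = TRUE)))) "\t" else ","
}

#' Parse a delimited miRNA-target interaction table
#'
#' Reads a headered TSV/CSV export of an MTI database and collapses duplicate
#' (miRNA, gene) rows into single interaction records. Duplicate-row
#' multiplicity becomes the record's `evidence_count`; extra mapped columns
#' are preserved as attributes with their first-seen value per pair.
#'
#' @param source path to a delimited text file with a header row.
#' @param column_map named list mapping roles to column names. Roles `mirna`
#'   and `gene` are required; the optional role `evidence` names an explicit
#'   per-row evidence-count column whose values are summed over duplicate
#'   rows instead of counting rows; any other entries name attribute columns
#'   to preserve.
#' @param name dataset name; defaults to the file name without extension.
#' @param delim field delimiter; by default auto-detected between tab and
#'   comma from the header line.
#' @return An [mti_dataset()].
#' @export
parse_interaction_table <- function(source,
                                    column_map = list(mirna = "mirna_id",
                                                      gene = "gene_id"),
                                    name = NULL, delim = NULL) {
  if (!file.exists(source)) stop("cannot read interaction table: ", source)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(source))
  if (is.null(delim)) delim <- detect_delim(source)
  tab <- utils::read.table(source, header = TRUE, sep = delim, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", comment.char = "")
  if (is.null(column_map$mirna) || is.null(column_map$gene)) {
    stop("column_map must name 'mirna' and 'gene' columns")
  }
  attr_roles <- setdiff(names(column_map), c("mirna", "gene", "evidence"))
  mapped <- unlist(column_map, use.names = FALSE)
  absent <- setdiff(mapped, names(tab))
  if (length(absent) > 0L) {
    stop("configuration error: mapped column(s) not in table: ",
         paste(absent, collapse = ", "))
  }
  attr_cols <- unlist(column_map[attr_roles], use.names = FALSE)
  if (nrow(tab) == 0L) {
    return(mti_dataset(empty_records(attr_cols), name = name))
  }

  mirna <- normalize_mirna_id(tab[[column_map$mirna]])
  gene <- normalize_gene_id(tab[[column_map$gene]])
  keep <- nzchar(mirna) & nzchar(gene)
  if (!all(keep)) {
    warning(sum(!keep), " row(s) with empty identifiers dropped")
    tab <- tab[keep, , drop = FALSE]
    mirna <- mirna[keep]
    gene <- gene[keep]
  }
  if (nrow(tab) == 0L) return(mti_dataset(empty_records(attr_cols), name = name))

  key <- paste(mirna, gene, sep = "\r")
  groups <- split(seq_along(key), factor(key, levels = unique(key)))
  first_idx <- vapply(groups, `[[`, integer(1), 1L)
  if (!is.null(column_map$evidence)) {
    ev_raw <- suppressWarnings(as.numeric(tab[[column_map$evidence]]))
    if (anyNA(ev_raw)) stop("evidence column contains non-numeric values")
    evidence <- vapply(groups, function(i) as.integer(sum(ev_raw[i])), integer(1))
  } else {
    evidence <- lengths(groups)
  }

  records <- data.frame(mirna_id = mirna[first_idx],
                        gene_id = gene[first_idx],
                        evidence_count = as.integer(evidence),
                        stringsAsFactors = FALSE)
  for (a in attr_cols) {
    vals <- trimws(tab[[a]])
    n_conflict <- sum(vapply(groups, function(i) length(unique(vals[i])) > 1L,
                             logical(1)))
    if (n_conflict > 0L) {
      warning("attribute '", a, "': ", n_conflict,
              " pair(s) with conflicting values; first-seen value kept")
    }
    records[[a]] <- vals[first_idx]
  }
  mti_dataset(records, name = name)
}

#' Keep interactions with enough evidence
#'
#' Retains records whose `evidence_count` is at least `min_evidence`. This
#' implements per-database quality rules of the form "keep interactions with
#' at least k duplicate entries".
#'
#' @param ds an [mti_dataset()].
#' @param min_evidence positive integer threshold.
#' @return A filtered [mti_dataset()]; the name records the filter applied.
#' @export
filter_min_evidence <- function(ds, min_evidence) {
  stopifnot(inherits(ds, "mti_dataset"))
  min_evidence <- as.integer(min_evidence)
  if (is.na(min_evidence) || min_evidence < 1L) stop("min_evidence must be >= 1")
  keep <- ds$records$evidence_count >= min_evidence
  mti_dataset(ds$records[keep, , drop = FALSE],
              name = sprintf("%s [evidence>=%d]", ds$name, min_evidence))
}

#' Keep interactions whose attribute value is allowed
#'
#' Retains records whose value in `column` (after whitespace trimming) is one
#' of `allowed`, e.g. keeping only interactions tagged "Functional MTI".
#'
#' @param ds an [mti_dataset()].
#' @param column attribute column name; must be present in the records.
#' @param allowed character vector of admissible values.
#' @return A filtered [mti_dataset()].
#' @export
filter_attribute <- function(ds, column, allowed) {
  stopifnot(inherits(ds, "mti_dataset"))
  if (!column %in% names(ds$records)) {
    stop("configuration error: attribute column '", column,
         "' absent from dataset '", ds$name, "'")
  }
  keep <- trimws(ds$records[[column]]) %in% trimws(allowed)
  mti_dataset(ds$records[keep, , drop = FALSE],
              name = sprintf("%s [%s in {%s}]", ds$name, column,
                             paste(allowed, collapse = ",")))
}

#' Construct a gene set
#'
#' @param genes character vector of gene identifiers; normalized (trimmed,
#'   upper-cased) and deduplicated.
#' @param name set name.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(genes, name = "gene_set") {
  genes <- normalize_gene_id(genes)
  genes <- unique(genes[nzchar(genes)])
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("Gene set '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Read a disease gene set from a one-identifier-per-line file
#'
#' Blank lines are skipped and identifiers are normalized (trimmed,
#' upper-cased) and deduplicated.
#'
#' @param source path to a plain-text file, one gene identifier per line.
#' @param name set name; defaults to the file name without extension.
#' @return A [gene_set()].
#' @export
read_gene_set <- function(source, name = NULL) {
  if (!file.exists(source)) stop("cannot read gene set: ", source)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(source))
  gene_set(readLines(source, warn = FALSE), name = name)
}

#' Summarize an MTI dataset
#'
#' @param ds an [mti_dataset()].
#' @return A list with counts `interactions`, `mirnas`, `genes`.
#' @export
summarize_dataset <- function(ds) {
  stopifnot(inherits(ds, "mti_dataset"))
  list(interactions = nrow(ds$records),
       mirnas = length(unique(ds$records$mirna_id)),
       genes = length(unique(ds$records$gene_id)))
}

#' Write an MTI dataset as TSV
#'
#' @param ds an [mti_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mti_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "mti_dataset"))
  utils::write.table(ds$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
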