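#' Read a gene expression matrix
#'
#' Reads a delimited text file with gene (or probe) identifiers in the first
#' column and one column per sample. The file must contain a header row with
#' sample identifiers and no missing values: co-expression inference assumes
#' pre-processed, complete data, and silent pairwise deletion would change the
#' effective sample size per gene pair and invalidate the permutation null.
#'
#' @param path Path to the expression file.
#' @param sep Field delimiter (default tab).
#' @param drop_na_rows If `TRUE`, rows (genes) containing any missing value are
#'   dropped with a warning instead of causing an error.
#' @return A numeric matrix (genes x samples) with gene identifiers as row
#'   names and sample identifiers as column names.
#' @export
read_expression <- function(path, sep = "\t", drop_na_rows = FALSE) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  tab <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           row.names = NULL, stringsAsFactors = FALSE,
                           comment.char = "")
  if (ncol(tab) < 2L) stop("expression file needs an id column and at least one sample column")
  ids <- as.character(tab[[1L]])
  samples <- colnames(tab)[-1L]
  if (anyDuplicated(samples))
    stop("duplicated sample identifiers: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(tab[-1L], is.numeric, logical(1L)))
    stop("non-numeric expression values in column(s): ",
         paste(samples[bad], collapse = ", "))
  }
  if (anyNA(vals)) {
    na_idx <- which(is.na(vals), arr.ind = TRUE)
    if (drop_na_rows) {
      drop <- unique(na_idx[, 1L])
      warning("dropping ", length(drop), " gene(s) with missing values: ",
              paste(utils::head(ids[drop], 5L), collapse = ", "),
              if (length(drop) > 5L) ", ..." else "")
      vals <- vals[-drop, , drop = FALSE]
      ids <- ids[-drop]
    } else {
      stop("missing value at gene '", ids[na_idx[1L, 1L]], "', sample '",
           samples[na_idx[1L, 2L]], "' (use drop_na_rows = TRUE to remove incomplete genes)")
    }
  }
  if (anyDuplicated(ids))
    stop("duplicated gene identifiers (collapse probes with an annotation table first): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  dimnames(vals) <- list(ids, samples)
  vals
}

#' Read phenotype labels
#'
#' Accepts either a two-column delimited file (`sample_id<TAB>label`, no
#' header required) or a CLS-style file (first line `<n> 2 1`, second line
#' `# <labelA> <labelB>`, third line the per-sample labels). The dialect is
#' auto-detected from the first line. Exactly two distinct phenotype labels
#' are required, each with at least two samples.
#'
#' CLS files carry no sample identifiers; the returned labels are positional
#' and are matched to expression columns in file order at analysis time.
#'
#' @param path Path to the label file.
#' @return A named character vector of labels (class `phenotype_labels`), with
#'   attribute `positional = TRUE` when read from a CLS file.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty label file")
  first <- strsplit(trimws(lines[1L]), "[ \t]+")[[1L]]
  is_cls <- length(first) >= 2L && !anyNA(suppressWarnings(as.numeric(first)))
  if (is_cls) {
    if (length(lines) < 3L) stop("malformed CLS file: expected 3 lines")
    lab <- strsplit(trimws(lines[3L]), "[ \t]+")[[1L]]
    labels <- stats::setNames(lab, as.character(seq_along(lab)))
    attr(labels, "positional") <- TRUE
  } else {
    tab <- utils::read.table(path, sep = "", header = FALSE,
                             stringsAsFactors = FALSE, comment.char = "")
    if (ncol(tab) < 2L) stop("label file must have two columns: sample_id, label")
    # tolerate an optional header line
    if (identical(tolower(as.character(tab[1L, 1L])), "sample_id"))
      tab <- tab[-1L, , drop = FALSE]
    labels <- stats::setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
    if (anyDuplicated(names(labels)))
      stop("duplicated sample identifiers in label file")
    attr(labels, "positional") <- FALSE
  }
  uniq <- unique(labels)
  if (length(uniq) != 2L)
    stop("exactly two phenotypes required, found ", length(uniq), ": ",
         paste(uniq, collapse = ", "))
  if (any(table(unclass(labels)) < 2L))
    stop("each phenotype needs at least 2 samples")
  class(labels) <- c("phenotype_labels", class(labels))
  labels
}

#' Align phenotype labels to an expression matrix
#'
#' Positional (CLS) labels are assigned to expression columns in order; named
#' labels are matched by sample id, warning about and dropping labelled
#' samples absent from the matrix. Every expression sample must end up
#' labelled.
#'
#' @param labels Labels from [read_labels()].
#' @param expr Expression matrix from [read_expression()].
#' @return Character vector of labels aligned to `colnames(expr)`.
#' @export
align_labels <- function(labels, expr) {
  samples <- colnames(expr)
  if (isTRUE(attr(labels, "positional"))) {
    if (length(labels) != length(samples))
      stop("CLS file has ", length(labels), " labels but expression matrix has ",
           length(samples), " samples")
    return(stats::setNames(as.character(labels), samples))
  }
  unknown <- setdiff(names(labels), samples)
  if (length(unknown) > 0L) {
    warning("dropping ", length(unknown), " labelled sample(s) absent from the expression matrix: ",
            paste(utils::head(unknown, 5L), collapse = ", "))
    labels <- labels[setdiff(names(labels), unknown)]
  }
  missing <- setdiff(samples, names(labels))
  if (length(missing) > 0L)
    stop("expression samples without labels: ", paste(utils::head(missing, 5L), collapse = ", "))
  out <- stats::setNames(as.character(labels[samples]), samples)
  if (length(unique(out)) != 2L) stop("exactly two phenotypes required after alignment")
  if (any(table(out) < 2L)) stop("each phenotype needs at least 2 samples after alignment")
  out
}

#' Read a GMT gene-set collection
#'
#' Each line is `set_name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' genes within a set are removed keeping the first occurrence; set and gene
#' order follow the file.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors (class `gene_set_collection`),
#'   with per-set descriptions in the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character(0L)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields (name, description, genes...)")
    name <- fields[1L]
    if (name %in% names(sets)) stop("duplicated gene set name: ", name)
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    genes <- genes[!duplicated(genes)]
    if (length(genes) == 0L) stop("GMT line ", i, " (", name, ") has no genes")
    sets[[name]] <- genes
    desc[name] <- fields[2L]
  }
  structure(sets, descriptions = desc, class = "gene_set_collection")
}

#' Read a probe-to-gene annotation table
#'
#' Two-column delimited file mapping probe ids to gene symbols. Probes mapped
#' to empty or NA symbols are dropped; duplicated probe ids are an error.
#'
#' @param path Path to the annotation file.
#' @param sep Field delimiter.
#' @return A data frame with columns `probe_id` and `gene_symbol`.
#' @export
read_annotation <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(tab) < 2L) stop("annotation table must have probe and gene columns")
  ann <- data.frame(probe_id = as.character(tab[[1L]]),
                    gene_symbol = as.character(tab[[2L]]),
                    stringsAsFactors = FALSE)
  ann <- ann[!is.na(ann$gene_symbol) & nzchar(trimws(ann$gene_symbol)), , drop = FALSE]
  if (anyDuplicated(ann$probe_id))
    stop("duplicated probe ids in annotation table: ",
         paste(unique(ann$probe_id[duplicated(ann$probe_id)]), collapse = ", "))
  ann
}

#' Collapse probe-level rows to gene symbols
#'
#' For every gene the representative probe is the one with maximal mean
#' expression across all samples (the common collapse rule for probe-level
#' microarray data); ties are broken by the lexicographically smallest probe
#' id. Probes absent from the annotation are dropped with a warning.
#'
#' @param expr Probe-level expression matrix.
#' @param annotation Annotation table from [read_annotation()] (columns
#'   `probe_id`, `gene_symbol`).
#' @return Gene-level expression matrix with unique gene symbols as row names.
#' @export
collapse_probes <- function(expr, annotation) {
  stopifnot(is.matrix(expr), all(c("probe_id", "gene_symbol") %in% colnames(annotation)))
  map <- stats::setNames(annotation$gene_symbol, annotation$probe_id)
  probes <- rownames(expr)
  mapped <- probes %in% names(map)
  if (!any(mapped)) stop("no probe in the expression matrix maps to a gene symbol")
  if (!all(mapped))
    warning("dropping ", sum(!mapped), " unmapped probe(s)")
  expr <- expr[mapped, , drop = FALSE]
  probes <- rownames(expr)
  genes <- unname(map[probes])
  means <- rowMeans(expr)
  ord <- order(genes, -means, probes, method = "radix")
  keep <- ord[!duplicated(genes[ord])]
  keep <- sort(keep)  # preserve input row order of the winning probes
  out <- expr[keep, , drop = FALSE]
  rownames(out) <- genes[keep]
  out
}

#' Write a differential co-expression result table
#'
#' Writes results as tab-delimited text with columns `set_name`, `set_size`,
#' `statistic_name`, `statistic`, `p_value`, `q_value`, sorted by increasing
#' p-value.
#'
#' @param results Data frame of test results, e.g. from [analyze_collection()].
#' @param path Output path.
#' @return Invisibly, the sorted data frame that was written.
#' @export
write_results <- function(results, path) {
  cols <- c("set_name", "set_size", "statistic_name", "statistic", "p_value", "q_value")
  stopifnot(is.data.frame(results), nrow(results) > 0L, all(cols %in% colnames(results)))
  out <- results[order(results$p_value), cols, drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
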