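#' Abundance tables for paired bacterial/fungal surveys
#'
#' An `abundance_table` holds a taxa-by-samples matrix of sequence counts or
#' relative abundances, the domain (bacteria or fungi) of each taxon, and a
#' flag saying whether entries are relative. It is the common currency of the
#' whole pipeline: filtering, diversity, networks, and the assembly models all
#' consume it.
#'
#' @param counts numeric matrix, taxa in rows, samples in columns; rownames
#'   are taxon IDs and colnames sample IDs. All entries must be `>= 0`.
#' @param domain character vector (or single string, recycled) giving
#'   `"bacteria"` or `"fungi"` per taxon.
#' @param is_relative logical; if `NULL`, inferred: `TRUE` when every sample
#'   column sums to 1 within `1e-6`.
#' @return an object of class `abundance_table` with fields `counts`,
#'   `domain` (named by taxon), `is_relative`.
#' @examples
#' m <- matrix(c(5, 3, 0, 2, 1, 4), nrow = 3,
#'             dimnames = list(paste0("otu", 1:3), c("s1", "s2")))
#' abundance_table(m, domain = "bacteria")
#' @export
abundance_table <- function(counts, domain = "bacteria", is_relative = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop2("counts must have taxon rownames and sample colnames")
  }
  if (!is.numeric(counts)) stop2("counts must be numeric")
  if (anyNA(counts)) stop2("missing values are not allowed; write explicit zeros")
  if (any(counts < 0)) stop2("negative abundances found")
  if (anyDuplicated(rownames(counts))) {
    stop2("duplicate taxon IDs: ",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop2("duplicate sample IDs: ",
          paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  }
  domain <- rep_len(as.character(domain), nrow(counts))
  if (!all(domain %in% c("bacteria", "fungi"))) {
    stop2("domain must be 'bacteria' or 'fungi'")
  }
  names(domain) <- rownames(counts)
  if (is.null(is_relative)) {
    cs <- colSums(counts)
    is_relative <- ncol(counts) > 0 && all(abs(cs - 1) <= 1e-6)
  }
  structure(list(counts = counts, domain = domain,
                 is_relative = isTRUE(is_relative)),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d taxa x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$is_relative) "relative abundances" else "counts"))
  tab <- table(x$domain)
  cat("  domains:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$counts)

#' Taxon and sample identifiers of an abundance table
#' @param t an [abundance_table()].
#' @return character vector of IDs.
#' @export
taxa_ids <- function(t) rownames(t$counts)

#' @rdname taxa_ids
#' @export
sample_ids <- function(t) colnames(t$counts)

#' Convert an abundance table to relative abundances
#'
#' Each sample column is divided by its total. Columns with zero total are an
#' error (an all-zero sample carries no compositional information).
#'
#' @param t an [abundance_table()].
#' @return an `abundance_table` with `is_relative = TRUE`.
#' @export
to_relative <- function(t) {
  stopifnot(inherits(t, "abundance_table"))
  if (t$is_relative) return(t)
  cs <- colSums(t$counts)
  if (any(cs == 0)) {
    stop2("samples with zero total abundance: ",
          paste(colnames(t$counts)[cs == 0], collapse = ", "))
  }
  abundance_table(sweep(t$counts, 2, cs, "/"), t$domain, is_relative = TRUE)
}

#' Read an abundance table from a TSV matrix
#'
#' Expects a tab-separated file whose first column holds taxon IDs and whose
#' header row holds sample IDs; `.` is the decimal separator. Whether entries
#' are relative abundances is inferred (all column sums within 1e-6 of 1)
#' unless `is_relative` is given.
#'
#' @param path file path.
#' @param domain `"bacteria"` or `"fungi"` label recorded for every taxon.
#' @param is_relative optional logical override.
#' @return an [abundance_table()].
#' @export
read_abundance_table <- function(path, domain = "bacteria", is_relative = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop2("duplicate taxon IDs in ", path, ": ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  body <- df[, -1L, drop = FALSE]
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, colnames(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop2(sprintf("non-numeric cell at taxon '%s', sample '%s'",
                  ids[bad[1L]], colnames(body)[bad[2L]]))
  }
  rownames(num) <- ids
  abundance_table(num, domain = domain, is_relative = is_relative)
}

#' Write an abundance table as TSV
#'
#' Inverse of [read_abundance_table()]: `read(write(x))` preserves IDs,
#' values, and ordering exactly.
#'
#' @param t an [abundance_table()].
#' @param path output file path.
#' @export
write_abundance_table <- function(t, path) {
  stopifnot(inherits(t, "abundance_table"))
  df <- data.frame(taxon_id = rownames(t$counts), t$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a metabolite concentration table
#'
#' TSV matrix, metabolites in rows, samples in columns; concentrations in
#' mg/kg fermented grain (the unit is carried as an attribute, not
#' validated). Negative entries and duplicate IDs are errors.
#'
#' @param path file path.
#' @param unit unit label stored with the table.
#' @return a numeric matrix (metabolites x samples) of class
#'   `metabolite_table` with attribute `unit`.
#' @export
read_metabolite_table <- function(path, unit = "mg/kg") {
  t <- read_abundance_table(path, domain = "bacteria", is_relative = FALSE)
  metabolite_table(t$counts, unit = unit)
}

#' Construct a metabolite table from a matrix
#' @param concentrations numeric non-negative matrix, metabolites x samples.
#' @param unit unit label.
#' @export
metabolite_table <- function(concentrations, unit = "mg/kg") {
  concentrations <- as.matrix(concentrations)
  if (anyNA(concentrations) || any(concentrations < 0)) {
    stop2("metabolite concentrations must be non-negative and complete")
  }
  if (anyDuplicated(rownames(concentrations)) || anyDuplicated(colnames(concentrations))) {
    stop2("duplicate metabolite or sample IDs")
  }
  structure(concentrations, unit = unit, class = c("metabolite_table", "matrix", "array"))
}

#' Read sample metadata
#'
#' TSV with a `sample_id` column, a grouping column (e.g. workshop), a
#' numeric `time` column (fermentation day), and any further numeric
#' environmental covariates (temperature, moisture, acidity, ...).
#'
#' @param path file path.
#' @return a `data.frame` with rownames set to `sample_id`.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df)) stop2("metadata needs a 'sample_id' column")
  if (anyDuplicated(df$sample_id)) stop2("duplicate sample_id in metadata")
  rownames(df) <- df$sample_id
  df
}

#' Read a taxonomy map
#'
#' Two-column TSV: taxon ID, semicolon-delimited lineage string.
#'
#' @param path file path.
#' @return named character vector of lineages.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, comment.char = "")
  stats::setNames(df[[2L]], df[[1L]])
}

#' Merge bacterial and fungal abundance tables
#'
#' Row-concatenates two tables over an identical sample set (order may
#' differ; alignment is by sample ID, case sensitive). Because 16S and ITS
#' libraries are sequenced and normalized separately, relative abundances
#' are by default recomputed per domain, so that within each sample the
#' bacterial block and the fungal block each sum to 1; `normalize =
#' "global"` instead renormalizes jointly to a single composition, and
#' `normalize = "none"` keeps raw counts.
#'
#' @param bact,fungi [abundance_table()]s sharing a sample set.
#' @param normalize `"domain"` (default), `"global"`, or `"none"`.
#' @return merged [abundance_table()]; `is_relative` is `TRUE` unless
#'   `normalize = "none"`.
#' @export
merge_domains <- function(bact, fungi, normalize = c("domain", "global", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(bact, "abundance_table"), inherits(fungi, "abundance_table"))
  sa <- sample_ids(bact); sb <- sample_ids(fungi)
  if (!setequal(sa, sb)) {
    stop2("sample sets differ; only in first: {",
          paste(setdiff(sa, sb), collapse = ", "), "}; only in second: {",
          paste(setdiff(sb, sa), collapse = ", "), "}")
  }
  if (length(intersect(taxa_ids(bact), taxa_ids(fungi)))) {
    stop2("taxon IDs overlap between domains")
  }
  fungi_counts <- fungi$counts[, sa, drop = FALSE]
  b <- bact$counts; f <- fungi_counts
  if (normalize == "domain") {
    b <- sweep(b, 2, pmax(colSums(b), .Machine$double.eps), "/")
    f <- sweep(f, 2, pmax(colSums(f), .Machine$double.eps), "/")
  }
  m <- rbind(b, f)
  if (normalize == "global") {
    m <- sweep(m, 2, pmax(colSums(m), .Machine$double.eps), "/")
  }
  out <- abundance_table(m, domain = c(bact$domain, fungi$domain),
                         is_relative = normalize != "none")
  out
}

#' Write pipeline results to disk
#'
#' Dispatches on result type: per-taxon/matrix results go to TSV, scalar
#' model summaries to JSON, networks to GraphML plus a Gephi-compatible
#' edge-list TSV. Exported fields round-trip losslessly.
#'
#' @param obj a result object (`abundance_table`, `neutral_fit`,
#'   `cooccurrence_network`, `nst_result`, data.frame or matrix).
#' @param path output path; for networks, `<path>.graphml` and
#'   `<path>_edges.tsv` are written.
#' @return invisibly, the path(s) written.
#' @export
write_results <- function(obj, path) {
  UseMethod("write_results")
}

#' @export
write_results.abundance_table <- function(obj, path) write_abundance_table(obj, path)

#' @export
write_results.data.frame <- function(obj, path) {
  utils::write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.matrix <- function(obj, path) {
  df <- data.frame(id = rownames(obj), obj, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.default <- function(obj, path) {
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}

#' @export
write_results.neutral_fit <- function(obj, path) {
  base <- sub("\\.json$", "", path)
  fit_json <- list(m = obj$m, N = obj$N, d = obj$d, R2 = obj$R2,
                   n_boot = obj$n_boot, seed = obj$seed,
                   partition_counts = as.list(obj$partition_counts),
                   partition_cum_ra = as.list(obj$partition_cum_ra))
  jsonlite::write_json(fit_json, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.table(obj$taxa, paste0(base, "_taxa.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(paste0(base, ".json"), paste0(base, "_taxa.tsv")))
}

#' @export
write_results.cooccurrence_network <- function(obj, path) {
  base <- sub("\\.graphml$", "", path)
  g <- network_igraph(obj)
  igraph::write_graph(g, paste0(base, ".graphml"), format = "graphml")
  utils::write.table(obj$edges, paste0(base, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(paste0(base, ".graphml"), paste0(base, "_edges.tsv")))
}
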