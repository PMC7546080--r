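## Readers and writers for the standard input/output formats.

#' Read gene-level association results
#'
#' Whitespace- or tab-delimited table with a header; required columns
#' `GENE` and `P` (extra columns are ignored) — the layout of common
#' gene-level GWAS outputs.
#'
#' @param file path to the results table.
#' @return A data.frame with columns `GENE` (character) and `P`
#'   (numeric), plus any extra columns present.
#' @seealso [rankGenes()] to turn the table into a ranked background.
#' @export
readGeneResults <- function(file) {
  tab <- read.table(file, header = TRUE, stringsAsFactors = FALSE)
  need <- c("GENE", "P")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  tab$GENE <- as.character(tab$GENE)
  tab$P <- as.numeric(tab$P)
  tab
}

#' Read gene sets in GMT format
#'
#' Standard tab-delimited GMT: set name, description, then member genes.
#'
#' @param file path to a `.gmt` file.
#' @return Named list of character vectors of gene identifiers.
#' @export
readGMT <- function(file) {
  fgsea::gmtPathways(file)
}

#' Read or write gene weights as a two-column table
#'
#' Tab-separated `gene<TAB>weight`; the header line is optional on read
#' and written on write. The weight column must be non-negative.
#'
#' @param file path.
#' @return `readWeights`: a [WeightedGeneSet-class] (weights normalized).
#' @export
readWeights <- function(file) {
  first <- readLines(file, n = 1)
  hasHeader <- !grepl("^\\S+\\s+[0-9.eE+-]+$", first) ||
    is.na(suppressWarnings(as.numeric(strsplit(first, "\\s+")[[1]][2])))
  tab <- read.table(file, header = hasHeader, stringsAsFactors = FALSE)
  WeightedGeneSet(tab[[1]], as.numeric(tab[[2]]))
}

#' @rdname readWeights
#' @param set a [WeightedGeneSet-class].
#' @export
writeWeights <- function(set, file) {
  stopifnot(is(set, "WeightedGeneSet"))
  tab <- data.frame(gene = geneIds(set), weight = unname(geneWeights(set)))
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a correlation matrix from TSV
#'
#' Square numeric matrix with gene identifiers as header row and first
#' column.
#'
#' @param file path.
#' @return A numeric matrix with dimnames.
#' @export
readCorrelationMatrix <- function(file) {
  tab <- read.table(file, header = TRUE, row.names = 1, sep = "\t",
                    check.names = FALSE)
  as.matrix(tab)
}

#' Write a correlation matrix as TSV
#'
#' @rdname readCorrelationMatrix
#' @param x square numeric matrix with dimnames.
#' @export
writeCorrelationMatrix <- function(x, file) {
  write.table(cbind(gene = rownames(x), as.data.frame(x)), file,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a test result as TSV or JSON
#'
#' Serializes a [NullEstimate-class] (statistic, method, sidedness,
#' p-value, standard error, sample count, seed).
#'
#' @param est a [NullEstimate-class].
#' @param file output path.
#' @param format `"tsv"` or `"json"`.
#' @export
writeTestResult <- function(est, file, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is(est, "NullEstimate"))
  rec <- list(v = est@v, method = est@method, sided = est@sided,
              p = est@p, se = est@stdError, K = est@nSamples,
              seed = est@seed)
  if (format == "tsv") {
    write.table(as.data.frame(rec), file, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    jsonlite::write_json(rec, file, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(file)
}

#' Read parameter specifications from TSV or YAML
#'
#' TSV columns: `parameter` (or `name`), `baseline`, `units`, `genes`
#' (semicolon-separated), optional `excluded_genes`. A YAML file holds a
#' list of records with the same fields.
#'
#' @param file path (`.tsv`/`.txt` or `.yml`/`.yaml`).
#' @return A [ParameterSet-class].
#' @export
readParameterSpecs <- function(file) {
  splitGenes <- function(s) {
    s[is.na(s)] <- ""
    lapply(strsplit(as.character(s), ";", fixed = TRUE),
           function(g) g[nzchar(g)])
  }
  if (grepl("\\.ya?ml$", file, ignore.case = TRUE)) {
    cfg <- yaml::read_yaml(file)
    ParameterSet(
      name = vapply(cfg, function(p) p$name %||% p$parameter, ""),
      baseline = vapply(cfg, function(p) as.numeric(p$baseline), 0.0),
      units = vapply(cfg, function(p) p$units %||% "", ""),
      genes = lapply(cfg, function(p) unlist(p$genes)),
      excluded = lapply(cfg, function(p)
        as.character(unlist(p$excluded_genes))))
  } else {
    tab <- read.table(file, header = TRUE, sep = "\t", fill = TRUE,
                      quote = "", comment.char = "",
                      stringsAsFactors = FALSE, na.strings = NULL)
    nm <- if ("parameter" %in% names(tab)) tab$parameter else tab$name
    exc <- if ("excluded_genes" %in% names(tab))
      splitGenes(tab$excluded_genes)
    else rep(list(character(0)), nrow(tab))
    ParameterSet(nm, tab$baseline,
                 if ("units" %in% names(tab)) tab$units else
                   rep("", nrow(tab)),
                 genes = splitGenes(tab$genes), excluded = exc)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
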