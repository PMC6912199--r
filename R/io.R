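#' Readers and writers for the plain-text exchange formats
#'
#' All inputs are tab-separated text with a header line:
#' \itemize{
#'   \item gene network: `gene1 <TAB> gene2 <TAB> lls`
#'   \item disease-gene map: `disease <TAB> gene`
#'   \item miRNA target / family / cluster tables: `mirna <TAB> target`
#'     (or `family`, `cluster`)
#'   \item associations: `disease <TAB> mirna`
#'   \item precomputed miRNA similarity (disease-derived component):
#'     square TSV matrix with miRNA IDs as header row and first column
#' }
#' Similarity matrices are written the same way; node embeddings use the
#' word2vec text format (`|V| n` header then one `id v1 ... vn` line per node).
#'
#' @name stim-io
NULL

read_two_col <- function(path, col1, col2) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (!all(c(col1, col2) %in% names(df)))
    stop2("file ", path, " must have columns '", col1, "' and '", col2, "'")
  df[, c(col1, col2)]
}

#' @rdname stim-io
#' @param path file path.
#' @return `read_gene_network()`: a `gene_network` object.
#' @export
read_gene_network <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "numeric"))
  names(df) <- c("gene1", "gene2", "lls")
  gene_network(df)
}

#' @rdname stim-io
#' @return `read_disease_gene_map()`: named list mapping disease ID to a
#'   character vector of gene IDs.
#' @export
read_disease_gene_map <- function(path) {
  df <- read_two_col(path, "disease", "gene")
  lapply(split(df$gene, df$disease), unique)
}

#' @rdname stim-io
#' @param value_col name of the second column (`"target"`, `"family"`,
#'   `"cluster"`).
#' @return `read_mirna_map()`: named list mapping miRNA ID to a character
#'   vector of group/target IDs.
#' @export
read_mirna_map <- function(path, value_col = "target") {
  df <- read_two_col(path, "mirna", value_col)
  lapply(split(df[[value_col]], df$mirna), unique)
}

#' @rdname stim-io
#' @param diseases,mirnas optional full ID lists passed to
#'   [association_network()].
#' @return `read_associations()`: an `assoc_network`.
#' @export
read_associations <- function(path, diseases = NULL, mirnas = NULL) {
  df <- read_two_col(path, "disease", "mirna")
  association_network(df, diseases = diseases, mirnas = mirnas)
}

#' @rdname stim-io
#' @return `read_similarity_matrix()`: a symmetric numeric matrix with IDs as
#'   dimnames.
#' @export
read_similarity_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  mode(m) <- "numeric"
  check_similarity_matrix(m)
  m
}

#' @rdname stim-io
#' @param m similarity matrix with IDs as dimnames.
#' @export
write_similarity_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname stim-io
#' @param emb embedding matrix (rows = nodes, rownames = IDs).
#' @export
write_embeddings <- function(emb, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(emb), ncol(emb)), con)
  writeLines(paste(rownames(emb),
                   apply(emb, 1L, function(v)
                     paste(sprintf("%.17g", v), collapse = " "))),
             con)
  invisible(path)
}

#' @rdname stim-io
#' @return `read_embeddings()`: numeric matrix with node IDs as rownames.
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1L], " ")[[1L]])
  parts <- strsplit(lines[-1L], " ", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1L)
  emb <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1L])))
  if (nrow(emb) != hdr[1L] || ncol(emb) != hdr[2L])
    stop2("embedding file header disagrees with body: ", path)
  rownames(emb) <- ids
  emb
}

#' @rdname stim-io
#' @param walks list of character vectors (one walk per element).
#' @export
write_walks <- function(walks, path) {
  writeLines(vapply(walks, paste, "", collapse = " "), path)
  invisible(path)
}
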