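# TSV dialect used throughout: tab-separated, UTF-8, '#' comment lines
# ignored, empty cell or "NA" for missing.

read_tsv_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = c("", "NA"))
}

#' Read a log2 expression matrix from TSV
#'
#' Expects a header row of strain names; the first column holds gene
#' identifiers. Missing cells (empty or `NA`) are kept missing, never
#' coerced to zero.
#'
#' @param path Path to the TSV file.
#' @param condition Condition label to tag the matrix with.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, condition = "combined") {
  df <- read_tsv_table(path)
  genes <- as.character(df[[1]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene identifier(s) in ", path, ": ", paste(dup, collapse = ", "))
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      bad <- which(!is.na(col) & is.na(suppressWarnings(as.numeric(col))))
      if (length(bad))
        stop(sprintf("non-numeric cell at row %d, column '%s' in %s",
                     bad[1], names(vals)[j], path))
      vals[[j]] <- as.numeric(col)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  expression_matrix(m, condition)
}

#' Write an expression matrix to TSV
#'
#' @param expr An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), full_precision(unclass(expr)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# print doubles with enough digits that reading them back is lossless
full_precision <- function(m) {
  out <- apply(m, 2, function(col) {
    s <- sprintf("%.17g", col)
    s[is.na(col)] <- NA_character_
    s
  })
  rownames(out) <- rownames(m)
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Read a genotype matrix
#'
#' Two dialects are supported. Plain TSV: columns `marker`, `chr`, `pos`,
#' then one column per strain. GeneNetwork-style `.geno`: header lines
#' starting with `@` or `#` are skipped, and the data table has columns
#' `Chr`, `Locus`, `cM` followed by strain columns.
#'
#' @param path Input path.
#' @param alleles Named translation from allele symbols to codes. `NA`
#'   entries are recorded as missing.
#' @param pos_unit Unit of the position column.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, alleles = c(B = 0, D = 1, H = NA, U = NA),
                           pos_unit = "cM") {
  first <- readLines(path, n = 50L)
  is_geno <- grepl("\\.geno$", path) || any(startsWith(first, "@"))
  if (is_geno) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "@") & !startsWith(lines, "#") &
                     nzchar(trimws(lines))]
    con <- textConnection(lines)
    on.exit(close(con))
    df <- utils::read.delim(con, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    map <- data.frame(marker = as.character(df$Locus), chr = as.character(df$Chr),
                      pos = as.numeric(df$cM), stringsAsFactors = FALSE)
    strain_cols <- setdiff(names(df), c("Chr", "Locus", "cM", "Mb"))
  } else {
    df <- read_tsv_table(path)
    map <- data.frame(marker = as.character(df$marker), chr = as.character(df$chr),
                      pos = as.numeric(df$pos), stringsAsFactors = FALSE)
    strain_cols <- setdiff(names(df), c("marker", "chr", "pos"))
  }
  sym <- as.matrix(df[, strain_cols, drop = FALSE])
  known <- c(names(alleles), NA)
  if (is.numeric(sym)) {
    codes <- sym
  } else {
    sym[!is.na(sym)] <- trimws(sym[!is.na(sym)])
    unknown <- setdiff(unique(as.vector(sym)), known)
    if (length(unknown))
      stop("unknown allele symbol(s): ", paste(unknown, collapse = ", "))
    codes <- matrix(alleles[as.vector(sym)], nrow = nrow(sym),
                    dimnames = list(map$marker, strain_cols))
  }
  colnames(codes) <- strain_cols
  genotype_matrix(codes, map, pos_unit = pos_unit)
}

#' Write a genotype matrix to plain TSV
#'
#' @param geno A [genotype_matrix()].
#' @param path Output path.
#' @param alleles Code-to-symbol translation used for the strain columns.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, alleles = c(`0` = "B", `1` = "D")) {
  sym <- matrix(alleles[as.character(geno$codes)], nrow = nrow(geno$codes))
  sym[is.na(sym)] <- "U"
  colnames(sym) <- colnames(geno$codes)
  df <- data.frame(marker = geno$map$marker, chr = geno$map$chr,
                   pos = geno$map$pos, sym,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table (strains x traits TSV)
#'
#' @param path Input path; first column must be the strain identifier.
#' @return A [phenotype_table()].
#' @export
read_phenotypes <- function(path) {
  df <- read_tsv_table(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  phenotype_table(m)
}

#' Write a phenotype table to TSV
#' @param phen A [phenotype_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phen, path) {
  df <- data.frame(strain = rownames(phen), full_precision(unclass(phen)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a STRING-style protein-links TSV
#'
#' Columns `protein1`, `protein2`, `combined_score` (whitespace- or
#' tab-separated, as STRING distributes them).
#'
#' @param path Input path.
#' @return A [ppi_edgelist()].
#' @export
read_ppi <- function(path) {
  df <- utils::read.table(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(df)))
    stop("PPI file needs columns: ", paste(need, collapse = ", "))
  ppi_edgelist(df$protein1, df$protein2, df$combined_score)
}

#' Write a PPI edge list to TSV
#' @param ppi A [ppi_edgelist()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ppi <- function(ppi, path) {
  utils::write.table(ppi, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path Input path (set name, description, then members, tab-separated).
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) stop("GMT line ", bad[1], " has fewer than 3 fields")
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, "", 1L)
  gene_set_collection(sets, vapply(parts, `[`, "", 2L))
}

#' Write a gene-set collection as GMT
#' @param gsc A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gsc, path) {
  desc <- attr(gsc, "descriptions")
  lines <- vapply(names(gsc), function(nm) {
    paste(c(nm, desc[[nm]], gsc[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Export a weighted edge list as SIF, GraphML or TSV
#'
#' Node and edge order are made deterministic (lexicographic within each
#' edge, then by node pair) so repeated exports diff clean.
#'
#' @param edges Data frame with columns `from`, `to` and optionally
#'   `weight`.
#' @param format One of `"SIF"`, `"GraphML"`, `"TSV"`.
#' @param path Output path.
#' @param interaction Interaction label used in SIF lines.
#' @return `path`, invisibly.
#' @export
write_network <- function(edges, format = c("SIF", "GraphML", "TSV"), path,
                          interaction = "pp") {
  if (is.character(format) && length(format) == 1 &&
      !(format %in% c("SIF", "GraphML", "TSV")))
    stop("unknown network format: ", format)
  format <- match.arg(format)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    a <- pmin(as.character(edges$from), as.character(edges$to))
    b <- pmax(as.character(edges$from), as.character(edges$to))
    o <- order(a, b)
    edges$from <- a
    edges$to <- b
    edges <- edges[o, , drop = FALSE]
  }
  if (format == "SIF") {
    lines <- if (nrow(edges))
      paste(edges$from, interaction, edges$to, sep = "\t") else character(0)
    writeLines(lines, path)
  } else if (format == "TSV") {
    utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Z-score an expression matrix per gene
#'
#' Optional post-log2 standardization: each gene is centered and scaled to
#' unit variance across the strains of this matrix (i.e. per condition when
#' applied per condition). The transformation applied is recorded in the
#' `zscored` attribute.
#'
#' @param expr An [expression_matrix()].
#' @return The standardized `ExpressionMatrix`.
#' @export
zscore_expression <- function(expr) {
  m <- t(scale(t(unclass(expr))))
  attr(m, "scaled:center") <- NULL
  attr(m, "scaled:scale") <- NULL
  out <- expression_matrix(m, condition_of(expr))
  attr(out, "zscored") <- "per-matrix"
  out
}
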