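CONDITIONS <- c("NOS", "RSS", "NOE", "RSE")

#' Construct an expression matrix
#'
#' A log2-scale strain-mean expression matrix: genes in rows, strains in
#' columns, tagged with the treatment condition it was measured under.
#'
#' @param values Numeric matrix, genes x strains. Row names are gene
#'   identifiers, column names are strain identifiers. `NA` marks missing
#'   cells.
#' @param condition Condition label, one of `"NOS"`, `"RSS"`, `"NOE"`,
#'   `"RSE"`, or `"combined"`.
#' @return An object of class `ExpressionMatrix` (a numeric matrix with a
#'   `condition` attribute).
#' @export
expression_matrix <- function(values, condition = "combined") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene row names and strain column names")
  dup_g <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_g))
    stop("duplicate gene identifier(s): ", paste(unique(dup_g), collapse = ", "))
  dup_s <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_s))
    stop("duplicate strain identifier(s): ", paste(unique(dup_s), collapse = ", "))
  if (nrow(values) < 2) stop("need at least 2 genes")
  if (ncol(values) < 3) stop("need at least 3 strains")
  if (any(is.infinite(values)))
    stop("expression values must be finite or NA")
  if (!is.character(condition) || length(condition) != 1 ||
      !(condition %in% c(CONDITIONS, "combined")))
    stop("`condition` must be one of ", paste(c(CONDITIONS, "combined"), collapse = ", "))
  structure(values, condition = condition, class = c("ExpressionMatrix", "matrix", "array"))
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d strains, condition %s\n",
              nrow(x), ncol(x), attr(x, "condition")))
  invisible(x)
}

#' Condition label of an expression matrix
#' @param x An `ExpressionMatrix`.
#' @return The condition label.
#' @export
condition_of <- function(x) attr(x, "condition")

# matrix subsetting drops attributes; keep class/condition when result is
# still a matrix
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    attr(out, "condition") <- attr(x, "condition")
    class(out) <- class(x)
  }
  out
}

#' Construct a genotype matrix
#'
#' Biallelic RI-strain genotypes: markers in rows (with a genetic/physical
#' map), strains in columns, codes 0 (B6-like), 1 (D2-like), NA (missing or
#' heterozygous).
#'
#' @param codes Integer/numeric matrix markers x strains with values in
#'   \{0, 1, NA\}.
#' @param map Data frame with columns `marker`, `chr`, `pos` (one row per
#'   row of `codes`, same order).
#' @param pos_unit Unit of `pos`: `"cM"` (default) or `"Mb"`.
#' @return An object of class `GenotypeMatrix`: list with `codes`, `map`,
#'   `pos_unit`.
#' @export
genotype_matrix <- function(codes, map, pos_unit = c("cM", "Mb")) {
  pos_unit <- match.arg(pos_unit)
  if (!is.matrix(codes)) stop("`codes` must be a matrix")
  bad <- setdiff(unique(as.vector(codes)), c(0, 1, NA))
  if (length(bad))
    stop("genotype codes must be 0, 1 or NA; found: ", paste(bad, collapse = ", "))
  storage.mode(codes) <- "integer"
  need <- c("marker", "chr", "pos")
  if (!all(need %in% names(map))) stop("`map` needs columns marker, chr, pos")
  if (nrow(map) != nrow(codes)) stop("map rows must match code rows")
  rownames(codes) <- map$marker
  # positions must be non-decreasing within each chromosome
  for (ch in unique(map$chr)) {
    p <- map$pos[map$chr == ch]
    if (is.unsorted(p))
      stop("marker positions out of order on chromosome ", ch)
  }
  structure(list(codes = codes, map = map, pos_unit = pos_unit),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d markers x %d strains (%d chromosome(s), pos in %s)\n",
              nrow(x$codes), ncol(x$codes), length(unique(x$map$chr)), x$pos_unit))
  invisible(x)
}

#' Construct a phenotype table
#'
#' @param values Numeric matrix or data frame, strains x traits, with strain
#'   row names and trait column names.
#' @return A `PhenotypeTable` (numeric matrix strains x traits).
#' @export
phenotype_table <- function(values) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("phenotype values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("phenotype table needs strain row names and trait column names")
  structure(values, class = c("PhenotypeTable", "matrix", "array"))
}

#' Construct a protein-protein interaction edge list
#'
#' Unordered protein pairs with a STRING-style combined score. Self edges
#' are rejected; duplicate unordered pairs are collapsed keeping the
#' maximum score.
#'
#' @param protein1,protein2 Character vectors of interaction partners.
#' @param combined_score Integer scores in \[0, 1000\].
#' @return A `PPIEdgeList` data frame with columns `protein1`, `protein2`,
#'   `combined_score`, canonicalized so `protein1 < protein2`.
#' @export
ppi_edgelist <- function(protein1, protein2, combined_score) {
  protein1 <- as.character(protein1)
  protein2 <- as.character(protein2)
  combined_score <- as.numeric(combined_score)
  if (length(protein1) != length(protein2) ||
      length(protein1) != length(combined_score))
    stop("edge columns must have equal length")
  if (any(combined_score < 0 | combined_score > 1000, na.rm = TRUE))
    stop("combined_score must lie in [0, 1000]")
  if (any(protein1 == protein2))
    stop("self-edges are not allowed")
  a <- pmin(protein1, protein2)
  b <- pmax(protein1, protein2)
  df <- data.frame(protein1 = a, protein2 = b,
                   combined_score = combined_score,
                   stringsAsFactors = FALSE)
  key <- paste(df$protein1, df$protein2, sep = "\r")
  if (anyDuplicated(key)) {
    score <- tapply(df$combined_score, key, max)
    first <- !duplicated(key)
    df <- df[first, , drop = FALSE]
    df$combined_score <- as.numeric(score[paste(df$protein1, df$protein2, sep = "\r")])
  }
  df <- df[order(df$protein1, df$protein2), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("PPIEdgeList", "data.frame")
  df
}

#' Construct a gene-set collection (GMT semantics)
#'
#' @param sets Named list of character vectors (members, deduplicated).
#' @param descriptions Optional character vector of set descriptions.
#' @return A `GeneSetCollection`: named list with a `descriptions`
#'   attribute.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("every gene set must be named")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0)) stop("gene sets must be non-empty")
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(sets, descriptions = stats::setNames(descriptions, names(sets)),
            class = "GeneSetCollection")
}

#' Validate a module assignment
#'
#' A module assignment is a named character vector mapping each gene of a
#' network to a module label; `"grey"` is reserved for unassigned genes.
#'
#' @param x Named character vector.
#' @return The validated assignment.
#' @export
module_assignment <- function(x) {
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stop("assignment must be named by unique gene identifiers")
  as.character(x) -> labs
  names(labs) <- names(x)
  labs
}

GREY <- "grey"
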