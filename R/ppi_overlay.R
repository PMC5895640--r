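# PPI overlay: high-confidence score filter (> 700), intersection of PPI
# edges with co-expression module membership ("common interactions"), and
# extraction of connected intramodular subnetworks.

#' Filter a PPI edge list to high-confidence interactions
#'
#' Strictly greater-than filter on the combined score (the conventional
#' high-confidence cutoff is 700); duplicate unordered pairs were already
#' collapsed at construction.
#'
#' @param ppi A [ppi_edgelist()].
#' @param min_score Score cutoff, exclusive (default 700).
#' @param mapping Optional data frame (protein, gene) renaming protein
#'   identifiers to expression gene identifiers; unmapped proteins are
#'   dropped with a message.
#' @return A filtered `PPIEdgeList`.
#' @export
filter_ppi <- function(ppi, min_score = 700, mapping = NULL) {
  out <- ppi[ppi$combined_score > min_score, , drop = FALSE]
  if (!is.null(mapping)) {
    lut <- stats::setNames(as.character(mapping[[2]]), as.character(mapping[[1]]))
    known <- out$protein1 %in% names(lut) & out$protein2 %in% names(lut)
    dropped <- sum(!known)
    if (dropped) message(dropped, " edge(s) dropped: unmapped protein identifiers")
    out <- out[known, , drop = FALSE]
    if (nrow(out)) {
      out <- ppi_edgelist(lut[out$protein1], lut[out$protein2],
                          out$combined_score)
    }
  }
  rownames(out) <- NULL
  out
}

#' Intersect filtered PPIs with module membership
#'
#' The "common interactions": PPI edges whose two endpoints carry the same
#' non-grey module label. Each retained edge is annotated with its module.
#'
#' @param ppi A filtered [ppi_edgelist()] on gene identifiers.
#' @param assignment A [module_assignment()].
#' @param adjacency Optional adjacency matrix; when given together with
#'   `min_adjacency`, edges additionally require co-expression adjacency at
#'   least that strong.
#' @param min_adjacency Optional adjacency floor (default `NULL` = off).
#' @return Data frame: protein1, protein2, combined_score, module.
#' @export
intersect_with_modules <- function(ppi, assignment, adjacency = NULL,
                                   min_adjacency = NULL) {
  nodes <- unique(c(ppi$protein1, ppi$protein2))
  unmapped <- sum(!(nodes %in% names(assignment)))
  if (length(nodes) && unmapped / length(nodes) > 0.5)
    warning(unmapped, " of ", length(nodes),
            " PPI nodes are absent from the expression gene set")
  m1 <- assignment[ppi$protein1]
  m2 <- assignment[ppi$protein2]
  keep <- !is.na(m1) & !is.na(m2) & m1 == m2 & m1 != GREY
  out <- ppi[keep, , drop = FALSE]
  out$module <- unname(m1[keep])
  if (!is.null(min_adjacency) && !is.null(adjacency) && nrow(out)) {
    a <- unclass(adjacency)
    av <- mapply(function(x, y) a[x, y], out$protein1, out$protein2)
    out <- out[av >= min_adjacency, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' Extract connected intramodular subnetworks
#'
#' Connected components are computed within each module's common-
#' interaction edge set; components with at least `min_nodes` nodes are
#' reported, ordered by decreasing size.
#'
#' @param common_edges Output of [intersect_with_modules()].
#' @param min_nodes Minimum component size to report (default 5).
#' @return List of `Subnetwork` lists: `module`, `nodes`, `edges`, `size`.
#' @export
extract_subnetworks <- function(common_edges, min_nodes = 5) {
  subs <- list()
  for (mod in unique(common_edges$module)) {
    e <- common_edges[common_edges$module == mod, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      e[, c("protein1", "protein2")], directed = FALSE)
    comp <- igraph::components(g)
    for (ci in seq_len(comp$no)) {
      nodes <- names(comp$membership)[comp$membership == ci]
      if (length(nodes) < min_nodes) next
      in_comp <- e$protein1 %in% nodes & e$protein2 %in% nodes
      subs[[length(subs) + 1L]] <- structure(
        list(module = mod, nodes = sort(nodes),
             edges = e[in_comp, , drop = FALSE],
             size = length(nodes)),
        class = "Subnetwork")
    }
  }
  subs[order(-vapply(subs, `[[`, integer(1), "size"))]
}

#' Export subnetworks for visualization
#'
#' Writes one SIF or GraphML file per subnetwork plus a node-attribute TSV
#' (module, kME, intramodular connectivity) suitable for Cytoscape.
#'
#' @param subnets List from [extract_subnetworks()].
#' @param dir Output directory (created if needed).
#' @param format `"SIF"` or `"GraphML"`.
#' @param modules Optional `ModuleSet` supplying kME and k_in attributes.
#' @return Character vector of written file paths, invisibly.
#' @export
export_subnetworks <- function(subnets, dir, format = c("SIF", "GraphML"),
                               modules = NULL) {
  if (is.character(format) && length(format) == 1 &&
      !(format %in% c("SIF", "GraphML")))
    stop("unknown subnetwork export format: ", format)
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "SIF") "sif" else "graphml"
  paths <- character(0)
  for (i in seq_along(subnets)) {
    s <- subnets[[i]]
    path <- file.path(dir, sprintf("subnetwork_%02d_%s.%s", i, s$module, ext))
    edges <- data.frame(from = s$edges$protein1, to = s$edges$protein2,
                        weight = s$edges$combined_score,
                        stringsAsFactors = FALSE)
    write_network(edges, format = format, path = path)
    paths <- c(paths, path)
  }
  if (length(subnets)) {
    attr_rows <- do.call(rbind, lapply(subnets, function(s) {
      kme <- k_in <- rep(NA_real_, length(s$nodes))
      if (!is.null(modules)) {
        if (!is.null(modules$kme) && s$module %in% colnames(modules$kme))
          kme <- modules$kme[match(s$nodes, rownames(modules$kme)), s$module]
        k_in <- unname(modules$k_in[s$nodes])
      }
      data.frame(node = s$nodes, module = s$module, kme = kme, k_in = k_in,
                 stringsAsFactors = FALSE)
    }))
    attr_path <- file.path(dir, "subnetwork_nodes.tsv")
    utils::write.table(attr_rows, attr_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, attr_path)
  }
  invisible(paths)
}
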