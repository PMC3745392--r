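# Minimum spanning haplotype networks and two-layer comparison.

#' Build a minimum spanning network over haplotypes
#'
#' The MSN is the union of all minimum spanning trees of the complete
#' graph weighted by mutational distance: an edge of weight w belongs to
#' some MST exactly when its endpoints lie in different components of the
#' subgraph of strictly lighter edges (tie-inclusive Kruskal). Ties at
#' equal weight therefore create reticulations. Edge ordering is
#' deterministic: weight, then lexicographic node labels.
#'
#' @param haplotypes a `haplotype_set`, named character vector, or plain
#'   character vector of sequences (labels default to `HT1`, ...).
#' @param d optional symmetric distance matrix with zero diagonal;
#'   computed with [pairwise_diff_matrix()] when missing.
#' @return A list of class `haplo_network`: `nodes` (data frame `label`,
#'   `seq`), `edges` (data frame `from`, `to`, `weight`, `intermediates` =
#'   weight - 1), `layers` (NULL until [compare_layers()]).
#' @export
build_msn <- function(haplotypes, d = NULL) {
  if (is.data.frame(haplotypes)) {
    labels <- haplotypes$label; seqs <- haplotypes$seq
  } else {
    seqs <- as.character(haplotypes)
    labels <- names(haplotypes) %||% paste0("HT", seq_along(seqs))
    if (is.null(names(haplotypes)) && length(seqs))
      labels <- paste0("HT", seq_along(seqs))
  }
  k <- length(labels)
  if (!k) stop("no haplotypes", call. = FALSE)
  if (is.null(d)) d <- pairwise_diff_matrix(setNames(seqs, labels))
  stopifnot(nrow(d) == k, ncol(d) == k)
  edges <- data.frame(from = character(0), to = character(0),
                      weight = numeric(0), intermediates = numeric(0),
                      stringsAsFactors = FALSE)
  if (k > 1L) {
    idx <- which(upper.tri(d), arr.ind = TRUE)
    cand <- data.frame(i = idx[, 1L], j = idx[, 2L],
                       weight = d[idx])
    cand$from <- pmin(labels[cand$i], labels[cand$j])
    cand$to <- pmax(labels[cand$i], labels[cand$j])
    cand <- cand[order(cand$weight, cand$from, cand$to), , drop = FALSE]

    parent <- seq_len(k)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    keep <- logical(nrow(cand))
    for (w in unique(cand$weight)) {
      grp <- which(cand$weight == w)
      # decide all edges of this weight class against the components formed
      # by strictly lighter edges, then merge
      roots_i <- vapply(cand$i[grp], find, 1L)
      roots_j <- vapply(cand$j[grp], find, 1L)
      keep[grp] <- roots_i != roots_j
      for (g in grp[keep[grp]]) {
        ri <- find(cand$i[g]); rj <- find(cand$j[g])
        if (ri != rj) parent[ri] <- rj
      }
    }
    chosen <- cand[keep, , drop = FALSE]
    edges <- data.frame(from = chosen$from, to = chosen$to,
                        weight = chosen$weight,
                        intermediates = pmax(chosen$weight - 1, 0),
                        stringsAsFactors = FALSE)
    rownames(edges) <- NULL
  }
  structure(list(nodes = data.frame(label = labels, seq = seqs,
                                    stringsAsFactors = FALSE),
                 edges = edges, layers = NULL),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("haplo_network: %d nodes, %d edges (%d inferred intermediates)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$intermediates)))
  if (!is.null(x$layers)) {
    s <- attr(x$layers, "summary")
    cat(sprintf("layers %s/%s: %d shared, %d %s-only, %d %s-only\n",
                s$names[1], s$names[2], s$shared, s$a_only, s$names[1],
                s$b_only, s$names[2]))
  }
  invisible(x)
}

layer_counts <- function(layer, labels) {
  if (inherits(layer, "count_table"))
    layer <- rowSums(unclass(layer))
  if (is.null(names(layer))) stop("layer needs haplotype names", call. = FALSE)
  extra <- setdiff(names(layer)[layer > 0], labels)
  if (length(extra))
    stop(sprintf("layer haplotype '%s' absent from the network", extra[1L]),
         call. = FALSE)
  out <- setNames(numeric(length(labels)), labels)
  out[names(layer)] <- layer
  out
}

#' Annotate a network with two dataset layers
#'
#' Marks every node as shared between the two datasets, present in only
#' one ("white dot" in the other layer's rendering), or absent from both;
#' per-edge inferred intermediates (weight - 1) play the role of "black
#' dot" unobserved haplotypes on the path.
#'
#' @param net a `haplo_network` whose nodes cover both layers.
#' @param layer_a,layer_b named count vectors (haplotype label -> number
#'   of individuals) or [count_table]s with rownames matching node labels.
#' @param names length-2 character, display names of the layers.
#' @return The network with a `layers` data frame (`label`, `count_a`,
#'   `count_b`, `category`) carrying a `summary` attribute.
#' @export
compare_layers <- function(net, layer_a, layer_b, names = c("A", "B")) {
  labels <- net$nodes$label
  ca <- layer_counts(layer_a, labels)
  cb <- layer_counts(layer_b, labels)
  category <- ifelse(ca > 0 & cb > 0, "shared",
              ifelse(ca > 0, paste0(names[1L], "-only"),
              ifelse(cb > 0, paste0(names[2L], "-only"), "absent")))
  layers <- data.frame(label = labels, count_a = unname(ca),
                       count_b = unname(cb), category = category,
                       stringsAsFactors = FALSE)
  attr(layers, "summary") <- list(
    names = names,
    shared = sum(ca > 0 & cb > 0),
    a_only = sum(ca > 0 & cb == 0),
    b_only = sum(cb > 0 & ca == 0),
    absent = sum(ca == 0 & cb == 0))
  net$layers <- layers
  net
}

network_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  if (!is.null(net$layers)) {
    ord <- match(igraph::V(g)$name, net$layers$label)
    g <- igraph::set_vertex_attr(g, "count_a", value = net$layers$count_a[ord])
    g <- igraph::set_vertex_attr(g, "count_b", value = net$layers$count_b[ord])
    g <- igraph::set_vertex_attr(g, "category", value = net$layers$category[ord])
  }
  g
}

#' Export a haplotype network to GraphML or DOT
#'
#' Node attributes carry per-layer counts and the shared/one-layer
#' category when [compare_layers()] has been applied; edge attributes
#' carry mutational steps and inferred intermediate counts.
#'
#' @param net a `haplo_network`.
#' @param path output file.
#' @param format `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(network_igraph(net), path, format = format)
  invisible(path)
}
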