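#' Read and write edge-list files
#'
#' Layers and inter-edge sets are exchanged as plain TSV edge lists: one
#' undirected edge per line, two 1-based node indices separated by a tab,
#' `#` comment lines ignored. For inter-edge files the first column indexes
#' layer 1 and the second layer 2.
#'
#' @param layer a [layer_graph].
#' @param path file path.
#' @name edgelist_io
NULL

#' @rdname edgelist_io
#' @export
write_layer_edgelist <- function(layer, path) {
  idx <- which(upper.tri(layer$adjacency) & layer$adjacency == 1,
               arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# layer %s: %d nodes, %d edges (1-based indices)",
                     layer$label, layer$n_nodes, nrow(idx)), con)
  writeLines(sprintf("# n_nodes\t%d", layer$n_nodes), con)
  if (nrow(idx) > 0) {
    writeLines(paste(idx[, 1], idx[, 2], sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname edgelist_io
#' @param label label for the reconstructed layer.
#' @export
read_layer_edgelist <- function(path, label = basename(path)) {
  lines <- readLines(path)
  n <- NA_integer_
  hdr <- grep("^# n_nodes\t", lines, value = TRUE)
  if (length(hdr) > 0) n <- as.integer(sub("^# n_nodes\t", "", hdr[1]))
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  edges <- if (length(lines) > 0) {
    do.call(rbind, lapply(strsplit(lines, "\t"), as.integer))
  } else {
    matrix(integer(0), 0, 2)
  }
  if (is.na(n)) n <- max(edges)
  adj <- matrix(0, n, n)
  if (nrow(edges) > 0) {
    adj[edges] <- 1
    adj[edges[, c(2, 1), drop = FALSE]] <- 1
  }
  layer_graph(adj, label = label)
}

#' @rdname edgelist_io
#' @param inter_edges two-column matrix of inter-layer node pairs.
#' @export
write_inter_edgelist <- function(inter_edges, path) {
  inter_edges <- as.matrix(inter_edges)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# inter-edges: layer1_node\tlayer2_node (1-based)", con)
  if (nrow(inter_edges) > 0) {
    writeLines(paste(inter_edges[, 1], inter_edges[, 2], sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname edgelist_io
#' @export
read_inter_edgelist <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) return(matrix(integer(0), 0, 2))
  do.call(rbind, lapply(strsplit(lines, "\t"), as.integer))
}

#' Write / read a multiplex descriptor
#'
#' A JSON descriptor bundles the two layer edge-list files, the inter-edge
#' file and the coupling strengths so that a full multiplex experiment is
#' reproducible from files alone.
#'
#' @param g a [multiplex_graph].
#' @param dir output directory (created if needed).
#' @param name basename for the file set.
#' @param epsilon,gamma coupling strengths recorded in the descriptor.
#' @return Path to the descriptor JSON.
#' @export
write_multiplex <- function(g, dir, name = "multiplex",
                            epsilon = NA_real_, gamma = NA_real_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f1 <- file.path(dir, paste0(name, "_layer1.tsv"))
  f2 <- file.path(dir, paste0(name, "_layer2.tsv"))
  fi <- file.path(dir, paste0(name, "_inter.tsv"))
  write_layer_edgelist(g$layer1, f1)
  write_layer_edgelist(g$layer2, f2)
  write_inter_edgelist(g$inter_edges, fi)
  desc <- list(
    layer1 = basename(f1), layer2 = basename(f2), inter = basename(fi),
    l12 = g$l12, alpha = g$alpha, epsilon = epsilon, gamma = gamma
  )
  out <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(desc, out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  out
}

#' @rdname write_multiplex
#' @param path descriptor JSON path.
#' @export
read_multiplex <- function(path) {
  desc <- jsonlite::read_json(path, simplifyVector = TRUE)
  dir <- dirname(path)
  l1 <- read_layer_edgelist(file.path(dir, desc$layer1))
  l2 <- read_layer_edgelist(file.path(dir, desc$layer2))
  inter <- read_inter_edgelist(file.path(dir, desc$inter))
  g <- build_multiplex(l1, l2, inter)
  attr(g, "epsilon") <- desc$epsilon
  attr(g, "gamma") <- desc$gamma
  g
}
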