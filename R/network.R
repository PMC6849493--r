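#' Construct a symptom network
#'
#' A symptom network is an undirected, signed-weighted graph over labelled
#' symptoms, stored as a symmetric adjacency matrix with a zero diagonal.
#' An edge exists wherever the weight is nonzero; weights are typically
#' partial correlations (continuous data) or logistic couplings (binary
#' data), so negative values are legitimate.
#'
#' @param adjacency Square numeric matrix, symmetric with zero diagonal.
#' @param labels Optional character vector of symptom names; defaults to the
#'   matrix dimnames or `V1..Vp`.
#' @return An object of class `symptom_network` with elements `adjacency`
#'   (named symmetric matrix) and `labels`.
#' @examples
#' adj <- matrix(0, 3, 3)
#' adj[1, 2] <- adj[2, 1] <- 0.4
#' net <- symptom_network(adj, labels = c("anhedonia", "fatigue", "worry"))
#' net
#' @export
symptom_network <- function(adjacency, labels = NULL) {
  if (!is.matrix(adjacency) || !is.numeric(adjacency))
    stop("`adjacency` must be a numeric matrix")
  p <- nrow(adjacency)
  if (ncol(adjacency) != p)
    stop("`adjacency` must be square; got ", p, " x ", ncol(adjacency))
  if (any(!is.finite(adjacency)))
    stop("`adjacency` contains non-finite weights")
  if (!isTRUE(all.equal(adjacency, t(adjacency), tolerance = 1e-10)))
    stop("`adjacency` must be symmetric")
  if (any(abs(diag(adjacency)) > 1e-12))
    stop("`adjacency` must have a zero diagonal (no self-loops)")
  adjacency <- (adjacency + t(adjacency)) / 2
  diag(adjacency) <- 0
  if (is.null(labels)) {
    labels <- rownames(adjacency)
    if (is.null(labels)) labels <- paste0("V", seq_len(p))
  }
  labels <- as.character(labels)
  if (length(labels) != p) stop("`labels` length must equal node count")
  if (anyDuplicated(labels)) stop("duplicate symptom labels: ",
                                  paste(unique(labels[duplicated(labels)]), collapse = ", "))
  dimnames(adjacency) <- list(labels, labels)
  structure(list(adjacency = adjacency, labels = labels),
            class = "symptom_network")
}

#' @export
print.symptom_network <- function(x, ...) {
  p <- length(x$labels)
  m <- n_edges(x)
  dens <- if (p > 1) m / (p * (p - 1) / 2) else 0
  cat("symptom_network: ", p, " symptoms, ", m, " edges (density ",
      sprintf("%.3f", dens), ")\n", sep = "")
  neg <- sum(x$adjacency[upper.tri(x$adjacency)] < 0)
  if (m > 0)
    cat("  weights in [", sprintf("%.3f", min(x$adjacency)), ", ",
        sprintf("%.3f", max(x$adjacency)), "], ", neg, " negative edge(s)\n",
        sep = "")
  invisible(x)
}

n_nodes <- function(network) length(network$labels)

n_edges <- function(network) sum(network$adjacency[upper.tri(network$adjacency)] != 0)

#' Network density
#'
#' Fraction of the `p(p-1)/2` possible edges that are present.
#'
#' @param network A `symptom_network`.
#' @return Density in \[0, 1\].
#' @export
network_density <- function(network) {
  p <- n_nodes(network)
  if (p < 2) return(0)
  n_edges(network) / (p * (p - 1) / 2)
}

#' Convert a symptom network to an igraph graph
#'
#' Edge weights keep their sign in the `weight` attribute; `abs_weight`
#' carries the magnitude for algorithms requiring positive weights.
#'
#' @param network A `symptom_network`.
#' @return An undirected igraph object with a `weight` edge attribute.
#' @export
as_igraph <- function(network) {
  g <- igraph::graph_from_adjacency_matrix(network$adjacency, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) > 0)
    igraph::E(g)$abs_weight <- abs(igraph::E(g)$weight)
  g
}

#' Remove nodes from a network
#'
#' @param network A `symptom_network`.
#' @param labels Labels of the symptoms to drop.
#' @return The induced subnetwork on the remaining symptoms.
#' @export
remove_nodes <- function(network, labels) {
  unknown <- setdiff(labels, network$labels)
  if (length(unknown) > 0)
    stop("unknown symptom(s): ", paste(unknown, collapse = ", "))
  keep <- setdiff(network$labels, labels)
  symptom_network(network$adjacency[keep, keep, drop = FALSE], labels = keep)
}

#' Read a network from disk
#'
#' Supported formats: square adjacency CSV (first column holds symptom
#' labels, header row repeats them), weighted edge-list TSV with columns
#' source/target/weight, and GraphML. Asymmetric adjacency input is
#' symmetrized by averaging with a warning.
#'
#' @param path File path.
#' @param format One of `"adjacency-csv"`, `"edgelist-tsv"`, `"graphml"`;
#'   guessed from the file extension by default.
#' @return A `symptom_network`.
#' @export
read_network <- function(path, format = c("auto", "adjacency-csv", "edgelist-tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "adjacency-csv",
                     tsv = "edgelist-tsv",
                     graphml = "graphml",
                     stop("cannot guess format from extension of ", path))
  }
  if (format == "adjacency-csv") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    labels <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    if (nrow(m) != ncol(m))
      stop("adjacency in ", path, " is not square: ", nrow(m), " rows x ",
           ncol(m), " value columns")
    if (anyDuplicated(labels))
      stop("duplicate labels in ", path, ": ",
           paste(unique(labels[duplicated(labels)]), collapse = ", "))
    if (any(is.na(m))) {
      bad <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop("NaN/NA weight in ", path, " at row ", bad[1], ", column ", bad[2])
    }
    if (!isTRUE(all.equal(unname(m), t(unname(m)), tolerance = 1e-8))) {
      warning("asymmetric adjacency in ", path, "; symmetrizing by averaging")
      m <- (m + t(m)) / 2
    }
    diag(m) <- 0
    dimnames(m) <- list(labels, labels)
    return(symptom_network(m, labels = labels))
  }
  if (format == "edgelist-tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (ncol(df) < 3) stop("edge list ", path, " needs source, target, weight columns")
    if (any(is.na(df[[3]]))) stop("NaN/NA weight in edge list ", path)
    labels <- sort(unique(c(as.character(df[[1]]), as.character(df[[2]]))))
    p <- length(labels)
    m <- matrix(0, p, p, dimnames = list(labels, labels))
    for (i in seq_len(nrow(df))) {
      a <- as.character(df[i, 1]); b <- as.character(df[i, 2])
      m[a, b] <- m[b, a] <- as.numeric(df[i, 3])
    }
    return(symptom_network(m, labels = labels))
  }
  g <- igraph::read_graph(path, format = "graphml")
  labels <- igraph::V(g)$name
  if (is.null(labels)) labels <- paste0("V", seq_len(igraph::vcount(g)))
  m <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE))
  dimnames(m) <- list(labels, labels)
  symptom_network(m, labels = labels)
}

#' Write a network to disk
#'
#' @param network A `symptom_network`.
#' @param path Output path.
#' @param format As in [read_network()].
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path,
                          format = c("auto", "adjacency-csv", "edgelist-tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "adjacency-csv",
                     tsv = "edgelist-tsv",
                     graphml = "graphml",
                     stop("cannot guess format from extension of ", path))
  }
  if (format == "adjacency-csv") {
    df <- data.frame(symptom = network$labels, network$adjacency,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  } else if (format == "edgelist-tsv") {
    idx <- which(upper.tri(network$adjacency) & network$adjacency != 0, arr.ind = TRUE)
    df <- data.frame(source = network$labels[idx[, 1]],
                     target = network$labels[idx[, 2]],
                     weight = network$adjacency[idx],
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    g <- as_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
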