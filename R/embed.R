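#' PCA embedding of cells
#'
#' Centers and unit-scales each gene of the log-normalized HVG matrix and
#' projects cells onto the top principal components. Also reports the
#' fraction of variance explained per PC and an elbow suggestion: the
#' first PC at which the drop in explained variance falls below 5\% of the
#' previous drop (the point where the scree plateaus).
#'
#' @param logcounts gene x cell matrix restricted to the selected HVGs.
#' @param nPcs number of PCs to keep (truncated with a warning if it
#'   exceeds the matrix rank); NA keeps \code{min(dim) - 1}.
#' @return list with \code{latent} (cells x nPcs), \code{varExplained}
#'   and \code{elbow}.
#' @export
pcaEmbed <- function(logcounts, nPcs = 30) {
  x <- as.matrix(Matrix::t(logcounts))
  maxRank <- min(dim(x)) - 1L
  if (is.na(nPcs)) nPcs <- maxRank
  if (nPcs > maxRank) {
    warning("nPcs (", nPcs, ") exceeds rank; truncated to ", maxRank)
    nPcs <- maxRank
  }
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0] <- 1 # constant genes carry no signal; avoid 0/0
  pc <- stats::prcomp(x, center = TRUE, scale. = sds, rank. = nPcs)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  drops <- -diff(ev)
  elbow <- NA_integer_
  if (length(drops) >= 2) {
    hit <- which(drops[-1] < 0.05 * pmax(drops[-length(drops)], 1e-300))
    if (length(hit)) elbow <- hit[1] + 1L
  }
  if (is.na(elbow)) elbow <- length(ev)
  list(latent = pc$x[, seq_len(nPcs), drop = FALSE],
       varExplained = ev, elbow = as.integer(elbow))
}

#' kNN graph construction and Leiden clustering
#'
#' Builds the exact Euclidean k-nearest-neighbor graph in latent space
#' (symmetrized by union, all edge weights 1) and partitions it with
#' Leiden community detection under a resolution-parameterized modularity
#' quality function. The result is deterministic given the seed; distance
#' ties are broken by cell index.
#'
#' @param latent cells x PCs matrix.
#' @param nNeighbors neighbors per cell (15 by default).
#' @param resolution Leiden resolution (5 in the reference analysis).
#' @param seed RNG seed for the community detection.
#' @return a \linkS4class{CellEmbedding}.
#' @export
knnCluster <- function(latent, nNeighbors = 15, resolution = 5, seed = 1) {
  latent <- as.matrix(latent)
  if (!all(is.finite(latent))) stop("latent matrix must be finite")
  n <- nrow(latent)
  if (nNeighbors >= n)
    stop("nNeighbors (", nNeighbors, ") must be smaller than the number ",
         "of cells (", n, ")")
  nbr <- .cpp_knn(latent, as.integer(nNeighbors))
  i <- rep(seq_len(n), times = nNeighbors)
  j <- as.vector(nbr)
  edges <- unique(cbind(pmin(i, j), pmax(i, j)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  cl <- withSeed(stageSeed(seed, "cluster"),
                 igraph::cluster_leiden(g, objective_function = "modularity",
                                        resolution = resolution,
                                        n_iterations = 10))
  memb <- igraph::membership(cl)
  memb <- as.integer(factor(memb, levels = sort(unique(memb)))) - 1L
  methods::new("CellEmbedding", latent = latent, neighbors = nbr,
               clusters = memb,
               varExplained = numeric(), elbow = NA_integer_)
}

#' Full embedding step
#'
#' Convenience wrapper: HVG selection, PCA and Leiden clustering with the
#' configured parameters; records the explained variance and elbow in the
#' returned object.
#'
#' @param ae an \linkS4class{AntennalExperiment} with a \code{logcounts}
#'   assay.
#' @param config a \code{PipelineConfig}.
#' @param batch per-cell batch labels for HVG selection (default: library
#'   id).
#' @return a \linkS4class{CellEmbedding}.
#' @export
embedCells <- function(ae, config = deskConfig(), batch = libraryId(ae)) {
  lc <- assay(ae, "logcounts")
  hvgs <- selectHVGs(lc, nTop = min(config$n_hvg, nrow(lc)), batch = batch)
  pca <- pcaEmbed(lc[hvgs, , drop = FALSE],
                  nPcs = if (is.na(config$n_pcs)) NA else config$n_pcs)
  nPcs <- if (is.na(config$n_pcs)) pca$elbow else
    min(config$n_pcs, ncol(pca$latent))
  emb <- knnCluster(pca$latent[, seq_len(nPcs), drop = FALSE],
                    nNeighbors = config$n_neighbors,
                    resolution = config$cluster_resolution,
                    seed = config$rng_seed)
  emb@varExplained <- pca$varExplained
  emb@elbow <- pca$elbow
  rownames(emb@latent) <- colnames(ae)
  emb
}
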