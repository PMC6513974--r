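#' Feature point cloud
#'
#' Transposes a z-scored feature matrix so that the 155 features become the
#' points (rows) and the trials the coordinates (columns), and computes the
#' Euclidean pairwise distance matrix.
#'
#' @param matrix A z-scored `pf_feature_matrix`.
#' @return A `pf_cloud`: list with `points` (features x trials matrix) and
#'   `dist` (symmetric distance matrix).
#' @export
feature_point_cloud <- function(matrix) {
  stopifnot(inherits(matrix, "pf_feature_matrix"))
  if (matrix$normalization != "zscored")
    stop("the point cloud requires a z-scored feature matrix")
  pts <- t(matrix$values)
  D <- as.matrix(stats::dist(pts))
  structure(list(points = pts, dist = D), class = "pf_cloud")
}

#' @export
print.pf_cloud <- function(x, ...) {
  cat(sprintf("<pf_cloud> %d feature points x %d trial coordinates\n",
              nrow(x$points), ncol(x$points)))
  invisible(x)
}

#' k-NN distance lens
#'
#' The filter (lens) value of each feature point: the Euclidean distance to
#' its k-th nearest other point (k = 2 in the reference configuration), an
#' inverse measure of local density.
#'
#' @param cloud A `pf_cloud`.
#' @param k Neighbor rank (default 2; must satisfy `1 <= k < n_points`).
#' @return Named numeric lens vector, one value per feature.
#' @export
knn_filter <- function(cloud, k = 2) {
  n <- nrow(cloud$dist)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < number of points")
  lens <- vapply(seq_len(n), function(i) sort(cloud$dist[i, -i])[k], numeric(1))
  names(lens) <- rownames(cloud$dist)
  lens
}

#' Overlapping interval cover of the lens range
#'
#' Uniform cover of `[min(lens), max(lens)]` by `N` intervals of length
#' `range / (N - (N-1) * L)` stepped by `length * (1 - L)`, so consecutive
#' intervals overlap by the fraction `L` of their length. Boundary lens
#' values are assigned inclusively. A constant lens yields a single interval
#' containing every feature.
#'
#' @param lens Named lens values from [knn_filter()].
#' @param N Number of intervals (default 4).
#' @param L Overlap fraction in `[0, 1)` (default 0.5).
#' @return List of intervals: each has `low`, `high`, `members` (feature
#'   names).
#' @export
build_cover <- function(lens, N = 4, L = 0.5) {
  if (N < 1) stop("N must be >= 1")
  if (L < 0 || L >= 1) stop("L must be in [0, 1)")
  lo <- min(lens); hi <- max(lens)
  if (hi == lo || N == 1)
    return(list(list(low = lo, high = hi, members = names(lens))))
  len <- (hi - lo) / (N - (N - 1) * L)
  step <- len * (1 - L)
  lapply(seq_len(N), function(i) {
    a <- lo + (i - 1) * step
    b <- a + len
    if (i == N) b <- hi  # guard the top edge against rounding
    list(low = a, high = b, members = names(lens)[lens >= a & lens <= b])
  })
}

#' Cluster the features of one cover region
#'
#' Ward (minimum-variance) agglomerative clustering of the region's feature
#' points, cut by a largest-gap heuristic on the merge heights: the tree is
#' cut at the first gap exceeding the mean plus one SD of all gaps; if no
#' gap qualifies the region stays a single cluster.
#'
#' @param members Feature names of the region.
#' @param cloud A `pf_cloud`.
#' @return List of character vectors (feature clusters).
#' @export
cluster_region <- function(members, cloud) {
  if (!length(members)) stop("region is empty")
  if (length(members) == 1) return(list(members))
  if (length(members) == 2) {
    # no gap structure to inspect with a single merge; keep one cluster
    return(list(members))
  }
  d <- stats::as.dist(cloud$dist[members, members])
  hc <- stats::hclust(d, method = "ward.D2")
  h <- hc$height
  gaps <- diff(h)
  k <- 1L
  if (length(gaps) >= 2) {
    thr <- mean(gaps) + stats::sd(gaps)
    big <- which(gaps > thr)
    if (length(big)) {
      # cut below the first qualifying gap: merges above it are discarded
      k <- length(h) - big[1] + 1L
    }
  }
  cl <- stats::cutree(hc, k = k)
  unname(split(members, cl))
}

#' Assemble the topological feature chart
#'
#' One node per per-region cluster; nodes are connected when their feature
#' sets intersect, the edge weight being the intersection size. Nodes carry
#' their size, mean lens value, and modality composition (proportions of
#' z/c/t/s/h features).
#'
#' @param clusters List of feature clusters (from all cover regions).
#' @param lens Lens values.
#' @param params Optional list of chart parameters to record (k, N, L).
#' @return A `pf_chart`: list with `nodes` (list of feature sets plus
#'   annotations), `edges` (data.frame `from`, `to`, `weight`), `lens`,
#'   `params`.
#' @export
assemble_chart <- function(clusters, lens, params = list()) {
  reg <- feature_registry()
  nodes <- lapply(seq_along(clusters), function(i) {
    feats <- clusters[[i]]
    mods <- table(factor(reg$modality[match(feats, reg$name)],
                         levels = c("z", "c", "t", "s", "h")))
    list(id = i, features = feats, size = length(feats),
         mean_lens = mean(lens[feats]),
         modality_prop = as.numeric(mods) / length(feats),
         modality_names = names(mods), sets = character(0))
  })
  edges <- list()
  if (length(nodes) > 1) {
    for (i in seq_len(length(nodes) - 1)) {
      for (j in (i + 1):length(nodes)) {
        w <- length(intersect(nodes[[i]]$features, nodes[[j]]$features))
        if (w > 0) edges[[length(edges) + 1]] <- c(i, j, w)
      }
    }
  }
  edges <- if (length(edges))
    stats::setNames(as.data.frame(do.call(rbind, edges)),
                    c("from", "to", "weight"))
  else data.frame(from = integer(0), to = integer(0), weight = integer(0))
  structure(list(nodes = nodes, edges = edges, lens = lens, params = params),
            class = "pf_chart")
}

#' @export
print.pf_chart <- function(x, ...) {
  cat(sprintf("<pf_chart> %d nodes, %d edges; %d distinct features covered\n",
              length(x$nodes), nrow(x$edges),
              length(unique(unlist(lapply(x$nodes, `[[`, "features"))))))
  invisible(x)
}

#' Build a Mapper feature chart from a feature matrix
#'
#' End-to-end Mapper: point cloud, k-NN lens, overlapping cover, per-region
#' Ward clustering, and chart assembly.
#'
#' @param matrix A z-scored `pf_feature_matrix`.
#' @param k Lens neighbor rank (default 2).
#' @param N Cover intervals (default 4).
#' @param L Cover overlap fraction (default 0.5).
#' @return A `pf_chart`.
#' @export
mapper_chart <- function(matrix, k = 2, N = 4, L = 0.5) {
  cloud <- feature_point_cloud(matrix)
  lens <- knn_filter(cloud, k)
  cover <- build_cover(lens, N, L)
  clusters <- list()
  for (iv in cover) {
    if (!length(iv$members)) next
    clusters <- c(clusters, cluster_region(iv$members, cloud))
  }
  assemble_chart(clusters, lens, params = list(k = k, N = N, L = L))
}

#' Tag chart nodes with named feature sets
#'
#' Annotates every node containing a member of a named set (e.g. the
#' selected sets FSa--FSd or literature sets FS1--FS4) with that set's name.
#'
#' @param chart A `pf_chart`.
#' @param sets Named list: set name -> character vector of feature names.
#' @return The chart with per-node `sets` annotations filled in.
#' @export
annotate_feature_sets <- function(chart, sets) {
  all_feats <- feature_names()
  for (s in names(sets)) {
    unknown <- setdiff(sets[[s]], all_feats)
    if (length(unknown))
      stop("unknown feature name(s) in set ", s, ": ",
           paste(unknown, collapse = ", "))
  }
  for (i in seq_along(chart$nodes)) {
    hits <- names(sets)[vapply(sets, function(f)
      length(intersect(f, chart$nodes[[i]]$features)) > 0, logical(1))]
    chart$nodes[[i]]$sets <- union(chart$nodes[[i]]$sets, hits)
  }
  chart
}

# igraph representation of a chart (internal; also used for export and
# component counts)
.chart_igraph <- function(chart) {
  n <- length(chart$nodes)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- paste0("n", seq_len(n))
  igraph::V(g)$size <- vapply(chart$nodes, `[[`, numeric(1), "size")
  igraph::V(g)$mean_lens <- vapply(chart$nodes, `[[`, numeric(1), "mean_lens")
  igraph::V(g)$features <- vapply(chart$nodes, function(nd)
    paste(nd$features, collapse = ";"), character(1))
  igraph::V(g)$sets <- vapply(chart$nodes, function(nd)
    paste(nd$sets, collapse = ";"), character(1))
  for (m in seq_along(chart$nodes[[1]]$modality_names)) {
    igraph::vertex_attr(g, paste0("prop_", chart$nodes[[1]]$modality_names[m])) <-
      vapply(chart$nodes, function(nd) nd$modality_prop[m], numeric(1))
  }
  if (nrow(chart$edges)) {
    g <- igraph::add_edges(g, rbind(chart$edges$from, chart$edges$to))
    igraph::E(g)$weight <- chart$edges$weight
  }
  g
}

#' Number of connected components of a chart
#'
#' @param chart A `pf_chart`.
#' @return Integer component count.
#' @export
chart_components <- function(chart) {
  igraph::components(.chart_igraph(chart))$no
}

#' Export a chart to GraphML (plus a JSON companion)
#'
#' Nodes carry size, mean lens, modality proportions, and set tags; edges
#' carry the shared-feature weight.
#'
#' @param chart A `pf_chart`.
#' @param path Output GraphML path; a `.json` companion is written next to
#'   it.
#' @return `path`, invisibly.
#' @export
write_chart_graphml <- function(chart, path) {
  g <- .chart_igraph(chart)
  igraph::write_graph(g, path, format = "graphml")
  json <- list(
    params = chart$params,
    nodes = lapply(chart$nodes, function(nd)
      list(id = nd$id, features = nd$features, size = nd$size,
           mean_lens = nd$mean_lens,
           modality_prop = stats::setNames(as.list(nd$modality_prop),
                                           nd$modality_names),
           sets = nd$sets)),
    edges = chart$edges
  )
  jsonlite::write_json(json, sub("\\.graphml$", ".json", path),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Export a chart in DOT format
#'
#' @param chart A `pf_chart`.
#' @param path Output `.dot` path.
#' @return `path`, invisibly.
#' @export
write_chart_dot <- function(chart, path) {
  igraph::write_graph(.chart_igraph(chart), path, format = "dot")
  invisible(path)
}
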