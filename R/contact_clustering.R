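#' Binary contact-formation matrix over transition frames
#'
#' Restricts a trajectory to its folding/unfolding transition segments and
#' records, for every native contact, whether it is formed (r < `formed_scale`
#' * sigma) in each transition frame. Columns that are constant across all
#' transition frames (formed or broken throughout) are flagged; they carry
#' no correlation information.
#'
#' @param traj an `sbm_trajectory`.
#' @param contacts a [contact_map] (or data.frame with i, j, sigma).
#' @param transitions data.frame from [detect_transitions()]; at least one
#'   segment is required.
#' @param formed_scale formation criterion as a multiple of sigma
#'   (default 1.2, consistent with the Q switching midpoint).
#' @return a `contact_formation_matrix`: binary matrix (rows = transition
#'   frames, columns = contacts, in contact-list order) with attributes
#'   `frames` (trajectory frame indices) and `constant` (logical per
#'   column).
#' @export
formation_matrix <- function(traj, contacts, transitions, formed_scale = 1.2) {
  if (nrow(transitions) == 0) stop("no transition segments supplied")
  frames <- sort(unique(unlist(mapply(seq, transitions$start, transitions$end,
                                      SIMPLIFY = FALSE))))
  r <- pair_distance_series_cpp(traj$frames[, , frames, drop = FALSE],
                                as.integer(contacts$i) - 1L,
                                as.integer(contacts$j) - 1L)
  m <- sweep(r, 2, formed_scale * contacts$sigma, "<") * 1L
  structure(m, frames = frames,
            constant = apply(m, 2, function(col) all(col == col[1])),
            class = c("contact_formation_matrix", class(m)))
}

#' Pairwise correlation of contact formation
#'
#' Pearson correlation coefficients between all pairs of contact-formation
#' columns. Constant columns (which mirror, e.g., intra-helical contacts
#' that never break over the transitions) are assigned zero correlation to
#' every other contact so that they drop out of clustering.
#'
#' @param m a `contact_formation_matrix` (or any frames x contacts binary
#'   matrix).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(m) {
  const <- apply(m, 2, function(col) all(col == col[1]))
  if (all(const)) stop("all contact columns are constant over the transition frames")
  cc <- matrix(0, ncol(m), ncol(m))
  live <- which(!const)
  cc[live, live] <- stats::cor(m[, live, drop = FALSE])
  diag(cc) <- 1
  cc
}

#' Cluster contacts that form and break together (foldons)
#'
#' Deterministic graph clustering: contacts are nodes, edges join pairs
#' whose formation correlation exceeds `threshold`, and clusters are the
#' connected components with at least `min_cluster_size` contacts. Smaller
#' components (and constant-formation contacts) are left unclustered.
#'
#' @param corr correlation matrix from [correlation_matrix()].
#' @param threshold correlation threshold in (0, 1) (default 0.5).
#' @param min_cluster_size minimum contacts per reported cluster.
#' @param method `"components"` (default) or `"average_linkage"`
#'   (agglomerative clustering cut at height 1 - threshold).
#' @return a `contact_cluster_set`: integer cluster id per contact (NA =
#'   unclustered), cluster ids renumbered 1..k by decreasing size.
#' @export
cluster_contacts <- function(corr, threshold = 0.5, min_cluster_size = 10L,
                             method = c("components", "average_linkage")) {
  method <- match.arg(method)
  stopifnot(threshold > 0, threshold < 1)
  nc <- ncol(corr)
  if (method == "components") {
    adj <- corr > threshold
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
  } else {
    d <- stats::as.dist(1 - corr)
    comp <- stats::cutree(stats::hclust(d, method = "average"), h = 1 - threshold)
  }
  sizes <- table(comp)
  keep <- as.integer(names(sizes)[sizes >= min_cluster_size])
  cluster <- rep(NA_integer_, nc)
  kept_sorted <- keep[order(-sizes[as.character(keep)])]
  for (k in seq_along(kept_sorted)) cluster[comp == kept_sorted[k]] <- k
  structure(list(cluster = cluster, n_clusters = length(kept_sorted),
                 parameters = list(threshold = threshold,
                                   min_cluster_size = min_cluster_size,
                                   method = method)),
            class = "contact_cluster_set")
}

#' @export
print.contact_cluster_set <- function(x, ...) {
  cat(sprintf("contact_cluster_set: %d clusters (threshold %.2f, min size %d); %d/%d contacts unclustered\n",
              x$n_clusters, x$parameters$threshold, x$parameters$min_cluster_size,
              sum(is.na(x$cluster)), length(x$cluster)))
  if (x$n_clusters > 0)
    for (k in seq_len(x$n_clusters))
      cat(sprintf("  cluster %d: %d contacts\n", k, sum(x$cluster == k, na.rm = TRUE)))
  invisible(x)
}

#' Project contact clusters onto residues
#'
#' A residue belongs to every cluster that contains at least one of its
#' contacts; residues touched by several clusters are also reported with
#' their majority cluster (most contacts; ties broken by lower cluster id).
#'
#' @param clusters a `contact_cluster_set`.
#' @param contacts the contact list the clustering was computed over (same
#'   order).
#' @return list with `residues` (list of sorted residue vectors per
#'   cluster) and `majority` (named integer vector: majority cluster per
#'   residue appearing in any cluster).
#' @export
project_to_residues <- function(clusters, contacts) {
  if (length(clusters$cluster) != nrow(contacts))
    stop("cluster assignment and contact list lengths differ")
  if (clusters$n_clusters == 0) return(list(residues = list(), majority = integer(0)))
  residues <- lapply(seq_len(clusters$n_clusters), function(k) {
    sel <- which(!is.na(clusters$cluster) & clusters$cluster == k)
    sort(unique(c(contacts$i[sel], contacts$j[sel])))
  })
  all_res <- sort(unique(unlist(residues)))
  majority <- vapply(all_res, function(r) {
    counts <- vapply(seq_len(clusters$n_clusters), function(k) {
      sel <- !is.na(clusters$cluster) & clusters$cluster == k
      sum((contacts$i[sel] == r) + (contacts$j[sel] == r))
    }, 0L)
    which.max(counts)
  }, 0L)
  names(majority) <- all_res
  list(residues = residues, majority = majority)
}
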