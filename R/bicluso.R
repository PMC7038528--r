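#' Construct a bipartite MTI graph
#'
#' A bipartite graph over miRNAs (primary side) and genes (secondary side).
#' Node sets must be disjoint and every edge must connect a miRNA to a gene.
#'
#' @param edges data.frame with columns `mirna_id` and `gene_id`; duplicate
#'   edges are collapsed.
#' @param mirnas,genes optional character vectors of node ids; defaults to
#'   the ids seen in `edges`. Extra ids add isolated nodes.
#' @param name graph name.
#' @return An object of class `bipartite_graph` with fields `mirnas`,
#'   `genes`, `edges`, `targets` (per-miRNA gene neighbor sets) and `name`.
#' @export
bipartite_graph <- function(edges, mirnas = NULL, genes = NULL,
                            name = "mti") {
  stopifnot(is.data.frame(edges), all(c("mirna_id", "gene_id") %in% names(edges)))
  edges <- unique(edges[, c("mirna_id", "gene_id")])
  rownames(edges) <- NULL
  mirnas <- sort(unique(c(as.character(edges$mirna_id), mirnas)))
  genes <- sort(unique(c(as.character(edges$gene_id), genes)))
  clash <- intersect(mirnas, genes)
  if (length(clash) > 0L) {
    stop("node sets not disjoint; ids on both sides: ",
         paste(utils::head(clash, 5), collapse = ", "))
  }
  targets <- lapply(split(as.character(edges$gene_id),
                          factor(edges$mirna_id, levels = mirnas)),
                    function(g) sort(unique(g)))
  structure(list(mirnas = mirnas, genes = genes, edges = edges,
                 targets = targets, name = name),
            class = "bipartite_graph")
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat(sprintf("Bipartite MTI graph '%s': %d miRNAs, %d genes, %d edges\n",
              x$name, length(x$mirnas), length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Convert an MTI dataset to a bipartite graph
#'
#' @param ds an [mti_dataset()].
#' @return A [bipartite_graph()].
#' @export
as_bipartite_graph <- function(ds) {
  stopifnot(inherits(ds, "mti_dataset"))
  bipartite_graph(ds$records[, c("mirna_id", "gene_id")], name = ds$name)
}

#' Biclustering parameters
#'
#' Parameters of the fold/cluster/attach biclustering procedure. The
#' defaults are the setting used throughout: cluster density 0.5, cluster
#' property 0.5, relation number 3, Tanimoto coefficient 0.33, attachment
#' probability 0.5, and a minimum of 2 miRNAs per cluster.
#'
#' @param density_min minimum simple-graph density of an emitted cluster,
#'   in (0, 1].
#' @param cp_min minimum cluster property of an admitted node, in (0, 1].
#' @param relation_number minimum shared-target count for two miRNAs to be
#'   associated when folding.
#' @param tanimoto_min minimum Tanimoto coefficient of two miRNAs' target
#'   sets for association when folding, in (0, 1].
#' @param attachment_min minimum fraction of a cluster's miRNAs a gene must
#'   be targeted by to be attached, in (0, 1].
#' @param min_cluster_size minimum number of miRNAs in an emitted cluster.
#' @return An object of class `bicluso_params`.
#' @export
bicluso_params <- function(density_min = 0.5, cp_min = 0.5,
                           relation_number = 3L, tanimoto_min = 0.33,
                           attachment_min = 0.5, min_cluster_size = 2L) {
  stopifnot(density_min > 0, density_min <= 1,
            cp_min > 0, cp_min <= 1,
            relation_number >= 1,
            tanimoto_min > 0, tanimoto_min <= 1,
            attachment_min > 0, attachment_min <= 1,
            min_cluster_size >= 1)
  structure(list(density_min = density_min, cp_min = cp_min,
                 relation_number = as.integer(relation_number),
                 tanimoto_min = tanimoto_min,
                 attachment_min = attachment_min,
                 min_cluster_size = as.integer(min_cluster_size)),
            class = "bicluso_params")
}

#' Tanimoto coefficient of two finite sets
#'
#' `|a intersect b| / |a union b|`; 0 when both sets are empty.
#'
#' @param a,b vectors treated as sets.
#' @return A fraction in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(a) + length(b) - length(intersect(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Fold a bipartite graph onto the miRNA side
#'
#' Projects the bipartite MTI graph onto its miRNA set: two miRNAs are
#' connected in the folded simple graph when their target sets are
#' associated, i.e. they share at least `relation_number` targets OR the
#' Tanimoto coefficient of their target sets is at least `tanimoto_min`.
#' The disjunction lets both hub miRNAs (many shared targets, diluted
#' Tanimoto) and low-degree miRNAs (few targets, high Tanimoto) fold.
#'
#' @param g a [bipartite_graph()].
#' @param params a [bicluso_params()].
#' @return An object of class `folded_graph` with fields `nodes`, `edges`
#'   (data.frame `u`, `v` with `u < v`), `adj` (named adjacency list) and
#'   `targets` (the miRNA target sets, retained for auditing).
#' @export
fold_bipartite <- function(g, params = bicluso_params()) {
  stopifnot(inherits(g, "bipartite_graph"), inherits(params, "bicluso_params"))
  nodes <- g$mirnas
  targets <- g$targets
  deg <- lengths(targets)

  # candidate pairs: miRNAs co-targeting at least one gene (association is
  # impossible otherwise), found through the gene-side incidence lists
  shared <- new.env(parent = emptyenv())
  by_gene <- split(as.character(g$edges$mirna_id), as.character(g$edges$gene_id))
  for (ms in by_gene) {
    ms <- sort(unique(ms))
    if (length(ms) < 2L) next
    for (i in seq_len(length(ms) - 1L)) {
      for (j in seq(i + 1L, length(ms))) {
        k <- paste(ms[i], ms[j], sep = "\r")
        shared[[k]] <- (if (is.null(shared[[k]])) 0L else shared[[k]]) + 1L
      }
    }
  }
  keys <- ls(shared)
  e_u <- character(0); e_v <- character(0)
  for (k in keys) {
    s <- shared[[k]]
    pair <- strsplit(k, "\r", fixed = TRUE)[[1]]
    tani <- s / (deg[[pair[1]]] + deg[[pair[2]]] - s)
    if (s >= params$relation_number || tani >= params$tanimoto_min) {
      e_u <- c(e_u, pair[1]); e_v <- c(e_v, pair[2])
    }
  }
  edges <- data.frame(u = e_u, v = e_v, stringsAsFactors = FALSE)
  edges <- edges[order(edges$u, edges$v), , drop = FALSE]
  rownames(edges) <- NULL
  adj <- lapply(stats::setNames(nodes, nodes), function(n) character(0))
  for (i in seq_len(nrow(edges))) {
    adj[[edges$u[i]]] <- c(adj[[edges$u[i]]], edges$v[i])
    adj[[edges$v[i]]] <- c(adj[[edges$v[i]]], edges$u[i])
  }
  adj <- lapply(adj, sort)
  structure(list(nodes = nodes, edges = edges, adj = adj, targets = targets),
            class = "folded_graph")
}

#' @export
print.folded_graph <- function(x, ...) {
  cat(sprintf("Folded miRNA graph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Density of a node set in a folded graph
#'
#' Standard simple-graph density `2|E| / (n (n - 1))`; a singleton has
#' density 1 by convention.
#'
#' @param members character vector of node ids.
#' @param f a [folded_graph()].
#' @return A fraction in \[0, 1\].
#' @export
graph_density <- function(members, f) {
  members <- unique(members)
  bad <- setdiff(members, f$nodes)
  if (length(bad) > 0L) stop("members not in graph: ", paste(bad, collapse = ", "))
  n <- length(members)
  if (n < 1L) stop("members must be nonempty")
  if (n == 1L) return(1)
  m <- sum(vapply(members, function(x) length(intersect(f$adj[[x]], members)),
                  integer(1))) / 2
  2 * m / (n * (n - 1))
}

#' Cluster property of a candidate node
#'
#' Connectivity of node `v` to a cluster, normalized by cluster density and
#' size: `|E(v, K)| / (density(K) * |K|)`. When the cluster density is 0 the
#' value is `Inf` for any connected candidate (treated as passing).
#'
#' @param v a node id not in `members`.
#' @param members cluster node ids.
#' @param f a [folded_graph()].
#' @return A nonnegative ratio (possibly `Inf`).
#' @export
cluster_property <- function(v, members, f) {
  if (v %in% members) stop("v must not be a cluster member")
  k <- length(intersect(f$adj[[v]], members))
  d <- graph_density(members, f)
  if (d == 0) return(if (k >= 1L) Inf else 0)
  k / (d * length(members))
}

#' Overlapping density clustering of a folded graph
#'
#' Greedy seed-growth clustering in the DPClus family. The seed is the
#' highest-degree unconsumed node (ties broken by id); the cluster grows by
#' repeatedly scanning neighbors of the current cluster (ordered by edges
#' into the cluster, then total degree, then id) and admitting the first
#' candidate whose admission keeps the density at or above `density_min`
#' and whose cluster property is at least `cp_min`. After a cluster is
#' emitted only its seed is consumed, so members remain available as future
#' seeds and clusters may overlap. A completeness pass then grows one
#' additional cluster from every associated pair not yet co-clustered, so
#' every folded edge is contained in at least one cluster. Entirely
#' deterministic.
#'
#' @param f a [folded_graph()].
#' @param params a [bicluso_params()].
#' @return A list of clusters, each a list with fields `members` (sorted
#'   ids), `seed` and `density`. Duplicate member sets are emitted once.
#' @export
dpcluso <- function(f, params = bicluso_params()) {
  stopifnot(inherits(f, "folded_graph"), inherits(params, "bicluso_params"))
  nodes <- f$nodes
  degree <- stats::setNames(lengths(f$adj), nodes)

  grow <- function(members) {
    repeat {
      cand <- setdiff(sort(unique(unlist(f$adj[members], use.names = FALSE))),
                      members)
      if (length(cand) == 0L) break
      ein <- vapply(cand, function(x) length(intersect(f$adj[[x]], members)),
                    integer(1))
      cand <- cand[order(-ein, -degree[cand], cand)]
      admitted <- FALSE
      for (x in cand) {
        cp <- cluster_property(x, members, f)
        if (cp < params$cp_min) next
        if (graph_density(c(members, x), f) < params$density_min) next
        members <- c(members, x)
        admitted <- TRUE
        break
      }
      if (!admitted) break
    }
    members
  }

  clusters <- list()
  seen <- character(0)
  emit <- function(members, seed) {
    if (length(members) < params$min_cluster_size) return(invisible())
    members <- sort(members)
    key <- paste(members, collapse = ";")
    if (key %in% seen) return(invisible())
    seen <<- c(seen, key)
    clusters[[length(clusters) + 1L]] <<-
      list(members = members, seed = seed,
           density = graph_density(members, f))
    invisible()
  }

  consumed <- stats::setNames(degree == 0L, nodes)  # isolated nodes never seed
  while (any(!consumed)) {
    avail <- nodes[!consumed]
    seed <- avail[order(-degree[avail], avail)][1L]
    emit(grow(seed), seed)
    consumed[seed] <- TRUE
  }

  # completeness pass: any associated pair not co-clustered yet seeds a
  # pair-grown cluster, so every folded edge lies in at least one cluster
  if (params$min_cluster_size <= 2L) {
    for (i in seq_len(nrow(f$edges))) {
      u <- f$edges$u[i]; v <- f$edges$v[i]
      co <- any(vapply(clusters,
                       function(cl) u %in% cl$members && v %in% cl$members,
                       logical(1)))
      if (!co) {
        seed <- if (degree[[u]] >= degree[[v]]) u else v
        emit(grow(c(u, v)), seed)
      }
    }
  }
  clusters
}

#' Attach genes to a miRNA cluster, forming a bicluster
#'
#' A gene is attached when the fraction of cluster miRNAs targeting it is at
#' least `attachment_min` (the threshold is inclusive, so a gene targeted by
#' exactly half the miRNAs attaches).
#'
#' @param cluster a cluster from [dpcluso()] (list with `members`).
#' @param g the original [bipartite_graph()].
#' @param params a [bicluso_params()].
#' @param dataset_name name stored on the bicluster; defaults to `g$name`.
#' @return A `bicluster` (list with `mirnas`, `genes`, `density`, `seed`,
#'   `dataset_name`), or `NULL` when no gene qualifies.
#' @export
attach_secondary <- function(cluster, g, params = bicluso_params(),
                             dataset_name = g$name) {
  members <- cluster$members
  stopifnot(all(members %in% g$mirnas))
  sub <- g$edges[g$edges$mirna_id %in% members, , drop = FALSE]
  if (nrow(sub) == 0L) return(NULL)
  counts <- table(sub$gene_id)
  ratio <- as.numeric(counts) / length(members)
  genes <- sort(names(counts)[ratio >= params$attachment_min])
  if (length(genes) == 0L) return(NULL)
  structure(list(mirnas = sort(members), genes = genes,
                 density = cluster$density, seed = cluster$seed,
                 dataset_name = dataset_name),
            class = "bicluster")
}

#' @export
print.bicluster <- function(x, ...) {
  cat(sprintf("Bicluster [%s]: %d miRNAs x %d genes (density %.3f)\n",
              x$dataset_name, length(x$mirnas), length(x$genes), x$density))
  invisible(x)
}

#' Run the full fold / cluster / attach biclustering
#'
#' Folds the bipartite graph onto one side, clusters the folded simple graph
#' with [dpcluso()], and attaches nodes of the other side to each cluster.
#' Clusters attaching no secondary node are dropped and duplicate biclusters
#' (identical miRNA and gene sets) are emitted once. Each bicluster is a
#' miRNA regulatory module (MRM).
#'
#' @param g a [bipartite_graph()].
#' @param params a [bicluso_params()].
#' @param side which side to fold on: `"mirna"` (default; modules are
#'   defined by miRNA co-regulation) or `"gene"`.
#' @param dataset_name name stored on the biclusters; defaults to `g$name`.
#' @return A list of `bicluster` objects, each with an `id` field
#'   `<dataset>_MRM<k>`.
#' @export
run_bicluso <- function(g, params = bicluso_params(),
                        side = c("mirna", "gene"), dataset_name = g$name) {
  side <- match.arg(side)
  stopifnot(inherits(g, "bipartite_graph"))
  gg <- g
  if (side == "gene") {
    gg <- bipartite_graph(data.frame(mirna_id = g$edges$gene_id,
                                     gene_id = g$edges$mirna_id,
                                     stringsAsFactors = FALSE),
                          mirnas = g$genes, genes = g$mirnas, name = g$name)
  }
  folded <- fold_bipartite(gg, params)
  clusters <- dpcluso(folded, params)
  out <- list()
  seen <- character(0)
  for (cl in clusters) {
    bc <- attach_secondary(cl, gg, params, dataset_name = dataset_name)
    if (is.null(bc)) next
    if (side == "gene") {
      bc[c("mirnas", "genes")] <- bc[c("genes", "mirnas")]
    }
    key <- paste(paste(bc$mirnas, collapse = ";"),
                 paste(bc$genes, collapse = ";"), sep = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    bc$id <- sprintf("%s_MRM%d", dataset_name, length(out) + 1L)
    out[[length(out) + 1L]] <- bc
  }
  out
}

#' Tabulate biclusters
#'
#' @param biclusters a list of `bicluster` objects from [run_bicluso()].
#' @return data.frame with one row per bicluster: `id`, `dataset`,
#'   `n_mirnas`, `n_genes`, `density`, and semicolon-joined member lists.
#' @export
biclusters_to_df <- function(biclusters) {
  if (length(biclusters) == 0L) {
    return(data.frame(id = character(), dataset = character(),
                      n_mirnas = integer(), n_genes = integer(),
                      density = numeric(), mirnas = character(),
                      genes = character(), stringsAsFactors = FALSE))
  }
  data.frame(
    id = vapply(biclusters, `[[`, character(1), "id"),
    dataset = vapply(biclusters, `[[`, character(1), "dataset_name"),
    n_mirnas = vapply(biclusters, function(b) length(b$mirnas), integer(1)),
    n_genes = vapply(biclusters, function(b) length(b$genes), integer(1)),
    density = vapply(biclusters, `[[`, numeric(1), "density"),
    mirnas = vapply(biclusters, function(b) paste(b$mirnas, collapse = ";"),
                    character(1)),
    genes = vapply(biclusters, function(b) paste(b$genes, collapse = ";"),
                   character(1)),
    stringsAsFactors = FALSE)
}

#' Write biclusters as TSV
#'
#' @param biclusters a list of `bicluster` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_biclusters_tsv <- function(biclusters, path) {
  utils::write.table(biclusters_to_df(biclusters), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
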