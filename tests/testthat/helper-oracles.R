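# Independent oracle implementations used to cross-check the package's
# graph routines. Deliberately written with naive set arithmetic over the
# raw edge table, not via the package's adjacency structures.

rand_bipartite <- function(n_mirnas, n_genes, p, name = "rand") {
  cells <- expand.grid(m = sprintf("m%02d", seq_len(n_mirnas)),
                       g = sprintf("G%02d", seq_len(n_genes)),
                       stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(cells)) < p
  bipartite_graph(data.frame(mirna_id = cells$m[keep],
                             gene_id = cells$g[keep],
                             stringsAsFactors = FALSE),
                  mirnas = sprintf("m%02d", seq_len(n_mirnas)),
                  genes = sprintf("G%02d", seq_len(n_genes)),
                  name = name)
}

targets_oracle <- function(g, m) sort(unique(g$edges$gene_id[g$edges$mirna_id == m]))

# brute-force fold: loop over all unordered miRNA pairs
fold_edges_oracle <- function(g, params) {
  ms <- g$mirnas
  out <- list()
  if (length(ms) >= 2) {
    for (i in seq_len(length(ms) - 1)) {
      for (j in seq(i + 1, length(ms))) {
        a <- targets_oracle(g, ms[i]); b <- targets_oracle(g, ms[j])
        shared <- length(intersect(a, b))
        uni <- length(union(a, b))
        tani <- if (uni == 0) 0 else shared / uni
        if (shared >= params$relation_number || tani >= params$tanimoto_min) {
          out[[length(out) + 1L]] <- sort(c(ms[i], ms[j]))
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(u = character(), v = character(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(out, function(e) {
    data.frame(u = e[1], v = e[2], stringsAsFactors = FALSE)
  }))
  df[order(df$u, df$v), , drop = FALSE]
}

density_oracle <- function(members, edge_df) {
  n <- length(members)
  if (n == 1) return(1)
  m <- sum(edge_df$u %in% members & edge_df$v %in% members)
  2 * m / (n * (n - 1))
}

attachment_ratio_oracle <- function(gene, members, g) {
  sum(g$edges$gene_id == gene & g$edges$mirna_id %in% members) / length(members)
}

venn_oracle <- function(membership) {
  ids <- unique(unlist(membership))
  vec <- vapply(ids, function(id) {
    paste(names(membership)[vapply(membership, function(s) id %in% s,
                                   logical(1))], collapse = "&")
  }, character(1))
  table(vec)
}
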