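# Per-operation seeding: each generator operation derives its own seed from
# the model's master seed and a short label, so results do not depend on the
# order in which operations are called. Derived seeds stay below 2^31.
derive_seed <- function(master, label) {
  v <- utf8ToInt(label)
  h <- sum(v * seq_along(v)) %% 100000L
  (abs(as.integer(master)) %% 1000003L) * 1009L + h
}

#' Specify a planted-block synthetic MTI model
#'
#' Describes a bipartite miRNA-gene network with dense planted blocks on a
#' sparse background: an edge (m, g) exists with probability `p_in` when m
#' and g co-occur in a block and `p_out` otherwise. A designated subset of
#' miRNAs is disease-biased: genes in their blocks are labelled disease
#' genes with high probability, emulating modules that preferentially
#' regulate a disease gene set.
#'
#' By default blocks are disjoint on both sides (3-8 miRNAs by 5-15 genes,
#' the small-module scale the clustering targets); overlapping designs are
#' expressed by passing `blocks` explicitly.
#'
#' @param n_mirnas,n_genes universe sizes; ids are `mir001...`, `G0001...`.
#' @param n_blocks number of planted blocks when `blocks` is NULL.
#' @param blocks optional list of blocks, each a list with character vectors
#'   `mirnas` and `genes` (both nonempty).
#' @param p_in within-block edge probability.
#' @param p_out background edge probability; must be < `p_in` unless both 0.
#' @param disease_fraction probability that a gene outside the biased
#'   blocks is labelled a disease gene.
#' @param disease_bias_mirnas miRNA ids whose blocks' genes are
#'   disease-labelled with probability `disease_bias_prob`.
#' @param disease_bias_prob disease-label probability for biased-block genes.
#' @param seed master seed for all generator operations.
#' @return An object of class `planted_model`.
#' @export
planted_model <- function(n_mirnas = 50L, n_genes = 120L, n_blocks = 5L,
                          blocks = NULL, p_in = 0.9, p_out = 0.02,
                          disease_fraction = 0.1,
                          disease_bias_mirnas = character(),
                          disease_bias_prob = 0.9, seed = 1L) {
  stopifnot(p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1,
            p_out <= p_in, disease_fraction >= 0, disease_fraction < 1,
            disease_bias_prob >= 0, disease_bias_prob <= 1)
  mirna_ids <- sprintf("mir%03d", seq_len(n_mirnas))
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  if (is.null(blocks)) {
    set.seed(derive_seed(seed, "blocks"))
    blocks <- list()
    mir_pool <- mirna_ids
    gene_pool <- gene_ids
    for (b in seq_len(n_blocks)) {
      nm <- sample(3:8, 1)
      ng <- sample(5:15, 1)
      if (length(mir_pool) < nm || length(gene_pool) < ng) {
        stop("universe too small for ", n_blocks, " disjoint blocks")
      }
      bm <- sort(sample(mir_pool, nm))
      bg <- sort(sample(gene_pool, ng))
      mir_pool <- setdiff(mir_pool, bm)
      gene_pool <- setdiff(gene_pool, bg)
      blocks[[b]] <- list(mirnas = bm, genes = bg)
    }
  }
  for (b in blocks) {
    if (length(b$mirnas) == 0L || length(b$genes) == 0L) {
      stop("configuration error: block with an empty side")
    }
    if (!all(b$mirnas %in% mirna_ids) || !all(b$genes %in% gene_ids)) {
      stop("configuration error: block ids outside the id universe")
    }
  }
  structure(list(n_mirnas = as.integer(n_mirnas),
                 n_genes = as.integer(n_genes),
                 mirna_ids = mirna_ids, gene_ids = gene_ids,
                 blocks = blocks, p_in = p_in, p_out = p_out,
                 disease_fraction = disease_fraction,
                 disease_bias_mirnas = disease_bias_mirnas,
                 disease_bias_prob = disease_bias_prob,
                 seed = as.integer(seed)),
            class = "planted_model")
}

#' Generate a synthetic MTI network from a planted model
#'
#' @param model a [planted_model()].
#' @param name name for the generated graph.
#' @return A list with `graph` (a [bipartite_graph()] over the full id
#'   universe, isolated nodes included) and `truth` (a `planted_truth`:
#'   the blocks, the block-membership cell matrix, and the model).
#' @export
generate_planted_mti <- function(model, name = "synthetic_mti") {
  stopifnot(inherits(model, "planted_model"))
  set.seed(derive_seed(model$seed, "edges"))
  in_block <- matrix(FALSE, model$n_mirnas, model$n_genes,
                     dimnames = list(model$mirna_ids, model$gene_ids))
  for (b in model$blocks) in_block[b$mirnas, b$genes] <- TRUE
  p <- ifelse(in_block, model$p_in, model$p_out)
  draw <- matrix(stats::runif(length(p)), nrow = nrow(p))
  hit <- which(draw < p, arr.ind = TRUE)
  edges <- data.frame(mirna_id = model$mirna_ids[hit[, 1]],
                      gene_id = model$gene_ids[hit[, 2]],
                      stringsAsFactors = FALSE)
  graph <- bipartite_graph(edges, mirnas = model$mirna_ids,
                           genes = model$gene_ids, name = name)
  truth <- structure(list(blocks = model$blocks, in_block = in_block,
                          model = model),
                     class = "planted_truth")
  list(graph = graph, truth = truth)
}

#' Generate a disease gene set from a planted truth
#'
#' Genes belonging to blocks that contain at least one disease-biased miRNA
#' are labelled disease genes with probability `disease_bias_prob`; all
#' other genes with probability `disease_fraction`.
#'
#' @param truth a `planted_truth` from [generate_planted_mti()].
#' @param model the corresponding [planted_model()].
#' @param name name of the returned gene set.
#' @return A [gene_set()].
#' @export
generate_disease_gene_set <- function(truth, model = truth$model,
                                      name = "synthetic_disease_genes") {
  stopifnot(inherits(truth, "planted_truth"), inherits(model, "planted_model"))
  set.seed(derive_seed(model$seed, "disease"))
  biased_genes <- unique(unlist(lapply(model$blocks, function(b) {
    if (any(b$mirnas %in% model$disease_bias_mirnas)) b$genes else character(0)
  })))
  p <- ifelse(model$gene_ids %in% biased_genes,
              model$disease_bias_prob, model$disease_fraction)
  labelled <- model$gene_ids[stats::runif(length(p)) < p]
  gene_set(labelled, name = name)
}

jaccard <- function(a, b) {
  u <- union(a, b)
  if (length(u) == 0L) return(0)
  length(intersect(a, b)) / length(u)
}

#' Planted-block recovery metrics
#'
#' For each planted block, the best-match Jaccard similarity to any found
#' bicluster, computed separately on the miRNA side and the gene side.
#'
#' @param truth a `planted_truth`.
#' @param found list of `bicluster` objects.
#' @return A list with `per_block` (data.frame: `block`, `jaccard_mirna`,
#'   `jaccard_gene`), `mean_mirna`, `mean_gene`, and `mean_overall` (mean
#'   of the two side means).
#' @export
recovery_metrics <- function(truth, found) {
  stopifnot(inherits(truth, "planted_truth"))
  per_block <- do.call(rbind, lapply(seq_along(truth$blocks), function(i) {
    b <- truth$blocks[[i]]
    jm <- 0; jg <- 0
    for (f in found) {
      jm <- max(jm, jaccard(b$mirnas, f$mirnas))
      jg <- max(jg, jaccard(b$genes, f$genes))
    }
    data.frame(block = i, jaccard_mirna = jm, jaccard_gene = jg)
  }))
  list(per_block = per_block,
       mean_mirna = mean(per_block$jaccard_mirna),
       mean_gene = mean(per_block$jaccard_gene),
       mean_overall = mean(c(per_block$jaccard_mirna, per_block$jaccard_gene)))
}

#' Generate a multi-dataset synthetic study
#'
#' Builds several MTI datasets over a shared miRNA universe, each with
#' planted blocks, plus one global disease gene set. A designated group of
#' disease-biased miRNAs is planted in dense blocks of every dataset and
#' the genes of those blocks are preferentially disease-labelled, so the
#' biased miRNAs should dominate the total-relevance ranking; the remaining
#' miRNAs form background blocks (re-sampled per dataset) whose genes carry
#' only the baseline disease rate.
#'
#' @param n_datasets number of datasets (1-4).
#' @param n_mirnas shared miRNA universe size.
#' @param n_genes shared gene universe size.
#' @param n_biased number of disease-biased miRNAs (the first ids).
#' @param n_background_blocks background blocks per dataset.
#' @param p_in,p_out,disease_fraction,disease_bias_prob see [planted_model()].
#' @param seed master seed.
#' @return A list with `graphs` (named list of [bipartite_graph()]),
#'   `disease` (a [gene_set()]), `biased_mirnas`, and `truths` (per-dataset
#'   `planted_truth` objects).
#' @export
generate_study <- function(n_datasets = 3L, n_mirnas = 50L, n_genes = 150L,
                           n_biased = 10L, n_background_blocks = 4L,
                           p_in = 0.9, p_out = 0.02, disease_fraction = 0.1,
                           disease_bias_prob = 0.9, seed = 1L) {
  stopifnot(n_datasets >= 1L, n_datasets <= 4L)
  mirna_ids <- sprintf("mir%03d", seq_len(n_mirnas))
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  biased <- mirna_ids[seq_len(n_biased)]
  others <- setdiff(mirna_ids, biased)
  ds_names <- paste0("synth", seq_len(n_datasets))

  # biased modules regulate a consistent disease-gene pool in every dataset
  # (the same disease genes recur across databases); background blocks draw
  # from the remaining genes only
  set.seed(derive_seed(seed, "biased_pool"))
  biased_pool <- sort(sample(gene_ids, min(30L, n_genes %/% 3L)))

  graphs <- list()
  truths <- list()
  all_biased_genes <- character(0)
  for (d in seq_len(n_datasets)) {
    set.seed(derive_seed(seed, paste0("layout", d)))
    gene_pool <- setdiff(gene_ids, biased_pool)
    blocks <- list()
    # biased miRNAs split into two dense blocks covering all of them
    split_at <- ceiling(length(biased) / 2)
    bm_list <- if (length(biased) > split_at) {
      list(biased[seq_len(split_at)],
           biased[seq(split_at + 1L, length(biased))])
    } else {
      list(biased)
    }
    pool_d <- biased_pool
    for (bm in bm_list) {
      ng <- min(sample(8:12, 1), length(pool_d))
      bg <- sort(sample(pool_d, ng))
      pool_d <- setdiff(pool_d, bg)
      blocks[[length(blocks) + 1L]] <- list(mirnas = bm, genes = bg)
      all_biased_genes <- union(all_biased_genes, bg)
    }
    pool <- others
    for (b in seq_len(n_background_blocks)) {
      nm <- sample(3:8, 1)
      ng <- sample(5:15, 1)
      bm <- sort(sample(pool, nm))
      pool <- setdiff(pool, bm)
      bg <- sort(sample(gene_pool, ng))
      gene_pool <- setdiff(gene_pool, bg)
      blocks[[length(blocks) + 1L]] <- list(mirnas = bm, genes = bg)
    }
    model <- planted_model(n_mirnas = n_mirnas, n_genes = n_genes,
                           blocks = blocks, p_in = p_in, p_out = p_out,
                           disease_fraction = disease_fraction,
                           disease_bias_mirnas = biased,
                           disease_bias_prob = disease_bias_prob,
                           seed = derive_seed(seed, paste0("dataset", d)))
    gen <- generate_planted_mti(model, name = ds_names[d])
    graphs[[ds_names[d]]] <- gen$graph
    truths[[ds_names[d]]] <- gen$truth
  }

  set.seed(derive_seed(seed, "study_disease"))
  p <- ifelse(gene_ids %in% all_biased_genes, disease_bias_prob,
              disease_fraction)
  disease <- gene_set(gene_ids[stats::runif(length(p)) < p],
                      name = "synthetic_disease_genes")
  list(graphs = graphs, disease = disease, biased_mirnas = biased,
       truths = truths)
}

#' Write a synthetic fixture study to disk
#'
#' Emits a ready-to-run study: one TSV edge table per dataset (the format
#' [parse_interaction_table()] reads), a disease gene list, a ground-truth
#' JSON, and a `study.yaml` configuration for [run_study()]. The four
#' datasets emulate the relative shapes of typical MTI database exports at
#' roughly 1/20 of their miRNA and gene counts; interaction counts follow
#' from the planted blocks plus a sparse background rather than being
#' scaled directly (a direct 1/20 scaling of edges would exceed the number
#' of available miRNA-gene cells).
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed.
#' @return The path to the written `study.yaml`, invisibly.
#' @export
make_fixture_study <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  # miRNA x gene universe sizes ~1/20 of the four source exports
  shapes <- list(mirwalk_like = c(26L, 31L),
                 mirtarbase_like = c(37L, 138L),
                 mirecords_like = c(12L, 55L),
                 diana_like = c(26L, 275L))
  study <- generate_study(n_datasets = 4L, n_mirnas = 60L, n_genes = 300L,
                          n_biased = 10L, seed = seed)
  paths <- character(0)
  for (nm in names(study$graphs)) paths[nm] <- file.path(out_dir, paste0(nm, ".tsv"))
  for (nm in names(study$graphs)) {
    g <- study$graphs[[nm]]
    df <- data.frame(mirna_id = g$edges$mirna_id, gene_id = g$edges$gene_id,
                     evidence_count = 1L, stringsAsFactors = FALSE)
    utils::write.table(df, paths[nm], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  gene_path <- file.path(out_dir, "disease_genes.txt")
  writeLines(study$disease$genes, gene_path)
  truth <- list(biased_mirnas = study$biased_mirnas,
                blocks = lapply(study$truths, function(t) t$blocks),
                shapes_reference = shapes)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  cfg <- list(
    datasets = lapply(names(study$graphs), function(nm) {
      list(name = nm, path = paste0(nm, ".tsv"),
           column_map = list(mirna = "mirna_id", gene = "gene_id"))
    }),
    disease_gene_path = "disease_genes.txt",
    bicluso = unclass(bicluso_params()),
    top_k = 20L,
    output_dir = "results")
  yaml_path <- file.path(out_dir, "study.yaml")
  yaml::write_yaml(cfg, yaml_path)
  invisible(yaml_path)
}
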