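# Build a list of sub-modules in which `mirna` occurs in exactly `n_subs`
# sub-modules and the union of their disease genes has exactly `n_genes`
# members (genes distributed round-robin, every sub-module nonempty).
make_worked_subs <- function(mirna, n_subs, n_genes, dataset,
                             gene_prefix = "GENE") {
  genes <- sprintf("%s_%s_%03d", gene_prefix, dataset, seq_len(n_genes))
  assignment <- split(genes, rep_len(seq_len(n_subs), n_genes))
  lapply(seq_len(n_subs), function(i) {
    gs <- assignment[[((i - 1L) %% length(assignment)) + 1L]]
    sub_mrm(parent_id = sprintf("%s_MRM%d", dataset, i),
            mirnas = mirna, disease_genes = gs, dataset_name = dataset)
  })
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
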