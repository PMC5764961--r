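# Small programmatic fixtures shared across test files.

make_ct_df <- function(sample_id, group, gene, replicate, ct) {
  data.frame(sample_id = sample_id, group = group, gene = gene,
             replicate = replicate, ct = ct, stringsAsFactors = FALSE)
}

# complete one-measurement-per-well ct_table from a gene x sample matrix
ct_from_matrix <- function(m, groups = NULL) {
  if (is.null(groups)) groups <- setNames(colnames(m), colnames(m))
  df <- expand.grid(gene = rownames(m), sample_id = colnames(m),
                    stringsAsFactors = FALSE)
  df$group <- unname(groups[df$sample_id])
  df$replicate <- 1L
  df$ct <- m[cbind(df$gene, df$sample_id)]
  ct_table(df)
}

write_temp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
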